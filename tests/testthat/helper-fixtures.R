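# shared data-generating fixtures for the model and spatial tests

make_sf_data <- function(n, seed = 1, sd = 5) {
  set.seed(seed)
  d <- data.frame(mat = runif(n, 14, 28), map = runif(n, 500, 1400),
                  bd = runif(n, 1.2, 1.5), sand = runif(n, 20, 60),
                  silt = runif(n, 20, 50), clay = runif(n, 10, 40),
                  tc = runif(n, 5, 25), tn = runif(n, 0.5, 2.5),
                  tp = runif(n, 0.3, 0.9), ap = runif(n, 5, 30),
                  ph = runif(n, 5, 8), input_n = runif(n, 30, 180),
                  input_p = runif(n, 5, 40),
                  crop = sample(c("rice", "wheat"), n, TRUE))
  truth <- 100 * (0.1 + 0.8 * plogis(0.2 * (d$mat - 22) +
    0.0025 * (d$map - 900) + 0.6 * (d$ph - 6.5) + 1.0 * (d$tn - 1.5) -
    0.025 * (d$input_n - 90)))
  d$sf <- truth + rnorm(n, 0, sd)
  attr(d, "truth") <- truth
  d
}
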