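test_that("monotone pairs give rho one and tiny p", {
  d <- data.frame(eff = 1:30, x = (1:30)^2, z = rnorm(30))
  out <- spearman_bh(d, "eff", c("x", "z"))
  row <- out[out$covariate == "x", ]
  expect_equal(row$rho, 1)
  expect_lt(row$p_adjusted, 1e-6)
})

test_that("constant covariates are reported as missing, not zero", {
  d <- data.frame(eff = rnorm(20), flat = rep(3, 20))
  out <- spearman_bh(d, "eff", "flat")
  expect_true(is.na(out$rho))
  expect_true(is.na(out$p_adjusted))
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  # and the package's family-wise adjustment equals the brute-force oracle
  set.seed(30)
  for (i in 1:10) {
    m <- sample(3:50, 1)
    p <- runif(m)
    expect_equal(p.adjust(p, "BH"), bh_stepup_oracle(p), tolerance = 1e-14)
  }
})

test_that("adjustment family is per target and group", {
  set.seed(31)
  d <- data.frame(eff = rnorm(40), a = rnorm(40), b = rnorm(40),
                  g = rep(c("x", "y"), each = 20))
  out <- spearman_bh(d, "eff", c("a", "b"), by = "g")
  expect_equal(nrow(out), 4)
  for (gg in c("x", "y")) {
    sub <- out[out$group == gg, ]
    expect_equal(sub$p_adjusted, bh_stepup_oracle(sub$p_raw),
                 tolerance = 1e-14)
  }
})

test_that("single-indicator perfect linear relation gives unit path and GOF", {
  set.seed(32)
  x <- rnorm(200)
  d <- data.frame(x = x, y = 2 * x)
  fit <- fit_plspm(d, blocks = list(climate = "x", efficiency = "y"),
                   paths = list(efficiency = "climate"), bootstrap_n = 0)
  expect_equal(abs(fit$path_coefficients$estimate), 1, tolerance = 1e-9)
  expect_equal(unname(fit$r2["efficiency"]), 1, tolerance = 1e-9)
  expect_equal(fit$gof, 1, tolerance = 1e-9)
})

test_that("latent scores have unit variance and communalities lie in [0,1]", {
  out <- generate_latent_data(n = 400, seed = 33)
  blocks <- list(climate = paste0("climate_", 1:3),
                 soil = paste0("soil_", 1:3),
                 management = paste0("management_", 1:3),
                 socioeconomy = paste0("socioeconomy_", 1:3),
                 efficiency = "efficiency")
  paths <- list(efficiency = c("climate", "soil", "management",
                               "socioeconomy"))
  fit <- fit_plspm(out$data, blocks, paths, bootstrap_n = 0)
  vars <- apply(fit$scores, 2, var)
  expect_equal(unname(vars), rep(1, 5), tolerance = 1e-8)
  expect_true(all(fit$communality >= 0 & fit$communality <= 1))
  expect_true(fit$gof >= 0 && fit$gof <= 1)
})

test_that("bootstrap is reproducible under a fixed seed", {
  out <- generate_latent_data(n = 150, seed = 34)
  blocks <- list(climate = paste0("climate_", 1:3),
                 management = paste0("management_", 1:3),
                 efficiency = "efficiency")
  paths <- list(efficiency = c("climate", "management"))
  f1 <- fit_plspm(out$data, blocks, paths, bootstrap_n = 25, seed = 99)
  f2 <- fit_plspm(out$data, blocks, paths, bootstrap_n = 25, seed = 99)
  expect_identical(f1$path_coefficients, f2$path_coefficients)
})

test_that("GOF is invariant to relabelling the blocks", {
  out <- generate_latent_data(n = 300, seed = 35)
  blocks <- list(climate = paste0("climate_", 1:3),
                 management = paste0("management_", 1:3),
                 efficiency = "efficiency")
  paths <- list(efficiency = c("climate", "management"))
  f1 <- fit_plspm(out$data, blocks, paths, bootstrap_n = 0)
  blocks2 <- blocks[c("management", "climate", "efficiency")]
  names(blocks2) <- c("mgmt", "clim", "efficiency")
  blocks2$mgmt <- paste0("management_", 1:3)
  blocks2$clim <- paste0("climate_", 1:3)
  f2 <- fit_plspm(out$data, blocks2,
                  list(efficiency = c("clim", "mgmt")), bootstrap_n = 0)
  expect_equal(f1$gof, f2$gof, tolerance = 1e-8)
})

test_that("weak manifests are dropped once by the loading filter", {
  set.seed(36)
  n <- 500
  lv <- rnorm(n)
  d <- data.frame(c1 = 0.9 * lv + rnorm(n, 0, 0.4),
                  c2 = 0.9 * lv + rnorm(n, 0, 0.4),
                  junk = rnorm(n), # uncorrelated with the block
                  y = lv + rnorm(n, 0, 0.5))
  fit <- fit_plspm(d, blocks = list(climate = c("c1", "c2", "junk"),
                                    efficiency = "y"),
                   paths = list(efficiency = "climate"), bootstrap_n = 0)
  expect_true("junk" %in% fit$dropped)
  expect_setequal(fit$blocks$climate, c("c1", "c2"))
})

test_that("cyclic path structures are rejected", {
  d <- data.frame(a = rnorm(20), b = rnorm(20))
  expect_error(fit_plspm(d, blocks = list(x = "a", y = "b"),
                         paths = list(x = "y", y = "x"), bootstrap_n = 0),
               "cycle")
})

test_that("configured path signs are recovered on latent-structured data", {
  hits <- 0
  for (s in 1:10) {
    out <- generate_latent_data(n = 600, seed = 200 + s)
    blocks <- list(climate = paste0("climate_", 1:3),
                   soil = paste0("soil_", 1:3),
                   management = paste0("management_", 1:3),
                   socioeconomy = paste0("socioeconomy_", 1:3),
                   efficiency = "efficiency")
    paths <- list(efficiency = c("climate", "soil", "management",
                                 "socioeconomy"))
    fit <- fit_plspm(out$data, blocks, paths, bootstrap_n = 0)
    pc <- fit$path_coefficients
    signs <- sign(pc$estimate[match(names(out$truth$path_coefficients),
                                    pc$from)])
    if (all(signs == out$truth$true_path_signs)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
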