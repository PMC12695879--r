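# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (enumeration, grid search, direct formulas)
# and share no code with the functions they validate.

# best single-breakpoint broken-line RSS over integer candidate breakpoints
grid_search_segmented_rss <- function(x, y) {
  cands <- x[3:(length(x) - 2)]
  min(vapply(cands, function(psi) {
    h <- pmax(x - psi, 0)
    sum(resid(lm(y ~ x + h))^2)
  }, numeric(1)))
}

# breakpoint position chosen by the same grid search
grid_search_segmented_bp <- function(x, y) {
  cands <- x[3:(length(x) - 2)]
  rss <- vapply(cands, function(psi) {
    h <- pmax(x - psi, 0)
    sum(resid(lm(y ~ x + h))^2)
  }, numeric(1))
  cands[which.min(rss)]
}

# Benjamini-Hochberg step-up, written from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, m / k * p[o[k]])
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of assignments
wilcoxon_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- combn(n, na)
  ws <- apply(combs, 2, function(id) sum(r[id]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Dunn pairwise z statistic from the textbook formula, loop-based
dunn_oracle <- function(values, groups, g1, g2) {
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  m1 <- mean(r[groups == g1]); m2 <- mean(r[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  z <- (m1 - m2) / sqrt((n * (n + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# group-by aggregation oracle (plain loops)
groupby_mean_oracle <- function(values, groups) {
  out <- c()
  for (g in sort(unique(groups))) out[g] <- mean(values[groups == g])
  out
}

# small default generator for quick tests
tiny_config <- function(seed = 1, ...) {
  generator_config(seed = seed, n_sites = 300, n_countries = 8,
                   n_years = 20, resolution = 2, ...)
}
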