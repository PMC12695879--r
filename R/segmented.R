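#' Segmented (broken-line) regression with one breakpoint
#'
#' Fits a two-segment linear trend with an unknown kink by iterative
#' linearisation: starting from the median of `x`, the model
#' `y ~ x + pmax(x - psi, 0) + I(x > psi)` is refit and the breakpoint
#' updated by the ratio of the indicator to the hinge coefficient until the
#' change falls below `tol`. The iteration is also restarted from the best
#' integer-grid candidate and the lower-RSS solution kept, which guards
#' against local minima on short noisy series. The breakpoint standard
#' error comes from the delta method (SE of the re-parameterised gap term
#' over the slope difference). Per-segment slopes are tested by two-tailed
#' t-tests from separate ordinary regressions before and after the
#' breakpoint; observations at the breakpoint belong to the later segment.
#'
#' @param x numeric, strictly increasing (e.g. years); length >= 6.
#' @param y numeric response.
#' @param tol convergence tolerance on the breakpoint (same units as `x`).
#' @param max_iter maximum iterations.
#' @return object of class `segmented_fit`: `breakpoint`, `breakpoint_se`,
#'   `slopes` (length 2), `intercepts`, `rss`, `slope_pvalues`,
#'   `slope_change_p` (t-test of the slope difference), `converged`,
#'   `n_iter`, plus the data.
#' @export
fit_segmented <- function(x, y, tol = 1e-4, max_iter = 100) {
  stopifnot(length(x) == length(y), length(x) >= 6, all(diff(x) > 0),
            all(is.finite(x)), all(is.finite(y)))
  lo <- x[2]; hi <- x[length(x) - 1]

  run_from <- function(psi) {
    n_iter <- 0L; converged <- FALSE
    repeat {
      n_iter <- n_iter + 1L
      u <- pmax(x - psi, 0)
      v <- -as.numeric(x > psi)
      fit <- stats::lm(y ~ x + u + v)
      cf <- stats::coef(fit)
      beta <- cf[["u"]]; gamma <- cf[["v"]]
      if (is.na(beta) || is.na(gamma) || abs(beta) < 1e-12) break
      step <- gamma / beta
      psi_new <- min(max(psi + step, lo), hi)
      if (abs(psi_new - psi) < tol) {
        psi <- psi_new; converged <- TRUE
        break
      }
      psi <- psi_new
      if (n_iter >= max_iter) break
    }
    u <- pmax(x - psi, 0)
    v <- -as.numeric(x > psi)
    fit <- stats::lm(y ~ x + u + v)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
    beta <- stats::coef(fit)[["u"]]
    se_psi <- if (!is.na(beta) && abs(beta) > 1e-12 && !is.null(se) &&
                  "v" %in% names(se))
      unname(se[["v"]]) / abs(beta) else NA_real_
    red <- stats::lm(y ~ x + u) # breakpoint fixed: continuous broken line
    list(psi = psi, rss = sum(stats::resid(red)^2), fit = red,
         se_psi = se_psi, converged = converged, n_iter = n_iter)
  }

  cand <- run_from(stats::median(x))
  # restart from the best integer-grid candidate; keep the better solution
  grid <- x[3:(length(x) - 2)]
  grid_rss <- vapply(grid, function(p)
    sum(stats::resid(stats::lm(y ~ x + pmax(x - p, 0)))^2), numeric(1))
  cand2 <- run_from(grid[which.min(grid_rss)])
  best <- if (cand2$rss < cand$rss - 1e-12) cand2 else cand
  # the returned fit can never do worse than the best grid candidate
  if (min(grid_rss) < best$rss - 1e-12) {
    psi0 <- grid[which.min(grid_rss)]
    red <- stats::lm(y ~ x + pmax(x - psi0, 0))
    best <- list(psi = psi0, rss = sum(stats::resid(red)^2), fit = red,
                 se_psi = best$se_psi, converged = best$converged,
                 n_iter = best$n_iter)
  }
  psi <- best$psi
  if (psi <= x[1] || psi >= x[length(x)])
    stop("breakpoint escaped the observed range", call. = FALSE)
  # an unsettled iteration that nevertheless sits at the profile optimum
  # (no grid candidate does better) is a stable solution
  if (!best$converged && best$rss <= min(grid_rss) + 1e-9)
    best$converged <- TRUE

  cf <- stats::coef(best$fit)
  slope1 <- unname(cf[2]); slope2 <- unname(cf[2] + cf[3])
  int1 <- unname(cf[1]); int2 <- unname(cf[1] - cf[3] * psi)
  sm <- summary(best$fit)$coefficients
  slope_change_p <- if (nrow(sm) >= 3) unname(sm[3, 4]) else NA_real_

  seg_p <- function(sel) {
    if (sum(sel) < 3) return(NA_real_)
    co <- summary(stats::lm(y[sel] ~ x[sel]))$coefficients
    if (nrow(co) < 2) NA_real_ else unname(co[2, 4])
  }
  slope_pvalues <- c(pre = seg_p(x < psi), post = seg_p(x >= psi))

  structure(list(breakpoint = psi, breakpoint_se = best$se_psi,
                 slopes = c(pre = slope1, post = slope2),
                 intercepts = c(pre = int1, post = int2),
                 rss = best$rss, slope_pvalues = slope_pvalues,
                 slope_change_p = slope_change_p,
                 converged = best$converged, n_iter = best$n_iter,
                 x = x, y = y),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented fit: breakpoint %.2f +/- %.2f\n",
              x$breakpoint, x$breakpoint_se))
  cat(sprintf("  slopes: %.4f (pre), %.4f (post); RSS %.4f\n",
              x$slopes[1], x$slopes[2], x$rss))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact enumeration when both samples have at most 10 observations and no
#' ties; otherwise the tie-corrected normal approximation with continuity
#' correction. Returns the familiar significance star coding.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `statistic` (rank-sum W), `p_value`, `stars`
#'   (`"***"` p < 0.001, `"**"` p < 0.01, `"*"` p < 0.05, `"ns"` otherwise).
#' @export
compare_groups <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  exact <- length(a) <= 10 && length(b) <= 10 && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  p <- ht$p.value
  list(statistic = unname(ht$statistic), p_value = p,
       stars = significance_stars(p))
}

#' @rdname compare_groups
#' @param p numeric vector of p-values.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE) |> as.character()
}

#' Contrast a series before and after its fitted breakpoint
#'
#' Splits the series at the estimated breakpoint (the breakpoint
#' observation joins the later segment) and applies [compare_groups()].
#'
#' @param x,y the series.
#' @param fit a converged [fit_segmented()] result.
#' @return the [compare_groups()] result plus group sizes.
#' @export
pre_post_break_contrast <- function(x, y, fit) {
  stopifnot(inherits(fit, "segmented_fit"))
  if (!fit$converged)
    stop("breakpoint fit did not converge; contrast not defined", call. = FALSE)
  pre <- y[x < fit$breakpoint]
  post <- y[x >= fit$breakpoint]
  out <- compare_groups(pre, post)
  out$n <- c(pre = length(pre), post = length(post))
  out
}
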