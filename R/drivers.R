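#' Spearman rank correlations with Benjamini-Hochberg control
#'
#' Rank correlation (average ranks under ties) between each target and each
#' covariate, two-sided p-values, adjusted by the Benjamini-Hochberg
#' step-up within each target's comparison family (optionally further
#' split by a grouping column such as crop). Constant covariates yield an
#' undefined correlation and are reported as missing, not zero.
#'
#' @param data data frame.
#' @param targets character vector of target columns (e.g. `"nue"`).
#' @param covariates character vector of covariate columns.
#' @param by optional grouping column; correlations and the adjustment
#'   family are computed per group.
#' @return data frame `group`, `target`, `covariate`, `n`, `rho`, `p_raw`,
#'   `p_adjusted`, `stars`.
#' @export
spearman_bh <- function(data, targets, covariates, by = NULL) {
  groups <- if (is.null(by)) list(`all` = data) else split(data, data[[by]])
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (tg in targets) {
      rows <- lapply(covariates, function(cv) {
        x <- d[[tg]]; y <- d[[cv]]
        if (!is.numeric(y)) y <- as.numeric(factor(y))
        ok <- !is.na(x) & !is.na(y)
        n <- sum(ok)
        if (n < 4 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0)
          return(data.frame(group = g, target = tg, covariate = cv, n = n,
                            rho = NA_real_, p_raw = NA_real_,
                            stringsAsFactors = FALSE))
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
        data.frame(group = g, target = tg, covariate = cv, n = n,
                   rho = unname(ct$estimate), p_raw = ct$p.value,
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows)
      rows$p_adjusted <- stats::p.adjust(rows$p_raw, method = "BH")
      out[[length(out) + 1]] <- rows
    }
  }
  out <- do.call(rbind, out)
  out$stars <- ifelse(is.na(out$p_adjusted), NA_character_,
                      significance_stars(out$p_adjusted))
  rownames(out) <- NULL
  out
}

# one PLS-PM estimation pass (mode A outer, factorial/centroid inner);
# manifests assumed standardized, blocks a named list of column indices
plspm_engine <- function(x, blocks, adjacency, scheme = c("factorial",
                                                          "centroid"),
                         tol = 1e-6, max_iter = 300) {
  scheme <- match.arg(scheme)
  bn <- names(blocks)
  w <- lapply(blocks, function(cols) rep(1 / sqrt(length(cols)),
                                         length(cols)))
  scores <- function(w) {
    s <- sapply(bn, function(b) {
      y <- x[, blocks[[b]], drop = FALSE] %*% w[[b]]
      as.numeric(scale(y))
    })
    colnames(s) <- bn
    s
  }
  y <- scores(w)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    r <- stats::cor(y)
    inner_w <- r * adjacency
    if (scheme == "centroid") inner_w <- sign(r) * adjacency
    z <- y %*% inner_w # inner estimates (adjacency is symmetric)
    w_new <- lapply(bn, function(b) {
      wb <- as.numeric(stats::cor(x[, blocks[[b]], drop = FALSE], z[, b]))
      if (sum(wb) < 0) wb <- -wb
      wb / sqrt(sum(wb^2))
    })
    names(w_new) <- bn
    delta <- max(unlist(Map(function(a, b) max(abs(a - b)), w_new, w)))
    w <- w_new
    y <- scores(w)
    if (delta < tol) break
    if (iter >= max_iter)
      stop("PLS path model did not converge in ", max_iter, " iterations",
           call. = FALSE)
  }
  loadings <- lapply(bn, function(b)
    as.numeric(stats::cor(x[, blocks[[b]], drop = FALSE], y[, b])))
  names(loadings) <- bn
  list(weights = w, scores = y, loadings = loadings, n_iter = iter)
}

#' Partial least squares path modelling
#'
#' Estimates a structural model among latent blocks by the classical PLS
#' algorithm: mode-A outer estimation, factorial (or centroid) inner
#' weighting, iterated to convergence of the outer weights; latent scores
#' are standardized to unit variance. Manifest variables are z-scored
#' first. After an initial fit, manifests with loadings below
#' `loading_threshold` are excluded and the model refit once (a single
#' filter pass, not iterated). Path coefficients are ordinary least
#' squares of each endogenous latent's scores on its predecessors';
#' bootstrap resampling of observations gives standard errors and
#' two-sided normal-approximation p-values. The goodness of fit is
#' \eqn{GOF = \sqrt{\overline{communality} \times \overline{R^2}}}.
#'
#' @param data data frame of manifest variables.
#' @param blocks named list: latent name to character vector of manifest
#'   columns. Non-numeric manifests are coded as ordinal integers.
#' @param paths named list: endogenous latent to character vector of its
#'   predecessor latents (must be acyclic).
#' @param scheme inner weighting scheme.
#' @param bootstrap_n bootstrap replicates (0 skips the bootstrap).
#' @param seed integer seed (mandatory for the bootstrap).
#' @param loading_threshold minimum retained loading (default 0.7).
#' @return object of class `plspm_fit`: `path_coefficients` (data frame
#'   `to`, `from`, `estimate`, `se`, `p_value`), `loadings`, `dropped`,
#'   `r2`, `communality`, `gof`, `scores`, `n_iter`.
#' @export
fit_plspm <- function(data, blocks, paths, scheme = "factorial",
                      bootstrap_n = 100, seed = 1,
                      loading_threshold = 0.7) {
  bn <- names(blocks)
  stopifnot(length(bn) >= 2, all(unlist(paths) %in% bn),
            all(names(paths) %in% bn))
  # acyclicity: topological order must exist
  check_acyclic(paths, bn)

  xall <- data[, unlist(blocks), drop = FALSE]
  for (j in seq_along(xall))
    if (!is.numeric(xall[[j]])) xall[[j]] <- as.numeric(factor(xall[[j]]))
  xall <- scale(as.matrix(xall))
  if (anyNA(xall)) stop("manifest variables contain missing or constant columns",
                        call. = FALSE)
  colidx <- function(blk) lapply(blk, function(cols) match(cols, colnames(xall)))

  adjacency <- matrix(0, length(bn), length(bn), dimnames = list(bn, bn))
  for (to in names(paths)) for (fr in paths[[to]]) {
    adjacency[fr, to] <- 1; adjacency[to, fr] <- 1
  }

  fit1 <- plspm_engine(xall, colidx(blocks), adjacency, scheme)
  # single loading filter pass
  blocks2 <- blocks
  dropped <- character(0)
  for (b in bn) {
    keep <- fit1$loadings[[b]] >= loading_threshold
    if (length(blocks[[b]]) == 1) keep <- TRUE # nothing to filter against
    if (!any(keep))
      stop("all manifest variables of block '", b,
           "' fall below the loading threshold", call. = FALSE)
    dropped <- c(dropped, blocks[[b]][!keep])
    blocks2[[b]] <- blocks[[b]][keep]
  }
  fit2 <- plspm_engine(xall, colidx(blocks2), adjacency, scheme)

  est <- plspm_structural(fit2$scores, paths)
  communality <- vapply(fit2$loadings, function(l) mean(l^2), numeric(1))
  mean_comm <- mean(unlist(lapply(fit2$loadings, function(l) l^2)))
  gof <- sqrt(mean_comm * mean(est$r2))

  pc <- est$coefficients
  if (bootstrap_n > 0) {
    set.seed(seed)
    boots <- replicate(bootstrap_n, {
      id <- sample.int(nrow(xall), replace = TRUE)
      xb <- scale(xall[id, , drop = FALSE])
      fb <- tryCatch(plspm_engine(xb, colidx(blocks2), adjacency, scheme),
                     error = function(e) NULL)
      if (is.null(fb)) rep(NA_real_, nrow(pc))
      else plspm_structural(fb$scores, paths)$coefficients$estimate
    })
    boots <- matrix(boots, nrow = nrow(pc))
    pc$se <- apply(boots, 1, stats::sd, na.rm = TRUE)
    pc$p_value <- 2 * stats::pnorm(-abs(pc$estimate / pc$se))
  } else {
    pc$se <- NA_real_
    pc$p_value <- NA_real_
  }

  structure(list(path_coefficients = pc, loadings = fit2$loadings,
                 blocks = blocks2, dropped = dropped,
                 r2 = est$r2, communality = communality, gof = gof,
                 scores = fit2$scores, n_iter = fit2$n_iter),
            class = "plspm_fit")
}

# OLS structural relations on latent scores
plspm_structural <- function(scores, paths) {
  coefs <- list(); r2 <- numeric(0)
  for (to in names(paths)) {
    fr <- paths[[to]]
    fit <- stats::lm(scores[, to] ~ scores[, fr, drop = FALSE])
    b <- stats::coef(fit)[-1]
    coefs[[to]] <- data.frame(to = to, from = fr, estimate = unname(b),
                              stringsAsFactors = FALSE)
    r2[to] <- summary(fit)$r.squared
  }
  list(coefficients = do.call(rbind, coefs), r2 = r2)
}

# Kahn's algorithm on the directed predecessor lists
check_acyclic <- function(paths, bn) {
  remaining <- bn
  repeat {
    incoming <- vapply(remaining, function(b) {
      fr <- intersect(paths[[b]], remaining)
      length(fr) > 0
    }, logical(1))
    if (all(incoming))
      stop("path structure contains a cycle", call. = FALSE)
    remaining <- remaining[incoming]
    if (length(remaining) == 0) return(invisible(TRUE))
  }
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("PLS path model: GOF = %.3f\n", x$gof))
  print(x$path_coefficients, row.names = FALSE)
  invisible(x)
}
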