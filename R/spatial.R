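#' Predict an efficiency surface on a covariate grid
#'
#' Applies a fitted forest to every grid cell with positive planted area
#' for the crop, attaching the per-tree mean and standard deviation.
#' Cells without planted area are excluded from the surface.
#'
#' @param model a [tune_and_fit()] result.
#' @param grid covariate grid data frame (`lon`, `lat` plus layers).
#' @param area_col name of the planted-area layer used as the mask (and
#'   carried along as `area`).
#' @param clip optional range to clip predictions to (e.g. `c(0, 100)`).
#' @return data frame `lon`, `lat`, `area`, `mean`, `sd` (one row per
#'   masked cell), with grid resolution carried over as an attribute.
#' @export
predict_grid <- function(model, grid, area_col, clip = NULL) {
  stopifnot(area_col %in% names(grid))
  mask <- !is.na(grid[[area_col]]) & grid[[area_col]] > 0
  cells <- grid[mask, , drop = FALSE]
  pred <- predict_with_uncertainty(model, cells, clip = clip)
  out <- data.frame(lon = cells$lon, lat = cells$lat,
                    area = cells[[area_col]],
                    mean = pred$mean, sd = pred$sd)
  attr(out, "resolution") <- attr(grid, "resolution")
  out
}

#' Empirical semivariogram
#'
#' Semivariance by distance bin, \eqn{\gamma(h) = mean(0.5 (z_i - z_j)^2)}
#' over point pairs with separation in the bin. Distances are Euclidean on
#' lon/lat degrees, appropriate at the desk scales this package targets
#' (domains of a few tens of degrees).
#'
#' @param lon,lat coordinates.
#' @param z values.
#' @param n_bins number of lag bins (default 15).
#' @param cutoff maximum lag considered; default half the maximum
#'   separation.
#' @return data frame `lag`, `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(lon, lat, z, n_bins = 15, cutoff = NULL) {
  d <- stats::dist(cbind(lon, lat))
  g <- 0.5 * stats::dist(z)^2
  d <- as.numeric(d); g <- as.numeric(g)
  if (is.null(cutoff)) cutoff <- max(d) / 2
  keep <- d <= cutoff & d > 0
  d <- d[keep]; g <- g[keep]
  bin <- cut(d, breaks = seq(0, cutoff, length.out = n_bins + 1),
             include.lowest = TRUE)
  out <- data.frame(
    lag = tapply(d, bin, mean),
    gamma = tapply(g, bin, mean),
    n_pairs = as.integer(table(bin)))
  out <- out[!is.na(out$gamma), ]
  rownames(out) <- NULL
  out
}

# theoretical semivariogram models
variogram_model_fn <- function(model = c("spherical", "exponential")) {
  model <- match.arg(model)
  if (model == "spherical") {
    function(h, nugget, psill, range) {
      s <- pmin(h / range, 1)
      nugget + psill * (1.5 * s - 0.5 * s^3)
    }
  } else {
    function(h, nugget, psill, range) nugget + psill * (1 - exp(-h / range))
  }
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget, partial sill and range of a spherical (default) or
#' exponential semivariogram to an empirical variogram, weighting bins by
#' `n_pairs / gamma_model^2` (Cressie weights) via box-constrained
#' optimisation.
#'
#' @param vg empirical variogram from [empirical_variogram()].
#' @param model `"spherical"` or `"exponential"`.
#' @return list with `nugget`, `psill`, `range`, `model`, `converged`.
#' @export
fit_variogram <- function(vg, model = c("spherical", "exponential")) {
  model <- match.arg(model)
  fn <- variogram_model_fn(model)
  s0 <- max(vg$gamma)
  obj <- function(p) {
    gm <- fn(vg$lag, p[1], p[2], p[3])
    sum(vg$n_pairs * (vg$gamma - gm)^2 / pmax(gm, 1e-8)^2)
  }
  # multi-start over range initialisations; the optimiser's iteration-cap
  # code is not treated as failure when the solution itself is usable
  starts <- lapply(c(0.15, 0.5, 1) * max(vg$lag),
                   function(r0) c(0.1 * s0, 0.9 * s0, r0))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = c(0, 1e-8, max(vg$lag) * 1e-3),
                   upper = c(2 * s0, 4 * s0, 4 * max(vg$lag)),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(list(nugget = s0, psill = 0, range = max(vg$lag) / 2,
                model = model, converged = FALSE))
  list(nugget = best$par[1], psill = best$par[2], range = best$par[3],
       model = model, converged = best$par[2] > 1e-8)
}

#' Ordinary kriging
#'
#' Ordinary kriging of scattered observations onto target locations under a
#' fitted variogram. The kriging system is solved in covariance form with
#' the Lagrange multiplier enforcing unbiasedness; predictions at an
#' observation's exact location reproduce the observation (exact
#' interpolation) when the nugget is zero.
#'
#' @param obs data frame `lon`, `lat`, `z`.
#' @param targets data frame `lon`, `lat`.
#' @param vgm fitted variogram from [fit_variogram()].
#' @return numeric vector of kriged values at the targets.
#' @export
krige_ordinary <- function(obs, targets, vgm) {
  n <- nrow(obs)
  stopifnot(n >= 2)
  fn <- variogram_model_fn(vgm$model)
  sill <- vgm$nugget + vgm$psill
  cov_of <- function(h) {
    cv <- sill - fn(h, vgm$nugget, vgm$psill, vgm$range)
    cv[h == 0] <- sill
    cv
  }
  d_obs <- as.matrix(stats::dist(cbind(obs$lon, obs$lat)))
  a <- rbind(cbind(cov_of(d_obs), 1), c(rep(1, n), 0))
  diag(a)[seq_len(n)] <- sill + 1e-10
  d_t <- sqrt(outer(targets$lon, obs$lon, "-")^2 +
                outer(targets$lat, obs$lat, "-")^2)
  b <- rbind(t(cov_of(d_t)), 1)
  w <- solve(a, b)
  as.numeric(crossprod(w[seq_len(n), , drop = FALSE], obs$z))
}

#' Kriging residual correction of a predicted surface
#'
#' Interpolates the observation residuals (observed minus predicted) of a
#' model by ordinary kriging and adds the interpolated residual field to
#' the predicted surface, tightening the surface toward the observations
#' where they disagree with the model. A leave-one-out cross-validation
#' report compares the residual RMSE before and after correction. If the
#' variogram fit fails (degenerates to pure nugget), the surface is
#' returned uncorrected with a warning.
#'
#' @param surface predicted surface from [predict_grid()].
#' @param observations data frame `lon`, `lat`, `observed`, `predicted`.
#' @param model variogram model name.
#' @param loo logical; compute the leave-one-out report (default TRUE).
#' @return list: `surface` (input plus `corrected` column), `variogram`,
#'   `cv_report` (`rmse_before`, `rmse_after`, `n`).
#' @export
krige_residual_correction <- function(surface, observations,
                                      model = "spherical", loo = TRUE) {
  stopifnot(nrow(observations) >= 20)
  obs <- data.frame(lon = observations$lon, lat = observations$lat,
                    z = observations$observed - observations$predicted)
  vg <- empirical_variogram(obs$lon, obs$lat, obs$z)
  vgm <- fit_variogram(vg, model)
  if (!vgm$converged || vgm$psill <= 1e-10) {
    warning("variogram fit failed; surface returned uncorrected")
    surface$corrected <- surface$mean
    return(list(surface = surface, variogram = vgm,
                cv_report = data.frame(rmse_before = sqrt(mean(obs$z^2)),
                                       rmse_after = sqrt(mean(obs$z^2)),
                                       n = nrow(obs))))
  }
  surface$corrected <- surface$mean +
    krige_ordinary(obs, surface[, c("lon", "lat")], vgm)
  cv <- NULL
  if (loo) {
    loo_pred <- vapply(seq_len(nrow(obs)), function(i) {
      krige_ordinary(obs[-i, ], obs[i, c("lon", "lat")], vgm)
    }, numeric(1))
    cv <- data.frame(rmse_before = sqrt(mean(obs$z^2)),
                     rmse_after = sqrt(mean((obs$z - loo_pred)^2)),
                     n = nrow(obs))
  }
  list(surface = surface, variogram = vgm, cv_report = cv)
}

#' Latitudinal profile of a surface
#'
#' Planted-area-weighted mean and standard deviation of a surface value by
#' latitude band.
#'
#' @param surface surface data frame with `lat`, `area` and the value.
#' @param value name of the value column (default `"mean"`).
#' @param band_width band height in degrees (default 1).
#' @return data frame `lat` (band centre), `mean`, `sd`, `area`.
#' @export
latitudinal_profile <- function(surface, value = "mean", band_width = 1) {
  stopifnot(nrow(surface) > 0, value %in% names(surface))
  band <- floor(surface$lat / band_width) * band_width + band_width / 2
  out <- lapply(split(seq_len(nrow(surface)), band), function(id) {
    w <- surface$area[id]; v <- surface[[value]][id]
    m <- stats::weighted.mean(v, w)
    data.frame(lat = band[id[1]], mean = m,
               sd = sqrt(sum(w * (v - m)^2) / sum(w)),
               area = sum(w))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$lat), ]
}

#' Dunn's Kruskal-Wallis pairwise comparisons
#'
#' Kruskal-Wallis rank test across groups followed by Dunn's pairwise
#' z-tests on mean ranks with the tie correction, two-sided p-values and
#' optional Benjamini-Hochberg adjustment.
#'
#' @param values numeric vector.
#' @param groups grouping vector (same length).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list: `kruskal_p`, `pairs` (data frame `a`, `b`, `z`, `p`).
#' @export
dunn_test <- function(values, groups, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  kw <- stats::kruskal.test(values, factor(groups))
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- sort(unique(groups))
  mean_rank <- tapply(r, groups, mean)[lev]
  n_g <- tapply(r, groups, length)[lev]
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(ab) {
    i <- ab[1]; j <- ab[2]
    (mean_rank[[i]] - mean_rank[[j]]) /
      sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  list(kruskal_p = kw$p.value,
       pairs = data.frame(a = pairs[1, ], b = pairs[2, ], z = z, p = p,
                          stringsAsFactors = FALSE))
}

# Bron-Kerbosch maximal cliques on an adjacency matrix (small graphs)
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      cliques[[length(cliques) + 1]] <<- r
      return()
    }
    pivot_candidates <- c(p, x)
    u <- pivot_candidates[which.max(vapply(pivot_candidates, function(v)
      sum(adj[v, p]), numeric(1)))]
    for (v in p[!adj[u, p]]) {
      nb <- which(adj[v, ])
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

#' Compact letter display from pairwise p-values
#'
#' Assigns letters to groups such that two groups share a letter if and
#' only if their pairwise difference is not significant at `alpha`.
#' Letters correspond to the maximal cliques of the "not significantly
#' different" graph.
#'
#' @param pairs data frame `a`, `b`, `p` of pairwise comparisons.
#' @param groups character vector of all group names (fixes ordering).
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings per group.
#' @export
compact_letters <- function(pairs, groups, alpha = 0.05) {
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    sig <- pairs$p[i] < alpha
    adj[pairs$a[i], pairs$b[i]] <- !sig
    adj[pairs$b[i], pairs$a[i]] <- !sig
  }
  diag(adj) <- FALSE
  cl <- maximal_cliques(adj)
  # include isolated groups (cliques of one) and order deterministically
  cl <- cl[order(vapply(cl, min, numeric(1)))]
  letters_used <- letters[seq_along(cl)]
  out <- vapply(seq_len(k), function(g) {
    paste0(letters_used[vapply(cl, function(c) g %in% c, logical(1))],
           collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

#' Zonal summary of a surface with multiple-comparison letters
#'
#' Per-zone mean and SD of a surface value, with Kruskal-Wallis and Dunn
#' pairwise tests across zones and a compact letter display (groups not
#' sharing a letter differ at `alpha`).
#'
#' @param surface surface data frame.
#' @param zone_col name of the zone (or country) column in `surface`.
#' @param value name of the value column (default `"mean"`).
#' @param alpha significance level for the letters.
#' @param adjust p-value adjustment passed to [dunn_test()].
#' @return list: `summary` (zone, n, mean, sd, letter), `dunn`.
#' @export
zonal_summary <- function(surface, zone_col, value = "mean", alpha = 0.05,
                          adjust = "none") {
  stopifnot(zone_col %in% names(surface), value %in% names(surface))
  z <- as.character(surface[[zone_col]])
  v <- surface[[value]]
  dn <- dunn_test(v, z, adjust = adjust)
  lev <- sort(unique(z[!is.na(z)]))
  letter <- compact_letters(dn$pairs, lev, alpha)
  smry <- data.frame(
    zone = lev,
    n = as.integer(tapply(v, z, length)[lev]),
    mean = as.numeric(tapply(v, z, mean)[lev]),
    sd = as.numeric(tapply(v, z, stats::sd)[lev]),
    letter = letter[lev], stringsAsFactors = FALSE)
  rownames(smry) <- NULL
  list(summary = smry, dunn = dn)
}

#' Re-predict surfaces under perturbed climate scenarios
#'
#' Applies the model to the base grid and to each labelled perturbed grid
#' (same registration), returning per-scenario surfaces and efficiency
#' deltas relative to the base prediction.
#'
#' @param model a [tune_and_fit()] result.
#' @param base_grid base covariate grid.
#' @param perturbed_grids named list of perturbed grids.
#' @param area_col planted-area mask column.
#' @param clip optional prediction clip range.
#' @return list: `base` surface and `scenarios`, a named list of surfaces
#'   with a `delta` column (scenario mean minus base mean).
#' @export
scenario_reprediction <- function(model, base_grid, perturbed_grids,
                                  area_col, clip = NULL) {
  stopifnot(length(names(perturbed_grids)) == length(perturbed_grids))
  base <- predict_grid(model, base_grid, area_col, clip = clip)
  scen <- lapply(perturbed_grids, function(g) {
    stopifnot(nrow(g) == nrow(base_grid))
    s <- predict_grid(model, g, area_col, clip = clip)
    s$delta <- s$mean - base$mean
    s
  })
  list(base = base, scenarios = scen)
}
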