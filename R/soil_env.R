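#' Empirical semivariogram
#'
#' Method-of-moments estimator: for each lag bin k,
#' `gamma_hat(h_k) = mean over pairs in the bin of 0.5 * (z_i - z_j)^2`.
#' Lags are binned into `n_bins` equal-width classes on `(0, max_lag]`;
#' pairs beyond `max_lag` are ignored; empty bins are dropped with a
#' warning.
#'
#' @param samples data.frame with `x`, `y` and the value column.
#' @param property name of the value column.
#' @param n_bins number of equal-width lag bins (default 15).
#' @param max_lag maximum lag in metres; default half the maximum pairwise
#'   distance.
#' @return An object of class `empirical_variogram`: data.frame with `h`
#'   (mean pair distance in the bin), `gamma` and `n_pairs`.
#' @export
empirical_variogram <- function(samples, property, n_bins = 15, max_lag = NULL) {
  stopifnot(is.data.frame(samples), property %in% names(samples))
  if (nrow(samples) < 2) stop("need at least 2 samples for a variogram")
  if (nrow(samples) < 10)
    warning("fewer than 10 samples; empirical variogram will be unreliable")
  z <- samples[[property]]
  if (any(!is.finite(z))) stop("non-finite values in '", property, "'")
  d <- as.vector(stats::dist(cbind(samples$x, samples$y)))
  g <- 0.5 * as.vector(stats::dist(z))^2
  if (is.null(max_lag)) max_lag <- max(d) / 2
  keep <- d > 0 & d <= max_lag
  d <- d[keep]; g <- g[keep]
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    h = tapply(d, factor(bin, levels = 1:n_bins), mean),
    gamma = tapply(g, factor(bin, levels = 1:n_bins), mean),
    n_pairs = as.integer(table(factor(bin, levels = 1:n_bins))))
  if (any(is.na(out$h))) {
    warning(sum(is.na(out$h)), " empty lag bin(s) dropped")
    out <- out[!is.na(out$h), ]
  }
  rownames(out) <- NULL
  structure(out, class = c("empirical_variogram", "data.frame"),
            max_lag = max_lag)
}

#' Variogram model semivariance
#'
#' Spherical: `gamma(h) = c0 + c1 * (1.5 h/a - 0.5 (h/a)^3)` for `h < a`,
#' `c0 + c1` beyond.  Exponential (practical-range convention):
#' `gamma(h) = c0 + c1 * (1 - exp(-3h/a))`.  By convention `gamma(0) = 0`
#' (the nugget `c0` applies only for `h > 0`).
#'
#' @param model a `variogram_model` from [fit_variogram()] or a list with
#'   `family`, `nugget`, `psill`, `range`.
#' @param h lag distance(s) in metres.
#' @return semivariance value(s).
#' @export
semivariance <- function(model, h) {
  c0 <- model$nugget; c1 <- model$psill; a <- model$range
  hr <- h / a
  base <- switch(model$family,
    spherical   = ifelse(hr < 1, c1 * (1.5 * hr - 0.5 * hr^3), c1),
    exponential = c1 * (1 - exp(-3 * hr)),
    stop("unknown variogram family: ", model$family))
  ifelse(h > 0, c0 + base, 0)
}

#' Fit a variogram model to binned semivariances
#'
#' Weighted least squares with pair-count weights
#' `SSE = sum_k N_k (gamma_hat_k - gamma(h_k))^2`, minimised by L-BFGS-B
#' under bounds `nugget >= 0`, `psill > 0`, `0 < range <= 2 * max(h)`.
#' A range estimate at the upper bound (flat variogram) triggers a warning.
#'
#' @param emp an [empirical_variogram()] with at least 3 bins.
#' @param family `"spherical"` (default) or `"exponential"`.
#' @return An object of class `variogram_model`: list with `family`,
#'   `nugget`, `psill`, `range`, `sse`, `converged`, and the input bins.
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential")) {
  family <- match.arg(family)
  if (nrow(emp) < 3) stop("need at least 3 non-empty lag bins to fit a variogram")
  h <- emp$h; g <- emp$gamma; w <- emp$n_pairs
  # normalise scales so the optimiser works on O(1) quantities
  gs <- max(g, 1e-300); hs <- max(h)
  gn <- g / gs; hn <- h / hs
  wn <- w / sum(w)
  hi <- 2
  start <- c(nugget = max(min(gn), 1e-6), psill = max(max(gn) - min(gn), 1e-6),
             range = 0.5)
  obj <- function(p) {
    m <- list(family = family, nugget = p[1], psill = p[2], range = p[3])
    sum(wn * (gn - semivariance(m, hn))^2)
  }
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-9, 1e-6), upper = c(11, 11, hi),
                      control = list(maxit = 500, factr = 1e10))
  if (fit$convergence != 0) {
    fit2 <- stats::optim(start, function(p)
      if (any(p < c(0, 1e-9, 1e-6)) || any(p > c(11, 11, hi))) 1e10 else obj(p),
      method = "Nelder-Mead", control = list(maxit = 2000))
    if (fit2$value <= fit$value) fit <- fit2
    if (fit$convergence != 0 && !is.finite(fit$value))
      stop("variogram fit did not converge: ", fit$message)
  }
  if (fit$par[2] < 1e-6 * max(fit$par[1], 1e-12)) {
    # no resolvable spatial structure: the range is unidentifiable
    fit$par[3] <- hi
    warning("range estimate hit its upper bound (", signif(hi * hs, 4),
            " m); empirical variogram is flat")
  } else if (fit$par[3] > 0.999 * hi) {
    warning("range estimate hit its upper bound (", signif(hi * hs, 4),
            " m); empirical variogram may be flat")
  }
  structure(list(family = family,
                 nugget = unname(fit$par[1]) * gs,
                 psill = unname(fit$par[2]) * gs,
                 range = unname(fit$par[3]) * hs,
                 sse = fit$value * gs^2,
                 converged = fit$convergence == 0,
                 bins = as.data.frame(emp)),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s, nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Ordinary kriging
#'
#' Best linear unbiased prediction at target points: for each target the
#' ordinary-kriging system (pairwise sample semivariance matrix augmented
#' with the unit-sum unbiasedness constraint through a Lagrange multiplier)
#' is solved; weights sum to 1 and the predictor interpolates exactly at
#' sample locations.  Duplicate sample locations are averaged with a
#' warning to keep the system non-singular.  The neighbourhood is global
#' (all samples).
#'
#' @param samples data.frame with `x`, `y`.
#' @param values numeric vector of sample values (same length).
#' @param model a `variogram_model`.
#' @param targets data.frame with target `x`, `y` (e.g. [quadrat_centers()]).
#' @param return_weights keep the full weight matrix (n_samples x n_targets)?
#' @return list with `pred`, `var` (kriging variance) per target, and
#'   optionally `weights`.
#' @export
ordinary_krige <- function(samples, values, model, targets,
                           return_weights = FALSE) {
  stopifnot(nrow(samples) == length(values))
  xy <- cbind(samples$x, samples$y)
  key <- paste(xy[, 1], xy[, 2], sep = "_")
  if (anyDuplicated(key)) {
    warning("duplicate sample locations averaged before kriging")
    agg <- rowsum(cbind(values, 1), key, reorder = FALSE)
    first <- !duplicated(key)
    xy <- xy[first, , drop = FALSE]
    values <- (agg[, 1] / agg[, 2])[match(key[first], rownames(agg))]
  }
  n <- nrow(xy)
  G <- semivariance(model, as.matrix(stats::dist(xy)))
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  tx <- cbind(targets$x, targets$y)
  # distances samples -> targets
  D0 <- sqrt(outer(xy[, 1], tx[, 1], "-")^2 + outer(xy[, 2], tx[, 2], "-")^2)
  B <- rbind(semivariance(model, D0), 1)
  W <- solve(A, B)
  pred <- as.vector(crossprod(W[1:n, , drop = FALSE], values))
  kvar <- colSums(W * B)   # sum_i w_i gamma_i0 + mu
  kvar[kvar < 0] <- 0
  out <- list(pred = pred, var = kvar)
  if (return_weights) out$weights <- W[1:n, , drop = FALSE]
  out
}

# canonical soil property column names (units: mg/g except water_content %
# and pH)
.soil_properties <- c("total_n", "total_p", "total_k",
                      "avail_n", "avail_p", "avail_k",
                      "organic_matter", "water_content", "ph")

#' Krige soil properties to quadrat centres
#'
#' For each property: empirical variogram, weighted-least-squares model
#' fit, then ordinary kriging to the quadrat centres of `grid`.
#'
#' @param samples soil sample data.frame (`sample_id`, `x`, `y`, nine
#'   property columns).
#' @param grid a [plot_grid()].
#' @param properties property columns to interpolate.
#' @param family variogram family passed to [fit_variogram()].
#' @param n_bins,max_lag passed to [empirical_variogram()].
#' @return list with `table` (data.frame `quadrat_id` + kriged properties)
#'   and `models` (named list of `variogram_model`s).
#' @export
krige_soil <- function(samples, grid, properties = .soil_properties,
                       family = "spherical", n_bins = 15, max_lag = NULL) {
  missing <- setdiff(properties, names(samples))
  if (length(missing) > 0)
    stop("soil samples lack column(s): ", paste(missing, collapse = ", "))
  ctr <- quadrat_centers(grid)
  out <- data.frame(quadrat_id = ctr$quadrat_id)
  models <- list()
  for (p in properties) {
    emp <- empirical_variogram(samples, p, n_bins = n_bins, max_lag = max_lag)
    vm <- fit_variogram(emp, family = family)
    kr <- ordinary_krige(samples, samples[[p]], vm, ctr)
    out[[p]] <- kr$pred
    models[[p]] <- vm
  }
  list(table = out, models = models)
}

#' PCA of quadrat soil properties, oriented to fertility
#'
#' Principal component analysis of the z-scored (correlation-matrix) soil
#' variables.  PC1 is sign-anchored so that the mean loading of the
#' `orient_positive` variables (defaults: total N, organic matter, water
#' content — markers of high fertility) is positive, making the fertility
#' axis deterministic.
#'
#' @param x data.frame/matrix of quadrat-level soil variables (no missing
#'   values, >= 2 rows).
#' @param orient_positive variables whose mean PC1 loading is forced
#'   positive.
#' @return list with `scores` (matrix), `loadings` (variables x PCs),
#'   `var_fraction` (explained-variance fractions summing to 1), `center`,
#'   `scale`.
#' @export
soil_pca <- function(x, orient_positive = c("total_n", "organic_matter",
                                            "water_content")) {
  x <- as.data.frame(x)
  if ("quadrat_id" %in% names(x)) x$quadrat_id <- NULL
  if (nrow(x) < 2) stop("need at least 2 quadrats for PCA")
  if (any(!is.finite(as.matrix(x)))) stop("missing values in soil table")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance column(s): ", paste(names(x)[sds == 0], collapse = ", "))
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  orient <- intersect(orient_positive, rownames(pr$rotation))
  if (length(orient) > 0 && mean(pr$rotation[orient, 1]) < 0) {
    pr$rotation[, 1] <- -pr$rotation[, 1]
    pr$x[, 1] <- -pr$x[, 1]
  }
  list(scores = pr$x,
       loadings = pr$rotation,
       var_fraction = pr$sdev^2 / sum(pr$sdev^2),
       center = pr$center, scale = pr$scale)
}
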