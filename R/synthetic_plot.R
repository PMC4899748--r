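#' Default log-scale trait correlation matrix for the synthetic species pool
#'
#' Encodes the leaf-economics / wood-economics trade-offs typical of
#' subtropical tree floras: SLA and LDMC strongly negatively correlated,
#' SLA negatively related to wood density, LDMC positively related to wood
#' density, and a mild positive association of leaf area and maximum DBH.
#' Correlations apply on the log-trait scale.
#'
#' @return 5 x 5 positive-definite correlation matrix (la, sla, ldmc, wd,
#'   max_dbh).
#' @export
default_trait_corr <- function() {
  tn <- c("la", "sla", "ldmc", "wd", "max_dbh")
  R <- diag(5)
  dimnames(R) <- list(tn, tn)
  set_ <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set_("la", "sla", 0.30); set_("la", "ldmc", -0.20)
  set_("la", "wd", -0.20); set_("la", "max_dbh", 0.20)
  set_("sla", "ldmc", -0.70); set_("sla", "wd", -0.30)
  set_("sla", "max_dbh", -0.20)
  set_("ldmc", "wd", 0.40); set_("ldmc", "max_dbh", 0.20)
  set_("wd", "max_dbh", 0.20)
  R
}

#' Default marginal specification of the nine soil properties
#'
#' Means and coefficients of variation on the scale the field reports
#' (mg/g for nutrients and organic matter, % for water content, pH units),
#' plus the loading of each property on the single latent fertility
#' factor.  Fertility markers (N, P, K, organic matter, water) load
#' positively; pH loads negatively by default (acidic subtropical soils
#' are more leached where organic inputs are high).
#'
#' @return data.frame `property`, `mean`, `cv`, `loading`.
#' @export
default_soil_properties <- function() {
  data.frame(
    property = c("total_n", "total_p", "total_k", "avail_n", "avail_p",
                 "avail_k", "organic_matter", "water_content", "ph"),
    mean = c(1.2, 0.25, 14, 0.12, 0.004, 0.07, 35, 25, 4.0),
    cv   = c(0.30, 0.30, 0.25, 0.30, 0.35, 0.30, 0.35, 0.20, 0.06),
    loading = c(0.85, 0.75, 0.60, 0.80, 0.70, 0.65, 0.85, 0.80, -0.60),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic plot generator
#'
#' The defaults emulate the canonical 20-ha (400 m x 500 m) forest
#' dynamics plot: 20 m quadrats, corner elevations spanning 230-470 m,
#' a ~30 m soil sampling lattice with two offset satellite points each,
#' nine soil properties driven by one latent fertility field, a 92-species
#' pool with correlated log-normal traits, and habitat-dependent stem
#' placement with known effect coefficients (high-wood-density species
#' favour convex sites; high-SLA acquisitive species favour fertile
#' sites).
#'
#' @param plot_width,plot_height,quadrat_size plot geometry (m).
#' @param elevation_range target altitude range (m a.s.l.).
#' @param n_hills,hill_height,hill_width Gaussian hills: count and
#'   uniform ranges for height (m) and kernel width (m).
#' @param terrain_noise,terrain_noise_scale amplitude (m) and kernel width
#'   (m) of the smooth terrain bump noise; `terrain_noise = 0` disables it.
#' @param soil_grid_spacing base soil lattice spacing (m).
#' @param satellite_distances candidate offsets (m) for the two satellite
#'   samples per base point.
#' @param soil_n_kernels,soil_kernel_width number and width (m) of the
#'   Gaussian kernels building the latent fertility field; 0 kernels gives
#'   a constant field.
#' @param soil_noise multiplier on the property-specific residual noise
#'   (1 = the variance implied by the factor loadings; 0 = noiseless).
#' @param soil_properties data.frame as [default_soil_properties()].
#' @param n_species species-pool size.
#' @param trait_means,trait_cv named marginal means and coefficients of
#'   variation of the five traits (lognormal marginals).
#' @param trait_corr log-scale trait correlation matrix (positive
#'   definite).
#' @param mean_prevalence mean per-quadrat occurrence probability of a
#'   species at an average site.
#' @param prevalence_sd species spread of logit prevalence.
#' @param lambda_meanlog,lambda_sdlog lognormal parameters of the
#'   species-level expected extra stems per occupied quadrat.
#' @param beta_conv,beta_conv_trait convexity habitat effect: per-species
#'   log-odds slope is `beta_conv * z(log trait)` of `beta_conv_trait`.
#' @param beta_fert,beta_fert_trait same for the latent fertility axis.
#' @param dbh_shape,dbh_scale_frac Weibull DBH distribution: shape and
#'   scale as a fraction of the species maximum DBH; DBH is truncated to
#'   `[1, max_dbh]`.
#' @param seed master seed; stage seeds are derived as small offsets.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    plot_width = 400, plot_height = 500, quadrat_size = 20,
    elevation_range = c(230, 470),
    n_hills = 3, hill_height = c(60, 120), hill_width = c(80, 180),
    terrain_noise = 6, terrain_noise_scale = 60,
    soil_grid_spacing = 30, satellite_distances = c(2, 5, 15),
    soil_n_kernels = 40, soil_kernel_width = 60, soil_noise = 1,
    soil_properties = default_soil_properties(),
    n_species = 92,
    trait_means = c(la = 50, sla = 120, ldmc = 0.35, wd = 0.55, max_dbh = 45),
    trait_cv = c(la = 0.9, sla = 0.35, ldmc = 0.20, wd = 0.25, max_dbh = 0.6),
    trait_corr = default_trait_corr(),
    mean_prevalence = 0.32, prevalence_sd = 1,
    lambda_meanlog = log(2.5), lambda_sdlog = 1,
    beta_conv = 1.0, beta_conv_trait = "wd",
    beta_fert = 1.0, beta_fert_trait = "sla",
    dbh_shape = 0.8, dbh_scale_frac = 0.10,
    seed = 1) {
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("trait_corr is not positive definite")
  if (any(trait_cv <= 0) || any(trait_means <= 0))
    stop("trait means and CVs must be > 0")
  if (n_species < 1) stop("n_species must be >= 1")
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# smooth analytic surface: list of Gaussian kernels (cx, cy, amp, width)
.eval_kernels <- function(kern, x, y) {
  z <- numeric(length(x))
  if (length(kern$cx) == 0) return(z)
  for (k in seq_along(kern$cx)) {
    z <- z + kern$amp[k] *
      exp(-((x - kern$cx[k])^2 + (y - kern$cy[k])^2) / (2 * kern$width[k]^2))
  }
  z
}

#' Generate synthetic terrain
#'
#' Builds an analytic surface (random Gaussian hills plus smooth bump
#' noise), evaluates it at the quadrat-corner lattice *and* at quadrat
#' centres, and rescales both jointly and affinely into
#' `cfg$elevation_range`.  Because corners and centres are evaluated from
#' the same surface, the centre-point edge-convexity rule is exactly
#' applicable.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (defaults to `cfg$seed + 1`).
#' @return An [elevation_grid()] with centre altitudes; the kernel list is
#'   attached as attribute `"surface"`.
#' @export
generate_terrain <- function(cfg, seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  grid <- plot_grid(cfg$plot_width, cfg$plot_height, cfg$quadrat_size)
  nh <- cfg$n_hills
  kern <- list(
    cx = stats::runif(nh, 0, cfg$plot_width),
    cy = stats::runif(nh, 0, cfg$plot_height),
    amp = stats::runif(nh, cfg$hill_height[1], cfg$hill_height[2]),
    width = stats::runif(nh, cfg$hill_width[1], cfg$hill_width[2]))
  if (cfg$terrain_noise > 0) {
    nb <- 60
    kern$cx <- c(kern$cx, stats::runif(nb, 0, cfg$plot_width))
    kern$cy <- c(kern$cy, stats::runif(nb, 0, cfg$plot_height))
    kern$amp <- c(kern$amp, stats::runif(nb, -cfg$terrain_noise, cfg$terrain_noise))
    kern$width <- c(kern$width, rep(cfg$terrain_noise_scale, nb))
  }
  s <- cfg$quadrat_size
  ci <- expand.grid(x = (0:grid$n_qx) * s, y = (0:grid$n_qy) * s)
  ctr <- quadrat_centers(grid)
  zc <- .eval_kernels(kern, ci$x, ci$y)
  zm <- .eval_kernels(kern, ctr$x, ctr$y)
  all_z <- c(zc, zm)
  lo <- cfg$elevation_range[1]; hi <- cfg$elevation_range[2]
  if (diff(range(all_z)) < 1e-12) {        # flat surface: park at mid-range
    zc <- rep(mean(c(lo, hi)), length(zc))
    zm <- rep(mean(c(lo, hi)), length(zm))
  } else {
    f <- function(z) lo + (z - min(all_z)) / diff(range(all_z)) * (hi - lo)
    zc <- f(zc); zm <- f(zm)
  }
  corner <- matrix(zc, grid$n_qx + 1L, grid$n_qy + 1L)
  center <- matrix(zm, grid$n_qx, grid$n_qy)
  eg <- elevation_grid(corner, grid, center)
  attr(eg, "surface") <- kern
  eg
}

#' Generate soil samples from a latent fertility field
#'
#' Base points on a `soil_grid_spacing` lattice (offset half a spacing
#' from the plot edge); each base point gets two satellite points at a
#' distance drawn from `satellite_distances` in a uniform random compass
#' direction, clipped into the plot.  A smooth latent fertility field
#' (sum of Gaussian kernels, standardized over the sample set) drives the
#' nine properties: `value = mean * (1 + cv * (loading * f +
#' soil_noise * sqrt(1 - loading^2) * eps))`, so with `soil_noise = 1`
#' every property has unit standardized variance and the cross-property
#' correlation matrix has the planted one-factor structure
#' `R[p,q] = loading_p * loading_q`.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (defaults to `cfg$seed + 2`).
#' @return list with `samples` (data.frame `sample_id`, `x`, `y`, `kind`
#'   (base/satellite), nine property columns), `fertility_centers`
#'   (standardized latent field at the quadrat centres of the config
#'   grid), and `field` (kernel list plus standardizing affine).
#' @export
generate_soil_samples <- function(cfg, seed = cfg$seed + 2) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  sp <- cfg$soil_grid_spacing
  bx <- seq(sp / 2, cfg$plot_width - 1e-9, by = sp)
  by <- seq(sp / 2, cfg$plot_height - 1e-9, by = sp)
  base <- expand.grid(x = bx, y = by)
  nb <- nrow(base)
  dist2 <- sample(cfg$satellite_distances, 2 * nb, replace = TRUE)
  ang <- stats::runif(2 * nb, 0, 2 * pi)
  sat <- data.frame(
    x = rep(base$x, each = 2) + dist2 * cos(ang),
    y = rep(base$y, each = 2) + dist2 * sin(ang))
  eps <- 1e-6
  sat$x <- pmin(pmax(sat$x, 0), cfg$plot_width - eps)
  sat$y <- pmin(pmax(sat$y, 0), cfg$plot_height - eps)
  pts <- rbind(cbind(base, kind = "base"), cbind(sat, kind = "satellite"))
  n <- nrow(pts)

  K <- cfg$soil_n_kernels
  kern <- list(cx = stats::runif(K, 0, cfg$plot_width),
               cy = stats::runif(K, 0, cfg$plot_height),
               amp = stats::rnorm(K),
               width = rep(cfg$soil_kernel_width, K))
  raw <- .eval_kernels(kern, pts$x, pts$y)
  mu <- mean(raw); sdv <- stats::sd(raw)
  if (!is.finite(sdv) || sdv < 1e-12) { mu <- if (length(raw)) raw[1] else 0; sdv <- 1 }
  f <- (raw - mu) / sdv

  props <- cfg$soil_properties
  out <- data.frame(sample_id = sprintf("soil%04d", seq_len(n)),
                    x = pts$x, y = pts$y, kind = pts$kind,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(props))) {
    l <- props$loading[i]
    e <- stats::rnorm(n)
    u <- l * f + cfg$soil_noise * sqrt(max(1 - l^2, 0)) * e
    out[[props$property[i]]] <- props$mean[i] * (1 + props$cv[i] * u)
  }
  grid <- plot_grid(cfg$plot_width, cfg$plot_height, cfg$quadrat_size)
  ctr <- quadrat_centers(grid)
  fert_ctr <- (.eval_kernels(kern, ctr$x, ctr$y) - mu) / sdv
  list(samples = out,
       fertility_centers = fert_ctr,
       field = list(kernels = kern, center = mu, scale = sdv))
}

#' Generate a correlated species trait pool
#'
#' Species traits are drawn from a multivariate lognormal: a Gaussian copula
#' with correlation `cfg$trait_corr` on the log scale and lognormal
#' marginals matching `trait_means` / `trait_cv`.  LDMC is capped at 0.99
#' (a dry:fresh mass ratio cannot exceed 1).
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (defaults to `cfg$seed + 3`).
#' @return A `trait_table` with species `sp001 ...`.
#' @export
generate_species_pool <- function(cfg, seed = cfg$seed + 3) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  tn <- c("la", "sla", "ldmc", "wd", "max_dbh")
  R <- cfg$trait_corr[tn, tn]
  Z <- MASS::mvrnorm(cfg$n_species, mu = rep(0, 5), Sigma = R)
  if (cfg$n_species == 1) Z <- matrix(Z, nrow = 1)
  out <- data.frame(species_id = sprintf("sp%03d", seq_len(cfg$n_species)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(tn)) {
    cv <- cfg$trait_cv[[tn[k]]]
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(cfg$trait_means[[tn[k]]]) - sdlog^2 / 2
    out[[tn[k]]] <- exp(meanlog + sdlog * Z[, k])
  }
  out$ldmc <- pmin(out$ldmc, 0.99)
  out$max_dbh <- pmax(out$max_dbh, 1.5)   # a species must be censusable
  validate_trait_table(out)
}

# truncated Weibull draw on [1, upper], vectorised over upper
.rdbh_trunc_weibull <- function(n, shape, scale, upper) {
  f1 <- stats::pweibull(1, shape, scale)
  f2 <- stats::pweibull(upper, shape, scale)
  u <- stats::runif(n)
  d <- stats::qweibull(f1 + u * pmax(f2 - f1, 0), shape, scale)
  d[!is.finite(d) | f2 <= f1] <- 1
  pmin(pmax(d, 1), upper)
}

#' Generate a habitat-filtered stem map
#'
#' Per-quadrat species occurrence follows a logistic model in standardized
#' convexity and latent fertility with per-species coefficients
#' `beta_conv_j = cfg$beta_conv * z(log trait)` (default trait: wood
#' density) and `beta_fert_j = cfg$beta_fert * z(log trait)` (default:
#' SLA).  Occupied cells receive `1 + Poisson(lambda_j)` stems; stems get
#' uniform coordinates within their quadrat and a DBH from a species-level
#' Weibull truncated to `[1 cm, max_dbh]`.  The realized coefficients and
#' latent fields are returned as ground truth.
#'
#' @param terrain an [elevation_grid()] (with centres, as produced by
#'   [generate_terrain()]).
#' @param fertility standardized latent fertility at quadrat centres
#'   (from [generate_soil_samples()]).
#' @param pool a `trait_table` species pool.
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (defaults to `cfg$seed + 4`).
#' @return list with `stems` (a `stem_table` with `quadrat_id` columns)
#'   and `ground_truth` (coefficients, latent fields, expected correlation
#'   signs).
#' @export
generate_stem_map <- function(terrain, fertility, pool, cfg,
                              seed = cfg$seed + 4) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(terrain, "elevation_grid"))
  set.seed(seed)
  grid <- terrain$grid
  conv <- convexity(terrain)
  zs <- function(v) if (stats::sd(v) < 1e-12) rep(0, length(v)) else
    (v - mean(v)) / stats::sd(v)
  convz <- zs(conv$convexity)
  fertz <- zs(fertility)
  S <- nrow(pool); Q <- grid$n_quadrats

  bconv <- cfg$beta_conv * zs(log(pool[[cfg$beta_conv_trait]]))
  bfert <- cfg$beta_fert * zs(log(pool[[cfg$beta_fert_trait]]))
  names(bconv) <- names(bfert) <- pool$species_id

  alpha <- stats::rnorm(S, stats::qlogis(cfg$mean_prevalence), cfg$prevalence_sd)
  lambda <- stats::rlnorm(S, cfg$lambda_meanlog, cfg$lambda_sdlog)

  # Q x S occurrence probabilities
  eta <- outer(convz, bconv) + outer(fertz, bfert) +
    matrix(alpha, Q, S, byrow = TRUE)
  p <- stats::plogis(eta)
  occ <- matrix(stats::rbinom(Q * S, 1, p), Q, S)
  counts <- occ * (occ + matrix(stats::rpois(Q * S, rep(lambda, each = Q)), Q, S))

  idx <- which(counts > 0, arr.ind = TRUE)
  n_per <- counts[idx]
  qid <- rep(idx[, 1] - 1L, n_per)
  spi <- rep(idx[, 2], n_per)
  n <- length(qid)
  s <- grid$quadrat_size
  qx <- qid %% grid$n_qx; qy <- qid %/% grid$n_qx
  x <- (qx + stats::runif(n)) * s
  y <- (qy + stats::runif(n)) * s
  maxd <- pool$max_dbh[spi]
  dbh <- .rdbh_trunc_weibull(n, cfg$dbh_shape, cfg$dbh_scale_frac * maxd, maxd)
  ord <- order(qid, spi)
  stems <- data.frame(stem_id = sprintf("s%06d", seq_len(n)),
                      x = x[ord], y = y[ord],
                      species_id = pool$species_id[spi[ord]],
                      dbh = round(dbh[ord], 2),
                      stringsAsFactors = FALSE)
  stems <- assign_quadrats(validate_stem_table(stems, grid), grid)
  gt <- list(
    beta_conv = bconv, beta_fert = bfert,
    beta_conv_trait = cfg$beta_conv_trait, beta_fert_trait = cfg$beta_fert_trait,
    alpha = stats::setNames(alpha, pool$species_id),
    lambda = stats::setNames(lambda, pool$species_id),
    convexity_z = convz, fertility_z = fertz,
    expected_signs = list(
      cwm_vs_convexity = if (cfg$beta_conv > 0) "+" else if (cfg$beta_conv < 0) "-" else "0",
      cwm_vs_fertility = if (cfg$beta_fert > 0) "+" else if (cfg$beta_fert < 0) "-" else "0"))
  list(stems = stems, ground_truth = gt)
}

#' Generate a complete synthetic plot
#'
#' Runs all generator stages with seeds derived from `cfg$seed` and
#' returns the full bundle: terrain, soil samples, species pool, stem map
#' and ground truth.  Fully deterministic under a fixed config.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_plot` with elements `config`, `grid`,
#'   `terrain`, `soil_samples`, `traits`, `stems`, `ground_truth`.
#' @export
simulate_plot <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  grid <- plot_grid(cfg$plot_width, cfg$plot_height, cfg$quadrat_size)
  terrain <- generate_terrain(cfg)
  soils <- generate_soil_samples(cfg)
  pool <- generate_species_pool(cfg)
  sm <- generate_stem_map(terrain, soils$fertility_centers, pool, cfg)
  gt <- sm$ground_truth
  gt$soil_field <- soils$field
  structure(list(config = cfg, grid = grid, terrain = terrain,
                 soil_samples = soils$samples, traits = pool,
                 stems = sm$stems, ground_truth = gt),
            class = "synthetic_plot")
}

#' Write a synthetic plot to CSV + JSON
#'
#' Writes `stems.csv`, `traits.csv`, `elevation_corners.csv`,
#' `elevation_centers.csv`, `soil_samples.csv` and `ground_truth.json`
#' into `dir` using the documented schemas.
#'
#' @param sim a [simulate_plot()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_plot <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_plot"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stem_table(sim$stems, file.path(dir, "stems.csv"))
  write_trait_table(sim$traits, file.path(dir, "traits.csv"))
  write_elevation_grid(sim$terrain, file.path(dir, "elevation_corners.csv"),
                       file.path(dir, "elevation_centers.csv"))
  utils::write.csv(sim$soil_samples, file.path(dir, "soil_samples.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- sim$ground_truth
  gt$soil_field <- NULL    # kernel lists are bulky; keep the JSON compact
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
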