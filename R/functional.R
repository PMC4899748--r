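#' @keywords internal
.trait_names <- c("la", "sla", "ldmc", "wd", "max_dbh")

# species x trait matrix for the requested traits, restricted to species
# present in both the community matrix and the trait table
.trait_matrix <- function(comm, traits, trait_set) {
  bad <- setdiff(trait_set, .trait_names)
  if (length(bad) > 0) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  covered <- intersect(colnames(comm), traits$species_id)
  X <- as.matrix(traits[match(covered, traits$species_id), trait_set,
                        drop = FALSE])
  rownames(X) <- covered
  X
}

#' Community-weighted mean (CWM) trait value
#'
#' Abundance-weighted mean trait value per quadrat,
#' `CWM = sum_j a_j x_j / sum_j a_j`, over species covered by the trait
#' table.  Stems of uncovered species do not contribute (they still count
#' for carbon).  Quadrats with no covered stems get `NA` with a warning;
#' they are excluded from downstream analyses.
#'
#' @param comm a [community_matrix()].
#' @param traits a trait table ([validate_trait_table()]).
#' @param trait one of `"la"`, `"sla"`, `"ldmc"`, `"wd"`, `"max_dbh"`.
#' @return named numeric vector, one CWM per quadrat (names = quadrat ids).
#' @export
cwm <- function(comm, traits, trait) {
  stopifnot(length(trait) == 1)
  X <- .trait_matrix(comm, traits, trait)
  A <- comm[, rownames(X), drop = FALSE]
  tot <- rowSums(A)
  if (any(tot == 0 & rowSums(comm) > 0))
    warning(sum(tot == 0 & rowSums(comm) > 0),
            " quadrat(s) have stems but no trait-covered species; CWM is NA")
  out <- as.vector(A %*% X[, 1]) / tot
  out[tot == 0] <- NA_real_
  stats::setNames(out, rownames(comm))
}

#' Abundance-weighted trait-space centroid
#'
#' `c_i = sum_j a_j x_ij / sum_j a_j` for each trait dimension i.
#'
#' @param abundances nonnegative species abundances `a_j`.
#' @param trait_matrix species x traits matrix `x_ij` (rows align with
#'   `abundances`).
#' @return numeric vector, one coordinate per trait dimension.
#' @export
weighted_centroid <- function(abundances, trait_matrix) {
  trait_matrix <- as.matrix(trait_matrix)
  stopifnot(length(abundances) == nrow(trait_matrix), all(abundances >= 0))
  tot <- sum(abundances)
  if (tot == 0) stop("all abundances are zero; centroid undefined")
  as.vector(crossprod(trait_matrix, abundances)) / tot
}

# standardize a species x trait matrix using pool-level statistics
.standardize_traits <- function(X, mode) {
  switch(mode,
    none = X,
    zscore = scale(X, center = TRUE, scale = TRUE),
    range = {
      rng <- apply(X, 2, range)
      span <- rng[2, ] - rng[1, ]
      if (any(span == 0)) span[span == 0] <- 1   # constant trait: no spread
      sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
    },
    stop("unknown standardization mode: ", mode))
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean distance of species to the abundance-weighted
#' trait centroid: with `z_j` the Euclidean distance of species j's
#' (optionally standardized) trait vector to the centroid `c`,
#' `FDis = sum_j a_j z_j / sum_j a_j`.  For a single raw trait this is the
#' abundance-weighted mean absolute deviation from the weighted mean.
#' Standardization statistics are computed over the whole species pool
#' (every species in the trait table), not per quadrat, so quadrats share
#' one trait space.
#'
#' @inheritParams cwm
#' @param trait_set character vector of traits spanning the space.
#' @param standardize `"none"` (raw trait units), `"zscore"` (pool z-score;
#'   default for multi-trait spaces) or `"range"` (pool range scaling, a
#'   Gower-style alternative).
#' @param details if `TRUE` also return per-quadrat centroids and species
#'   distances.
#' @return data.frame `quadrat_id`, `fdis`, `richness` (number of
#'   trait-covered species present); with `details = TRUE` a list that adds
#'   `centroid` (quadrat x trait) and `z` (quadrat x species distances).
#' @export
fdis <- function(comm, traits, trait_set, standardize = "none",
                 details = FALSE) {
  if (length(trait_set) == 0) stop("trait_set must name at least one trait")
  X <- .trait_matrix(comm, traits, trait_set)
  # pool statistics: all species in the trait table
  pool <- as.matrix(traits[, trait_set, drop = FALSE])
  Xs <- switch(standardize,
    none = X,
    zscore = {
      sds <- apply(pool, 2, stats::sd)
      sds[sds == 0] <- 1   # constant trait: zero spread, zero contribution
      sweep(sweep(X, 2, colMeans(pool)), 2, sds, "/")
    },
    range = {
      rng <- apply(pool, 2, range); span <- pmax(rng[2, ] - rng[1, ], 1e-12)
      sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
    },
    stop("unknown standardization mode: ", standardize))
  A <- comm[, rownames(X), drop = FALSE]
  tot <- rowSums(A)
  nq <- nrow(comm)
  fd <- rep(NA_real_, nq); rich <- integer(nq)
  cents <- matrix(NA_real_, nq, ncol(Xs), dimnames = list(rownames(comm), trait_set))
  zmat <- matrix(NA_real_, nq, nrow(Xs), dimnames = list(rownames(comm), rownames(Xs)))
  for (q in seq_len(nq)) {
    a <- A[q, ]
    if (tot[q] == 0) next
    ctr <- as.vector(crossprod(Xs, a)) / tot[q]
    z <- sqrt(rowSums(sweep(Xs, 2, ctr)^2))
    fd[q] <- sum(a * z) / tot[q]
    rich[q] <- sum(a > 0)
    cents[q, ] <- ctr
    zmat[q, ] <- z
  }
  res <- data.frame(quadrat_id = as.integer(rownames(comm)), fdis = fd,
                    richness = rich)
  if (details) list(result = res, centroid = cents, z = zmat) else res
}

#' Multivariate functional dispersion over all five traits
#'
#' [fdis()] in the pool-z-scored five-trait space (LA, SLA, LDMC, WD,
#' maximum DBH).
#'
#' @inheritParams fdis
#' @export
multivariate_fdis <- function(comm, traits, standardize = "zscore") {
  fdis(comm, traits, .trait_names, standardize = standardize)
}

#' Per-quadrat functional summary
#'
#' CWM and single-trait FDis for each of the five traits plus the
#' multivariate FDis, assembled into one data.frame (columns `<trait>_cwm`,
#' `<trait>_fdis`, `multi_fdis`).
#'
#' @inheritParams fdis
#' @param fdis_standardize standardization for the *multivariate* FDis;
#'   single-trait FDis is reported in raw trait units.
#' @return data.frame keyed by `quadrat_id`.
#' @export
functional_summary <- function(comm, traits, fdis_standardize = "zscore") {
  out <- data.frame(quadrat_id = as.integer(rownames(comm)))
  for (tr in .trait_names) {
    out[[paste0(tr, "_cwm")]] <- unname(cwm(comm, traits, tr))
    out[[paste0(tr, "_fdis")]] <- fdis(comm, traits, tr, standardize = "none")$fdis
  }
  out$multi_fdis <- multivariate_fdis(comm, traits,
                                      standardize = fdis_standardize)$fdis
  out
}
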