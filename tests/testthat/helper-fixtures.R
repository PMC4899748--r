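# Shared fixture builders and independent brute-force oracles.
# Oracles are deliberately naive (loops, direct linear algebra) and never
# call the implementation they check.

make_stems <- function(x, y, species, dbh, ids = NULL) {
  data.frame(stem_id = if (is.null(ids)) sprintf("s%03d", seq_along(x)) else ids,
             x = x, y = y, species_id = species, dbh = dbh,
             stringsAsFactors = FALSE)
}

make_traits <- function(species, la = 10, sla = 100, ldmc = 0.4, wd = 0.5,
                        max_dbh = 50) {
  n <- length(species)
  data.frame(species_id = species,
             la = rep_len(la, n), sla = rep_len(sla, n),
             ldmc = rep_len(ldmc, n), wd = rep_len(wd, n),
             max_dbh = rep_len(max_dbh, n), stringsAsFactors = FALSE)
}

# corner lattice from an analytic surface z(x, y)
make_elevation <- function(grid, f, centers = TRUE) {
  s <- grid$quadrat_size
  corner <- outer((0:grid$n_qx) * s, (0:grid$n_qy) * s, f)
  center <- NULL
  if (centers) {
    cx <- ((0:(grid$n_qx - 1)) + 0.5) * s
    cy <- ((0:(grid$n_qy - 1)) + 0.5) * s
    center <- outer(cx, cy, f)
  }
  elevation_grid(corner, grid, center)
}

# naive FDis: explicit loops over species, no matrix algebra
naive_fdis <- function(abund, X, standardize_pool = NULL) {
  if (!is.null(standardize_pool)) {
    for (k in seq_len(ncol(X)))
      X[, k] <- (X[, k] - mean(standardize_pool[, k])) / sd(standardize_pool[, k])
  }
  tot <- sum(abund)
  ctr <- numeric(ncol(X))
  for (j in seq_len(nrow(X))) ctr <- ctr + abund[j] * X[j, ]
  ctr <- ctr / tot
  num <- 0
  for (j in seq_len(nrow(X))) {
    z <- sqrt(sum((X[j, ] - ctr)^2))
    num <- num + abund[j] * z
  }
  num / tot
}

# LMG by explicit enumeration of all orderings
perm_lmg <- function(y, X) {
  p <- ncol(X)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(lm(y ~ ., data = as.data.frame(X[, cols, drop = FALSE])))$r.squared
  }
  shares <- setNames(numeric(p), colnames(X))
  all_p <- perms(seq_len(p))
  for (ord in all_p) {
    prev <- numeric(0)
    for (i in ord) {
      shares[i] <- shares[i] + r2(c(prev, i)) - r2(prev)
      prev <- c(prev, i)
    }
  }
  shares / length(all_p)
}

# direct ordinary-kriging solve for a single target: build the augmented
# system explicitly and invert it
direct_krige <- function(xy, z, model, target) {
  n <- nrow(xy)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    A[i, j] <- if (h > 0) semivariance(model, h) else 0
  }
  A[n + 1, 1:n] <- 1; A[1:n, n + 1] <- 1
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    h <- sqrt(sum((xy[i, ] - target)^2))
    b[i] <- if (h > 0) semivariance(model, h) else 0
  }
  b[n + 1] <- 1
  w <- solve(A, b)
  sum(w[1:n] * z)
}

# exact draw from a Gaussian random field with a spherical-variogram
# covariance (sill - semivariance), via Cholesky
gp_draw_spherical <- function(xy, nugget, psill, range_) {
  n <- nrow(xy)
  H <- as.matrix(dist(xy))
  model <- list(family = "spherical", nugget = 0, psill = psill, range = range_)
  C <- psill - semivariance(model, H)
  diag(C) <- psill + nugget
  L <- chol(C + diag(1e-10, n))
  as.vector(t(L) %*% rnorm(n))
}
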