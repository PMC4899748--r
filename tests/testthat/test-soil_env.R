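test_that("empirical variogram: hand cases and white-noise expectation", {
  # constant field -> gamma 0 everywhere
  set.seed(1)
  s <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100), v = 5)
  ev <- empirical_variogram(s, "v", n_bins = 5)
  expect_equal(ev$gamma, rep(0, nrow(ev)))

  # two samples, values 0 and 2, one bin -> gamma = 0.5*(0-2)^2 = 2
  s2 <- data.frame(x = c(0, 10), y = c(0, 0), v = c(0, 2))
  expect_warning(ev2 <- empirical_variogram(s2, "v", n_bins = 1, max_lag = 20),
                 "fewer than 10")
  expect_equal(ev2$gamma, 2)
  expect_equal(ev2$n_pairs, 1L)

  # iid noise: E[gamma(h)] = sigma^2 at all lags
  set.seed(2)
  sn <- data.frame(x = runif(400, 0, 100), y = runif(400, 0, 100),
                   v = rnorm(400, sd = 3))
  evn <- empirical_variogram(sn, "v", n_bins = 8)
  expect_equal(evn$gamma, rep(9, 8), tolerance = 0.15)

  expect_error(empirical_variogram(s2[1, ], "v"), "at least 2")
})

test_that("variogram fitting recovers parameters and flags degeneracy", {
  # noiseless binned semivariances from a known spherical model
  true <- list(family = "spherical", nugget = 0.1, psill = 1.0, range = 60)
  h <- seq(5, 120, by = 5)
  emp <- structure(data.frame(h = h, gamma = semivariance(true, h),
                              n_pairs = rep(50L, length(h))),
                   class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 0.01)
  expect_equal(fit$psill, 1.0, tolerance = 0.01)
  expect_equal(fit$range, 60, tolerance = 0.6)

  # exponential family round-trip
  true_e <- list(family = "exponential", nugget = 0.05, psill = 2, range = 40)
  emp_e <- structure(data.frame(h = h, gamma = semivariance(true_e, h),
                                n_pairs = rep(50L, length(h))),
                     class = c("empirical_variogram", "data.frame"))
  fit_e <- fit_variogram(emp_e, "exponential")
  expect_equal(fit_e$psill, 2, tolerance = 0.05)

  # flat variogram -> range at bound with warning
  flat <- structure(data.frame(h = h, gamma = rep(1, length(h)),
                               n_pairs = rep(50L, length(h))),
                    class = c("empirical_variogram", "data.frame"))
  expect_warning(fit_variogram(flat), "upper bound")

  expect_error(fit_variogram(emp[1, ]), "at least 3")
})

test_that("ordinary kriging is exact, unbiased, and matches a direct solve", {
  model <- list(family = "spherical", nugget = 0.05, psill = 1, range = 50)
  set.seed(4)
  xy <- data.frame(x = runif(25, 0, 100), y = runif(25, 0, 100))
  z <- sin(xy$x / 20) + cos(xy$y / 30)

  # exactness at a sample location
  kr <- ordinary_krige(xy, z, model, xy[3, , drop = FALSE],
                       return_weights = TRUE)
  expect_equal(kr$pred, z[3], tolerance = 1e-8)
  expect_equal(colSums(kr$weights), 1, ignore_attr = TRUE, tolerance = 1e-10)

  # weights sum to 1 at arbitrary targets
  tg <- data.frame(x = runif(10, 0, 100), y = runif(10, 0, 100))
  kr2 <- ordinary_krige(xy, z, model, tg, return_weights = TRUE)
  expect_equal(unname(colSums(kr2$weights)), rep(1, 10), tolerance = 1e-10)

  # 3-sample configurations vs the brute-force augmented 4x4 solve
  for (rep_i in 1:10) {
    xy3 <- matrix(runif(6, 0, 80), 3, 2)
    z3 <- rnorm(3)
    tgt <- runif(2, 0, 80)
    got <- ordinary_krige(data.frame(x = xy3[, 1], y = xy3[, 2]), z3, model,
                          data.frame(x = tgt[1], y = tgt[2]))
    expect_equal(got$pred, direct_krige(xy3, z3, model, tgt), tolerance = 1e-9)
  }

  # constant field -> constant prediction
  krc <- ordinary_krige(xy, rep(7, 25), model, tg)
  expect_equal(krc$pred, rep(7, 10))

  # duplicated locations averaged with a warning
  xyd <- rbind(xy, xy[1, ]); zd <- c(z, z[1] + 2)
  expect_warning(krd <- ordinary_krige(xyd, zd, model, tg), "duplicate")
  expect_true(all(is.finite(krd$pred)))
})

test_that("soil PCA: orientation, variance fractions, exact reconstruction", {
  set.seed(6)
  n <- 120
  shared <- rnorm(n)
  x <- data.frame(total_n = shared + rnorm(n, sd = 0.3),
                  organic_matter = shared + rnorm(n, sd = 0.3),
                  water_content = shared + rnorm(n, sd = 0.3),
                  ph = -0.5 * shared + rnorm(n, sd = 0.5),
                  total_k = rnorm(n))
  p <- soil_pca(x)
  expect_equal(sum(p$var_fraction), 1)
  expect_true(mean(p$loadings[c("total_n", "organic_matter", "water_content"), 1]) > 0)
  # flipping the sign of every input flips nothing after orientation
  p2 <- soil_pca(-x, orient_positive = c("total_n", "organic_matter",
                                         "water_content"))
  expect_equal(abs(p2$loadings[, 1]), abs(p$loadings[, 1]), tolerance = 1e-10)
  # scores are uncorrelated and reconstruction from all PCs is exact
  cc <- cor(p$scores)
  expect_equal(cc, diag(ncol(cc)), ignore_attr = TRUE, tolerance = 1e-8)
  recon <- p$scores %*% t(p$loadings)
  zx <- scale(as.matrix(x))
  expect_equal(unname(recon), unname(zx[, colnames(x)]), tolerance = 1e-10,
               ignore_attr = TRUE)
  x$dead <- 1
  expect_error(soil_pca(x), "dead")
})

test_that("two perfectly correlated variables load equally on PC1", {
  set.seed(7)
  v <- rnorm(50)
  x <- data.frame(a = v, b = 2 * v + 3)   # perfectly correlated pair
  p <- soil_pca(x, orient_positive = "a")
  expect_equal(p$var_fraction[1], 1)
  expect_equal(abs(p$loadings["a", 1]), abs(p$loadings["b", 1]), tolerance = 1e-12)
})

test_that("krige_soil interpolates all nine properties to quadrat centres", {
  cfg <- synthetic_config(plot_width = 200, plot_height = 200, seed = 3,
                          soil_grid_spacing = 25)
  soils <- generate_soil_samples(cfg)
  g <- plot_grid(200, 200, 20)
  # a 200 m world can leave some property variograms flat; that warning is
  # exercised elsewhere
  suppressWarnings(ks <- krige_soil(soils$samples, g))
  expect_equal(nrow(ks$table), 100)
  expect_true(all(!is.na(as.matrix(ks$table))))
  expect_length(ks$models, 9)
  expect_error(krige_soil(soils$samples[, 1:4], g), "lack column")
})
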