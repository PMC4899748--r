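# A small config keeps generator unit tests fast; the acceptance suite
# exercises the default (400 x 500 m) world.
small_cfg <- function(...) {
  synthetic_config(plot_width = 200, plot_height = 200, n_species = 20, ...)
}

test_that("terrain generation: determinism, flatness, single-hill shape", {
  cfg <- small_cfg(seed = 31)
  t1 <- generate_terrain(cfg)
  t2 <- generate_terrain(cfg)
  expect_identical(t1$corner, t2$corner)        # bit-identical under a seed
  expect_identical(t1$center, t2$center)

  flat <- small_cfg(n_hills = 0, terrain_noise = 0, seed = 31)
  tf <- generate_terrain(flat)
  expect_equal(max(tf$corner) - min(tf$corner), 0)
  expect_equal(unique(as.vector(tf$center)), mean(flat$elevation_range))

  # altitudes within the configured range
  expect_true(all(t1$corner >= cfg$elevation_range[1] - 1e-9))
  expect_true(all(t1$corner <= cfg$elevation_range[2] + 1e-9))

  # one central hill: altitude decays monotonically along a ray from the
  # summit (radial ordering across angles mixes slightly different corner
  # means, so the clean statement is per-ray)
  g <- plot_grid(200, 200, 20)
  one <- make_elevation(g, function(x, y)
    300 + 80 * exp(-((x - 100)^2 + (y - 100)^2) / (2 * 60^2)))
  alt <- quadrat_altitude(one)
  ctr <- quadrat_centers(g)
  row5 <- alt$altitude[ctr$y == 90]      # the row straddling the summit
  right <- row5[ctr$x[ctr$y == 90] >= 100]
  expect_true(all(diff(right) < 0))
  expect_true(all(diff(rev(row5[ctr$x[ctr$y == 90] < 100])) < 0))
})

test_that("soil samples: lattice + satellites at the prescribed offsets", {
  cfg <- small_cfg(seed = 32)
  so <- generate_soil_samples(cfg)
  s <- so$samples
  base <- s[s$kind == "base", ]
  sat <- s[s$kind == "satellite", ]
  nb <- length(seq(15, 200 - 1e-9, by = 30))^2
  expect_equal(nrow(base), nb)
  expect_equal(nrow(s), 3 * nb)               # count oracle

  # each satellite sits at 2, 5 or 15 m from its base point unless clipped
  bx <- rep(base$x, each = 2); by <- rep(base$y, each = 2)
  d <- sqrt((sat$x - bx)^2 + (sat$y - by)^2)
  clipped <- sat$x <= 0 | sat$x >= 200 - 1e-5 | sat$y <= 0 | sat$y >= 200 - 1e-5
  expect_true(all(abs(outer(d[!clipped], c(2, 5, 15), "-")) < 1e-9 |
                    sapply(d[!clipped], function(di) min(abs(di - c(2, 5, 15))) < 1e-9)))
  expect_true(all(vapply(d[!clipped],
                         function(di) min(abs(di - c(2, 5, 15))) < 1e-9,
                         logical(1))))

  # zero kernels + zero noise -> all samples identical
  cfg0 <- small_cfg(soil_n_kernels = 0, soil_noise = 0, seed = 32)
  s0 <- generate_soil_samples(cfg0)$samples
  for (p in c("total_n", "ph", "organic_matter"))
    expect_equal(length(unique(s0[[p]])), 1L)

  # planted one-factor structure: property correlations ~ l_p * l_q
  cfgf <- synthetic_config(seed = 33, soil_grid_spacing = 20)
  sf <- generate_soil_samples(cfgf)$samples
  props <- default_soil_properties()
  cr <- cor(sf[, props$property])
  expect_gt(cr["total_n", "organic_matter"], 0.4)
  expect_lt(cr["ph", "total_n"], -0.2)
})

test_that("species pool: lognormal marginals with configured log correlations", {
  idc <- diag(5); dimnames(idc) <- dimnames(default_trait_corr())
  cfg_id <- synthetic_config(n_species = 2000, trait_corr = idc, seed = 34)
  pool <- generate_species_pool(cfg_id)
  lg <- log(as.matrix(pool[, c("la", "sla", "ldmc", "wd", "max_dbh")]))
  off <- cor(lg)[upper.tri(diag(5))]
  expect_true(all(abs(off) < 4 / sqrt(2000) + 0.02))

  R <- default_trait_corr(); R["sla", "ldmc"] <- R["ldmc", "sla"] <- -0.7
  cfg_c <- synthetic_config(n_species = 2000, trait_corr = R, seed = 35)
  lg2 <- log(as.matrix(generate_species_pool(cfg_c)[,
            c("la", "sla", "ldmc", "wd", "max_dbh")]))
  expect_equal(cor(lg2)["sla", "ldmc"], -0.7, tolerance = 0.05)

  one <- synthetic_config(n_species = 1, seed = 36)
  expect_equal(nrow(generate_species_pool(one)), 1)

  badR <- matrix(1, 5, 5); dimnames(badR) <- dimnames(idc)
  expect_error(synthetic_config(trait_corr = badR), "positive definite")
})

test_that("stem map: determinism, bounds, DBH truncation, ground truth", {
  cfg <- small_cfg(seed = 37)
  terr <- generate_terrain(cfg)
  soil <- generate_soil_samples(cfg)
  pool <- generate_species_pool(cfg)
  sm1 <- generate_stem_map(terr, soil$fertility_centers, pool, cfg)
  sm2 <- generate_stem_map(terr, soil$fertility_centers, pool, cfg)
  expect_identical(sm1$stems, sm2$stems)

  st <- sm1$stems
  expect_true(all(st$x >= 0 & st$x < 200 & st$y >= 0 & st$y < 200))
  maxd <- pool$max_dbh[match(st$species_id, pool$species_id)]
  expect_true(all(st$dbh >= 1 & st$dbh <= maxd + 1e-9))
  # quadrat ids agree with coordinates
  expect_equal(st$quadrat_id,
               floor(st$x / 20) + 10 * floor(st$y / 20))

  gt <- sm1$ground_truth
  expect_equal(unname(gt$beta_conv),
               unname(cfg$beta_conv * scale(log(pool$wd))[, 1]))
  expect_equal(gt$expected_signs$cwm_vs_convexity, "+")

  # null effects: beta vectors all zero
  cfg0 <- small_cfg(beta_conv = 0, beta_fert = 0, seed = 37)
  sm0 <- generate_stem_map(terr, soil$fertility_centers, pool, cfg0)
  expect_true(all(sm0$ground_truth$beta_conv == 0))
  expect_equal(sm0$ground_truth$expected_signs$cwm_vs_convexity, "0")
})

test_that("simulate_plot is reproducible end to end and writes the bundle", {
  cfg <- small_cfg(seed = 38)
  s1 <- simulate_plot(cfg)
  s2 <- simulate_plot(cfg)
  expect_identical(s1$stems, s2$stems)
  expect_identical(s1$soil_samples, s2$soil_samples)
  expect_identical(s1$traits, s2$traits)

  dir <- withr::local_tempdir()
  write_synthetic_plot(s1, dir)
  expect_setequal(list.files(dir),
                  c("stems.csv", "traits.csv", "elevation_corners.csv",
                    "elevation_centers.csv", "soil_samples.csv",
                    "ground_truth.json"))
  g <- s1$grid
  rt <- read_stem_table(file.path(dir, "stems.csv"), g)
  expect_equal(nrow(rt), nrow(s1$stems))
})
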