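test_that("pearson table: identities, exact t-distribution p, star coding", {
  set.seed(41)
  d <- data.frame(x = rnorm(40))
  d$xx <- d$x
  d$neg <- -d$x
  d$z <- rnorm(40)
  pt1 <- pearson_table(d, c("x", "xx", "neg", "z"))
  get <- function(a, b) pt1[pt1$var1 == a & pt1$var2 == b, ]
  expect_equal(get("x", "xx")$r, 1)
  expect_equal(get("x", "neg")$r, -1)
  # p-values match the exact t CDF (independent oracle: cor.test)
  ct <- cor.test(d$x, d$z)
  expect_equal(get("x", "z")$r, unname(ct$estimate))
  expect_equal(get("x", "z")$p, ct$p.value)
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
  d$const <- 1
  expect_error(pearson_table(d, c("x", "const")), "zero-variance")
  expect_error(pearson_table(d[1:2, ], c("x", "z")), "at least 3")
})

test_that("pearson r estimates a planted correlation within Fisher-z bounds", {
  set.seed(42)
  n <- 500; rho <- 0.5
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  r <- pearson_table(data.frame(x = x, y = y), "x", "y")$r
  expect_equal(r, 0.5, tolerance = 0.08 / 0.5)  # +-0.08 absolute
})

test_that("stepwise OLS: signal retained, planted support recovered", {
  set.seed(43)
  n <- 500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  for (k in 1:5) d[[paste0("noise", k)]] <- rnorm(n)
  d$y <- 2 * d$x1 - d$x2 + rnorm(n, sd = 0.3)
  fit <- stepwise_ols("y", setdiff(names(d), "y"), d)
  expect_setequal(fit$retained, c("x1", "x2"))
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 0.05)
  expect_lte(fit$adj_r_squared, fit$r_squared)
  expect_equal(fit$aic, AIC(fit$model))

  # single informative candidate is kept
  d2 <- data.frame(x = rnorm(100))
  d2$y <- d2$x + rnorm(100, sd = 0.5)
  expect_equal(stepwise_ols("y", "x", d2)$retained, "x")

  # aliased column dropped with warning
  d$dup <- d$x1
  expect_warning(fitd <- stepwise_ols("y", c("x1", "dup", "x2"), d), "alias")
  expect_setequal(fitd$retained, c("x1", "x2"))
})

test_that("null stepwise models stay approximately intercept-only", {
  # AIC-based entry admits a pure-noise regressor with p ~ 0.157 each, so
  # exact intercept-only is not the >=90% event; near-null fits are
  set.seed(44)
  reps <- 50
  ok <- logical(reps)
  for (i in seq_len(reps)) {
    d <- as.data.frame(matrix(rnorm(500 * 5), 500, 5))
    names(d) <- paste0("n", 1:5)
    d$y <- rnorm(500)
    f <- stepwise_ols("y", paste0("n", 1:5), d)
    ok[i] <- f$adj_r_squared < 0.02 && length(f$retained) <= 2
  }
  expect_gte(mean(ok), 0.9)
})

test_that("LMG shares: identities and brute-force ordering enumeration", {
  set.seed(45)
  n <- 300
  # orthogonal designs: share_i equals the marginal R^2 (centre first so
  # orthogonality holds for covariances, not just cross-products)
  X <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)))
  d <- data.frame(X); names(d) <- c("a", "b", "c")
  d$y <- 1.5 * d$a - 1 * d$b + 0.5 * d$c + rnorm(n, sd = 0.5)
  lm_ <- lmg_partition("y", c("a", "b", "c"), d)
  marg <- vapply(c("a", "b", "c"),
                 function(v) summary(lm(reformulate(v, "y"), d))$r.squared,
                 numeric(1))
  expect_equal(lm_$shares, marg, tolerance = 1e-10)
  expect_equal(sum(lm_$shares), lm_$r_squared, tolerance = 1e-10)

  # duplicated regressors split their contribution equally
  d$b2 <- d$b + rnorm(n, sd = 1e-8)
  lm2 <- lmg_partition("y", c("b", "b2"), d)
  expect_equal(unname(lm2$shares["b"]), unname(lm2$shares["b2"]),
               tolerance = 1e-4)

  # correlated 4-regressor fixture vs enumeration of all 24 orderings
  S <- matrix(0.5, 4, 4); diag(S) <- 1
  Z <- MASS::mvrnorm(n, rep(0, 4), S)
  colnames(Z) <- paste0("v", 1:4)
  dz <- as.data.frame(Z)
  dz$y <- Z %*% c(1, -0.5, 0.25, 0) + rnorm(n)
  got <- lmg_partition("y", paste0("v", 1:4), dz)
  oracle <- perm_lmg(dz$y, Z)
  expect_equal(got$shares, oracle, tolerance = 1e-10)
  # permutation invariance of input order
  got_rev <- lmg_partition("y", rev(paste0("v", 1:4)), dz)
  expect_equal(got_rev$shares[names(got$shares)], got$shares, tolerance = 1e-12)

  # groups subtotal
  gr <- c(v1 = "g1", v2 = "g1", v3 = "g2", v4 = "g2")
  gshare <- lmg_partition("y", paste0("v", 1:4), dz, groups = gr)$group_shares
  expect_equal(sum(gshare), got$r_squared, tolerance = 1e-10)

  expect_error(lmg_partition("y", rep(paste0("v", 1:4), 4)[1:13], dz), "12")
})

test_that("path model specification enforces acyclicity", {
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"))
  m <- path_model(edges)
  expect_equal(m$exogenous, "a")
  expect_setequal(m$endogenous, c("b", "c"))
  expect_error(path_model(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "cyclic")
})

test_that("saturated path model: chi-square 0, df 0, AIC = 2t", {
  set.seed(46)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$m <- 0.5 * d$x1 - 0.3 * d$x2 + rnorm(n, sd = 0.7)
  d$y <- 0.4 * d$x1 + 0.5 * d$m + rnorm(n, sd = 0.6)
  sat <- path_model(rbind(
    data.frame(from = c("x1", "x2"), to = "m"),
    data.frame(from = c("x1", "x2", "m"), to = "y")))
  fit <- fit_path_model(sat, d)
  # t = 5 paths + 2 exog var + 1 exog cov + 2 error var = 10 = p(p+1)/2
  expect_equal(fit$t, 10)
  expect_equal(fit$df, 0)
  expect_equal(fit$chisq, 0, tolerance = 1e-8)
  expect_equal(fit$aic, 2 * fit$t, tolerance = 1e-8)
  expect_equal(fit$implied, fit$observed, tolerance = 1e-10)

  # dropping a path can only increase chi-square
  m1 <- path_model(rbind(
    data.frame(from = c("x1", "x2"), to = "m"),
    data.frame(from = c("x1", "m"), to = "y")))
  expect_gte(fit_path_model(m1, d)$chisq, 0)
  expect_equal(fit_path_model(m1, d)$df, 1)
})

test_that("standardized path coefficients recover a known model", {
  set.seed(47)
  n <- 5000
  # standardized truth: x1, x2 exogenous (r = 0.3)
  x <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.3, 0.3, 1), 2))
  b_m <- c(0.5, -0.4)
  vm <- 1 - (t(b_m) %*% matrix(c(1, 0.3, 0.3, 1), 2) %*% b_m)
  m <- x %*% b_m + rnorm(n, sd = sqrt(vm))
  y <- 0.3 * x[, 1] + 0.5 * m + rnorm(n, sd = 0.6)
  d <- data.frame(x1 = x[, 1], x2 = x[, 2], m = as.vector(m), y = as.vector(y))
  mod <- path_model(rbind(
    data.frame(from = c("x1", "x2"), to = "m"),
    data.frame(from = c("x1", "m"), to = "y")))
  fit <- fit_path_model(mod, d)
  co <- fit$paths
  expect_equal(co$coefficient[co$from == "x1" & co$to == "m"], 0.5,
               tolerance = 0.05)
  expect_equal(co$coefficient[co$from == "x2" & co$to == "m"], -0.4,
               tolerance = 0.06)
  expect_true(all(fit$r_squared > 0 & fit$r_squared < 1))
  expect_error(fit_path_model(mod, d[1:3, ]), "N >")
})

test_that("pruning removes exactly the planted noise path, deterministically", {
  set.seed(48)
  n <- 800
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), irr = rnorm(n))
  d$m <- 0.6 * d$x1 + rnorm(n, sd = 0.8)
  d$y <- 0.5 * d$m + 0.4 * d$x2 + rnorm(n, sd = 0.7)
  edges <- rbind(
    data.frame(from = c("x1", "x2"), to = "m"),
    data.frame(from = c("x1", "x2", "m", "irr"), to = "y"))
  pr <- prune_path_model(path_model(edges), d, alpha = 0.05)
  kept <- paste(pr$model$edges$from, pr$model$edges$to)
  expect_true(all(c("x1 m", "x2 y", "m y") %in% kept))
  expect_false("irr y" %in% kept)
  expect_true(all(pr$fit$paths$p < 0.05))
  # deterministic trace under fixed data
  pr2 <- prune_path_model(path_model(edges), d, alpha = 0.05)
  expect_identical(pr$trace, pr2$trace)

  # an all-significant model is a fixed point
  pr3 <- prune_path_model(pr$model, d, alpha = 0.05)
  expect_equal(nrow(pr3$trace), 0)
  expect_identical(pr3$model$edges, pr$model$edges)
})

test_that("SEM fit-statistic conventions and AIC identity", {
  fs <- sem_fit_stats(1.7, df = 4, t = 11)
  expect_equal(fs$aic, 1.7 + 22)
  expect_equal(fs$p_value, pchisq(1.7, 4, lower.tail = FALSE))
  # t deduced from p_obs: p(p+1)/2 - df
  fs2 <- sem_fit_stats(1.7, df = 4, p_obs = 5)
  expect_equal(fs2$t, 11)
  expect_error(sem_fit_stats(1, df = 2), "either")
})
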