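#' Significance stars
#'
#' `***`, `**`, `*` at p < 0.001, 0.01, 0.05; empty otherwise.
#' @param p p-value(s).
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pearson correlation table
#'
#' Pearson r with two-sided p-values from the exact t distribution with
#' N - 2 degrees of freedom, for every pair of one variable from `vars_x`
#' and one from `vars_y` (default: all pairs within `vars_x`).  Rows with
#' any missing value across the requested variables are dropped casewise.
#'
#' @param data data.frame of quadrat-level variables.
#' @param vars_x,vars_y character vectors of column names.
#' @return data.frame `var1`, `var2`, `r`, `p`, `stars`, `n` of class
#'   `correlation_table`.
#' @export
pearson_table <- function(data, vars_x, vars_y = NULL) {
  vars <- unique(c(vars_x, vars_y))
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0)
    stop("variable(s) not in data: ", paste(missing, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  n <- nrow(d)
  if (n < 3) stop("need at least 3 complete quadrats")
  sds <- vapply(d, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance variable(s): ", paste(vars[sds == 0], collapse = ", "))
  if (is.null(vars_y)) {
    pairs <- t(utils::combn(vars_x, 2))
  } else {
    pairs <- as.matrix(expand.grid(var1 = vars_x, var2 = vars_y,
                                   stringsAsFactors = FALSE))
  }
  r <- vapply(seq_len(nrow(pairs)),
              function(i) stats::cor(d[[pairs[i, 1]]], d[[pairs[i, 2]]]),
              numeric(1))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  out <- data.frame(var1 = pairs[, 1], var2 = pairs[, 2], r = r, p = p,
                    stars = significance_stars(p), n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Bidirectional AIC-stepwise linear regression
#'
#' Stepwise search in both directions starting from the intercept-only
#' model, minimising AIC (`k = 2`), over the candidate regressors.
#' Deterministic given the data.  Aliased (rank-deficient) candidates are
#' dropped with a warning before the search.
#'
#' @param response response column name.
#' @param candidates candidate regressor column names.
#' @param data data.frame; rows with missing values in the used columns
#'   are dropped casewise.
#' @return list of class `stepwise_fit`: `formula` (character),
#'   `coefficients` (named, incl. intercept), `retained`, `r_squared`,
#'   `adj_r_squared`, `aic` (stats::AIC of the final model), `n`, `model`
#'   (the `lm`).
#' @export
stepwise_ols <- function(response, candidates, data) {
  vars <- c(response, candidates)
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0)
    stop("variable(s) not in data: ", paste(missing, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  if (nrow(d) <= length(candidates) + 2)
    stop("need N > number of candidates + 2")
  full <- stats::lm(stats::reformulate(candidates, response), data = d)
  alias <- is.na(stats::coef(full))
  if (any(alias)) {
    drop <- names(stats::coef(full))[alias]
    warning("dropping aliased candidate(s): ", paste(drop, collapse = ", "))
    candidates <- setdiff(candidates, drop)
  }
  null <- stats::lm(stats::reformulate("1", response), data = d)
  fit <- stats::step(null, scope = list(
    lower = stats::reformulate("1", response),
    upper = stats::reformulate(candidates, response)),
    direction = "both", trace = 0, k = 2)
  sm <- summary(fit)
  retained <- setdiff(names(stats::coef(fit)), "(Intercept)")
  structure(list(
    formula = paste(deparse(stats::formula(fit)), collapse = ""),
    coefficients = stats::coef(fit),
    retained = retained,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    aic = stats::AIC(fit),
    n = nrow(d),
    model = fit), class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(x$formula, "\n  adj R^2 =", signif(x$adj_r_squared, 3),
      " AIC =", round(x$aic, 2), " N =", x$n, "\n")
  invisible(x)
}

# R^2 of the regression of y on the subset S, from the joint covariance
.r2_subset <- function(C, yi, S) {
  if (length(S) == 0) return(0)
  as.numeric(C[yi, S, drop = FALSE] %*%
               solve(C[S, S, drop = FALSE], C[S, yi, drop = FALSE])) / C[yi, yi]
}

#' LMG hierarchical partitioning of regression R-squared
#'
#' Decomposes the full-model R^2 into nonnegative per-regressor shares by
#' averaging each regressor's sequential R^2 increment over all orderings
#' of the regressors (computed by exact enumeration of all subsets, so at
#' most 12 regressors).  Shares sum to the full model's R^2.  Optional
#' regressor groups (e.g. environment / dominance / diversity) give
#' component subtotals.
#'
#' @param response response column name.
#' @param regressors regressor column names (<= 12).
#' @param data data.frame (complete cases over used columns).
#' @param groups optional named character vector mapping regressor ->
#'   group label.
#' @return list of class `lmg_decomposition`: `shares` (named, summing to
#'   R^2), `proportions` (shares / R^2), `r_squared`, `group_shares`
#'   (or NULL), `n`.
#' @export
lmg_partition <- function(response, regressors, data, groups = NULL) {
  p <- length(regressors)
  if (p > 12)
    stop("exact LMG enumeration supports at most 12 regressors; ",
         "reduce the model (a sampling variant is out of scope)")
  vars <- c(response, regressors)
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  n <- nrow(d)
  C <- stats::cov(d)
  if (any(diag(C) == 0)) stop("zero-variance variable in LMG inputs")
  qrX <- qr(as.matrix(d[, regressors, drop = FALSE]))
  if (qrX$rank < p) stop("rank-deficient design; remove collinear regressors")
  # enumerate subsets as bitmasks; cache R^2 per subset
  r2 <- numeric(2^p)
  for (m in 1:(2^p - 1)) {
    S <- regressors[bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0]
    r2[m + 1] <- .r2_subset(C, response, S)
  }
  wfac <- factorial(0:(p - 1)) * factorial(p - 1:p) / factorial(p)
  shares <- stats::setNames(numeric(p), regressors)
  for (i in seq_len(p)) {
    bit_i <- bitwShiftL(1, i - 1)
    for (m in 0:(2^p - 1)) {
      if (bitwAnd(m, bit_i) > 0) next
      k <- sum(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0)
      shares[i] <- shares[i] + wfac[k + 1] * (r2[bitwOr(m, bit_i) + 1] - r2[m + 1])
    }
  }
  full_r2 <- r2[2^p]
  group_shares <- NULL
  if (!is.null(groups)) {
    g <- groups[regressors]
    group_shares <- tapply(shares, g, sum)
  }
  structure(list(shares = shares, proportions = shares / full_r2,
                 r_squared = full_r2, group_shares = group_shares, n = n),
            class = "lmg_decomposition")
}

#' Specify a recursive path model
#'
#' Directed edges among observed variables; the graph must be acyclic
#' (recursive).  Exogenous variables (no incoming edge) carry free
#' variances and, by default, free pairwise covariances (the
#' double-headed arrows of a path diagram).  Endogenous variables carry
#' free error variances; optional correlated errors can be declared for
#' pairs of endogenous variables.
#'
#' @param edges data.frame with character columns `from`, `to`.
#' @param error_cov optional data.frame `a`, `b` of endogenous pairs with
#'   free error covariance.
#' @param variables optional full variable set (defaults to those in
#'   `edges`).
#' @return list of class `path_model` with `variables`, `edges`,
#'   `error_cov`, `exogenous`, `endogenous`, `order` (a topological
#'   ordering).
#' @export
path_model <- function(edges, error_cov = NULL, variables = NULL) {
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to), stringsAsFactors = FALSE)
  if (is.null(variables)) variables <- unique(c(edges$from, edges$to))
  endo <- unique(edges$to)
  exo <- setdiff(variables, endo)
  # Kahn topological sort to certify acyclicity
  remaining <- variables
  E <- edges
  topo <- character(0)
  while (length(remaining) > 0) {
    src <- setdiff(remaining, E$to)
    if (length(src) == 0) stop("path model is cyclic; a recursive (acyclic) graph is required")
    topo <- c(topo, src)
    remaining <- setdiff(remaining, src)
    E <- E[!(E$from %in% src), , drop = FALSE]
  }
  if (!is.null(error_cov)) {
    error_cov <- data.frame(a = as.character(error_cov$a),
                            b = as.character(error_cov$b),
                            stringsAsFactors = FALSE)
    if (!all(c(error_cov$a, error_cov$b) %in% endo))
      stop("error covariances may only link endogenous variables")
  }
  structure(list(variables = variables, edges = edges, error_cov = error_cov,
                 exogenous = exo, endogenous = endo, order = topo),
            class = "path_model")
}

#' Count of free parameters of a path model
#'
#' Paths + exogenous variances and covariances + endogenous error
#' variances + declared error covariances.
#' @param model a [path_model()].
#' @return integer t.
#' @export
path_free_parameters <- function(model) {
  ne <- length(model$exogenous)
  nrow(model$edges) + ne * (ne + 1) / 2 + length(model$endogenous) +
    if (is.null(model$error_cov)) 0L else nrow(model$error_cov)
}

#' Chi-square fit statistics from model and sample covariance
#'
#' `F = log det(Sigma_hat) - log det(S) + tr(S Sigma_hat^-1) - p`;
#' `chisq = (N - 1) F`; `P` is the upper tail of the chi-square with
#' `df = p(p+1)/2 - t`; `AIC = chisq + 2 t`.
#'
#' @param chisq chi-square statistic.
#' @param df model degrees of freedom.
#' @param t number of free parameters; alternatively give `p_obs` (number
#'   of observed variables) and `t` is deduced as `p(p+1)/2 - df`.
#' @param p_obs number of observed variables (optional, see `t`).
#' @return list `chisq`, `df`, `t`, `p_value`, `aic`.
#' @export
sem_fit_stats <- function(chisq, df, t = NULL, p_obs = NULL) {
  if (is.null(t)) {
    if (is.null(p_obs)) stop("give either t or p_obs")
    t <- p_obs * (p_obs + 1) / 2 - df
  }
  list(chisq = chisq, df = df, t = t,
       p_value = stats::pchisq(chisq, df = df, lower.tail = FALSE),
       aic = chisq + 2 * t)
}

#' Fit a recursive path model
#'
#' Estimation by per-equation ordinary least squares on z-scored
#' variables (maximum-likelihood-equivalent for recursive models with
#' independent errors); coefficients are therefore standardized.  The
#' model-implied covariance is assembled by path tracing,
#' `Sigma_hat = (I - B)^-1 Psi (I - B)^-T`, with the exogenous block of
#' `Psi` free (set to its observed value) and error (co)variances from the
#' residuals.  Fit: `chisq = (N - 1) * (log det Sigma_hat - log det S +
#' tr(S Sigma_hat^-1) - p)` with `df = p(p+1)/2 - t` and
#' `AIC = chisq + 2 t`.
#'
#' @param model a [path_model()].
#' @param data data.frame containing all model variables (complete cases
#'   used).
#' @return list of class `path_fit`: `paths` (data.frame `from`, `to`,
#'   `coefficient`, `se`, `p`), `r_squared` (per endogenous variable),
#'   `chisq`, `df`, `t`, `p_value`, `aic`, `n`, `implied`, `observed`,
#'   `model`.
#' @export
fit_path_model <- function(model, data) {
  stopifnot(inherits(model, "path_model"))
  vars <- model$variables
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0)
    stop("variable(s) not in data: ", paste(missing, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  n <- nrow(d)
  p <- length(vars)
  if (n <= p) stop("need N > number of observed variables")
  z <- as.data.frame(scale(d))
  S <- stats::cov(z)
  if (!all(is.finite(S)) || abs(det(S)) < 1e-300)
    stop("singular or degenerate sample covariance")

  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  exo <- model$exogenous
  Psi[exo, exo] <- S[exo, exo]
  paths <- model$edges
  paths$coefficient <- NA_real_; paths$se <- NA_real_; paths$p <- NA_real_
  r2 <- stats::setNames(numeric(length(model$endogenous)), model$endogenous)
  resid <- matrix(NA_real_, n, p, dimnames = list(NULL, vars))
  for (v in model$endogenous) {
    parents <- paths$from[paths$to == v]
    fit <- stats::lm(stats::reformulate(parents, v), data = z)
    cf <- summary(fit)$coefficients
    for (pa in parents) {
      i <- which(paths$to == v & paths$from == pa)
      paths$coefficient[i] <- cf[pa, 1]
      paths$se[i] <- cf[pa, 2]
      paths$p[i] <- cf[pa, 4]
      B[v, pa] <- cf[pa, 1]
    }
    r2[v] <- summary(fit)$r.squared
    resid[, v] <- stats::residuals(fit)
    Psi[v, v] <- sum(resid[, v]^2) / (n - 1)
  }
  if (!is.null(model$error_cov) && nrow(model$error_cov) > 0) {
    for (i in seq_len(nrow(model$error_cov))) {
      a <- model$error_cov$a[i]; b <- model$error_cov$b[i]
      cv <- sum(resid[, a] * resid[, b]) / (n - 1)
      Psi[a, b] <- Psi[b, a] <- cv
    }
  }
  Ainv <- solve(diag(p) - B)
  implied <- Ainv %*% Psi %*% t(Ainv)
  dimnames(implied) <- dimnames(S)
  Fml <- as.numeric(determinant(implied)$modulus -
                      determinant(S)$modulus +
                      sum(diag(S %*% solve(implied))) - p)
  t_free <- path_free_parameters(model)
  df <- p * (p + 1) / 2 - t_free
  chisq <- max((n - 1) * Fml, 0)
  structure(list(paths = paths, r_squared = r2,
                 chisq = chisq, df = df, t = t_free,
                 p_value = if (df > 0)
                   stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
                 aic = chisq + 2 * t_free,
                 n = n, implied = implied, observed = S, model = model),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("path_fit: chi^2 = %.3f, N = %d, d.f. = %d, P = %s, AIC = %.2f\n",
              x$chisq, x$n, x$df,
              if (is.na(x$p_value)) "NA" else sprintf("%.3f", x$p_value),
              x$aic))
  pr <- x$paths
  pr$coefficient <- round(pr$coefficient, 3)
  pr$p <- signif(pr$p, 3)
  print(pr[, c("from", "to", "coefficient", "p")], row.names = FALSE)
  invisible(x)
}

#' Stepwise pruning of a path model
#'
#' Iteratively removes the single directed path with the largest
#' p-value >= `alpha` and refits, until every retained path is
#' significant.  The removal trace is returned.  If every path is removed
#' the empty model is returned with a warning.
#'
#' @param model initial [path_model()].
#' @param data data.frame of observed variables.
#' @param alpha significance threshold (default 0.05).
#' @return list with `model` (final [path_model()]), `fit` (final
#'   [fit_path_model()]), `trace` (data.frame `step`, `from`, `to`, `p`).
#' @export
prune_path_model <- function(model, data, alpha = 0.05) {
  trace <- data.frame(step = integer(0), from = character(0),
                      to = character(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  step_i <- 0
  repeat {
    fit <- fit_path_model(model, data)
    worst <- which.max(fit$paths$p)
    if (length(worst) == 0 || fit$paths$p[worst] < alpha) break
    step_i <- step_i + 1
    trace <- rbind(trace, data.frame(step = step_i,
                                     from = fit$paths$from[worst],
                                     to = fit$paths$to[worst],
                                     p = fit$paths$p[worst],
                                     stringsAsFactors = FALSE))
    keep <- setdiff(seq_len(nrow(model$edges)), worst)
    if (length(keep) == 0) {
      warning("all paths removed during pruning; returning the empty model")
      model <- path_model(model$edges[0, ], error_cov = NULL,
                          variables = model$variables)
      return(list(model = model, fit = NULL, trace = trace))
    }
    # drop error covariances that reference a variable no longer endogenous
    new_edges <- model$edges[keep, , drop = FALSE]
    ec <- model$error_cov
    if (!is.null(ec)) {
      endo <- unique(new_edges$to)
      ec <- ec[ec$a %in% endo & ec$b %in% endo, , drop = FALSE]
      if (nrow(ec) == 0) ec <- NULL
    }
    model <- path_model(new_edges, error_cov = ec,
                        variables = model$variables)
  }
  list(model = model, fit = fit, trace = trace)
}

#' Export a path fit as a Graphviz DOT diagram
#'
#' @param fit a `path_fit`.
#' @param path output `.dot` file.
#' @return `path`, invisibly.
#' @export
write_path_dot <- function(fit, path) {
  stopifnot(inherits(fit, "path_fit"))
  lines <- c("digraph path_model {", "  rankdir=LR;",
             sprintf("  \"%s\";", fit$model$variables))
  for (i in seq_len(nrow(fit$paths))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%.2f%s\", penwidth=%.2f];",
      fit$paths$from[i], fit$paths$to[i], fit$paths$coefficient[i],
      significance_stars(fit$paths$p[i]),
      0.5 + 4 * abs(fit$paths$coefficient[i])))
  }
  ne <- fit$model$exogenous
  if (length(ne) > 1) {
    cmb <- utils::combn(ne, 2)
    for (k in seq_len(ncol(cmb))) {
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [dir=both, style=dashed];", cmb[1, k], cmb[2, k]))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
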