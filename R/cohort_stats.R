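# Cohort inference: propensity matching, multivariate outlier screening,
# MANCOVA (Wilks lambda, Rao's F approximation, partial eta squared,
# observed power, per-metric post-hoc ANCOVA), demographic group tests, and
# noncentral-F MANOVA power / sample-size computation.

smd <- function(x, g) {
  x <- as.numeric(x)
  l <- levels(g)
  m1 <- mean(x[g == l[1]]); m2 <- mean(x[g == l[2]])
  sp <- sqrt((var(x[g == l[1]]) + var(x[g == l[2]])) / 2)
  if (sp == 0) return(0)
  (m1 - m2) / sp
}

as_num_covariate <- function(x) {
  if (is.numeric(x)) x
  else if (is.logical(x)) as.numeric(x)
  else as.numeric(factor(x)) - 1
}

# ridge-penalized logistic IRLS, used when the ML fit separates
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100L) {
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))  # intercept unpenalized
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X * w, z))
    if (max(abs(new - beta)) < 1e-10) { beta <- new; break }
    beta <- new
  }
  as.numeric(X %*% beta)
}

#' Propensity-score matching of a two-group cohort
#'
#' Estimates a logistic-regression propensity score on the stated
#' covariates and performs greedy nearest-neighbor 1:1 matching without
#' replacement: the globally closest remaining pair (on the score) is
#' matched first, with ties broken by subject-id order so the result is
#' deterministic. If the logistic fit separates, a ridge-penalized fit is
#' substituted with a warning.
#'
#' @param cohort Cohort data frame with a two-level `group` column.
#' @param covariates Covariate column names entering the score.
#' @param n_target Number of matched pairs (default: the smaller group
#'   size; requesting more is an error).
#' @return List: `matched` (cohort subset, `n_target` per group), `pairs`,
#'   `smd_before`, `smd_after` (standardized mean differences).
#' @export
propensity_match <- function(cohort,
                             covariates = c("age", "sex", "edss",
                                            "duration", "treatment_naive"),
                             n_target = NULL) {
  g <- factor(cohort$group)
  stopifnot(nlevels(g) == 2L)
  covariates <- intersect(covariates, names(cohort))
  Xd <- as.data.frame(lapply(cohort[covariates], as_num_covariate))
  X <- cbind(1, as.matrix(Xd))
  y <- as.numeric(g) - 1
  ps <- tryCatch({
    fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
    if (!fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
        any(fit$fitted.values < 1e-8))
      stop("separation")
    as.numeric(X %*% coef(fit))
  }, error = function(e) {
    warning("logistic propensity fit separated; using ridge-penalized fit")
    ridge_logistic(X, y)
  })
  n1 <- sum(y == 0); n2 <- sum(y == 1)
  if (is.null(n_target)) n_target <- min(n1, n2)
  if (n_target > min(n1, n2))
    stop("n_target (", n_target, ") exceeds the smaller group size (",
         min(n1, n2), ")")
  i1 <- which(y == 0); i2 <- which(y == 1)
  pairs <- expand.grid(a = i1, b = i2)
  pairs$dist <- abs(ps[pairs$a] - ps[pairs$b])
  pairs <- pairs[order(pairs$dist, cohort$subject_id[pairs$a],
                       cohort$subject_id[pairs$b]), ]
  used <- logical(nrow(cohort))
  keep <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    if (used[a] || used[b]) next
    used[a] <- used[b] <- TRUE
    keep[[length(keep) + 1L]] <- pairs[r, ]
    if (length(keep) == n_target) break
  }
  keep <- do.call(rbind, keep)
  sel <- sort(c(keep$a, keep$b))
  smd_tab <- function(d, gg) vapply(covariates,
                                    function(v) smd(as_num_covariate(d[[v]]), gg),
                                    0)
  list(matched = cohort[sel, , drop = FALSE],
       pairs = data.frame(id_a = cohort$subject_id[keep$a],
                          id_b = cohort$subject_id[keep$b],
                          distance = keep$dist),
       propensity = ps,
       smd_before = smd_tab(cohort, g),
       smd_after = smd_tab(cohort[sel, ], factor(cohort$group[sel])))
}

#' Mahalanobis-distance multivariate outlier screening
#'
#' Computes each subject's squared Mahalanobis distance to the
#' dependent-variable centroid under the pooled sample covariance and
#' excludes, in a single pass, rows whose distance exceeds the chi-square
#' quantile with `length(dv_columns)` degrees of freedom at
#' `1 - alpha_cut` (default p < 0.001).
#'
#' @param cohort Cohort data frame.
#' @param dv_columns Dependent-variable column names.
#' @param alpha_cut Upper-tail probability of the exclusion cutoff.
#' @return List: `cohort` (retained rows), `excluded` (ids and distances),
#'   `d2`, `cutoff`.
#' @export
mahalanobis_screen <- function(cohort, dv_columns, alpha_cut = 0.001) {
  Y <- as.matrix(cohort[dv_columns])
  p <- ncol(Y)
  if (nrow(Y) < p + 2L) stop("need at least p + 2 rows for screening")
  S <- cov(Y)
  kap <- suppressWarnings(kappa(S, exact = TRUE))
  if (!is.finite(kap) || kap > 1e12)
    stop("singular dependent-variable covariance (condition number ",
         format(kap, digits = 4), ")")
  d2 <- mahalanobis(Y, colMeans(Y), S)
  cutoff <- qchisq(1 - alpha_cut, df = p)
  out <- d2 > cutoff
  list(cohort = cohort[!out, , drop = FALSE],
       excluded = data.frame(subject_id = cohort$subject_id[out],
                             d2 = d2[out]),
       d2 = setNames(d2, cohort$subject_id), cutoff = cutoff)
}

# Wilks lambda -> Rao's F approximation
rao_f <- function(lambda, p, q, v) {
  t <- if (p^2 + q^2 - 5 > 0 && p^2 * q^2 - 4 > 0)
    sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * t - (p * q - 2) / 2
  lt <- lambda^(1 / t)
  Fs <- (1 - lt) / lt * df2 / df1
  list(F = Fs, df1 = df1, df2 = df2,
       p = pf(Fs, df1, df2, lower.tail = FALSE))
}

#' Multivariate analysis of covariance for a two-level factor
#'
#' Fits the multivariate linear model `DV ~ covariates + factor`, forms the
#' residual (E) and hypothesis (H) sums-of-squares-and-cross-products
#' matrices for the factor, and tests the factor with Wilks
#' `lambda = det(E) / det(H + E)` via Rao's F approximation. Effect size is
#' partial eta squared `1 - lambda^(1/s)` with
#' `s = min(n_DV, hypothesis df)` (so `1 - lambda` exactly for a two-level
#' factor); observed power uses the noncentral F with noncentrality
#' `F * df1` estimated from the observed statistic (the convention is
#' recorded in the result). Post-hoc per-DV ANCOVAs (factor adjusted for
#' the covariates) and covariate-adjusted group means are reported
#' unadjusted for multiplicity by default.
#'
#' Rows with missing DVs or covariates are excluded with a message; a
#' rank-deficient design is a fatal error naming the aliased columns.
#'
#' @param cohort Cohort data frame.
#' @param dv_columns Dependent-variable column names.
#' @param factor_col Name of the two-level grouping factor.
#' @param covariates Covariate column names (default `c("age", "edss")`;
#'   use `character(0)` for a pure MANOVA).
#' @param posthoc_adjust P-adjustment method for the post-hoc tests
#'   (default `"none"`, optionally e.g. `"holm"`).
#' @param alpha Significance level used by the observed-power computation.
#' @return Object of class `mancova_result`.
#' @export
mancova <- function(cohort, dv_columns, factor_col = "group",
                    covariates = c("age", "edss"),
                    posthoc_adjust = "none", alpha = 0.05) {
  g <- factor(cohort[[factor_col]])
  if (nlevels(g) != 2L)
    stop("factor must have exactly 2 levels, got ", nlevels(g))
  use <- complete.cases(cohort[c(dv_columns, covariates)])
  if (any(!use)) {
    message(sum(!use), " subject(s) excluded for missing values")
    cohort <- cohort[use, , drop = FALSE]
    g <- factor(cohort[[factor_col]])
  }
  Y <- as.matrix(cohort[dv_columns])
  n <- nrow(Y); p <- ncol(Y); q <- 1L
  if (n <= p + length(covariates) + 2L)
    stop("too few subjects (", n, ") for ", p, " DVs and ",
         length(covariates), " covariates")
  Z <- if (length(covariates))
    as.matrix(as.data.frame(lapply(cohort[covariates], as_num_covariate)))
  else NULL
  X <- cbind(`(Intercept)` = 1, Z, group = as.numeric(g) - 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; aliased columns: ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  Bh <- solve(crossprod(X), crossprod(X, Y))
  E <- crossprod(Y - X %*% Bh)
  X0 <- X[, -ncol(X), drop = FALSE]
  B0 <- solve(crossprod(X0), crossprod(X0, Y))
  H <- crossprod(Y - X0 %*% B0) - E
  lambda <- det(E) / det(H + E)
  v <- n - ncol(X)
  rf <- rao_f(lambda, p, q, v)
  s <- min(p, q)
  eta2 <- 1 - lambda^(1 / s)
  ncp <- rf$F * rf$df1
  power <- 1 - pf(qf(1 - alpha, rf$df1, rf$df2), rf$df1, rf$df2, ncp = ncp)
  # post-hoc per-DV ANCOVA: F for the factor adjusted for the covariates
  ph <- lapply(seq_len(p), function(j) {
    rss1 <- sum((Y[, j] - X %*% Bh[, j])^2)
    rss0 <- sum((Y[, j] - X0 %*% B0[, j])^2)
    Fj <- (rss0 - rss1) / (rss1 / v)
    # covariate-adjusted group means: prediction at covariate means
    xm <- colMeans(X)
    adj <- vapply(0:1, function(lev) {
      xx <- xm; xx["group"] <- lev
      sum(xx * Bh[, j])
    }, 0)
    c(F = Fj, p = pf(Fj, 1, v, lower.tail = FALSE), adj1 = adj[1],
      adj2 = adj[2])
  })
  ph <- do.call(rbind, ph)
  posthoc <- data.frame(dv = dv_columns, F = ph[, "F"],
                        p = stats::p.adjust(ph[, "p"], posthoc_adjust))
  posthoc[[paste0("adj_mean_", levels(g)[1])]] <- ph[, "adj1"]
  posthoc[[paste0("adj_mean_", levels(g)[2])]] <- ph[, "adj2"]
  structure(list(lambda = lambda, F = rf$F, df1 = rf$df1, df2 = rf$df2,
                 p = rf$p, s = s, partial_eta_sq = eta2,
                 observed_power = power,
                 power_convention = "ncp = F * df1 (observed statistic)",
                 posthoc = posthoc, n = n, factor_col = factor_col,
                 levels = levels(g), covariates = covariates,
                 dv_columns = dv_columns, E = E, H = H),
            class = "mancova_result")
}

#' @export
print.mancova_result <- function(x, ...) {
  cat(sprintf(
    "MANCOVA (%s: %s vs %s; covariates: %s)\n", x$factor_col, x$levels[1],
    x$levels[2],
    if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"))
  cat(sprintf(
    "  Wilks lambda = %.4f, F(%g, %g) = %.3f, p = %.4g\n  partial eta^2 = %.3f, observed power = %.3f (%s)\n",
    x$lambda, x$df1, x$df2, x$F, x$p, x$partial_eta_sq, x$observed_power,
    x$power_convention))
  cat("Post-hoc ANCOVA per dependent variable:\n")
  print(x$posthoc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Partial eta squared from Wilks lambda
#'
#' `1 - lambda^(1/s)` with `s = min(n_DV, hypothesis df)`; for a two-group
#' factor (`s = 1`) this is exactly `1 - lambda`.
#' @param lambda Wilks lambda in (0, 1].
#' @param s `min(n_DV, hypothesis df)`.
#' @export
partial_eta_squared <- function(lambda, s = 1) {
  stopifnot(all(lambda > 0), all(lambda <= 1), s >= 1)
  1 - lambda^(1 / s)
}

#' Demographic group comparisons
#'
#' Welch two-sample t-tests for continuous variables and Fisher's exact
#' test for categorical ones, between the two cohort groups. A variable
#' with zero variance in both groups is reported with a missing p-value and
#' an explanatory note.
#'
#' @param cohort Cohort data frame.
#' @param variables Columns to compare (default: the standard clinical set
#'   present in the table).
#' @param factor_col Grouping column.
#' @return Data frame: `variable`, `type`, `statistic`, `p`, `note`.
#' @export
demographic_tests <- function(cohort,
                              variables = intersect(
                                c("age", "sex", "edss", "duration",
                                  "treatment_naive"), names(cohort)),
                              factor_col = "group") {
  g <- factor(cohort[[factor_col]])
  stopifnot(nlevels(g) == 2L, all(table(g) >= 2L))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      if (var(x) == 0)
        return(data.frame(variable = v, type = "continuous",
                          statistic = NA_real_, p = NA_real_,
                          note = "zero variance"))
      tt <- t.test(x ~ g)
      data.frame(variable = v, type = "continuous",
                 statistic = unname(tt$statistic), p = tt$p.value, note = "")
    } else {
      tab <- table(factor(x), g)
      if (nrow(tab) < 2L)
        return(data.frame(variable = v, type = "categorical",
                          statistic = NA_real_, p = NA_real_,
                          note = "single level"))
      ft <- fisher.test(tab)
      data.frame(variable = v, type = "categorical", statistic = NA_real_,
                 p = ft$p.value, note = "")
    }
  })
  do.call(rbind, rows)
}

# Pillai F-approximation dfs for the MANOVA global effect
manova_dfs <- function(N, n_groups, n_dvs) {
  p <- n_dvs; q <- n_groups - 1
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (N - n_groups - p - 1) / 2
  list(s = s, df1 = s * (2 * m + s + 1), df2 = s * (2 * nn + s + 1))
}

#' Power of the MANOVA global-effects test
#'
#' Noncentral-F approximation in the convention of common a-priori power
#' software for MANOVA global effects: effect size
#' `f2 = (V/s) / (1 - V/s)` from Pillai's trace V with
#' `s = min(n_dvs, n_groups - 1)`, numerator df `n_dvs * (n_groups - 1)`,
#' denominator df `s * (N - n_groups - n_dvs + s)`, and noncentrality
#' `lambda = f2 * N`.
#'
#' @param N Total sample size.
#' @param pillai_v Population Pillai trace (0 < V < s).
#' @param n_groups,n_dvs Number of groups and response variables.
#' @param alpha Significance level.
#' @export
manova_power_at_n <- function(N, pillai_v, n_groups = 2L, n_dvs = 4L,
                              alpha = 0.05) {
  d <- manova_dfs(N, n_groups, n_dvs)
  if (pillai_v <= 0 || pillai_v >= d$s)
    stop("Pillai V must lie in (0, s) with s = ", d$s)
  if (d$df2 <= 0) return(0)
  f2 <- (pillai_v / d$s) / (1 - pillai_v / d$s)
  ncp <- f2 * N
  1 - pf(qf(1 - alpha, d$df1, d$df2), d$df1, d$df2, ncp = ncp)
}

#' A-priori sample size for the MANOVA global-effects test
#'
#' Returns the smallest total N whose power ([manova_power_at_n()]) reaches
#' `target_power`, together with the convention used and an independent
#' cross-check of the power at that N computed by the Poisson-mixture
#' series of the noncentral F distribution ([ncf_power_series()], which
#' only uses the central beta distribution).
#'
#' @param pillai_v Population Pillai trace.
#' @param n_groups,n_dvs Number of groups and response variables.
#' @param alpha Significance level.
#' @param target_power Required power.
#' @return List: `N`, `power`, `power_crosscheck`, `df1`, `df2`, `ncp`,
#'   `convention`.
#' @export
manova_power <- function(pillai_v = 0.4, n_groups = 2L, n_dvs = 4L,
                         alpha = 0.05, target_power = 0.80) {
  stopifnot(alpha > 0, alpha < 1, target_power > alpha, target_power < 1)
  s <- min(n_dvs, n_groups - 1)
  if (pillai_v <= 0 || pillai_v >= s)
    stop("Pillai V must lie in (0, s) with s = ", s)
  N <- n_groups + n_dvs + 2L
  repeat {
    pw <- manova_power_at_n(N, pillai_v, n_groups, n_dvs, alpha)
    if (pw >= target_power) break
    N <- N + 1L
    if (N > 1e6) stop("required sample size exceeds 1e6; effect too small")
  }
  d <- manova_dfs(N, n_groups, n_dvs)
  f2 <- (pillai_v / s) / (1 - pillai_v / s)
  list(N = N, power = pw,
       power_crosscheck = ncf_power_series(d$df1, d$df2, f2 * N, alpha),
       df1 = d$df1, df2 = d$df2, ncp = f2 * N,
       convention = paste(
         "f2 = (V/s)/(1 - V/s); df1 = p*(k-1); df2 = s*(N-k-p+s);",
         "ncp = f2*N (noncentral F)"))
}

#' Noncentral-F tail probability via the Poisson-beta series
#'
#' Independent evaluation of `P(F' > crit)` for the noncentral F
#' distribution, as the Poisson(ncp/2)-weighted mixture of central beta
#' tail probabilities -- no noncentral distribution routine involved.
#' @param df1,df2 Degrees of freedom.
#' @param ncp Noncentrality parameter.
#' @param alpha Significance level defining the central-F critical value.
#' @export
ncf_power_series <- function(df1, df2, ncp, alpha = 0.05) {
  crit <- qf(1 - alpha, df1, df2)
  xb <- df1 * crit / (df1 * crit + df2)
  k <- 0:ceiling(ncp / 2 + 12 * sqrt(ncp / 2 + 1) + 25)
  wts <- dpois(k, ncp / 2)
  cdf <- sum(wts * pbeta(xb, df1 / 2 + k, df2 / 2))
  1 - cdf
}
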