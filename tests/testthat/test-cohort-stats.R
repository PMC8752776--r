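make_cohort <- function(n1 = 10, n2 = 10, shift = 0, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n1 + n2)),
    group = factor(rep(c("NMOSD", "MS"), c(n1, n2)),
                   levels = c("NMOSD", "MS")),
    age = rnorm(n1 + n2, 40, 10),
    sex = sample(c("M", "F"), n1 + n2, replace = TRUE),
    edss = round(abs(rnorm(n1 + n2, 2, 1)) * 2) / 2,
    fa = rnorm(n1 + n2, 0.5, 0.04) + rep(c(shift, 0), c(n1, n2)),
    md = rnorm(n1 + n2, 6.4e-4, 4e-5),
    stringsAsFactors = FALSE)
}

test_that("matching identical groups equalizes covariates", {
  co <- make_cohort(12, 12, seed = 2)
  m <- propensity_match(co, covariates = c("age", "edss"))
  expect_equal(nrow(m$matched), 24L)
  expect_true(all(abs(m$smd_after) < 1))
  expect_equal(as.integer(table(m$matched$group)), c(12L, 12L))
})

test_that("the most extreme subject is left unmatched first", {
  co <- make_cohort(6, 6, seed = 3)
  co$age[1] <- 95  # far outside every other subject's range
  m <- propensity_match(co, covariates = c("age"), n_target = 5)
  expect_false(co$subject_id[1] %in% m$matched$subject_id)
  expect_error(propensity_match(co, covariates = c("age"), n_target = 7),
               "exceeds")
})

test_that("separated logistic fits fall back to ridge with a warning", {
  co <- make_cohort(8, 8, seed = 4)
  co$age <- c(rep(20, 8), rep(60, 8))  # perfect separation on age
  expect_warning(m <- propensity_match(co, covariates = c("age")),
                 "ridge")
  expect_equal(nrow(m$matched), 16L)
})

test_that("Mahalanobis screening excludes exactly the planted outlier", {
  co <- make_cohort(12, 12, seed = 5)
  co$fa[3] <- mean(co$fa) + 10 * sd(co$fa)
  scr <- mahalanobis_screen(co, c("fa", "md"), alpha_cut = 0.001)
  expect_equal(scr$excluded$subject_id, "S003")
  expect_equal(nrow(scr$cohort), 23L)
  # hand-computed distance for the planted row against the chi-square cutoff
  Y <- as.matrix(co[c("fa", "md")])
  S <- cov(Y)
  dev <- Y[3, ] - colMeans(Y)
  d2_hand <- drop(t(dev) %*% solve(S, dev))
  expect_equal(unname(scr$d2["S003"]), d2_hand, tolerance = 1e-10)
  expect_gt(d2_hand, qchisq(0.999, 2))
  # a row exactly at the centroid has distance 0 and is retained
  set.seed(6)
  Z <- matrix(rnorm(10), 5, 2)
  co2 <- data.frame(subject_id = sprintf("C%02d", 1:11),
                    fa = 0.5 + c(0, Z[, 1], -Z[, 1]) * 0.02,
                    md = 6e-4 + c(0, Z[, 2], -Z[, 2]) * 2e-5)
  scr2 <- mahalanobis_screen(co2, c("fa", "md"))
  expect_equal(unname(scr2$d2["C01"]), 0, tolerance = 1e-18)
  expect_true("C01" %in% scr2$cohort$subject_id)
  # degenerate identical rows give a singular-covariance error
  co3 <- make_cohort(6, 6, seed = 7)
  co3$fa <- 0.5; co3$md <- 6e-4
  expect_error(mahalanobis_screen(co3, c("fa", "md")), "singular")
})

test_that("Wilks lambda matches explicit scatter matrices on a fixed fixture", {
  # 12-row fixture with two DVs and one covariate, fixed numbers
  fx <- data.frame(
    subject_id = sprintf("F%02d", 1:12),
    group = factor(rep(c("a", "b"), each = 6)),
    age = c(31, 45, 52, 38, 47, 41, 29, 35, 44, 50, 33, 39),
    y1 = c(0.52, 0.48, 0.50, 0.55, 0.47, 0.51,
           0.56, 0.58, 0.54, 0.57, 0.59, 0.53),
    y2 = c(0.61, 0.64, 0.60, 0.66, 0.63, 0.62,
           0.58, 0.56, 0.60, 0.57, 0.55, 0.59))
  m <- mancova(fx, c("y1", "y2"), factor_col = "group",
               covariates = "age")
  # oracle: residual scatter from stats::lm (independent fitting route)
  full <- lm(cbind(y1, y2) ~ age + group, data = fx)
  red <- lm(cbind(y1, y2) ~ age, data = fx)
  E <- crossprod(residuals(full))
  H <- crossprod(residuals(red)) - E
  expect_equal(m$lambda, det(E) / det(H + E), tolerance = 1e-12)
  # and against the built-in multivariate ANOVA table
  aw <- anova(full, test = "Wilks")
  expect_equal(m$lambda, aw["group", "Wilks"], tolerance = 1e-10)
  expect_equal(m$F, aw["group", "approx F"], tolerance = 1e-10)
  expect_equal(m$p, aw["group", "Pr(>F)"], tolerance = 1e-10)
})

test_that("MANCOVA agrees with anova.mlm on random cohorts", {
  for (seed in 1:4) {
    co <- make_cohort(14, 16, shift = -0.03, seed = seed)
    m <- mancova(co, c("fa", "md"), covariates = c("age", "edss"))
    fit <- lm(cbind(fa, md) ~ age + edss + group, data = co)
    aw <- anova(fit, test = "Wilks")
    expect_equal(m$lambda, aw["group", "Wilks"], tolerance = 1e-10)
    expect_equal(m$F, aw["group", "approx F"], tolerance = 1e-10)
    expect_equal(m$df1, aw["group", "num Df"])
    expect_equal(m$df2, aw["group", "den Df"])
  }
})

test_that("per-DV post-hoc ANCOVA matches single-response model fits", {
  co <- make_cohort(12, 14, shift = -0.04, seed = 9)
  m <- mancova(co, c("fa", "md"), covariates = c("age", "edss"))
  a_fa <- anova(lm(fa ~ age + edss + group, data = co))
  expect_equal(m$posthoc$F[1], a_fa["group", "F value"], tolerance = 1e-10)
  expect_equal(m$posthoc$p[1], a_fa["group", "Pr(>F)"], tolerance = 1e-10)
})

test_that("with no covariates, Wilks lambda reduces to Hotelling's T^2", {
  set.seed(11)
  co <- make_cohort(10, 12, shift = -0.05, seed = 11)
  m <- mancova(co, c("fa", "md"), covariates = character(0))
  g <- co$group; Y <- as.matrix(co[c("fa", "md")])
  n1 <- sum(g == "NMOSD"); n2 <- sum(g == "MS"); n <- n1 + n2
  d <- colMeans(Y[g == "NMOSD", ]) - colMeans(Y[g == "MS", ])
  Sp <- ((n1 - 1) * cov(Y[g == "NMOSD", ]) +
           (n2 - 1) * cov(Y[g == "MS", ])) / (n - 2)
  T2 <- (n1 * n2 / n) * drop(t(d) %*% solve(Sp, d))
  expect_equal(m$lambda, 1 / (1 + T2 / (n - 2)), tolerance = 1e-10)
})

test_that("Wilks lambda is invariant to invertible DV transforms", {
  set.seed(15)
  co <- make_cohort(12, 12, shift = -0.03, seed = 15)
  m0 <- mancova(co, c("fa", "md"), covariates = "age")
  for (i in 1:5) {
    A <- matrix(rnorm(4), 2); while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2)
    Z <- as.matrix(co[c("fa", "md")]) %*% t(A)
    co$z1 <- Z[, 1]; co$z2 <- Z[, 2]
    mt <- mancova(co, c("z1", "z2"), covariates = "age")
    expect_equal(mt$lambda, m0$lambda, tolerance = 1e-6)
  }
})

test_that("degenerate designs and missing data are handled explicitly", {
  co <- make_cohort(10, 10, seed = 17)
  co$age2 <- co$age
  expect_error(mancova(co, c("fa", "md"), covariates = c("age", "age2")),
               "aliased")
  co$fa[2] <- NA
  expect_message(m <- mancova(co, c("fa", "md"), covariates = "age"),
                 "excluded")
  expect_equal(m$n, 19L)
})

test_that("partial eta squared follows the lambda identity", {
  expect_equal(partial_eta_squared(0.462), 0.538)
  expect_equal(partial_eta_squared(0.790), 0.210)
  expect_equal(partial_eta_squared(0.25, s = 2), 1 - sqrt(0.25))
  expect_error(partial_eta_squared(0), ">")
})

test_that("demographic tests match base distributions and oracles", {
  co <- make_cohort(10, 10, seed = 19)
  co2 <- co
  co2[co2$group == "MS", c("age", "edss", "fa", "md")] <-
    co2[co2$group == "NMOSD", c("age", "edss", "fa", "md")]
  co2$sex <- rep(co$sex[1:10], 2)
  d <- demographic_tests(co2, variables = c("age", "sex", "edss"))
  expect_equal(d$statistic[d$variable == "age"], 0, tolerance = 1e-12)
  expect_equal(d$p[d$variable == "sex"], 1)
  # Fisher's exact p for the study's sex table (2,17 vs 8,12) against
  # exhaustive hypergeometric enumeration
  tab <- matrix(c(2, 17, 8, 12), 2, byrow = TRUE)
  p_fisher <- fisher.test(tab)$p.value
  k <- 0:10
  probs <- dhyper(k, m = 10, n = 29, k = 19)  # males=10, females=29, col1=19
  p_enum <- sum(probs[probs <= dhyper(2, 10, 29, 19) * (1 + 1e-7)])
  expect_equal(p_fisher, p_enum, tolerance = 1e-10)
  expect_equal(p_fisher, 0.0648, tolerance = 1e-3)
  # zero-variance variable reported as missing with a note
  co$edss <- 2
  d2 <- demographic_tests(co, variables = "edss")
  expect_true(is.na(d2$p))
  expect_match(d2$note, "zero variance")
})

test_that("MANOVA power is monotone, null-limited, and series-consistent", {
  # power approaches alpha as the effect vanishes
  expect_equal(manova_power_at_n(40, 1e-9, 2, 4, alpha = 0.05), 0.05,
               tolerance = 1e-4)
  # nondecreasing in N at fixed V
  pw <- vapply(seq(12, 120, by = 4), manova_power_at_n, 0, pillai_v = 0.4,
               n_groups = 2, n_dvs = 4)
  expect_true(all(diff(pw) > -1e-12))
  # the pf-based power matches the independent Poisson-beta series
  for (N in c(20, 24, 32, 48)) {
    d1 <- 4; d2 <- N - 5; ncp <- (0.4 / 0.6) * N
    expect_equal(1 - pf(qf(0.95, d1, d2), d1, d2, ncp = ncp),
                 ncf_power_series(d1, d2, ncp, 0.05), tolerance = 1e-9)
  }
  expect_error(manova_power(1.5, 2, 4), "Pillai")
})

test_that("a-priori sample sizes bracket the target power", {
  for (p in c(4L, 8L)) {
    r <- manova_power(0.4, 2, p, 0.05, 0.80)
    expect_gte(r$power, 0.80)
    expect_lt(manova_power_at_n(r$N - 1L, 0.4, 2, p), 0.80)
    expect_equal(r$power, r$power_crosscheck, tolerance = 1e-8)
    expect_match(r$convention, "ncp = f2\\*N")
  }
})
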