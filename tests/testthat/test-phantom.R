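test_that("a degenerate single-voxel ventricle voxelizes exactly", {
  spec <- phantom_spec(grid_shape = c(7, 7, 7), voxel_size = c(2, 2, 2),
                       ventricles = list(third = list(center = c(4, 4, 4),
                                                      radii = c(0.5, 0.5, 0.5))),
                       brain = "full", n_lesions = 0L)
  lab <- build_label_volume(spec)
  expect_equal(sum(lab$data == lab$labels[["third"]]), 1L)
  expect_equal(sum(lab$data == 0), 0L)  # all-WM grid
  expect_equal(sum(lab$data == lab$labels[["wm"]]), 7^3 - 1L)
})

test_that("default ventricles are disjoint and match analytic volumes", {
  lab <- build_label_volume(phantom_spec(n_lesions = 0L))
  vs <- default_ventricles()
  for (nm in names(vs)) {
    n <- sum(lab$data == lab$labels[[nm]])
    analytic <- 4 / 3 * pi * prod(vs[[nm]]$radii)
    expect_gt(n, 0)
    expect_lt(abs(n - analytic) / analytic, 0.10)
  }
  # disjoint by construction: label values partition the voxels
  expect_equal(sum(lab$data %in% lab$labels[c("lateral_l", "lateral_r",
                                              "third", "fourth")]),
               sum(vapply(names(vs),
                          function(nm) sum(lab$data == lab$labels[[nm]]), 0L)))
})

test_that("lesion count zero leaves no lesion label", {
  lab <- build_label_volume(phantom_spec(n_lesions = 0L))
  expect_equal(sum(lab$data == lab$labels[["lesion"]]), 0L)
  lab2 <- build_label_volume(phantom_spec(n_lesions = 3L, seed = 4L))
  expect_gt(sum(lab2$data == lab2$labels[["lesion"]]), 0L)
})

test_that("geometry overflow raises an explicit error", {
  spec <- phantom_spec(grid_shape = c(20, 20, 16),
                       ventricles = list(third = list(center = c(2, 10, 8),
                                                      radii = c(3, 3, 3))),
                       n_lesions = 0L)
  expect_error(build_label_volume(spec), "geometry")
})

test_that("gradient scheme matches the single-shell acquisition contract", {
  gt <- design_gradient_table(32L, 1000)
  expect_equal(length(gt$bvals), 33L)      # 32 directions + one b0
  expect_equal(gt$bvals[1], 0)
  expect_equal(unique(gt$bvals[-1]), 1000)
  expect_equal(max(abs(sqrt(rowSums(gt$bvecs[-1, ]^2)) - 1)), 0,
               tolerance = 1e-12)
  # minimal six-direction table still yields a full-rank tensor design
  gt6 <- design_gradient_table(6L)
  X <- cbind(1, -gt6$bvals * cbind(gt6$bvecs[, 1]^2,
                                   2 * gt6$bvecs[, 1] * gt6$bvecs[, 2],
                                   2 * gt6$bvecs[, 1] * gt6$bvecs[, 3],
                                   gt6$bvecs[, 2]^2,
                                   2 * gt6$bvecs[, 2] * gt6$bvecs[, 3],
                                   gt6$bvecs[, 3]^2))
  expect_equal(qr(X)$rank, 7L)
  expect_error(design_gradient_table(5L), "insufficient")
})

test_that("the forward model matches closed-form attenuations", {
  lab <- build_label_volume(mini_spec())
  gt <- gradient_table(c(0, 1000, 1000),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  # pure free water: S/S0 = exp(-b d_w) = exp(-3)
  par_csf <- tissue_params()
  dwi <- synthesize_dwi(lab, par_csf, gt)
  vent <- which(lab$data == lab$labels[["third"]])[1]
  v <- matrix(dwi, prod(dim(lab$data)), 3)[vent, ]
  expect_equal(v[1], 1)                       # b0 = S0
  expect_equal(v[2] / v[1], exp(-3), tolerance = 1e-12)
  # f = 0, D = diag(1.7, 0.2, 0.2)e-3, g along x: S/S0 = exp(-1.7)
  par_wm <- tissue_params(wm = list(f = 0, evals = c(1.7e-3, 0.2e-3, 0.2e-3),
                                    dir = c(1, 0, 0), s0 = 1),
                          f_rings = c(0, 0))
  dwi2 <- synthesize_dwi(lab, par_wm, gt)
  wmv <- which(lab$data == lab$labels[["wm"]])[1]
  v2 <- matrix(dwi2, prod(dim(lab$data)), 3)[wmv, ]
  expect_equal(v2[2] / v2[1], exp(-1.7), tolerance = 1e-12)
  expect_equal(v2[3] / v2[1], exp(-0.2), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical noisy volumes", {
  lab <- build_label_volume(mini_spec())
  a <- synthesize_dwi(lab, tissue_params(), std_gtab, snr_b0 = 20, seed = 9L)
  b <- synthesize_dwi(lab, tissue_params(), std_gtab, snr_b0 = 20, seed = 9L)
  cc <- synthesize_dwi(lab, tissue_params(), std_gtab, snr_b0 = 20, seed = 10L)
  expect_identical(a, b)
  expect_false(identical(a, cc))
})

test_that("synthesis does not disturb the caller's RNG stream", {
  lab <- build_label_volume(mini_spec())
  set.seed(123); x1 <- rnorm(1)
  set.seed(123)
  invisible(synthesize_dwi(lab, tissue_params(), std_gtab, snr_b0 = 20,
                           seed = 5L))
  expect_identical(rnorm(1), x1)
})

test_that("Rician noise at SNR 20 gives the nominal b0 coefficient of variation", {
  lab <- build_label_volume(mini_spec(grid = c(20, 20, 16)))
  dwi <- synthesize_dwi(lab, tissue_params(), std_gtab, snr_b0 = 20,
                        seed = 3L)
  wm <- lab$data == lab$labels[["wm"]]
  b0 <- dwi[, , , 1]
  cv <- sd(b0[wm]) / mean(b0[wm])
  expect_lt(abs(cv - 1 / 20) / (1 / 20), 0.10)
})

test_that("missing tissue parameters for a present label are a configuration error", {
  lab <- build_label_volume(mini_spec())
  lab$data[1, 1, 1] <- 9L
  lab$labels <- c(lab$labels, other = 9L)
  expect_error(synthesize_dwi(lab, tissue_params(), std_gtab),
               "configuration")
})

test_that("large-n shell metric means converge to the group targets", {
  es <- group_effect_spec()
  co <- simulate_cohort_table(es, c(NMOSD = 500L, MS = 500L), seed = 21L)
  suffix <- c(lateral = "lat", third = "v3", fourth = "v4")
  for (g in c("NMOSD", "MS")) for (sh in names(suffix)) {
    t <- es$metrics[[g]][[sh]]
    for (met in c("fa", "md")) {
      x <- co[co$group == g, paste0(met, "_", suffix[[sh]])]
      expect_lt(abs(mean(x) - t[[met]][1]), 3 * t[[met]][2] / sqrt(500))
    }
  }
  # the headline contrast: NMOSD third-ventricle FA mean near 0.4962
  expect_lt(abs(mean(co$fa_v3[co$group == "NMOSD"]) - 0.4962), 0.01)
})

test_that("a zero-effect specification yields matched group means", {
  es <- group_effect_spec()
  es$metrics$NMOSD <- es$metrics$MS
  co <- simulate_cohort_table(es, c(NMOSD = 500L, MS = 500L), seed = 8L)
  for (col in c("fa_v3", "md_v3", "fa_v4")) {
    d <- abs(mean(co[co$group == "NMOSD", col]) -
               mean(co[co$group == "MS", col]))
    se <- sd(co[[col]]) * sqrt(2 / 500)
    expect_lt(d, 2 * se)
  }
})

test_that("infeasible metric targets are rejected by name", {
  es <- group_effect_spec()
  expect_error({
    es$metrics$MS$third$fa <- c(1.2, 0.03)
    do.call(group_effect_spec, list(metrics = es$metrics))
  }, "MS third")
  es2 <- group_effect_spec()
  expect_error({
    es2$metrics$NMOSD$fourth$md <- c(2.9e-3, 1e-5)  # implied AD beyond d_w
    do.call(group_effect_spec, list(metrics = es2$metrics))
  }, "NMOSD fourth")
})

test_that("generate_cohort emits complete miniature subjects", {
  cg <- generate_cohort(n_per_group = c(NMOSD = 2L, MS = 2L),
                        spec = mini_spec(snr = 30), gtab = std_gtab,
                        seed = 2L)
  expect_equal(nrow(cg$cohort), 4L)
  expect_length(cg$subjects, 4L)
  s <- cg$subjects[[1]]
  expect_equal(dim(s$dwi), c(14, 14, 12, 33))
  expect_s3_class(s$labels, "label_volume")
  # drawn targets are carried into the ring tissue eigenvalues
  expect_equal(compute_metrics(s$truth$ring_evals$third)$fa,
               s$record$fa_v3, tolerance = 0.05)
})
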