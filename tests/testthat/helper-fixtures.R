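# Shared fixtures. Forward-model evaluations here are written out longhand
# (plain R, no package internals) so they stay independent of the code
# paths they are used to check.

D_W <- 3.0e-3

# bi-tensor forward signal for one voxel, evaluated from first principles
forward_signal <- function(gtab, f, evals, dir = c(0, 1, 0), s0 = 1,
                           d_w = D_W) {
  u <- dir / sqrt(sum(dir^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  D <- evals[1] * tcrossprod(u) + evals[2] * tcrossprod(v) +
    evals[3] * tcrossprod(w)
  q <- rowSums((gtab$bvecs %*% D) * gtab$bvecs)
  s0 * ((1 - f) * exp(-gtab$bvals * q) + f * exp(-gtab$bvals * d_w))
}

# single-tensor forward signal from an explicit 3x3 tensor
tensor_signal <- function(gtab, D, s0 = 1) {
  q <- rowSums((gtab$bvecs %*% D) * gtab$bvecs)
  s0 * exp(-gtab$bvals * q)
}

# random symmetric positive-definite tensor with eigenvalues in [lo, hi]
random_spd_tensor <- function(lo = 0.2e-3, hi = 2.0e-3) {
  ev <- sort(runif(3, lo, hi), decreasing = TRUE)
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  Q %*% diag(ev) %*% t(Q)
}

# a small phantom spec: single ventricle inside an all-WM grid
mini_spec <- function(grid = c(14, 14, 12), vr = c(2, 2.5, 2), seed = 1L,
                      snr = Inf) {
  phantom_spec(grid_shape = grid, voxel_size = c(2, 2, 2),
               ventricles = list(third = list(center = (grid + 1) / 2,
                                              radii = vr)),
               brain = "full", n_lesions = 0L, snr_b0 = snr, seed = seed)
}

std_gtab <- design_gradient_table(32L, 1000)
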