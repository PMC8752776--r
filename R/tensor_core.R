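# Single-tensor fitting, scalar diffusion metrics, and temporal-SNR quality
# control. The log-linear estimators here also provide the initialization
# for the free-water bi-tensor fit.

#' Design matrix of the log-linear diffusion tensor model
#'
#' Row i is `c(1, -b_i * (gx^2, 2 gx gy, 2 gx gz, gy^2, 2 gy gz, gz^2))` so
#' that `log S = X %*% c(log S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`.
#' @param gtab A [gradient_table()].
#' @keywords internal
dti_design_matrix <- function(gtab) {
  g <- gtab$bvecs
  b <- gtab$bvals
  cbind(1, -b * cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                      g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2))
}

tensor_from_elements <- function(d) {
  matrix(c(d[1], d[2], d[3],
           d[2], d[4], d[5],
           d[3], d[5], d[6]), 3, 3)
}

#' Fit the single diffusion tensor model
#'
#' Log-linear least-squares estimation of the symmetric diffusion tensor and
#' baseline signal S0 from single- or multi-voxel DWI signals. `method
#' = "wls"` (the default) weights the log-residuals by the squared predicted
#' signal, the standard correction for the log transform; `"ols"` is the
#' unweighted fit.
#'
#' Voxels containing non-positive signals cannot enter the log-linear fit;
#' they are returned as `NA` with `flag_nonpositive` set rather than
#' aborting the whole fit. A rank-deficient gradient scheme (fewer than six
#' independent directions) is a fatal error.
#'
#' @param signals Numeric vector (one voxel) or matrix (voxels x volumes).
#' @param gtab A [gradient_table()].
#' @param method `"wls"` or `"ols"`.
#' @return An object of class `dti_fit`: `tensors` (voxels x 6, elements
#'   Dxx, Dxy, Dxz, Dyy, Dyz, Dzz in mm^2/s), `s0`, `evals` (descending,
#'   negative values clamped to 0 with `flag_clamped`), `flag_nonpositive`.
#' @export
fit_tensor <- function(signals, gtab, method = c("wls", "ols")) {
  method <- match.arg(method)
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1L)
  if (ncol(signals) != length(gtab$bvals))
    stop("signal count ", ncol(signals), " does not match gradient table rows ",
         length(gtab$bvals))
  X <- dti_design_matrix(gtab)
  if (qr(X)$rank < 7L)
    stop("rank-deficient gradient design: need >= 6 non-collinear ",
         "directions plus a b=0 volume")
  nv <- nrow(signals)
  ok <- rowSums(signals <= 0) == 0L
  coefs <- matrix(NA_real_, nv, 7L)
  if (any(ok)) {
    logs <- log(signals[ok, , drop = FALSE])
    xtx <- crossprod(X)
    cf <- t(solve(xtx, crossprod(X, t(logs))))
    if (method == "wls") {
      pred <- cf %*% t(X)           # predicted log-signal
      w <- exp(2 * pred)            # squared predicted signal
      for (i in seq_len(nrow(cf))) {
        wi <- w[i, ]
        cf[i, ] <- solve(crossprod(X * sqrt(wi)), crossprod(X * wi, logs[i, ]))
      }
    }
    coefs[ok, ] <- cf
  }
  evals <- matrix(NA_real_, nv, 3L)
  evecs <- vector("list", nv)
  clamped <- rep(NA, nv)
  for (i in seq_len(nv)) {
    if (!ok[i]) next
    e <- eigen(tensor_from_elements(coefs[i, -1L]), symmetric = TRUE)
    clamped[i] <- any(e$values < 0)
    evals[i, ] <- pmax(e$values, 0)
    evecs[[i]] <- e$vectors
  }
  structure(list(tensors = coefs[, -1L, drop = FALSE],
                 s0 = exp(coefs[, 1L]),
                 evals = evals, evecs = evecs,
                 flag_clamped = clamped, flag_nonpositive = !ok,
                 method = method),
            class = "dti_fit")
}

#' Scalar diffusion metrics from tensor eigenvalues
#'
#' Computes, per voxel: mean diffusivity `MD = (l1+l2+l3)/3`, axial
#' diffusivity `AD = l1`, radial diffusivity `RD = (l2+l3)/2`, and
#' fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2))`.
#' The FA of the all-zero tensor is defined as 0 (its limit along isotropic
#' shrinkage) so ROI means never ingest NaN.
#'
#' @param x A `dti_fit` object, a 3-column matrix of eigenvalues, or a
#'   length-3 eigenvalue vector.
#' @return A data frame with columns `fa`, `md`, `ad`, `rd`.
#' @export
compute_metrics <- function(x) {
  ev <- if (inherits(x, "dti_fit")) x$evals
        else if (is.null(dim(x))) matrix(x, nrow = 1L)
        else as.matrix(x)
  stopifnot(ncol(ev) == 3L)
  ev <- t(apply(ev, 1L, sort, decreasing = TRUE))
  md <- rowMeans(ev)
  ss <- rowSums(ev^2)
  dev <- rowSums((ev - md)^2)
  fa <- ifelse(ss > 0, sqrt(1.5) * sqrt(dev) / sqrt(ss), 0)
  data.frame(fa = pmin(fa, 1), md = md, ad = ev[, 1L],
             rd = (ev[, 2L] + ev[, 3L]) / 2)
}

#' Temporal signal-to-noise ratio quality control
#'
#' Per-voxel temporal mean divided by temporal standard deviation across the
#' 4th dimension, averaged over a mask. Series with zero temporal variation
#' report infinite tSNR and pass. The default cutoff 6.47 is the suggested
#' screening threshold for poor diffusion data; a b0-only variant is
#' reported alongside when a gradient table is supplied (requires at least
#' two b=0 volumes, otherwise `NA`).
#'
#' @param dwi 4-D array.
#' @param mask Logical 3-D array; must be nonempty.
#' @param cutoff Pass/fail threshold (default 6.47).
#' @param gtab Optional [gradient_table()] enabling the b0-only variant.
#' @return List with `tsnr`, `pass`, `cutoff`, `tsnr_b0`.
#' @export
tsnr_qc <- function(dwi, mask, cutoff = 6.47, gtab = NULL) {
  stopifnot(length(dim(dwi)) == 4L)
  if (dim(dwi)[4] < 2L) stop("tSNR needs at least 2 volumes")
  mask <- array(as.logical(mask), dim(dwi)[1:3])
  if (!any(mask)) stop("empty mask")
  tsnr_of <- function(vols) {
    m <- apply(vols, 1:3, mean)
    s <- apply(vols, 1:3, sd)
    r <- ifelse(s == 0, Inf, m / s)
    mean(r[mask])
  }
  tsnr <- tsnr_of(dwi)
  tsnr_b0 <- NA_real_
  if (!is.null(gtab) && sum(gtab$b0) >= 2L)
    tsnr_b0 <- tsnr_of(dwi[, , , gtab$b0, drop = FALSE])
  list(tsnr = tsnr, pass = tsnr > cutoff, cutoff = cutoff, tsnr_b0 = tsnr_b0)
}
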