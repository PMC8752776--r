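# Digital DWI phantom: ventricle/white-matter geometry, a single-shell
# gradient scheme, bi-tensor signal synthesis with Rician noise, and a
# two-group cohort generator that injects group-level metric contrasts.

#' Default ventricle geometry, scaled to the grid
#'
#' Centers and radii (in voxels) of four ellipsoidal ventricles: left and
#' right lateral, third (narrow midline), fourth (lower posterior midline).
#' The layout is schematic, not anatomical; what matters downstream is that
#' each ventricle is embedded in white matter with margin to spare.
#' @param grid_shape Voxels per axis.
#' @export
default_ventricles <- function(grid_shape = c(64, 64, 40)) {
  sc <- grid_shape / c(64, 64, 40)
  v <- function(center, radii) list(center = center * sc, radii = radii * sc)
  list(
    lateral_l = v(c(24, 36, 26), c(4.2, 9.5, 4.5)),
    lateral_r = v(c(41, 36, 26), c(4.2, 9.5, 4.5)),
    third     = v(c(32.5, 34, 17), c(1.8, 4.5, 3.5)),
    fourth    = v(c(32.5, 20, 10), c(2.8, 3.5, 3.2))
  )
}

#' Specification of a synthetic DWI phantom
#'
#' @param grid_shape Voxels per axis (default 64 x 64 x 40).
#' @param voxel_size mm per axis (default 1.8 x 1.8 x 2.0: a 230 mm field of
#'   view at matrix 128, 2 mm slices).
#' @param ventricles Named list of ellipsoids (`center`, `radii` in voxels);
#'   see [default_ventricles()].
#' @param brain `"ellipsoid"` embeds everything in an ellipsoidal
#'   white-matter compartment; `"full"` makes the whole grid white matter
#'   (useful for degenerate test geometries).
#' @param n_lesions Number of spherical white-matter lesions.
#' @param lesion_radius Range (voxels) lesion radii are drawn from.
#' @param snr_b0 Signal-to-noise ratio at b=0 (`Inf` = noiseless).
#' @param seed Integer RNG seed for lesion placement and noise.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 40),
                         voxel_size = c(1.8, 1.8, 2.0),
                         ventricles = default_ventricles(grid_shape),
                         brain = c("ellipsoid", "full"),
                         n_lesions = 3L,
                         lesion_radius = c(1.5, 3),
                         snr_b0 = 20,
                         seed = 1L) {
  brain <- match.arg(brain)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3),
            length(voxel_size) == 3L, all(voxel_size > 0),
            n_lesions >= 0, snr_b0 > 0)
  for (nm in names(ventricles)) {
    v <- ventricles[[nm]]
    if (any(v$radii <= 0)) stop("ventricle ", nm, " has non-positive radii")
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 ventricles = ventricles, brain = brain,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = lesion_radius,
                 snr_b0 = snr_b0, seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  ax <- ((seq_len(grid_shape[1]) - center[1]) / radii[1])^2
  ay <- ((seq_len(grid_shape[2]) - center[2]) / radii[2])^2
  az <- ((seq_len(grid_shape[3]) - center[3]) / radii[3])^2
  outer(outer(ax, ay, `+`), az, `+`) <= 1
}

PHANTOM_LABELS <- c(background = 0L, wm = 1L, lateral_l = 2L, lateral_r = 3L,
                    third = 4L, fourth = 5L, lesion = 6L)

#' Build the phantom label volume
#'
#' Voxelizes the white-matter compartment, the four ventricles, and random
#' spherical lesions into an integer label volume. Every ventricle must be
#' strictly inside white matter (2-voxel margin) and ventricles must be
#' pairwise disjoint; violations raise a geometry error.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()] with labels background/wm/lateral_l/
#'   lateral_r/third/fourth/lesion.
#' @export
build_label_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  brain <- if (spec$brain == "full") array(TRUE, gs)
           else ellipsoid_mask(gs, (gs + 1) / 2, gs / 2 - 2)
  lab <- array(0L, gs)
  lab[brain] <- PHANTOM_LABELS[["wm"]]
  vmasks <- lapply(spec$ventricles, function(v)
    ellipsoid_mask(gs, v$center, v$radii))
  for (nm in names(vmasks)) {
    if (!any(vmasks[[nm]]))
      stop("geometry error: ventricle ", nm, " voxelizes to zero voxels")
    if (!nm %in% names(PHANTOM_LABELS))
      stop("unknown ventricle name: ", nm)
  }
  vu <- Reduce(`|`, vmasks)
  if (sum(vu) != sum(vapply(vmasks, sum, 0)))
    stop("geometry error: ventricles overlap")
  # 2-voxel white-matter margin: twice-dilated ventricles stay in the brain
  margin <- dilate_mask(dilate_mask(vu, 6L), 6L)
  if (any(margin & !brain))
    stop("geometry error: ventricle within 2 voxels of the brain boundary")
  for (nm in names(vmasks)) lab[vmasks[[nm]]] <- PHANTOM_LABELS[[nm]]
  if (spec$n_lesions > 0L) {
    with_preserved_rng(spec$seed, {
      wm_idx <- which(lab == PHANTOM_LABELS[["wm"]] & !margin)
      centers <- sample(wm_idx, spec$n_lesions)
      radii <- runif(spec$n_lesions, spec$lesion_radius[1], spec$lesion_radius[2])
      for (i in seq_len(spec$n_lesions)) {
        cc <- arrayInd(centers[i], gs)
        sph <- ellipsoid_mask(gs, as.numeric(cc), rep(radii[i], 3))
        lab[sph & lab == PHANTOM_LABELS[["wm"]]] <- PHANTOM_LABELS[["lesion"]]
      }
    })
  }
  af <- diag(c(spec$voxel_size, 1))
  label_volume(lab, PHANTOM_LABELS, affine = af)
}

#' Single-shell gradient scheme
#'
#' One b=0 row followed by `n_dirs` unit directions laid out on a Fibonacci
#' spiral over the upper hemisphere -- a deterministic, well-spread scheme
#' whose tensor design matrix is full rank from six directions up.
#'
#' @param n_dirs Number of diffusion-weighted directions (>= 6).
#' @param b b-value of the shell in s/mm^2 (default 1000).
#' @param seed Unused (the layout is deterministic); kept so callers can
#'   treat all generators uniformly.
#' @return A [gradient_table()] with `n_dirs + 1` rows.
#' @export
design_gradient_table <- function(n_dirs = 32L, b = 1000, seed = 1L) {
  if (n_dirs < 6L)
    stop("insufficient directions: tensor estimation needs >= 6, got ", n_dirs)
  i <- seq_len(n_dirs)
  z <- (i - 0.5) / n_dirs
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  gradient_table(c(0, rep(b, n_dirs)), rbind(c(0, 0, 0), dirs))
}

#' Map (FA, MD) to axially symmetric tensor eigenvalues
#'
#' With the two minor eigenvalues equal, the pair (FA, MD) determines the
#' eigenvalues in closed form: `l1 = MD (1 + 2 d)`, `l2 = l3 = MD (1 - d)`
#' with `d = FA / sqrt(3 - 2 FA^2)`.
#' @param fa Fractional anisotropy in `[0, 1]`.
#' @param md Mean diffusivity (mm^2/s).
#' @return Numeric vector `c(l1, l2, l3)` (or a 3-column matrix).
#' @export
fa_md_to_evals <- function(fa, md) {
  if (any(fa < 0 | fa > 1)) stop("FA must lie in [0, 1]")
  if (any(md < 0)) stop("MD must be non-negative")
  d <- fa / sqrt(3 - 2 * fa^2)
  out <- cbind(md * (1 + 2 * d), md * (1 - d), md * (1 - d))
  if (length(fa) == 1L) out[1L, ] else out
}

#' Per-label bi-tensor tissue parameters
#'
#' Each compartment carries a free-water volume fraction `f`, tissue tensor
#' eigenvalues, a principal direction, and a baseline signal `s0`. The white
#' matter free-water fraction rises toward the CSF border: `f_rings[1]`
#' applies 1 voxel from a ventricle, `f_rings[2]` two voxels away, and
#' `wm$f` elsewhere. `ring_evals` optionally overrides the tissue
#' eigenvalues of the 1-voxel lining shell per ventricle group, which is how
#' the cohort generator injects subject-specific periependymal contrasts.
#'
#' @param wm,lesion Lists with `f`, `evals`, `dir`, `s0`.
#' @param csf List with `f = 1` (free water) and `s0`.
#' @param f_rings Free-water fraction at distance 1 and 2 from a ventricle.
#' @param ring_evals Named list (`lateral`, `third`, `fourth`) of eigenvalue
#'   triples for the lining shell, or `NULL` to use `wm$evals`.
#' @param d_w Free-water diffusivity (mm^2/s).
#' @export
tissue_params <- function(
    wm = list(f = 0.10, evals = fa_md_to_evals(0.60, 0.70e-3),
              dir = c(0, 1, 0), s0 = 1),
    csf = list(f = 1, s0 = 1),
    lesion = list(f = 0.30, evals = c(1.2e-3, 1.0e-3, 1.0e-3),
                  dir = c(1, 0, 0), s0 = 1),
    f_rings = c(0.60, 0.35),
    ring_evals = list(lateral = NULL, third = NULL, fourth = NULL),
    d_w = FREE_WATER_DIFFUSIVITY) {
  stopifnot(wm$f >= 0, wm$f <= 1, csf$f == 1,
            all(f_rings >= 0), all(f_rings <= 1))
  check_evals <- function(e, what) {
    if (!is.null(e) && (length(e) != 3L || any(diff(e) > 1e-12) || any(e < 0)))
      stop(what, " eigenvalues must satisfy l1 >= l2 >= l3 >= 0")
  }
  check_evals(wm$evals, "wm")
  check_evals(lesion$evals, "lesion")
  for (nm in names(ring_evals)) check_evals(ring_evals[[nm]], nm)
  structure(list(wm = wm, csf = csf, lesion = lesion, f_rings = f_rings,
                 ring_evals = ring_evals, d_w = d_w),
            class = "tissue_params")
}

# Orthonormal frame with first axis along u (deterministic completion).
principal_frame <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(u, v, w)
}

# Region partition used by the synthesizer: each region is a set of voxels
# sharing one bi-tensor parameter set.
phantom_regions <- function(labvol, params) {
  lab <- labvol$data
  L <- labvol$labels
  wm <- lab == L[["wm"]]
  vent <- list(
    lateral = lab == L[["lateral_l"]] | lab == L[["lateral_r"]],
    third = lab == L[["third"]],
    fourth = lab == L[["fourth"]])
  csf <- Reduce(`|`, vent)
  region <- array(0L, dim(lab))
  region[wm] <- 1L                                   # deep WM
  ring2 <- dilate_mask(dilate_mask(csf, 6L), 6L) & wm
  region[ring2] <- 2L
  code <- c(lateral = 3L, third = 4L, fourth = 5L)
  for (nm in names(vent)) {
    ring1 <- dilate_mask(vent[[nm]], 6L) & wm
    region[ring1] <- code[[nm]]
  }
  region[csf] <- 6L
  region[lab == L[["lesion"]]] <- 7L
  ring_ev <- function(nm) {
    e <- params$ring_evals[[nm]]
    if (is.null(e)) params$wm$evals else e
  }
  defs <- list(
    `1` = list(f = params$wm$f, evals = params$wm$evals,
               dir = params$wm$dir, s0 = params$wm$s0),
    `2` = list(f = params$f_rings[2], evals = params$wm$evals,
               dir = params$wm$dir, s0 = params$wm$s0),
    `3` = list(f = params$f_rings[1], evals = ring_ev("lateral"),
               dir = params$wm$dir, s0 = params$wm$s0),
    `4` = list(f = params$f_rings[1], evals = ring_ev("third"),
               dir = params$wm$dir, s0 = params$wm$s0),
    `5` = list(f = params$f_rings[1], evals = ring_ev("fourth"),
               dir = params$wm$dir, s0 = params$wm$s0),
    `6` = list(f = 1, evals = rep(params$d_w, 3), dir = c(1, 0, 0),
               s0 = params$csf$s0),
    `7` = list(f = params$lesion$f, evals = params$lesion$evals,
               dir = params$lesion$dir, s0 = params$lesion$s0))
  list(region = region, defs = defs)
}

#' Synthesize a 4-D DWI volume from a label volume
#'
#' Evaluates the two-compartment forward model per voxel,
#' `S(g, b) = S0 * ((1 - f) exp(-b g' D g) + f exp(-b d_w))`,
#' and corrupts it with Rician noise (two independent Gaussian channels of
#' standard deviation `S0 / snr_b0`) unless `snr_b0` is infinite. The
#' global RNG state is left untouched; identical `(labels, params, gtab,
#' snr_b0, seed)` give bit-identical output.
#'
#' @param labels A [label_volume()] from [build_label_volume()].
#' @param params A [tissue_params()]; every label present must be covered.
#' @param gtab A [gradient_table()].
#' @param snr_b0 b=0 signal-to-noise ratio; `Inf` for noiseless.
#' @param seed Integer seed for the noise draw.
#' @return 4-D array (grid x volumes) with the label volume's affine.
#' @export
synthesize_dwi <- function(labels, params, gtab, snr_b0 = Inf, seed = 1L) {
  stopifnot(inherits(labels, "label_volume"), inherits(params, "tissue_params"),
            inherits(gtab, "gradient_table"))
  present <- setdiff(unique(as.vector(labels$data)), 0L)
  known <- labels$labels[c("wm", "lateral_l", "lateral_r", "third", "fourth",
                           "lesion")]
  if (length(setdiff(present, known)))
    stop("configuration error: no tissue parameters for label value(s) ",
         paste(setdiff(present, known), collapse = ", "))
  rg <- phantom_regions(labels, params)
  gs <- dim(labels$data)
  nmeas <- length(gtab$bvals)
  nvox <- prod(gs)
  sig <- matrix(0, nvox, nmeas)
  sigma <- numeric(nvox)
  for (rc in names(rg$defs)) {
    idx <- which(rg$region == as.integer(rc))
    if (!length(idx)) next
    p <- rg$defs[[rc]]
    R <- principal_frame(p$dir)
    D <- R %*% diag(p$evals) %*% t(R)
    q <- rowSums((gtab$bvecs %*% D) * gtab$bvecs)      # g' D g per row
    s <- p$s0 * ((1 - p$f) * exp(-gtab$bvals * q) +
                 p$f * exp(-gtab$bvals * params$d_w))
    sig[idx, ] <- rep(s, each = length(idx))
    sigma[idx] <- p$s0 / snr_b0
  }
  if (is.finite(snr_b0)) {
    with_preserved_rng(seed, {
      n1 <- matrix(rnorm(nvox * nmeas), nvox, nmeas) * sigma
      n2 <- matrix(rnorm(nvox * nmeas), nvox, nmeas) * sigma
      sig <- sqrt((sig + n1)^2 + n2^2)
    })
  }
  dim(sig) <- c(gs, nmeas)
  attr(sig, "affine") <- labels$affine
  sig
}

#' Ground-truth parameter maps of a phantom
#'
#' Expands the per-region tissue parameters into voxel maps of the true
#' free-water fraction and tissue-tensor metrics, plus the region partition
#' itself (useful for excluding region boundaries when scoring a fit).
#'
#' @param labels A [label_volume()] from [build_label_volume()].
#' @param params The [tissue_params()] used for synthesis.
#' @return List of 3-D arrays: `f`, `fa`, `md`, `ad`, `rd`, integer
#'   `region`, and logical `interior` (voxels whose face neighbors share
#'   their region).
#' @export
phantom_ground_truth <- function(labels, params) {
  rg <- phantom_regions(labels, params)
  gs <- dim(labels$data)
  out <- list(f = array(NA_real_, gs), fa = array(NA_real_, gs),
              md = array(NA_real_, gs), ad = array(NA_real_, gs),
              rd = array(NA_real_, gs), region = rg$region)
  for (rc in names(rg$defs)) {
    idx <- rg$region == as.integer(rc)
    if (!any(idx)) next
    p <- rg$defs[[rc]]
    m <- compute_metrics(p$evals)
    out$f[idx] <- p$f
    out$fa[idx] <- m$fa
    out$md[idx] <- m$md
    out$ad[idx] <- m$ad
    out$rd[idx] <- m$rd
  }
  interior <- array(FALSE, gs)
  for (rc in unique(as.vector(rg$region))) {
    if (rc == 0) next
    m <- rg$region == rc
    interior <- interior | (m & !dilate_mask(!m, 6L))
  }
  out$interior <- interior
  out
}

# Run code under a fixed seed, then restore the caller's RNG state.
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
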