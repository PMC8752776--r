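# Periependymal lining shells: one-voxel-thick layers of white matter
# immediately adjacent to each ventricle, with lesion subtraction and
# per-shell metric summaries.

connectivity_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

shift_mask <- function(m, d) {
  out <- array(FALSE, dim(m))
  n <- dim(m)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (d[a] >= 0) { dst[[a]] <- seq_len(n[a] - d[a]) + d[a]
                     src[[a]] <- seq_len(n[a] - d[a]) }
    else           { dst[[a]] <- seq_len(n[a] + d[a])
                     src[[a]] <- seq_len(n[a] + d[a]) - d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary dilation of a 3-D logical array by one voxel.
dilate_mask <- function(m, connectivity = 6L) {
  off <- connectivity_offsets(connectivity)
  out <- m
  for (i in seq_len(nrow(off))) out <- out | shift_mask(m, off[i, ])
  out
}

#' Extract a 1-voxel-thick periependymal lining shell
#'
#' The shell is the set of white-matter voxels adjacent (face adjacency for
#' connectivity 6, face+edge+corner for 26) to the ventricle:
#' `dilate(ventricle) & wm & !ventricle`. It is exactly one voxel thick by
#' construction, disjoint from the ventricle, and contained in white
#' matter.
#'
#' @param ventricle_mask,wm_mask Logical 3-D arrays on a shared grid; they
#'   must be disjoint.
#' @param connectivity 6 (default) or 26.
#' @return An object of class `shell_mask`: `mask`, `n_voxels`,
#'   `connectivity`, `removed_lesion` (provenance of lesion subtraction).
#' @export
extract_shell <- function(ventricle_mask, wm_mask, connectivity = 6L) {
  stopifnot(identical(dim(ventricle_mask), dim(wm_mask)))
  ventricle_mask <- ventricle_mask != 0
  wm_mask <- wm_mask != 0
  nover <- sum(ventricle_mask & wm_mask)
  if (nover > 0)
    stop("ventricle and white-matter masks overlap in ", nover, " voxel(s)")
  shell <- dilate_mask(ventricle_mask, connectivity) & wm_mask & !ventricle_mask
  if (!any(shell) && any(ventricle_mask))
    warning("empty shell: ventricle has no adjacent white-matter voxels")
  structure(list(mask = shell, n_voxels = sum(shell),
                 connectivity = as.integer(connectivity),
                 removed_lesion = 0L),
            class = "shell_mask")
}

#' Remove lesion voxels from a lining shell
#'
#' Drops shell voxels intersecting the lesion mask, so downstream summaries
#' only see normal-appearing tissue. The number of removed voxels is
#' recorded in the shell's provenance; the voxel count never increases.
#'
#' @param shell A `shell_mask`.
#' @param lesion_mask Logical 3-D array on the same grid.
#' @export
subtract_lesions <- function(shell, lesion_mask) {
  stopifnot(inherits(shell, "shell_mask"),
            identical(dim(shell$mask), dim(lesion_mask)))
  lesion_mask <- lesion_mask != 0
  removed <- sum(shell$mask & lesion_mask)
  shell$mask <- shell$mask & !lesion_mask
  shell$n_voxels <- sum(shell$mask)
  shell$removed_lesion <- shell$removed_lesion + removed
  shell
}

#' Build the three analysis shells from a phantom label volume
#'
#' Convenience wrapper: extracts the lining shells of the lateral (left and
#' right combined), third, and fourth ventricles within white matter and
#' subtracts the lesion mask from each.
#'
#' @param labels A [label_volume()] with the phantom label set.
#' @param connectivity 6 or 26.
#' @return Named list of `shell_mask` objects (`lateral`, `third`, `fourth`).
#' @export
periependymal_shells <- function(labels, connectivity = 6L) {
  wm <- label_mask(labels, "wm")
  lesion <- label_mask(labels, "lesion")
  sh <- list(
    lateral = extract_shell(label_mask(labels, "lateral_l") |
                              label_mask(labels, "lateral_r"),
                            wm, connectivity),
    third = extract_shell(label_mask(labels, "third"), wm, connectivity),
    fourth = extract_shell(label_mask(labels, "fourth"), wm, connectivity))
  lapply(sh, subtract_lesions, lesion_mask = lesion)
}

#' Summarize metric maps over lining shells
#'
#' Arithmetic mean of each metric map over each shell. An empty shell
#' yields `NA` means and a raised `missing` flag -- never a silent zero.
#'
#' @param metric_maps A named list of 3-D arrays (typically `fa`, `md`,
#'   `ad`, `rd`) or an `fwe_result` (its corrected maps are used).
#' @param shells A named list of `shell_mask` objects.
#' @return Data frame: one row per shell with `n_voxels`, one column per
#'   metric, and a logical `missing` column.
#' @export
summarize_roi <- function(metric_maps, shells) {
  if (inherits(metric_maps, "fwe_result")) metric_maps <- metric_maps$metrics
  stopifnot(is.list(metric_maps), length(names(metric_maps)) > 0)
  if (inherits(shells, "shell_mask")) shells <- list(shell = shells)
  out <- data.frame(shell = names(shells), n_voxels = NA_integer_,
                    stringsAsFactors = FALSE)
  for (m in names(metric_maps)) out[[m]] <- NA_real_
  out$missing <- FALSE
  for (i in seq_along(shells)) {
    sh <- shells[[i]]
    stopifnot(inherits(sh, "shell_mask"))
    out$n_voxels[i] <- sh$n_voxels
    if (sh$n_voxels == 0L) {
      out$missing[i] <- TRUE
      next
    }
    for (m in names(metric_maps)) {
      map <- metric_maps[[m]]
      stopifnot(identical(dim(map), dim(sh$mask)))
      out[[m]][i] <- mean(map[sh$mask])
    }
  }
  out
}
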