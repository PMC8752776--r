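# On-disk interchange: NIfTI-1 volumes, FSL-style bval/bvec gradient tables,
# integer label volumes and tabular cohort files. All readers validate; all
# writers round-trip bit-identically through their paired reader.

#' Construct a validated gradient table
#'
#' A gradient table pairs one b-value and one unit gradient direction with
#' every volume of a 4-D diffusion-weighted series. Zero directions are only
#' allowed on b=0 rows, and at least one b=0 row must be present.
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Numeric matrix of gradient directions, one row per volume
#'   (n x 3). Rows for b=0 volumes may be zero vectors.
#' @return An object of class `gradient_table` with elements `bvals`,
#'   `bvecs`, and logical `b0` marking non-diffusion-weighted rows.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 columns, got ", ncol(bvecs))
  if (length(bvals) != nrow(bvecs))
    stop("gradient table mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " directions")
  b0 <- bvals <= 10
  if (!any(b0))
    stop("gradient table must contain at least one b=0 row")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[!b0] - 1) > 1e-6))
    stop("non-b0 gradient directions must be unit vectors (worst deviation ",
         format(max(abs(nrm[!b0] - 1))), ")")
  if (any(nrm[b0] > 1e-6 & abs(nrm[b0] - 1) > 1e-6))
    stop("b=0 directions must be zero or unit vectors")
  structure(list(bvals = bvals, bvecs = bvecs, b0 = b0),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("<gradient_table: %d volumes (%d b0), b = %s s/mm^2>\n",
              length(x$bvals), sum(x$b0),
              paste(unique(round(x$bvals[!x$b0])), collapse = "/")))
  invisible(x)
}

#' Read FSL-style bval/bvec files
#'
#' Accepts both common bvec layouts: 3 rows by N columns (one row per
#' coordinate axis, the FSL convention) and N rows by 3 columns. The layout
#' is auto-detected from the shape; the ambiguous 3x3 case is resolved as
#' three row-wise directions with a warning. Directions off unit norm by
#' less than 1e-3 are re-normalized with a warning; larger deviations are a
#' format error.
#'
#' @param path_bval,path_bvec Paths to whitespace-delimited text files.
#' @return A [gradient_table()].
#' @export
read_bvals_bvecs <- function(path_bval, path_bvec) {
  for (p in c(path_bval, path_bvec))
    if (!file.exists(p)) stop("file not found: ", p)
  bvals <- scan(path_bval, quiet = TRUE)
  lines <- readLines(path_bvec)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  nc <- unique(lengths(rows))
  if (length(nc) != 1L)
    stop("ragged bvec file: rows have ", paste(nc, collapse = "/"), " entries")
  m <- do.call(rbind, rows)
  if (nrow(m) == 3L && ncol(m) == 3L) {
    warning("ambiguous 3x3 bvec file: interpreting rows as directions")
  } else if (nrow(m) == 3L && ncol(m) != 3L) {
    m <- t(m)  # FSL dialect: 3 coordinate rows
  } else if (ncol(m) != 3L) {
    stop("bvec file is neither 3xN nor Nx3 (", nrow(m), "x", ncol(m), ")")
  }
  if (nrow(m) != length(bvals))
    stop("gradient table mismatch: ", nrow(m), " directions vs ",
         length(bvals), " b-values")
  b0 <- bvals <= 10
  nrm <- sqrt(rowSums(m^2))
  off <- !b0 & abs(nrm - 1) > 1e-6
  if (any(abs(nrm[!b0] - 1) > 1e-3))
    stop("non-unit gradient direction beyond tolerance (norm ",
         format(max(abs(nrm[!b0]))), ")")
  if (any(off)) {
    warning(sum(off), " direction(s) re-normalized (off unit by < 1e-3)")
    m[off, ] <- m[off, ] / nrm[off]
  }
  gradient_table(bvals, m)
}

#' Write FSL-style bval/bvec files
#'
#' Writes the 3-row-by-N FSL dialect.
#' @param gtab A [gradient_table()].
#' @param path_bval,path_bvec Output paths.
#' @export
write_bvals_bvecs <- function(gtab, path_bval, path_bvec) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, trim = TRUE, digits = 15),
                   collapse = " "), path_bval)
  tm <- t(gtab$bvecs)
  writeLines(apply(tm, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), path_bvec)
  invisible(c(path_bval, path_bvec))
}

#' Read a 4-D DWI volume with its gradient table
#'
#' @param path_nifti Path to a 4-D NIfTI-1 volume.
#' @param path_bval,path_bvec Paths to the FSL gradient-table files.
#' @return A list with `dwi` (4-D array with an `affine` attribute) and
#'   `gtab` (a [gradient_table()]).
#' @export
read_dwi <- function(path_nifti, path_bval, path_bvec) {
  if (!file.exists(path_nifti)) stop("file not found: ", path_nifti)
  gtab <- read_bvals_bvecs(path_bval, path_bvec)
  img <- RNifti::readNifti(path_nifti)
  arr <- unclass_keep_dim(as.array(img))
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D volume, got ", length(dim(arr)), " dimensions")
  if (dim(arr)[4] != length(gtab$bvals))
    stop("gradient table mismatch: ", length(gtab$bvals),
         " table rows vs ", dim(arr)[4], " volumes")
  attr(arr, "affine") <- unclass(RNifti::xform(img))
  list(dwi = arr, gtab = gtab)
}

#' Write a 4-D DWI volume with its gradient table
#'
#' @param dwi 4-D array (optionally carrying an `affine` attribute).
#' @param gtab A [gradient_table()].
#' @param path_nifti,path_bval,path_bvec Output paths.
#' @export
write_dwi <- function(dwi, gtab, path_nifti, path_bval, path_bvec) {
  stopifnot(length(dim(dwi)) == 4L)
  if (dim(dwi)[4] != length(gtab$bvals))
    stop("gradient table mismatch: ", length(gtab$bvals),
         " table rows vs ", dim(dwi)[4], " volumes")
  img <- RNifti::asNifti(unclass_keep_dim(dwi))
  af <- attr(dwi, "affine")
  if (!is.null(af)) RNifti::qform(img) <- structure(af, code = 2L)
  RNifti::writeNifti(img, path_nifti)
  write_bvals_bvecs(gtab, path_bval, path_bvec)
  invisible(path_nifti)
}

unclass_keep_dim <- function(x) {
  y <- as.vector(x)
  dim(y) <- dim(x)
  y
}

#' Construct a label volume
#'
#' @param data 3-D integer array of labels (0 = background).
#' @param labels Named integer vector mapping label names to values; must
#'   cover every nonzero value present in `data`.
#' @param affine Optional 4x4 voxel-to-world transform.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, labels, affine = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (any(data < 0)) stop("labels must be non-negative")
  if (any(data != round(data))) stop("label image must be integer-valued")
  present <- sort(unique(as.vector(data)))
  present <- present[present != 0]
  unknown <- setdiff(present, labels)
  if (length(unknown))
    stop("label image contains values absent from the label map: ",
         paste(unknown, collapse = ", "))
  storage.mode(data) <- "integer"
  structure(list(data = data, labels = setNames(as.integer(labels),
                                                names(labels)),
                 affine = affine),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s: %d labels>\n",
              paste(dim(x$data), collapse = "x"), length(x$labels)))
  invisible(x)
}

#' Extract a binary mask for one label
#' @param labvol A [label_volume()].
#' @param name Label name.
#' @export
label_mask <- function(labvol, name) {
  stopifnot(inherits(labvol, "label_volume"))
  if (!name %in% names(labvol$labels)) stop("unknown label: ", name)
  labvol$data == labvol$labels[[name]]
}

#' Read an integer label volume from NIfTI
#'
#' @param path_nifti Path to a 3-D NIfTI-1 volume with integer labels.
#' @param label_map Named integer vector; values in the image not covered by
#'   the map are a format error, non-integer voxel values a type error.
#' @export
read_labels <- function(path_nifti, label_map) {
  if (!file.exists(path_nifti)) stop("file not found: ", path_nifti)
  img <- RNifti::readNifti(path_nifti)
  arr <- unclass_keep_dim(as.array(img))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D label volume, got ", length(dim(arr)), " dimensions")
  if (any(arr != round(arr)))
    stop("label image is not integer-valued (float labels rejected)")
  label_volume(arr, label_map, affine = unclass(RNifti::xform(img)))
}

#' Write a label volume to NIfTI (int16 on disk)
#' @param labvol A [label_volume()].
#' @param path_nifti Output path.
#' @export
write_labels <- function(labvol, path_nifti) {
  stopifnot(inherits(labvol, "label_volume"))
  img <- RNifti::asNifti(unclass_keep_dim(labvol$data), datatype = "int16")
  if (!is.null(labvol$affine))
    RNifti::qform(img) <- structure(labvol$affine, code = 2L)
  RNifti::writeNifti(img, path_nifti)
  invisible(path_nifti)
}

#' Read / write a cohort table (TSV)
#'
#' The cohort table has one row per subject with at least the columns
#' `subject_id`, `group`, `age`, `sex`, `edss`, `treatment_naive`; per-shell
#' metric columns (e.g. `fa_v3`) are carried through untouched.
#' @param path Path to a tab-separated file.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "group", "age", "sex", "edss", "treatment_naive")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort table missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$subject_id))
    stop("duplicated subject ids in cohort table")
  d$group <- factor(d$group)
  d
}

#' @rdname read_cohort
#' @param cohort A cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
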