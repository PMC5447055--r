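#' Labeled 3D volume
#'
#' Lightweight container for an integer-labeled image on a voxel grid:
#' a 3D integer array (0 = background) plus a 4x4 voxel-to-world affine in
#' millimetres. This is the in-memory form of every mask, parcellation and
#' maximum probability map the pipeline touches.
#'
#' @param data 3D array of non-negative integer labels (0 = background).
#' @param affine 4x4 invertible voxel-to-world transform (mm). Defaults to
#'   identity.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4))) {
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  }
  if (abs(det(affine)) < 1e-12) {
    stop("`affine` must be invertible", call. = FALSE)
  }
  dv <- as.vector(data)
  if (anyNA(dv) || any(abs(dv - round(dv)) > 1e-6)) {
    stop("label data must be integer-valued (within 1e-6)", call. = FALSE)
  }
  if (any(dv < 0)) {
    stop("labels must be non-negative", call. = FALSE)
  }
  arr <- array(as.integer(round(dv)), dim = dim(data))
  structure(
    list(data = arr, affine = unname(affine)),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(x$data[x$data != 0]))
  cat(
    "<label_volume> ", paste(dim(x$data), collapse = " x "),
    " grid, ", sum(x$data != 0), " labeled voxels, labels {",
    paste(utils::head(labs, 8), collapse = ", "),
    if (length(labs) > 8) ", ..." else "", "}\n",
    sep = ""
  )
  invisible(x)
}

#' Read a labeled NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` image and checks that its data are
#' integer-valued labels. The sform affine is preserved.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) {
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4, 4))
  label_volume(arr, aff)
}

#' Write a labeled volume as NIfTI-1
#'
#' Stored with an integer datatype so label round-trips are bit-exact.
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Write a real-valued probability volume as NIfTI-1
#'
#' Probability maps are stored as 32-bit float; label images use
#' [write_label_volume()].
#'
#' @param data 3D numeric array.
#' @param path Output path.
#' @param affine 4x4 voxel-to-world transform.
#' @return Invisibly, `path`.
#' @export
write_probability_volume <- function(data, path, affine = diag(4)) {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(unname(affine), code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Extract seed-voxel coordinates from a mask
#'
#' Returns the 0-based voxel coordinates of all non-zero voxels, in
#' lexicographic (x, then y, then z) order. This ordering is the row order
#' of every downstream matrix and is deterministic.
#'
#' @param vol A [label_volume()] seed mask.
#' @return A tibble with integer columns `x`, `y`, `z` (0-based), carrying
#'   the grid shape in attribute `"shape"`.
#' @export
extract_seed_coordinates <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  idx <- which(vol$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop("seed mask is empty (no non-zero voxels)", call. = FALSE)
  }
  idx <- idx - 1L # 0-based
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  out <- tibble::tibble(
    x = as.integer(idx[ord, 1]),
    y = as.integer(idx[ord, 2]),
    z = as.integer(idx[ord, 3])
  )
  attr(out, "shape") <- dim(vol$data)
  out
}

#' Write / read seed coordinates as plain text
#'
#' One "x y z" triple per line, 0-based voxel indices.
#'
#' @param coords Tibble or matrix with columns x, y, z.
#' @param path File path.
#' @return `write_seed_coordinates()`: invisibly, `path`;
#'   `read_seed_coordinates()`: a tibble of integer coordinates.
#' @export
write_seed_coordinates <- function(coords, path) {
  m <- as.matrix(coords[, c("x", "y", "z")])
  lines <- if (nrow(m) == 0) character(0) else apply(m, 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_seed_coordinates
#' @export
read_seed_coordinates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  tibble::tibble(
    x = as.integer(m[, 1]), y = as.integer(m[, 2]), z = as.integer(m[, 3])
  )
}

#' Write / read a numeric matrix as delimited text
#'
#' The format is a one-line header "rows cols" followed by one
#' whitespace-delimited row per line, full double precision. Round-trips
#' are exact to below 1e-12.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `write_matrix()`: invisibly, `path`; `read_matrix()`: a matrix.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  utils::write.table(
    format(m, digits = 17, trim = TRUE, scientific = TRUE),
    con,
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- scan(path, what = integer(), n = 2, quiet = TRUE)
  body <- scan(path, what = double(), skip = 1, quiet = TRUE)
  if (length(body) != hdr[1] * hdr[2]) {
    stop(
      "matrix file dimension mismatch: header says ", hdr[1], "x", hdr[2],
      " but ", length(body), " values present",
      call. = FALSE
    )
  }
  matrix(body, nrow = hdr[1], ncol = hdr[2], byrow = TRUE)
}
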