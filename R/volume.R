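#' 3D image volume
#'
#' A `oto_volume` holds a 3D scalar image together with its voxel spacing.
#' Arrays are stored internally in (depth, height, width) = (Z, Y, X) order;
#' the NIfTI on-disk (X, Y, Z) order is mapped to this convention at read time
#' and restored at write time, so one unambiguous internal order is used
#' throughout the package.
#'
#' @param data 3D numeric array, axis order (Z, Y, X).
#' @param spacing Numeric length-3, mm per voxel along (Z, Y, X); all > 0.
#' @param source_id Character identifier for provenance.
#' @return An object of class `oto_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), source_id = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("every axis of `data` must have length >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive reals (mm per voxel)", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, source_id = as.character(source_id)[1]),
    class = "oto_volume"
  )
}

#' Binary label mask
#'
#' A label mask aligned to a [volume()]: same shape, same spacing, values
#' exactly 0 or 1.  Foreground (1) marks aneurysm voxels; vessels and brain
#' are background, since the segmentation target is the aneurysm alone.
#'
#' @inheritParams volume
#' @return An object of class `c("oto_mask", "oto_volume")`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), source_id = "mask") {
  v <- volume(data, spacing, source_id)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1)))
    stop("label mask values must be exactly 0 or 1", call. = FALSE)
  class(v) <- c("oto_mask", "oto_volume")
  v
}

#' @export
print.oto_volume <- function(x, ...) {
  kind <- if (inherits(x, "oto_mask")) "label mask" else "volume"
  cat(sprintf("<%s '%s'> %s, spacing %s mm (Z,Y,X)\n", kind, x$source_id,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  if (inherits(x, "oto_mask"))
    cat(sprintf("  foreground voxels: %d (%.3g%%)\n", sum(x$data),
                100 * mean(x$data)))
  invisible(x)
}

# Accept an oto_volume or a bare 3D array.
as_vol_array <- function(x) {
  if (inherits(x, "oto_volume")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected an oto_volume or a 3D array", call. = FALSE)
}

vol_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "oto_volume")) x$spacing else default
}

#' Read a NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file into an [volume()] (or [label_mask()] with
#' `mask = TRUE`).  Intensities are passed through unmodified: no rescaling,
#' no reorientation beyond the axis permutation into the internal (Z, Y, X)
#' order.  Voxel spacing is taken from the header `pixdim`.
#'
#' @param path Path to a NIfTI file.
#' @param mask Logical; validate and return as a [label_mask()].
#' @param source_id Identifier; defaults to the file name.
#' @return An `oto_volume` (or `oto_mask`).
#' @export
read_volume <- function(path, mask = FALSE, source_id = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  img <- tryCatch(
    suppressWarnings(RNifti::readNifti(path)),
    error = function(e) stop(sprintf("not a readable NIfTI file: '%s' (%s)",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s' is not a 3D image", path), call. = FALSE)
  sp_xyz <- RNifti::pixdim(img)[1:3]
  dat <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  if (is.null(source_id)) source_id <- basename(path)
  if (mask) label_mask(dat, rev(sp_xyz), source_id)
  else volume(dat, rev(sp_xyz), source_id)
}

#' Write a volume to NIfTI
#'
#' Lossless within float representation; integer-valued data (e.g. masks)
#' round-trips bit for bit.  The internal (Z, Y, X) array is written in NIfTI
#' (X, Y, Z) order with spacing restored to the header.
#'
#' @param v An [volume()] or [label_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "oto_volume"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: '%s'", dirname(path)), call. = FALSE)
  img <- RNifti::asNifti(aperm(v$data, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(v$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a dataset manifest
#'
#' A manifest is a CSV with columns `image`, `label`, `split` pairing image
#' volumes with their label masks and assigning each case to the train or
#' test split.  Every train entry must have a label; paths must be unique.
#'
#' @param path Path to a manifest CSV.
#' @return A data frame of class `oto_manifest`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(df, dir = dirname(path))
}

validate_manifest <- function(df, dir = ".") {
  req <- c("image", "label", "split")
  if (!all(req %in% names(df)))
    stop("manifest must have columns image, label, split", call. = FALSE)
  df <- df[, req, drop = FALSE]
  if (nrow(df) > 0) {
    if (!all(df$split %in% c("train", "test")))
      stop("manifest split tags must be 'train' or 'test'", call. = FALSE)
    nolab <- is.na(df$label) | df$label == ""
    if (any(df$split == "train" & nolab))
      stop("every train entry must have a label path", call. = FALSE)
    paths <- c(df$image, df$label[!nolab])
    if (anyDuplicated(paths))
      stop("manifest paths must be unique", call. = FALSE)
  }
  attr(df, "dir") <- dir
  class(df) <- c("oto_manifest", "data.frame")
  df
}

#' @export
print.oto_manifest <- function(x, ...) {
  cat(sprintf("<manifest> %d train / %d test cases\n",
              sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

# Resolve a manifest path relative to the manifest's own directory.
manifest_path <- function(m, p) {
  dir <- attr(m, "dir")
  if (is.null(dir)) return(p)
  ifelse(file.exists(p), p, file.path(dir, p))
}
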