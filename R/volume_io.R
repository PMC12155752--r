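## Multi-contrast volume container and canonicalisation: NIfTI I/O,
## adaptive resampling, brain-mask application, channel concatenation,
## per-channel intensity normalisation and grid resizing.  Skull stripping
## and cross-contrast registration are accepted as precomputed inputs.

CHANNEL_NAMES <- c("t1", "t2", "flair")

#' Construct a multi-contrast volume
#'
#' Three co-registered 3D intensity channels on one voxel grid, in the
#' fixed order T1-weighted, T2-weighted, FLAIR.
#'
#' @param data numeric 4D array, dim `c(X, Y, Z, 3)`, all values finite.
#' @param spacing_mm voxel size triple in millimetres.
#' @param provenance free-text source tag.
#' @return an object of class `multicontrast_volume` with fields `data`,
#'   `spacing_mm`, `provenance`.
#' @export
multicontrast_volume <- function(data, spacing_mm = c(1, 1, 1),
                                 provenance = "unknown") {
  if (length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop_mcmae("expected a 4D array with 3 channels on the 4th axis, got dim %s",
               paste(dim(data), collapse = "x"))
  if (!all(is.finite(data)))
    stop_mcmae("volume contains non-finite voxels")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop_mcmae("spacing_mm must be three positive values")
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 provenance = provenance),
            class = "multicontrast_volume")
}

#' @export
print.multicontrast_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("multicontrast_volume %dx%dx%d (T1/T2/FLAIR), spacing %s mm [%s]\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 3), collapse = "x"), x$provenance))
  invisible(x)
}

vol_shape <- function(vol) dim(vol$data)[1:3]

#' Read / write a multi-contrast volume as 4D NIfTI
#'
#' Files carry the three contrasts as 3 volumes along the 4th axis in
#' T1/T2/FLAIR order.  `read_volume` rejects files with any other channel
#' count or non-finite voxels; a write/read round trip preserves voxel
#' values to within 1e-6 (float storage) and spacing exactly.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param vol a `multicontrast_volume`.
#' @return `read_volume`: a `multicontrast_volume`; `write_volume`: the
#'   path, invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop_mcmae("'%s': expected 3 volumes along the 4th axis, got dim %s",
               path, paste(dim(arr), collapse = "x"))
  if (!all(is.finite(arr)))
    stop_mcmae("'%s' contains non-finite voxels", path)
  spacing <- RNifti::pixdim(img)[1:3]
  multicontrast_volume(array(as.numeric(arr), dim = dim(arr)),
                       spacing_mm = spacing, provenance = path)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "multicontrast_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$spacing_mm, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Concatenate three single-channel grids into a multi-contrast volume
#'
#' @param t1,t2,flair 3D numeric arrays of identical shape.
#' @param spacing_mm voxel spacing.
#' @return a `multicontrast_volume` with channels in T1/T2/FLAIR order.
#' @export
concatenate_channels <- function(t1, t2, flair, spacing_mm = c(1, 1, 1)) {
  chans <- list(t1 = t1, t2 = t2, flair = flair)
  ref <- dim(t1)
  if (length(ref) != 3L) stop_mcmae("t1 must be a 3D array")
  for (nm in names(chans))
    if (!identical(dim(chans[[nm]]), ref))
      stop_mcmae("channel '%s' has shape %s, expected %s", nm,
                 paste(dim(chans[[nm]]), collapse = "x"),
                 paste(ref, collapse = "x"))
  data <- array(0, dim = c(ref, 3L))
  for (i in 1:3) data[, , , i] <- chans[[i]]
  multicontrast_volume(data, spacing_mm, provenance = "concatenated")
}

#' Split a multi-contrast volume into its named channels
#'
#' @param vol a `multicontrast_volume`.
#' @return list with 3D arrays `t1`, `t2`, `flair`.
#' @export
split_channels <- function(vol) {
  stopifnot(inherits(vol, "multicontrast_volume"))
  out <- lapply(1:3, function(i) vol$data[, , , i, drop = TRUE])
  names(out) <- CHANNEL_NAMES
  out
}

# trilinear sample of a 3D grid at separable 0-based input coordinates
trilinear_grid <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  array(cpp_trilinear(as.numeric(arr), d[1], d[2], d[3],
                      as.numeric(xi), as.numeric(yi), as.numeric(zi)),
        dim = c(length(xi), length(yi), length(zi)))
}

#' Adaptively resample a single-channel grid
#'
#' Volumetric T1-style acquisitions are resampled to 1 mm isotropic;
#' planar (2D multi-slice) acquisitions are resampled to 0.8 x 0.8 mm
#' in-plane with the slice spacing left unchanged.  Interpolation is
#' trilinear with voxel-centre alignment; the output grid covers the
#' input's physical extent.
#'
#' @param grid 3D numeric array.
#' @param spacing_mm input voxel spacing (positive).
#' @param acquisition_kind `"volumetric_t1"` or `"planar"`.
#' @return list with `grid` (resampled array) and `spacing_mm`.
#' @export
resample_adaptive <- function(grid, spacing_mm,
                              acquisition_kind = c("volumetric_t1", "planar")) {
  acquisition_kind <- match.arg(acquisition_kind)
  if (length(dim(grid)) != 3L) stop_mcmae("grid must be a 3D array")
  if (any(spacing_mm <= 0)) stop_mcmae("spacing must be positive")
  new_spacing <- if (acquisition_kind == "volumetric_t1") c(1, 1, 1)
                 else c(0.8, 0.8, spacing_mm[3])
  d <- dim(grid)
  extent <- d * spacing_mm
  nd <- pmax(1L, as.integer(round(extent / new_spacing)))
  coords <- lapply(1:3, function(a) {
    # output voxel centres mapped into input voxel-index space
    ((seq_len(nd[a]) - 0.5) * new_spacing[a]) / spacing_mm[a] - 0.5
  })
  list(grid = trilinear_grid(grid, coords[[1]], coords[[2]], coords[[3]]),
       spacing_mm = new_spacing)
}

#' Apply a brain mask to a multi-contrast volume
#'
#' Voxels outside the mask are set to exactly 0 in all channels; voxels
#' inside are untouched (the skull-stripping mask multiplication step).
#'
#' @param vol a `multicontrast_volume`.
#' @param mask logical 3D array matching the channel shape.
#' @return the masked `multicontrast_volume`.
#' @export
apply_brain_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "multicontrast_volume"))
  if (!identical(dim(mask), as.integer(vol_shape(vol))) &&
      !identical(as.integer(dim(mask)), as.integer(vol_shape(vol))))
    stop_mcmae("mask shape %s does not match volume shape %s",
               paste(dim(mask), collapse = "x"),
               paste(vol_shape(vol), collapse = "x"))
  m <- array(as.numeric(mask != 0), dim = dim(mask))
  for (i in 1:3) vol$data[, , , i] <- vol$data[, , , i] * m
  vol
}

#' Min-max normalise each channel to [0, 1]
#'
#' Scaling statistics are computed over non-zero voxels only (skull-
#' stripped backgrounds are exact zeros and would otherwise pin the
#' minimum); exact-zero background stays 0.  A channel whose non-zero
#' values already span `[0, 1]` and attain 1 is left unchanged — this
#' makes the operation idempotent even though the first pass maps the
#' channel minimum to an exact 0 that is indistinguishable from
#' background afterwards.  A constant non-zero channel maps its voxels
#' to 0 with a warning.
#'
#' @param vol a `multicontrast_volume`.
#' @return the normalised volume (idempotent).
#' @export
normalize_intensity <- function(vol) {
  stopifnot(inherits(vol, "multicontrast_volume"))
  for (i in 1:3) {
    ch <- vol$data[, , , i]
    nz <- ch != 0
    if (!any(nz)) next
    rng <- range(ch[nz])
    if (rng[1] >= 0 && rng[2] == 1 && rng[1] < rng[2]) next
    if (rng[2] > rng[1]) {
      ch[nz] <- (ch[nz] - rng[1]) / (rng[2] - rng[1])
    } else {
      warning(sprintf("channel %s is constant (value %g); mapped to 0",
                      CHANNEL_NAMES[i], rng[1]))
      ch[nz] <- 0
    }
    vol$data[, , , i] <- ch
  }
  vol
}

#' Trilinearly resize a multi-contrast volume to a target grid
#'
#' Voxel-centre aligned trilinear resize of every channel; if the input
#' was normalised (all values in `[0, 1]`) the output is clipped back to
#' `[0, 1]`.  Spacing metadata is scaled so the physical extent is
#' preserved.
#'
#' @param vol a `multicontrast_volume`.
#' @param target_shape integer triple, each >= 4.
#' @return the resized `multicontrast_volume`.
#' @export
resize_to_grid <- function(vol, target_shape) {
  stopifnot(inherits(vol, "multicontrast_volume"))
  target_shape <- assert_shape3(target_shape, "target_shape")
  if (any(target_shape < 4))
    stop_mcmae("every target dimension must be >= 4")
  d <- vol_shape(vol)
  was_normalised <- min(vol$data) >= 0 && max(vol$data) <= 1
  scale <- d / target_shape
  coords <- lapply(1:3, function(a)
    (seq_len(target_shape[a]) - 0.5) * scale[a] - 0.5)
  data <- array(0, dim = c(target_shape, 3L))
  for (i in 1:3)
    data[, , , i] <- trilinear_grid(vol$data[, , , i, drop = TRUE],
                                    coords[[1]], coords[[2]], coords[[3]])
  if (was_normalised) data <- pmin(pmax(data, 0), 1)
  multicontrast_volume(data, spacing_mm = vol$spacing_mm * scale,
                       provenance = vol$provenance)
}

#' Standard preprocessing chain
#'
#' Applies brain-mask multiplication, per-channel normalisation and the
#' resize to the model grid, in that order (resampling to standard
#' spacing is applied per input channel with [resample_adaptive()] before
#' concatenation when starting from raw grids).
#'
#' @param vol a `multicontrast_volume` (already co-registered channels).
#' @param mask logical brain mask, or `NULL` to skip.
#' @param target_shape model grid.
#' @return the preprocessed volume.
#' @export
preprocess_volume <- function(vol, mask = NULL, target_shape = c(128, 128, 64)) {
  if (!is.null(mask)) vol <- apply_brain_mask(vol, mask)
  vol <- normalize_intensity(vol)
  resize_to_grid(vol, target_shape)
}
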