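## Random block masking for the cross-contrast context-recovery pretext
## task.  Each channel receives an independent draw of axis-aligned cubic
## blocks placed uniformly over all fully-inside positions, so recovery of
## a masked region can rely on the other contrasts at the same location.

#' Define a block-masking scheme
#'
#' @param n_blocks number of cubic blocks (default 84).
#' @param block_edge block edge length in voxels (default 16).
#' @param fill_value value written into masked voxels (default 0, equal to
#'   the background of a normalised volume).
#' @param seed integer seed.
#' @return a `mask_scheme` object.
#' @export
mask_scheme <- function(n_blocks = 84, block_edge = 16, fill_value = 0,
                        seed = 1) {
  if (n_blocks < 0) stop_mcmae("n_blocks must be >= 0")
  if (block_edge < 1) stop_mcmae("block_edge must be >= 1")
  structure(list(n_blocks = as.integer(n_blocks),
                 block_edge = as.integer(block_edge),
                 fill_value = fill_value, seed = as.integer(seed)),
            class = "mask_scheme")
}

#' Draw one random block mask
#'
#' `n_blocks` axis-aligned cubes of edge `block_edge` with corner offsets
#' drawn uniformly over all placements fully inside the grid; blocks may
#' overlap.  Deterministic per `(shape, scheme)`.
#'
#' @param shape grid dimensions.
#' @param scheme a [mask_scheme()].
#' @return logical 3D array, `TRUE` = masked.
#' @export
make_mask <- function(shape, scheme) {
  shape <- assert_shape3(shape)
  e <- scheme$block_edge
  if (any(e > shape))
    stop_mcmae("block_edge %d exceeds grid dimension (%s)", e,
               paste(shape, collapse = "x"))
  mask <- array(FALSE, dim = shape)
  if (scheme$n_blocks == 0) return(mask)
  with_seed(hash_seed(scheme$seed, 303L), {
    for (b in seq_len(scheme$n_blocks)) {
      corner <- vapply(1:3, function(a) sample.int(shape[a] - e + 1L, 1L),
                       integer(1))
      mask[corner[1]:(corner[1] + e - 1L),
           corner[2]:(corner[2] + e - 1L),
           corner[3]:(corner[3] + e - 1L)] <- TRUE
    }
  })
  mask
}

#' Draw independent masks for the three channels
#'
#' Three independent draws with channel-derived sub-seeds
#' (`hash(seed, channel)`), so the channels hide different regions and
#' cross-channel context stays informative.
#'
#' @inheritParams make_mask
#' @return a `channel_mask_set`: list of 3 logical arrays plus the scheme.
#' @export
make_channel_masks <- function(shape, scheme) {
  masks <- lapply(1:3, function(ch) {
    s <- scheme
    s$seed <- hash_seed(scheme$seed, ch)
    make_mask(shape, s)
  })
  names(masks) <- CHANNEL_NAMES
  structure(list(masks = masks, scheme = scheme), class = "channel_mask_set")
}

#' Apply channel masks to a multi-contrast volume
#'
#' Masked voxels are set to `fill_value`; unmasked voxels are untouched.
#' Pure: the input volume is not modified.
#'
#' @param vol a `multicontrast_volume`.
#' @param cms a `channel_mask_set`.
#' @param fill_value overrides the scheme's fill value if given.
#' @return the masked `multicontrast_volume`.
#' @export
apply_mask <- function(vol, cms, fill_value = NULL) {
  stopifnot(inherits(vol, "multicontrast_volume"),
            inherits(cms, "channel_mask_set"))
  fill <- fill_value %||% cms$scheme$fill_value
  for (i in 1:3) {
    m <- cms$masks[[i]]
    if (!identical(as.integer(dim(m)), as.integer(vol_shape(vol))))
      stop_mcmae("mask shape %s does not match volume shape %s",
                 paste(dim(m), collapse = "x"),
                 paste(vol_shape(vol), collapse = "x"))
    ch <- vol$data[, , , i]
    ch[m] <- fill
    vol$data[, , , i] <- ch
  }
  vol
}

#' Masked fraction of a mask, optionally within a reference region
#'
#' The whole-grid fraction is `mean(mask)`; with a `within` region (e.g.
#' the brain mask) the fraction of that region's voxels that are masked is
#' returned instead — the two accountings of "content masked" that the
#' block-count parameterisation supports.
#'
#' @param mask logical array.
#' @param within optional logical array of the same shape.
#' @return scalar fraction in `[0, 1]`.
#' @export
masked_fraction <- function(mask, within = NULL) {
  if (is.null(within)) return(mean(mask))
  stopifnot(identical(dim(mask), dim(within)))
  if (!any(within)) return(NA_real_)
  mean(mask[within])
}

#' Exact expected masked fraction under uniform fully-inside placement
#'
#' For a voxel v the per-block coverage probability is
#' `p(v) = cx(x) cy(y) cz(z) / n_placements`, with `c.(i)` the number of
#' admissible 1D offsets whose block covers coordinate i; the expected
#' masked fraction is the grid mean of `1 - (1 - p(v))^n_blocks`.  Exact
#' (separable) evaluation, used as the oracle for Monte-Carlo checks.
#'
#' @param shape grid dimensions.
#' @param n_blocks,block_edge scheme parameters.
#' @return expected fraction of grid voxels masked by at least one block.
#' @export
expected_mask_fraction <- function(shape, n_blocks, block_edge) {
  shape <- assert_shape3(shape)
  e <- block_edge
  cov1d <- function(n) {
    # admissible offsets 1..(n-e+1); coordinate i covered by offsets
    # max(1, i-e+1)..min(i, n-e+1)
    i <- seq_len(n)
    pmin(i, n - e + 1) - pmax(1, i - e + 1) + 1
  }
  cx <- cov1d(shape[1]); cy <- cov1d(shape[2]); cz <- cov1d(shape[3])
  total <- prod(shape - e + 1)
  p <- outer(outer(cx, cy), cz) / total
  mean(1 - (1 - p)^n_blocks)
}
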