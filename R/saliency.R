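## Occlusion-sensitivity saliency and the group-statistics chain:
## spatial smoothing, voxelwise GLM group contrast, and a max-statistic
## permutation test with threshold-free cluster enhancement (TFCE) for
## family-wise error control.

#' Occlusion parameters
#'
#' @param patch_edge cubic occlusion patch edge in voxels.
#' @param stride lattice stride between patch corners.
#' @param fill_value value written into the occluded patch (all
#'   channels).
#' @return an `occlusion_params` object.
#' @export
occlusion_params <- function(patch_edge = 16, stride = 8, fill_value = 0) {
  stopifnot(patch_edge >= 1, stride >= 1)
  structure(list(patch_edge = as.integer(patch_edge),
                 stride = as.integer(stride), fill_value = fill_value),
            class = "occlusion_params")
}

score_true_class <- function(model, arr, true_label) {
  if (is.function(model)) return(model(arr))
  fw <- cls_forward(model, arr2mat(arr))
  softmax2(fw$logits)[match(true_label, CLASS_LEVELS)]
}

#' Occlusion-sensitivity saliency map
#'
#' For every patch position on the stride lattice the patch is filled
#' with `fill_value` in all channels and the drop in the predicted
#' probability of the true class is recorded; per-voxel contributions are
#' accumulated over all covering patches and divided by the coverage
#' count.  Deterministic.
#'
#' @param model an `mcmae_classifier`, or a `function(array) -> score`
#'   stub returning the probability of the true class.
#' @param volume a `phantom_subject`, `multicontrast_volume` or 4D array
#'   on the model grid.
#' @param true_label the subject's true class (`"A"` or `"B"`).
#' @param params an [occlusion_params()].
#' @return a 3D saliency array with the volume's grid shape.
#' @export
occlusion_map <- function(model, volume, true_label,
                          params = occlusion_params()) {
  arr <- as_vol_array(volume)
  grid <- dim(arr)[1:3]
  e <- params$patch_edge
  if (any(e > grid))
    stop_mcmae("patch edge %d exceeds grid (%s)", e,
               paste(grid, collapse = "x"))
  base <- score_true_class(model, arr, true_label)
  acc <- array(0, dim = grid)
  cov <- array(0, dim = grid)
  offs <- lapply(1:3, function(a) seq(1L, grid[a] - e + 1L, by = params$stride))
  for (z0 in offs[[3]]) for (y0 in offs[[2]]) for (x0 in offs[[1]]) {
    occluded <- arr
    occluded[x0:(x0 + e - 1), y0:(y0 + e - 1), z0:(z0 + e - 1), ] <-
      params$fill_value
    drop <- base - score_true_class(model, occluded, true_label)
    acc[x0:(x0 + e - 1), y0:(y0 + e - 1), z0:(z0 + e - 1)] <-
      acc[x0:(x0 + e - 1), y0:(y0 + e - 1), z0:(z0 + e - 1)] + drop
    cov[x0:(x0 + e - 1), y0:(y0 + e - 1), z0:(z0 + e - 1)] <-
      cov[x0:(x0 + e - 1), y0:(y0 + e - 1), z0:(z0 + e - 1)] + 1
  }
  acc[cov > 0] <- acc[cov > 0] / cov[cov > 0]
  acc
}

#' Gaussian smoothing of a saliency map
#'
#' Smoothing with `sigma = fwhm / 2.3548` voxels and reflective
#' boundaries; `fwhm = 0` is the identity.
#'
#' @param map 3D numeric array.
#' @param fwhm_voxels full width at half maximum, in voxels (>= 0).
#' @return the smoothed map.
#' @export
smooth_map <- function(map, fwhm_voxels) {
  if (fwhm_voxels < 0) stop_mcmae("fwhm must be non-negative")
  if (fwhm_voxels == 0) return(map)
  gaussian_filter3(map, fwhm_voxels / (2 * sqrt(2 * log(2))))
}

#' Voxelwise two-sample GLM group contrast
#'
#' Pooled-variance two-sample t statistic for group A minus group B at
#' every voxel (the group-difference contrast of a two-column GLM).
#' Zero-variance voxels yield `t = 0` and are flagged in the
#' `zero_variance` attribute.
#'
#' @param maps_A,maps_B lists (>= 2 each) of 3D arrays on a common grid.
#' @return 3D t-statistic array with attribute `zero_variance`.
#' @export
glm_group_contrast <- function(maps_A, maps_B) {
  if (length(maps_A) < 2 || length(maps_B) < 2)
    stop_mcmae("each group needs at least 2 maps")
  grid <- dim(maps_A[[1]])
  a <- vapply(maps_A, as.numeric, numeric(prod(grid)))
  b <- vapply(maps_B, as.numeric, numeric(prod(grid)))
  tv <- pooled_t(cbind(a, b), seq_len(ncol(a)), ncol(a) + seq_len(ncol(b)))
  out <- array(tv$t, dim = grid)
  attr(out, "zero_variance") <- array(tv$zero_variance, dim = grid)
  out
}

# voxelwise pooled two-sample t from a V x n matrix and column indices
pooled_t <- function(M, idxA, idxB) {
  na <- length(idxA); nb <- length(idxB)
  a <- M[, idxA, drop = FALSE]; b <- M[, idxB, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums(a * a) - na * ma^2
  vb <- rowSums(b * b) - nb * mb^2
  sp2 <- pmax(va + vb, 0) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  zv <- se == 0
  t[zv] <- 0
  list(t = t, zero_variance = zv)
}

#' TFCE parameters
#'
#' @param E cluster-extent exponent (field-standard 0.5).
#' @param H cluster-height exponent (field-standard 2).
#' @param n_steps number of threshold integration steps.
#' @param connectivity 6, 18 or 26 (face/edge/corner neighbours).
#' @return a `tfce_params` object.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, n_steps = 100, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop_mcmae("connectivity must be 6, 18 or 26")
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel v, `TFCE(v) = sum over thresholds h of
#' e(v, h)^E * h^H * dh`, where `e(v, h)` is the voxel count of the
#' connected component containing v at threshold h.  The threshold axis
#' is discretised into `n_steps` midpoint steps up to the map maximum.
#' Negative values are enhanced separately on the negated map and
#' recombined with their sign.
#'
#' @param stat_map finite 3D statistic array.
#' @param params a [tfce_params()].
#' @return the TFCE-enhanced map (same shape, sign preserved).
#' @export
tfce <- function(stat_map, params = tfce_params()) {
  if (!all(is.finite(stat_map))) stop_mcmae("stat_map has non-finite values")
  d <- dim(stat_map)
  pos <- pmax(as.numeric(stat_map), 0)
  neg <- pmax(-as.numeric(stat_map), 0)
  out <- cpp_tfce_nonneg(pos, d[1], d[2], d[3], params$E, params$H,
                         params$n_steps, params$connectivity) -
         cpp_tfce_nonneg(neg, d[1], d[2], d[3], params$E, params$H,
                         params$n_steps, params$connectivity)
  array(out, dim = d)
}

#' Permutation test with TFCE and max-statistic FWER correction
#'
#' The observed pipeline is GLM contrast followed by TFCE.  The null
#' distribution is built by permuting group labels `n_perm` times and
#' recording the image-wide maximum absolute TFCE value per permutation;
#' the corrected p-value at voxel v is
#' `(1 + #\{perm max >= |TFCE_obs(v)|\}) / (n_perm + 1)` and the
#' significance mask thresholds it at `alpha`.
#'
#' @param maps_A,maps_B lists of 3D maps (>= 2 per group).
#' @param n_perm number of permutations (>= 99).
#' @param seed permutation seed.
#' @param params a [tfce_params()].
#' @param alpha family-wise significance level.
#' @return a `group_stats_result`: `t_map`, `tfce_map`, `p_map_fwer`,
#'   `sig_mask`, `perm_max`, `n_perm`, `alpha`.
#' @export
permutation_fwer <- function(maps_A, maps_B, n_perm = 199, seed = 1,
                             params = tfce_params(), alpha = 0.05) {
  if (n_perm < 99) stop_mcmae("n_perm must be >= 99")
  na <- length(maps_A); nb <- length(maps_B)
  n_distinct <- choose(na + nb, na)
  if (n_distinct < 20)
    warning(sprintf(
      "only %d distinct relabelings; minimum attainable corrected p is %.4f",
      n_distinct, 1 / n_distinct))
  t_obs <- glm_group_contrast(maps_A, maps_B)
  tf_obs <- tfce(t_obs, params)
  grid <- dim(t_obs)
  M <- vapply(c(maps_A, maps_B), as.numeric, numeric(prod(grid)))
  perm_max <- numeric(n_perm)
  with_seed(hash_seed(seed, 505L), {
    for (p in seq_len(n_perm)) {
      idx <- sample.int(na + nb)
      tp <- array(pooled_t(M, idx[seq_len(na)], idx[na + seq_len(nb)])$t,
                  dim = grid)
      perm_max[p] <- max(abs(tfce(tp, params)))
    }
  })
  obs <- abs(as.numeric(tf_obs))
  cnt <- vapply(obs, function(v) sum(perm_max >= v), numeric(1))
  p_map <- array((1 + cnt) / (n_perm + 1), dim = dim(t_obs))
  structure(list(t_map = t_obs, tfce_map = tf_obs, p_map_fwer = p_map,
                 sig_mask = p_map < alpha, perm_max = perm_max,
                 n_perm = n_perm, alpha = alpha),
            class = "group_stats_result")
}

#' Summarise significant clusters
#'
#' @param result a `group_stats_result`.
#' @return data.frame: cluster id, size (voxels), peak |t|, minimum
#'   corrected p, centroid voxel coordinates.
#' @export
cluster_summary <- function(result) {
  stopifnot(inherits(result, "group_stats_result"))
  d <- dim(result$sig_mask)
  lab <- array(cpp_label_components(as.vector(result$sig_mask),
                                    d[1], d[2], d[3], 26L), dim = d)
  if (max(lab) == 0)
    return(data.frame(cluster = integer(), size = integer(),
                      peak_t = numeric(), min_p = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric()))
  do.call(rbind, lapply(seq_len(max(lab)), function(k) {
    vox <- which(lab == k, arr.ind = TRUE)
    data.frame(cluster = k, size = nrow(vox),
               peak_t = max(abs(result$t_map[lab == k])),
               min_p = min(result$p_map_fwer[lab == k]),
               cx = mean(vox[, 1]), cy = mean(vox[, 2]), cz = mean(vox[, 3]))
  }))
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|a & b| / (|a| + |b|)`; `NA` when both masks are empty.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

#' Full saliency group-statistics chain
#'
#' Computes occlusion maps for the correctly classified subjects, smooths
#' them, and runs the GLM + TFCE permutation test between the two class
#' groups.
#'
#' @param model a trained `mcmae_classifier`.
#' @param subjects list of `phantom_subject`s.
#' @param occ an [occlusion_params()].
#' @param fwhm_voxels smoothing kernel FWHM.
#' @param n_perm,seed,tfce permutation settings.
#' @return list with `result` (a `group_stats_result`), `maps_A`,
#'   `maps_B`, `n_correct`, `records`.
#' @export
saliency_chain <- function(model, subjects, occ = occlusion_params(8, 4),
                           fwhm_voxels = 4, n_perm = 199, seed = 1,
                           tfce = tfce_params()) {
  records <- predict(model, subjects)
  correct <- which(records$predicted_label == records$true_label)
  maps <- list(A = list(), B = list())
  for (i in correct) {
    s <- subjects[[i]]
    m <- occlusion_map(model, s, s$class_label, occ)
    m <- smooth_map(m, fwhm_voxels)
    maps[[s$class_label]] <- c(maps[[s$class_label]], list(m))
  }
  res <- permutation_fwer(maps$A, maps$B, n_perm = n_perm, seed = seed,
                          params = tfce)
  list(result = res, maps_A = maps$A, maps_B = maps$B,
       n_correct = length(correct), records = records)
}
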