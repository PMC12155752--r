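## Synthetic multi-contrast phantom cohorts.
##
## A procedural stand-in for a clinical multi-contrast brain MRI cohort:
## one shared tissue-label map per subject (ellipsoidal shells plus a
## midline core, a ventricle and a posterior mass), rendered into three
## channels (T1w, T2w, FLAIR) whose tissue contrast rank orders differ, so
## that cross-channel context is genuinely informative for masked
## recovery.  Two classes differ by a localised structural effect whose
## voxels are recorded as a ground-truth lesion mask for validating the
## saliency statistics.

TISSUE_LABELS <- c(background = 0L, ventricle = 1L, grey = 2L,
                   white = 3L, midline_core = 4L, posterior_mass = 5L)

#' Channel lookup tables for phantom rendering
#'
#' Mean intensity per tissue label (rows: labels 0-5) for each channel
#' (columns: T1, T2, FLAIR).  The tables are fixed package constants; the
#' rank order of the five tissue intensities differs between channels
#' (e.g. CSF is darkest on T1/FLAIR but brightest on T2), which makes the
#' cross-contrast relationship non-trivial.
#'
#' @return a 6 x 3 numeric matrix with dimnames.
#' @export
tissue_lookup_tables <- function() {
  luts <- cbind(
    t1    = c(0, 0.15, 0.55, 0.90, 0.70, 0.62),
    t2    = c(0, 0.95, 0.62, 0.28, 0.50, 0.56),
    flair = c(0, 0.10, 0.80, 0.48, 0.66, 0.72))
  rownames(luts) <- names(TISSUE_LABELS)
  luts
}

# voxel-centre coordinates normalised to [-1, 1] along each axis
norm_coords <- function(n) 2 * (seq_len(n) - 0.5) / n - 1

ellipsoid_mask <- function(shape, centre, radii) {
  ux <- norm_coords(shape[1]); uy <- norm_coords(shape[2])
  uz <- norm_coords(shape[3])
  dx2 <- ((ux - centre[1]) / radii[1])^2
  dy2 <- ((uy - centre[2]) / radii[2])^2
  dz2 <- ((uz - centre[3]) / radii[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(arr <= 1, dim = shape)
}

#' Generate a seeded synthetic tissue-label map
#'
#' Builds a brain-like label geometry from jittered ellipsoids: a grey
#' matter shell (2) around a white matter core (3), with a midline
#' ventricle (1), a brainstem-like midline core (4) and a cerebellum-like
#' posterior mass (5); 0 is background.  Geometry parameters receive a
#' small per-seed jitter so subjects differ anatomically.
#'
#' @param shape integer triple of grid dimensions, each >= 16.
#' @param seed integer seed; identical `(shape, seed)` give bit-identical
#'   maps.
#' @return an object of class `tissue_map`: list with `labels` (integer
#'   array), `shape`, `seed`.
#' @export
generate_tissue_map <- function(shape = c(32, 32, 16), seed = 1) {
  shape <- assert_shape3(shape)
  if (any(shape < 16))
    stop_mcmae(
      "shape (%s) too small to place all six tissue classes; every dimension must be >= 16",
      paste(shape, collapse = "x"))
  with_seed(hash_seed(seed, 101L), {
    j <- function(scale = 0.05) 1 + runif(1, -scale, scale)
    o <- function(scale = 0.03) runif(1, -scale, scale)
    brain_r <- c(0.92 * j(), 0.92 * j(), 0.88 * j())
    brain_c <- c(o(), o(), o(0.02))
    labels <- array(0L, dim = shape)
    brain <- ellipsoid_mask(shape, brain_c, brain_r)
    labels[brain] <- TISSUE_LABELS[["grey"]]
    white <- ellipsoid_mask(shape, brain_c, 0.66 * brain_r) & brain
    labels[white] <- TISSUE_LABELS[["white"]]
    posterior <- ellipsoid_mask(
      shape, c(brain_c[1] + o(), 0.58 * j(0.04), -0.28 * j(0.04)),
      c(0.50 * j(), 0.33 * j(), 0.42 * j())) & brain
    labels[posterior] <- TISSUE_LABELS[["posterior_mass"]]
    core <- ellipsoid_mask(
      shape, c(brain_c[1] + o(0.02), 0.10 * j(0.04), -0.28 * j(0.04)),
      c(0.20 * j(), 0.28 * j(), 0.46 * j())) & brain
    labels[core] <- TISSUE_LABELS[["midline_core"]]
    ventricle <- ellipsoid_mask(
      shape, c(brain_c[1] + o(0.02), -0.08 * j(0.04), 0.14 * j(0.04)),
      c(0.28 * j(), 0.34 * j(), 0.30 * j())) & brain
    labels[ventricle] <- TISSUE_LABELS[["ventricle"]]
    structure(list(labels = labels, shape = shape, seed = as.integer(seed)),
              class = "tissue_map")
  })
}

# one 6-connected binary morphology step via array shifts
shift3 <- function(a, d, axis) {
  out <- array(FALSE, dim = dim(a))
  n <- dim(a)[axis]
  src <- seq_len(n - abs(d))
  if (d > 0) dst <- src + d else { dst <- src; src <- src + abs(d) }
  ix <- rep(list(quote(expr = )), 3)
  ixs <- ix; ixs[[axis]] <- src
  ixd <- ix; ixd[[axis]] <- dst
  out_call <- as.call(c(list(quote(`[<-`), quote(out)), ixd,
                        list(as.call(c(list(quote(`[`), quote(a)), ixs)))))
  eval(out_call)
}

dilate6 <- function(mask) {
  out <- mask
  for (axis in 1:3) for (d in c(-1, 1)) out <- out | shift3(mask, d, axis)
  out
}

erode6 <- function(mask) !dilate6(!mask)

#' Apply the class-specific structural effect to a tissue map
#'
#' Class `"B"` (the midline phenotype) dilates the ventricle and erodes
#' the midline core; class `"A"` (the posterior phenotype) thins the
#' posterior mass.  The number of 6-connected morphology steps grows with
#' `effect_size` (`ceiling(2 * effect_size)` for the ventricle dilation,
#' `ceiling(effect_size)` for the erosions), so any positive effect
#' changes at least one voxel.  `effect_size = 0` returns the map
#' unchanged with an empty lesion mask.  The operation is deterministic;
#' `seed` is accepted for interface symmetry.
#'
#' @param map a `tissue_map`.
#' @param class_label `"A"` or `"B"`.
#' @param effect_size non-negative scalar.
#' @param seed unused (deterministic operation).
#' @return list with `map` (modified `tissue_map`) and `lesion_mask`
#'   (logical array marking exactly the changed voxels).
#' @export
apply_class_effect <- function(map, class_label, effect_size, seed = 0) {
  stopifnot(inherits(map, "tissue_map"))
  if (!is.numeric(effect_size) || effect_size < 0)
    stop_mcmae("effect_size must be a non-negative scalar")
  if (!class_label %in% c("A", "B"))
    stop_mcmae("unknown class label '%s' (expected 'A' or 'B')", class_label)
  labels <- map$labels
  if (effect_size > 0) {
    brain <- labels != 0L
    if (class_label == "B") {
      vent <- labels == TISSUE_LABELS[["ventricle"]]
      for (i in seq_len(ceiling(2 * effect_size))) vent <- dilate6(vent) & brain
      labels[vent] <- TISSUE_LABELS[["ventricle"]]
      core <- labels == TISSUE_LABELS[["midline_core"]]
      shrunk <- core
      for (i in seq_len(ceiling(effect_size))) shrunk <- erode6(shrunk)
      labels[core & !shrunk] <- TISSUE_LABELS[["white"]]
    } else {
      post <- labels == TISSUE_LABELS[["posterior_mass"]]
      shrunk <- post
      for (i in seq_len(ceiling(effect_size))) shrunk <- erode6(shrunk)
      labels[post & !shrunk] <- TISSUE_LABELS[["grey"]]
    }
  }
  lesion <- labels != map$labels
  out <- map
  out$labels <- labels
  list(map = out, lesion_mask = lesion)
}

# smooth multiplicative bias: two low-frequency plane waves
bias_field <- function(shape, amplitude) {
  if (amplitude == 0) return(array(1, dim = shape))
  ux <- norm_coords(shape[1]); uy <- norm_coords(shape[2])
  uz <- norm_coords(shape[3])
  f <- array(0, dim = shape)
  for (w in 1:2) {
    k <- runif(3, 0.4, 1.2); phi <- runif(1, 0, 2 * pi)
    phase <- outer(outer(k[1] * ux, k[2] * uy, `+`), k[3] * uz, `+`)
    f <- f + cos(pi * phase / 2 + phi)
  }
  1 + amplitude * f / 2
}

#' Render a tissue map into a three-channel intensity volume
#'
#' Each channel assigns its lookup-table intensity per tissue label, adds
#' Gaussian noise (non-background voxels only), multiplies by a smooth
#' random bias field, then min-max normalises the non-background voxels to
#' `[0, 1]`.  Background stays exactly 0 in every channel.
#'
#' @param map a `tissue_map`.
#' @param noise_sd,bias_field_amplitude non-negative scalars.
#' @param seed integer seed for noise and bias draw.
#' @return a [multicontrast_volume()].
#' @export
render_contrasts <- function(map, noise_sd = 0.05, bias_field_amplitude = 0.2,
                             seed = 1) {
  stopifnot(inherits(map, "tissue_map"))
  if (noise_sd < 0 || bias_field_amplitude < 0)
    stop_mcmae("noise_sd and bias_field_amplitude must be non-negative")
  shape <- map$shape
  luts <- tissue_lookup_tables()
  nb <- map$labels != 0L
  data <- array(0, dim = c(shape, 3L))
  with_seed(hash_seed(seed, 202L), {
    for (ch in 1:3) {
      v <- array(luts[map$labels + 1L, ch], dim = shape)
      if (noise_sd > 0) v[nb] <- v[nb] + rnorm(sum(nb), 0, noise_sd)
      if (bias_field_amplitude > 0)
        v <- v * bias_field(shape, bias_field_amplitude)
      vals <- v[nb]
      rng <- range(vals)
      if (rng[2] > rng[1]) vals <- (vals - rng[1]) / (rng[2] - rng[1])
      else vals <- rep(0, length(vals))
      v[] <- 0; v[nb] <- vals
      data[, , , ch] <- v
    }
  })
  multicontrast_volume(data, spacing_mm = c(1, 1, 1),
                       provenance = sprintf("phantom seed=%d", map$seed))
}

#' Generate one phantom subject
#'
#' Composes [generate_tissue_map()], [apply_class_effect()] and
#' [render_contrasts()] under sub-seeds derived from `seed`.
#'
#' @param class_label `"A"` (posterior phenotype, the PD-like positive
#'   class) or `"B"` (midline phenotype).
#' @param shape grid dimensions.
#' @param effect_size,noise_sd,bias_field_amplitude generator parameters.
#' @param seed subject seed.
#' @return an object of class `phantom_subject`: `volume`, `class_label`,
#'   `lesion_mask`, `subject_seed`.
#' @export
phantom_subject <- function(class_label, shape = c(32, 32, 16),
                            effect_size = 1, noise_sd = 0.05,
                            bias_field_amplitude = 0.2, seed = 1) {
  map <- generate_tissue_map(shape, seed = hash_seed(seed, 1L))
  eff <- apply_class_effect(map, class_label, effect_size)
  vol <- render_contrasts(eff$map, noise_sd, bias_field_amplitude,
                          seed = hash_seed(seed, 2L))
  structure(list(volume = vol, class_label = class_label,
                 lesion_mask = eff$lesion_mask,
                 subject_seed = as.integer(seed)),
            class = "phantom_subject")
}

#' Specify a phantom cohort
#'
#' @param n_per_class subjects per class (>= 10).
#' @param effect_size fractional morphological change between classes
#'   (0 = null cohort).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units, pre-normalisation).
#' @param bias_field_amplitude relative amplitude of the smooth
#'   multiplicative intensity bias.
#' @param shape grid dimensions (test profile default 32 x 32 x 16).
#' @param split_ratios train/validation/test ratios, normalised to sum 1.
#' @param master_seed master seed; subject seeds are hashed from it.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_class = 20, effect_size = 1, noise_sd = 0.05,
                        bias_field_amplitude = 0.2, shape = c(32, 32, 16),
                        split_ratios = c(8, 1, 1), master_seed = 1) {
  if (any(split_ratios < 0) || sum(split_ratios) <= 0)
    stop_mcmae("split_ratios must be non-negative with a positive sum")
  structure(list(n_per_class = as.integer(n_per_class),
                 effect_size = effect_size, noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 shape = assert_shape3(shape),
                 split_ratios = split_ratios / sum(split_ratios),
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# largest-remainder apportionment of n into splits
split_counts <- function(n, ratios) {
  raw <- n * ratios
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Generate a labelled, split phantom cohort
#'
#' Generates `n_per_class` subjects per class with per-subject seeds
#' hashed from the master seed, and a seeded stratified
#' train/validation/test split.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `phantom_cohort`: `subjects` (list of
#'   `phantom_subject`, each annotated with `subject_id` and `split`),
#'   `manifest` (data.frame: subject_id, class, split, seed), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_per_class < 10)
    stop_mcmae("n_per_class must be >= 10 (got %d)", spec$n_per_class)
  subjects <- list()
  manifest <- NULL
  split_names <- c("train", "val", "test")
  for (cls in c("A", "B")) {
    n <- spec$n_per_class
    cnt <- split_counts(n, spec$split_ratios)
    assign_split <- rep(split_names, times = cnt)
    perm <- with_seed(hash_seed(spec$master_seed, match(cls, c("A", "B")), 7L),
                      sample.int(n))
    splits <- assign_split[order(perm)]
    for (i in seq_len(n)) {
      sseed <- hash_seed(spec$master_seed, match(cls, c("A", "B")), i)
      subj <- phantom_subject(cls, spec$shape, spec$effect_size,
                              spec$noise_sd, spec$bias_field_amplitude,
                              seed = sseed)
      subj$subject_id <- sprintf("%s%03d", cls, i)
      subj$split <- splits[i]
      subjects[[subj$subject_id]] <- subj
      manifest <- rbind(manifest, data.frame(
        subject_id = subj$subject_id, class = cls, split = splits[i],
        seed = sseed, stringsAsFactors = FALSE))
    }
  }
  structure(list(subjects = subjects, manifest = manifest, spec = spec),
            class = "phantom_cohort")
}

#' Write a phantom cohort to disk
#'
#' One 4D NIfTI per subject plus a `manifest.csv`
#' (subject_id, class, split, seed, path).
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$path <- file.path(dir, paste0(manifest$subject_id, ".nii.gz"))
  for (i in seq_len(nrow(manifest)))
    write_volume(cohort$subjects[[manifest$subject_id[i]]]$volume,
                 manifest$path[i])
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf(
    "phantom_cohort: %d subjects/class, grid %s, effect_size %.3g\n",
    x$spec$n_per_class, paste(x$spec$shape, collapse = "x"),
    x$spec$effect_size))
  print(table(x$manifest$class, x$manifest$split))
  invisible(x)
}
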