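test_that("tissue maps are deterministic, complete and connected", {
  m1 <- generate_tissue_map(c(32, 32, 16), seed = 7)
  m2 <- generate_tissue_map(c(32, 32, 16), seed = 7)
  expect_identical(m1$labels, m2$labels)
  expect_setequal(unique(as.vector(m1$labels)), 0:5)
  # non-background voxels form one 26-connected component
  d <- dim(m1$labels)
  lab <- mcmae:::cpp_label_components(as.vector(m1$labels != 0),
                                      d[1], d[2], d[3], 26L)
  expect_equal(max(lab), 1L)
})

test_that("brain fraction stays in [0.2, 0.9] across a seed sweep", {
  fracs <- vapply(1:100, function(s)
    mean(generate_tissue_map(c(32, 32, 16), seed = s)$labels != 0),
    numeric(1))
  expect_true(all(fracs >= 0.2 & fracs <= 0.9))
  labsets <- vapply(c(2, 17, 63), function(s)
    length(unique(as.vector(generate_tissue_map(c(32, 32, 16), s)$labels))),
    numeric(1))
  expect_true(all(labsets == 6))
})

test_that("too-small grids are rejected with an explicit message", {
  expect_error(generate_tissue_map(c(12, 32, 16), 1), "16")
})

test_that("class effect: identity at zero, dilation for B, exact lesion mask", {
  m <- generate_tissue_map(c(32, 32, 16), seed = 3)
  id <- apply_class_effect(m, "B", 0)
  expect_identical(id$map$labels, m$labels)
  expect_false(any(id$lesion_mask))

  eff <- apply_class_effect(m, "B", 1)
  expect_gt(sum(eff$map$labels == 1), sum(m$labels == 1))
  # lesion mask equals the brute-force voxelwise diff
  expect_identical(eff$lesion_mask, eff$map$labels != m$labels)
  expect_true(all(m$labels[eff$lesion_mask] != 0 |
                  eff$map$labels[eff$lesion_mask] != 0))
  # lesions stay inside the brain
  expect_true(all(m$labels[eff$lesion_mask] != 0))

  effA <- apply_class_effect(m, "A", 1)
  expect_lt(sum(effA$map$labels == 5), sum(m$labels == 5))
  expect_identical(effA$lesion_mask, effA$map$labels != m$labels)
  expect_error(apply_class_effect(m, "C", 1), "unknown class")
})

test_that("ventricle growth is monotone in effect size for class B", {
  m <- generate_tissue_map(c(32, 32, 16), seed = 5)
  counts <- vapply(c(0, 0.5, 1, 1.5, 2, 3), function(e)
    sum(apply_class_effect(m, "B", e)$map$labels == 1), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # any positive effect changes at least one voxel
  expect_gt(sum(apply_class_effect(m, "B", 0.1)$lesion_mask), 0)
  expect_gt(sum(apply_class_effect(m, "A", 0.1)$lesion_mask), 0)
})

test_that("noise-free rendering is the normalised lookup table", {
  m <- generate_tissue_map(c(32, 32, 16), seed = 2)
  vol <- render_contrasts(m, noise_sd = 0, bias_field_amplitude = 0, seed = 1)
  luts <- tissue_lookup_tables()
  for (ch in 1:3) {
    lut <- luts[2:6, ch]
    lutn <- (lut - min(lut)) / (max(lut) - min(lut))
    v <- vol$data[, , , ch]
    expect_equal(sort(unique(v[m$labels != 0])), sort(unname(unique(lutn))),
                 tolerance = 1e-12)
    # piecewise constant per label, background exactly zero
    for (l in 1:5)
      expect_true(all(v[m$labels == l] == lutn[l]))
    expect_true(all(v[m$labels == 0] == 0))
  }
  # channels are not voxelwise identical
  expect_false(isTRUE(all.equal(vol$data[, , , 1], vol$data[, , , 2])))
  expect_false(isTRUE(all.equal(vol$data[, , , 2], vol$data[, , , 3])))
})

test_that("channel-pair mutual information matches the label-histogram oracle", {
  m <- generate_tissue_map(c(32, 32, 16), seed = 4)
  vol <- render_contrasts(m, 0, 0, seed = 1)
  nb <- m$labels != 0
  mi <- function(joint) {
    p <- joint / sum(joint)
    px <- rowSums(p); py <- colSums(p)
    s <- 0
    for (i in seq_along(px)) for (j in seq_along(py))
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    s
  }
  v1 <- vol$data[, , , 1][nb]; v2 <- vol$data[, , , 2][nb]
  mi_vox <- mi(table(v1, v2))
  # oracle: joint distribution reconstructed from tissue-label counts
  luts <- tissue_lookup_tables()
  norm_lut <- function(ch) {
    lut <- luts[2:6, ch]; (lut - min(lut)) / (max(lut) - min(lut))
  }
  lab <- m$labels[nb]
  joint <- table(norm_lut(1)[lab], norm_lut(2)[lab])
  expect_equal(mi_vox, mi(joint), tolerance = 1e-6)
})

test_that("rendering adds noise and bias but keeps range and background", {
  m <- generate_tissue_map(c(32, 32, 16), seed = 6)
  vol <- render_contrasts(m, 0.05, 0.3, seed = 9)
  expect_true(all(vol$data >= 0 & vol$data <= 1))
  for (ch in 1:3) expect_true(all(vol$data[, , , ch][m$labels == 0] == 0))
  vol2 <- render_contrasts(m, 0.05, 0.3, seed = 9)
  expect_identical(vol$data, vol2$data)
})

test_that("cohorts split 8:1:1 deterministically into disjoint exhaustive sets", {
  spec <- cohort_spec(20, 1, 0.05, 0.2, c(32, 32, 16), master_seed = 3)
  coh <- generate_cohort(spec)
  tab <- table(coh$manifest$class, coh$manifest$split)
  expect_equal(unname(tab["A", c("train", "val", "test")]), c(16, 2, 2))
  expect_equal(unname(tab["B", c("train", "val", "test")]), c(16, 2, 2))
  # partition property
  expect_setequal(coh$manifest$subject_id, names(coh$subjects))
  expect_equal(anyDuplicated(coh$manifest$subject_id), 0L)
  # determinism: same spec twice gives identical volumes and assignment
  coh2 <- generate_cohort(spec)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$subjects[["A005"]]$volume$data,
                   coh2$subjects[["A005"]]$volume$data)
  expect_error(generate_cohort(cohort_spec(5)), "n_per_class")
  expect_error(cohort_spec(20, split_ratios = c(8, -1, 1)), "non-negative")
})

test_that("effect-free cohorts are exchangeable in brain volume", {
  vols <- vapply(1:2, function(cl_i) {
    vapply(1:50, function(i) {
      s <- phantom_subject(c("A", "B")[cl_i], c(32, 32, 16), 0, 0.05, 0.2,
                           seed = hash_seed(321, cl_i, i))
      sum(s$volume$data[, , , 1] > 0)
    }, numeric(1))
  }, numeric(50))
  obs <- abs(mean(vols[, 1]) - mean(vols[, 2]))
  pooled <- c(vols[, 1], vols[, 2])
  set.seed(17)
  perm <- replicate(999, {
    p <- sample(100)
    abs(mean(pooled[p[1:50]]) - mean(pooled[p[51:100]]))
  })
  p_val <- (1 + sum(perm >= obs)) / 1000
  expect_gt(p_val, 0.01)
})

test_that("lesion mask is empty iff effect size is zero", {
  for (e in c(0, 0.25, 1, 2)) {
    s <- phantom_subject("B", c(32, 32, 16), e, 0.05, 0.2, seed = 8)
    expect_identical(sum(s$lesion_mask) > 0, e > 0)
  }
})

test_that("cohorts round-trip through NIfTI with a manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(10, 1, 0.05, 0.2, c(32, 32, 16),
                                     master_seed = 2))
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 20)
  v <- read_volume(man$path[1])
  expect_lt(max(abs(v$data - coh$subjects[[man$subject_id[1]]]$volume$data)),
            1e-6)
})
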