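test_that("occlusion maps: stubs behave analytically", {
  vol <- rand_volume(c(16, 16, 8), seed = 2)
  # constant-output model: no probability ever changes
  m0 <- occlusion_map(function(arr) 0.75, vol, "A",
                      occlusion_params(4, 2, 0))
  expect_equal(dim(m0), c(16, 16, 8))
  expect_true(all(m0 == 0))
  # scorer that reads a single voxel: saliency peaks on that voxel and is
  # zero away from every patch that covers it
  v <- c(9, 8, 5)
  stub <- function(arr) arr[v[1], v[2], v[3], 1]
  m <- occlusion_map(stub, vol, "A", occlusion_params(4, 2, 0))
  # the read voxel attains the maximum (voxels sharing all its covering
  # patches tie with it), and voxels far from it stay at zero
  expect_equal(m[v[1], v[2], v[3]], max(m))
  expect_gt(max(m), 0)
  expect_equal(m[1, 1, 1], 0)
  expect_error(occlusion_map(stub, vol, "A", occlusion_params(32, 2)),
               "patch edge")
})

test_that("smoothing: identity at zero, kernel peak, constants preserved", {
  set.seed(3)
  m <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  expect_identical(smooth_map(m, 0), m)
  expect_error(smooth_map(m, -1), "non-negative")
  expect_true(all(abs(smooth_map(array(2.5, c(12, 12, 8)), 4) - 2.5) < 1e-12))
  # delta response equals the separable kernel's central weight
  d <- array(0, c(17, 17, 17)); d[9, 9, 9] <- 1
  sm <- smooth_map(d, 4)
  sigma <- 4 / (2 * sqrt(2 * log(2)))
  r <- floor(3.5 * sigma + 0.5)
  k <- exp(-0.5 * ((-r:r) / sigma)^2); k <- k / sum(k)
  expect_equal(sm[9, 9, 9], max(k)^3, tolerance = 1e-6)
})

test_that("group contrast matches a hand-computed pooled t", {
  # 2 voxels, 3 vs 3 subjects
  mk <- function(a, b) array(c(a, b), c(2, 1, 1))
  A <- list(mk(1.0, 0.2), mk(1.4, 0.1), mk(1.2, 0.3))
  B <- list(mk(0.2, 0.2), mk(0.5, 0.2), mk(0.2, 0.2))
  t_map <- glm_group_contrast(A, B)
  hand_t <- function(x, y) {
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  expect_equal(t_map[1, 1, 1], hand_t(c(1, 1.4, 1.2), c(0.2, 0.5, 0.2)),
               tolerance = 1e-10)
  expect_equal(t_map[2, 1, 1], hand_t(c(0.2, 0.1, 0.3), c(0.2, 0.2, 0.2)),
               tolerance = 1e-10)
  # antisymmetry and the zero-variance flag
  expect_equal(as.vector(glm_group_contrast(B, A)), -as.vector(t_map))
  same <- glm_group_contrast(A, A)
  expect_true(all(same == 0))
  zv <- glm_group_contrast(list(mk(1, 1), mk(1, 1)), list(mk(1, 2), mk(1, 0)))
  expect_true(attr(zv, "zero_variance")[1, 1, 1])
  expect_equal(zv[1, 1, 1], 0)
  expect_error(glm_group_contrast(A[1], B), "at least 2")
})

test_that("tfce reproduces the single-voxel closed form and its scaling", {
  m <- array(0, c(8, 8, 8))
  expect_true(all(tfce(m) == 0))
  m[4, 4, 4] <- 0.7
  v <- tfce(m, tfce_params(E = 0.5, H = 2, n_steps = 1000))[4, 4, 4]
  expect_lt(abs(v - 0.7^3 / 3) / (0.7^3 / 3), 0.01)
  m2 <- m * 2
  v2 <- tfce(m2, tfce_params(n_steps = 1000))[4, 4, 4]
  expect_lt(abs(v2 / v - 8) / 8, 0.01)
  # negative lobes are enhanced with their sign
  expect_equal(as.vector(tfce(-m, tfce_params(n_steps = 200))),
               -as.vector(tfce(m, tfce_params(n_steps = 200))))
  expect_error(tfce(array(NA_real_, c(4, 4, 4))), "finite")
})

test_that("tfce matches a per-threshold labelling oracle on random maps", {
  set.seed(3)
  for (rep in 1:3) {
    m <- array(pmax(rnorm(8 * 8 * 6), 0), c(8, 8, 6))
    p <- tfce_params(E = 0.5, H = 2, n_steps = 37, connectivity = 26)
    got <- tfce(m, p)
    dh <- max(m) / 37
    want <- array(0, dim(m))
    for (s in 1:37) {
      h <- (s - 0.5) * dh
      mask <- m >= h
      lab <- array(mcmae:::cpp_label_components(as.vector(mask), 8, 8, 6, 26L),
                   dim(m))
      if (max(lab) > 0) {
        sz <- tabulate(lab[lab > 0])
        want[mask] <- want[mask] + sz[lab[mask]]^0.5 * h^2 * dh
      }
    }
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("tfce is pointwise monotone on nested non-negative maps", {
  # maps share their maximum so both integrals use the same threshold
  # grid (monotonicity holds exactly on a common discretisation)
  set.seed(8)
  for (rep in 1:5) {
    m1 <- array(runif(10 * 10 * 6, 0, 0.8), c(10, 10, 6))
    m2 <- pmin(m1 + array(runif(600, 0, 0.4), c(10, 10, 6)), 1)
    m1[1, 1, 1] <- 1; m2[1, 1, 1] <- 1
    t1 <- tfce(m1, tfce_params(n_steps = 50))
    t2 <- tfce(m2, tfce_params(n_steps = 50))
    expect_true(all(t2 - t1 >= -1e-9))
  }
})

test_that("permutation p-values respect estimator bounds and rescaling", {
  set.seed(12)
  mk <- function() array(rnorm(6 * 6 * 4), c(6, 6, 4))
  A <- replicate(5, mk(), simplify = FALSE)
  B <- replicate(5, mk(), simplify = FALSE)
  res <- permutation_fwer(A, B, n_perm = 99, seed = 3,
                          params = tfce_params(n_steps = 30))
  expect_true(all(res$p_map_fwer >= 1 / 100 & res$p_map_fwer <= 1))
  # common affine (monotone) rescaling leaves the p-map unchanged
  A2 <- lapply(A, function(m) 3 * m + 1)
  B2 <- lapply(B, function(m) 3 * m + 1)
  res2 <- permutation_fwer(A2, B2, n_perm = 99, seed = 3,
                           params = tfce_params(n_steps = 30))
  expect_equal(res$p_map_fwer, res2$p_map_fwer, tolerance = 1e-12)
  # too few distinct relabelings warns with the attainable minimum
  expect_warning(
    permutation_fwer(A[1:2], B[1:2], n_perm = 99, seed = 1,
                     params = tfce_params(n_steps = 10)),
    "distinct relabelings")
  expect_error(permutation_fwer(A, B, n_perm = 50), "99")
})

test_that("the saliency chain localises the implanted class effect", {
  ch <- fx_saliency_chain()
  expect_gte(ch$n_correct, 20)
  res <- ch$result
  cs <- cluster_summary(res)
  expect_gte(nrow(cs), 1)
  # centroid of the largest significant cluster lies inside the dilated
  # ground-truth lesion region
  les <- Reduce(`|`, lapply(fx_saliency_subjects(), function(s) s$lesion_mask))
  dil <- mcmae:::dilate6(mcmae:::dilate6(les))
  ci <- round(as.numeric(cs[which.max(cs$size), c("cx", "cy", "cz")]))
  expect_true(dil[ci[1], ci[2], ci[3]])
  # desk-scale analogue of the anatomical claim: Dice >= 0.2
  expect_gte(dice_overlap(res$sig_mask, dil), 0.2)
})

test_that("the permutation test controls family-wise error under the null", {
  # per-repetition rejection probability is 9/200 = 0.045 by construction
  # (n_perm = 199, alpha = 0.05); 20 repetitions admit at most 3
  # rejections at the 2% binomial tail
  empty <- fx_null_fwer_empty()
  expect_lte(sum(!empty), 3)
})
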