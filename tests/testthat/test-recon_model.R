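test_that("encoder stage shapes follow the halving/width formula", {
  cfg <- encoder_config(24, 5, c(128, 128, 64))
  sh <- encoder_stage_shapes(cfg)
  for (i in 0:5) {
    expect_equal(unlist(sh[sh$stage == i, c("x", "y", "z")], use.names = FALSE),
                 c(128, 128, 64) / 2^i)
    expect_equal(sh$channels[sh$stage == i], 2^(max(i, 1) - 1) * 24)
  }
  # at any admissible feature size
  sh8 <- encoder_stage_shapes(encoder_config(8, 3, c(32, 32, 16)))
  expect_equal(sh8$channels, c(8, 8, 16, 32))
  expect_error(encoder_config(8, 5, c(128, 128, 60)), "dimension 3")
})

test_that("a forward pass realises the stage shapes and sigmoid range", {
  cfg <- encoder_config(4, 5, c(32, 32, 32))
  ae <- build_autoencoder(cfg, seed = 2)
  set.seed(3)
  x <- matrix(runif(32 * 32 * 32 * 3), ncol = 3)
  ec <- mcmae:::encoder_forward(ae$params, cfg, x)
  sh <- encoder_stage_shapes(cfg)
  for (i in 0:5) {
    expect_equal(nrow(ec$act[[i + 1]]), prod(32 / 2^i, 32 / 2^i, 32 / 2^i))
    expect_equal(ncol(ec$act[[i + 1]]), sh$channels[i + 1])
  }
  fw <- mcmae:::ae_forward(ae, x)
  expect_equal(dim(fw$recon), dim(x))
  expect_gt(min(fw$recon), 0)
  expect_lt(max(fw$recon), 1)
})

test_that("the compiled convolution matches a naive reference", {
  set.seed(10)
  X <- 5; Y <- 4; Z <- 3; Cin <- 2; Cout <- 2
  x <- matrix(rnorm(X * Y * Z * Cin), ncol = Cin)
  W <- matrix(rnorm(Cout * 27 * Cin, 0, 0.5), nrow = Cout)
  b <- rnorm(Cout)
  got <- mcmae:::conv3_fwd(x, c(X, Y, Z), W, b)
  xa <- array(x, c(X, Y, Z, Cin))
  naive <- array(0, c(X, Y, Z, Cout))
  for (co in 1:Cout) for (zz in 1:Z) for (yy in 1:Y) for (xx in 1:X) {
    acc <- b[co]; k <- 0
    for (ci in 1:Cin) for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      k <- k + 1
      px <- xx + dx; py <- yy + dy; pz <- zz + dz
      v <- if (px >= 1 && px <= X && py >= 1 && py <= Y &&
               pz >= 1 && pz <= Z) xa[px, py, pz, ci] else 0
      acc <- acc + W[co, k] * v
    }
    naive[xx, yy, zz, co] <- acc
  }
  expect_equal(as.vector(got), as.vector(matrix(naive, ncol = Cout)),
               tolerance = 1e-12)
})

test_that("loss components satisfy their algebraic contracts", {
  v <- rand_volume(c(16, 16, 8), seed = 1)$data
  expect_equal(recon_loss(v, v), 0)
  expect_equal(recon_loss(v, v + 0.1), 0.1, tolerance = 1e-12)
  # loop oracle on a random pair
  set.seed(2)
  a <- array(runif(120), c(5, 4, 3, 2)); b <- array(runif(120), c(5, 4, 3, 2))
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  expect_equal(recon_loss(a, b), s / length(a), tolerance = 1e-7)
  expect_equal(contrast_loss(a, b), contrast_loss(b, a))
  expect_equal(contrast_loss(a, a), 0)
  expect_equal(contrast_loss(a, a + 0.05), 0.05, tolerance = 1e-12)
  expect_equal(total_loss(0.5, 0), 0.5)
  expect_equal(total_loss(0.2, 0.1), 0.22, tolerance = 1e-15)
  expect_equal(total_loss(0, 17), 0)
  expect_error(total_loss(-0.1, 0.1), "non-negative")
  expect_error(recon_loss(a, array(0, c(5, 4, 3, 1))), "shape")
})

test_that("ssim and psnr match their closed forms", {
  set.seed(4)
  x <- array(runif(16 * 16 * 12), c(16, 16, 12))
  expect_equal(ssim3d(x, x), 1, tolerance = 1e-12)
  expect_equal(psnr(x, x + 0.1, max_value = 1), 20, tolerance = 1e-12)
  expect_equal(psnr(x, x), Inf)
  expect_error(ssim3d(x, array(0, c(16, 16, 11))), "shape")
})

test_that("ssim agrees with the reference implementation on random pairs", {
  # Expected values computed once with scikit-image
  # structural_similarity(gaussian_weights=TRUE, sigma=1.5,
  # use_sample_covariance=FALSE, data_range=1) on pairs generated exactly
  # as below, and frozen.
  expected <- c(
    0.94689001, 0.94989465, 0.95072361, 0.94673906, 0.93736396,
    0.93475296, 0.94389875, 0.94732086, 0.94846684, 0.94775784,
    0.94661136, 0.95496351, 0.93708180, 0.94992209, 0.95775948,
    0.94935593, 0.94358106, 0.95188908, 0.94910600, 0.94998798)
  set.seed(314)
  pairs <- lapply(1:20, function(i) {
    x <- array(runif(16 * 16 * 12), c(16, 16, 12))
    y <- pmin(pmax(x + rnorm(length(x), 0, 0.1), 0), 1)
    list(x = x, y = y)
  })
  got <- vapply(pairs, function(p) ssim3d(p$x, p$y), numeric(1))
  expect_true(all(abs(got - expected) < 1e-5))
})

test_that("pretrain step: stub-model oracle and loss identities", {
  s <- fx_pretrain_vols()[[1]]
  identity_stub <- function(arr) arr
  scheme <- mask_scheme(6, 8, fill_value = 0, seed = 42)
  st <- pretrain_step(identity_stub, list(s), scheme)
  # identity-on-masked-input model: L_recon is the mean absolute value of
  # the masked-out voxels, averaged over the two documented mask draws
  arr <- s$volume$data
  expected_lr <- mean(vapply(1:2, function(d) {
    sc <- scheme; sc$seed <- hash_seed(scheme$seed, 1L, d)
    cms <- make_channel_masks(dim(arr)[1:3], sc)
    masked <- apply_mask(s$volume, cms)
    mean(abs(arr - masked$data))
  }, numeric(1)))
  expect_equal(unname(st$loss["L_recon"]), expected_lr, tolerance = 1e-12)
  expect_equal(unname(st$loss["L_total"]),
               unname(st$loss["L_recon"] * (1 + st$loss["L_contrast"])),
               tolerance = 1e-12)
  # empty masks: both draws coincide, so the pair is consistent
  st0 <- pretrain_step(identity_stub, list(s), mask_scheme(0, 8, seed = 1))
  expect_equal(unname(st0$loss["L_contrast"]), 0)
  expect_equal(unname(st0$loss["L_total"]), unname(st0$loss["L_recon"]))
  # unnormalised input rejected
  bad <- s; bad$volume$data[1] <- 1.5
  expect_error(pretrain_step(identity_stub, list(bad), scheme), "\\[0, 1\\]")
})

test_that("pretrain losses are finite, non-negative, with L_total >= L_recon", {
  ae <- build_autoencoder(fx_encoder(), seed = 6)
  sc <- mask_scheme(12, 8, seed = 3)
  st <- pretrain_step(ae, fx_pretrain_vols()[1:2], sc)
  expect_true(all(is.finite(st$loss)) && all(st$loss >= 0))
  expect_gte(st$loss[["L_total"]], st$loss[["L_recon"]])
  expect_setequal(names(st$grads), names(ae$params))
})

test_that("pretraining improves held-out reconstruction and bookkeeps", {
  run <- fx_pretrain()
  h <- run$history
  expect_equal(h$epoch, c(0, 5, 10, 15, 20))
  # training reduces held-out L1 by at least 20% over 20 epochs
  expect_lt(h$L_recon_heldout[nrow(h)], 0.8 * h$L_recon_heldout[1])
  # final held-out SSIM beats the untrained model
  expect_gt(h$ssim[nrow(h)], h$ssim[1])
  expect_gte(run$best_epoch, 0)
  expect_equal(max(h$ssim), h$ssim[h$epoch == run$best_epoch])
})

test_that("pretraining runs are deterministic and checkpoints persist", {
  vols <- fx_pretrain_vols()
  cfg <- pretrain_config(fx_encoder(), 12, 8, learning_rate = 3e-3,
                         epochs = 2, eval_interval = 5, batch_size = 2,
                         seed = 4, out_dir = withr::local_tempdir())
  r1 <- train_pretrain(list(train = vols[1:4], test = vols[9:10]), cfg)
  r2 <- train_pretrain(list(train = vols[1:4], test = vols[9:10]), cfg)
  expect_equal(r1$history$L_total[nrow(r1$history)],
               r2$history$L_total[nrow(r2$history)], tolerance = 1e-6)
  expect_true(file.exists(file.path(cfg$out_dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(cfg$out_dir, "history.csv")))
  back <- load_checkpoint(cfg$out_dir)
  expect_identical(back$model$params, r2$model$params)
  expect_error(train_pretrain(list(train = list(), test = vols[1]), cfg),
               "non-empty")
})
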