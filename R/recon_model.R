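## The U-shaped masked-reconstruction autoencoder, the hybrid
## reconstruction-consistency loss, reconstruction quality metrics, and
## the self-supervised pretraining loop.
##
## The encoder is a hierarchical convolutional pyramid honouring the
## stage-shape contract: stage i has spatial size grid / 2^i and
## 2^(j-1) * C feature maps with j = max(i, 1).  Features are passed to a
## convolutional decoder through skip connections at each resolution; the
## reconstruction head is a 1x1x1 convolution followed by a sigmoid, so
## outputs always lie in (0, 1).

stage_widths <- function(C, n_stages) {
  mult <- c(1, 2^(pmax(seq_len(n_stages), 1) - 1))
  as.integer(C * mult)
}

#' Configure the hierarchical encoder
#'
#' @param feature_size base feature count C (reference profile 24; test
#'   profile default 8).
#' @param n_stages number of 2x downsampling steps (reference profile 5,
#'   giving stages 0..5; smaller grids use fewer).
#' @param input_grid voxel grid, each dimension divisible by
#'   `2^n_stages`.
#' @param depths,num_heads per-stage layer/attention-head counts of the
#'   reference shifted-window profile; recorded for provenance, not used
#'   by the convolutional backbone.
#' @return an `encoder_config` object.
#' @export
encoder_config <- function(feature_size = 8, n_stages = 5,
                           input_grid = c(128, 128, 64),
                           depths = c(2, 2, 2, 2),
                           num_heads = c(3, 6, 12, 24)) {
  input_grid <- assert_shape3(input_grid, "input_grid")
  div <- 2^n_stages
  for (a in 1:3)
    if (input_grid[a] %% div != 0)
      stop_mcmae("input grid dimension %d (= %d) is not divisible by 2^%d = %d",
                 a, input_grid[a], n_stages, div)
  structure(list(feature_size = as.integer(feature_size),
                 n_stages = as.integer(n_stages),
                 input_grid = input_grid,
                 depths = depths, num_heads = num_heads),
            class = "encoder_config")
}

#' Per-stage encoder representation shapes
#'
#' Stage i (i = 0..n_stages) has spatial shape `input_grid / 2^i` and
#' `2^(j-1) * C` feature maps with `j = i` except `j = 1` at `i = 0`.
#'
#' @param cfg an [encoder_config()].
#' @return data.frame with columns stage, x, y, z, channels.
#' @export
encoder_stage_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  i <- 0:cfg$n_stages
  data.frame(stage = i,
             x = cfg$input_grid[1] / 2^i,
             y = cfg$input_grid[2] / 2^i,
             z = cfg$input_grid[3] / 2^i,
             channels = stage_widths(cfg$feature_size, cfg$n_stages))
}

#' Build the masked-reconstruction autoencoder
#'
#' Encoder: per stage one 3x3x3 convolution + ReLU, with 2x average
#' pooling between stages.  Decoder: nearest-neighbour upsampling,
#' concatenation with the same-resolution encoder feature map (skip
#' connection), 3x3x3 convolution + ReLU; final 1x1x1 convolution +
#' sigmoid to 3 channels.  The encoder stages are shared verbatim with
#' the downstream classifier, so a pretraining checkpoint is directly
#' loadable for fine-tuning.
#'
#' @param cfg an [encoder_config()].
#' @param seed seed for weight initialisation.
#' @return an object of class `mcmae_autoencoder` (fields `params`,
#'   `cfg`).
#' @export
build_autoencoder <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "encoder_config"))
  w <- stage_widths(cfg$feature_size, cfg$n_stages)
  n <- cfg$n_stages
  params <- list()
  with_seed(hash_seed(seed, 404L), {
    for (i in 0:n) {
      cin <- if (i == 0) 3L else w[i]
      params[[sprintf("enc%d.W", i)]] <- he_init(w[i + 1], 27 * cin)
      params[[sprintf("enc%d.b", i)]] <- numeric(w[i + 1])
    }
    for (i in n:1) {
      cin <- w[i + 1] + w[i]
      params[[sprintf("dec%d.W", i)]] <- he_init(w[i], 27 * cin)
      params[[sprintf("dec%d.b", i)]] <- numeric(w[i])
    }
    params[["out.W"]] <- matrix(rnorm(3 * w[1], 0, 0.05), nrow = 3)
    params[["out.b"]] <- numeric(3)
  })
  structure(list(params = params, cfg = cfg), class = "mcmae_autoencoder")
}

# ---- encoder forward/backward (shared with the classifier) ---------------

encoder_forward <- function(params, cfg, xmat) {
  n <- cfg$n_stages
  w <- stage_widths(cfg$feature_size, n)
  grids <- lapply(0:n, function(i) cfg$input_grid %/% 2L^i)
  xin <- vector("list", n + 1); pre <- vector("list", n + 1)
  act <- vector("list", n + 1)
  for (i in 0:n) {
    inp <- if (i == 0) xmat else pool2_fwd(act[[i]], grids[[i]])$y
    xin[[i + 1]] <- inp
    pre[[i + 1]] <- conv3_fwd(inp, grids[[i + 1]],
                              params[[sprintf("enc%d.W", i)]],
                              params[[sprintf("enc%d.b", i)]])
    act[[i + 1]] <- relu_fwd(pre[[i + 1]])
  }
  list(xin = xin, pre = pre, act = act, grids = grids, widths = w)
}

# g_act: list of gradients on stage activations (NULL allowed); returns
# parameter gradients.
encoder_backward <- function(params, cfg, ec, g_act) {
  n <- cfg$n_stages
  grads <- list()
  chain <- NULL
  for (i in n:0) {
    g <- g_act[[i + 1]]
    if (is.null(g)) g <- chain
    else if (!is.null(chain)) g <- g + chain
    if (is.null(g)) break
    gp <- relu_bwd(ec$pre[[i + 1]], g)
    bwd <- conv3_bwd(ec$xin[[i + 1]], ec$grids[[i + 1]],
                     params[[sprintf("enc%d.W", i)]], gp)
    grads[[sprintf("enc%d.W", i)]] <- bwd$dW
    grads[[sprintf("enc%d.b", i)]] <- as.numeric(bwd$db)
    chain <- if (i > 0)
      pool2_bwd(bwd$dx, ec$grids[[i + 1]], ec$widths[i]) else NULL
  }
  grads
}

ae_forward <- function(model, xmat) {
  params <- model$params; cfg <- model$cfg
  n <- cfg$n_stages
  ec <- encoder_forward(params, cfg, xmat)
  w <- ec$widths
  d <- ec$act[[n + 1]]
  dec_cat <- vector("list", n); dec_pre <- vector("list", n)
  for (i in n:1) {
    u <- up2_fwd(d, ec$grids[[i + 1]])
    cat_i <- cbind(u$y, ec$act[[i]])
    pre_i <- conv3_fwd(cat_i, ec$grids[[i]],
                       params[[sprintf("dec%d.W", i)]],
                       params[[sprintf("dec%d.b", i)]])
    d <- relu_fwd(pre_i)
    dec_cat[[i]] <- cat_i; dec_pre[[i]] <- pre_i
  }
  logits <- d %*% t(params[["out.W"]])
  logits <- sweep(logits, 2, params[["out.b"]], `+`)
  recon <- sigmoid(logits)
  list(recon = recon, ec = ec, dec_cat = dec_cat, dec_pre = dec_pre,
       d0 = d)
}

ae_backward <- function(model, fw, g_recon) {
  params <- model$params; cfg <- model$cfg
  n <- cfg$n_stages
  w <- fw$ec$widths
  grads <- list()
  g_logits <- g_recon * fw$recon * (1 - fw$recon)
  grads[["out.W"]] <- t(g_logits) %*% fw$d0
  grads[["out.b"]] <- colSums(g_logits)
  g_d <- g_logits %*% params[["out.W"]]
  g_act <- vector("list", n + 1)
  for (i in 1:n) {
    gp <- relu_bwd(fw$dec_pre[[i]], g_d)
    bwd <- conv3_bwd(fw$dec_cat[[i]], fw$ec$grids[[i]],
                     params[[sprintf("dec%d.W", i)]], gp)
    grads[[sprintf("dec%d.W", i)]] <- bwd$dW
    grads[[sprintf("dec%d.b", i)]] <- as.numeric(bwd$db)
    g_up <- bwd$dx[, seq_len(w[i + 1]), drop = FALSE]
    g_act[[i]] <- bwd$dx[, w[i + 1] + seq_len(w[i]), drop = FALSE]
    g_d <- up2_bwd(g_up, fw$ec$grids[[i + 1]], w[i + 1])
  }
  g_act[[n + 1]] <- g_d
  c(grads, encoder_backward(params, cfg, fw$ec, g_act))
}

as_vol_array <- function(x) {
  if (inherits(x, "phantom_subject")) x <- x$volume
  if (inherits(x, "multicontrast_volume")) x <- x$data
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == 3L)
  x
}

# dispatch: full model or a plain function(array) -> array (test stubs)
model_reconstruct <- function(model, arr) {
  if (is.function(model)) return(model(arr))
  fw <- ae_forward(model, arr2mat(arr))
  mat2arr(fw$recon, model$cfg$input_grid)
}

#' Reconstruct a (masked) volume with the autoencoder
#'
#' @param model an `mcmae_autoencoder`.
#' @param x a `multicontrast_volume`, `phantom_subject` or 4D array on
#'   the model grid.
#' @return a 4D array of reconstructed intensities in (0, 1).
#' @export
reconstruct <- function(model, x) {
  arr <- as_vol_array(x)
  if (!is.function(model) &&
      !identical(as.integer(dim(arr)[1:3]), as.integer(model$cfg$input_grid)))
    stop_mcmae("volume grid %s does not match the model grid %s",
               paste(dim(arr)[1:3], collapse = "x"),
               paste(model$cfg$input_grid, collapse = "x"))
  model_reconstruct(model, arr)
}

# ---- losses ---------------------------------------------------------------

#' Hybrid loss components
#'
#' `recon_loss` is the L1 reconstruction loss: the mean absolute error
#' between corresponding voxels of the original and the reconstruction.
#' `contrast_loss` quantifies the discrepancy between a pair of
#' reconstructions of the same sample under different masking schemes; the
#' concrete form is the mean absolute difference (symmetric, zero iff the
#' pair coincides, on the same scale as the reconstruction loss).
#' `total_loss` combines them multiplicatively:
#' `L_total = L_recon * (1 + L_contrast)`.
#'
#' @param original,reconstruction,recon_a,recon_b numeric arrays of
#'   identical shape.
#' @param l_recon,l_contrast non-negative scalars.
#' @return a scalar loss value.
#' @export
recon_loss <- function(original, reconstruction) {
  if (!identical(dim(original), dim(reconstruction)))
    stop_mcmae("shape mismatch between original and reconstruction")
  mean(abs(original - reconstruction))
}

#' @rdname recon_loss
#' @export
contrast_loss <- function(recon_a, recon_b) {
  if (!identical(dim(recon_a), dim(recon_b)))
    stop_mcmae("shape mismatch between the paired reconstructions")
  mean(abs(recon_a - recon_b))
}

#' @rdname recon_loss
#' @export
total_loss <- function(l_recon, l_contrast) {
  if (l_recon < 0 || l_contrast < 0)
    stop_mcmae("loss terms must be non-negative")
  l_recon * (1 + l_contrast)
}

# ---- reconstruction quality metrics --------------------------------------

# separable Gaussian filter, half-sample symmetric ("reflect") boundaries
gaussian_filter3 <- function(arr, sigma, truncate = 3.5) {
  if (sigma <= 0) return(arr)
  r <- as.integer(floor(truncate * sigma + 0.5))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  d <- dim(arr)
  for (axis in 1:3) {
    n <- d[axis]
    idx <- c(r:1, 1:n, n:(n - r + 1))   # reflect padding indices
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dims_p <- dim(a)
    m <- matrix(a, nrow = n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[(j - 1) + seq_len(n), , drop = FALSE]
    arr <- aperm(array(out, dims_p), order(perm))
  }
  arr
}

#' Structural similarity of two 3D grids
#'
#' Gaussian-weighted SSIM (window sigma 1.5, truncated at 3.5 sigma,
#' population covariances, reflective boundaries, edge crop of one window
#' radius), matching the standard reference implementation used in the
#' image-processing literature.  Multi-channel inputs are scored per
#' channel and averaged.
#'
#' @param x,y numeric 3D arrays (or 4D with a channel axis) of identical
#'   shape.
#' @param sigma Gaussian window standard deviation in voxels.
#' @param k1,k2 stabilisation constants.
#' @param data_range value range of the data (1 for normalised volumes).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim3d <- function(x, y, sigma = 1.5, k1 = 0.01, k2 = 0.03, data_range = 1) {
  if (!identical(dim(x), dim(y))) stop_mcmae("ssim3d: shape mismatch")
  if (data_range <= 0) stop_mcmae("data_range must be positive")
  if (length(dim(x)) == 4L) {
    return(mean(vapply(seq_len(dim(x)[4]), function(c)
      ssim3d(x[, , , c, drop = TRUE], y[, , , c, drop = TRUE],
             sigma, k1, k2, data_range), numeric(1))))
  }
  r <- as.integer(floor(3.5 * sigma + 0.5))
  if (any(dim(x) <= 2 * r))
    stop_mcmae("grid too small for an SSIM window of radius %d", r)
  ux <- gaussian_filter3(x, sigma);  uy <- gaussian_filter3(y, sigma)
  uxx <- gaussian_filter3(x * x, sigma)
  uyy <- gaussian_filter3(y * y, sigma)
  uxy <- gaussian_filter3(x * y, sigma)
  vx <- uxx - ux^2; vy <- uyy - uy^2; vxy <- uxy - ux * uy
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  S <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
       ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  d <- dim(S)
  mean(S[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r)])
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_value^2 / MSE)` in decibels; `Inf` when the inputs are
#' identical (zero mean squared error).
#'
#' @param x,y numeric arrays of identical shape.
#' @param max_value maximum possible signal value.
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, max_value = 1) {
  if (!identical(dim(x), dim(y))) stop_mcmae("psnr: shape mismatch")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

# ---- pretraining ----------------------------------------------------------

#' Configure self-supervised pretraining
#'
#' The reference profile follows fixed-learning-rate Adam at 1e-4 with
#' held-out evaluation every 5 epochs; the desk-scale test profile keeps
#' the schedule but typically passes a larger learning rate (see the
#' methods vignette for the step-budget reasoning).
#'
#' @param encoder an [encoder_config()].
#' @param n_blocks,block_edge,fill_value masking scheme parameters.
#' @param learning_rate fixed Adam learning rate.
#' @param epochs training epochs.
#' @param eval_interval held-out evaluation period in epochs.
#' @param batch_size samples per update.
#' @param seed master seed for init, shuffling and mask draws.
#' @param out_dir if non-NULL, checkpoint and history are written there.
#' @return a `pretrain_config` object.
#' @export
pretrain_config <- function(encoder, n_blocks = 84, block_edge = 16,
                            fill_value = 0, learning_rate = 1e-4,
                            epochs = 20, eval_interval = 5, batch_size = 2,
                            seed = 1, out_dir = NULL) {
  stopifnot(inherits(encoder, "encoder_config"))
  structure(list(encoder = encoder, n_blocks = as.integer(n_blocks),
                 block_edge = as.integer(block_edge),
                 fill_value = fill_value, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 eval_interval = as.integer(eval_interval),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pretrain_config")
}

mask_volume_mat <- function(xmat, cms, fill) {
  for (ch in 1:3) xmat[as.vector(cms$masks[[ch]]), ch] <- fill
  xmat
}

#' One pretraining step: paired masked reconstruction
#'
#' For every sample two independent channel-mask sets are drawn, two
#' forward passes are run, and the hybrid loss is assembled:
#' `L_recon` = mean of the two L1 reconstruction losses against the
#' original, `L_contrast` = mean absolute discrepancy between the two
#' reconstructions, `L_total = L_recon * (1 + L_contrast)`.  Gradients of
#' `L_total` (averaged over the batch) flow through both passes.
#'
#' @param model an `mcmae_autoencoder`, or a plain
#'   `function(array) -> array` stub (no gradients computed).
#' @param batch list of normalised volumes (values in `[0, 1]`).
#' @param scheme a [mask_scheme()]; the two draws for sample s use the
#'   sub-seeds `hash_seed(scheme$seed, s, 1)` and
#'   `hash_seed(scheme$seed, s, 2)` (a documented contract, so the step
#'   is reproducible and externally checkable).
#' @param compute_grads if `FALSE`, only the loss terms are returned.
#' @return list with `loss` (named vector `L_recon`, `L_contrast`,
#'   `L_total`) and `grads` (parameter gradients or `NULL`).
#' @export
pretrain_step <- function(model, batch, scheme, compute_grads = !is.function(model)) {
  stopifnot(length(batch) >= 1)
  arrs <- lapply(batch, as_vol_array)
  grid <- dim(arrs[[1]])[1:3]
  nb <- length(arrs)
  lr_sum <- 0; lc_sum <- 0; lt_sum <- 0
  grads <- NULL
  for (s in seq_len(nb)) {
    arr <- arrs[[s]]
    if (min(arr) < 0 || max(arr) > 1)
      stop_mcmae("pretrain_step expects normalised volumes in [0, 1]")
    x <- arr2mat(arr)
    sa <- scheme; sa$seed <- hash_seed(scheme$seed, s, 1L)
    sb <- scheme; sb$seed <- hash_seed(scheme$seed, s, 2L)
    ma <- make_channel_masks(grid, sa)
    mb <- make_channel_masks(grid, sb)
    xa <- mask_volume_mat(x, ma, scheme$fill_value)
    xb <- mask_volume_mat(x, mb, scheme$fill_value)
    if (is.function(model)) {
      fa <- arr2mat(model(mat2arr(xa, grid)))
      fb <- arr2mat(model(mat2arr(xb, grid)))
    } else {
      fwa <- ae_forward(model, xa)
      fwb <- ae_forward(model, xb)
      fa <- fwa$recon; fb <- fwb$recon
    }
    l1a <- mean(abs(fa - x)); l1b <- mean(abs(fb - x))
    lr <- (l1a + l1b) / 2
    lc <- mean(abs(fa - fb))
    lt <- total_loss(lr, lc)
    lr_sum <- lr_sum + lr; lc_sum <- lc_sum + lc; lt_sum <- lt_sum + lt
    if (compute_grads && !is.function(model)) {
      n_el <- length(fa)
      ga <- ((1 + lc) / 2 * sign(fa - x) + lr * sign(fa - fb)) / n_el / nb
      gb <- ((1 + lc) / 2 * sign(fb - x) + lr * sign(fb - fa)) / n_el / nb
      gsa <- ae_backward(model, fwa, ga)
      gsb <- ae_backward(model, fwb, gb)
      if (is.null(grads)) {
        grads <- gsa
        for (nm in names(gsb)) grads[[nm]] <- grads[[nm]] + gsb[[nm]]
      } else {
        for (nm in names(gsa))
          grads[[nm]] <- grads[[nm]] + gsa[[nm]] + gsb[[nm]]
      }
    }
  }
  list(loss = c(L_recon = lr_sum / nb, L_contrast = lc_sum / nb,
                L_total = lt_sum / nb),
       grads = grads)
}

evaluate_recon <- function(model, vols, scheme, seed_tag = 909L) {
  cfg_seed <- scheme$seed
  ss <- 0; pp <- 0; ll <- 0
  for (i in seq_along(vols)) {
    arr <- as_vol_array(vols[[i]])
    s <- scheme; s$seed <- hash_seed(cfg_seed, seed_tag, i)
    cms <- make_channel_masks(dim(arr)[1:3], s)
    xm <- mask_volume_mat(arr2mat(arr), cms, scheme$fill_value)
    rec <- model_reconstruct(model, mat2arr(xm, dim(arr)[1:3]))
    ss <- ss + ssim3d(unclass(rec), arr)
    pp <- pp + psnr(rec, arr)
    ll <- ll + mean(abs(rec - arr))
  }
  c(ssim = ss / length(vols), psnr = pp / length(vols),
    L_recon_heldout = ll / length(vols))
}

#' Run self-supervised pretraining
#'
#' Trains the autoencoder with fixed-learning-rate Adam on the training
#' volumes, evaluating held-out SSIM/PSNR (under fixed evaluation masks)
#' at `eval_interval` epochs and at the start and end; the parameters with
#' the best held-out SSIM are kept.  Fully seeded and single-threaded:
#' reruns are bit-identical.
#'
#' @param dataset list with `train` and `test` lists of normalised
#'   volumes (`multicontrast_volume`, `phantom_subject` or 4D arrays);
#'   test volumes are never used for updates.
#' @param cfg a [pretrain_config()].
#' @return a `pretrain_run`: `model` (best checkpoint), `history`
#'   (data.frame: epoch, L_recon, L_contrast, L_total, ssim, psnr),
#'   `best_epoch`, `cfg`.
#' @export
train_pretrain <- function(dataset, cfg) {
  stopifnot(inherits(cfg, "pretrain_config"))
  if (length(dataset$train) == 0 || length(dataset$test) == 0)
    stop_mcmae("pretraining requires non-empty train and test splits")
  model <- build_autoencoder(cfg$encoder, seed = cfg$seed)
  opt <- adam_init(model$params)
  scheme0 <- mask_scheme(cfg$n_blocks, cfg$block_edge, cfg$fill_value,
                         seed = cfg$seed)
  history <- NULL
  eval_and_log <- function(epoch, tr_loss) {
    ev <- evaluate_recon(model, dataset$test, scheme0)
    rbind(history, data.frame(epoch = epoch, L_recon = tr_loss[1],
                              L_contrast = tr_loss[2], L_total = tr_loss[3],
                              ssim = ev["ssim"], psnr = ev["psnr"],
                              L_recon_heldout = ev["L_recon_heldout"],
                              row.names = NULL))
  }
  history <- eval_and_log(0L, c(NA, NA, NA))
  best_ssim <- history$ssim[1]
  best_params <- model$params
  best_epoch <- 0L
  n_tr <- length(dataset$train)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(hash_seed(cfg$seed, 11L, epoch), sample.int(n_tr))
    ep_loss <- c(0, 0, 0); n_steps <- 0
    for (start in seq(1, n_tr, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n_tr)]
      scheme <- scheme0
      scheme$seed <- hash_seed(cfg$seed, 13L, epoch, start)
      st <- pretrain_step(model, dataset$train[idx], scheme)
      res <- adam_step(model$params, st$grads, opt, lr = cfg$learning_rate)
      model$params <- res$params; opt <- res$state
      ep_loss <- ep_loss + st$loss; n_steps <- n_steps + 1
    }
    if (epoch %% cfg$eval_interval == 0 || epoch == cfg$epochs) {
      history <- eval_and_log(epoch, ep_loss / n_steps)
      cur <- history$ssim[nrow(history)]
      if (cur > best_ssim) {
        best_ssim <- cur; best_params <- model$params
        best_epoch <- epoch
      }
    }
  }
  best_model <- model; best_model$params <- best_params
  run <- structure(list(model = best_model, final_model = model,
                        history = history, best_epoch = best_epoch,
                        cfg = cfg),
                   class = "pretrain_run")
  if (!is.null(cfg$out_dir)) save_checkpoint(run, cfg$out_dir)
  run
}

#' Persist / restore a training run
#'
#' Writes `checkpoint.rds` (weights + config + history) and a readable
#' `history.csv` into `dir`.
#'
#' @param run a `pretrain_run` or `finetune_run`.
#' @param dir output directory.
#' @return the checkpoint path (`save_checkpoint`) or the restored run
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "checkpoint.rds")
  saveRDS(run, path)
  write.csv(run$history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path a checkpoint file or its directory.
#' @export
load_checkpoint <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "checkpoint.rds")
  readRDS(path)
}
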