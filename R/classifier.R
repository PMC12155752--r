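## Downstream fine-tuning of the pretrained encoder into a two-class
## discriminator: global average pooling of the deepest encoder stage,
## a fully-connected hidden layer with ReLU, and a 2-logit output, trained
## with cross-entropy and AdamW under cosine learning-rate decay.
## Class "A" (the PD-like posterior phenotype) is the positive class, so
## sensitivity counts its detection rate.

POSITIVE_CLASS <- "A"
CLASS_LEVELS <- c("A", "B")

encoder_cfg_diff <- function(a, b) {
  keys <- c("feature_size", "n_stages", "input_grid")
  keys[!vapply(keys, function(k) identical(a[[k]], b[[k]]), logical(1))]
}

#' Build the two-class classifier head on an encoder
#'
#' The deepest encoder stage is global-average-pooled into a feature
#' vector, passed through a fully-connected layer with ReLU, and mapped to
#' 2 logits.  The encoder weights are taken from a pretraining run (an
#' `mcmae_autoencoder` or `pretrain_run`) or randomly initialised from an
#' [encoder_config()] (scratch).  The output layer starts at zero, so the
#' untrained classifier scores every subject 0.5.
#'
#' @param encoder an `mcmae_autoencoder`, `pretrain_run`, or
#'   [encoder_config()] for scratch initialisation.
#' @param hidden_width width of the hidden fully-connected layer.
#' @param seed seed for head (and scratch-encoder) initialisation.
#' @return an object of class `mcmae_classifier` (fields `params`, `cfg`,
#'   `hidden_width`, `init`).
#' @export
build_classifier <- function(encoder, hidden_width = 128, seed = 1) {
  if (inherits(encoder, "pretrain_run")) encoder <- encoder$model
  if (inherits(encoder, "mcmae_autoencoder")) {
    cfg <- encoder$cfg
    enc_params <- encoder$params[grep("^enc", names(encoder$params))]
    init <- "pretrained"
  } else if (inherits(encoder, "encoder_config")) {
    cfg <- encoder
    ae <- build_autoencoder(cfg, seed = hash_seed(seed, 21L))
    enc_params <- ae$params[grep("^enc", names(ae$params))]
    init <- "scratch"
  } else stop_mcmae("encoder must be an autoencoder, pretrain run or encoder_config")
  w <- stage_widths(cfg$feature_size, cfg$n_stages)
  deep <- w[cfg$n_stages + 1]
  params <- enc_params
  with_seed(hash_seed(seed, 22L), {
    params[["head.W1"]] <- he_init(hidden_width, deep)
    params[["head.b1"]] <- numeric(hidden_width)
    params[["head.W2"]] <- matrix(0, nrow = 2, ncol = hidden_width)
    params[["head.b2"]] <- numeric(2)
  })
  structure(list(params = params, cfg = cfg,
                 hidden_width = as.integer(hidden_width), init = init),
            class = "mcmae_classifier")
}

#' Load pretrained encoder weights into a classifier
#'
#' Fails with an explicit list of differing configuration keys when the
#' checkpoint's encoder does not match the classifier's.
#'
#' @param clf an `mcmae_classifier`.
#' @param checkpoint an `mcmae_autoencoder` or `pretrain_run`.
#' @return the classifier with encoder weights replaced.
#' @export
load_encoder_weights <- function(clf, checkpoint) {
  stopifnot(inherits(clf, "mcmae_classifier"))
  if (inherits(checkpoint, "pretrain_run")) checkpoint <- checkpoint$model
  bad <- encoder_cfg_diff(clf$cfg, checkpoint$cfg)
  if (length(bad))
    stop_mcmae("checkpoint/encoder config mismatch in key(s): %s",
               paste(bad, collapse = ", "))
  enc <- grep("^enc", names(checkpoint$params), value = TRUE)
  clf$params[enc] <- checkpoint$params[enc]
  clf$init <- "pretrained"
  clf
}

cls_forward <- function(clf, xmat) {
  ec <- encoder_forward(clf$params, clf$cfg, xmat)
  n <- clf$cfg$n_stages
  feat <- colMeans(ec$act[[n + 1]])
  h_pre <- as.vector(clf$params[["head.W1"]] %*% feat) + clf$params[["head.b1"]]
  h <- pmax(h_pre, 0)
  logits <- as.vector(clf$params[["head.W2"]] %*% h) + clf$params[["head.b2"]]
  list(logits = logits, ec = ec, feat = feat, h_pre = h_pre, h = h)
}

cls_backward <- function(clf, fw, dlogits) {
  grads <- list()
  grads[["head.W2"]] <- outer(dlogits, fw$h)
  grads[["head.b2"]] <- dlogits
  dh <- as.vector(t(clf$params[["head.W2"]]) %*% dlogits) * (fw$h_pre > 0)
  grads[["head.W1"]] <- outer(dh, fw$feat)
  grads[["head.b1"]] <- dh
  dfeat <- as.vector(t(clf$params[["head.W1"]]) %*% dh)
  n <- clf$cfg$n_stages
  nvox <- nrow(fw$ec$act[[n + 1]])
  g_act <- vector("list", n + 1)
  g_act[[n + 1]] <- matrix(dfeat / nvox, nrow = nvox,
                           ncol = length(dfeat), byrow = TRUE)
  c(grads, encoder_backward(clf$params, clf$cfg, fw$ec, g_act))
}

softmax2 <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Configure downstream fine-tuning
#'
#' Cross-entropy loss, AdamW, cosine learning-rate decay from `lr_init`
#' to `lr_floor` (reference profile 1e-5 to 1e-9 over 200 epochs; the
#' desk-scale fixtures pass a larger `lr_init`, see the methods
#' vignette).
#'
#' @param epochs training epochs.
#' @param lr_init,lr_floor cosine schedule endpoints.
#' @param weight_decay decoupled AdamW weight decay.
#' @param hidden_width classifier head width.
#' @param seed master seed.
#' @param out_dir if non-NULL, checkpoint and history are written there.
#' @return a `finetune_config` object.
#' @export
finetune_config <- function(epochs = 30, lr_init = 1e-5, lr_floor = 1e-9,
                            weight_decay = 1e-2, hidden_width = 128,
                            seed = 1, out_dir = NULL) {
  structure(list(epochs = as.integer(epochs), lr_init = lr_init,
                 lr_floor = lr_floor, weight_decay = weight_decay,
                 hidden_width = as.integer(hidden_width),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "finetune_config")
}

split_subjects <- function(data) {
  if (inherits(data, "phantom_cohort")) {
    out <- lapply(c(train = "train", val = "val", test = "test"),
                  function(s) data$subjects[data$manifest$subject_id[
                    data$manifest$split == s]])
    return(out)
  }
  stopifnot(all(c("train", "val", "test") %in% names(data)))
  data
}

subject_label <- function(s) s$class_label
subject_mat <- function(s) arr2mat(as_vol_array(s))

ce_loss_grad <- function(logits, label) {
  p <- softmax2(logits)
  y <- as.numeric(CLASS_LEVELS == label)
  list(loss = -sum(y * log(pmax(p, 1e-12))), dlogits = p - y)
}

accuracy_on <- function(clf, subjects) {
  if (length(subjects) == 0) return(NA_real_)
  correct <- 0; loss <- 0
  for (s in subjects) {
    fw <- cls_forward(clf, subject_mat(s))
    p <- softmax2(fw$logits)
    pred <- CLASS_LEVELS[which.max(p)]
    correct <- correct + (pred == subject_label(s))
    loss <- loss + ce_loss_grad(fw$logits, subject_label(s))$loss
  }
  c(acc = correct / length(subjects), loss = loss / length(subjects))
}

#' Fine-tune a classifier on a split cohort
#'
#' Trains with per-subject AdamW updates under cosine learning-rate
#' decay; validation accuracy is monitored every epoch and the weights
#' with the highest validation accuracy are kept (earliest epoch wins
#' ties).  The test split is never touched during training.
#'
#' @param model an `mcmae_classifier` (see [build_classifier()]).
#' @param data a `phantom_cohort` with train/val/test splits, or a list
#'   with `train`, `val`, `test` lists of `phantom_subject`s.
#' @param cfg a [finetune_config()].
#' @return a `finetune_run`: `model` (best validation checkpoint),
#'   `final_model`, `history` (epoch, lr, train_loss, val_acc, val_loss),
#'   `best_epoch`, `cfg`.
#' @export
train_finetune <- function(model, data, cfg) {
  stopifnot(inherits(model, "mcmae_classifier"),
            inherits(cfg, "finetune_config"))
  splits <- split_subjects(data)
  for (s in c("train", "val")) {
    labs <- vapply(splits[[s]], subject_label, character(1))
    if (!all(CLASS_LEVELS %in% labs))
      stop_mcmae("split '%s' is missing a class (has: %s)", s,
                 paste(unique(labs), collapse = ", "))
  }
  opt <- adam_init(model$params)
  history <- NULL
  best_acc <- -Inf; best_params <- model$params; best_epoch <- 0L
  n_tr <- length(splits$train)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch, cfg$epochs, cfg$lr_init, cfg$lr_floor)
    ord <- with_seed(hash_seed(cfg$seed, 31L, epoch), sample.int(n_tr))
    tr_loss <- 0
    for (i in ord) {
      s <- splits$train[[i]]
      fw <- cls_forward(model, subject_mat(s))
      lg <- ce_loss_grad(fw$logits, subject_label(s))
      grads <- cls_backward(model, fw, lg$dlogits)
      res <- adam_step(model$params, grads, opt, lr = lr,
                       weight_decay = cfg$weight_decay)
      model$params <- res$params; opt <- res$state
      tr_loss <- tr_loss + lg$loss
    }
    val <- accuracy_on(model, splits$val)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = tr_loss / n_tr,
      val_acc = val["acc"], val_loss = val["loss"], row.names = NULL))
    if (val["acc"] > best_acc) {        # strict: earliest epoch wins ties
      best_acc <- val["acc"]; best_params <- model$params
      best_epoch <- epoch
    }
  }
  best_model <- model; best_model$params <- best_params
  run <- structure(list(model = best_model, final_model = model,
                        history = history, best_epoch = best_epoch,
                        cfg = cfg),
                   class = "finetune_run")
  if (!is.null(cfg$out_dir)) save_checkpoint(run, cfg$out_dir)
  run
}

#' Predict class probabilities for a set of subjects
#'
#' @param object an `mcmae_classifier`.
#' @param subjects list of `phantom_subject`s or `multicontrast_volume`s
#'   preprocessed to the training grid.
#' @param ... unused.
#' @return a data.frame of prediction records: `subject_id`,
#'   `true_label`, `predicted_label`, `score` (probability of the
#'   positive, PD-like class `"A"`).
#' @export
predict.mcmae_classifier <- function(object, subjects, ...) {
  recs <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    arr <- as_vol_array(s)
    if (!identical(as.integer(dim(arr)[1:3]),
                   as.integer(object$cfg$input_grid)))
      stop_mcmae("subject %d grid %s does not match model grid %s", i,
                 paste(dim(arr)[1:3], collapse = "x"),
                 paste(object$cfg$input_grid, collapse = "x"))
    fw <- cls_forward(object, arr2mat(arr))
    p <- softmax2(fw$logits)
    data.frame(
      subject_id = if (!is.null(s$subject_id)) s$subject_id else sprintf("S%03d", i),
      true_label = if (inherits(s, "phantom_subject")) s$class_label else NA_character_,
      predicted_label = CLASS_LEVELS[which.max(p)],
      score = p[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
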