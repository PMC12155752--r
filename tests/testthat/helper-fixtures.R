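# Shared, lazily-built fixtures.  Training runs are expensive, so every
# test file pulls them from this memoised store; all fixtures are fully
# seeded and deterministic.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

FX_SHAPE <- c(32L, 32L, 16L)

fx_encoder <- function() encoder_config(8, 3, FX_SHAPE)

# standard fixture cohort: 40 subjects/class, strong structural effect
fx_cohort <- function(effect = 2) {
  fx_get(paste0("cohort_", effect), function()
    generate_cohort(cohort_spec(40, effect, 0.05, 0.2, FX_SHAPE,
                                master_seed = 11)))
}

# independent evaluation cohort, 25/class, disjoint seed stream
fx_eval_set <- function(effect = 2) {
  fx_get(paste0("eval_", effect), function()
    unlist(lapply(c("A", "B"), function(cl) lapply(1:25, function(i)
      phantom_subject(cl, FX_SHAPE, effect, 0.05, 0.2,
                      seed = hash_seed(77, match(cl, c("A", "B")), i)))),
      recursive = FALSE))
}

# desk-scale fine-tuning profile (see the methods vignette)
fx_finetune <- function(effect = 2) {
  fx_get(paste0("finetune_", effect), function() {
    clf <- build_classifier(fx_encoder(), 128, seed = 1)
    train_finetune(clf, fx_cohort(effect),
                   finetune_config(epochs = 15, lr_init = 1e-3, seed = 2))
  })
}

# no-noise pretraining volumes and a 20-epoch pretraining run
fx_pretrain_vols <- function() {
  fx_get("pretrain_vols", function()
    lapply(1:10, function(i)
      phantom_subject(c("A", "B")[1 + i %% 2], FX_SHAPE, 1, 0, 0, seed = i)))
}

fx_pretrain <- function() {
  fx_get("pretrain_run", function() {
    vols <- fx_pretrain_vols()
    cfg <- pretrain_config(fx_encoder(), n_blocks = 12, block_edge = 8,
                           learning_rate = 3e-3, epochs = 20,
                           eval_interval = 5, batch_size = 2, seed = 4)
    train_pretrain(list(train = vols[1:8], test = vols[9:10]), cfg)
  })
}

# saliency subjects (15/class, fresh seeds) and the full statistics chain
fx_saliency_subjects <- function() {
  fx_get("saliency_subjects", function()
    unlist(lapply(c("A", "B"), function(cl) lapply(1:15, function(i)
      phantom_subject(cl, FX_SHAPE, 2, 0.05, 0.2,
                      seed = hash_seed(99, match(cl, c("A", "B")), i)))),
      recursive = FALSE))
}

fx_saliency_chain <- function() {
  fx_get("saliency_chain", function()
    saliency_chain(fx_finetune(2)$model, fx_saliency_subjects(),
                   occ = occlusion_params(8, 4, 0), fwhm_voxels = 4,
                   n_perm = 199, seed = 5))
}

# 20 seeded repetitions of the permutation test under the class null
fx_null_fwer_empty <- function() {
  fx_get("null_fwer_empty", function() {
    vapply(1:20, function(rep) {
      subj <- lapply(1:30, function(i)
        phantom_subject(c("A", "B")[1 + i %% 2], FX_SHAPE, 0, 0.05, 0.2,
                        seed = hash_seed(1234, rep, i)))
      maps <- lapply(subj, function(s) smooth_map(s$volume$data[, , , 1], 4))
      res <- permutation_fwer(maps[1:15], maps[16:30], n_perm = 199,
                              seed = hash_seed(55, rep))
      sum(res$sig_mask) == 0
    }, logical(1))
  })
}

rand_volume <- function(shape = FX_SHAPE, seed = 1) {
  set.seed(seed)
  multicontrast_volume(array(runif(prod(shape) * 3), c(shape, 3)))
}
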