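## Orchestration: a versioned YAML experiment configuration with full
## defaulting and validation, and a resumable pipeline binding the stages
## phantom -> pretrain -> finetune -> evaluate -> saliency, writing a
## manifest of every produced artifact with content hashes.

default_config <- function() {
  list(
    version = 1L,
    seed = 1L,
    out_dir = "mcmae_out",
    log_level = "info",
    phantom = list(n_pretrain = 10L, n_per_class = 20L, effect_size = 2,
                   noise_sd = 0.05, bias_field_amplitude = 0.2,
                   shape = c(32L, 32L, 16L), split_ratios = c(8, 1, 1)),
    mask = list(n_blocks = 6L, block_edge = 8L, fill_value = 0),
    pretrain = list(feature_size = 8L, n_stages = 3L, learning_rate = 1e-2,
                    epochs = 10L, eval_interval = 5L, batch_size = 2L),
    finetune = list(epochs = 20L, lr_init = 1e-3, lr_floor = 1e-9,
                    weight_decay = 1e-2, hidden_width = 128L),
    saliency = list(patch_edge = 8L, stride = 4L, fill_value = 0,
                    fwhm = 4, n_perm = 199L, n_per_class = 15L),
    evaluate = list(n_boot = 500L))
}

merge_config <- function(base, user, path = "", errors = new.env()) {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown key '%s'", full))
      next
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) {
        errors$msgs <- c(errors$msgs,
                         sprintf("key '%s' must be a mapping", full))
      } else {
        base[[nm]] <- merge_config(base[[nm]], user[[nm]], full, errors)
      }
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

check_config <- function(cfg) {
  msgs <- character()
  chk <- function(ok, msg) if (!ok) msgs <<- c(msgs, msg)
  chk(cfg$mask$n_blocks >= 0, "mask.n_blocks must be >= 0")
  chk(cfg$mask$block_edge >= 1, "mask.block_edge must be >= 1")
  chk(cfg$phantom$n_per_class >= 10, "phantom.n_per_class must be >= 10")
  chk(cfg$phantom$effect_size >= 0, "phantom.effect_size must be >= 0")
  chk(cfg$phantom$noise_sd >= 0, "phantom.noise_sd must be >= 0")
  chk(all(cfg$phantom$split_ratios >= 0),
      "phantom.split_ratios must be non-negative")
  chk(cfg$pretrain$epochs >= 1, "pretrain.epochs must be >= 1")
  chk(cfg$pretrain$learning_rate > 0, "pretrain.learning_rate must be > 0")
  chk(cfg$finetune$epochs >= 1, "finetune.epochs must be >= 1")
  chk(cfg$finetune$lr_init >= cfg$finetune$lr_floor,
      "finetune.lr_init must be >= finetune.lr_floor")
  chk(cfg$saliency$n_perm >= 99, "saliency.n_perm must be >= 99")
  msgs
}

#' Validate and normalise an experiment configuration
#'
#' Reads a YAML configuration, fills every missing key with its default
#' (an empty file yields the fully-defaulted configuration) and reports
#' every violation, not just the first.  Unknown keys are listed by name.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return list with `config` (normalised configuration) and `errors`
#'   (character vector; empty when valid).
#' @export
validate_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_mcmae("config file '%s' does not exist", path)
    user <- yaml::read_yaml(path) %||% list()
  }
  errors <- new.env(); errors$msgs <- character()
  cfg <- merge_config(default_config(), user, errors = errors)
  msgs <- c(errors$msgs, check_config(cfg))
  list(config = cfg, errors = msgs)
}

# content hash that ignores container-level bytes (gzip metadata etc.)
content_hash <- function(path) {
  obj <- if (grepl("\\.nii(\\.gz)?$", path)) {
    as.array(RNifti::readNifti(path))
  } else if (grepl("\\.rds$", path)) {
    readRDS(path)
  } else {
    readLines(path, warn = FALSE)
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(obj, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

log_msg <- function(cfg, level, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[mcmae:%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full experiment pipeline
#'
#' Executes phantom -> pretrain -> finetune -> evaluate -> saliency,
#' writing every artifact under `config$out_dir` and a `manifest.json`
#' with content hashes.  With `resume = TRUE` a stage whose outputs
#' already exist is skipped unless an upstream stage reran; a stage whose
#' required upstream artifact is missing fails with the name of the stage
#' to rerun.
#'
#' @param config a configuration list from [validate_config()], or a
#'   path to a YAML file.
#' @param stages subset of stages to run (defaults to all, in order).
#' @param resume reuse existing artifacts where possible.
#' @return the manifest data.frame (file, stage, md5), invisibly written
#'   to `manifest.json`.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("phantom", "pretrain", "finetune",
                                    "evaluate", "saliency"),
                         resume = TRUE) {
  if (is.null(config) || is.character(config)) {
    v <- validate_config(config)
    if (length(v$errors))
      stop_mcmae("invalid configuration:\n  %s",
                 paste(v$errors, collapse = "\n  "))
    config <- v$config
  } else if (!is.null(config$config)) config <- config$config
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    phantom  = file.path(out, "phantom", "cohort.rds"),
    pretrain = file.path(out, "pretrain", "checkpoint.rds"),
    finetune = file.path(out, "finetune", "checkpoint.rds"),
    evaluate = file.path(out, "evaluate", "report.json"),
    saliency = file.path(out, "saliency", "summary.csv"))
  changed <- list()
  need <- function(stage) {
    if (!file.exists(paths[[stage]]))
      stop_mcmae("missing upstream artifact '%s'; rerun stage '%s'",
                 paths[[stage]], stage)
    invisible(TRUE)
  }
  upstream_changed <- function(...) any(unlist(changed[c(...)]))

  if ("phantom" %in% stages) {
    if (!resume || !file.exists(paths$phantom)) {
      log_msg(cfg, "info", "generating phantom cohort")
      ph <- cfg$phantom
      cohort <- generate_cohort(cohort_spec(
        ph$n_per_class, ph$effect_size, ph$noise_sd,
        ph$bias_field_amplitude, ph$shape, ph$split_ratios,
        master_seed = hash_seed(cfg$seed, 1L)))
      pre_subj <- lapply(seq_len(ph$n_pretrain), function(i)
        phantom_subject(c("A", "B")[1 + i %% 2], ph$shape, ph$effect_size,
                        ph$noise_sd, ph$bias_field_amplitude,
                        seed = hash_seed(cfg$seed, 2L, i)))
      dir.create(dirname(paths$phantom), recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(cohort = cohort, pretrain_subjects = pre_subj),
              paths$phantom)
      write.csv(cohort$manifest,
                file.path(dirname(paths$phantom), "manifest.csv"),
                row.names = FALSE)
      changed$phantom <- TRUE
    } else changed$phantom <- FALSE
  }

  if ("pretrain" %in% stages) {
    need("phantom")
    if (!resume || !file.exists(paths$pretrain) || upstream_changed("phantom")) {
      log_msg(cfg, "info", "self-supervised pretraining")
      ph_art <- readRDS(paths$phantom)
      vols <- ph_art$pretrain_subjects
      n_test <- max(2L, length(vols) %/% 5L)
      enc <- encoder_config(cfg$pretrain$feature_size, cfg$pretrain$n_stages,
                            cfg$phantom$shape)
      pcfg <- pretrain_config(
        enc, cfg$mask$n_blocks, cfg$mask$block_edge, cfg$mask$fill_value,
        cfg$pretrain$learning_rate, cfg$pretrain$epochs,
        cfg$pretrain$eval_interval, cfg$pretrain$batch_size,
        seed = hash_seed(cfg$seed, 3L),
        out_dir = dirname(paths$pretrain))
      train_pretrain(list(train = vols[seq_len(length(vols) - n_test)],
                          test = vols[length(vols) - n_test + seq_len(n_test)]),
                     pcfg)
      changed$pretrain <- TRUE
    } else changed$pretrain <- FALSE
  }

  if ("finetune" %in% stages) {
    need("phantom"); need("pretrain")
    if (!resume || !file.exists(paths$finetune) ||
        upstream_changed("phantom", "pretrain")) {
      log_msg(cfg, "info", "fine-tuning the classifier")
      ph_art <- readRDS(paths$phantom)
      pre_run <- load_checkpoint(paths$pretrain)
      clf <- build_classifier(pre_run, cfg$finetune$hidden_width,
                              seed = hash_seed(cfg$seed, 4L))
      fcfg <- finetune_config(cfg$finetune$epochs, cfg$finetune$lr_init,
                              cfg$finetune$lr_floor, cfg$finetune$weight_decay,
                              cfg$finetune$hidden_width,
                              seed = hash_seed(cfg$seed, 5L),
                              out_dir = dirname(paths$finetune))
      train_finetune(clf, ph_art$cohort, fcfg)
      changed$finetune <- TRUE
    } else changed$finetune <- FALSE
  }

  if ("evaluate" %in% stages) {
    need("phantom"); need("finetune")
    if (!resume || !file.exists(paths$evaluate) ||
        upstream_changed("phantom", "pretrain", "finetune")) {
      log_msg(cfg, "info", "evaluating on the test split")
      ph_art <- readRDS(paths$phantom)
      run <- load_checkpoint(paths$finetune)
      test_subj <- split_subjects(ph_art$cohort)$test
      records <- predict(run$model, test_subj)
      dir.create(dirname(paths$evaluate), recursive = TRUE, showWarnings = FALSE)
      write.csv(records, file.path(dirname(paths$evaluate), "predictions.csv"),
                row.names = FALSE)
      rep <- metric_report(records, n_boot = cfg$evaluate$n_boot,
                           seed = hash_seed(cfg$seed, 6L))
      jsonlite::write_json(
        list(accuracy = rep$accuracy, sensitivity = rep$sensitivity,
             specificity = rep$specificity, precision = rep$precision,
             f1 = rep$f1, auc = rep$auc,
             ci95 = lapply(rep$ci95, function(x) unname(as.numeric(x)))),
        paths$evaluate, auto_unbox = TRUE, digits = NA)
      changed$evaluate <- TRUE
    } else changed$evaluate <- FALSE
  }

  if ("saliency" %in% stages) {
    need("finetune")
    if (!resume || !file.exists(paths$saliency) ||
        upstream_changed("phantom", "pretrain", "finetune")) {
      log_msg(cfg, "info", "saliency group statistics")
      run <- load_checkpoint(paths$finetune)
      sal <- cfg$saliency
      subj <- unlist(lapply(c("A", "B"), function(cl)
        lapply(seq_len(sal$n_per_class), function(i)
          phantom_subject(cl, cfg$phantom$shape, cfg$phantom$effect_size,
                          cfg$phantom$noise_sd,
                          cfg$phantom$bias_field_amplitude,
                          seed = hash_seed(cfg$seed, 7L, match(cl, c("A", "B")), i)))),
        recursive = FALSE)
      chain <- saliency_chain(
        run$model, subj,
        occ = occlusion_params(sal$patch_edge, sal$stride, sal$fill_value),
        fwhm_voxels = sal$fwhm, n_perm = sal$n_perm,
        seed = hash_seed(cfg$seed, 8L))
      dir.create(dirname(paths$saliency), recursive = TRUE, showWarnings = FALSE)
      for (nm in c("t_map", "tfce_map", "p_map_fwer")) {
        img <- RNifti::asNifti(array(chain$result[[nm]],
                                     dim = dim(chain$result$t_map)))
        RNifti::writeNifti(img, file.path(dirname(paths$saliency),
                                          paste0(nm, ".nii.gz")))
      }
      write.csv(cluster_summary(chain$result), paths$saliency,
                row.names = FALSE)
      saveRDS(chain, file.path(dirname(paths$saliency), "chain.rds"))
      changed$saliency <- TRUE
    } else changed$saliency <- FALSE
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(
    file = sub(paste0("^", out, "/?"), "", files),
    stage = vapply(files, function(f)
      strsplit(sub(paste0("^", out, "/?"), "", f), "/")[[1]][1], character(1)),
    md5 = vapply(files, content_hash, character(1)),
    row.names = NULL)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
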