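#' Assemble a run configuration for the end-to-end pipeline
#'
#' @param manifest_path path to a cohort manifest CSV (frames relative to
#'   its directory).
#' @param workdir directory for checkpoints, logs and reports.
#' @param image_types branch image types (1 to 4 branches).
#' @param variant fusion variant; required when more than one branch.
#' @param encoder_cfg an [encoder_config()].
#' @param train_cfg a [train_config()].
#' @param split list of `train`/`valid`/`test` case-id vectors, or `NULL`
#'   to draw a stratified split from `seed`.
#' @param seed pipeline seed.
#' @return a `run_config` list.
#' @export
run_config <- function(manifest_path, workdir, image_types,
                       variant = "ffm_v2", encoder_cfg = encoder_config(),
                       train_cfg = train_config(), split = NULL, seed = 1L) {
  problems <- character()
  if (length(image_types) < 1 || length(image_types) > 4)
    problems <- c(problems, "branch count must lie in 1..4")
  if (length(image_types) >= 2 && is.null(variant))
    problems <- c(problems, "a fusion variant is required for 2+ branches")
  if (length(problems)) abort_config(paste(problems, collapse = "; "))
  structure(list(manifest_path = manifest_path, workdir = workdir,
                 image_types = image_types, variant = variant,
                 encoder_cfg = encoder_cfg, train_cfg = train_cfg,
                 split = split, seed = as.integer(seed)),
            class = "run_config")
}

config_fingerprint <- function(config) {
  string_hash(jsonlite::toJSON(list(
    image_types = config$image_types, variant = config$variant,
    encoder = unclass(config$encoder_cfg), train = unclass(config$train_cfg),
    seed = config$seed), auto_unbox = TRUE))
}

# stratified train/valid/test case split at roughly 45/25/30 per class
default_split <- function(cases, seed) {
  withr::with_seed(derive_seed(seed, 13), {
    out <- list(train = character(), valid = character(), test = character())
    for (lb in unique(cases$label)) {
      ids <- sample(cases$case_id[cases$label == lb])
      n <- length(ids)
      n_test <- max(1L, round(0.3 * n))
      n_valid <- max(1L, round(0.25 * n))
      out$test <- c(out$test, ids[seq_len(n_test)])
      out$valid <- c(out$valid, ids[n_test + seq_len(n_valid)])
      out$train <- c(out$train, ids[(n_test + n_valid + 1):n])
    }
    out
  })
}

#' Run the full two-stage pipeline
#'
#' Preprocess -> stage-1 encoder fine-tuning per branch -> stage-2 fusion
#' training on the frozen encoders (skipped for a single branch) -> held-out
#' evaluation. Every artifact lands under `config$workdir` together with a
#' config snapshot and its fingerprint; a rerun with identical configuration
#' resumes from existing checkpoints instead of retraining, and a rerun with
#' a different configuration in the same workdir aborts.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with `fits` (stage-1), `fusion_fit` (or `NULL`), `report`
#'   (test-set `metrics_report`), `split`, and `workdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) abort_config("config must be a run_config")
  manifest <- read_manifest(config$manifest_path)
  root <- dirname(config$manifest_path)
  wd <- config$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  fp <- config_fingerprint(config)
  fp_file <- file.path(wd, "config_fingerprint.txt")
  if (file.exists(fp_file)) {
    old <- readLines(fp_file)[1]
    if (!identical(old, fp))
      abort_config("workdir holds artifacts from a different configuration; refusing to resume")
  } else {
    writeLines(fp, fp_file)
    jsonlite::write_json(list(image_types = config$image_types, variant = config$variant,
                              seed = config$seed, fingerprint = fp),
                         file.path(wd, "config_snapshot.json"), auto_unbox = TRUE)
  }

  split <- config$split %||% default_split(cohort_cases(manifest), config$seed)
  tcfg <- config$train_cfg
  tcfg$seed <- derive_seed(config$seed, 17)

  fits <- vector("list", length(config$image_types))
  for (k in seq_along(config$image_types)) {
    ty <- config$image_types[[k]]
    ck <- file.path(wd, sprintf("stage1_%s.rds", gsub("[^a-z0-9]", "", tolower(ty))))
    if (file.exists(ck)) {
      say("resuming stage-1 checkpoint for ", ty)
      fits[[k]] <- readRDS(ck)
    } else {
      say("stage 1: fine-tuning encoder on ", ty)
      fits[[k]] <- train_stage1(manifest, root, ty, split, config$encoder_cfg, tcfg)
      saveRDS(fits[[k]], ck)
    }
  }

  fusion_fit <- NULL
  if (length(config$image_types) > 1) {
    ck2 <- file.path(wd, "stage2_fusion.rds")
    if (file.exists(ck2)) {
      say("resuming stage-2 checkpoint")
      fusion_fit <- readRDS(ck2)
    } else {
      say("stage 2: training ", config$variant, " fusion on frozen encoders")
      fusion_fit <- train_stage2(fits, config$image_types, manifest, root, split,
                                 variant = config$variant, config = tcfg)
      saveRDS(fusion_fit, ck2)
    }
    preds <- predict_fusion(fusion_fit, manifest, root, split$test)
  } else {
    preds <- predict_stage1(fits[[1]], manifest, root, split$test)
  }

  report <- evaluate_scores(preds$score, preds$label)
  jsonlite::write_json(list(metrics = glance(report),
                            counts = unclass(report$counts),
                            roc = report$roc),
                       file.path(wd, "metrics.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  say(sprintf("test AUC %.3f, accuracy %.3f", report$auc, report$acc))
  invisible(list(fits = fits, fusion_fit = fusion_fit, report = report,
                 split = split, workdir = wd))
}

#' Zero-data demonstration run
#'
#' Generates a small phantom cohort and runs the whole two-branch pipeline
#' (probe-centered crop branch + polar branch, FFM-v2 fusion) end-to-end on
#' the CPU. Scaled to finish in a few minutes.
#'
#' @param dir working directory (cohort + artifacts).
#' @param seed seed for cohort generation and training.
#' @param n_benign,n_malignant phantom case counts.
#' @param quiet suppress progress messages.
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(dir = tempfile("ebusdemo"), seed = 1L,
                     n_benign = 8L, n_malignant = 16L, quiet = FALSE) {
  pc <- phantom_config(image_size_px = 220L, pixels_per_cm = 50,
                       n_cases_benign = n_benign, n_cases_malignant = n_malignant,
                       frames_per_case = 4L, seed = derive_seed(seed, 19))
  cohort_dir <- file.path(dir, "cohort")
  if (!quiet) message("generating phantom cohort (", n_benign, " benign / ",
                      n_malignant, " malignant cases)")
  generate_cohort(pc, cohort_dir)
  cfg <- run_config(
    manifest_path = file.path(cohort_dir, "manifest.csv"),
    workdir = file.path(dir, "work"),
    image_types = c("type4", "polar3"), variant = "ffm_v2",
    train_cfg = train_config(input_size = 64L, max_epochs = 25L,
                             early_stop_patience = 6L, seed = seed),
    seed = seed)
  run_pipeline(cfg, quiet = quiet)
}
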