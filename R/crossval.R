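#' Build the segment table of a cohort
#'
#' For every envelope: split at signal cuts ([remove_cuts()]), slide
#' fixed-length windows ([segment_signal()]) and annotate quality
#' ([auto_annotate()]); a non-missing `quality` column in the manifest
#' overrides the heuristic for all segments of that envelope.  Rejected
#' segments are dropped — they never reach training or evaluation.
#'
#' @param cohort a `synthetic_cohort`, or a list with `manifest` and
#'   `envelopes` in the same layout.
#' @param length window length, samples (default 1024).
#' @param overlap_fraction window overlap in `[0, 1)`; use 0.8 for
#'   training augmentation, 0 for evaluation.
#' @param include_corrupted keep `corrupted` segments (default TRUE).
#' @return List with `segments` (matrix, one window per row) and `meta`
#'   (data frame: session_id, subject_id, class_label, quality,
#'   start_index, label with Healthy = 0 / ICU = 1).
#' @export
build_segment_table <- function(cohort, length = 1024L, overlap_fraction = 0,
                                include_corrupted = TRUE) {
  manifest <- cohort$manifest
  validate_manifest(manifest)
  seg_list <- list()
  meta_list <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$session_id[i]
    env <- cohort$envelopes[[sid]]
    if (is.null(env)) stop("no envelope for session ", sid)
    override <- if ("quality" %in% names(manifest)) manifest$quality[i] else NA
    runs <- remove_cuts(env, min_run = length)
    for (run in runs) {
      sm <- segment_signal(run, length = length,
                           overlap_fraction = overlap_fraction)
      if (nrow(sm) == 0L) next
      qual <- if (!is.na(override) && nzchar(override))
        rep(override, nrow(sm))
      else apply(sm, 1L, auto_annotate, fs = env$sample_rate)
      keep <- qual != "rejected" & (include_corrupted | qual == "clear")
      if (!any(keep)) next
      seg_list[[base::length(seg_list) + 1L]] <- sm[keep, , drop = FALSE]
      meta_list[[base::length(meta_list) + 1L]] <- data.frame(
        session_id = sid, subject_id = env$subject_id,
        class_label = env$class_label, quality = qual[keep],
        start_index = attr(run, "start_index") +
          attr(sm, "start_index")[keep])
    }
  }
  if (base::length(seg_list) == 0L)
    return(list(segments = matrix(numeric(0), 0L, length),
                meta = data.frame()))
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  meta$label <- as.integer(meta$class_label == "ICU")
  list(segments = do.call(rbind, seg_list), meta = meta)
}

#' Session-independent cross-validated classification
#'
#' The full experiment: builds training (overlapped) and evaluation
#' (non-overlapping) segment tables, forms the session-independent fold
#' plan, and for each requested fold trains a freshly initialized network
#' with [train_fold()] and evaluates it on the held-out sessions with
#' [evaluate_fold()].  The leakage guard is re-asserted per fold at run
#' time.  Overlap augmentation is applied to training data only, so no
#' near-duplicate windows cross the evaluation boundary.
#'
#' @param cohort a `synthetic_cohort` (or compatible list).
#' @param arch an [architecture_spec()].
#' @param config a [train_config()].
#' @param train_overlap training window overlap (default 0.8).
#' @param segment_length window length, samples (default 1024).
#' @param folds optional integer vector of fold indices to run (default:
#'   all `config$n_folds`).
#' @param include_corrupted keep corrupted-quality segments in training.
#' @param verbose print per-epoch progress.
#' @return An object of class `cbfv_cv`: per-fold fits and
#'   [classification_report()]s, a pooled report over all test segments,
#'   and the fold plan.
#' @export
run_crossval <- function(cohort, arch = architecture_spec(),
                         config = train_config(), train_overlap = 0.8,
                         segment_length = 1024L, folds = NULL,
                         include_corrupted = TRUE, verbose = FALSE) {
  plan <- make_session_folds(cohort$manifest, k = config$n_folds,
                             seed = config$seed)
  train_tab <- build_segment_table(cohort, length = segment_length,
                                   overlap_fraction = train_overlap,
                                   include_corrupted = include_corrupted)
  eval_tab <- build_segment_table(cohort, length = segment_length,
                                  overlap_fraction = 0,
                                  include_corrupted = include_corrupted)
  if (is.null(folds)) folds <- seq_len(config$n_folds)
  fold_results <- list()
  pooled_labels <- integer(0)
  pooled_preds <- integer(0)
  pooled_scores <- numeric(0)
  for (f in folds) {
    assert_no_leakage(plan)
    fold <- plan$folds[[f]]
    tr <- train_tab$meta$session_id %in% fold$train_sessions
    te <- eval_tab$meta$session_id %in% fold$test_sessions
    if (!any(tr) || !any(te)) stop("fold ", f, " has an empty split")
    if (any(eval_tab$meta$session_id[te] %in% fold$train_sessions))
      stop("session leakage detected in fold ", f)
    net <- if (arch$attention_enabled)
      build_self_resattentionet18(arch, seed = config$seed + f)
    else build_self_resnet18(arch, seed = config$seed + f)
    cfg_f <- config
    cfg_f$seed <- config$seed + 1000L * f
    fit <- train_fold(net, train_tab$segments[tr, , drop = FALSE],
                      train_tab$meta$label[tr],
                      sessions = train_tab$meta$session_id[tr],
                      config = cfg_f, verbose = verbose)
    probs <- predict(fit, eval_tab$segments[te, , drop = FALSE], type = "prob")
    preds <- max.col(probs, ties.method = "first") - 1L
    labels <- eval_tab$meta$label[te]
    report <- classification_report(labels, preds, scores = probs[, 2L])
    fold_results[[as.character(f)]] <- list(fold = f, fit = fit,
                                            report = report,
                                            test_sessions = fold$test_sessions)
    pooled_labels <- c(pooled_labels, labels)
    pooled_preds <- c(pooled_preds, preds)
    pooled_scores <- c(pooled_scores, probs[, 2L])
  }
  pooled <- classification_report(pooled_labels, pooled_preds, pooled_scores)
  structure(list(folds = fold_results, pooled = pooled, plan = plan,
                 arch = arch, config = config),
            class = "cbfv_cv")
}

#' @export
print.cbfv_cv <- function(x, ...) {
  cat(sprintf("Session-independent cross-validation: %s, Q = %d, %d fold(s) run\n",
              if (x$arch$attention_enabled) "Self-ResAttentioNet18" else "Self-ResNet18",
              x$arch$taylor_order, length(x$folds)))
  for (fr in x$folds)
    cat(sprintf("  fold %d: accuracy %.4f, AUC %.4f (test sessions: %s)\n",
                fr$fold, fr$report$overall_accuracy, fr$report$auc,
                paste(fr$test_sessions, collapse = ", ")))
  cat("Pooled over held-out segments:\n")
  print(x$pooled)
  invisible(x)
}

#' @export
summary.cbfv_cv <- function(object, ...) {
  accs <- vapply(object$folds, function(f) f$report$overall_accuracy, numeric(1))
  aucs <- vapply(object$folds, function(f) f$report$auc, numeric(1))
  list(fold_accuracy = accs, fold_auc = aucs,
       mean_accuracy = mean(accs), sd_accuracy = sd(accs),
       pooled = object$pooled)
}

#' Read a run configuration from YAML
#'
#' Recognized blocks: `architecture` (fields of [architecture_spec()]),
#' `training` (fields of [train_config()]) and `cohort` (fields of
#' [synthetic_cohort_spec()]); absent fields keep their defaults.
#'
#' @param path YAML file path.
#' @return List with elements `arch`, `config`, `cohort_spec`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fill <- function(fn, args) do.call(fn, args[names(args) %in% names(formals(fn))])
  list(arch = fill(architecture_spec, y$architecture %||% list()),
       config = fill(train_config, y$training %||% list()),
       cohort_spec = fill(synthetic_cohort_spec, y$cohort %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize layer kernels to YAML-friendly lists
#'
#' @param net a `selfonn_net`.
#' @param path YAML output path.
#' @return `path`, invisibly.
#' @export
write_network_yaml <- function(net, path) {
  stopifnot(inherits(net, "selfonn_net"))
  arch <- net$arch
  yaml::write_yaml(list(architecture = unclass(arch),
                        parameters = lapply(net$params, function(p)
                          list(dim = dim(p) %||% length(p),
                               values = as.numeric(p)))),
                   path)
  invisible(path)
}
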