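#' Session-independent k-fold plan
#'
#' Partitions the recording sessions of each class into `k` disjoint test
#' groups of balanced size; the sessions not under test form the training
#' set of that fold.  Whole sessions are assigned to exactly one side of
#' the split, so no segment of a session ever appears in both train and
#' test of a fold (the session-independent contract), and the k test sets
#' jointly partition the sessions.  A 10% validation split is taken from
#' the training segments later, at training time.
#'
#' @param manifest data frame with columns `session_id`, `subject_id` and
#'   `class_label` (one row per session, envelope or segment); a session id
#'   must map to a single subject and class.
#' @param k number of folds (default 5); every class must have at least
#'   `k` sessions and `k` must be at least 2.
#' @param seed integer; the partition is deterministic given the seed.
#' @param val_fraction fraction of training segments to reserve for
#'   validation during training (recorded in the plan).
#' @return An object of class `fold_plan`.
#' @export
make_session_folds <- function(manifest, k = 5L, seed = 1L,
                               val_fraction = 0.10) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2: k = 1 leaves no held-out training data")
  need <- c("session_id", "subject_id", "class_label")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  sess <- unique(manifest[, need])
  if (anyDuplicated(sess$session_id))
    stop("a session_id maps to more than one subject or class")
  set.seed(as.integer(seed))
  classes <- sort(unique(sess$class_label))
  groups <- vector("list", k)
  for (cl in classes) {
    ids <- sample(sess$session_id[sess$class_label == cl])
    if (length(ids) < k)
      stop("class ", cl, " has ", length(ids), " sessions; need at least k = ", k)
    sizes <- rep(length(ids) %/% k, k)
    extra <- length(ids) %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    at <- 1L
    for (i in seq_len(k)) {
      groups[[i]] <- c(groups[[i]], ids[at:(at + sizes[i] - 1L)])
      at <- at + sizes[i]
    }
  }
  all_ids <- sess$session_id
  folds <- lapply(seq_len(k), function(i) {
    test <- groups[[i]]
    list(fold = i, train_sessions = setdiff(all_ids, test),
         test_sessions = test)
  })
  plan <- structure(list(folds = folds, k = k, val_fraction = val_fraction,
                         sessions = sess, seed = as.integer(seed)),
                    class = "fold_plan")
  assert_no_leakage(plan)
  plan
}

#' Leakage guard for a fold plan
#'
#' Asserts that within every fold the train and test session sets are
#' disjoint, that test sets are pairwise disjoint across folds, and that
#' the test sets jointly cover every session.  Called automatically by
#' [make_session_folds()]; exported so pipelines can re-assert the
#' invariant at run time on deserialized plans.
#'
#' @param plan a `fold_plan`.
#' @return `TRUE`, invisibly; stops with an error on any violation.
#' @export
assert_no_leakage <- function(plan) {
  stopifnot(inherits(plan, "fold_plan"))
  all_ids <- plan$sessions$session_id
  seen <- character(0)
  for (f in plan$folds) {
    if (length(intersect(f$train_sessions, f$test_sessions)) > 0L)
      stop("session leakage: fold ", f$fold, " shares sessions between train and test")
    if (length(intersect(seen, f$test_sessions)) > 0L)
      stop("fold test sets are not pairwise disjoint")
    seen <- c(seen, f$test_sessions)
  }
  if (!setequal(seen, all_ids))
    stop("fold test sets do not partition the sessions")
  invisible(TRUE)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Session-independent %d-fold plan (%d sessions, seed %d)\n",
              x$k, nrow(x$sessions), x$seed))
  for (f in x$folds)
    cat(sprintf("  fold %d: %2d train / %2d test sessions [test: %s]\n",
                f$fold, length(f$train_sessions), length(f$test_sessions),
                paste(f$test_sessions, collapse = ", ")))
  invisible(x)
}

#' Serialize / restore a fold plan as JSON
#' @param plan a `fold_plan`; @param path file path.
#' @return `write_fold_plan` returns `path`; `read_fold_plan` the plan.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$folds <- lapply(seq_len(nrow(raw$folds)), function(i) {
    list(fold = raw$folds$fold[i],
         train_sessions = unlist(raw$folds$train_sessions[i]),
         test_sessions = unlist(raw$folds$test_sessions[i]))
  })
  plan <- structure(raw, class = "fold_plan")
  assert_no_leakage(plan)
  plan
}
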