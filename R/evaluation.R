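#' Stratified folds for cross-validation
#'
#' Randomly permutes the sessions (seeded) and partitions them into
#' `n_folds` folds with equal class composition: with the reference
#' protocol of 30 correct + 30 incorrect sessions and 10 folds, every
#' fold holds exactly 3 correct and 3 incorrect sessions.
#'
#' @param labels Character vector of `"correct"`/`"incorrect"` labels.
#' @param n_folds Number of folds.
#' @param seed Seed for the permutation (same seed, same folds).
#' @return A list of `n_folds` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
make_folds <- function(labels, n_folds = 10L, seed = NULL) {
  classes <- unique(labels)
  per_class <- lapply(classes, function(cl) which(labels == cl))
  bad <- vapply(per_class, function(ix) length(ix) %% n_folds != 0L, logical(1))
  if (any(bad))
    stop("class counts (", paste(lengths(per_class), collapse = ", "),
         ") must be divisible by the fold count (", n_folds, ")")
  shuffled <- with_seed(seed, lapply(per_class, sample))
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    folds[[f]] <- sort(unlist(lapply(shuffled, function(ix) {
      k <- length(ix) / n_folds
      ix[((f - 1L) * k + 1L):(f * k)]
    })))
  }
  folds
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Confusion counts and classification metrics
#'
#' The positive class is the *correct* sessions: sensitivity is the
#' detection rate of correct executions and specificity that of
#' incorrect ones. `accuracy = (TP+TN)/N`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`.
#'
#' @param truth,predicted Character vectors of `"correct"`/`"incorrect"`.
#' @param positive The positive class.
#' @return `confusion_counts()`: a list with integers `TP`, `TN`, `FP`,
#'   `FN`; `classification_metrics()`: a list with `accuracy`,
#'   `specificity`, `sensitivity`, `kappa`, `kappa_band` and the counts.
#' @export
confusion_counts <- function(truth, predicted, positive = "correct") {
  stopifnot(length(truth) == length(predicted))
  pos_t <- truth == positive
  pos_p <- predicted == positive
  list(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
       FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p))
}

#' @rdname confusion_counts
#' @param counts A list with `TP`, `TN`, `FP`, `FN`.
#' @export
classification_metrics <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0L) stop("no classified sessions")
  kap <- cohen_kappa(counts)
  list(accuracy = (counts$TP + counts$TN) / n,
       specificity = if (counts$TN + counts$FP > 0)
         counts$TN / (counts$TN + counts$FP) else NA_real_,
       sensitivity = if (counts$TP + counts$FN > 0)
         counts$TP / (counts$TP + counts$FN) else NA_real_,
       kappa = kap,
       kappa_band = if (is.na(kap)) NA_character_ else kappa_band(kap),
       counts = counts)
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement between predicted and gold-standard labels:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with observed agreement
#' `p_o = (TP+TN)/N` and chance agreement `p_e` from the marginal
#' products. In the degenerate case `p_e = 1` (all labels in one class),
#' kappa is 1 if agreement is also perfect and `NA` (with a warning)
#' otherwise.
#'
#' @param counts A list with `TP`, `TN`, `FP`, `FN` (total > 0).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  n <- tp + tn + fp + fn
  if (n == 0L) stop("no classified sessions")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe >= 1) {
    if (po == 1) return(1)
    warning("chance agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Interpretation band of a kappa value
#'
#' Bands: `(0.8, 1]` almost perfect, `(0.6, 0.8]` substantial,
#' `(0.4, 0.6]` moderate, `(0.2, 0.4]` fair, `[0, 0.2]` slight,
#' `< 0` poor (a kappa of exactly 0 is mapped to "slight").
#'
#' @param kappa A value in `[-1, 1]`.
#' @return One of `"almost perfect"`, `"substantial"`, `"moderate"`,
#'   `"fair"`, `"slight"`, `"poor"`.
#' @export
kappa_band <- function(kappa) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1)
    stop("kappa must be in [-1, 1]")
  if (kappa < 0) "poor"
  else if (kappa <= 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "almost perfect"
}

#' Repeated tenfold cross-validation of the assessment method
#'
#' Runs the full participant-specific, exercise-specific evaluation
#' protocol on one set of labeled sessions (the reference design: 30
#' correct + 30 incorrect). Per repetition, the sessions are randomly
#' split into `n_folds` stratified folds; each fold in turn is held out,
#' a gold-standard bank is built from the remaining folds, backward
#' elimination selects a feature subset on that bank only (when
#' `select = TRUE` and `selection_scope = "nested"`), and the held-out
#' sessions are classified with the selected subset, so every session is
#' classified exactly once per repetition. Confusion counts are
#' aggregated into accuracy, specificity, sensitivity and Cohen's kappa;
#' results are summarized as mean and SD over repetitions.
#'
#' `selection_scope = "per_repetition"` instead selects one subset per
#' repetition on all sessions before the fold loop (the literal
#' one-combination-per-repetition reading; optimistic, since selection
#' then sees the test sessions).
#'
#' For CBOFF/PBOFIF bookkeeping each repetition reports one "optimized
#' features combination": under nested selection, the features selected
#' in at least `majority_folds` of the folds (falling back to the most
#' frequently selected features if that set is empty).
#'
#' @param series List of `"feature_series"` for one participant and
#'   exercise, each labeled `"correct"` or `"incorrect"`.
#' @param repetitions Number of evaluation repetitions (reference: 10).
#' @param n_folds Number of folds (reference: 10).
#' @param seed Base seed; repetition `r` uses `seed + r`.
#' @param select Run backward elimination (otherwise all 38 features).
#' @param selection_scope `"nested"` or `"per_repetition"`.
#' @param inner_max_per_class Passed to [backward_eliminate()].
#' @param normalize_by_path,paper_literal_rule Passed to the classifier.
#' @param majority_folds Fold-count threshold for the per-repetition
#'   combination (default: half the folds, rounded up).
#' @return An object of class `"cv_report"`: `metrics` (one row per
#'   repetition), `summary` (mean/SD per metric), `subsets` (per
#'   repetition: per-fold subsets and the combination), and the run
#'   configuration.
#' @export
run_repeated_cv <- function(series, repetitions = 10L, n_folds = 10L,
                            seed = 1L, select = TRUE,
                            selection_scope = c("nested", "per_repetition"),
                            inner_max_per_class = 8L,
                            normalize_by_path = TRUE,
                            paper_literal_rule = FALSE,
                            majority_folds = ceiling(n_folds / 2)) {
  selection_scope <- match.arg(selection_scope)
  labels <- vapply(series, `[[`, "", "label")
  if (!all(labels %in% c("correct", "incorrect")))
    stop("all sessions must be labeled 'correct' or 'incorrect'")
  meta <- bank_metadata(series)

  metrics <- vector("list", repetitions)
  subsets <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    rep_seed <- seed + r
    folds <- make_folds(labels, n_folds, seed = rep_seed)
    rep_subset_once <- NULL
    if (select && selection_scope == "per_repetition") {
      bank_all <- gold_standard_bank(series[labels == "correct"],
                                     series[labels == "incorrect"])
      rep_subset_once <- backward_eliminate(
        bank_all, inner_max_per_class = inner_max_per_class,
        normalize_by_path = normalize_by_path, seed = rep_seed)$features
    }
    predicted <- character(length(series))
    fold_subsets <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_along(series), test_idx)
      bank <- gold_standard_bank(
        series[train_idx][labels[train_idx] == "correct"],
        series[train_idx][labels[train_idx] == "incorrect"])
      feats <- if (!select) feature_names()
      else if (selection_scope == "per_repetition") rep_subset_once
      else backward_eliminate(bank, inner_max_per_class = inner_max_per_class,
                              normalize_by_path = normalize_by_path,
                              seed = rep_seed * 100L + f)$features
      fold_subsets[[f]] <- feats
      for (i in test_idx) {
        predicted[i] <- classify_session(
          series[[i]], bank, features = feats,
          normalize_by_path = normalize_by_path,
          paper_literal_rule = paper_literal_rule)$predicted_label
      }
    }
    counts <- confusion_counts(labels, predicted)
    m <- classification_metrics(counts)
    metrics[[r]] <- data.frame(
      repetition = r, seed = rep_seed,
      TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN,
      accuracy = m$accuracy, specificity = m$specificity,
      sensitivity = m$sensitivity, kappa = m$kappa,
      kappa_band = m$kappa_band, stringsAsFactors = FALSE)
    combination <- if (!select) feature_names()
    else if (selection_scope == "per_repetition") rep_subset_once
    else majority_combination(fold_subsets, majority_folds)
    subsets[[r]] <- list(folds = fold_subsets, combination = combination)
  }
  metrics <- do.call(rbind, metrics)
  num <- c("accuracy", "specificity", "sensitivity", "kappa")
  summ <- data.frame(
    metric = num,
    mean = vapply(num, function(m) mean(metrics[[m]]), numeric(1)),
    sd = vapply(num, function(m) sd(metrics[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(participant_id = meta$participant_id,
                 exercise = meta$exercise,
                 metrics = metrics, summary = summ, subsets = subsets,
                 config = list(repetitions = repetitions, n_folds = n_folds,
                               seed = seed, select = select,
                               selection_scope = selection_scope,
                               inner_max_per_class = inner_max_per_class,
                               normalize_by_path = normalize_by_path,
                               paper_literal_rule = paper_literal_rule)),
            class = "cv_report")
}

majority_combination <- function(fold_subsets, majority_folds) {
  counts <- table(unlist(fold_subsets))
  keep <- names(counts)[counts >= majority_folds]
  if (!length(keep)) keep <- names(counts)[counts == max(counts)]
  canon <- feature_names()
  canon[canon %in% keep]
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s | %s | %d repetitions x %d folds\n",
              x$participant_id, x$exercise,
              x$config$repetitions, x$config$n_folds))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  mk <- mean(x$metrics$kappa)
  cat(sprintf("  mean kappa band: %s\n", kappa_band(mk)))
  invisible(x)
}

#' Feature-occurrence summaries over optimized combinations
#'
#' `cboff()` is the combination-based occurrence frequency: for each of
#' the 38 features, the number of optimized feature combinations that
#' contain it (with 6 participants x 10 repetitions the maximum is 60).
#' `pbofif()` is the participant-based occurrence frequency of the
#' important features: a feature is *important* for a participant when it
#' appears more than `threshold` (default 2) times among that
#' participant's per-repetition combinations, and PBOFIF counts the
#' participants for which the feature is important (maximum = number of
#' participants).
#'
#' @param subsets A list of character vectors (optimized combinations),
#'   or a list of `"cv_report"` objects whose per-repetition combinations
#'   are pooled.
#' @return A named integer vector over [feature_names()].
#' @export
cboff <- function(subsets) {
  combos <- as_combinations(subsets)
  if (!length(combos)) stop("empty subset collection")
  vapply(feature_names(), function(f)
    sum(vapply(combos, function(s) f %in% s, logical(1))), integer(1))
}

#' @rdname cboff
#' @param subsets_by_participant A named list, one element per
#'   participant, each a list of character vectors (or a `"cv_report"`).
#' @param threshold A feature is important when it occurs more than this
#'   many times within one participant's combinations.
#' @export
pbofif <- function(subsets_by_participant, threshold = 2L) {
  per_part <- lapply(subsets_by_participant, as_combinations)
  vapply(feature_names(), function(f) {
    sum(vapply(per_part, function(combos)
      sum(vapply(combos, function(s) f %in% s, logical(1))) > threshold,
      logical(1)))
  }, integer(1))
}

as_combinations <- function(x) {
  if (inherits(x, "cv_report")) return(lapply(x$subsets, `[[`, "combination"))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "cv_report")))
    return(unlist(lapply(x, function(r)
      lapply(r$subsets, `[[`, "combination")), recursive = FALSE))
  if (is.character(x)) return(list(x))
  x
}
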