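#' Gold-standard session bank for one participant and exercise
#'
#' Collects the labeled training sessions against which a new session is
#' compared: `N1` correct and `N2` incorrect feature series. Per-feature
#' normalization statistics (mean and SD pooled over every frame of every
#' member, both sides) are computed once here and reused for each
#' comparison, so that angle, position, velocity and acceleration
#' features enter the warping cost on a comparable scale.
#'
#' @param correct,incorrect Non-empty lists of `"feature_series"` (or
#'   plain feature matrices) with the same columns.
#' @return An object of class `"gs_bank"`: lists `correct`/`incorrect` of
#'   raw matrices, their z-scored copies, `stats`, and the shared
#'   metadata.
#' @export
gold_standard_bank <- function(correct, incorrect) {
  if (!length(correct) || !length(incorrect))
    stop("both bank sides must be non-empty")
  meta <- bank_metadata(c(correct, incorrect))
  cm <- lapply(correct, feature_matrix)
  im <- lapply(incorrect, feature_matrix)
  pooled <- do.call(rbind, c(cm, im))
  stats <- list(mean = colMeans(pooled), sd = apply(pooled, 2, sd))
  stats$sd[!is.finite(stats$sd) | stats$sd <= 0] <- 1
  structure(list(participant_id = meta$participant_id,
                 exercise = meta$exercise,
                 correct = cm, incorrect = im,
                 z_correct = lapply(cm, zscore_features, stats = stats),
                 z_incorrect = lapply(im, zscore_features, stats = stats),
                 stats = stats,
                 n1 = length(cm), n2 = length(im)),
            class = "gs_bank")
}

bank_metadata <- function(series) {
  fs <- Filter(function(s) inherits(s, "feature_series"), series)
  if (!length(fs)) return(list(participant_id = NA_character_, exercise = NA_character_))
  pid <- unique(vapply(fs, `[[`, "", "participant_id"))
  exe <- unique(vapply(fs, `[[`, "", "exercise"))
  if (length(pid) > 1L || length(exe) > 1L)
    stop("all bank members must share participant and exercise")
  list(participant_id = pid, exercise = exe)
}

#' @export
print.gs_bank <- function(x, ...) {
  cat(sprintf("<gs_bank> %s | %s | %d correct + %d incorrect sessions\n",
              x$participant_id, x$exercise, x$n1, x$n2))
  invisible(x)
}

#' Average warping distance from a session to one side of a bank
#'
#' The arithmetic mean of the MD-DTW distances between the query series
#' and each member of the given side, restricted to the selected feature
#' subset, after z-scoring both with the bank statistics.
#'
#' @param sfv Query `"feature_series"` or matrix.
#' @param bank A `"gs_bank"`.
#' @param side `"correct"` or `"incorrect"`.
#' @param features Feature subset (default: all 38).
#' @param normalize_by_path Use path-length-normalized distances
#'   (default `TRUE`; removes the session-length confound).
#' @return A single non-negative number.
#' @export
average_distance <- function(sfv, bank, side = c("correct", "incorrect"),
                             features = feature_names(),
                             normalize_by_path = TRUE) {
  stopifnot(inherits(bank, "gs_bank"))
  side <- match.arg(side)
  members <- if (side == "correct") bank$z_correct else bank$z_incorrect
  if (!length(members)) stop("empty bank side: ", side)
  q <- zscore_features(feature_matrix(sfv), bank$stats)
  cols <- feature_cols(q, features)
  mean(mddtw_query_cpp(q, members, cols, normalize_by_path))
}

#' Classify a session against a gold-standard bank
#'
#' Computes the average MD-DTW distance from the query to the correct
#' side (`d_C`) and to the incorrect side (`d_IC`) and predicts
#' `"correct"` when `d_C <= d_IC` (nearest bank wins; ties go to
#' correct). `paper_literal_rule = TRUE` applies the opposite inequality
#' (`d_C >= d_IC` predicts correct), which inverts the labels on
#' separable data and is provided only for comparison.
#'
#' @inheritParams average_distance
#' @param paper_literal_rule Apply the inverted decision direction.
#' @return A list: `predicted_label`, `d_C`, `d_IC`, `margin = d_IC - d_C`.
#' @export
classify_session <- function(sfv, bank, features = feature_names(),
                             normalize_by_path = TRUE,
                             paper_literal_rule = FALSE) {
  d_C <- average_distance(sfv, bank, "correct", features, normalize_by_path)
  d_IC <- average_distance(sfv, bank, "incorrect", features, normalize_by_path)
  correct_wins <- if (paper_literal_rule) d_C >= d_IC else d_C <= d_IC
  list(predicted_label = if (correct_wins) "correct" else "incorrect",
       d_C = d_C, d_IC = d_IC, margin = d_IC - d_C)
}
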