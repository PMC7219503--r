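#' Leave-one-out accuracy of a feature subset within a bank
#'
#' Scores a candidate feature subset by classifying each bank member
#' against the bank minus itself (nearest-bank rule, ties predicting
#' correct) and returning the fraction classified correctly. This is the
#' inner criterion of [backward_eliminate()]; it never touches held-out
#' test sessions.
#'
#' @param bank A `"gs_bank"` with at least 2 members per side.
#' @param features Feature subset to score.
#' @param normalize_by_path Passed through to the warping distance.
#' @param use_idx Optional integer indices (into the concatenation of the
#'   correct then incorrect members) restricting the evaluation to a
#'   member subsample; used by [backward_eliminate()] to bound the
#'   quadratic leave-one-out cost.
#' @return Accuracy in `[0, 1]`. Deterministic for fixed inputs.
#' @export
inner_score <- function(bank, features, normalize_by_path = TRUE,
                        use_idx = NULL) {
  stopifnot(inherits(bank, "gs_bank"))
  if (bank$n1 < 2L || bank$n2 < 2L)
    stop("leave-one-out scoring needs at least 2 members per side")
  members <- c(bank$z_correct, bank$z_incorrect)
  labels <- rep(c(TRUE, FALSE), c(bank$n1, bank$n2))  # TRUE = correct
  if (!is.null(use_idx)) {
    members <- members[use_idx]
    labels <- labels[use_idx]
    if (sum(labels) < 2L || sum(!labels) < 2L)
      stop("member subsample must keep at least 2 per side")
  }
  cols <- feature_cols(members[[1]], features)
  D <- mddtw_pairwise_cpp(members, cols, normalize_by_path)
  loo_accuracy(D, labels)
}

loo_accuracy <- function(D, labels) {
  n <- length(labels)
  hits <- 0L
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dC <- mean(D[i, others[labels[others]]])
    dIC <- mean(D[i, others[!labels[others]]])
    pred <- dC <= dIC
    hits <- hits + (pred == labels[i])
  }
  hits / n
}

#' Recursive backward feature elimination
#'
#' Starting from the full feature set, repeatedly scores every
#' one-feature-removed candidate with [inner_score()] and permanently
#' removes the feature whose removal gives the highest score, as long as
#' that score is at least the current score (equality is not a reduction,
#' so ties favor the smaller subset). Stops when every removal strictly
#' reduces the score, or when one feature remains. Among equal-scoring
#' removals the feature with the lowest canonical index is removed, so
#' the procedure is deterministic given the bank (and the member
#' subsample, which is drawn once per run from `seed`).
#'
#' @param bank A `"gs_bank"`.
#' @param features Starting feature set (default: all 38).
#' @param normalize_by_path Passed to the warping distance.
#' @param inner_max_per_class If set, the leave-one-out evaluation uses a
#'   stratified subsample of at most this many members per side, drawn
#'   once (seeded); bounds the otherwise quadratic cost in bank size.
#' @param seed Seed for the member subsample draw.
#' @return An object of class `"feature_subset"`: `features` (surviving
#'   subset, canonical order), `score` (its inner accuracy), and
#'   `history` (one row per accepted elimination; the recorded score
#'   never decreases).
#' @export
backward_eliminate <- function(bank, features = feature_names(),
                               normalize_by_path = TRUE,
                               inner_max_per_class = NULL, seed = NULL) {
  stopifnot(inherits(bank, "gs_bank"))
  canon <- feature_names()
  features <- canon[canon %in% features]
  if (!length(features)) stop("empty starting feature set")

  use_idx <- NULL
  if (!is.null(inner_max_per_class) &&
      (bank$n1 > inner_max_per_class || bank$n2 > inner_max_per_class)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    ic <- sort(sample.int(bank$n1, min(bank$n1, inner_max_per_class)))
    ii <- sort(sample.int(bank$n2, min(bank$n2, inner_max_per_class)))
    use_idx <- c(ic, bank$n1 + ii)
  }
  score <- function(fs) inner_score(bank, fs, normalize_by_path, use_idx)

  current <- features
  current_score <- score(current)
  history <- list()
  step <- 0L
  while (length(current) > 1L) {
    cand <- vapply(seq_along(current), function(i)
      score(current[-i]), numeric(1))
    best <- max(cand)
    if (best < current_score) break
    drop_i <- which(cand == best)[1L]   # lowest canonical index among ties
    step <- step + 1L
    history[[step]] <- data.frame(step = step, removed = current[drop_i],
                                  score = best, n_features = length(current) - 1L,
                                  stringsAsFactors = FALSE)
    current <- current[-drop_i]
    current_score <- best
  }
  structure(list(features = current, score = current_score,
                 history = if (length(history)) do.call(rbind, history) else
                   data.frame(step = integer(), removed = character(),
                              score = numeric(), n_features = integer())),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset> %d features, inner score %.3f\n",
              length(x$features), x$score))
  cat(" ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
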