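# Scoring against the unigram null model, recall-precision evaluation,
# descriptive (contact-prediction) metrics of parse trees, sliding-window
# motif search and the cross-validation harness.  All reported scores are
# decimal (base-10) log-odds: a score of 3 means the sequence is 1,000
# times more probable under the grammar than under the null model.

#' Unigram null model
#'
#' @param frequencies Named numeric vector of background frequencies, one
#'   per terminal symbol; must sum to 1 (tolerance 1e-9 after optional
#'   normalization).
#' @param normalize If `TRUE`, rescale the input to sum to 1.
#' @return Object of class `null_model`.
#' @export
null_model <- function(frequencies, normalize = FALSE) {
  f <- as.numeric(frequencies)
  names(f) <- names(frequencies)
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stop("frequencies must be named by terminal symbol")
  if (any(f < 0)) stop("frequencies must be non-negative")
  if (normalize) f <- f / sum(f)
  if (abs(sum(f) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(f)), "); ",
         "use normalize = TRUE to rescale")
  structure(list(frequencies = f), class = "null_model")
}

#' Default amino-acid background null model
#'
#' Swiss-Prot database background frequencies of the 20 amino acids,
#' shipped as a plain-text table (`extdata/aa_background_frequencies.tsv`)
#' and renormalized to sum to exactly 1. Fully overridable via
#' [null_model()].
#'
#' @return A `null_model`.
#' @export
default_null_model <- function() {
  path <- system.file("extdata", "aa_background_frequencies.tsv",
                      package = "contactpcfg", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  null_model(setNames(tab$frequency, tab$aa), normalize = TRUE)
}

#' Decimal-log probability of a sequence under the null model
#'
#' @param x Sequence string or character vector.
#' @param null A [null_model()].
#' @return `sum(log10 f(x_i))`.
#' @export
null_logprob <- function(x, null) {
  stopifnot(inherits(null, "null_model"))
  if (length(x) == 1L && is.character(x)) x <- strsplit(x, "")[[1]]
  f <- null$frequencies[x]
  if (anyNA(f)) stop("sequence contains symbol(s) not covered by the null model: ",
                     paste(unique(x[is.na(f)]), collapse = ", "))
  sum(log10(f))
}

#' Log-odds score of a sequence against the null model
#'
#' `log10 prob(x | g) - log10 prob(x | null)`; with a contact map the
#' grammar probability is restricted to map-consistent parse trees.
#'
#' @param g A `cfc_grammar`.
#' @param x Sequence.
#' @param null A [null_model()].
#' @param map Optional `contact_map`.
#' @return Decimal log-odds score (`-Inf` when the grammar cannot parse).
#' @export
score_sequence <- function(g, x, null, map = NULL) {
  lp <- inside(g, x, map) / log(10)
  lp - null_logprob(x, null)
}

#' Mean log-odds score over an ensemble of grammars
#'
#' Arithmetic mean of [score_sequence()] over the grammars (as used when
#' combining several training runs); `-Inf` as soon as one member cannot
#' parse the sequence.
#'
#' @param grammars Non-empty list of `cfc_grammar` objects.
#' @inheritParams score_sequence
#' @return Mean decimal log-odds score.
#' @export
ensemble_score <- function(grammars, x, null, map = NULL) {
  stopifnot(is.list(grammars), length(grammars) >= 1L)
  mean(vapply(grammars, function(g) score_sequence(g, x, null, map), 0))
}

#' Recall-precision curve and average precision
#'
#' Ranks all scores in decreasing order and steps through the unique score
#' values as thresholds (ties share one step). Average precision is the
#' step sum `AP = sum_k (R_k - R_{k-1}) P_k`, which approximates the area
#' under the recall-precision curve and is invariant under strictly
#' monotone transformations of the scores.
#'
#' @param positives,negatives Numeric score vectors (finite or `-Inf`).
#' @return List with `curve` (data frame: threshold, recall, precision)
#'   and `ap`.
#' @export
recall_precision_ap <- function(positives, negatives) {
  stopifnot(length(positives) >= 1L)
  scores <- c(positives, negatives)
  labels <- c(rep(TRUE, length(positives)), rep(FALSE, length(negatives)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  # group ties: one threshold step per unique score value
  grp <- cumsum(!duplicated(scores))
  tp <- tapply(labels, grp, sum)
  nn <- tapply(labels, grp, length)
  ctp <- cumsum(tp)
  cn <- cumsum(nn)
  recall <- ctp / length(positives)
  precision <- ctp / cn
  thr <- scores[!duplicated(scores)]
  dr <- diff(c(0, recall))
  ap <- sum(dr * precision)
  list(curve = data.frame(threshold = thr, recall = as.numeric(recall),
                          precision = as.numeric(precision)),
       ap = ap)
}

#' Descriptive (contact-prediction) metrics of a parse tree
#'
#' Uses leaf distances in the tree skeleton as a contact predictor: the
#' pair `(i, j)` is predicted to be in contact at cutoff `delta` when
#' `d_u(i, j) <= delta`; at the natural CFC cutoff `delta = 4` this means
#' the pair is parsed with a contact rule. Reports recall at `delta`
#' against the (partial) training map, precision at `delta` against the
#' full reference map, average precision over all distance cutoffs (pairs
#' at equal distance share a threshold step) and local per-residue AP.
#' Only pairs with sequence separation `>= min_separation` are considered.
#'
#' @param tree A `parse_tree` (typically from [viterbi()]).
#' @param training_map Partial `contact_map` used in training (recall
#'   reference), or `NULL`.
#' @param full_map Full reference `contact_map` (precision/AP reference),
#'   or `NULL`.
#' @param delta Distance cutoff in edges (default 4).
#' @param min_separation Minimum sequence separation of scored pairs
#'   (default 3).
#' @return List with `recall_at_delta`, `precision_at_delta`,
#'   `ap_over_deltas`, `n_predicted`, and `local` (data frame of
#'   per-residue AP; `NA` for residues with no reference contact in
#'   range). Metrics without a usable reference are `NA`.
#' @export
descriptive_metrics <- function(tree, training_map = NULL, full_map = NULL,
                                delta = 4L, min_separation = 3L) {
  n <- length(tree_yield(tree))
  D <- leaf_distance_matrix(tree)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] >= min_separation, , drop = FALSE]
  d_u <- D[idx]
  pred <- d_u <= delta

  restrict <- function(map) {
    if (is.null(map)) return(NULL)
    stopifnot(inherits(map, "contact_map"))
    if (map$length != n) stop("map length does not match tree yield")
    p <- map$pairs
    p[p[, 2L] - p[, 1L] >= min_separation, , drop = FALSE]
  }
  tp_pairs <- restrict(training_map)
  fp_pairs <- restrict(full_map)

  recall_at_delta <- if (is.null(tp_pairs) || nrow(tp_pairs) == 0L) NA_real_ else
    mean(D[tp_pairs] <= delta)

  precision_at_delta <- NA_real_
  ap_over_deltas <- NA_real_
  local <- NULL
  if (!is.null(fp_pairs)) {
    if (nrow(fp_pairs) == 0L) {
      message("empty reference map: precision/AP undefined")
    } else {
      is_contact <- matrix(FALSE, n, n)
      is_contact[fp_pairs] <- TRUE
      is_contact[fp_pairs[, 2:1, drop = FALSE]] <- TRUE
      truth <- is_contact[idx]
      if (any(pred)) precision_at_delta <- sum(truth & pred) / sum(pred)
      else precision_at_delta <- NA_real_
      # rank by ascending tree distance: smaller d_u = stronger prediction
      ap_over_deltas <- recall_precision_ap(-d_u[truth], -d_u[!truth])$ap
      local_ap <- rep(NA_real_, n)
      for (k in seq_len(n)) {
        row_k <- idx[, 1L] == k | idx[, 2L] == k
        if (!any(row_k & truth)) next
        local_ap[k] <- recall_precision_ap(-d_u[row_k & truth],
                                           -d_u[row_k & !truth])$ap
      }
      local <- data.frame(position = seq_len(n),
                          n_reference_contacts = vapply(seq_len(n), function(k)
                            sum((idx[, 1L] == k | idx[, 2L] == k) & truth), 1L),
                          local_ap = local_ap)
    }
  }
  list(recall_at_delta = recall_at_delta,
       precision_at_delta = precision_at_delta,
       ap_over_deltas = ap_over_deltas,
       n_predicted = sum(pred),
       delta = delta, min_separation = min_separation,
       local = local)
}

#' Sliding-window motif search
#'
#' Scores every window of widths `window_min..window_max` at every start
#' position against the grammar (or grammar ensemble) and the null model,
#' and reports the best window per start plus all above-threshold hits.
#'
#' @param x Long sequence (string).
#' @param grammars A `cfc_grammar` or list of them (ensemble mean score).
#' @param null A [null_model()].
#' @param window_min,window_max Window width range (defaults 20 and 30).
#' @param threshold Decimal log-odds threshold for reporting hits.
#' @return List with `windows` (data frame: start, width, score), `best`
#'   (best-scoring window per start) and `hits` (windows with
#'   `score >= threshold`).
#' @export
scan_sequence <- function(x, grammars, null, window_min = 20L,
                          window_max = 30L, threshold = 3) {
  if (inherits(grammars, "cfc_grammar")) grammars <- list(grammars)
  stopifnot(window_min >= 2L, window_min <= window_max)
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  out <- list()
  if (n >= window_min) {
    for (start in seq_len(n - window_min + 1L)) {
      for (w in window_min:min(window_max, n - start + 1L)) {
        sub <- paste(chars[start:(start + w - 1L)], collapse = "")
        out[[length(out) + 1L]] <-
          data.frame(start = start, width = w,
                     score = ensemble_score(grammars, sub, null))
      }
    }
  }
  windows <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), width = integer(0), score = numeric(0))
  best <- if (nrow(windows)) do.call(rbind, lapply(split(windows, windows$start),
    function(d) d[which.max(d$score), ])) else windows
  rownames(best) <- NULL
  hits <- windows[is.finite(windows$score) & windows$score >= threshold, ]
  rownames(hits) <- NULL
  list(windows = windows, best = best, hits = hits)
}

#' Cross-validation splits (8-fold, train/validation/test)
#'
#' Partitions the items into `folds` parts at random (seed-reproducible)
#' and enumerates every ordered combination of one validation part and one
#' different test part, with the remaining parts forming the training set:
#' `folds * (folds - 1)` combinations (56 for the default 8 folds).
#'
#' @param n_items Number of items (>= `folds`).
#' @param folds Number of parts (default 8).
#' @param seed Integer seed for the partition.
#' @return List of splits, each with `train`, `validation`, `test` index
#'   vectors and `fold_validation`/`fold_test` labels.
#' @export
cv_split <- function(n_items, folds = 8L, seed = 1L) {
  n_items <- as.integer(n_items)
  folds <- as.integer(folds)
  if (n_items < folds) stop("need at least as many items as folds")
  set.seed(seed)
  part <- sample(rep(seq_len(folds), length.out = n_items))
  splits <- list()
  for (v in seq_len(folds)) for (t in seq_len(folds)) {
    if (v == t) next
    splits[[length(splits) + 1L]] <- list(
      train = which(!part %in% c(v, t)),
      validation = which(part == v),
      test = which(part == t),
      fold_validation = v, fold_test = t)
  }
  splits
}
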