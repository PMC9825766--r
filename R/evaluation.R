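# Scoring and experiment orchestration: AUC/AUPRC, repeated random-split
# experiments, per-tissue rank aggregation of methods by median AUC
# ("mAUC"), two-sided Wilcoxon rank-sum comparisons, and PE<->PP cross
# prediction.

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney form: the probability that a random positive
#' scores above a random negative, with ties counting one half. Invariant to
#' strictly monotone transforms of the scores.
#'
#' @param labels Binary 0/1 vector (both classes must be present).
#' @param scores Numeric scores, higher = more likely positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  check_two_class(labels, scores)
  pos <- labels == 1
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision convention: the mean of the precision values
#' at each recall increment, walking the ranking from the highest score
#' down. Tied scores are grouped and contribute their block-level precision.
#'
#' @inheritParams auc_score
#' @return AUPRC in `(0, 1]`.
#' @export
auprc_score <- function(labels, scores) {
  check_two_class(labels, scores)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # group ties: within a tie block precision is evaluated at the block end
  grp <- cumsum(!duplicated(s))
  tp_cum <- cumsum(y)
  n_cum <- seq_along(y)
  block_end <- !duplicated(grp, fromLast = TRUE)
  tp_b <- tp_cum[block_end]
  n_b <- n_cum[block_end]
  prec <- tp_b / n_b
  dtp <- diff(c(0, tp_b))
  sum(prec * dtp) / sum(labels == 1)
}

check_two_class <- function(labels, scores) {
  if (length(labels) != length(scores)) stopf("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  if (length(unique(labels)) < 2) stopf("both classes must be present to score")
}

#' Repeated random-split experiments
#'
#' Re-splits the labeled data `repeats` times (70/15/15 by default),
#' retrains every method on each split, and scores the held-out test set.
#' This absorbs split-sampling variance; the per-method median AUC over
#' repeats is the "mAUC" used for ranking.
#'
#' @param bundles `"feature_bundles"` for one tissue.
#' @param methods Named list of functions `f(bundles, split)` returning test
#'   scores for `split$test` (see [method_base()] and friends).
#' @param repeats Number of repeats (default 10; 2 supported for smoke runs).
#' @param seeds Integer vector of distinct split seeds, length `repeats`.
#' @param fractions Split fractions (default `c(0.70, 0.15, 0.15)`).
#' @param tissue,itype Labels recorded in the result rows.
#' @return A data.frame with columns
#'   `tissue,itype,method,repeat_idx,seed,auc,auprc`.
#' @export
run_experiments <- function(bundles, methods, repeats = 10L,
                            seeds = seq_len(repeats),
                            fractions = c(0.70, 0.15, 0.15),
                            tissue = bundles$meta$tissue[1],
                            itype = bundles$meta$itype[1]) {
  if (length(seeds) != repeats) stopf("`seeds` must have length `repeats`")
  if (anyDuplicated(seeds)) stopf("split seeds must be distinct")
  if (is.null(names(methods)) || any(!nzchar(names(methods)))) {
    stopf("`methods` must be a named list")
  }
  n <- bundles$meta$n
  rows <- list()
  for (r in seq_len(repeats)) {
    split <- split_dataset(n, fractions, seed = seeds[r])
    y_test <- bundles$label[split$test]
    for (m in names(methods)) {
      scores <- methods[[m]](bundles, split)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tissue, itype = itype, method = m, repeat_idx = r,
        seed = seeds[r], auc = auc_score(y_test, scores),
        auprc = auprc_score(y_test, scores), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Method adaptors for [run_experiments()]
#'
#' Each returns a closure `f(bundles, split)` producing test-set scores:
#' `method_base` trains the base model; `method_transfer` and
#' `method_multitask` additionally consume a pretrained shared network.
#'
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param shared A `"trained_network"` from [pretrain_shared()].
#' @return A function `f(bundles, split)`.
#' @export
method_base <- function(model_cfg, train_cfg = train_config()) {
  function(bundles, split) {
    fit <- train_base(bundles, split, model_cfg, train_cfg)
    predict(fit$model, subset_bundles(bundles, split$test))
  }
}

#' @rdname method_base
#' @export
method_transfer <- function(shared, model_cfg, train_cfg = train_config()) {
  function(bundles, split) {
    fit <- train_transfer(bundles, split, shared, model_cfg, train_cfg)
    predict(fit$model, subset_bundles(bundles, split$test))
  }
}

#' @rdname method_base
#' @export
method_multitask <- function(shared, model_cfg, train_cfg = train_config()) {
  function(bundles, split) {
    fit <- train_multitask(bundles, split, shared, model_cfg, train_cfg)
    predict(fit$model, subset_bundles(bundles, split$test))
  }
}

#' Rank methods per tissue by median AUC
#'
#' For each tissue, computes the median AUC over repeats ("mAUC") per
#' method and ranks methods descending (rank 1 = best); ties receive
#' average ranks. Also tabulates how often each method attains each rank.
#'
#' @param results Data.frame from [run_experiments()] (possibly several
#'   tissues row-bound together).
#' @return A list of class `"rank_summary"`: `mauc` (tissue x method),
#'   `ranks` (tissue x method) and `rank_counts` (method x rank position).
#' @export
rank_methods <- function(results) {
  if (length(unique(results$method)) < 2) stopf("need at least 2 methods to rank")
  tab <- table(results$tissue, results$method)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stopf("missing result cell(s): %s",
          paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
                sep = "/", collapse = ", "))
  }
  agg <- stats::aggregate(auc ~ tissue + method, data = results, FUN = median)
  mauc <- stats::xtabs(auc ~ tissue + method, data = agg)
  ranks <- t(apply(mauc, 1, function(v) rank(-v, ties.method = "average")))
  m <- ncol(mauc)
  counts <- sapply(seq_len(m), function(pos) colSums(ranks == pos))
  counts <- matrix(counts, nrow = m,
                   dimnames = list(colnames(mauc), paste0("rank", seq_len(m))))
  structure(list(mauc = mauc, ranks = ranks, rank_counts = counts),
            class = "rank_summary")
}

#' Compare two methods' per-tissue mAUC vectors
#'
#' Two-sided Wilcoxon rank-sum test on the two methods' per-tissue median
#' AUCs: exact when both groups are small (n <= 10) and tie-free, otherwise
#' the tie-corrected normal approximation.
#'
#' @param mauc_by_tissue Matrix of mAUC values (tissues x methods), e.g.
#'   `rank_methods(results)$mauc`.
#' @param m1,m2 Method (column) names to compare.
#' @return The two-sided p-value.
#' @export
compare_methods <- function(mauc_by_tissue, m1, m2) {
  x <- mauc_by_tissue[, m1]
  y <- mauc_by_tissue[, m2]
  if (length(x) != length(y)) stopf("per-tissue vectors differ in length")
  if (length(x) < 3) stopf("need at least 3 tissues per group")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 10 && length(y) <= 10
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact)$p.value
  )
}

#' Cross-prediction: score a model trained on one interaction type on the
#' other
#'
#' Evaluates a trained model on a dataset of a different interaction type
#' (PE-to-PP or PP-to-PE) without any weight update; labels are taken from
#' the evaluated dataset.
#'
#' @param model A trained `"phic_model"` (or `"trained_network"`).
#' @param bundles `"feature_bundles"` of the other interaction type, with
#'   the same feature configuration.
#' @param tissue,method Labels recorded in the result row.
#' @return A one-row data.frame with `tissue,itype,method,auc,auprc`.
#' @export
cross_predict <- function(model, bundles, tissue = bundles$meta$tissue[1],
                          method = "cross") {
  m <- if (inherits(model, "trained_network")) model$model else model
  need <- intersect(c("S", "R", "aux"), m$cfg$active)
  if (!all(need %in% names(bundles))) {
    stopf("incompatible feature sets: model needs %s", paste(need, collapse = ","))
  }
  scores <- predict(m, bundles)
  data.frame(tissue = tissue, itype = bundles$meta$itype[1], method = method,
             auc = auc_score(bundles$label, scores),
             auprc = auprc_score(bundles$label, scores),
             stringsAsFactors = FALSE)
}

#' Write experiment results / summaries as tab-separated text
#' @param results Data.frame of results.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
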