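#' Geometric-mean signature scores
#'
#' Scores every sample of a dataset with a signature: the score is the
#' geometric mean of the sample's linear-scale expression over the
#' signature genes present in the dataset,
#' \eqn{(\prod_g \max(x_g, \mathrm{floor}))^{1/k}}. Genes absent from the
#' dataset reduce \eqn{k} rather than invalidating the score (with a
#' minimum-coverage guard), and values below `floor` (default 1 linear
#' unit) are floored so zeros cannot annihilate the product. Gene symbols
#' are matched case-insensitively.
#'
#' @param dataset An [expression_dataset()] (gene-level).
#' @param signature A [gene_signature()].
#' @param floor Lower clamp on expression values before the product.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present in the dataset (default 0.5); below it, an error.
#' @return Data frame with columns `sample_id`, `study_id`, `subset`,
#'   `disease` (when annotated) and `score`; attributes `"signature"`,
#'   `"coverage"` and `"all_at_floor"` (TRUE when every used value was
#'   clamped, a sign the signature does not apply to the data).
#' @export
score_samples <- function(dataset, signature, floor = 1,
                          min_coverage = 0.5) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(signature, "Signature"))
  hit <- match(toupper(signature$genes), toupper(rownames(dataset$values)))
  present <- which(!is.na(hit))
  coverage <- length(present) / length(signature$genes)
  if (!length(present))
    stop("no signature gene is present in the dataset")
  if (coverage < min_coverage)
    stop(sprintf("signature coverage %.2f below min_coverage %.2f",
                 coverage, min_coverage))
  x <- dataset$values[hit[present], , drop = FALSE]
  clamped <- pmax(x, floor)
  score <- 2^colMeans(log2(clamped), na.rm = TRUE)
  ann <- dataset$annotations
  out <- data.frame(sample_id = ann$sample_id,
                    study_id = dataset$study_id,
                    stringsAsFactors = FALSE)
  for (col in c("subset", "disease"))
    if (col %in% names(ann)) out[[col]] <- ann[[col]]
  out$score <- as.numeric(score[ann$sample_id])
  attr(out, "signature") <- signature$name
  attr(out, "coverage") <- coverage
  attr(out, "all_at_floor") <- all(x <= floor, na.rm = TRUE)
  out
}

#' AUROC with DeLong confidence interval
#'
#' Area under the ROC curve of a score against a binary label: the
#' probability that a random positive outscores a random negative, ties
#' counted one half (the normalized Mann-Whitney U statistic). The 95%
#' confidence interval is DeLong's, via the pROC package.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (logical, 0/1, or factor relative to
#'   `positive`); both classes must be present.
#' @param positive Value of `labels` defining the positive class
#'   (default `1`/`TRUE`).
#' @return List of class `RocResult`: `auroc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`.
#' @export
auroc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  if (is.null(positive))
    positive <- if (is.logical(labels)) TRUE else 1
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present to compute an AUROC")
  r <- pROC::roc(response = as.integer(pos), predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  structure(list(auroc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3],
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("AUROC = %.3f (95%% CI %.3f-%.3f; %d pos, %d neg)\n",
              x$auroc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare signature scores between two groups
#'
#' Two-sided Welch t-test or Wilcoxon test (rank-sum unpaired,
#' signed-rank paired) of scores between two groups.
#'
#' @param scores Numeric vector.
#' @param groups Binary group labels, same length as `scores`.
#' @param test `"t"` (Welch) or `"wilcoxon"`.
#' @param paired If `TRUE`, observations are matched by position within
#'   group (e.g. pre/post treatment) and a paired test is used.
#' @return List with `statistic`, `p`, `method`.
#' @export
compare_groups <- function(scores, groups, test = c("t", "wilcoxon"),
                           paired = FALSE) {
  test <- match.arg(test)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("groups must have exactly two levels")
  x <- scores[groups == lv[1]]
  y <- scores[groups == lv[2]]
  if (paired && length(x) != length(y))
    stop("paired comparison needs equal group sizes")
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs >= 2 observations")
  res <- if (test == "t") {
    stats::t.test(x, y, paired = paired, var.equal = FALSE)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, paired = paired, exact = FALSE))
  }
  list(statistic = unname(res$statistic), p = res$p.value,
       method = res$method)
}

#' Correlate signature scores with measured cell fractions
#'
#' Pearson correlation (two-sided t-distribution p-value) between
#' per-sample scores and cytometry-measured subset fractions.
#'
#' @param scores Numeric vector.
#' @param fractions Numeric vector in `[0, 1]`, same length (>= 3).
#' @return List with `r` and `p`.
#' @export
correlate_with_fractions <- function(scores, fractions) {
  if (length(scores) != length(fractions)) stop("length mismatch")
  if (length(scores) < 3L) stop("need >= 3 paired observations")
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  if (stats::sd(scores) == 0 || stats::sd(fractions) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(scores, fractions, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Check the transitional ordering of a subset's scores
#'
#' Tests whether the middle subset's mean score lies strictly between the
#' mean scores of the two flanking subsets — the expected pattern when
#' the middle subset is a transitional state between the other two.
#'
#' @param score_table Data frame with columns `subset` and `score` (as
#'   from [score_samples()]).
#' @param subsets Character vector of three subset labels, the middle one
#'   being the putative transitional state.
#' @return List with `ok` (logical) and `means` (named, in `subsets`
#'   order).
#' @export
ordering_check <- function(score_table,
                           subsets = c("classical", "intermediate",
                                       "nonclassical")) {
  if (length(subsets) != 3L) stop("exactly three subset labels required")
  missing <- setdiff(subsets, score_table$subset)
  if (length(missing))
    stop("subset(s) absent from score table: ",
         paste(missing, collapse = ", "))
  means <- vapply(subsets, function(s)
    mean(score_table$score[score_table$subset == s]), numeric(1))
  lo <- min(means[1], means[3]); hi <- max(means[1], means[3])
  list(ok = means[2] > lo && means[2] < hi, means = means)
}
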