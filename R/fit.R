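#' Fit a multicohort subset-signature model
#'
#' The package's central estimator: given a list of gene-level expression
#' datasets from independent studies, it (optionally) co-normalizes them,
#' runs the per-gene Hedges' g / DerSimonian-Laird random-effects
#' meta-analysis against the chosen cell subset, and applies the
#' four-rule parsimonious selector to produce the subset's signature.
#' The returned object supports `print`, `summary`, `coef` (pooled
#' effect sizes), `plot` (forest plot of the signature genes) and
#' `predict` (geometric-mean scores for new samples).
#'
#' @param datasets List of gene-level [expression_dataset()] objects
#'   (quantile-normalized and probe-summarized upstream as needed).
#' @param subset Cell-subset label whose signature is sought.
#' @param criteria A [selection_criteria()].
#' @param min_studies Minimum contributing studies per gene (see
#'   [run_meta()]).
#' @param conormalize If `TRUE` (default) datasets are co-normalized with
#'   [conormalize()] before the meta-analysis.
#' @return Object of class `meta_signature` with elements `meta` (the
#'   per-gene [run_meta()] table), `signature` (a [gene_signature()]),
#'   `subset`, `criteria`, `n_datasets`, `call`.
#' @seealso [run_meta()], [select_signature()], [score_samples()]
#' @examples
#' sim <- simulate_sorted_studies(simulation_config(n_studies = 4,
#'   n_genes = 200, seed = 42))
#' fit <- meta_signature(sim$datasets, "classical")
#' fit
#' head(coef(fit))
#' @export
meta_signature <- function(datasets, subset,
                           criteria = selection_criteria(),
                           min_studies = 1L, conormalize = TRUE) {
  cl <- match.call()
  if (conormalize && length(datasets) >= 2L)
    datasets <- monosig::conormalize(datasets)
  meta <- run_meta(datasets, subset, min_studies = min_studies)
  sig <- select_signature(meta, criteria, subset)
  structure(list(meta = meta, signature = sig, subset = subset,
                 criteria = criteria, n_datasets = length(datasets),
                 call = cl),
            class = "meta_signature")
}

#' @export
print.meta_signature <- function(x, ...) {
  cat("Multicohort subset-signature model\n")
  cat(sprintf("  subset: %s  (%d studies, %d genes meta-analyzed)\n",
              x$subset, x$n_datasets, nrow(x$meta)))
  n_sig <- sum(x$meta$fdr <= x$criteria$fdr_max & x$meta$pooled_g > 0)
  cat(sprintf("  significantly over-expressed (FDR <= %.2g): %d genes\n",
              x$criteria$fdr_max, n_sig))
  print(x$signature)
  if (isTRUE(attr(x$signature, "shortfall")))
    cat("  note: fewer survivors than requested top_k\n")
  invisible(x)
}

#' @export
summary.meta_signature <- function(object, ...) {
  sig_rows <- object$meta[object$meta$gene %in% object$signature$genes, ,
                          drop = FALSE]
  out <- list(subset = object$subset, n_datasets = object$n_datasets,
              n_genes = nrow(object$meta),
              n_significant = sum(object$meta$fdr <= object$criteria$fdr_max &
                                    object$meta$pooled_g > 0),
              criteria = object$criteria, signature_table = sig_rows)
  class(out) <- "summary.meta_signature"
  out
}

#' @export
print.summary.meta_signature <- function(x, ...) {
  cat(sprintf("Subset '%s': %d genes across %d studies; %d significant\n",
              x$subset, x$n_genes, x$n_datasets, x$n_significant))
  cat("Signature genes (pooled effects):\n")
  print(x$signature_table[, c("gene", "pooled_g", "se", "tau2",
                              "n_studies", "fdr",
                              "pooled_mean_diff_linear")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.meta_signature <- function(object, ...) {
  stats::setNames(object$meta$pooled_g, object$meta$gene)
}

#' Score new samples with a fitted signature
#'
#' @param object A [meta_signature()] fit.
#' @param newdata An [expression_dataset()] or a list of them.
#' @param ... Passed to [score_samples()] (`floor`, `min_coverage`).
#' @return A score table (rows bound across datasets).
#' @export
predict.meta_signature <- function(object, newdata, ...) {
  if (inherits(newdata, "ExpressionDataset")) newdata <- list(newdata)
  do.call(rbind, lapply(newdata, score_samples,
                        signature = object$signature, ...))
}

#' Forest plot of the signature genes
#'
#' Pooled Hedges' g of each signature gene with a 95% normal interval,
#' largest effects on top.
#'
#' @param x A [meta_signature()] fit.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.meta_signature <- function(x, ...) {
  tab <- x$meta[x$meta$gene %in% x$signature$genes, , drop = FALSE]
  tab <- tab[order(tab$pooled_g), , drop = FALSE]
  n <- nrow(tab)
  lo <- tab$pooled_g - 1.96 * tab$se
  hi <- tab$pooled_g + 1.96 * tab$se
  graphics::plot(tab$pooled_g, seq_len(n), xlim = range(0, lo, hi),
                 yaxt = "n", ylab = "", pch = 19,
                 xlab = "pooled Hedges' g (95% CI)",
                 main = sprintf("%s signature", x$subset), ...)
  graphics::segments(lo, seq_len(n), hi, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = tab$gene, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}
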