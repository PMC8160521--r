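#' Quantile-normalize one dataset
#'
#' Forces every sample (column) of a dataset onto the common empirical
#' distribution given by the per-rank mean of sorted values across
#' samples; within-sample ranks are preserved, and samples with missing
#' values are mapped by interpolation at their own quantile grid. The
#' computation is delegated to `limma::normalizeQuantiles` (ties averaged)
#' and applied on the linear scale on which values are stored.
#'
#' @param dataset An [expression_dataset()] with at least 2 samples.
#' @return The dataset with normalized values.
#' @export
quantile_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (ncol(dataset$values) < 2L)
    stop("quantile normalization needs >= 2 samples (reference undefined)")
  v <- limma::normalizeQuantiles(dataset$values, ties = TRUE)
  dimnames(v) <- dimnames(dataset$values)
  dataset$values <- v
  dataset
}

#' Summarize probe-level values to gene level
#'
#' Each gene's expression in a sample is the arithmetic mean of its
#' mapped probes' values (missing probe values excluded pairwise); a
#' probe annotated to several genes contributes to each of them.
#' Unmapped probes are dropped and counted in the report attribute.
#'
#' @param dataset Probe-level [expression_dataset()].
#' @param map Probe map data frame (`probe_id`, `gene_symbol`), as from
#'   [read_probe_map()].
#' @return Gene-level [expression_dataset()] with unique gene symbols as
#'   features and attribute `"report"` (probes mapped/dropped, genes out).
#' @export
summarize_probes <- function(dataset, map) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  map <- map[map$probe_id %in% rownames(dataset$values), , drop = FALSE]
  if (!nrow(map)) stop("no probe maps to any gene")
  n_unmapped <- sum(!rownames(dataset$values) %in% map$probe_id)
  x <- dataset$values[map$probe_id, , drop = FALSE]
  num <- rowsum(ifelse(is.na(x), 0, x), map$gene_symbol)
  den <- rowsum((!is.na(x)) * 1, map$gene_symbol)
  g <- num / den
  g[den == 0] <- NA_real_
  dataset$values <- g
  attr(dataset, "report") <- list(
    n_probes_mapped = length(unique(map$probe_id)),
    n_probes_dropped = n_unmapped,
    n_genes_out = nrow(g))
  dataset
}

#' Co-normalize gene-level datasets across studies
#'
#' Removes study-level location differences so expression is comparable
#' across cohorts: for every gene, each study's log2 values are shifted by
#' a constant so that the study's per-gene mean over its sorted-subset
#' samples (samples labelled `"mixed"` are excluded from the reference but
#' shifted along) equals the unweighted cross-study mean of those study
#' means. Being a per-study location shift on the log2 scale, the
#' transform leaves every within-study contrast — and hence every
#' within-study standardized effect size — exactly unchanged. A gene
#' measured in no study is dropped with a warning.
#'
#' @param datasets List of gene-level [expression_dataset()] objects,
#'   already aligned with [align_genes()] in `"union"` mode (they are
#'   aligned on the fly if their rownames differ).
#' @return List of co-normalized datasets; attribute `"report"` holds the
#'   per-study, per-gene log2 offsets applied.
#' @export
conormalize <- function(datasets) {
  if (length(datasets) < 2L) stop("co-normalization needs >= 2 datasets")
  same_space <- all(vapply(datasets, function(d)
    identical(rownames(d$values), rownames(datasets[[1]]$values)),
    logical(1)))
  if (!same_space) datasets <- align_genes(datasets, mode = "union")
  eps <- 2^-20  # guard for exact zeros before log2
  study_means <- vapply(datasets, function(d) {
    ref <- d$annotations$subset != "mixed"
    rowMeans(log2(pmax(d$values[, ref, drop = FALSE], eps)), na.rm = TRUE)
  }, numeric(nrow(datasets[[1]]$values)))
  study_means[is.nan(study_means)] <- NA_real_
  global <- rowMeans(study_means, na.rm = TRUE)
  dead <- !is.finite(global)
  if (any(dead)) {
    warning(sum(dead), " gene(s) measured in no study were excluded")
    global[dead] <- NA_real_
  }
  offsets <- global - study_means
  out <- lapply(seq_along(datasets), function(j) {
    d <- datasets[[j]]
    off <- offsets[, j]
    off[!is.finite(off)] <- 0
    d$values <- d$values * 2^off
    if (any(dead)) d$values[dead, ] <- NA_real_
    d
  })
  attr(out, "report") <- list(offsets_log2 = offsets)
  out
}
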