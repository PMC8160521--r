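#' Construct an expression dataset
#'
#' An `ExpressionDataset` bundles one study's expression matrix
#' (features x samples, linear-scale intensities) with its per-sample
#' annotations. It is the unit of input to normalization, meta-analysis
#' and scoring.
#'
#' @param values Numeric matrix, features in rows (rownames = probe or gene
#'   identifiers), samples in columns (colnames = sample ids). Values are
#'   linear-scale expression intensities; `NA` marks a missing measurement.
#' @param annotations Data frame with one row per sample. Must contain a
#'   `sample_id` column matching `colnames(values)` and a `subset` column
#'   holding the sorted cell-subset label (or the literal label `"mixed"`
#'   for mixed-cell samples). Optional columns: `study_id`, `platform_id`,
#'   `disease`, and anything else the caller wants to carry along.
#' @param study_id,platform_id Scalar identifiers for the study and the
#'   profiling platform. Default to the corresponding annotation columns
#'   when present.
#' @param log2_input If `TRUE`, `values` are interpreted as log2-scale and
#'   anti-logged on construction so the stored matrix is always linear.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `study_id`, `platform_id`, `values` and `annotations` (columns
#'   reordered to match the annotation order).
#' @export
expression_dataset <- function(values, annotations, study_id = NULL,
                               platform_id = NULL, log2_input = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(annotations))
    stop("annotations must contain a `sample_id` column")
  if (!"subset" %in% names(annotations))
    stop("annotations must contain a `subset` column")
  if (anyDuplicated(annotations$sample_id))
    stop("duplicate sample ids in annotations: ",
         paste(unique(annotations$sample_id[duplicated(annotations$sample_id)]),
               collapse = ", "))
  missing_ann <- setdiff(colnames(values), annotations$sample_id)
  if (length(missing_ann))
    stop("samples missing from annotations: ",
         paste(missing_ann, collapse = ", "))
  extra_ann <- setdiff(annotations$sample_id, colnames(values))
  if (length(extra_ann))
    stop("annotated samples absent from matrix: ",
         paste(extra_ann, collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (nrow(values) < 1L) stop("matrix must have at least 1 feature")
  if (ncol(values) < 2L) stop("matrix must have at least 2 samples")
  if (any(is.infinite(values)))
    stop("matrix contains non-finite values")
  if (is.null(study_id))
    study_id <- if ("study_id" %in% names(annotations))
      as.character(annotations$study_id[1L]) else "study"
  if (is.null(platform_id))
    platform_id <- if ("platform_id" %in% names(annotations))
      as.character(annotations$platform_id[1L]) else "platform"
  if (log2_input) values <- 2^values
  if (any(values < 0, na.rm = TRUE))
    stop("linear-scale expression values must be non-negative")
  # column order follows the annotation table
  values <- values[, annotations$sample_id, drop = FALSE]
  structure(
    list(study_id = as.character(study_id),
         platform_id = as.character(platform_id),
         values = values,
         annotations = annotations),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", x$study_id,
      sprintf("(platform %s)\n", x$platform_id))
  cat("  ", nrow(x$values), "features x", ncol(x$values), "samples\n")
  tab <- table(x$annotations$subset)
  cat("  subsets:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Restrict datasets to a common gene space
#'
#' Aligns the feature spaces of several gene-level datasets so they can be
#' co-normalized and meta-analyzed. Gene symbols are matched
#' case-insensitively; the first-seen spelling is kept. In `"union"` mode a
#' gene absent from a study is carried as a row of `NA` (missing, never
#' imputed; that study simply contributes no effect size for the gene). In
#' `"intersection"` mode only genes measured in every study are retained.
#'
#' @param datasets List of [expression_dataset()] objects with gene-level
#'   features.
#' @param mode `"union"` (default) or `"intersection"`.
#' @return List of aligned datasets, all sharing the same rownames. The
#'   attribute `"coverage"` holds a named integer vector giving, for each
#'   gene, the number of studies in which it is measured.
#' @export
align_genes <- function(datasets, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!length(datasets)) stop("need at least one dataset")
  keys <- lapply(datasets, function(d) toupper(rownames(d$values)))
  # first-seen case-preserved spelling per upper-cased key
  all_keys <- unlist(keys, use.names = FALSE)
  all_names <- unlist(lapply(datasets, function(d) rownames(d$values)),
                      use.names = FALSE)
  display <- all_names[!duplicated(all_keys)]
  names(display) <- all_keys[!duplicated(all_keys)]
  coverage <- table(unlist(lapply(keys, unique)))
  coverage <- structure(as.integer(coverage), names = names(coverage))
  if (mode == "intersection") {
    shared <- Reduce(intersect, keys)
    if (!length(shared))
      stop("no genes are shared by all datasets in intersection mode")
    target <- shared
  } else {
    target <- names(coverage)
  }
  out <- lapply(datasets, function(d) {
    key <- toupper(rownames(d$values))
    idx <- match(target, key)
    v <- d$values[idx, , drop = FALSE]
    rownames(v) <- unname(display[target])
    d$values <- v
    d
  })
  names(coverage) <- unname(display[names(coverage)])
  attr(out, "coverage") <- coverage[rownames(out[[1]]$values)]
  out
}
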