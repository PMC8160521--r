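#' Read an expression matrix and its sample annotations
#'
#' Expression matrices are tab-separated: first column feature id, header
#' row = sample ids. Annotations are tab-separated with at least
#' `sample_id` and `subset` columns (conventionally also `study_id`,
#' `platform_id`, `disease`). Cells that are empty or `"NA"` are stored as
#' missing; any other non-numeric cell is a parse error reported with its
#' coordinates. Rows whose field count differs from the header are
#' rejected rather than padded.
#'
#' @param matrix_path,annotation_path Paths to the two TSV files.
#' @param log2_input If `TRUE` the matrix is anti-logged on load (stored
#'   values are always linear scale).
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(matrix_path, annotation_path,
                                    log2_input = FALSE) {
  .check_rectangular(matrix_path)
  .check_rectangular(annotation_path)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column")
  feats <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                dimnames = dimnames(cells)))
  # read.delim has already turned "NA" into NA; empty cells stay ""
  missing_cell <- is.na(cells) | cells %in% c("", "na", "NaN")
  bad <- which(is.na(num) & !missing_cell, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d (feature '%s'), column '%s': '%s'",
                 bad[1, 1], feats[bad[1, 1]], colnames(cells)[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]))
  rownames(num) <- feats
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(colnames(num), ann$sample_id)
  if (length(missing))
    stop("annotation is missing sample ids: ", paste(missing, collapse = ", "))
  expression_dataset(num, ann[match(colnames(num), ann$sample_id), ,
                              drop = FALSE],
                     log2_input = log2_input)
}

.check_rectangular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L)
    stop("ragged/truncated TSV (unequal field counts): ", path)
  invisible(TRUE)
}

#' Write an expression dataset to TSV
#'
#' Inverse of [read_expression_dataset()]: writes the linear-scale matrix
#' (first column `feature_id`) and the annotation table as UTF-8,
#' LF-terminated TSV.
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,annotation_path Output paths.
#' @export
write_expression_dataset <- function(dataset, matrix_path, annotation_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  df <- data.frame(feature_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, annotation_path))
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene_symbol`); a probe mapping to several
#' genes appears once per gene. Empty gene symbols are rejected.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `probe_id` and `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  .check_rectangular(path)
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(pm)))
    stop("probe map must have columns probe_id, gene_symbol")
  if (any(!nzchar(pm$gene_symbol)) || anyNA(pm$gene_symbol))
    stop("probe map contains empty gene symbols")
  pm
}

#' Construct a gene signature
#'
#' A signature is a named, ordered list of gene symbols over-expressed in
#' one cell subset (direction is always "up": selection keeps only genes
#' elevated in the subset of interest).
#'
#' @param name Signature name.
#' @param subset Cell-subset label the signature targets.
#' @param genes Character vector of unique gene symbols.
#' @param aliases Optional named character vector mapping a printed symbol
#'   to a corrected/current alias.
#' @return An object of class `Signature`.
#' @export
gene_signature <- function(name, subset, genes, aliases = NULL) {
  genes <- as.character(genes)
  if (!length(genes)) stop("signature genes must be non-empty")
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  if (any(grepl("[\t\n]", genes)))
    stop("gene symbols may not contain tabs or newlines")
  structure(list(name = as.character(name), subset = as.character(subset),
                 genes = genes, direction = "up", aliases = aliases),
            class = "Signature")
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature '%s' (%s, %d genes, up):\n  %s\n",
              x$name, x$subset, length(x$genes),
              paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Write signatures in GMT format
#'
#' One tab-separated line per signature: name, description (the subset
#' label), then the gene symbols. GMT is the interchange format consumed
#' by gene-set enrichment tools.
#'
#' @param signatures Non-empty list of [gene_signature()] objects.
#' @param path Output path.
#' @export
write_signature_gmt <- function(signatures, path) {
  if (inherits(signatures, "Signature")) signatures <- list(signatures)
  if (!length(signatures)) stop("empty signature list")
  lines <- vapply(signatures, function(s) {
    stopifnot(inherits(s, "Signature"))
    if (any(grepl("\t", c(s$name, s$subset, s$genes))))
      stop("GMT fields may not contain tab characters")
    paste(c(s$name, s$subset, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read signatures from a GMT file
#'
#' @param path Path to a GMT file (name, description, genes per line). The
#'   description field is taken as the subset label.
#' @return List of [gene_signature()] objects.
#' @export
read_signature_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line has fewer than 3 fields: ", f[1])
    gene_signature(f[1], f[2], f[-(1:2)])
  })
}

#' Write or read signatures as JSON
#'
#' JSON carries the alias table that GMT cannot.
#' @param signatures List of [gene_signature()] objects.
#' @param path File path.
#' @export
write_signature_json <- function(signatures, path) {
  if (inherits(signatures, "Signature")) signatures <- list(signatures)
  if (!length(signatures)) stop("empty signature list")
  payload <- lapply(signatures, function(s)
    list(name = s$name, subset = s$subset, genes = s$genes,
         direction = s$direction,
         aliases = if (is.null(s$aliases)) NULL else as.list(s$aliases)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(s) {
    al <- if (is.null(s$aliases)) NULL else unlist(s$aliases)
    gene_signature(s$name, s$subset, unlist(s$genes), aliases = al)
  })
}

#' Write or read a score table
#'
#' @param scores Data frame as returned by [score_samples()].
#' @param path TSV path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  .check_rectangular(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
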