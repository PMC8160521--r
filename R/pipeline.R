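#' Run the signature-discovery pipeline end to end
#'
#' Orchestrates simulate -> normalize -> meta-analysis -> selection ->
#' scoring -> evaluation (-> enrichment when gene sets are supplied) from
#' a single configuration, writing every artifact as TSV/GMT/JSON under
#' `out_dir` and recording a manifest with file checksums and the seeds
#' used. Reruns with an identical configuration write byte-identical
#' manifests. Progress is logged to `stderr`; a stage failure aborts with
#' the stage named, and files of the failed stage are kept with a
#' `.partial` suffix.
#'
#' @param config A named list, or path to a YAML file, with entries:
#'   `out_dir` (required); `stages` (character vector among `"simulate"`,
#'   `"normalize"`, `"meta"`, `"select"`, `"score"`, `"evaluate"`,
#'   `"enrich"`; default all but `"enrich"`); `simulate` (arguments for
#'   [simulation_config()]); `subsets` (labels to discover signatures
#'   for; default classical + nonclassical); `min_studies`; `criteria`
#'   (arguments for [selection_criteria()]); `enrich` (list with `gmt`,
#'   `n_perm`, `seed`).
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "normalize", "meta",
                                 "select", "score", "evaluate")
  subsets <- config$subsets %||% c("classical", "nonclassical")
  crit <- do.call(selection_criteria, as.list(config$criteria))
  min_studies <- config$min_studies %||% 1L

  manifest <- list(stages = as.list(stages), seeds = list(),
                   files = list())
  log_msg <- function(...) message(sprintf("[monosig] %s", sprintf(...)))
  register <- function(paths) {
    for (p in paths)
      manifest$files[[basename(p)]] <<-
        unname(tools::md5sum(p))
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return(invisible(NULL))
    log_msg("stage %s", stage)
    before <- list.files(out_dir, full.names = TRUE)
    tryCatch(fun(), error = function(e) {
      created <- setdiff(list.files(out_dir, full.names = TRUE), before)
      for (p in created) file.rename(p, paste0(p, ".partial"))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  datasets <- NULL
  truth <- NULL

  run_stage("simulate", function() {
    sim_cfg <- do.call(simulation_config, as.list(config$simulate))
    manifest$seeds$simulate <<- sim_cfg$seed
    sim <- simulate_sorted_studies(sim_cfg)
    datasets <<- sim$datasets
    truth <<- sim$truth
    paths <- unlist(lapply(sim$datasets, function(d) {
      mp <- file.path(out_dir, sprintf("%s_matrix.tsv", d$study_id))
      ap <- file.path(out_dir, sprintf("%s_annotation.tsv", d$study_id))
      write_expression_dataset(d, mp, ap)
    }))
    tp <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(marker_genes_by_subset = sim$truth$marker_genes_by_subset,
           planted_effect_size =
             unique(unname(sim$truth$planted_effect_sizes)),
           seed = sim$truth$seed),
      tp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    register(c(paths, tp))
  })

  run_stage("normalize", function() {
    if (is.null(datasets)) stop("no datasets in memory (enable simulate)")
    datasets <<- conormalize(lapply(datasets, quantile_normalize))
  })

  meta_tabs <- list()
  run_stage("meta", function() {
    if (is.null(datasets)) stop("no datasets in memory")
    for (s in subsets) {
      tab <- run_meta(datasets, s, min_studies = min_studies)
      meta_tabs[[s]] <<- tab
      p <- file.path(out_dir, sprintf("meta_%s.tsv", s))
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      register(p)
    }
  })

  signatures <- list()
  run_stage("select", function() {
    if (!length(meta_tabs)) stop("no meta-analysis tables in memory")
    for (s in subsets)
      signatures[[s]] <<- select_signature(meta_tabs[[s]], crit, s)
    gp <- file.path(out_dir, "signatures.gmt")
    jp <- file.path(out_dir, "signatures.json")
    write_signature_gmt(unname(signatures), gp)
    write_signature_json(unname(signatures), jp)
    register(c(gp, jp))
  })

  score_tab <- NULL
  run_stage("score", function() {
    if (!length(signatures)) stop("no signatures in memory")
    tabs <- lapply(names(signatures), function(s) {
      st <- do.call(rbind, lapply(datasets, score_samples,
                                  signature = signatures[[s]]))
      st$signature <- signatures[[s]]$name
      st
    })
    score_tab <<- do.call(rbind, tabs)
    p <- file.path(out_dir, "scores.tsv")
    write_score_table(score_tab, p)
    register(p)
  })

  run_stage("evaluate", function() {
    if (is.null(score_tab)) stop("no scores in memory")
    evals <- lapply(names(signatures), function(s) {
      st <- score_tab[score_tab$signature == signatures[[s]]$name, ]
      roc <- auroc(st$score, st$subset == s, positive = TRUE)
      rec <- if (!is.null(truth))
        length(intersect(signatures[[s]]$genes,
                         truth$marker_genes_by_subset[[s]]))
      else NA_integer_
      list(subset = s, auroc = roc$auroc, ci_low = roc$ci_low,
           ci_high = roc$ci_high, n_pos = roc$n_pos, n_neg = roc$n_neg,
           signature_size = length(signatures[[s]]$genes),
           planted_markers_recovered = rec)
    })
    p <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(evals, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    register(p)
  })

  run_stage("enrich", function() {
    if (!length(meta_tabs)) stop("no meta-analysis tables in memory")
    ecfg <- config$enrich %||% list()
    if (is.null(ecfg$gmt)) stop("enrich stage needs a `gmt` path")
    seed <- ecfg$seed %||% 1L
    manifest$seeds$enrich <<- seed
    for (s in subsets) {
      tab <- meta_tabs[[s]]
      enr <- preranked_gsea(stats::setNames(tab$pooled_g, tab$gene),
                            ecfg$gmt, n_perm = ecfg$n_perm %||% 10000L,
                            seed = seed)
      p <- file.path(out_dir, sprintf("enrichment_%s.tsv", s))
      utils::write.table(enr, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      register(p)
    }
  })

  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  log_msg("done (%d files)", length(manifest$files))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
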