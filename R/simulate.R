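#' Simulation configuration
#'
#' Bundles and validates the parameters of the multi-study generator.
#' Expression is modelled as log2-normal: each gene's per-sample log2
#' value is Gaussian, and matrices are stored on the linear scale, so
#' thresholds phrased in "expression units" (e.g. the 32-unit mean
#' difference filter) act on linear intensities. `baseline_mean` and
#' `baseline_sd` are linear-scale moments; they are moment-matched to the
#' log2-normal, which fixes the within-group log2 standard deviation that
#' planted effects are expressed against.
#'
#' @param n_studies Number of independent studies to simulate.
#' @param samples_per_subset_per_study Sorted samples per subset per study.
#' @param n_genes Number of genes.
#' @param n_markers_per_subset Planted over-expressed markers per subset.
#' @param planted_effect_size Target standardized mean difference (Hedges'
#'   g scale, unitless) of each planted marker: markers are shifted on the
#'   log2 scale by `planted_effect_size` times the within-group log2 sd.
#' @param baseline_mean,baseline_sd Linear-scale mean and sd of baseline
#'   expression.
#' @param batch_sd Standard deviation (log2 units) of the per-study
#'   additive shift applied to every gene of a study. Study-to-study
#'   heterogeneity of public compendia is not something with a canonical
#'   value; 0.5 log2 units (a ~1.4-fold typical study offset) is the
#'   recorded default.
#' @param dropout_fraction Fraction of genes absent from each study
#'   (platform coverage differences), in `[0, 1)`.
#' @param include_intermediate If `TRUE`, each study also carries an
#'   intermediate subset whose log2 mean profile is the
#'   `intermediate_lambda`-weighted mixture of the classical and
#'   nonclassical mean profiles.
#' @param intermediate_lambda Mixing weight in `[0, 1]` (1 = classical).
#' @param seed Integer seed; one global seed feeds a hierarchical
#'   per-study stream so studies are independent yet reproducible.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_studies = 6L,
                              samples_per_subset_per_study = 10L,
                              n_genes = 1000L,
                              n_markers_per_subset = 10L,
                              planted_effect_size = 2.0,
                              baseline_mean = 256,
                              baseline_sd = 128,
                              batch_sd = 0.5,
                              dropout_fraction = 0.1,
                              include_intermediate = FALSE,
                              intermediate_lambda = 0.5,
                              seed = 1L) {
  chk <- function(ok, field, why) if (!ok) stop(sprintf(
    "invalid simulation parameter `%s`: %s", field, why), call. = FALSE)
  chk(is.numeric(n_studies) && n_studies >= 1, "n_studies", "must be >= 1")
  chk(samples_per_subset_per_study >= 2, "samples_per_subset_per_study",
      "must be >= 2")
  chk(n_genes >= 1, "n_genes", "must be >= 1")
  chk(n_markers_per_subset >= 0, "n_markers_per_subset", "must be >= 0")
  n_marker_subsets <- 2L  # markers are planted for classical and nonclassical
  chk(n_markers_per_subset * n_marker_subsets <= n_genes,
      "n_markers_per_subset", "marker sets must fit inside n_genes")
  chk(baseline_mean > 0, "baseline_mean", "must be > 0")
  chk(baseline_sd >= 0, "baseline_sd", "must be >= 0")
  chk(batch_sd >= 0, "batch_sd", "must be >= 0")
  chk(dropout_fraction >= 0 && dropout_fraction < 1, "dropout_fraction",
      "must be in [0, 1)")
  chk(intermediate_lambda >= 0 && intermediate_lambda <= 1,
      "intermediate_lambda", "must be in [0, 1]")
  chk(is.numeric(seed) && length(seed) == 1L, "seed", "must be an integer")
  structure(list(n_studies = as.integer(n_studies),
                 samples_per_subset_per_study =
                   as.integer(samples_per_subset_per_study),
                 n_genes = as.integer(n_genes),
                 n_markers_per_subset = as.integer(n_markers_per_subset),
                 planted_effect_size = planted_effect_size,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 batch_sd = batch_sd, dropout_fraction = dropout_fraction,
                 include_intermediate = isTRUE(include_intermediate),
                 intermediate_lambda = intermediate_lambda,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# log2-scale (mu, sigma) whose lognormal has the requested linear mean/sd
.log2_moments <- function(mean_linear, sd_linear) {
  sln <- sqrt(log1p((sd_linear / mean_linear)^2))
  list(mu = (log(mean_linear) - sln^2 / 2) / log(2), sigma = sln / log(2))
}

# spread of per-gene baseline log2 means around the global baseline; a
# fixed realism constant, not a tuning knob
.GENE_BASELINE_SPREAD <- 0.5

#' Simulate a compendium of sorted-subset studies
#'
#' Generates `n_studies` independent studies, each profiling sorted
#' classical and nonclassical (optionally intermediate) samples, with:
#' planted subset-specific over-expressed markers whose log2-mean shift is
#' `planted_effect_size` within-group standard deviations; a per-study
#' additive log2 batch shift shared by all genes of the study; and a
#' random per-study gene dropout emulating platform coverage. The
#' intermediate subset, when present, is a log2-scale
#' `intermediate_lambda` mixture of the two pure mean profiles (a
#' transitional state, not an independent population).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `datasets` (list of
#'   [expression_dataset()]) and `truth` (class `SimulationTruth`:
#'   `marker_genes_by_subset`, `planted_effect_sizes`, `gene_means_log2`,
#'   `within_sd_log2`, `seed`).
#' @export
simulate_sorted_studies <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simulation_config, as.list(config))
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  mom <- .log2_moments(config$baseline_mean, max(config$baseline_sd, 1e-12))
  gene_mu <- mom$mu + stats::rnorm(config$n_genes, 0, .GENE_BASELINE_SPREAD)
  names(gene_mu) <- genes
  sigma <- mom$sigma
  delta <- config$planted_effect_size * sigma

  subsets <- c("classical", "nonclassical")
  marker_idx <- sample.int(config$n_genes, 2L * config$n_markers_per_subset)
  markers <- list(
    classical = genes[marker_idx[seq_len(config$n_markers_per_subset)]],
    nonclassical = genes[marker_idx[config$n_markers_per_subset +
                                      seq_len(config$n_markers_per_subset)]])
  shift <- matrix(0, config$n_genes, 2L,
                  dimnames = list(genes, subsets))
  shift[markers$classical, "classical"] <- delta
  shift[markers$nonclassical, "nonclassical"] <- delta
  if (config$include_intermediate) {
    lam <- config$intermediate_lambda
    shift <- cbind(shift,
                   intermediate = lam * shift[, "classical"] +
                     (1 - lam) * shift[, "nonclassical"])
    subsets <- c(subsets, "intermediate")
  }

  study_seeds <- sample.int(.Machine$integer.max - 1L, config$n_studies)
  n_drop <- floor(config$dropout_fraction * config$n_genes)
  nss <- config$samples_per_subset_per_study
  datasets <- vector("list", config$n_studies)
  for (j in seq_len(config$n_studies)) {
    set.seed(study_seeds[j])
    sid <- sprintf("SIM%02d", j)
    batch <- stats::rnorm(1L, 0, config$batch_sd)
    keep <- if (n_drop > 0)
      sort(sample.int(config$n_genes, config$n_genes - n_drop))
    else seq_len(config$n_genes)
    per_subset <- lapply(subsets, function(s) {
      m <- gene_mu[keep] + shift[keep, s] + batch +
        stats::rnorm(length(keep) * nss, 0, sigma)
      matrix(m, nrow = length(keep), ncol = nss,
             dimnames = list(genes[keep],
                             sprintf("%s_%s_%02d", sid, s, seq_len(nss))))
    })
    vals <- 2^do.call(cbind, per_subset)
    ann <- data.frame(
      sample_id = colnames(vals),
      study_id = sid,
      platform_id = sprintf("SIMPL%d", (j - 1L) %% 3L + 1L),
      subset = rep(subsets, each = nss),
      disease = "healthy",
      stringsAsFactors = FALSE)
    datasets[[j]] <- expression_dataset(vals, ann)
  }
  planted <- stats::setNames(
    rep(config$planted_effect_size, length(unlist(markers))),
    unlist(markers, use.names = FALSE))
  truth <- structure(list(marker_genes_by_subset = markers,
                          planted_effect_sizes = planted,
                          mixture_fractions = NULL,
                          gene_means_log2 = gene_mu,
                          within_sd_log2 = sigma,
                          seed = config$seed),
                     class = "SimulationTruth")
  list(datasets = datasets, truth = truth)
}

#' Simulate intermediate (transitional) expression profiles
#'
#' Draws samples whose per-gene log2 mean is the convex combination
#' `lambda * log2(classical) + (1 - lambda) * log2(nonclassical)` of two
#' pure-subset mean profiles, plus Gaussian log2 noise — the
#' transitional-state model of the intermediate subset.
#'
#' @param classical_mean_profile,nonclassical_mean_profile Named numeric
#'   vectors of strictly positive linear-scale mean expression, sharing
#'   the same gene index.
#' @param lambda Mixing weight in `[0, 1]` (1 = pure classical).
#' @param n_samples Number of samples to draw.
#' @param noise_sd Per-gene Gaussian noise sd in log2 units.
#' @param seed Integer seed.
#' @return An [expression_dataset()] whose samples carry subset label
#'   `"intermediate"`.
#' @export
simulate_intermediate_profiles <- function(classical_mean_profile,
                                           nonclassical_mean_profile,
                                           lambda, n_samples,
                                           noise_sd = 0.2, seed = 1L) {
  if (is.null(names(classical_mean_profile)) ||
      !identical(names(classical_mean_profile),
                 names(nonclassical_mean_profile)))
    stop("profiles must share an identical gene index")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (any(classical_mean_profile <= 0) || any(nonclassical_mean_profile <= 0))
    stop("mean profiles must be strictly positive")
  set.seed(seed)
  mix <- lambda * log2(classical_mean_profile) +
    (1 - lambda) * log2(nonclassical_mean_profile)
  g <- length(mix)
  vals <- 2^(matrix(mix, g, n_samples) +
               matrix(stats::rnorm(g * n_samples, 0, noise_sd), g, n_samples))
  dimnames(vals) <- list(names(mix),
                         sprintf("INT_%02d", seq_len(n_samples)))
  ann <- data.frame(sample_id = colnames(vals), study_id = "SIMINT",
                    platform_id = "SIMPL1", subset = "intermediate",
                    disease = "healthy", stringsAsFactors = FALSE)
  expression_dataset(vals, ann)
}

#' Simulate mixed-cell (PBMC-like) samples with known fractions
#'
#' Each mixed sample's linear-scale expression is the fraction-weighted
#' convex combination of the pure subset mean profiles, multiplied by
#' log2-normal noise. Fractions are drawn from a Dirichlet distribution
#' (or fixed by the caller) and recorded in the returned truth.
#'
#' @param subset_mean_profiles Named list of positive gene-indexed vectors
#'   (one per subset), all sharing the same gene index.
#' @param n_samples Number of mixed samples.
#' @param dirichlet_alpha Positive numeric vector, one entry per subset.
#' @param noise_sd Multiplicative log2 noise sd.
#' @param seed Integer seed.
#' @param fractions Optional `n_samples` x `n_subsets` matrix of fixed
#'   mixing fractions (rows summing to 1) overriding the Dirichlet draw.
#' @return List with `dataset` (subset label `"mixed"`) and `truth` (class
#'   `SimulationTruth` with the `mixture_fractions` matrix).
#' @export
simulate_mixtures <- function(subset_mean_profiles, n_samples,
                              dirichlet_alpha = NULL, noise_sd = 0.2,
                              seed = 1L, fractions = NULL) {
  k <- length(subset_mean_profiles)
  if (k < 2L) stop("need at least two subset profiles")
  idx <- names(subset_mean_profiles[[1]])
  if (is.null(idx) ||
      !all(vapply(subset_mean_profiles, function(p)
        identical(names(p), idx), logical(1))))
    stop("all profiles must share an identical gene index")
  if (is.null(dirichlet_alpha)) dirichlet_alpha <- rep(1, k)
  if (length(dirichlet_alpha) != k)
    stop(sprintf("dirichlet_alpha has length %d but there are %d subsets",
                 length(dirichlet_alpha), k))
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  set.seed(seed)
  if (is.null(fractions)) {
    gam <- matrix(stats::rgamma(n_samples * k, shape = dirichlet_alpha),
                  nrow = n_samples, byrow = TRUE)
    fractions <- gam / rowSums(gam)
  } else {
    fractions <- as.matrix(fractions)
    if (nrow(fractions) != n_samples || ncol(fractions) != k)
      stop("fractions must be an n_samples x n_subsets matrix")
    if (any(abs(rowSums(fractions) - 1) > 1e-9))
      stop("fraction rows must sum to 1")
  }
  colnames(fractions) <- names(subset_mean_profiles)
  P <- do.call(cbind, subset_mean_profiles)      # genes x subsets
  base <- P %*% t(fractions)                     # genes x samples
  noise <- 2^matrix(stats::rnorm(length(base), 0, noise_sd),
                    nrow(base), ncol(base))
  vals <- base * noise
  dimnames(vals) <- list(idx, sprintf("MIX_%02d", seq_len(n_samples)))
  rownames(fractions) <- colnames(vals)
  ann <- data.frame(sample_id = colnames(vals), study_id = "SIMMIX",
                    platform_id = "SIMPL1", subset = "mixed",
                    disease = "healthy", stringsAsFactors = FALSE)
  truth <- structure(list(marker_genes_by_subset = NULL,
                          planted_effect_sizes = NULL,
                          mixture_fractions = fractions, seed = seed),
                     class = "SimulationTruth")
  list(dataset = expression_dataset(vals, ann), truth = truth)
}
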