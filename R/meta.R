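#' Hedges' g standardized mean difference
#'
#' Computes the small-sample-corrected standardized mean difference
#' between two groups of values and its sampling variance:
#' \deqn{d = (\bar x_1 - \bar x_0) / s_p,\quad
#'       J = 1 - 3 / (4(n_1+n_0) - 9),\quad g = J d,}
#' \deqn{\mathrm{var}(g) = (n_1+n_0)/(n_1 n_0) + g^2 / (2(n_1+n_0)),}
#' with \eqn{s_p} the square root of the df-weighted pooled variance.
#' The function is scale-agnostic: it standardizes whatever values it is
#' given ([run_meta()] passes log2-scale expression).
#'
#' @param case_values,control_values Numeric vectors with at least 2
#'   finite values each.
#' @return List with elements `g`, `var_g`, `n_case`, `n_control`.
#' @export
hedges_g <- function(case_values, control_values) {
  x1 <- case_values[is.finite(case_values)]
  x0 <- control_values[is.finite(control_values)]
  n1 <- length(x1); n0 <- length(x0)
  if (n1 < 2L || n0 < 2L)
    stop("insufficient data: each group needs >= 2 finite values")
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) /
    (n1 + n0 - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation: effect undefined")
  d <- (mean(x1) - mean(x0)) / sqrt(sp2)
  n <- n1 + n0
  J <- 1 - 3 / (4 * n - 9)
  g <- J * d
  list(g = g, var_g = n / (n1 * n0) + g^2 / (2 * n),
       n_case = n1, n_control = n0)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-study effect sizes for one gene under the random-effects
#' model with the DerSimonian-Laird moment estimator of between-study
#' variance: fixed-effect weights \eqn{w_i = 1/v_i} give Cochran's
#' \eqn{Q}; \eqn{\tau^2 = \max(0, (Q - (k-1)) /
#' (\sum w_i - \sum w_i^2/\sum w_i))}; random-effects weights
#' \eqn{w_i^* = 1/(v_i + \tau^2)} give the pooled effect, its standard
#' error \eqn{\sqrt{1/\sum w_i^*}}, and a two-sided normal p-value.
#' With a single study \eqn{\tau^2} is taken as 0 and the study's effect
#' is returned unchanged.
#'
#' @param g Numeric vector of per-study Hedges' g values.
#' @param var_g Matching vector of sampling variances (all > 0).
#' @return List with `pooled_g`, `se`, `tau2`, `q_stat`, `n_studies`,
#'   `z`, `p`.
#' @export
pool_random_effects <- function(g, var_g) {
  if (!length(g)) stop("no study effects to pool")
  if (length(g) != length(var_g)) stop("g and var_g lengths differ")
  if (any(var_g <= 0)) stop("all sampling variances must be > 0")
  w <- 1 / var_g
  sw <- sum(w)
  g_fe <- sum(w * g) / sw
  q <- sum(w * (g - g_fe)^2)
  k <- length(g)
  tau2 <- if (k > 1L) {
    cc <- sw - sum(w^2) / sw
    max(0, (q - (k - 1)) / cc)
  } else 0
  ws <- 1 / (var_g + tau2)
  pooled <- sum(ws * g) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- pooled / se
  list(pooled_g = pooled, se = se, tau2 = tau2, q_stat = q,
       n_studies = k, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a p-value vector (monotone, capped at 1),
#' delegating to `stats::p.adjust(method = "BH")` after validating the
#' input range.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Per-gene group moments of a log2 matrix: means, sds, non-missing counts.
.group_moments <- function(log2_values, cols) {
  x <- log2_values[, cols, drop = FALSE]
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  s2 <- ifelse(n > 1, ss / (n - 1), NA_real_)
  list(n = n, mean = m, var = s2)
}

#' Per-gene multicohort meta-analysis of a cell subset
#'
#' For every gene, computes within each eligible study the Hedges' g
#' between the subset of interest and all other sorted samples (log2
#' scale), then pools across studies with [pool_random_effects()] and
#' applies Benjamini-Hochberg correction across genes. A study
#' contributes a gene only if both groups have >= 2 non-missing values
#' and a positive pooled sd for it; a gene must reach `min_studies`
#' contributing studies to be reported. The linear-scale case-minus-
#' control mean difference is tracked per study and combined with
#' fixed-effect (inverse-variance) weights — it feeds the expression-
#' difference filter of signature selection.
#'
#' @param datasets List of co-normalized gene-level
#'   [expression_dataset()] objects (aligned on the fly if needed).
#' @param subset_of_interest Subset label defining the case group; all
#'   other non-`"mixed"` sorted samples form the control group.
#' @param min_studies Minimum number of contributing studies per gene
#'   (default 1; multicohort discovery typically demands >= 4).
#' @return Data frame (one row per gene) with columns `gene`, `pooled_g`,
#'   `se`, `tau2`, `q_stat`, `n_studies`, `z`, `p`, `fdr`,
#'   `pooled_mean_diff_linear`, sorted by `pooled_g` descending (ties:
#'   smaller FDR, then gene symbol). Attribute `"skipped"` lists genes
#'   excluded for insufficient coverage.
#' @export
run_meta <- function(datasets, subset_of_interest, min_studies = 1L) {
  if (inherits(datasets, "ExpressionDataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("no datasets supplied")
  same_space <- all(vapply(datasets, function(d)
    identical(rownames(d$values), rownames(datasets[[1]]$values)),
    logical(1)))
  if (!same_space) datasets <- align_genes(datasets, mode = "union")
  genes <- rownames(datasets[[1]]$values)
  eps <- 2^-20
  eligible <- 0L
  G <- V <- MD <- matrix(NA_real_, length(genes), length(datasets),
                         dimnames = list(genes, NULL))
  for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    case <- d$annotations$subset == subset_of_interest
    ctrl <- !case & d$annotations$subset != "mixed"
    if (sum(case) < 2L || sum(ctrl) < 2L) next
    eligible <- eligible + 1L
    lv <- log2(pmax(d$values, eps))
    a <- .group_moments(lv, case)
    b <- .group_moments(lv, ctrl)
    ok <- a$n >= 2 & b$n >= 2
    sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
    ok <- ok & !is.na(sp2) & sp2 > 0
    n <- a$n + b$n
    J <- 1 - 3 / (4 * n - 9)
    g <- J * (a$mean - b$mean) / sqrt(sp2)
    v <- n / (a$n * b$n) + g^2 / (2 * n)
    G[ok, j] <- g[ok]
    V[ok, j] <- v[ok]
    lin_case <- rowMeans(d$values[, case, drop = FALSE], na.rm = TRUE)
    lin_ctrl <- rowMeans(d$values[, ctrl, drop = FALSE], na.rm = TRUE)
    MD[ok, j] <- (lin_case - lin_ctrl)[ok]
  }
  if (eligible == 0L)
    stop("no eligible studies (need >= 2 case and >= 2 control samples)")
  k <- rowSums(!is.na(G))
  keep <- k >= max(1L, min_studies)
  skipped <- genes[!keep]
  G <- G[keep, , drop = FALSE]; V <- V[keep, , drop = FALSE]
  MD <- MD[keep, , drop = FALSE]; k <- k[keep]
  if (!nrow(G)) stop("no gene reaches min_studies = ", min_studies)
  W <- 1 / V
  sw <- rowSums(W, na.rm = TRUE)
  g_fe <- rowSums(W * G, na.rm = TRUE) / sw
  q <- rowSums(W * (G - g_fe)^2, na.rm = TRUE)
  cc <- sw - rowSums(W^2, na.rm = TRUE) / sw
  tau2 <- ifelse(k > 1, pmax(0, (q - (k - 1)) / cc), 0)
  WS <- 1 / (V + tau2)
  sws <- rowSums(WS, na.rm = TRUE)
  pooled <- rowSums(WS * G, na.rm = TRUE) / sws
  se <- sqrt(1 / sws)
  z <- pooled / se
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(
    gene = rownames(G),
    pooled_g = pooled, se = se, tau2 = tau2, q_stat = q,
    n_studies = as.integer(k), z = z, p = p,
    fdr = benjamini_hochberg(p),
    pooled_mean_diff_linear = rowSums(W * MD, na.rm = TRUE) / sw,
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(-res$pooled_g, res$fdr, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
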