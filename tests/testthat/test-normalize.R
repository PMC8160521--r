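test_that("quantile normalization matches the hand-worked example", {
  v <- matrix(c(5, 2, 3, 4, 1, 8), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  ann <- data.frame(sample_id = c("A", "B"), subset = "classical")
  qn <- quantile_normalize(expression_dataset(v, ann))
  # sorted row means (1.5, 3.5, 6.5) assigned back by within-sample rank
  expect_equal(unname(qn$values[, "A"]), c(6.5, 1.5, 3.5))
  expect_equal(unname(qn$values[, "B"]), c(3.5, 1.5, 6.5))
})

test_that("quantile normalization is idempotent and a fixed point on
           identical samples", {
  set.seed(1)
  v <- matrix(2^rnorm(200, 8, 1), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  ann <- data.frame(sample_id = colnames(v),
                    subset = rep(c("classical", "nonclassical"), 2))
  ds <- expression_dataset(v, ann)
  once <- quantile_normalize(ds)
  twice <- quantile_normalize(once)
  expect_equal(twice$values, once$values, tolerance = 1e-9)
  # complete samples share the same sorted value vector
  expect_equal(sort(once$values[, 1]), sort(once$values[, 3]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # all-identical samples are left untouched
  same <- expression_dataset(matrix(v[, 1], 50, 3,
                                    dimnames = list(rownames(v),
                                                    paste0("t", 1:3))),
                             data.frame(sample_id = paste0("t", 1:3),
                                        subset = "classical"))
  expect_equal(quantile_normalize(same)$values, same$values)
  one <- expression_dataset(v[, 1:2, drop = FALSE], ann[1:2, ])
  expect_error(quantile_normalize(
    structure(list(values = v[, 1, drop = FALSE],
                   annotations = ann[1, , drop = FALSE]),
              class = "ExpressionDataset")), ">= 2 samples")
})

test_that("probe summarization averages probes, multi-gene probes count
           for every target", {
  v <- matrix(c(10, 30,
                20, 50,
                40, 70), 3, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  ann <- data.frame(sample_id = c("s1", "s2"),
                    subset = c("classical", "nonclassical"))
  ds <- expression_dataset(v, ann)
  # p1 -> GX; p2 -> GX and GY (multi-mapped); p3 -> GY; p4 unmapped
  map <- data.frame(probe_id = c("p1", "p2", "p2", "p3", "p4"),
                    gene_symbol = c("GX", "GX", "GY", "GY", "GZ"))
  out <- summarize_probes(ds, map)
  expect_equal(out$values["GX", "s1"], mean(c(10, 20)))
  expect_equal(out$values["GY", "s1"], mean(c(20, 40)))
  expect_equal(out$values["GX", "s2"], mean(c(30, 50)))
  expect_false(anyDuplicated(rownames(out$values)) > 0)
  # single-probe gene passes through unchanged
  single <- summarize_probes(ds, data.frame(probe_id = "p1",
                                            gene_symbol = "GX"))
  expect_equal(unname(single$values["GX", ]), unname(v["p1", ]))
  expect_error(summarize_probes(ds, data.frame(probe_id = "q9",
                                               gene_symbol = "GQ")),
               "no probe")
})

test_that("co-normalization removes a planted batch shift and preserves
           within-study effect sizes", {
  sim <- simulate_sorted_studies(simulation_config(
    n_studies = 3, n_genes = 80, batch_sd = 0, dropout_fraction = 0,
    seed = 21))
  ds <- sim$datasets
  shifted <- ds
  shifted[[2]]$values <- shifted[[2]]$values * 2  # +1 log2 unit batch

  g_before <- lapply(shifted, function(d) {
    cla <- d$annotations$subset == "classical"
    vapply(seq_len(nrow(d$values)), function(i)
      hedges_g(log2(d$values[i, cla]), log2(d$values[i, !cla]))$g,
      numeric(1))
  })
  co <- conormalize(shifted)
  means <- vapply(co, function(d) rowMeans(log2(d$values)),
                  numeric(nrow(ds[[1]]$values)))
  expect_lt(max(abs(means - rowMeans(means))), 1e-9)

  g_after <- lapply(co, function(d) {
    cla <- d$annotations$subset == "classical"
    vapply(seq_len(nrow(d$values)), function(i)
      hedges_g(log2(d$values[i, cla]), log2(d$values[i, !cla]))$g,
      numeric(1))
  })
  expect_equal(g_after, g_before, tolerance = 1e-9)

  # within-study class contrast on log2 scale is exactly preserved
  cla <- shifted[[2]]$annotations$subset == "classical"
  before_diff <- rowMeans(log2(shifted[[2]]$values[, cla])) -
    rowMeans(log2(shifted[[2]]$values[, !cla]))
  after_diff <- rowMeans(log2(co[[2]]$values[, cla])) -
    rowMeans(log2(co[[2]]$values[, !cla]))
  expect_equal(after_diff, before_diff, tolerance = 1e-12)
})

test_that("co-normalizing identical studies is a no-op", {
  sim <- simulate_sorted_studies(simulation_config(
    n_studies = 1, n_genes = 40, batch_sd = 0, dropout_fraction = 0,
    seed = 33))
  d <- sim$datasets[[1]]
  d2 <- d; d2$study_id <- "S2"
  co <- conormalize(list(d, d2))
  expect_equal(co[[1]]$values, d$values, tolerance = 1e-12)
  expect_equal(co[[2]]$values, d$values, tolerance = 1e-12)
})
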