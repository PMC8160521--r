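mk_score_ds <- function(values, subsets) {
  ann <- data.frame(sample_id = colnames(values), subset = subsets,
                    stringsAsFactors = FALSE)
  expression_dataset(values, ann)
}

test_that("geometric-mean scores reproduce closed forms", {
  v <- matrix(c(4, 16, 100, 100), 2, 2,
              dimnames = list(c("GA", "GB"), c("s1", "s2")))
  ds <- mk_score_ds(v, c("classical", "nonclassical"))
  sig <- gene_signature("sig", "classical", c("GA", "GB"))
  sc <- score_samples(ds, sig)
  expect_equal(sc$score[sc$sample_id == "s1"], sqrt(4 * 16))
  expect_equal(sc$score[sc$sample_id == "s2"], 100)  # constant vector

  # permuting gene order changes nothing
  sig_rev <- gene_signature("sig", "classical", c("GB", "GA"))
  expect_equal(score_samples(ds, sig_rev)$score, sc$score)

  # degree-1 homogeneity: scaling a sample scales its score
  v2 <- v; v2[, "s1"] <- v2[, "s1"] * 3
  sc2 <- score_samples(mk_score_ds(v2, c("classical", "nonclassical")),
                       sig)
  expect_equal(sc2$score[1], 3 * sc$score[1], tolerance = 1e-12)
})

test_that("missing signature genes reduce k, with a coverage guard", {
  v <- matrix(c(4, 9, 16, 25), 2, 2,
              dimnames = list(c("GA", "GB"), c("s1", "s2")))
  ds <- mk_score_ds(v, c("classical", "nonclassical"))
  sig3 <- gene_signature("sig", "classical", c("GA", "GB", "ABSENT", "GONE"))
  sc <- score_samples(ds, sig3, min_coverage = 0.5)
  expect_equal(attr(sc, "coverage"), 0.5)
  expect_equal(sc$score[1], sqrt(4 * 9))
  sig_bad <- gene_signature("sig", "classical",
                            c("GA", "X1", "X2", "X3"))
  expect_error(score_samples(ds, sig_bad), "coverage")
  # floor guards zeros
  v0 <- v; v0["GA", "s1"] <- 0
  sc0 <- score_samples(mk_score_ds(v0, c("classical", "nonclassical")),
                       gene_signature("s", "classical", c("GA", "GB")))
  expect_equal(sc0$score[1], sqrt(1 * 9))
})

test_that("AUROC matches the toy and brute-force pair enumeration", {
  r <- auroc(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(r$auroc, 0.875)
  expect_equal(r$n_pos, 2); expect_equal(r$n_neg, 2)
  expect_true(r$ci_low <= r$auroc && r$auroc <= r$ci_high)

  sep <- auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auroc, 1.0)

  inv <- auroc(c(1, 2, 2, 3), c(1, 1, 0, 0))
  expect_equal(inv$auroc, 1 - 0.875)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    s <- round(rnorm(n), 1)          # rounded to force ties
    lab <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(auroc(s, lab)$auroc, auroc_brute(s, lab == 1),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("group comparisons reproduce hand-computed statistics", {
  w <- compare_groups(c(5, 6, 7, 5, 6, 7), rep(c("a", "b"), each = 3),
                      test = "wilcoxon")
  expect_equal(w$p, 1)

  tt <- compare_groups(c(1, 2, 3, 11, 12, 13),
                       rep(c("a", "b"), each = 3), test = "t")
  expect_equal(abs(tt$statistic), 10 * sqrt(3 / 2), tolerance = 1e-8)
  expect_lt(tt$p, 0.01)

  sw <- compare_groups(c(11, 12, 13, 1, 2, 3),
                       rep(c("a", "b"), each = 3), test = "t")
  expect_equal(sw$statistic, -tt$statistic, tolerance = 1e-12)
  expect_equal(sw$p, tt$p, tolerance = 1e-12)

  expect_error(compare_groups(1:4, c("a", "a", "a", "b")), ">= 2")
  expect_error(compare_groups(1:5, c("a", "a", "a", "b", "b"),
                              paired = TRUE), "equal group sizes")
})

test_that("score-fraction correlation behaves at the extremes", {
  expect_equal(correlate_with_fractions(c(1, 2, 3, 4),
                                        c(0.1, 0.2, 0.3, 0.4))$r, 1)
  expect_equal(correlate_with_fractions(1:5, seq(0.5, 0.1, by = -0.1))$r,
               -1)
  expect_error(correlate_with_fractions(c(1, 1, 1), c(0.1, 0.2, 0.3)),
               "zero variance")
  expect_error(correlate_with_fractions(1:3, c(0.1, 0.2, 1.3)),
               "\\[0, 1\\]")
})

test_that("ordering check detects betweenness and its violation", {
  st <- data.frame(subset = rep(c("classical", "intermediate",
                                  "nonclassical"), each = 2),
                   score = c(10, 10, 6, 6, 2, 2))
  ok <- ordering_check(st)
  expect_true(ok$ok)
  expect_equal(unname(ok$means), c(10, 6, 2))
  st$score[3:4] <- 12
  expect_false(ordering_check(st)$ok)
  expect_error(ordering_check(st[st$subset != "intermediate", ]),
               "absent")
})

test_that("scores of lambda-mixed intermediates fall between the pure
           subsets for both signatures", {
  prof <- pure_profiles(n_genes = 80, n_markers = 10, fold = 8)
  c_sig <- gene_signature("cMSS", "classical", prof$classical_markers)
  n_sig <- gene_signature("ncMSS", "nonclassical",
                          prof$nonclassical_markers)
  pure_c <- simulate_intermediate_profiles(prof$classical,
                                           prof$nonclassical, 1, 10,
                                           noise_sd = 0.05, seed = 1)
  pure_n <- simulate_intermediate_profiles(prof$classical,
                                           prof$nonclassical, 0, 10,
                                           noise_sd = 0.05, seed = 2)
  mid <- simulate_intermediate_profiles(prof$classical, prof$nonclassical,
                                        0.5, 10, noise_sd = 0.05, seed = 3)
  for (sig in list(c_sig, n_sig)) {
    sc <- function(d, lab) {
      t <- score_samples(d, sig); t$subset <- lab; t
    }
    tab <- rbind(sc(pure_c, "classical"), sc(mid, "intermediate"),
                 sc(pure_n, "nonclassical"))
    expect_true(ordering_check(tab)$ok)
  }
})
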