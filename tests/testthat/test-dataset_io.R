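test_that("expression datasets round-trip through TSV", {
  ds <- toy_dataset()
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_expression_dataset(ds, mp, ap)
  back <- read_expression_dataset(mp, ap)
  expect_equal(back$values, ds$values)
  expect_equal(back$annotations, ds$annotations)
  expect_equal(back$study_id, ds$study_id)
})

test_that("dataset validation rejects malformed inputs", {
  v <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  ann <- data.frame(sample_id = paste0("s", 1:3), subset = "classical")
  expect_silent(expression_dataset(v + 0.0, ann))
  expect_error(expression_dataset(v + 0.0, ann[1:2, ]), "s3")
  expect_error(expression_dataset(v + 0.0, rbind(ann, ann[1, ])),
               "duplicate")
  dup <- v; rownames(dup) <- c("g1", "g1")
  expect_error(expression_dataset(dup + 0.0, ann), "duplicate feature")
  expect_error(expression_dataset(-v + 0.0, ann), "non-negative")
  one <- v[, 1, drop = FALSE]
  expect_error(expression_dataset(one + 0.0, ann[1, , drop = FALSE]),
               "2 samples")
})

test_that("reader flags missing annotation rows, bad cells, ragged files", {
  ds <- toy_dataset()
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_expression_dataset(ds, mp, ap)

  ann <- read.delim(ap)
  write.table(ann[-2, ], ap, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_dataset(mp, ap), "s2")

  write_expression_dataset(ds, mp, ap)
  lines <- readLines(mp)
  lines[2] <- sub("12", "twelve", lines[2])
  writeLines(lines, mp)
  expect_error(read_expression_dataset(mp, ap), "non-numeric cell")

  write_expression_dataset(ds, mp, ap)
  lines <- readLines(mp)
  lines[3] <- sub("\t10$", "", lines[3])
  writeLines(lines, mp)
  expect_error(read_expression_dataset(mp, ap), "ragged|truncated")
})

test_that("NA cells load as missing values", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\tNA\t5", "g2\t3\t"), mp)
  writeLines(c("sample_id\tsubset", "s1\tclassical", "s2\tnonclassical"),
             ap)
  ds <- read_expression_dataset(mp, ap)
  expect_true(is.na(ds$values["g1", "s1"]))
  expect_true(is.na(ds$values["g2", "s2"]))
  expect_equal(ds$values["g1", "s2"], 5)
})

test_that("log2 input is anti-logged on load", {
  v <- matrix(c(3, 4, 5, 6), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ann <- data.frame(sample_id = c("s1", "s2"), subset = "classical")
  ds <- expression_dataset(v, ann, log2_input = TRUE)
  expect_equal(unname(ds$values[1, ]), c(8, 32))
})

test_that("GMT serialization is a lossless round trip", {
  sigs <- list(gene_signature("a", "classical", paste0("G", 1:10)),
               gene_signature("b", "nonclassical", paste0("H", 1:10)))
  p <- withr::local_tempfile(fileext = ".gmt")
  write_signature_gmt(sigs, p)
  lines <- readLines(p)
  expect_length(lines, 2)
  expect_length(strsplit(lines[1], "\t")[[1]], 12)
  back <- read_signature_gmt(p)
  expect_equal(lapply(back, `[[`, "genes"), lapply(sigs, `[[`, "genes"))
  expect_equal(vapply(back, `[[`, "", "subset"),
               vapply(sigs, `[[`, "", "subset"))
  expect_error(write_signature_gmt(list(), p), "empty")
  expect_error(gene_signature("x", "classical", "BAD\tGENE"), "tab")
})

test_that("JSON signature round trip preserves aliases", {
  sig <- bundled_signatures()$intermediate
  p <- withr::local_tempfile(fileext = ".json")
  write_signature_json(list(sig), p)
  back <- read_signature_json(p)[[1]]
  expect_equal(back$genes, sig$genes)
  expect_equal(back$aliases, sig$aliases)
})

test_that("gene alignment matches hand enumeration", {
  mk <- function(genes, study) {
    v <- matrix(seq_along(genes) * 1.0, length(genes), 2,
                dimnames = list(genes, paste0(study, c("a", "b"))))
    ann <- data.frame(sample_id = colnames(v), study_id = study,
                      subset = c("classical", "nonclassical"))
    expression_dataset(v, ann)
  }
  d1 <- mk(c("A", "B", "C"), "S1")
  d2 <- mk(c("B", "C", "D"), "S2")

  ali <- align_genes(list(d1, d2), mode = "intersection")
  expect_setequal(rownames(ali[[1]]$values), c("B", "C"))

  alu <- align_genes(list(d1, d2), mode = "union")
  cov <- attr(alu, "coverage")
  expect_equal(cov[c("A", "B", "C", "D")],
               c(A = 1L, B = 2L, C = 2L, D = 1L))
  expect_true(all(is.na(alu[[2]]$values["A", ])))
  expect_true(all(is.na(alu[[1]]$values["D", ])))

  # identical gene sets: both modes are a no-op
  same <- align_genes(list(d1, mk(c("A", "B", "C"), "S3")))
  expect_equal(same[[1]]$values, d1$values)

  d3 <- mk(c("X", "Y"), "S3")
  expect_error(align_genes(list(d1, d3), mode = "intersection"),
               "no genes")
})
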