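test_that("read_beta_matrix parses well-formed files and missing tokens", {
  f <- write_tsv_text(c("probe_id\ts1\ts2",
                        "cg01\t0.10\t0.90",
                        "cg02\tNA\t0.50",
                        "cg03\t0.00\t1.00"))
  m <- read_beta_matrix(f)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("cg01", "cg02", "cg03"))
  expect_identical(sum(is.na(m)), 1L)
  expect_true(is.na(m["cg02", "s1"]))
  expect_equal(m["cg01", "s2"], 0.9)
})

test_that("read_beta_matrix validates range, strictly or by clipping", {
  f <- write_tsv_text(c("probe_id\ts1\ts2",
                        "cg01\t0.2\t1.2"))
  expect_error(read_beta_matrix(f, strict = TRUE), "cg01/s2")
  expect_warning(m <- read_beta_matrix(f, strict = FALSE), "clipped")
  expect_equal(unname(m["cg01", "s2"]), 1)
  expect_identical(attr(m, "n_clipped"), 1L)
})

test_that("matrix readers reject duplicates and empty data", {
  f <- write_tsv_text(c("probe_id\ts1", "cg01\t0.5", "cg01\t0.4"))
  expect_error(read_beta_matrix(f), "duplicate probe id")
  f2 <- write_tsv_text(c("id\ts1\ts1", "cg01\t0.5\t0.4"))
  expect_error(read_beta_matrix(f2), "duplicate sample id")
  f3 <- write_tsv_text("feature_id\ts1")
  expect_error(read_expression_matrix(f3), "no feature")
})

test_that("read_expression_matrix accepts intensities and rejects negatives", {
  f <- write_tsv_text(c("feature_id\ta\tb\tc\td\te\tf",
                        paste("g1", paste(1:6, collapse = "\t"), sep = "\t"),
                        paste("g2", paste(7:12, collapse = "\t"), sep = "\t"),
                        paste("g3", paste(2:7, collapse = "\t"), sep = "\t"),
                        paste("g4", paste(3:8, collapse = "\t"), sep = "\t")))
  m <- read_expression_matrix(f)
  expect_identical(dim(m), c(4L, 6L))
  f2 <- write_tsv_text(c("feature_id\ta\tb", "g1\t5\t-1"))
  expect_error(read_expression_matrix(f2), "negative intensity")
})

test_that("matrix write/read round-trips values exactly", {
  cfg <- small_config(seed = 3)
  d <- generate_methylation_dataset(cfg)
  b <- round(d$beta[1:50, ], 6)               # stated decimal precision
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(b, f)
  b2 <- read_beta_matrix(f)
  expect_equal(b2, b, ignore_attr = TRUE)
  expect_identical(dimnames(b2), dimnames(b))
})

test_that("read_probe_annotation splits aligned fields and flags enhancers", {
  f <- write_tsv_text(c(
    "probe_id\tchromosome\tposition\tgene_symbols\tgene_region\tisland_relation\tenhancer",
    "cg0001\tchr1\t100\tA;A\tTSS200;5UTR\tisland\tTRUE",
    "cg0002\tchr2\t55\t\t\topen_sea\t"))
  ann <- read_probe_annotation(f)
  expect_identical(ann$gene_symbols[[1]], c("A", "A"))
  expect_identical(ann$gene_region[[1]], c("TSS200", "5UTR"))
  expect_true(ann$enhancer[1])
  expect_false(ann$enhancer[2])                # empty cell means FALSE
  expect_identical(ann$gene_symbols[[2]], character(0))
})

test_that("read_probe_annotation rejects misaligned gene fields with row number", {
  f <- write_tsv_text(c(
    "probe_id\tchromosome\tposition\tgene_symbols\tgene_region\tisland_relation\tenhancer",
    "cg0001\tchr1\t100\tA\tTSS200\tisland\tTRUE",
    "cg0002\tchr1\t200\tA;B\tTSS200\tshore\tFALSE"))
  expect_error(read_probe_annotation(f), "row\\(s\\): 2")
})

test_that("probe annotation round-trips through write/read", {
  ann <- toy_annotation()
  f <- tempfile(fileext = ".tsv")
  write_probe_annotation(ann, f)
  ann2 <- read_probe_annotation(f)
  expect_identical(ann2$probe_id, ann$probe_id)
  expect_identical(ann2$gene_symbols, ann$gene_symbols)
  expect_identical(ann2$gene_region, ann$gene_region)
  expect_identical(ann2$enhancer, ann$enhancer)
})

test_that("beta_to_m matches the clipped logit formula", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0, epsilon = 1e-6), log2(1e-6 / (1 - 1e-6)))
  expect_equal(beta_to_m(0, epsilon = 1e-6), -19.93157, tolerance = 1e-6)
  expect_true(is.na(beta_to_m(NA_real_)))
  expect_error(beta_to_m(0.5, epsilon = 0.7), "epsilon")
  expect_error(beta_to_m(0.5, epsilon = 0), "epsilon")
})

test_that("beta_to_m is strictly increasing and antisymmetric about 0.5", {
  b <- seq(0.01, 0.99, by = 0.01)
  m <- beta_to_m(b)
  expect_true(all(diff(m) > 0))
  expect_equal(m, -rev(m))                     # m(b) = -m(1-b)
  expect_equal(m_to_beta(m), b)                # inverse transform
})

test_that("write_signature_outputs honors BED conventions and deduplicates genes", {
  ann <- toy_annotation()
  sig <- structure(list(common_hyper = c("cg01", "cg02"), common_hypo = "cg03",
                        universe = ann$probe_id, pairs = NULL),
                   class = "signature_set")
  out <- tempfile()
  man <- write_signature_outputs(sig, ann, out,
                                 scores = c(cg01 = 0.4, cg02 = 0.3, cg03 = -0.5))
  bed <- read.table(man[["bed"]], sep = "\t", stringsAsFactors = FALSE)
  expect_identical(bed$V2, c(99L, 249L, 49L))  # 1-based 100 -> BED start 99
  expect_true(all(bed$V3 - bed$V2 == 1L))
  expect_identical(bed$V5, c(400L, 300L, 500L))
  # cg01 and cg02 both map to gene A: listed once
  expect_identical(readLines(man[["genes_hyper"]]), "A")
  expect_identical(readLines(man[["genes_hypo"]]), c("A", "B"))
  rep <- jsonlite::read_json(man[["report"]])
  expect_identical(rep$n_common_hyper, 2L)
})

test_that("write_signature_outputs handles empty signatures and unknown probes", {
  ann <- toy_annotation()
  empty <- structure(list(common_hyper = character(0), common_hypo = character(0),
                          universe = ann$probe_id, pairs = NULL),
                     class = "signature_set")
  man <- write_signature_outputs(empty, ann, tempfile())
  expect_identical(length(readLines(man[["bed"]])), 0L)
  expect_identical(length(readLines(man[["genes_hypo"]])), 0L)
  expect_identical(jsonlite::read_json(man[["report"]])$n_common_hypo, 0L)
  bad <- structure(list(common_hyper = "cgXX", common_hypo = character(0),
                        universe = ann$probe_id, pairs = NULL),
                   class = "signature_set")
  expect_error(write_signature_outputs(bad, ann, tempfile()), "cgXX")
})

test_that("sample sheets are validated", {
  f <- write_tsv_text(c("sample_id\ttissue\tphenotype\treplicate",
                        "a1\tbreast\tinvasive\t1",
                        "a2\tbreast\tinvasive\t2",
                        "b1\tbreast\tnon_invasive\t1",
                        "b2\tbreast\tnon_invasive\t2"))
  sheet <- read_sample_sheet(f)
  expect_identical(nrow(sheet), 4L)
  bad <- sheet[-1, ]
  expect_error(validate_sample_sheet(bad), ">= 2 samples")
  sheet$phenotype[1] <- "odd"
  expect_error(validate_sample_sheet(sheet), "phenotype")
})
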