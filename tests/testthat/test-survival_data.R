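test_that("expression files round-trip and normalize orientation", {
  tsv <- write_tiny_expression(withr::local_tempfile(fileext = ".tsv"))
  expr <- read_expression(tsv)
  expect_identical(expr$feature_ids, c("G1", "G2", "G3"))
  expect_identical(expr$sample_ids, c("SA", "SB"))
  expect_equal(expr$values[3, 2], 4.125)

  # write -> read reproduces labels and values
  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, out)
  again <- read_expression(out)
  expect_identical(again$feature_ids, expr$feature_ids)
  expect_identical(again$sample_ids, expr$sample_ids)
  expect_equal(again$values, expr$values)

  # transposed file with samples_in_rows gives the identical matrix
  tr <- withr::local_tempfile(fileext = ".tsv")
  m <- expr$values
  writeLines(c(
    paste(c("sample_id", expr$feature_ids), collapse = "\t"),
    vapply(1:2, function(i) paste(c(expr$sample_ids[i], m[, i]), collapse = "\t"), "")
  ), tr)
  expr_t <- read_expression(tr, orientation = "samples_in_rows")
  expect_identical(expr_t$feature_ids, expr$feature_ids)
  expect_equal(expr_t$values, expr$values)
})

test_that("expression reader enforces its error contracts", {
  bad_cell <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tSA\tSB", "G1\t1\tNA", "G2\t2\t3"), bad_cell)
  expect_error(read_expression(bad_cell), "row 'G1', column 'SB'")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tSA\tSA", "G1\t1\t2"), dup)
  expect_error(read_expression(dup), "duplicate column label.*SA")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_expression(empty), "empty")
})

test_that("assemble_dataset intersects samples in survival order", {
  expr <- structure(list(
    values = matrix(1:6, nrow = 2, dimnames = NULL),
    feature_ids = c("G1", "G2"), sample_ids = c("A", "B", "C")
  ), class = "expression_matrix")
  surv <- data.frame(sample_id = c("C", "B", "D"), time = c(5, 3, 1),
                     event = c(1, 1, 0))
  ds <- assemble_dataset(expr, surv)
  expect_identical(ds$sample_ids, c("C", "B"))
  expect_equal(ds$X["C", "G1"], 5)
  expect_identical(attr(ds, "dropped")$expression_only, "A")
  expect_identical(attr(ds, "dropped")$survival_only, "D")
  expect_lte(ds$n, min(3, nrow(surv)))

  # identical id sets: nothing dropped
  surv2 <- data.frame(sample_id = c("A", "B", "C"), time = 1:3, event = c(1, 1, 0))
  ds2 <- assemble_dataset(expr, surv2)
  expect_equal(ds2$n, 3)
  expect_length(attr(ds2, "dropped")$expression_only, 0)

  # all-censored survival is degenerate
  surv3 <- transform(surv2, event = 0)
  expect_error(assemble_dataset(expr, surv3), "fewer than 2 events")
  expect_error(
    assemble_dataset(expr, data.frame(sample_id = "Z", time = 1, event = 1)),
    "share no sample ids")
})

test_that("iqr_filter keeps the most variable features deterministically", {
  X <- cbind(f1 = c(1, 1, 1, 1), f2 = c(0, 10, 20, 30),
             f3 = c(5, 6, 7, 8), f4 = c(2, 2, 3, 3))
  ds <- survival_dataset(X, time = 1:4, event = c(1, 1, 0, 1))
  kept <- iqr_filter(ds, keep_fraction = 0.5)
  # type-7 IQRs: 0, 15, 1.5, 1 -> top two are f2 and f3
  expect_identical(kept$feature_ids, c("f2", "f3"))
  expect_equal(unname(attr(kept, "iqr")), c(15, 1.5))
  # values and survival fields untouched
  expect_equal(kept$X[, "f2"], ds$X[, "f2"])
  expect_identical(kept$time, ds$time)

  # idempotent at the same setting, identity at keep_fraction = 1
  expect_identical(iqr_filter(kept, keep_fraction = 1)$feature_ids,
                   kept$feature_ids)
  expect_identical(iqr_filter(ds, keep_fraction = 1)$feature_ids,
                   ds$feature_ids)
  # constant feature never survives a selective filter
  expect_false("f1" %in% iqr_filter(ds, keep_fraction = 0.75)$feature_ids)
  # absolute cutoff mode
  expect_identical(iqr_filter(ds, min_iqr = 1.5)$feature_ids, c("f2", "f3"))
})

test_that("GMT parsing honours the format and its error contracts", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tG1\tG2\tG3", "S2\tdesc\tG1\tG1"), gmt)
  sets <- read_gmt(gmt)
  expect_identical(sets$S1$genes, c("G1", "G2", "G3"))
  expect_identical(sets$S2$genes, "G1")   # de-duplicated

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_identical(read_gmt(out)$S1$genes, sets$S1$genes)

  writeLines(c("S1\tdesc\tG1", "S1\tdesc\tG2"), gmt)
  expect_error(read_gmt(gmt), "duplicate gene-set name")
  writeLines(c("S1\tdesc"), gmt)
  expect_error(read_gmt(gmt), "line 1")
})

test_that("survival table reader validates its columns", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,time,event", "A,5,1", "B,3,0"), csv)
  surv <- read_survival(csv)
  expect_identical(surv$sample_id, c("A", "B"))
  writeLines(c("sample_id,time,event", "A,-5,1", "B,3,0"), csv)
  expect_error(read_survival(csv), "positive")
  writeLines(c("sample_id,time,event", "A,5,2"), csv)
  expect_error(read_survival(csv), "0 or 1")
  writeLines(c("sample_id,time", "A,5"), csv)
  expect_error(read_survival(csv), "event")
})
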