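test_that("beta matrix TSV round-trips, flags missing probes, rejects bad cells", {
  set.seed(1)
  beta <- matrix(runif(12, 0.05, 0.95), 3, 4,
                 dimnames = list(paste0("cg", 1:3), paste0("S", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(beta, f, digits = 8L)
  ds <- read_beta_matrix(f)
  expect_equal(dim(ds$beta), c(3L, 4L))
  expect_equal(ds$beta, beta, tolerance = 1e-7)

  # one NA cell: that probe dropped, two retained
  beta_na <- beta; beta_na[2, 3] <- NA
  writeLines(c(paste(c("probe_id", colnames(beta)), collapse = "\t"),
               sapply(1:3, function(i) paste(c(rownames(beta)[i],
                 ifelse(is.na(beta_na[i, ]), "NA", beta_na[i, ])), collapse = "\t"))),
             f)
  expect_message(ds2 <- read_beta_matrix(f), "missing")
  expect_equal(nrow(ds2$beta), 2L)
  expect_identical(attr(ds2, "n_removed_missing"), 1L)

  # out-of-range value: error names probe and sample
  beta_bad <- beta; beta_bad[1, 2] <- 1.2
  write_beta_matrix(beta_bad, f, digits = 8L)
  expect_error(read_beta_matrix(f), "cg1.*S2")

  # exact 0/1 clipped with a warning
  beta_edge <- beta; beta_edge[1, 1] <- 0; beta_edge[3, 4] <- 1
  write_beta_matrix(beta_edge, f, digits = 8L)
  expect_warning(ds3 <- read_beta_matrix(f), "clipped")
  expect_true(all(ds3$beta > 0 & ds3$beta < 1))

  # duplicate probe IDs rejected
  writeLines(c("probe_id\tS1\tS2", "cg1\t0.5\t0.5", "cg1\t0.4\t0.4"), f)
  expect_error(read_beta_matrix(f), "duplicate probe")
})

test_that("sample sheet validates BMI bins, normalizes FA, checks cell sums", {
  sheet <- make_sheet()
  f <- withr::local_tempfile(fileext = ".csv")

  # a BMI of 27.1 labelled Ow is accepted
  sheet$bmi[5] <- 27.1; sheet$bmi_class[5] <- "Ow"
  write_sample_sheet(sheet, f)
  rd <- read_sample_sheet(f)
  expect_s3_class(rd, "sample_sheet")
  fa_cols <- grep("^fa_", names(rd))
  expect_equal(unname(rowSums(rd[fa_cols])), rep(100, nrow(rd)))

  # bmi 31 labelled N violates the bins
  bad <- sheet; bad$bmi[1] <- 31
  write_sample_sheet(bad, f)
  expect_error(read_sample_sheet(f), "inconsistent")

  # arbitrary-unit FA rows become percentages of the measured total
  sheet3 <- sheet
  fa_cols <- grep("^fa_", names(sheet3))
  sheet3[fa_cols] <- 0
  sheet3[["fa_PA"]] <- 20; sheet3[["fa_OA"]] <- 30; sheet3[["fa_LA"]] <- 50
  sheet3[fa_cols][sheet3[fa_cols] == 0] <- 1e-9
  write_sample_sheet(sheet3, f)
  rd3 <- read_sample_sheet(f)
  expect_equal(rd3$fa_PA, rep(20, 12), tolerance = 1e-6)
  expect_equal(rd3$fa_LA, rep(50, 12), tolerance = 1e-6)

  # cell proportions must sum to 1
  bad2 <- sheet; bad2$cell_Gran <- bad2$cell_Gran + 0.01
  write_sample_sheet(bad2, f)
  expect_error(read_sample_sheet(f), "sum")
})

test_that("island BED sets merge abutting/overlapping intervals and sort input", {
  f <- withr::local_tempfile(fileext = ".bed")

  writeLines(c("chr1\t100\t200", "chr1\t200\t300"), f)
  isl <- read_island_bed(f)
  expect_equal(nrow(isl), 1L)
  expect_equal(c(isl$start, isl$end), c(100L, 300L))

  writeLines(c("chr1\t100\t250", "chr1\t200\t300"), f)
  isl2 <- read_island_bed(f)
  expect_equal(c(isl2$start, isl2$end), c(100L, 300L))

  # unsorted input accepted; disjoint intervals stay separate and sorted
  writeLines(c("chr1\t5000\t5100", "chr1\t100\t200"), f)
  isl3 <- read_island_bed(f)
  expect_equal(isl3$start, c(100L, 5000L))

  writeLines(character(), f)
  expect_equal(nrow(read_island_bed(f)), 0L)

  writeLines("chr1\t300\t300", f)
  expect_error(read_island_bed(f), "end > start")
})

test_that("results tables write deterministically and round-trip", {
  res <- data.frame(
    probe_id = c("cg2", "cg1"), covariate = "BMI", prandial_state = "FS",
    method = "pearson", r = c(0.912345678, -0.5), p = c(0.001234567, 0.2),
    p_cell_adjusted = NA_real_, delta_beta = c(0.15, -0.02),
    direction = c("hyper", "hypo"), is_dmcpg = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  class(res) <- c("association_result", "data.frame")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, f, params = list(alpha = 0.05))
  expect_match(readLines(f, n = 1L), "^# prandem")
  back <- read_results(f)
  expect_s3_class(back, "association_result")
  expect_equal(back$probe_id, c("cg1", "cg2")) # sorted
  expect_equal(back$r[back$probe_id == "cg2"], signif(0.912345678, 6))

  # empty table -> header-only (comment + column header)
  write_results(res[0, ], f)
  expect_equal(length(readLines(f)), 2L)

  # mixed schemas rejected
  mixed <- cbind(res, bmi_class = "N")
  class(mixed) <- "data.frame"
  expect_error(write_results(mixed, f), "homogeneous")
})

test_that("permuting sample-sheet rows never changes downstream statistics", {
  set.seed(7)
  sheet <- make_sheet()
  beta <- matrix(runif(50 * 12, 0.1, 0.9), 50,
                 dimnames = list(sprintf("cg%03d", 1:50), sheet$sample_id))
  ds1 <- methylation_dataset(beta, sheet)
  ds2 <- methylation_dataset(beta, sheet[sample(nrow(sheet)), ])
  r1 <- call_dm_for_covariate(ds1, covariate_spec("BMI"))
  r2 <- call_dm_for_covariate(ds2, covariate_spec("BMI"))
  expect_equal(r1, r2)
})
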