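test_that("expression TSV round-trips in canonical orientation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_expr_tsv(path)
  m <- read_expression_tsv(path)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("hsa-miR-21", "hsa-miR-24", "hsa-miR-222"))
  expect_identical(colnames(m), c("S1", "S2"))
  expect_equal(m["hsa-miR-24", "S2"], 0.25)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(m, out)
  expect_equal(read_expression_tsv(out), m)
})

test_that("transposed input with samples_in_rows yields the identical matrix", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_expr_tsv(p1)
  m <- read_expression_tsv(p1)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  df <- t(m)
  writeLines(c(paste(c("sample", rownames(m)), collapse = "\t"),
               vapply(seq_len(nrow(df)), function(i) {
                 paste(c(rownames(df)[i], df[i, ]), collapse = "\t")
               }, character(1))), p2)
  expect_equal(read_expression_tsv(p2, orientation = "samples_in_rows"), m)
})

test_that("duplicate and malformed expression inputs are hard errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\tS1\tS2",
               "hsa-miR-24\t1\t2",
               "hsa-miR-24\t3\t4"), path)
  expect_error(read_expression_tsv(path), "hsa-miR-24")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\tS1\tS2",
               "hsa-miR-21\t1\toops"), path2)
  expect_error(read_expression_tsv(path2), "oops")
  expect_error(read_expression_tsv(path2), "S2")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\tS1\tS2", "hsa-miR-21\t1\t"), path3)
  expect_error(read_expression_tsv(path3), "missing")
  m <- read_expression_tsv(path3, impute_missing = TRUE)
  expect_equal(m["hsa-miR-21", "S2"], 1)  # per-feature mean imputation
})

test_that("clinical parsing keeps absent survival absent and duplicates intact", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_lines(path, c(
    "P1\t365\tTRUE\tdead",
    "P2\t\tTRUE\talive",
    "P3\t50\tTRUE\tdead",
    "P3\t50\tTRUE\tdead"))
  rec <- read_clinical_tsv(path)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$days_to_death[1], 365L)
  expect_true(is.na(rec$days_to_death[2]))
  expect_equal(sum(rec$sample_id == "P3"), 2)  # dedup deferred to the filters

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdays\ttherapy", "P1\t10\tTRUE"), bad)
  expect_error(read_clinical_tsv(bad), "available columns")
})

test_that("cohort filters apply the four criteria in order with a faithful report", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_lines(path, c(
    "P1\t365\tTRUE\tdead",
    "P2\t20\tTRUE\tdead",     # fails (iii): < 30 days
    "P3\t\tTRUE\talive",      # fails (ii): no survival info
    "P4\t400\tFALSE\tdead",   # fails (i): no therapy
    "P5\t90\tTRUE\tdead"))
  rec <- read_clinical_tsv(path)
  res <- apply_cohort_filters(rec)
  expect_setequal(res$records$sample_id, c("P1", "P5"))
  expect_equal(res$report$removed$short_survival, 1)
  expect_equal(res$report$removed$no_survival_info, 1)
  expect_equal(res$report$removed$no_therapy, 1)
  expect_equal(res$report$input,
               res$report$retained + sum(unlist(res$report$removed)))

  # identical duplicates merge silently; conflicting ones need a policy
  rec2 <- rbind(rec, rec[1, ])
  res2 <- apply_cohort_filters(rec2)
  expect_equal(res2$report$removed$duplicate_merged, 1)
  expect_equal(sum(res2$records$sample_id == "P1"), 1)

  rec3 <- rec
  rec3 <- rbind(rec3, data.frame(sample_id = "P1", days_to_death = 500L,
                                 received_therapy = TRUE, vital_status = "dead"))
  expect_error(apply_cohort_filters(rec3), "conflicting")
  res3 <- apply_cohort_filters(rec3, duplicate_policy = "keep_max")
  expect_equal(res3$records$days_to_death[res3$records$sample_id == "P1"], 500L)
})

test_that("filtering is idempotent and counts are conserved on random tables", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    rec <- data.frame(
      sample_id = paste0("P", sample.int(20, n, replace = TRUE)),
      days_to_death = ifelse(runif(n) < 0.2, NA_integer_,
                             sample.int(2000, n, replace = TRUE)),
      received_therapy = runif(n) < 0.8,
      vital_status = "dead", stringsAsFactors = FALSE)
    res <- apply_cohort_filters(rec, duplicate_policy = "keep_max")
    expect_equal(res$report$input, res$report$retained + sum(unlist(res$report$removed)))
    twice <- apply_cohort_filters(res$records, duplicate_policy = "keep_max")
    expect_equal(sort(twice$records$sample_id), sort(res$records$sample_id))
    expect_equal(sum(unlist(twice$report$removed)), 0)
  }
})

test_that("cohort assembly intersects, sorts, converts days to years", {
  expr <- expression_matrix(matrix(1:9, 3, 3), paste0("m", 1:3),
                            c("P3", "P1", "P9"))
  rec <- data.frame(sample_id = c("P1", "P3", "P7"),
                    days_to_death = c(3652L, 730L, 100L),
                    received_therapy = TRUE, vital_status = "dead",
                    stringsAsFactors = FALSE)
  expect_message(co <- assemble_cohort(expr, rec), "P7")
  expect_identical(colnames(co$expression), c("P1", "P3"))
  expect_equal(unname(co$survival_years["P1"]), 3652 / 365.25, tolerance = 1e-12)
  expect_equal(unname(co$survival_years["P1"]), 9.998, tolerance = 1e-4)

  # permutation invariance in both inputs
  co2 <- suppressMessages(
    assemble_cohort(expr[, c(2, 3, 1)], rec[c(3, 1, 2), ]))
  expect_equal(co2$expression, co$expression)
  expect_equal(co2$survival_years, co$survival_years)

  rec_empty <- data.frame(sample_id = "PX", days_to_death = 100L,
                          received_therapy = TRUE, vital_status = "dead")
  expect_error(assemble_cohort(expr, rec_empty), "overlap")
})

test_that("a cohort writes back to paired TSVs and reloads", {
  sim <- toy_cohort(n = 8, p = 4, seed = 11)
  ep <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(sim$cohort, ep, cp)
  m <- read_expression_tsv(ep)
  expect_equal(m, sim$cohort$expression, tolerance = 1e-12)
  surv <- read.table(cp, header = TRUE, sep = "\t")
  expect_equal(surv$survival_years, unname(sim$cohort$survival_years),
               tolerance = 1e-12)
})
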