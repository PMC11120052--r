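test_that("quantification files parse in order and invalid files are rejected", {
  f <- write_quant_fixture(tempfile(fileext = ".tsv"))
  rec <- read_quantification_file(f)
  expect_equal(rec$mirna_id, c("mir-a", "mir-b", "mir-c"))
  expect_equal(rec$rpm, c(1, 2, 0))
  expect_equal(rec$read_count, c(10L, 20L, 0L))

  # header only -> empty record set
  f2 <- write_quant_fixture(tempfile(fileext = ".tsv"),
                            ids = character(0), counts = integer(0),
                            rpm = numeric(0))
  expect_equal(nrow(read_quantification_file(f2)), 0)

  # duplicated identifier
  f3 <- write_quant_fixture(tempfile(fileext = ".tsv"),
                            ids = c("mir-a", "mir-a"), counts = c(1L, 2L),
                            rpm = c(1, 2))
  expect_error(read_quantification_file(f3), "duplicate")

  # negative rpm names the row
  f4 <- write_quant_fixture(tempfile(fileext = ".tsv"),
                            ids = c("mir-a", "mir-b"), counts = c(1L, 2L),
                            rpm = c(1, -2))
  expect_error(read_quantification_file(f4), "row 2")

  # missing rpm column named in the error
  df <- data.frame(miRNA_ID = "mir-a", read_count = 1L)
  f5 <- tempfile(fileext = ".tsv")
  write.table(df, f5, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_quantification_file(f5), "reads per million")
})

test_that("cohort assembly joins on file id, sorts miRNAs, and flags orphans", {
  q1 <- data.frame(mirna_id = c("mir-b", "mir-a"), read_count = c(1L, 2L),
                   rpm = c(1, 2))
  q2 <- data.frame(mirna_id = c("mir-a", "mir-b"), read_count = c(3L, 4L),
                   rpm = c(3, 4))
  clin <- data.frame(case_id = c("c1", "c2"), file_id = c("f1", "f2"),
                     stage = c("normal", "2"), sample_type = "tissue",
                     age = NA_integer_, gender = NA_character_)
  co <- assemble_cohort(list(f1 = q1, f2 = q2), clin)
  expect_equal(colnames(co$expr), c("mir-a", "mir-b"))  # lexicographic
  expect_equal(unname(co$expr["c1", ]), c(2, 1))        # reordered from file
  expect_equal(as.character(co$stage), c("normal", "2"))

  # quantification without clinical match is an error listing the orphan
  expect_error(assemble_cohort(list(f1 = q1, zz = q2), clin), "zz")

  # clinical record without quantification is dropped with a warning
  clin3 <- rbind(clin, data.frame(case_id = "c3", file_id = "f3",
                                  stage = "1", sample_type = "tissue",
                                  age = NA_integer_, gender = NA_character_))
  expect_warning(co3 <- assemble_cohort(list(f1 = q1, f2 = q2), clin3),
                 "without a quantification file")
  expect_equal(n_samples(co3), 2)

  # inconsistent miRNA universes
  q3 <- data.frame(mirna_id = c("mir-a", "mir-z"), read_count = c(1L, 1L),
                   rpm = c(1, 1))
  expect_error(assemble_cohort(list(f1 = q1, f2 = q3), clin), "universe")
})

test_that("clinical JSON reader handles the flat dialect and bad stages", {
  clin <- data.frame(case_id = c("c1", "c2"), file_id = c("f1", "f2"),
                     stage = c("Normal", "X"), sample_type = "tissue")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(clin, f, dataframe = "rows")
  got <- read_clinical(f)
  expect_equal(got$stage, c("normal", "X"))

  bad <- data.frame(case_id = "c1", file_id = "f1", stage = "IIA",
                    sample_type = "tissue")
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, dataframe = "rows")
  expect_error(read_clinical(f2), "invalid stage")
})

test_that("stage-X and blood exclusions retain the printed 716 of 1207 samples", {
  co <- paper_shaped_cohort()
  expect_equal(n_samples(co), 1207)
  kept <- filter_cohort(co)
  expect_equal(n_samples(kept), 716)
  expect_equal(as.integer(table(kept$stage)[c("normal", "1", "2", "3", "4")]),
               c(113L, 111L, 350L, 131L, 11L))
  expect_true(all(kept$sample_type == "tissue"))
})

test_that("filter_cohort is idempotent and counts decompose by group", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 40
    stages <- sample(c("normal", "1", "2", "3", "4", "X"), n, replace = TRUE)
    types <- sample(c("tissue", "blood"), n, replace = TRUE)
    co <- toy_cohort(stages, types, p = 4, seed = seed)
    kept <- filter_cohort(co)
    expect_identical(filter_cohort(kept)$expr, kept$expr)
    expect_equal(n_samples(kept),
                 sum(types == "tissue" & stages != "X"))
  }
  # all-blood cohort filters to empty
  allb <- toy_cohort(c("1", "2"), c("blood", "blood"))
  expect_equal(n_samples(filter_cohort(allb)), 0)
})

test_that("cohort files round-trip at full precision", {
  co <- toy_cohort(c("normal", "1", "X"), c("tissue", "tissue", "blood"), p = 4)
  ep <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_cohort(co, ep, lp)
  back <- read_cohort(ep, lp)
  expect_identical(back$expr, co$expr)
  expect_identical(back$stage, co$stage)
  expect_identical(back$sample_type, co$sample_type)

  # empty cohort round-trips
  e <- filter_cohort(toy_cohort(c("1", "2"), c("blood", "blood")))
  write_cohort(e, ep, lp)
  expect_equal(n_samples(read_cohort(ep, lp)), 0)

  # label outside the enum is a validation error
  lab <- read.delim(lp)
  writeLines(c("sample_id\tstage\tsample_type", "s1\tstage9\ttissue"), lp)
  writeLines(c(paste(c("sample_id", colnames(co$expr)), collapse = "\t"),
               paste(c("s1", rep("1", 4)), collapse = "\t")), ep)
  expect_error(read_cohort(ep, lp), "invalid stage")
})

test_that("exported per-sample files re-assemble into the same cohort", {
  co <- toy_cohort(c("normal", "1", "2"), rep("tissue", 3), p = 5)
  d <- file.path(tempdir(), "gdc-style")
  export_cohort_files(co, d)
  clin <- read_clinical(file.path(d, "clinical.json"))
  quant <- lapply(clin$file_id, function(f)
    read_quantification_file(file.path(d, paste0(f, ".tsv"))))
  names(quant) <- clin$file_id
  back <- assemble_cohort(quant, clin)
  expect_equal(unname(back$expr), unname(co$expr))
  expect_equal(as.character(back$stage), as.character(co$stage))
  unlink(d, recursive = TRUE)
})
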