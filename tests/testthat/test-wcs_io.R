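test_that("response tables read, validate and round-trip", {
  grid <- wcs_grid()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("language\tspeaker\tchip\tterm",
               "L1\ts1\t2\tred", "L1\ts1\t7\tred", "L1\ts2\t3\tblue"), f)
  rt <- read_responses(f, grid)
  expect_equal(nrow(rt), 3)

  g <- withr::local_tempfile(fileext = ".tsv")
  write_responses(rt, g)
  expect_equal(read_responses(g, grid), rt)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("language\tspeaker\tchip\tterm", "L1\ts1\t999\tred"), bad)
  expect_error(read_responses(bad, grid), "unknown chip_id 999")

  conflict <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("language\tspeaker\tchip\tterm",
               "L1\ts1\t5\tred", "L1\ts1\t5\tblue"), conflict)
  expect_error(read_responses(conflict, grid),
               "conflicting terms for \\(language=L1, speaker=s1, chip=5\\)")
})

test_that("speaker response vectors are 0/1 indicators per (language, speaker, term)", {
  grid <- wcs_grid()
  rt <- toy_response_table(grid)
  sv <- speaker_response_vectors(rt, grid)
  expect_equal(sv$level, "speaker")
  expect_true(all(sv$values %in% c(0, 1)))
  red1 <- sv$values["L1:s1:red", ]
  expect_equal(sum(red1), 2)
  expect_equal(unname(which(red1 == 1)), c(2, 7))
  # chart count equals distinct (language, speaker, term) triples, brute force
  set.seed(5)
  big <- data.frame(language = sample(c("A", "B"), 60, TRUE),
                    speaker = sample(c("s1", "s2", "s3"), 60, TRUE),
                    chip_id = sample.int(330, 60, replace = FALSE),
                    term = sample(c("x", "y", "z"), 60, TRUE),
                    stringsAsFactors = FALSE)
  big <- chartmetrics:::validate_responses(big, grid)
  svb <- speaker_response_vectors(big, grid)
  expect_equal(nrow(svb$values),
               nrow(unique(big[c("language", "speaker", "term")])))
  # each speaker's chips are partitioned across that speaker's terms
  for (sp in c("s1", "s2", "s3")) for (lg in c("A", "B")) {
    rows <- svb$info$speaker == sp & svb$info$language == lg
    if (!any(rows)) next
    expect_true(all(colSums(svb$values[rows, , drop = FALSE]) <= 1))
  }
})

test_that("language vectors are entrywise sums of speaker vectors", {
  grid <- wcs_grid()
  rt <- toy_response_table(grid)
  sv <- speaker_response_vectors(rt, grid)
  lv <- language_response_vectors(sv)
  expect_equal(lv$level, "language")
  red <- lv$values["L1:red", ]
  expect_equal(unname(red[2:3]), c(2, 1))   # chip 2 used by both, chip 3 by s2
  expect_equal(sum(lv$values), nrow(rt))    # conservation over all records
  # brute-force accumulation on a random table
  set.seed(9)
  big <- data.frame(language = "A", speaker = sample(paste0("s", 1:4), 80, TRUE),
                    chip_id = sample.int(330, 80), term = sample(c("x", "y"), 80, TRUE))
  big <- chartmetrics:::validate_responses(big, grid)
  lvb <- language_response_vectors(speaker_response_vectors(big, grid))
  for (tm in c("x", "y")) {
    manual <- tabulate(big$chip_id[big$term == tm], nbins = 330)
    expect_equal(unname(lvb$values[paste0("A:", tm), ]), manual)
  }
  expect_error(language_response_vectors(lv), "speaker-level")
})

test_that("the achromatic filter keeps exactly the chromatic-support charts", {
  grid <- wcs_grid()
  vals <- matrix(0, 10, 330)
  for (i in 1:10) vals[i, 100 + i] <- 1
  vals[1, 1] <- 1     # A0
  vals[2, 2] <- 1     # B0
  vals[3, which(grid$is_achromatic)[5]] <- 1
  vals[4, 330] <- 1   # J0
  cs <- chart_set(vals, data.frame(language = "L", term = paste0("t", 1:10),
                                   speaker = paste0("s", 1:10)),
                  grid$chip_id, "speaker")
  kept <- filter_achromatic(cs, grid)
  expect_equal(nrow(kept$values), 6)
  expect_true(all(kept$values[, grid$is_achromatic] == 0))
  # a chart whose only response is achromatic is removed
  solo <- chart_set(matrix(c(1, rep(0, 329)), 1), data.frame(language = "L",
                    term = "grey", speaker = "s"), grid$chip_id, "speaker")
  expect_error(filter_achromatic(solo, grid), "no charts left")
  # idempotence
  expect_equal(filter_achromatic(kept, grid)$values, kept$values)
})

test_that("centroid projection averages speakers first, then the language", {
  grid <- wcs_grid()[1:4, ]
  grid$chip_id <- 1:4
  class(grid) <- c("chip_grid", "data.frame")
  lab <- data.frame(chip_id = 1:4, L = c(0, 10, 8, 6.9), a = 0, b = 0)

  single <- chart_set(matrix(c(0, 1, 0, 0), 1),
                      data.frame(language = "L", term = "t", speaker = "s1"),
                      1:4, "speaker")
  expect_equal(centroid_representative(single, lab), 2)

  two <- chart_set(rbind(c(1, 0, 0, 0), c(0, 0, 0, 1)),
                   data.frame(language = "L", term = "t", speaker = c("s1", "s2")),
                   1:4, "speaker")
  # speaker means L = 0 and 6.9 -> language mean 3.45; exhaustive nearest chip:
  expect_equal(centroid_representative(two, lab),
               lab$chip_id[which.min(abs(lab$L - 3.45))])

  # unbalanced case where pooling chips would disagree with speaker averaging
  unb <- chart_set(rbind(c(1, 1, 0, 0),   # s1 mean L = (0 + 10) / 2 = 5
                         c(0, 1, 0, 0)),  # s2 mean L = 10
                   data.frame(language = "L", term = "t", speaker = c("s1", "s2")),
                   1:4, "speaker")
  speaker_then_language <- mean(c(5, 10))        # 7.5  -> chip 3 (L = 8)
  pooled <- mean(c(0, 10, 10))                   # 6.67 -> chip 4 (L = 6.9)
  expect_false(identical(
    which.min(abs(lab$L - speaker_then_language)),
    which.min(abs(lab$L - pooled))))
  expect_equal(centroid_representative(unb, lab), 3)
})

test_that("chart sets round-trip through the TSV matrix format", {
  grid <- wcs_grid()
  sv <- speaker_response_vectors(toy_response_table(grid), grid)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_charts(sv, f, header_lines = "test fixture")
  back <- read_charts(f)
  expect_equal(back$values, sv$values, ignore_attr = FALSE)
  expect_equal(back$level, "speaker")
  lv <- language_response_vectors(sv)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_charts(lv, g)
  expect_equal(read_charts(g)$values, lv$values)
})
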