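# minimal hand-built subject reports for table logic (the full pipeline
# is exercised in the acceptance suite)
fake_scan <- function(artifacts = character(), misaligned = FALSE,
                      offset = 0, rd_mean = 100, rd_max = 100,
                      lung = 2.6) {
  list(artifacts = artifacts, misaligned = misaligned, offset_mm = offset,
       recovered_mm = -offset, rd_mean = rd_mean, rd_max = rd_max,
       lung_volume_L = lung)
}

fake_subject <- function(id, test, retest) {
  pm <- structure(list(segments = rep(100, 17), defect_extent_pct = 0,
                       defect_segments = rep(FALSE, 17), threshold = 50),
                  class = "polar_map17")
  v <- viability_scores(pm, pm)
  structure(list(subject = id,
                 scans = list(test = test, retest = retest),
                 lung_report = test_retest(test$lung_volume_L,
                                           retest$lung_volume_L),
                 viability = list(original = v, corrected = v)),
            class = "subject_report")
}

test_that("frequency tables use union semantics for the combined column", {
  s1 <- fake_subject(1, fake_scan("STN"), fake_scan("STN"))
  s2 <- fake_subject(2, fake_scan("PMA"), fake_scan())
  study <- structure(list(subjects = list(s1, s2),
                          config = cohort_config(n_subjects = 2),
                          seed = 1), class = "study_report")
  tabs <- summarize_study(study)
  freq <- tabs$frequency
  stn <- freq[freq$artifact == "STN", ]
  expect_equal(c(stn$test, stn$retest, stn$combined), c(1, 1, 1))
  pma <- freq[freq$artifact == "PMA", ]
  expect_equal(c(pma$test, pma$retest, pma$combined), c(1, 0, 1))
  # rows never exceed subject count; combined >= per-scan counts
  expect_true(all(freq$combined <= 2))
  expect_true(all(freq$combined >= pmax(freq$test, freq$retest)))
})

test_that("an artifact-free cohort produces an all-zero frequency table", {
  s <- fake_subject(1, fake_scan(), fake_scan())
  study <- structure(list(subjects = list(s),
                          config = cohort_config(n_subjects = 1),
                          seed = 1), class = "study_report")
  freq <- summarize_study(study)$frequency
  expect_true(all(freq$test == 0 & freq$retest == 0 & freq$combined == 0))
})

test_that("artifact draws follow the configured prevalences", {
  ph <- fx_phantom32()
  cfg <- cohort_config(n_subjects = 1)
  set.seed(31)
  n <- 300
  draws <- replicate(n, names(dixonac:::draw_scan_artifacts(cfg, ph)),
                     simplify = FALSE)
  for (kind in names(cfg$prevalence)) {
    p <- cfg$prevalence[[kind]]
    k <- sum(vapply(draws, function(d) kind %in% d, logical(1)))
    ci <- stats::binom.test(k, n)$conf.int
    expect_true(p >= ci[1] - 0.02 && p <= ci[2] + 0.02,
                label = sprintf("%s prevalence %.2f in CI [%.2f, %.2f]",
                                kind, p, ci[1], ci[2]))
  }
  # truncation is certain
  expect_true(all(vapply(draws, function(d) "TRUNCATION" %in% d,
                         logical(1))))
})

test_that("cohort configuration validates probabilities", {
  expect_error(cohort_config(n_subjects = 0))
  expect_error(cohort_config(prevalence = c(STN = 1.5)))
})

test_that("study table writer emits one CSV per table", {
  s <- fake_subject(1, fake_scan("STN"), fake_scan())
  study <- structure(list(subjects = list(s),
                          config = cohort_config(n_subjects = 1),
                          seed = 1), class = "study_report")
  dir <- tempfile()
  write_study_tables(summarize_study(study), dir)
  expect_true(all(file.exists(file.path(dir, c("frequency.csv", "lung.csv",
                                               "polar.csv")))))
  unlink(dir, recursive = TRUE)
})
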