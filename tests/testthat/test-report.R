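test_that("frequencies are raw ratios with separate half-up display", {
  expect_equal(round_half_up(frequency(7, 1919), 1), 0.4)
  expect_equal(frequency(0, 1919), 0)
  expect_equal(round_half_up(frequency(183, 983), 1), 18.6)
  # raw value never carries display rounding
  expect_equal(frequency(7, 1919), 700 / 1919, tolerance = 1e-12)
  expect_error(frequency(1, 0))
  expect_error(frequency(5, 4))
  expect_error(frequency(-1, 10))
})

test_that("rounding is half away from zero, not banker's", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.35, 1), 0.4)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("the report reproduces every printed abnormality percentage", {
  counts <- abnormality_counts()
  printed <- c(0, 0, 0.4, 0, 0, 0.7,
               0, 0, 3.2, 0, 0, 4.1,
               0.1, 0, 4.5, 0.7, 0.11, 8.4,
               0.1, 0.1, 4.1, 0, 0.2, 18.6)
  rep <- build_report(counts[, c("condition", "genotype", "category",
                                 "events", "total")])
  expect_equal(round_half_up(rep$pct, counts$decimals), printed)
  # significance asterisks appear exactly on the two high-oxidative SFE rows
  starred <- rep[rep$significant, ]
  expect_equal(nrow(starred), 2)
  expect_true(all(starred$category == "sfe"))
  expect_setequal(starred$condition, c("mef_20pct_o2", "mef_paraquat"))
  expect_true(all(starred$genotype == "ogg1_null"))
  expect_match(rep$display[rep$condition == "mef_20pct_o2" &
                             rep$genotype == "ogg1_null" &
                             rep$category == "sfe"],
               "8.4% \\(79/946\\)\\*", fixed = FALSE)
})

test_that("identical genotype counts earn no asterisk", {
  counts <- data.frame(condition = "c1",
                       genotype = rep(c("a", "b"), each = 2),
                       category = rep(c("x", "y"), 2),
                       events = c(5, 1, 5, 1), total = 1000)
  rep <- build_report(counts)
  expect_false(any(rep$significant))
  expect_true(all(rep$p_value == 1))
})

test_that("reports demand complete categories and stay deterministic", {
  bad <- data.frame(condition = "c1", genotype = c("a", "a", "b"),
                    category = c("x", "y", "x"),
                    events = 1, total = 100)
  expect_error(build_report(bad), "missing categories")
  counts <- abnormality_counts()[, 1:5]
  expect_identical(build_report(counts), build_report(counts))
})

test_that("lesion fold-change tables normalize replicate-wise", {
  est <- data.frame(sample_id = rep(c("ctrl", "ko"), each = 3),
                    replicate = rep(1:3, 2),
                    lesions_per_fragment = c(0.2, 0.25, 0.22,
                                             0.4, 0.5, 0.44))
  tab <- aggregate_lesions(est, "ctrl")
  expect_equal(tab$sample_id, c("ctrl", "ko"))  # input order preserved
  expect_equal(tab$mean_fold[1], 1)
  expect_equal(tab$mean_fold[2], 2)
  expect_equal(tab$n, c(3, 3))

  single <- aggregate_lesions(est[1:3, ], "ctrl")
  expect_equal(nrow(single), 1)
  expect_equal(single$mean_fold, 1)

  est$lesions_per_fragment[1] <- 0
  expect_warning(out <- aggregate_lesions(est, "ctrl"), "unnormalized")
  expect_true("mean_lesions" %in% names(out))
})

test_that("a simulated doubled lesion rate yields a two-fold change", {
  folds <- vapply(1:3, function(s) {
    ctl <- sim_lane_pair(n = 5000, rate = 0.05, seed = 200 + s)
    smp <- sim_lane_pair(n = 5000, rate = 0.10, seed = 300 + s)
    fold_change(estimate_lesions(smp$mock, smp$fpg),
                estimate_lesions(ctl$mock, ctl$fpg))
  }, numeric(1))
  expect_lt(abs(mean(folds) - 2) / 2, 0.2)
})

test_that("report serialization writes TSV, Markdown and JSON mirrors", {
  rep <- build_report(abnormality_counts()[, 1:5])
  prefix <- tempfile()
  on.exit(unlink(paste0(prefix, c(".tsv", ".md", ".json"))))
  paths <- write_report(rep, prefix)
  expect_true(all(file.exists(paths)))
  back <- read.delim(paths["tsv"])
  expect_equal(nrow(back), nrow(rep))
  js <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  expect_equal(js$pct, rep$pct)
})
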