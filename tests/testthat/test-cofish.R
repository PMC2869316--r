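test_that("scoring rules classify the canonical signal patterns", {
  rec <- data.frame(lagging_signals = c(3, 2, 1, 2, 0, 4),
                    leading_signals = c(3, 2, 2, 1, 1, 4))
  out <- classify_cofish(rec)
  expect_equal(as.character(out$label),
               c("t_sce", "normal", "lagging_loss", "leading_loss",
                 "both_loss", "t_sce"))
  expect_false(any(out$flag_review))
})

test_that("unaddressed count combinations fall to normal but are flagged", {
  odd <- classify_cofish(data.frame(lagging_signals = 1,
                                    leading_signals = 4))
  expect_equal(as.character(odd$label), "normal")
  expect_true(odd$flag_review)
  expect_error(classify_cofish(data.frame(lagging_signals = -1,
                                          leading_signals = 2)),
               "malformed")
})

test_that("generated records classify back to their generating label", {
  s <- sim_cofish(2000, rates = c(t_sce = 0.03, lagging_loss = 0.035,
                                  leading_loss = 0.02, both_loss = 0.01),
                  seed = 5)
  out <- classify_cofish(s$records)
  expect_equal(as.character(out$label), as.character(s$truth$label))

  all_norm <- sim_cofish(500, rates = c(t_sce = 0), seed = 1)
  expect_true(all(classify_cofish(all_norm$records)$label == "normal"))

  all_tsce <- sim_cofish(500, rates = c(t_sce = 1), seed = 2)
  expect_true(all(all_tsce$records$lagging_signals > 2 &
                    all_tsce$records$leading_signals > 2))
})

test_that("realized event fractions stay inside binomial bounds", {
  s <- sim_cofish(2000, rates = c(lagging_loss = 0.035), seed = 7)
  frac <- mean(classify_cofish(s$records)$label == "lagging_loss")
  ci <- binom_ci(0.035, 2000)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("tallies conserve counts and average correctly across specimens", {
  rec <- data.frame(specimen_id = "s1",
                    label = factor(c(rep("t_sce", 40), rep("normal", 1960)),
                                   levels = telodamage:::COFISH_EVENTS))
  tal <- tally_events(rec)
  ps <- tal$per_specimen
  expect_equal(ps$pct[ps$category == "t_sce"], 2.0)
  expect_equal(sum(ps$events), 2000)
  expect_true(all(tapply(ps$events, ps$specimen_id, sum) == ps$total[1]))

  # group mean over specimens recovers the generating rate
  recs <- do.call(rbind, lapply(1:6, function(i) {
    x <- sim_cofish(2000, rates = c(t_sce = 0.028),
                    specimen_id = paste0("m", i), seed = 100 + i)
    classify_cofish(x$records)
  }))
  tal2 <- tally_events(recs, groups = setNames(rep("ko", 6),
                                               paste0("m", 1:6)))
  g <- tal2$per_group[tal2$per_group$category == "t_sce", ]
  ci <- 100 * binom_ci(0.028, 6 * 2000)
  expect_gte(g$mean_pct, ci[1])
  expect_lte(g$mean_pct, ci[2])
  expect_equal(g$n_specimens, 6)
  expect_true(is.finite(g$sem_pct))
})

test_that("group comparison is an exact test with sane null behaviour", {
  same <- compare_groups(10, 100, 10, 100)
  expect_equal(same$p_value, 1)
  expect_equal(same$effect_pct, 0)

  # pooled signal-free-end counts at high oxygen differ significantly
  cmp <- compare_groups(38, 846, 79, 946)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$effect_pct, 0)
  expect_error(compare_groups(1, 0, 1, 10))
})

test_that("cofish tables survive a TSV round trip", {
  s <- sim_cofish(50, seed = 9)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_cofish_table(s$records, path)
  back <- read_cofish_table(path)
  expect_equal(back$lagging_signals, s$records$lagging_signals)
  expect_equal(back$leading_signals, s$records$leading_signals)
})
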