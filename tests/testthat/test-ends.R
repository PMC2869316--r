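test_that("spots on anchors assign perfectly; distant spots stay SFE", {
  templates <- data.frame(chromosome = rep(1:2, each = 4), end = rep(1:4, 2),
                          row = c(10, 10, 40, 40, 100, 100, 130, 130),
                          col = c(10, 20, 10, 20, 10, 20, 10, 20))
  spots <- data.frame(row = templates$row, col = templates$col,
                      channel = "telo", intensity = 100, response = 50)
  calls <- assign_spots(spots, templates)
  expect_true(all(calls$status == "signal"))

  # a spot beyond the capture radius leaves its end signal-free
  far <- spots[1, ]
  far$row <- far$row + 9
  calls2 <- assign_spots(rbind(spots[-1, ], far), templates,
                         capture_radius = 6)
  expect_equal(sum(calls2$status == "SFE"), 1)
  expect_equal(nrow(attr(calls2, "unassigned")), 1)
})

test_that("signal plus SFE counts always total four per chromosome", {
  for (s in 1:3) {
    m <- sim_metaphase(n_chrom = 12, sfe_fraction = 0.3, seed = s)
    calls <- quantify_channel(m)
    expect_equal(nrow(calls), 12 * 4)
    tab <- table(calls$chromosome)
    expect_true(all(tab == 4))
  }
})

test_that("intensity summaries are normalized and quantile-correct", {
  calls <- data.frame(status = "signal", intensity = rep(100, 8))
  s <- summarize_intensities(calls)
  expect_equal(s$summary[["median"]], 100)
  expect_equal(s$mean, 100)
  expect_equal(sum(s$freq), 1)

  calls2 <- data.frame(status = c(rep("signal", 99), "SFE"),
                       intensity = c(1:99, NA))
  s2 <- summarize_intensities(calls2, n_bins = 10)
  expect_equal(sum(s2$freq), 1)
  expect_equal(s2$n, 99)
  expect_equal(unname(s2$summary), unname(quantile(1:99, c(0, .25, .5, .75, 1))))
  expect_error(summarize_intensities(data.frame(status = "SFE",
                                                intensity = NA)))
})

test_that("two-colour strand-loss classes follow presence/absence rules", {
  g <- data.frame(chromosome = 1, end = 1:4,
                  status = c("signal", "SFE", "signal", "SFE"),
                  intensity = c(5, NA, 7, NA))
  c_ <- data.frame(chromosome = 1, end = 1:4,
                   status = c("signal", "signal", "SFE", "SFE"),
                   intensity = c(6, 8, NA, NA))
  res <- classify_two_color(g, c_)
  expect_equal(as.character(res$category),
               c("normal", "g_loss", "c_loss", "both_loss"))
  # categories partition the scored chromatids
  expect_equal(sum(table(res$category)), nrow(res))
  expect_equal(attr(res, "n_unscored"), 0)

  res2 <- classify_two_color(g[1:3, ], c_)
  expect_equal(nrow(res2), 3)
  expect_equal(attr(res2, "n_unscored"), 1)
})

test_that("foci colocalization fractions hit the designed extremes", {
  tel <- data.frame(cell = 1, row = c(10, 50, 90), col = c(10, 50, 90),
                    channel = "telo", intensity = 1)
  at_tel <- data.frame(cell = 1, row = tel$row, col = tel$col,
                       channel = "focus", intensity = 1)
  expect_equal(colocalize_foci(at_tel, tel)$fraction_colocalized, 1)

  far <- data.frame(cell = 1, row = c(30, 70), col = c(30, 70),
                    channel = "focus", intensity = 1)
  expect_equal(colocalize_foci(far, tel)$fraction_colocalized, 0)
})

test_that("per-cell focus counts are binned as 1-3 vs >3", {
  tel <- data.frame(cell = rep(1:2, each = 2),
                    row = c(10, 90, 10, 90), col = c(10, 90, 10, 90))
  foci <- data.frame(cell = c(1, 1, rep(2, 5)),
                     row = c(10, 90, 10, 90, 30, 40, 50),
                     col = c(10, 90, 10, 90, 30, 40, 50))
  res <- colocalize_foci(foci, tel)
  expect_equal(as.character(res$per_cell$bin), c("1-3", ">3"))
  expect_equal(res$per_cell$n_foci, c(2, 5))
})

test_that("simulated colocalization probability is recovered", {
  m <- sim_metaphase(n_chrom = 25, sfe_fraction = 0, seed = 21)
  tel <- data.frame(cell = 1, row = m$truth$row, col = m$truth$col)
  foci <- sim_foci(tel, n_foci = 200, coloc_prob = 0.2, seed = 22)
  res <- colocalize_foci(foci, tel, max_dist = 3)
  ci <- binom_ci(0.2, 200)
  expect_gte(res$fraction_colocalized, ci[1])
  expect_lte(res$fraction_colocalized, ci[2])
  # scorer agrees with generator truth focus by focus
  expect_equal(res$per_focus$colocalized, foci$true_colocalized)
})
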