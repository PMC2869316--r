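COFISH_EVENTS <- c("normal", "t_sce", "lagging_loss", "leading_loss",
                   "both_loss")

#' Simulate a CO-FISH per-chromosome signal table with known events
#'
#' Draws an event label per chromosome independently at the stated rates
#' and constructs the signal counts each class shows after chromosome
#' orientation FISH, where the FITC-(CCCTAA)3 probe reads the
#' lagging-strand telomeres and the TAMRA-(TTAGGG)3 probe the
#' leading-strand telomeres: a normal chromosome has 2 signals per probe;
#' a telomere sister-chromatid exchange (T-SCE) shows more than 2 signals
#' in both probes; a lagging- (leading-) strand loss shows 0 or 1 signals
#' in the lagging (leading) probe with the other probe intact; a loss in
#' both shows fewer than 2 in each.
#'
#' @param n_chrom number of chromosomes to score.
#' @param rates named vector of event probabilities over
#'   `t_sce`, `lagging_loss`, `leading_loss`, `both_loss`; each >= 0 and
#'   summing to <= 1 (the remainder is `normal`).
#' @param mean_intensity,cv log-normal law for per-signal intensities.
#' @param specimen_id specimen label stored on every record.
#' @param seed integer seed.
#' @return list with `records` (data frame: `specimen_id`,
#'   `chromosome_id`, `lagging_signals`, `leading_signals`,
#'   `mean_intensity_lagging`, `mean_intensity_leading`), `truth` (data
#'   frame with the generating `label` per chromosome) and `rates`.
#' @export
sim_cofish <- function(n_chrom, rates = c(t_sce = 0.0112,
                                          lagging_loss = 0.018,
                                          leading_loss = 0.012,
                                          both_loss = 0.005),
                       mean_intensity = 1000, cv = 0.35,
                       specimen_id = "s1", seed = 1L) {
  stopifnot(n_chrom >= 1, all(rates >= 0), sum(rates) <= 1,
            all(names(rates) %in% COFISH_EVENTS[-1]))
  p <- stats::setNames(rep(0, 4), COFISH_EVENTS[-1])
  p[names(rates)] <- rates
  probs <- c(normal = 1 - sum(p), p)
  out <- with_seed(seed, {
    label <- sample(names(probs), n_chrom, replace = TRUE, prob = probs)
    lag_n <- lead_n <- rep(2L, n_chrom)
    i <- label == "t_sce"
    lag_n[i] <- sample(3:4, sum(i), replace = TRUE)
    lead_n[i] <- sample(3:4, sum(i), replace = TRUE)
    i <- label == "lagging_loss"
    lag_n[i] <- sample(0:1, sum(i), replace = TRUE)
    i <- label == "leading_loss"
    lead_n[i] <- sample(0:1, sum(i), replace = TRUE)
    i <- label == "both_loss"
    lag_n[i] <- sample(0:1, sum(i), replace = TRUE)
    lead_n[i] <- sample(0:1, sum(i), replace = TRUE)
    sdlog <- sqrt(log(1 + cv^2))
    draw_mean <- function(n_sig) {
      ifelse(n_sig > 0,
             mean_intensity * rlnorm(n_chrom, -sdlog^2 / 2, sdlog),
             NA_real_)
    }
    list(label = label, lag_n = lag_n, lead_n = lead_n,
         lag_i = draw_mean(lag_n), lead_i = draw_mean(lead_n))
  })
  records <- data.frame(specimen_id = specimen_id,
                        chromosome_id = seq_len(n_chrom),
                        lagging_signals = out$lag_n,
                        leading_signals = out$lead_n,
                        mean_intensity_lagging = out$lag_i,
                        mean_intensity_leading = out$lead_i)
  truth <- data.frame(chromosome_id = seq_len(n_chrom),
                      label = factor(out$label, levels = COFISH_EVENTS))
  list(records = records, truth = truth, rates = probs)
}

#' Classify CO-FISH chromosomes into exchange and strand-loss events
#'
#' Scoring rules, applied per chromosome: more than two telomeric signals
#' in *both* probe channels = `t_sce`; fewer than two signals in the
#' lagging probe with two in the leading probe = `lagging_loss` (and
#' symmetrically `leading_loss`); fewer than two in both = `both_loss`;
#' anything else = `normal`. T-SCE takes precedence — its pattern (>2 in
#' both) is disjoint from every loss pattern. Count combinations outside
#' these patterns (e.g. one channel lost while the other shows >2) fall to
#' `normal` and are flagged for manual review.
#'
#' @param records data frame with integer columns `lagging_signals` and
#'   `leading_signals` (counts >= 0), one row per chromosome.
#' @return `records` with added `label` (factor) and logical
#'   `flag_review` columns.
#' @export
classify_cofish <- function(records) {
  lag <- records$lagging_signals
  lead <- records$leading_signals
  if (any(is.na(lag) | is.na(lead) | lag < 0 | lead < 0 |
          lag != floor(lag) | lead != floor(lead))) {
    bad <- which(is.na(lag) | is.na(lead) | lag < 0 | lead < 0 |
                   lag != floor(lag) | lead != floor(lead))
    stop("malformed signal counts in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  label <- ifelse(lag > 2 & lead > 2, "t_sce",
           ifelse(lag < 2 & lead < 2, "both_loss",
           ifelse(lag < 2 & lead == 2, "lagging_loss",
           ifelse(lead < 2 & lag == 2, "leading_loss", "normal"))))
  flag <- (lag < 2 & lead > 2) | (lead < 2 & lag > 2) |
    xor(lag > 2, lead > 2)
  records$label <- factor(label, levels = COFISH_EVENTS)
  records$flag_review <- flag
  records
}

#' Tally event frequencies per specimen and summarize per group
#'
#' Computes per-specimen event counts and percentages per chromosome, then
#' group summaries as mean +/- SEM across specimens (matching the
#' n-animals-per-genotype reporting structure of cytogenetic studies, not
#' a pooled binomial SE).
#'
#' @param records a classified record table from [classify_cofish()]
#'   (needs `specimen_id` and `label`).
#' @param groups named character vector mapping specimen_id -> group
#'   label; defaults to one group.
#' @return an `event_counts`: list with `per_specimen` (counts and
#'   percentages per category) and `per_group` (n specimens, mean and SEM
#'   of each category percentage).
#' @export
tally_events <- function(records, groups = NULL) {
  stopifnot(all(c("specimen_id", "label") %in% names(records)))
  specs <- unique(records$specimen_id)
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(specs)),
                                                 specs)
  per_specimen <- do.call(rbind, lapply(specs, function(s) {
    lab <- records$label[records$specimen_id == s]
    total <- length(lab)
    cnt <- table(factor(lab, levels = COFISH_EVENTS))
    data.frame(specimen_id = s, group = unname(groups[as.character(s)]),
               category = COFISH_EVENTS, events = as.integer(cnt),
               total = total, pct = 100 * as.integer(cnt) / total)
  }))
  per_group <- do.call(rbind, lapply(split(per_specimen,
                                           list(per_specimen$group,
                                                per_specimen$category),
                                           drop = TRUE), function(d) {
    data.frame(group = d$group[1], category = d$category[1],
               n_specimens = nrow(d), mean_pct = mean(d$pct),
               sem_pct = if (nrow(d) > 1)
                 stats::sd(d$pct) / sqrt(nrow(d)) else NA_real_)
  }))
  rownames(per_group) <- NULL
  structure(list(per_specimen = per_specimen, per_group = per_group),
            class = "event_counts")
}

#' Compare event frequencies between two groups
#'
#' Two-sided Fisher exact test on the pooled events-vs-rest contingency
#' table — the conservative default for sparse cytogenetic event counts —
#' with the difference of pooled percentages as the effect size.
#'
#' @param events_a,total_a pooled event and chromosome counts, group A.
#' @param events_b,total_b same for group B.
#' @return list with `p_value`, `effect_pct` (percentage-point difference
#'   B - A), the pooled percentages, and `method`.
#' @export
compare_groups <- function(events_a, total_a, events_b, total_b) {
  stopifnot(total_a > 0, total_b > 0, events_a >= 0, events_b >= 0,
            events_a <= total_a, events_b <= total_b)
  tab <- matrix(c(events_a, total_a - events_a,
                  events_b, total_b - events_b), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  pct_a <- 100 * events_a / total_a
  pct_b <- 100 * events_b / total_b
  list(p_value = ft$p.value, effect_pct = pct_b - pct_a,
       pct_a = pct_a, pct_b = pct_b,
       method = "two-sided Fisher exact test on pooled counts")
}

#' Write / read a CO-FISH record table as TSV
#'
#' @param records record data frame.
#' @param path file path.
#' @return `write_cofish_table` returns `path` invisibly;
#'   `read_cofish_table` returns the data frame.
#' @export
write_cofish_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cofish_table
#' @export
read_cofish_table <- function(path) {
  utils::read.delim(path, sep = "\t")
}
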