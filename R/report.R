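#' Round half away from zero
#'
#' Display rounding for frequency tables: exact halves round up
#' (`0.05 -> 0.1` at one decimal), unlike R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' Event frequency as a percentage
#'
#' Raw percentage of abnormal events per chromosome scored,
#' `100 * events / total`. Display rounding is applied separately (see
#' [round_half_up()]) and never feeds back into computation.
#'
#' @param events event count, `0 <= events <= total`.
#' @param total total chromosomes scored, > 0.
#' @return the raw percentage (numeric).
#' @export
frequency <- function(events, total) {
  stopifnot(length(events) == length(total))
  if (any(total <= 0)) stop("total chromosomes scored must be positive")
  if (any(events < 0 | events > total))
    stop("events must lie in [0, total]")
  100 * events / total
}

#' Build a chromosomal/telomeric abnormality frequency report
#'
#' Produces the standard frequency table of cytogenetic abnormalities —
#' one row per (condition, genotype), one column set per event category —
#' with each cell carrying events, total, the raw percentage and a
#' half-up-rounded display value ("events/total shown in parentheses"
#' style). For every condition with exactly two genotypes, each category
#' is compared between them by [compare_groups()] and an asterisk is
#' rendered on the second genotype's cell when p < `alpha`.
#'
#' @param counts data frame with columns `condition`, `genotype`,
#'   `category`, `events`, `total`; each (condition, genotype) must supply
#'   every category appearing in `counts`.
#' @param decimals decimal places for the display percentage.
#' @param alpha significance threshold for the asterisk.
#' @return an `abnormality_report`: the input augmented with `pct` (raw),
#'   `display` (e.g. `"4.5% (38/846)"`), `p_value` and `significant`;
#'   attribute `method` records the test and threshold.
#' @export
build_report <- function(counts, decimals = 1, alpha = 0.05) {
  need <- c("condition", "genotype", "category", "events", "total")
  stopifnot(all(need %in% names(counts)))
  cats <- unique(counts$category)
  for (key in unique(paste(counts$condition, counts$genotype, sep = "||"))) {
    have <- counts$category[paste(counts$condition, counts$genotype,
                                  sep = "||") == key]
    missing <- setdiff(cats, have)
    if (length(missing))
      stop("row '", key, "' is missing categories: ",
           paste(missing, collapse = ", "))
  }
  counts$pct <- frequency(counts$events, counts$total)
  counts$p_value <- NA_real_
  counts$significant <- FALSE
  for (cond in unique(counts$condition)) {
    rows <- counts$condition == cond
    gts <- unique(counts$genotype[rows])
    if (length(gts) != 2) next
    for (cat in cats) {
      i_a <- which(rows & counts$genotype == gts[1] & counts$category == cat)
      i_b <- which(rows & counts$genotype == gts[2] & counts$category == cat)
      cmp <- compare_groups(counts$events[i_a], counts$total[i_a],
                            counts$events[i_b], counts$total[i_b])
      counts$p_value[c(i_a, i_b)] <- cmp$p_value
      counts$significant[i_b] <- cmp$p_value < alpha
    }
  }
  counts$display <- sprintf("%s%% (%d/%d)%s",
                            formatC(round_half_up(counts$pct, decimals),
                                    format = "f", digits = decimals),
                            counts$events, counts$total,
                            ifelse(counts$significant, "*", ""))
  structure(counts, class = c("abnormality_report", "data.frame"),
            method = sprintf(
              "two-sided Fisher exact test per category; * p < %g", alpha))
}

#' Aggregate lesion estimates into a fold-change table
#'
#' Normalizes replicate lesion estimates to a control sample, replicate by
#' replicate, and reports the per-sample mean fold change with n and SD.
#' The control row is exactly 1. If the control's lesion estimate is not
#' positive in some replicate, normalization is impossible and the
#' unnormalized lesion values are returned with a warning.
#'
#' @param estimates data frame with columns `sample_id`, `replicate` and
#'   `lesions_per_fragment` (one row per sample x replicate).
#' @param control_id the sample to normalize against; must be present.
#' @return data frame with `sample_id`, `n`, `mean_fold`, `sd_fold` in the
#'   input's sample order (control first retained as given). When
#'   normalization fails, columns are `mean_lesions`/`sd_lesions` instead.
#' @export
aggregate_lesions <- function(estimates, control_id) {
  need <- c("sample_id", "replicate", "lesions_per_fragment")
  stopifnot(all(need %in% names(estimates)))
  if (!control_id %in% estimates$sample_id)
    stop("control '", control_id, "' not found among samples")
  samples <- unique(estimates$sample_id)
  ctrl <- estimates[estimates$sample_id == control_id, ]
  if (any(ctrl$lesions_per_fragment <= 0)) {
    warning("control lesion estimate not positive in every replicate; ",
            "returning unnormalized lesion values")
    out <- do.call(rbind, lapply(samples, function(s) {
      x <- estimates$lesions_per_fragment[estimates$sample_id == s]
      data.frame(sample_id = s, n = length(x), mean_lesions = mean(x),
                 sd_lesions = if (length(x) > 1) stats::sd(x) else NA_real_)
    }))
    rownames(out) <- NULL
    return(out)
  }
  out <- do.call(rbind, lapply(samples, function(s) {
    d <- estimates[estimates$sample_id == s, ]
    ref <- ctrl$lesions_per_fragment[match(d$replicate, ctrl$replicate)]
    if (any(is.na(ref)))
      stop("sample '", s, "' has replicates without a matching control")
    fold <- d$lesions_per_fragment / ref
    data.frame(sample_id = s, n = length(fold), mean_fold = mean(fold),
               sd_fold = if (length(fold) > 1) stats::sd(fold) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Published abnormality counts fixture
#'
#' Event/total counts of chromosome fragments & breaks, end-to-end fusions
#' and telomere signal-free ends scored by metaphase Q-FISH in wild-type
#' and Ogg1-null mouse bone marrow cells and primary MEFs under different
#' oxidative conditions. Shipped as a plain-text input for the frequency
#' report.
#'
#' @return data frame with `condition`, `genotype`, `category`, `events`,
#'   `total` and the printed decimals per cell (`decimals`).
#' @export
abnormality_counts <- function() {
  utils::read.delim(system.file("extdata", "abnormality_counts.tsv",
                                package = "telodamage"),
                    sep = "\t")
}

#' Write a report (or any table) as TSV, Markdown and JSON
#'
#' @param report a data frame.
#' @param path_prefix output path without extension; `.tsv`, `.md` and
#'   `.json` files are written next to each other.
#' @return invisibly, the three paths.
#' @export
write_report <- function(report, path_prefix) {
  d <- as.data.frame(report)
  tsv <- paste0(path_prefix, ".tsv")
  md <- paste0(path_prefix, ".md")
  js <- paste0(path_prefix, ".json")
  utils::write.table(d, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  fmt <- vapply(d, function(col) as.character(col), character(nrow(d)))
  if (nrow(d) == 1) fmt <- matrix(fmt, nrow = 1)
  lines <- c(paste0("| ", paste(names(d), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|"),
             apply(fmt, 1, function(r)
               paste0("| ", paste(r, collapse = " | "), " |")))
  meth <- attr(report, "method")
  if (!is.null(meth)) lines <- c(lines, "", meth)
  writeLines(lines, md)
  jsonlite::write_json(d, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, md = md, json = js))
}
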