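#' Assign detected spots to chromosome ends and call signal-free ends
#'
#' Each spot is assigned to its nearest end anchor if that anchor lies
#' within the capture radius; per (end, channel) the closest such spot wins
#' (ties broken by larger intensity). Ends left without a spot are called
#' signal-free (SFE). Spots with no anchor in range stay unassigned and are
#' returned in an attribute for QC.
#'
#' @param spots a spot table from [detect_spots()] (0-based `row`, `col`,
#'   `channel`, `intensity`).
#' @param templates data frame of end anchors with columns `chromosome`,
#'   `end`, `row`, `col` (as in [sim_metaphase()]`$templates`; 0-based).
#' @param capture_radius maximum anchor-to-spot distance in pixels;
#'   default 6 (twice a 3 px expected spot radius).
#' @param channels probe channels to score; defaults to those present in
#'   `spots`.
#' @return an end-call table: data frame with one row per
#'   (chromosome, end, channel): `status` (`"signal"` or `"SFE"`) and
#'   `intensity` (`NA` for SFE). Attribute `unassigned` holds the leftover
#'   spots.
#' @export
assign_spots <- function(spots, templates, capture_radius = 6,
                         channels = unique(spots$channel)) {
  stopifnot(all(c("chromosome", "end", "row", "col") %in% names(templates)))
  if (length(channels) == 0) channels <- "telo"
  calls <- expand.grid(chromosome = unique(templates$chromosome),
                       end = 1:4, channel = channels,
                       stringsAsFactors = FALSE)
  calls <- calls[order(calls$channel, calls$chromosome, calls$end), ]
  rownames(calls) <- NULL
  calls$status <- "SFE"
  calls$intensity <- NA_real_
  unassigned <- spots[0, , drop = FALSE]

  for (ch in channels) {
    sp <- spots[spots$channel == ch, , drop = FALSE]
    if (nrow(sp) == 0) next
    d <- outer(sp$row, templates$row, "-")^2 +
      outer(sp$col, templates$col, "-")^2
    nearest <- max.col(-d, ties.method = "first")
    dist2 <- d[cbind(seq_len(nrow(sp)), nearest)]
    in_range <- dist2 <= capture_radius^2
    unassigned <- rbind(unassigned, sp[!in_range, , drop = FALSE])
    sp <- sp[in_range, , drop = FALSE]
    nearest <- nearest[in_range]
    dist2 <- dist2[in_range]
    if (nrow(sp) == 0) next
    # per anchor keep nearest spot, ties to the brighter one
    ord <- order(nearest, dist2, -sp$intensity)
    first <- !duplicated(nearest[ord])
    winners <- ord[first]
    anchors <- nearest[winners]
    key <- paste(templates$chromosome[anchors], templates$end[anchors], ch)
    row_i <- match(key, paste(calls$chromosome, calls$end, calls$channel))
    calls$status[row_i] <- "signal"
    calls$intensity[row_i] <- sp$intensity[winners]
    extras <- ord[!first]
    unassigned <- rbind(unassigned, sp[extras, , drop = FALSE])
  }
  structure(calls, unassigned = unassigned)
}

#' Summarize per-end telomere signal intensities
#'
#' Normalized intensity histogram (frequencies of telomeres within a given
#' intensity range, arbitrary units) plus box-plot statistics, the standard
#' Q-FISH presentation of a telomere-length distribution.
#'
#' @param calls an end-call table from [assign_spots()], or any data frame
#'   with `status` and `intensity` columns.
#' @param n_bins number of histogram bins.
#' @return list with `breaks`, `freq` (sums to 1), `summary` (min, q1,
#'   median, q3, max), `mean` and `n` (number of signal ends).
#' @export
summarize_intensities <- function(calls, n_bins = 30) {
  x <- calls$intensity[calls$status == "signal"]
  if (length(x) == 0) stop("no signal ends to summarize")
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(breaks = h$breaks, freq = h$counts / length(x),
       summary = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                   max = q[5]),
       mean = mean(x), n = length(x))
}

#' Classify two-colour G-/C-strand telomere loss per chromatid
#'
#' Joins G-strand and C-strand end calls on (chromosome, end) — each end
#' being one chromatid telomere — and scores: both present = `normal`, only
#' the G-strand signal missing = `g_loss`, only the C-strand missing =
#' `c_loss`, both missing = `both_loss` (sister telomere loss of that
#' chromatid). Probe convention: the (CCCTAA)3 probe hybridizes to and
#' therefore measures the G-rich strand; the (TTAGGG)3 probe measures the
#' C-rich strand.
#'
#' @param calls_g end-call table of the G-strand channel.
#' @param calls_c end-call table of the C-strand channel.
#' @return data frame with `chromosome`, `end` and `category` (factor with
#'   levels normal, g_loss, c_loss, both_loss). Chromatids scored in only
#'   one channel are excluded and counted in attribute `n_unscored`.
#' @export
classify_two_color <- function(calls_g, calls_c) {
  key_g <- paste(calls_g$chromosome, calls_g$end)
  key_c <- paste(calls_c$chromosome, calls_c$end)
  common <- intersect(key_g, key_c)
  n_unscored <- length(union(key_g, key_c)) - length(common)
  g <- calls_g[match(common, key_g), ]
  c_ <- calls_c[match(common, key_c), ]
  g_present <- g$status == "signal"
  c_present <- c_$status == "signal"
  category <- ifelse(g_present & c_present, "normal",
              ifelse(!g_present & c_present, "g_loss",
              ifelse(g_present & !c_present, "c_loss", "both_loss")))
  structure(data.frame(chromosome = g$chromosome, end = g$end,
                       category = factor(category,
                                         levels = c("normal", "g_loss",
                                                    "c_loss", "both_loss"))),
            n_unscored = n_unscored)
}

#' Score colocalization of DNA-damage foci with telomere signals
#'
#' A focus colocalizes when its nearest telomere spot centre in the same
#' cell lies within `max_dist` pixels — the image-analysis criterion for a
#' telomere dysfunction-induced focus (TIF). Cells are binned by their
#' focus count (1–3 vs >3 by default); cells without foci carry no defined
#' fraction and are excluded with a QC count.
#'
#' @param foci spot table of damage foci with a `cell` column.
#' @param telomeres spot table of telomere signals with a `cell` column.
#' @param max_dist colocalization distance in pixels.
#' @param count_breaks breakpoints for the per-cell focus-count bins.
#' @return list with `per_focus` (each focus with `colocalized` flag),
#'   `per_cell` (focus count, colocalized fraction, count bin),
#'   `fraction_colocalized` (over all foci) and `n_cells_excluded`.
#' @export
colocalize_foci <- function(foci, telomeres, max_dist = 3,
                            count_breaks = c(0, 3, Inf)) {
  stopifnot("cell" %in% names(foci), "cell" %in% names(telomeres))
  all_cells <- unique(c(foci$cell, telomeres$cell))
  n_excluded <- length(setdiff(all_cells, unique(foci$cell)))
  if (nrow(foci) == 0) stop("no foci to score")
  coloc <- vapply(seq_len(nrow(foci)), function(i) {
    tel <- telomeres[telomeres$cell == foci$cell[i], , drop = FALSE]
    if (nrow(tel) == 0) return(FALSE)
    min((tel$row - foci$row[i])^2 + (tel$col - foci$col[i])^2) <=
      max_dist^2
  }, logical(1))
  per_focus <- cbind(foci, colocalized = coloc)
  agg <- stats::aggregate(colocalized ~ cell, per_focus,
                          function(z) c(n = length(z), frac = mean(z)))
  per_cell <- data.frame(cell = agg$cell,
                         n_foci = agg$colocalized[, "n"],
                         fraction = agg$colocalized[, "frac"])
  lo <- utils::head(count_breaks, -1)
  hi <- utils::tail(count_breaks, -1)
  labels <- ifelse(is.infinite(hi), paste0(">", lo), paste0(lo + 1, "-", hi))
  per_cell$bin <- cut(per_cell$n_foci, count_breaks, labels = labels)
  list(per_focus = per_focus, per_cell = per_cell,
       fraction_colocalized = mean(coloc),
       n_cells_excluded = n_excluded)
}

#' Simulate damage foci around telomere positions
#'
#' Places `n_foci` foci in a cell: with probability `coloc_prob` a focus
#' lands on a randomly chosen telomere (jittered within half the
#' colocalization distance), otherwise at a position farther than twice
#' that distance from every telomere.
#'
#' @param telomeres spot table of telomere positions (needs `row`, `col`).
#' @param n_foci number of foci.
#' @param coloc_prob true colocalization probability.
#' @param dim image extent `c(rows, cols)`.
#' @param max_dist colocalization distance the scorer will use.
#' @param cell cell identifier stored in the output.
#' @param seed integer seed.
#' @return spot table of foci with a logical `true_colocalized` column.
#' @export
sim_foci <- function(telomeres, n_foci, coloc_prob, dim = c(512, 512),
                     max_dist = 3, cell = 1L, seed = 1L) {
  stopifnot(nrow(telomeres) >= 1, coloc_prob >= 0, coloc_prob <= 1)
  with_seed(seed, {
    is_coloc <- runif(n_foci) < coloc_prob
    row <- col <- numeric(n_foci)
    for (i in seq_len(n_foci)) {
      if (is_coloc[i]) {
        j <- sample.int(nrow(telomeres), 1)
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, max_dist / 2)
        row[i] <- telomeres$row[j] + rad * cos(ang)
        col[i] <- telomeres$col[j] + rad * sin(ang)
      } else {
        repeat {
          r <- runif(1, 0, dim[1] - 1)
          c_ <- runif(1, 0, dim[2] - 1)
          if (min((telomeres$row - r)^2 + (telomeres$col - c_)^2) >
              (2 * max_dist)^2) break
        }
        row[i] <- r
        col[i] <- c_
      }
    }
    data.frame(cell = cell, row = row, col = col, channel = "focus",
               intensity = 1, true_colocalized = is_coloc)
  })
}
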