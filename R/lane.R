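#' Default densitometry size grid
#'
#' Geometric size bins covering the usable range of an alkaline agarose
#' telomere gel, largest size first, mirroring a molecular-weight ladder
#' read from the top of the lane down.
#'
#' @param max_kb largest bin size (top of gel), kb.
#' @param min_kb smallest bin size (bottom of gel), kb.
#' @param n_bins number of bins.
#' @return numeric vector of bin centre sizes in kb, strictly decreasing.
#' @export
lane_grid <- function(max_kb = 48.5, min_kb = 0.5, n_bins = 60) {
  stopifnot(max_kb > min_kb, min_kb > 0, n_bins >= 2)
  exp(seq(log(max_kb), log(min_kb), length.out = n_bins))
}

#' Construct a digitized Southern lane profile
#'
#' A lane profile is the grid measurement of a gel lane: ordered
#' (molecular size, optical density) pairs, sizes strictly decreasing from
#' the top of the gel.
#'
#' @param size_kb bin sizes in kb, strictly decreasing, all > 0.
#' @param od optical densities, all >= 0, at least one > 0.
#' @param lane_id identifier string.
#' @param treatment `"mock"` or `"fpg"`.
#' @return a `lane_profile` data frame with columns `size_kb`, `od` and
#'   attributes `lane_id`, `treatment`.
#' @export
lane_profile <- function(size_kb, od, lane_id = "lane", treatment = "mock") {
  stopifnot(length(size_kb) == length(od), length(size_kb) >= 1,
            all(size_kb > 0), all(diff(size_kb) < 0),
            all(od >= 0), any(od > 0))
  treatment <- match.arg(treatment, c("mock", "fpg"))
  structure(data.frame(size_kb = as.numeric(size_kb), od = as.numeric(od)),
            class = c("lane_profile", "data.frame"),
            lane_id = lane_id, treatment = treatment)
}

# Bin edges for a (decreasing) grid of bin centres: geometric midpoints,
# outer edges open (+/- Inf) so every fragment lands somewhere, as on a gel
# where material beyond the ladder piles at the well or runs off the bottom.
lane_grid_edges <- function(grid) {
  asc <- rev(grid)                          # ascending sizes
  mids <- sqrt(asc[-1] * asc[-length(asc)]) # geometric midpoints
  c(-Inf, mids, Inf)
}

#' Half bin width of a lane grid at a given size
#'
#' Discretization scale of the densitometry grid, used to bound the error of
#' grid-based mean-length estimates.
#'
#' @param grid decreasing vector of bin centre sizes (kb).
#' @param at size (kb) at which to evaluate.
#' @return half the local bin width in kb.
#' @export
half_bin_width <- function(grid, at) {
  asc <- rev(grid)
  i <- which.min(abs(asc - at))
  lo <- if (i == 1) asc[1] / sqrt(asc[2] / asc[1]) else sqrt(asc[i - 1] * asc[i])
  hi <- if (i == length(asc)) asc[i] * sqrt(asc[i] / asc[i - 1])
        else sqrt(asc[i] * asc[i + 1])
  (hi - lo) / 2
}

#' Render a fragment population as a densitometer lane profile
#'
#' Deposits each fragment's probe-signal weight into the size bin containing
#' its length, optionally diffusing it over neighbouring bins with a Gaussian
#' band-spread kernel (in kb), then adds Gaussian densitometer noise and
#' clips at zero.
#'
#' @param pop a `fragment_population`; must be non-empty.
#' @param grid decreasing vector of bin centre sizes (kb); see [lane_grid()].
#' @param blur_sigma band spread in kb (>= 0). Default 1 kb.
#' @param noise_sd densitometer noise SD in OD units. `NULL` (default) uses
#'   1% of the peak noiseless OD; `0` disables noise.
#' @param seed integer seed for the noise draw.
#' @param lane_id,treatment metadata passed to [lane_profile()].
#' @return a `lane_profile` on `grid`.
#' @export
render_lane <- function(pop, grid = lane_grid(), blur_sigma = 1,
                        noise_sd = NULL, seed = 1L,
                        lane_id = "lane", treatment = "mock") {
  stopifnot(inherits(pop, "fragment_population"), nrow(pop) >= 1,
            all(diff(grid) < 0), blur_sigma >= 0)
  edges <- lane_grid_edges(grid)           # ascending, length n+1
  n <- length(grid)
  if (blur_sigma == 0) {
    idx <- findInterval(pop$length_kb, edges, rightmost.closed = FALSE)
    od_asc <- vapply(seq_len(n),
                     function(b) sum(pop$weight[idx == b]), numeric(1))
  } else {
    # mass of each fragment's Gaussian band falling in each bin
    od_asc <- numeric(n)
    P <- outer(edges, pop$length_kb,
               function(e, l) pnorm(e, mean = l, sd = blur_sigma))
    mass <- P[-1, , drop = FALSE] - P[-(n + 1), , drop = FALSE]
    od_asc <- as.numeric(mass %*% pop$weight)
  }
  od <- rev(od_asc)                        # back to decreasing-size order
  if (is.null(noise_sd)) noise_sd <- 0.01 * max(od)
  if (noise_sd > 0) {
    od <- od + with_seed(seed, rnorm(n, 0, noise_sd))
    od <- pmax(od, 0)
  }
  if (all(od == 0)) stop("rendered lane has no signal")
  lane_profile(grid, od, lane_id = lane_id, treatment = treatment)
}

#' Write / read a lane profile as TSV
#'
#' Plain-text interchange format: `#`-prefixed metadata header lines
#' (`lane_id`, `treatment`), then tab-separated `size_kb` and `od` columns.
#'
#' @param profile a `lane_profile`.
#' @param path file path.
#' @return `write_lane_profile` returns `path` invisibly;
#'   `read_lane_profile` returns a `lane_profile`.
#' @export
write_lane_profile <- function(profile, path) {
  stopifnot(inherits(profile, "lane_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# lane_id=", attr(profile, "lane_id")),
               paste0("# treatment=", attr(profile, "treatment"))), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lane_profile
#' @export
read_lane_profile <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  lane_profile(tab$size_kb, tab$od,
               lane_id = get_meta("lane_id"),
               treatment = get_meta("treatment"))
}
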