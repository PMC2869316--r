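#' Detect fluorescent spots in one image channel
#'
#' Blob detection at a single expected scale. Candidates are local maxima
#' of a zero-mean, negated Laplacian-of-Gaussian response. Each candidate's
#' peak amplitude above background is then estimated efficiently as the
#' sub-pixel-interpolated maximum of a zero-mean matched-Gaussian
#' correlation map (the least-squares amplitude estimate under a locally
#' constant background), and the candidate is retained when that amplitude
#' exceeds `threshold_k` times the raw median absolute deviation of the
#' channel — i.e. its peak stands `threshold_k` MADs above the channel
#' median, which makes detection invariant to constant offsets and
#' equivariant under intensity scaling.
#'
#' Integrated intensity is the pixel sum over a disc footprint around the
#' spot minus the local background (median of a surrounding annulus) times
#' the footprint area, floored at zero.
#'
#' @param img numeric matrix (one channel).
#' @param expected_radius expected spot radius in pixels (>= 1);
#'   the Gaussian spot SD is taken as `expected_radius / 2`.
#' @param threshold_k detection threshold in MADs above the median
#'   (default 6).
#' @param channel channel label stored in the output.
#' @return a spot table: data frame with columns `row`, `col` (0-based
#'   pixel coordinates), `channel`, `intensity` (integrated,
#'   background-corrected, >= 0) and `response` (estimated peak amplitude).
#'   Empty or constant images yield an empty table.
#' @export
detect_spots <- function(img, expected_radius = 3, threshold_k = 6,
                         channel = "telo") {
  stopifnot(is.matrix(img), expected_radius >= 1)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      channel = character(0), intensity = numeric(0),
                      response = numeric(0))
  noise <- stats::mad(img, constant = 1)   # raw median absolute deviation
  if (noise == 0) return(empty)

  sigma <- expected_radius / 2
  resp <- log_response(img, sigma)
  amp <- matched_amplitude(img, sigma)
  thr <- threshold_k * noise

  # strict local maxima over the 8-neighbourhood, away from the border
  nr <- nrow(resp); nc <- ncol(resp)
  is_max <- matrix(FALSE, nr, nc)
  core_r <- 2:(nr - 1); core_c <- 2:(nc - 1)
  m <- resp[core_r, core_c]
  is_max[core_r, core_c] <-
    m > resp[core_r - 1, core_c - 1] & m > resp[core_r - 1, core_c] &
    m > resp[core_r - 1, core_c + 1] & m > resp[core_r, core_c - 1] &
    m > resp[core_r, core_c + 1] & m > resp[core_r + 1, core_c - 1] &
    m > resp[core_r + 1, core_c] & m > resp[core_r + 1, core_c + 1] &
    m > 0.5 * thr                     # permissive candidate gate; final
                                      # retention uses the amplitude estimate
  b <- ceiling(2 * expected_radius)   # exclude a filter-artefact border
  if (nr > 2 * b && nc > 2 * b) {
    is_max[c(seq_len(b), (nr - b + 1):nr), ] <- FALSE
    is_max[, c(seq_len(b), (nc - b + 1):nc)] <- FALSE
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)

  # merge maxima closer than the expected radius, keeping the stronger
  val <- resp[idx]
  ord <- order(val, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  val <- val[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1):nrow(idx)
      d2 <- (idx[later, 1] - idx[i, 1])^2 + (idx[later, 2] - idx[i, 2])^2
      keep[later][d2 <= expected_radius^2] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]

  # the retained peak estimate is the sub-pixel-interpolated maximum of the
  # matched-Gaussian amplitude map — an efficient, unbiased estimate of the
  # spot's peak height above background
  val <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    if (r > 1 && c > 1 && r < nrow(amp) && c < ncol(amp)) {
      sub <- amp[(r - 1):(r + 1), (c - 1):(c + 1)]
      w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      r <- r + w[1] - 2L
      c <- c + w[2] - 2L
    }
    peak_interp(amp, r, c)
  }, numeric(1))
  above <- val > thr
  idx <- idx[above, , drop = FALSE]
  val <- val[above]
  if (nrow(idx) == 0) return(empty)

  # sub-pixel centre: response-weighted centroid over the 3x3 neighbourhood
  ctr <- t(vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    w <- pmax(resp[(r - 1):(r + 1), (c - 1):(c + 1)], 0)
    if (sum(w) == 0) return(c(r, c))
    c(sum((r + (-1:1)) * rowSums(w)) / sum(w),
      sum((c + (-1:1)) * colSums(w)) / sum(w))
  }, numeric(2)))

  inten <- vapply(seq_len(nrow(idx)), function(i) {
    integrate_spot(img, idx[i, 1], idx[i, 2], expected_radius,
                   others = idx[-i, , drop = FALSE])
  }, numeric(1))

  # report 0-based coordinates
  data.frame(row = ctr[, 1] - 1, col = ctr[, 2] - 1,
             channel = channel, intensity = inten, response = val)
}

# Matched-filter response: convolve with zero-mean -LoG at scale `sigma`,
# scaled so a unit-peak Gaussian spot of SD `sigma` gives response 1.
log_response <- function(img, sigma) {
  r <- ceiling(4 * sigma)
  x <- (-r):r
  g1 <- exp(-x^2 / (2 * sigma^2))
  G <- outer(g1, g1)
  d2 <- outer(x^2, x^2, "+")
  K <- (d2 / sigma^4 - 2 / sigma^2) * G     # Laplacian of Gaussian
  K <- -K
  K <- K - mean(K)                          # exact offset invariance
  K <- K / sum(K * G)                       # unit response to matched spot
  EBImage::filter2(img, K, boundary = "replicate")
}

# Matched-Gaussian amplitude map: correlation with a zero-mean Gaussian
# template, normalized so the response to a unit-peak spot of SD `sigma`
# equals 1. The least-squares (hence minimum-variance linear) estimate of
# peak height above a locally constant background.
matched_amplitude <- function(img, sigma) {
  r <- ceiling(4 * sigma)
  x <- (-r):r
  g1 <- exp(-x^2 / (2 * sigma^2))
  G <- outer(g1, g1)
  K <- G - mean(G)
  K <- K / sum(K * G)
  EBImage::filter2(img, K, boundary = "replicate")
}

# Quadratic sub-pixel interpolation of a local maximum of `m` at (r0, c0):
# separable three-point parabola per axis, clamped to the 3x3 patch.
peak_interp <- function(m, r0, c0) {
  if (r0 <= 1 || c0 <= 1 || r0 >= nrow(m) || c0 >= ncol(m))
    return(m[r0, c0])
  f0 <- m[r0, c0]
  corr <- 0
  for (d in list(c(1, 0), c(0, 1))) {
    fm <- m[r0 - d[1], c0 - d[2]]
    fp <- m[r0 + d[1], c0 + d[2]]
    den <- 2 * f0 - fp - fm
    if (den > 0) corr <- corr + (fp - fm)^2 / (8 * den)
  }
  f0 + corr
}

# Background-corrected integrated intensity over a disc footprint. Annulus
# pixels lying within a footprint of any *other* detected spot are masked
# so neighbouring chromatid telomeres do not inflate the local background.
integrate_spot <- function(img, r0, c0, radius, others = NULL) {
  fp_r <- ceiling(radius * 5 / 3)           # captures >99.5% of the spot
  an_r <- fp_r + c(2L, 5L)
  span <- (-an_r[2]):an_r[2]
  rr <- r0 + span
  cc <- c0 + span
  ok_r <- rr >= 1 & rr <= nrow(img)
  ok_c <- cc >= 1 & cc <= ncol(img)
  patch <- img[rr[ok_r], cc[ok_c], drop = FALSE]
  d2 <- outer(span[ok_r]^2, span[ok_c]^2, "+")
  disc <- d2 <= fp_r^2
  annulus <- d2 > an_r[1]^2 & d2 <= an_r[2]^2
  if (!is.null(others) && nrow(others) > 0) {
    near <- others[abs(others[, 1] - r0) <= 2 * an_r[2] &
                     abs(others[, 2] - c0) <= 2 * an_r[2], , drop = FALSE]
    for (k in seq_len(nrow(near))) {
      dk <- outer((rr[ok_r] - near[k, 1])^2, (cc[ok_c] - near[k, 2])^2, "+")
      annulus <- annulus & dk > fp_r^2
    }
  }
  if (!any(annulus)) annulus <- d2 > an_r[1]^2 & d2 <= an_r[2]^2
  bg <- stats::median(patch[annulus])
  max(sum(patch[disc]) - bg * sum(disc), 0)
}

#' Check rigid channel registration by cross-correlation
#'
#' Estimates the translation between two channels from the peak of their
#' FFT cross-correlation and warns when it exceeds `tol` pixels. Channels
#' are assumed registered upstream; this is a guard, not a correction.
#'
#' @param a,b numeric matrices of equal size.
#' @param tol tolerated shift in pixels (default 2).
#' @return the estimated `c(row, col)` shift, invisibly.
#' @export
check_registration <- function(a, b, tol = 2) {
  stopifnot(all(dim(a) == dim(b)))
  fa <- stats::fft(a - mean(a))
  fb <- stats::fft(b - mean(b))
  xc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  shift <- ((pk - 1 + floor(dim(a) / 2)) %% dim(a)) - floor(dim(a) / 2)
  if (any(abs(shift) > tol))
    warning("channels appear misregistered by (", shift[1], ", ", shift[2],
            ") px; register upstream before quantification")
  invisible(shift)
}
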