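#' Simulate a metaphase-spread fluorescence image with known ground truth
#'
#' Builds a multi-channel 16-bit-range image emulating a Q-FISH metaphase
#' spread: a DAPI channel showing chromosome bodies (two sister chromatids
#' per chromosome) and one or two telomere-probe channels in which every
#' non-signal-free chromosome end carries one Gaussian spot whose integrated
#' intensity is drawn from a log-normal law (spot intensity is the Q-FISH
#' proxy for telomere length). A camera model adds Poisson shot noise plus
#' additive Gaussian read noise; SNR is defined as the mean spot peak
#' amplitude divided by the read-noise SD.
#'
#' Chromosomes are placed by rejection sampling so templates never overlap;
#' placement failing after `max_retry` proposals is an error (image too
#' crowded for `n_chrom`).
#'
#' @param n_chrom number of chromosomes (mouse metaphases have 40).
#' @param channels names of the telomere-probe channels, e.g. `"telo"` for
#'   single-probe Q-FISH or `c("telo_g", "telo_c")` for two-colour
#'   G-/C-strand hybridization.
#' @param mean_intensity mean integrated spot intensity, arbitrary units.
#' @param cv coefficient of variation of the log-normal intensity law.
#' @param sfe_fraction probability that a chromosome end is signal-free
#'   (no spot in any probe channel), in `[0, 1]`.
#' @param snr mean spot peak amplitude / read-noise SD (> 0).
#' @param dim image size `c(rows, cols)`.
#' @param spot_sigma Gaussian spot SD in pixels.
#' @param background uniform probe-channel background level (counts).
#' @param seed integer seed.
#' @param max_retry placement proposals before giving up.
#' @return a `synthetic_metaphase`: list with `image` (named list of
#'   numeric matrices: `dapi` plus one per probe channel), `truth` (data
#'   frame of ground-truth spots: chromosome, end, channel, row, col,
#'   intensity), `templates` (data frame of the 4 end anchor points per
#'   chromosome), and `params`.
#'
#' Coordinates are 0-based `(row, col)` with pixel centres at integer
#' positions, used consistently across the package.
#' @export
sim_metaphase <- function(n_chrom = 40, channels = "telo",
                          mean_intensity = 5000, cv = 0.35,
                          sfe_fraction = 0, snr = 10,
                          dim = c(512, 512), spot_sigma = 1.5,
                          background = 100, seed = 1L,
                          max_retry = 5000) {
  stopifnot(n_chrom >= 1, length(channels) >= 1,
            mean_intensity > 0, cv >= 0,
            sfe_fraction >= 0, sfe_fraction <= 1, snr > 0)
  # template geometry (pixels): two chromatids 10 px apart, telomere anchors
  # 34 px apart along each chromatid
  chromatid_dx <- 5
  anchor_dy <- 17
  body_halfwidth <- 2.5
  body_halfheight <- 19
  pad <- 8                                  # min gap between bounding boxes
  margin <- 30

  out <- with_seed(seed, {
    # --- non-overlapping placement ---------------------------------------
    centers <- matrix(NA_real_, n_chrom, 2)
    placed <- 0L
    tries <- 0L
    bw <- 2 * (chromatid_dx + body_halfwidth) + pad   # box width + gap
    bh <- 2 * body_halfheight + pad
    while (placed < n_chrom) {
      tries <- tries + 1L
      if (tries > max_retry)
        stop("could not place ", n_chrom,
             " non-overlapping chromosomes; reduce n_chrom or enlarge dim")
      cand <- c(runif(1, margin, dim[1] - margin),
                runif(1, margin, dim[2] - margin))
      ok <- placed == 0L ||
        all(abs(centers[seq_len(placed), 1] - cand[1]) > bh |
            abs(centers[seq_len(placed), 2] - cand[2]) > bw)
      if (ok) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }

    templates <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      data.frame(chromosome = i, end = 1:4,
                 row = centers[i, 1] + c(-1, -1, 1, 1) * anchor_dy,
                 col = centers[i, 2] + c(-1, 1, -1, 1) * chromatid_dx)
    }))

    # --- ground truth ----------------------------------------------------
    sfe <- matrix(runif(n_chrom * 4) < sfe_fraction, n_chrom, 4)
    truth <- expand.grid(chromosome = seq_len(n_chrom), end = 1:4,
                         channel = channels, stringsAsFactors = FALSE)
    truth <- truth[!sfe[cbind(truth$chromosome, truth$end)], , drop = FALSE]
    truth <- truth[order(truth$channel, truth$chromosome, truth$end), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    m <- merge(truth, templates, by = c("chromosome", "end"), sort = FALSE)
    truth$row <- m$row[match(paste(truth$chromosome, truth$end),
                             paste(m$chromosome, m$end))] +
      runif(nrow(truth), -0.5, 0.5)
    truth$col <- m$col[match(paste(truth$chromosome, truth$end),
                             paste(m$chromosome, m$end))] +
      runif(nrow(truth), -0.5, 0.5)
    sdlog <- sqrt(log(1 + cv^2))
    truth$intensity <- mean_intensity *
      rlnorm(nrow(truth), meanlog = -sdlog^2 / 2, sdlog = sdlog)

    # --- rendering -------------------------------------------------------
    peak_mean <- mean_intensity / (2 * pi * spot_sigma^2)
    read_sd <- peak_mean / snr
    render_channel <- function(ch) {
      img <- matrix(background, dim[1], dim[2])
      sub <- truth[truth$channel == ch, , drop = FALSE]
      r_k <- ceiling(4 * spot_sigma)
      for (i in seq_len(nrow(sub))) {
        r0 <- round(sub$row[i])
        c0 <- round(sub$col[i])
        rr <- max(0, r0 - r_k):min(dim[1] - 1, r0 + r_k)
        cc <- max(0, c0 - r_k):min(dim[2] - 1, c0 + r_k)
        g <- outer(exp(-(rr - sub$row[i])^2 / (2 * spot_sigma^2)),
                   exp(-(cc - sub$col[i])^2 / (2 * spot_sigma^2)))
        img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] +
          sub$intensity[i] * g / (2 * pi * spot_sigma^2)
      }
      img
    }
    dapi <- matrix(50, dim[1], dim[2])
    for (i in seq_len(n_chrom)) {
      for (s in c(-1, 1)) {
        rr <- max(0, round(centers[i, 1] - body_halfheight)):
          min(dim[1] - 1, round(centers[i, 1] + body_halfheight))
        cc <- max(0, round(centers[i, 2] + s * chromatid_dx -
                             body_halfwidth)):
          min(dim[2] - 1, round(centers[i, 2] + s * chromatid_dx +
                                  body_halfwidth))
        dapi[rr + 1, cc + 1] <- dapi[rr + 1, cc + 1] + 1500
      }
    }
    imgs <- c(list(dapi = dapi),
              stats::setNames(lapply(channels, render_channel), channels))
    imgs <- lapply(imgs, function(img) {
      noisy <- matrix(rpois(length(img), lambda = img), nrow(img)) +
        rnorm(length(img), 0, read_sd)
      pmin(pmax(noisy, 0), 65535)
    })
    list(imgs = imgs, truth = truth, templates = templates)
  })

  structure(list(image = out$imgs, truth = out$truth,
                 templates = out$templates,
                 params = list(n_chrom = n_chrom, channels = channels,
                               mean_intensity = mean_intensity, cv = cv,
                               sfe_fraction = sfe_fraction, snr = snr,
                               dim = dim, spot_sigma = spot_sigma,
                               background = background, seed = seed)),
            class = "synthetic_metaphase")
}

#' Write a synthetic metaphase to disk
#'
#' Saves the image stack as one 16-bit multi-page TIFF and the ground truth
#' and templates as JSON sidecar files.
#'
#' @param m a `synthetic_metaphase`.
#' @param dir output directory (created if absent).
#' @param name base file name.
#' @return invisibly, the TIFF path.
#' @export
write_metaphase <- function(m, dir, name = "metaphase") {
  stopifnot(inherits(m, "synthetic_metaphase"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(lapply(m$image, function(x) x / 65535), path,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(truth = m$truth, templates = m$templates,
                            params = m$params),
                       file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
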