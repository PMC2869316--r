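#' Simulate a population of telomeric restriction fragments
#'
#' Draws fragment lengths from a log-normal law, the standard model for the
#' broad, right-skewed telomere restriction fragment smears seen on mouse
#' Southern blots. Each fragment carries a probe-signal weight proportional
#' to its length: a telomere-repeat probe hybridizes along the whole tract,
#' so densitometric optical density is proportional to telomeric mass, not
#' to molecule count.
#'
#' @param n number of fragments (>= 1).
#' @param median_kb median fragment length in kb (> 0). Default 20 kb,
#'   typical of mouse telomeres.
#' @param sigma_log standard deviation of log-length (>= 0). `0` gives a
#'   degenerate population with every fragment at `median_kb`.
#' @param seed integer seed.
#' @return a `fragment_population`: data frame with columns `length_kb` and
#'   `weight` (probe-signal mass, equal to `length_kb` by construction).
#' @export
sim_fragments <- function(n, median_kb = 20, sigma_log = 0.35, seed = 1L) {
  stopifnot(n >= 1, median_kb > 0, sigma_log >= 0)
  lengths <- with_seed(seed, rlnorm(n, meanlog = log(median_kb),
                                    sdlog = sigma_log))
  fragment_population(lengths)
}

#' Construct a fragment population from explicit lengths
#'
#' @param length_kb fragment lengths in kb, all > 0.
#' @param weight probe-signal mass per fragment; defaults to `length_kb`.
#' @return a `fragment_population` data frame.
#' @export
fragment_population <- function(length_kb, weight = length_kb) {
  stopifnot(length(length_kb) >= 1, all(length_kb > 0),
            length(weight) == length(length_kb), all(weight >= 0))
  structure(data.frame(length_kb = as.numeric(length_kb),
                       weight = as.numeric(weight)),
            class = c("fragment_population", "data.frame"))
}

#' Place Fpg-incisable lesions along fragments
#'
#' Forward model for oxidized-guanine sites: each fragment receives a
#' Poisson(rate * length) number of lesions at positions uniform along its
#' length. This is the ground truth the paired mock/Fpg densitometry
#' estimator is later asked to recover.
#'
#' @param pop a `fragment_population`.
#' @param rate lesion density in lesions/kb (>= 0).
#' @param seed integer seed.
#' @return a `lesion_placement`: list of numeric vectors, one per fragment,
#'   holding lesion offsets in kb strictly inside `(0, length)`; attribute
#'   `rate` records the generating density.
#' @export
sim_lesions <- function(pop, rate, seed = 1L) {
  stopifnot(inherits(pop, "fragment_population"), rate >= 0)
  placement <- with_seed(seed, {
    counts <- rpois(nrow(pop), rate * pop$length_kb)
    lapply(seq_len(nrow(pop)), function(i) {
      if (counts[i] == 0L) return(numeric(0))
      sort(runif(counts[i], 0, pop$length_kb[i]))
    })
  })
  structure(placement, class = "lesion_placement", rate = rate)
}

#' Incise fragments at lesion sites
#'
#' Emulates Fpg glycosylase/AP-lyase treatment on an alkaline gel: every
#' lesion is independently converted into a single-strand cut with the given
#' efficiency, and each fragment is replaced by the sub-fragments between
#' realized cuts. Total DNA length is conserved exactly; probe-signal weight
#' is split in proportion to sub-fragment length.
#'
#' @param pop a `fragment_population`.
#' @param lesions a `lesion_placement` for `pop`.
#' @param efficiency probability that a lesion is incised, in `[0, 1]`.
#'   Default 1: complete digestion.
#' @param seed integer seed (used only when `efficiency` is in `(0, 1)`).
#' @return the digested `fragment_population`.
#' @export
digest_fragments <- function(pop, lesions, efficiency = 1, seed = 1L) {
  stopifnot(inherits(pop, "fragment_population"),
            inherits(lesions, "lesion_placement"),
            length(lesions) == nrow(pop),
            efficiency >= 0, efficiency <= 1)
  if (efficiency == 0) return(pop)
  cut_sets <- if (efficiency >= 1) {
    lesions
  } else {
    with_seed(seed, lapply(lesions, function(pos) {
      pos[runif(length(pos)) < efficiency]
    }))
  }
  out_len <- vector("list", nrow(pop))
  out_w <- vector("list", nrow(pop))
  for (i in seq_len(nrow(pop))) {
    cuts <- cut_sets[[i]]
    L <- pop$length_kb[i]
    pieces <- if (length(cuts) == 0L) L else diff(c(0, cuts, L))
    out_len[[i]] <- pieces
    out_w[[i]] <- pop$weight[i] * pieces / L
  }
  fragment_population(unlist(out_len), unlist(out_w))
}
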