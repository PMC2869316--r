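#' Mean telomere fragment length of a lane (centre of mass)
#'
#' The mean length of a digitized Southern lane is its densitometric centre
#' of mass, `ML = sum(MW_i * OD_i) / sum(OD_i)` in kb, where `MW_i` is the
#' molecular size at grid row i and `OD_i` the optical density there. The
#' value is invariant to global OD scaling (exposure, probe activity).
#'
#' @param profile a `lane_profile`.
#' @param window optional `c(min_kb, max_kb)` size window; only bins inside
#'   it contribute. Default `NULL`: the whole recorded lane.
#' @param baseline constant background OD subtracted from every bin before
#'   the computation (clipped at zero). Default 0.
#' @return mean length in kb.
#' @export
mean_length <- function(profile, window = NULL, baseline = 0) {
  stopifnot(inherits(profile, "lane_profile"), baseline >= 0)
  od <- pmax(profile$od - baseline, 0)
  size <- profile$size_kb
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    keep <- size >= window[1] & size <= window[2]
    od <- od[keep]
    size <- size[keep]
  }
  tot <- sum(od)
  if (length(od) == 0 || tot <= 0)
    stop("mean length undefined: no optical density in the evaluated bins")
  sum(size * od) / tot
}

#' Mass-weighted mean length of a fragment population
#'
#' The quantity the lane centre of mass estimates, computed directly on the
#' fragments: `sum(length * weight) / sum(weight)`. Used as the independent
#' reference for validating the densitometry path.
#'
#' @param pop a `fragment_population`.
#' @return mean length in kb.
#' @export
population_mean_length <- function(pop) {
  stopifnot(inherits(pop, "fragment_population"), sum(pop$weight) > 0)
  sum(pop$length_kb * pop$weight) / sum(pop$weight)
}

#' Estimate Fpg-sensitive lesions per fragment from a paired lane
#'
#' Fpg incision converts each lesion into a cut, so the mean fragment length
#' drops in proportion to the number of lesions per fragment:
#' `lesions = ML(mock) / ML(fpg) - 1`. Noise can drive the estimate slightly
#' negative; such values are reported raw and flagged, never clipped, so
#' replicate means stay unbiased.
#'
#' @param mock `lane_profile` of the mock-treated half of the sample.
#' @param fpg `lane_profile` of the Fpg-treated half.
#' @param ... passed on to [mean_length()] (window, baseline).
#' @return a `lesion_estimate`: list with `ml_mock`, `ml_fpg` (kb),
#'   `lesions_per_fragment`, and logical `flag_negative`.
#' @export
estimate_lesions <- function(mock, fpg, ...) {
  stopifnot(inherits(mock, "lane_profile"), inherits(fpg, "lane_profile"))
  fpg <- match_lane_grid(fpg, mock)
  ml_mock <- mean_length(mock, ...)
  ml_fpg <- mean_length(fpg, ...)
  lesions <- ml_mock / ml_fpg - 1
  structure(list(ml_mock = ml_mock, ml_fpg = ml_fpg,
                 lesions_per_fragment = lesions,
                 flag_negative = lesions < 0),
            class = "lesion_estimate")
}

# Put `profile` onto `target`'s grid. Identical grids pass through; grids
# whose bins differ by < 5% are linearly interpolated (same gel, slightly
# different ladder reads); anything larger is refused — silently resampling
# across different gels is unsafe.
match_lane_grid <- function(profile, target) {
  a <- profile$size_kb
  b <- target$size_kb
  if (length(a) == length(b) && all(a == b)) return(profile)
  if (length(a) != length(b) || any(abs(a - b) / b >= 0.05))
    stop("lane grids differ by more than 5%; re-digitize on a common grid")
  od <- stats::approx(x = a, y = profile$od, xout = b, rule = 2)$y
  lane_profile(b, od, lane_id = attr(profile, "lane_id"),
               treatment = attr(profile, "treatment"))
}

#' Fold change in lesion load versus a control sample
#'
#' Normalizes a sample's lesions-per-fragment to a control's, so the control
#' takes the value 1 against itself.
#'
#' @param sample,control `lesion_estimate` objects.
#' @return dimensionless fold change.
#' @export
fold_change <- function(sample, control) {
  stopifnot(inherits(sample, "lesion_estimate"),
            inherits(control, "lesion_estimate"))
  if (control$lesions_per_fragment <= 0)
    stop("control lesion estimate is not positive; ",
         "report unnormalized lesions_per_fragment instead")
  sample$lesions_per_fragment / control$lesions_per_fragment
}

#' Lesion density per kb
#'
#' Converts lesions per fragment into lesions per kb of telomeric DNA using
#' the undigested mean length, for comparison against a simulated lesion
#' density.
#'
#' @param est a `lesion_estimate`.
#' @return lesions per kb.
#' @export
lesions_per_kb <- function(est) {
  stopifnot(inherits(est, "lesion_estimate"))
  est$lesions_per_fragment / est$ml_mock
}

#' Simulate one complete paired-lane lesion experiment
#'
#' Convenience wrapper chaining fragment simulation, lesion placement,
#' digestion and lane rendering into a (mock, fpg) profile pair, the unit a
#' dose-response or fold-change experiment is built from.
#'
#' @param n number of fragments.
#' @param rate lesion density, lesions/kb.
#' @param median_kb,sigma_log fragment length law, see [sim_fragments()].
#' @param efficiency Fpg incision efficiency.
#' @param blur_sigma,noise_sd lane rendering parameters, see [render_lane()].
#' @param grid densitometry grid.
#' @param seed master seed; sub-streams are derived with [child_seed()].
#' @return list with `mock` and `fpg` lane profiles and the two underlying
#'   populations (`pop_mock`, `pop_fpg`) for oracle checks.
#' @export
sim_lane_pair <- function(n = 10000, rate = 0.05, median_kb = 20,
                          sigma_log = 0.35, efficiency = 1,
                          blur_sigma = 1, noise_sd = NULL,
                          grid = lane_grid(), seed = 1L) {
  pop <- sim_fragments(n, median_kb, sigma_log, seed = child_seed(seed, 1))
  les <- sim_lesions(pop, rate, seed = child_seed(seed, 2))
  cut <- digest_fragments(pop, les, efficiency, seed = child_seed(seed, 3))
  list(
    mock = render_lane(pop, grid, blur_sigma, noise_sd,
                       seed = child_seed(seed, 4), treatment = "mock"),
    fpg = render_lane(cut, grid, blur_sigma, noise_sd,
                      seed = child_seed(seed, 5), treatment = "fpg"),
    pop_mock = pop, pop_fpg = cut
  )
}
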