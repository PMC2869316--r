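# Match detected spots to ground-truth positions within `tol` pixels and
# return recall/precision plus the matched index map.
match_spots <- function(spots, truth, tol = 2) {
  if (nrow(spots) == 0)
    return(list(recall = 0, precision = NA_real_,
                nearest = integer(0), matched = logical(0)))
  d2 <- outer(spots$row, truth$row, "-")^2 +
    outer(spots$col, truth$col, "-")^2
  matched <- apply(d2, 1, min) <= tol^2
  list(recall = mean(apply(d2, 2, min) <= tol^2),
       precision = mean(matched),
       nearest = apply(d2, 1, which.min),
       matched = matched)
}

# Two-sided binomial confidence bounds on a realized proportion.
binom_ci <- function(p, n, level = 0.99) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(p - z * se, p + z * se)
}

# One full quantification pass over a synthetic metaphase channel.
quantify_channel <- function(m, channel = "telo", threshold_k = 6) {
  sp <- detect_spots(m$image[[channel]], expected_radius = 3,
                     threshold_k = threshold_k, channel = channel)
  assign_spots(sp, m$templates, channels = channel)
}
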