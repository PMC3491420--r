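#' Fragment size-selection models
#'
#' Two retention models connect the digest to the sequencing library:
#'
#' * `"gel"` — the classical preparative-gel protocol: a hard indicator on the
#'   gel window, by default the manual 40-220 bp size cut.
#' * `"gel_free"` — the multiplexed protocol: no gel. SPRI bead clean-up
#'   removes fragments below `spri_cutoff` (hard zero below 40 bp); a logistic
#'   ramp centred at `soft_midpoint_low` models incomplete small-fragment
#'   recovery just above the cutoff, and an exponential decay starting at
#'   `upper_onset` (tau `upper_decay_tau`) models bisulfite-induced
#'   fragmentation plus PCR/cluster amplification bias against long fragments.
#'   The soft-tail parameters are tunable stand-ins for mechanisms the
#'   protocol literature describes only qualitatively; the defaults keep
#'   60-300 bp fragments well covered.
#'
#' @param mode `"gel_free"` (default) or `"gel"`.
#' @param gel_window Inclusive retention window for gel mode, bp.
#' @param spri_cutoff Hard lower cutoff for gel-free mode, bp.
#' @param soft_midpoint_low Logistic midpoint of the lower ramp, bp.
#' @param soft_steepness Logistic scale of the lower ramp, bp.
#' @param upper_onset Length at which the upper decay begins, bp.
#' @param upper_decay_tau Exponential decay constant of the upper tail, bp.
#' @export
size_selection_model <- function(mode = c("gel_free", "gel"),
                                 gel_window = c(40L, 220L), spri_cutoff = 40L,
                                 soft_midpoint_low = 45, soft_steepness = 5,
                                 upper_onset = 250, upper_decay_tau = 50) {
  mode <- match.arg(mode)
  stopifnot(length(gel_window) == 2L, gel_window[1] <= gel_window[2],
            spri_cutoff >= 0, soft_steepness > 0, upper_decay_tau > 0)
  structure(list(mode = mode, gel_window = as.integer(gel_window),
                 spri_cutoff = spri_cutoff,
                 soft_midpoint_low = soft_midpoint_low,
                 soft_steepness = soft_steepness, upper_onset = upper_onset,
                 upper_decay_tau = upper_decay_tau),
            class = "size_selection_model")
}

#' Probability that a fragment of a given length is retained in the library
#'
#' Gel mode: 1 inside the gel window (inclusive), 0 outside. Gel-free mode:
#' `logistic((length - soft_midpoint_low)/soft_steepness) *
#' exp(-max(0, length - upper_onset)/upper_decay_tau)`, and exactly 0 below
#' `spri_cutoff`. Vectorized over `length`.
#'
#' @param length Fragment length(s), bp (>= 1).
#' @param model A [size_selection_model()].
#' @return Retention probabilities in `[0, 1]`.
#' @examples
#' m <- size_selection_model("gel")
#' retention_probability(c(39, 100, 221), m)  # 0 1 0
#' retention_probability(45, size_selection_model("gel_free"))  # 0.5
#' @export
retention_probability <- function(length, model) {
  stopifnot(inherits(model, "size_selection_model"), all(length >= 1))
  if (model$mode == "gel") {
    return(as.numeric(length >= model$gel_window[1] &
                        length <= model$gel_window[2]))
  }
  p <- plogis((length - model$soft_midpoint_low) / model$soft_steepness) *
    exp(-pmax(0, length - model$upper_onset) / model$upper_decay_tau)
  p[length < model$spri_cutoff] <- 0
  p
}
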