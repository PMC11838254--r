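#' Radioactive decay-rate conversions
#'
#' \eqn{\lambda = \ln 2 / t_{1/2}}; the two conversions are exact
#' inverses.
#'
#' @param half_life Half-life, in any time unit; > 0.
#' @return Decay rate in the reciprocal of that unit.
#' @export
decay_rate_from_half_life <- function(half_life) {
  .check_pos(half_life, "half_life")
  log(2) / half_life
}

#' @param decay_rate Decay rate, > 0.
#' @rdname decay_rate_from_half_life
#' @export
half_life_from_decay_rate <- function(decay_rate) {
  .check_pos(decay_rate, "decay_rate")
  log(2) / decay_rate
}

#' PET detection scenario
#'
#' Bundles the quantities that set the detection threshold for a region of
#' tissue: the scanner's minimum countable rate M (counts per unit time
#' per unit volume), the tracer's decay rate \eqn{\lambda} (or half-life),
#' the fibril concentration \eqn{[F]} (per the same volume), and the number
#' of binding sites per fibril N.  The convention used throughout: fibrils
#' at concentration \eqn{[F]} each with \eqn{n_L} bound tracers emit
#' \eqn{\lambda\, n_L\, [F]} counts per unit time per unit volume, so M and
#' \eqn{[F]} must share the volume unit; all results that matter are
#' ratios, which makes them convention-independent.
#'
#' @param detector_limit M, > 0.
#' @param decay_rate \eqn{\lambda}, > 0 (give this or `half_life`).
#' @param half_life Tracer half-life (same time unit as `decay_rate`).
#' @param fibril_conc \eqn{[F]} > 0.
#' @param n_sites Sites per fibril N, a positive integer.
#' @return An object of class `detection_spec`.
#' @export
detection_spec <- function(detector_limit, decay_rate = NULL,
                           half_life = NULL, fibril_conc, n_sites) {
  .check_pos(detector_limit, "detector_limit")
  if (is.null(decay_rate) == is.null(half_life)) {
    stop("give exactly one of `decay_rate` or `half_life`")
  }
  if (is.null(decay_rate)) decay_rate <- decay_rate_from_half_life(half_life)
  .check_pos(decay_rate, "decay_rate")
  .check_pos(fibril_conc, "fibril_conc")
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1 ||
      n_sites != round(n_sites)) {
    stop("`n_sites` must be a positive integer")
  }
  structure(list(detector_limit = detector_limit, decay_rate = decay_rate,
                 fibril_conc = fibril_conc, n_sites = as.integer(n_sites)),
            class = "detection_spec")
}

#' Critical bound-site count for detection
#'
#' Detection of a voxel requires \eqn{\lambda\, n_L\, [F] \ge M}, i.e.
#' \eqn{n_L \ge n_C = M / (\lambda [F])}.  The threshold is real-valued;
#' compare counts with `>=`.
#'
#' @param spec A [detection_spec()].
#' @return The critical count \eqn{n_C} (dimensionless).
#' @export
critical_occupancy <- function(spec) {
  stopifnot(inherits(spec, "detection_spec"))
  spec$detector_limit / (spec$decay_rate * spec$fibril_conc)
}

#' Minimum detectable free-tracer concentration (no cooperativity)
#'
#' With independent sites the mean bound count is
#' \eqn{\langle n_L\rangle = N [L]/(K_D + [L])}; requiring
#' \eqn{\langle n_L\rangle \ge n_C} gives
#' \eqn{[L] \ge K_D\, n_C / (N - n_C)}.  Because a fibril offers many
#' sites (\eqn{N \gg n_C}), the detectable concentration can sit far below
#' the \eqn{K_D} even without cooperativity.
#'
#' @param kd Tracer dissociation constant (molar), > 0.
#' @param n_c Critical count, with \eqn{0 < n_C < N}.
#' @param n_sites Sites per fibril N.
#' @return Minimum detectable concentration (molar).
#' @export
min_detectable_conc <- function(kd, n_c, n_sites) {
  .check_pos(kd, "kd")
  .check_pos(n_c, "n_c")
  .check_pos(n_sites, "n_sites")
  if (n_c >= n_sites) {
    stop("n_c >= n_sites: the fibril cannot emit enough counts at any concentration")
  }
  kd * n_c / (n_sites - n_c)
}

#' Probability that a fibril is detectable at a single time point
#'
#' Tail probability \eqn{P(n_L \ge n_C)} of the exact bound-count
#' distribution from [occupancy_distribution()], together with the
#' time-averaged criterion \eqn{\langle n_L\rangle \ge n_C} that applies
#' when the measurement integrates over many binding equilibrations.  For
#' a non-cooperative tracer (\eqn{\alpha_L = 1}) the count is binomial and
#' the tail equals the binomial survival function with success probability
#' \eqn{[L]/(K_D + [L])}.
#'
#' @param model A [lattice_model()] for the tracer (2-state).
#' @param config A [fibril_config()].
#' @param n_c Critical count, >= 0. Thresholds above N give probability 0.
#' @param species Counted species, default `"L"`.
#' @return A list of class `detection_report`: `probability`
#'   (\eqn{P(n_L \ge n_C)}), `mean_count` (\eqn{\langle n_L\rangle}),
#'   `mean_criterion` (logical), and `n_c`.
#' @export
detection_probability <- function(model, config, n_c, species = "L") {
  stopifnot(inherits(model, "lattice_model"), inherits(config, "fibril_config"))
  if (!is.numeric(n_c) || length(n_c) != 1L || !is.finite(n_c) || n_c < 0) {
    stop("`n_c` must be a single finite value >= 0")
  }
  dist <- occupancy_distribution(model, config, species = species)
  counts <- as.integer(names(dist))
  prob <- sum(dist[counts >= n_c])
  mean_count <- sum(counts * dist)
  structure(list(probability = prob, mean_count = mean_count,
                 mean_criterion = mean_count >= n_c, n_c = n_c),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> nC = %g\n", x$n_c))
  cat(sprintf("  P(nL >= nC)  = %.6g (single time point)\n", x$probability))
  cat(sprintf("  <nL> = %.6g => mean criterion %s (time-averaged)\n",
              x$mean_count, if (x$mean_criterion) "MET" else "not met"))
  invisible(x)
}
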