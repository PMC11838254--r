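#' Nearest-neighbor lattice model of a fibril's binding sites
#'
#' Each of the equivalent sites along a fibril is empty, holds a
#' radioligand (L), or -- in a competition setting -- holds an inhibitor
#' (I).  A configuration's statistical weight is the product of per-site
#' activities (\eqn{[L]/K_D}, \eqn{[I]/K_I}; empty sites have weight 1)
#' and one nearest-neighbor pair factor per adjacent pair of occupied
#' sites: \eqn{\alpha_L} for L-L, \eqn{\alpha_I} for I-I, \eqn{\chi} for
#' L-I.  Pairs involving an empty site carry factor 1.  Energies are
#' additive, so the factors multiply.
#'
#' @param conc_ratio_l Radioligand activity \eqn{[L]/K_D}, >= 0.
#' @param alpha_l L-L pair factor, >= 0. Default 1 (no cooperativity).
#' @param conc_ratio_i Inhibitor activity \eqn{[I]/K_I}, >= 0, or `NULL`
#'   for the two-state (saturation) model.
#' @param alpha_i I-I pair factor, >= 0.
#' @param chi L-I cross pair factor, >= 0.
#' @return An object of class `lattice_model`: `species` (character),
#'   `weights` (named, empty site = 1), `pairs` (named symmetric matrix of
#'   nearest-neighbor factors).
#' @examples
#' lattice_model(conc_ratio_l = 1, alpha_l = 10)
#' lattice_model(1, 10, conc_ratio_i = 2, alpha_i = 5, chi = 7)
#' @export
lattice_model <- function(conc_ratio_l, alpha_l = 1,
                          conc_ratio_i = NULL, alpha_i = 1, chi = 1) {
  .check_nonneg(conc_ratio_l, "conc_ratio_l", scalar = TRUE)
  .check_nonneg(alpha_l, "alpha_l", scalar = TRUE)
  if (is.null(conc_ratio_i)) {
    species <- c("empty", "L")
    weights <- c(empty = 1, L = conc_ratio_l)
    pairs <- matrix(1, 2, 2, dimnames = list(species, species))
    pairs["L", "L"] <- alpha_l
  } else {
    .check_nonneg(conc_ratio_i, "conc_ratio_i", scalar = TRUE)
    .check_nonneg(alpha_i, "alpha_i", scalar = TRUE)
    .check_nonneg(chi, "chi", scalar = TRUE)
    species <- c("empty", "L", "I")
    weights <- c(empty = 1, L = conc_ratio_l, I = conc_ratio_i)
    pairs <- matrix(1, 3, 3, dimnames = list(species, species))
    pairs["L", "L"] <- alpha_l
    pairs["I", "I"] <- alpha_i
    pairs["L", "I"] <- pairs["I", "L"] <- chi
  }
  structure(list(species = species, weights = weights, pairs = pairs),
            class = "lattice_model")
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf("<lattice_model> %d states: %s\n",
              length(x$species), paste(x$species, collapse = ", ")))
  cat("site weights:", paste(sprintf("%s=%g", names(x$weights), x$weights),
                             collapse = ", "), "\n")
  cat("pair factors:\n")
  print(x$pairs)
  invisible(x)
}

#' Finite-fibril geometry
#'
#' @param n_sites Number of binding sites N, a positive integer.
#' @param boundary `"free"` (a physical fibril with two ends, the default)
#'   or `"periodic"` (a ring, useful for convergence studies against the
#'   infinite-lattice limit).
#' @return An object of class `fibril_config`.
#' @export
fibril_config <- function(n_sites, boundary = c("free", "periodic")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(n_sites) || length(n_sites) != 1L || !is.finite(n_sites) ||
      n_sites < 1 || n_sites != round(n_sites)) {
    stop("`n_sites` must be a positive integer")
  }
  structure(list(n_sites = as.integer(n_sites), boundary = boundary),
            class = "fibril_config")
}

# symmetric transfer matrix T(s,s') = sqrt(w_s) pair(s,s') sqrt(w_s')
.transfer_matrix <- function(model) {
  sw <- sqrt(model$weights)
  t_mat <- model$pairs * outer(sw, sw)
  dimnames(t_mat) <- dimnames(model$pairs)
  t_mat
}

.new_occupancy_result <- function(mean_fraction, pair_fraction,
                                  count_distribution = NULL) {
  structure(list(mean_fraction = mean_fraction,
                 pair_fraction = pair_fraction,
                 count_distribution = count_distribution),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat("<occupancy_result>\n  mean fractions: ",
      paste(sprintf("%s=%.6g", names(x$mean_fraction), x$mean_fraction),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$pair_fraction)) {
    cat("  neighbor-pair fractions (ordered, sum to 1):\n")
    print(round(x$pair_fraction, 6))
  }
  if (!is.null(x$count_distribution)) {
    k <- seq_along(x$count_distribution) - 1L
    cat(sprintf("  count distribution over 0..%d (mean %.6g)\n",
                max(k), sum(k * x$count_distribution)))
  }
  invisible(x)
}
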