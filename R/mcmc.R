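#' MCMC run settings
#'
#' @param sweeps Total number of sweeps (one sweep = N single-site
#'   updates in randomized order). Default 5000, which together with the
#'   other defaults gives 3-standard-error agreement with exact
#'   finite-lattice results at N = 1000 for moderate cooperativities.
#' @param burn_in Sweeps discarded before recording; must be < `sweeps`.
#' @param thinning Record every `thinning`-th sweep after burn-in.
#' @param seed Integer seed; the run is fully deterministic given it.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(sweeps = 5000L, burn_in = 1000L, thinning = 10L,
                          seed = 1L) {
  stopifnot(sweeps >= 1, burn_in >= 0, burn_in < sweeps, thinning >= 1)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  structure(list(sweeps = as.integer(sweeps), burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Heat-bath Monte Carlo simulation of a finite fibril
#'
#' Grand-canonical single-site Gibbs sampling of the nearest-neighbor
#' lattice: at each update the site's state is redrawn from its exact
#' conditional distribution (proportional to the site weight times the two
#' neighbor pair factors).  Sweeps visit sites in a freshly randomized
#' order; all randomness comes from R's RNG seeded by
#' `settings$seed`, so repeated calls are bitwise reproducible and the
#' caller's RNG state is left untouched.
#'
#' @param model A [lattice_model()].
#' @param config A [fibril_config()].
#' @param settings An [mcmc_settings()].
#' @return A list of class `mcmc_result`:
#'   \describe{
#'     \item{trace}{data.frame of recorded sweeps with one bound-fraction
#'       column per species (`f_empty`, `f_L`, `f_I`).}
#'     \item{estimate}{an `occupancy_result` of trace means (mean and
#'       neighbor-pair fractions).}
#'     \item{std_error}{named batch-means standard errors of the mean
#'       fractions (about 20 batches).}
#'     \item{n_samples}{number of recorded sweeps.}
#'   }
#' @examples
#' m <- lattice_model(conc_ratio_l = 0.1, alpha_l = 10)
#' res <- mcmc_sample(m, fibril_config(200), mcmc_settings(seed = 42))
#' res$estimate$mean_fraction["L"]
#' @export
mcmc_sample <- function(model, config, settings = mcmc_settings()) {
  stopifnot(inherits(model, "lattice_model"),
            inherits(config, "fibril_config"),
            inherits(settings, "mcmc_settings"))
  # seed locally; restore the caller's RNG state on exit
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(settings$seed)

  raw <- gibbs_lattice(unname(model$weights), unname(model$pairs),
                       config$n_sites, config$boundary == "periodic",
                       settings$sweeps, settings$burn_in, settings$thinning)
  k <- length(model$species)
  frac <- raw$state_counts / config$n_sites
  colnames(frac) <- paste0("f_", model$species)
  trace <- data.frame(sweep = raw$sweep, frac, check.names = FALSE)

  mean_fraction <- stats::setNames(colMeans(frac), model$species)
  n_bonds <- if (config$boundary == "periodic") config$n_sites
             else config$n_sites - 1L
  pair <- NULL
  if (n_bonds >= 1L) {
    pair <- matrix(colMeans(raw$pair_counts) / n_bonds, k, k,
                   dimnames = dimnames(model$pairs))
    pair <- (pair + t(pair)) / 2
  }
  std_error <- apply(frac, 2L, .batch_means_se)
  names(std_error) <- model$species

  structure(list(trace = trace,
                 estimate = .new_occupancy_result(mean_fraction, pair),
                 std_error = std_error,
                 n_samples = nrow(frac),
                 settings = settings),
            class = "mcmc_result")
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat(sprintf("<mcmc_result> %d recorded sweeps (seed %d)\n",
              x$n_samples, x$settings$seed))
  est <- x$estimate$mean_fraction
  for (s in names(est)) {
    cat(sprintf("  f_%s = %.5f (batch-means SE %.2g)\n",
                s, est[s], x$std_error[s]))
  }
  invisible(x)
}

# batch-means standard error of the mean of a (possibly autocorrelated)
# scalar trace, using ~20 equal batches
.batch_means_se <- function(x, n_batches = 20L) {
  n <- length(x)
  n_batches <- max(2L, min(n_batches, n %/% 2L))
  if (n < 4L) return(stats::sd(x) / sqrt(n))
  size <- n %/% n_batches
  used <- size * n_batches
  bm <- colMeans(matrix(x[seq_len(used)], nrow = size))
  stats::sd(bm) / sqrt(n_batches)
}
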