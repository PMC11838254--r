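#' Infinite-lattice occupancies by the transfer matrix
#'
#' Exact per-site state probabilities and nearest-neighbor pair
#' probabilities of the 1-D lattice in the limit of infinitely many sites.
#' The symmetric transfer matrix
#' \eqn{T(s,s') = \sqrt{w_s}\, p(s,s') \sqrt{w_{s'}}} is diagonalized; with
#' principal eigenpair \eqn{(\lambda, v)} (the Perron pair, \eqn{v}
#' normalized), the probability of a site being in state \eqn{s} is
#' \eqn{v_s^2} -- equivalent to the Hellmann-Feynman derivative
#' \eqn{w_s\,\partial\ln\lambda/\partial w_s} -- and the ordered
#' neighbor-pair probability is \eqn{v_s T(s,s') v_{s'} / \lambda}.
#' For the two-state model the radioligand fraction equals
#' [saturation_fraction()] analytically.
#'
#' @param model A [lattice_model()].
#' @return An `occupancy_result` with `mean_fraction` (named, sums to 1)
#'   and `pair_fraction` (ordered symmetric matrix, sums to 1).
#' @export
infinite_occupancy <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  if (all(model$weights == 0)) stop("all site weights are zero")
  t_mat <- .transfer_matrix(model)
  es <- eigen(t_mat, symmetric = TRUE)
  lambda <- es$values[1L]
  if (!is.finite(lambda) || lambda <= 0) {
    stop("transfer-matrix eigensolve failed (non-positive principal eigenvalue)")
  }
  v <- es$vectors[, 1L]
  v <- abs(v) / sqrt(sum(v^2))  # Perron vector is sign-free and non-negative
  mean_fraction <- stats::setNames(v^2, model$species)
  pair <- outer(v, v) * t_mat / lambda
  dimnames(pair) <- dimnames(t_mat)
  .new_occupancy_result(mean_fraction, pair)
}

#' Exact occupancies of a finite fibril
#'
#' Matrix-product evaluation of the finite-N partition function.  For free
#' ends the partition function is \eqn{a^\top T^{N-1} a} with boundary
#' vector \eqn{a_s = \sqrt{w_s}}; for a ring it is \eqn{tr(T^N)}.  Site and
#' bond probabilities come from normalized forward/backward vector products
#' (free) or the eigendecomposition with eigenvalue ratios (periodic), so
#' no partition function is ever formed explicitly and arbitrarily large N
#' cannot overflow.
#'
#' @param model A [lattice_model()].
#' @param config A [fibril_config()].
#' @return An `occupancy_result`; `pair_fraction` is `NULL` when
#'   `n_sites == 1` (no bonds).  Fractions are averages over sites/bonds,
#'   so free-boundary results carry edge effects of order 1/N.
#' @export
finite_occupancy <- function(model, config) {
  stopifnot(inherits(model, "lattice_model"), inherits(config, "fibril_config"))
  n <- config$n_sites
  t_mat <- .transfer_matrix(model)
  k <- nrow(t_mat)
  if (n == 1L) {
    # a single site has no neighbors under either boundary convention
    w <- model$weights
    if (sum(w) == 0) stop("all site weights are zero")
    return(.new_occupancy_result(w / sum(w), NULL))
  }
  if (config$boundary == "free") {
    a <- sqrt(model$weights)
    if (sum(a) == 0) stop("all site weights are zero")
    # forward[, i] propto T^{i-1} a, renormalized each step
    forward <- matrix(0, k, n)
    vec <- a
    for (i in seq_len(n)) {
      vec <- vec / sum(vec)
      forward[, i] <- vec
      vec <- drop(t_mat %*% vec)
    }
    backward <- matrix(0, k, n)  # backward[, i] propto T^(n-i) a
    vec <- a
    for (i in rev(seq_len(n))) {
      vec <- vec / sum(vec)
      backward[, i] <- vec
      vec <- drop(t_mat %*% vec)
    }
    site_prob <- forward * backward
    site_prob <- sweep(site_prob, 2L, colSums(site_prob), "/")
    mean_fraction <- stats::setNames(rowMeans(site_prob), model$species)
    pair <- NULL
    if (n >= 2L) {
      pair <- matrix(0, k, k, dimnames = dimnames(t_mat))
      for (i in seq_len(n - 1L)) {
        joint <- outer(forward[, i], backward[, i + 1L]) * t_mat
        pair <- pair + joint / sum(joint)
      }
      pair <- pair / (n - 1L)
    }
    .new_occupancy_result(mean_fraction, pair)
  } else {
    es <- eigen(t_mat, symmetric = TRUE)
    d <- es$values
    v_mat <- es$vectors
    dmax <- max(abs(d))
    if (dmax == 0) stop("all site weights are zero")
    r_n <- (d / dmax)^n            # tr(T^N) = sum_j d_j^N, scaled
    z_scaled <- sum(r_n)
    site_prob <- drop((v_mat^2) %*% r_n) / z_scaled
    mean_fraction <- stats::setNames(site_prob, model$species)
    pair <- NULL
    if (n >= 2L) {
      r_n1 <- (d / dmax)^(n - 1L)
      # P(s, s') = T(s,s') (T^{N-1})(s',s) / tr(T^N)
      t_pow <- v_mat %*% (r_n1 * t(v_mat))
      pair <- t_mat * t(t_pow) / (z_scaled * dmax)
      dimnames(pair) <- dimnames(t_mat)
    }
    .new_occupancy_result(mean_fraction, pair)
  }
}

#' Brute-force enumeration oracle for small lattices
#'
#' Sums Boltzmann weights over every configuration explicitly.  Exponential
#' in N; it exists to validate [finite_occupancy()] and
#' [occupancy_distribution()] and is guarded to at most 10^6
#' configurations.
#'
#' @param model A [lattice_model()].
#' @param config A [fibril_config()].
#' @param count_species Species whose bound-count distribution to
#'   accumulate (default `"L"`), or `NULL` to skip.
#' @return An `occupancy_result` including `count_distribution`.
#' @export
enumerate_oracle <- function(model, config, count_species = "L") {
  stopifnot(inherits(model, "lattice_model"), inherits(config, "fibril_config"))
  n <- config$n_sites
  k <- length(model$species)
  if (k^n > 1e6) {
    stop("state space exceeds 10^6 configurations; use finite_occupancy()")
  }
  confs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  w <- rep(1, nrow(confs))
  for (i in seq_len(n)) w <- w * model$weights[confs[, i]]
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      w <- w * model$pairs[cbind(confs[, i], confs[, i + 1L])]
    }
  }
  if (config$boundary == "periodic" && n >= 2L) {
    w <- w * model$pairs[cbind(confs[, n], confs[, 1L])]
  }
  z <- sum(w)
  if (z <= 0) stop("all configurations have zero weight")
  mean_fraction <- numeric(k)
  for (s in seq_len(k)) {
    mean_fraction[s] <- sum(w * rowSums(confs == s)) / (n * z)
  }
  names(mean_fraction) <- model$species
  pair <- NULL
  n_bonds <- if (config$boundary == "periodic") n else n - 1L
  if (n_bonds >= 1L && n >= 2L) {
    pair <- matrix(0, k, k, dimnames = dimnames(model$pairs))
    bonds <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
    if (config$boundary == "periodic") bonds <- rbind(bonds, c(n, 1L))
    for (b in seq_len(nrow(bonds))) {
      for (s in seq_len(k)) for (s2 in seq_len(k)) {
        sel <- confs[, bonds[b, 1L]] == s & confs[, bonds[b, 2L]] == s2
        pair[s, s2] <- pair[s, s2] + sum(w[sel])
      }
    }
    pair <- (pair + t(pair)) / 2  # symmetrize ordered-bond counts
    pair <- pair / sum(pair)
  }
  cd <- NULL
  if (!is.null(count_species)) {
    si <- match(count_species, model$species)
    if (is.na(si)) stop("unknown `count_species`")
    counts <- rowSums(confs == si)
    cd <- vapply(0:n, function(m) sum(w[counts == m]), numeric(1)) / z
    names(cd) <- 0:n
  }
  .new_occupancy_result(mean_fraction, pair, cd)
}

#' Exact distribution of the bound-site count
#'
#' Probability that exactly k of the N sites hold the given species,
#' computed by dynamic programming over (site, end state, running count);
#' cost O(N^2 states^2).  For the two-state non-cooperative case
#' (`alpha_l = 1`) the count is Binomial(N, \eqn{[L]/(K_D+[L])}).
#'
#' @param model A [lattice_model()].
#' @param config A [fibril_config()].
#' @param species Species to count (default `"L"`).
#' @return Named probability vector over counts 0..N (sums to 1).
#' @export
occupancy_distribution <- function(model, config, species = "L") {
  stopifnot(inherits(model, "lattice_model"), inherits(config, "fibril_config"))
  n <- config$n_sites
  k <- length(model$species)
  si <- match(species, model$species)
  if (is.na(si)) stop("unknown `species`")
  ind <- as.integer(seq_len(k) == si)

  # g[s, m+1] = weight of chains ending in state s with m counted sites,
  # renormalized each step with the log of the accumulated scale returned
  # so that independent branches remain comparable.
  run_dp <- function(start_states) {
    g <- matrix(0, k, n + 1L)
    for (s in start_states) g[s, 1L + ind[s]] <- model$weights[s]
    log_scale <- 0
    if (n >= 2L) {
      for (i in 2:n) {
        g_new <- matrix(0, k, n + 1L)
        for (s in seq_len(k)) {
          incoming <- drop(model$pairs[, s] %*% g)   # over previous states
          if (ind[s] == 1L) incoming <- c(0, incoming[-(n + 1L)])
          g_new[s, ] <- model$weights[s] * incoming
        }
        tot <- sum(g_new)
        if (tot <= 0) return(NULL)  # this branch carries zero weight
        g <- g_new / tot
        log_scale <- log_scale + log(tot)
      }
    }
    list(g = g, log_scale = log_scale)
  }

  if (config$boundary == "free" || n == 1L) {
    dp <- run_dp(seq_len(k))
    if (is.null(dp)) stop("all configurations have zero weight")
    p <- colSums(dp$g)
  } else {
    # condition on the first site's state to close the ring
    branches <- lapply(seq_len(k), function(s0) {
      if (model$weights[s0] == 0) return(NULL)
      dp <- run_dp(s0)
      if (is.null(dp)) return(NULL)
      list(p = drop(model$pairs[, s0] %*% dp$g), log_scale = dp$log_scale)
    })
    branches <- Filter(Negate(is.null), branches)
    if (length(branches) == 0L) stop("all configurations have zero weight")
    ref <- max(vapply(branches, `[[`, numeric(1), "log_scale"))
    p <- Reduce(`+`, lapply(branches,
                            function(b) b$p * exp(b$log_scale - ref)))
  }
  p <- p / sum(p)
  stats::setNames(p, 0:n)
}

#' Saturation-assumption check: full 3-state model at scaled activities
#'
#' Multiplies both activities of the 3-state model by a large factor and
#' returns the radioligand fraction among occupied sites from the full
#' [infinite_occupancy()].  As `scale` grows this converges to the
#' saturated two-state isotherm [competition_fraction()], verifying
#' numerically the reduction that the closed-form competition curve
#' assumes.
#'
#' @param x Dimensionless \eqn{[I]/IC_{50}} at which to evaluate.
#' @param beta Relative cross-cooperativity, > 0.
#' @param scale Common activity multiplier, >> 1.
#' @return Radioligand fraction of occupied sites.
#' @export
saturating_limit_check <- function(x, beta, scale = 1e6) {
  .check_nonneg(x, "x", scalar = TRUE)
  .check_pos(beta, "beta")
  .check_pos(scale, "scale")
  # alpha_l = alpha_i = 1, chi = sqrt(beta) realizes the requested beta;
  # with equal alphas, x = [I]/IC50 = w_I / w_L.
  model <- lattice_model(conc_ratio_l = scale, alpha_l = 1,
                         conc_ratio_i = scale * x, alpha_i = 1,
                         chi = sqrt(beta))
  occ <- infinite_occupancy(model)
  f <- occ$mean_fraction
  unname(f["L"] / (f["L"] + f["I"]))
}
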