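#' A concentration-response dataset
#'
#' Container for a saturation or competition assay: concentrations (molar;
#' ligand for saturation, inhibitor for competition) and the measured
#' signal in counts per minute.  Rows are sorted by concentration, which
#' must be unique and non-negative.
#'
#' @param concentration Numeric vector of molar concentrations, >= 0.
#' @param signal Numeric vector of CPM values (may be negative after
#'   noise; values are never clipped).
#' @param assay_type `"saturation"` or `"competition"`.
#' @param radioligand_conc Free radioligand concentration (molar), required
#'   for competition assays.
#' @param label Free-text metadata label.
#' @return A data.frame of class `binding_curve` with columns
#'   `concentration` and `signal` and attributes `assay_type`,
#'   `radioligand_conc`, `label`.
#' @export
binding_curve <- function(concentration, signal,
                          assay_type = c("saturation", "competition"),
                          radioligand_conc = NULL, label = "") {
  assay_type <- match.arg(assay_type)
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration < 0)) {
    stop("`concentration` must be finite and >= 0 (molar)")
  }
  if (!is.numeric(signal) || any(!is.finite(signal))) {
    stop("`signal` must be finite (CPM)")
  }
  if (length(concentration) != length(signal)) {
    stop("`concentration` and `signal` must have equal length")
  }
  ord <- order(concentration)
  concentration <- concentration[ord]
  signal <- signal[ord]
  if (anyDuplicated(concentration)) {
    stop("concentrations must be strictly increasing after sorting (no duplicates)")
  }
  if (assay_type == "competition") {
    if (is.null(radioligand_conc)) {
      stop("competition curves require `radioligand_conc`")
    }
    .check_pos(radioligand_conc, "radioligand_conc")
  }
  structure(data.frame(concentration = concentration, signal = signal),
            assay_type = assay_type,
            radioligand_conc = radioligand_conc,
            label = label,
            class = c("binding_curve", "data.frame"))
}

.new_fit <- function(estimates, standard_errors, covariance, residuals,
                     fitted, converged, ci = NULL, notes = character(),
                     terms = NULL) {
  structure(list(estimates = estimates,
                 standard_errors = standard_errors,
                 covariance = covariance,
                 residuals = residuals,
                 fitted = fitted,
                 converged = converged,
                 objective = sum(residuals^2),
                 ci = ci,
                 notes = notes,
                 terms = terms),
            class = "fibril_fit")
}

#' @export
print.fibril_fit <- function(x, ...) {
  cat(sprintf("<fibril_fit> converged: %s, SSR = %.6g\n",
              x$converged, x$objective))
  tab <- data.frame(estimate = x$estimates,
                    std_error = x$standard_errors[names(x$estimates)])
  if (!is.null(x$ci)) {
    tab$ci_lower <- x$ci[names(x$estimates), 1L]
    tab$ci_upper <- x$ci[names(x$estimates), 2L]
  }
  print(tab)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Concentration grid for fitting a theoretical isotherm
#'
#' Evaluates a monotone fraction-valued isotherm on `n_points` log-spaced
#' concentrations chosen (by root-finding) so the fractions span
#' `f_range`.  This fixed protocol makes effective Hill coefficients of
#' theoretical curves well-defined: they depend on the fitted range.
#'
#' @param fraction_fn Function of concentration returning a fraction;
#'   monotone increasing or decreasing.
#' @param n_points Number of points (default 200).
#' @param f_range Fraction range to span, default c(0.01, 0.99).
#' @param search Concentration bracket for the root search.
#' @return data.frame with columns `concentration`, `fraction`.
#' @examples
#' tab <- theoretical_curve(function(c) saturation_fraction(c, 10))
#' range(tab$fraction)
#' @export
theoretical_curve <- function(fraction_fn, n_points = 200,
                              f_range = c(0.01, 0.99),
                              search = c(1e-12, 1e12)) {
  stopifnot(n_points >= 2, length(f_range) == 2, all(f_range > 0),
            all(f_range < 1))
  conc_at <- function(f) {
    exp(stats::uniroot(function(lc) fraction_fn(exp(lc)) - f,
                       lower = log(search[1]), upper = log(search[2]),
                       tol = 1e-12)$root)
  }
  bounds <- sort(c(conc_at(f_range[1]), conc_at(f_range[2])))
  conc <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_points))
  data.frame(concentration = conc, fraction = fraction_fn(conc))
}

#' Fit the empirical Hill equation
#'
#' Unweighted least-squares fit of
#' \eqn{f = [X]^n / (EC_{50}^n + [X]^n)} (ascending) or
#' \eqn{f = EC_{50}^n / (EC_{50}^n + [X]^n)} (descending) to a
#' fraction-scale curve, reporting the midpoint and the effective Hill
#' coefficient `hill_n`.  Applied to the cooperative saturation isotherm
#' this measures apparent steepness: \eqn{\alpha_L = 10} gives an
#' effective n between 2 and 3 under the [theoretical_curve()] protocol,
#' while the \eqn{\beta = 1} competition curve gives exactly n = 1.
#'
#' @param data A data.frame with columns `concentration` and `fraction`
#'   (e.g. from [theoretical_curve()]), or a [binding_curve()] whose signal
#'   is first rescaled to fractions by its observed range.
#' @param direction `"auto"` (from the data trend), `"ascending"`, or
#'   `"descending"`.
#' @return A `fibril_fit` with estimates `midpoint` and `hill_n`.
#' @export
fit_hill <- function(data, direction = c("auto", "ascending", "descending")) {
  direction <- match.arg(direction)
  if (inherits(data, "binding_curve")) {
    rng <- range(data$signal)
    if (diff(rng) <= 0) stop("signal has no dynamic range")
    data <- data.frame(concentration = data$concentration,
                       fraction = (data$signal - rng[1]) / diff(rng))
  }
  stopifnot(all(c("concentration", "fraction") %in% names(data)))
  x <- data$concentration
  f <- data$fraction
  if (length(x) < 5L) stop("need at least 5 points for a Hill fit")
  if (direction == "auto") {
    direction <- if (stats::cor(log(pmax(x, min(x[x > 0]))), f) >= 0)
      "ascending" else "descending"
  }
  # midpoint start: concentration where the curve crosses 1/2
  mid0 <- tryCatch(
    stats::approx(f, x, xout = 0.5, ties = "ordered")$y,
    error = function(e) NA_real_)
  if (!is.finite(mid0) || mid0 <= 0) mid0 <- exp(mean(log(x[x > 0])))
  if (!any(f > 0.5) || !any(f < 0.5)) {
    return(.new_fit(c(midpoint = mid0, hill_n = NA_real_),
                    c(midpoint = NA_real_, hill_n = NA_real_),
                    matrix(NA_real_, 2, 2), rep(NA_real_, length(f)),
                    rep(NA_real_, length(f)), converged = FALSE,
                    notes = "midpoint not bracketed by the data"))
  }
  form <- if (direction == "ascending") {
    f ~ x^n / (k^n + x^n)
  } else {
    f ~ k^n / (k^n + x^n)
  }
  fit <- minpack.lm::nlsLM(form, start = list(n = 1, k = mid0),
                           lower = c(n = 1e-3, k = 0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- stats::setNames(sqrt(pmax(diag(vc), 0)), names(est))
  estimates <- c(midpoint = unname(est["k"]), hill_n = unname(est["n"]))
  ses <- c(midpoint = unname(se["k"]), hill_n = unname(se["n"]))
  ci <- cbind(lower = estimates - 1.96 * ses, upper = estimates + 1.96 * ses)
  .new_fit(estimates, ses,
           vc[2:1, 2:1, drop = FALSE],
           stats::resid(fit), stats::fitted(fit),
           converged = TRUE, ci = ci)
}

# internal: multi-start bounded Levenberg-Marquardt on a log10-parameterized
# model; returns the best nlsLM fit object
.multistart_nls <- function(formula, data, start_log, lower, upper,
                            n_starts = 5L, seed = 1L, jitter_sd = 0.3,
                            weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(data))
  # nls resolves its `weights` argument in the formula environment, so give
  # the vector an unambiguous home in both the data and that environment
  data$.fit_weights <- weights
  assign(".fit_weights", weights, envir = environment(formula))
  .fit_weights <- weights
  fits <- list()
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  starts <- c(list(start_log), lapply(seq_len(max(0L, n_starts - 1L)),
    function(i) {
      s <- unlist(start_log) + stats::rnorm(length(start_log), 0, jitter_sd)
      as.list(pmin(pmax(s, lower + 1e-9), upper - 1e-9))
    }))
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = s,
                        lower = lower, upper = upper, weights = .fit_weights,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) stop("all optimizer starts failed")
  obj <- vapply(fits, function(f) sum(weights * stats::resid(f)^2), numeric(1))
  fits[[which.min(obj)]]
}

# delta-method conversion of a log10-scale fit to the natural scale;
# log_idx flags which internal parameters are log10-transformed
.natural_scale <- function(fit, names_out, log_idx) {
  est_int <- stats::coef(fit)
  df_resid <- length(stats::resid(fit)) - length(est_int)
  tq <- stats::qt(0.975, max(df_resid, 1L))
  vc_int <- tryCatch(stats::vcov(fit),
                     error = function(e) matrix(NA_real_, length(est_int),
                                                length(est_int)))
  est <- est_int
  est[log_idx] <- 10^est_int[log_idx]
  jac <- rep(1, length(est_int))
  jac[log_idx] <- est[log_idx] * log(10)
  vc <- diag(jac) %*% vc_int %*% diag(jac)
  se <- sqrt(pmax(diag(vc), 0))
  # t-based Wald intervals on the internal (log) scale, mapped back
  se_int <- sqrt(pmax(diag(vc_int), 0))
  lo <- est_int - tq * se_int
  hi <- est_int + tq * se_int
  lo[log_idx] <- 10^lo[log_idx]
  hi[log_idx] <- 10^hi[log_idx]
  dimnames(vc) <- list(names_out, names_out)
  list(estimates = stats::setNames(unname(est), names_out),
       standard_errors = stats::setNames(unname(se), names_out),
       covariance = vc,
       ci = matrix(c(lo, hi), ncol = 2,
                   dimnames = list(names_out, c("lower", "upper"))))
}

#' Fit the cooperative saturation model to a CPM curve
#'
#' Nonlinear least squares of
#' \eqn{CPM = B_{max} f_L([L]/K_D, \alpha_L) + ns\,[L] + b_0}
#' with \eqn{f_L} the infinite-lattice saturation isotherm.  \eqn{K_D},
#' \eqn{\alpha_L} and \eqn{B_{max}} are optimized on the log10 scale
#' (bounded Levenberg-Marquardt, 5 seeded starts); standard errors come
#' from the Jacobian and 95\% Wald intervals are formed on the log scale.
#' Because the midpoint fixes only the ratio \eqn{K_D/\alpha_L}, data
#' confined to the midpoint region leave \eqn{(K_D, \alpha_L)} strongly
#' anti-correlated; the fit flags this (see also
#' [identifiability_profile()]).
#'
#' @param curve A saturation [binding_curve()].
#' @param fix_alpha Optionally fix \eqn{\alpha_L} at this value (e.g. 1
#'   for the non-cooperative model).
#' @param include_ns Include the linear non-specific term? Default FALSE.
#' @param include_baseline Include a constant baseline? Default FALSE.
#' @param weights `"none"` (homoscedastic CPM noise) or `"proportional"`
#'   (noise sd proportional to the signal; weights 1/CPM^2), matching the
#'   assay's error structure.
#' @param n_starts Number of optimizer starts.
#' @param seed Seed for the start jitter (the fit itself is
#'   deterministic).
#' @return A `fibril_fit` with estimates among `kd`, `alpha_l`, `bmax`,
#'   `ns_slope`, `baseline`.
#' @export
fit_saturation <- function(curve, fix_alpha = NULL, include_ns = FALSE,
                           include_baseline = FALSE,
                           weights = c("none", "proportional"),
                           n_starts = 5L, seed = 1L) {
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "binding_curve"))
  if (attr(curve, "assay_type") != "saturation") {
    stop("`curve` is not a saturation assay")
  }
  if (nrow(curve) < 5L) stop("need at least 5 records")
  d <- data.frame(conc = curve$concentration, cpm = curve$signal)
  bmax0 <- max(d$cpm)
  ec50_0 <- {
    half <- which(d$cpm >= bmax0 / 2)
    if (length(half)) d$conc[half[1L]] else stats::median(d$conc)
  }
  alpha0 <- if (is.null(fix_alpha)) 1 else fix_alpha
  free_alpha <- is.null(fix_alpha)

  # the non-specific regressor is scaled to order 1 (sconc = conc/max(conc))
  # so the gradient QR does not treat its molar-scale column as rank zero
  cmax <- max(d$conc)
  d$sconc <- d$conc / cmax
  rhs <- "10^lbmax * saturation_fraction(conc / 10^lkd, %s)%s%s"
  alpha_term <- if (free_alpha) "10^lalpha" else deparse(fix_alpha)
  ns_term <- if (include_ns) " + ns * sconc" else ""
  base_term <- if (include_baseline) " + b0" else ""
  form <- stats::as.formula(
    paste("cpm ~", sprintf(rhs, alpha_term, ns_term, base_term)))

  start <- list(lkd = log10(ec50_0 * alpha0), lbmax = log10(bmax0))
  lower <- c(lkd = log10(min(d$conc[d$conc > 0])) - 6,
             lbmax = log10(bmax0) - 4)
  upper <- c(lkd = log10(max(d$conc)) + 6, lbmax = log10(bmax0) + 4)
  if (free_alpha) {
    start$lalpha <- 0
    lower <- c(lower, lalpha = -6)
    upper <- c(upper, lalpha = 6)
  }
  if (include_ns) {
    start$ns <- 0     # CPM at the top concentration; ns_slope = ns / cmax
    lower <- c(lower, ns = 0)
    upper <- c(upper, ns = Inf)
  }
  if (include_baseline) {
    start$b0 <- min(d$cpm)
    lower <- c(lower, b0 = -Inf)
    upper <- c(upper, b0 = Inf)
  }
  start <- start[order(match(names(start), names(lower)))]

  wt <- if (weights == "proportional") {
    1 / pmax(abs(d$cpm), max(abs(d$cpm)) * 1e-3)^2
  } else NULL
  fit <- .multistart_nls(form, d, start, lower, upper, n_starts, seed,
                         weights = wt)

  names_map <- c(lkd = "kd", lbmax = "bmax", lalpha = "alpha_l",
                 ns = "ns_slope", b0 = "baseline")
  names_out <- unname(names_map[names(stats::coef(fit))])
  log_idx <- names(stats::coef(fit)) %in% c("lkd", "lbmax", "lalpha")
  nat <- .natural_scale(fit, names_out, log_idx)
  if (include_ns) {
    # undo the order-1 regressor scaling: slope in CPM per molar
    i <- match("ns_slope", names(nat$estimates))
    nat$estimates[i] <- nat$estimates[i] / cmax
    nat$standard_errors[i] <- nat$standard_errors[i] / cmax
    nat$ci[i, ] <- nat$ci[i, ] / cmax
    nat$covariance[i, ] <- nat$covariance[i, ] / cmax
    nat$covariance[, i] <- nat$covariance[, i] / cmax
  }

  notes <- character()
  if (free_alpha && all(is.finite(diag(nat$covariance))) &&
      all(diag(nat$covariance) > 0)) {
    cr <- stats::cov2cor(nat$covariance)["kd", "alpha_l"]
    if (is.finite(cr) && abs(cr) > 0.99) {
      notes <- c(notes, paste0(
        "(kd, alpha_l) nearly degenerate (correlation ",
        sprintf("%.3f", cr),
        "): midpoint-dominated data constrain only kd/alpha_l"))
    }
  }
  if (!free_alpha) {
    nat$estimates <- c(nat$estimates, alpha_l = fix_alpha)
    nat$standard_errors <- c(nat$standard_errors, alpha_l = 0)
  }
  .new_fit(nat$estimates, nat$standard_errors, nat$covariance,
           stats::resid(fit), stats::fitted(fit), converged = TRUE,
           ci = nat$ci, notes = notes,
           terms = list(include_ns = include_ns,
                        include_baseline = include_baseline))
}

#' Fit the saturated competition model to a CPM curve
#'
#' Nonlinear least squares of
#' \eqn{CPM = B_{max} f_L([I]/IC_{50}, \beta) + b_0} with \eqn{f_L} the
#' saturated competition isotherm.  Only \eqn{(IC_{50}, \beta)} and the
#' signal parameters are estimable from a competition curve; the molecular
#' decomposition (into \eqn{EC_{50,L}}, \eqn{EC_{50,I}}, or the individual
#' cooperativity factors) is over-determined and is deliberately not
#' attempted.  \eqn{\beta} estimates hitting the bounds (1e-3, 1e3) are
#' flagged.
#'
#' @param curve A competition [binding_curve()].
#' @param include_baseline Include a constant baseline? Default FALSE.
#' @inheritParams fit_saturation
#' @return A `fibril_fit` with estimates among `ic50`, `beta`, `bmax`,
#'   `baseline`.
#' @export
fit_competition <- function(curve, include_baseline = FALSE,
                            weights = c("none", "proportional"),
                            n_starts = 5L, seed = 1L) {
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "binding_curve"))
  if (attr(curve, "assay_type") != "competition") {
    stop("`curve` is not a competition assay")
  }
  if (nrow(curve) < 5L) stop("need at least 5 records")
  d <- data.frame(conc = curve$concentration, cpm = curve$signal)
  bmax0 <- max(d$cpm)
  ic50_0 <- {
    half <- which(d$cpm <= bmax0 / 2)
    if (length(half)) d$conc[half[1L]]
    else stats::median(d$conc[d$conc > 0])
  }
  if (!is.finite(ic50_0) || ic50_0 <= 0) {
    ic50_0 <- exp(mean(log(d$conc[d$conc > 0])))
  }
  base_term <- if (include_baseline) " + b0" else ""
  form <- stats::as.formula(paste0(
    "cpm ~ 10^lbmax * competition_fraction(conc / 10^lic50, 10^lbeta)",
    base_term))
  start <- list(lic50 = log10(ic50_0), lbeta = 0, lbmax = log10(bmax0))
  lower <- c(lic50 = log10(min(d$conc[d$conc > 0])) - 6, lbeta = -3,
             lbmax = log10(bmax0) - 4)
  upper <- c(lic50 = log10(max(d$conc)) + 6, lbeta = 3,
             lbmax = log10(bmax0) + 4)
  if (include_baseline) {
    start$b0 <- min(d$cpm)
    lower <- c(lower, b0 = -Inf)
    upper <- c(upper, b0 = Inf)
  }
  wt <- if (weights == "proportional") {
    1 / pmax(abs(d$cpm), max(abs(d$cpm)) * 1e-3)^2
  } else NULL
  fit <- .multistart_nls(form, d, start, lower, upper, n_starts, seed,
                         weights = wt)

  names_map <- c(lic50 = "ic50", lbeta = "beta", lbmax = "bmax",
                 b0 = "baseline")
  names_out <- unname(names_map[names(stats::coef(fit))])
  log_idx <- names(stats::coef(fit)) %in% c("lic50", "lbeta", "lbmax")
  nat <- .natural_scale(fit, names_out, log_idx)
  notes <- character()
  lbeta_hat <- stats::coef(fit)["lbeta"]
  if (lbeta_hat <= -3 + 1e-6 || lbeta_hat >= 3 - 1e-6) {
    notes <- c(notes, "beta estimate at its bound (1e-3 or 1e3)")
  }
  .new_fit(nat$estimates, nat$standard_errors, nat$covariance,
           stats::resid(fit), stats::fitted(fit), converged = TRUE,
           ci = nat$ci, notes = notes,
           terms = list(include_baseline = include_baseline))
}

#' Profile the fit objective along the (KD, alpha_L) ridge
#'
#' For each value of \eqn{\alpha_L} on a grid, fixes the midpoint ratio
#' \eqn{K_D/\alpha_L} at its fitted value, sets
#' \eqn{K_D = \alpha_L \cdot (K_D/\alpha_L)}, re-solves the linear signal
#' parameters (Bmax and, if present, non-specific slope and baseline) by
#' ordinary least squares, and records the residual sum of squares.  For a
#' competition fit the predicted curve is rebuilt through the molecular
#' route (\eqn{EC_{50,L} = K_D/\alpha_L}, \eqn{\beta} from the pair
#' factors), so the profile is exactly flat: the competition assay cannot
#' decompose its midpoint into per-site affinity and cooperativity.  For a
#' saturation curve with wide dynamic range the profile is curved, because
#' steepness breaks the degeneracy.
#'
#' @param curve The fitted [binding_curve()].
#' @param fit The corresponding `fibril_fit` from [fit_saturation()] or
#'   [fit_competition()].
#' @param alpha_grid Grid of \eqn{\alpha_L} values (default 30 log-spaced
#'   values over 3 orders of magnitude around 1).
#' @return data.frame with columns `alpha_l`, `kd`, `objective`.
#' @export
identifiability_profile <- function(curve, fit,
                                    alpha_grid = 10^seq(-1.5, 1.5,
                                                        length.out = 30)) {
  stopifnot(inherits(curve, "binding_curve"), inherits(fit, "fibril_fit"))
  assay <- attr(curve, "assay_type")
  conc <- curve$concentration
  y <- curve$signal
  include_ns <- isTRUE(fit$terms$include_ns)
  include_baseline <- isTRUE(fit$terms$include_baseline)

  shape_for <- function(alpha) {
    if (assay == "saturation") {
      ec50 <- fit$estimates["kd"] / fit$estimates["alpha_l"]
      kd <- ec50 * alpha
      saturation_fraction(conc / kd, alpha)
    } else {
      # molecular route: pick alpha_i = alpha, chi to realize fitted beta;
      # the saturated isotherm depends on them only through (IC50, beta)
      beta <- fit$estimates["beta"]
      ic50 <- fit$estimates["ic50"]
      conc_l <- attr(curve, "radioligand_conc")
      ec50_l <- conc_l  # any positive choice cancels in x below
      ec50_i <- ic50 * ec50_l / conc_l
      chi <- sqrt(beta * alpha * alpha)
      beta_check <- beta_from_factors(alpha, alpha, chi)
      x <- conc * ec50_l / (ec50_i * conc_l)
      competition_fraction(x, beta_check)
    }
  }
  objective_for <- function(alpha) {
    f <- shape_for(alpha)
    design <- cbind(bmax = f)
    if (include_ns) design <- cbind(design, ns = conc)
    if (include_baseline || assay == "competition") {
      if (include_baseline) design <- cbind(design, b0 = 1)
    }
    coef <- stats::lm.fit(design, y)$coefficients
    sum((y - design %*% ifelse(is.na(coef), 0, coef))^2)
  }
  kd <- if (assay == "saturation") {
    fit$estimates["kd"] / fit$estimates["alpha_l"] * alpha_grid
  } else {
    rep(NA_real_, length(alpha_grid))
  }
  data.frame(alpha_l = alpha_grid, kd = kd,
             objective = vapply(alpha_grid, objective_for, numeric(1)))
}
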