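#' Non-cooperative (Langmuir) binding fraction
#'
#' Fraction of independent receptor sites occupied at a reduced ligand
#' concentration \eqn{c = [L]/K_D}: \eqn{f = c / (1 + c)}.
#'
#' @param conc_ratio Dimensionless ratio \eqn{[L]/K_D}, >= 0. Vectorized.
#' @return Fraction bound in \[0, 1\].
#' @examples
#' langmuir_fraction(1) # 0.5, midpoint at [L] = KD
#' @export
langmuir_fraction <- function(conc_ratio) {
  .check_nonneg(conc_ratio, "conc_ratio")
  conc_ratio / (1 + conc_ratio)
}

#' Cooperative saturation isotherm (infinite 1-D lattice)
#'
#' Mean fraction of fibril sites bound by a ligand whose adjacent bound
#' pairs carry a nearest-neighbor Boltzmann factor `alpha_l`, in the limit
#' of infinitely many sites.  With \eqn{c = [L]/K_D} and
#' \eqn{\alpha = \alpha_L}:
#' \deqn{f_L = \frac{(\alpha c - 1) + \sqrt{(\alpha c - 1)^2 + 4c}}
#'                  {2\sqrt{(\alpha c - 1)^2 + 4c}}.}
#' This is the largest-eigenvalue result of the two-state transfer matrix;
#' `alpha_l = 1` recovers [langmuir_fraction()].  The midpoint sits at
#' \eqn{c = 1/\alpha_L}, i.e. \eqn{EC_{50} = K_D/\alpha_L}.
#'
#' @param conc_ratio Dimensionless \eqn{[L]/K_D}, >= 0. Vectorized.
#' @param alpha_l Dimensionless nearest-neighbor Boltzmann factor, >= 0.
#'   Values > 1 mean favorable ligand-ligand stacking.
#' @return Fraction bound in \[0, 1\]; 0 at `conc_ratio = 0` (continuous
#'   limit).
#' @examples
#' saturation_fraction(1, 1)      # 0.5
#' saturation_fraction(0.1, 10)   # 0.5: midpoint shifted to KD/alpha
#' @export
saturation_fraction <- function(conc_ratio, alpha_l) {
  .check_nonneg(conc_ratio, "conc_ratio")
  .check_nonneg(alpha_l, "alpha_l", scalar = TRUE)
  a <- alpha_l * conc_ratio - 1
  disc <- sqrt(a^2 + 4 * conc_ratio)
  # disc = 0 only when conc_ratio = 0 and alpha*0 - 1 = -1 => disc = 1; the
  # truly degenerate denominator cannot occur for conc_ratio >= 0, but guard
  # the c = 0 limit explicitly.
  out <- (a + disc) / (2 * disc)
  out[conc_ratio == 0] <- 0
  out
}

#' Saturation-assay midpoint
#'
#' \eqn{EC_{50,L} = K_D / \alpha_L}: cooperativity shifts the apparent
#' affinity left of the intrinsic per-site \eqn{K_D}.
#'
#' @param kd Single-site dissociation constant (molar), > 0.
#' @param alpha_l Nearest-neighbor Boltzmann factor, > 0.
#' @return Midpoint concentration (molar).
#' @export
ec50_saturation <- function(kd, alpha_l) {
  .check_pos(kd, "kd")
  .check_pos(alpha_l, "alpha_l")
  kd / alpha_l
}

#' Saturated competition isotherm
#'
#' Fraction of sites occupied by the radioligand when every site holds
#' either radioligand or inhibitor (the fully saturated two-state
#' reduction), as a function of \eqn{x = [I]/IC_{50}} and the relative
#' cross-cooperativity \eqn{\beta = \chi^2/(\alpha_L\alpha_I)}:
#' \deqn{f_L = \frac{(1-x) + \sqrt{(1-x)^2 + 4\beta x}}
#'                  {2\sqrt{(1-x)^2 + 4\beta x}}.}
#' \eqn{\beta} is a pure shape parameter: \eqn{\beta = 1} gives the
#' non-steep hyperbola \eqn{IC_{50}/(IC_{50}+[I])}, \eqn{\beta < 1} a steep
#' curve, and \eqn{\beta > 3} a biphasic curve with a plateau around
#' \eqn{f_L = 1/2}.  The curve obeys \eqn{f(x) + f(1/x) = 1}.
#'
#' @param x Dimensionless \eqn{[I]/IC_{50}}, >= 0. Vectorized.
#' @param beta Relative cross-cooperativity, >= 0.
#' @return Radioligand fraction of occupied sites, in \[0, 1\].
#' @examples
#' competition_fraction(1, 5)     # 0.5 at the midpoint for any beta
#' competition_fraction(10, 1)    # 1/11, independent-site limit
#' @export
competition_fraction <- function(x, beta) {
  .check_nonneg(x, "x")
  .check_nonneg(beta, "beta", scalar = TRUE)
  a <- 1 - x
  disc <- sqrt(a^2 + 4 * beta * x)
  out <- ifelse(disc > 0, (a + disc) / (2 * disc), NA_real_)
  # beta = 0, x = 1 is a 0/0 point; the symmetric limit is 1/2.  beta = 0
  # with x < 1 gives 1 (all radioligand), x > 1 gives 0; x = 0 gives 1.
  out[disc == 0] <- 0.5
  out
}

#' Competition-assay midpoint in the saturated model
#'
#' \eqn{IC_{50} = EC_{50,I}\,[L]/EC_{50,L}} where \eqn{EC_{50,L} =
#' K_D/\alpha_L} and \eqn{EC_{50,I} = K_I/\alpha_I} are the standalone
#' midpoints of the radioligand and inhibitor.  Unlike the Cheng-Prusoff
#' relation there is no "+1": the saturated lattice has no empty sites.
#' At equal radioligand concentration the IC50 ratio of two inhibitors
#' equals the ratio of their \eqn{EC_{50,I}}.
#'
#' @param ec50_i Inhibitor standalone midpoint (molar), > 0.
#' @param conc_l Free radioligand concentration (molar), > 0.
#' @param ec50_l Radioligand standalone midpoint (molar), > 0.
#' @return IC50 (molar).
#' @seealso [cheng_prusoff_ic50()] for the receptor-style relation.
#' @export
ic50_saturated <- function(ec50_i, conc_l, ec50_l) {
  .check_pos(ec50_i, "ec50_i")
  .check_pos(conc_l, "conc_l")
  .check_pos(ec50_l, "ec50_l")
  ec50_i * conc_l / ec50_l
}

#' Cheng-Prusoff IC50 for independent receptor sites
#'
#' The classical competitive-displacement relation
#' \eqn{IC_{50} = K_I (1 + [L]/K_D)}, provided for comparison with
#' [ic50_saturated()]; the two agree as \eqn{[L]/K_D \to \infty} (when
#' \eqn{EC_{50}}s equal the \eqn{K}s).
#'
#' @param ki Inhibitor dissociation constant (molar), > 0.
#' @param conc_l Free radioligand concentration (molar), > 0.
#' @param kd Radioligand dissociation constant (molar), > 0.
#' @return IC50 (molar).
#' @export
cheng_prusoff_ic50 <- function(ki, conc_l, kd) {
  .check_pos(ki, "ki")
  .check_pos(conc_l, "conc_l")
  .check_pos(kd, "kd")
  ki * (1 + conc_l / kd)
}

#' Hot/cold displacement fraction
#'
#' When the inhibitor is the chemically identical unlabeled ("cold") form
#' of the radioligand, all binding parameters coincide, \eqn{\beta = 1}
#' trivially, and the bound radioligand fraction is just the hot mole
#' fraction \eqn{[L]/([L]+[I])}.  Equivalently
#' `competition_fraction(conc_i/conc_l, beta = 1)`.
#'
#' @param conc_l Free radioligand ("hot") concentration (molar), >= 0.
#' @param conc_i Free unlabeled ("cold") concentration (molar), >= 0.
#'   `conc_l + conc_i` must be > 0.
#' @return Hot mole fraction in \[0, 1\].
#' @export
hot_cold_fraction <- function(conc_l, conc_i) {
  .check_nonneg(conc_l, "conc_l")
  .check_nonneg(conc_i, "conc_i")
  if (any(conc_l + conc_i <= 0)) {
    stop("`conc_l + conc_i` must be > 0")
  }
  conc_l / (conc_l + conc_i)
}

#' Relative cross-cooperativity from Boltzmann factors
#'
#' \eqn{\beta = \chi^2 / (\alpha_L \alpha_I)}.  In energy space
#' \eqn{\beta = 1} exactly when the cross-cooperativity energy is the
#' arithmetic mean of the two self-cooperativity energies,
#' \eqn{C_{L-I} = (C_L + C_I)/2}.
#'
#' @param alpha_l Radioligand self-cooperativity factor, > 0.
#' @param alpha_i Inhibitor self-cooperativity factor, > 0.
#' @param chi Radioligand-inhibitor cross-cooperativity factor, >= 0.
#' @return Dimensionless beta >= 0.
#' @export
beta_from_factors <- function(alpha_l, alpha_i, chi) {
  .check_pos(alpha_l, "alpha_l")
  .check_pos(alpha_i, "alpha_i")
  .check_nonneg(chi, "chi")
  chi^2 / (alpha_l * alpha_i)
}

#' Log-concentration derivatives of the competition isotherm at its midpoint
#'
#' Numerically differentiates [competition_fraction()] with respect to
#' \eqn{u = \ln([I]/IC_{50})} at \eqn{u = 0}, by central differences with
#' one step of Richardson extrapolation (error \eqn{O(h^4)}; the odd
#' symmetry of the curve about its midpoint cancels even-order error terms).
#' Closed forms, used as cross-checks in the test-suite:
#' first derivative \eqn{-1/(4\sqrt\beta)}; third derivative
#' \eqn{(3-\beta)/(16\,\beta^{3/2})}, which changes sign at \eqn{\beta = 3}
#' -- the onset of the mid-curve plateau of the biphasic regime.
#'
#' @param beta Relative cross-cooperativity, > 0.
#' @param order Derivative order: 1 or 3.
#' @param h Base step in \eqn{\ln x}. The default is accurate to well below
#'   1e-8 for order 3 over beta in \[0.1, 100\].
#' @return The derivative value (dimensionless).
#' @seealso [critical_beta()]
#' @export
midpoint_log_derivative <- function(beta, order = 1, h = 0.05) {
  .check_pos(beta, "beta")
  if (!order %in% c(1, 3)) stop("`order` must be 1 or 3")
  g <- function(u) competition_fraction(exp(u), beta)
  stencil <- if (order == 1) {
    function(h) (g(h) - g(-h)) / (2 * h)
  } else {
    function(h) (g(2 * h) - 2 * g(h) + 2 * g(-h) - g(-2 * h)) / (2 * h^3)
  }
  # central stencils have O(h^2) leading error; two Richardson levels give
  # O(h^6) while h stays large enough to avoid roundoff in the h^3 divisor
  d0 <- stencil(h)
  d1 <- stencil(h / 2)
  d2 <- stencil(h / 4)
  r1 <- (4 * d1 - d0) / 3
  r2 <- (4 * d2 - d1) / 3
  (16 * r2 - r1) / 15
}

#' Critical relative cross-cooperativity for the biphasic plateau
#'
#' Root of the third midpoint log-derivative of the saturated competition
#' isotherm over \eqn{\beta \in (1, 10)}.  Below the root the curve is a
#' monotone sigmoid steeper than its tails; above it the midpoint develops
#' a plateau (the curve "splits"), resembling a two-site system.  The
#' analytic value is exactly 3.
#'
#' @param interval Search bracket for the root.
#' @param tol Root-finder tolerance.
#' @return The critical beta (about 3).
#' @export
critical_beta <- function(interval = c(1.5, 10), tol = 1e-10) {
  stats::uniroot(function(b) midpoint_log_derivative(b, order = 3),
                 interval = interval, tol = tol)$root
}

# -- input guards -------------------------------------------------------

.check_nonneg <- function(x, name, scalar = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      (scalar && length(x) != 1L)) {
    stop(sprintf("`%s` must be %sfinite and >= 0",
                 name, if (scalar) "a single value, " else ""))
  }
  invisible(x)
}

.check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name))
  }
  invisible(x)
}
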