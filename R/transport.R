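#' Brush porosity
#'
#' Fraction of the brush volume not occupied by chain beads,
#' \eqn{\phi = 1 - \frac{4}{3}\pi a_f^3 N_\mathrm{bead} / (d^2 L_z)}:
#' each chain of `n_bead` spheres of radius `a_f` occupies a column of
#' footprint \eqn{d^2} and height \eqn{L_z}.
#'
#' @param a_f Bead radius (\eqn{\sigma}); left free in the tortuosity fits.
#' @param n_bead Beads per chain.
#' @param d Tether spacing (\eqn{\sigma}).
#' @param L_z Brush height (\eqn{\sigma}).
#' @return Porosity in (0, 1].
#' @examples
#' porosity(0.5, 101, 3, 50)  # about 0.8825
#' @export
porosity <- function(a_f, n_bead, d, L_z) {
  stopifnot(a_f >= 0, n_bead > 0, d > 0, L_z > 0)
  phi <- 1 - (4 / 3) * pi * a_f^3 * n_bead / (d^2 * L_z)
  if (any(phi <= 0))
    stop("overpacked geometry: porosity must be positive")
  phi
}

#' Tortuosity-porosity models
#'
#' Squared tortuosity \eqn{\tau^2(\phi)} for the model families used to
#' describe effective diffusion, \eqn{D_\mathrm{eff}/D_\mathrm{bulk} = 1/\tau^2}:
#' \describe{
#'   \item{`hyperbola_of_revolution`}{\eqn{\tau^2 = 2 - \phi}}
#'   \item{`ordered_packings`}{\eqn{\tau^2 = (3 - \phi)/2}}
#'   \item{`heterogeneous_catalyst`}{\eqn{\tau^2 = \phi / [1 - (1-\phi)^{1/3}]}}
#'   \item{`cation_exchange_resin`}{\eqn{\tau = (2 - \phi)/\phi}
#'     (Mackie-Meares random-walk lattice model)}
#'   \item{`custom`}{the generalized random-walk model with
#'     \eqn{p_\mathrm{first} = 1 - \phi} and
#'     \eqn{p_\mathrm{next} = k + (k - 1)(1 - \phi)}; see
#'     [generalized_tau()].}
#' }
#' All families satisfy \eqn{\tau^2(1) = 1} and \eqn{\tau^2 \ge 1} on (0,1).
#'
#' @param family Model family name.
#' @param phi Porosity values in (0, 1].
#' @param k Tunable parameter of the custom family, in (0, 1).
#' @return \eqn{\tau^2} evaluated at `phi`.
#' @examples
#' tau_squared("cation_exchange_resin", 0.5)  # ((2-0.5)/0.5)^2 = 9
#' @export
tau_squared <- function(family = c("hyperbola_of_revolution", "ordered_packings",
                                   "heterogeneous_catalyst",
                                   "cation_exchange_resin", "custom"),
                        phi, k = NULL) {
  family <- match.arg(family)
  stopifnot(all(phi > 0), all(phi <= 1))
  switch(family,
    hyperbola_of_revolution = 2 - phi,
    ordered_packings = (3 - phi) / 2,
    heterogeneous_catalyst = ifelse(phi == 1, 1, phi / (1 - (1 - phi)^(1 / 3))),
    cation_exchange_resin = ((2 - phi) / phi)^2,
    custom = {
      if (is.null(k)) stop("the custom family needs the parameter k")
      p_next <- k + (k - 1) * (1 - phi)
      if (any(phi < 1 & (p_next <= 0 | p_next >= 1)))
        stop("domain error: p_next outside (0,1) over the requested phi range")
      generalized_tau(1 - phi, pmin(p_next, 1 - 1e-15))^2
    })
}

#' Generalized random-walk tortuosity
#'
#' Closed form of the geometric-series tortuosity
#' \eqn{\tau = 1 + p_\mathrm{first} \sum_{n \ge 0} p_\mathrm{next}^n
#'      = 1 + p_\mathrm{first} / (1 - p_\mathrm{next})}:
#' a lattice walker pays one extra step with probability
#' \eqn{p_\mathrm{first}} of first hitting an obstacle, and further extra
#' steps with probability \eqn{p_\mathrm{next}} each of the obstacle
#' continuing. Mackie-Meares' resin model is the special case
#' \eqn{p_\mathrm{first} = 1 - \phi}, \eqn{p_\mathrm{next} = (2 - \phi)/2}.
#'
#' @param p_first Probability of first hitting an obstacle, in [0, 1].
#' @param p_next Probability that the obstacle continues, in [0, 1).
#' @return The tortuosity \eqn{\tau} (not squared).
#' @examples
#' generalized_tau(0.5, 0.75)  # 1 + 0.5/0.25 = 3
#' @export
generalized_tau <- function(p_first, p_next) {
  stopifnot(all(p_first >= 0), all(p_first <= 1), all(p_next >= 0))
  if (any(p_next >= 1)) stop("divergence error: p_next must be below 1")
  1 + p_first / (1 - p_next)
}

# model curves D/D_bulk as a function of d -------------------------------

.d_over_db <- function(family, d, L_z_of_d, n_bead, a_f = NULL, k = NULL,
                       n = NULL, c_ = NULL, power_form = "offset") {
  if (family == "power_law_d") {
    if (power_form == "offset") return(1 - d^(-n) / c_)
    return(1 - c_ * d^(-n))
  }
  phi <- 1 - (4 / 3) * pi * a_f^3 * n_bead / (d^2 * L_z_of_d)
  phi <- pmin(pmax(phi, 1e-10), 1)
  1 / tau_squared(family, phi, k = k)
}

#' Fit an effective-diffusion model to D(d)/D_bulk
#'
#' Fits one model family to measured diffusion-constant ratios over a
#' spacing range (the dense-brush regime, d = 2-10 \eqn{\sigma}, in the
#' reference analysis). For the tortuosity families each spacing is mapped
#' to a porosity through [porosity()] using the simulated brush height
#' `L_z(d)` of that system type, with the bead radius `a_f` as the free
#' parameter (Levenberg-Marquardt). The `custom` family instead fixes
#' `a_f` at the physical bead radius (0.5 \eqn{\sigma}) and fits its
#' parameter k in (0, 1) by bounded trust-region least squares. The
#' `power_law_d` family fits \eqn{D/D_\mathrm{bulk} = 1 - d^{-n}/c}
#' (set `power_form = "prefactor"` for the variant \eqn{1 - c\,d^{-n}}).
#'
#' @param data A data frame with columns `d`, `ratio` (D/D_bulk) and, for
#'   tortuosity families, `L_z`.
#' @param family One of the [tau_squared()] families or `"power_law_d"`.
#' @param fit_range Spacing range `c(lo, hi)` used for the fit.
#' @param n_bead Beads per chain entering the porosity.
#' @param a_f_custom Fixed bead radius for the custom family.
#' @param power_form Which algebraic form of the power law to use.
#' @param start Optional named list of start values.
#' @return An object of class `brush_fit` with `coef`, `se`, the residual
#'   norm, the family and the fitted data; methods: `print`, `summary`,
#'   `coef`, `predict`.
#' @export
fit_D_vs_d <- function(data, family = c("hyperbola_of_revolution",
                                        "ordered_packings",
                                        "heterogeneous_catalyst",
                                        "cation_exchange_resin", "custom",
                                        "power_law_d"),
                       fit_range = c(2, 10), n_bead = 101,
                       a_f_custom = 0.5, power_form = c("offset", "prefactor"),
                       start = NULL) {
  family <- match.arg(family)
  power_form <- match.arg(power_form)
  sel <- data$d >= fit_range[1] & data$d <= fit_range[2]
  df <- data[sel, , drop = FALSE]
  if (nrow(df) < (if (family == "power_law_d") 4 else 3))
    stop("too few points in the fit range")
  lz_fun <- if (family != "power_law_d") {
    stopifnot("L_z" %in% names(data))
    function(d) approx(df$d, df$L_z, xout = d, rule = 2)$y
  } else NULL

  if (family == "power_law_d" && all(abs(df$ratio - 1) < 1e-10)) {
    # bulk-limit data: the obstruction term is driven to zero and its decay
    # exponent is unidentifiable
    return(structure(list(family = family, coef = c(n = 0, c = Inf),
                          se = c(n = NA_real_, c = NA_real_),
                          residual_norm = 0, fit_range_d = fit_range,
                          data = df, n_bead = n_bead,
                          power_form = power_form, nls = NULL),
                     class = "brush_fit"))
  }
  if (family == "power_law_d") {
    st <- if (is.null(start)) list(n = 0.5, c_ = 1.2) else start
    fit <- minpack.lm::nlsLM(
      ratio ~ .d_over_db("power_law_d", d, NULL, n_bead, n = n, c_ = c_,
                         power_form = power_form),
      data = df, start = st, control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit); names(cf) <- c("n", "c")
  } else if (family == "custom") {
    st <- if (is.null(start)) list(k = 0.9) else start
    fit <- minpack.lm::nlsLM(
      ratio ~ .d_over_db("custom", d, L_z, n_bead, a_f = a_f_custom, k = k),
      data = df, start = st, lower = 1e-6, upper = 1 - 1e-6,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit); names(cf) <- "k"
  } else {
    st <- if (is.null(start)) list(a_f = 1) else start
    fit <- minpack.lm::nlsLM(
      ratio ~ .d_over_db(family, d, L_z, n_bead, a_f = a_f),
      data = df, start = st, lower = 1e-6,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit); names(cf) <- "a_f"
  }
  se <- sqrt(diag(vcov(fit)))
  names(se) <- names(cf)
  structure(list(family = family, coef = cf, se = se,
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 fit_range_d = fit_range, data = df, n_bead = n_bead,
                 a_f_custom = a_f_custom, power_form = power_form,
                 lz_fun = lz_fun, nls = fit),
            class = "brush_fit")
}

#' Fit the anisotropy ratio power law
#'
#' Fits \eqn{D_\perp/D_\parallel = A d^{-l} + 1} over a spacing range by
#' Levenberg-Marquardt least squares. Ratio points at or below 1 are
#' retained in the fit (they are simply invisible in a log-log diagnostic
#' of ratio - 1).
#'
#' @param data Data frame with columns `d` and `ratio` (\eqn{D_\perp/D_\parallel}).
#' @param fit_range Spacing range, default d in [2.5, 25] \eqn{\sigma}.
#' @param start Optional start values, list(A =, l =).
#' @return A `brush_fit` with coefficients `A` and `l`.
#' @export
fit_ratio_power_law <- function(data, fit_range = c(2.5, 25), start = NULL) {
  sel <- data$d >= fit_range[1] & data$d <= fit_range[2]
  df <- data[sel, , drop = FALSE]
  if (nrow(df) < 4) stop("too few points in the fit range")
  stopifnot(all(df$ratio > 0))
  if (all(abs(df$ratio - 1) < 1e-10)) {
    # exactly isotropic input: the decay exponent is unidentifiable
    return(structure(list(family = "ratio_power_law",
                          coef = c(A = 0, l = NA_real_),
                          se = c(A = 0, l = NA_real_), residual_norm = 0,
                          fit_range_d = fit_range, data = df, nls = NULL),
                     class = "brush_fit"))
  }
  st <- if (is.null(start)) list(A = 10, l = 2) else start
  fit <- minpack.lm::nlsLM(ratio ~ A * d^(-l) + 1, data = df, start = st,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(family = "ratio_power_law", coef = cf, se = se,
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 fit_range_d = fit_range, data = df, nls = fit),
            class = "brush_fit")
}

#' Fit the mean-field brush-height scaling
#'
#' One-parameter fit of \eqn{L_z = A d^{-2/3}}; linear in A, so the least
#' squares solution is closed-form. Residuals are reported for judging how
#' well the system is inside the scaling regime.
#'
#' @param data Data frame with columns `d` and `L_z`.
#' @return A `brush_fit` with coefficient `A` and per-point residuals.
#' @export
fit_height_scaling <- function(data) {
  stopifnot(nrow(data) >= 3)
  x <- data$d^(-2 / 3)
  A <- sum(data$L_z * x) / sum(x^2)
  res <- data$L_z - A * x
  se <- sqrt(sum(res^2) / (nrow(data) - 1) / sum(x^2))
  structure(list(family = "height_scaling", coef = c(A = A), se = c(A = se),
                 residual_norm = sqrt(sum(res^2)), residuals = res,
                 fit_range_d = range(data$d), data = data),
            class = "brush_fit")
}

#' @export
print.brush_fit <- function(x, ...) {
  cat(sprintf("brush_fit [%s], d in [%g, %g]\n", x$family,
              x$fit_range_d[1], x$fit_range_d[2]))
  for (nm in names(x$coef))
    cat(sprintf("  %-4s = %.4g +- %.2g\n", nm, x$coef[[nm]], x$se[[nm]]))
  cat(sprintf("  residual norm %.3g on %d points\n", x$residual_norm,
              nrow(x$data)))
  invisible(x)
}

#' @export
coef.brush_fit <- function(object, ...) object$coef

#' @export
summary.brush_fit <- function(object, ...) {
  out <- data.frame(estimate = unname(object$coef), se = unname(object$se),
                    row.names = names(object$coef))
  attr(out, "family") <- object$family
  out
}

#' @export
predict.brush_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  d <- newdata$d
  cf <- as.list(object$coef)
  switch(object$family,
    ratio_power_law = cf$A * d^(-cf$l) + 1,
    height_scaling = cf$A * d^(-2 / 3),
    power_law_d = .d_over_db("power_law_d", d, NULL, object$n_bead,
                             n = cf$n, c_ = cf$c,
                             power_form = object$power_form),
    custom = .d_over_db("custom", d, object$lz_fun(d), object$n_bead,
                        a_f = object$a_f_custom, k = cf$k),
    .d_over_db(object$family, d, object$lz_fun(d), object$n_bead,
               a_f = cf$a_f))
}

# transport endpoint ------------------------------------------------------

#' Ion mixture for conductivity estimates
#'
#' Container for ionic species entering the Nernst-Einstein conductivity:
#' valency, concentration (mol/m^3) and diffusion constant (m^2/s) per
#' species, plus the temperature.
#'
#' `csf_ion_mixture()` builds a cerebrospinal-fluid-like composition from
#' standard literature values, grouped by valency magnitude (|z| = 1:
#' Na+ 147, K+ 3, Cl- 113, HCO3- 23; |z| = 2: Ca2+ 1.2, Mg2+ 1.1, all in
#' mmol/L = mol/m^3): 286 mol/m^3 of monovalent and 2.3 mol/m^3 of
#' divalent charge carriers. Supply the simulated diffusion constants (in
#' SI units, e.g. via [diffusion_si()]) for each valency group.
#'
#' @param z Integer valencies.
#' @param conc Concentrations, mol/m^3.
#' @param D Diffusion constants, m^2/s.
#' @param temperature Temperature in kelvin.
#' @return An object of class `ion_mixture`.
#' @export
ion_mixture <- function(z, conc, D, temperature = 310) {
  stopifnot(length(z) == length(conc), length(z) == length(D),
            length(z) >= 1, all(conc >= 0), all(D >= 0), temperature > 0)
  structure(list(z = as.integer(z), conc = conc, D = D,
                 temperature = temperature), class = "ion_mixture")
}

#' @rdname ion_mixture
#' @param D_mono,D_di Diffusion constants (m^2/s) of the monovalent and
#'   divalent groups.
#' @export
csf_ion_mixture <- function(D_mono, D_di = D_mono, temperature = 310) {
  ion_mixture(z = c(1L, 2L), conc = c(286, 2.3), D = c(D_mono, D_di),
              temperature = temperature)
}

#' Nernst-Einstein electrical conductivity
#'
#' \eqn{\sigma_e = \frac{F^2}{RT} \sum_x D_x z_x^2 [x]} with Faraday's
#' constant F and the gas constant R, in SI units (S/m).
#'
#' @param mixture An [ion_mixture()].
#' @return Conductivity in S/m.
#' @export
conductivity <- function(mixture) {
  stopifnot(inherits(mixture, "ion_mixture"))
  faraday <- 96485.33212
  gas_r <- 8.314462618
  faraday^2 / (gas_r * mixture$temperature) *
    sum(mixture$D * mixture$z^2 * mixture$conc)
}

#' Resistance of a thin spherical shell
#'
#' Resistance of a resistive shell of thickness `h` around a sphere of
#' radius `r` with resistivity `rho_e`:
#' \eqn{R = \frac{\rho_e}{4\pi} \frac{h}{r (r + h)}}, the radial integral
#' of \eqn{\rho_e\, \mathrm{d}r' / (4\pi r'^2)} over \eqn{[r, r+h]}. Models
#' the net wrapping a neuron soma.
#'
#' @param rho_e Resistivity, ohm m.
#' @param r_neuron Neuron radius, m.
#' @param h Shell thickness, m.
#' @return Resistance in ohm.
#' @export
shell_resistance <- function(rho_e, r_neuron, h) {
  stopifnot(all(rho_e > 0), all(r_neuron > 0), all(h >= 0))
  rho_e / (4 * pi) * h / (r_neuron * (r_neuron + h))
}

#' Diffusive traversal time through the brush
#'
#' Time for a particle with perpendicular diffusion constant `D_perp` to
#' traverse a height `h`, from \eqn{\langle\Delta z^2\rangle = 2 D_\perp t}:
#' \eqn{t = h^2 / (2 D_\perp)}.
#'
#' @param D_perp Perpendicular diffusion constant in \eqn{\sigma^2/\tau}
#'   (reduced units).
#' @param h Height in metres (e.g. 500e-9 for a 500 nm brush).
#' @param units A [unit_system()] supplying the physical time and length
#'   mapping.
#' @return Traversal time in seconds.
#' @export
traversal_time <- function(D_perp, h, units = unit_system()) {
  stopifnot(all(D_perp > 0), all(h >= 0))
  if (!inherits(units, "unit_system"))
    stop("a unit_system is required to express the time in seconds")
  h^2 / (2 * diffusion_si(D_perp, units))
}
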