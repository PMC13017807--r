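#' Species-level photosynthetic parameters
#'
#' Constructor for the parameter set describing one species (or one
#' calibration): maximum carboxylation and electron-transport capacities at
#' 25 degC, day respiration, quantum yield, oxygen concentration, the
#' minimum stomatal conductance floor, and the fixed coefficients of the
#' peaked-Arrhenius temperature responses.
#'
#' Defaults are the calibrated values for orchard citrus (averages over five
#' A-ci response curves) together with the standard temperature-response
#' coefficients.
#'
#' @param Vcmax25 Maximum Rubisco carboxylation rate at 25 degC,
#'   umol m-2 s-1.
#' @param Jmax25 Potential maximum electron transport rate at 25 degC,
#'   umol m-2 s-1.
#' @param Rd25 Mitochondrial (day) respiration at 25 degC, umol m-2 s-1.
#' @param alpha Quantum yield of electron transport (dimensionless).
#' @param O Intercellular O2 concentration, mmol mol-1.
#' @param gmin Minimum stomatal conductance to water, mol m-2 s-1.
#' @param R Universal gas constant, J mol-1 K-1.
#' @param dS_v,dS_j Entropy terms for Vcmax and Jmax, J mol-1 K-1.
#' @param Ea_v,Ea_j Activation energies for Vcmax and Jmax, J mol-1.
#' @param Hd Deactivation energy (shared), J mol-1.
#' @param rd_temperature_mode Either `"constant"` (Rd = Rd25 at all
#'   temperatures; the default, since no entropy/activation coefficients are
#'   calibrated for Rd) or `"arrhenius"` (simple exponential response with
#'   activation energy `Ea_rd`).
#' @param Ea_rd Activation energy for Rd when
#'   `rd_temperature_mode = "arrhenius"`, J mol-1.
#' @return An object of class `species_params` (a validated list).
#' @examples
#' p <- species_params()
#' p$Vcmax25
#' @export
species_params <- function(Vcmax25 = 43.21, Jmax25 = 75.56, Rd25 = 1.77,
                           alpha = 0.24, O = 210, gmin = 0.01, R = 8.314,
                           dS_v = 629.26, dS_j = 631.88,
                           Ea_v = 58550, Ea_j = 29680, Hd = 200000,
                           rd_temperature_mode = c("constant", "arrhenius"),
                           Ea_rd = 46390) {
  rd_temperature_mode <- match.arg(rd_temperature_mode)
  p <- list(Vcmax25 = Vcmax25, Jmax25 = Jmax25, Rd25 = Rd25, alpha = alpha,
            O = O, gmin = gmin, R = R, dS_v = dS_v, dS_j = dS_j,
            Ea_v = Ea_v, Ea_j = Ea_j, Hd = Hd,
            rd_temperature_mode = rd_temperature_mode, Ea_rd = Ea_rd,
            gm = Inf)
  validate_species_params(p)
  class(p) <- "species_params"
  p
}

validate_species_params <- function(p) {
  num <- c("Vcmax25", "Jmax25", "Rd25", "alpha", "O", "gmin", "R",
           "dS_v", "dS_j", "Ea_v", "Ea_j", "Hd")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("species_params: '", f, "' must be a single finite number",
           call. = FALSE)
  }
  stopifnot(p$Vcmax25 > 0, p$Jmax25 > 0, p$Rd25 > 0,
            p$alpha > 0, p$alpha < 1, p$O > 0, p$gmin > 0, p$R > 0)
  invisible(p)
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species photosynthetic parameters\n")
  cat(sprintf("  Vcmax25 %.2f  Jmax25 %.2f  Rd25 %.2f  umol m-2 s-1\n",
              x$Vcmax25, x$Jmax25, x$Rd25))
  cat(sprintf("  alpha %.2f  O %.0f mmol mol-1  gmin %.3f mol m-2 s-1\n",
              x$alpha, x$O, x$gmin))
  cat(sprintf("  Rd temperature mode: %s\n", x$rd_temperature_mode))
  invisible(x)
}

#' Meteorological drivers for one or more leaf observations
#'
#' Builds a data frame of leaf-surface drivers. Leaf temperature `Tl`
#' defaults to the leaf-surface air temperature `Ta`; the Kelvin temperature
#' is always `Tl + 273.15`.
#'
#' @param Q Photosynthetic photon flux density, umol m-2 s-1.
#' @param Ta Leaf-surface air temperature, degC.
#' @param D Vapor pressure deficit, kPa.
#' @param ca Ambient CO2 concentration, umol mol-1.
#' @param P Air pressure at the leaf surface, kPa.
#' @param Tl Leaf temperature, degC; defaults to `Ta`.
#' @param day_id Grouping key for measurement day (recycled).
#' @param timestamp Optional timestamps (recycled).
#' @return A `data.frame` with columns `Q, Ta, Tl, Tk, D, ca, P, day_id`
#'   (and `timestamp` if supplied).
#' @examples
#' meteo_inputs(Q = 1000, Ta = 30, D = 2, ca = 400, P = 95)
#' @export
meteo_inputs <- function(Q, Ta, D, ca, P, Tl = Ta, day_id = 1L,
                         timestamp = NULL) {
  n <- max(length(Q), length(Ta), length(D), length(ca), length(P))
  m <- data.frame(Q = rep_len(Q, n), Ta = rep_len(Ta, n),
                  Tl = rep_len(Tl, n), D = rep_len(D, n),
                  ca = rep_len(ca, n), P = rep_len(P, n),
                  day_id = rep_len(day_id, n))
  m$Tk <- m$Tl + 273.15
  if (!is.null(timestamp)) m$timestamp <- rep_len(timestamp, n)
  bad <- !is.finite(m$Q) | !is.finite(m$D) | !is.finite(m$ca) |
    !is.finite(m$P) | !is.finite(m$Tk)
  if (any(bad)) stop("meteo_inputs: non-finite driver values", call. = FALSE)
  if (any(m$Q < 0)) stop("meteo_inputs: Q must be >= 0", call. = FALSE)
  if (any(m$D <= 0)) stop("meteo_inputs: D must be > 0", call. = FALSE)
  if (any(m$P <= 0)) stop("meteo_inputs: P must be > 0", call. = FALSE)
  if (any(m$ca <= 0)) stop("meteo_inputs: ca must be > 0", call. = FALSE)
  m[c("Q", "Ta", "Tl", "Tk", "D", "ca", "P", "day_id",
      intersect("timestamp", names(m)))]
}

#' Peaked Arrhenius temperature response
#'
#' Scales a biochemical rate from its 25 degC reference value to leaf
#' temperature using the peaked (deactivating) Arrhenius function
#' \deqn{f(T_k) = k_{25}\, e^{E_a (T_k-298)/(298 R T_k)}
#'   \frac{1 + e^{(298\Delta S - H_d)/(298R)}}
#'        {1 + e^{(T_k\Delta S - H_d)/(T_k R)}}.}
#' The reference temperature in the exponents is 298 K, exactly as the
#' calibrated coefficients assume (not 298.15).
#'
#' @param k25 Rate at 25 degC (any rate unit; returned in the same unit).
#' @param Tk Leaf temperature, K. Vectorised.
#' @param Ea Activation energy, J mol-1.
#' @param dS Entropy term, J mol-1 K-1.
#' @param Hd Deactivation energy, J mol-1.
#' @param R Gas constant, J mol-1 K-1.
#' @return The rate at `Tk`; equals `k25` at `Tk = 298` by construction.
#' @examples
#' peaked_arrhenius(43.21, 308, 58550, 629.26, 200000)
#' @export
peaked_arrhenius <- function(k25, Tk, Ea, dS, Hd, R = 8.314) {
  if (!all(is.finite(c(k25, Tk, Ea, dS, Hd, R))))
    stop("peaked_arrhenius: non-finite input", call. = FALSE)
  if (any(k25 <= 0) || any(Tk <= 0))
    stop("peaked_arrhenius: k25 and Tk must be positive", call. = FALSE)
  k25 * exp(Ea * (Tk - 298) / (298 * R * Tk)) *
    (1 + exp((298 * dS - Hd) / (298 * R))) /
    (1 + exp((Tk * dS - Hd) / (Tk * R)))
}

# Simple (non-peaked) Arrhenius used for gamma*, Kc, Ko and optionally Rd.
arrhenius_scale <- function(k25, Tk, Ea, R = 8.314) {
  k25 * exp(Ea * (Tk - 298) / (298 * R * Tk))
}

#' CO2 compensation point in the absence of day respiration
#'
#' \eqn{\Gamma^* = 42.75\, e^{37830 (T_k - 298)/(298 R T_k)}} umol mol-1.
#'
#' @param Tk Leaf temperature, K. Vectorised.
#' @param R Gas constant, J mol-1 K-1.
#' @return Gamma-star, umol mol-1; monotone increasing in `Tk`.
#' @examples
#' gamma_star(298)  # 42.75
#' @export
gamma_star <- function(Tk, R = 8.314) {
  if (!all(is.finite(Tk)) || any(Tk <= 0))
    stop("gamma_star: Tk must be finite and positive", call. = FALSE)
  arrhenius_scale(42.75, Tk, 37830, R)
}

#' Michaelis-Menten coefficients of Rubisco
#'
#' Temperature-corrected Kc (for CO2, umol mol-1) and Ko (for O2,
#' mmol mol-1), and the effective Michaelis coefficient
#' `Km = Kc * (1 + O / Ko)`.
#'
#' @param Tk Leaf temperature, K. Vectorised.
#' @param O Intercellular O2 concentration, mmol mol-1.
#' @param R Gas constant, J mol-1 K-1.
#' @return A list with components `Kc`, `Ko`, `Km`.
#' @examples
#' michaelis(298, O = 210)
#' @export
michaelis <- function(Tk, O = 210, R = 8.314) {
  if (!all(is.finite(c(Tk, O))) || any(Tk <= 0) || any(O <= 0))
    stop("michaelis: Tk and O must be finite and positive", call. = FALSE)
  Kc <- arrhenius_scale(274.6, Tk, 80500, R)
  Ko <- arrhenius_scale(419.8, Tk, 14500, R)
  list(Kc = Kc, Ko = Ko, Km = Kc * (1 + O / Ko))
}

#' Rate of electron transport
#'
#' Non-rectangular light response
#' \eqn{J = \alpha Q / \sqrt{1 + \alpha^2 Q^2 / J_{max}^2}}: linear with
#' slope `alpha` at low light, saturating towards `Jmax` at high light.
#'
#' @param Q Photosynthetic photon flux density, umol m-2 s-1. Vectorised.
#' @param Jmax Maximum electron transport rate at leaf temperature,
#'   umol m-2 s-1.
#' @param alpha Quantum yield of electron transport.
#' @return J, umol m-2 s-1; `0 <= J < Jmax` for finite `Q`.
#' @examples
#' electron_transport(1000, 75.56, 0.24)
#' @export
electron_transport <- function(Q, Jmax, alpha) {
  stopifnot(all(Q >= 0), all(Jmax > 0), alpha > 0)
  alpha * Q / sqrt(1 + alpha^2 * Q^2 / Jmax^2)
}

#' Temperature-adjusted kinetic state at one observation
#'
#' Bundles every temperature (and light) correction needed by the FvCB
#' model at one leaf observation: peaked-Arrhenius scaling of `Vcmax` and
#' `Jmax`, the configured Rd response, gamma-star, the Michaelis
#' coefficients and the electron transport rate at the observed `Q`.
#'
#' @param meteo A single-row data frame from [meteo_inputs()] (or any list
#'   providing `Tk` and `Q`).
#' @param params A [species_params()] object.
#' @return An object of class `kinetics` with fields `Vcmax, Jmax, Rd, Kc,
#'   Ko, Km, gamma_star, J` plus the `alpha`, `Q` and `Tk` they were
#'   evaluated at.
#' @examples
#' m <- meteo_inputs(Q = 1000, Ta = 24.85, D = 2, ca = 400, P = 95)
#' kinetics_at(m, species_params())
#' @export
kinetics_at <- function(meteo, params) {
  validate_species_params(params)
  Tk <- meteo$Tk[1L]
  Q <- meteo$Q[1L]
  if (!is.finite(Tk) || !is.finite(Q))
    stop("kinetics_at: non-finite Tk or Q", call. = FALSE)
  Vcmax <- peaked_arrhenius(params$Vcmax25, Tk, params$Ea_v, params$dS_v,
                            params$Hd, params$R)
  Jmax <- peaked_arrhenius(params$Jmax25, Tk, params$Ea_j, params$dS_j,
                           params$Hd, params$R)
  Rd <- switch(params$rd_temperature_mode,
               constant = params$Rd25,
               arrhenius = arrhenius_scale(params$Rd25, Tk, params$Ea_rd,
                                           params$R))
  mm <- michaelis(Tk, params$O, params$R)
  kin <- list(Vcmax = Vcmax, Jmax = Jmax, Rd = Rd,
              Kc = mm$Kc, Ko = mm$Ko, Km = mm$Km,
              gamma_star = gamma_star(Tk, params$R),
              J = electron_transport(Q, Jmax, params$alpha),
              alpha = params$alpha, Q = Q, Tk = Tk)
  class(kin) <- "kinetics"
  kin
}

#' Net assimilation at a given intercellular CO2
#'
#' FvCB net photosynthesis with Rubisco-limited (`Ac`) and
#' RuBP-regeneration-limited (`Aj`) branches; the realised rate is the
#' minimum of the two. Mesophyll conductance is treated as infinite, so the
#' chloroplast CO2 concentration equals `ci`. TPU limitation is excluded by
#' construction.
#'
#' @param ci Intercellular CO2 concentration, umol mol-1 (vectorised).
#' @param kin A `kinetics` object from [kinetics_at()].
#' @return A list with `A` (net rate, = min(Ac, Aj)), the branch rates `Ac`
#'   and `Aj`, the gross carboxylation rates `wc` and `wJ`, the `limitation`
#'   tag (`"Vc"` when `Ac <= Aj`, else `"Vj"`) and `cc` (= `ci`).
#' @examples
#' m <- meteo_inputs(Q = 1000, Ta = 24.85, D = 2, ca = 400, P = 95)
#' assimilation(300, kinetics_at(m, species_params()))
#' @export
assimilation <- function(ci, kin) {
  if (any(!is.finite(ci)) || any(ci <= 0))
    stop("assimilation: ci must be finite and > 0", call. = FALSE)
  g <- kin$gamma_star
  wc <- kin$Vcmax * ci / (ci + kin$Km)
  wJ <- kin$J * ci / (4 * ci + 8 * g)
  Ac <- kin$Vcmax * (ci - g) / (ci + kin$Km) - kin$Rd
  Aj <- kin$J * (ci - g) / (4 * ci + 8 * g) - kin$Rd
  list(A = pmin(Ac, Aj), Ac = Ac, Aj = Aj, wc = wc, wJ = wJ,
       limitation = ifelse(Ac <= Aj, "Vc", "Vj"), cc = ci)
}

#' Analytic derivative of assimilation with respect to ci
#'
#' Branch-wise partial derivative of the FvCB net rate:
#' `Vc` branch `Vcmax (Km + gamma*) / (ci + Km)^2`;
#' `Vj` branch `3 J gamma* / (4 (ci + 2 gamma*)^2)`.
#' Both are strictly positive and strictly decreasing in `ci`.
#'
#' @param ci Intercellular CO2 concentration, umol mol-1 (vectorised).
#' @param kin A `kinetics` object.
#' @param branch `"Vc"` or `"Vj"`.
#' @return dA/dci in umol m-2 s-1 per umol mol-1.
#' @export
assimilation_slope <- function(ci, kin, branch = c("Vc", "Vj")) {
  branch <- match.arg(branch)
  if (any(!is.finite(ci)) || any(ci <= 0))
    stop("assimilation_slope: ci must be finite and > 0", call. = FALSE)
  g <- kin$gamma_star
  switch(branch,
         Vc = kin$Vcmax * (kin$Km + g) / (ci + kin$Km)^2,
         Vj = 3 * kin$J * g / (4 * (ci + 2 * g)^2))
}
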