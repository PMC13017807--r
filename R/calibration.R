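#' A-ci response curve container
#'
#' One measured (or simulated) net photosynthesis response to a stepped
#' chamber CO2 ladder, together with the leaf temperature and light level
#' the curve was measured at. Repeated ci steps (the ladder returns to
#' 400 umol mol-1 mid-sequence) are ordinary observations.
#'
#' @param ci Intercellular CO2 concentrations, umol mol-1.
#' @param A Observed net assimilation, umol m-2 s-1.
#' @param Tl Leaf temperature during the curve, degC.
#' @param Q Photon flux density during the curve, umol m-2 s-1.
#' @param curve_id Identifier.
#' @return An object of class `aci_curve`.
#' @export
aci_curve <- function(ci, A, Tl, Q = 1000, curve_id = "curve1") {
  stopifnot(length(ci) == length(A))
  if (length(ci) < 6L)
    stop("aci_curve: at least 6 points are required", call. = FALSE)
  if (any(!is.finite(ci)) || any(ci <= 0))
    stop("aci_curve: ci values must be finite and positive", call. = FALSE)
  if (any(!is.finite(A)))
    stop("aci_curve: A values must be finite", call. = FALSE)
  structure(list(ci = as.numeric(ci), A = as.numeric(A),
                 Tl = Tl, Q = Q, curve_id = curve_id),
            class = "aci_curve")
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("A-ci curve '%s': %d points, Tl = %.2f degC, Q = %.0f\n",
              x$curve_id, length(x$ci), x$Tl, x$Q))
  invisible(x)
}

#' Invert the peaked Arrhenius response to the 25 degC reference
#'
#' Exact inverse of [peaked_arrhenius()]: converts a rate observed (or
#' fitted) at leaf temperature `Tk` back to its 25 degC reference value, so
#' `peaked_arrhenius(normalize_to_25(x, Tk, ...), Tk, ...) == x`.
#'
#' @param value_at_T Rate at `Tk` (must be positive).
#' @inheritParams peaked_arrhenius
#' @return The 25 degC reference rate.
#' @export
normalize_to_25 <- function(value_at_T, Tk, Ea, dS, Hd, R = 8.314) {
  if (!all(is.finite(c(value_at_T, Tk))) || any(value_at_T <= 0))
    stop("normalize_to_25: value_at_T must be finite and positive",
         call. = FALSE)
  value_at_T / peaked_arrhenius(1, Tk, Ea, dS, Hd, R)
}

# Data-driven starting values (at-temperature scale): invert the Vc branch
# at the lowest-ci points and the Vj branch at the highest-ci point, with a
# modest Rd guess. Keeps the optimiser near the global basin despite the
# min() kink.
aci_start <- function(curve, params, fv, fj) {
  Tk <- curve$Tl + 273.15
  g <- gamma_star(Tk, params$R)
  Km <- michaelis(Tk, params$O, params$R)$Km
  Rd0 <- params$Rd25
  ord <- order(curve$ci)
  lo <- ord[seq_len(min(3L, length(ord)))]
  vc0 <- stats::median((curve$A[lo] + Rd0) * (curve$ci[lo] + Km) /
                         pmax(curve$ci[lo] - g, 1))
  hi <- ord[length(ord)]
  J0 <- 4 * (curve$A[hi] + Rd0) * (curve$ci[hi] + 2 * g) /
    max(curve$ci[hi] - g, 1)
  aQ <- params$alpha * curve$Q
  jm0 <- if (is.finite(J0) && J0 > 0 && J0 < 0.99 * aQ)
    aQ * J0 / sqrt(aQ^2 - J0^2) else params$Jmax25 * fj
  clamp <- function(x, lo_, hi_, fb) {
    if (!is.finite(x) || x <= lo_ || x >= hi_) fb else x
  }
  c(Vcmax = clamp(vc0, 1 * fv, 300 * fv, params$Vcmax25 * fv),
    Jmax = clamp(jm0, 1 * fj, 500 * fj, params$Jmax25 * fj),
    Rd = Rd0)
}

# Residual vector of an A-ci curve against the FvCB min(Ac, Aj) prediction.
# theta carries at-temperature values (Vcmax_T, Jmax_T, Rd_T [, Km, gamma*]).
aci_residuals <- function(theta, curve, params, mode) {
  Tk <- curve$Tl + 273.15
  g <- if (mode == "free") theta[["gamma_star"]] else
    gamma_star(Tk, params$R)
  Km <- if (mode == "free") theta[["Km"]] else
    michaelis(Tk, params$O, params$R)$Km
  J <- electron_transport(curve$Q, theta[["Jmax"]], params$alpha)
  Ac <- theta[["Vcmax"]] * (curve$ci - g) / (curve$ci + Km) - theta[["Rd"]]
  Aj <- J * (curve$ci - g) / (4 * curve$ci + 8 * g) - theta[["Rd"]]
  pmin(Ac, Aj) - curve$A
}

#' Fit FvCB parameters to an A-ci response curve
#'
#' Bounded nonlinear least squares of observed net assimilation against the
#' point-wise `min(Ac, Aj)` FvCB prediction evaluated at the curve's leaf
#' temperature and light level. The limitation of each point is decided
#' inside the objective by the min rule, not pre-assigned. Because the min
#' operator makes the objective piecewise smooth, the optimiser is restarted
#' from three jittered starting points (fixed seed) and the best solution is
#' kept.
#'
#' In `"constrained"` mode `Km` and `gamma*` are fixed at their
#' temperature-response values and only (Vcmax, Jmax, Rd) are free; in
#' `"free"` mode per-curve `Km` and `gamma*` are fitted as well. Fitted
#' at-temperature rates are normalised back to 25 degC with
#' [normalize_to_25()].
#'
#' @param curve An [aci_curve()].
#' @param params0 A [species_params()] object providing fixed coefficients
#'   and starting values.
#' @param mode `"constrained"` (default) or `"free"`.
#' @param n_starts Number of jittered multi-starts.
#' @param seed Seed for the start jitter.
#' @return An object of class `aci_fit`: list with `Vcmax25`, `Jmax25`,
#'   `Rd25`, optional `Km_fit` and `gamma_star_fit`, `residual_sse`,
#'   `mode`, `converged`, `curve_id` and the at-temperature estimates.
#' @export
fit_aci <- function(curve, params0 = species_params(),
                    mode = c("constrained", "free"), n_starts = 3L,
                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "aci_curve"))
  validate_species_params(params0)
  if (diff(range(curve$A)) < 1e-10)
    stop("fit_aci: degenerate curve (constant A), cannot fit", call. = FALSE)

  Tk <- curve$Tl + 273.15
  fv <- peaked_arrhenius(1, Tk, params0$Ea_v, params0$dS_v, params0$Hd,
                         params0$R)
  fj <- peaked_arrhenius(1, Tk, params0$Ea_j, params0$dS_j, params0$Hd,
                         params0$R)
  # bounds stated on the 25 degC scale, mapped to at-temperature values
  lower <- c(Vcmax = 1 * fv, Jmax = 1 * fj, Rd = 0.01)
  upper <- c(Vcmax = 300 * fv, Jmax = 500 * fj, Rd = 10)
  start <- aci_start(curve, params0, fv, fj)
  if (mode == "free") {
    mm <- michaelis(Tk, params0$O, params0$R)
    lower <- c(lower, Km = 50, gamma_star = 10)
    upper <- c(upper, Km = 3000, gamma_star = 150)
    start <- c(start, Km = mm$Km, gamma_star = gamma_star(Tk, params0$R))
  }
  n_par <- length(start)
  if (length(curve$ci) <= n_par)
    stop("fit_aci: fewer points than free parameters", call. = FALSE)

  obj <- function(theta) {
    r <- aci_residuals(theta, curve, params0, mode)
    sum(r * r)
  }
  starts <- with_seed(seed, {
    s <- replicate(max(1L, n_starts) - 1L,
                   pmin(pmax(start * exp(stats::rnorm(n_par, 0, 0.25)),
                             lower * 1.001), upper * 0.999),
                   simplify = FALSE)
    c(list(start), s)
  })
  fits <- lapply(starts, function(s0) {
    stats::nlminb(s0, obj, lower = lower, upper = upper,
                  control = list(iter.max = 500, eval.max = 1000,
                                 rel.tol = 1e-12))
  })
  ok <- vapply(fits, function(f) {
    f$convergence == 0 ||
      grepl(paste0("relative convergence|X-convergence|",
                   "singular convergence|absolute function convergence"),
            f$message %||% "")
  }, NA)
  if (!any(ok)) {
    tr <- paste(vapply(fits, function(f)
      sprintf("[iter %d, obj %.4g: %s]", f$iterations, f$objective,
              f$message %||% "?"), ""), collapse = " ")
    stop("fit_aci: optimiser failed to converge from every start ", tr,
         call. = FALSE)
  }
  sse <- ifelse(ok, vapply(fits, `[[`, 0, "objective"), Inf)
  best <- fits[[which.min(sse)]]
  th <- best$par
  out <- list(
    Vcmax25 = normalize_to_25(th[["Vcmax"]], Tk, params0$Ea_v, params0$dS_v,
                              params0$Hd, params0$R),
    Jmax25 = normalize_to_25(th[["Jmax"]], Tk, params0$Ea_j, params0$dS_j,
                             params0$Hd, params0$R),
    Rd25 = th[["Rd"]],
    Km_fit = if (mode == "free") th[["Km"]] else
      michaelis(Tk, params0$O, params0$R)$Km,
    gamma_star_fit = if (mode == "free") th[["gamma_star"]] else
      gamma_star(Tk, params0$R),
    Vcmax_at_T = th[["Vcmax"]], Jmax_at_T = th[["Jmax"]],
    residual_sse = best$objective, mode = mode, converged = TRUE,
    curve_id = curve$curve_id, Tl = curve$Tl)
  class(out) <- "aci_fit"
  out
}

#' @export
print.aci_fit <- function(x, ...) {
  cat(sprintf(
    "A-ci fit '%s' (%s): Vcmax25 %.2f  Jmax25 %.2f  Rd25 %.2f  SSE %.4g\n",
    x$curve_id, x$mode, x$Vcmax25, x$Jmax25, x$Rd25, x$residual_sse))
  invisible(x)
}

#' Average fitted parameters across curves
#'
#' Arithmetic mean of `Vcmax25`, `Jmax25` and `Rd25` over a list of
#' [fit_aci()] results (or any lists carrying those fields), returned as a
#' [species_params()] object inheriting every other coefficient from
#' `template`.
#'
#' @param fits Non-empty list of fits.
#' @param template A [species_params()] supplying the fixed coefficients.
#' @return A `species_params` object with averaged rates.
#' @export
average_params <- function(fits, template = species_params()) {
  if (length(fits) == 0L)
    stop("average_params: empty fit list", call. = FALSE)
  pick <- function(f, what) vapply(f, function(x) x[[what]], 0)
  species_params(
    Vcmax25 = mean(pick(fits, "Vcmax25")),
    Jmax25 = mean(pick(fits, "Jmax25")),
    Rd25 = mean(pick(fits, "Rd25")),
    alpha = template$alpha, O = template$O, gmin = template$gmin,
    R = template$R, dS_v = template$dS_v, dS_j = template$dS_j,
    Ea_v = template$Ea_v, Ea_j = template$Ea_j, Hd = template$Hd,
    rd_temperature_mode = template$rd_temperature_mode,
    Ea_rd = template$Ea_rd)
}
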