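#' Synthetic-data generator configuration
#'
#' Describes a synthetic measurement campaign: how many days, how many
#' observations per day, the uniform sampling ranges of the meteorological
#' drivers, the true marginal water cost, and the observation noise model.
#' The defaults emulate a two-season orchard campaign: 17 measurement days
#' with the per-day observation counts of the reference campaign (1852
#' records in total), sub-tropical growing-season meteorology, and the
#' citrus characteristic lambda as ground truth.
#'
#' @param n_days Number of measurement days.
#' @param points_per_day Observations per day; a scalar or a vector of
#'   length `n_days`. Default: the reference campaign counts.
#' @param Q_range,Ta_range,D_range,ca_range,P_range Uniform sampling
#'   ranges (umol m-2 s-1, degC, kPa, umol mol-1, kPa).
#' @param lambda_truth True lambda: a scalar, or a vector of length
#'   `n_days` for per-day truth.
#' @param noise_sd Multiplicative Gaussian noise standard deviation
#'   (fraction) applied to observed gs.
#' @param noise_model `"gs_fick"` (noise gs, re-derive A and E through
#'   Fick's law at the solved ci; the default) or `"gs_only"` (noise gs
#'   alone, keep model A and E).
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_days = 17L,
                         points_per_day = c(325L, 80L, 141L, 115L, 67L,
                                            113L, 37L, 37L, 86L, 26L, 28L,
                                            302L, 226L, 86L, 76L, 26L, 81L),
                         Q_range = c(50, 2000), Ta_range = c(15, 42),
                         D_range = c(0.5, 4.5), ca_range = c(380, 420),
                         P_range = c(94, 96),
                         lambda_truth = CITRUS_LAMBDA_CO,
                         noise_sd = 0.05,
                         noise_model = c("gs_fick", "gs_only"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  chk_range <- function(r, lo, hi, name) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < lo || r[2] > hi)
      stop("synth_config: ", name, " range must lie within [", lo, ", ",
           hi, "]", call. = FALSE)
  }
  chk_range(Q_range, 0, 2500, "Q")
  chk_range(Ta_range, 5, 50, "Ta")
  chk_range(D_range, 1e-6, 6, "D")
  chk_range(ca_range, 300, 2000, "ca")
  chk_range(P_range, 70, 105, "P")
  stopifnot(n_days >= 1L, noise_sd >= 0, all(lambda_truth > 0),
            length(lambda_truth) %in% c(1L, n_days))
  points_per_day <- rep_len(points_per_day, n_days)
  stopifnot(all(points_per_day >= 1L))
  structure(list(n_days = as.integer(n_days),
                 points_per_day = as.integer(points_per_day),
                 Q_range = Q_range, Ta_range = Ta_range, D_range = D_range,
                 ca_range = ca_range, P_range = P_range,
                 lambda_truth = lambda_truth, noise_sd = noise_sd,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate synthetic meteorology
#'
#' Draws leaf-surface drivers uniformly within the configured ranges, one
#' block of observations per day, tagged with `day_id`. Pure function of
#' the configuration (including its seed).
#'
#' @param cfg A [synth_config()].
#' @return A meteorology `data.frame` (see [meteo_inputs()]).
#' @export
gen_meteo <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- sum(cfg$points_per_day)
  with_seed(sub_seed(cfg$seed, 1L), {
    u <- function(r) stats::runif(n, r[1], r[2])
    meteo_inputs(Q = u(cfg$Q_range), Ta = u(cfg$Ta_range),
                 D = u(cfg$D_range), ca = u(cfg$ca_range),
                 P = u(cfg$P_range),
                 day_id = rep(seq_len(cfg$n_days), cfg$points_per_day))
  })
}

#' Generate synthetic gas-exchange records with known lambda
#'
#' Runs the forward optimal stomatal conductance model on each
#' meteorological record at the true lambda, then perturbs the
#' "observations" with multiplicative Gaussian noise on gs. Under the
#' default `"gs_fick"` noise model, A and E are re-derived from the noised
#' gs through Fick's law at the solved ci, mimicking an instrument whose
#' flux estimates inherit the conductance error. Floored records keep
#' their flag so recovery studies can exclude them from truth sets.
#'
#' @param meteo Meteorology data frame (e.g. from [gen_meteo()]).
#' @param params A [species_params()] object.
#' @param lambda_truth Scalar lambda, or per-day vector matching the
#'   `day_id` levels in `meteo`.
#' @param noise_sd Fractional noise standard deviation on gs.
#' @param seed Seed for the noise draws.
#' @param noise_model `"gs_fick"` or `"gs_only"`.
#' @param form Forward model form.
#' @return A `data.frame` of gas-exchange records: the drivers plus
#'   observed `A`, `E`, `gs`, `ci`, the truth columns `lambda_true`,
#'   `floored`, `branch`, and the noise-free `gs_true`.
#' @export
gen_gas_exchange <- function(meteo, params = species_params(),
                             lambda_truth = CITRUS_LAMBDA_CO,
                             noise_sd = 0.05, seed = 1L,
                             noise_model = c("gs_fick", "gs_only"),
                             form = "OSC") {
  noise_model <- match.arg(noise_model)
  stopifnot(all(lambda_truth > 0))
  days <- sort(unique(meteo$day_id))
  if (length(lambda_truth) == 1L) {
    schedule <- lambda_schedule("long_term", value = lambda_truth)
  } else {
    stopifnot(length(lambda_truth) == length(days))
    schedule <- lambda_schedule("daily",
                                daily = stats::setNames(lambda_truth,
                                                        days))
  }
  sim <- simulate_dataset(meteo, schedule, form = form, params = params)
  n <- nrow(sim)
  eps <- with_seed(sub_seed(seed, 2L), stats::rnorm(n, 0, 1))
  fac <- exp(noise_sd * eps - noise_sd^2 / 2)
  out <- sim
  out$gs_true <- sim$gs
  out$lambda_true <- sim$lambda_used
  out$gs <- sim$gs * fac
  if (noise_model == "gs_fick") {
    out$A <- out$gs * (sim$ca - sim$ci) / 1.6
    out$E <- out$gs * sim$D / sim$P * 1e3
  }
  out
}

#' Default chamber CO2 ladder for A-ci curves
#'
#' The 15-step chamber CO2 sequence used for response-curve measurements:
#' a descending limb from 400 to 50 umol mol-1, two recovery steps at 400,
#' then an ascending limb to 2000.
#'
#' @return Numeric vector of 15 set points, umol mol-1.
#' @export
aci_ladder <- function() {
  c(400, 300, 200, 150, 100, 50, 400, 400, 600, 800, 1000, 1200, 1500,
    1800, 2000)
}

#' Generate a synthetic A-ci response curve
#'
#' Simulates a response curve from known kinetics: net assimilation is the
#' FvCB `min(Ac, Aj)` at each ladder step, with optional multiplicative
#' Gaussian noise. For fixture purposes `ci` is taken equal to the chamber
#' set point (real instruments infer `ci` from conductance; that inversion
#' is out of scope here).
#'
#' @param params True [species_params()].
#' @param Tl Leaf temperature of the curve, degC.
#' @param Q Photon flux density during the curve, umol m-2 s-1.
#' @param ladder Chamber CO2 set points; default [aci_ladder()].
#' @param noise_sd Fractional noise standard deviation on A.
#' @param seed Seed for the noise draws.
#' @param curve_id Identifier.
#' @return An [aci_curve()].
#' @export
gen_aci <- function(params = species_params(), Tl = 25, Q = 1000,
                    ladder = aci_ladder(), noise_sd = 0, seed = 1L,
                    curve_id = "synthetic") {
  stopifnot(length(ladder) > 0L, all(ladder > 0), noise_sd >= 0)
  m <- meteo_inputs(Q = Q, Ta = Tl, D = 1.5, ca = max(ladder), P = 101.325,
                    Tl = Tl)
  kin <- kinetics_at(m, params)
  A <- assimilation(ladder, kin)$A
  if (noise_sd > 0) {
    eps <- with_seed(sub_seed(seed, 3L), stats::rnorm(length(ladder), 0, 1))
    A <- A * exp(noise_sd * eps - noise_sd^2 / 2)
  }
  aci_curve(ci = ladder, A = A, Tl = Tl, Q = Q, curve_id = curve_id)
}
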