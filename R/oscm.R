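#' Characteristic lambda values for orchard citrus
#'
#' Long-term trimmed-median marginal water cost of carbon gain (mol H2O per
#' mol CO2) calibrated for orchard citrus over a full phenological period:
#' co-limited, Rubisco-limited (`Vc`) and RuBP-regeneration-limited (`Vj`)
#' pools.
#'
#' @format Length-1 numerics.
#' @name citrus_lambda
#' @export
CITRUS_LAMBDA_CO <- 1787.10

#' @rdname citrus_lambda
#' @export
CITRUS_LAMBDA_VC <- 1478.51

#' @rdname citrus_lambda
#' @export
CITRUS_LAMBDA_VJ <- 2703.65

# Branch-wise assimilation used by the solvers: forces the requested branch
# for OSCvc/OSCvj, the min rule for the combined form.
branch_A <- function(ci, kin, branch) {
  as_ <- assimilation(ci, kin)
  switch(branch, Vc = as_$Ac, Vj = as_$Aj, min = as_$A)
}

# Branch-wise slope; for the combined form use the limiting branch at ci.
branch_slope <- function(ci, kin, branch) {
  if (branch == "min") branch <- assimilation(ci, kin)$limitation
  assimilation_slope(ci, kin, branch)
}

# Intercellular CO2 at which branch assimilation crosses zero (the
# compensation point including day respiration). NA when the branch cannot
# reach positive A at any ci (e.g. J <= 4 Rd at low light).
ci_compensation <- function(kin, branch) {
  g <- kin$gamma_star
  switch(branch,
         Vc = if (kin$Vcmax > kin$Rd)
           (kin$Rd * kin$Km + kin$Vcmax * g) / (kin$Vcmax - kin$Rd)
         else NA_real_,
         Vj = if (kin$J > 4 * kin$Rd)
           g * (kin$J + 8 * kin$Rd) / (kin$J - 4 * kin$Rd)
         else NA_real_,
         min = {
           a <- ci_compensation(kin, "Vc")
           b <- ci_compensation(kin, "Vj")
           if (is.na(a) || is.na(b)) NA_real_ else max(a, b)
         })
}

#' Marginal water cost implied by a candidate intercellular CO2
#'
#' Closes the coupled system at a candidate `ci`: assimilation from the
#' requested FvCB branch, stomatal conductance from Fick's law
#' `gs = 1.6 A / (ca - ci)`, transpiration `E = gs D / P`, then evaluates
#' lambda exactly as [lambda_point()] does. This is the objective the
#' forward solvers invert: it is strictly increasing in `ci` between the
#' branch compensation point and `ca`, diverging as `ci` approaches `ca`.
#'
#' @param ci Candidate intercellular CO2, umol mol-1 (vectorised).
#' @param meteo One-row meteorology from [meteo_inputs()].
#' @param kin `kinetics` object at that meteorology.
#' @param branch `"Vc"`, `"Vj"` or `"min"` (combined).
#' @return Lambda in mol H2O per mol CO2.
#' @export
lambda_of_ci <- function(ci, meteo, kin, branch = c("Vc", "Vj", "min")) {
  branch <- match.arg(branch)
  lo <- ci_compensation(kin, branch)
  if (is.na(lo))
    stop("lambda_of_ci: branch has no positive-assimilation domain",
         call. = FALSE)
  if (any(ci <= lo) || any(ci >= meteo$ca))
    stop("lambda_of_ci: ci outside (compensation point, ca)", call. = FALSE)
  A <- branch_A(ci, kin, branch)
  slope <- branch_slope(ci, kin, branch)
  # With Fick closure gs = 1.6 A/(ca - ci): E/A in mol/mol is
  # 1e6 * 1.6 D / (P (ca - ci)) (ca - ci in umol/mol), and the bracket term
  # gs/(1.6 dA/dci) reduces to A / (slope (ca - ci)).
  (1.6 * meteo$D / (meteo$P * (meteo$ca - ci))) *
    (1 + A / (slope * (meteo$ca - ci))) * 1e6
}

#' Solve the optimality condition for intercellular CO2
#'
#' Finds the `ci` at which [lambda_of_ci()] equals the prescribed lambda,
#' by Brent root bracketing on `(ci_comp + eps, ca - eps)` with
#' `eps = 1e-6 * ca`. When the target lies below the bracket's lower-limit
#' lambda (no positive-assimilation solution exists, e.g. in darkness), a
#' no-root sentinel (`NA`) is returned; [forward()] then engages the
#' minimum-conductance floor.
#'
#' @param branch `"Vc"`, `"Vj"` or `"min"`.
#' @param lam Target lambda, mol mol-1 (> 0).
#' @param meteo One-row meteorology.
#' @param kin `kinetics` object.
#' @param tol Relative convergence tolerance on `ci`.
#' @return The root `ci` in umol mol-1, or `NA_real_` if no root exists.
#' @export
solve_ci <- function(branch, lam, meteo, kin, tol = 1e-10) {
  stopifnot(is.finite(lam), lam > 0)
  if (branch != "min") branch <- match.arg(branch, c("Vc", "Vj"))
  lo <- ci_compensation(kin, branch)
  ca <- meteo$ca
  if (is.na(lo) || lo >= ca) return(NA_real_)
  eps <- 1e-6 * ca
  lower <- lo + eps
  upper <- ca - eps
  if (lower >= upper) return(NA_real_)
  f <- function(ci) lambda_of_ci(ci, meteo, kin, branch) - lam
  flo <- f(lower)
  if (flo >= 0) return(NA_real_)  # target below attainable lambda
  fhi <- f(upper)
  if (fhi <= 0)
    stop("solve_ci: objective not monotone on bracket (unexpected)",
         call. = FALSE)
  r <- stats::uniroot(f, lower = lower, upper = upper,
                      f.lower = flo, f.upper = fhi,
                      tol = tol * ca, maxiter = 200L)
  r$root
}

# Floored solution: gs pinned at gmin, ci from A(ci) = gmin (ca - ci) / 1.6.
# The supply line is decreasing and demand increasing in ci, so the crossing
# is unique; ci may exceed ca when A < 0 (respiratory CO2 efflux).
solve_floored <- function(branch, meteo, kin, gmin) {
  ca <- meteo$ca
  f <- function(ci) branch_A(ci, kin, branch) - gmin * (ca - ci) / 1.6
  upper <- ca + 1.6 * (kin$Rd + kin$Vcmax) / gmin
  r <- stats::uniroot(f, lower = 1e-6, upper = upper, tol = 1e-10 * ca,
                      maxiter = 200L)
  r$root
}

new_solution <- function(ci, A, gs, E, branch, form, converged, floored,
                         lambda_used) {
  data.frame(ci = ci, A = A, gs = gs, E = E, branch = branch, form = form,
             converged = converged, floored = floored,
             lambda_used = lambda_used, stringsAsFactors = FALSE)
}

#' Forward optimal stomatal conductance solution
#'
#' Predicts intercellular CO2, net assimilation, stomatal conductance and
#' transpiration for one observation from meteorology, species parameters
#' and a prescribed marginal water cost lambda, under the constant-lambda
#' optimal stomatal regulation hypothesis coupled to Fick's law and the
#' FvCB model.
#'
#' Forms: `"OSCvc"` assumes Rubisco limitation, `"OSCvj"` RuBP-regeneration
#' limitation, `"OSC"` solves on the composite `min(Ac, Aj)` assimilation
#' directly, so the realised rate is always the lower branch and the
#' reported `branch` is the limitation prevailing at the solved `ci`. The
#' composite optimality objective is strictly increasing in `ci` on each
#' branch with an upward jump at the branch crossover; a prescribed lambda
#' falling inside that jump has no exact solution, and the solver then
#' returns the crossover kink state (where `Ac = Aj` to solver tolerance)
#' flagged `converged = FALSE`. When no positive-assimilation
#' root exists (e.g. `Q = 0`), conductance is pinned at the floor `gmin`
#' and `ci` solved from the Fick supply line; the solution is flagged
#' `floored`.
#'
#' Units: `ci` umol mol-1, `A` umol m-2 s-1, `gs` mol m-2 s-1, `E`
#' mmol m-2 s-1 (`E = gs D / P * 1000`).
#'
#' @param form `"OSCvc"`, `"OSCvj"` or `"OSC"`.
#' @param lam Prescribed lambda, mol H2O per mol CO2.
#' @param meteo One-row meteorology from [meteo_inputs()].
#' @param params A [species_params()] object.
#' @param tol Relative tolerance on the `ci` root.
#' @return One-row `data.frame` with `ci, A, gs, E, branch, form,
#'   converged, floored, lambda_used`.
#' @examples
#' m <- meteo_inputs(Q = 1000, Ta = 30, D = 2, ca = 400, P = 95)
#' forward("OSC", CITRUS_LAMBDA_CO, m, species_params())
#' @export
forward <- function(form = c("OSC", "OSCvc", "OSCvj"), lam, meteo, params,
                    tol = 1e-10) {
  form <- match.arg(form)
  validate_species_params(params)
  stopifnot(is.finite(lam), lam > 0)
  kin <- kinetics_at(meteo, params)
  gmin <- params$gmin
  ca <- meteo$ca

  finish <- function(ci, branch_eff, floored, converged = TRUE) {
    A <- branch_A(ci, kin, branch_eff)
    gs <- if (floored) gmin else max(1.6 * A / (ca - ci), gmin)
    refloored <- floored || gs <= gmin
    E <- gs * meteo$D / meteo$P * 1e3
    lim <- if (branch_eff == "min") assimilation(ci, kin)$limitation else
      branch_eff
    new_solution(ci, A, gs, E, lim, form, converged, refloored, lam)
  }

  single <- function(branch) {
    ci <- solve_ci(branch, lam, meteo, kin, tol)
    if (is.na(ci)) {
      ci <- solve_floored(branch, meteo, kin, gmin)
      return(finish(ci, branch, floored = TRUE))
    }
    # the composite min objective jumps upward at the branch crossover; a
    # target inside the jump has no root, and uniroot lands on the kink.
    # Report the kink state but flag non-convergence on the target.
    attained <- abs(lambda_of_ci(ci, meteo, kin, branch) - lam) / lam <=
      1e-7
    finish(ci, branch, floored = FALSE, converged = attained)
  }

  switch(form, OSCvc = single("Vc"), OSCvj = single("Vj"),
         OSC = single("min"))
}

#' Lambda schedule
#'
#' Either a single long-term characteristic lambda applied to every record,
#' or a per-day map of daily median lambdas (the "d" model variants).
#'
#' @param mode `"long_term"` or `"daily"`.
#' @param value Scalar lambda (long-term mode).
#' @param daily Named numeric vector or data frame (`day_id`, `lam`)
#'   mapping day ids to lambdas (daily mode).
#' @return An object of class `lambda_schedule`.
#' @export
lambda_schedule <- function(mode = c("long_term", "daily"),
                            value = CITRUS_LAMBDA_CO, daily = NULL) {
  mode <- match.arg(mode)
  if (mode == "long_term") {
    stopifnot(is.finite(value), value > 0)
    sch <- list(mode = mode, value = value)
  } else {
    if (is.data.frame(daily)) {
      daily <- stats::setNames(daily$lam, daily$day_id)
    }
    if (is.null(daily) || is.null(names(daily)) || any(!is.finite(daily)) ||
        any(daily <= 0))
      stop("lambda_schedule: daily mode needs a named positive lambda map",
           call. = FALSE)
    sch <- list(mode = mode, daily = daily)
  }
  class(sch) <- "lambda_schedule"
  sch
}

schedule_lambda_for <- function(schedule, day_id) {
  if (schedule$mode == "long_term") return(rep(schedule$value,
                                               length(day_id)))
  key <- as.character(day_id)
  miss <- setdiff(unique(key), names(schedule$daily))
  if (length(miss) > 0L)
    stop("lambda_schedule: no lambda for day(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  unname(schedule$daily[key])
}

#' Simulate gas exchange for a meteorology table
#'
#' Runs [forward()] for every row of a meteorology table with the lambda
#' prescribed by a [lambda_schedule()] (a long-term constant or daily
#' medians). Deterministic and order-preserving; missing daily lambdas are
#' rejected before any computation.
#'
#' @param records Meteorology data frame from [meteo_inputs()] (or the
#'   same columns).
#' @param schedule A [lambda_schedule()], or a single number (treated as a
#'   long-term schedule).
#' @param form Model form passed to [forward()].
#' @param params A [species_params()] object.
#' @return A `data.frame`: the input drivers cbind-ed with the solution
#'   columns.
#' @export
simulate_dataset <- function(records, schedule, form = "OSC",
                             params = species_params()) {
  if (is.numeric(schedule) && length(schedule) == 1L)
    schedule <- lambda_schedule("long_term", value = schedule)
  stopifnot(inherits(schedule, "lambda_schedule"), is.data.frame(records))
  if (nrow(records) == 0L)
    return(cbind(records[0, , drop = FALSE],
                 new_solution(numeric(0), numeric(0), numeric(0),
                              numeric(0), character(0), character(0),
                              logical(0), logical(0), numeric(0))))
  lams <- schedule_lambda_for(schedule, records$day_id)
  sols <- lapply(seq_len(nrow(records)), function(i)
    forward(form, lams[i], records[i, , drop = FALSE], params))
  cbind(records, do.call(rbind, sols))
}
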