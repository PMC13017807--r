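#' Model evaluation metrics
#'
#' Scores predictions against observations with the four standard
#' indicators: the determination coefficient R2 (squared Pearson
#' correlation of predictions and observations), the mean absolute error
#' MAE (units of the variable), the relative mean bias error
#' MBE = sum(P - O) / sum(O) in percent, and the per-point absolute
#' relative error |RE|_i = |P_i - O_i| / O_i in percent.
#'
#' Note R2 here is a squared correlation, not 1 - SSE/SST; the two differ
#' for biased predictions.
#'
#' @param pred Numeric vector of predictions.
#' @param obs Numeric vector of observations, same length, n >= 2.
#' @return An object of class `eval_report`: list with `r2`, `mae`, `mbe`
#'   (percent), `re` (percent, per point; `NA` where `obs == 0`), `n`.
#' @examples
#' score(c(1.5, 2.5, 2.5, 4.5), c(1, 2, 3, 4))
#' @export
score <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("score: pred and obs must have equal length", call. = FALSE)
  if (length(obs) < 2L)
    stop("score: need at least two points", call. = FALSE)
  if (stats::sd(obs) == 0)
    stop("score: observations are all identical; R2 undefined",
         call. = FALSE)
  re <- ifelse(obs == 0, NA_real_, abs(pred - obs) / abs(obs) * 100)
  if (anyNA(re))
    warning("score: |RE| skipped for ", sum(is.na(re)),
            " zero observation(s)")
  out <- list(r2 = stats::cor(pred, obs)^2,
              mae = mean(abs(pred - obs)),
              mbe = sum(pred - obs) / sum(obs) * 100,
              re = re, n = length(obs))
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n = %d  R2 = %.4f  MAE = %.4g  MBE = %.2f%%  mean|RE| = %.2f%%\n",
              x$n, x$r2, x$mae, x$mbe, mean(x$re, na.rm = TRUE)))
  invisible(x)
}

#' Binned mean absolute relative error surface
#'
#' Bins per-point |RE| values over two meteorological axes (e.g. Ta x D)
#' and reports the mean |RE| and the point count per 2-D cell. Bins are
#' right-closed (`(e_k, e_{k+1}]`, lowest edge included), so a point lying
#' exactly on an interior edge belongs to the bin whose upper bound equals
#' it. Empty cells are `NA`, never zero.
#'
#' @param re Per-point |RE| values in percent (e.g. from [score()]).
#' @param meteo Data frame aligned with `re` holding the axis columns.
#' @param axes Character pair naming the two binning columns (default
#'   `c("Ta", "D")`).
#' @param bin_edges List of two strictly increasing numeric edge vectors,
#'   one per axis.
#' @return A list with `mean_re` and `count` matrices (rows = first axis
#'   bins, cols = second axis bins) plus the edge vectors.
#' @export
error_surface <- function(re, meteo, axes = c("Ta", "D"), bin_edges) {
  stopifnot(length(axes) == 2L, all(axes %in% names(meteo)),
            length(re) == nrow(meteo), is.list(bin_edges),
            length(bin_edges) == 2L)
  for (e in bin_edges)
    if (is.unsorted(e, strictly = TRUE))
      stop("error_surface: bin edges must be strictly increasing",
           call. = FALSE)
  bx <- cut(meteo[[axes[1]]], bin_edges[[1]], right = TRUE,
            include.lowest = TRUE)
  by <- cut(meteo[[axes[2]]], bin_edges[[2]], right = TRUE,
            include.lowest = TRUE)
  keep <- !is.na(bx) & !is.na(by) & !is.na(re)
  mean_re <- tapply(re[keep], list(bx[keep], by[keep]), mean)
  count <- tapply(re[keep], list(bx[keep], by[keep]), length)
  count[is.na(count)] <- 0L
  list(mean_re = mean_re, count = count,
       edges = stats::setNames(bin_edges, axes))
}

#' Perturbation sensitivity coefficient of a forward model output
#'
#' Quantifies how strongly one model factor drives one predicted gas
#' exchange variable. The reference state (moderate conditions, by default
#' Ta = 35 degC and D = 2 kPa) is solved with [forward()]; the factor is
#' then perturbed one at a time by -20, -15, -10, -5, +5, +10, +15 and
#' +20 percent and the sensitivity coefficient at each level is
#' \deqn{SC_i = \frac{(S_i - S)/S}{(F_i - F)/F},}
#' with the summary SC the arithmetic mean over the eight levels. Factors
#' the chosen form does not use (e.g. `Jmax25` under Rubisco limitation)
#' yield exactly zero.
#'
#' @param reference One-row meteorology from [meteo_inputs()]; the
#'   reference state.
#' @param factor One of `"P", "D", "ca", "Q", "Ta", "lambda", "Vcmax25",
#'   "Jmax25", "Rd25"`.
#' @param output One of `"ci", "A", "gs", "E"`.
#' @param form Model form for [forward()] (`"OSCvc"`, `"OSCvj"`, `"OSC"`).
#' @param params A [species_params()] object.
#' @param lam Reference lambda.
#' @param levels Perturbation fractions (default
#'   `c(-0.20 ... -0.05, 0.05 ... 0.20)`).
#' @return An object of class `sensitivity_result`: list with `factor`,
#'   `output`, `form`, `sc_levels` (named by level), `sc_mean`,
#'   `reference_value`.
#' @export
sensitivity <- function(reference, factor, output = c("gs", "ci", "A", "E"),
                        form = "OSC", params = species_params(),
                        lam = CITRUS_LAMBDA_CO,
                        levels = c(-0.20, -0.15, -0.10, -0.05,
                                   0.05, 0.10, 0.15, 0.20)) {
  output <- match.arg(output)
  factor <- match.arg(factor, c("P", "D", "ca", "Q", "Ta", "lambda",
                                "Vcmax25", "Jmax25", "Rd25"))
  base <- forward(form, lam, reference, params)
  if (!base$converged)
    stop("sensitivity: reference forward solution did not converge",
         call. = FALSE)
  S <- base[[output]]
  if (S == 0)
    stop("sensitivity: reference output is zero; SC undefined",
         call. = FALSE)
  run_at <- function(f) {
    m <- reference
    p <- params
    l <- lam
    if (factor %in% c("P", "D", "ca", "Q")) {
      m[[factor]] <- reference[[factor]] * (1 + f)
    } else if (factor == "Ta") {
      m$Ta <- reference$Ta * (1 + f)
      m$Tl <- m$Ta
      m$Tk <- m$Tl + 273.15
    } else if (factor == "lambda") {
      l <- lam * (1 + f)
    } else {
      p[[factor]] <- params[[factor]] * (1 + f)
    }
    forward(form, l, m, p)[[output]]
  }
  sc <- vapply(levels, function(f) ((run_at(f) - S) / S) / f, 0)
  names(sc) <- sprintf("%+d%%", round(levels * 100))
  out <- list(factor = factor, output = output, form = form,
              sc_levels = sc, sc_mean = mean(sc), reference_value = S)
  class(out) <- "sensitivity_result"
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity of %s to %s (%s): SC = %.3f\n",
              x$output, x$factor, x$form, x$sc_mean))
  invisible(x)
}
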