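#' Point-wise marginal water cost of carbon gain
#'
#' Estimates the Cowan-Farquhar marginal water cost of carbon gain,
#' \eqn{\lambda = \partial E / \partial A} (mol H2O per mol CO2), from a
#' single gas-exchange observation. With mesophyll and boundary-layer
#' conductances assumed negligible resistances,
#' \deqn{\lambda = \frac{E}{A}\left(1 +
#'   \frac{g_s}{1.6\,\partial A/\partial c_i}\right) \times 10^3,}
#' with E in mmol m-2 s-1, A in umol m-2 s-1 and the analytic FvCB slope
#' from [assimilation_slope()] evaluated on the limiting branch at the
#' observed `ci`. The factor 10^3 converts to mol mol-1. The limitation is
#' decided by comparing `Ac` and `Aj` at the observed `ci` (ties count as
#' Rubisco-limited).
#'
#' Records that cannot yield a meaningful positive lambda (non-positive A,
#' E or gs, or `ci >= ca`) are returned flagged invalid, not as errors, so
#' whole campaigns can be processed and filtered downstream.
#'
#' @param rec A one-row gas-exchange record: a list or data-frame row with
#'   fields `Q, Ta, Tl (optional), D, ca, P, day_id` plus observed `A`
#'   (umol m-2 s-1), `E` (mmol m-2 s-1), `gs` (mol m-2 s-1), `ci`
#'   (umol mol-1).
#' @param params A [species_params()] object.
#' @return A one-row `data.frame`: `lam`, `limitation`, `day_id`, `valid`,
#'   `reason`.
#' @seealso [lambda_points()] for whole tables, [characteristic_lambda()]
#'   for trimmed-median aggregation.
#' @export
lambda_point <- function(rec, params) {
  day <- rec$day_id %||% NA
  fail <- function(reason) data.frame(
    lam = NA_real_, limitation = NA_character_, day_id = day,
    valid = FALSE, reason = reason, stringsAsFactors = FALSE)
  need <- c("A", "E", "gs", "ci", "Q", "D", "ca", "P")
  vals <- unlist(rec[need], use.names = FALSE)
  if (any(!is.finite(as.numeric(vals)))) return(fail("non-finite field"))
  if (rec$A <= 0) return(fail("non-positive assimilation"))
  if (rec$E <= 0) return(fail("non-positive transpiration"))
  if (rec$gs <= 0) return(fail("non-positive conductance"))
  if (rec$ci >= rec$ca) return(fail("ci >= ca"))
  if (rec$ci <= 0) return(fail("non-positive ci"))
  Tl <- rec$Tl %||% rec$Ta
  if (is.null(Tl) || is.na(Tl)) Tl <- rec$Ta
  m <- meteo_inputs(Q = rec$Q, Ta = rec$Ta, D = rec$D, ca = rec$ca,
                    P = rec$P, Tl = Tl, day_id = day)
  kin <- kinetics_at(m, params)
  as_ <- assimilation(rec$ci, kin)
  branch <- as_$limitation
  slope <- assimilation_slope(rec$ci, kin, branch)
  lam <- (rec$E / rec$A) * (1 + rec$gs / (1.6 * slope)) * 1e3
  if (!is.finite(lam) || lam <= 0) return(fail("non-positive lambda"))
  data.frame(lam = lam, limitation = branch, day_id = day, valid = TRUE,
             reason = "", stringsAsFactors = FALSE)
}

#' Lambda estimates for a whole gas-exchange table
#'
#' Applies [lambda_point()] row-wise to a data frame of gas-exchange
#' records (the layout written by [write_gas_exchange()] /
#' [gen_gas_exchange()]).
#'
#' @param records Data frame with the fields documented in
#'   [lambda_point()].
#' @param params A [species_params()] object.
#' @return A `data.frame` of estimates, one row per input record, in input
#'   order.
#' @export
lambda_points <- function(records, params) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  out <- lapply(seq_len(nrow(records)),
                function(i) lambda_point(as.list(records[i, ]), params))
  do.call(rbind, out)
}

#' Drop invalid lambda estimates
#'
#' Keeps only estimates flagged valid, preserving order, and reports the
#' rejection counts by reason as a message.
#'
#' @param estimates Data frame from [lambda_points()].
#' @param quiet Suppress the rejection-count message.
#' @return The valid subset.
#' @export
filter_valid <- function(estimates, quiet = FALSE) {
  if (nrow(estimates) == 0L) return(estimates)
  bad <- estimates[!estimates$valid, , drop = FALSE]
  if (!quiet && nrow(bad) > 0L) {
    tab <- table(bad$reason)
    message("filter_valid: dropped ", nrow(bad), " estimate(s): ",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "))
  }
  estimates[estimates$valid, , drop = FALSE]
}

# Trimmed median of one group of lambda values: discard points outside the
# [lo, hi] percentile band (linear-interpolation quantiles), median the rest.
trimmed_median <- function(x, trim, qtype) {
  qs <- stats::quantile(x, trim / 100, type = qtype, names = FALSE)
  keep <- x >= qs[1] & x <= qs[2]
  list(median = stats::median(x[keep]), n_kept = sum(keep), n_total = length(x))
}

#' Characteristic lambda by trimmed median
#'
#' Aggregates valid point estimates of lambda into characteristic values:
#' within each group (each measurement day for `scope = "daily"`, the
#' pooled campaign for `scope = "long_term"`), values outside the 10th-90th
#' percentile band are discarded and the median of the survivors is taken.
#' Limitation-specific variants (`limitation = "Vc"` or `"Vj"`) first
#' subset by the limitation tag; `"co"` uses all valid points.
#'
#' @param estimates Data frame from [lambda_points()] (invalid rows are
#'   ignored).
#' @param scope `"long_term"` (pooled) or `"daily"` (per `day_id`).
#' @param limitation `"co"`, `"Vc"` or `"Vj"`.
#' @param trim Percentile pair, default `c(10, 90)`.
#' @param quantile_type Quantile definition passed to [stats::quantile()]
#'   (default 7, the linear-interpolation definition).
#' @return A `data.frame` with one row per group: `scope`, `limitation`,
#'   `day_id` (NA for long-term), `median_lam`, `n_points` (pre-trim),
#'   `n_kept`, `trim_lo`, `trim_hi`.
#' @export
characteristic_lambda <- function(estimates,
                                  scope = c("long_term", "daily"),
                                  limitation = c("co", "Vc", "Vj"),
                                  trim = c(10, 90), quantile_type = 7) {
  scope <- match.arg(scope)
  limitation <- match.arg(limitation)
  stopifnot(length(trim) == 2L, trim[1] < trim[2],
            trim[1] >= 0, trim[2] <= 100)
  est <- estimates[estimates$valid, , drop = FALSE]
  if (limitation != "co")
    est <- est[est$limitation == limitation, , drop = FALSE]
  if (nrow(est) == 0L)
    stop("characteristic_lambda: no valid estimates in scope", call. = FALSE)
  groups <- if (scope == "daily") split(est$lam, est$day_id) else
    list(`NA` = est$lam)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    tm <- trimmed_median(x, trim, quantile_type)
    if (tm$n_kept == 0L) {
      warning("characteristic_lambda: group '", g,
              "' empty after trimming; omitted")
      return(NULL)
    }
    data.frame(scope = scope, limitation = limitation,
               day_id = if (scope == "daily") g else NA,
               median_lam = tm$median, n_points = tm$n_total,
               n_kept = tm$n_kept, trim_lo = trim[1], trim_hi = trim[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}
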