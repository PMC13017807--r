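# CSV readers/writers and run configuration.
#
# One canonical dialect everywhere: comma-separated, UTF-8, '.' decimal,
# header mandatory. Thousands separators of the form "1,787.10" are
# accepted on read (values quoted in the file).

strip_thousands <- function(x) {
  if (is.character(x)) as.numeric(gsub(",", "", x, fixed = TRUE)) else
    as.numeric(x)
}

check_columns <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("missing required column(s) in '", path, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read a gas-exchange measurement table
#'
#' Reads the canonical gas-exchange CSV (columns `day_id, Q, Ta, D, ca, P,
#' A, E, gs, ci`; optional `timestamp`, `Tl`). Rows with missing required
#' numeric fields are skipped with their line numbers logged as a message;
#' missing columns are a hard failure naming the column. Thousands
#' separators ("1,787.10") are accepted.
#'
#' @param path CSV file path.
#' @return A `data.frame` of typed records with a computed `Tl` (defaulting
#'   to `Ta`) and `Tk` column.
#' @export
read_gas_exchange <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("day_id", "Q", "Ta", "D", "ca", "P", "A", "E", "gs", "ci")
  check_columns(df, required, path)
  num_cols <- setdiff(required, "day_id")
  if ("Tl" %in% names(df)) num_cols <- c(num_cols, "Tl")
  for (cc in num_cols) df[[cc]] <- strip_thousands(df[[cc]])
  bad <- Reduce(`|`, lapply(setdiff(required, "day_id"),
                            function(cc) !is.finite(df[[cc]])))
  if (any(bad))
    message("read_gas_exchange: skipped ", sum(bad), " row(s) with ",
            "missing fields (lines ",
            paste(utils::head(which(bad) + 1L, 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", ")")
  df <- df[!bad, , drop = FALSE]
  if (!"Tl" %in% names(df)) df$Tl <- df$Ta
  df$Tl[!is.finite(df$Tl)] <- df$Ta[!is.finite(df$Tl)]
  df$Tk <- df$Tl + 273.15
  rownames(df) <- NULL
  df
}

#' Write a gas-exchange table
#'
#' @param records Data frame of gas-exchange records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read A-ci response curves
#'
#' Reads the canonical A-ci CSV (columns `curve_id, ci, A, Tl, Q`) and
#' groups rows into [aci_curve()] objects by `curve_id`, preserving row
#' order within each curve. An empty file yields an empty list with a
#' warning.
#'
#' @param path CSV file path.
#' @return A list of `aci_curve` objects, in order of first appearance.
#' @export
read_aci <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("curve_id", "ci", "A", "Tl", "Q"), path)
  if (nrow(df) == 0L) {
    warning("read_aci: '", path, "' contains no data rows")
    return(list())
  }
  for (cc in c("ci", "A", "Tl", "Q")) df[[cc]] <- strip_thousands(df[[cc]])
  ids <- unique(df$curve_id)
  lapply(ids, function(id) {
    d <- df[df$curve_id == id, , drop = FALSE]
    aci_curve(ci = d$ci, A = d$A, Tl = d$Tl[1L], Q = d$Q[1L], curve_id = id)
  })
}

#' Write A-ci curves
#'
#' @param curves A list of [aci_curve()] objects (or a single curve).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_aci <- function(curves, path) {
  if (inherits(curves, "aci_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv)
    data.frame(curve_id = cv$curve_id, ci = cv$ci, A = cv$A, Tl = cv$Tl,
               Q = cv$Q, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Parses a JSON run configuration into a validated list: a
#' `species_params` block, lambda defaults, solver tolerances, trim bounds
#' and a seed. Unknown top-level keys or unknown species-parameter keys are
#' rejected. All keys are optional; omitted ones take package defaults.
#'
#' @param path JSON file path.
#' @return A list with elements `params` ([species_params()]), `lambda`
#'   (named vector `co`, `Vc`, `Vj`), `trim`, `ci_tol`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("species", "lambda", "trim", "ci_tol", "seed", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("read_run_config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sp <- cfg$species %||% list()
  sp_known <- names(formals(species_params))
  sp_unknown <- setdiff(names(sp), sp_known)
  if (length(sp_unknown) > 0L)
    stop("read_run_config: unknown species key(s): ",
         paste(sp_unknown, collapse = ", "), call. = FALSE)
  params <- do.call(species_params, sp)
  lam_default <- c(co = CITRUS_LAMBDA_CO, Vc = CITRUS_LAMBDA_VC,
                   Vj = CITRUS_LAMBDA_VJ)
  lam <- unlist(cfg$lambda %||% list())
  lam_unknown <- setdiff(names(lam), names(lam_default))
  if (length(lam_unknown) > 0L)
    stop("read_run_config: unknown lambda key(s): ",
         paste(lam_unknown, collapse = ", "), call. = FALSE)
  lam_default[names(lam)] <- lam
  list(params = params, lambda = lam_default,
       trim = as.numeric(cfg$trim %||% c(10, 90)),
       ci_tol = as.numeric(cfg$ci_tol %||% 1e-10),
       seed = as.integer(cfg$seed %||% 1L))
}

# --- bundled reference tables (plain-text fixtures under extdata) --------

oscm_extdata <- function(file) {
  p <- system.file("extdata", file, package = "oscm")
  if (p == "") stop("bundled file not found: ", file, call. = FALSE)
  p
}

#' Bundled citrus reference tables
#'
#' Small reference tables shipped with the package, transcribed from the
#' citrus calibration campaign: the measurement-day summary (17 days, 1852
#' leaf observations over two seasons), the daily and overall
#' characteristic lambda values per limitation pool, and the per-curve
#' A-ci calibration results whose averages are the package's default
#' species parameters.
#'
#' @return A `data.frame`.
#' @name citrus_tables
#' @export
citrus_measurement_days <- function() {
  utils::read.csv(oscm_extdata("citrus_measurement_days.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname citrus_tables
#' @export
citrus_daily_lambda <- function() {
  df <- utils::read.csv(oscm_extdata("citrus_daily_lambda.csv"),
                        stringsAsFactors = FALSE)
  for (cc in c("lambda_co", "lambda_vc", "lambda_vj"))
    df[[cc]] <- strip_thousands(df[[cc]])
  df
}

#' @rdname citrus_tables
#' @export
citrus_aci_parameters <- function() {
  df <- utils::read.csv(oscm_extdata("citrus_aci_parameters.csv"),
                        stringsAsFactors = FALSE)
  for (cc in c("Tl", "Km", "gamma_star", "Vcmax25", "Jmax25", "Rd25"))
    df[[cc]] <- strip_thousands(df[[cc]])
  df
}
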