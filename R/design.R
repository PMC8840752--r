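#' Declare the factors of an experimental design
#'
#' A factor declaration records, for each process variable, its unit and the
#' three levels used by the design (two-level factorials use `low`/`high` with
#' the centre point at `center`; Box-Behnken designs use all three). Coded
#' values map `low` to -1, `center` to 0 and `high` to +1. Levels need not be
#' equally spaced (e.g. Tyler mesh sizes 42/60/150), in which case the coded
#' scale is level-indexed rather than affine.
#'
#' @param name Character vector of factor names (must match design columns).
#' @param unit Character vector of units ("" for coded/ordinal factors).
#' @param low,center,high Numeric vectors of the declared levels.
#' @return A tibble with one row per factor, usable as the `factors` argument
#'   of [design_table()].
#' @examples
#' design_factors(
#'   name = c("P", "T"), unit = c("bar", "degC"),
#'   low = c(200, 40), center = c(250, 50), high = c(300, 60)
#' )
#' @export
design_factors <- function(name, unit, low, center, high) {
  fac <- tibble::tibble(
    name = as.character(name), unit = as.character(unit),
    low = as.numeric(low), center = as.numeric(center), high = as.numeric(high)
  )
  bad <- fac$name[!(fac$low < fac$center & fac$center < fac$high)]
  if (length(bad) > 0) {
    abort(paste0("factor levels must satisfy low < center < high: ",
                 paste(bad, collapse = ", ")))
  }
  fac
}

#' Assemble a design table from runs, factors and responses
#'
#' Binds a data frame of experimental runs to its factor and response
#' metadata and validates the design structure: every setting of a declared
#' factor must equal one of its three levels, run identifiers must be unique,
#' and responses must be numeric. Responses may be stored on the percent or
#' fraction w/w scale; the scale travels with the table so downstream fits
#' can convert explicitly.
#'
#' @param data Data frame with a `run` column, one column per factor
#'   (natural units) and one column per response.
#' @param factors Factor declaration from [design_factors()].
#' @param responses Named character vector: response column -> scale
#'   (`"percent"` or `"fraction"`).
#' @return A tibble of class `sfe_design` carrying `factors`, `responses` and
#'   `coding` attributes.
#' @export
design_table <- function(data, factors, responses) {
  data <- tibble::as_tibble(data)
  if (!"run" %in% names(data)) abort("design data must have a `run` column")
  if (anyDuplicated(data$run)) {
    abort(paste0("duplicate run ids: ",
                 paste(unique(data$run[duplicated(data$run)]), collapse = ", ")))
  }
  missing_cols <- setdiff(c(factors$name, names(responses)), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("design data lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(responses %in% c("percent", "fraction"))) {
    abort("response scales must be 'percent' or 'fraction'")
  }
  for (i in seq_len(nrow(factors))) {
    fname <- factors$name[i]
    levels_i <- c(factors$low[i], factors$center[i], factors$high[i])
    vals <- data[[fname]]
    if (!is.numeric(vals)) abort(paste0("factor column `", fname, "` must be numeric"))
    ok <- vapply(vals, function(v) any(abs(v - levels_i) <= 1e-8 * pmax(1, abs(levels_i))),
                 logical(1))
    if (!all(ok)) {
      abort(paste0("factor `", fname, "` has settings off the declared levels (",
                   paste(levels_i, collapse = ", "), ") in run(s): ",
                   paste(data$run[!ok], collapse = ", ")))
    }
  }
  for (rname in names(responses)) {
    if (!is.numeric(data[[rname]])) {
      abort(paste0("response column `", rname, "` must be numeric"))
    }
    if (any(is.infinite(data[[rname]]))) {
      abort(paste0("response column `", rname, "` contains non-finite values"))
    }
  }
  structure(data,
    class = c("sfe_design", class(data)),
    factors = factors,
    responses = responses,
    coding = "natural"
  )
}

design_meta <- function(x) {
  list(
    factors = attr(x, "factors"),
    responses = attr(x, "responses"),
    coding = attr(x, "coding") %||% "natural"
  )
}

#' Convert a design between natural units and coded levels
#'
#' `encode_design()` maps each factor setting to its coded level (-1 for low,
#' 0 for centre, +1 for high); `decode_design()` inverts the mapping exactly,
#' so the round trip reproduces natural units bit-for-bit.
#'
#' @param x A design table from [design_table()].
#' @return The design with factor columns on the other scale.
#' @export
encode_design <- function(x) {
  meta <- design_meta(x)
  if (meta$coding == "coded") return(x)
  fac <- meta$factors
  for (i in seq_len(nrow(fac))) {
    levels_i <- c(fac$low[i], fac$center[i], fac$high[i])
    idx <- vapply(x[[fac$name[i]]], function(v) which.min(abs(v - levels_i)), integer(1))
    x[[fac$name[i]]] <- c(-1, 0, 1)[idx]
  }
  attr(x, "coding") <- "coded"
  x
}

#' @rdname encode_design
#' @export
decode_design <- function(x) {
  meta <- design_meta(x)
  if (meta$coding == "natural") return(x)
  fac <- meta$factors
  for (i in seq_len(nrow(fac))) {
    levels_i <- c(fac$low[i], fac$center[i], fac$high[i])
    x[[fac$name[i]]] <- levels_i[match(x[[fac$name[i]]], c(-1, 0, 1))]
  }
  attr(x, "coding") <- "natural"
  x
}

#' Convert a stored response column between percent and fraction w/w
#'
#' @param x A design table.
#' @param response Response column name.
#' @param scale Target scale, `"percent"` or `"fraction"`.
#' @return The design with the response rescaled and its metadata updated.
#' @export
convert_response_scale <- function(x, response, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  meta <- design_meta(x)
  if (!response %in% names(meta$responses)) {
    abort(paste0("unknown response `", response, "`"))
  }
  from <- meta$responses[[response]]
  if (from != scale) {
    x[[response]] <- if (scale == "fraction") x[[response]] / 100 else x[[response]] * 100
    responses <- meta$responses
    responses[[response]] <- scale
    attr(x, "responses") <- responses
  }
  x
}

# replicate structure: groups of runs with identical factor settings
replicate_groups <- function(x) {
  fac <- design_meta(x)$factors$name
  key <- do.call(paste, c(lapply(fac, function(f) format(x[[f]], digits = 12)), sep = "|"))
  split(seq_len(nrow(x)), key)
}

pure_error_df <- function(x) {
  sum(vapply(replicate_groups(x), function(idx) length(idx) - 1L, integer(1)))
}

#' Load an embedded experimental-design fixture
#'
#' Two designs from a supercritical-CO2 extraction study of *Acacia mearnsii*
#' flowers ship with the package as plain CSV + YAML fixtures:
#'
#' * `"table1"` - the 2^2 factorial (pressure 120/180/240 bar; cosolvent
#'   water / 1:1 water-ethanol / ethanol stored pre-coded as -1/0/+1) with 7
#'   runs and the global extract yield (% w/w) response.
#' * `"table3"` - the 15-run Box-Behnken design in pressure (200-300 bar),
#'   temperature (40-60 degC) and mean particle size (42/60/150 mesh) with
#'   the p-anisic acid selectivity and global extract yield responses
#'   (% w/w).
#'
#' The files are checksum-pinned; a mismatch aborts rather than silently
#' analysing altered data.
#'
#' @param name `"table1"` or `"table3"`.
#' @return A design table (see [design_table()]).
#' @examples
#' sfe_fixture("table3")
#' @export
sfe_fixture <- function(name = c("table1", "table3")) {
  name <- match.arg(name)
  csv <- system.file("extdata", paste0(name, ".csv"), package = "sfekin", mustWork = TRUE)
  yml <- system.file("extdata", paste0(name, ".yml"), package = "sfekin", mustWork = TRUE)
  pinned <- c(
    table1 = "5edf513e93722e8e6d65e735895dfd0b",
    table3 = "51b0ccadd54b2825100548c19acc2849"
  )
  sum_now <- unname(tools::md5sum(csv))
  if (!identical(sum_now, unname(pinned[[name]]))) {
    abort(paste0("fixture ", name, ".csv checksum mismatch (", sum_now, ")"))
  }
  read_design_csv(csv, yml)
}
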