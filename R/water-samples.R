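## Canonical units per parameter. Metal concentrations are stored in ug/L
## (the dose equations take ug/L and the reference doses are in ug/kg/day);
## hardness ions and TDS stay in mg/L, EC in uS/cm, pH unitless.
.param_units <- c(
  pH = "unitless", EC = "uS/cm", TDS = "mg/L",
  Ca = "mg/L", Mg = "mg/L",
  Pb = "ug/L", Cr = "ug/L", Ni = "ug/L", Fe = "ug/L",
  Mn = "ug/L", Al = "ug/L", Cu = "ug/L", Cd = "ug/L")

.canonical_unit <- function(parameter) {
  u <- .param_units[parameter]
  ifelse(is.na(u), "ug/L", u)
}

## multiplicative factor from a declared unit to the canonical unit
.unit_factor <- function(parameter, unit) {
  canon <- .canonical_unit(parameter)
  if (is.na(unit) || unit == "" || unit == canon) return(1)
  key <- paste(unit, canon, sep = "->")
  f <- c("mg/L->ug/L" = 1000, "ug/L->mg/L" = 1e-3,
         "mS/cm->uS/cm" = 1000, "g/L->mg/L" = 1000)[key]
  if (is.na(f))
    stop("cannot convert unit '", unit, "' to canonical '", canon,
         "' for parameter ", parameter, call. = FALSE)
  unname(f)
}

#' Construct a validated long-format water-sample table
#'
#' The package represents a dataset as one row per (location, replicate,
#' parameter): columns `location_id`, `district`, `source_type`, `replicate`,
#' `x`, `y`, `parameter`, `value` (canonical units), `flag` (one of
#' `"measured"`, `"below_detection"`, `"not_detected"`) and `detection_limit`
#' (recorded for below-detection entries, otherwise `NA`).
#'
#' @param df a data frame with the columns above.
#' @return the data frame with class `water_samples`, after validation:
#'   measured values finite and non-negative, pH in `[0, 14]`, and
#'   (location, replicate) pairs carrying a consistent stratum.
#' @export
water_samples <- function(df) {
  need <- c("location_id", "district", "source_type", "replicate", "x", "y",
            "parameter", "value", "flag", "detection_limit")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  df$district <- as.character(df$district)
  df$source_type <- as.character(df$source_type)
  if (!all(df$source_type %in% c("borehole", "well")))
    stop("source_type must be 'borehole' or 'well'", call. = FALSE)
  if (!all(df$flag %in% c("measured", "below_detection", "not_detected")))
    stop("invalid detection flag", call. = FALSE)
  if (any(df$replicate < 1 | df$replicate != round(df$replicate)))
    stop("replicate must be a positive integer", call. = FALSE)
  meas <- df$flag == "measured"
  if (any(!is.finite(df$value[meas]) | df$value[meas] < 0))
    stop("measured concentrations must be finite and >= 0", call. = FALSE)
  ph <- meas & df$parameter == "pH"
  if (any(df$value[ph] < 0 | df$value[ph] > 14))
    stop("pH outside [0, 14]", call. = FALSE)
  key <- paste(df$location_id, df$replicate, df$parameter)
  if (anyDuplicated(key))
    stop("duplicate (location_id, replicate, parameter) entries", call. = FALSE)
  class(df) <- c("water_samples", "data.frame")
  df
}

#' Read a per-sample water-quality CSV
#'
#' Expects a wide table with header
#' `location_id,district,source_type,replicate,x,y` followed by parameter
#' columns, optionally annotated with a unit in square brackets (e.g.
#' `Pb[mg/L]`). Cells may be numbers, `ND` (analyte not detected) or `<x`
#' (below the detection limit `x`, recorded after unit conversion). All
#' concentrations are converted to canonical units on ingest.
#'
#' @param path path to the CSV file.
#' @return a [water_samples()] table.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  id_cols <- c("location_id", "district", "source_type", "replicate", "x", "y")
  missing <- setdiff(id_cols, names(raw))
  if (length(missing))
    stop("missing header column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  param_cols <- setdiff(names(raw), id_cols)
  if (nrow(raw) == 0) {
    empty <- data.frame(location_id = character(), district = character(),
                        source_type = character(), replicate = integer(),
                        x = numeric(), y = numeric(), parameter = character(),
                        value = numeric(), flag = character(),
                        detection_limit = numeric())
    return(water_samples(empty))
  }
  key <- paste(raw$location_id, raw$replicate)
  if (anyDuplicated(key))
    stop("integrity error: duplicate (location_id, replicate) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  out <- vector("list", length(param_cols))
  for (j in seq_along(param_cols)) {
    col <- param_cols[j]
    m <- regmatches(col, regexec("^([^\\[]+)(\\[(.*)\\])?$", col))[[1]]
    pname <- trimws(m[2])
    unit <- if (length(m) >= 4 && nzchar(m[4])) m[4] else NA_character_
    fac <- .unit_factor(pname, unit)
    cells <- trimws(raw[[col]])
    value <- rep(NA_real_, nrow(raw))
    flag <- rep("measured", nrow(raw))
    dl <- rep(NA_real_, nrow(raw))
    nd <- toupper(cells) %in% c("ND", "N.D.", "")
    bd <- grepl("^<", cells)
    flag[nd] <- "not_detected"
    flag[bd] <- "below_detection"
    if (any(bd)) {
      lim <- suppressWarnings(as.numeric(sub("^<", "", cells[bd])))
      if (anyNA(lim))
        stop("malformed '<' cell in column '", col, "', row ",
             which(bd)[which(is.na(lim))[1]], call. = FALSE)
      dl[bd] <- lim * fac
    }
    plain <- !nd & !bd
    if (any(plain)) {
      num <- suppressWarnings(as.numeric(cells[plain]))
      if (anyNA(num))
        stop("malformed numeric cell in column '", col, "', row ",
             which(plain)[which(is.na(num))[1]], call. = FALSE)
      value[plain] <- num * fac
    }
    out[[j]] <- data.frame(
      location_id = raw$location_id, district = raw$district,
      source_type = raw$source_type, replicate = as.integer(raw$replicate),
      x = as.numeric(raw$x), y = as.numeric(raw$y),
      parameter = pname, value = value, flag = flag, detection_limit = dl)
  }
  water_samples(do.call(rbind, out))
}

#' Write a water-sample table as a wide CSV
#'
#' Inverse of [read_sample_table()]: canonical units, `ND` for not-detected
#' and `<dl` for below-detection cells, parameter columns annotated with
#' their unit.
#'
#' @param samples a [water_samples()] table.
#' @param path output path.
#' @export
write_sample_table <- function(samples, path) {
  stopifnot(inherits(samples, "water_samples"))
  ids <- unique(samples[c("location_id", "district", "source_type",
                          "replicate", "x", "y")])
  ids <- ids[order(ids$district, ids$source_type, ids$location_id, ids$replicate), ]
  params <- unique(samples$parameter)
  wide <- ids
  for (p in params) {
    sub <- samples[samples$parameter == p, ]
    idx <- match(paste(ids$location_id, ids$replicate),
                 paste(sub$location_id, sub$replicate))
    cell <- rep("ND", nrow(ids))
    f <- sub$flag[idx]; v <- sub$value[idx]; d <- sub$detection_limit[idx]
    meas <- !is.na(f) & f == "measured"
    bd <- !is.na(f) & f == "below_detection"
    cell[meas] <- format(v[meas], digits = 15, trim = TRUE, scientific = FALSE)
    cell[bd] <- paste0("<", format(d[bd], digits = 15, trim = TRUE, scientific = FALSE))
    wide[[sprintf("%s[%s]", p, .canonical_unit(p))]] <- cell
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## rows of a stratum; district / source_type may be NULL meaning "both"
.stratum_rows <- function(samples, parameter, district = NULL, source_type = NULL) {
  keep <- samples$parameter == parameter
  if (!is.null(district)) keep <- keep & samples$district == district
  if (!is.null(source_type)) keep <- keep & samples$source_type == source_type
  samples[keep, , drop = FALSE]
}

## analysis values of a set of rows: measured values as-is, below-detection
## substituted by DL/2 (standard censoring convention), not-detected dropped
.analysis_values <- function(rows) {
  v <- rows$value
  bd <- rows$flag == "below_detection"
  v[bd] <- rows$detection_limit[bd] / 2
  v[rows$flag != "not_detected"]
}

#' Descriptive statistics for one parameter in one stratum
#'
#' Below-detection entries enter at half their detection limit; not-detected
#' entries are excluded. The SD uses the sample (n - 1) convention.
#'
#' @param samples a [water_samples()] table.
#' @param parameter parameter name.
#' @param district,source_type stratum selectors; `NULL` pools across the
#'   corresponding dimension.
#' @return a list with `n`, `min`, `max`, `mean`, `sd`.
#' @export
summarize_stratum <- function(samples, parameter, district = NULL, source_type = NULL) {
  stopifnot(inherits(samples, "water_samples"))
  rows <- .stratum_rows(samples, parameter, district, source_type)
  v <- .analysis_values(rows)
  if (length(v) == 0)
    stop("no measured values for ", parameter, " in the selected stratum",
         call. = FALSE)
  list(n = length(v), min = min(v), max = max(v), mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0)
}

#' Location-level values (replicate means) for one parameter
#'
#' Replicates are field triplicates of the same source; violation accounting
#' and multivariate analyses operate on the per-location mean.
#'
#' @inheritParams summarize_stratum
#' @return named numeric vector, one entry per location.
#' @export
location_values <- function(samples, parameter, district = NULL, source_type = NULL) {
  rows <- .stratum_rows(samples, parameter, district, source_type)
  rows <- rows[rows$flag != "not_detected", , drop = FALSE]
  if (nrow(rows) == 0) return(stats::setNames(numeric(0), character(0)))
  bd <- rows$flag == "below_detection"
  rows$value[bd] <- rows$detection_limit[bd] / 2
  tapply(rows$value, rows$location_id, mean)
}

#' Percentage of locations exceeding a guideline limit
#'
#' The ratio of location-level values (replicate means) strictly above the
#' limit to the number of locations in the stratum, times 100.
#'
#' @inheritParams summarize_stratum
#' @param limit guideline value in the parameter's canonical unit.
#' @export
violation_rate <- function(samples, parameter, limit, district = NULL,
                           source_type = NULL) {
  stopifnot(is.numeric(limit), length(limit) == 1L, is.finite(limit))
  if (!parameter %in% samples$parameter)
    stop("unknown parameter: ", parameter, call. = FALSE)
  v <- location_values(samples, parameter, district, source_type)
  if (length(v) == 0)
    stop("empty stratum for ", parameter, call. = FALSE)
  100 * sum(v > limit) / length(v)
}

#' Classify the strength of a correlation coefficient
#'
#' Magnitudes below 0.5 are weak, 0.5 to 0.6999 moderate, and 0.7 or above
#' strong. Negative coefficients are classified by their absolute value.
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @return character vector of `"weak"`, `"moderate"`, `"strong"`.
#' @export
classify_correlation <- function(r) {
  if (any(!is.finite(r) | abs(r) > 1))
    stop("correlation coefficients must lie in [-1, 1]", call. = FALSE)
  a <- abs(r)
  ifelse(a >= 0.7, "strong", ifelse(a >= 0.5, "moderate", "weak"))
}

#' Default drinking-water guideline table
#'
#' WHO and Nigerian (NSDWQ) limits in canonical units, plus the WHO "most
#' desirable limit" tier for the hardness ions. These are configuration data;
#' replace or extend the returned data frame for other jurisdictions.
#'
#' @return data frame with columns `parameter`, `authority`
#'   (`WHO`, `NSDWQ`, `WHO_MDL`), `limit`, `unit`.
#' @export
default_guidelines <- function() {
  g <- rbind(
    data.frame(parameter = "Pb", authority = c("WHO", "NSDWQ"), limit = c(10, 10)),
    data.frame(parameter = "Al", authority = c("WHO", "NSDWQ"), limit = c(200, 200)),
    data.frame(parameter = "Fe", authority = c("WHO", "NSDWQ"), limit = c(300, 300)),
    data.frame(parameter = "Mn", authority = c("WHO", "NSDWQ"), limit = c(400, 200)),
    data.frame(parameter = "Ni", authority = c("WHO", "NSDWQ"), limit = c(70, 20)),
    data.frame(parameter = "Cr", authority = c("WHO", "NSDWQ"), limit = c(50, 50)),
    data.frame(parameter = "Cd", authority = c("WHO", "NSDWQ"), limit = c(3, 3)),
    data.frame(parameter = "Cu", authority = c("WHO", "NSDWQ"), limit = c(2000, 1000)),
    data.frame(parameter = "TDS", authority = "WHO", limit = 1000),
    data.frame(parameter = "Ca", authority = c("WHO_MDL", "NSDWQ"), limit = c(50, 75)),
    data.frame(parameter = "Mg", authority = c("WHO_MDL", "NSDWQ"), limit = c(50, 20)))
  g$unit <- .canonical_unit(g$parameter)
  g
}

#' Guideline lookup
#'
#' @param guidelines a guideline table as from [default_guidelines()].
#' @param parameter,authority entry to look up; absent entries are an error
#'   (never silently zero).
#' @export
guideline_limit <- function(guidelines, parameter, authority) {
  hit <- guidelines$parameter == parameter & guidelines$authority == authority
  if (!any(hit))
    stop("no ", authority, " guideline for ", parameter, call. = FALSE)
  guidelines$limit[hit][1]
}

#' Per-stratum summary table with guideline-violation percentages
#'
#' One row per (district, source_type, parameter) with descriptive statistics
#' and the percentage of locations above the WHO and NSDWQ limits (NA when no
#' limit exists or the parameter was never measured in the stratum).
#'
#' @param samples a [water_samples()] table.
#' @param guidelines guideline table, default [default_guidelines()].
#' @export
summary_table <- function(samples, guidelines = default_guidelines()) {
  stopifnot(inherits(samples, "water_samples"))
  combos <- unique(samples[c("district", "source_type", "parameter")])
  combos <- combos[order(combos$district, combos$source_type, combos$parameter), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    d <- combos$district[i]; s <- combos$source_type[i]; p <- combos$parameter[i]
    st <- tryCatch(summarize_stratum(samples, p, d, s), error = function(e) NULL)
    vr <- function(auth) {
      lim <- tryCatch(guideline_limit(guidelines, p, auth), error = function(e) NA)
      if (is.na(lim) || is.null(st)) return(NA_real_)
      violation_rate(samples, p, lim, d, s)
    }
    data.frame(district = d, source_type = s, parameter = p,
               n = if (is.null(st)) 0L else st$n,
               min = if (is.null(st)) NA_real_ else st$min,
               max = if (is.null(st)) NA_real_ else st$max,
               mean = if (is.null(st)) NA_real_ else st$mean,
               sd = if (is.null(st)) NA_real_ else st$sd,
               pct_above_WHO = vr("WHO"), pct_above_NSDWQ = vr("NSDWQ"))
  })
  do.call(rbind, rows)
}
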