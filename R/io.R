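#' @import data.table
NULL

# Internal: read a delimited file and check required columns.
.read_table <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, data.table = FALSE)
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dt
}

.known_states <- function() datasets::state.abb

#' Read a daily weather table
#'
#' Reads a Daymet-style daily weather CSV with columns
#' `location_id,latitude,longitude,year,doy,tmin_c,tmax_c,precip_mm,srad,vp,dayl_s`
#' into the internal schema (`tmin`, `tmax`, `precip`, `srad`, `vp`,
#' `dayl`). Vapor pressure is converted to kPa when the source stores Pa
#' (Daymet does). Leap-day rows (doy 366) are dropped with a warning so
#' every year has exactly 365 day slots, which keeps window arithmetic
#' uniform. Rows are validated (`tmax >= tmin`, `precip >= 0`, `vp >= 0`,
#' unique (location, year, doy)) and each location-year must be gap-free:
#' missing days are rejected, not imputed.
#'
#' @param path Path to the CSV file.
#' @param vp_unit Unit of the `vp` column in the source file: `"kPa"`
#'   (internal unit) or `"Pa"`.
#' @return Data frame sorted by (location_id, year, doy) with columns
#'   `location_id, latitude, longitude, year, doy, tmin, tmax, precip,
#'   srad, vp, dayl`; `vp` in kPa.
#' @export
read_daily_weather <- function(path, vp_unit = c("kPa", "Pa")) {
  vp_unit <- match.arg(vp_unit)
  req <- c("location_id", "latitude", "longitude", "year", "doy",
           "tmin_c", "tmax_c", "precip_mm", "srad", "vp", "dayl_s")
  dt <- .read_table(path, req, "daily weather")
  names(dt)[match(c("tmin_c", "tmax_c", "precip_mm", "dayl_s"), names(dt))] <-
    c("tmin", "tmax", "precip", "dayl")
  if (vp_unit == "Pa") dt$vp <- dt$vp / 1000
  n366 <- sum(dt$doy == 366)
  if (n366 > 0) {
    warning("dropping ", n366, " leap-day row(s) (doy 366)", call. = FALSE)
    dt <- dt[dt$doy != 366, , drop = FALSE]
  }
  if (any(dt$doy < 1 | dt$doy > 365)) {
    stop("doy outside 1..365", call. = FALSE)
  }
  bad <- which(dt$tmax < dt$tmin)
  if (length(bad)) {
    stop("tmax < tmin at row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(dt$precip < 0)) stop("negative precipitation", call. = FALSE)
  if (any(dt$vp < 0)) stop("negative vapor pressure", call. = FALSE)
  key <- paste(dt$location_id, dt$year, dt$doy, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (location_id, year, doy) key(s), e.g. row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  dt <- dt[order(dt$location_id, dt$year, dt$doy), , drop = FALSE]
  # reject gaps within each location-year: days must be contiguous
  gap <- vapply(split(dt$doy, paste(dt$location_id, dt$year)), function(d) {
    any(diff(sort(d)) != 1L)
  }, logical(1))
  if (any(gap)) {
    stop("gap(s) in daily coverage for location-year(s): ",
         paste(utils::head(names(gap)[gap], 5), collapse = "; "),
         " (missing days are rejected, not imputed)", call. = FALSE)
  }
  rownames(dt) <- NULL
  dt
}

#' Write a daily weather table in the on-disk schema
#'
#' Inverse of [read_daily_weather()] (always writes `vp` in kPa).
#' @param weather Data frame in the internal schema.
#' @param path Output CSV path.
#' @export
write_daily_weather <- function(weather, path) {
  out <- data.frame(
    location_id = weather$location_id, latitude = weather$latitude,
    longitude = weather$longitude, year = weather$year, doy = weather$doy,
    tmin_c = weather$tmin, tmax_c = weather$tmax, precip_mm = weather$precip,
    srad = weather$srad, vp = weather$vp, dayl_s = weather$dayl)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a trial-yield table (long format)
#'
#' One row per (trial, maturity group): columns
#' `trial_id,state,year,location_id,sowing_doy,mg,yield_kg_ha`.
#' States must be valid 2-letter US postal codes, yields positive, and
#' sowing days within 1..200.
#'
#' @param path Path to the CSV file.
#' @return Data frame in the same long schema (possibly empty).
#' @export
read_trials <- function(path) {
  req <- c("trial_id", "state", "year", "location_id", "sowing_doy",
           "mg", "yield_kg_ha")
  dt <- .read_table(path, req, "trials")
  if (nrow(dt) == 0) return(dt)
  unk <- setdiff(unique(dt$state), .known_states())
  if (length(unk)) {
    stop("unknown state code(s): ", paste(unk, collapse = ", "), call. = FALSE)
  }
  if (any(dt$yield_kg_ha <= 0)) stop("yields must be positive", call. = FALSE)
  if (any(dt$sowing_doy < 1 | dt$sowing_doy > 200)) {
    stop("sowing_doy outside 1..200", call. = FALSE)
  }
  dt
}

#' Read a weekly crop-progress table
#'
#' Columns `state,year,doy,pct_sown` with percentages in 0..100.
#' @param path Path to the CSV file.
#' @return Data frame.
#' @export
read_crop_progress <- function(path) {
  dt <- .read_table(path, c("state", "year", "doy", "pct_sown"), "crop progress")
  if (nrow(dt) && any(dt$pct_sown < 0 | dt$pct_sown > 100)) {
    stop("pct_sown outside 0..100", call. = FALSE)
  }
  dt
}

#' Read state economics and CPI deflator tables
#'
#' The economics table has columns
#' `state,year,income_usd,production_t,hectares`; the CPI table has
#' `year,deflator_to_2016` (deflator multiplies a nominal value to
#' express it in 2016 US$; the 2016 deflator is 1).
#'
#' @param econ_path,cpi_path CSV paths.
#' @return List with elements `econ` and `cpi`.
#' @export
read_state_tables <- function(econ_path, cpi_path) {
  econ <- .read_table(econ_path,
                      c("state", "year", "income_usd", "production_t", "hectares"),
                      "economics")
  unk <- setdiff(unique(econ$state), .known_states())
  if (length(unk)) {
    stop("unknown state code(s) in economics table: ",
         paste(unk, collapse = ", "), call. = FALSE)
  }
  if (any(econ$production_t < 0)) stop("negative production", call. = FALSE)
  cpi <- .read_table(cpi_path, c("year", "deflator_to_2016"), "CPI")
  list(econ = econ, cpi = cpi)
}

#' Write pipeline outputs to a directory
#'
#' Data frames are written as CSV, everything else as JSON, one file per
#' element named after the list element.
#'
#' @param results Named list of data frames and/or lists.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      data.table::fwrite(x, p)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
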