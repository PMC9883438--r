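# CSV I/O for the three annual series used by the analysis:
# abundance (year, S, R), climate index (year, value), cycle covariate (year, T).
# All files are comma-delimited UTF-8 with a header row.

#' Read an annual abundance table from CSV
#'
#' Reads a delimited file of annual nester and hatchling counts and returns the
#' standard abundance tibble with columns `year`, `S` (nesting females) and
#' `R` (hatchlings). File column names are configurable through `cols`, since
#' monitoring programmes name these columns differently.
#'
#' @param path Path to a CSV file with a header row.
#' @param cols Named character vector mapping the roles `year`, `nesters`,
#'   `hatchlings` to the column names used in the file.
#' @return A validated tibble with columns `year`, `S`, `R`.
#' @seealso [write_abundance()], [validate_abundance()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("year,nesters,hatchlings", "1984,10,2000", "1985,12,2600"), tf)
#' read_abundance(tf)
#' @export
read_abundance <- function(path,
                           cols = c(year = "year", nesters = "nesters",
                                    hatchlings = "hatchlings")) {
  roles <- c("year", "nesters", "hatchlings")
  if (!all(roles %in% names(cols))) {
    stop_param("`cols` must name entries for year, nesters and hatchlings.")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  missing_cols <- setdiff(unname(cols[roles]), names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("file ", path, " is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    year = raw[[cols[["year"]]]],
    S = raw[[cols[["nesters"]]]],
    R = raw[[cols[["hatchlings"]]]]
  )
  validate_abundance(out)
}

#' Write an annual abundance table to CSV
#'
#' @param data Abundance tibble with columns `year`, `S`, `R`.
#' @param path Output file path.
#' @param cols Column names to use in the file, as in [read_abundance()].
#' @return `path`, invisibly.
#' @export
write_abundance <- function(data, path,
                            cols = c(year = "year", nesters = "nesters",
                                     hatchlings = "hatchlings")) {
  data <- validate_abundance(data)
  out <- stats::setNames(data[c("year", "S", "R")],
                         unname(cols[c("year", "nesters", "hatchlings")]))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an annual climate-index series from CSV
#'
#' Accepts either an annual file (columns `year`, `value`) or a monthly file
#' (columns `year`, `month`, `value`). Monthly input is reduced to annual
#' means; every year inside the span must have all 12 months. The year span
#' must be gap-free.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with columns `year`, `value` (one row per year).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("year,value", "1900,0.1", "1901,-0.2"), tf)
#' read_climate_index(tf)
#' @export
read_climate_index <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("year", "value") %in% names(raw))) {
    stop_schema(paste0("file ", path, " must have columns year,value or year,month,value."))
  }
  monthly <- "month" %in% names(raw)
  parse_num <- function(col, name) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(x))
    if (length(bad) > 0 || anyNA(col)) {
      lines <- sort(unique(c(bad, which(is.na(col))))) + 1L  # +1 for header row
      stop_validation(paste0("unparseable ", name, " in ", path,
                             " at line(s): ", paste(lines, collapse = ", ")))
    }
    x
  }
  year <- parse_num(raw$year, "year")
  value <- parse_num(raw$value, "value")
  if (monthly) {
    month <- parse_num(raw$month, "month")
    by_year <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(year, month, value), year),
      missing = paste(setdiff(1:12, .data$month), collapse = ","),
      value = mean(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
    incomplete <- dplyr::filter(by_year, .data$n != 12L | .data$missing != "")
    if (nrow(incomplete) > 0) {
      stop_validation(paste0(
        "monthly climate file is incomplete: ",
        paste(sprintf("year %d missing month(s) %s", incomplete$year,
                      incomplete$missing), collapse = "; ")))
    }
    out <- dplyr::arrange(by_year[c("year", "value")], .data$year)
  } else {
    out <- dplyr::arrange(tibble::tibble(year, value), .data$year)
  }
  if (anyDuplicated(out$year)) {
    stop_validation("duplicate years in climate index.")
  }
  missing_years <- setdiff(seq(min(out$year), max(out$year)), out$year)
  if (length(missing_years) > 0) {
    stop_validation(paste0("gap in climate-index years; missing: ",
                           paste(missing_years, collapse = ", ")))
  }
  out
}

#' Write an annual climate-index series to CSV
#'
#' @param data Tibble with columns `year`, `value`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_climate_index <- function(data, path) {
  if (!all(c("year", "value") %in% names(data))) {
    stop_schema("climate index must have columns year, value.")
  }
  readr::write_csv(tibble::as_tibble(data)[c("year", "value")], path, progress = FALSE)
  invisible(path)
}

#' Read a precomputed cycle covariate series from CSV
#'
#' A cycle series carries the (possibly lagged) climate-cycle covariate `T`
#' for each year, as produced by [eval_cycle()] or supplied externally. Using
#' one bypasses harmonic extraction entirely.
#'
#' @param path Path to a CSV file with header `year,T`.
#' @return A tibble with columns `year`, `T`.
#' @export
read_cycle <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  if (!all(c("year", "T") %in% names(raw))) {
    stop_schema(paste0("file ", path, " must have columns year, T."))
  }
  out <- dplyr::arrange(tibble::as_tibble(raw)[c("year", "T")], .data$year)
  if (anyDuplicated(out$year) || is.unsorted(out$year, strictly = TRUE)) {
    stop_validation("cycle series years must be strictly increasing.")
  }
  out
}

#' Write a cycle covariate series to CSV
#'
#' @param data Tibble with columns `year`, `T`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cycle <- function(data, path) {
  if (!all(c("year", "T") %in% names(data))) {
    stop_schema("cycle series must have columns year, T.")
  }
  readr::write_csv(tibble::as_tibble(data)[c("year", "T")], path, progress = FALSE)
  invisible(path)
}
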