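# Shared validators. All user-facing errors carry a subclass of
# "cushingsr_error" so callers can condition on them.

stop_schema <- function(msg) abort(msg, class = c("cushingsr_error_schema", "cushingsr_error"))
stop_validation <- function(msg) abort(msg, class = c("cushingsr_error_validation", "cushingsr_error"))
stop_domain <- function(msg) abort(msg, class = c("cushingsr_error_domain", "cushingsr_error"))
stop_param <- function(msg) abort(msg, class = c("cushingsr_error_parameter", "cushingsr_error"))
stop_data <- function(msg) abort(msg, class = c("cushingsr_error_data", "cushingsr_error"))

is_whole <- function(x) is.numeric(x) && all(is.finite(x)) && all(x == round(x))

#' Validate an annual abundance table
#'
#' Checks the invariants every abundance series must satisfy before it can be
#' used by the model-fitting functions: integer years in strictly increasing
#' order with no duplicates, and strictly positive nester (`S`) and hatchling
#' (`R`) counts in every year (the log and square-root transforms used
#' throughout must be defined).
#'
#' @param data A data frame with columns `year`, `S` (nesting females) and
#'   `R` (hatchlings).
#' @param require_consecutive If `TRUE`, additionally require consecutive
#'   years with no gaps (needed by the sliding-window regression).
#' @return The validated data, invisibly coerced to a tibble, for piping.
#' @examples
#' validate_abundance(tibble::tibble(year = 1984:1985, S = c(10, 12), R = c(2000, 2600)))
#' @export
validate_abundance <- function(data, require_consecutive = FALSE) {
  if (!is.data.frame(data)) stop_schema("`data` must be a data frame with columns year, S, R.")
  missing_cols <- setdiff(c("year", "S", "R"), names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("abundance table is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) < 2) stop_validation("abundance series must contain at least 2 years.")
  if (!is_whole(data$year)) stop_validation("`year` must be whole calendar years.")
  dup <- data$year[duplicated(data$year)]
  if (length(dup) > 0) {
    stop_validation(paste0("duplicate year(s) in abundance series: ",
                           paste(unique(dup), collapse = ", ")))
  }
  if (is.unsorted(data$year, strictly = TRUE)) {
    stop_validation("years must be strictly increasing.")
  }
  bad <- data$year[!is.finite(data$S) | !is.finite(data$R) | data$S <= 0 | data$R <= 0]
  if (length(bad) > 0) {
    stop_validation(paste0("S and R must be positive; offending year(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (require_consecutive && !all(diff(data$year) == 1)) {
    gaps <- data$year[-1][diff(data$year) != 1]
    stop_validation(paste0("abundance years must be consecutive; gap before year(s): ",
                           paste(gaps, collapse = ", ")))
  }
  invisible(data)
}
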