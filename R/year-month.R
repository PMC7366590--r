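#' Year-month arithmetic
#'
#' Calendar months are represented as ISO `"YYYY-MM"` strings and, internally,
#' as a running month count (`year * 12 + month - 1`). All calendar arithmetic
#' in the package is whole-month: "one month prior" means the previous calendar
#' month; there is no day-level resolution because the panels are monthly.
#'
#' @param ym character vector of `"YYYY-MM"` strings.
#' @param n integer month counts as produced by `ym_to_int()`.
#' @param k integer number of months to add (may be negative).
#' @return `ym_to_int()` returns an integer vector; `int_to_ym()` a character
#'   vector; `ym_add()` a character vector shifted by `k` months.
#' @examples
#' ym_add("2012-05", -1)  # "2012-04"
#' ym_to_int("2000-01") + 148 == ym_to_int("2012-05")
#' @name year_month
NULL

#' @rdname year_month
#' @export
ym_to_int <- function(ym) {
  ok <- grepl("^\\d{4}-\\d{2}$", ym)
  if (any(!ok)) {
    stop("calendar months must be 'YYYY-MM' strings; offending value(s): ",
         paste(utils::head(ym[!ok], 3L), collapse = ", "), call. = FALSE)
  }
  y <- as.integer(substr(ym, 1L, 4L))
  m <- as.integer(substr(ym, 6L, 7L))
  if (any(m < 1L | m > 12L)) stop("month component outside 01..12", call. = FALSE)
  y * 12L + (m - 1L)
}

#' @rdname year_month
#' @export
int_to_ym <- function(n) {
  n <- as.integer(n)
  sprintf("%04d-%02d", n %/% 12L, n %% 12L + 1L)
}

#' @rdname year_month
#' @export
ym_add <- function(ym, k) int_to_ym(ym_to_int(ym) + as.integer(k))
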