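# Period life tables over single ages with an open terminal interval,
# and life expectancy.

#' Construct a single-stratum period life table
#'
#' @param age integer vector of consecutive single ages, starting at the
#'   youngest tabulated age (15 for the standard input); the last age is
#'   the open interval.
#' @param l survivors at exact age (any radix); must be non-increasing.
#' @param L person-years lived in each age interval; the last value is
#'   the open-interval person-years.
#' @param e optional remaining life expectancy column; if supplied, the
#'   open-interval consistency L_omega = l_omega * e_omega is checked.
#' @param country,sex optional stratum labels.
#' @return An object of class \code{wahe_lifetable}.
#' @export
lifetable <- function(age, l, L, e = NULL, country = NA_character_,
                      sex = NA_character_) {
  age <- as.integer(age)
  n <- length(age)
  if (n < 2L) stop("life table needs at least two ages")
  if (any(diff(age) != 1L))
    stop(sprintf("format error: gap in age sequence after age %d",
                 age[which(diff(age) != 1L)[1]]))
  if (length(l) != n || length(L) != n)
    stop("age, l and L must have equal length")
  bad <- which(diff(l) > 0)
  if (length(bad))
    stop(sprintf("validation error: survivors l increase at age %d", age[bad[1] + 1L]))
  if (any(l <= 0)) stop("validation error: non-positive survivors l")
  if (any(L < 0)) stop("validation error: negative person-years L")
  # within closed single-year intervals, person-years are bracketed by the
  # bounding survivorship counts
  up <- which(L[-n] > l[-n] + 1e-9 * l[1] | L[-n] < l[-1] - 1e-9 * l[1])
  if (length(up))
    stop(sprintf("validation error: L outside [l(a+1), l(a)] at age %d", age[up[1]]))
  if (!is.null(e)) {
    if (length(e) != n) stop("e must have the same length as age")
    if (is.finite(e[n]) &&
        abs(L[n] - l[n] * e[n]) > 1e-6 * max(1, abs(L[n])))
      stop("validation error: open interval violates L_omega = l_omega * e_omega")
  }
  structure(list(age = age, l = as.numeric(l), L = as.numeric(L),
                 e = if (is.null(e)) NULL else as.numeric(e),
                 radix = l[1], omega = age[n],
                 country = country, sex = sex),
            class = "wahe_lifetable")
}

#' @export
print.wahe_lifetable <- function(x, ...) {
  cat(sprintf("<wahe_lifetable> %s/%s ages %d..%d+ (radix %g)\n",
              x$country, x$sex, x$age[1], x$omega, x$radix))
  invisible(x)
}

#' @export
as.data.frame.wahe_lifetable <- function(x, ...) {
  d <- data.frame(country = x$country, sex = x$sex, age = x$age,
                  l = x$l, L = x$L, stringsAsFactors = FALSE)
  if (!is.null(x$e)) d$e <- x$e
  d
}

#' Read period life tables from CSV
#'
#' Expects a long-format CSV with columns \code{country, sex, age, l, L}
#' and optionally \code{e} (the Eurostat mortality-table layout), one row
#' per single age per (country, sex) stratum. Each stratum is validated
#' (consecutive ages, non-increasing survivors, person-year bounds).
#'
#' @param path CSV path.
#' @param dialect optional named list renaming columns, e.g.
#'   \code{list(l = "SURVIVORS")}.
#' @return A named list of \code{\link{lifetable}} objects, names
#'   \code{"<country>:<sex>"}.
#' @export
read_lifetable <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop(sprintf("I/O error: file '%s' not found", path))
  cm <- utils::modifyList(list(country = "country", sex = "sex", age = "age",
                               l = "l", L = "L", e = "e"),
                          as.list(dialect %||% list()))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("country", "sex", "age", "l", "L")
  miss <- need[!vapply(need, function(f) cm[[f]] %in% names(raw), TRUE)]
  if (length(miss))
    stop(sprintf("configuration error: column(s) %s absent from '%s'",
                 paste(sprintf("'%s'", unlist(cm[miss])), collapse = ", "), path))
  has_e <- cm$e %in% names(raw)
  key <- paste(raw[[cm$country]], raw[[cm$sex]], sep = ":")
  out <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    d <- raw[idx, , drop = FALSE]
    d <- d[order(d[[cm$age]]), , drop = FALSE]
    lifetable(d[[cm$age]], d[[cm$l]], d[[cm$L]],
              e = if (has_e) d[[cm$e]] else NULL,
              country = d[[cm$country]][1], sex = d[[cm$sex]][1])
  })
  out[sort(names(out))]
}

#' Write life tables to CSV
#'
#' @param lts a \code{wahe_lifetable} or list of them.
#' @param path output CSV path.
#' @export
write_lifetable <- function(lts, path) {
  if (inherits(lts, "wahe_lifetable")) lts <- list(lts)
  d <- do.call(rbind, lapply(lts, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Remaining life expectancy from a life table
#'
#' \eqn{LE_x = \sum_{a \ge x} L_a / l_x}, in years.
#'
#' @param lt a \code{\link{lifetable}}.
#' @param x exact age, within the table's age range.
#' @return Years of remaining life expectancy at age \code{x}.
#' @export
life_expectancy <- function(lt, x = 15) {
  stopifnot(inherits(lt, "wahe_lifetable"))
  i <- match(x, lt$age)
  if (is.na(i)) stop(sprintf("domain error: age %s outside the life table", x))
  kahan_sum(lt$L[lt$age >= x]) / lt$l[i]
}
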