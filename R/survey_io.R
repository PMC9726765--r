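# Reading and validating survey microdata, and survey-weighted
# health-state prevalence with scheme-local listwise deletion.

default_column_map <- function() {
  list(person_id = "person_id", country = "country", sex = "sex",
       age = "age", chronic = "chronic", gali = "gali", srh = "srh",
       life_satisfaction = "life_satisfaction", cs_weight = "cs_weight")
}

.recode_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "2")] <- "female"
  out
}

.recode_chronic <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("yes", "y", "1")] <- "yes"
  out[x %in% c("no", "n", "2", "0")] <- "no"
  out[x %in% c("", "na", "missing")] <- NA_character_
  out
}

.recode_gali <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("severely_limited", "severely limited", "1")] <- "severely_limited"
  out[x %in% c("limited_not_severely", "limited but not severely", "2")] <- "limited_not_severely"
  out[x %in% c("not_limited", "not limited at all", "not limited", "3")] <- "not_limited"
  out
}

#' Read survey microdata
#'
#' Reads a cross-sectional survey CSV (one row per respondent) carrying the
#' three MEHM health items, life satisfaction and a cross-sectional survey
#' weight, validates every row, and returns the valid records together with
#' a machine-readable validation report. Rows failing validation are
#' excluded and reported with their row numbers; nothing is dropped
#' silently. Explicitly missing item values (empty, NA) are retained as
#' missing and handled listwise per scheme downstream.
#'
#' @param path path to a CSV file.
#' @param column_map named list (or path to a YAML file containing one)
#'   mapping the canonical field names \code{person_id, country, sex, age,
#'   chronic, gali, srh, life_satisfaction, cs_weight} to the column names
#'   in the file. Fields omitted from the map keep the canonical name.
#'   \code{person_id} is optional in the file (row numbers are used).
#' @return A data.frame of class \code{wahe_survey} with canonical columns,
#'   carrying the validation report in \code{attr(, "validation")}
#'   (a data.frame with \code{row}, \code{field}, \code{value},
#'   \code{reason}).
#' @export
read_microdata <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop(sprintf("I/O error: file '%s' not found", path))
  if (is.character(column_map) && length(column_map) == 1L)
    column_map <- yaml::read_yaml(column_map)
  cm <- utils::modifyList(default_column_map(), as.list(column_map %||% list()))

  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("I/O error reading '%s': %s",
                                     path, conditionMessage(e)))
  )
  mandatory <- setdiff(names(default_column_map()), "person_id")
  missing_cols <- vapply(mandatory, function(f) !(cm[[f]] %in% names(raw)), TRUE)
  if (any(missing_cols))
    stop(sprintf("configuration error: mapped column(s) %s absent from '%s'",
                 paste(sprintf("'%s'", unlist(cm[mandatory[missing_cols]])),
                       collapse = ", "), path))

  n <- nrow(raw)
  id <- if (cm$person_id %in% names(raw)) as.character(raw[[cm$person_id]])
        else as.character(seq_len(n))
  d <- data.frame(
    person_id = id,
    country = trimws(as.character(raw[[cm$country]])),
    sex = .recode_sex(raw[[cm$sex]]),
    age = suppressWarnings(as.integer(raw[[cm$age]])),
    chronic = .recode_chronic(raw[[cm$chronic]]),
    gali = .recode_gali(raw[[cm$gali]]),
    srh = suppressWarnings(as.integer(raw[[cm$srh]])),
    life_satisfaction = suppressWarnings(as.integer(raw[[cm$life_satisfaction]])),
    cs_weight = suppressWarnings(as.numeric(raw[[cm$cs_weight]])),
    stringsAsFactors = FALSE
  )

  rep_rows <- list()
  note <- function(rows, field, values, reason) {
    if (length(rows))
      rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
        row = rows, field = field, value = as.character(values),
        reason = reason, stringsAsFactors = FALSE)
  }
  bad <- rep(FALSE, n)

  i <- which(is.na(d$sex)); note(i, "sex", raw[[cm$sex]][i], "unrecognized sex code")
  bad[i] <- TRUE
  i <- which(is.na(d$age) | d$age < 15L | d$age > 120L)
  note(i, "age", raw[[cm$age]][i], "age missing or outside [15, 120]")
  bad[i] <- TRUE
  i <- which(is.na(d$cs_weight) | d$cs_weight <= 0)
  note(i, "cs_weight", raw[[cm$cs_weight]][i], "survey weight missing or not > 0")
  bad[i] <- TRUE
  i <- which(d$country == "" | is.na(d$country))
  note(i, "country", raw[[cm$country]][i], "empty country code")
  bad[i] <- TRUE

  # out-of-range ordinal codes invalidate the record; explicit missing does not
  srh_raw <- trimws(as.character(raw[[cm$srh]]))
  i <- which(!(srh_raw %in% c("", "NA")) & (is.na(d$srh) | d$srh < 1L | d$srh > 5L))
  note(i, "srh", srh_raw[i], "self-rated health outside 1..5")
  bad[i] <- TRUE
  ls_raw <- trimws(as.character(raw[[cm$life_satisfaction]]))
  i <- which(!(ls_raw %in% c("", "NA")) &
               (is.na(d$life_satisfaction) | d$life_satisfaction < 1L |
                  d$life_satisfaction > 10L))
  note(i, "life_satisfaction", ls_raw[i], "life satisfaction outside 1..10")
  bad[i] <- TRUE
  chr_raw <- trimws(as.character(raw[[cm$chronic]]))
  i <- which(!(tolower(chr_raw) %in% c("", "na", "missing")) & is.na(d$chronic))
  note(i, "chronic", chr_raw[i], "unrecognized chronic morbidity code")
  bad[i] <- TRUE
  gali_raw <- trimws(as.character(raw[[cm$gali]]))
  i <- which(!(tolower(gali_raw) %in% c("", "na", "missing")) & is.na(d$gali))
  note(i, "gali", gali_raw[i], "unrecognized activity limitation code")
  bad[i] <- TRUE

  report <- if (length(rep_rows)) do.call(rbind, rep_rows)
            else data.frame(row = integer(), field = character(),
                            value = character(), reason = character(),
                            stringsAsFactors = FALSE)
  report <- report[order(report$row), , drop = FALSE]
  rownames(report) <- NULL
  out <- d[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(report))
    message(sprintf("read_microdata: %d of %d row(s) failed validation (see attr(x, 'validation'))",
                    length(unique(report$row)), n))
  structure(out, validation = report,
            class = c("wahe_survey", "data.frame"))
}

#' Validation report of a microdata read
#'
#' @param data a \code{wahe_survey} object.
#' @return The validation report data.frame.
#' @export
validation_report <- function(data) {
  attr(data, "validation") %||%
    data.frame(row = integer(), field = character(), value = character(),
               reason = character(), stringsAsFactors = FALSE)
}

#' Survey-weighted health-state prevalence
#'
#' Estimates, per country, sex and age group, the distribution of the
#' population over the states of a health scheme, weighting respondents by
#' their cross-sectional survey weights. Records whose coded state is
#' missing are excluded listwise for this scheme only (no imputation);
#' the effective (unweighted) count of contributing respondents is
#' reported per cell.
#'
#' @param data a \code{wahe_survey} data.frame (see
#'   \code{\link{read_microdata}} or \code{\link{generate_survey}}).
#' @param scheme a \code{\link{health_scheme}}.
#' @param ages an \code{\link{age_groups}} scheme.
#' @return A tidy data.frame of class \code{wahe_prevalence} with columns
#'   \code{country, sex, age_group, state, share, n_effective}. Shares sum
#'   to one within each (country, sex, age_group) cell; every state of the
#'   scheme is present (possibly with share 0). Attributes: \code{scheme}
#'   (name), \code{states}, \code{full_state}, \code{age_scheme}.
#' @export
estimate_prevalence <- function(data, scheme, ages = age_groups()) {
  stopifnot(inherits(scheme, "health_scheme"),
            inherits(ages, "age_group_scheme"))
  if (any(data$cs_weight <= 0 | !is.finite(data$cs_weight)))
    stop("validation error: non-positive survey weight")
  state <- scheme$code(data)
  states <- scheme$states %||% sort(unique(state[!is.na(state)]))
  if (!length(states)) stop("no non-missing states observed for this scheme")
  if (is.null(scheme$states) && !(scheme$full_state %in% states))
    states <- c(scheme$full_state, states)  # keep full state representable

  grp <- assign_age_group(data$age, ages)
  keep <- !is.na(state)
  cell_all <- interaction(data$country, data$sex, grp, drop = TRUE, sep = "\r")
  empty <- setdiff(levels(cell_all), levels(droplevels(cell_all[keep])))
  if (length(empty)) {
    parts <- strsplit(empty[1], "\r", fixed = TRUE)[[1]]
    stop(sprintf(
      "empty cell: no valid '%s' records for country=%s sex=%s age_group=%s",
      scheme$name, parts[1], parts[2], parts[3]))
  }

  d <- data.frame(country = data$country[keep], sex = data$sex[keep],
                  age_group = grp[keep], state = factor(state[keep], levels = states),
                  w = data$cs_weight[keep], stringsAsFactors = FALSE)
  key <- interaction(d$country, d$sex, d$age_group, drop = TRUE, sep = "\r")
  wsum <- tapply(d$w, list(key, d$state), sum, default = 0)
  tot <- rowSums(wsum)
  shares <- wsum / tot
  neff <- tapply(rep(1L, nrow(d)), key, sum)

  kk <- do.call(rbind, strsplit(rownames(wsum), "\r", fixed = TRUE))
  out <- data.frame(
    country = rep(kk[, 1], times = ncol(shares)),
    sex = rep(kk[, 2], times = ncol(shares)),
    age_group = rep(kk[, 3], times = ncol(shares)),
    state = rep(colnames(shares), each = nrow(shares)),
    share = as.vector(shares),
    n_effective = rep(as.integer(neff), times = ncol(shares)),
    stringsAsFactors = FALSE
  )
  ord <- order(out$country, out$sex,
               match(out$age_group, ages$label), match(out$state, states))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, scheme = scheme$name, states = states,
            full_state = scheme$full_state, age_scheme = ages,
            class = c("wahe_prevalence", "data.frame"))
}

#' Write / read a prevalence table as tidy CSV
#'
#' @param prev a \code{wahe_prevalence} object.
#' @param path output CSV path.
#' @return \code{write_prevalence} invisibly returns \code{path}.
#' @export
write_prevalence <- function(prev, path) {
  utils::write.csv(as.data.frame(prev), path, row.names = FALSE)
  invisible(path)
}
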