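#' Immunization schedule objects
#'
#' A `vax_schedule` holds the recommended immunization schedule the audit is
#' run against: one row per dose with its antigen label, series membership,
#' recommended age in days since birth, the early/delay margins that bound the
#' timeliness window, whether the dose counts towards full-immunization (FIC)
#' status, and an optional same-day companion dose (pentavalent doses are
#' companioned with the corresponding oral polio doses).
#'
#' @param doses data.frame with columns `antigen`, `series`, `dose_index`,
#'   `recommended_age`, `early_margin`, `delay_margin`, `in_fic`, `companion`
#'   (NA when none). Ages and margins are integer days.
#' @param fic_cutoff integer days: age by which FIC-basis doses must have been
#'   received (default 365, i.e. 12 months).
#' @param rollout_dates named vector of ISO dates (or `Date`s), one per antigen
#'   that was introduced mid-study; the antigen is not offered before its
#'   rollout date. May be empty.
#' @return An object of class `vax_schedule`.
#' @seealso [default_epi_schedule()], [load_schedule()], [timeliness_window()]
#' @export
vax_schedule <- function(doses, fic_cutoff = 365L, rollout_dates = NULL) {
  stopifnot(is.data.frame(doses))
  req <- c("antigen", "series", "dose_index", "recommended_age",
           "early_margin", "delay_margin", "in_fic", "companion")
  missing_cols <- setdiff(req, names(doses))
  if (length(missing_cols))
    stop("schedule doses table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  doses <- doses[, req]
  doses$antigen <- as.character(doses$antigen)
  doses$series <- as.character(doses$series)
  doses$dose_index <- as.integer(doses$dose_index)
  doses$recommended_age <- as.integer(doses$recommended_age)
  doses$early_margin <- as.integer(doses$early_margin)
  doses$delay_margin <- as.integer(doses$delay_margin)
  doses$in_fic <- as.logical(doses$in_fic)
  doses$companion <- as.character(doses$companion)
  rownames(doses) <- NULL
  if (is.null(rollout_dates)) rollout_dates <- character(0)
  rd <- as.Date(unlist(rollout_dates))
  names(rd) <- names(rollout_dates)
  obj <- structure(
    list(doses = doses, fic_cutoff = as.integer(fic_cutoff),
         rollout_dates = rd),
    class = "vax_schedule")
  validate_schedule(obj)
  obj
}

#' Validate a schedule's invariants
#'
#' Checks dose-label uniqueness, non-negative ages and margins, strictly
#' increasing recommended ages within each series, and symmetry of companion
#' links. Called by every schedule constructor; exported so externally built
#' objects can be re-checked.
#'
#' @param schedule a `vax_schedule`.
#' @return Invisibly, the schedule. Throws an error naming the offending dose
#'   and field on violation.
#' @export
validate_schedule <- function(schedule) {
  d <- schedule$doses
  if (anyDuplicated(d$antigen))
    stop("duplicate dose label(s): ",
         paste(unique(d$antigen[duplicated(d$antigen)]), collapse = ", "))
  for (col in c("recommended_age", "early_margin", "delay_margin")) {
    bad <- is.na(d[[col]]) | d[[col]] < 0L
    if (any(bad))
      stop("dose ", d$antigen[which(bad)[1]], ": ", col,
           " must be a non-negative integer")
  }
  # recommended age strictly increasing along each series
  for (s in unique(d$series)) {
    rows <- d[d$series == s, ]
    rows <- rows[order(rows$dose_index), ]
    if (nrow(rows) > 1 && any(diff(rows$recommended_age) <= 0))
      stop("series ", s,
           ": recommended_age must strictly increase with dose_index")
    if (anyDuplicated(rows$dose_index))
      stop("series ", s, ": duplicate dose_index")
  }
  # companion symmetry
  has_comp <- !is.na(d$companion)
  for (i in which(has_comp)) {
    comp <- d$companion[i]
    j <- match(comp, d$antigen)
    if (is.na(j))
      stop("dose ", d$antigen[i], ": companion ", comp, " not in schedule")
    if (is.na(d$companion[j]) || d$companion[j] != d$antigen[i])
      stop("asymmetric companion link: ", d$antigen[i], " -> ", comp)
  }
  if (is.na(schedule$fic_cutoff) || schedule$fic_cutoff <= 0L)
    stop("fic_cutoff must be a positive number of days")
  if (length(schedule$rollout_dates)) {
    unknown <- setdiff(names(schedule$rollout_dates), c(d$antigen, d$series))
    if (length(unknown))
      stop("rollout date for unknown antigen/series: ",
           paste(unknown, collapse = ", "))
  }
  invisible(schedule)
}

#' The default EPI study schedule
#'
#' The Kenyan routine (EPI) schedule used throughout: BCG and the polio birth
#' dose at day 0; three doses each of oral polio (OPV), pentavalent and
#' pneumococcal conjugate (PCV) vaccine at 6, 10 and 14 weeks (days 42, 70,
#' 98); measles (MV) at 9 months (day 274). Every dose is "early" when given
#' more than 4 days before its recommended age and "delayed" when given more
#' than 14 days after it, except measles whose delay margin is a 30-day month.
#' The 8-dose FIC basis is BCG, OPV1-3, pentavalent 1-3 and MV; the polio
#' birth dose and PCV are carried in the schedule (for coverage reporting and
#' sequencing context) but do not count towards FIC. Pentavalent dose k is
#' companioned with OPV k: the pair is expected on the same day, and a split
#' pair is one of the out-of-sequence rules. PCV carries a rollout date of
#' 2011-02-01, before which it was not offered.
#'
#' @return A `vax_schedule` with 12 doses and `fic_cutoff` 365 days.
#' @examples
#' sched <- default_epi_schedule()
#' sched$doses[sched$doses$in_fic, "antigen"]
#' @export
default_epi_schedule <- function() {
  doses <- data.frame(
    antigen = c("BCG", "OPV0", "OPV1", "OPV2", "OPV3",
                "PENTA1", "PENTA2", "PENTA3",
                "PCV1", "PCV2", "PCV3", "MV"),
    series = c("BCG", "OPV", "OPV", "OPV", "OPV",
               "PENTA", "PENTA", "PENTA",
               "PCV", "PCV", "PCV", "MV"),
    dose_index = c(1L, 0L, 1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L, 1L),
    recommended_age = c(0L, 0L, 42L, 70L, 98L, 42L, 70L, 98L,
                        42L, 70L, 98L, 274L),
    early_margin = rep(4L, 12L),
    delay_margin = c(rep(14L, 11L), 30L),
    in_fic = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
               FALSE, FALSE, FALSE, TRUE),
    companion = c(NA, NA, "PENTA1", "PENTA2", "PENTA3",
                  "OPV1", "OPV2", "OPV3", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  vax_schedule(doses, fic_cutoff = 365L,
               rollout_dates = c(PCV = "2011-02-01"))
}

#' Timeliness window of a dose
#'
#' The inclusive age interval within which a dose counts as timely:
#' `[max(0, recommended_age - early_margin), recommended_age + delay_margin]`.
#' A dose given strictly before the lower bound is early; strictly after the
#' upper bound, delayed.
#'
#' @param spec one row of a schedule's `doses` table (or a list with fields
#'   `recommended_age`, `early_margin`, `delay_margin`).
#' @return Integer vector `c(earliest_timely, latest_timely)` in days.
#' @examples
#' sched <- default_epi_schedule()
#' timeliness_window(sched$doses[sched$doses$antigen == "OPV1", ])  # 38 56
#' @export
timeliness_window <- function(spec) {
  lo <- max(0L, as.integer(spec$recommended_age) - as.integer(spec$early_margin))
  hi <- as.integer(spec$recommended_age) + as.integer(spec$delay_margin)
  c(earliest_timely = lo, latest_timely = hi)
}

#' Read a schedule from a JSON file
#'
#' The file holds an object with keys `doses` (array of objects with fields
#' `antigen`, `series`, `dose_index`, `recommended_age_days`,
#' `early_margin_days`, `delay_margin_days`, `in_fic`, optional `companion`),
#' `fic_cutoff_days`, and optional `rollout_dates` (antigen to ISO-8601 date).
#' Unknown keys are rejected, and all schedule invariants are validated.
#'
#' @param path path to the JSON schedule file.
#' @return A `vax_schedule`.
#' @seealso [write_schedule()]
#' @export
load_schedule <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  allowed <- c("doses", "fic_cutoff_days", "rollout_dates")
  extra <- setdiff(names(raw), allowed)
  if (length(extra))
    stop("unknown schedule key(s): ", paste(extra, collapse = ", "))
  if (is.null(raw$doses) || !length(raw$doses))
    stop("schedule file has no doses")
  dose_fields <- c("antigen", "series", "dose_index", "recommended_age_days",
                   "early_margin_days", "delay_margin_days", "in_fic",
                   "companion")
  rows <- lapply(seq_along(raw$doses), function(i) {
    dd <- raw$doses[[i]]
    extra <- setdiff(names(dd), dose_fields)
    if (length(extra))
      stop("dose ", i, ": unknown field(s): ", paste(extra, collapse = ", "))
    need <- setdiff(dose_fields, c("companion", names(dd)))
    if (length(need))
      stop("dose ", i, ": missing field(s): ", paste(need, collapse = ", "))
    data.frame(antigen = dd$antigen, series = dd$series,
               dose_index = dd$dose_index,
               recommended_age = dd$recommended_age_days,
               early_margin = dd$early_margin_days,
               delay_margin = dd$delay_margin_days,
               in_fic = dd$in_fic,
               companion = if (is.null(dd$companion)) NA_character_
                           else dd$companion,
               stringsAsFactors = FALSE)
  })
  doses <- do.call(rbind, rows)
  cutoff <- if (is.null(raw$fic_cutoff_days)) 365L else raw$fic_cutoff_days
  rollout <- NULL
  if (!is.null(raw$rollout_dates) && length(raw$rollout_dates)) {
    rollout <- vapply(raw$rollout_dates, as.character, character(1))
  }
  vax_schedule(doses, fic_cutoff = cutoff, rollout_dates = rollout)
}

#' Write a schedule to a JSON file
#'
#' Inverse of [load_schedule()]: the written file round-trips to an equal
#' schedule.
#'
#' @param schedule a `vax_schedule`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_schedule <- function(schedule, path) {
  d <- schedule$doses
  doses <- lapply(seq_len(nrow(d)), function(i) {
    out <- list(antigen = d$antigen[i], series = d$series[i],
                dose_index = d$dose_index[i],
                recommended_age_days = d$recommended_age[i],
                early_margin_days = d$early_margin[i],
                delay_margin_days = d$delay_margin[i],
                in_fic = d$in_fic[i])
    if (!is.na(d$companion[i])) out$companion <- d$companion[i]
    out
  })
  obj <- list(doses = doses, fic_cutoff_days = schedule$fic_cutoff)
  if (length(schedule$rollout_dates)) {
    obj$rollout_dates <- as.list(format(schedule$rollout_dates, "%Y-%m-%d"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.vax_schedule <- function(x, ...) {
  cat("Immunization schedule:", nrow(x$doses), "doses, FIC cutoff",
      x$fic_cutoff, "days\n")
  print(x$doses, row.names = FALSE)
  if (length(x$rollout_dates)) {
    cat("Rollout dates:",
        paste(names(x$rollout_dates), format(x$rollout_dates, "%Y-%m-%d"),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

# internal: one schedule row by antigen label, error if absent
schedule_dose <- function(schedule, antigen) {
  i <- match(antigen, schedule$doses$antigen)
  if (is.na(i)) stop("dose label not in schedule: ", antigen)
  schedule$doses[i, ]
}
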