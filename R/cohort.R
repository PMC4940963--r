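#' Vaccination-card cohort containers
#'
#' A `vax_cohort` is a relational container for card data: a `children` table
#' (one row per child: id, date of birth, sex and the categorical covariates),
#' a `visits` table (one row per follow-up interview: date, whether the card
#' was physically seen), and an `events` table (one row per recorded dose:
#' schedule antigen label, calendar date). After [apply_inclusion()] the
#' `children` table additionally carries the analysis visit date, the child's
#' age at that visit and its calendar year.
#'
#' @param children data.frame with at least `child_id` (unique) and `dob`;
#'   any further columns are treated as covariates.
#' @param visits data.frame `child_id`, `date`, `card_seen`.
#' @param events data.frame `child_id`, `antigen`, `date`.
#' @param provenance list describing the source; inclusion/error logs are
#'   appended here by the pipeline.
#' @return An object of class `vax_cohort`.
#' @export
vax_cohort <- function(children, visits = NULL, events = NULL,
                       provenance = list()) {
  stopifnot(is.data.frame(children), all(c("child_id", "dob") %in% names(children)))
  children$child_id <- as.character(children$child_id)
  children$dob <- as.Date(children$dob)
  if (anyDuplicated(children$child_id))
    stop("duplicate child_id in cohort")
  empty_visits <- data.frame(child_id = character(0),
                             date = as.Date(character(0)),
                             card_seen = logical(0))
  empty_events <- data.frame(child_id = character(0),
                             antigen = character(0),
                             date = as.Date(character(0)))
  if (is.null(visits) || !nrow(visits)) visits <- empty_visits else {
    visits <- data.frame(child_id = as.character(visits$child_id),
                         date = as.Date(visits$date),
                         card_seen = as.logical(visits$card_seen))
    visits <- visits[order(visits$child_id, visits$date), ]
  }
  if (is.null(events) || !nrow(events)) events <- empty_events else {
    events <- data.frame(child_id = as.character(events$child_id),
                         antigen = as.character(events$antigen),
                         date = as.Date(events$date))
    events <- unique(events)            # dedup (child, antigen, date)
    events <- events[order(events$child_id, events$date, events$antigen), ]
  }
  rownames(visits) <- rownames(events) <- rownames(children) <- NULL
  structure(list(children = children, visits = visits, events = events,
                 provenance = provenance),
            class = "vax_cohort")
}

#' @export
print.vax_cohort <- function(x, ...) {
  cat("Vaccination-card cohort:", nrow(x$children), "children,",
      nrow(x$visits), "visits,", nrow(x$events), "vaccination events\n")
  if (!is.null(x$provenance$inclusion_log)) {
    log <- x$provenance$inclusion_log
    cat(sprintf("Inclusion: %d of %d children (%.1f%%)\n",
                log$included, log$total, 100 * log$included_fraction))
  }
  invisible(x)
}

#' A single child's record
#'
#' Convenience constructor for per-child classification: bundles one child's
#' identifiers, covariates, visit history and vaccination events. Events are
#' deduplicated on (antigen, date) and sorted by date; an event dated before
#' the date of birth is an error.
#'
#' @param child_id identifier string.
#' @param dob date of birth.
#' @param events data.frame `antigen`, `date` (may be empty).
#' @param visits data.frame `date`, `card_seen` (may be empty).
#' @param sex,covariates optional child sex and named list/vector of further
#'   categorical covariates.
#' @return An object of class `child_record`.
#' @export
child_record <- function(child_id, dob, events = NULL, visits = NULL,
                         sex = NA_character_, covariates = list()) {
  dob <- as.Date(dob)
  if (!is.null(events) && nrow(events)) {
    events <- data.frame(antigen = as.character(events$antigen),
                         date = as.Date(events$date))
    if (any(events$date < dob))
      stop("child ", child_id, ": vaccination event before date of birth")
    events <- unique(events)
    events <- events[order(events$date, events$antigen), ]
    rownames(events) <- NULL
  } else {
    events <- data.frame(antigen = character(0), date = as.Date(character(0)))
  }
  if (!is.null(visits) && nrow(visits)) {
    visits <- data.frame(date = as.Date(visits$date),
                         card_seen = as.logical(visits$card_seen))
    visits <- visits[order(visits$date), ]
    rownames(visits) <- NULL
  } else {
    visits <- data.frame(date = as.Date(character(0)), card_seen = logical(0))
  }
  structure(list(child_id = as.character(child_id), dob = dob, sex = sex,
                 covariates = covariates, visits = visits, events = events),
            class = "child_record")
}

#' Extract one child from a cohort as a `child_record`
#' @param cohort a `vax_cohort`.
#' @param child_id the child to extract.
#' @return A `child_record`.
#' @export
cohort_child <- function(cohort, child_id) {
  i <- match(child_id, cohort$children$child_id)
  if (is.na(i)) stop("no such child: ", child_id)
  row <- cohort$children[i, ]
  covar_cols <- setdiff(names(row), c("child_id", "dob", "sex",
                                      "analysis_visit", "age_at_visit",
                                      "year_of_visit"))
  child_record(
    child_id = row$child_id, dob = row$dob,
    sex = if ("sex" %in% names(row)) row$sex else NA_character_,
    covariates = as.list(row[covar_cols]),
    visits = cohort$visits[cohort$visits$child_id == child_id,
                           c("date", "card_seen")],
    events = cohort$events[cohort$events$child_id == child_id,
                           c("antigen", "date")])
}

# internal: wrap a child_record as a one-child cohort
as_one_child_cohort <- function(child) {
  covar <- child$covariates
  children <- data.frame(child_id = child$child_id, dob = child$dob,
                         sex = child$sex, stringsAsFactors = FALSE)
  for (nm in names(covar)) children[[nm]] <- covar[[nm]]
  visits <- events <- NULL
  if (nrow(child$visits))
    visits <- cbind(child_id = child$child_id, child$visits)
  if (nrow(child$events))
    events <- cbind(child_id = child$child_id, child$events)
  vax_cohort(children, visits, events)
}

#' Read a vaccination-card cohort from delimited text
#'
#' Long-format records file with fixed columns `child_id, dob, event_type,
#' antigen, date, card_seen`; `event_type` is `"vaccination"` (then `antigen`
#' and `date` are used) or `"visit"` (then `date` and `card_seen`). Dates are
#' ISO-8601. An optional covariates file has `child_id` plus one column per
#' categorical covariate (sex, postnatal_care, mother_age_group, education,
#' delivery_place, parity, ethnicity, wealth, site).
#'
#' Antigen labels must come from the schedule vocabulary; as a convenience a
#' bare series name (`OPV`, `PENTA`, `PCV`) is accepted and its dated events
#' are numbered chronologically 1..k within the child, since many cards omit
#' dose numbers. The polio birth dose cannot be inferred that way and must be
#' written explicitly as `OPV0`. Duplicate (child, antigen, date) rows are
#' deduplicated. Malformed rows (unknown label, unparseable date, event before
#' date of birth) are collected into an error report in
#' `cohort$provenance$errors` with their row numbers, and a warning is issued;
#' they never enter the cohort silently.
#'
#' @param records_path path to the records CSV/TSV (delimiter sniffed from the
#'   extension: `.tsv` means tab, otherwise comma).
#' @param schedule a `vax_schedule` supplying the closed antigen vocabulary.
#' @param covariates_path optional path to the covariates file.
#' @return A `vax_cohort`.
#' @seealso [write_cohort()], [apply_inclusion()]
#' @export
read_cohort <- function(records_path, schedule, covariates_path = NULL) {
  sep <- if (grepl("\\.tsv$", records_path)) "\t" else ","
  raw <- utils::read.table(records_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  req <- c("child_id", "dob", "event_type", "antigen", "date", "card_seen")
  if (!all(req %in% names(raw)))
    stop("records file must have columns: ", paste(req, collapse = ", "))
  errors <- data.frame(row = integer(0), child_id = character(0),
                       problem = character(0))
  note <- function(rows, problem) {
    if (length(rows))
      errors <<- rbind(errors, data.frame(row = rows,
                                          child_id = raw$child_id[rows],
                                          problem = problem))
  }
  dob <- as.Date(raw$dob, optional = TRUE)
  date <- as.Date(raw$date, optional = TRUE)
  bad <- which(is.na(dob) | is.na(date))
  note(bad, "unparseable date")
  vocab <- schedule$doses$antigen
  families <- setdiff(unique(schedule$doses$series), vocab)
  is_vax <- raw$event_type == "vaccination"
  bad_label <- which(is_vax & !(raw$antigen %in% c(vocab, families)))
  note(bad_label, "unknown antigen label")
  before_dob <- which(is_vax & !is.na(date) & !is.na(dob) & date < dob)
  note(before_dob, "vaccination before date of birth")
  drop <- union(bad, union(bad_label, before_dob))
  keep <- setdiff(seq_len(nrow(raw)), drop)
  raw <- raw[keep, ]; dob <- dob[keep]; date <- date[keep]
  is_vax <- raw$event_type == "vaccination"

  children <- unique(data.frame(child_id = raw$child_id, dob = dob))
  visits <- data.frame(child_id = raw$child_id[!is_vax],
                       date = date[!is_vax],
                       card_seen = tolower(raw$card_seen[!is_vax]) %in%
                         c("true", "t", "1", "yes"))
  events <- data.frame(child_id = raw$child_id[is_vax],
                       antigen = raw$antigen[is_vax],
                       date = date[is_vax])
  events <- unique(events)
  # chronological dose numbering for bare series labels
  fam_rows <- events$antigen %in% families
  if (any(fam_rows)) {
    key <- paste(events$child_id, events$antigen)
    ord <- order(key, events$date)
    rk <- stats::ave(as.integer(events$date)[ord],
                     key[ord], FUN = seq_along)
    lab <- paste0(events$antigen[ord], rk)
    sel <- fam_rows[ord]
    events$antigen[ord][sel] <- lab[sel]
    unknown <- !(events$antigen %in% vocab)
    if (any(unknown))
      stop("chronological numbering produced label(s) outside the schedule: ",
           paste(unique(events$antigen[unknown]), collapse = ", "),
           " (more dated events than doses in the series?)")
    events <- unique(events)
  }
  if (!is.null(covariates_path)) {
    csep <- if (grepl("\\.tsv$", covariates_path)) "\t" else ","
    cov <- utils::read.table(covariates_path, header = TRUE, sep = csep,
                             stringsAsFactors = FALSE)
    cov$child_id <- as.character(cov$child_id)
    children <- merge(children, cov, by = "child_id", all.x = TRUE,
                      sort = FALSE)
  }
  if (nrow(errors)) {
    warning(nrow(errors), " malformed row(s) excluded; see provenance$errors")
  }
  vax_cohort(children, visits, events,
             provenance = list(source = records_path, errors = errors))
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()]: writes the long-format records file and,
#' optionally, the covariates file. Reading the written files back yields an
#' equal cohort.
#'
#' @param cohort a `vax_cohort`.
#' @param records_path output records CSV path.
#' @param covariates_path optional output covariates CSV path.
#' @return Invisibly, `records_path`.
#' @export
write_cohort <- function(cohort, records_path, covariates_path = NULL) {
  ch <- cohort$children
  ev <- cohort$events
  vi <- cohort$visits
  dob_of <- ch$dob[match(ev$child_id, ch$child_id)]
  rec <- rbind(
    data.frame(child_id = ev$child_id, dob = format(dob_of, "%Y-%m-%d"),
               event_type = "vaccination", antigen = ev$antigen,
               date = format(ev$date, "%Y-%m-%d"), card_seen = NA),
    data.frame(child_id = vi$child_id,
               dob = format(ch$dob[match(vi$child_id, ch$child_id)], "%Y-%m-%d"),
               event_type = "visit", antigen = NA,
               date = format(vi$date, "%Y-%m-%d"),
               card_seen = ifelse(vi$card_seen, "true", "false")))
  # children with no rows at all still need to appear once
  missing_children <- setdiff(ch$child_id, rec$child_id)
  if (length(missing_children)) {
    i <- match(missing_children, ch$child_id)
    rec <- rbind(rec, data.frame(child_id = missing_children,
                                 dob = format(ch$dob[i], "%Y-%m-%d"),
                                 event_type = "visit", antigen = NA,
                                 date = format(ch$dob[i], "%Y-%m-%d"),
                                 card_seen = "false"))
  }
  rec <- rec[order(rec$child_id, rec$date, rec$event_type), ]
  utils::write.csv(rec, records_path, row.names = FALSE, na = "")
  if (!is.null(covariates_path)) {
    covar_cols <- setdiff(names(ch), c("dob", "analysis_visit",
                                       "age_at_visit", "year_of_visit"))
    utils::write.csv(ch[, covar_cols], covariates_path, row.names = FALSE,
                     na = "")
  }
  invisible(records_path)
}

#' Select a child's analysis visit
#'
#' The earliest interview visit at which the vaccination card was seen and the
#' child's age lay in the analysis window. The window is half-open:
#' `[min_age, max_age)` days, defaulting to `[365, 730)` for "aged 12-23
#' months". When a child has several qualifying visits the earliest is used.
#'
#' @param child a `child_record`.
#' @param min_age,max_age window bounds in days.
#' @return One-row data.frame `date`, `card_seen`, `age` — or `NULL` when no
#'   visit qualifies.
#' @export
select_analysis_visit <- function(child, min_age = 365, max_age = 730) {
  v <- child$visits
  if (!nrow(v)) return(NULL)
  age <- as.integer(v$date - child$dob)
  ok <- v$card_seen & age >= min_age & age < max_age
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(v$date[ok])]
  out <- v[i, , drop = FALSE]
  out$age <- age[i]
  rownames(out) <- NULL
  out
}

#' Apply the study inclusion rule to a cohort
#'
#' Keeps exactly the children with a qualifying card-seen visit aged 12-23
#' months (see [select_analysis_visit()]); attaches the selected visit date,
#' the child's age at it, and its calendar year (`year_of_visit`) to the
#' `children` table. The inclusion log records the total, the included count,
#' counts of children excluded for having no visit in the age window versus
#' having window visits but never with a card seen, and the included fraction.
#' The operation is idempotent.
#'
#' @param cohort a `vax_cohort`.
#' @param min_age,max_age analysis window in days (default 365 to 730,
#'   half-open).
#' @return List with elements `cohort` (included children only, with the
#'   inclusion log in `provenance$inclusion_log`) and `log`.
#' @export
apply_inclusion <- function(cohort, min_age = 365, max_age = 730) {
  ch <- cohort$children
  vi <- cohort$visits
  age <- as.integer(vi$date - ch$dob[match(vi$child_id, ch$child_id)])
  in_window <- age >= min_age & age < max_age
  qualifying <- in_window & vi$card_seen
  # earliest qualifying visit per child
  q <- vi[qualifying, ]
  q_age <- age[qualifying]
  if (nrow(q)) {
    ord <- order(q$child_id, q$date)
    q <- q[ord, ]; q_age <- q_age[ord]
    first <- !duplicated(q$child_id)
    sel <- data.frame(child_id = q$child_id[first],
                      analysis_visit = q$date[first],
                      age_at_visit = q_age[first])
  } else {
    sel <- data.frame(child_id = character(0),
                      analysis_visit = as.Date(character(0)),
                      age_at_visit = integer(0))
  }
  has_window_visit <- unique(vi$child_id[in_window])
  included_ids <- sel$child_id
  excluded <- setdiff(ch$child_id, included_ids)
  n_no_window <- sum(!(excluded %in% has_window_visit))
  n_no_card <- length(excluded) - n_no_window
  log <- list(total = nrow(ch), included = length(included_ids),
              excluded_no_window = n_no_window,
              excluded_no_card = n_no_card,
              included_fraction = if (nrow(ch)) length(included_ids) / nrow(ch)
                                  else NA_real_)
  keep <- ch[ch$child_id %in% included_ids,
             setdiff(names(ch), c("analysis_visit", "age_at_visit",
                                  "year_of_visit")),
             drop = FALSE]
  keep <- merge(keep, sel, by = "child_id", sort = FALSE)
  keep$year_of_visit <- as.integer(format(keep$analysis_visit, "%Y"))
  prov <- cohort$provenance
  prov$inclusion_log <- log
  out <- vax_cohort(keep,
                    vi[vi$child_id %in% included_ids, ],
                    cohort$events[cohort$events$child_id %in% included_ids, ],
                    provenance = prov)
  list(cohort = out, log = log)
}
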