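#' Age at a recorded dose
#'
#' Whole-day age (vaccination date minus date of birth) at which the child
#' received the given schedule dose; `NA` when the dose is not on the card.
#' When a dose label somehow occurs on several dates the earliest is used
#' (duplicates are already removed at ingestion).
#'
#' @param child a `child_record`.
#' @param dose dose label, e.g. `"OPV1"`.
#' @param schedule optional `vax_schedule`; when supplied the label is checked
#'   against its vocabulary.
#' @return Integer days, or `NA_integer_`.
#' @export
age_at_dose <- function(child, dose, schedule = NULL) {
  if (!is.null(schedule) && !(dose %in% schedule$doses$antigen))
    stop("dose label not in schedule: ", dose)
  ev <- child$events
  hit <- ev$antigen == dose
  if (!any(hit)) return(NA_integer_)
  as.integer(min(ev$date[hit]) - child$dob)
}

# ---------------------------------------------------------------------------
# Vectorized core: one row per child, one age column per schedule dose.
# All per-child classifiers delegate here so there is a single code path.
# ---------------------------------------------------------------------------

# internal: children x doses matrix of ages at first receipt (NA = never)
dose_age_matrix <- function(cohort, schedule) {
  ids <- cohort$children$child_id
  labels <- schedule$doses$antigen
  m <- matrix(NA_integer_, nrow = length(ids), ncol = length(labels),
              dimnames = list(ids, labels))
  ev <- cohort$events
  if (!nrow(ev)) return(m)
  ev <- ev[ev$antigen %in% labels, ]
  age <- as.integer(ev$date -
                      cohort$children$dob[match(ev$child_id, ids)])
  ord <- order(ev$child_id, ev$antigen, age)
  key_first <- !duplicated(paste(ev$child_id, ev$antigen)[ord])
  i <- ord[key_first]
  m[cbind(match(ev$child_id[i], ids), match(ev$antigen[i], labels))] <- age[i]
  m
}

#' Classify a whole cohort
#'
#' Runs every per-child classification (FIC, per-dose timeliness,
#' out-of-sequence flags, FIC-OS, missing-dose profile) across a cohort in one
#' pass and returns one row per child.
#'
#' Out-of-sequence rules, evaluated among doses received by the FIC cutoff
#' (default; set `os_scope = "all"` to use every recorded dose):
#' \describe{
#'   \item{late_bcg}{BCG given on the same day as, or after, any other
#'     recorded schedule dose. The polio birth dose (OPV0) is never part of
#'     the comparison set (it is co-administered with BCG by design); with
#'     `bcg_rule = "penta_mv"` the comparison narrows to pentavalent and
#'     measles doses only.}
#'   \item{penta_opv_split}{some pentavalent dose k and its companion OPV k
#'     are both recorded but on different days.}
#'   \item{penta_after_mv}{some pentavalent dose given on or after the day of
#'     the measles vaccine.}
#' }
#' A child is FIC-OS when FIC and at least one flag is raised.
#'
#' @param cohort a `vax_cohort` (normally after [apply_inclusion()], so that
#'   every child is fully observed to the cutoff).
#' @param schedule a `vax_schedule`.
#' @param os_scope `"by_cutoff"` (default) or `"all"`: which recorded doses
#'   enter the sequencing rules.
#' @param bcg_rule `"all"` (default) or `"penta_mv"`: comparison set for the
#'   late-BCG rule.
#' @return data.frame with columns `child_id`; `age_<dose>` and
#'   `status_<dose>` (`early` / `timely` / `delayed` / `missing`) for every
#'   schedule dose; `mv_early_strict` (measles more than 14 days early);
#'   `fic`, `fic_after_cutoff`, `n_missing`, `missing_doses`
#'   (comma-separated); `late_bcg`, `penta_opv_split`, `penta_after_mv`,
#'   `out_of_sequence`, `fic_os`.
#' @export
classify_cohort <- function(cohort, schedule,
                            os_scope = c("by_cutoff", "all"),
                            bcg_rule = c("all", "penta_mv")) {
  os_scope <- match.arg(os_scope)
  bcg_rule <- match.arg(bcg_rule)
  d <- schedule$doses
  cutoff <- schedule$fic_cutoff
  ages <- dose_age_matrix(cohort, schedule)
  n <- nrow(ages)
  received <- !is.na(ages)
  by_cutoff <- received & !is.na(ages) & ages <= cutoff

  # --- FIC -----------------------------------------------------------------
  fic_labels <- d$antigen[d$in_fic]
  fic_ok <- by_cutoff[, fic_labels, drop = FALSE]
  fic <- rowSums(fic_ok) == length(fic_labels)
  missing_m <- !received[, fic_labels, drop = FALSE]
  n_missing <- rowSums(missing_m)
  missing_doses <- apply(missing_m, 1, function(r)
    paste(fic_labels[r], collapse = ","))
  fic_after_cutoff <- !fic & n_missing == 0L

  # --- timeliness ----------------------------------------------------------
  lo <- pmax(0L, d$recommended_age - d$early_margin)
  hi <- d$recommended_age + d$delay_margin
  status <- matrix("missing", nrow = n, ncol = nrow(d),
                   dimnames = dimnames(ages))
  for (j in seq_len(nrow(d))) {
    a <- ages[, j]
    s <- ifelse(is.na(a), "missing",
                ifelse(a < lo[j], "early",
                       ifelse(a > hi[j], "delayed", "timely")))
    status[, j] <- s
  }
  mv_rec <- d$recommended_age[match("MV", d$antigen)]
  mv_early_strict <- if ("MV" %in% colnames(ages)) {
    a <- ages[, "MV"]
    !is.na(a) & (mv_rec - a) > 14L
  } else rep(FALSE, n)

  # --- out-of-sequence -----------------------------------------------------
  scope <- if (os_scope == "by_cutoff") by_cutoff else received
  s_age <- ages
  s_age[!scope] <- NA_integer_
  bcg_cmp <- switch(bcg_rule,
    all = setdiff(d$antigen, c("BCG", "OPV0")),
    penta_mv = intersect(c("PENTA1", "PENTA2", "PENTA3", "MV"), d$antigen))
  late_bcg <- rep(FALSE, n)
  if ("BCG" %in% colnames(s_age) && length(bcg_cmp)) {
    other_min <- suppressWarnings(
      apply(s_age[, bcg_cmp, drop = FALSE], 1, min, na.rm = TRUE))
    other_min[!is.finite(other_min)] <- NA_integer_
    late_bcg <- !is.na(s_age[, "BCG"]) & !is.na(other_min) &
      s_age[, "BCG"] >= other_min
  }
  penta_after_mv <- rep(FALSE, n)
  if ("MV" %in% colnames(s_age)) {
    pentas <- grep("^PENTA", colnames(s_age), value = TRUE)
    if (length(pentas)) {
      pa <- s_age[, pentas, drop = FALSE] >= s_age[, "MV"]
      penta_after_mv <- rowSums(pa, na.rm = TRUE) > 0
    }
  }
  penta_opv_split <- rep(FALSE, n)
  comp <- d[!is.na(d$companion) & grepl("^PENTA", d$antigen), ]
  for (i in seq_len(nrow(comp))) {
    pk <- s_age[, comp$antigen[i]]
    ok <- s_age[, comp$companion[i]]
    penta_opv_split <- penta_opv_split |
      (!is.na(pk) & !is.na(ok) & pk != ok)
  }
  out_of_sequence <- late_bcg | penta_opv_split | penta_after_mv
  fic_os <- fic & out_of_sequence

  out <- data.frame(child_id = cohort$children$child_id,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(d))) {
    out[[paste0("age_", d$antigen[j])]] <- unname(ages[, j])
    out[[paste0("status_", d$antigen[j])]] <- unname(status[, j])
  }
  out$mv_early_strict <- unname(mv_early_strict)
  out$fic <- unname(fic)
  out$fic_after_cutoff <- unname(fic_after_cutoff)
  out$n_missing <- unname(as.integer(n_missing))
  out$missing_doses <- unname(missing_doses)
  out$late_bcg <- unname(late_bcg)
  out$penta_opv_split <- unname(penta_opv_split)
  out$penta_after_mv <- unname(penta_after_mv)
  out$out_of_sequence <- unname(out_of_sequence)
  out$fic_os <- unname(fic_os)
  out
}

# internal: classify a single child_record through the cohort path
classify_one <- function(child, schedule, ...) {
  classify_cohort(as_one_child_cohort(child), schedule, ...)
}

#' Full-immunization (FIC) status of one child
#'
#' A child is FIC when every FIC-basis dose (by default BCG, OPV1-3,
#' pentavalent 1-3 and measles) was received by the cutoff age (365 days).
#' `missing_doses` lists basis doses never recorded; `fic_after_cutoff` marks
#' children with every basis dose on the card but at least one given after the
#' cutoff.
#'
#' @param child a `child_record`.
#' @param schedule a `vax_schedule`.
#' @return List of class `fic_result`: `fic`, `missing_doses` (character
#'   vector), `fic_after_cutoff`.
#' @export
classify_fic <- function(child, schedule) {
  row <- classify_one(child, schedule)
  miss <- if (nzchar(row$missing_doses))
    strsplit(row$missing_doses, ",", fixed = TRUE)[[1]] else character(0)
  structure(list(fic = row$fic, missing_doses = miss,
                 fic_after_cutoff = row$fic_after_cutoff),
            class = "fic_result")
}

#' Per-dose timeliness of one child
#'
#' Each schedule dose is exactly one of `early` (given more than
#' `early_margin` days before the recommended age), `timely`, `delayed` (more
#' than `delay_margin` days after), or `missing` (not on the card). For the
#' measles vaccine an additional strict-early indicator is returned (more than
#' 14 days before the recommended age), which the headline early-measles
#' figures use.
#'
#' @inheritParams classify_fic
#' @return List of class `timeliness_result`: `doses` (data.frame `antigen`,
#'   `age`, `status`) and `mv_early_strict`.
#' @export
classify_timeliness <- function(child, schedule) {
  row <- classify_one(child, schedule)
  labels <- schedule$doses$antigen
  doses <- data.frame(
    antigen = labels,
    age = vapply(labels, function(l) row[[paste0("age_", l)]], integer(1)),
    status = vapply(labels, function(l) row[[paste0("status_", l)]],
                    character(1)),
    stringsAsFactors = FALSE)
  rownames(doses) <- NULL
  structure(list(doses = doses, mv_early_strict = row$mv_early_strict),
            class = "timeliness_result")
}

#' Out-of-sequence flags for one child
#'
#' The three sequencing rules (see [classify_cohort()] for definitions) and
#' their disjunction. Unrecorded doses never raise a flag; by default only
#' doses received by the FIC cutoff are compared.
#'
#' @inheritParams classify_fic
#' @param os_scope,bcg_rule see [classify_cohort()].
#' @return List of class `sequence_flags`: `late_bcg`, `penta_opv_split`,
#'   `penta_after_mv`, `out_of_sequence`.
#' @export
flag_out_of_sequence <- function(child, schedule,
                                 os_scope = c("by_cutoff", "all"),
                                 bcg_rule = c("all", "penta_mv")) {
  row <- classify_one(child, schedule, os_scope = match.arg(os_scope),
                      bcg_rule = match.arg(bcg_rule))
  structure(list(late_bcg = row$late_bcg,
                 penta_opv_split = row$penta_opv_split,
                 penta_after_mv = row$penta_after_mv,
                 out_of_sequence = row$out_of_sequence),
            class = "sequence_flags")
}

#' Fully immunized out-of-sequence (FIC-OS)
#'
#' A child is FIC-OS when FIC and at least one dose was given out of sequence;
#' the notion is defined only among FIC children, so a non-FIC child is never
#' FIC-OS regardless of its flags.
#'
#' @param fic a `fic_result`.
#' @param flags a `sequence_flags` computed from the same child.
#' @return Logical.
#' @export
classify_fic_os <- function(fic, flags) {
  isTRUE(fic$fic) && isTRUE(flags$out_of_sequence)
}

#' Missing-dose profile of a non-FIC child
#'
#' For a child who is not FIC at the cutoff: how many FIC-basis doses are
#' absent from the card and which. Doses received after the cutoff are not
#' "missing" — a child with a complete card but a late dose has `n_missing` 0
#' and `fic_after_cutoff` `TRUE` (the "FIC after 12 months" bin of the
#' missing-dose table).
#'
#' @inheritParams classify_fic
#' @return List: `n_missing` (0..size of FIC basis), `missing` (labels),
#'   `fic_after_cutoff`.
#' @export
missing_profile <- function(child, schedule) {
  row <- classify_one(child, schedule)
  if (row$fic)
    stop("missing_profile is defined for non-FIC children only")
  miss <- if (nzchar(row$missing_doses))
    strsplit(row$missing_doses, ",", fixed = TRUE)[[1]] else character(0)
  list(n_missing = row$n_missing, missing = miss,
       fic_after_cutoff = row$fic_after_cutoff)
}
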