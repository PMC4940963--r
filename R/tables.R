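#' Round half-up
#'
#' Commercial rounding (0.5 always rounds away from zero for the
#' non-negative quantities used here), as opposed to R's round-half-even.
#' All table percentages use one decimal under this rule.
#'
#' @param x non-negative numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

#' One-decimal percentage
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal — the cell
#' arithmetic every coverage table uses.
#'
#' @param numerator,denominator non-negative counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @return Numeric percentage with one decimal.
#' @examples
#' percent(2541, 3814)  # 66.6
#' @export
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must lie in [0, denominator]")
  round_half_up(100 * numerator / denominator, 1)
}

#' Coverage cell
#'
#' A numerator/denominator pair with its one-decimal percentage; the percent
#' is always recomputed from the counts, so cells are self-consistent by
#' construction.
#'
#' @inheritParams percent
#' @return List `numerator`, `denominator`, `percent`.
#' @export
coverage_cell <- function(numerator, denominator) {
  list(numerator = numerator, denominator = denominator,
       percent = percent(numerator, denominator))
}

# internal: which children count as covered for a dose at the cutoff
covered_by_cutoff <- function(classification, dose, cutoff) {
  a <- classification[[paste0("age_", dose)]]
  !is.na(a) & a <= cutoff
}

#' Antigen coverage by year of visit
#'
#' Per-antigen coverage at the FIC cutoff (dose received by day 365), by
#' calendar year of the analysis visit and pooled over all years, plus an
#' `FIC` row. For antigens with a rollout date (PCV) the denominator is
#' restricted to children whose analysis visit fell in or after the rollout
#' year, and such cells are simply absent for earlier years.
#'
#' @param cohort an included `vax_cohort` (with `year_of_visit`).
#' @param classification output of [classify_cohort()] on the same cohort.
#' @param schedule the `vax_schedule` used.
#' @return data.frame `outcome`, `year` (character, `"overall"` for the pooled
#'   column), `numerator`, `denominator`, `percent`.
#' @export
antigen_coverage_table <- function(cohort, classification, schedule) {
  ch <- cohort$children
  if (is.null(ch$year_of_visit))
    stop("cohort has no year_of_visit; run apply_inclusion() first")
  stopifnot(identical(ch$child_id, classification$child_id))
  years <- sort(unique(ch$year_of_visit))
  rollout_year <- rep(NA_integer_, nrow(schedule$doses))
  for (nm in names(schedule$rollout_dates)) {
    hit <- schedule$doses$antigen == nm | schedule$doses$series == nm
    rollout_year[hit] <- as.integer(format(schedule$rollout_dates[[nm]], "%Y"))
  }
  rows <- list()
  emit <- function(outcome, year, num, den) {
    if (den > 0)
      rows[[length(rows) + 1]] <<- data.frame(
        outcome = outcome, year = as.character(year),
        numerator = num, denominator = den, percent = percent(num, den))
  }
  for (j in seq_len(nrow(schedule$doses))) {
    lab <- schedule$doses$antigen[j]
    cov <- covered_by_cutoff(classification, lab, schedule$fic_cutoff)
    eligible <- if (is.na(rollout_year[j])) rep(TRUE, nrow(ch))
                else ch$year_of_visit >= rollout_year[j]
    for (y in years) {
      sel <- ch$year_of_visit == y & eligible
      if (any(sel)) emit(lab, y, sum(cov[sel]), sum(sel))
    }
    emit(lab, "overall", sum(cov[eligible]), sum(eligible))
  }
  for (y in years) {
    sel <- ch$year_of_visit == y
    emit("FIC", y, sum(classification$fic[sel]), sum(sel))
  }
  emit("FIC", "overall", sum(classification$fic), nrow(ch))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: stratum vector with explicit "(missing)" level
stratify <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "(missing)"
  x
}

#' FIC coverage by background characteristics
#'
#' The sample-description table: per covariate stratum, the number of
#' children, their share of the sample, FIC coverage, and a chi-square test of
#' independence between the covariate and FIC status. Missing covariate values
#' form an explicit `"(missing)"` stratum that is excluded from the test.
#'
#' @param cohort an included `vax_cohort`.
#' @param classification output of [classify_cohort()].
#' @param covariates character vector of covariate column names; defaults to
#'   every column of `children` that is not structural.
#' @return data.frame `covariate`, `stratum`, `n`, `pct_of_sample`, `n_fic`,
#'   `pct_fic`, `p_value` (repeated within covariate; `NA` when the test is
#'   undefined).
#' @export
fic_covariate_table <- function(cohort, classification, covariates = NULL) {
  ch <- cohort$children
  stopifnot(identical(ch$child_id, classification$child_id))
  if (is.null(covariates))
    covariates <- setdiff(names(ch), c("child_id", "dob", "analysis_visit",
                                       "age_at_visit"))
  rows <- list()
  for (cv in covariates) {
    s <- stratify(ch[[cv]])
    levs <- sort(unique(s))
    test_levs <- setdiff(levs, "(missing)")
    p <- NA_real_
    if (length(test_levs) >= 2) {
      tab <- table(factor(s[s %in% test_levs], levels = test_levs),
                   factor(classification$fic[s %in% test_levs],
                          levels = c(FALSE, TRUE)))
      p <- tryCatch(suppressWarnings(chisq_independence(tab)$p_value),
                    error = function(e) NA_real_)
    }
    for (lv in levs) {
      sel <- s == lv
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, stratum = lv, n = sum(sel),
        pct_of_sample = percent(sum(sel), nrow(ch)),
        n_fic = sum(classification$fic[sel]),
        pct_fic = percent(sum(classification$fic[sel]), sum(sel)),
        p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Out-of-sequence rates among FIC children
#'
#' The FIC-OS table: among fully immunized children only, the proportion with
#' late BCG, with a pentavalent/OPV pair split across days, with a pentavalent
#' dose on/after measles, and with any of the three (FIC-OS), optionally
#' stratified by one covariate with a chi-square test on FIC-OS across strata.
#' Non-FIC children never enter the denominators.
#'
#' @param cohort an included `vax_cohort`.
#' @param classification output of [classify_cohort()].
#' @param covariate optional covariate column name for stratification.
#' @return data.frame `stratum`, `n_fic`, `pct_late_bcg`,
#'   `pct_penta_opv_split`, `pct_penta_after_mv`, `pct_fic_os`, `p_value`.
#' @export
fic_os_table <- function(cohort, classification, covariate = NULL) {
  ch <- cohort$children
  stopifnot(identical(ch$child_id, classification$child_id))
  fic <- classification$fic
  cls <- classification[fic, ]
  strata <- if (is.null(covariate)) rep("overall", nrow(cls))
            else stratify(ch[[covariate]][fic])
  levs <- unique(c("overall"[is.null(covariate)], sort(unique(strata))))
  rows <- list()
  for (lv in levs) {
    sel <- strata == lv
    if (!any(sel)) next
    n <- sum(sel)
    rows[[length(rows) + 1]] <- data.frame(
      stratum = lv, n_fic = n,
      pct_late_bcg = percent(sum(cls$late_bcg[sel]), n),
      pct_penta_opv_split = percent(sum(cls$penta_opv_split[sel]), n),
      pct_penta_after_mv = percent(sum(cls$penta_after_mv[sel]), n),
      pct_fic_os = percent(sum(cls$fic_os[sel]), n))
  }
  out <- do.call(rbind, rows)
  p <- NA_real_
  if (!is.null(covariate)) {
    test_levs <- setdiff(unique(strata), "(missing)")
    if (length(test_levs) >= 2) {
      tab <- table(factor(strata[strata %in% test_levs], levels = test_levs),
                   factor(cls$fic_os[strata %in% test_levs],
                          levels = c(FALSE, TRUE)))
      p <- tryCatch(suppressWarnings(chisq_independence(tab)$p_value),
                    error = function(e) NA_real_)
    }
  }
  out$p_value <- p
  rownames(out) <- NULL
  out
}

#' Missing-dose distribution among non-FIC children
#'
#' Among children who are not FIC at the cutoff: the distribution of the
#' number of missing FIC-basis doses (the `0` bin holds children whose card is
#' complete but with a dose after the cutoff — "FIC after 12 months"), and the
#' proportion missing each basis dose by type. Type rows can sum to more than
#' 100% since a child can miss several doses.
#'
#' @param cohort an included `vax_cohort`.
#' @param classification output of [classify_cohort()].
#' @param schedule the `vax_schedule` used.
#' @return List with `n_non_fic`, `by_count` (data.frame `n_missing`, `n`,
#'   `percent`) and `by_type` (data.frame `dose`, `n`, `percent`).
#' @export
missing_vaccine_table <- function(cohort, classification, schedule) {
  stopifnot(identical(cohort$children$child_id, classification$child_id))
  non_fic <- classification[!classification$fic, ]
  n <- nrow(non_fic)
  if (!n) stop("no non-FIC children")
  fic_labels <- schedule$doses$antigen[schedule$doses$in_fic]
  counts <- 0:length(fic_labels)
  by_count <- data.frame(
    n_missing = counts,
    n = vapply(counts, function(k) sum(non_fic$n_missing == k), integer(1)))
  by_count$percent <- percent(by_count$n, n)
  miss_sets <- strsplit(non_fic$missing_doses, ",", fixed = TRUE)
  by_type <- data.frame(
    dose = fic_labels,
    n = vapply(fic_labels, function(lab)
      sum(vapply(miss_sets, function(s) lab %in% s, logical(1))), integer(1)))
  by_type$percent <- percent(by_type$n, n)
  rownames(by_count) <- rownames(by_type) <- NULL
  list(n_non_fic = n, by_count = by_count, by_type = by_type)
}

#' Write the summary tables of a classified cohort
#'
#' Writes the four table families as TSV files: FIC by covariates
#' (`table1_fic_by_covariates.tsv`), antigen coverage by year
#' (`table2_coverage_by_year.tsv`), out-of-sequence among FIC
#' (`table3_fic_os.tsv`, one block per covariate), and the missing-dose
#' distribution (`table4_missing.tsv`). Every percentage cell is recomputed
#' from its own numerator and denominator on the way out.
#'
#' @param cohort an included `vax_cohort`.
#' @param classification output of [classify_cohort()].
#' @param schedule the `vax_schedule` used.
#' @param out_dir output directory (created if needed).
#' @param covariates covariates for tables 1 and 3.
#' @return Invisibly, the paths written.
#' @export
write_summary_tables <- function(cohort, classification, schedule, out_dir,
                                 covariates = c("sex", "site", "education",
                                                "wealth", "postnatal_care")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  covariates <- intersect(covariates, names(cohort$children))
  t1 <- fic_covariate_table(cohort, classification, covariates)
  t2 <- antigen_coverage_table(cohort, classification, schedule)
  t3 <- do.call(rbind, lapply(covariates, function(cv) {
    tab <- fic_os_table(cohort, classification, cv)
    cbind(covariate = cv, tab)
  }))
  t3 <- rbind(cbind(covariate = "overall",
                    fic_os_table(cohort, classification)), t3)
  t4 <- missing_vaccine_table(cohort, classification, schedule)
  paths <- file.path(out_dir, c("table1_fic_by_covariates.tsv",
                                "table2_coverage_by_year.tsv",
                                "table3_fic_os.tsv",
                                "table4_missing.tsv"))
  utils::write.table(t1, paths[1], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(t2, paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(t3, paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  t4flat <- rbind(
    data.frame(section = "by_count", label = as.character(t4$by_count$n_missing),
               n = t4$by_count$n, percent = t4$by_count$percent),
    data.frame(section = "by_type", label = t4$by_type$dose,
               n = t4$by_type$n, percent = t4$by_type$percent))
  utils::write.table(t4flat, paths[4], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
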