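# Independent straight-from-the-definitions classifier used as an oracle.
# Deliberately written as explicit per-child conditionals with its own
# hard-coded window table; shares no code with the package implementation.

oracle_windows <- data.frame(
  antigen = c("BCG", "OPV0", "OPV1", "OPV2", "OPV3",
              "PENTA1", "PENTA2", "PENTA3", "PCV1", "PCV2", "PCV3", "MV"),
  rec = c(0, 0, 42, 70, 98, 42, 70, 98, 42, 70, 98, 274),
  lo = c(0, 0, 38, 66, 94, 38, 66, 94, 38, 66, 94, 270),
  hi = c(14, 14, 56, 84, 112, 56, 84, 112, 56, 84, 112, 304),
  stringsAsFactors = FALSE)
oracle_fic_basis <- c("BCG", "OPV1", "OPV2", "OPV3",
                      "PENTA1", "PENTA2", "PENTA3", "MV")

# ages: named integer vector (days), NA when dose absent
oracle_classify <- function(ages) {
  cutoff <- 365
  get <- function(lab) if (lab %in% names(ages)) ages[[lab]] else NA_integer_

  fic <- TRUE
  missing <- character(0)
  any_after <- FALSE
  for (lab in oracle_fic_basis) {
    a <- get(lab)
    if (is.na(a)) {
      fic <- FALSE
      missing <- c(missing, lab)
    } else if (a > cutoff) {
      fic <- FALSE
      any_after <- TRUE
    }
  }
  fic_after_cutoff <- !fic && length(missing) == 0 && any_after

  status <- character(0)
  for (i in seq_len(nrow(oracle_windows))) {
    lab <- oracle_windows$antigen[i]
    a <- get(lab)
    status[lab] <- if (is.na(a)) "missing"
      else if (a < oracle_windows$lo[i]) "early"
      else if (a > oracle_windows$hi[i]) "delayed"
      else "timely"
  }
  mv <- get("MV")
  mv_early_strict <- !is.na(mv) && (274 - mv) > 14

  # sequencing among doses received by the cutoff
  by_cut <- function(lab) {
    a <- get(lab)
    if (is.na(a) || a > cutoff) NA_integer_ else a
  }
  bcg <- by_cut("BCG")
  late_bcg <- FALSE
  if (!is.na(bcg)) {
    for (lab in setdiff(oracle_windows$antigen, c("BCG", "OPV0"))) {
      a <- by_cut(lab)
      if (!is.na(a) && bcg >= a) late_bcg <- TRUE
    }
  }
  split <- FALSE
  for (k in 1:3) {
    p <- by_cut(paste0("PENTA", k))
    o <- by_cut(paste0("OPV", k))
    if (!is.na(p) && !is.na(o) && p != o) split <- TRUE
  }
  pam <- FALSE
  mvc <- by_cut("MV")
  if (!is.na(mvc)) {
    for (k in 1:3) {
      p <- by_cut(paste0("PENTA", k))
      if (!is.na(p) && p >= mvc) pam <- TRUE
    }
  }
  oos <- late_bcg || split || pam
  list(fic = fic, missing = sort(missing), fic_after_cutoff = fic_after_cutoff,
       status = status, mv_early_strict = mv_early_strict,
       late_bcg = late_bcg, penta_opv_split = split, penta_after_mv = pam,
       out_of_sequence = oos, fic_os = fic && oos)
}

# build a child_record from a named vector of dose ages
make_child <- function(ages, id = "X1", dob = as.Date("2010-01-01"),
                       visit_age = 400) {
  ages <- ages[!is.na(ages)]
  events <- if (length(ages))
    data.frame(antigen = names(ages), date = dob + unname(ages))
  else NULL
  child_record(id, dob, events = events,
               visits = data.frame(date = dob + visit_age, card_seen = TRUE))
}

# compare one classify_cohort row against the oracle; returns character(0) or
# a description of every disagreement
compare_row_to_oracle <- function(row, ages) {
  o <- oracle_classify(ages)
  bad <- character(0)
  chk <- function(name, got, want) {
    if (!identical(got, want))
      bad <<- c(bad, sprintf("%s: got %s want %s", name,
                             paste(got, collapse = ","),
                             paste(want, collapse = ",")))
  }
  chk("fic", row$fic, o$fic)
  chk("fic_after_cutoff", row$fic_after_cutoff, o$fic_after_cutoff)
  got_missing <- if (nzchar(row$missing_doses))
    sort(strsplit(row$missing_doses, ",", fixed = TRUE)[[1]]) else character(0)
  chk("missing", got_missing, o$missing)
  for (lab in names(o$status))
    chk(paste0("status_", lab), row[[paste0("status_", lab)]],
        unname(o$status[lab]))
  chk("mv_early_strict", row$mv_early_strict, o$mv_early_strict)
  chk("late_bcg", row$late_bcg, o$late_bcg)
  chk("penta_opv_split", row$penta_opv_split, o$penta_opv_split)
  chk("penta_after_mv", row$penta_after_mv, o$penta_after_mv)
  chk("fic_os", row$fic_os, o$fic_os)
  bad
}

# run oracle-vs-implementation comparison over a generated cohort; returns
# all disagreement strings
oracle_audit <- function(n_children, seed) {
  sim <- generate_cohort(default_study_like_config(n_children = n_children,
                                                   seed = seed))
  inc <- apply_inclusion(sim$cohort)
  cls <- classify_cohort(inc$cohort, default_epi_schedule())
  tr <- sim$truth[match(cls$child_id, sim$truth$child_id), ]
  labs <- c("BCG", "OPV0", "OPV1", "OPV2", "OPV3", "PENTA1", "PENTA2",
            "PENTA3", "PCV1", "PCV2", "PCV3", "MV")
  bad <- character(0)
  for (i in seq_len(nrow(cls))) {
    ages <- vapply(labs, function(l) tr[[paste0("age_", l)]][i], numeric(1))
    names(ages) <- labs
    d <- compare_row_to_oracle(cls[i, ], ages)
    if (length(d))
      bad <- c(bad, paste(cls$child_id[i], d, sep = ": "))
  }
  bad
}
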