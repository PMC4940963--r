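sched <- default_epi_schedule()
dob <- as.Date("2010-01-01")

full_ages <- c(BCG = 0, OPV0 = 0, OPV1 = 42, OPV2 = 70, OPV3 = 98,
               PENTA1 = 42, PENTA2 = 70, PENTA3 = 98, MV = 274)

test_that("age_at_dose is whole-day date arithmetic", {
  ch <- make_child(c(OPV1 = 42, MV = 274), dob = dob)
  expect_equal(age_at_dose(ch, "OPV1"), 42L)
  expect_equal(age_at_dose(ch, "MV"), 274L)
  expect_true(is.na(age_at_dose(ch, "PENTA1")))
  expect_error(age_at_dose(ch, "MMR", sched), "not in schedule")
  # explicit dates: 2010-01-01 to 2010-02-12 is 42 days
  ch2 <- child_record("B", dob,
                      events = data.frame(antigen = "OPV1",
                                          date = as.Date("2010-02-12")))
  expect_equal(age_at_dose(ch2, "OPV1"), 42L)
})

test_that("classify_fic separates FIC, missing and after-cutoff children", {
  r <- classify_fic(make_child(full_ages), sched)
  expect_true(r$fic)
  expect_length(r$missing_doses, 0)
  expect_false(r$fic_after_cutoff)

  late_mv <- full_ages; late_mv["MV"] <- 380
  r <- classify_fic(make_child(late_mv), sched)
  expect_false(r$fic)
  expect_true(r$fic_after_cutoff)
  expect_length(r$missing_doses, 0)

  r <- classify_fic(make_child(full_ages[names(full_ages) != "OPV3"]), sched)
  expect_false(r$fic)
  expect_equal(r$missing_doses, "OPV3")
  expect_false(r$fic_after_cutoff)
  # dose exactly at the cutoff still counts
  at_cut <- full_ages; at_cut["MV"] <- 365
  expect_true(classify_fic(make_child(at_cut), sched)$fic)
})

test_that("timeliness boundaries follow the margin definitions exactly", {
  status_of <- function(ages, dose) {
    t <- classify_timeliness(make_child(ages), sched)
    t$doses$status[t$doses$antigen == dose]
  }
  expect_equal(status_of(c(OPV1 = 37), "OPV1"), "early")    # 42-37 = 5 > 4
  expect_equal(status_of(c(OPV1 = 38), "OPV1"), "timely")
  expect_equal(status_of(c(BCG = 14), "BCG"), "timely")
  expect_equal(status_of(c(BCG = 15), "BCG"), "delayed")
  expect_equal(status_of(c(MV = 304), "MV"), "timely")      # 30-day month
  expect_equal(status_of(c(MV = 305), "MV"), "delayed")
  expect_equal(status_of(c(MV = 269), "MV"), "early")
  expect_equal(status_of(c(MV = 270), "MV"), "timely")
  expect_equal(status_of(c(OPV1 = NA, MV = 274), "OPV1"), "missing")
  # strict early measles: more than 14 days before day 274
  t <- classify_timeliness(make_child(c(MV = 259)), sched)
  expect_true(t$mv_early_strict)
  t <- classify_timeliness(make_child(c(MV = 260)), sched)
  expect_false(t$mv_early_strict)
})

test_that("per-dose status always partitions {early, timely, delayed, missing}", {
  set.seed(31)
  for (i in 1:50) {
    labs <- sample(sched$doses$antigen, sample(0:12, 1))
    ages <- stats::setNames(sample(0:500, length(labs), replace = TRUE), labs)
    t <- classify_timeliness(make_child(ages), sched)
    expect_true(all(t$doses$status %in%
                      c("early", "timely", "delayed", "missing")))
    expect_equal(sum(t$doses$status != "missing"), length(labs))
  }
})

test_that("out-of-sequence flags implement the three rules", {
  f <- function(ages, ...) flag_out_of_sequence(make_child(ages), sched, ...)
  r <- f(c(PENTA1 = 45, OPV1 = 47))
  expect_true(r$penta_opv_split)
  expect_true(r$out_of_sequence)
  r <- f(c(BCG = 50, OPV1 = 45, PENTA1 = 45))
  expect_true(r$late_bcg)
  # BCG with the birth polio dose only: OPV0 never triggers the rule
  r <- f(c(BCG = 0, OPV0 = 0))
  expect_false(r$late_bcg)
  expect_false(r$out_of_sequence)
  r <- f(c(PENTA3 = 280, MV = 275))
  expect_true(r$penta_after_mv)
  # "with" counts: same-day pentavalent and measles
  r <- f(c(PENTA3 = 275, MV = 275))
  expect_true(r$penta_after_mv)
  # same-day pairs are in sequence
  r <- f(c(PENTA1 = 45, OPV1 = 45, PENTA2 = 72, OPV2 = 72))
  expect_false(r$out_of_sequence)
  # doses after the cutoff are out of scope by default but not under "all"
  late <- c(PENTA3 = 370, OPV3 = 380)
  expect_false(f(late)$penta_opv_split)
  expect_true(f(late, os_scope = "all")$penta_opv_split)
  # narrower footnote rule: BCG after OPV alone does not flag
  with_opv <- c(BCG = 50, OPV1 = 45)
  expect_true(f(with_opv)$late_bcg)
  expect_false(f(with_opv, bcg_rule = "penta_mv")$late_bcg)
})

test_that("flag monotonicity: removing events clears dependent flags", {
  base <- c(PENTA1 = 45, OPV1 = 47, PENTA3 = 280, MV = 275)
  r <- flag_out_of_sequence(make_child(base), sched)
  expect_true(r$penta_after_mv)
  no_mv <- base[names(base) != "MV"]
  expect_false(flag_out_of_sequence(make_child(no_mv), sched)$penta_after_mv)
  no_penta <- base[!grepl("^PENTA", names(base))]
  r <- flag_out_of_sequence(make_child(no_penta), sched)
  expect_false(r$penta_opv_split)
  expect_false(r$penta_after_mv)
})

test_that("FIC-OS is defined only among FIC children", {
  fic <- classify_fic(make_child(full_ages), sched)
  split_flags <- flag_out_of_sequence(
    make_child(replace(full_ages, "OPV1", 44)), sched)
  expect_true(split_flags$penta_opv_split)
  expect_true(classify_fic_os(fic, split_flags))
  non_fic <- classify_fic(make_child(full_ages[names(full_ages) != "MV"]),
                          sched)
  expect_false(classify_fic_os(non_fic, split_flags))
})

test_that("missing_profile counts absent basis doses, not late ones", {
  ages <- full_ages[!(names(full_ages) %in% "OPV3")]
  p <- missing_profile(make_child(ages), sched)
  expect_equal(p$n_missing, 1L)
  expect_equal(p$missing, "OPV3")
  expect_false(p$fic_after_cutoff)
  late_mv <- replace(full_ages, "MV", 380)
  p <- missing_profile(make_child(late_mv), sched)
  expect_equal(p$n_missing, 0L)
  expect_true(p$fic_after_cutoff)
  expect_error(missing_profile(make_child(full_ages), sched),
               "non-FIC children only")
})

test_that("adding a within-cutoff event never breaks FIC (monotonicity)", {
  set.seed(77)
  for (i in 1:40) {
    labs <- sample(names(full_ages), sample(1:8, 1))
    ages <- stats::setNames(sample(0:400, length(labs), replace = TRUE), labs)
    before <- classify_fic(make_child(ages), sched)$fic
    extra <- setdiff(names(full_ages), names(ages))
    if (!length(extra)) next
    add <- sample(extra, 1)
    ages2 <- c(ages, stats::setNames(sample(0:365, 1), add))
    after <- classify_fic(make_child(ages2), sched)$fic
    expect_true(!before || after)
  }
})

test_that("classification matches the literal oracle on 500 synthetic children", {
  bad <- oracle_audit(500, seed = 404)
  expect_length(bad, 0)
})
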