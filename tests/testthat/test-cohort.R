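sched <- default_epi_schedule()

write_records <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(c("child_id,dob,event_type,antigen,date,card_seen", lines), path)
  path
}

test_that("read_cohort parses, validates and deduplicates", {
  path <- write_records(c(
    "A,2010-01-01,vaccination,BCG,2010-01-03,",
    "A,2010-01-01,vaccination,BCG,2010-01-03,",   # duplicate row
    "A,2010-01-01,vaccination,OPV0,2010-01-03,",
    "A,2010-01-01,vaccination,OPV1,2010-02-15,",
    "A,2010-01-01,vaccination,PENTA1,2010-02-15,",
    "A,2010-01-01,vaccination,OPV2,2010-03-15,",
    "A,2010-01-01,vaccination,PENTA2,2010-03-15,",
    "A,2010-01-01,vaccination,PENTA3,2010-04-12,",
    "A,2010-01-01,vaccination,MV,2010-10-02,",
    "A,2010-01-01,visit,,2011-02-01,true"))
  co <- read_cohort(path, sched)
  expect_equal(nrow(co$children), 1L)
  expect_equal(nrow(co$events), 8L)   # dedup left 8 distinct events
  expect_equal(nrow(co$visits), 1L)
})

test_that("malformed rows are reported, not silently dropped", {
  path <- write_records(c(
    "A,2010-01-01,vaccination,MMR,2010-01-03,",       # unknown label
    "A,2010-01-01,vaccination,BCG,2009-12-25,",       # before dob
    "A,2010-01-01,vaccination,OPV1,not-a-date,",      # bad date
    "A,2010-01-01,visit,,2011-02-01,true"))
  expect_warning(co <- read_cohort(path, sched), "malformed")
  err <- co$provenance$errors
  expect_equal(nrow(err), 3L)
  expect_setequal(err$problem, c("unknown antigen label",
                                 "vaccination before date of birth",
                                 "unparseable date"))
  expect_equal(nrow(co$events), 0L)
})

test_that("bare series labels are numbered chronologically", {
  path <- write_records(c(
    "A,2010-01-01,vaccination,PENTA,2010-03-15,",   # out of file order
    "A,2010-01-01,vaccination,PENTA,2010-02-12,",
    "A,2010-01-01,vaccination,PENTA,2010-04-12,",
    "A,2010-01-01,visit,,2011-02-01,true"))
  co <- read_cohort(path, sched)
  ev <- co$events[order(co$events$date), ]
  expect_equal(ev$antigen, c("PENTA1", "PENTA2", "PENTA3"))
})

test_that("cohort write/read round-trips", {
  sim <- generate_cohort(sim_config(n_children = 30, seed = 11))
  rec <- withr::local_tempfile(fileext = ".csv")
  cov <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, rec, cov)
  co2 <- read_cohort(rec, sched, cov)
  for (part in c("children", "visits", "events")) {
    a <- sim$cohort[[part]]
    b <- co2[[part]]
    key_a <- do.call(order, unname(a))
    key_b <- do.call(order, unname(b))
    a <- a[key_a, names(a)]
    b <- b[key_b, names(a)]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a, ignore_attr = TRUE)
  }
})

test_that("select_analysis_visit picks the earliest qualifying visit", {
  dob <- as.Date("2010-01-01")
  mk <- function(ages, card) {
    child_record("A", dob,
                 visits = data.frame(date = dob + ages, card_seen = card))
  }
  v <- select_analysis_visit(mk(c(200, 380, 500), c(TRUE, TRUE, TRUE)))
  expect_equal(v$age, 380L)
  v <- select_analysis_visit(mk(c(380, 500), c(FALSE, TRUE)))
  expect_equal(v$age, 500L)   # card requirement
  expect_null(select_analysis_visit(mk(c(200, 750), c(TRUE, TRUE))))
  # half-open window: 365 in, 730 out
  expect_equal(select_analysis_visit(mk(365, TRUE))$age, 365L)
  expect_null(select_analysis_visit(mk(730, TRUE)))
})

test_that("apply_inclusion keeps exactly qualifying children with a full log", {
  dob <- as.Date("2010-01-01")
  n <- 100
  ids <- sprintf("K%03d", 1:n)
  # children 1..38 have a qualifying card-seen visit; 39..80 window visit but
  # no card; 81..100 no visit in window at all
  visits <- do.call(rbind, lapply(1:n, function(i) {
    if (i <= 80) data.frame(child_id = ids[i], date = dob + 400,
                            card_seen = i <= 38)
    else data.frame(child_id = ids[i], date = dob + 200, card_seen = TRUE)
  }))
  co <- vax_cohort(data.frame(child_id = ids, dob = dob), visits)
  inc <- apply_inclusion(co)
  expect_equal(inc$log$included, 38L)
  expect_equal(inc$log$included_fraction, 0.38)
  expect_equal(inc$log$excluded_no_card, 42L)
  expect_equal(inc$log$excluded_no_window, 20L)
  expect_equal(inc$log$included + inc$log$excluded_no_card +
                 inc$log$excluded_no_window, inc$log$total)
  expect_setequal(inc$cohort$children$child_id, ids[1:38])
  expect_true(all(inc$cohort$children$year_of_visit == 2011L))
  # idempotent
  inc2 <- apply_inclusion(inc$cohort)
  expect_equal(inc2$cohort$children$child_id, inc$cohort$children$child_id)
  expect_equal(inc2$log$included, inc$log$included)
  # all qualifying -> identity on children
  co_all <- vax_cohort(data.frame(child_id = ids, dob = dob),
                       data.frame(child_id = ids, date = dob + 400,
                                  card_seen = TRUE))
  expect_setequal(apply_inclusion(co_all)$cohort$children$child_id, ids)
})

test_that("included fraction tracks the configured card-seen probability", {
  sim <- generate_cohort(sim_config(n_children = 2000, seed = 5,
                                    card_seen_prob = 0.38))
  inc <- apply_inclusion(sim$cohort)
  se <- sqrt(0.38 * 0.62 / 2000)
  expect_lt(abs(inc$log$included_fraction - 0.38), 3 * se)
})
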