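#' Test-result container
#'
#' Light S3 wrapper shared by all hypothesis tests in the package.
#'
#' @param statistic test statistic.
#' @param df degrees of freedom.
#' @param p_value p-value in `[0, 1]`.
#' @param method label of the test.
#' @param note optional annotation (e.g. degenerate-input flag).
#' @return Object of class `vax_test`.
#' @keywords internal
vax_test <- function(statistic, df, p_value, method, note = NULL) {
  structure(list(statistic = statistic, df = as.integer(df),
                 p_value = p_value, method = method, note = note),
            class = "vax_test")
}

#' @export
print.vax_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Kaplan-Meier age-at-vaccination curve
#'
#' Product-limit estimate of the age-at-vaccination distribution, reported as
#' a rising coverage curve (`coverage = 1 - survival`: the probability of
#' having received the dose by each age). Children not vaccinated by the
#' analysis horizon are administratively censored at the horizon, as are
#' events recorded after it; this matches "coverage by 12 months" tables.
#' Ties are handled in the standard way: at any time, events are processed
#' before censorings, so observations censored at an event time are still at
#' risk for it.
#'
#' @param age ages in days (event or censoring times).
#' @param observed logical: `TRUE` for a vaccination (event), `FALSE` for a
#'   censored observation. Defaults to all events.
#' @param horizon administrative censoring horizon in days (default 365);
#'   `Inf` disables it.
#' @return data.frame of class `vax_km` with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`, `coverage`.
#' @examples
#' km <- km_curve(c(10, 20, 30), horizon = Inf)
#' km_coverage_at(km, 25)  # 2/3
#' @export
km_curve <- function(age, observed = rep(TRUE, length(age)), horizon = 365) {
  if (!length(age)) stop("empty input")
  if (any(is.na(age)) || any(age < 0)) stop("ages must be non-negative days")
  observed <- as.logical(observed)
  over <- age > horizon
  age[over] <- horizon
  observed[over] <- FALSE
  ord <- order(age, !observed)   # events before censorings at equal time
  age <- age[ord]; observed <- observed[ord]
  times <- sort(unique(age[observed]))
  n <- length(age)
  if (!length(times)) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), n_censor = integer(0),
                      survival = numeric(0), coverage = numeric(0))
    return(structure(out, class = c("vax_km", "data.frame"),
                     n = n, horizon = horizon))
  }
  n_risk <- vapply(times, function(t) sum(age >= t), integer(1))
  n_event <- vapply(times, function(t) sum(age == t & observed), integer(1))
  n_censor <- vapply(times, function(t) sum(age == t & !observed), integer(1))
  survival <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = times, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = survival,
                    coverage = 1 - survival)
  structure(out, class = c("vax_km", "data.frame"), n = n, horizon = horizon)
}

#' Evaluate a KM coverage curve at given ages
#'
#' Step-function evaluation: coverage just after `t` (right-continuous).
#'
#' @param km a `vax_km`.
#' @param t ages in days.
#' @return Numeric coverage values in `[0, 1]`.
#' @export
km_coverage_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 0 else km$coverage[max(i)]
  }, numeric(1))
}

#' Age samples for a dose from a classified cohort
#'
#' Builds the (age, observed) pairs the KM machinery consumes: a child
#' vaccinated by the horizon contributes an event at its age at the dose;
#' every other child contributes a censoring at the horizon.
#'
#' @param classification output of [classify_cohort()].
#' @param dose dose label.
#' @param horizon administrative horizon (days, default 365).
#' @param group optional vector (length = rows of `classification`) of
#'   stratum labels to carry through.
#' @return data.frame `age`, `observed` (and `group` when given).
#' @export
km_age_samples <- function(classification, dose, horizon = 365,
                           group = NULL) {
  a <- classification[[paste0("age_", dose)]]
  if (is.null(a)) stop("no such dose in classification: ", dose)
  event <- !is.na(a) & a <= horizon
  out <- data.frame(age = ifelse(event, a, horizon), observed = event)
  if (!is.null(group)) out$group <- group
  out
}

#' Log-rank test for equality of age-at-vaccination curves
#'
#' Standard g-sample log-rank test: at every distinct event time the observed
#' event counts per group are compared with their hypergeometric expectation
#' given the risk sets; the quadratic form of the summed differences against
#' the summed covariance (dropping one group) is chi-square with g-1 degrees
#' of freedom under the null of equal curves.
#'
#' @param age event/censoring ages in days.
#' @param observed logical event indicators.
#' @param group stratum labels (at least two levels, each non-empty).
#' @return A `vax_test`.
#' @export
logrank_test <- function(age, observed, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(tabulate(group, nlevels(group)) == 0))
    stop("every group must be non-empty")
  if (!any(observed)) stop("need at least one event overall")
  g <- nlevels(group)
  times <- sort(unique(age[observed]))
  O <- E <- numeric(g)
  V <- matrix(0, g, g)
  for (t in times) {
    at_risk <- age >= t
    n <- sum(at_risk)
    d <- sum(age == t & observed)
    if (n <= 1) next
    nj <- vapply(seq_len(g), function(j) sum(at_risk & group == levels(group)[j]),
                 numeric(1))
    dj <- vapply(seq_len(g), function(j)
      sum(age == t & observed & group == levels(group)[j]), numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    mult <- d * (n - d) / (n - 1)
    V <- V + mult * (diag(nj / n, g) - tcrossprod(nj / n))
  }
  idx <- seq_len(g - 1)
  u <- (O - E)[idx]
  Vm <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vm, u)),
                   error = function(e) {   # singular: generalized inverse
                     s <- svd(Vm)
                     pos <- s$d > max(s$d) * 1e-12
                     ginv <- s$v[, pos, drop = FALSE] %*%
                       (t(s$u[, pos, drop = FALSE]) / s$d[pos])
                     drop(t(u) %*% ginv %*% u)
                   })
  stat <- max(stat, 0)
  df <- g - 1
  vax_test(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
           "Log-rank test")
}

#' Median and interquartile range
#'
#' Sample median and 25th/75th percentiles with linear interpolation between
#' the closest order statistics (the same rule as R's default quantile type).
#' Full precision is returned; table writers round half-up to whole days.
#'
#' @param ages non-empty numeric vector (days).
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(ages) {
  if (!length(ages)) stop("empty input")
  x <- sort(ages)
  n <- length(x)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  c(median = q(0.5), q1 = q(0.25), q3 = q(0.75))
}

#' Mood's median test
#'
#' Tests equality of group medians: pool all groups, take the grand median,
#' classify every observation as above the grand median or not (ties at the
#' grand median count as "not above"), and apply the Pearson chi-square test
#' of independence to the resulting 2 x g table. When the pooled values are
#' all identical (or no observation falls on either side) the table is
#' degenerate and the test returns p = 1 with a note.
#'
#' @param groups list of at least two non-empty numeric vectors (days).
#' @return A `vax_test`.
#' @export
mood_median_test <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!lengths(groups))) stop("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  m <- unname(median_iqr(pooled)["median"])
  above <- vapply(groups, function(gr) sum(gr > m), numeric(1))
  not_above <- lengths(groups) - above
  tab <- rbind(above = above, not_above = not_above)
  if (any(rowSums(tab) == 0))
    return(vax_test(0, length(groups) - 1, 1, "Mood's median test",
                    note = "degenerate: all values on one side of the grand median"))
  res <- chisq_independence(tab)
  vax_test(res$statistic, res$df, res$p_value, "Mood's median test")
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic on an r x c contingency table, no continuity
#' correction, df = (r-1)(c-1), p-value from the upper chi-square tail.
#' Expected counts below 5 trigger a warning (not an error); a zero row or
#' column margin is an error.
#'
#' @param table matrix of non-negative counts, at least 2 x 2.
#' @return A `vax_test`.
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least a 2 x 2 table")
  if (any(table < 0) || any(is.na(table))) stop("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  expected <- outer(rs, cs) / n
  if (any(expected < 5))
    warning("some expected counts are below 5; chi-square approximation may be poor")
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  vax_test(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
           "Pearson chi-square test of independence")
}
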