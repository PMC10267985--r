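#' Kaplan-Meier curve and median survival
#'
#' Product-limit estimator via [survival::survfit]. The median is the
#' smallest observed time t with S(t) <= 0.5; if the curve never reaches
#' 0.5 (heavy censoring) the median is `NA` with `median_defined = FALSE`.
#'
#' @param time event/censoring times in days (>= 0).
#' @param event 1 = death, 0 = censored (default all events).
#' @return List of class `km_curve`: `time`, `n_risk`, `n_event`, `surv`
#'   (step function values, S(0) = 1 implicit), `median`, `median_defined`.
#' @examples
#' kmCurve(c(157, 64, 61, 67))$median  # 64
#' @export
kmCurve <- function(time, event = rep(1L, length(time))) {
    if (!length(time)) stop("empty survival input")
    stopifnot(all(time >= 0), all(event %in% c(0, 1)))
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    med_idx <- which(fit$surv <= 0.5 + 1e-12)
    defined <- length(med_idx) > 0
    structure(list(time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, surv = fit$surv,
                   median = if (defined) fit$time[min(med_idx)] else NA_real_,
                   median_defined = defined),
              class = "km_curve")
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on 1 degree of freedom, two-sided, via
#' [survival::survdiff].
#'
#' @param time times in days.
#' @param event 1 = death, 0 = censored.
#' @param arm two-level group labels.
#' @return List with `statistic`, `df` (1) and `p`.
#' @export
logrankTest <- function(time, event, arm) {
    arm <- as.factor(arm)
    if (nlevels(droplevels(arm)) != 2)
        stop("log-rank test needs exactly two non-empty arms")
    sd <- survival::survdiff(survival::Surv(time, event) ~ arm)
    stat <- sd$chisq
    list(statistic = stat, df = 1L,
         p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Chi-squared test on a 2x2 contingency table
#'
#' Pearson chi-square on 1 df, with Yates continuity correction by default
#' (the conventional choice for 2x2 tables). A zero row or column margin
#' makes the test undefined; an exact test is suggested instead.
#'
#' @param tbl 2x2 matrix of nonnegative counts
#'   (event/no-event x exposure/nonexposure).
#' @param correct apply the Yates correction (default TRUE).
#' @return List with `statistic`, `df` (1) and `p`.
#' @examples
#' chisq2x2(matrix(c(10, 19, 40, 28), 2))  # leukopenia counts, Yates
#' @export
chisq2x2 <- function(tbl, correct = TRUE) {
    tbl <- as.matrix(tbl)
    if (!all(dim(tbl) == c(2, 2)) || any(tbl < 0) || sum(tbl) == 0)
        stop("need a 2x2 table of nonnegative counts with positive total")
    if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
        stop("zero margin: chi-squared undefined; use an exact test")
    ht <- stats::chisq.test(tbl, correct = correct)
    list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Incidence percentage as printed in adverse-event tables
#'
#' 100 x events / total, rounded half-up to the nearest integer percent
#' (display convention of clinical tables; `round()` would round half to
#' even).
#'
#' @param events event count in the arm.
#' @param total arm size (> 0).
#' @return Integer percentage.
#' @examples
#' incidencePct(10, 50)  # 20
#' incidencePct(29, 47)  # 62
#' @export
incidencePct <- function(events, total) {
    stopifnot(total > 0, events >= 0, events <= total)
    as.integer(floor(100 * events / total + 0.5))
}

#' Stage-D survival fixture (nine-patient two-arm cohort)
#'
#' Patient-level survival times, in days, of the nine late-stage patients
#' printed in the source cohort's stage-D table: five exposure-arm and four
#' nonexposure-arm cases, all treated as observed deaths.
#'
#' @return data.frame with columns `id`, `time_days`, `event`, `arm`.
#' @export
stageDFixture <- function() {
    read.delim(system.file("extdata", "table3_stage_d.tsv",
                           package = "netscreen"),
               stringsAsFactors = FALSE)
}

#' Treatment-related adverse-event fixture
#'
#' Printed 2x2 adverse-event counts for ten event categories in a 50 vs 47
#' patient two-arm cohort, together with the percentages the source table
#' displays.
#'
#' @return data.frame with columns `event_name`, `exposure_events`,
#'   `exposure_total`, `nonexposure_events`, `nonexposure_total`,
#'   `printed_exposure_pct`, `printed_nonexposure_pct`.
#' @export
traeFixture <- function() {
    read.delim(system.file("extdata", "table4_trae.tsv",
                           package = "netscreen"),
               stringsAsFactors = FALSE)
}
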