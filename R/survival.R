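#' Assign top/bottom expression-percentile groups
#'
#' Orders subjects by expression and labels the bottom `floor(low_pct * n)`
#' subjects `"low"`, the top `floor(high_pct * n)` subjects `"high"`, and
#' the remainder `"excluded"`. Ties at a boundary are broken by stable
#' subject order (input row order), so the grouping is deterministic.
#'
#' @param cohort Data frame with at least an `expression` column (the
#'   layout of [simulate_survival_cohort()]).
#' @param low_pct,high_pct Fractions in (0,1\] with `low_pct + high_pct <=
#'   1`. The study convention is 0.10/0.10 for miRNA stratification and
#'   0.20/0.20 for single-gene stratification.
#' @return `cohort` with a `group` column added.
#' @export
#' @examples
#' ch <- simulate_survival_cohort(n = 50, hazard_ratio = 2, seed = 1)
#' table(assign_percentile_groups(ch, 0.2, 0.2)$group)
assign_percentile_groups <- function(cohort, low_pct = 0.1,
                                     high_pct = 0.1) {
  if (low_pct <= 0 || high_pct <= 0 || low_pct + high_pct > 1) {
    stop("need 0 < low_pct, high_pct and low_pct + high_pct <= 1",
         call. = FALSE)
  }
  n <- nrow(cohort)
  n_low <- floor(low_pct * n)
  n_high <- floor(high_pct * n)
  if (n_low == 0L || n_high == 0L) {
    stop("percentile group of size 0: cohort too small for the requested ",
         "percentiles", call. = FALSE)
  }
  ord <- order(cohort$expression, seq_len(n))  # stable under ties
  group <- rep("excluded", n)
  group[ord[seq_len(n_low)]] <- "low"
  group[ord[seq.int(n - n_high + 1L, n)]] <- "high"
  cohort$group <- group
  cohort
}

#' Kaplan-Meier product-limit estimate with Greenwood standard errors
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; times with
#' only censoring deplete the risk set without an event factor. Standard
#' errors are Greenwood: `SE(S)^2 = S^2 sum d_i / (n_i (n_i - d_i))`. When
#' an event and a censoring fall on the same time, the event is counted
#' first (the censored subject is still in that time's risk set).
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = death observed, 0 = censored).
#' @return Data frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `std_err`, one row per distinct observed time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one subject", call. = FALSE)
  if (any(time < 0)) stop("negative follow-up times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  s <- summary(fit, censored = TRUE)
  data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
             n_censor = s$n.censor, surv = s$surv,
             std_err = s$std.err)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in one group
#' is compared with its hypergeometric expectation given the risk sets;
#' `chi^2 = (sum O - sum E)^2 / sum V` on 1 degree of freedom, with the
#' p-value from the asymptotic chi-square upper tail.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level grouping vector (e.g. `"low"` / `"high"`); both
#'   groups must be non-empty.
#' @return List `chi_square`, `p`, `observed`, `expected` (per group), `n`
#'   (per group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L || any(table(group) == 0L)) {
    stop("`group` must have exactly two non-empty levels", call. = FALSE)
  }
  if (sum(event) == 0) {
    stop("no events observed: log-rank statistic undefined", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p = pchisq(chi, df = 1, lower.tail = FALSE),
       observed = setNames(as.numeric(sd$obs), levels(group)),
       expected = setNames(as.numeric(sd$exp), levels(group)),
       n = setNames(as.numeric(sd$n), levels(group)))
}

#' Percentile-stratified survival comparison
#'
#' Convenience wrapper: assigns percentile groups, estimates a KM curve per
#' group, and runs the log-rank test between the low and high groups.
#'
#' @inheritParams assign_percentile_groups
#' @param cohort Data frame with columns `time`, `event`, `expression`.
#' @return List `cohort` (with groups), `km` (named list of KM tables for
#'   `low` and `high`), `logrank` (the [logrank_test()] result).
#' @export
survival_stratify <- function(cohort, low_pct = 0.1, high_pct = 0.1) {
  cohort <- assign_percentile_groups(cohort, low_pct, high_pct)
  sel <- cohort$group %in% c("low", "high")
  sub <- cohort[sel, , drop = FALSE]
  km <- lapply(split(sub, sub$group),
               function(g) km_estimate(g$time, g$event))
  lr <- logrank_test(sub$time, sub$event, sub$group)
  list(cohort = cohort, km = km, logrank = lr)
}
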