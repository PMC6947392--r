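# Cohort statistics: contingency tables, one-way ANOVA on scores,
# Kaplan-Meier estimation and the two-group log-rank test.

#' Contingency analysis of a clinical factor against a binary outcome
#'
#' Pearson chi-square without continuity correction on the level x outcome
#' table. Levels with zero observations are dropped with a warning;
#' expected counts are returned so small-cell (< 5) situations are
#' explicit rather than silently "corrected".
#'
#' @param records data.frame of clinical records.
#' @param factor_col name of the factor column (>= 2 observed levels).
#' @param outcome_col name of a logical/binary outcome column.
#' @return list: `table` (counts), `expected`, `percent` (per-level
#'   outcome rate, one-decimal truncation), `chi2`, `df`, `p`,
#'   `small_cells` (any expected count < 5).
#' @export
contingency_analysis <- function(records, factor_col, outcome_col) {
  f <- records[[factor_col]]
  y <- as.logical(records[[outcome_col]])
  keep <- !is.na(f) & !is.na(y)
  f <- if (is.factor(f)) f[keep] else factor(f[keep])
  y <- y[keep]
  if (any(table(f) == 0)) {
    warning("dropping factor level(s) with zero observations: ",
            paste(names(which(table(f) == 0)), collapse = ", "))
    f <- droplevels(f)
  }
  if (nlevels(f) < 2) stop("factor must have >= 2 observed levels")
  O <- table(f, factor(y, levels = c(FALSE, TRUE)))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  pct <- vapply(levels(f), function(l)
    pct_trunc(sum(y[f == l]), sum(f == l)), numeric(1))
  list(table = O, expected = E, percent = pct, chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE),
       small_cells = any(E < 5))
}

#' One-way analysis of variance on score values
#'
#' Classic decomposition: `F = MS_between / MS_within` with `(k - 1,
#' N - k)` degrees of freedom.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, at
#'   least one group with >= 2 values).
#' @return list: `F`, `df1`, `df2`, `p`, `ss_between`, `ss_within`.
#' @export
anova_scores <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1),
            any(lengths(groups) >= 2))
  x <- unlist(groups)
  n <- lengths(groups)
  N <- sum(n); k <- length(groups)
  gm <- mean(x)
  mj <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (mj - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0 && ssb == 0) {
    warning("zero variance within and between groups: F undefined")
    return(list(F = NA_real_, df1 = k - 1, df2 = N - k, p = NA_real_,
                ss_between = 0, ss_within = 0))
  }
  Fs <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fs, df1 = k - 1, df2 = N - k,
       p = pf(Fs, k - 1, N - k, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t)` multiplies `1 - d_i / n_i` over event times up to `t`. Censored
#' subjects leave the risk set after their recorded time; at tied times
#' deaths are processed before censorings (both counted in the risk set
#' at that time).
#'
#' @param times positive follow-up times.
#' @param events logical/0-1 event indicators.
#' @return data.frame step function: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (non-increasing, starting from 1).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0))
  events <- as.logical(events)
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), integer(1))
  n_event <- vapply(ut, function(t) sum(times == t & events), integer(1))
  n_cens <- vapply(ut, function(t) sum(times == t & !events), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_cens, survival = surv)
}

#' Two-group log-rank test
#'
#' Sums observed-minus-expected events for group 1 over event times with
#' the hypergeometric variance; `chi2 = (sum(O1 - E1))^2 / V`, p from
#' chi-square with 1 df.
#'
#' @param times positive follow-up times.
#' @param events logical event indicators.
#' @param group two-level grouping vector.
#' @return list: `chi2`, `p`, `observed`, `expected` (per group),
#'   `defined` (FALSE when there are no events).
#' @export
logrank_test <- function(times, events, group) {
  events <- as.logical(events)
  g <- factor(group)
  stopifnot(length(times) == length(events),
            length(times) == length(group))
  if (nlevels(g) != 2) stop("log-rank test requires exactly 2 groups")
  if (!any(events)) {
    warning("no events: log-rank statistic undefined")
    return(list(chi2 = NA_real_, p = NA_real_,
                observed = c(0, 0), expected = c(0, 0), defined = FALSE))
  }
  dtimes <- sort(unique(times[events]))
  o1 <- e1 <- v <- 0
  O <- c(0, 0); E <- c(0, 0)
  for (t_k in dtimes) {
    at <- times >= t_k
    nk <- sum(at)
    n1k <- sum(at & g == levels(g)[1])
    dk <- sum(times == t_k & events)
    d1k <- sum(times == t_k & events & g == levels(g)[1])
    ek <- dk * n1k / nk
    o1 <- o1 + d1k
    e1 <- e1 + ek
    if (nk > 1)
      v <- v + dk * (n1k / nk) * (1 - n1k / nk) * (nk - dk) / (nk - 1)
    O <- O + c(d1k, dk - d1k)
    E <- E + c(ek, dk - ek)
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
       observed = setNames(O, levels(g)), expected = setNames(E, levels(g)),
       defined = TRUE)
}

#' Kaplan-Meier curves by group with log-rank comparison
#'
#' @inheritParams logrank_test
#' @return list: `curves` (named list of [km_estimate()] tables) and
#'   `logrank` (the [logrank_test()] result, `NULL` for a single group).
#' @export
km_by_group <- function(times, events, group) {
  g <- factor(group)
  curves <- lapply(levels(g), function(l)
    km_estimate(times[g == l], events[g == l]))
  names(curves) <- levels(g)
  lr <- if (nlevels(g) == 2) logrank_test(times, events, g) else NULL
  list(curves = curves, logrank = lr)
}
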