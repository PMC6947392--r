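# Cox proportional hazards by Newton-Raphson on the Efron partial
# likelihood, with Wald inference, a Schoenfeld-residual proportionality
# score test, and bidirectional stepwise selection treating multi-level
# factors as blocks.

# Efron log partial likelihood, score and information for one beta.
# X: n x p design; returns list(loglik, grad, info).
efron_quantities <- function(beta, X, time, event) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(-time)                     # decreasing: risk set = prefix
  Xo <- X[ord, , drop = FALSE]; to <- time[ord]; eo <- event[ord]
  wo <- w[ord]; etao <- eta[ord]
  cs0 <- cumsum(wo)
  cs1 <- apply(Xo * wo, 2, cumsum)
  if (p == 1) cs1 <- matrix(cs1, ncol = 1)
  # upper-triangular packing of cumulative w * x x'
  pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  xx <- Xo[, pr[, 1], drop = FALSE] * Xo[, pr[, 2], drop = FALSE] * wo
  cs2 <- apply(xx, 2, cumsum)
  if (nrow(pr) == 1) cs2 <- matrix(cs2, ncol = 1)
  unpack <- function(v) {
    S <- matrix(0, p, p)
    S[cbind(pr[, 1], pr[, 2])] <- v
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    S
  }
  dtimes <- unique(to[eo])
  ll <- 0; g <- numeric(p); H <- matrix(0, p, p)
  for (t_k in dtimes) {
    at_risk <- max(which(to >= t_k))      # prefix length
    died <- which(to == t_k & eo)
    d <- length(died)
    S0 <- cs0[at_risk]
    S1 <- cs1[at_risk, ]
    S2 <- unpack(cs2[at_risk, ])
    s0d <- sum(wo[died])
    s1d <- colSums(Xo[died, , drop = FALSE] * wo[died])
    xxd <- Xo[died, pr[, 1], drop = FALSE] *
      Xo[died, pr[, 2], drop = FALSE] * wo[died]
    s2d <- unpack(colSums(xxd))
    ll <- ll + sum(etao[died])
    g <- g + colSums(Xo[died, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      den <- S0 - f * s0d
      num <- S1 - f * s1d
      ll <- ll - log(den)
      g <- g - num / den
      H <- H + (S2 - f * s2d) / den - tcrossprod(num / den)
    }
  }
  list(loglik = as.numeric(ll), grad = unname(g), info = H)
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the Efron-tie-corrected partial likelihood by
#' Newton-Raphson (relative log-likelihood tolerance 1e-9, at most 50
#' iterations). Categorical covariates are expanded to treatment-contrast
#' indicators and tracked as blocks. Inference is Wald: HR = exp(beta),
#' 95% CI exp(beta +/- 1.96 se). Monotone likelihood (complete
#' separation) is detected as |beta| > 15 and reported as non-estimable.
#'
#' @param data data.frame containing `time` (> 0), `event` (logical/0-1)
#'   and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col column names, defaults `"time"`, `"event"`.
#' @return a `cox_fit` object: `table` (term, hazard_ratio, ci_low,
#'   ci_high, se, z, p, df, block), `beta`, `var`, `loglik`,
#'   `loglik_null`, `converged`, `non_estimable`, plus the design kept for
#'   diagnostics.
#' @export
cox_fit <- function(data, covariates, time_col = "time",
                    event_col = "event") {
  stopifnot(length(covariates) >= 1,
            all(covariates %in% names(data)))
  time <- as.numeric(data[[time_col]])
  event <- as.logical(data[[event_col]])
  keep <- complete.cases(data[covariates]) & !is.na(time) & !is.na(event)
  data <- data[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (sum(event) < 1) stop("no events: Cox model undefined")
  mf <- data[covariates]
  mf[] <- lapply(mf, function(x) if (is.character(x)) factor(x) else x)
  mm <- model.matrix(~ ., mf)
  assign_idx <- attr(mm, "assign")[-1]
  X <- mm[, -1, drop = FALSE]
  block <- covariates[assign_idx]
  p <- ncol(X)
  # center columns for numerical stability (invariant for Cox)
  X <- scale(X, center = TRUE, scale = FALSE)

  beta <- numeric(p)
  q0 <- efron_quantities(beta, X, time, event)
  ll_null <- q0$loglik
  ll_old <- q0$loglik
  q <- q0
  converged <- FALSE
  for (it in seq_len(50)) {
    step <- tryCatch(solve(q$info, q$grad), error = function(e)
      solve(q$info + diag(1e-8, p), q$grad))
    beta_new <- beta + step
    q_new <- efron_quantities(beta_new, X, time, event)
    # step-halving if the likelihood decreased
    h <- 0
    while (q_new$loglik < ll_old && h < 10) {
      step <- step / 2
      beta_new <- beta + step
      q_new <- efron_quantities(beta_new, X, time, event)
      h <- h + 1
    }
    beta <- beta_new; q <- q_new
    if (abs(q$loglik - ll_old) < 1e-9 * (abs(ll_old) + 1e-9)) {
      converged <- TRUE
      break
    }
    ll_old <- q$loglik
  }
  non_est <- abs(beta) > 15
  V <- tryCatch(solve(q$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  tab <- data.frame(
    term = colnames(X),
    hazard_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    se = se, z = z,
    p = 2 * pnorm(-abs(z)),
    df = 1L, block = block,
    stringsAsFactors = FALSE)
  tab$hazard_ratio[non_est] <- NA_real_
  tab$ci_low[non_est] <- NA_real_
  tab$ci_high[non_est] <- NA_real_
  if (any(non_est))
    warning("monotone likelihood detected for: ",
            paste(tab$term[non_est], collapse = ", "),
            " (reported non-estimable)")
  structure(list(table = tab, beta = setNames(beta, colnames(X)),
                 var = V, loglik = q$loglik, loglik_null = ll_null,
                 converged = converged, non_estimable = non_est,
                 covariates = covariates, X = X, time = time,
                 event = event),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties),", sum(x$event), "events /",
      length(x$event), "subjects\n")
  tab <- x$table
  tab$hazard_ratio <- sprintf("%.3f (%.3f-%.3f)", tab$hazard_ratio,
                              tab$ci_low, tab$ci_high)
  print(tab[, c("term", "hazard_ratio", "p", "df")], row.names = FALSE)
  invisible(x)
}

# likelihood-ratio p-value between nested cox fits (df = block size)
cox_lrt <- function(fit_full, fit_reduced, df) {
  lr <- 2 * (fit_full$loglik - fit_reduced$loglik)
  pchisq(max(lr, 0), df = df, lower.tail = FALSE)
}

null_loglik <- function(data, time_col = "time", event_col = "event") {
  # loglik of the empty model: evaluate with a constant pseudo-covariate
  time <- as.numeric(data[[time_col]]); event <- as.logical(data[[event_col]])
  efron_quantities(0, matrix(0, length(time), 1), time, event)$loglik
}

#' Global Schoenfeld proportionality test
#'
#' Score test for the addition of covariate-by-time interactions
#' `x * g(t)` (identity transform `g(t) = t`, centred over event times) to
#' a fitted Cox model: the score vector collects time-weighted Schoenfeld
#' residuals and the statistic is the quadratic form with the
#' interaction-block information, chi-square with df = number of terms.
#'
#' @param fit a [cox_fit()] object.
#' @return list: `chi2`, `df`, `p`.
#' @export
schoenfeld_global_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  X <- fit$X; time <- fit$time; event <- fit$event; beta <- fit$beta
  p <- ncol(X)
  d_total <- sum(event)
  if (d_total <= p)
    stop("fewer events than model terms (+1): Schoenfeld test undefined")
  eta <- drop(X %*% beta); w <- exp(eta)
  ord <- order(-time)
  Xo <- X[ord, , drop = FALSE]; to <- time[ord]; eo <- event[ord]
  wo <- w[ord]
  cs0 <- cumsum(wo)
  cs1 <- apply(Xo * wo, 2, cumsum)
  if (p == 1) cs1 <- matrix(cs1, ncol = 1)
  pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  xx <- Xo[, pr[, 1], drop = FALSE] * Xo[, pr[, 2], drop = FALSE] * wo
  cs2 <- apply(xx, 2, cumsum)
  if (nrow(pr) == 1) cs2 <- matrix(cs2, ncol = 1)
  unpack <- function(v) {
    S <- matrix(0, p, p)
    S[cbind(pr[, 1], pr[, 2])] <- v
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    S
  }
  idx_death <- which(eo)
  g_raw <- to[idx_death]
  gb <- g_raw - mean(g_raw)
  U <- numeric(p)
  Igg <- matrix(0, p, p); Igb <- matrix(0, p, p); Ibb <- matrix(0, p, p)
  for (j in seq_along(idx_death)) {
    i <- idx_death[j]
    at_risk <- max(which(to >= to[i]))
    S0 <- cs0[at_risk]
    xbar <- cs1[at_risk, ] / S0
    Vk <- unpack(cs2[at_risk, ]) / S0 - tcrossprod(xbar)
    s <- Xo[i, ] - xbar
    U <- U + gb[j] * s
    Igg <- Igg + gb[j]^2 * Vk
    Igb <- Igb + gb[j] * Vk
    Ibb <- Ibb + Vk
  }
  Ieff <- Igg - Igb %*% solve(Ibb) %*% Igb
  stat <- drop(t(U) %*% solve(Ieff) %*% U)
  list(chi2 = stat, df = p, p = pchisq(stat, df = p, lower.tail = FALSE))
}

#' Bidirectional stepwise Cox covariate selection
#'
#' Candidates are first screened univariately (likelihood-ratio test per
#' block) at `prefilter_p`; the survivors then undergo forward selection
#' (best-p entry while p < `p_enter`) interleaved with backward
#' elimination (drop any term whose removal LRT p exceeds `p_remove`)
#' until a fixpoint. Multi-level factors enter and leave as blocks with
#' their block df. Revisiting a model stops the search with a warning.
#'
#' @param data cohort data.frame with `time`, `event` and candidates.
#' @param candidates character vector of candidate covariate names.
#' @param p_enter,p_remove entry/removal significance levels (0.05).
#' @param prefilter_p univariate screen level (0.25).
#' @return list: `model` (final [cox_fit()] or `NULL` if empty),
#'   `selected`, `screen` (univariate p table), `trace` (step log).
#' @export
stepwise_select <- function(data, candidates, p_enter = 0.05,
                            p_remove = 0.05, prefilter_p = 0.25) {
  stopifnot(length(candidates) >= 1)
  block_df <- vapply(candidates, function(v) {
    x <- data[[v]]
    if (is.numeric(x) || is.logical(x)) 1L
    else max(1L, length(unique(stats::na.omit(x))) - 1L)
  }, integer(1))
  ll0 <- null_loglik(data)
  uni_p <- vapply(candidates, function(v) {
    f <- tryCatch(cox_fit(data, v), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    pchisq(max(2 * (f$loglik - ll0), 0), df = block_df[[v]],
           lower.tail = FALSE)
  }, numeric(1))
  screen <- data.frame(covariate = candidates, p = uni_p, df = block_df,
                       kept = !is.na(uni_p) & uni_p < prefilter_p,
                       stringsAsFactors = FALSE)
  pool <- candidates[screen$kept]
  current <- character(0)
  trace <- list()
  visited <- character(0)
  fit_of <- function(set) if (length(set)) cox_fit(data, set) else NULL
  ll_of <- function(f) if (is.null(f)) ll0 else f$loglik
  cur_fit <- NULL
  repeat {
    changed <- FALSE
    key <- paste(sort(current), collapse = "+")
    if (key %in% visited) {
      warning("stepwise selection revisited a model; stopping")
      break
    }
    visited <- c(visited, key)
    # forward
    avail <- setdiff(pool, current)
    if (length(avail)) {
      ps <- vapply(avail, function(v) {
        f <- tryCatch(fit_of(c(current, v)), error = function(e) NULL)
        if (is.null(f)) return(NA_real_)
        pchisq(max(2 * (f$loglik - ll_of(cur_fit)), 0),
               df = block_df[[v]], lower.tail = FALSE)
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < p_enter) {
        v <- avail[which.min(ps)]
        current <- c(current, v)
        cur_fit <- fit_of(current)
        trace[[length(trace) + 1]] <-
          data.frame(step = length(trace) + 1, action = "add",
                     term = v, p = min(ps, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # backward
    if (length(current) > 1 ||
        (length(current) == 1 && !changed)) {
      repeat {
        if (!length(current)) break
        ps <- vapply(current, function(v) {
          f <- tryCatch(fit_of(setdiff(current, v)),
                        error = function(e) NULL)
          full <- cur_fit
          pchisq(max(2 * (full$loglik - ll_of(f)), 0),
                 df = block_df[[v]], lower.tail = FALSE)
        }, numeric(1))
        worst <- which.max(ps)
        if (ps[worst] > p_remove) {
          v <- current[worst]
          current <- setdiff(current, v)
          cur_fit <- fit_of(current)
          trace[[length(trace) + 1]] <-
            data.frame(step = length(trace) + 1, action = "drop",
                       term = v, p = ps[worst])
          changed <- TRUE
        } else break
      }
    }
    if (!changed) break
  }
  list(model = cur_fit, selected = current, screen = screen,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(step = integer(0), action = character(0),
                               term = character(0), p = numeric(0)))
}
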