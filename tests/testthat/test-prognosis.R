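test_that("contingency_analysis equals the direct chi-square formula", {
  # homogeneous table -> chi-square 0
  rec <- data.frame(f = rep(c("a", "b"), each = 10),
                    y = rep(c(TRUE, FALSE), 10))
  expect_equal(contingency_analysis(rec, "f", "y")$chi2, 0)
  # any 2x2 vs Sum (O-E)^2/E recomputed independently
  set.seed(3)
  for (i in 1:10) {
    rec <- data.frame(f = sample(c("a", "b"), 40, TRUE),
                      y = sample(c(TRUE, FALSE), 40, TRUE))
    got <- contingency_analysis(rec, "f", "y")
    O <- table(rec$f, rec$y)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(got$chi2, sum((O - E)^2 / E))
    ref <- suppressWarnings(chisq.test(O, correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
  # zero-observation level dropped with warning
  rec2 <- data.frame(f = factor(rep(c("a", "b"), each = 5),
                                levels = c("a", "b", "ghost")),
                     y = rep(c(TRUE, FALSE), 5))
  expect_warning(contingency_analysis(rec2, "f", "y"), "ghost")
})

test_that("anova_scores matches the t^2 identity and manual sums of squares", {
  expect_equal(anova_scores(list(c(1, 2, 3), c(2, 1, 3)))$F, 0)
  # two groups: F equals the square of the pooled t statistic
  set.seed(7)
  g1 <- rnorm(8); g2 <- rnorm(10, 0.5)
  got <- anova_scores(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
  # textbook 3x5 fixture with hand-computed sums of squares:
  # groups (1..5), (2..6), (4..8); means 3, 4, 6; grand mean 13/3
  # SSB = 5[(3-13/3)^2+(4-13/3)^2+(6-13/3)^2] = 5*42/9 = 70/3
  # SSW = 3*10 = 30 ; F = (70/6)/(30/12) = 14/3
  hand <- anova_scores(list(1:5, 2:6, 4:8))
  expect_equal(hand$ss_between, 70 / 3)
  expect_equal(hand$ss_within, 30)
  expect_equal(hand$F, 14 / 3)
  expect_equal(hand$df1, 2); expect_equal(hand$df2, 12)
  expect_warning(anova_scores(list(c(1, 1), c(1, 1))), "undefined")
})

test_that("km_estimate reproduces hand product-limit computations", {
  # all censored -> survival 1 everywhere
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # 5 distinct events, no censoring: steps 4/5, 3/5, 2/5, 1/5, 0
  km1 <- km_estimate(1:5, rep(TRUE, 5))
  expect_equal(km1$survival, c(4, 3, 2, 1, 0) / 5)
  # 6-subject toy, censoring at t=3:
  # t=1 (d,n=6): 5/6 ; t=2 (d,n=5): 5/6*4/5=2/3 ; t=3 censored: 2/3
  # t=4 (d,n=3): 2/3*2/3=4/9 ; t=5 (d,n=2): 2/9 ; t=6 (d,n=1): 0
  km2 <- km_estimate(1:6, c(1, 1, 0, 1, 1, 1))
  expect_equal(km2$survival, c(5 / 6, 2 / 3, 2 / 3, 4 / 9, 2 / 9, 0))
  expect_equal(km2$n_risk, 6:1)
  # no censoring: equals the empirical survival function exactly
  set.seed(9)
  t <- sample(1:8, 30, replace = TRUE)
  km3 <- km_estimate(t, rep(TRUE, 30))
  expect_equal(km3$survival,
               vapply(km3$time, function(u) mean(t > u), numeric(1)))
  # survival is non-increasing and record-order invariant
  t2 <- rexp(40); e2 <- rbinom(40, 1, 0.6)
  kma <- km_estimate(t2, e2)
  expect_true(all(diff(kma$survival) <= 1e-12))
  p <- sample(40)
  expect_equal(kma, km_estimate(t2[p], e2[p]))
})

test_that("logrank_test matches enumeration and is label-symmetric", {
  # identical samples in both groups -> 0
  t <- c(1, 2, 3, 4, 5); e <- c(1, 0, 1, 1, 0)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("x", "y"), each = 5))
  expect_equal(lr0$chi2, 0)
  # single event time: equals the 2x2 hypergeometric score statistic
  tt <- c(5, 5, 5, 5, 5, 5); ee <- c(1, 1, 0, 0, 0, 0)
  gg <- c("a", "b", "a", "a", "b", "b")
  lr1 <- logrank_test(tt, ee, gg)
  # enumeration: n=6, n1=3, d=2; O1=1, E1=d*n1/n=1,
  # V = d*(n1/n)*(1-n1/n)*(n-d)/(n-1) = 2*(1/2)*(1/2)*(4/5) = 0.4
  expect_equal(lr1$chi2, (1 - 1)^2 / 0.4)
  tt2 <- c(5, 5, 5, 5); ee2 <- c(1, 1, 0, 0); gg2 <- c("a", "a", "b", "b")
  lr2 <- logrank_test(tt2, ee2, gg2)
  # O1=2, E1=1, V = 2*(1/2)*(1/2)*(2/3) = 1/3 -> chi2 = 3
  expect_equal(lr2$chi2, 3)
  # label swap invariance
  set.seed(11)
  d <- sim_surv(80, beta = 0.8)
  a <- logrank_test(d$time, d$event, d$x)
  b <- logrank_test(d$time, d$event, 1 - d$x)
  expect_equal(a$chi2, b$chi2)
  expect_warning(lrna <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_false(lrna$defined)
})

test_that("cox_fit maximizes the Efron partial likelihood (local max + oracle)", {
  set.seed(13)
  d <- sim_surv(120, beta = 1)
  f <- cox_fit(d, "x")
  x_c <- d$x - mean(d$x)
  ll_hat <- oracle_efron_loglik(f$beta, x_c, d$time, d$event)
  expect_gt(ll_hat, oracle_efron_loglik(f$beta + 0.01, x_c, d$time, d$event))
  expect_gt(ll_hat, oracle_efron_loglik(f$beta - 0.01, x_c, d$time, d$event))
  expect_equal(ll_hat, f$loglik, tolerance = 1e-8)
  # record order invariance
  p <- sample(nrow(d))
  expect_equal(unname(cox_fit(d[p, ], "x")$beta), unname(f$beta),
               tolerance = 1e-9)
})

test_that("cox_fit agrees with the survival package on ties and factors", {
  skip_if_not_installed("survival")
  set.seed(17)
  d <- sim_surv(150, beta = 0.7)
  d$time <- ceiling(d$time)           # monthly ties
  d$g <- sample(c("lo", "mid", "hi"), 150, TRUE)
  f <- cox_fit(d, c("x", "g"))
  ref <- survival::coxph(survival::Surv(time, event) ~ x + g,
                         data = d, ties = "efron")
  expect_equal(sort(unname(f$beta)), sort(unname(coef(ref))),
               tolerance = 1e-6)
  expect_equal(sort(f$table$se), sort(unname(sqrt(diag(vcov(ref))))),
               tolerance = 1e-6)
})

test_that("cox_fit flags monotone likelihood instead of fake estimates", {
  d <- data.frame(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                  event = c(1, 1, 1, 1, 1, 1, 1, 1),
                  x = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_warning(f <- cox_fit(d, "x"), "monotone|non-estimable")
  expect_true(any(f$non_estimable))
  expect_true(is.na(f$table$hazard_ratio[1]))
  expect_error(cox_fit(data.frame(time = 1:3, event = c(0, 0, 0), x = 1:3),
                       "x"), "no events")
})

test_that("null covariate recovers HR 1 at n = 2000", {
  set.seed(19)
  d <- sim_surv(2000, beta = 0)
  f <- cox_fit(d, "x")
  expect_lt(abs(f$beta), 3 * f$table$se)
})

test_that("schoenfeld test flags insufficient events and matches cox.zph", {
  d1 <- data.frame(time = c(1, 2, 3), event = c(1, 0, 0), x = c(0, 1, 1))
  f1 <- suppressWarnings(cox_fit(d1, "x"))
  expect_error(schoenfeld_global_test(f1), "undefined|fewer events")
  skip_if_not_installed("survival")
  set.seed(23)
  d <- sim_surv(200, beta = 0.5)
  f <- cox_fit(d, "x")
  got <- schoenfeld_global_test(f)
  ref <- survival::cox.zph(
    survival::coxph(survival::Surv(time, event) ~ x, d, ties = "efron"),
    transform = "identity", global = TRUE)
  expect_equal(got$chi2, ref$table["GLOBAL", "chisq"], tolerance = 1e-4)
  expect_equal(got$p, ref$table["GLOBAL", "p"], tolerance = 1e-4)
})

test_that("schoenfeld test detects a gross proportionality violation", {
  # hazard effect reverses at t = 15: strong violation
  set.seed(29)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  t1 <- rexp(n, 0.05 * exp(1.5 * x))
  flip <- t1 > 15
  t2 <- 15 + rexp(n, 0.05 * exp(-1.5 * x))
  tm <- ifelse(flip, t2, t1)
  d <- data.frame(time = pmin(tm, 40), event = tm <= 40, x = x)
  f <- cox_fit(d, "x")
  expect_lt(schoenfeld_global_test(f)$p, 0.05)
})

test_that("stepwise_select keeps a strong single candidate with trace length 1", {
  set.seed(31)
  d <- sim_surv(200, beta = 1.5)
  sel <- stepwise_select(d, "x")
  expect_identical(sel$selected, "x")
  expect_equal(nrow(sel$trace), 1)
  expect_identical(sel$trace$action, "add")
})

test_that("stepwise_select retains true factors and screens noise", {
  set.seed(33)
  hits <- 0
  reps <- 3
  for (r in seq_len(reps)) {
    n <- 400
    x1 <- rbinom(n, 1, 0.3)           # score positivity analog
    x2 <- rbinom(n, 1, 0.15)          # perineural analog
    z1 <- rnorm(n); z2 <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.01 * exp(1.4 * x1 + 1.2 * x2))
    t_c <- runif(n, 0, 60)
    d <- data.frame(time = pmin(t_ev, t_c), event = t_ev <= t_c,
                    x1 = x1, x2 = x2, z1 = z1, z2 = z2)
    sel <- stepwise_select(d, c("x1", "x2", "z1", "z2"))
    if (all(c("x1", "x2") %in% sel$selected)) hits <- hits + 1
  }
  expect_gte(hits, reps - 1)
})

test_that("noise candidates enter at roughly the entry rate", {
  set.seed(37)
  enters <- replicate(150, {
    d <- sim_surv(80, beta = 0)
    length(stepwise_select(d, "x")$selected) > 0
  })
  rate <- mean(enters)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 150) + 0.01)
})
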