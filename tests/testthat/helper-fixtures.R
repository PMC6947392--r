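# Shared fixtures and independent oracles. Oracles are deliberately
# naive re-implementations kept separate from the package code paths.

tiny_panel <- function(seed = 11) {
  generate_panel(n_genes = 3, total_cpgs = 12, amplicon_length = 90,
                 seed = seed, gene_names = c("GA", "GB", "GC"))
}

# brute-force AUC: (concordant + 0.5 * tied) / (n1 * n0)
oracle_auc <- function(x, labels) {
  pos <- x[labels]; neg <- x[!labels]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# naive Efron log partial likelihood for a single covariate
oracle_efron_loglik <- function(beta, x, time, event) {
  event <- as.logical(event)
  ll <- 0
  for (t_k in sort(unique(time[event]))) {
    died <- which(time == t_k & event)
    risk <- which(time >= t_k)
    d <- length(died)
    s0 <- sum(exp(beta * x[risk]))
    s0d <- sum(exp(beta * x[died]))
    ll <- ll + sum(beta * x[died])
    for (l in seq_len(d) - 1)
      ll <- ll - log(s0 - (l / d) * s0d)
  }
  ll
}

# exhaustive Youden search over all finite cut-points (strict >)
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        (head(sort(scores), -1) + tail(sort(scores), -1)) / 2)))
  J <- vapply(cand, function(t)
    mean(scores[labels] > t) + mean(scores[!labels] <= t) - 1, numeric(1))
  max(J)
}

# simulate a simple survival data.frame with one binary covariate
sim_surv <- function(n, beta, base = 0.02, cmax = 60, p = 0.4) {
  x <- rbinom(n, 1, p)
  t_ev <- rexp(n, base * exp(beta * x))
  t_c <- runif(n, 0, cmax)
  data.frame(time = pmin(t_ev, t_c), event = t_ev <= t_c, x = x)
}

# small fully-characterised training matrix for the scoring tests
toy_training <- function(n_per = 10, k_inf = 3, k_noise = 3, seed = 5,
                         sep = c(8, 2)) {
  set.seed(seed)
  n <- 2 * n_per
  labels <- rep(c(TRUE, FALSE), each = n_per)
  m <- matrix(NA_real_, n, k_inf + k_noise)
  for (j in seq_len(k_inf))
    m[, j] <- ifelse(labels, rbeta(n, sep[1], sep[2]),
                     rbeta(n, sep[2], sep[1]))
  for (j in k_inf + seq_len(k_noise)) m[, j] <- rbeta(n, 2, 2)
  colnames(m) <- sprintf("G:%d", seq_len(ncol(m)))
  rownames(m) <- sprintf("S%02d", seq_len(n))
  list(m = m, labels = labels)
}
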