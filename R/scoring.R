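# The 13-gene CpG score: ROC-based CpG ranking, two-class linear
# discriminant, Youden threshold, positivity calls.
# Score of a sample: S = sum_i c_i * m_i + b; positive iff S > threshold
# (strict: a score exactly at the threshold is negative).

#' Construct a score model
#'
#' @param cpg_ids ordered CpG ids entering the score.
#' @param coefficients per-CpG weights, same length.
#' @param constant additive constant of the score.
#' @param threshold positivity cut-off (strictly-greater convention).
#' @param impute_means training mean per CpG in \[0, 1\], used to impute
#'   missing ratios at scoring time.
#' @param provenance free-text training metadata.
#' @return a `ScoreModel`.
#' @export
score_model <- function(cpg_ids, coefficients, constant,
                        threshold = oscc_score_threshold,
                        impute_means = NULL, provenance = "") {
  stopifnot(length(cpg_ids) == length(coefficients), is.finite(threshold))
  if (is.null(impute_means))
    impute_means <- setNames(rep(0.5, length(cpg_ids)), cpg_ids)
  stopifnot(length(impute_means) == length(cpg_ids),
            all(impute_means >= 0 & impute_means <= 1))
  structure(list(cpg_ids = as.character(cpg_ids),
                 coefficients = setNames(as.numeric(coefficients), cpg_ids),
                 constant = as.numeric(constant),
                 threshold = as.numeric(threshold),
                 impute_means = setNames(as.numeric(impute_means), cpg_ids),
                 provenance = provenance),
            class = "ScoreModel")
}

#' @export
print.ScoreModel <- function(x, ...) {
  cat("ScoreModel:", length(x$cpg_ids), "CpGs, constant",
      format(x$constant, digits = 4), ", threshold",
      format(x$threshold, digits = 8), "\n")
  invisible(x)
}

#' Rank CpGs by two-class ROC AUC
#'
#' AUC is the rank (Mann-Whitney) statistic: U / (n1 * n0), ties sharing
#' average rank. CpGs with any missing ratio across the training samples
#' are dropped with a message.
#'
#' @param mat a `MethylationMatrix` or plain samples x CpGs matrix.
#' @param labels logical (or 0/1) per sample, `TRUE` = positive class.
#' @return data.frame `cpg_id`, `auc`, sorted by decreasing AUC (ties keep
#'   column order).
#' @export
rank_cpgs_by_auc <- function(mat, labels) {
  m <- if (inherits(mat, "MethylationMatrix")) mat$ratios else mat
  labels <- as.logical(labels)
  stopifnot(nrow(m) == length(labels))
  if (all(labels) || !any(labels))
    stop("both classes must be represented to rank CpGs")
  keep <- colSums(is.na(m)) == 0
  if (any(!keep))
    message(sum(!keep), " CpGs dropped for missing training values")
  m <- m[, keep, drop = FALSE]
  n1 <- sum(labels); n0 <- sum(!labels)
  auc <- apply(m, 2, function(x) {
    r <- rank(x)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  out <- data.frame(cpg_id = colnames(m), auc = as.numeric(auc),
                    stringsAsFactors = FALSE)
  out[order(-out$auc), , drop = FALSE]
}

#' Fit a two-class linear discriminant score
#'
#' Coefficients are `w = S_pooled^{-1} (mu1 - mu0)` with the pooled
#' within-class covariance; the constant centres the score at zero on the
#' midpoint between class means, `b = -w . (mu0 + mu1) / 2`. When the
#' pooled covariance is singular or ill-conditioned a ridge term
#' `lambda * I` is added (features can outnumber samples); pass
#' `ridge = NULL` to forbid the fallback and fail instead.
#'
#' @param mat samples x CpGs matrix (or `MethylationMatrix`) restricted to
#'   the selected CpGs; no missing values.
#' @param labels logical per sample, `TRUE` = positive class.
#' @param ridge ridge magnitude for the singular fallback (default 1e-6).
#' @return a `ScoreModel` without a data-driven threshold (threshold slot
#'   holds the published default until [choose_threshold()] is applied).
#' @export
fit_lda <- function(mat, labels, ridge = 1e-6) {
  m <- if (inherits(mat, "MethylationMatrix")) mat$ratios else mat
  labels <- as.logical(labels)
  stopifnot(nrow(m) == length(labels), !anyNA(m))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 < 2 || n0 < 2) stop("need at least 2 samples per class")
  x1 <- m[labels, , drop = FALSE]; x0 <- m[!labels, , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  S <- ((n1 - 1) * cov_mat(x1) + (n0 - 1) * cov_mat(x0)) / (n1 + n0 - 2)
  delta <- mu1 - mu0
  w <- tryCatch({
    if (rcond_sym(S) < 1e-10) stop("ill-conditioned")
    solve(S, delta)
  }, error = function(e) {
    if (is.null(ridge))
      stop("pooled within-class covariance is singular and ridge ",
           "fallback is disabled")
    solve(S + diag(ridge, ncol(S)), delta)
  })
  degenerate <- all(abs(delta) < .Machine$double.eps^0.5)
  if (degenerate) {
    warning("identical class means: degenerate zero-coefficient model")
    w[] <- 0
  }
  model <- score_model(colnames(m), w, constant = -sum(w * (mu0 + mu1) / 2),
                       impute_means = pmin(1, pmax(0, colMeans(m))),
                       provenance = sprintf(
                         "lda fit: n1=%d n0=%d k=%d", n1, n0, ncol(m)))
  attr(model, "degenerate") <- degenerate
  model
}

cov_mat <- function(x) {
  if (nrow(x) < 2) matrix(0, ncol(x), ncol(x)) else stats::cov(x)
}

rcond_sym <- function(S) {
  if (!all(is.finite(S))) return(0)
  tryCatch(1 / kappa(S, exact = FALSE), error = function(e) 0)
}

#' Choose a positivity threshold by Youden's J
#'
#' Maximizes J = sensitivity + specificity - 1 over midpoints of adjacent
#' sorted unique scores (classification is strict `score > threshold`).
#' Ties are broken toward higher sensitivity, then the lower threshold.
#'
#' @param scores numeric scores.
#' @param labels logical, `TRUE` = positive class.
#' @return the selected threshold.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (all(labels) || !any(labels)) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all scores identical: no threshold exists")
  cand <- (u[-1] + u[-length(u)]) / 2
  sens <- vapply(cand, function(t) mean(scores[labels] > t), numeric(1))
  spc <- vapply(cand, function(t) mean(scores[!labels] <= t), numeric(1))
  J <- sens + spc - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[sens[best] >= max(sens[best]) - 1e-12]
  cand[min(best)]
}

#' Score one sample
#'
#' `S = sum_i c_i * m_i + b`, positive iff `S` strictly exceeds the model
#' threshold. Missing CpG ratios are imputed from the model's training
#' means; a sample missing more than `max_missing_fraction` of the model
#' CpGs is flagged unevaluable instead of being scored.
#'
#' @param model a `ScoreModel`.
#' @param values named numeric vector of methylation ratios (extra names
#'   ignored; absent or `NA` model CpGs are imputed).
#' @param sample_id sample label.
#' @param max_missing_fraction unevaluability cut-off, default 0.5.
#' @return list: `sample_id`, `score`, `positive`, `n_imputed`,
#'   `evaluable`.
#' @export
apply_score <- function(model, values, sample_id = "S1",
                        max_missing_fraction = 0.5) {
  stopifnot(inherits(model, "ScoreModel"))
  m <- values[model$cpg_ids]
  names(m) <- model$cpg_ids
  miss <- is.na(m)
  if (mean(miss) > max_missing_fraction) {
    warning("sample ", sample_id, " unevaluable: ",
            sum(miss), "/", length(m), " model CpGs missing")
    return(list(sample_id = sample_id, score = NA_real_,
                positive = NA, n_imputed = sum(miss), evaluable = FALSE))
  }
  m[miss] <- model$impute_means[miss]
  s <- sum(model$coefficients * m) + model$constant
  list(sample_id = sample_id, score = s,
       positive = s > model$threshold, n_imputed = sum(miss),
       evaluable = TRUE)
}

#' Score every sample of a methylation matrix
#'
#' @inheritParams apply_score
#' @param mat a `MethylationMatrix` (or plain matrix with rownames).
#' @return data.frame: `sample_id`, `score`, `positive`, `evaluable`.
#' @export
score_samples <- function(model, mat, max_missing_fraction = 0.5) {
  m <- if (inherits(mat, "MethylationMatrix")) mat$ratios else mat
  rows <- lapply(seq_len(nrow(m)), function(i)
    apply_score(model, setNames(as.numeric(m[i, ]), colnames(m)),
                sample_id = rownames(m)[i] %||% paste0("S", i),
                max_missing_fraction = max_missing_fraction))
  data.frame(sample_id = vapply(rows, `[[`, character(1), "sample_id"),
             score = vapply(rows, `[[`, numeric(1), "score"),
             positive = vapply(rows, function(r)
               as.logical(r$positive), logical(1)),
             evaluable = vapply(rows, `[[`, logical(1), "evaluable"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-decimal percentage by truncation toward zero, the convention the
# printed cohort summaries follow (16/49 -> 32.6, 47/49 -> 95.9)
pct_trunc <- function(k, n) if (n == 0) NA_real_ else floor(1000 * k / n) / 10

#' Classify a cohort and summarize positivity
#'
#' @inheritParams score_samples
#' @return list: `scores` (per-sample data.frame), `summary` with `n`,
#'   `n_positive`, `n_negative`, `pct_positive`, `pct_negative`
#'   (percentages truncated to one decimal).
#' @export
classify_cohort <- function(model, mat, max_missing_fraction = 0.5) {
  m <- if (inherits(mat, "MethylationMatrix")) mat$ratios else mat
  if (nrow(m) == 0)
    return(list(scores = data.frame(), summary = list(
      n = 0L, n_positive = 0L, n_negative = 0L,
      pct_positive = NA_real_, pct_negative = NA_real_)))
  sc <- score_samples(model, mat, max_missing_fraction)
  ev <- sc[sc$evaluable, , drop = FALSE]
  npos <- sum(ev$positive)
  n <- nrow(ev)
  list(scores = sc,
       summary = list(n = n, n_positive = npos, n_negative = n - npos,
                      pct_positive = pct_trunc(npos, n),
                      pct_negative = pct_trunc(n - npos, n)))
}

#' Train the CpG score end-to-end
#'
#' Ranks CpGs by AUC, keeps the top `k`, fits the linear discriminant and
#' sets the positivity threshold either by Youden's J on the training
#' scores (`"refit"`) or at the published fixed value 1.0615547
#' (`"fixed"`).
#'
#' @param mat training `MethylationMatrix`.
#' @param labels logical per sample, `TRUE` = tumor-like class.
#' @param k number of top-AUC CpGs entering the score, default 20.
#' @param threshold_mode `"refit"` or `"fixed"`.
#' @param ridge see [fit_lda()].
#' @return a `ScoreModel`; `attr(, "auc_table")` holds the per-CpG AUC
#'   ranking.
#' @export
train_score_model <- function(mat, labels, k = 20L,
                              threshold_mode = c("refit", "fixed"),
                              ridge = 1e-6) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(k >= 1)
  m <- if (inherits(mat, "MethylationMatrix")) mat$ratios else mat
  tab <- rank_cpgs_by_auc(m, labels)
  top <- head(tab$cpg_id, k)
  model <- fit_lda(m[, top, drop = FALSE], labels, ridge = ridge)
  if (threshold_mode == "refit") {
    s <- score_samples(model, m[, top, drop = FALSE])$score
    model$threshold <- choose_threshold(s, labels)
  } else {
    model$threshold <- oscc_score_threshold
  }
  model$provenance <- paste0(model$provenance, "; threshold_mode=",
                             threshold_mode)
  attr(model, "auc_table") <- tab
  model
}

#' Serialize / deserialize a score model as JSON
#'
#' Keys: `cpg_ids`, `coefficients`, `constant`, `threshold`,
#' `impute_means`, `provenance`. A threshold present in the file always
#' wins over the published default (reported via a message).
#'
#' @param model a `ScoreModel`.
#' @param path JSON path.
#' @return `write_score_model`: invisibly, `path`; `read_score_model`: a
#'   `ScoreModel`.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "ScoreModel"))
  jsonlite::write_json(
    list(cpg_ids = model$cpg_ids,
         coefficients = unname(model$coefficients),
         constant = model$constant, threshold = model$threshold,
         impute_means = unname(model$impute_means),
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- if (!is.null(x$threshold)) {
    if (!isTRUE(all.equal(x$threshold, oscc_score_threshold)))
      message("model file supplies its own threshold (",
              format(x$threshold, digits = 8), "); file wins")
    x$threshold
  } else oscc_score_threshold
  score_model(x$cpg_ids, x$coefficients, x$constant, thr,
              setNames(x$impute_means, x$cpg_ids),
              x$provenance %||% "")
}
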