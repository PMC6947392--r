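# Class-conditional methylation profiles and bisulfite read simulation.
#
# Only the bisulfite-converted top strand is simulated: locus-specific
# amplicon assays target one strand. CpG states are independent across
# positions and reads (the score uses marginal per-CpG ratios only).

#' Default class-conditional Beta parameters for simulated profiles
#'
#' For each sample class, `informative` and `background` are `c(alpha,
#' beta)` shape pairs of the Beta distribution of per-CpG methylation
#' levels. Tumor samples are hypermethylated at informative CpGs;
#' healthy mucosa is lowly methylated everywhere; `regenerative` is an
#' intermediate post-treatment state.
#'
#' @export
default_beta_params <- list(
  tumor        = list(informative = c(8, 2),  background = c(1, 9)),
  healthy      = list(informative = c(1, 12), background = c(1, 9)),
  regenerative = list(informative = c(3, 6),  background = c(1, 9))
)

#' Select the informative CpG subset of a panel
#'
#' Deterministically samples a fraction of the panel's CpGs to act as the
#' class-separating ("most informative") sites in simulations.
#'
#' @param panel an `AmpliconPanel`.
#' @param fraction fraction of CpGs that separate classes.
#' @param seed integer seed.
#' @return character vector of cpg_ids.
#' @export
select_informative <- function(panel, fraction = 0.15, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  ids <- panel$cpg_ids
  k <- max(1L, round(fraction * length(ids)))
  if (!length(ids)) return(character(0))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  sort(sample(ids, min(k, length(ids))))
}

#' Simulate a per-CpG methylation profile for one sample
#'
#' Informative CpGs draw their methylation level from the class's
#' informative Beta distribution; all remaining CpGs draw from the
#' background Beta.
#'
#' @param panel an `AmpliconPanel`.
#' @param class_label one of `"tumor"`, `"healthy"`, `"regenerative"`.
#' @param informative character vector of informative cpg_ids (see
#'   [select_informative()]); may be empty.
#' @param beta_params per-class Beta shape pairs, see
#'   [default_beta_params].
#' @param seed integer seed.
#' @param sample_id sample identifier.
#' @return A `MethylationProfile`: list with `sample_id`, `class_label`
#'   and `levels` (named numeric in \[0, 1\] over all panel CpGs).
#' @export
simulate_profile <- function(panel, class_label,
                             informative = character(0),
                             beta_params = default_beta_params,
                             seed = 1L, sample_id = "S1") {
  stopifnot(inherits(panel, "AmpliconPanel"))
  if (!class_label %in% names(beta_params))
    stop("unknown class label: ", class_label)
  bad <- setdiff(informative, panel$cpg_ids)
  if (length(bad)) stop("informative CpGs not in panel: ",
                        paste(head(bad, 3), collapse = ", "))
  par <- beta_params[[class_label]]
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ids <- panel$cpg_ids
  lev <- setNames(numeric(length(ids)), ids)
  is_inf <- ids %in% informative
  if (any(is_inf))
    lev[is_inf] <- rbeta(sum(is_inf), par$informative[1], par$informative[2])
  if (any(!is_inf))
    lev[!is_inf] <- rbeta(sum(!is_inf), par$background[1], par$background[2])
  structure(list(sample_id = sample_id, class_label = class_label,
                 levels = lev),
            class = "MethylationProfile")
}

#' Simulate bisulfite amplicon reads for one sample
#'
#' Emulates bisulfite chemistry on the top strand: a CpG cytosine stays
#' `C` with probability `m` (methylated, protected); otherwise, like every
#' non-CpG cytosine, it converts to `T` with probability
#' `conversion_efficiency`. Uniform substitution errors are applied after
#' conversion. Read ids carry ground truth as `"amplicon|index"`.
#'
#' @param panel an `AmpliconPanel`.
#' @param profile a `MethylationProfile` over the panel's CpGs.
#' @param depth reads per amplicon.
#' @param conversion_efficiency probability an unmethylated C reads as T.
#' @param error_rate per-base substitution error probability.
#' @param quality Phred value for every base (uniform quality string).
#' @param read_length read length; `NULL` (default) reads the whole
#'   amplicon, shorter reads start at uniform random offsets.
#' @param degraded_tail number of 3' bases whose quality is dropped to
#'   Phred 2 (exercises quality filtering); default 0.
#' @param seed integer seed.
#' @return data.frame of FASTQ records: `id`, `seq`, `qual` (class
#'   `fastq_records`).
#' @export
simulate_reads <- function(panel, profile, depth = 100L,
                           conversion_efficiency = 1, error_rate = 0,
                           quality = 37L, read_length = NULL,
                           degraded_tail = 0L, seed = 1L) {
  stopifnot(inherits(panel, "AmpliconPanel"),
            inherits(profile, "MethylationProfile"),
            depth >= 0, conversion_efficiency >= 0,
            conversion_efficiency <= 1, error_rate >= 0, error_rate <= 1)
  bad <- setdiff(names(profile$levels), panel$cpg_ids)
  if (length(bad))
    stop("profile references CpGs absent from panel: ",
         paste(head(bad, 3), collapse = ", "))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  out <- vector("list", length(panel$genes))
  bases <- c("A", "C", "G", "T")
  for (gi in seq_along(panel$genes)) {
    g <- panel$genes[gi]
    ref <- strsplit(panel$sequences[[g]], "")[[1]]
    L <- length(ref)
    rl <- if (is.null(read_length)) L else min(as.integer(read_length), L)
    if (depth == 0L) { out[[gi]] <- NULL; next }
    starts <- if (rl == L) rep(1L, depth)
              else sample.int(L - rl + 1L, depth, replace = TRUE)
    cpg_p <- panel$cpg_positions[[g]]           # 0-based C offsets
    m <- profile$levels[paste0(g, ":", cpg_p)]  # per-CpG methylation
    mat <- matrix(rep(ref, each = depth), nrow = depth)  # depth x L
    c_cols <- which(ref == "C")
    cpg_cols <- cpg_p + 1L
    for (j in c_cols) {
      if (j %in% cpg_cols) {
        mj <- m[[match(j, cpg_cols)]]
        meth <- runif(depth) < mj
        conv <- !meth & (runif(depth) < conversion_efficiency)
      } else {
        conv <- runif(depth) < conversion_efficiency
      }
      mat[conv, j] <- "T"
    }
    if (error_rate > 0) {
      hit <- which(runif(depth * L) < error_rate)
      if (length(hit)) {
        cur <- mat[hit]
        sub <- vapply(cur, function(b)
          sample(setdiff(bases, b), 1L), character(1))
        mat[hit] <- sub
      }
    }
    # clip to read windows
    seqs <- vapply(seq_len(depth), function(i)
      paste(mat[i, starts[i]:(starts[i] + rl - 1L)], collapse = ""),
      character(1))
    qual <- make_qual(rl, quality, degraded_tail)
    out[[gi]] <- data.frame(
      id = paste0(g, "|", seq_len(depth),
                  if (rl < L) paste0("|", starts - 1L) else ""),
      seq = seqs, qual = qual, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(id = character(0), seq = character(0),
                      qual = character(0))
  class(res) <- c("fastq_records", "data.frame")
  res
}

make_qual <- function(len, quality, degraded_tail = 0L) {
  q <- rep(as.integer(quality), len)
  if (degraded_tail > 0L) {
    k <- min(as.integer(degraded_tail), len)
    q[(len - k + 1L):len] <- 2L
  }
  paste(intToUtf8(q + 33L, multiple = TRUE), collapse = "")
}

#' Cohort simulation specification
#'
#' Defaults mirror the treated-OSCC cohort the analysis targets: 49
#' patients, 16/49 score-positive in the regenerative area, relapse hazard
#' ratio 15.02 for positives, uniform censoring on (0, 72\] months, and a
#' baseline hazard of 0.001 events/month giving roughly 15% cumulative
#' events.
#'
#' @param n_patients cohort size.
#' @param prop_score_positive fraction with a positive post-treatment
#'   score.
#' @param baseline_hazard events per month among score-negatives.
#' @param hazard_ratio_positive relapse hazard ratio for score-positives.
#' @param censor_time_max months; censoring is uniform on (0, max\].
#' @param covariate_prevalences named list of factor level probabilities.
#' @param seed integer seed.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(n_patients = 49L, prop_score_positive = 16 / 49,
                        baseline_hazard = 0.001,
                        hazard_ratio_positive = 15.02,
                        censor_time_max = 72,
                        covariate_prevalences = default_prevalences(),
                        seed = 1L) {
  stopifnot(n_patients >= 0, prop_score_positive >= 0,
            prop_score_positive <= 1, baseline_hazard > 0,
            hazard_ratio_positive > 0, censor_time_max > 0)
  structure(list(n_patients = as.integer(n_patients),
                 prop_score_positive = prop_score_positive,
                 baseline_hazard = baseline_hazard,
                 hazard_ratio_positive = hazard_ratio_positive,
                 censor_time_max = censor_time_max,
                 covariate_prevalences = covariate_prevalences,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# factor prevalences of the study population (counts out of 49)
default_prevalences <- function() list(
  sex = c(Male = 19, Female = 30) / 49,
  site = c(Tongue = 17, `Floor of mouth` = 1, Cheek = 4,
           `Superior gum/hard palate` = 7, `Inferior gum` = 19, Lip = 1) / 49,
  grade = c(G1 = 20, G2 = 21, G3 = 8) / 49,
  t_stage = c(`T1-2` = 28, `T3-4` = 21) / 49,
  n_positive = c(N0 = 42, `N+` = 7) / 49,
  perineural = c(No = 42, Yes = 7) / 49,
  vascular = c(No = 46, Yes = 3) / 49,
  margin = c(Clear = 45, Close = 3, Dysplasia = 1) / 49,
  opmd = c(No = 42, `Oral Lichen Planus` = 5, Leukoplakia = 2) / 49,
  radiotherapy = c(No = 27, Yes = 22) / 49,
  flap = c(No = 23, Yes = 26) / 49
)

#' Simulate a treated-cancer follow-up cohort
#'
#' Event times are exponential with hazard `baseline_hazard *
#' hazard_ratio_positive^(score_positive)`; censoring is uniform on
#' (0, `censor_time_max`\]; recorded time is the minimum with the event
#' flag set accordingly. Clinical covariates are drawn independently at
#' the configured prevalences; age is Normal(67.27, 11.56) truncated to
#' \[18, 95\].
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of clinical records: `patient_id`, the Table-2-style
#'   factors, `age`, `score_positive`, `time` (months > 0), `event`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$n_patients
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  empty <- data.frame(patient_id = character(0))
  if (n == 0L) {
    cols <- c("patient_id", names(spec$covariate_prevalences), "age",
              "score_positive", "time", "event")
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                 cols))
    return(df)
  }
  draw <- function(pr) {
    factor(sample(names(pr), n, replace = TRUE, prob = pr),
           levels = names(pr))
  }
  covs <- lapply(spec$covariate_prevalences, draw)
  age <- round(pmin(95, pmax(18, rnorm(n, 67.27, 11.56))))
  positive <- runif(n) < spec$prop_score_positive
  haz <- spec$baseline_hazard *
    ifelse(positive, spec$hazard_ratio_positive, 1)
  t_event <- rexp(n, rate = haz)
  t_cens <- runif(n, 0, spec$censor_time_max)
  t_cens <- pmax(t_cens, .Machine$double.eps)  # censoring in (0, max]
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n))),
        as.data.frame(covs, check.names = FALSE),
        data.frame(age = age, score_positive = positive,
                   time = time, event = event))
}

#' Simulate paired post-treatment methylation profiles for a cohort
#'
#' Score-positive patients receive a tumor-like regenerative profile
#' (informative CpGs hypermethylated); negatives receive a healthy-like
#' one.
#'
#' @param panel an `AmpliconPanel`.
#' @param cohort a cohort data.frame from [simulate_cohort()].
#' @param informative informative cpg_ids, see [select_informative()].
#' @param beta_params per-class Beta shapes, see [default_beta_params].
#' @param seed integer seed.
#' @return named list of `MethylationProfile`, one per patient.
#' @export
cohort_profiles <- function(panel, cohort,
                            informative = select_informative(panel),
                            beta_params = default_beta_params,
                            seed = 1L) {
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$patient_id
  for (i in seq_len(nrow(cohort))) {
    cls <- if (isTRUE(cohort$score_positive[i])) "tumor" else "healthy"
    out[[i]] <- simulate_profile(panel, cls, informative, beta_params,
                                 seed = seed + i,
                                 sample_id = cohort$patient_id[i])
  }
  out
}
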