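# Pipeline commands: simulate -> call -> train -> score -> survive,
# with a JSON config, manifest checksums and seed determinism.

#' Pipeline run configuration
#'
#' Defaults encode "paper mode": Q30 read filter, coverage floor 50,
#' 20-CpG score, 13-gene / 243-CpG panel, 49-patient cohort. The
#' `threshold_mode` is `"refit"` (Youden on the training scores) by
#' default because a freshly trained discriminant has its own scale;
#' `"fixed"` pins the published cut-off 1.0615547.
#'
#' @param seed integer master seed.
#' @param out_dir output directory for all stages.
#' @param n_genes,total_cpgs,amplicon_length panel geometry.
#' @param n_train_per_class training samples per class (tumor/healthy).
#' @param depth simulated reads per amplicon per sample.
#' @param conversion_efficiency,error_rate read chemistry knobs.
#' @param n_patients,hazard_ratio_positive,baseline_hazard,censor_time_max
#'   cohort simulation knobs (see [cohort_spec()]).
#' @param prop_score_positive fraction of score-positive patients.
#' @param q_threshold mean-Phred read filter (default 30).
#' @param min_coverage per-CpG coverage floor (default 50).
#' @param k_cpgs CpGs entering the score (default 20).
#' @param threshold_mode `"refit"` or `"fixed"`.
#' @param max_mismatch_rate assignment rejection rate.
#' @return a `RunConfig` list.
#' @export
run_config <- function(seed = 1L, out_dir = "methbrush_run",
                       n_genes = 13L, total_cpgs = 243L,
                       amplicon_length = 300L, n_train_per_class = 20L,
                       depth = 80L, conversion_efficiency = 0.995,
                       error_rate = 0.001, n_patients = 49L,
                       prop_score_positive = 16 / 49,
                       hazard_ratio_positive = 15.02,
                       baseline_hazard = 0.001, censor_time_max = 72,
                       q_threshold = 30, min_coverage = 50L,
                       k_cpgs = 20L,
                       threshold_mode = c("refit", "fixed"),
                       max_mismatch_rate = 0.1) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              n_genes = as.integer(n_genes),
              total_cpgs = as.integer(total_cpgs),
              amplicon_length = as.integer(amplicon_length),
              n_train_per_class = as.integer(n_train_per_class),
              depth = as.integer(depth),
              conversion_efficiency = conversion_efficiency,
              error_rate = error_rate,
              n_patients = as.integer(n_patients),
              prop_score_positive = prop_score_positive,
              hazard_ratio_positive = hazard_ratio_positive,
              baseline_hazard = baseline_hazard,
              censor_time_max = censor_time_max,
              q_threshold = q_threshold,
              min_coverage = as.integer(min_coverage),
              k_cpgs = as.integer(k_cpgs),
              threshold_mode = match.arg(threshold_mode),
              max_mismatch_rate = max_mismatch_rate)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read / write a run configuration as JSON
#' @param path JSON path.
#' @param cfg a `RunConfig`.
#' @return `read_run_config`: a `RunConfig`; `write_run_config`:
#'   invisibly, `path`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pipe_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

log_msg <- function(...) message("[methbrush] ", ...)

write_manifest <- function(cfg, files, name = "manifest.json") {
  files <- files[file.exists(files)]
  sums <- tools::md5sum(files)
  jsonlite::write_json(
    list(config = unclass(cfg),
         checksums = as.list(setNames(unname(sums), basename(files)))),
    pipe_path(cfg, name), auto_unbox = TRUE, digits = NA)
}

#' Simulate panel, reads and cohort to disk
#'
#' Writes the panel FASTA + CpG sidecar, one FASTQ per sample (training
#' tumor/healthy samples plus one post-treatment sample per cohort
#' patient), the cohort CSV, a sample sheet and a manifest with md5
#' checksums. Reruns with the same config are byte-identical.
#'
#' @param cfg a [run_config()].
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the output directory.
#' @export
cmd_simulate <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (dir.exists(cfg$out_dir) &&
      length(dir(cfg$out_dir, all.files = FALSE)) && !force)
    stop("output directory ", cfg$out_dir,
         " is not empty; use force = TRUE to overwrite")
  dir.create(pipe_path(cfg, "reads"), recursive = TRUE,
             showWarnings = FALSE)
  panel <- generate_panel(cfg$n_genes, cfg$total_cpgs,
                          cfg$amplicon_length, seed = cfg$seed)
  write_panel(panel, pipe_path(cfg, "panel.fasta"),
              pipe_path(cfg, "panel_cpgs.tsv"))
  informative <- select_informative(panel, seed = cfg$seed)

  sheet <- list()
  fq <- character(0)
  emit <- function(profile, sample_id) {
    rec <- simulate_reads(panel, profile, depth = cfg$depth,
                          conversion_efficiency = cfg$conversion_efficiency,
                          error_rate = cfg$error_rate,
                          seed = seed_for(cfg$seed, sample_id))
    p <- pipe_path(cfg, "reads", paste0(sample_id, ".fastq"))
    write_fastq(rec, p)
    p
  }
  for (cls in c("tumor", "healthy")) {
    for (i in seq_len(cfg$n_train_per_class)) {
      sid <- sprintf("train_%s_%02d", cls, i)
      prof <- simulate_profile(panel, cls, informative,
                               seed = seed_for(cfg$seed, sid),
                               sample_id = sid)
      fq <- c(fq, emit(prof, sid))
      sheet[[length(sheet) + 1]] <-
        data.frame(sample_id = sid, role = "train", class_label = cls,
                   patient_id = NA_character_)
    }
  }
  spec <- cohort_spec(n_patients = cfg$n_patients,
                      prop_score_positive = cfg$prop_score_positive,
                      baseline_hazard = cfg$baseline_hazard,
                      hazard_ratio_positive = cfg$hazard_ratio_positive,
                      censor_time_max = cfg$censor_time_max,
                      seed = cfg$seed)
  cohort <- simulate_cohort(spec)
  write.csv(cohort, pipe_path(cfg, "cohort.csv"), row.names = FALSE)
  if (nrow(cohort)) {
    profs <- cohort_profiles(panel, cohort, informative,
                             seed = cfg$seed + 1000L)
    for (pid in names(profs)) {
      fq <- c(fq, emit(profs[[pid]], pid))
      sheet[[length(sheet) + 1]] <-
        data.frame(sample_id = pid, role = "cohort",
                   class_label = profs[[pid]]$class_label,
                   patient_id = pid)
    }
  }
  sheet <- do.call(rbind, sheet)
  write.csv(sheet, pipe_path(cfg, "samples.csv"), row.names = FALSE)
  write_manifest(cfg, c(pipe_path(cfg, c("panel.fasta", "panel_cpgs.tsv",
                                         "cohort.csv", "samples.csv")),
                        fq))
  log_msg("simulated ", length(fq), " samples, panel of ",
          n_cpgs(panel), " CpGs")
  invisible(cfg$out_dir)
}

# deterministic small sub-seed from a master seed and a sample label
seed_for <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  (as.integer(seed) * 1009L + h) %% 2000000000L
}

#' Call methylation for every simulated sample
#'
#' Quality-filters, assigns and calls each FASTQ under `reads/`, writing
#' the ratio and coverage TSV twins plus a per-sample QC JSON (reads in /
#' kept / assigned).
#'
#' @param cfg a [run_config()] whose `cmd_simulate` outputs exist.
#' @return invisibly, the `MethylationMatrix`.
#' @export
cmd_call <- function(cfg) {
  panel <- read_panel(pipe_path(cfg, "panel.fasta"),
                      pipe_path(cfg, "panel_cpgs.tsv"))
  fq <- sort(dir(pipe_path(cfg, "reads"),
                 pattern = "\\.fastq(\\.gz)?$", full.names = TRUE))
  if (!length(fq)) stop("no FASTQ files under ", pipe_path(cfg, "reads"))
  rows <- list(); qc <- list()
  total_assigned <- 0
  for (f in fq) {
    sid <- sub("\\.fastq(\\.gz)?$", "", basename(f))
    rec <- read_fastq(f)
    kept <- quality_filter(rec, cfg$q_threshold)
    al <- align_sample(kept, panel, cfg$max_mismatch_rate)
    rows[[sid]] <- call_methylation(al, panel, cfg$min_coverage, sid)
    qc[[sid]] <- list(n_in = nrow(rec), n_kept = nrow(kept),
                      n_assigned = sum(al$assigned))
    total_assigned <- total_assigned + sum(al$assigned)
  }
  if (total_assigned == 0)
    stop("zero assignable reads across all samples")
  mat <- bind_samples(rows)
  write_meth_matrix(mat, pipe_path(cfg, "methylation.tsv"),
                    pipe_path(cfg, "coverage.tsv"))
  jsonlite::write_json(qc, pipe_path(cfg, "qc.json"), auto_unbox = TRUE)
  log_msg("called ", length(rows), " samples, ",
          sum(is.na(mat$ratios)), " missing ratios")
  invisible(mat)
}

#' Train the score model from the called training samples
#'
#' @param cfg a [run_config()].
#' @return invisibly, the `ScoreModel` (also written to `model.json`
#'   with the per-CpG AUC table in `auc_table.tsv`).
#' @export
cmd_train <- function(cfg) {
  mat <- read_meth_matrix(pipe_path(cfg, "methylation.tsv"),
                          pipe_path(cfg, "coverage.tsv"))
  sheet <- read.csv(pipe_path(cfg, "samples.csv"))
  tr <- sheet[sheet$role == "train", ]
  sub <- methylation_matrix(
    mat$ratios[tr$sample_id, , drop = FALSE],
    mat$coverage[tr$sample_id, , drop = FALSE])
  model <- train_score_model(sub, tr$class_label == "tumor",
                             k = cfg$k_cpgs,
                             threshold_mode = cfg$threshold_mode)
  write_score_model(model, pipe_path(cfg, "model.json"))
  write.table(attr(model, "auc_table"), pipe_path(cfg, "auc_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("trained ", length(model$cpg_ids), "-CpG model, threshold ",
          format(model$threshold, digits = 6))
  invisible(model)
}

#' Score all called samples against the trained model
#'
#' @param cfg a [run_config()].
#' @return invisibly, the [classify_cohort()] result (also written to
#'   `scores.csv`).
#' @export
cmd_score <- function(cfg) {
  model <- read_score_model(pipe_path(cfg, "model.json"))
  mat <- read_meth_matrix(pipe_path(cfg, "methylation.tsv"),
                          pipe_path(cfg, "coverage.tsv"))
  missing_cpgs <- setdiff(model$cpg_ids, colnames(mat$ratios))
  if (length(missing_cpgs))
    stop("matrix lacks model CpGs: ",
         paste(head(missing_cpgs, 5), collapse = ", "))
  res <- classify_cohort(model, mat)
  write.csv(res$scores, pipe_path(cfg, "scores.csv"), row.names = FALSE)
  log_msg(res$summary$n_positive, "/", res$summary$n, " positive (",
          res$summary$pct_positive, "%)")
  invisible(res)
}

#' Survival analysis of the scored cohort
#'
#' Merges the computed positivity calls into the cohort, estimates
#' Kaplan-Meier curves by score status with the log-rank test, runs
#' bidirectional stepwise Cox selection over the clinical candidates plus
#' score positivity, and checks proportional hazards (Schoenfeld). The
#' report is written to `survival.json`, per-group KM curves to
#' `km_<group>.tsv`, and a Table-2-style factor summary to
#' `factor_summary.csv`.
#'
#' @param cfg a [run_config()].
#' @param candidates candidate covariates for stepwise selection.
#' @return invisibly, the report list.
#' @export
cmd_survive <- function(cfg,
                        candidates = c("score_called", "sex", "grade",
                                       "t_stage", "perineural",
                                       "vascular")) {
  cohort <- read.csv(pipe_path(cfg, "cohort.csv"))
  if (!nrow(cohort)) stop("empty cohort")
  scores <- read.csv(pipe_path(cfg, "scores.csv"))
  cohort$score_called <-
    scores$positive[match(cohort$patient_id, scores$sample_id)]
  km <- km_by_group(cohort$time, cohort$event,
                    ifelse(cohort$score_called, "positive", "negative"))
  for (gname in names(km$curves))
    write.table(km$curves[[gname]],
                pipe_path(cfg, paste0("km_", gname, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  lr <- km$logrank
  if (is.null(lr) || !any(cohort$event)) {
    lr <- list(chi2 = NA_real_, p = NA_real_, defined = FALSE)
    warning("log-rank undefined for this cohort")
  }
  sel <- stepwise_select(cohort, candidates)
  sch <- if (!is.null(sel$model) &&
             sum(cohort$event) > ncol(sel$model$X))
    schoenfeld_global_test(sel$model) else
    list(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
  fac <- lapply(intersect(c("sex", "grade", "t_stage", "perineural",
                            "vascular", "score_called"), names(cohort)),
                function(v) {
    ca <- tryCatch(contingency_analysis(cohort, v, "event"),
                   error = function(e) NULL)
    if (is.null(ca)) return(NULL)
    data.frame(factor = v, level = rownames(ca$table),
               n = as.integer(rowSums(ca$table)),
               pct_event = as.numeric(ca$percent), p = ca$p)
  })
  fac <- do.call(rbind, fac)
  write.csv(fac, pipe_path(cfg, "factor_summary.csv"), row.names = FALSE)
  report <- list(
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    cox_terms = if (is.null(sel$model)) list() else sel$model$table,
    selected = sel$selected,
    schoenfeld_chi2 = sch$chi2, schoenfeld_p = sch$p)
  jsonlite::write_json(report, pipe_path(cfg, "survival.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_msg("log-rank chi2 ", format(lr$chi2, digits = 5),
          "; selected: ", paste(sel$selected, collapse = ", "))
  invisible(report)
}

#' Run the full pipeline
#' @param cfg a [run_config()].
#' @param force passed to [cmd_simulate()].
#' @return invisibly, the survival report.
#' @export
run_all <- function(cfg, force = FALSE) {
  cmd_simulate(cfg, force = force)
  cmd_call(cfg)
  cmd_train(cfg)
  cmd_score(cfg)
  invisible(cmd_survive(cfg))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `call`, `train`, `score`, `survive`,
#' `run-all`. Flags: `--config <json>` (otherwise defaults), `--out
#' <dir>`, `--seed <int>`, `--force`.
#'
#' @param args character vector, default `commandArgs(trailingOnly =
#'   TRUE)`.
#' @return invisibly, the subcommand's result.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: methbrush <simulate|call|train|score|survive|run-all> ",
         "[--config cfg.json] [--out dir] [--seed n] [--force]")
  cmd <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else NULL
  }
  cfg <- if (!is.null(opt("--config"))) read_run_config(opt("--config"))
         else run_config()
  if (!is.null(opt("--out"))) cfg$out_dir <- opt("--out")
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  force <- "--force" %in% args
  res <- switch(cmd,
    simulate = cmd_simulate(cfg, force = force),
    call = cmd_call(cfg),
    train = cmd_train(cfg),
    score = cmd_score(cfg),
    survive = cmd_survive(cfg),
    `run-all` = run_all(cfg, force = force),
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
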