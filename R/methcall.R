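# Native methylation-ratio calling from bisulfite amplicon FASTQ:
# quality filter, in-silico converted reference, ungapped assignment,
# per-CpG C/T counting.

#' Read a FASTQ file into a records data.frame
#'
#' @param path FASTQ path, plain or gzipped.
#' @return data.frame with `id`, `seq`, `qual` (class `fastq_records`).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  res <- data.frame(id = names(x), seq = as.character(x),
                    qual = as.character(S4Vectors::mcols(x)$qualities),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("fastq_records", "data.frame")
  res
}

#' Write FASTQ records to disk
#'
#' @param records a `fastq_records` data.frame (`id`, `seq`, `qual`).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(records, path) {
  dna <- Biostrings::DNAStringSet(records$seq)
  names(dna) <- records$id
  Biostrings::writeXStringSet(
    dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(records$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Mean Phred quality of each read
#' @param records `fastq_records`.
#' @return numeric vector of per-read mean Phred scores.
#' @export
mean_phred <- function(records) {
  vapply(records$qual,
         function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Quality-filter reads on mean Phred score
#'
#' Retains exactly the reads whose mean Phred score is strictly greater
#' than `q_threshold` (the "> Q30" convention: a read at uniform Q30 is
#' discarded). Order is preserved; kept/discarded counts are attached as
#' the `"qc"` attribute.
#'
#' @param records `fastq_records`.
#' @param q_threshold Phred threshold, default 30.
#' @return filtered `fastq_records`; `attr(, "qc")` holds `n_in`,
#'   `n_kept`, `n_discarded`.
#' @export
quality_filter <- function(records, q_threshold = 30) {
  bad <- nchar(records$seq) != nchar(records$qual)
  if (any(bad))
    stop("malformed FASTQ record (sequence/quality length mismatch): ",
         records$id[which(bad)[1]])
  keep <- mean_phred(records) > q_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fastq_records", "data.frame")
  attr(out, "qc") <- list(n_in = nrow(records), n_kept = sum(keep),
                          n_discarded = sum(!keep))
  out
}

#' In-silico bisulfite conversion of the panel reference
#'
#' Replaces every `C` with `T` in each amplicon sequence (full conversion
#' of the top strand); CpG coordinates are unchanged (identity position
#' map).
#'
#' @param panel an `AmpliconPanel`.
#' @return list with `sequences` (converted, named by gene) and
#'   `cpg_positions` (identical to the panel's).
#' @export
convert_reference <- function(panel) {
  stopifnot(inherits(panel, "AmpliconPanel"))
  list(sequences = vapply(panel$sequences, gsub, character(1),
                          pattern = "C", replacement = "T", fixed = TRUE),
       cpg_positions = panel$cpg_positions)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assign reads to panel amplicons by ungapped converted-space comparison
#'
#' Each read is C-to-T collapsed and slid over every converted amplicon;
#' the placement with the fewest mismatches wins, with CpG positions
#' excluded from the mismatch count (a methylated C over a converted-T
#' reference is signal, not error). Both orientations are tried (the
#' reverse complement is re-oriented before collapsing); an orientation or
#' cross-amplicon tie at the best score leaves the read unassigned. Reads
#' whose best mismatch rate exceeds `max_mismatch_rate` are unassigned.
#'
#' @param records `fastq_records` for one sample.
#' @param panel an `AmpliconPanel` (non-empty).
#' @param max_mismatch_rate maximum tolerated mismatches / read length.
#' @return data.frame (class `aligned_reads`): `id`, `amplicon`, `offset`
#'   (0-based), `mismatches`, `assigned`, `orientation` (`"+"`/`"-"`),
#'   `seq` (the read re-oriented to the top strand; original bases).
#' @export
align_sample <- function(records, panel, max_mismatch_rate = 0.1) {
  stopifnot(inherits(panel, "AmpliconPanel"))
  if (!length(panel$genes)) stop("panel is empty")
  conv <- convert_reference(panel)
  masks <- lapply(panel$genes, function(g) {
    L <- nchar(panel$sequences[[g]])
    m <- rep(FALSE, L)
    m[panel$cpg_positions[[g]] + 1L] <- TRUE
    m
  })
  n <- nrow(records)
  if (n == 0L) {
    return(structure(data.frame(id = character(0), amplicon = character(0),
                                offset = integer(0), mismatches = integer(0),
                                assigned = logical(0),
                                orientation = character(0),
                                seq = character(0)),
                     class = c("aligned_reads", "data.frame")))
  }
  collapse <- function(s) gsub("C", "T", s, fixed = TRUE)
  fwd <- .cpp_assign_reads(collapse(records$seq), unname(conv$sequences),
                           masks, max_mismatch_rate)
  rc <- revcomp(records$seq)
  rev <- .cpp_assign_reads(collapse(rc), unname(conv$sequences),
                           masks, max_mismatch_rate)
  pick_rev <- logical(n)
  assigned <- logical(n)
  amp <- integer(n); off <- integer(n); mm <- integer(n)
  for (i in seq_len(n)) {
    f_ok <- fwd[i, 1] > 0L
    r_ok <- rev[i, 1] > 0L
    if (f_ok && r_ok) {
      if (fwd[i, 3] == rev[i, 3]) { assigned[i] <- FALSE; next }
      pick_rev[i] <- rev[i, 3] < fwd[i, 3]
    } else if (r_ok) pick_rev[i] <- TRUE
    else if (!f_ok) { assigned[i] <- FALSE; next }
    src <- if (pick_rev[i]) rev else fwd
    assigned[i] <- TRUE
    amp[i] <- src[i, 1]; off[i] <- src[i, 2]; mm[i] <- src[i, 3]
  }
  res <- data.frame(
    id = records$id,
    amplicon = ifelse(assigned, panel$genes[pmax(amp, 1L)], NA_character_),
    offset = ifelse(assigned, off, NA_integer_),
    mismatches = ifelse(assigned, mm, NA_integer_),
    assigned = assigned,
    orientation = ifelse(assigned, ifelse(pick_rev, "-", "+"),
                         NA_character_),
    seq = ifelse(pick_rev, rc, records$seq),
    stringsAsFactors = FALSE)
  class(res) <- c("aligned_reads", "data.frame")
  res
}

#' Construct a methylation matrix
#'
#' @param ratios numeric matrix, samples x CpGs, values in \[0, 1\] or NA.
#' @param coverage integer matrix of C+T call counts, same shape.
#' @return a `MethylationMatrix` (list of the two matrices).
#' @export
methylation_matrix <- function(ratios, coverage) {
  stopifnot(is.matrix(ratios), is.matrix(coverage),
            all(dim(ratios) == dim(coverage)))
  ok <- is.na(ratios) | (ratios >= 0 & ratios <= 1)
  if (!all(ok)) stop("methylation ratios must lie in [0, 1]")
  structure(list(ratios = ratios, coverage = coverage),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat("MethylationMatrix:", nrow(x$ratios), "samples x",
      ncol(x$ratios), "CpGs;", sum(is.na(x$ratios)), "missing\n")
  invisible(x)
}

#' Call per-CpG methylation ratios for one sample
#'
#' For every panel CpG covered by an assigned read, the original read base
#' at the CpG's C is counted: `C` as methylated, `T` as unmethylated, any
#' other base ignored. The ratio is #C / (#C + #T); CpGs whose denominator
#' is below `min_coverage` are reported missing (`NA`) but keep their
#' coverage count.
#'
#' @param aligned `aligned_reads` from [align_sample()] (one sample).
#' @param panel the `AmpliconPanel`.
#' @param min_coverage minimum C+T calls for a ratio, default 50.
#' @param sample_id row label.
#' @return one-row `MethylationMatrix` over all panel CpGs.
#' @export
call_methylation <- function(aligned, panel, min_coverage = 50L,
                             sample_id = "S1") {
  stopifnot(inherits(panel, "AmpliconPanel"))
  ids <- panel$cpg_ids
  c_cnt <- setNames(integer(length(ids)), ids)
  t_cnt <- setNames(integer(length(ids)), ids)
  use <- aligned[aligned$assigned, , drop = FALSE]
  if (!nrow(use))
    warning("zero aligned reads for sample ", sample_id,
            "; all ratios missing")
  for (g in unique(use$amplicon)) {
    sub <- use[use$amplicon == g, , drop = FALSE]
    rl <- nchar(sub$seq)
    for (p in panel$cpg_positions[[g]]) {
      col <- p - sub$offset + 1L           # 1-based index into the read
      inside <- col >= 1L & col <= rl
      if (!any(inside)) next
      b <- substring(sub$seq[inside], col[inside], col[inside])
      key <- paste0(g, ":", p)
      c_cnt[key] <- c_cnt[key] + sum(b == "C")
      t_cnt[key] <- t_cnt[key] + sum(b == "T")
    }
  }
  cov <- c_cnt + t_cnt
  ratio <- ifelse(cov >= min_coverage, c_cnt / pmax(cov, 1L), NA_real_)
  methylation_matrix(matrix(ratio, nrow = 1,
                            dimnames = list(sample_id, ids)),
                     matrix(as.integer(cov), nrow = 1,
                            dimnames = list(sample_id, ids)))
}

#' Stack per-sample methylation rows into one matrix
#' @param rows list of one-row `MethylationMatrix` objects sharing CpGs.
#' @return combined `MethylationMatrix`.
#' @export
bind_samples <- function(rows) {
  stopifnot(length(rows) > 0)
  methylation_matrix(do.call(rbind, lapply(rows, `[[`, "ratios")),
                     do.call(rbind, lapply(rows, `[[`, "coverage")))
}

#' Write / read a methylation matrix as TSV twins
#'
#' Ratios and coverage are written as tab-separated tables (rows samples,
#' columns CpG ids, missing ratios as `NA`).
#'
#' @param mat a `MethylationMatrix`.
#' @param ratio_path,coverage_path output TSV paths.
#' @return invisibly, the paths.
#' @export
write_meth_matrix <- function(mat, ratio_path, coverage_path) {
  wr <- function(m, p) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(mat$ratios, ratio_path)
  wr(mat$coverage, coverage_path)
  invisible(c(ratio_path, coverage_path))
}

#' @rdname write_meth_matrix
#' @export
read_meth_matrix <- function(ratio_path, coverage_path) {
  rd <- function(p) {
    df <- read.delim(p, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  methylation_matrix(rd(ratio_path), rd(coverage_path))
}

#' Duplicate-assay reliability by linear regression
#'
#' Ordinary least-squares of duplicate-2 values on duplicate-1 values
#' (per-sample scores, or per-sample mean methylation when matrices are
#' given); returns the coefficient of determination and the slope-test
#' p-value.
#'
#' @param a,b paired per-sample numeric vectors, or two
#'   `MethylationMatrix` objects with identical sample ordering (their
#'   per-sample mean ratios are compared).
#' @return list: `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
assay_reliability <- function(a, b) {
  as_vec <- function(x) {
    if (inherits(x, "MethylationMatrix"))
      rowMeans(x$ratios, na.rm = TRUE)
    else as.numeric(x)
  }
  x <- as_vec(a); y <- as_vec(b)
  if (length(x) != length(y)) stop("duplicate vectors differ in length")
  if (length(x) < 3) stop("need at least 3 duplicate pairs for regression")
  if (isTRUE(all.equal(var(x), 0)) || var(x) == 0)
    stop("degenerate duplicates: duplicate-1 values are constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["x", "Pr(>|t|)"],
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}
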