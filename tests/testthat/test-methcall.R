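test_that("quality_filter applies the strict > Q30 rule", {
  mk <- function(n, q) data.frame(
    id = paste0("r", seq_len(n)), seq = strrep("ACGT", 5),
    qual = strrep(intToUtf8(q + 33), 20), stringsAsFactors = FALSE)
  all37 <- quality_filter(mk(10, 37))
  expect_equal(nrow(all37), 10)
  # a read at uniform Q30 has mean exactly 30: discarded
  all30 <- quality_filter(mk(10, 30))
  expect_equal(nrow(all30), 0)
  expect_equal(attr(all30, "qc")$n_discarded, 10)
})

test_that("quality_filter kept-count matches a brute-force mean recomputation", {
  set.seed(13)
  n <- 100
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    len <- sample(30:60, 1)
    q <- sample(20:40, len, replace = TRUE)
    data.frame(id = paste0("r", i),
               seq = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                           collapse = ""),
               qual = intToUtf8(q + 33), stringsAsFactors = FALSE)
  }))
  kept <- quality_filter(recs, 30)
  oracle <- vapply(recs$qual, function(q) mean(utf8ToInt(q) - 33) > 30,
                   logical(1))
  expect_equal(nrow(kept), sum(oracle))
  expect_identical(kept$id, recs$id[oracle])  # order preserved
  bad <- recs; bad$qual[7] <- substr(bad$qual[7], 1, 5)
  expect_error(quality_filter(bad), "r7")
})

test_that("convert_reference strips every C and keeps coordinates", {
  p <- amplicon_panel("g", "ACGT", list(1L))
  expect_equal(unname(convert_reference(p)$sequences), "ATGT")
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  s <- gsub("CG", "CA", s)  # no CpGs, simpler
  p2 <- amplicon_panel("h", s, list(integer(0)))
  cv <- convert_reference(p2)$sequences[[1]]
  expect_equal(lengths(regmatches(cv, gregexpr("C", cv)))[[1]], 0)
  expect_equal(nchar(cv), nchar(s))
  p3 <- amplicon_panel("k", "ATTGGA", list(integer(0)))
  expect_equal(unname(convert_reference(p3)$sequences), "ATTGGA")
})

test_that("assignment recovers the simulator's truth tags", {
  p <- tiny_panel()
  inf <- select_informative(p, 0.3, seed = 1)
  pr <- simulate_profile(p, "tumor", inf, seed = 2)
  r <- simulate_reads(p, pr, depth = 40, conversion_efficiency = 1,
                      error_rate = 0, seed = 3)
  al <- align_sample(r, p)
  expect_true(all(al$assigned))
  expect_identical(al$amplicon, sub("\\|.*", "", r$id))
  expect_true(all(al$offset == 0))
  # with 1% error, accuracy still exceeds 99%
  r2 <- simulate_reads(p, pr, depth = 100, conversion_efficiency = 1,
                       error_rate = 0.01, seed = 4)
  al2 <- align_sample(r2, p)
  acc <- mean(al2$assigned & al2$amplicon == sub("\\|.*", "", r2$id))
  expect_gt(acc, 0.99)
})

test_that("unrelated and ambiguous reads are rejected", {
  p <- tiny_panel()
  set.seed(6)
  junk <- data.frame(
    id = "junk",
    seq = paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
    qual = strrep("F", 80), stringsAsFactors = FALSE)
  al <- align_sample(junk, p, max_mismatch_rate = 0.1)
  expect_false(any(al$assigned))
  # identical amplicons force a cross-amplicon tie -> unassigned
  dup <- amplicon_panel(c("d1", "d2"),
                        rep(p$sequences[[1]], 2),
                        rep(p$cpg_positions[1], 2))
  probe <- data.frame(id = "t", seq = p$sequences[[1]],
                      qual = strrep("F", nchar(p$sequences[[1]])),
                      stringsAsFactors = FALSE)
  expect_false(any(align_sample(probe, dup)$assigned))
})

test_that("methylation mismatches are masked during assignment", {
  # fully methylated error-free read differs from the converted
  # reference only at CpG positions; those are tolerated
  p <- tiny_panel()
  g <- p$genes[1]
  pr <- structure(list(sample_id = "s", class_label = "tumor",
                       levels = setNames(rep(1, n_cpgs(p)), p$cpg_ids)),
                  class = "MethylationProfile")
  r <- simulate_reads(p, pr, depth = 3, conversion_efficiency = 1,
                      error_rate = 0, seed = 5)
  al <- align_sample(r, p)
  expect_true(all(al$assigned))
  expect_true(all(al$mismatches == 0))
  # per-position oracle: collapsed read vs converted reference differs
  # exactly at the declared CpG positions before collapsing
  conv <- convert_reference(p)$sequences[[g]]
  rd <- r$seq[r$id == paste0(g, "|1")]
  diff_pos <- which(strsplit(rd, "")[[1]] != strsplit(conv, "")[[1]])
  expect_identical(diff_pos - 1L, p$cpg_positions[[g]])
})

test_that("reverse-complemented reads are re-oriented before assignment", {
  p <- tiny_panel()
  pr <- simulate_profile(p, "tumor", select_informative(p, 0.3, 1),
                         seed = 7)
  r <- simulate_reads(p, pr, depth = 10, seed = 8)
  flip <- seq(1, nrow(r), by = 2)
  rc <- r
  rc$seq[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r$seq[flip])))
  al <- align_sample(rc, p)
  expect_true(all(al$assigned))
  expect_identical(al$amplicon, sub("\\|.*", "", r$id))
  expect_true(all(al$orientation[flip] == "-"))
  expect_identical(al$seq, r$seq)  # original top-strand bases restored
})

test_that("call_methylation counts C/T calls per CpG", {
  p <- amplicon_panel("g", "AACGTT", list(2L))
  mk_read <- function(base, i) data.frame(
    id = paste0("g|", i), amplicon = "g", offset = 0L, mismatches = 0L,
    assigned = TRUE, orientation = "+",
    seq = paste0("AA", base, "GTT"), stringsAsFactors = FALSE)
  aligned <- do.call(rbind, c(lapply(1:10, function(i) mk_read("C", i))))
  m1 <- call_methylation(aligned, p, min_coverage = 5)
  expect_equal(unname(m1$ratios[1, 1]), 1.0)
  aligned2 <- do.call(rbind, c(lapply(1:3, function(i) mk_read("C", i)),
                               lapply(4:10, function(i) mk_read("T", i))))
  m2 <- call_methylation(aligned2, p, min_coverage = 5)
  expect_equal(unname(m2$ratios[1, 1]), 0.3)
  expect_equal(unname(m2$coverage[1, 1]), 10L)
  # non-C/T calls excluded from numerator and denominator
  aligned3 <- rbind(aligned2, mk_read("A", 11))
  m3 <- call_methylation(aligned3, p, min_coverage = 5)
  expect_equal(unname(m3$ratios[1, 1]), 0.3)
  expect_equal(unname(m3$coverage[1, 1]), 10L)
  # below coverage floor -> missing, coverage kept
  m4 <- call_methylation(aligned2, p, min_coverage = 11)
  expect_true(is.na(m4$ratios[1, 1]))
  expect_equal(unname(m4$coverage[1, 1]), 10L)
  expect_warning(
    m0 <- call_methylation(aligned[0, ], p, min_coverage = 5),
    "zero aligned reads")
  expect_true(all(is.na(m0$ratios)))
})

test_that("caller conserves counts, ignores read order, is coverage-monotone", {
  p <- tiny_panel()
  pr <- simulate_profile(p, "regenerative", select_informative(p, 0.3, 1),
                         seed = 9)
  r <- simulate_reads(p, pr, depth = 60, conversion_efficiency = 0.98,
                      error_rate = 0.005, seed = 10)
  al <- align_sample(r, p)
  m <- call_methylation(al, p, min_coverage = 10)
  # ratio * coverage reproduces an integer C count
  cc <- m$ratios * m$coverage
  expect_true(all(abs(cc - round(cc)) < 1e-9, na.rm = TRUE))
  # read order invariance
  set.seed(1); perm <- sample(nrow(r))
  m_perm <- call_methylation(align_sample(r[perm, ], p), p,
                             min_coverage = 10)
  expect_equal(m$ratios, m_perm$ratios)
  expect_equal(m$coverage, m_perm$coverage)
  # raising min_coverage only changes missingness
  m_hi <- call_methylation(al, p, min_coverage = 40)
  both <- !is.na(m$ratios) & !is.na(m_hi$ratios)
  expect_equal(m$ratios[both], m_hi$ratios[both])
  expect_true(all(is.na(m_hi$ratios[m_hi$coverage < 40])))
})

test_that("simulate -> call round trip recovers the profile (binomial CI)", {
  p <- generate_panel(1, 4, 80, seed = 3, gene_names = "g")
  m_true <- c(0.1, 0.35, 0.6, 0.9)
  pr <- structure(list(sample_id = "s", class_label = "tumor",
                       levels = setNames(m_true, p$cpg_ids)),
                  class = "MethylationProfile")
  depth <- 2000
  r <- simulate_reads(p, pr, depth = depth, conversion_efficiency = 1,
                      error_rate = 0, seed = 4)
  mm <- call_methylation(align_sample(r, p), p, min_coverage = 50)
  for (j in seq_along(m_true))
    expect_lt(abs(mm$ratios[1, j] - m_true[j]),
              3 * sqrt(m_true[j] * (1 - m_true[j]) / depth))
})

test_that("FASTQ writing/reading round trips, gzip included", {
  p <- tiny_panel()
  pr <- simulate_profile(p, "tumor", character(0), seed = 1)
  r <- simulate_reads(p, pr, depth = 5, seed = 2)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq.gz")
  write_fastq(r, f1); write_fastq(r, f2)
  r1 <- read_fastq(f1); r2 <- read_fastq(f2)
  expect_equal(r1$seq, r$seq)
  expect_equal(r1$qual, r$qual)
  expect_equal(r1, r2)
})

test_that("assay_reliability returns OLS R^2 and flags degeneracy", {
  expect_equal(assay_reliability(1:10, 1:10)$r_squared, 1.0)
  expect_error(assay_reliability(1:2, 1:2), "at least 3")
  expect_error(assay_reliability(rep(1, 5), rnorm(5)), "constant")
  # Monte-Carlo oracle: y = x + noise, theoretical R^2 = v_x/(v_x+v_e)
  set.seed(31)
  r2s <- replicate(200, {
    x <- rnorm(10, sd = 1)
    y <- x + rnorm(10, sd = 0.5)
    assay_reliability(x, y)$r_squared
  })
  theo <- 1 / (1 + 0.25)
  expect_lt(abs(mean(r2s) - theo), 3 * sd(r2s) / sqrt(200) + 0.02)
})
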