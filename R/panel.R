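# Amplicon panel: reference sequences plus declared CpG coordinates.
# CpG offsets are 0-based positions of the C of each CpG dinucleotide;
# the site occupies the half-open interval [offset, offset + 2).

#' Construct an amplicon panel object
#'
#' @param genes character vector of amplicon (gene) names, unique.
#' @param sequences character vector of A/C/G/T sequences, same length.
#' @param cpg_positions list of integer vectors (0-based offsets of the C
#'   of each CpG), parallel to `genes`, each sorted ascending.
#' @return An `AmpliconPanel`: list with `genes`, `sequences` (named),
#'   `cpg_positions` (named list) and `cpg_ids` ("gene:offset", panel-wide
#'   unique).
#' @export
amplicon_panel <- function(genes, sequences, cpg_positions) {
  stopifnot(length(genes) == length(sequences),
            length(genes) == length(cpg_positions),
            !anyDuplicated(genes))
  sequences <- toupper(as.character(sequences))
  names(sequences) <- genes
  cpg_positions <- lapply(cpg_positions, function(p) sort(as.integer(p)))
  names(cpg_positions) <- genes
  for (g in genes) {
    s <- sequences[[g]]
    if (grepl("[^ACGT]", s))
      stop("sequence for ", g, " contains non-ACGT characters")
    p <- cpg_positions[[g]]
    if (length(p)) {
      if (any(p < 0L) || any(p + 2L > nchar(s)))
        stop("CpG offset out of range in amplicon ", g)
      dinuc <- substring(s, p + 1L, p + 2L)
      if (any(dinuc != "CG"))
        stop("declared CpG position without CG dinucleotide in amplicon ", g)
    }
  }
  cpg_ids <- unlist(lapply(genes, function(g)
    if (length(cpg_positions[[g]])) paste0(g, ":", cpg_positions[[g]])
    else character(0)), use.names = FALSE)
  if (anyDuplicated(cpg_ids)) stop("duplicate CpG ids in panel")
  structure(list(genes = genes, sequences = sequences,
                 cpg_positions = cpg_positions, cpg_ids = cpg_ids),
            class = "AmpliconPanel")
}

#' Number of CpG sites declared in a panel
#' @param panel an `AmpliconPanel`.
#' @return integer total CpG count (sum of per-amplicon counts).
#' @export
n_cpgs <- function(panel) {
  stopifnot(inherits(panel, "AmpliconPanel"))
  sum(lengths(panel$cpg_positions))
}

#' @export
print.AmpliconPanel <- function(x, ...) {
  cat("AmpliconPanel:", length(x$genes), "amplicons,", n_cpgs(x),
      "CpG sites\n")
  if (length(x$genes)) {
    w <- utils::head(x$genes, 5)
    cat("  genes:", paste(w, collapse = ", "),
        if (length(x$genes) > 5) "..." else "", "\n")
  }
  invisible(x)
}

#' Generate a synthetic amplicon panel
#'
#' Builds `n_genes` random amplicon sequences, each carrying a declared set
#' of CpG dinucleotides and *no* accidental CG dinucleotide elsewhere, so
#' that the declared coordinates are exactly the CG content of the
#' sequence. The total CpG count is split as evenly as possible across
#' amplicons. Defaults emulate a 13-gene / 243-CpG promoter panel.
#'
#' @param n_genes number of amplicons (>= 0).
#' @param total_cpgs total number of CpG sites across the panel.
#' @param amplicon_length length of every amplicon in bp (>= 30).
#' @param seed integer seed; the generator is bit-reproducible.
#' @param gene_names optional names; defaults to [oscc_panel_genes] when 13
#'   genes are requested, `"GENE01"...` otherwise.
#' @return An [amplicon_panel()] object.
#' @export
generate_panel <- function(n_genes = 13L, total_cpgs = 243L,
                           amplicon_length = 300L, seed = 1L,
                           gene_names = NULL) {
  stopifnot(n_genes >= 0, amplicon_length >= 30)
  n_genes <- as.integer(n_genes)
  total_cpgs <- as.integer(total_cpgs)
  if (n_genes == 0L) {
    if (total_cpgs != 0L) stop("total_cpgs must be 0 for an empty panel")
    return(amplicon_panel(character(0), character(0), list()))
  }
  if (total_cpgs < n_genes)
    stop("need at least one CpG per amplicon (total_cpgs >= n_genes)")
  if (is.null(gene_names)) {
    gene_names <- if (n_genes == length(oscc_panel_genes)) oscc_panel_genes
                  else sprintf("GENE%02d", seq_len(n_genes))
  }
  stopifnot(length(gene_names) == n_genes)

  # even split: first `extra` amplicons carry one more CpG
  base <- total_cpgs %/% n_genes
  extra <- total_cpgs %% n_genes
  counts <- rep(base, n_genes) + c(rep(1L, extra), rep(0L, n_genes - extra))

  # CpGs need >= 2 bp each and must not overlap the final base
  max_per_amp <- (amplicon_length - 1L) %/% 2L
  if (any(counts > max_per_amp))
    stop("cannot pack ", max(counts), " CpGs into a ", amplicon_length,
         " bp amplicon (max ", max_per_amp, "): packing error")

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  seqs <- character(n_genes)
  pos <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    k <- counts[i]
    # choose CpG start offsets with pairwise gap >= 2, in [0, L-2]
    slots <- sort(sample.int(amplicon_length - 1L - k, k, replace = FALSE))
    p <- slots + seq_len(k) - 1L  # expand: inserting 2-mers shifts later ones
    stopifnot(all(diff(p) >= 2L), all(p + 2L <= amplicon_length))
    s <- sample(c("A", "C", "G", "T"), amplicon_length, replace = TRUE)
    s[p + 1L] <- "C"
    s[p + 2L] <- "G"
    # kill accidental CG dinucleotides: replace their G with A or T.
    # Replacement bases are never C or G, so no new CG can arise.
    declared_c <- p + 1L
    repeat {
      is_cg <- which(s[-length(s)] == "C" & s[-1L] == "G")
      rogue <- setdiff(is_cg, declared_c)
      if (!length(rogue)) break
      s[rogue + 1L] <- sample(c("A", "T"), length(rogue), replace = TRUE)
    }
    seqs[i] <- paste(s, collapse = "")
    pos[[i]] <- p
  }
  amplicon_panel(gene_names, seqs, pos)
}

# base-R seed save/restore so generators are reproducible without
# clobbering the caller's RNG stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Write a panel as FASTA plus a CpG sidecar table
#'
#' The sidecar is tab-separated with columns `gene`, `offset` (0-based
#' position of the CpG's C; the site is the half-open interval
#' `[offset, offset + 2)`) and `cpg_id`.
#'
#' @param panel an `AmpliconPanel`.
#' @param fasta_path output FASTA path.
#' @param sidecar_path output TSV path.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, fasta_path, sidecar_path) {
  stopifnot(inherits(panel, "AmpliconPanel"))
  dna <- Biostrings::DNAStringSet(panel$sequences)
  names(dna) <- panel$genes
  Biostrings::writeXStringSet(dna, fasta_path)
  side <- do.call(rbind, lapply(panel$genes, function(g) {
    p <- panel$cpg_positions[[g]]
    if (!length(p)) return(NULL)
    data.frame(gene = g, offset = p, cpg_id = paste0(g, ":", p))
  }))
  if (is.null(side))
    side <- data.frame(gene = character(0), offset = integer(0),
                       cpg_id = character(0))
  write.table(side, sidecar_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta_path, sidecar = sidecar_path))
}

#' Read a panel from FASTA plus CpG sidecar
#' @param fasta_path FASTA of amplicon sequences.
#' @param sidecar_path TSV with columns gene, offset, cpg_id.
#' @return An `AmpliconPanel`.
#' @export
read_panel <- function(fasta_path, sidecar_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  genes <- names(dna)
  side <- read.delim(sidecar_path, stringsAsFactors = FALSE)
  pos <- lapply(genes, function(g)
    sort(as.integer(side$offset[side$gene == g])))
  amplicon_panel(genes, as.character(dna), pos)
}
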