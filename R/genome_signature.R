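#' Reverse complement of a DNA motif
#' @param motif character string over A/C/G/T.
#' @return character string.
#' @export
reverse_complement <- function(motif) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
}

check_motif <- function(motif, min_len = 2L) {
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) < min_len ||
        grepl("[^ACGT]", motif)) {
    stop("motif must be a string of length >= ", min_len, " over A/C/G/T")
  }
  invisible(motif)
}

as_dna <- function(genome) {
  if (inherits(genome, "DNAString")) return(genome)
  if (inherits(genome, "DNAStringSet")) {
    if (length(genome) != 1) stop("expected a single sequence")
    return(genome[[1]])
  }
  Biostrings::DNAString(toupper(as.character(genome)))
}

# number of length-k windows consisting only of A/C/G/T (windows touching
# ambiguity codes are excluded from frequency denominators)
valid_windows <- function(dna, k) {
  ok <- strsplit(as.character(dna), "")[[1]] %in% c("A", "C", "G", "T")
  r <- rle(ok)
  sum(pmax(0L, r$lengths[r$values] - k + 1L))
}

#' Count motif occurrences in a genome
#'
#' Overlapping occurrences are counted by sliding window on the forward
#' strand; with \code{both_strands = TRUE}, occurrences of the reverse
#' complement on the forward strand are added unless the motif is its own
#' reverse complement (a palindromic recognition site), in which case the
#' two strands carry the same sites.  Windows containing non-ACGT symbols
#' never match.
#'
#' @param genome character string, \code{DNAString}, or single-sequence
#'   \code{DNAStringSet}.
#' @param motif motif over A/C/G/T, length >= 2.
#' @param both_strands logical; count reverse-complement occurrences too.
#' @param genome_id optional id for the output row.
#' @return one-row data.frame: \code{genome_id}, \code{motif},
#'   \code{count_forward}, \code{count_both_strands}, \code{count} (the
#'   requested total) and \code{density_per_kb} (requested count per kb of
#'   genome).
#' @examples
#' count_motif("CTAGCTAGCTAG", "CTAG")$count  # 3
#' @export
count_motif <- function(genome, motif, both_strands = FALSE,
                        genome_id = "genome") {
  check_motif(motif)
  dna <- as_dna(genome)
  fwd <- Biostrings::countPattern(motif, dna)
  rc <- reverse_complement(motif)
  both <- if (rc == motif) fwd else fwd + Biostrings::countPattern(rc, dna)
  cnt <- if (both_strands) both else fwd
  data.frame(
    genome_id = genome_id, motif = motif,
    count_forward = fwd, count_both_strands = both, count = cnt,
    density_per_kb = cnt / (length(dna) / 1000),
    stringsAsFactors = FALSE
  )
}

# strand-symmetrized overlapping word frequency: counts of w on the genome
# plus counts of w on the reverse-complemented genome, over the matching
# number of valid windows
sym_word_freq <- function(dna, w) {
  cnt <- Biostrings::countPattern(w, dna) +
    Biostrings::countPattern(reverse_complement(w), dna)
  denom <- 2 * valid_windows(dna, nchar(w))
  if (denom == 0) return(NA_real_)
  cnt / denom
}

#' Tetranucleotide relative abundance (tau)
#'
#' Karlin-style genome-signature statistic: the observed frequency of a
#' tetramer relative to its maximal-order (trinucleotide) expectation,
#'
#'   tau(abcd) = f(abcd) f(bc) / ( f(abc) f(bcd) )
#'
#' where f(w) is the overlapping frequency of word w computed on the genome
#' symmetrized with its reverse complement, so the statistic is
#' strand-independent.  Under an order-2 Markov null tau is 1; genomes that
#' avoid a motif (for example a restriction-modification recognition site)
#' show tau well below 1.  The conventional under-representation cut-off is
#' tau < 0.78.
#'
#' @inheritParams count_motif
#' @param motif tetramer over A/C/G/T.
#' @param threshold under-representation threshold on tau (default 0.78).
#' @return one-row data.frame: \code{genome_id}, \code{motif}, \code{tau},
#'   \code{underrepresented}, \code{evaluable}.  When a component word is
#'   absent the ratio is undefined and \code{evaluable} is \code{FALSE}.
#' @export
tetramer_tau <- function(genome, motif, threshold = 0.78,
                         genome_id = "genome") {
  check_motif(motif, min_len = 4L)
  if (nchar(motif) != 4) stop("tau is defined for tetramers")
  dna <- as_dna(genome)
  f4 <- sym_word_freq(dna, motif)
  f2 <- sym_word_freq(dna, substr(motif, 2, 3))
  f3a <- sym_word_freq(dna, substr(motif, 1, 3))
  f3b <- sym_word_freq(dna, substr(motif, 2, 4))
  denom_ok <- !is.na(f3a) && !is.na(f3b) && f3a > 0 && f3b > 0 &&
    !is.na(f2) && f2 > 0
  tau <- if (denom_ok) (f4 * f2) / (f3a * f3b) else NA_real_
  data.frame(
    genome_id = genome_id, motif = motif, tau = tau,
    underrepresented = if (denom_ok) tau < threshold else NA,
    evaluable = denom_ok,
    stringsAsFactors = FALSE
  )
}

#' Motif-avoidance profile across genomes
#'
#' Per-genome, per-motif counts and densities; tetramers additionally get
#' the \code{\link{tetramer_tau}} relative-abundance statistic and the
#' under-representation flag, while longer motifs (such as methylation
#' targets like GCGCTG) are summarized by density only.
#'
#' @param genomes named character vector or \code{DNAStringSet}.
#' @param motifs character vector of motifs over A/C/G/T.
#' @param both_strands count on both strands (default TRUE, matching the
#'   double-stranded biology of restriction sites).
#' @param threshold tau under-representation threshold.
#' @return data.frame with one row per genome x motif: \code{genome_id},
#'   \code{motif}, \code{count_fwd}, \code{count_both},
#'   \code{density_per_kb}, \code{tau}, \code{underrepresented}.
#' @export
signature_profile <- function(genomes, motifs, both_strands = TRUE,
                              threshold = 0.78) {
  if (is.character(genomes)) {
    if (is.null(names(genomes))) {
      names(genomes) <- paste0("genome", seq_along(genomes))
    }
    genomes <- Biostrings::DNAStringSet(toupper(genomes))
  }
  if (!length(genomes)) stop("at least one genome is required")
  if (!length(motifs)) {
    return(data.frame(genome_id = character(), motif = character(),
                      count_fwd = integer(), count_both = integer(),
                      density_per_kb = numeric(), tau = numeric(),
                      underrepresented = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (gi in seq_along(genomes)) {
    gid <- names(genomes)[gi]
    dna <- genomes[[gi]]
    for (m in motifs) {
      mc <- count_motif(dna, m, both_strands = both_strands, genome_id = gid)
      if (nchar(m) == 4) {
        tt <- tetramer_tau(dna, m, threshold = threshold, genome_id = gid)
        tau <- tt$tau; under <- tt$underrepresented
      } else {
        tau <- NA_real_; under <- NA
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, motif = m,
        count_fwd = mc$count_forward, count_both = mc$count_both_strands,
        density_per_kb = mc$density_per_kb,
        tau = tau, underrepresented = under,
        stringsAsFactors = FALSE
      )
    }
  }
  rbind_rows(rows)
}

#' Scan a protein alignment for substitutions at conserved columns
#'
#' Reports every alignment column where the non-focal sequences agree on a
#' single residue (at or above \code{min_conservation}, gaps excluded) but
#' the focal sequence carries a different, non-gap residue.  This is the
#' operation that localizes candidate host-range substitutions such as a
#' single amino-acid change in an otherwise conserved adhesin motif.
#'
#' @param alignment \code{AAStringSet} of equal-length aligned sequences,
#'   or a named character vector of aligned strings (gap character "-").
#' @param focal_id id of the focal sequence.
#' @param min_conservation minimum fraction (in (0.5, 1]) of non-focal,
#'   non-gap residues sharing the consensus.
#' @return data.frame with one row per reported column:
#'   \code{column} (1-based alignment coordinate), \code{focal_position}
#'   (1-based ungapped coordinate in the focal sequence),
#'   \code{consensus}, \code{focal}, \code{conservation},
#'   \code{n_informative}.  Columns with a tied consensus, an all-gap
#'   background, or a gapped focal residue are skipped.
#' @export
conserved_column_scan <- function(alignment, focal_id,
                                  min_conservation = 0.9) {
  if (min_conservation <= 0.5 || min_conservation > 1) {
    stop("min_conservation must be in (0.5, 1]")
  }
  if (inherits(alignment, "XStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  alignment <- toupper(alignment)
  if (length(unique(nchar(alignment))) != 1) {
    stop("aligned sequences must all have the same length")
  }
  if (!focal_id %in% names(alignment)) {
    stop("focal sequence not found: ", focal_id)
  }
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  focal <- mat[focal_id, ]
  others <- mat[setdiff(rownames(mat), focal_id), , drop = FALSE]
  focal_pos <- cumsum(focal != "-")
  rows <- list()
  for (j in seq_len(ncol(mat))) {
    res <- others[, j]
    res <- res[res != "-"]
    if (!length(res)) next                     # all-gap background
    tab <- table(res)
    top <- max(tab)
    if (sum(tab == top) > 1) next              # tied consensus
    cons <- names(tab)[which.max(tab)]
    conserv <- top / length(res)
    if (conserv < min_conservation) next
    if (focal[j] == "-" || focal[j] == cons) next
    rows[[length(rows) + 1L]] <- data.frame(
      column = j, focal_position = focal_pos[j],
      consensus = cons, focal = focal[j],
      conservation = conserv, n_informative = length(res),
      stringsAsFactors = FALSE
    )
  }
  rbind_rows(rows) %||%
    data.frame(column = integer(), focal_position = integer(),
               consensus = character(), focal = character(),
               conservation = numeric(), n_informative = integer(),
               stringsAsFactors = FALSE)
}
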