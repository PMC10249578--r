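# Shared pairwise-alignment machinery. Scoring is fixed package-wide to
# match +5 / mismatch -4, gap open 10, gap extend 0.5 (EMBOSS Needle/Water
# default-like), the scheme under which all percent similarities are defined.

ALN_MATCH <- 5
ALN_MISMATCH <- -4
ALN_GAP_OPEN <- 10
ALN_GAP_EXTEND <- 0.5

# Gene assignment uses a stiffer gap extension: immunoglobulin V/J genes
# carry at most short indels relative to a read, and the cheap EMBOSS-style
# extension lets a local alignment bridge from the V into the junction/J
# over long spurious gaps, corrupting region coordinates on hybrid
# (receptor-revised) reads. Pairwise percent similarities (align_pair) keep
# the EMBOSS-like extension.
ASSIGN_GAP_EXTEND <- 4

nuc_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(
        match = ALN_MATCH, mismatch = ALN_MISMATCH, baseOnly = FALSE)
    }
    m
  }
})

pw_align <- function(patterns, subject, type = "local", score_only = FALSE,
                     gap_open = ALN_GAP_OPEN, gap_extend = ALN_GAP_EXTEND) {
  Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject,
    substitutionMatrix = nuc_submat(),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = type, scoreOnly = score_only)
}

# Per-pair coordinate map between pattern (read) and subject (germline)
# positions of an alignment, as aligned column vectors over the aligned
# region only. Gap columns carry NA on the gapped side.
aln_maps <- function(pa) {
  ps <- Biostrings::pattern(pa)
  ss <- Biostrings::subject(pa)
  pat <- strsplit(as.character(ps), "")
  sub <- strsplit(as.character(ss), "")
  p0 <- BiocGenerics::start(ps); p1 <- BiocGenerics::end(ps)
  s0 <- BiocGenerics::start(ss); s1 <- BiocGenerics::end(ss)
  lapply(seq_along(pat), function(i) {
    pc <- pat[[i]]
    sc <- sub[[i]]
    ppos <- ifelse(pc == "-", NA_integer_, cumsum(pc != "-") + p0[i] - 1L)
    spos <- ifelse(sc == "-", NA_integer_, cumsum(sc != "-") + s0[i] - 1L)
    list(pat = pc, sub = sc, ppos = ppos, spos = spos,
         p0 = p0[i], p1 = p1[i], s0 = s0[i], s1 = s1[i])
  })
}

# Read-side position (1-based) aligned to a 1-based germline position, or NA
# if that germline position is not covered or is deleted on the read.
map_sub_to_pat <- function(map, gpos) {
  i <- match(gpos, map$spos)
  if (is.na(i)) return(NA_integer_)
  map$ppos[i]
}

# As map_sub_to_pat, but germline positions outside the aligned region are
# extrapolated colinearly past the alignment ends (local alignments clip
# terminal mismatches; coordinates must still resolve there). NA when the
# extrapolated position falls off the read.
map_sub_to_pat_ext <- function(map, gpos, read_len) {
  if (gpos < map$s0) {
    cand <- map$p0 - (map$s0 - gpos)
    return(if (cand >= 1L) cand else NA_integer_)
  }
  if (gpos > map$s1) {
    cand <- map$p1 + (gpos - map$s1)
    return(if (cand <= read_len) cand else NA_integer_)
  }
  map_sub_to_pat(map, gpos)
}

#' Global pairwise alignment with percent similarity
#'
#' Needleman–Wunsch global alignment of two nucleotide sequences under the
#' package-wide scoring scheme (match +5, mismatch -4, gap open 10, gap
#' extend 0.5). Percent similarity is the number of identical aligned columns
#' divided by the full alignment length (gap columns count in the
#' denominator), times 100.
#'
#' @param a,b Nucleotide strings.
#' @return A list with `score`, `percent_similarity`, `aligned_a`,
#'   `aligned_b`, and `length` (alignment length in columns).
#' @export
align_pair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("align_pair requires non-empty sequences")
  pa <- pw_align(Biostrings::DNAStringSet(a), Biostrings::DNAString(b),
                 type = "global")
  ga <- as.character(Biostrings::pattern(pa))
  gb <- as.character(Biostrings::subject(pa))
  # full alignment length includes terminal gap columns, which the aligned
  # strings do not display
  flanks <- (BiocGenerics::start(Biostrings::pattern(pa)) - 1L) +
    (nchar(a) - BiocGenerics::end(Biostrings::pattern(pa))) +
    (BiocGenerics::start(Biostrings::subject(pa)) - 1L) +
    (nchar(b) - BiocGenerics::end(Biostrings::subject(pa)))
  len <- nchar(ga) + flanks
  list(
    score = as.numeric(Biostrings::score(pa)),
    percent_similarity = 100 * Biostrings::nmatch(pa) / len,
    aligned_a = ga,
    aligned_b = gb,
    length = len
  )
}

# codon-table translation; trailing partial codon dropped, unknown -> X
translate_nt <- local({
  code <- NULL
  function(s) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    n <- nchar(s) - nchar(s) %% 3
    if (n == 0) return("")
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- code[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})
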