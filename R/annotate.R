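#' V(D)J annotation of immunoglobulin reads
#'
#' Assigns germline V and J (and, for heavy chains, D) alleles to each read
#' by pairwise alignment against the germline reference, extracts the
#' junction and CDR3, and records alignment coordinates used by downstream
#' productivity calling and mutation profiling.
#'
#' V and J are assigned by best-scoring local alignment (match +5, mismatch
#' -4, gap open 10; gap extension is stiffened to 4 for assignment so that
#' cheap long gaps cannot bridge a V alignment into the junction); D by the
#' highest-scoring ungapped match
#' of at least 8 nt inside the junction interior, else left unassigned. The
#' CDR3 is delimited by the conserved V-end cysteine codon and the J-frame
#' tryptophan (heavy) / phenylalanine (light) codon; `junction` spans both
#' anchor codons and `cdr3_aa` is the translated junction interior. Ties
#' between equally scoring alleles are broken by lower locus position P, then
#' lexicographic allele name. Reads with no V or J above the score floor are
#' retained with `unannotatable = TRUE`.
#'
#' @param reads A data frame with columns `id`, `sample_id`, `compartment`,
#'   `cell_id`, `chain` (`heavy`/`kappa`/`lambda`), `sequence`.
#' @param model A [locus_model()].
#' @param v_score_floor,j_score_floor Minimum local alignment scores to
#'   accept a V / J call.
#' @param with_d Assign D genes inside heavy-chain junctions.
#' @return A tibble of partial annotations, one row per read.
#' @export
assign_vdj <- function(reads, model, v_score_floor = 150, j_score_floor = 40,
                       with_d = TRUE) {
  reads <- as_tibble(reads)
  stopifnot(all(c("id", "chain", "sequence") %in% names(reads)))
  if (anyDuplicated(paste(reads$sample_id, reads$id))) {
    stop("read ids must be unique within sample")
  }
  out <- vector("list", 3)
  chains <- intersect(c("heavy", "kappa", "lambda"), unique(reads$chain))
  for (ch in chains) {
    sub <- reads[reads$chain == ch, ]
    locus <- c(heavy = "IGH", kappa = "IGK", lambda = "IGL")[[ch]]
    out[[ch]] <- annotate_chain(sub, model, locus, ch,
                                v_score_floor, j_score_floor, with_d)
  }
  dplyr::bind_rows(out)
}

empty_annotation_cols <- function(n) {
  tibble(
    v_call = NA_character_, d_call = NA_character_, j_call = NA_character_,
    v_score = NA_real_, j_score = NA_real_, v_identity = NA_real_,
    v_read_start = NA_integer_, v_read_end = NA_integer_,
    v_germ_start = NA_integer_, v_germ_end = NA_integer_,
    v_frame_start = NA_integer_,
    cys_start = NA_integer_, j_read_start = NA_integer_,
    j_read_end = NA_integer_, j_anchor_start = NA_integer_,
    junction = NA_character_, junction_aa = NA_character_,
    cdr3_aa = NA_character_, unannotatable = TRUE
  )[rep(1, n), ]
}

# tie-break helper: order candidate columns by (score desc, P asc, name asc)
best_gene_call <- function(scores, names, positions) {
  ord <- order(-scores, positions, names)
  ord[1]
}

annotate_chain <- function(sub, model, locus, chain,
                           v_score_floor, j_score_floor, with_d = TRUE) {
  genes <- model$genes
  vg <- genes[genes$locus == locus & genes$segment == "V", ]
  jg <- genes[genes$locus == locus & genes$segment == "J", ]
  n <- nrow(sub)
  ann <- dplyr::bind_cols(
    sub[, intersect(c("id", "sample_id", "compartment", "cell_id", "chain",
                      "sequence"), names(sub))],
    empty_annotation_cols(n))
  # all-N / degenerate reads never reach the score floor; alignment handles it
  dss <- Biostrings::DNAStringSet(sub$sequence)

  vscores <- vapply(seq_len(nrow(vg)), function(k) {
    as.numeric(pw_align(dss, Biostrings::DNAString(vg$sequence[k]),
                        score_only = TRUE,
                        gap_extend = ASSIGN_GAP_EXTEND))
  }, numeric(n))
  if (n == 1) vscores <- matrix(vscores, nrow = 1)

  v_idx <- integer(n)
  for (i in seq_len(n)) {
    v_idx[i] <- best_gene_call(vscores[i, ], vg$name, vg$locus_position)
  }
  v_ok <- vscores[cbind(seq_len(n), v_idx)] >= v_score_floor

  # realign per assigned germline to extract coordinates
  for (k in sort(unique(v_idx[v_ok]))) {
    sel <- which(v_idx == k & v_ok)
    pa <- pw_align(dss[sel], Biostrings::DNAString(vg$sequence[k]),
                   gap_extend = ASSIGN_GAP_EXTEND)
    maps <- aln_maps(pa)
    b <- vg$boundaries[[k]]
    fr3_end <- b[["fr3_end"]]           # 0-based exclusive == 1-based end
    for (m in seq_along(sel)) {
      i <- sel[m]
      mp <- maps[[m]]
      s0 <- BiocGenerics::start(Biostrings::subject(pa))[m]
      ann$v_call[i] <- vg$name[k]
      ann$v_score[i] <- as.numeric(Biostrings::score(pa))[m]
      ann$v_identity[i] <- 100 * Biostrings::nmatch(pa)[m] /
        Biostrings::nchar(pa)[m]
      ann$v_read_start[i] <- BiocGenerics::start(Biostrings::pattern(pa))[m]
      ann$v_read_end[i] <- BiocGenerics::end(Biostrings::pattern(pa))[m]
      ann$v_germ_start[i] <- s0
      ann$v_germ_end[i] <- BiocGenerics::end(Biostrings::subject(pa))[m]
      g0 <- s0 + ((1 - s0) %% 3)        # first full germline codon covered
      rl <- nchar(ann$sequence[i])
      ann$v_frame_start[i] <- map_sub_to_pat_ext(mp, g0, rl)
      ann$cys_start[i] <- map_sub_to_pat_ext(mp, fr3_end - 2L, rl)
    }
  }

  # J assignment on the read 3' of the V match
  v_end <- ifelse(v_ok, ann$v_read_end, 0L)
  tails <- substr(sub$sequence, v_end + 1L, nchar(sub$sequence))
  has_tail <- nzchar(tails)
  if (any(has_tail)) {
    tss <- Biostrings::DNAStringSet(tails[has_tail])
    jscores <- vapply(seq_len(nrow(jg)), function(k) {
      as.numeric(pw_align(tss, Biostrings::DNAString(jg$sequence[k]),
                          score_only = TRUE,
                          gap_extend = ASSIGN_GAP_EXTEND))
    }, numeric(sum(has_tail)))
    if (sum(has_tail) == 1) jscores <- matrix(jscores, nrow = 1)
    ji <- which(has_tail)
    j_idx <- integer(length(ji))
    for (m in seq_along(ji)) {
      j_idx[m] <- best_gene_call(jscores[m, ], jg$name, jg$locus_position)
    }
    j_ok <- jscores[cbind(seq_along(ji), j_idx)] >= j_score_floor
    for (k in sort(unique(j_idx[j_ok]))) {
      selm <- which(j_idx == k & j_ok)
      pa <- pw_align(tss[selm], Biostrings::DNAString(jg$sequence[k]),
                     gap_extend = ASSIGN_GAP_EXTEND)
      maps <- aln_maps(pa)
      anchor <- jg$boundaries[[k]]
      for (m2 in seq_along(selm)) {
        i <- ji[selm[m2]]
        off <- v_end[i]                 # tail coordinates -> read coordinates
        mp <- maps[[m2]]
        ann$j_call[i] <- jg$name[k]
        ann$j_score[i] <- as.numeric(Biostrings::score(pa))[m2]
        ann$j_read_start[i] <- off +
          BiocGenerics::start(Biostrings::pattern(pa))[m2]
        ann$j_read_end[i] <- off +
          BiocGenerics::end(Biostrings::pattern(pa))[m2]
        a0 <- map_sub_to_pat_ext(mp, anchor[["anchor_start"]] + 1L,
                                 nchar(tails[i]))
        ann$j_anchor_start[i] <- if (is.na(a0)) NA_integer_ else off + a0
      }
    }
  }

  annotated <- !is.na(ann$v_call) & !is.na(ann$j_call) &
    !is.na(ann$cys_start) & !is.na(ann$j_anchor_start)
  ann$unannotatable <- !annotated
  sel <- which(annotated)
  ann$junction[sel] <- substr(ann$sequence[sel], ann$cys_start[sel],
                              ann$j_anchor_start[sel] + 2L)
  ann$junction_aa[sel] <- vapply(ann$junction[sel], translate_nt, character(1))
  ann$cdr3_aa[sel] <- substr(ann$junction_aa[sel], 2L,
                             nchar(ann$junction_aa[sel]) - 1L)

  # D assignment inside the junction interior (heavy only)
  if (chain == "heavy" && with_d) {
    dg <- genes[genes$locus == locus & genes$segment == "D", ]
    ann <- assign_d(ann, dg)
  }
  ann
}

# Highest-scoring ungapped match >= 8 nt of a D germline inside the junction
# interior (between V end and J start on the read).
assign_d <- function(ann, dg, min_len = 8L) {
  sel <- which(!ann$unannotatable)
  if (length(sel) == 0 || nrow(dg) == 0) return(ann)
  interior <- substr(ann$sequence[sel], ann$v_read_end[sel] + 1L,
                     ann$j_read_start[sel] - 1L)
  ok <- nchar(interior) >= min_len
  if (!any(ok)) return(ann)
  idx <- sel[ok]
  iss <- Biostrings::DNAStringSet(interior[ok])
  nr <- length(idx)
  scores <- matrix(-Inf, nr, nrow(dg))
  for (k in seq_len(nrow(dg))) {
    pa <- pw_align(iss, Biostrings::DNAString(dg$sequence[k]),
                   gap_open = 1e6)    # effectively ungapped
    sc <- as.numeric(Biostrings::score(pa))
    sc[Biostrings::nchar(pa) < min_len] <- -Inf
    scores[, k] <- sc
  }
  for (m in seq_len(nr)) {
    if (all(!is.finite(scores[m, ]))) next
    ann$d_call[idx[m]] <- dg$name[best_gene_call(scores[m, ], dg$name,
                                                 dg$locus_position)]
  }
  ann
}

# Shared productivity rule: a rearrangement is productive iff both anchor
# codons are intact, the junction length is 0 mod 3, and no in-frame stop
# occurs between the first full V codon and the J end. Reason precedence:
# missing_anchor > frameshift > stop_codon.
productivity_rule <- function(sequence, v_frame_start, cys_start,
                              j_anchor_start, j_end, chain) {
  cys <- substr(sequence, cys_start, cys_start + 2L)
  anchor <- substr(sequence, j_anchor_start, j_anchor_start + 2L)
  anchor_ok <- cys %in% c("TGT", "TGC") &&
    anchor %in% (if (chain == "heavy") "TGG" else c("TTT", "TTC"))
  if (!anchor_ok) return(list(productive = FALSE, reason = "missing_anchor"))
  jlen <- (j_anchor_start + 2L) - cys_start + 1L
  if (jlen %% 3L != 0L) return(list(productive = FALSE, reason = "frameshift"))
  # stop scan starts at the first read position in the V reading frame, so
  # terminal mismatches clipped by a local alignment still get scanned
  scan_start <- ((v_frame_start - 1L) %% 3L) + 1L
  aa <- translate_nt(substr(sequence, scan_start, j_end))
  if (grepl("\\*", aa)) return(list(productive = FALSE, reason = "stop_codon"))
  list(productive = TRUE, reason = "in_frame")
}

#' Call productivity of annotated rearrangements
#'
#' A rearrangement is productive iff the junction length is 0 mod 3, no
#' in-frame stop codon occurs from the first full V codon through the J end,
#' and both anchor codons (V-end Cys; J-frame Trp for heavy, Phe for light)
#' are present. The `productivity_reason` field distinguishes
#' `missing_anchor`, `frameshift`, `stop_codon` and `in_frame`; `productive`
#' is `FALSE` whenever the reason is not `in_frame`.
#'
#' @param ann Annotations from [assign_vdj()].
#' @return `ann` with `productive` and `productivity_reason` columns.
#' @export
call_productivity <- function(ann) {
  ann$productive <- NA
  ann$productivity_reason <- NA_character_
  sel <- which(!ann$unannotatable)
  for (i in sel) {
    r <- productivity_rule(ann$sequence[i], ann$v_frame_start[i],
                           ann$cys_start[i], ann$j_anchor_start[i],
                           ann$j_read_end[i], ann$chain[i])
    ann$productive[i] <- r$productive
    ann$productivity_reason[i] <- r$reason
  }
  ann
}

#' Assign heavy-chain isotype from the constant-region fragment
#'
#' Locally aligns the 3'-most 120 nt of each heavy-chain read against the 5'
#' constant-region reference of each IGH constant gene and calls the top
#' scorer when it exceeds the runner-up by at least `margin` score units,
#' otherwise `unassigned`.
#'
#' @param ann Annotations (heavy chain reads; light chains raise an error
#'   when passed exclusively, and are skipped in mixed input).
#' @param model A [locus_model()].
#' @param margin Minimum score separation between best and runner-up.
#' @param score_floor Minimum best score to call at all; the default sits
#'   well above the score a 120-nt window reaches against an unrelated
#'   constant gene by chance, and well below a genuine constant fragment.
#' @return `ann` with a `c_call` column (IgM, IgD, IgG1..4, IgA1..2, IgE or
#'   `unassigned`).
#' @export
assign_isotype <- function(ann, model, margin = 5, score_floor = 100) {
  if (!any(ann$chain == "heavy")) {
    stop("assign_isotype requires heavy-chain reads")
  }
  cg <- model$genes[model$genes$segment == "C" & model$genes$locus == "IGH", ]
  cg <- cg[match(model$constant_order, cg$name), ]
  ann$c_call <- ifelse(ann$chain == "heavy", "unassigned", NA_character_)
  sel <- which(ann$chain == "heavy")
  tails <- substr(ann$sequence[sel],
                  pmax(1L, nchar(ann$sequence[sel]) - 119L),
                  nchar(ann$sequence[sel]))
  tss <- Biostrings::DNAStringSet(tails)
  scores <- vapply(seq_len(nrow(cg)), function(k) {
    as.numeric(pw_align(tss, Biostrings::DNAString(cg$sequence[k]),
                        score_only = TRUE,
                        gap_extend = ASSIGN_GAP_EXTEND))
  }, numeric(length(sel)))
  if (length(sel) == 1) scores <- matrix(scores, nrow = 1)
  for (m in seq_along(sel)) {
    o <- order(scores[m, ], decreasing = TRUE)
    top <- scores[m, o[1]]
    second <- scores[m, o[2]]
    if (top >= score_floor && (top - second) >= margin) {
      ann$c_call[sel[m]] <- unname(ISOTYPE_LABEL[cg$name[o[1]]])
    }
  }
  ann
}

#' Region-resolved silent/replacement mutation profiling
#'
#' Re-aligns each read's V region to its assigned germline and classifies
#' every aligned mismatch as Silent (S) or Replacement (R) by codon
#' translation in the germline reading frame, and as Framework (FR) or CDR
#' by the germline region boundaries. Populates `s_fr`, `r_fr`, `s_cdr`,
#' `r_cdr`, the percent of total mutations over the aligned V length
#' (`pct_mut`), and `mut_reliable` (`FALSE` when fewer than 50 V nucleotides
#' aligned).
#'
#' @param ann Annotations with `v_call` assigned.
#' @param model A [locus_model()].
#' @return `ann` with mutation-count columns added.
#' @export
profile_mutations <- function(ann, model) {
  ann$s_fr <- ann$r_fr <- ann$s_cdr <- ann$r_cdr <- NA_integer_
  ann$v_aligned_len <- NA_integer_
  ann$pct_mut <- NA_real_
  ann$mut_reliable <- NA
  sel <- which(!is.na(ann$v_call))
  for (vname in unique(ann$v_call[sel])) {
    g <- get_gene(model, vname)
    b <- g$boundaries[[1]]
    gseq <- g$sequence
    idx <- sel[ann$v_call[sel] == vname]
    vregs <- substr(ann$sequence[idx], ann$v_read_start[idx],
                    ann$v_read_end[idx])
    pa <- pw_align(Biostrings::DNAStringSet(vregs),
                   Biostrings::DNAString(gseq), type = "global",
                   gap_extend = ASSIGN_GAP_EXTEND)
    maps <- aln_maps(pa)
    cdr <- germline_cdr_mask(b, nchar(gseq))
    gchars <- strsplit(gseq, "")[[1]]
    for (m in seq_along(idx)) {
      i <- idx[m]
      mp <- maps[[m]]
      res <- classify_mismatches(mp, gchars, cdr)
      ann$s_fr[i] <- res["s_fr"]; ann$r_fr[i] <- res["r_fr"]
      ann$s_cdr[i] <- res["s_cdr"]; ann$r_cdr[i] <- res["r_cdr"]
      ann$v_aligned_len[i] <- res["aligned"]
      tot <- sum(res[c("s_fr", "r_fr", "s_cdr", "r_cdr")])
      ann$pct_mut[i] <- if (res["aligned"] > 0) 100 * tot / res["aligned"] else NA
      ann$mut_reliable[i] <- res["aligned"] >= 50
    }
  }
  ann
}

# logical mask over germline V positions: TRUE = CDR (1 or 2)
germline_cdr_mask <- function(b, len) {
  mask <- rep(FALSE, len)
  mask[(b[["cdr1_start"]] + 1L):b[["cdr1_end"]]] <- TRUE
  mask[(b[["cdr2_start"]] + 1L):b[["cdr2_end"]]] <- TRUE
  mask
}

classify_mismatches <- function(mp, gchars, cdr_mask) {
  both <- !is.na(mp$ppos) & !is.na(mp$spos)
  aligned <- sum(both)
  # read base observed at each germline position (NA where unaligned)
  rb <- rep(NA_character_, length(gchars))
  rb[mp$spos[both]] <- mp$pat[both]
  mism <- which(!is.na(rb) & rb != gchars)
  s_fr <- r_fr <- s_cdr <- r_cdr <- 0L
  for (gpos in mism) {
    c0 <- ((gpos - 1L) %/% 3L) * 3L + 1L
    if (c0 + 2L > length(gchars)) next  # trailing partial codon
    gcodon <- gchars[c0:(c0 + 2L)]
    mcodon <- gcodon
    have <- !is.na(rb[c0:(c0 + 2L)])
    mcodon[have] <- rb[c0:(c0 + 2L)][have]
    silent <- translate_nt(paste(gcodon, collapse = "")) ==
      translate_nt(paste(mcodon, collapse = ""))
    if (cdr_mask[gpos]) {
      if (silent) s_cdr <- s_cdr + 1L else r_cdr <- r_cdr + 1L
    } else {
      if (silent) s_fr <- s_fr + 1L else r_fr <- r_fr + 1L
    }
  }
  c(s_fr = s_fr, r_fr = r_fr, s_cdr = s_cdr, r_cdr = r_cdr, aligned = aligned)
}

#' Collapse to unique variable-domain sequences
#'
#' Reduces exact duplicates of the variable-domain nucleotide sequence
#' (V-gene start through J-gene end on the read) to a single record carrying
#' a `copy_count`, within each sample. Records differing only in the
#' constant fragment are therefore kept separate copies of one unique
#' sequence, and unannotatable reads are kept as-is with `copy_count = 1`.
#'
#' @param ann Annotations.
#' @return Collapsed annotations with `copy_count`.
#' @export
collapse_unique <- function(ann) {
  ann$variable_domain <- ifelse(
    ann$unannotatable, ann$sequence,
    substr(ann$sequence, ann$v_read_start, ann$j_read_end))
  ann %>%
    group_by(.data$sample_id, .data$variable_domain) %>%
    mutate(copy_count = n()) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    arrange(.data$sample_id, .data$id)
}

#' Full annotation pipeline for a read set
#'
#' Runs [assign_vdj()], [call_productivity()], [assign_isotype()] (heavy
#' chains) and optionally [profile_mutations()] and [collapse_unique()].
#'
#' @param reads Read tibble (see [assign_vdj()]).
#' @param model A [locus_model()].
#' @param with_d Assign D genes (heavy chains).
#' @param with_mutations Run the mutation profiler.
#' @param with_isotype Run the isotype caller.
#' @param collapse Collapse to unique variable-domain sequences.
#' @return Annotation tibble.
#' @export
annotate_repertoire <- function(reads, model, with_d = TRUE,
                                with_mutations = TRUE, with_isotype = TRUE,
                                collapse = FALSE) {
  ann <- assign_vdj(reads, model, with_d = with_d)
  ann <- call_productivity(ann)
  if (with_isotype && any(ann$chain == "heavy")) {
    ann <- assign_isotype(ann, model)
  } else {
    ann$c_call <- NA_character_
  }
  if (with_mutations) ann <- profile_mutations(ann, model)
  if (collapse) ann <- collapse_unique(ann)
  ann
}
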