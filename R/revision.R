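#' Find cryptic recombination-signal heptamers
#'
#' Scans a nucleotide sequence for occurrences of the RSS heptamer CACAGTG
#' with at most `max_mismatch` mismatches, requiring the CAC core to be
#' intact (the convention for cryptic heptamers embedded in V coding
#' sequence). Hits are reported 5' to 3' with 0-based, half-open
#' coordinates.
#'
#' @param v_sequence Nucleotide string.
#' @param max_mismatch Maximum mismatches outside the CAC core (default 1).
#' @return Tibble with `start`, `end` (0-based, half-open), `heptamer`,
#'   `mismatches`.
#' @export
find_cryptic_heptamers <- function(v_sequence, max_mismatch = 1L) {
  if (!nzchar(v_sequence)) stop("empty sequence")
  motif <- strsplit("CACAGTG", "")[[1]]
  x <- strsplit(v_sequence, "")[[1]]
  n <- length(x)
  if (n < 7L) {
    return(tibble(start = integer(0), end = integer(0),
                  heptamer = character(0), mismatches = integer(0)))
  }
  starts <- seq_len(n - 6L)
  wins <- vapply(starts, function(s) paste(x[s:(s + 6L)], collapse = ""),
                 character(1))
  core_ok <- substr(wins, 1, 3) == "CAC"
  mm <- vapply(wins, function(w) {
    sum(strsplit(w, "")[[1]] != motif)
  }, integer(1))
  keep <- core_ok & mm <= max_mismatch
  tibble(
    start = starts[keep] - 1L,
    end = starts[keep] + 6L,
    heptamer = unname(wins[keep]),
    mismatches = unname(mm[keep])
  )
}

# Per-germline-position read-base vector from a read-vs-germline global
# alignment: entry g is the read base aligned to germline position g (NA
# where the germline position is deleted on the read or uncovered).
germline_profile <- function(read_v, germline) {
  pa <- pw_align(Biostrings::DNAStringSet(read_v),
                 Biostrings::DNAString(germline), type = "global")
  mp <- aln_maps(pa)[[1]]
  prof <- rep(NA_character_, nchar(germline))
  both <- !is.na(mp$ppos) & !is.na(mp$spos)
  prof[mp$spos[both]] <- mp$pat[both]
  prof
}

# Changepoint for hybrid-V detection: match indicators of one read against
# two germlines on the read coordinate; the crossover maximizes
# (prefix agreement with A) + (suffix agreement with B).
locate_crossover <- function(read_v, germ_a, germ_b, window = 15L) {
  pa_a <- pw_align(Biostrings::DNAStringSet(read_v),
                   Biostrings::DNAString(germ_a), type = "global")
  pa_b <- pw_align(Biostrings::DNAStringSet(read_v),
                   Biostrings::DNAString(germ_b), type = "global")
  map_a <- aln_maps(pa_a)[[1]]
  map_b <- aln_maps(pa_b)[[1]]
  L <- nchar(read_v)
  mA <- mB <- rep(FALSE, L)
  ok_a <- !is.na(map_a$ppos) & !is.na(map_a$spos)
  mA[map_a$ppos[ok_a]] <- map_a$pat[ok_a] == map_a$sub[ok_a]
  ok_b <- !is.na(map_b$ppos) & !is.na(map_b$spos)
  mB[map_b$ppos[ok_b]] <- map_b$pat[ok_b] == map_b$sub[ok_b]
  diffv <- as.integer(mA) - as.integer(mB)
  # f(s) = sum_{i<=s} diff + sum_{i>s} (-diff); maximize over s = 0..L
  pref <- c(0, cumsum(diffv))
  tot <- pref[L + 1]
  f <- 2 * pref - tot
  best <- max(f)
  cand <- which(f == best) - 1L           # candidate split points s
  list(candidates = cand, f = f, mA = mA, mB = mB,
       map_b = map_b, value = best)
}

# allegiance-switch check at a split point s (read coords): the prefix must
# favor germline A and the suffix germline B. Window votes abstain where the
# two germlines are locally identical, so the requirement is on the
# cumulative advantage on each side, not on the windows adjacent to s.
split_margin <- function(mA, mB, s, window) {
  L <- length(mA)
  if (s < 1L || s >= L) return(-Inf)
  wa <- sum(mA[1:s]) - sum(mB[1:s])
  wb <- sum(mB[(s + 1L):L]) - sum(mA[(s + 1L):L])
  if (wa < 1 || wb < 1) return(-Inf)
  (wa + wb) / L
}

#' Detect VH replacement events
#'
#' Searches an annotated heavy-chain set for hybrid V sequences produced by
#' VH replacement: an upstream V gene invading a rearranged V at a cryptic
#' RSS heptamer, leaving the DJ (and hence the CDR3) unaltered. Sequences
#' are grouped by identical CDR-H3 amino-acid sequence; within groups
#' carrying at least two distinct V calls, each read is tested as a
#' candidate hybrid of its own V call (5' invader) and a partner's V call
#' (3' invaded gene). The crossover is located where sliding-window
#' (15 nt, majority-vote) identity switches allegiance between the two
#' germlines; ties across stretches where the germlines are locally
#' identical are resolved toward the nearest cryptic heptamer. An event
#' requires (i) the allegiance switch, (ii) a cryptic heptamer within
#' `heptamer_window` nt of the crossover on the invaded germline, and
#' (iii) the invader strictly upstream of the invaded gene.
#'
#' @param ann Annotated heavy reads (needs `id`, `v_call`, `cdr3_aa`,
#'   `sequence`, `v_read_start`, `v_read_end`, `sample_id`).
#' @param model A [locus_model()].
#' @param window Sliding window size (nt) for allegiance voting.
#' @param heptamer_window Maximum distance (nt) between crossover and
#'   heptamer on the invaded germline.
#' @return Tibble of events: `kind`, `sequence_id` (the revised read),
#'   `partner_ids`, `invader`, `invaded`, `crossover_start`/`crossover_end`
#'   (0-based half-open window on the read), `heptamer`, `heptamer_pos`,
#'   `heptamer_mismatches`, `locus_feasible`, `evidence`.
#' @export
detect_vh_replacement <- function(ann, model, window = 15L,
                                  heptamer_window = 10L) {
  ann <- ann[ann$chain == "heavy" & !is.na(ann$v_call) &
               !is.na(ann$cdr3_aa) & nzchar(ann$cdr3_aa), ]
  events <- list()
  hept_cache <- new.env(parent = emptyenv())
  get_hepts <- function(gene) {
    if (is.null(hept_cache[[gene]])) {
      hept_cache[[gene]] <- find_cryptic_heptamers(
        get_gene(model, gene)$sequence)
    }
    hept_cache[[gene]]
  }
  groups <- split(seq_len(nrow(ann)), paste(ann$sample_id, ann$cdr3_aa))
  for (ix in groups) {
    vs <- unique(ann$v_call[ix])
    if (length(vs) < 2) next
    for (i in ix) {
      a_name <- ann$v_call[i]
      # the read V region runs to the junction Cys anchor: the local V
      # alignment of a hybrid stops at the crossover, so its extent must
      # not bound the region analyzed for the allegiance switch
      v_end_i <- if (!is.na(ann$cys_start[i])) {
        ann$cys_start[i] + 2L
      } else {
        ann$v_read_end[i]
      }
      read_v <- substr(ann$sequence[i], ann$v_read_start[i], v_end_i)
      partners_by_b <- split(ix[ann$v_call[ix] != a_name],
                             ann$v_call[ix][ann$v_call[ix] != a_name])
      best <- NULL
      for (b_name in names(partners_by_b)) {
        if (relative_position(a_name, b_name, model) != "upstream") next
        germ_a <- get_gene(model, a_name)$sequence
        germ_b <- get_gene(model, b_name)$sequence
        cx <- locate_crossover(read_v, germ_a, germ_b, window)
        hepts <- get_hepts(b_name)
        if (nrow(hepts) == 0) next
        # resolve changepoint ties toward the nearest cryptic heptamer
        scored <- lapply(cx$candidates, function(s) {
          marg <- split_margin(cx$mA, cx$mB, s, window)
          if (!is.finite(marg)) return(NULL)
          gpos <- map_sub_to_pat(list(ppos = cx$map_b$spos,
                                      spos = cx$map_b$ppos), s)
          if (is.na(gpos)) return(NULL)
          dist <- min(abs(hepts$end - gpos), abs(hepts$start + 1L - gpos))
          list(s = s, margin = marg, gpos = gpos, dist = dist)
        })
        scored <- Filter(Negate(is.null), scored)
        if (length(scored) == 0) next
        dists <- vapply(scored, `[[`, numeric(1), "dist")
        pick <- scored[[which.min(dists)]]
        if (pick$dist > heptamer_window) next
        hi <- which.min(pmin(abs(hepts$end - pick$gpos),
                             abs(hepts$start + 1L - pick$gpos)))
        cand <- list(
          a = a_name, b = b_name, s = pick$s, margin = pick$margin,
          heptamer = hepts$heptamer[hi], heptamer_pos = hepts$start[hi],
          heptamer_mm = hepts$mismatches[hi],
          partners = ann$id[partners_by_b[[b_name]]]
        )
        if (is.null(best) || cand$margin > best$margin) best <- cand
      }
      if (!is.null(best)) {
        v0 <- ann$v_read_start[i] - 1L       # read offset of the V region
        events[[length(events) + 1L]] <- tibble(
          kind = "vh_replacement",
          sample_id = ann$sample_id[i],
          sequence_id = ann$id[i],
          partner_ids = paste(best$partners, collapse = ","),
          invader = best$a, invaded = best$b,
          crossover_start = v0 + max(0L, best$s - window),
          crossover_end = v0 + min(nchar(read_v), best$s + window),
          heptamer = best$heptamer,
          heptamer_pos = best$heptamer_pos,
          heptamer_mismatches = best$heptamer_mm,
          locus_feasible = TRUE,
          evidence = best$margin
        )
      }
    }
  }
  if (length(events) == 0) return(empty_events())
  dplyr::bind_rows(events)
}

empty_events <- function() {
  tibble(
    kind = character(0), sample_id = character(0), sequence_id = character(0),
    partner_ids = character(0), invader = character(0), invaded = character(0),
    crossover_start = integer(0), crossover_end = integer(0),
    heptamer = character(0), heptamer_pos = integer(0),
    heptamer_mismatches = integer(0), locus_feasible = logical(0),
    evidence = numeric(0)
  )
}

#' Detect secondary lambda-locus rearrangements
#'
#' Looks for cells (or, in bulk mode, clonotype groups used as a documented
#' proxy for cells) expressing two lambda light chains with the same J
#' family but different V genes, at least one of them unproductive — the
#' signature of a secondary rearrangement at the lambda locus. The
#' secondary (unproductive) V is checked for locus feasibility: a
#' sequential rearrangement on the same chromosome requires the secondary V
#' upstream of the primary V; pairs that fail this are still reported with
#' `locus_feasible = FALSE` (alternative-chromosome interpretation).
#'
#' @param ann Annotated light-chain reads (kappa reads are ignored); needs
#'   `cell_id` in single-cell mode or `clone_id` in bulk mode.
#' @param model A [locus_model()].
#' @param mode `"singlecell"` (group by `cell_id`) or `"bulk"` (group by
#'   `clone_id`).
#' @return Tibble of events (see [detect_vh_replacement()] for the shape);
#'   `sequence_id` is the secondary (unproductive) read.
#' @export
detect_lambda_secondary <- function(ann, model, mode = c("singlecell", "bulk")) {
  mode <- match.arg(mode)
  key <- if (mode == "singlecell") "cell_id" else "clone_id"
  if (!key %in% names(ann)) stop("grouping column missing: ", key)
  lam <- ann[ann$chain == "lambda" & !is.na(ann$v_call) &
               !is.na(ann$j_call), ]
  events <- list()
  for (ix in split(seq_len(nrow(lam)), paste(lam$sample_id, lam[[key]]))) {
    if (length(ix) < 2) next
    jfam <- sub("\\*.*$", "", lam$j_call[ix])
    for (fam in unique(jfam)) {
      sub <- ix[jfam == fam]
      vg <- sub("\\*.*$", "", lam$v_call[sub])
      if (length(sub) < 2 || length(unique(vg)) < 2) next
      unprod <- sub[!lam$productive[sub]]
      prod <- sub[lam$productive[sub]]
      if (length(unprod) == 0) next
      primary <- if (length(prod) > 0) prod[1] else sub[1]
      for (s2 in setdiff(unprod, primary)) {
        if (sub("\\*.*$", "", lam$v_call[s2]) ==
            sub("\\*.*$", "", lam$v_call[primary])) next
        feas <- relative_position(lam$v_call[s2], lam$v_call[primary],
                                  model) == "upstream"
        events[[length(events) + 1L]] <- tibble(
          kind = "lambda_secondary",
          sample_id = lam$sample_id[s2],
          sequence_id = lam$id[s2],
          partner_ids = lam$id[primary],
          invader = lam$v_call[s2], invaded = lam$v_call[primary],
          crossover_start = NA_integer_, crossover_end = NA_integer_,
          heptamer = NA_character_, heptamer_pos = NA_integer_,
          heptamer_mismatches = NA_integer_,
          locus_feasible = feas,
          evidence = NA_real_
        )
      }
    }
  }
  if (length(events) == 0) return(empty_events())
  dplyr::bind_rows(events)
}

#' Per-sample receptor-revision frequency
#'
#' Fraction of qualifying sequences carrying a revised receptor: the
#' numerator counts unique revised sequences (the read carrying the hybrid
#' V for VH replacement; the secondary lambda rearrangement for lambda
#' events), and the denominator is the per-sample universe of qualifying
#' sequences (heavy for VH replacement, lambda for lambda rearrangement),
#' normally the unique-sequence set after [collapse_unique()].
#'
#' @param events Event tibble from the detectors.
#' @param universe Tibble of qualifying sequences with `sample_id` and `id`.
#' @return List with `per_sample` (tibble: `sample_id`, `n_events`,
#'   `n_sequences`, `frequency`) and overall `mean` and `sd` across
#'   samples.
#' @export
revision_frequency <- function(events, universe) {
  samples <- unique(universe$sample_id)
  if (length(samples) == 0) {
    return(list(per_sample = tibble(sample_id = character(0),
                                    n_events = integer(0),
                                    n_sequences = integer(0),
                                    frequency = numeric(0)),
                mean = NA_real_, sd = NA_real_))
  }
  per <- dplyr::bind_rows(lapply(samples, function(s) {
    denom <- sum(universe$sample_id == s)
    revised <- unique(events$sequence_id[events$sample_id == s])
    revised <- revised[revised %in% universe$id[universe$sample_id == s]]
    tibble(
      sample_id = s,
      n_events = length(revised),
      n_sequences = denom,
      frequency = if (denom == 0) NA_real_ else length(revised) / denom
    )
  }))
  list(per_sample = per,
       mean = mean(per$frequency, na.rm = TRUE),
       sd = stats::sd(per$frequency, na.rm = TRUE))
}
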