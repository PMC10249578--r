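#' Simulation configuration for synthetic BCR repertoires
#'
#' Bundles and validates all parameters of the synthetic repertoire
#' generator. Defaults describe an IgD- memory-like repertoire: heavy-tailed
#' clone sizes, moderate somatic hypermutation (SHM) concentrated in the
#' CDRs, class-switch recombination (CSR) restricted to downstream constant
#' genes, a class-switched isotype prior, and a small rate of unproductive
#' rearrangements. Receptor-revision rates default to zero.
#'
#' @param model A [locus_model()].
#' @param n_cells Number of B cells to emit (each gives one heavy and one
#'   light chain read).
#' @param clone_exponent,clone_max Truncated power-law clone-size law:
#'   P(size = k) proportional to k^-exponent for k in 1..clone_max.
#' @param shm_rate Per-base mutation probability over the V region.
#' @param cdr_hotspot_multiplier Factor (>= 1) raising the CDR1/CDR2
#'   mutation rate relative to framework.
#' @param transition_bias Probability that a mutation is a transition.
#' @param csr_probability Per-descendant probability of one downstream
#'   isotype switch.
#' @param isotype_prior Named probability vector over the nine IGH constant
#'   genes for clone founders; must sum to 1.
#' @param unproductive_rate Probability that a cell also emits a frameshifted
#'   or stop-containing heavy rearrangement.
#' @param vh_replacement_rate Per-heavy-sequence probability of a VH
#'   replacement event.
#' @param lambda_secondary_rate Per-lambda-cell probability of a secondary
#'   lambda rearrangement.
#' @param lambda_fraction Probability a cell uses the lambda (vs kappa)
#'   light locus.
#' @param junction_trim_range,n_insertion_range Integer ranges (min, max)
#'   for exonuclease trimming and N-insertion lengths.
#' @param constant_trunc Number of constant-region nucleotides carried by
#'   each heavy read.
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model,
                       n_cells = 200,
                       clone_exponent = 2.5,
                       clone_max = 50,
                       shm_rate = 0.02,
                       cdr_hotspot_multiplier = 3,
                       transition_bias = 0.5,
                       csr_probability = 0.2,
                       isotype_prior = c(IGHM = 0.15, IGHD = 0.01,
                                         IGHG3 = 0.06, IGHG1 = 0.35,
                                         IGHA1 = 0.18, IGHG2 = 0.14,
                                         IGHG4 = 0.03, IGHE = 0.01,
                                         IGHA2 = 0.07),
                       unproductive_rate = 0.08,
                       vh_replacement_rate = 0,
                       lambda_secondary_rate = 0,
                       lambda_fraction = 0.4,
                       junction_trim_range = c(0L, 3L),
                       n_insertion_range = c(0L, 6L),
                       constant_trunc = 60L,
                       seed = 1L) {
  stopifnot(inherits(model, "locus_model"))
  probs <- c(shm_rate, transition_bias, csr_probability, unproductive_rate,
             vh_replacement_rate, lambda_secondary_rate, lambda_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (cdr_hotspot_multiplier < 1) stop("cdr_hotspot_multiplier must be >= 1")
  if (abs(sum(isotype_prior) - 1) > 1e-8) stop("isotype_prior must sum to 1")
  if (!setequal(names(isotype_prior), model$constant_order)) {
    stop("isotype_prior must be named over the IGH constant genes")
  }
  if (any(junction_trim_range < 0) || any(n_insertion_range < 0)) {
    stop("trim and insertion ranges must be non-negative")
  }
  structure(list(
    model = model, n_cells = as.integer(n_cells),
    clone_exponent = clone_exponent, clone_max = as.integer(clone_max),
    shm_rate = shm_rate, cdr_hotspot_multiplier = cdr_hotspot_multiplier,
    transition_bias = transition_bias, csr_probability = csr_probability,
    isotype_prior = isotype_prior[model$constant_order],
    unproductive_rate = unproductive_rate,
    vh_replacement_rate = vh_replacement_rate,
    lambda_secondary_rate = lambda_secondary_rate,
    lambda_fraction = lambda_fraction,
    junction_trim_range = as.integer(junction_trim_range),
    n_insertion_range = as.integer(n_insertion_range),
    constant_trunc = as.integer(constant_trunc),
    seed = as.integer(seed)
  ), class = "sim_config")
}

rand_bases <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

draw_clone_sizes <- function(n_cells, exponent, kmax) {
  p <- (1:kmax)^(-exponent)
  sizes <- integer(0)
  total <- 0L
  while (total < n_cells) {
    k <- sample.int(kmax, 1, prob = p)
    if (total + k > n_cells) k <- n_cells - total
    sizes <- c(sizes, k)
    total <- total + k
  }
  sizes
}

# Assemble a junction 3' of a V segment: N1 + trimmed D + N2 + trimmed J.
# Returns NULL if no stop-free in-frame assembly is found (productive case).
build_junction <- function(vseq, dseq, jseq, j_anchor_start, cfg,
                           productive = TRUE,
                           force_reason = NULL) {
  vlen <- nchar(vseq)
  for (attempt in 1:40) {
    tr <- cfg$junction_trim_range
    ni <- cfg$n_insertion_range
    n1 <- sample(ni[1]:ni[2], 1)
    n2 <- sample(ni[1]:ni[2], 1)
    jtrim <- sample(tr[1]:tr[2], 1)
    dl <- 0L
    dpart <- ""
    if (!is.null(dseq)) {
      dt1 <- sample(tr[1]:tr[2], 1)
      dt2 <- sample(tr[1]:tr[2], 1)
      dpart <- substr(dseq, dt1 + 1L, nchar(dseq) - dt2)
      dl <- nchar(dpart)
    }
    len <- 6L + n1 + dl + n2 + (j_anchor_start - jtrim)
    # pad N2 so the junction is in frame for the productive case
    n2 <- n2 + (3L - len %% 3L) %% 3L
    if (!is.null(force_reason) && force_reason == "frameshift") {
      n2 <- n2 + sample(1:2, 1)   # knock the junction out of frame
    }
    n1seq <- rand_bases(n1)
    n2seq <- rand_bases(n2)
    if (!is.null(force_reason) && force_reason == "stop_codon") {
      if (n1 >= 3) {
        substr(n1seq, 1, 3) <- "TAA"  # in frame right after the Cys codon
      } else {
        n2 <- n2 + 1L                 # frameshift fallback
        n2seq <- rand_bases(n2)
      }
    }
    jpart <- substr(jseq, jtrim + 1L, nchar(jseq))
    insert <- paste0(n1seq, dpart, n2seq)
    junction_nt <- paste0(substr(vseq, vlen - 2L, vlen), insert,
                          substr(jpart, 1L, j_anchor_start - jtrim + 3L))
    in_frame <- nchar(junction_nt) %% 3L == 0L
    has_stop <- in_frame && grepl("\\*", translate_nt(junction_nt))
    if (productive && (!in_frame || has_stop)) next
    return(list(insert = insert, jpart = jpart, n1 = n1, n2 = n2, dl = dl,
                jtrim = jtrim, junction_len = nchar(junction_nt)))
  }
  NULL
}

apply_shm <- function(seq, vlen, cdr_mask, cfg) {
  if (cfg$shm_rate == 0) return(list(seq = seq, mutations = NULL))
  x <- strsplit(seq, "")[[1]]
  rate <- rep(cfg$shm_rate, vlen)
  rate[cdr_mask] <- pmin(1, cfg$shm_rate * cfg$cdr_hotspot_multiplier)
  pos <- which(stats::runif(vlen) < rate)
  if (length(pos) == 0) return(list(seq = seq, mutations = NULL))
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  # the two transversion targets per base, in fixed order
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  from <- x[pos]
  is_ts <- stats::runif(length(pos)) < cfg$transition_bias
  pick2 <- stats::runif(length(pos)) < 0.5
  to <- ifelse(is_ts, transitions[from],
               ifelse(pick2, tv1[from], tv2[from]))
  to <- unname(to)
  x[pos] <- to
  mutated <- paste(x, collapse = "")
  # classify against the unmutated sequence with all codon mutations applied
  gchars <- strsplit(substr(seq, 1, vlen), "")[[1]]
  mchars <- x[seq_len(vlen)]
  cls <- vapply(pos, function(p) {
    c0 <- ((p - 1L) %/% 3L) * 3L + 1L
    if (c0 + 2L > vlen) return("S")
    ga <- translate_nt(paste(gchars[c0:(c0 + 2L)], collapse = ""))
    ma <- translate_nt(paste(mchars[c0:(c0 + 2L)], collapse = ""))
    if (ga == ma) "S" else "R"
  }, character(1))
  muts <- tibble(
    position = pos - 1L,                      # 0-based
    from = from, to = to,
    region = ifelse(cdr_mask[pos], "CDR", "FR"),
    class = cls
  )
  list(seq = mutated, mutations = muts)
}

pick_gene <- function(genes) genes[sample.int(nrow(genes), 1), ]

#' Simulate a ground-truthed BCR repertoire
#'
#' Generates a repertoire of heavy and light chain reads with clonal
#' expansion, SHM, CSR, unproductive rearrangements and (optionally)
#' receptor-revision events, together with a per-read ground-truth table.
#'
#' Each cell emits one heavy read (full V, N-inserted trimmed D, trimmed J,
#' plus a 5' fragment of its constant gene) and one light read. Clone
#' members share the founder junction (heavy and light) and accumulate
#' independent SHM over the V region; the junction and J are spared, a
#' deliberate simplification (see the package vignette) that keeps clonal
#' identity of the CDR3 exact. CSR only ever moves downstream in the
#' constant-gene order. A VH-replacement event rewrites the 5' of the V up
#' to a cryptic recombination-signal heptamer (which the simulator verifies
#' exists) with an upstream V gene, preserving the junction; when such an
#' event lands in a singleton clone one unrevised sibling read is also
#' emitted so the event is in principle detectable. A secondary-lambda event
#' adds an unproductive lambda read with the same J gene and a different,
#' locus-feasible V.
#'
#' @param config A [sim_config()].
#' @return A list of class `bcr_sim` with `reads` (tibble: `id`,
#'   `sample_id`, `compartment`, `cell_id`, `chain`, `sequence`) and `truth`
#'   (one row per emitted read).
#' @param sample_id,compartment Labels stamped on every read.
#' @export
simulate_repertoire <- function(config, sample_id = "S1",
                                compartment = "blood") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- config$model
  genes <- model$genes
  hv <- genes[genes$locus == "IGH" & genes$segment == "V", ]
  hd <- genes[genes$locus == "IGH" & genes$segment == "D", ]
  hj <- genes[genes$locus == "IGH" & genes$segment == "J", ]
  hc <- genes[genes$locus == "IGH" & genes$segment == "C", ]
  hc <- hc[match(model$constant_order, hc$name), ]

  sizes <- draw_clone_sizes(config$n_cells, config$clone_exponent,
                            config$clone_max)
  reads <- list()
  truth <- list()
  cell_counter <- 0L
  skipped_vh <- 0L

  emit <- function(read_row, truth_row) {
    reads[[length(reads) + 1L]] <<- read_row
    truth[[length(truth) + 1L]] <<- truth_row
  }

  for (ci in seq_along(sizes)) {
    clone_id <- sprintf("clone%04d", ci)
    founder <- make_founder(model, hv, hd, hj, config)
    if (is.null(founder)) next
    iso0 <- sample(names(config$isotype_prior), 1,
                   prob = config$isotype_prior)
    # replacement flags drawn per member up front, so a clone left with no
    # unrevised member can be given one sibling read (the event would
    # otherwise be undetectable in principle)
    rep_flags <- stats::runif(sizes[ci]) < config$vh_replacement_rate
    need_sibling <- all(rep_flags)
    for (mi in seq_len(sizes[ci])) {
      cell_counter <- cell_counter + 1L
      cell_id <- sprintf("cell%05d", cell_counter)

      # class switch: downstream only
      iso <- iso0
      if (stats::runif(1) < config$csr_probability) {
        i0 <- match(iso0, model$constant_order)
        if (i0 < length(model$constant_order)) {
          iso <- sample(model$constant_order[(i0 + 1):9], 1)
        }
      }

      res <- emit_heavy(founder, model, hv, hc, iso, config, sample_id,
                        compartment, cell_id, clone_id,
                        id = paste0(sample_id, "_", cell_id, "_H"),
                        do_replace = rep_flags[mi],
                        with_sibling = need_sibling && mi == 1L)
      emit(res$read, res$truth)
      if (!is.null(res$sibling)) {
        emit(res$sibling$read, res$sibling$truth)
      }
      if (isTRUE(res$vh_skipped)) skipped_vh <- skipped_vh + 1L

      lres <- emit_light(founder, model, config, sample_id, compartment,
                         cell_id, clone_id,
                         id = paste0(sample_id, "_", cell_id, "_L"))
      emit(lres$read, lres$truth)
      if (!is.null(lres$secondary)) emit(lres$secondary$read,
                                         lres$secondary$truth)

      # additional unproductive heavy rearrangement
      if (stats::runif(1) < config$unproductive_rate) {
        ur <- emit_unproductive_heavy(model, hv, hd, hj, hc, iso, config,
                                      sample_id, compartment, cell_id,
                                      clone_id = NA_character_,
                                      id = paste0(sample_id, "_", cell_id,
                                                  "_Hu"))
        if (!is.null(ur)) emit(ur$read, ur$truth)
      }
    }
  }
  if (skipped_vh > 0) {
    warning(skipped_vh, " VH replacement event(s) infeasible on the ",
            "reference (no upstream V) and not emitted")
  }
  truth_tbl <- dplyr::bind_rows(lapply(truth, `[[`, "row"))
  truth_tbl$mutations <- lapply(truth, `[[`, "mut")
  structure(list(
    reads = dplyr::bind_rows(reads),
    truth = truth_tbl,
    config = config
  ), class = "bcr_sim")
}

make_founder <- function(model, hv, hd, hj, config) {
  v <- pick_gene(hv)
  d <- pick_gene(hd)
  j <- pick_gene(hj)
  jun <- build_junction(v$sequence, d$sequence, j$sequence,
                        j$boundaries[[1]][["anchor_start"]], config)
  if (is.null(jun)) return(NULL)
  lambda <- stats::runif(1) < config$lambda_fraction
  locus <- if (lambda) "IGL" else "IGK"
  lv <- pick_gene(model$genes[model$genes$locus == locus &
                                model$genes$segment == "V", ])
  lj <- pick_gene(model$genes[model$genes$locus == locus &
                                model$genes$segment == "J", ])
  ljun <- build_junction(lv$sequence, NULL, lj$sequence,
                         lj$boundaries[[1]][["anchor_start"]], config)
  if (is.null(ljun)) return(NULL)
  list(v = v, d = d, j = j, jun = jun,
       lambda = lambda, lv = lv, lj = lj, ljun = ljun)
}

v_cdr_mask <- function(boundaries, vlen) {
  m <- rep(FALSE, vlen)
  m[(boundaries[["cdr1_start"]] + 1L):boundaries[["cdr1_end"]]] <- TRUE
  m[(boundaries[["cdr2_start"]] + 1L):boundaries[["cdr2_end"]]] <- TRUE
  m
}

assemble_read <- function(vseq, jun, jseq_trimmed_anchor, cseq = "") {
  paste0(vseq, jun$insert, jun$jpart, cseq)
}

# plain-list row (tibble construction per read dominates run time); the
# mutation table travels alongside and becomes a list column at the end
truth_row <- function(id, sample_id, cell_id, clone_id, chain, v_call, d_call,
                      j_call, c_call, productive, reason, junction_nt,
                      mutations, vlen,
                      revision_kind = NA_character_,
                      revision_partner = NA_character_,
                      invader = NA_character_, invaded = NA_character_,
                      crossover_start = NA_integer_,
                      crossover_end = NA_integer_,
                      heptamer = NA_character_,
                      heptamer_pos = NA_integer_,
                      locus_feasible = NA) {
  junction_aa <- translate_nt(junction_nt)
  list(row = list(
    id = id, sample_id = sample_id, cell_id = cell_id, clone_id = clone_id,
    chain = chain, v_call = v_call, d_call = d_call, j_call = j_call,
    c_call = c_call, productive = productive, reason = reason,
    junction = junction_nt, junction_aa = junction_aa,
    cdr3_aa = substr(junction_aa, 2L, nchar(junction_aa) - 1L),
    v_len = vlen,
    n_mutations = if (is.null(mutations)) 0L else nrow(mutations),
    revision_kind = revision_kind, revision_partner = revision_partner,
    invader = invader, invaded = invaded,
    crossover_start = crossover_start, crossover_end = crossover_end,
    heptamer = heptamer, heptamer_pos = heptamer_pos,
    locus_feasible = locus_feasible
  ), mut = mutations)
}

finish_heavy <- function(vseq, boundaries, founder, iso, hc, config,
                         sample_id, compartment, cell_id, clone_id, id,
                         v_call, d_call, j_call, chain = "heavy",
                         ...) {
  vlen <- nchar(vseq)
  cseq <- substr(hc$sequence[match(iso, hc$name)], 1L, config$constant_trunc)
  body <- paste0(vseq, founder$jun$insert, founder$jun$jpart)
  shm <- apply_shm(body, vlen, v_cdr_mask(boundaries, vlen), config)
  seq_full <- paste0(shm$seq, cseq)
  jun <- founder$jun
  j_anchor_germ <- founder$j$boundaries[[1]][["anchor_start"]]
  j_read_start <- vlen + jun$n1 + jun$dl + jun$n2 + 1L
  j_anchor_read <- j_read_start + j_anchor_germ - jun$jtrim
  j_read_end <- j_read_start + nchar(jun$jpart) - 1L
  pr <- productivity_rule(seq_full, 1L, vlen - 2L, j_anchor_read,
                          j_read_end, chain)
  junction_nt <- substr(seq_full, vlen - 2L, j_anchor_read + 2L)
  list(
    read = list(id = id, sample_id = sample_id, compartment = compartment,
                cell_id = cell_id, chain = chain, sequence = seq_full),
    truth = truth_row(id, sample_id, cell_id, clone_id, chain, v_call,
                      d_call, j_call, unname(ISOTYPE_LABEL[iso]),
                      pr$productive, pr$reason, junction_nt, shm$mutations,
                      vlen, ...)
  )
}

emit_heavy <- function(founder, model, hv, hc, iso, config, sample_id,
                       compartment, cell_id, clone_id, id,
                       do_replace = FALSE, with_sibling = FALSE) {
  v <- founder$v
  b <- v$boundaries[[1]]
  vh_skipped <- FALSE

  if (do_replace) {
    hept <- find_cryptic_heptamers(v$sequence, max_mismatch = 0L)
    upstream <- hv[hv$locus_position < v$locus_position, ]
    if (nrow(hept) == 0 || nrow(upstream) == 0) {
      vh_skipped <- TRUE
    } else {
      # prefer the heptamer closest to the end of CDR2
      hpos <- hept[which.min(abs(hept$end - b[["cdr2_end"]])), ]
      invader <- pick_gene(upstream)
      h_end <- hpos$end                    # 0-based exclusive
      hybrid <- paste0(substr(invader$sequence, 1L,
                              min(h_end, nchar(invader$sequence))),
                       substr(v$sequence, h_end + 1L, nchar(v$sequence)))
      res <- finish_heavy(hybrid, b, founder, iso, hc, config, sample_id,
                          compartment, cell_id, clone_id, id,
                          v_call = invader$name, d_call = founder$d$name,
                          j_call = founder$j$name,
                          revision_kind = "vh_replacement",
                          revision_partner = NA_character_,
                          invader = invader$name, invaded = v$name,
                          crossover_start = hpos$start,
                          crossover_end = h_end,
                          heptamer = hpos$heptamer,
                          heptamer_pos = hpos$start,
                          locus_feasible = TRUE)
      sib <- NULL
      if (with_sibling) {
        # no clone member stays unrevised: emit one, else the event is
        # undetectable in principle
        sib <- finish_heavy(v$sequence, b, founder, iso, hc, config,
                            sample_id, compartment, paste0(cell_id, "s"),
                            clone_id, paste0(id, "s"), v_call = v$name,
                            d_call = founder$d$name,
                            j_call = founder$j$name)
      }
      return(list(read = res$read, truth = res$truth, sibling = sib,
                  vh_skipped = FALSE))
    }
  }
  res <- finish_heavy(v$sequence, b, founder, iso, hc, config, sample_id,
                      compartment, cell_id, clone_id, id,
                      v_call = v$name, d_call = founder$d$name,
                      j_call = founder$j$name)
  list(read = res$read, truth = res$truth, sibling = NULL,
       vh_skipped = vh_skipped)
}

finish_light <- function(lv, lj, ljun, config, sample_id, compartment,
                         cell_id, clone_id, id, chain, ...) {
  vlen <- nchar(lv$sequence)
  body <- paste0(lv$sequence, ljun$insert, ljun$jpart)
  shm <- apply_shm(body, vlen, v_cdr_mask(lv$boundaries[[1]], vlen), config)
  j_anchor_germ <- lj$boundaries[[1]][["anchor_start"]]
  j_read_start <- vlen + ljun$n1 + ljun$dl + ljun$n2 + 1L
  j_anchor_read <- j_read_start + j_anchor_germ - ljun$jtrim
  j_read_end <- j_read_start + nchar(ljun$jpart) - 1L
  pr <- productivity_rule(shm$seq, 1L, vlen - 2L, j_anchor_read,
                          j_read_end, chain)
  junction_nt <- substr(shm$seq, vlen - 2L, j_anchor_read + 2L)
  list(
    read = list(id = id, sample_id = sample_id, compartment = compartment,
                cell_id = cell_id, chain = chain, sequence = shm$seq),
    truth = truth_row(id, sample_id, cell_id, clone_id, chain, lv$name,
                      NA_character_, lj$name, NA_character_, pr$productive,
                      pr$reason, junction_nt, shm$mutations, vlen, ...)
  )
}

emit_light <- function(founder, model, config, sample_id, compartment,
                       cell_id, clone_id, id, allow_secondary = TRUE) {
  chain <- if (founder$lambda) "lambda" else "kappa"
  res <- finish_light(founder$lv, founder$lj, founder$ljun, config,
                      sample_id, compartment, cell_id, clone_id, id, chain)
  secondary <- NULL
  if (allow_secondary && founder$lambda &&
      stats::runif(1) < config$lambda_secondary_rate) {
    lvs <- model$genes[model$genes$locus == "IGL" &
                         model$genes$segment == "V", ]
    upstream <- lvs[lvs$locus_position < founder$lv$locus_position, ]
    feasible <- nrow(upstream) > 0
    pool <- if (feasible) upstream else
      lvs[lvs$name != founder$lv$name, ]
    if (nrow(pool) > 0) {
      v2 <- pick_gene(pool)
      jun2 <- build_junction(v2$sequence, NULL, founder$lj$sequence,
                             founder$lj$boundaries[[1]][["anchor_start"]],
                             config, productive = FALSE,
                             force_reason = "frameshift")
      if (!is.null(jun2)) {
        secondary <- finish_light(
          v2, founder$lj, jun2, config, sample_id, compartment, cell_id,
          clone_id, paste0(id, "2"), chain,
          revision_kind = "lambda_secondary", revision_partner = id,
          invader = v2$name, invaded = founder$lv$name,
          locus_feasible = feasible)
      }
    }
  }
  list(read = res$read, truth = res$truth, secondary = secondary)
}

emit_unproductive_heavy <- function(model, hv, hd, hj, hc, iso, config,
                                    sample_id, compartment, cell_id,
                                    clone_id, id) {
  v <- pick_gene(hv); d <- pick_gene(hd); j <- pick_gene(hj)
  reason <- sample(c("frameshift", "stop_codon"), 1)
  jun <- build_junction(v$sequence, d$sequence, j$sequence,
                        j$boundaries[[1]][["anchor_start"]], config,
                        productive = FALSE, force_reason = reason)
  if (is.null(jun)) return(NULL)
  founder <- list(v = v, d = d, j = j, jun = jun)
  finish_heavy(v$sequence, v$boundaries[[1]], founder, iso, hc, config,
               sample_id, compartment, cell_id, clone_id, id,
               v_call = v$name, d_call = d$name, j_call = j$name)
}

#' Write / read a simulation ground-truth table
#'
#' Serializes the per-read truth table to TSV. Per-read mutation lists are
#' packed into a single column as `pos:from>to:region:class` records joined
#' by `|`; [read_truth()] unpacks them, so the round trip is lossless.
#'
#' @param truth Truth tibble from [simulate_repertoire()].
#' @param path Output TSV path.
#' @export
write_truth <- function(truth, path) {
  flat <- truth
  flat$mutations <- vapply(truth$mutations, function(m) {
    if (is.null(m) || nrow(m) == 0) return("")
    paste(sprintf("%d:%s>%s:%s:%s", m$position, m$from, m$to, m$region,
                  m$class), collapse = "|")
  }, character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()` returns the truth tibble.
#' @export
read_truth <- function(path) {
  flat <- as_tibble(utils::read.delim(path, colClasses = "character",
                                      na.strings = "NA"))
  if (nrow(flat) == 0) {
    flat$mutations <- list()
    return(flat)
  }
  for (col in c("v_len", "n_mutations", "crossover_start", "crossover_end",
                "heptamer_pos")) {
    flat[[col]] <- as.integer(flat[[col]])
  }
  for (col in c("productive", "locus_feasible")) {
    flat[[col]] <- as.logical(flat[[col]])
  }
  flat$mutations <- lapply(flat$mutations, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], "[:>]")
    tibble(
      position = as.integer(vapply(parts, `[`, character(1), 1)),
      from = vapply(parts, `[`, character(1), 2),
      to = vapply(parts, `[`, character(1), 3),
      region = vapply(parts, `[`, character(1), 4),
      class = vapply(parts, `[`, character(1), 5)
    )
  })
  flat
}
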