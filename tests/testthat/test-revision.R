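test_that("cryptic heptamer scan honors the CAC core and mismatch budget", {
  hits <- find_cryptic_heptamers("AACACAGTGTT")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2L)
  expect_equal(hits$mismatches, 0L)
  # core violated -> no hit even within one mismatch of the motif
  expect_equal(nrow(find_cryptic_heptamers("TACAGTG")), 0)
  # one mismatch outside the core is allowed
  h2 <- find_cryptic_heptamers("CACAGTT")
  expect_equal(h2$mismatches, 1L)
  expect_error(find_cryptic_heptamers(""), "empty")
})

test_that("heptamer scan matches an exhaustive oracle on random sequence", {
  set.seed(123)
  for (rep in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
    got <- find_cryptic_heptamers(s)
    oracle <- brute_heptamers(s)
    expect_equal(got$start, oracle$start)
    expect_equal(got$mismatches, oracle$mismatches)
    # count within 3 SDs of the motif-class expectation:
    # P(CAC core) * P(<=1 mismatch over the 4 remaining positions)
    p <- (1 / 4)^3 * ((1 / 4)^4 + 4 * (3 / 4) * (1 / 4)^3)
    n <- 10000 - 6
    expect_lt(abs(nrow(got) - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("global alignment percent similarity matches hand values", {
  expect_equal(align_pair("ACGTACGT", "ACGTACGT")$percent_similarity, 100)
  expect_equal(align_pair("ACGT", "ACGA")$percent_similarity, 75)
  expect_lte(align_pair("A", "ACGT")$percent_similarity, 25)
  expect_error(align_pair("", "ACGT"), "non-empty")
  # symmetric in percent similarity
  a <- "ACGTACGTTGCA"; b <- "ACGTTCGTTGCA"
  expect_equal(align_pair(a, b)$percent_similarity,
               align_pair(b, a)$percent_similarity)
})

test_that("a constructed hybrid pair is detected with the right invader", {
  model <- demo_model_cached()
  # mirror the canonical event: IGHV4-59 invading an IGHV4-4 rearrangement
  # at the cryptic heptamer closing CDR2
  invaded <- model$genes[model$genes$name == "IGHV4-4*01", ]
  invader <- model$genes[model$genes$name == "IGHV4-59*01", ]
  hep <- find_cryptic_heptamers(invaded$sequence, max_mismatch = 0)
  h_end <- hep$end[which.min(abs(hep$end - 177))]
  hybrid_v <- paste0(substr(invader$sequence, 1, h_end),
                     substr(invaded$sequence, h_end + 1, 297))
  jun <- "GGGACTACGATTAC"   # junction interior shared by the pair
  j <- model$genes[model$genes$name == "IGHJ4*02", ]
  tail <- paste0(jun, j$sequence)
  ann <- annotate_repertoire(tibble::tibble(
    id = c("revised", "partner"), sample_id = "S", compartment = "tumor",
    cell_id = c("c1", "c2"), chain = "heavy",
    sequence = c(paste0(hybrid_v, tail), paste0(invaded$sequence, tail))),
    model, with_d = FALSE, with_mutations = FALSE, with_isotype = FALSE)
  expect_equal(ann$cdr3_aa[1], ann$cdr3_aa[2])
  ev <- detect_vh_replacement(ann, model)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$sequence_id, "revised")
  expect_equal(ev$invader, "IGHV4-59*01")
  expect_equal(ev$invaded, "IGHV4-4*01")
  expect_true(ev$locus_feasible)
  expect_equal(ev$heptamer_mismatches, 0L)
  # the heptamer lies within the +-10 nt window of the crossover
  expect_lte(abs(ev$heptamer_pos + 7L - h_end), 10)
})

test_that("sequences with different CDR-H3 never pair into an event", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 30, seed = 19, shm_rate = 0)
  ann <- annotate_repertoire(s$reads[s$reads$chain == "heavy", ], model,
                             with_d = FALSE, with_mutations = FALSE,
                             with_isotype = FALSE)
  ev <- detect_vh_replacement(ann, model)
  expect_equal(nrow(ev), 0)
})

test_that("lambda secondary detection requires the published signature", {
  model <- demo_model_cached()
  base <- tibble::tibble(
    sample_id = "S", compartment = "tumor", chain = "lambda",
    v_read_start = 1L, v_read_end = 297L, cys_start = 295L)
  grp <- dplyr::bind_rows(
    dplyr::mutate(base, id = "p", cell_id = "c1", v_call = "IGLV1-51*01",
                  j_call = "IGLJ2*01", productive = TRUE),
    dplyr::mutate(base, id = "s", cell_id = "c1", v_call = "IGLV2-14*01",
                  j_call = "IGLJ2*01", productive = FALSE))
  ev <- detect_lambda_secondary(grp, model)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$sequence_id, "s")
  expect_equal(ev$kind, "lambda_secondary")
  # secondary V downstream of primary -> reported but flagged infeasible
  expect_false(ev$locus_feasible)
  grp2 <- grp
  grp2$v_call <- c("IGLV2-14*01", "IGLV1-51*01")  # secondary now upstream
  expect_true(detect_lambda_secondary(grp2, model)$locus_feasible)
  # kappa + lambda in a cell is not an event
  grp3 <- grp
  grp3$chain <- c("kappa", "lambda")
  expect_equal(nrow(detect_lambda_secondary(grp3, model)), 0)
  # same V gene -> no event; both productive -> no event
  grp4 <- grp; grp4$v_call <- rep("IGLV1-51*01", 2)
  expect_equal(nrow(detect_lambda_secondary(grp4, model)), 0)
  grp5 <- grp; grp5$productive <- c(TRUE, TRUE)
  expect_equal(nrow(detect_lambda_secondary(grp5, model)), 0)
})

test_that("revision frequency handles the degenerate extremes", {
  universe <- tibble::tibble(sample_id = rep("S", 10),
                             id = sprintf("r%02d", 1:10))
  none <- bcrpipe:::empty_events()
  expect_equal(revision_frequency(none, universe)$per_sample$frequency, 0)
  all_ev <- tibble::tibble(kind = "vh_replacement", sample_id = "S",
                           sequence_id = universe$id)
  expect_equal(revision_frequency(all_ev, universe)$per_sample$frequency, 1)
  empty_universe <- universe[0, ]
  fr <- revision_frequency(none, empty_universe)
  expect_equal(nrow(fr$per_sample), 0)
})

test_that("detectors recover simulated revision rates", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 500, seed = 23, vh_replacement_rate = 0.2,
                 lambda_secondary_rate = 0.17)
  keep <- s$reads$chain %in% c("heavy", "lambda")
  ann <- annotate_repertoire(s$reads[keep, ], model, with_d = FALSE,
                             with_mutations = FALSE, with_isotype = FALSE)
  h <- ann[ann$chain == "heavy", ]
  vh <- detect_vh_replacement(h, model)
  true_vh <- s$truth$id[!is.na(s$truth$revision_kind) &
                          s$truth$revision_kind == "vh_replacement"]
  expect_gte(mean(true_vh %in% vh$sequence_id), 0.8)
  expect_lte(length(setdiff(vh$sequence_id, true_vh)) / nrow(h), 0.02)
  # invader upstream of invaded in every reported event (hard invariant)
  for (i in seq_len(nrow(vh))) {
    expect_equal(relative_position(vh$invader[i], vh$invaded[i], model),
                 "upstream")
  }
  lam <- ann[ann$chain == "lambda", ]
  lv <- detect_lambda_secondary(lam, model)
  true_l <- s$truth$id[!is.na(s$truth$revision_kind) &
                         s$truth$revision_kind == "lambda_secondary"]
  expect_gte(mean(true_l %in% lv$sequence_id), 0.95)
  rec <- revision_frequency(lv, lam)$mean
  expect_lt(abs(rec - length(true_l) / nrow(lam)), 0.05)
})
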