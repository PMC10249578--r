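test_that("annotation of unmutated reads recovers the truth exactly", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 40, seed = 4, shm_rate = 0,
                 unproductive_rate = 0.3)
  ann <- annotate_repertoire(s$reads, model)
  m <- match(ann$id, s$truth$id)
  expect_false(any(ann$unannotatable))
  expect_equal(ann$v_call, s$truth$v_call[m])
  expect_equal(ann$j_call, s$truth$j_call[m])
  h <- ann$chain == "heavy"
  expect_equal(ann$d_call[h], s$truth$d_call[m][h])
  expect_equal(ann$c_call[h], s$truth$c_call[m][h])
  expect_equal(ann$productive, s$truth$productive[m])
  expect_equal(ann$productivity_reason, s$truth$reason[m])
  expect_equal(ann$junction, s$truth$junction[m])
  expect_equal(ann$cdr3_aa, s$truth$cdr3_aa[m])
  # no mutations on unmutated reads
  expect_true(all(ann$s_fr + ann$r_fr + ann$s_cdr + ann$r_cdr == 0))
  expect_true(all(ann$v_identity == 100))
})

test_that("degenerate reads are retained with the unannotatable flag", {
  model <- demo_model_cached()
  reads <- tibble::tibble(
    id = "allN", sample_id = "S", compartment = "other",
    cell_id = NA_character_, chain = "heavy",
    sequence = paste(rep("N", 400), collapse = ""))
  ann <- assign_vdj(reads, model)
  expect_equal(nrow(ann), 1)
  expect_true(ann$unannotatable)
  expect_true(is.na(ann$v_call))
})

test_that("a frameshifted junction is called unproductive", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 10, seed = 8, shm_rate = 0)
  r <- s$reads[s$reads$chain == "heavy", ][1, ]
  t <- s$truth[s$truth$id == r$id, ]
  # delete one base inside the junction interior
  pos <- t$v_len + 4L
  r$sequence <- paste0(substr(r$sequence, 1, pos - 1),
                       substr(r$sequence, pos + 1, nchar(r$sequence)))
  ann <- call_productivity(assign_vdj(r, model))
  expect_false(ann$productive)
  expect_equal(ann$productivity_reason, "frameshift")
})

test_that("S/R classification follows the codon-table oracle", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 5, seed = 6, shm_rate = 0)
  r <- s$reads[s$reads$chain == "heavy", ][1, ]
  t <- s$truth[s$truth$id == r$id, ]
  g <- model$genes[model$genes$name == t$v_call, ]
  gseq <- g$sequence
  code <- Biostrings::GENETIC_CODE
  # find a synonymous substitution in FR1 (codons 2..20)
  syn <- NULL; rep_mut <- NULL
  for (cdn in 2:20) {
    c0 <- (cdn - 1) * 3 + 1
    codon <- substr(gseq, c0, c0 + 2)
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- b
      if (is.null(syn) && code[[mut]] == code[[codon]]) {
        syn <- c0 + p - 1
        syn_base <- b
      }
      if (is.null(rep_mut) && code[[mut]] != code[[codon]] &&
          code[[mut]] != "*") {
        rep_mut <- c0 + p - 1
        rep_base <- b
      }
    }
  }
  r_syn <- r
  substr(r_syn$sequence, syn, syn) <- syn_base
  ann <- profile_mutations(call_productivity(assign_vdj(r_syn, model)), model)
  expect_equal(ann$s_fr, 1L)
  expect_equal(ann$r_fr + ann$s_cdr + ann$r_cdr, 0L)
  r_rep <- r
  substr(r_rep$sequence, rep_mut, rep_mut) <- rep_base
  ann2 <- profile_mutations(call_productivity(assign_vdj(r_rep, model)), model)
  expect_equal(ann2$r_fr, 1L)
  expect_equal(ann2$s_fr + ann2$s_cdr + ann2$r_cdr, 0L)
})

test_that("S+R equals the Hamming mismatches of the aligned V region", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 40, seed = 9, shm_rate = 0.02)
  ann <- annotate_repertoire(s$reads, model)
  ok <- !ann$unannotatable
  for (i in which(ok)) {
    g <- model$genes$sequence[model$genes$name == ann$v_call[i]]
    read_v <- substr(ann$sequence[i], ann$v_read_start[i], ann$v_read_end[i])
    germ_v <- substr(g, ann$v_germ_start[i], ann$v_germ_end[i])
    if (nchar(read_v) != nchar(germ_v)) next  # oracle defined gap-free
    hamming <- sum(strsplit(read_v, "")[[1]] != strsplit(germ_v, "")[[1]])
    expect_equal(ann$s_fr[i] + ann$r_fr[i] + ann$s_cdr[i] + ann$r_cdr[i],
                 hamming)
  }
})

test_that("isotype calling needs a constant fragment and a clear margin", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 10, seed = 12, shm_rate = 0, constant_trunc = 60)
  r <- s$reads[s$reads$chain == "heavy", ][1, ]
  t <- s$truth[s$truth$id == r$id, ]
  ann <- annotate_repertoire(r, model)
  expect_equal(ann$c_call, t$c_call)
  # strip the constant fragment -> unassigned
  r2 <- r
  r2$sequence <- substr(r2$sequence, 1, nchar(r2$sequence) - 60)
  ann2 <- annotate_repertoire(r2, model)
  expect_equal(ann2$c_call, "unassigned")
  # light chains alone are rejected
  lt <- s$reads[s$reads$chain != "heavy", ][1, ]
  expect_error(assign_isotype(assign_vdj(lt, model), model), "heavy")
})

test_that("gene-call accuracy holds under SHM", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 150, seed = 10, shm_rate = 0.02)
  ann <- annotate_repertoire(s$reads, model, with_d = FALSE,
                             with_mutations = FALSE)
  m <- match(ann$id, s$truth$id)
  expect_gte(mean(ann$v_call == s$truth$v_call[m], na.rm = TRUE), 0.99)
  expect_gte(mean(ann$j_call == s$truth$j_call[m], na.rm = TRUE), 0.99)
  h <- ann$chain == "heavy"
  expect_gte(mean(ann$c_call[h] == s$truth$c_call[m][h], na.rm = TRUE), 0.98)
})

test_that("collapse_unique keeps one copy per variable domain with counts", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 4, seed = 14, shm_rate = 0)
  r <- s$reads[s$reads$chain == "heavy", ][1, ]
  reads <- dplyr::bind_rows(
    r,
    dplyr::mutate(r, id = paste0(r$id, "_dup1")),
    dplyr::mutate(r, id = paste0(r$id, "_dup2")),
    dplyr::mutate(s$reads[s$reads$chain == "heavy", ][2, ], id = "other"))
  ann <- collapse_unique(annotate_repertoire(reads, model,
                                             with_mutations = FALSE))
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$copy_count, c(3L, 1L))
  # duplicates differing only in the constant fragment stay one sequence
  r_c <- dplyr::mutate(r, id = "swapc")
  r_c$sequence <- paste0(substr(r_c$sequence, 1, nchar(r_c$sequence) - 60),
                         substr(model$genes$sequence[
                           model$genes$name == "IGHE"], 1, 60))
  ann2 <- collapse_unique(annotate_repertoire(dplyr::bind_rows(r, r_c),
                                              model, with_mutations = FALSE))
  expect_equal(nrow(ann2), 1)
  expect_equal(ann2$copy_count, 2L)
})
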