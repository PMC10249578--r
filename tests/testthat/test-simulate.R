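test_that("simulation is deterministic given a seed", {
  s1 <- quick_sim(n_cells = 40, seed = 7, vh_replacement_rate = 0.1,
                  lambda_secondary_rate = 0.1)
  s2 <- quick_sim(n_cells = 40, seed = 7, vh_replacement_rate = 0.1,
                  lambda_secondary_rate = 0.1)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero revision rates produce zero revision events", {
  s <- quick_sim(n_cells = 60, seed = 3)
  expect_true(all(is.na(s$truth$revision_kind)))
})

test_that("sim_config validates its inputs", {
  model <- demo_model_cached()
  expect_error(sim_config(model, shm_rate = 1.5), "probabilities")
  expect_error(sim_config(model, cdr_hotspot_multiplier = 0.5))
  expect_error(sim_config(model,
                          isotype_prior = c(IGHM = 0.5, IGHG1 = 0.4)))
  expect_error(sim_config(model, junction_trim_range = c(-1, 3)))
})

test_that("replacement event count follows the binomial oracle", {
  # events are drawn per heavy sequence at rate 0.2; draws whose founder V
  # has no upstream neighbor (1 of 10 genes) are infeasible and skipped, so
  # realized counts are Binomial(n_cells, 0.2 * 9/10)
  s <- quick_sim(n_cells = 2000, seed = 21, vh_replacement_rate = 0.2)
  n_events <- sum(!is.na(s$truth$revision_kind) &
                    s$truth$revision_kind == "vh_replacement")
  p <- 0.2 * 9 / 10
  expected <- 2000 * p
  sd3 <- 3 * sqrt(2000 * p * (1 - p))
  expect_gt(n_events, expected - sd3)
  expect_lt(n_events, expected + sd3)
})

test_that("every simulated replacement invader lies upstream of the invaded", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 300, seed = 5, vh_replacement_rate = 0.3,
                 lambda_secondary_rate = 0.3)
  ev <- s$truth[!is.na(s$truth$revision_kind) &
                  s$truth$revision_kind == "vh_replacement", ]
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev))) {
    expect_equal(relative_position(ev$invader[i], ev$invaded[i], model),
                 "upstream")
  }
  lam <- s$truth[!is.na(s$truth$revision_kind) &
                   s$truth$revision_kind == "lambda_secondary", ]
  expect_gt(nrow(lam), 0)
  expect_true(all(!lam$productive))
  # locus-feasible secondaries use an upstream V
  feas <- lam[lam$locus_feasible, ]
  for (i in seq_len(nrow(feas))) {
    expect_equal(relative_position(feas$invader[i], feas$invaded[i], model),
                 "upstream")
  }
})

test_that("emitted constant fragment always matches the truth isotype", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 80, seed = 13, csr_probability = 0.4)
  h <- s$truth[s$truth$chain == "heavy", ]
  reads <- s$reads[match(h$id, s$reads$id), ]
  iso2gene <- stats::setNames(names(bcrpipe:::ISOTYPE_LABEL),
                              bcrpipe:::ISOTYPE_LABEL)
  for (i in seq_len(nrow(h))) {
    gene <- iso2gene[[h$c_call[i]]]
    cseq <- substr(model$genes$sequence[model$genes$name == gene], 1, 60)
    expect_identical(substr(reads$sequence[i],
                            nchar(reads$sequence[i]) - 59,
                            nchar(reads$sequence[i])), cseq)
  }
})

test_that("class switching never moves upstream within a clone", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 200, seed = 17, csr_probability = 0.5)
  h <- s$truth[s$truth$chain == "heavy" & !is.na(s$truth$clone_id), ]
  iso2gene <- stats::setNames(names(bcrpipe:::ISOTYPE_LABEL),
                              bcrpipe:::ISOTYPE_LABEL)
  ranks <- match(iso2gene[h$c_call], model$constant_order)
  # members of a clone are the founder isotype or strictly downstream of
  # it, so the clone minimum is the founder and nothing is upstream of it
  by_clone <- split(ranks, h$clone_id)
  n_multi_iso <- 0
  for (r in by_clone) {
    expect_true(all(r >= min(r)))
    if (length(unique(r)) > 1) n_multi_iso <- n_multi_iso + 1
  }
  expect_gt(n_multi_iso, 0)  # CSR actually exercised
})

test_that("realized mutation rates match configuration (chi-square GOF)", {
  # FR bases mutate at shm_rate and CDR bases at shm_rate * multiplier;
  # test realized counts per region over >= 10^4 bases, across seeds
  model <- demo_model_cached()
  rate <- 0.02
  mult <- 3
  rejected <- 0
  for (seed in 1:6) {
    s <- quick_sim(n_cells = 60, seed = seed, shm_rate = rate,
                   cdr_hotspot_multiplier = mult)
    n_reads <- nrow(s$truth)
    fr_bases <- sum(s$truth$v_len) - n_reads * 48  # 48 CDR1+CDR2 nt per V
    cdr_bases <- n_reads * 48
    muts <- dplyr::bind_rows(s$truth$mutations)
    obs <- c(FR = sum(muts$region == "FR"), CDR = sum(muts$region == "CDR"))
    expected <- c(fr_bases * rate, cdr_bases * rate * mult)
    chi <- sum((obs - expected)^2 / expected)
    if (chi > stats::qchisq(0.99, df = 2)) rejected <- rejected + 1
  }
  expect_lte(rejected, 1)
})

test_that("truth table round-trips through TSV", {
  s <- quick_sim(n_cells = 30, seed = 2, vh_replacement_rate = 0.2,
                 lambda_secondary_rate = 0.2)
  path <- tempfile(fileext = ".tsv")
  write_truth(s$truth, path)
  back <- read_truth(path)
  expect_equal(nrow(back), nrow(s$truth))
  expect_equal(back$id, s$truth$id)
  expect_equal(back$v_call, s$truth$v_call)
  expect_equal(back$productive, s$truth$productive)
  expect_equal(back$n_mutations, s$truth$n_mutations)
  # mutation lists are reconstructed exactly
  for (i in which(s$truth$n_mutations > 0)[1:5]) {
    expect_equal(as.data.frame(back$mutations[[i]]),
                 as.data.frame(s$truth$mutations[[i]]))
  }
  # empty truth gives a header-only file
  p2 <- tempfile(fileext = ".tsv")
  write_truth(s$truth[0, ], p2)
  expect_length(readLines(p2), 1)
})
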