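make_seq <- function(base, positions, to = "T") {
  x <- base
  for (p in positions) substr(x, p, p) <- to
  x
}

test_that("a single-member clone yields one edge carrying all mutations", {
  g <- paste(rep("ACG", 40), collapse = "")
  s <- make_seq(g, c(4, 31))
  lt <- build_lineage(g, c(m = s))
  expect_equal(nrow(lt$edges), 1)
  expect_equal(lt$edges$parent, "germline")
  expect_equal(lt$edges$child, "m")
  expect_equal(lt$edges$n_mutations, 2L)
  expect_equal(sort(lt$edges$mutations[[1]]$position), c(3L, 30L))
})

test_that("a mutation shared by two members sits on their shared branch", {
  g <- paste(rep("ACG", 40), collapse = "")
  s1 <- make_seq(g, 4)
  s2 <- make_seq(g, c(4, 31))
  s3 <- make_seq(g, 61)
  lt <- build_lineage(g, c(m1 = s1, m2 = s2, m3 = s3))
  shared <- lt$edges[lt$edges$parent == "germline" &
                       grepl("inferred", lt$edges$child), ]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$mutations[[1]]$position, 3L)
  # private mutations hang off the intermediate
  kids <- lt$edges[lt$edges$parent == shared$child, ]
  expect_setequal(kids$child, c("m1", "m2"))
  expect_equal(kids$n_mutations[kids$child == "m1"], 0L)
  expect_equal(kids$n_mutations[kids$child == "m2"], 1L)
})

test_that("mutations along any root-to-leaf path sum to the leaf's own set", {
  g <- paste(rep("ACGTG", 30), collapse = "")
  set.seed(42)
  members <- stats::setNames(lapply(1:5, function(i) {
    make_seq(g, sample(nchar(g), sample(1:5, 1)))
  }), paste0("m", 1:5))
  lt <- build_lineage(g, unlist(members))
  gchars <- strsplit(g, "")[[1]]
  paths <- function(node) {
    kids <- lt$edges[lt$edges$parent == node, ]
    if (nrow(kids) == 0) return(list(node))
    unlist(lapply(seq_len(nrow(kids)), function(e) {
      lapply(paths(kids$child[e]), function(p) c(node, p))
    }), recursive = FALSE)
  }
  for (p in paths("germline")) {
    leaf <- p[length(p)]
    if (!leaf %in% names(members)) next
    accum <- integer(0)
    for (i in seq_len(length(p) - 1)) {
      e <- which(lt$edges$parent == p[i] & lt$edges$child == p[i + 1])
      m <- lt$edges$mutations[[e]]
      if (!is.null(m)) accum <- c(accum, m$position)
    }
    truth <- which(strsplit(members[[leaf]], "")[[1]] != gchars) - 1L
    expect_setequal(accum, truth)
  }
})

test_that("parsimony score never exceeds the generating genealogy's score", {
  g <- paste(rep("ACGTG", 30), collapse = "")
  # true genealogy: root -> a (2 muts); a -> b (+1), a -> c (+2); root -> d (1)
  a <- make_seq(g, c(10, 50))
  b <- make_seq(a, 80)
  c_ <- make_seq(a, c(100, 120))
  d <- make_seq(g, 140)
  true_score <- 2 + 1 + 2 + 1
  lt <- build_lineage(g, c(a = a, b = b, c = c_, d = d))
  expect_lte(lt$parsimony_score, true_score)
  # and the reconstruction places the shared pair on one branch
  expect_gte(sum(grepl("inferred", lt$edges$child) |
                   lt$edges$child == "a"), 1)
})

test_that("members with incompatible length are excluded with a warning", {
  g <- paste(rep("ACG", 30), collapse = "")
  expect_warning(
    lt <- build_lineage(g, c(ok = make_seq(g, 5), bad = substr(g, 1, 50))),
    "incompatible")
  expect_equal(nrow(lt$edges), 1)
})

test_that("lineage export writes Newick plus a JSON mutation sidecar", {
  g <- paste(rep("ACG", 40), collapse = "")
  lt <- build_lineage(g, c(m1 = make_seq(g, 4), m2 = make_seq(g, c(4, 31))))
  nwk_path <- tempfile(fileext = ".nwk")
  json_path <- tempfile(fileext = ".json")
  nwk <- write_lineage(lt, nwk_path, json_path)
  expect_true(file.exists(nwk_path))
  expect_match(nwk, "germline;$")
  expect_match(nwk, "\\[&&NHX:muts=")
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  expect_equal(nrow(side), nrow(lt$edges))
  expect_setequal(side$child, lt$edges$child)
})

test_that("intra-clone CSR events are always downstream in constant order", {
  model <- demo_model_cached()
  ev <- detect_csr_within_clone(c("IgG1", "IgG2", "IgG1"), model)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$from, "IgG1")
  expect_equal(ev$events$to, "IgG2")
  expect_equal(ev$events$n_from, 2L)
  expect_equal(nrow(detect_csr_within_clone(rep("IgM", 4), model)$events), 0)
  ev2 <- detect_csr_within_clone(c("IgA2", "IgG1"), model)
  expect_equal(ev2$events$from, "IgG1")
  expect_equal(ev2$events$to, "IgA2")
  # order constraint holds across random isotype multisets
  isos <- unname(bcrpipe:::ISOTYPE_LABEL)
  iso2gene <- stats::setNames(names(bcrpipe:::ISOTYPE_LABEL), isos)
  set.seed(1)
  for (i in 1:20) {
    members <- sample(isos, sample(2:6, 1), replace = TRUE)
    evs <- detect_csr_within_clone(members, model)$events
    if (nrow(evs) == 0) next
    expect_true(all(match(iso2gene[evs$from], model$constant_order) <
                      match(iso2gene[evs$to], model$constant_order)))
  }
})

test_that("parsimony recovers internal mutation placements on simulated clones", {
  model <- demo_model_cached()
  g <- paste(rep("ACGTG", 30), collapse = "")
  set.seed(7)
  hits <- 0; total <- 0
  for (rep in 1:5) {
    shared <- sample(nchar(g), 2)
    a <- make_seq(g, shared)
    leaves <- stats::setNames(lapply(1:4, function(i) {
      make_seq(a, sample(setdiff(seq_len(nchar(g)), shared), 2))
    }), paste0("m", 1:4))
    lt <- build_lineage(g, unlist(leaves))
    internal <- lt$edges[grepl("inferred", lt$edges$child), ]
    placed <- unlist(lapply(internal$mutations, function(m) m$position))
    hits <- hits + sum((shared - 1L) %in% placed)
    total <- total + length(shared)
  }
  expect_gte(hits / total, 0.9)
})
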