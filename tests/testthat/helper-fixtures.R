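# Shared fixtures and independent oracles for the test suite.

demo_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- demo_locus_model()
    m
  }
})

# Rand index between two partitions (pair-counting, contingency form)
rand_index <- function(x, y) {
  n <- length(x)
  ct <- table(x, y)
  a <- sum(choose(ct, 2))
  r <- sum(choose(rowSums(ct), 2))
  cc <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  (tot + 2 * a - r - cc) / tot
}

# brute-force clonotype oracle: connected components of the <= cut graph
brute_clone_components <- function(cdr3, cut) {
  n <- length(cdr3)
  d <- utils::adist(cdr3) / outer(nchar(cdr3), nchar(cdr3), pmax)
  g <- igraph::graph_from_adjacency_matrix(d <= cut, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# brute-force cryptic heptamer scan, independent of the implementation
brute_heptamers <- function(s, max_mm = 1L) {
  motif <- c("C", "A", "C", "A", "G", "T", "G")
  x <- strsplit(s, "")[[1]]
  hits <- integer(0)
  mms <- integer(0)
  for (p in seq_len(max(0, length(x) - 6L))) {
    w <- x[p:(p + 6L)]
    if (!identical(w[1:3], c("C", "A", "C"))) next
    mm <- sum(w != motif)
    if (mm <= max_mm) {
      hits <- c(hits, p - 1L)
      mms <- c(mms, mm)
    }
  }
  list(start = hits, mismatches = mms)
}

random_cdr3s <- function(n, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # a few founder motifs plus noise, so clusters of various sizes form
  founders <- replicate(max(2, n %/% 8), paste(
    sample(aa, sample(8:14, 1), replace = TRUE), collapse = ""))
  vapply(seq_len(n), function(i) {
    base <- sample(founders, 1)
    x <- strsplit(base, "")[[1]]
    k <- sample(0:2, 1)
    if (k > 0) {
      pos <- sample(seq_along(x), k)
      x[pos] <- sample(aa, k, replace = TRUE)
    }
    paste(x, collapse = "")
  }, character(1))
}

# small simulated repertoire shared by a few tests
quick_sim <- function(n_cells = 100, seed = 1, ...) {
  suppressWarnings(simulate_repertoire(
    sim_config(demo_model_cached(), n_cells = n_cells, seed = seed, ...)))
}
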