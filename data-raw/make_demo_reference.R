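# One-off generator for the packaged synthetic demo germline reference.
# Deterministic; writes inst/extdata/demo_germline_synthetic.{fasta,tsv}.
set.seed(20231)

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")
CODONS <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
NONSTOP <- setdiff(CODONS, STOPS)

random_orf <- function(n_codons) {
  paste(sample(NONSTOP, n_codons, replace = TRUE), collapse = "")
}

# Mutate ~rate of positions, keeping codons stop-free and fixed windows intact.
mutate_seq <- function(s, rate, fixed = integer(0)) {
  x <- strsplit(s, "")[[1]]
  k <- max(1L, round(rate * length(x)))
  pos <- sample(setdiff(seq_along(x), fixed), k)
  for (p in pos) x[p] <- sample(setdiff(BASES, x[p]), 1)
  # repair stop codons outside fixed windows
  for (c0 in seq(1, length(x) - 2, by = 3)) {
    if (paste(x[c0:(c0 + 2)], collapse = "") %in% STOPS &&
        !any((c0:(c0 + 2)) %in% fixed)) {
      x[c0:(c0 + 2)] <- strsplit(sample(NONSTOP, 1), "")[[1]]
    }
  }
  paste(x, collapse = "")
}

make_v <- function(base = NULL, heptamer = TRUE) {
  # 297 nt = 99 codons; FR1 [0,78) CDR1 [78,102) FR2 [102,153) CDR2 [153,177)
  # FR3 [177,297); cryptic RSS heptamer CACAGTG at [170,177) (end of CDR2);
  # conserved Cys codon TGT at [294,297).
  if (is.null(base)) base <- random_orf(99)
  x <- strsplit(base, "")[[1]]
  fixed <- c(295:297)
  x[295:297] <- c("T", "G", "T")
  if (heptamer) {
    x[171:177] <- strsplit("CACAGTG", "")[[1]]
    fixed <- c(fixed, 171:177)
  }
  s <- paste(x, collapse = "")
  # fix any stop introduced by the overlay
  mutate_seq(s, rate = 0, fixed = fixed)
}

sibling_v <- function(parent, heptamer = TRUE) {
  fixed <- c(295:297, if (heptamer) 171:177)
  mutate_seq(parent, 0.06, fixed = fixed)
}

# random sequence with no stop triplet at ANY offset: J overhangs and D
# segments are read in junction-dependent frames, so a stop in every frame
# would make some rearrangements unbuildable
no_stop_seq <- function(n) {
  repeat {
    s <- paste(sample(BASES, n, replace = TRUE), collapse = "")
    windows <- substring(s, 1:(n - 2), 3:n)
    if (!any(windows %in% STOPS)) return(s)
  }
}

make_j_heavy <- function() {
  # 12 nt overhang + TGG anchor + 30 nt in-frame tail; anchor [12,15)
  paste0(no_stop_seq(12), "TGG", random_orf(10))
}
make_j_light <- function() {
  # 10 nt overhang + TTC anchor + 27 nt in-frame tail; anchor [10,13)
  paste0(no_stop_seq(10), "TTC", random_orf(9))
}

v_bounds <- "0,78,78,102,102,153,153,177,177,297"

rows <- list()
add <- function(name, locus, segment, family, position, sequence, boundaries = "") {
  rows[[length(rows) + 1]] <<- data.frame(
    name = name, locus = locus, segment = segment, family = family,
    position = position, sequence = sequence, boundaries = boundaries,
    stringsAsFactors = FALSE)
}

# --- IGHV: 10 alleles ----------------------------------------------------
# Real V genes descend from a common ancestor: families diverge ~12% from
# a locus ancestor and alleles ~5% within a family, giving realistic
# within-family (~10%) and between-family (~20-25%) divergence.
anc_h <- make_v()
fam_of <- function(anc, heptamer = TRUE) {
  fixed <- c(295:297, if (heptamer) 171:177)
  mutate_seq(anc, 0.12, fixed = fixed)
}
fam1 <- fam_of(anc_h); fam3 <- fam_of(anc_h); fam4 <- fam_of(anc_h)
fam6 <- fam_of(anc_h)
ighv <- list(
  list("IGHV3-74*01", "IGHV3", 1, sibling_v(fam3)),
  list("IGHV4-61*01", "IGHV4", 2, sibling_v(fam4)),
  list("IGHV4-59*01", "IGHV4", 3, sibling_v(fam4)),
  list("IGHV1-46*01", "IGHV1", 4, sibling_v(fam1)),
  list("IGHV3-33*01", "IGHV3", 5, sibling_v(fam3)),
  list("IGHV4-34*01", "IGHV4", 6, sibling_v(fam4)),
  list("IGHV3-23*01", "IGHV3", 7, sibling_v(fam3)),
  list("IGHV1-18*01", "IGHV1", 8, sibling_v(fam1)),
  list("IGHV4-4*01",  "IGHV4", 9, sibling_v(fam4)),
  list("IGHV6-1*01",  "IGHV6", 10, sibling_v(fam6))
)
for (g in ighv) add(g[[1]], "IGH", "V", g[[2]], g[[3]], g[[4]], v_bounds)

# --- IGHD: 5 alleles ------------------------------------------------------
ighd <- list(
  list("IGHD1-26*01", "IGHD1", 1, 18),
  list("IGHD2-15*01", "IGHD2", 2, 22),
  list("IGHD3-10*01", "IGHD3", 3, 20),
  list("IGHD4-17*01", "IGHD4", 4, 17),
  list("IGHD6-19*01", "IGHD6", 5, 19)
)
for (g in ighd) {
  add(g[[1]], "IGH", "D", g[[2]], g[[3]], no_stop_seq(g[[4]]))
}

# --- IGHJ: 6 alleles ------------------------------------------------------
j_names <- c("IGHJ1*01", "IGHJ2*01", "IGHJ3*01", "IGHJ4*02", "IGHJ5*01", "IGHJ6*01")
for (i in seq_along(j_names)) {
  add(j_names[i], "IGH", "J", sub("\\*.*", "", j_names[i]), i,
      make_j_heavy(), "12,15")
}

# --- IGHC: 9 alleles in deletional CSR order ------------------------------
ighc <- c("IGHM", "IGHD", "IGHG3", "IGHG1", "IGHA1", "IGHG2", "IGHG4",
          "IGHE", "IGHA2")
for (i in seq_along(ighc)) {
  add(ighc[i], "IGH", "C", ighc[i], i,
      paste(sample(BASES, 120, replace = TRUE), collapse = ""))
}

# --- light-chain V (kappa + lambda), no packaged heptamer -----------------
anc_k <- make_v(heptamer = FALSE)
kfam <- replicate(4, fam_of(anc_k, heptamer = FALSE))
igkv <- list(
  list("IGKV1-5*01",  "IGKV1", 1), list("IGKV3-20*01", "IGKV3", 2),
  list("IGKV2-28*01", "IGKV2", 3), list("IGKV4-1*01",  "IGKV4", 4)
)
for (i in seq_along(igkv)) {
  add(igkv[[i]][[1]], "IGK", "V", igkv[[i]][[2]], igkv[[i]][[3]],
      kfam[i], v_bounds)
}
anc_l <- make_v(heptamer = FALSE)
lfam <- replicate(4, fam_of(anc_l, heptamer = FALSE))
iglv <- list(
  list("IGLV1-51*01", "IGLV1", 1), list("IGLV2-23*01", "IGLV2", 2),
  list("IGLV2-14*01", "IGLV2", 3), list("IGLV3-21*01", "IGLV3", 4)
)
for (i in seq_along(iglv)) {
  add(iglv[[i]][[1]], "IGL", "V", iglv[[i]][[2]], iglv[[i]][[3]],
      lfam[i], v_bounds)
}

# --- light-chain J --------------------------------------------------------
for (g in list(list("IGKJ1*01", 1), list("IGKJ4*01", 2))) {
  add(g[[1]], "IGK", "J", sub("\\*.*", "", g[[1]]), g[[2]],
      make_j_light(), "10,13")
}
for (g in list(list("IGLJ1*01", 1), list("IGLJ2*01", 2), list("IGLJ3*01", 3))) {
  add(g[[1]], "IGL", "J", sub("\\*.*", "", g[[1]]), g[[2]],
      make_j_light(), "10,13")
}

tab <- do.call(rbind, rows)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
fa <- file("inst/extdata/demo_germline_synthetic.fasta", "w")
for (i in seq_len(nrow(tab))) {
  cat(">", tab$name[i], "\n", sep = "", file = fa)
  s <- tab$sequence[i]
  for (j in seq(1, nchar(s), by = 70)) {
    cat(substr(s, j, min(j + 69, nchar(s))), "\n", sep = "", file = fa)
  }
}
close(fa)

hdr <- paste0(
  "# Synthetic demo germline locus table (invented sequences, valid structure).\n",
  "# position: 5'->3' rank P within (locus, segment); 1 = most distal/upstream.\n",
  "# boundaries: comma-separated 0-based half-open offsets. V genes:\n",
  "#   fr1_start,fr1_end,cdr1_start,cdr1_end,fr2_start,fr2_end,cdr2_start,\n",
  "#   cdr2_end,fr3_start,fr3_end (FR3 ends after the conserved Cys codon).\n",
  "# J genes: anchor_start,anchor_end of the conserved Trp (heavy) / Phe\n",
  "# (light) codon. Empty for D and C genes.\n")
out <- "inst/extdata/demo_locus_table_synthetic.tsv"
cat(hdr, file = out)
suppressWarnings(write.table(
  tab[, c("name", "locus", "segment", "family", "position", "boundaries")],
  out, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
cat("written", nrow(tab), "alleles\n")
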