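#' @importFrom dplyr %>% filter mutate arrange group_by summarise ungroup n
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# Deletional class-switch order of the human IGH constant locus, 5' to 3'.
IGHC_ORDER <- c("IGHM", "IGHD", "IGHG3", "IGHG1", "IGHA1",
                "IGHG2", "IGHG4", "IGHE", "IGHA2")

# Constant gene -> isotype label used in outputs.
ISOTYPE_LABEL <- c(IGHM = "IgM", IGHD = "IgD", IGHG3 = "IgG3", IGHG1 = "IgG1",
                   IGHA1 = "IgA1", IGHG2 = "IgG2", IGHG4 = "IgG4",
                   IGHE = "IgE", IGHA2 = "IgA2")

#' Construct a germline locus model
#'
#' A `locus_model` bundles the germline V/D/J/C alleles of the heavy and light
#' chain loci together with their locus geometry: each allele carries a 5'->3'
#' rank `locus_position` (P, 1 = most distal/upstream within its locus and
#' segment class) that grounds all upstream/downstream reasoning, and the nine
#' IGH constant genes are held in deletional class-switch order
#' (IgM ... IgA2), so that class switching can only move to genes later in
#' that order.
#'
#' @param genes A data frame with columns `name`, `locus` (IGH/IGK/IGL),
#'   `segment` (V/D/J/C), `family`, `sequence` (A/C/G/T, ungapped),
#'   `locus_position` (integer rank P), and `boundaries` (list column; for V
#'   genes a named integer vector of 0-based half-open region offsets
#'   `fr1_start, fr1_end, cdr1_start, cdr1_end, fr2_start, fr2_end,
#'   cdr2_start, cdr2_end, fr3_start, fr3_end`; for J genes the anchor codon
#'   offsets `anchor_start, anchor_end`; empty otherwise).
#' @param constant_order Character vector giving the IGH constant genes in
#'   deletional CSR order; defaults to the canonical nine-gene order.
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(genes, constant_order = IGHC_ORDER) {
  genes <- as_tibble(genes)
  required <- c("name", "locus", "segment", "family", "sequence",
                "locus_position", "boundaries")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("germline table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(genes$name)) {
    stop("duplicate allele name(s): ",
         paste(unique(genes$name[duplicated(genes$name)]), collapse = ", "))
  }
  if (any(!nzchar(genes$sequence)) ||
      any(grepl("[^ACGT]", genes$sequence))) {
    stop("germline sequences must be non-empty and over {A,C,G,T}")
  }
  if (!setequal(constant_order, IGHC_ORDER) || length(constant_order) != 9) {
    stop("constant_order must contain exactly the 9 IGH constant genes")
  }
  # locus_position unique within (locus, segment)
  dup <- genes %>%
    group_by(.data$locus, .data$segment, .data$locus_position) %>%
    summarise(k = n(), .groups = "drop") %>%
    filter(.data$k > 1)
  if (nrow(dup) > 0) {
    stop("locus_position not unique within (locus, segment)")
  }
  # V-gene region boundaries strictly increasing and within sequence
  for (i in which(genes$segment == "V")) {
    b <- genes$boundaries[[i]]
    if (length(b) != 10 || any(diff(b) < 0) || any(b < 0) ||
        max(b) > nchar(genes$sequence[i]) || b[1] >= b[10]) {
      stop("invalid V region boundaries for ", genes$name[i])
    }
  }
  for (i in which(genes$segment == "J")) {
    b <- genes$boundaries[[i]]
    if (length(b) != 2 || b[2] - b[1] != 3 ||
        b[2] > nchar(genes$sequence[i])) {
      stop("invalid J anchor offsets for ", genes$name[i])
    }
  }
  structure(list(genes = genes, constant_order = constant_order),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  tab <- table(x$genes$locus, x$genes$segment)
  cat("<locus_model> ", nrow(x$genes), " germline alleles\n", sep = "")
  print(tab)
  invisible(x)
}

#' Load a germline reference from FASTA plus a locus table
#'
#' Reads germline alleles from a FASTA file (plain or IMGT-gapped with `.`)
#' whose headers carry allele names, and a tab-separated locus table mapping
#' each allele to its locus, segment class, family, 5'->3' locus rank P and,
#' for V genes, 0-based half-open FR/CDR region offsets (for J genes, the
#' conserved Trp/Phe anchor codon offsets). Gapped V sequences are de-gapped
#' and the region offsets, which refer to gapped coordinates, are recomputed
#' on the ungapped sequence.
#'
#' @param fasta Path to the germline FASTA.
#' @param locus_table Path to the locus table TSV with columns `name`,
#'   `locus`, `segment`, `family`, `position` and `boundaries`
#'   (comma-separated 0-based offsets, empty for D/C genes).
#' @return A [locus_model()].
#' @export
load_germline_fasta <- function(fasta, locus_table) {
  seqs <- Biostrings::readBStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate allele name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  tab <- utils::read.delim(locus_table, comment.char = "#",
                           colClasses = "character")
  missing <- setdiff(nm, tab$name)
  if (length(missing) > 0) {
    stop("gene(s) in FASTA absent from locus table: ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[match(nm, tab$name), ]
  raw <- toupper(as.character(seqs))
  boundaries <- vector("list", length(nm))
  sequence <- character(length(nm))
  for (i in seq_along(nm)) {
    s <- raw[i]
    b <- if (nzchar(tab$boundaries[i])) {
      as.integer(strsplit(tab$boundaries[i], ",")[[1]])
    } else {
      integer(0)
    }
    if (grepl("\\.", s)) {
      # IMGT-gapped: offsets refer to gapped coordinates; shift each by the
      # number of gap characters preceding it.
      gap <- strsplit(s, "")[[1]] == "."
      cumgap <- cumsum(gap)
      b <- vapply(b, function(off) {
        off - if (off == 0) 0L else cumgap[off]
      }, integer(1))
      s <- gsub("\\.", "", s)
    }
    if (length(b) > 0) {
      names(b) <- if (tab$segment[i] == "V") {
        c("fr1_start", "fr1_end", "cdr1_start", "cdr1_end", "fr2_start",
          "fr2_end", "cdr2_start", "cdr2_end", "fr3_start", "fr3_end")
      } else {
        c("anchor_start", "anchor_end")
      }
    }
    boundaries[[i]] <- b
    sequence[i] <- s
  }
  genes <- tibble(
    name = nm,
    locus = tab$locus,
    segment = tab$segment,
    family = tab$family,
    sequence = sequence,
    locus_position = as.integer(tab$position),
    boundaries = boundaries
  )
  locus_model(genes)
}

#' Write a locus model back to FASTA + locus table
#'
#' Inverse of [load_germline_fasta()]; round-trips losslessly for ungapped
#' references.
#'
#' @param model A [locus_model()].
#' @param fasta,locus_table Output paths.
#' @export
write_germline_fasta <- function(model, fasta, locus_table) {
  g <- model$genes
  seqs <- Biostrings::DNAStringSet(g$sequence)
  names(seqs) <- g$name
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)
  tab <- data.frame(
    name = g$name, locus = g$locus, segment = g$segment, family = g$family,
    position = g$locus_position,
    boundaries = vapply(g$boundaries, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, locus_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(model)
}

get_gene <- function(model, name) {
  i <- match(name, model$genes$name)
  if (is.na(name) || is.na(i)) stop("unknown germline gene: ", name)
  model$genes[i, ]
}

gene_position <- function(model, name) {
  g <- get_gene(model, name)
  if (g$segment == "C") {
    match(g$name, model$constant_order)
  } else {
    g$locus_position
  }
}

#' Relative locus position of two germline genes
#'
#' Compares two alleles of the same locus and segment class by their 5'->3'
#' rank P. `"upstream"` means `a` lies 5' (distal) of `b` — for V genes, the
#' side from which a replacement invader must come; for constant genes the
#' order is the deletional class-switch order.
#'
#' @param a,b Allele names.
#' @param model A [locus_model()].
#' @return One of `"upstream"`, `"downstream"`, `"equal"`.
#' @export
relative_position <- function(a, b, model) {
  ga <- get_gene(model, a)
  gb <- get_gene(model, b)
  if (ga$locus != gb$locus || ga$segment != gb$segment) {
    stop("genes from different loci or segment classes: ", a, " vs ", b)
  }
  pa <- gene_position(model, a)
  pb <- gene_position(model, b)
  if (pa < pb) "upstream" else if (pa > pb) "downstream" else "equal"
}

#' Path to the packaged demo germline reference
#'
#' A small, synthetic (invented but structurally valid) germline reference
#' shipped with the package so that all examples and tests run without any
#' download: 10 IGHV, 5 IGHD, 6 IGHJ and the 9 IGHC alleles plus kappa and
#' lambda V/J alleles, under real-world IMGT-style names with a documented
#' locus table. Real IMGT reference files load through the same
#' [load_germline_fasta()] interface.
#'
#' @return Named list with elements `fasta` and `locus_table`.
#' @export
demo_germline_files <- function() {
  list(
    fasta = system.file("extdata", "demo_germline_synthetic.fasta",
                        package = "bcrpipe", mustWork = TRUE),
    locus_table = system.file("extdata", "demo_locus_table_synthetic.tsv",
                              package = "bcrpipe", mustWork = TRUE)
  )
}

#' Load the packaged demo germline reference
#'
#' @return A [locus_model()]; see [demo_germline_files()].
#' @export
demo_locus_model <- function() {
  f <- demo_germline_files()
  load_germline_fasta(f$fasta, f$locus_table)
}
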