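# Ten-factor Kidera set: orthogonal physicochemical descriptors per amino
# acid derived from 188 physical properties; a peptide-level value is the
# arithmetic mean over residues. Rows are the 20 canonical amino acids.
KIDERA <- matrix(c(
  # KF1    KF2    KF3    KF4    KF5    KF6    KF7    KF8    KF9    KF10
  -1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48, # A
   0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93, # R
   1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73, # N
   0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70, # D
   0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10, # C
  -0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33, # Q
  -1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12, # E
   1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46, # G
  -0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63, # H
  -0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78, # I
  -1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93, # L
  -0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60, # K
  -1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27, # M
  -0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44, # F
   2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28, # P
   0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23, # S
   0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19, # T
   0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60, # W
   1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53, # Y
  -0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -1.07,  0.06, -0.46,  0.65  # V
), nrow = 20, byrow = TRUE,
dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                paste0("KF", 1:10)))

# Frozen checksum of the canonical serialization of the packaged table;
# kidera_table() refuses to return a silently altered copy.
KIDERA_MD5 <- "63c087c69db072ee48eed8c117cb53da"

kidera_serialize <- function(m) {
  paste(c(rownames(m), colnames(m), sprintf("%.2f", t(m))), collapse = ",")
}

#' The packaged Kidera factor table
#'
#' Returns the 20 x 10 matrix of Kidera factors after verifying its MD5
#' checksum, guarding against accidental modification of the packaged
#' constant.
#'
#' @return Numeric matrix, rows = amino acids, columns = KF1..KF10.
#' @export
kidera_table <- function() {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(kidera_serialize(KIDERA), f)
  if (unname(tools::md5sum(f)) != KIDERA_MD5) {
    stop("packaged Kidera table failed its checksum")
  }
  KIDERA
}

# Chou-Fasman conformational propensities (P_alpha, P_beta, P_turn); each
# amino acid is assigned to the argmax class. Ties (only Cys) break toward
# strand, documented in the vignette. The mapping is configuration: a
# two-column replacement table can be supplied to structure_propensity().
CHOU_FASMAN <- matrix(c(
  142,  83,  66,  # A
   98,  93,  95,  # R
   67,  89, 156,  # N
  101,  54, 146,  # D
   70, 119, 119,  # C
  111, 110,  98,  # Q
  151,  37,  74,  # E
   57,  75, 156,  # G
  100,  87,  95,  # H
  108, 160,  47,  # I
  121, 130,  59,  # L
  114,  74, 101,  # K
  145, 105,  60,  # M
  113, 138,  60,  # F
   57,  55, 152,  # P
   77,  75, 143,  # S
   83, 119,  96,  # T
  108, 137,  96,  # W
   69, 147, 114,  # Y
  106, 170,  50   # V
), nrow = 20, byrow = TRUE,
dimnames = list(rownames(KIDERA), c("alpha", "beta", "coil")))

STRUCTURE_CLASS <- apply(CHOU_FASMAN, 1, function(p) {
  cls <- colnames(CHOU_FASMAN)[p == max(p)]
  if (length(cls) > 1) cls <- intersect(c("beta", "alpha", "coil"), cls)[1]
  cls
})

#' Kidera-factor descriptor of a CDR3
#'
#' Mean of the ten Kidera factors over the residues of a CDR3 amino-acid
#' sequence. Defined only over the 20 canonical amino acids; sequences with
#' non-canonical residues return `NA` with a warning (record skipped).
#'
#' @param cdr3_aa Amino-acid string (or vector; see [kidera_matrix()]).
#' @return Named numeric vector KF1..KF10.
#' @export
kidera <- function(cdr3_aa) {
  tab <- kidera_table()
  res <- strsplit(cdr3_aa, "")[[1]]
  if (length(res) == 0 || any(!res %in% rownames(tab))) {
    warning("CDR3 with non-canonical residues skipped: ", cdr3_aa)
    return(stats::setNames(rep(NA_real_, 10), colnames(tab)))
  }
  colMeans(tab[res, , drop = FALSE])
}

#' Kidera descriptors for many CDR3s
#'
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @return Numeric matrix, one row per input sequence.
#' @export
kidera_matrix <- function(cdr3_aa) {
  t(vapply(cdr3_aa, function(s) suppressWarnings(kidera(s)), numeric(10)))
}

#' PCA of Kidera descriptors with per-group medians
#'
#' Principal component analysis of the 10-dimensional Kidera vectors,
#' centered (standardization optional: the Kidera factors are already
#' variance-normalized descriptors, so scaling is off by default). Signs
#' are fixed deterministically by forcing the largest-magnitude loading of
#' each component positive. Group medians and inter-quartile ranges of the
#' projected PC1/PC2 coordinates are reported per group (typically
#' sample x isotype).
#'
#' @param vectors Numeric matrix of Kidera vectors (rows = sequences).
#' @param groups Optional grouping vector (length = rows).
#' @param scale. Standardize columns before PCA.
#' @return List with `scores` (PC coordinates), `loadings`, `sdev`,
#'   `group_summary` (median and IQR of PC1/PC2 per group), and
#'   `rank_deficient` flag.
#' @export
kidera_pca <- function(vectors, groups = NULL, scale. = FALSE) {
  keep <- stats::complete.cases(vectors)
  vectors <- vectors[keep, , drop = FALSE]
  if (!is.null(groups)) groups <- groups[keep]
  if (nrow(vectors) < 3) stop("kidera_pca requires at least 3 vectors")
  constant <- apply(vectors, 2, function(x) stats::var(x) == 0)
  if (scale. && any(constant)) scale. <- FALSE
  pc <- stats::prcomp(vectors, center = TRUE, scale. = scale.)
  rank_deficient <- length(pc$sdev) < ncol(vectors) ||
    any(pc$sdev < 1e-12)
  # deterministic signs: largest-|loading| positive
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  group_summary <- NULL
  if (!is.null(groups)) {
    df <- tibble(group = groups,
                 PC1 = pc$x[, 1],
                 PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)
    group_summary <- df %>%
      group_by(.data$group) %>%
      summarise(
        n = n(),
        pc1_median = stats::median(.data$PC1),
        pc1_iqr_lo = stats::quantile(.data$PC1, 0.25),
        pc1_iqr_hi = stats::quantile(.data$PC1, 0.75),
        pc2_median = stats::median(.data$PC2),
        pc2_iqr_lo = stats::quantile(.data$PC2, 0.25),
        pc2_iqr_hi = stats::quantile(.data$PC2, 0.75),
        .groups = "drop")
  }
  list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
       group_summary = group_summary, rank_deficient = rank_deficient)
}

#' Secondary-structure preference proportions of a CDR3
#'
#' Assigns every residue to exactly one preference class — alpha-helix,
#' beta-strand or coil — by the argmax of its Chou-Fasman conformational
#' propensities (packaged table; swappable), and returns the class
#' proportions, which sum to 1 by construction.
#'
#' @param cdr3_aa Amino-acid string.
#' @param class_map Optional named character vector amino acid -> class
#'   (values in `alpha`, `beta`, `coil`) replacing the packaged mapping.
#' @return Named numeric vector `p_alpha`, `p_beta`, `p_coil`.
#' @export
structure_propensity <- function(cdr3_aa, class_map = NULL) {
  map <- if (is.null(class_map)) STRUCTURE_CLASS else class_map
  res <- strsplit(cdr3_aa, "")[[1]]
  if (length(res) == 0 || any(!res %in% names(map))) {
    warning("CDR3 with non-canonical residues skipped: ", cdr3_aa)
    return(c(p_alpha = NA_real_, p_beta = NA_real_, p_coil = NA_real_))
  }
  cls <- map[res]
  c(p_alpha = mean(cls == "alpha"),
    p_beta = mean(cls == "beta"),
    p_coil = mean(cls == "coil"))
}

#' Per-sequence CDR3 descriptor table
#'
#' Kidera factors and structure-preference proportions for every annotated
#' sequence with a CDR3.
#'
#' @param ann Annotation tibble.
#' @return Tibble keyed by sequence id.
#' @export
cdr3_descriptors <- function(ann) {
  sel <- which(!is.na(ann$cdr3_aa) & nzchar(ann$cdr3_aa))
  km <- kidera_matrix(ann$cdr3_aa[sel])
  sp <- t(vapply(ann$cdr3_aa[sel],
                 function(s) suppressWarnings(structure_propensity(s)),
                 numeric(3)))
  dplyr::bind_cols(
    tibble(id = ann$id[sel], sample_id = ann$sample_id[sel],
           c_call = if ("c_call" %in% names(ann)) ann$c_call[sel]
                    else NA_character_,
           cdr3_aa = ann$cdr3_aa[sel]),
    as_tibble(km), as_tibble(sp))
}
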