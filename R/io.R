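# Reading and writing the repertoire interchange formats: AIRR
# Rearrangement TSV (the pipeline's lingua franca) and FASTA reads with
# metadata in the description line.

AIRR_CORE <- c("sequence_id", "sequence", "v_call", "d_call", "j_call",
               "c_call", "junction", "junction_aa", "productive",
               "v_identity")

#' Write annotations as AIRR Rearrangement TSV
#'
#' Emits the standard AIRR Rearrangement columns (`sequence_id`,
#' `sequence`, `v_call`, `d_call`, `j_call`, `c_call`, `junction`,
#' `junction_aa`, `productive`, `v_identity`) plus the package's extension
#' columns (`sample_id`, `compartment`, `cell_id`, `chain`, `cdr3_aa`,
#' `productivity_reason`, `s_fr`, `r_fr`, `s_cdr`, `r_cdr`, `copy_count`,
#' `clone_id` where present). Optional header comment lines (e.g. run
#' provenance) are prefixed with `#`.
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @param header Optional character vector of comment lines.
#' @export
write_airr <- function(ann, path, header = NULL) {
  out <- ann
  out$sequence_id <- out$id
  ext <- intersect(c("sample_id", "compartment", "cell_id", "chain",
                     "cdr3_aa", "productivity_reason", "s_fr", "r_fr",
                     "s_cdr", "r_cdr", "pct_mut", "copy_count", "clone_id"),
                   names(out))
  cols <- c(intersect(AIRR_CORE, names(out)), ext)
  cols <- c("sequence_id", setdiff(cols, "sequence_id"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an AIRR Rearrangement TSV
#'
#' @param path Input path (comment lines starting with `#` are skipped).
#' @return Tibble with an `id` column aliasing `sequence_id`.
#' @export
read_airr <- function(path) {
  df <- as_tibble(utils::read.delim(path, comment.char = "#",
                                    na.strings = c("NA", "")))
  if (!"id" %in% names(df) && "sequence_id" %in% names(df)) {
    df$id <- as.character(df$sequence_id)
  }
  df
}

#' Read immunoglobulin reads from FASTA
#'
#' Header convention: `id [sample=S] [compartment=C] [cell=CE] [chain=H]`;
#' missing fields fall back to the supplied defaults.
#'
#' @param path FASTA path.
#' @param sample_id,compartment,chain Defaults for absent header fields.
#' @return Read tibble suitable for [assign_vdj()].
#' @export
read_fasta_reads <- function(path, sample_id = "S1", compartment = "other",
                             chain = "heavy") {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  field <- function(key, default) {
    v <- sub(paste0(".*", key, "=(\\S+).*"), "\\1", hdr)
    ifelse(grepl(paste0(key, "="), hdr), v, default)
  }
  tibble(
    id = sub("\\s.*$", "", hdr),
    sample_id = field("sample", sample_id),
    compartment = field("compartment", compartment),
    cell_id = field("cell", NA_character_),
    chain = field("chain", chain),
    sequence = unname(as.character(ss))
  )
}

#' Write reads as FASTA with metadata headers
#'
#' @param reads Read tibble.
#' @param path Output path.
#' @export
write_fasta_reads <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- sprintf("%s sample=%s compartment=%s cell=%s chain=%s",
                       reads$id, reads$sample_id, reads$compartment,
                       reads$cell_id, reads$chain)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
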