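#' Normalized CDRH3 Levenshtein distance
#'
#' Levenshtein edit distance between two CDR3 amino-acid strings divided by
#' the longer length, so the distance lies in `[0, 1]`, is symmetric and is
#' 0 iff the strings are equal.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Normalized distance in `[0, 1]`.
#' @export
cdrh3_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b) || is.na(a) || is.na(b)) {
    stop("cdrh3_distance requires non-empty CDR3 strings")
  }
  as.numeric(utils::adist(a, b)) / max(nchar(a), nchar(b))
}

cdrh3_dist_matrix <- function(cdr3) {
  d <- utils::adist(cdr3)
  len <- nchar(cdr3)
  d / outer(len, len, pmax)
}

#' Cluster sequences into clones by CDRH3 distance
#'
#' Groups sequences into clonotypes by single-linkage hierarchical
#' clustering of the normalized CDRH3 Levenshtein distance matrix, cutting
#' the tree at height `cut` (merges at height less than or equal to the cut
#' stay together, so a pair at exactly the cut distance shares a clone).
#' Single-linkage tree cutting makes the clones exactly the connected
#' components of the graph joining pairs within the cut, which keeps the
#' result invariant to input order. V/J identity is deliberately NOT
#' required within a clone by default, so that receptor-revision events
#' (same CDR3, different V) are not split; `strict_vj = TRUE` additionally
#' splits clones by gene-level V and J call.
#'
#' @param ann Annotation tibble with `id` (or `sequence_id`), `cdr3_aa` and
#'   optionally `v_call`, `j_call`, `c_call`. Rows without a CDR3 are
#'   dropped.
#' @param cut Tree cut height on the normalized distance (default 0.05).
#' @param strict_vj Require identical gene-level V and J within a clone.
#' @return A list with `clones` (one row per clone: `clone_id`, `size`,
#'   `cdr3_aa` representative, consensus `v_call`/`j_call`, `isotypes`
#'   count table, `members` list) and `assignments` (`id` -> `clone_id`).
#' @export
cluster_clones <- function(ann, cut = 0.05, strict_vj = FALSE) {
  if (!"id" %in% names(ann) && "sequence_id" %in% names(ann)) {
    ann$id <- ann$sequence_id
  }
  keep <- !is.na(ann$cdr3_aa) & nzchar(ann$cdr3_aa)
  ann <- ann[keep, ]
  n <- nrow(ann)
  if (n == 0) {
    return(list(clones = tibble(), assignments = tibble()))
  }
  if (n == 1) {
    member <- 1L
  } else {
    dm <- cdrh3_dist_matrix(ann$cdr3_aa)
    hc <- stats::hclust(stats::as.dist(dm), method = "single")
    member <- stats::cutree(hc, h = cut)
  }
  if (strict_vj) {
    vg <- sub("\\*.*$", "", ifelse(is.na(ann$v_call), "", ann$v_call))
    jg <- sub("\\*.*$", "", ifelse(is.na(ann$j_call), "", ann$j_call))
    member <- match(paste(member, vg, jg),
                    unique(paste(member, vg, jg)))
  }
  # canonical clone ids: by decreasing size, ties by smallest member id
  groups <- split(seq_len(n), member)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(ix) min(ann$id[ix]), character(1)))
  groups <- groups[ord]
  clone_ids <- sprintf("clone%04d", seq_along(groups))
  assignments <- tibble(
    id = ann$id[unlist(groups)],
    clone_id = rep(clone_ids, lengths(groups))
  )
  clones <- dplyr::bind_rows(lapply(seq_along(groups), function(k) {
    ix <- groups[[k]]
    cdr3 <- ann$cdr3_aa[ix]
    iso <- if ("c_call" %in% names(ann)) {
      table(ann$c_call[ix][!is.na(ann$c_call[ix]) &
                             ann$c_call[ix] != "unassigned"])
    } else {
      table(character(0))
    }
    tibble(
      clone_id = clone_ids[k],
      size = length(ix),
      cdr3_aa = names(sort(table(cdr3), decreasing = TRUE))[1],
      v_call = if ("v_call" %in% names(ann)) majority_call(ann$v_call[ix])
               else NA_character_,
      j_call = if ("j_call" %in% names(ann)) majority_call(ann$j_call[ix])
               else NA_character_,
      isotypes = list(iso),
      members = list(ann$id[ix])
    )
  }))
  list(clones = clones, assignments = assignments)
}

majority_call <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

#' Summarize clone structure
#'
#' Counts of clones and non-singleton clones, the clone-size distribution,
#' and the isotype composition of the top-N clones.
#'
#' @param clones Result of [cluster_clones()].
#' @param top_n Number of largest clones to detail.
#' @return A list with `n_clones`, `n_nonsingleton`, `size_distribution`
#'   (tibble of size -> count) and `top_clones` (tibble with isotype
#'   composition).
#' @export
clone_summary <- function(clones, top_n = 10) {
  cl <- clones$clones
  if (nrow(cl) == 0) {
    return(list(n_clones = 0L, n_nonsingleton = 0L,
                size_distribution = tibble(), top_clones = tibble()))
  }
  sd <- cl %>%
    group_by(size = .data$size) %>%
    summarise(n_clones = n(), .groups = "drop") %>%
    arrange(.data$size)
  top <- cl %>% arrange(-.data$size) %>% utils::head(top_n)
  top$isotype_composition <- vapply(top$isotypes, function(t) {
    if (length(t) == 0) return("")
    paste(sprintf("%s:%d", names(t), as.integer(t)), collapse = ",")
  }, character(1))
  list(
    n_clones = nrow(cl),
    n_nonsingleton = sum(cl$size > 1),
    size_distribution = sd,
    top_clones = top[, c("clone_id", "size", "cdr3_aa", "v_call", "j_call",
                         "isotype_composition")]
  )
}
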