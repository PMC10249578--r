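# Germline-rooted maximum-parsimony lineage trees for B-cell clones.
# Tree search is delegated to phangorn (exhaustive enumeration of
# topologies for small clones, parsimony ratchet above); ancestral state
# assignment, edge mutation annotation, intermediate-node collapsing and
# export are implemented here so that mutations are expressed relative to
# the germline, which is also the root.

BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
BIT_BASE <- c("A", "C", "G", "T")

#' Build a germline-rooted lineage tree for one clone
#'
#' Reconstructs a maximum-parsimony genealogy of the clone members rooted
#' at the germline scaffold. For clones of up to `exhaustive_limit` members
#' every unrooted topology is scored (guaranteed optimum); larger clones
#' use the parsimony ratchet (greedy search with nearest-neighbor
#' interchange refinement). Ancestral sequences are assigned by Fitch
#' bottom-up state sets with a germline-anchored top-down pass (the root
#' state is the germline, and a child keeps its parent's state whenever the
#' parent state is in its Fitch set), so that every edge carries the exact
#' mutations separating parent from child and the mutations along any
#' root-to-leaf path sum to that leaf's differences from the germline.
#' Internal nodes whose incoming edge carries no mutation are collapsed, so
#' inferred intermediates remain only where at least two descendants share
#' a mutation.
#'
#' @param germline Germline scaffold nucleotide string (root state).
#' @param sequences Named character vector of member sequences, all the
#'   same length as `germline`; members of a different length are excluded
#'   with a warning.
#' @param isotypes Optional named vector of member isotype labels.
#' @param model,v_call Optional [locus_model()] and V allele used to label
#'   mutations FR/CDR and S/R (positions beyond the V get region
#'   `"junction"` and class `NA`).
#' @param exhaustive_limit Largest clone size searched exhaustively.
#' @return An object of class `lineage_tree`: list with `nodes` (tibble of
#'   node ids, labels, sequences, isotypes), `edges` (tibble with
#'   `parent`, `child`, `n_mutations`, `mutations` list column),
#'   `parsimony_score`, and `root` (node id).
#' @export
build_lineage <- function(germline, sequences, isotypes = NULL,
                          model = NULL, v_call = NULL,
                          exhaustive_limit = 6) {
  L <- nchar(germline)
  bad <- nchar(sequences) != L
  if (any(bad)) {
    warning("excluding ", sum(bad), " member(s) with incompatible length")
    sequences <- sequences[!bad]
  }
  m <- length(sequences)
  if (m == 0) stop("no compatible members")
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_len(m))
  }
  labels <- c("germline", names(sequences))
  chars <- do.call(rbind, strsplit(c(germline, unname(sequences)), ""))
  rownames(chars) <- labels

  if (m == 1) {
    tree_edge <- matrix(c(3L, 3L, 1L, 2L), ncol = 2)  # root -> both tips
    phy <- list(edge = tree_edge, tip.label = labels, Nnode = 1L)
    class(phy) <- "phylo"
  } else {
    dat <- phangorn::phyDat(chars, type = "DNA")
    if (m <= exhaustive_limit) {
      trees <- phangorn::allTrees(m + 1, rooted = FALSE, tip.label = labels)
      scores <- phangorn::parsimony(trees, dat)
      phy <- trees[[which.min(scores)]]
    } else {
      phy <- phangorn::pratchet(dat, trace = 0)
    }
    phy <- ape::root(phy, outgroup = "germline", resolve.root = TRUE)
  }

  states <- fitch_states(phy, chars)
  score <- if (m == 1) {
    sum(chars[1, ] != chars[2, ])
  } else {
    phangorn::parsimony(phy, phangorn::phyDat(chars, type = "DNA"))
  }

  lt <- assemble_lineage(phy, states, labels, isotypes, germline,
                         model, v_call)
  lt$parsimony_score <- score
  lt
}

# Fitch bottom-up + germline-anchored top-down; returns a character matrix
# of assigned sequences for every node (tips + internals) of the rooted
# (possibly multifurcating) tree.
fitch_states <- function(phy, chars) {
  ntip <- length(phy$tip.label)
  nnode <- max(phy$edge)
  L <- ncol(chars)
  sets <- matrix(0L, nnode, L)
  for (i in seq_len(ntip)) {
    sets[i, ] <- BASE_BITS[chars[phy$tip.label[i], ]]
  }
  # postorder over internal nodes
  ord <- rev(unique(phy$edge[order(phy$edge[, 1]), 1]))
  children <- split(phy$edge[, 2], phy$edge[, 1])
  po <- postorder_nodes(phy)
  for (v in po) {
    kids <- children[[as.character(v)]]
    s <- sets[kids[1], ]
    for (k in kids[-1]) {
      inter <- bitwAnd(s, sets[k, ])
      s <- ifelse(inter > 0L, inter, bitwOr(s, sets[k, ]))
    }
    sets[v, ] <- s
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  assigned <- matrix(NA_character_, nnode, L)
  for (i in seq_len(ntip)) assigned[i, ] <- chars[phy$tip.label[i], ]
  gl <- chars["germline", ]
  assigned[root, ] <- gl
  # preorder top-down
  for (e in order(node_depth(phy)[phy$edge[, 2]])) {
    p <- phy$edge[e, 1]
    v <- phy$edge[e, 2]
    if (v <= ntip) next
    pmaskbit <- BASE_BITS[assigned[p, ]]
    inset <- bitwAnd(sets[v, ], pmaskbit) > 0L
    pick <- assigned[p, ]
    low <- BIT_BASE[ceiling(log2(bitwAnd(sets[v, ], -sets[v, ])) + 1)]
    assigned[v, ] <- ifelse(inset, pick, low)
  }
  assigned
}

postorder_nodes <- function(phy) {
  ntip <- length(phy$tip.label)
  depth <- node_depth(phy)
  internal <- unique(phy$edge[, 1])
  internal[order(depth[internal], decreasing = TRUE)]
}

node_depth <- function(phy) {
  nnode <- max(phy$edge)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  depth <- rep(NA_integer_, nnode)
  depth[root] <- 0L
  repeat {
    known <- !is.na(depth[phy$edge[, 1]]) & is.na(depth[phy$edge[, 2]])
    if (!any(known)) break
    depth[phy$edge[known, 2]] <- depth[phy$edge[known, 1]] + 1L
  }
  depth
}

mutation_list <- function(from_seq, to_seq, germline, model, v_call) {
  pos <- which(from_seq != to_seq)
  if (length(pos) == 0) return(NULL)
  region <- rep("junction", length(pos))
  cls <- rep(NA_character_, length(pos))
  if (!is.null(model) && !is.null(v_call)) {
    g <- get_gene(model, v_call)
    b <- g$boundaries[[1]]
    vlen <- nchar(g$sequence)
    inV <- pos <= vlen
    cdr <- v_cdr_mask(b, vlen)
    region[inV] <- ifelse(cdr[pos[inV]], "CDR", "FR")
    for (k in which(inV)) {
      p <- pos[k]
      c0 <- ((p - 1L) %/% 3L) * 3L + 1L
      if (c0 + 2L > length(germline)) next
      gc <- germline[c0:(c0 + 2L)]
      mc <- to_seq[c0:(c0 + 2L)]
      cls[k] <- if (translate_nt(paste(gc, collapse = "")) ==
                      translate_nt(paste(mc, collapse = ""))) "S" else "R"
    }
  }
  tibble(position = pos - 1L,
         from = from_seq[pos], to = to_seq[pos],
         region = region, class = cls)
}

assemble_lineage <- function(phy, states, labels, isotypes, germline_seq,
                             model, v_call) {
  ntip <- length(phy$tip.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  gl_tip <- match("germline", phy$tip.label)
  gchars <- strsplit(germline_seq, "")[[1]]

  parent <- phy$edge[, 1]
  child <- phy$edge[, 2]
  # drop the germline tip: the root itself is the germline
  keep <- child != gl_tip
  parent <- parent[keep]; child <- child[keep]

  # collapse zero-mutation edges into internal nodes (root and tips stay)
  nmut <- vapply(seq_along(parent), function(e) {
    sum(states[parent[e], ] != states[child[e], ])
  }, integer(1))
  repeat {
    drop <- which(nmut == 0 & child > ntip)
    if (length(drop) == 0) break
    e <- drop[1]
    v <- child[e]; p <- parent[e]
    parent[parent == v] <- p
    parent <- parent[-e]; child <- child[-e]; nmut <- nmut[-e]
  }

  node_ids <- unique(c(root, parent, child))
  lab <- character(max(node_ids))
  lab[root] <- "germline"
  lab[seq_len(ntip)] <- phy$tip.label
  inferred <- setdiff(node_ids, c(root, seq_len(ntip)))
  lab[inferred] <- paste0("inferred", seq_along(inferred))

  iso <- rep(NA_character_, max(node_ids))
  if (!is.null(isotypes)) {
    iso[seq_len(ntip)] <- unname(isotypes[phy$tip.label])
  }

  mut_list <- lapply(seq_along(parent), function(e) {
    mutation_list(states[parent[e], ], states[child[e], ], gchars,
                  model, v_call)
  })
  edges <- tibble(
    parent = lab[parent],
    child = lab[child],
    n_mutations = nmut,
    mutations = mut_list
  )
  nodes <- tibble(
    id = node_ids,
    label = lab[node_ids],
    sequence = apply(states[node_ids, , drop = FALSE], 1, paste,
                     collapse = ""),
    isotype = iso[node_ids]
  )
  structure(list(nodes = nodes, edges = edges, root = "germline"),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges, parsimony score ",
      x$parsimony_score, "\n", sep = "")
  invisible(x)
}

#' Export a lineage tree as Newick plus a mutation sidecar
#'
#' Writes the tree in Newick format with branch lengths equal to the
#' per-edge mutation count and NHX-style bracketed edge annotations
#' carrying the mutation records; the full per-edge mutation lists go to a
#' sidecar JSON file.
#'
#' @param lt A `lineage_tree`.
#' @param newick_path,json_path Output paths (either may be `NULL`).
#' @return The Newick string, invisibly.
#' @export
write_lineage <- function(lt, newick_path = NULL, json_path = NULL) {
  kids <- split(seq_len(nrow(lt$edges)), lt$edges$parent)
  fmt_mut <- function(m) {
    if (is.null(m) || nrow(m) == 0) return("")
    paste(sprintf("%d%s>%s", m$position, m$from, m$to), collapse = "|")
  }
  rec <- function(label) {
    es <- kids[[label]]
    node <- if (is.null(es)) label else {
      paste0("(", paste(vapply(es, function(e) {
        paste0(rec(lt$edges$child[e]), ":", lt$edges$n_mutations[e],
               "[&&NHX:muts=", fmt_mut(lt$edges$mutations[[e]]), "]")
      }, character(1)), collapse = ","), ")", label)
    }
    node
  }
  nwk <- paste0(rec(lt$root), ";")
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(json_path)) {
    side <- lapply(seq_len(nrow(lt$edges)), function(e) {
      m <- lt$edges$mutations[[e]]
      list(parent = lt$edges$parent[e], child = lt$edges$child[e],
           n_mutations = lt$edges$n_mutations[e],
           mutations = if (is.null(m)) list() else m)
    })
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(nwk)
}

#' Detect class-switch recombination within a clone
#'
#' Reports a CSR event for every pair of isotypes co-occurring in a clone
#' where one precedes the other in the deletional constant-gene order; the
#' direction is always downstream, as deletional CSR admits no reverse
#' switch. If a lineage tree with node isotype labels is supplied, clones
#' in which some parent-to-child step would require an upstream switch are
#' flagged `inconsistent`.
#'
#' @param isotypes Character vector of member isotype labels (e.g.
#'   `"IgG1"`); `unassigned`/`NA` entries are ignored.
#' @param model A [locus_model()].
#' @param tree Optional `lineage_tree` with isotype labels.
#' @return List with `events` (tibble `from`, `to`, `n_from`, `n_to`) and
#'   `inconsistent` flag.
#' @export
detect_csr_within_clone <- function(isotypes, model, tree = NULL) {
  iso2gene <- stats::setNames(names(ISOTYPE_LABEL), ISOTYPE_LABEL)
  keep <- !is.na(isotypes) & isotypes %in% names(iso2gene)
  iso <- isotypes[keep]
  ranks <- match(iso2gene[iso], model$constant_order)
  tab <- table(iso)
  uniq <- names(tab)
  uranks <- match(iso2gene[uniq], model$constant_order)
  ord <- order(uranks)
  uniq <- uniq[ord]; uranks <- uranks[ord]
  events <- list()
  if (length(uniq) >= 2) {
    for (i in seq_len(length(uniq) - 1)) {
      for (j in (i + 1):length(uniq)) {
        events[[length(events) + 1L]] <- tibble(
          from = uniq[i], to = uniq[j],
          n_from = as.integer(tab[uniq[i]]),
          n_to = as.integer(tab[uniq[j]]))
      }
    }
  }
  inconsistent <- FALSE
  if (!is.null(tree)) {
    niso <- stats::setNames(tree$nodes$isotype, tree$nodes$label)
    for (e in seq_len(nrow(tree$edges))) {
      a <- niso[tree$edges$parent[e]]
      b <- niso[tree$edges$child[e]]
      if (!is.na(a) && !is.na(b) && a %in% names(iso2gene) &&
          b %in% names(iso2gene)) {
        if (match(iso2gene[[b]], model$constant_order) <
              match(iso2gene[[a]], model$constant_order)) {
          inconsistent <- TRUE
        }
      }
    }
  }
  list(events = if (length(events)) dplyr::bind_rows(events) else
         tibble(from = character(0), to = character(0),
                n_from = integer(0), n_to = integer(0)),
       inconsistent = inconsistent)
}

#' Build lineage trees for the largest clones of an annotated repertoire
#'
#' Convenience wrapper: for each selected clone, members sharing the
#' dominant variable-domain length are aligned on a scaffold made of the
#' consensus V germline followed by the member consensus beyond the V, and
#' passed to [build_lineage()].
#'
#' @param ann Annotation tibble with clone assignments (`clone_id`).
#' @param model A [locus_model()].
#' @param clone_ids Clones to build (default: all non-singletons).
#' @param max_members Largest clone size attempted (bigger clones are
#'   subsampled to this many members, largest copy counts first).
#' @return Named list of `lineage_tree` objects.
#' @export
build_clone_lineages <- function(ann, model, clone_ids = NULL,
                                 max_members = 12) {
  if (is.null(clone_ids)) {
    tab <- table(ann$clone_id)
    clone_ids <- names(tab[tab > 1])
  }
  out <- list()
  for (cid in clone_ids) {
    sub <- ann[!is.na(ann$clone_id) & ann$clone_id == cid &
                 !ann$unannotatable, ]
    if (nrow(sub) < 1) next
    vd <- substr(sub$sequence, sub$v_read_start, sub$j_read_end)
    len <- as.integer(names(sort(table(nchar(vd)), decreasing = TRUE))[1])
    sel <- which(nchar(vd) == len)
    if (length(sel) > max_members) sel <- sel[seq_len(max_members)]
    vcall <- majority_call(sub$v_call[sel])
    g <- get_gene(model, vcall)
    vlen <- nchar(g$sequence)
    if (len <= vlen) next
    tailmat <- do.call(rbind,
                       strsplit(substr(vd[sel], vlen + 1L, len), ""))
    consensus_tail <- apply(tailmat, 2, function(col) {
      names(sort(table(col), decreasing = TRUE))[1]
    })
    scaffold <- paste0(g$sequence, paste(consensus_tail, collapse = ""))
    seqs <- stats::setNames(vd[sel], sub$id[sel])
    isos <- stats::setNames(sub$c_call[sel], sub$id[sel])
    out[[cid]] <- tryCatch(
      build_lineage(scaffold, seqs, isotypes = isos, model = model,
                    v_call = vcall),
      error = function(e) NULL)
  }
  Filter(Negate(is.null), out)
}
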