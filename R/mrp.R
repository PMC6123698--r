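## Matrix representation with parsimony: Baum-Ragan encoding, weighted
## Fitch/Hartigan scoring, heuristic search, strict consensus, maximum
## agreement subtrees and rogue-taxon removal.

MRP_OUTGROUP <- "MRP_outgroup"

#' Encode source trees as an MRP matrix (Baum-Ragan coding)
#'
#' One binary character is produced per internal node per source tree,
#' excluding each source's root (the root character is uninformative against
#' the all-zero outgroup). Taxa subtended by the node are scored 1, taxa
#' present in that source but not subtended 0, and taxa absent from the
#' source `?` (missing). A hypothetical all-zero outgroup row roots the
#' analysis. Character weights equal their source tree's independence weight.
#'
#' @param sources List of [source_tree()] objects (standardized, weighted).
#' @return An object of class `mrp_matrix`: a taxa-by-characters integer
#'   matrix (`NA` = `?`) plus per-character `weights` and `source` ids.
#' @export
encode_baum_ragan <- function(sources) {
  stopifnot(length(sources) >= 1)
  taxa <- sort(unique(unlist(lapply(sources, function(s) s$tree$tip.label))))
  taxa <- c(taxa, MRP_OUTGROUP)
  cols <- list(); weights <- numeric(0); src <- character(0)
  for (s in sources) {
    tr <- s$tree
    nt <- ape::Ntip(tr)
    root <- nt + 1L
    internals <- setdiff(unique(tr$edge[, 1]), root)
    if (length(internals) == 0) {
      warning("source ", s$study_id, " has no non-root internal node; contributes no characters",
              call. = FALSE)
      next
    }
    cs <- clade_sets(tr)
    for (nd in internals) {
      col <- rep(NA_integer_, length(taxa))
      names(col) <- taxa
      col[tr$tip.label] <- 0L
      col[cs[[nd]]] <- 1L
      col[MRP_OUTGROUP] <- 0L
      cols[[length(cols) + 1L]] <- col
      weights <- c(weights, s$weight)
      src <- c(src, s$study_id)
    }
  }
  if (length(cols) == 0) stop("no informative characters in any source", call. = FALSE)
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  structure(list(matrix = m, weights = weights, source = src,
                 outgroup = MRP_OUTGROUP),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat("mrp_matrix:", nrow(x$matrix), "taxa (incl. outgroup) x",
      ncol(x$matrix), "characters from", length(unique(x$source)), "sources\n")
  invisible(x)
}

#' Weighted parsimony score of a tree against an MRP matrix
#'
#' Computes the minimum weighted number of 0/1 changes over the rooted tree,
#' summing `weight * changes` across characters. Missing cells (`?`) carry
#' the full state set. Polytomies are scored with the Hartigan
#' generalization of the Fitch pass: a node receives the intersection of its
#' children's state sets when non-empty, otherwise the states attained by
#' the maximal number of children, adding one change per child set not
#' containing the majority states.
#'
#' @param tree A rooted `phylo` whose leaves include every taxon scored in
#'   `matrix` (the outgroup row included).
#' @param matrix An [encode_baum_ragan()] matrix.
#' @return The weighted parsimony score (numeric scalar).
#' @export
fitch_score <- function(tree, matrix) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  m <- matrix$matrix
  missing_taxa <- setdiff(rownames(m), tree$tip.label)
  if (length(missing_taxa))
    stop("taxa in matrix absent from tree: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  nt <- ape::Ntip(tree)
  nchar_ <- ncol(m)
  nnode <- nt + tree$Nnode
  # state-set bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  mask <- matrix(3L, nnode, nchar_)
  idx <- match(rownames(m), tree$tip.label)
  leaf_mask <- m + 1L
  leaf_mask[is.na(leaf_mask)] <- 3L
  mask[idx, ] <- leaf_mask
  # leaves of the tree not in the matrix stay fully ambiguous (mask 3)

  kids <- split(tree$edge[, 2], tree$edge[, 1])
  ord <- unique(tree$edge[ape::postorder(tree), 1])  # tipward-first internals
  score <- 0
  for (nd in ord) {
    ch <- kids[[as.character(nd)]]
    k <- length(ch)
    sub <- mask[ch, , drop = FALSE]
    cnt0 <- colSums(sub == 1L | sub == 3L)
    cnt1 <- colSums(sub == 2L | sub == 3L)
    mx <- pmax(cnt0, cnt1)
    score <- score + sum(matrix$weights * (k - mx))
    mask[nd, ] <- (cnt0 == mx) * 1L + (cnt1 == mx) * 2L
  }
  score
}

# Convert an mrp_matrix to a weighted phangorn phyDat object.
mrp_to_phydat <- function(matrix) {
  chr <- matrix(as.character(matrix$matrix), nrow = nrow(matrix$matrix),
                dimnames = dimnames(matrix$matrix))
  chr[is.na(chr)] <- "?"
  pd <- phangorn::phyDat(chr, type = "USER", levels = c("0", "1"), ambiguity = "?")
  idx <- attr(pd, "index")
  w <- vapply(seq_len(max(idx)), function(p) sum(matrix$weights[idx == p]), numeric(1))
  attr(pd, "weight") <- w
  pd
}

#' Heuristic parsimony search over an MRP matrix
#'
#' Runs `replicates` independent searches, each from a different random
#' taxon-addition starting tree, hill-climbing first through
#' nearest-neighbour-interchange (NNI) and then subtree-prune-and-regraft
#' (SPR) neighbourhoods until no improving move remains (the rearrangement
#' machinery of \pkg{phangorn} drives the climb; scores are the weighted
#' Sankoff/Fitch lengths, identical to [fitch_score()]). The globally best
#' trees across replicates are pooled, rooted on the all-zero outgroup,
#' stripped of the outgroup and deduplicated by canonical topology.
#'
#' @param matrix An [encode_baum_ragan()] matrix.
#' @param replicates Number of random-addition replicates (>= 1).
#' @param seed Integer seed; the whole search is deterministic given it.
#' @return A `tree_set`: list with `trees` (rooted `phylo` list, outgroup
#'   removed) and `score` (their common weighted parsimony score).
#' @export
heuristic_search <- function(matrix, replicates = 10, seed = 1) {
  stopifnot(inherits(matrix, "mrp_matrix"), replicates >= 1)
  pd <- mrp_to_phydat(matrix)
  best_score <- Inf
  best <- list()
  seen <- character(0)
  for (rep_i in seq_len(replicates)) {
    set.seed(seed + rep_i - 1L)
    start <- phangorn::random.addition(pd)
    t1 <- phangorn::optim.parsimony(start, pd, method = "sankoff",
                                    rearrangements = "NNI", trace = 0)
    t2 <- phangorn::optim.parsimony(t1, pd, method = "sankoff",
                                    rearrangements = "SPR", trace = 0)
    rooted <- root_on_outgroup(t2, matrix$outgroup)
    sc <- fitch_score(rooted$with_og, matrix)
    if (sc < best_score - 1e-9) {
      best_score <- sc; best <- list(); seen <- character(0)
    }
    if (sc <= best_score + 1e-9) {
      h <- topo_hash(rooted$no_og)
      if (!(h %in% seen)) {
        seen <- c(seen, h)
        best[[length(best) + 1L]] <- rooted$no_og
      }
    }
  }
  structure(list(trees = best, score = best_score), class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat("tree_set:", length(x$trees), "equally parsimonious trees, score",
      format(x$score), "\n")
  invisible(x)
}

root_on_outgroup <- function(tree, outgroup) {
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  list(with_og = tr, no_og = ape::drop.tip(tr, outgroup))
}

#' Strict consensus of a set of trees
#'
#' @param trees A `tree_set` from [heuristic_search()] or a list of rooted
#'   `phylo` objects on a shared leaf set.
#' @return The rooted tree containing exactly the clades present in every
#'   input tree.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  stopifnot(length(trees) >= 1)
  if (length(trees) == 1) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = TRUE)
}

# ---- maximum agreement subtree ------------------------------------------

# Max-weight bipartite matching by DP over subsets of the (smaller) side.
# W: k1 x k2 weight matrix. Returns list(value, assignment: for each row,
# the matched column or NA).
max_weight_matching <- function(W) {
  k1 <- nrow(W); k2 <- ncol(W)
  if (k2 > k1) {
    res <- max_weight_matching(t(W))
    assign1 <- rep(NA_integer_, k1)
    for (j in seq_len(k2)) if (!is.na(res$assignment[j])) assign1[res$assignment[j]] <- j
    return(list(value = res$value, assignment = assign1))
  }
  if (k2 > 20) stop("polytomy too large for agreement-subtree matching", call. = FALSE)
  nmask <- bitwShiftL(1L, k2)
  dp <- matrix(0, k1 + 1L, nmask)
  for (i in seq_len(k1)) {
    for (s in 0:(nmask - 1L)) {
      v <- dp[i, s + 1L]   # row i left unmatched
      dp[i + 1L, s + 1L] <- max(dp[i + 1L, s + 1L], v)
      for (j in seq_len(k2)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) == 0L) {
          t_ <- bitwOr(s, bit)
          val <- dp[i, s + 1L] + W[i, j]
          if (val > dp[i + 1L, t_ + 1L]) dp[i + 1L, t_ + 1L] <- val
        }
      }
    }
  }
  best <- max(dp[k1 + 1L, ])
  # traceback
  s <- which.max(dp[k1 + 1L, ]) - 1L
  assignment <- rep(NA_integer_, k1)
  for (i in k1:1) {
    done <- FALSE
    if (abs(dp[i + 1L, s + 1L] - dp[i, s + 1L]) < 1e-12) {
      done <- TRUE  # row i unmatched
    } else {
      for (j in seq_len(k2)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) != 0L) {
          prev <- bitwAnd(s, bitwNot(bit))
          if (abs(dp[i + 1L, s + 1L] - (dp[i, prev + 1L] + W[i, j])) < 1e-12) {
            assignment[i] <- j
            s <- prev
            done <- TRUE
            break
          }
        }
      }
    }
    if (!done) stop("matching traceback failed")  # should not happen
  }
  list(value = best, assignment = assignment)
}

# Exact rooted MAST of two trees by dynamic programming over node pairs.
# Returns the selected leaf-label subset.
mast_pair <- function(t1, t2) {
  nt1 <- ape::Ntip(t1); nt2 <- ape::Ntip(t2)
  n1 <- nt1 + t1$Nnode; n2 <- nt2 + t2$Nnode
  cs1 <- clade_sets(t1); cs2 <- clade_sets(t2)
  kids1 <- split(t1$edge[, 2], t1$edge[, 1])
  kids2 <- split(t2$edge[, 2], t2$edge[, 1])
  ord1 <- c(seq_len(nt1), unique(t1$edge[ape::postorder(t1), 1]))
  ord2 <- c(seq_len(nt2), unique(t2$edge[ape::postorder(t2), 1]))
  M <- matrix(0L, n1, n2)
  for (u in ord1) for (v in ord2) {
    if (u <= nt1 && v <= nt2) {
      M[u, v] <- as.integer(t1$tip.label[u] == t2$tip.label[v])
    } else if (u <= nt1) {
      M[u, v] <- as.integer(t1$tip.label[u] %in% cs2[[v]])
    } else if (v <= nt2) {
      M[u, v] <- as.integer(t2$tip.label[v] %in% cs1[[u]])
    } else {
      ch1 <- kids1[[as.character(u)]]; ch2 <- kids2[[as.character(v)]]
      best <- max(M[ch1, v], M[u, ch2])
      W <- M[ch1, ch2, drop = FALSE]
      mm <- max_weight_matching(W)
      M[u, v] <- max(best, mm$value)
    }
  }

  # traceback collecting the selected leaves
  pick <- function(u, v) {
    val <- M[u, v]
    if (val == 0L) return(character(0))
    if (u <= nt1 && v <= nt2) return(t1$tip.label[u])
    if (u <= nt1) return(t1$tip.label[u])
    if (v <= nt2) return(t2$tip.label[v])
    ch1 <- kids1[[as.character(u)]]; ch2 <- kids2[[as.character(v)]]
    for (c in ch1) if (M[c, v] == val) return(pick(c, v))
    for (d in ch2) if (M[u, d] == val) return(pick(u, d))
    mm <- max_weight_matching(M[ch1, ch2, drop = FALSE])
    out <- character(0)
    for (i in seq_along(ch1)) {
      j <- mm$assignment[i]
      if (!is.na(j) && M[ch1[i], ch2[j]] > 0L)
        out <- c(out, pick(ch1[i], ch2[j]))
    }
    out
  }
  pick(n1 - t1$Nnode + 1L, n2 - t2$Nnode + 1L)  # roots are nt+1
}

#' Maximum agreement subtree
#'
#' For two rooted trees, an exact dynamic program over node pairs returns a
#' maximum-size leaf subset on which the restricted trees are isomorphic.
#' For more than two trees the result is folded sequentially (MAST of the
#' running result with the next tree, in input order); exactness is
#' guaranteed only pairwise since the multi-tree problem is NP-hard.
#'
#' @param trees List of at least two rooted `phylo` objects (or a
#'   `tree_set`) on a shared leaf set.
#' @return The restriction of the first tree to the selected leaves.
#' @export
mast <- function(trees) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  stopifnot(length(trees) >= 2)
  shared <- Reduce(intersect, lapply(trees, function(t) t$tip.label))
  if (length(shared) < 2)
    stop("fewer than 2 shared leaves across input trees", call. = FALSE)
  cur <- trees[[1]]
  for (i in seq(2, length(trees))) {
    keep <- mast_pair(cur, trees[[i]])
    if (length(keep) < 2)
      stop("agreement subtree collapsed below 2 leaves", call. = FALSE)
    cur <- prune_to(cur, keep)
  }
  cur
}

#' Remove rogue taxa from a tree
#'
#' @param tree A rooted `phylo`.
#' @param rogues Character vector of leaf labels to drop (may be empty).
#'   Unknown names are skipped with a warning.
#' @return The pruned tree.
#' @export
remove_taxa <- function(tree, rogues) {
  rogues <- unique(rogues)
  unknown <- setdiff(rogues, tree$tip.label)
  if (length(unknown)) {
    warning("unknown taxa skipped: ", paste(unknown, collapse = ", "), call. = FALSE)
    rogues <- intersect(rogues, tree$tip.label)
  }
  if (length(rogues) == 0) return(tree)
  prune_to(tree, setdiff(tree$tip.label, rogues))
}

#' Flag supertree clades found in no source tree
#'
#' A supertree clade is flagged as a candidate novel clade when its
#' restriction to each source's taxon set matches no clade of that source,
#' while being non-trivial (>= 2 taxa) in at least one source. Novel clades
#' are a known artefact of MRP and candidates for manual rogue-taxon review;
#' this report is advisory and removal requires a user-supplied rogue list.
#'
#' @param supertree A rooted `phylo`.
#' @param sources List of [source_tree()] objects with standardized names.
#' @return List of flagged clades, each a character vector of leaf labels.
#' @export
flag_novel_clades <- function(supertree, sources) {
  src_taxa <- lapply(sources, function(s) s$tree$tip.label)
  src_clades <- lapply(sources, function(s) {
    cl <- clade_sets(s$tree)
    lapply(cl, identity)
  })
  nt <- ape::Ntip(supertree)
  flagged <- list()
  cs <- clade_sets(supertree)
  for (nd in seq(nt + 1L, nt + supertree$Nnode)) {
    clade <- cs[[nd]]
    nontrivial_somewhere <- FALSE
    matched_somewhere <- FALSE
    for (k in seq_along(sources)) {
      r <- sort(intersect(clade, src_taxa[[k]]))
      if (length(r) < 2) next
      nontrivial_somewhere <- TRUE
      hit <- any(vapply(src_clades[[k]], function(s) identical(sort(s), r), logical(1)))
      if (hit) { matched_somewhere <- TRUE; break }
    }
    if (nontrivial_somewhere && !matched_somewhere)
      flagged[[length(flagged) + 1L]] <- clade
  }
  flagged
}

# ---- matrix writers -----------------------------------------------------

#' Write an MRP matrix as a NEXUS DATA block or TNT file
#'
#' @param matrix An [encode_baum_ragan()] matrix.
#' @param file Output path.
#' @export
write_nexus_data <- function(matrix, file) {
  m <- matrix$matrix
  sym <- matrix(as.character(m), nrow = nrow(m))
  sym[is.na(sym)] <- "?"
  rows <- apply(sym, 1, paste, collapse = "")
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
               "  FORMAT SYMBOLS=\"01\" MISSING=?;", "  MATRIX"), con)
  writeLines(sprintf("    %s %s", format(rownames(m)), rows), con)
  writeLines(c("  ;", "END;",
               paste0("[ character weights: ",
                      paste(format(matrix$weights, digits = 6), collapse = " "), " ]")), con)
  invisible(file)
}

#' @rdname write_nexus_data
#' @export
write_tnt <- function(matrix, file) {
  m <- matrix$matrix
  sym <- matrix(as.character(m), nrow = nrow(m))
  sym[is.na(sym)] <- "?"
  rows <- apply(sym, 1, paste, collapse = "")
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("xread", sprintf("%d %d", ncol(m), nrow(m))), con)
  writeLines(sprintf("%s %s", gsub(" ", "_", rownames(m)), rows), con)
  writeLines(";", con)
  writeLines(paste0("ccode ",
                    paste(sprintf("/%s %d", format(matrix$weights, digits = 6),
                                  seq_len(ncol(m)) - 1L), collapse = " "), ";"), con)
  invisible(file)
}
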