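#' @useDynLib caridiv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize optim runif rexp rpois rbinom dexp dpois
#'   wilcox.test ks.test setNames uniroot qchisq rgeom
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

## Trees throughout are rooted ape "phylo" objects: branch lengths in Myr,
## node ages (Ma before present) derivable from depths for ultrametric trees
## or carried explicitly by chronogram functions.

#' Parse a Newick string into a rooted tree
#'
#' Accepts standard Newick with optional branch lengths, polytomies, and
#' quoted or underscored labels. Internal whitespace in quoted labels is
#' normalised to a single underscore, matching the convention of digitised
#' source trees from heterogeneous publications.
#'
#' @param text A Newick string (terminated by `;`).
#' @return A rooted `phylo` object.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- normalize_newick_labels(text)
  validate_newick(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: unreadable tree string", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  tr
}

# Normalise quoted labels: 'Genus species' -> Genus_species
normalize_newick_labels <- function(text) {
  m <- gregexpr("'[^']*'", text)[[1]]
  if (m[1] == -1L) return(text)
  pieces <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
  fixed <- vapply(pieces, function(p) {
    p <- substr(p, 2L, nchar(p) - 1L)
    gsub("[[:space:]]+", "_", trimws(p))
  }, character(1))
  regmatches(text, gregexpr("'[^']*'", text)) <- list(fixed)
  text
}

# Structural validation with position-bearing error messages.
validate_newick <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  open_pos <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      depth <- depth + 1L
      open_pos <- c(open_pos, i)
    } else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at position ", i, call. = FALSE)
      open_pos <- open_pos[-length(open_pos)]
    }
  }
  if (depth != 0L)
    stop("Newick parse error: unbalanced '(' opened at position ",
         open_pos[1], call. = FALSE)
  if (!grepl(";[[:space:]]*$", text))
    stop("Newick parse error: missing terminal ';' at position ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string. `parse_newick(write_newick(t))` is isomorphic
#'   to `t` (identical nested leaf-label sets), with branch lengths
#'   preserved to numerical precision.
#' @export
write_newick <- function(tree, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Read and write trees in NEXUS format
#'
#' Thin wrappers over the TREES-block reader/writer in \pkg{ape}.
#'
#' @param file Path to a NEXUS file.
#' @return `read_nexus_trees()` returns a list of `phylo` objects.
#' @export
read_nexus_trees <- function(file) {
  tr <- ape::read.nexus(file)
  if (inherits(tr, "phylo")) tr <- list(tr)
  lapply(tr, identity)
}

#' @rdname read_nexus_trees
#' @param trees A `phylo` or list of `phylo` objects.
#' @export
write_nexus_trees <- function(trees, file) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.nexus(trees, file = file)
  invisible(file)
}

#' Most recent common ancestor of a taxon set
#'
#' @param tree A rooted `phylo`.
#' @param taxa Character vector of leaf labels (non-empty).
#' @return The node id (ape numbering) of the lowest node whose leaf set
#'   contains `taxa`; for a single taxon, the tip itself.
#' @export
mrca_node <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"), length(taxa) >= 1)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(unique(taxa)) == 1L) return(match(taxa[1], tree$tip.label))
  ape::getMRCA(tree, unique(taxa))
}

#' Restrict a tree to a taxon subset
#'
#' Returns the induced subtree: unary internal nodes created by the
#' restriction are suppressed and their branch lengths summed, so
#' leaf-to-leaf path lengths among retained taxa are preserved.
#'
#' @param tree A rooted `phylo`.
#' @param taxa Leaf labels to keep (at least one).
#' @return The restricted `phylo`.
#' @export
prune_to <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(taxa)
  if (length(taxa) == 0) stop("cannot prune to an empty taxon set", call. = FALSE)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(taxa) == length(tree$tip.label)) return(tree)
  if (length(taxa) == 1L) {
    # degenerate single-leaf tree: one root node, one edge
    len <- if (is.null(tree$edge.length)) NULL else {
      node_depths(tree)[match(taxa, tree$tip.label)]
    }
    out <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = taxa, Nnode = 1L)
    if (!is.null(len)) out$edge.length <- len
    class(out) <- "phylo"
    return(out)
  }
  ape::keep.tip(tree, taxa)
}

# Depth of every node from the root (0 at root), using edge lengths
# (unit lengths if absent).
node_depths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  el <- tree$edge.length
  if (is.null(el)) el <- rep(1, nrow(tree$edge))
  depth <- numeric(n)
  root <- ape::Ntip(tree) + 1L
  ord <- rev(ape::postorder(tree))   # rootward-first edge order
  for (e in ord) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + el[e]
  }
  depth
}

#' Node ages of a time-scaled tree
#'
#' Ages are in Ma before present: extant leaves have age 0 and the root is
#' the oldest node. Extinct leaves are handled through their shorter
#' root-to-tip path lengths.
#'
#' @param tree A `phylo` with branch lengths in Myr.
#' @return Numeric vector of ages indexed by ape node id.
#' @export
node_ages <- function(tree) {
  stopifnot(!is.null(tree$edge.length))
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

# Assign edge lengths from a node-age vector (indexed by node id).
ages_to_edge_lengths <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  tree
}

# -- topology utilities -------------------------------------------------

# Tip-label set for every internal node, named by node id.
clade_sets <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

# Canonical rooted-topology string: children sorted by their own canonical
# form; labels only (no lengths). Used to deduplicate equally parsimonious
# trees and to test isomorphism.
topo_hash <- function(tree) {
  nt <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- character(nt + tree$Nnode)
  for (i in seq_len(nt)) rec[i] <- tree$tip.label[i]
  ord <- unique(tree$edge[rev(ape::postorder(tree)), 1])  # rootward first
  for (nd in rev(ord)) {                                  # tipward first
    ch <- kids[[as.character(nd)]]
    rec[nd] <- paste0("(", paste(sort(rec[ch]), collapse = ","), ")")
  }
  rec[nt + 1L]
}

#' Test whether two rooted trees are topologically identical
#'
#' Compares nested leaf-label sets; branch lengths are ignored.
#' @param t1,t2 `phylo` objects.
#' @return Logical.
#' @export
trees_isomorphic <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  identical(topo_hash(t1), topo_hash(t2))
}

# Does `tree` display the clade (a tip-label set) within the given context
# (a source's taxon set)? The tree is first restricted to the shared context
# taxa; the clade then has to appear as a node's full leaf set there.
displays_clade <- function(tree, clade, context = NULL) {
  if (!is.null(context))
    tree <- prune_to(tree, intersect(context, tree$tip.label))
  clade <- sort(intersect(clade, tree$tip.label))
  if (length(clade) <= 1) return(TRUE)
  cs <- clade_sets(tree)
  any(vapply(cs, function(s) identical(s, clade), logical(1)))
}

# Number of tips subtended by each node.
tip_counts <- function(tree) {
  nt <- ape::Ntip(tree)
  cnt <- c(rep(1L, nt), integer(tree$Nnode))
  for (e in ape::postorder(tree)) {
    cnt[tree$edge[e, 1]] <- cnt[tree$edge[e, 1]] + cnt[tree$edge[e, 2]]
  }
  cnt
}
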