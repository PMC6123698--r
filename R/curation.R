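## Source-tree curation: taxon standardization, independence weighting and
## taxonomic-overlap checking. Source trees are treated as topologies
## (cladograms); branch lengths play no role in MRP encoding.

#' Construct a source tree with study metadata
#'
#' @param tree A rooted `phylo` with at least 2 leaves.
#' @param study_id Study identifier (string).
#' @param year Publication year.
#' @param evidence One of `"molecular"`, `"morphological"`, `"combined"`.
#' @param fingerprint Identifier of the underlying character matrix: a string
#'   of character-set tokens separated by `"+"` (e.g. `"16S+18S+COI"`). Two
#'   studies are non-independent when they analysed the same taxa and
#'   characters; the fingerprint (tokens plus the tree's taxon set) is the
#'   metadata-level record of matrix identity used by
#'   [assign_independence_weights()].
#' @param weight Initial weight in (0, 1].
#' @return An object of class `source_tree`.
#' @export
source_tree <- function(tree, study_id, year = NA_integer_,
                        evidence = c("molecular", "morphological", "combined"),
                        fingerprint = study_id, weight = 1.0) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 2)
  evidence <- match.arg(evidence)
  stopifnot(weight > 0, weight <= 1)
  structure(
    list(tree = tree, study_id = study_id, year = as.integer(year),
         evidence = evidence, fingerprint = fingerprint, weight = weight),
    class = "source_tree")
}

#' @export
print.source_tree <- function(x, ...) {
  cat("source_tree", x$study_id, "(", x$evidence, ",", ape::Ntip(x$tree),
      "taxa, weight", format(x$weight), ")\n")
  invisible(x)
}

#' Taxon standardization table
#'
#' @param synonyms Data frame with columns `synonym`, `canonical`.
#' @param higher_taxa Data frame with columns `higher_taxon`, `member`
#'   (one row per member species).
#' @return An object of class `taxon_map`.
#' @export
taxon_map <- function(synonyms = NULL, higher_taxa = NULL) {
  if (is.null(synonyms))
    synonyms <- data.frame(synonym = character(), canonical = character())
  if (is.null(higher_taxa))
    higher_taxa <- data.frame(higher_taxon = character(), member = character())
  stopifnot(all(c("synonym", "canonical") %in% names(synonyms)),
            all(c("higher_taxon", "member") %in% names(higher_taxa)))
  bad <- intersect(synonyms$canonical, synonyms$synonym)
  if (length(bad))
    stop("canonical names may not themselves be mapped synonyms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(synonyms = synonyms, higher_taxa = higher_taxa),
            class = "taxon_map")
}

#' Read a taxon map from two CSV files
#'
#' @param synonyms_csv CSV with columns `synonym,canonical`.
#' @param higher_taxa_csv CSV with columns `higher_taxon,member`.
#' @export
read_taxon_map <- function(synonyms_csv = NULL, higher_taxa_csv = NULL) {
  syn <- if (!is.null(synonyms_csv))
    read.csv(synonyms_csv, stringsAsFactors = FALSE) else NULL
  ht <- if (!is.null(higher_taxa_csv))
    read.csv(higher_taxa_csv, stringsAsFactors = FALSE) else NULL
  taxon_map(syn, ht)
}

# ---- internal mutable tree representation (parent vectors) -------------

phylo_to_ptree <- function(tree) {
  nt <- ape::Ntip(tree)
  n <- nt + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  label <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  is_leaf <- c(rep(TRUE, nt), rep(FALSE, tree$Nnode))
  list(parent = parent, label = label, is_leaf = is_leaf)
}

ptree_add_leaf <- function(pt, parent_id, label) {
  pt$parent <- c(pt$parent, parent_id)
  pt$label <- c(pt$label, label)
  pt$is_leaf <- c(pt$is_leaf, TRUE)
  pt
}

ptree_mrca <- function(pt, ids) {
  anc <- function(i) {
    path <- i
    while (!is.na(pt$parent[i])) { i <- pt$parent[i]; path <- c(path, i) }
    path
  }
  common <- Reduce(intersect, lapply(ids, anc))
  common[1]  # paths are tip-to-root, so first common element is the MRCA
}

# Rebuild newick from a ptree, dropping removed nodes (parent = -1 marks
# deleted), suppressing unary internals and empty internals.
ptree_to_phylo <- function(pt) {
  keep <- pt$parent != -1L | is.na(pt$parent)
  kids <- split(which(keep & !is.na(pt$parent)),
                pt$parent[keep & !is.na(pt$parent)])
  build <- function(i) {
    if (pt$is_leaf[i]) return(pt$label[i])
    ch <- kids[[as.character(i)]]
    ch <- ch[!vapply(ch, function(j) is_empty_subtree(j), logical(1))]
    parts <- vapply(ch, build, character(1))
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) return("")
    if (length(parts) == 1) return(parts[1])
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  is_empty_subtree <- function(i) {
    if (pt$is_leaf[i]) return(FALSE)
    ch <- kids[[as.character(i)]]
    if (is.null(ch)) return(TRUE)
    all(vapply(ch, is_empty_subtree, logical(1)))
  }
  root <- which(is.na(pt$parent))[1]
  n_live <- sum(pt$is_leaf & pt$parent != -1L, na.rm = TRUE)
  if (n_live < 2)
    stop("standardization left fewer than 2 leaves", call. = FALSE)
  nw <- build(root)
  parse_newick(paste0(nw, ";"))
}

ptree_delete_leaf <- function(pt, id) {
  pt$parent[id] <- -1L
  pt
}

# ---- operations --------------------------------------------------------

#' Standardize the taxa of a source tree
#'
#' Applies the curation protocol used for heterogeneous published trees:
#' synonyms are replaced by canonical names; a leaf naming a higher taxon is
#' replaced by a polytomy of those of its members that occur in `observed`
#' (the taxa seen across the other source trees), avoiding artificial
#' inflation of the taxon sample; a higher taxon with no observed members is
#' dropped with a warning. Duplicate leaves arising from these substitutions
#' are collapsed to a single leaf placed as a child of the duplicates' MRCA
#' (the placement retains every grouping shared by all copies).
#'
#' @param source A [source_tree()].
#' @param map A [taxon_map()].
#' @param observed Character vector: union of taxa across the other sources.
#' @return The standardized `source_tree` (topology only).
#' @export
standardize_taxa <- function(source, map, observed = character()) {
  stopifnot(inherits(source, "source_tree"), inherits(map, "taxon_map"))
  tree <- source$tree
  syn <- map$synonyms
  ht <- split(map$higher_taxa$member, map$higher_taxa$higher_taxon)

  pt <- phylo_to_ptree(tree)
  # 1. synonym replacement
  hit <- match(pt$label, syn$synonym)
  pt$label[!is.na(hit)] <- syn$canonical[hit[!is.na(hit)]]

  # 2. higher-taxon substitution
  for (i in which(pt$is_leaf)) {
    lab <- pt$label[i]
    if (!is.null(ht[[lab]])) {
      members <- intersect(ht[[lab]], observed)
      if (length(members) == 0) {
        warning("higher taxon '", lab, "' has no members among observed taxa; leaf dropped",
                call. = FALSE)
        pt <- ptree_delete_leaf(pt, i)
      } else if (length(members) == 1) {
        pt$label[i] <- members
      } else {
        # leaf becomes an internal node carrying a polytomy of members
        pt$is_leaf[i] <- FALSE
        pt$label[i] <- NA_character_
        for (m in members) pt <- ptree_add_leaf(pt, i, m)
      }
    }
  }

  # 3. collapse duplicate leaves at their MRCA
  repeat {
    live <- which(pt$is_leaf & pt$parent != -1L)
    dup_labs <- unique(pt$label[live][duplicated(pt$label[live])])
    if (length(dup_labs) == 0) break
    lab <- dup_labs[1]
    ids <- live[pt$label[live] == lab]
    anc <- ptree_mrca(pt, ids)
    for (id in ids) pt <- ptree_delete_leaf(pt, id)
    pt <- ptree_add_leaf(pt, anc, lab)
  }

  out <- source
  out$tree <- ptree_to_phylo(pt)
  out
}

#' Weight source trees by data-set independence
#'
#' Studies that analysed identical character matrices (same taxa, same
#' declared character sets) are down-weighted in inverse proportion to their
#' number; a study whose matrix is a strict subset of another's (taxa and
#' characters both nested, at least one strictly) is removed as less
#' inclusive. All remaining sources keep weight 1.
#'
#' @param sources List of [source_tree()] objects.
#' @return The filtered, re-weighted list. Removals are reported via message.
#' @export
assign_independence_weights <- function(sources) {
  stopifnot(length(sources) >= 1)
  fp_chars <- lapply(sources, function(s) sort(unique(strsplit(s$fingerprint, "+", fixed = TRUE)[[1]])))
  fp_taxa <- lapply(sources, function(s) sort(s$tree$tip.label))

  n <- length(sources)
  identical_fp <- function(i, j) {
    identical(fp_chars[[i]], fp_chars[[j]]) && identical(fp_taxa[[i]], fp_taxa[[j]])
  }
  strict_subset <- function(i, j) { # is i a strict subset of j?
    ci <- all(fp_chars[[i]] %in% fp_chars[[j]])
    ti <- all(fp_taxa[[i]] %in% fp_taxa[[j]])
    ci && ti && !identical_fp(i, j)
  }
  removed <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && !removed[j] && strict_subset(i, j)) removed[i] <- TRUE
  }
  if (any(removed))
    message("removed as strict data subsets: ",
            paste(vapply(sources[removed], `[[`, "", "study_id"), collapse = ", "))
  keep <- which(!removed)
  group_key <- vapply(keep, function(i)
    paste(paste(fp_chars[[i]], collapse = "+"), paste(fp_taxa[[i]], collapse = "|"), sep = "##"),
    character(1))
  gsize <- table(group_key)
  out <- lapply(seq_along(keep), function(k) {
    s <- sources[[keep[k]]]
    s$weight <- 1 / as.numeric(gsize[[group_key[k]]])
    s
  })
  out
}

#' Check pairwise taxonomic overlap among source trees
#'
#' Builds a graph with an edge between two sources sharing at least two
#' taxa, and reports its connected components. The corpus passes when the
#' graph is a single connected component and every source has at least one
#' qualifying edge.
#'
#' @param sources List of [source_tree()] objects.
#' @return List with elements `pass` (logical), `n_components`,
#'   `components` (membership vector named by study id), and `flagged`
#'   (study ids with no qualifying overlap).
#' @export
check_overlap <- function(sources) {
  stopifnot(length(sources) >= 1)
  ids <- vapply(sources, `[[`, "", "study_id")
  n <- length(sources)
  if (n == 1) {
    warning("single source tree: overlap check passes vacuously", call. = FALSE)
    return(list(pass = TRUE, n_components = 1L,
                components = setNames(1L, ids), flagged = character(0)))
  }
  taxa <- lapply(sources, function(s) s$tree$tip.label)
  edges <- integer(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (length(intersect(taxa[[i]], taxa[[j]])) >= 2) edges <- c(edges, i, j)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  flagged <- ids[igraph::degree(g) == 0]
  list(pass = comp$no == 1L && length(flagged) == 0,
       n_components = comp$no,
       components = setNames(comp$membership, ids),
       flagged = flagged)
}

#' Read a source-tree corpus from disk
#'
#' @param metadata_csv CSV with columns `study_id, year, evidence,
#'   matrix_fingerprint, file` (file paths relative to `dir`).
#' @param dir Directory containing the Newick files.
#' @return List of [source_tree()] objects.
#' @export
read_sources <- function(metadata_csv, dir = dirname(metadata_csv)) {
  md <- read.csv(metadata_csv, stringsAsFactors = FALSE)
  need <- c("study_id", "year", "evidence", "matrix_fingerprint", "file")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop("metadata CSV lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(md)), function(i) {
    txt <- paste(readLines(file.path(dir, md$file[i]), warn = FALSE), collapse = "")
    source_tree(parse_newick(txt), study_id = md$study_id[i], year = md$year[i],
                evidence = md$evidence[i], fingerprint = md$matrix_fingerprint[i])
  })
}
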