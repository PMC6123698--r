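## Fossil/molecular node calibration and 'equal'-method time scaling.
##
## Ages are Ma before present (extant leaves at 0); branch durations in Myr
## satisfy length = age(parent) - age(child).

#' Build a node-calibration table
#'
#' Each row fixes the age of the MRCA of a taxon pair.
#'
#' @param df Data frame with columns `taxon_a`, `taxon_b`, `age_ma`
#'   (positive, Ma) and `source` (`"fossil"` or `"molecular"`).
#' @return A `calibration_table`.
#' @export
calibration_table <- function(df) {
  need <- c("taxon_a", "taxon_b", "age_ma", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("calibration table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  stopifnot(all(df$age_ma > 0), all(df$source %in% c("fossil", "molecular")))
  structure(df, class = c("calibration_table", "data.frame"))
}

#' @rdname calibration_table
#' @param file CSV path with columns `taxonA,taxonB,age_ma,source` (the
#'   column names `taxon_a`/`taxon_b` are also accepted).
#' @export
read_calibrations <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  names(df)[names(df) == "taxonA"] <- "taxon_a"
  names(df)[names(df) == "taxonB"] <- "taxon_b"
  calibration_table(df)
}

# Ancestor node ids of a node (excluding the node itself), tipward-to-root.
ancestors_of <- function(tree, node) {
  parent <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  out <- integer(0)
  while (!is.na(parent[node])) { node <- parent[node]; out <- c(out, node) }
  out
}

#' Fix node ages from a calibration table
#'
#' Assigns each row's age to the MRCA of its taxon pair. Duplicate
#' calibrations of one node are resolved by taking the maximum age (logged
#' via message). A calibrated node older than a calibrated ancestor is an
#' error naming both nodes.
#'
#' @param tree A rooted `phylo`.
#' @param table A [calibration_table()].
#' @return The tree with an `ages` attribute: numeric vector indexed by node
#'   id, `NA` where unconstrained, plus a `calibrated` attribute of fixed
#'   node ids.
#' @export
apply_calibrations <- function(tree, table) {
  stopifnot(inherits(table, "calibration_table"))
  n <- ape::Ntip(tree) + tree$Nnode
  ages <- rep(NA_real_, n)
  for (i in seq_len(nrow(table))) {
    nd <- mrca_node(tree, c(table$taxon_a[i], table$taxon_b[i]))
    if (!is.na(ages[nd]) && abs(ages[nd] - table$age_ma[i]) > 1e-12) {
      message("conflicting calibrations at node ", nd, ": taking max of ",
              ages[nd], " and ", table$age_ma[i])
      ages[nd] <- max(ages[nd], table$age_ma[i])
    } else {
      ages[nd] <- table$age_ma[i]
    }
  }
  fixed <- which(!is.na(ages))
  for (nd in fixed) {
    anc <- intersect(ancestors_of(tree, nd), fixed)
    bad <- anc[ages[anc] < ages[nd] - 1e-12]
    if (length(bad))
      stop("calibration conflict: node ", nd, " (", ages[nd],
           " Ma) is older than its calibrated ancestor node ", bad[1],
           " (", ages[bad[1]], " Ma)", call. = FALSE)
  }
  attr(tree, "ages") <- ages
  attr(tree, "calibrated") <- fixed
  tree
}

#' Drop calibrations incompatible with a tree's topology
#'
#' When calibrations assembled against one topology are applied to another
#' (e.g. true-age calibrations applied to an inferred supertree), a pair's
#' MRCA can land on a node whose nesting contradicts the ages. Rows are
#' admitted greedily in input order; a row is dropped (with a message) when
#' its node age would exceed a calibrated ancestor's age minus `min_gap`
#' per intervening branch, or fall below a calibrated descendant's
#' correspondingly inflated age.
#'
#' @param tree A rooted `phylo`.
#' @param table A [calibration_table()].
#' @param min_gap Minimum age difference per branch between nested
#'   calibrated nodes (match the time-scaling `min_branch`).
#' @return The compatible subset, still a `calibration_table`.
#' @export
filter_compatible_calibrations <- function(tree, table, min_gap = 0.1) {
  # deepest tip below each node, in edge counts (room needed for minimum
  # branch durations)
  n_all <- ape::Ntip(tree) + tree$Nnode
  edge_depth <- integer(n_all)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    edge_depth[p] <- max(edge_depth[p], edge_depth[ch] + 1L)
  }
  keep <- logical(nrow(table))
  nodes <- integer(nrow(table))
  for (i in seq_len(nrow(table))) {
    nd <- mrca_node(tree, c(table$taxon_a[i], table$taxon_b[i]))
    age <- table$age_ma[i]
    ok <- age >= edge_depth[nd] * min_gap
    anc <- ancestors_of(tree, nd)
    for (j in if (ok) which(keep) else integer(0)) {
      other <- nodes[j]; oage <- table$age_ma[j]
      if (other == nd) { ok <- abs(oage - age) < 1e-9; if (!ok) break; next }
      if (other %in% anc) {
        gap <- min_gap * (which(anc == other))
        if (age > oage - gap) { ok <- FALSE; break }
      } else if (nd %in% ancestors_of(tree, other)) {
        gap <- min_gap * (which(ancestors_of(tree, other) == nd))
        if (oage > age - gap) { ok <- FALSE; break }
      }
    }
    keep[i] <- ok
    nodes[i] <- nd
  }
  if (any(!keep))
    message(sum(!keep), " calibration(s) incompatible with the topology dropped")
  calibration_table(table[keep, , drop = FALSE])
}

#' Time-scale a tree by the 'equal' method
#'
#' Uncalibrated internal nodes receive ages by equal spacing: along each
#' path between consecutive age-fixed nodes, the `k` undated nodes divide
#' the interval into `k + 1` equal durations. Where an undated node sits
#' above several dated descendants the most constraining (oldest) spacing
#' candidate is used, so every downstream interval remains feasible. A
#' second pass then lengthens any branch shorter than `min_branch` by
#' shifting its parent (and further ancestors as needed) rootward;
#' calibrated nodes are never moved -- if enforcing the minimum would
#' require moving one, the function errors naming the path.
#'
#' @param tree A rooted `phylo` (topology; existing branch lengths ignored).
#' @param table A [calibration_table()]; must constrain the root (directly
#'   or via a pair whose MRCA is the root).
#' @param min_branch Minimum branch duration in Myr (default 0.1).
#' @param tip_ages Optional named numeric vector of non-zero tip ages (Ma)
#'   for extinct leaves; extant leaves default to age 0.
#' @param root_age Optional fallback root age (Ma) used only when no
#'   calibration row maps onto the root.
#' @return The tree with branch lengths in Myr and an `ages` attribute.
#' @export
timescale_equal <- function(tree, table, min_branch = 0.1, tip_ages = NULL,
                            root_age = NULL) {
  tree2 <- apply_calibrations(tree, table)
  ages <- attr(tree2, "ages")
  fixed <- attr(tree2, "calibrated")
  if (is.na(ages[ape::Ntip(tree) + 1L]) && !is.null(root_age)) {
    if (root_age < max(ages, na.rm = TRUE))
      stop("fallback root age is younger than a calibrated node", call. = FALSE)
    ages[ape::Ntip(tree) + 1L] <- root_age
    fixed <- c(fixed, ape::Ntip(tree) + 1L)
    attr(tree2, "calibrated") <- fixed
  }
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  # leaves: age 0 unless supplied
  leaf_ages <- rep(0, nt)
  if (!is.null(tip_ages)) {
    idx <- match(names(tip_ages), tree$tip.label)
    stopifnot(!anyNA(idx))
    leaf_ages[idx] <- tip_ages
  }
  undated_leaves <- setdiff(seq_len(nt), fixed)
  ages[undated_leaves] <- leaf_ages[undated_leaves]
  fixed <- sort(unique(c(fixed, seq_len(nt))))
  if (is.na(ages[root]))
    stop("the root age must be constrained by the calibration table", call. = FALSE)

  kids <- split(tree$edge[, 2], tree$edge[, 1])
  parent <- rep(NA_integer_, nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # (dated-descendant age, number of undated nodes on the path) pairs
  spacing_pairs <- function(u) {
    out <- list()
    for (c_ in kids[[as.character(u)]]) {
      if (!is.na(ages[c_])) {
        out[[length(out) + 1L]] <- c(ages[c_], 1)
      } else {
        for (p in spacing_pairs(c_))
          out[[length(out) + 1L]] <- c(p[1], p[2] + 1)
      }
    }
    out
  }

  preord <- c(root, unique(tree$edge[rev(ape::postorder(tree)), 2]))
  preord <- preord[preord > nt]
  for (u in preord) {
    if (!is.na(ages[u])) next
    a_p <- ages[parent[u]]
    cand <- vapply(spacing_pairs(u), function(p) a_p - (a_p - p[1]) / (p[2] + 1),
                   numeric(1))
    ages[u] <- max(cand)
  }

  # minimum-branch enforcement, tips-to-root
  postord_nodes <- unique(tree$edge[ape::postorder(tree), 1])
  calibrated <- attr(tree2, "calibrated")
  for (nd in postord_nodes) {
    required <- max(ages[kids[[as.character(nd)]]]) + min_branch
    if (ages[nd] < required - 1e-12) {
      if (nd %in% calibrated || nd == root && nd %in% calibrated)
        stop("cannot enforce minimum branch of ", min_branch,
             " Myr below calibrated node ", nd,
             ": interval above its children is too short", call. = FALSE)
      if (nd == root && !is.na(ages[root]) && root %in% calibrated)
        stop("root interval too short for minimum branches", call. = FALSE)
      ages[nd] <- required
    }
  }
  if (ages[root] < max(ages[kids[[as.character(root)]]]) + min_branch - 1e-12)
    stop("root interval too short for minimum branches", call. = FALSE)

  out <- ages_to_edge_lengths(tree, ages)
  attr(out, "ages") <- ages
  attr(out, "calibrated") <- calibrated
  out
}
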