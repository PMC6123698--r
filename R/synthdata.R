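## Seeded generators for every input the pipeline consumes: birth-death and
## state-dependent trees, Mk traits, perturbed overlapping source-tree
## corpora, calibration tables from true node ages, and clade-wise
## incomplete tip sampling. Every generator is a pure function of its
## arguments including the seed.

# ---- forward birth-death engine -----------------------------------------

# Forward-time simulation from two crown lineages. Rates are per current
# state (single-state models pass equal entries). Stops at `n` extant tips
# (tree returned at the instant of the n-th birth) or at duration `time`.
# Resimulates until at least 2 extant tips survive. Returns the
# extinct-pruned (reconstructed) tree plus per-edge true state segments
# (rootward to tipward) and tip states.
sim_forward <- function(lambda, mu, q01 = 0, q10 = 0, n = NULL, time = NULL,
                        root_state = 0L, max_tries = 1000) {
  stopifnot(xor(is.null(n), is.null(time)), all(lambda > 0), all(mu >= 0))
  for (try_i in seq_len(max_tries)) {
    res <- sim_forward_once(lambda, mu, q01, q10, n, time, root_state)
    if (!is.null(res)) return(res)
  }
  stop("simulation failed to survive in ", max_tries, " attempts", call. = FALSE)
}

sim_forward_once <- function(lambda, mu, q01, q10, n, time, root_state) {
  # lineage records (grown dynamically)
  parent <- integer(0); t0 <- numeric(0); t1 <- numeric(0)
  fate <- character(0); kids <- list()
  seg_s <- list(); seg_t <- list()   # per-lineage state segments
  state <- integer(0); seg_start <- numeric(0)

  new_lineage <- function(par, t, st) {
    parent[length(parent) + 1L] <<- par
    t0[length(t0) + 1L] <<- t
    t1[length(t1) + 1L] <<- NA_real_
    fate[length(fate) + 1L] <<- "active"
    kids[[length(kids) + 1L]] <<- integer(0)
    seg_s[[length(seg_s) + 1L]] <<- integer(0)
    seg_t[[length(seg_t) + 1L]] <<- numeric(0)
    state[length(state) + 1L] <<- st
    seg_start[length(seg_start) + 1L] <<- t
    length(parent)
  }
  close_segment <- function(i, t) {
    seg_s[[i]] <<- c(seg_s[[i]], state[i])
    seg_t[[i]] <<- c(seg_t[[i]], t - seg_start[i])
    seg_start[i] <<- t
  }
  new_lineage(0L, 0, root_state)
  new_lineage(0L, 0, root_state)
  active <- c(1L, 2L)
  t <- 0
  qout <- c(q01, q10)
  repeat {
    rates <- lambda[state[active] + 1L] + mu[state[active] + 1L] +
      qout[state[active] + 1L]
    tot <- sum(rates)
    dt <- rexp(1, tot)
    if (!is.null(time) && t + dt > time) {
      t <- time
      break
    }
    t <- t + dt
    i <- active[sample.int(length(active), 1, prob = rates)]
    s <- state[i] + 1L
    ev <- sample.int(3L, 1, prob = c(lambda[s], mu[s], qout[s]))
    if (ev == 1L) {          # birth
      close_segment(i, t)
      t1[i] <- t; fate[i] <- "split"
      c1 <- new_lineage(i, t, state[i])
      c2 <- new_lineage(i, t, state[i])
      kids[[i]] <- c(c1, c2)
      active <- c(setdiff(active, i), c1, c2)
      if (!is.null(n) && length(active) == n) {
        # stop at a uniform time within the event-free interval that
        # follows the n-th birth, so the tree is not cut at a speciation
        rates_n <- lambda[state[active] + 1L] + mu[state[active] + 1L] +
          qout[state[active] + 1L]
        t <- t + runif(1) * rexp(1, sum(rates_n))
        break
      }
    } else if (ev == 2L) {   # death
      close_segment(i, t)
      t1[i] <- t; fate[i] <- "extinct"
      active <- setdiff(active, i)
      if (length(active) == 0L) return(NULL)
    } else {                 # state flip
      close_segment(i, t)
      state[i] <- 1L - state[i]
    }
  }
  for (i in active) { close_segment(i, t); t1[i] <- t; fate[i] <- "extant" }
  if (sum(fate == "extant") < 2) return(NULL)

  # survival (leaves a sampled descendant) per lineage
  nlin <- length(parent)
  surv <- logical(nlin)
  for (i in seq(nlin, 1L)) {
    surv[i] <- fate[i] == "extant" ||
      (fate[i] == "split" && any(surv[kids[[i]]]))
  }

  # assemble the reconstructed tree
  tip_lab <- character(0); tip_state <- integer(0)
  edges <- list(); edge_seg <- list()
  n_int <- 0L
  add_internal <- function() { n_int <<- n_int + 1L; -n_int }
  descend <- function(i) {
    # follow chains of single-survivor splits, concatenating segments
    ss <- seg_s[[i]]; st <- seg_t[[i]]
    len <- t1[i] - t0[i]
    while (fate[i] == "split") {
      sv <- kids[[i]][surv[kids[[i]]]]
      if (length(sv) != 1L) break
      i <- sv
      ss <- c(ss, seg_s[[i]]); st <- c(st, seg_t[[i]])
      len <- len + (t1[i] - t0[i])
    }
    # merge adjacent equal-state segments
    if (length(ss) > 1) {
      keep <- c(TRUE, ss[-1] != ss[-length(ss)])
      grp <- cumsum(keep)
      st <- as.numeric(tapply(st, grp, sum))
      ss <- ss[keep]
    }
    if (fate[i] == "extant") {
      tip_lab[length(tip_lab) + 1L] <<- paste0("t", length(tip_lab) + 1L)
      tip_state[length(tip_state) + 1L] <<- state[i]
      id <- length(tip_lab)
    } else {
      id <- add_internal()
      for (ch in kids[[i]][surv[kids[[i]]]]) {
        child <- descend(ch)
        edges[[length(edges) + 1L]] <<- c(id, child$id, child$len)
        edge_seg[[length(edge_seg) + 1L]] <<- child$seg
      }
    }
    list(id = id, len = len, seg = cbind(state = ss, duration = st))
  }
  roots <- which(parent == 0L & surv)
  if (length(roots) == 2L) {
    rid <- add_internal()
    stopifnot(rid == -1L)
    for (rl in roots) {
      child <- descend(rl)
      edges[[length(edges) + 1L]] <- c(rid, child$id, child$len)
      edge_seg[[length(edge_seg) + 1L]] <- child$seg
    }
  } else {
    # one crown lineage survived: its first surviving split is the root
    child <- descend(roots)
    if (child$id > 0) return(NULL)  # a single surviving tip: no tree
  }
  em <- do.call(rbind, edges)
  ntip <- length(tip_lab)
  renum <- function(x) ifelse(x > 0, x, ntip - x)   # -k -> ntip + k
  tree <- list(edge = cbind(renum(em[, 1]), renum(em[, 2])),
               edge.length = em[, 3], tip.label = tip_lab,
               Nnode = n_int)
  storage.mode(tree$edge) <- "integer"
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(tree$edge[, 1], tree$edge[, 2]),
               paste(renum(em[, 1]), renum(em[, 2])))
  list(tree = tree, edge_segments = edge_seg[ord],
       tip_states = setNames(tip_state, tip_lab))
}

#' Simulate a birth-death tree
#'
#' Forward-time constant-rate birth-death simulation from two crown
#' lineages, conditioned on survival (whole-tree extinction triggers a
#' resimulation). Extinct lineages are pruned; the result is ultrametric.
#'
#' @param lambda,mu Speciation and extinction rates per Myr.
#' @param n Stop at this extant tip count (tree returned at the n-th birth).
#' @param time Alternatively, stop at this duration (Myr).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with a `provenance` attribute recording
#'   the configuration and seed.
#' @export
sim_bd_tree <- function(lambda, mu = 0, n = NULL, time = NULL, seed = 1) {
  set.seed(seed)
  res <- sim_forward(rep(lambda, 2), rep(mu, 2), 0, 0, n = n, time = time)
  tr <- res$tree
  attr(tr, "provenance") <- list(generator = "sim_bd_tree", lambda = lambda,
                                 mu = mu, n = n, time = time, seed = seed)
  tr
}

#' Simulate a tree with state-dependent diversification
#'
#' Each lineage carries a binary state; birth and death follow the current
#' state's rates and the state flips at rates `q01`/`q10`. This produces the
#' structure the diversification stage is designed to detect: derived-state
#' clades with their own rates.
#'
#' @param lambda0,lambda1,mu0,mu1 Per-state speciation/extinction rates.
#' @param q01,q10 State transition rates per Myr.
#' @param n,time Stopping rule (tip count or duration).
#' @param root_state Crown state (default 0).
#' @param seed Integer seed.
#' @return List with `tree` (ultrametric `phylo`), `tip_states` (named 0/1),
#'   `edge_segments` (true per-edge state history, rootward to tipward),
#'   `n_transitions` (named counts `n01`, `n10` on the reconstructed tree).
#' @export
sim_state_dependent_tree <- function(lambda0, lambda1, mu0 = 0, mu1 = 0,
                                     q01 = 0, q10 = 0, n = NULL, time = NULL,
                                     root_state = 0L, seed = 1) {
  set.seed(seed)
  res <- sim_forward(c(lambda0, lambda1), c(mu0, mu1), q01, q10,
                     n = n, time = time, root_state = root_state)
  counts <- c(n01 = 0L, n10 = 0L)
  for (seg in res$edge_segments) {
    st <- seg[, "state"]
    if (length(st) > 1) {
      counts["n01"] <- counts["n01"] + sum(st[-length(st)] == 0 & st[-1] == 1)
      counts["n10"] <- counts["n10"] + sum(st[-length(st)] == 1 & st[-1] == 0)
    }
  }
  list(tree = res$tree, tip_states = res$tip_states,
       edge_segments = res$edge_segments, n_transitions = counts,
       provenance = list(generator = "sim_state_dependent_tree",
                         rates = c(lambda0, lambda1, mu0, mu1, q01, q10),
                         n = n, time = time, seed = seed))
}

#' Simulate a binary trait down a tree under the symmetric Mk model
#'
#' @param tree A time-scaled `phylo`.
#' @param q Transition rate per Myr.
#' @param seed Integer seed.
#' @param root_state Root state; drawn uniformly if `NULL`.
#' @return List with `states` (named 0/1 per tip), `n_changes` (true total
#'   flip count), `n01`/`n10` (directional counts), and `edge_segments`.
#' @export
sim_trait <- function(tree, q, seed = 1, root_state = NULL) {
  stopifnot(!is.null(tree$edge.length), q >= 0)
  set.seed(seed)
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  if (is.null(root_state)) root_state <- sample(0:1, 1)
  ns <- integer(nt + tree$Nnode)
  ns[root] <- root_state
  segs <- vector("list", nrow(tree$edge))
  n01 <- 0L; n10 <- 0L
  for (e in rev(ape::postorder(tree))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    k <- rpois(1, q * t_e)
    if (k == 0L) {
      segs[[e]] <- cbind(state = ns[p], duration = t_e)
      ns[c_] <- ns[p]
    } else {
      times <- sort(runif(k, 0, t_e))
      st <- (ns[p] + seq(0L, k)) %% 2L
      segs[[e]] <- cbind(state = st, duration = diff(c(0, times, t_e)))
      ns[c_] <- st[k + 1L]
      n01 <- n01 + sum(st[-(k + 1L)] == 0 & st[-1] == 1)
      n10 <- n10 + sum(st[-(k + 1L)] == 1 & st[-1] == 0)
    }
  }
  list(states = setNames(ns[seq_len(nt)], tree$tip.label),
       n_changes = n01 + n10, n01 = n01, n10 = n10,
       edge_segments = segs, root_state = root_state,
       provenance = list(generator = "sim_trait", q = q, seed = seed))
}

# one random rooted NNI move (in place on a phylo topology)
rooted_nni <- function(tree) {
  nt <- ape::Ntip(tree)
  parent <- rep(NA_integer_, nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  internal <- which(seq_along(parent) > nt & !is.na(parent))
  if (length(internal) == 0) return(tree)
  c_ <- if (length(internal) == 1) internal else sample(internal, 1)
  p <- parent[c_]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == p, 2], c_)
  ch <- tree$edge[tree$edge[, 1] == c_, 2]
  s <- if (length(sibs) == 1) sibs else sample(sibs, 1)
  x <- if (length(ch) == 1) ch else sample(ch, 1)
  e_s <- which(tree$edge[, 2] == s)
  e_x <- which(tree$edge[, 2] == x)
  tree$edge[e_s, 1] <- c_
  tree$edge[e_x, 1] <- p
  # lengths no longer meaningful after a topology move
  tree$edge.length <- NULL
  tree <- parse_newick(write_newick(tree))
  tree
}

#' Simulate a corpus of overlapping, optionally conflicting source trees
#'
#' Each source is the restriction of the true tree to a random taxon subset,
#' perturbed by `nni_moves` random rooted NNI moves (the smallest controlled
#' unit of topological conflict). The corpus is resimulated until the
#' taxonomic-overlap check passes.
#'
#' @param true_tree The generating `phylo`.
#' @param m Number of source trees (>= 2).
#' @param size_range Two integers: min/max subsample size (>= 4).
#' @param nni_moves Number of random NNI perturbations per source.
#' @param seed Integer seed.
#' @return List of [source_tree()] objects with distinct fingerprints.
#' @export
sim_source_trees <- function(true_tree, m, size_range = c(8, 20),
                             nni_moves = 0, seed = 1) {
  stopifnot(m >= 2, min(size_range) >= 4,
            max(size_range) <= ape::Ntip(true_tree))
  set.seed(seed)
  for (attempt in seq_len(1000)) {
    sources <- lapply(seq_len(m), function(j) {
      sz <- sample(seq(size_range[1], size_range[2]), 1)
      taxa <- sample(true_tree$tip.label, sz)
      tr <- prune_to(true_tree, taxa)
      tr$edge.length <- NULL
      if (nni_moves > 0) for (i in seq_len(nni_moves)) tr <- rooted_nni(tr)
      source_tree(tr, study_id = sprintf("study%03d", j),
                  year = 1984L + (j %% 31L),
                  evidence = c("molecular", "morphological", "combined")[1 + j %% 3],
                  fingerprint = sprintf("charset%03d", j))
    })
    ok <- withCallingHandlers(
      check_overlap(sources)$pass,
      warning = function(w) invokeRestart("muffleWarning"))
    if (ok) {
      attr(sources, "provenance") <- list(generator = "sim_source_trees",
                                          m = m, size_range = size_range,
                                          nni_moves = nni_moves, seed = seed)
      return(sources)
    }
  }
  stop("could not generate an overlapping corpus in 1000 attempts", call. = FALSE)
}

#' Drop tips with clade-dependent retention probabilities
#'
#' Emulates clade-dependent incomplete sampling: each tip is kept
#' independently with its clade's retention probability (smallest enclosing
#' listed clade, else `default_retention`). Resimulates (up to 100 times)
#' if any listed clade or the residual background loses all tips.
#'
#' @param tree A `phylo`.
#' @param retention Data frame `taxon_a, taxon_b, p` of per-clade retention
#'   probabilities, or `NULL`.
#' @param default_retention Retention outside listed clades.
#' @param seed Integer seed.
#' @return List with `tree` (pruned), `kept` (labels), and `sampling`: the
#'   realized per-clade sampled fractions as a `taxon_a, taxon_b, rho` table
#'   (clades re-anchored on retained tips) with the realized background
#'   fraction as attribute `default_rho`.
#' @export
drop_tips <- function(tree, retention = NULL, default_retention = 1, seed = 1) {
  set.seed(seed)
  nt <- ape::Ntip(tree)
  prob <- rep(default_retention, nt)
  clade_of <- rep(0L, nt)
  cs <- clade_sets(tree)
  if (!is.null(retention) && nrow(retention) > 0) {
    stopifnot(all(retention$p > 0), all(retention$p <= 1))
    sizes <- rep(Inf, nt)
    for (i in seq_len(nrow(retention))) {
      nd <- mrca_node(tree, c(retention$taxon_a[i], retention$taxon_b[i]))
      tips <- match(cs[[nd]], tree$tip.label)
      smaller <- length(tips) < sizes[tips]
      prob[tips[smaller]] <- retention$p[i]
      clade_of[tips[smaller]] <- i
      sizes[tips[smaller]] <- length(tips)
    }
  }
  for (try_i in seq_len(100)) {
    keep <- runif(nt) < prob
    ok <- sum(keep) >= 2 &&
      all(vapply(unique(clade_of), function(cl)
        any(keep[clade_of == cl]) && sum(clade_of == cl) > 0, logical(1)))
    # require >= 2 kept tips per listed clade so it stays anchorable
    if (ok && !is.null(retention) && nrow(retention) > 0)
      ok <- all(vapply(seq_len(nrow(retention)), function(cl)
        sum(keep[clade_of == cl]) >= 2, logical(1)))
    if (ok) break
    if (try_i == 100) warning("retention resampling hit 100 tries", call. = FALSE)
  }
  kept <- tree$tip.label[keep]
  pruned <- prune_to(tree, kept)
  samp <- NULL
  if (!is.null(retention) && nrow(retention) > 0) {
    rows <- lapply(seq_len(nrow(retention)), function(cl) {
      in_cl <- clade_of == cl
      kept_cl <- tree$tip.label[in_cl & keep]
      nd <- mrca_node(pruned, kept_cl)
      ab <- if (nd <= ape::Ntip(pruned)) rep(kept_cl[1], 2) else
        anchor_pair(pruned, nd)
      data.frame(taxon_a = ab[1], taxon_b = ab[2],
                 rho = sum(in_cl & keep) / sum(in_cl),
                 stringsAsFactors = FALSE)
    })
    samp <- do.call(rbind, rows)
  }
  bg <- clade_of == 0L
  default_rho <- if (any(bg)) sum(bg & keep) / sum(bg) else 1
  out <- list(tree = pruned, kept = kept, sampling = samp,
              provenance = list(generator = "drop_tips", seed = seed,
                                default_retention = default_retention))
  if (!is.null(samp)) attr(out$sampling, "default_rho") <- default_rho
  out$default_rho <- default_rho
  out
}

#' Maximal monophyletic single-state clades of a tree
#'
#' Finds the internal nodes whose tips are all in state `state` while the
#' parent's tip set is not, i.e. the maximal clades of that state; used to
#' name the clades entering the clade-rate comparisons.
#'
#' @param tree A `phylo`.
#' @param states Named 0/1 vector per tip.
#' @param state The state defining the clades (0 or 1).
#' @param min_tips Keep clades with more than this many tips.
#' @return Data frame `name, taxon_a, taxon_b, n_tips` (possibly 0 rows).
#' @export
trait_clades <- function(tree, states, state, min_tips = 10) {
  s <- check_states(tree, states)
  nt <- ape::Ntip(tree)
  cs <- clade_sets(tree)
  parent <- rep(NA_integer_, nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  pure <- vapply(seq_len(nt + tree$Nnode), function(nd)
    all(s[match(cs[[nd]], tree$tip.label)] == state), logical(1))
  rows <- list()
  for (nd in which(pure)) {
    if (!is.na(parent[nd]) && pure[parent[nd]]) next  # not maximal
    tips <- cs[[nd]]
    if (length(tips) <= min_tips || nd <= nt) next
    ab <- anchor_pair(tree, nd)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("state%d_clade_%d", state, nd),
      taxon_a = ab[1], taxon_b = ab[2],
      n_tips = length(tips), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(name = character(), taxon_a = character(),
                      taxon_b = character(), n_tips = integer()))
  do.call(rbind, rows)
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline consumes, with the statistical
#' structure the analysis assumes: a state-dependent birth-death "true" tree
#' in which derived-habitat (freshwater-like) clades have elevated
#' speciation, a second low-rate binary trait (lifestyle), a corpus of
#' partially overlapping and optionally conflicting source trees subsampled
#' from the true tree, fossil- and molecular-style node calibrations emitted
#' from true node ages, and clade-dependent incomplete tip sampling with the
#' realized fractions reported for use as sampling-bias corrections.
#'
#' @param seed Integer master seed (all sub-generators derive from it).
#' @param n_tips True-tree size before tip dropping.
#' @param lambda0,mu0 Background (marine) speciation/extinction per Myr.
#' @param lambda_ratio Derived-state speciation multiplier.
#' @param q01,q10 Habitat transition rates per Myr.
#' @param q_lifestyle Mk rate of the independent lifestyle trait.
#' @param m_sources,source_size_range,nni_moves Source-corpus settings.
#' @param n_fossil,n_molecular Calibration counts (root always calibrated,
#'   counted among the fossils).
#' @param retention_derived,retention_background Tip retention probabilities.
#' @param min_derived_clade Require a derived clade with more than this many
#'   tips (resimulating the tree), so the clade-rate stage is exercised.
#' @param out_dir Optional directory: write the study as the file layout the
#'   pipeline reads (Newick sources + CSV tables, provenance headers).
#' @return A list with the true tree, traits, sources, calibrations,
#'   sampling table and bookkeeping (see names).
#' @export
sim_study <- function(seed = 1, n_tips = 200, lambda0 = 0.06, mu0 = 0.015,
                      lambda_ratio = 2.5, q01 = 0.0025, q10 = 0.001,
                      q_lifestyle = 0.004, m_sources = 35,
                      source_size_range = c(10, 40), nni_moves = 1,
                      n_fossil = 6, n_molecular = 9,
                      retention_derived = 0.7, retention_background = 0.85,
                      min_derived_clade = 30, out_dir = NULL) {
  lambda1 <- lambda_ratio * lambda0
  # resimulate until, even after incomplete sampling, both habitats can
  # still furnish clades for the rate comparison
  sdt <- dropped <- NULL
  for (k in 0:200) {
    cand <- sim_state_dependent_tree(lambda0, lambda1, mu0, mu0, q01, q10,
                                     n = n_tips, seed = seed * 211L + k)
    dcl <- trait_clades(cand$tree, cand$tip_states, 1,
                        min_tips = min_derived_clade - 1)
    mcl <- trait_clades(cand$tree, cand$tip_states, 0,
                        min_tips = min_derived_clade - 1)
    if (nrow(dcl) < 1 || nrow(mcl) < 1) next
    retention <- data.frame(taxon_a = dcl$taxon_a, taxon_b = dcl$taxon_b,
                            p = retention_derived, stringsAsFactors = FALSE)
    drp <- drop_tips(cand$tree, retention,
                     default_retention = retention_background,
                     seed = seed + 4L + k)
    st_s <- cand$tip_states[drp$tree$tip.label]
    if (nrow(trait_clades(drp$tree, st_s, 1, min_derived_clade - 1)) >= 1 &&
        nrow(trait_clades(drp$tree, st_s, 0, min_derived_clade - 1)) >= 1) {
      sdt <- cand; dropped <- drp; break
    }
  }
  if (is.null(sdt))
    stop("no simulated tree met the clade-size requirements", call. = FALSE)
  tree <- sdt$tree          # complete (true) tree
  sampled <- dropped$tree   # the species available to the analysis

  lifestyle <- sim_trait(tree, q_lifestyle, seed = seed + 1L, root_state = 0L)
  traits <- data.frame(species = sampled$tip.label,
                       habitat = as.integer(sdt$tip_states[sampled$tip.label]),
                       lifestyle = as.integer(lifestyle$states[sampled$tip.label]),
                       stringsAsFactors = FALSE)

  sources <- sim_source_trees(sampled, m = m_sources,
                              size_range = source_size_range,
                              nni_moves = nni_moves, seed = seed + 2L)

  calibrations <- calibrations_from_true_ages(sampled, n_fossil, n_molecular,
                                              seed = seed + 3L)

  study <- list(true_tree = tree, traits = traits, sources = sources,
                calibrations = calibrations,
                true_transitions = sdt$n_transitions,
                lifestyle_changes = c(n01 = lifestyle$n01, n10 = lifestyle$n10),
                sampled_tree = sampled, sampling = dropped$sampling,
                default_rho = dropped$default_rho,
                config = list(seed = seed, n_tips = n_tips, lambda0 = lambda0,
                              lambda1 = lambda1, mu0 = mu0, q01 = q01,
                              q10 = q10, q_lifestyle = q_lifestyle,
                              m_sources = m_sources, nni_moves = nni_moves))
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

# a pair of tips from two different children of `node`, so their MRCA is
# exactly `node`
anchor_pair <- function(tree, node) {
  cs <- clade_sets(tree)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  c(cs[[kids[1]]][1], cs[[kids[2]]][1])
}

# Calibrations from true node ages. Fossil-style calibrations sit on the
# root and the largest clades (fossils are assigned to well-characterised
# families, i.e. speciose, recognisable groups); molecular-style points are
# random internal nodes.
calibrations_from_true_ages <- function(tree, n_fossil = 6, n_molecular = 9,
                                        seed = 1) {
  set.seed(seed)
  ages <- node_ages(tree)
  nt <- ape::Ntip(tree)
  cs <- clade_sets(tree)
  root <- nt + 1L
  pool <- setdiff(seq(nt + 1L, nt + tree$Nnode), root)
  sizes <- lengths(cs)[pool]
  fossil_extra <- pool[order(sizes, decreasing = TRUE)][
    seq_len(min(n_fossil - 1, length(pool)))]
  rest <- setdiff(pool, fossil_extra)
  n_mol <- min(length(rest), n_molecular)
  mol <- if (n_mol > 0) sample(rest, n_mol) else integer(0)
  nodes <- c(root, fossil_extra, mol)
  src <- c(rep("fossil", min(n_fossil, length(nodes))),
           rep("molecular", max(0, length(nodes) - n_fossil)))
  rows <- lapply(seq_along(nodes), function(i) {
    nd <- nodes[i]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    a <- cs[[kids[1]]][1]
    b <- cs[[kids[2]]][1]
    data.frame(taxon_a = a, taxon_b = b, age_ma = ages[nd], source = src[i],
               stringsAsFactors = FALSE)
  })
  calibration_table(do.call(rbind, rows))
}

#' Write a synthetic study as the directory layout the pipeline reads
#'
#' @param study A [sim_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "sources"), recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# generated by caridiv sim_study, seed %d",
                 study$config$seed)
  writeLines(c(hdr, write_newick(study$true_tree)),
             file.path(dir, "true_tree.nwk"))
  md <- data.frame(study_id = vapply(study$sources, `[[`, "", "study_id"),
                   year = vapply(study$sources, function(s) s$year, integer(1)),
                   evidence = vapply(study$sources, `[[`, "", "evidence"),
                   matrix_fingerprint = vapply(study$sources, `[[`, "", "fingerprint"),
                   file = sprintf("sources/%s.nwk",
                                  vapply(study$sources, `[[`, "", "study_id")),
                   stringsAsFactors = FALSE)
  for (i in seq_along(study$sources))
    writeLines(write_newick(study$sources[[i]]$tree),
               file.path(dir, md$file[i]))
  write.csv(md, file.path(dir, "sources.csv"), row.names = FALSE)
  write.csv(study$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  write.csv(as.data.frame(study$calibrations),
            file.path(dir, "calibrations.csv"), row.names = FALSE)
  if (!is.null(study$sampling))
    write.csv(study$sampling, file.path(dir, "sampling.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(study$config, auto_unbox = TRUE, digits = NA),
             file.path(dir, "study_config.json"))
  invisible(dir)
}
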