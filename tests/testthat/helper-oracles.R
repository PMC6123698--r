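# Independent oracles and small generators shared across tests. These stay
# deliberately naive (enumeration / brute force / numerical integration) and
# never call the code paths they check.

# random rooted topology with unique labels (and optional branch lengths)
random_rooted_tree <- function(n, lengths = TRUE) {
  tr <- ape::rtree(n, rooted = TRUE, tip.label = paste0("t", seq_len(n)))
  if (!lengths) tr$edge.length <- NULL
  tr
}

# brute-force parsimony: minimum weighted changes over all assignments of
# 0/1 to internal nodes and to '?' leaves
brute_force_parsimony <- function(tree, m, weights) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  total <- 0
  for (ch in seq_len(ncol(m))) {
    states <- m[match(tree$tip.label, rownames(m)), ch]
    free <- c(which(is.na(states)), nt + seq_len(nn))
    fixed <- states
    best <- Inf
    for (mask in 0:(2^length(free) - 1)) {
      asg <- fixed
      bits <- as.integer(intToBits(mask))[seq_along(free)]
      asg[free] <- bits
      changes <- sum(asg[tree$edge[, 1]] != asg[tree$edge[, 2]])
      best <- min(best, changes)
    }
    total <- total + weights[ch] * best
  }
  total
}

# exhaustive rooted MAST size for two trees on <= 8 shared leaves: try leaf
# subsets in decreasing size until the restrictions are isomorphic
brute_force_mast_size <- function(t1, t2) {
  leaves <- intersect(t1$tip.label, t2$tip.label)
  n <- length(leaves)
  subsets <- lapply(0:(2^n - 1), function(mask)
    leaves[as.logical(intToBits(mask)[seq_len(n)])])
  sizes <- vapply(subsets, length, integer(1))
  for (k in sort(unique(sizes), decreasing = TRUE)) {
    for (s in subsets[sizes == k]) {
      if (k < 2) return(k)
      if (trees_isomorphic(prune_to(t1, s), prune_to(t2, s))) return(k)
    }
  }
  0L
}

# numerical matrix exponential of the ER rate matrix via eigen decomposition
expm_er <- function(q, t) {
  Q <- matrix(c(-q, q, q, -q), 2, 2)
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# brute-force joint likelihood over all internal-node state assignments
# (for marginal posteriors on small trees)
brute_force_marginal <- function(tree, states, q) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  s <- states[tree$tip.label]
  post <- numeric(nn)
  tot <- 0
  for (mask in 0:(2^nn - 1)) {
    asg <- c(s, as.integer(intToBits(mask))[seq_len(nn)])
    lik <- 0.5
    for (e in seq_len(nrow(tree$edge))) {
      P <- transition_probability(q, tree$edge.length[e])
      lik <- lik * P[asg[tree$edge[e, 1]] + 1, asg[tree$edge[e, 2]] + 1]
    }
    tot <- tot + lik
    post <- post + lik * asg[nt + seq_len(nn)]
  }
  post / tot
}

# expected number of flips of the 2-state symmetric chain on a branch of
# duration t conditioned on the endpoints, by truncated series over the
# Poisson flip count (uniformization identity, computed independently)
expected_flips_conditioned <- function(q, t, same_endpoints, nmax = 400) {
  lam <- q * t
  ns <- 0:nmax
  keep <- if (same_endpoints) ns %% 2 == 0 else ns %% 2 == 1
  w <- dpois(ns[keep], lam)
  sum(ns[keep] * w) / sum(w)
}

# Yule log-likelihood closed form (crown tree, survival conditioning trivial)
yule_loglik <- function(tree, lambda) {
  -lambda * sum(tree$edge.length) + (ape::Ntip(tree) - 2) * log(lambda)
}
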