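## Two-state equal-rates Markov (Mk) model: transition probabilities,
## pruning likelihood, rate estimation and stochastic character mapping.
## States are coded 0 (ancestral: marine / free-living) and 1 (derived:
## freshwater-anchialine / symbiotic).

#' Equal-rates Mk model object
#'
#' @param q Symmetric transition rate per Myr (>= 0).
#' @return An `mk_er` model object.
#' @export
mk_er <- function(q) {
  stopifnot(is.numeric(q), length(q) == 1, q >= 0)
  structure(list(q = q), class = "mk_er")
}

#' Transition probability matrix of the 2-state symmetric chain
#'
#' Closed form: `P(stay) = (1 + exp(-2qt))/2`, `P(switch) = (1 - exp(-2qt))/2`.
#'
#' @param model An [mk_er()] model (or bare rate).
#' @param t Elapsed time in Myr (>= 0).
#' @return A 2x2 row-stochastic matrix with rows/cols `c("0","1")`.
#' @export
transition_probability <- function(model, t) {
  q <- if (inherits(model, "mk_er")) model$q else model
  if (t < 0) stop("elapsed time must be non-negative", call. = FALSE)
  stay <- 0.5 * (1 + exp(-2 * q * t))
  sw <- 1 - stay
  matrix(c(stay, sw, sw, stay), 2, 2, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# states: named integer/numeric vector of 0/1, names = tip labels.
check_states <- function(tree, states) {
  if (is.null(names(states))) stop("states must be named by tip label", call. = FALSE)
  unscored <- setdiff(tree$tip.label, names(states))
  if (length(unscored))
    stop("unscored leaves: ", paste(head(unscored, 5), collapse = ", "), call. = FALSE)
  s <- states[tree$tip.label]
  if (!all(s %in% c(0, 1))) stop("states must be 0 or 1", call. = FALSE)
  as.integer(s)
}

# Scaled postorder partial likelihoods. Returns list(F = n x 2 matrix,
# logscale = accumulated log scaling factor at the root).
mk_partials <- function(tree, s, q) {
  nt <- ape::Ntip(tree)
  n <- nt + tree$Nnode
  F <- matrix(1, n, 2)
  F[seq_len(nt), ] <- 0
  F[cbind(seq_len(nt), s + 1L)] <- 1
  logscale <- 0
  po <- ape::postorder(tree)
  for (e in po) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    P <- transition_probability(q, tree$edge.length[e])
    F[p, ] <- F[p, ] * as.vector(P %*% F[c_, ])
    m <- max(F[p, ])
    if (m > 0 && m < 1e-100) { F[p, ] <- F[p, ] / m; logscale <- logscale + log(m) }
  }
  list(F = F, logscale = logscale)
}

#' Felsenstein pruning log-likelihood of a binary trait
#'
#' Root prior is (1/2, 1/2), the stationary distribution of the symmetric
#' chain. Returns `-Inf` when the data are impossible under the model
#' (e.g. `q = 0` with both states observed).
#'
#' @param tree A time-scaled rooted `phylo`.
#' @param states Named 0/1 vector covering every leaf.
#' @param model An [mk_er()] model.
#' @return Log-likelihood (numeric scalar, possibly `-Inf`).
#' @export
pruning_loglik <- function(tree, states, model) {
  q <- if (inherits(model, "mk_er")) model$q else model
  s <- check_states(tree, states)
  if (ape::Ntip(tree) == 1) return(log(0.5))
  pr <- mk_partials(tree, s, q)
  root <- ape::Ntip(tree) + 1L
  lik <- 0.5 * sum(pr$F[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

#' Maximum-likelihood estimate of the equal transition rate
#'
#' Derivative-free scalar optimisation of the pruning log-likelihood over
#' `log q` on `[1e-8, 1e3]` per Myr.
#'
#' @inheritParams pruning_loglik
#' @return An [mk_er()] model with elements `q`, `loglik`, and
#'   `monomorphic` (TRUE when only one state was observed, in which case
#'   the reported rate is the search lower bound).
#' @export
fit_q <- function(tree, states) {
  s <- check_states(tree, states)
  stopifnot(ape::Ntip(tree) >= 2)
  mono <- length(unique(s)) == 1L
  if (mono)
    warning("monomorphic states: q estimate is the search lower bound", call. = FALSE)
  f <- function(lq) -pruning_loglik(tree, states, exp(lq))
  opt <- optimize(f, interval = log(c(1e-8, 1e3)), tol = 1e-10)
  out <- mk_er(exp(opt$minimum))
  out$loglik <- -opt$objective
  out$monomorphic <- mono
  if (mono) out$q <- 1e-8
  out
}

#' Likelihood-ratio confidence interval for the Mk rate
#'
#' @inheritParams pruning_loglik
#' @param fit A fitted [fit_q()] model (refitted if missing).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
q_confint <- function(tree, states, fit = NULL, level = 0.95) {
  if (is.null(fit)) fit <- fit_q(tree, states)
  drop_ <- qchisq(level, df = 1) / 2
  target <- fit$loglik - drop_
  g <- function(lq) pruning_loglik(tree, states, exp(lq)) - target
  lqhat <- log(fit$q)
  lo <- if (g(log(1e-8)) > 0) 1e-8 else
    exp(uniroot(g, c(log(1e-8), lqhat), tol = 1e-9)$root)
  hi <- if (g(log(1e3)) > 0) 1e3 else
    exp(uniroot(g, c(lqhat, log(1e3)), tol = 1e-9)$root)
  c(lower = lo, upper = hi)
}

# Sample the number of chain events on a branch of duration t conditioned on
# endpoint parity (uniformization with rate q: every event is a state flip).
sample_n_flips <- function(q, t, parity_odd) {
  lam <- q * t
  if (lam == 0) return(0L)
  Z <- if (parity_odd) (1 - exp(-2 * lam)) / 2 else (1 + exp(-2 * lam)) / 2
  u <- runif(1) * Z
  n <- if (parity_odd) 1L else 0L
  acc <- 0
  repeat {
    acc <- acc + dpois(n, lam)
    if (acc >= u) return(n)
    n <- n + 2L
    if (n > lam + 60 * sqrt(lam + 1) + 200) return(n)  # numerical guard
  }
}

#' Stochastic character maps under the fitted Mk model
#'
#' Joint node states are drawn from their conditional distribution given the
#' tip data (root from its posterior, children given parents via transition
#' probabilities times subtree partial likelihoods); each branch path is then
#' drawn conditional on its endpoints by uniformization (at rate `q` every
#' auxiliary event of the 2-state symmetric chain is a real flip, so the
#' flip count is Poisson conditioned on endpoint parity and flip times are
#' uniform order statistics).
#'
#' @inheritParams pruning_loglik
#' @param n_maps Number of maps to draw.
#' @param seed Integer seed; output is deterministic given it.
#' @return An object of class `simmap_histories`: list with `maps` (each map
#'   has `node_states` and `edge_segments`, a per-edge matrix of
#'   `state`/`duration` rows ordered rootward to tipward), plus the `tree`
#'   and `model`.
#' @export
sample_histories <- function(tree, states, model, n_maps = 100, seed = 1) {
  q <- if (inherits(model, "mk_er")) model$q else model
  s <- check_states(tree, states)
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  pr <- mk_partials(tree, s, q)
  F <- pr$F
  preord_edges <- rev(ape::postorder(tree))
  set.seed(seed)
  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    ns <- integer(nt + tree$Nnode)
    w <- 0.5 * F[root, ]
    ns[root] <- sample.int(2L, 1L, prob = w) - 1L
    segs <- vector("list", nrow(tree$edge))
    for (e in preord_edges) {
      p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
      t_e <- tree$edge.length[e]
      P <- transition_probability(q, t_e)
      w <- P[ns[p] + 1L, ] * F[c_, ]
      ns[c_] <- sample.int(2L, 1L, prob = w) - 1L
      nflip <- sample_n_flips(q, t_e, parity_odd = ns[p] != ns[c_])
      if (nflip == 0L) {
        segs[[e]] <- matrix(c(ns[p], t_e), 1, 2,
                            dimnames = list(NULL, c("state", "duration")))
      } else {
        times <- sort(runif(nflip, 0, t_e))
        bounds <- c(0, times, t_e)
        st <- (ns[p] + seq(0L, nflip)) %% 2L
        segs[[e]] <- cbind(state = st, duration = diff(bounds))
      }
    }
    maps[[m]] <- list(node_states = ns, edge_segments = segs)
  }
  structure(list(maps = maps, tree = tree, model = mk_er(q)),
            class = "simmap_histories")
}

#' @export
print.simmap_histories <- function(x, ...) {
  cat("simmap_histories:", length(x$maps), "maps on",
      ape::Ntip(x$tree), "tips (q =", format(x$model$q), ")\n")
  invisible(x)
}

#' Count trait origins across stochastic maps
#'
#' Counts directional transitions per map and summarizes the number of
#' independent origins as the modal count across maps (configurable to the
#' rounded mean). Origin clades are the subtrees whose stem branch shows a
#' net change in the stated direction, summarized by their frequency across
#' maps.
#'
#' @param histories A [sample_histories()] object.
#' @param direction `"01"` (gains of the derived state) or `"10"` (losses).
#' @param summary `"modal"` (default) or `"mean"` (rounded).
#' @return List with `per_map` counts, `count` (the summary), and
#'   `origin_clades`: data frame of clade label-set keys and their map
#'   frequency, for clades appearing in a majority of maps `majority` is TRUE.
#' @export
count_origins <- function(histories, direction = c("01", "10"),
                          summary = c("modal", "mean")) {
  direction <- match.arg(direction)
  summary <- match.arg(summary)
  from <- as.integer(substr(direction, 1, 1))
  to <- as.integer(substr(direction, 2, 2))
  tree <- histories$tree
  cs <- clade_sets(tree)
  per_map <- integer(length(histories$maps))
  clade_count <- new.env(parent = emptyenv())
  for (m in seq_along(histories$maps)) {
    map <- histories$maps[[m]]
    cnt <- 0L
    seen_clades <- character(0)
    for (e in seq_along(map$edge_segments)) {
      st <- map$edge_segments[[e]][, "state"]
      if (length(st) > 1) {
        trans <- sum(st[-length(st)] == from & st[-1] == to)
        cnt <- cnt + trans
        if (trans > 0 && st[1] == from && st[length(st)] == to) {
          child <- tree$edge[e, 2]
          seen_clades <- c(seen_clades, paste(cs[[child]], collapse = ";"))
        }
      }
    }
    per_map[m] <- cnt
    for (k in unique(seen_clades)) {
      clade_count[[k]] <- (if (is.null(clade_count[[k]])) 0L else clade_count[[k]]) + 1L
    }
  }
  count <- if (summary == "modal") {
    tb <- table(per_map)
    as.integer(names(tb)[which.max(tb)])
  } else as.integer(round(mean(per_map)))
  keys <- ls(clade_count)
  freq <- vapply(keys, function(k) clade_count[[k]] / length(per_map), numeric(1))
  oc <- data.frame(clade = keys, frequency = as.numeric(freq),
                   majority = as.numeric(freq) >= 0.5,
                   stringsAsFactors = FALSE)
  oc <- oc[order(-oc$frequency), , drop = FALSE]
  rownames(oc) <- NULL
  list(per_map = per_map, count = count, origin_clades = oc)
}

#' Read a two-trait table (habitat, lifestyle) from CSV
#'
#' @param file CSV with columns `species`, `habitat` (0 = marine,
#'   1 = freshwater/anchialine), `lifestyle` (0 = free-living, 1 = symbiotic).
#' @return Data frame; extract named state vectors with [trait_states()].
#' @export
read_traits <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "habitat", "lifestyle")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trait CSV lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_traits
#' @param traits Data frame from [read_traits()].
#' @param trait Column name (`"habitat"` or `"lifestyle"`).
#' @export
trait_states <- function(traits, trait = c("habitat", "lifestyle")) {
  trait <- match.arg(trait)
  setNames(as.integer(traits[[trait]]), traits$species)
}

#' Write stochastic maps in SIMMAP-style annotated Newick
#'
#' @param histories A [sample_histories()] object.
#' @param file Output path (one tree per line).
#' @export
write_simmap <- function(histories, file) {
  tree <- histories$tree
  nt <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lines <- vapply(histories$maps, function(map) {
    lab <- function(nd, e) {
      segs <- map$edge_segments[[e]]
      ann <- paste(sprintf("%d,%s", segs[, "state"],
                           format(segs[, "duration"], digits = 10)),
                   collapse = ":")
      core <- if (nd <= nt) tree$tip.label[nd] else rec(nd)
      paste0(core, ":{", ann, "}")
    }
    rec <- function(nd) {
      es <- kids[[as.character(nd)]]
      paste0("(", paste(vapply(es, function(e) lab(tree$edge[e, 2], e),
                               character(1)), collapse = ","), ")")
    }
    paste0(rec(nt + 1L), ";")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
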