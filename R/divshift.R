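## Birth-death diversification with rate shifts: constant-rate-per-regime
## likelihood with clade-wise incomplete sampling, reversible-jump MCMC over
## shift configurations, posterior summaries, clade-rate extraction and the
## nonparametric rate comparisons.

# Precompute the per-tree arrays consumed by the C++ likelihood.
bd_tree_data <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  nt <- ape::Ntip(tree)
  d <- node_depths(tree)
  tip_d <- d[seq_len(nt)]
  if (diff(range(tip_d)) > 1e-6 * max(tip_d))
    stop("tree must be ultrametric (extant tips only)", call. = FALSE)
  po <- ape::postorder(tree)
  list(tree = tree, ntip = nt, edge = tree$edge,
       edge_length = tree$edge.length,
       postorder = po, preorder = rev(po),
       tip_counts = tip_counts(tree))
}

#' Per-tip sampling fractions from a clade table
#'
#' Each tip receives the sampling fraction `rho` of the smallest enclosing
#' clade defined in the table (clades are named by MRCA-defining taxon
#' pairs); tips in no listed clade get `default_rho`.
#'
#' @param tree A rooted `phylo`.
#' @param sampling Data frame with columns `taxon_a`, `taxon_b`, `rho`
#'   (in (0, 1]), or `NULL` for complete sampling.
#' @param default_rho Fraction for tips outside all listed clades.
#' @return Numeric vector of per-tip sampling fractions (tip order).
#' @export
tip_sampling_fractions <- function(tree, sampling = NULL, default_rho = 1) {
  nt <- ape::Ntip(tree)
  rho <- rep(default_rho, nt)
  if (is.null(sampling) || nrow(sampling) == 0) return(rho)
  stopifnot(all(c("taxon_a", "taxon_b", "rho") %in% names(sampling)),
            all(sampling$rho > 0), all(sampling$rho <= 1))
  cs <- clade_sets(tree)
  sizes <- rep(Inf, nt)
  for (i in seq_len(nrow(sampling))) {
    nd <- mrca_node(tree, c(sampling$taxon_a[i], sampling$taxon_b[i]))
    tips <- match(cs[[nd]], tree$tip.label)
    smaller <- length(tips) < sizes[tips]
    rho[tips[smaller]] <- sampling$rho[i]
    sizes[tips[smaller]] <- length(tips)
  }
  rho
}

#' Piecewise-constant birth-death shift model
#'
#' Regime 1 is the root regime; regime `k + 1` applies to the subtree (stem
#' branch included) of `shifts[k]`, unless overridden by a nested shift.
#'
#' @param shifts Integer vector of shift node ids (possibly empty).
#' @param lambda,mu Numeric vectors of length `length(shifts) + 1`:
#'   speciation and extinction rates per Myr, root regime first.
#' @param sampling Optional clade sampling table (see
#'   [tip_sampling_fractions()]).
#' @param default_rho Sampling fraction outside listed clades.
#' @return A `shift_model` object.
#' @export
shift_model <- function(shifts = integer(0), lambda, mu,
                        sampling = NULL, default_rho = 1) {
  shifts <- as.integer(shifts)
  stopifnot(length(lambda) == length(shifts) + 1,
            length(mu) == length(shifts) + 1,
            all(lambda > 0), all(mu >= 0))
  structure(list(shifts = shifts, lambda = as.numeric(lambda),
                 mu = as.numeric(mu), sampling = sampling,
                 default_rho = default_rho),
            class = "shift_model")
}

#' Birth-death log-likelihood of a time-scaled tree under a shift model
#'
#' The likelihood is assembled branchwise from the standard rho-sampled
#' birth-death survival and density terms, each branch evaluated under its
#' regime's constant rates, with a speciation-rate factor at every internal
#' node (the root split is conditioned upon rather than counted) and
#' conditioning on survival of both root lineages. Where the two sides of a
#' node propagate different extinction probabilities (possible under
#' differing regimes or sampling fractions) their mean is carried rootward.
#'
#' @param tree An ultrametric `phylo` with branch lengths in Myr.
#' @param model A [shift_model()].
#' @param condition_survival Condition on survival of the two root lineages.
#' @return Log-likelihood (numeric scalar, possibly `-Inf`).
#' @export
bd_loglik <- function(tree, model, condition_survival = TRUE) {
  stopifnot(inherits(model, "shift_model"))
  td <- bd_tree_data(tree)
  rho <- tip_sampling_fractions(tree, model$sampling, model$default_rho)
  bd_loglik_cpp(td$edge, td$edge_length, td$postorder, td$preorder,
                td$ntip, model$shifts, model$lambda, model$mu,
                1 - rho, condition_survival)
}

#' Maximum-likelihood constant-rate birth-death fit
#'
#' Single-regime fit used to centre the rate priors of [run_rjmcmc()].
#'
#' @inheritParams bd_loglik
#' @param rho Per-tip sampling fractions (scalar or vector).
#' @return List with `lambda`, `mu`, `loglik`.
#' @export
ml_bd_constant <- function(tree, rho = 1) {
  td <- bd_tree_data(tree)
  e0 <- rep(1 - rho, length.out = td$ntip)
  nll <- function(par) {
    -bd_loglik_cpp(td$edge, td$edge_length, td$postorder, td$preorder,
                   td$ntip, integer(0), exp(par[1]), exp(par[2]), e0, TRUE)
  }
  init <- log(c(max(td$ntip / sum(td$edge_length), 1e-3), 1e-3))
  fit <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(lambda = exp(fit$par[1]), mu = exp(fit$par[2]), loglik = -fit$value)
}

# internal: adjacency among internal nodes for the shift-move proposal
internal_neighbours <- function(td) {
  nt <- td$ntip
  parent <- rep(NA_integer_, nt + td$tree$Nnode)
  parent[td$edge[, 2]] <- td$edge[, 1]
  kids <- split(td$edge[, 2], td$edge[, 1])
  function(node, eligible, shifts) {
    nb <- c(parent[node], kids[[as.character(node)]])
    nb <- nb[!is.na(nb) & nb > nt]
    setdiff(intersect(nb, eligible), shifts)
  }
}

#' Reversible-jump MCMC over birth-death shift configurations
#'
#' Samples the joint posterior of the number of rate shifts, their node
#' locations and per-regime rates. Moves: log-scale perturbations of a
#' regime's speciation or extinction rate, shift birth (rates drawn from
#' their priors, so the dimension-matching factor cancels), shift death, and
#' relocation of a shift to a neighbouring eligible node. Priors: Poisson on
#' the number of shifts, exponential on every speciation and extinction
#' rate. Eligible shift nodes are non-root internal nodes subtending at
#' least `min_clade_size` tips.
#'
#' @param tree Ultrametric `phylo`, branch lengths in Myr.
#' @param config List; recognised entries (and defaults): `generations`
#'   (2e5), `store` (1e4) samples kept before burn-in, `burnin_fraction`
#'   (0.1), `min_clade_size` (5), `poisson_mean` (1) for the shift-count
#'   prior, `lambda_prior_mean` / `mu_prior_mean` (centred on the
#'   single-regime ML fit), `sampling` (NULL) clade sampling table,
#'   `default_rho` (1), `proposal_scale` (0.6), `move_weights`,
#'   `likelihood_off` (FALSE) to sample the prior only (prior-recovery
#'   checks), `condition_survival` (TRUE).
#' @param seed Integer seed; the chain is bit-reproducible given it.
#' @param chains Number of independent chains (seeds `seed`, `seed + 1`, ...).
#' @return For `chains = 1` a `posterior_chain`: list with `samples` (one
#'   row per stored generation: generation, n_shifts, log-likelihood, log
#'   posterior, shift nodes, rates), `burnin` (count of stored samples to
#'   discard), `tree`, `config`, `acceptance`. For several chains, a
#'   `posterior_chains` list of them.
#' @export
run_rjmcmc <- function(tree, config = list(), seed = 1, chains = 1) {
  if (chains > 1) {
    out <- lapply(seq_len(chains), function(i)
      run_rjmcmc(tree, config, seed = seed + i - 1L, chains = 1))
    class(out) <- "posterior_chains"
    return(out)
  }
  defaults <- list(generations = 2e5, store = 1e4, burnin_fraction = 0.1,
                   min_clade_size = 5, poisson_mean = 1,
                   lambda_prior_mean = NULL, mu_prior_mean = NULL,
                   sampling = NULL, default_rho = 1, proposal_scale = 0.6,
                   move_weights = c(update_lambda = 0.3, update_mu = 0.15,
                                    add = 0.2, delete = 0.2, move = 0.15),
                   likelihood_off = FALSE, condition_survival = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)

  td <- bd_tree_data(tree)
  rho <- tip_sampling_fractions(tree, cfg$sampling, cfg$default_rho)
  e0 <- 1 - rho
  if (is.null(cfg$lambda_prior_mean) || is.null(cfg$mu_prior_mean)) {
    ml <- ml_bd_constant(tree, rho)
    if (is.null(cfg$lambda_prior_mean)) cfg$lambda_prior_mean <- ml$lambda
    if (is.null(cfg$mu_prior_mean))
      cfg$mu_prior_mean <- max(ml$mu, ml$lambda / 10)
  }
  nt <- td$ntip
  eligible <- which(td$tip_counts >= cfg$min_clade_size)
  eligible <- setdiff(eligible[eligible > nt], nt + 1L)
  if (length(eligible) == 0)
    warning("no eligible shift nodes (tree smaller than the minimum clade size); ",
            "running as single-regime MCMC", call. = FALSE)
  nbr_fun <- internal_neighbours(td)

  loglik_fun <- function(shifts, lambda, mu) {
    if (cfg$likelihood_off) return(0)
    bd_loglik_cpp(td$edge, td$edge_length, td$postorder, td$preorder,
                  nt, shifts, lambda, mu, e0, cfg$condition_survival)
  }
  # Shift locations are a priori a uniformly chosen subset of the eligible
  # nodes, so the marginal shift-count prior is exactly Poisson.
  logprior_fun <- function(shifts, lambda, mu) {
    K <- length(shifts)
    dpois(K, cfg$poisson_mean, log = TRUE) -
      lchoose(length(eligible), K) +
      sum(dexp(lambda, 1 / cfg$lambda_prior_mean, log = TRUE)) +
      sum(dexp(mu, 1 / cfg$mu_prior_mean, log = TRUE))
  }

  set.seed(seed)
  shifts <- integer(0)
  lambda <- cfg$lambda_prior_mean
  mu <- cfg$mu_prior_mean / 2
  ll <- loglik_fun(shifts, lambda, mu)
  lp <- logprior_fun(shifts, lambda, mu)
  mw <- cfg$move_weights / sum(cfg$move_weights)
  move_names <- names(mw)
  gens <- as.integer(cfg$generations)
  thin <- max(1L, as.integer(floor(gens / cfg$store)))
  n_store <- floor(gens / thin)
  samples <- vector("list", n_store)
  acc <- setNames(numeric(length(mw)), move_names)
  tries <- setNames(numeric(length(mw)), move_names)
  delta <- cfg$proposal_scale

  for (g in seq_len(gens)) {
    mv <- sample(move_names, 1, prob = mw)
    tries[mv] <- tries[mv] + 1
    if (mv == "update_lambda" || mv == "update_mu") {
      j <- sample.int(length(lambda), 1)
      lam2 <- lambda; mu2 <- mu
      if (mv == "update_lambda") {
        lam2[j] <- lambda[j] * exp(runif(1, -delta, delta))
        jac <- log(lam2[j] / lambda[j])
      } else {
        mu2[j] <- mu[j] * exp(runif(1, -delta, delta))
        jac <- log(mu2[j] / mu[j])
      }
      ll2 <- loglik_fun(shifts, lam2, mu2)
      lp2 <- logprior_fun(shifts, lam2, mu2)
      if (log(runif(1)) < (ll2 - ll) + (lp2 - lp) + jac) {
        lambda <- lam2; mu <- mu2; ll <- ll2; lp <- lp2
        acc[mv] <- acc[mv] + 1
      }
    } else if (mv == "add") {
      free <- setdiff(eligible, shifts)
      if (length(free) > 0) {
        nd <- if (length(free) == 1) free else sample(free, 1)
        K <- length(shifts)
        shifts2 <- c(shifts, nd)
        lam2 <- c(lambda, rexp(1, 1 / cfg$lambda_prior_mean))
        mu2 <- c(mu, rexp(1, 1 / cfg$mu_prior_mean))
        ll2 <- loglik_fun(shifts2, lam2, mu2)
        # location-prior and subset-proposal combinatorics cancel exactly
        lr <- (ll2 - ll) +
          (dpois(K + 1, cfg$poisson_mean, log = TRUE) -
             dpois(K, cfg$poisson_mean, log = TRUE)) +
          log(mw[["delete"]] / mw[["add"]])
        if (log(runif(1)) < lr) {
          shifts <- shifts2; lambda <- lam2; mu <- mu2; ll <- ll2
          lp <- logprior_fun(shifts, lambda, mu)
          acc[mv] <- acc[mv] + 1
        }
      }
    } else if (mv == "delete") {
      K <- length(shifts)
      if (K > 0) {
        j <- sample.int(K, 1)
        shifts2 <- shifts[-j]
        lam2 <- lambda[-(j + 1)]; mu2 <- mu[-(j + 1)]
        ll2 <- loglik_fun(shifts2, lam2, mu2)
        lr <- (ll2 - ll) +
          (dpois(K - 1, cfg$poisson_mean, log = TRUE) -
             dpois(K, cfg$poisson_mean, log = TRUE)) +
          log(mw[["add"]] / mw[["delete"]])
        if (log(runif(1)) < lr) {
          shifts <- shifts2; lambda <- lam2; mu <- mu2; ll <- ll2
          lp <- logprior_fun(shifts, lambda, mu)
          acc[mv] <- acc[mv] + 1
        }
      }
    } else if (mv == "move") {
      K <- length(shifts)
      if (K > 0) {
        j <- sample.int(K, 1)
        others <- shifts[-j]
        nb_old <- nbr_fun(shifts[j], eligible, others)
        if (length(nb_old) > 0) {
          nd <- if (length(nb_old) == 1) nb_old else sample(nb_old, 1)
          shifts2 <- shifts; shifts2[j] <- nd
          nb_new <- nbr_fun(nd, eligible, others)
          ll2 <- loglik_fun(shifts2, lambda, mu)
          lr <- (ll2 - ll) + log(length(nb_old)) - log(length(nb_new))
          if (log(runif(1)) < lr) {
            shifts <- shifts2; ll <- ll2
            acc[mv] <- acc[mv] + 1
          }
        }
      }
    }
    if (g %% thin == 0L) {
      samples[[g %/% thin]] <- list(generation = g, shifts = shifts,
                                    lambda = lambda, mu = mu,
                                    loglik = ll, logpost = ll + lp)
    }
  }
  burnin <- floor(cfg$burnin_fraction * n_store)
  structure(list(samples = samples, burnin = burnin, tree = tree,
                 config = cfg, seed = seed,
                 acceptance = ifelse(tries > 0, acc / tries, NA_real_)),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("posterior_chain:", length(x$samples), "stored samples (",
      x$burnin, "burn-in ),", ape::Ntip(x$tree), "tips\n")
  invisible(x)
}

#' Retained (post burn-in) samples of a chain
#' @param chain A `posterior_chain`.
#' @return List of samples.
#' @export
retained_samples <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  chain$samples[seq(chain$burnin + 1L, length(chain$samples))]
}

#' Geweke convergence diagnostic on the log-posterior trace
#'
#' Compares the means of the first `frac1` and last `frac2` of the retained
#' trace with a z-test using batch-mean variance estimates.
#'
#' @param chain A `posterior_chain`.
#' @param frac1,frac2 Window fractions (defaults 0.1 and 0.5).
#' @return List with `z` and `p`.
#' @export
geweke_logpost <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  lp <- vapply(retained_samples(chain), `[[`, numeric(1), "logpost")
  n <- length(lp)
  a <- lp[seq_len(max(2, floor(frac1 * n)))]
  b <- lp[seq(n - max(2, floor(frac2 * n)) + 1, n)]
  bm_var <- function(x) {
    nb <- max(2, floor(sqrt(length(x))))
    bs <- floor(length(x) / nb)
    means <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * bs + 1):(i * bs)]),
                    numeric(1))
    stats::var(means) / nb
  }
  z <- (mean(a) - mean(b)) / sqrt(bm_var(a) + bm_var(b))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Credible shift configurations and marginal shift probabilities
#'
#' @param chain A `posterior_chain`.
#' @return List with `configurations` (data frame: shift node set key,
#'   frequency, sorted descending) and `marginal` (named per-node shift
#'   probability).
#' @export
credible_shift_summary <- function(chain) {
  rs <- retained_samples(chain)
  keys <- vapply(rs, function(s)
    if (length(s$shifts) == 0) "" else paste(sort(s$shifts), collapse = ","),
    character(1))
  tb <- sort(table(keys), decreasing = TRUE)
  cfgs <- data.frame(shift_nodes = names(tb),
                     frequency = as.numeric(tb) / length(rs),
                     stringsAsFactors = FALSE)
  all_nodes <- sort(unique(unlist(lapply(rs, `[[`, "shifts"))))
  marginal <- vapply(all_nodes, function(nd)
    mean(vapply(rs, function(s) nd %in% s$shifts, logical(1))), numeric(1))
  names(marginal) <- as.character(all_nodes)
  list(configurations = cfgs, marginal = marginal)
}

#' Per-sample mean diversification rates for clade categories
#'
#' For every retained posterior sample and every named clade, computes the
#' branch-duration-weighted mean speciation and extinction rate over the
#' branches within the clade (the subtree below its MRCA) under that
#' sample's regime map; clades are then averaged (unweighted) within each
#' category. Only clades with more than `min_tips` tips are accepted.
#'
#' @param chain A `posterior_chain`.
#' @param clades Data frame with columns `name`, `taxon_a`, `taxon_b`,
#'   `category`.
#' @param min_tips Minimum clade size (exclusive bound; default 10).
#' @return Named list (one per category) of `rate_series` data frames with
#'   columns `sample`, `lambda`, `mu`, `r` (`r = lambda - mu` exactly).
#' @export
clade_rates <- function(chain, clades, min_tips = 10) {
  stopifnot(all(c("name", "taxon_a", "taxon_b", "category") %in% names(clades)))
  tree <- chain$tree
  td <- bd_tree_data(tree)
  cs <- clade_sets(tree)
  nedge <- nrow(td$edge)
  wts <- vector("list", nrow(clades))
  for (i in seq_len(nrow(clades))) {
    nd <- mrca_node(tree, c(clades$taxon_a[i], clades$taxon_b[i]))
    ntips_cl <- sum(cs[[nd]] %in% tree$tip.label)
    if (ntips_cl <= min_tips)
      stop("clade '", clades$name[i], "' has ", ntips_cl,
           " tips; need more than ", min_tips, call. = FALSE)
    in_clade <- td$edge[, 2] %in% setdiff(which_descendants(td, nd), nd)
    w <- ifelse(in_clade, td$edge_length, 0)
    wts[[i]] <- w / sum(w)
  }
  W <- do.call(cbind, wts)  # nedge x nclades
  rs <- retained_samples(chain)
  n <- length(rs)
  lam_cl <- matrix(0, n, nrow(clades))
  mu_cl <- matrix(0, n, nrow(clades))
  for (k in seq_len(n)) {
    s <- rs[[k]]
    reg <- edge_regimes_cpp(td$edge, td$preorder, td$ntip, s$shifts)
    lam_cl[k, ] <- as.vector(crossprod(W, s$lambda[reg]))
    mu_cl[k, ] <- as.vector(crossprod(W, s$mu[reg]))
  }
  out <- list()
  for (cat in unique(clades$category)) {
    idx <- which(clades$category == cat)
    lam <- rowMeans(lam_cl[, idx, drop = FALSE])
    mu_ <- rowMeans(mu_cl[, idx, drop = FALSE])
    df <- data.frame(sample = seq_len(n), lambda = lam, mu = mu_,
                     r = lam - mu_)
    class(df) <- c("rate_series", "data.frame")
    out[[cat]] <- df
  }
  out
}

# node ids (tips and internals) descending from nd, nd included
which_descendants <- function(td, nd) {
  n <- td$ntip + td$tree$Nnode
  below <- logical(n)
  below[nd] <- TRUE
  for (e in td$preorder) {
    p <- td$edge[e, 1]; c_ <- td$edge[e, 2]
    if (below[p]) below[c_] <- TRUE
  }
  which(below)
}

#' Nonparametric comparison of two clade-category rate series
#'
#' Applies, per rate (speciation, extinction, net diversification), the
#' paired Wilcoxon signed-rank test on per-sample differences and the
#' two-sample Kolmogorov-Smirnov test on the marginal distributions, plus
#' the ratio of category means. Identical series give Wilcoxon p = 1 and
#' D = 0 by convention (no nonzero differences to rank).
#'
#' @param a,b `rate_series` data frames of equal length (paired by sample).
#' @return A `comparison_result`: per-rate list with `wilcoxon` (statistic,
#'   p), `ks` (D, p) and `mean_ratio` (mean of `a` over mean of `b`).
#' @export
compare_categories <- function(a, b) {
  if (nrow(a) != nrow(b))
    stop("rate series differ in length: ", nrow(a), " vs ", nrow(b), call. = FALSE)
  one <- function(x, y) {
    if (all(abs(x - y) < 1e-12)) {
      wil <- list(statistic = 0, p.value = 1)
    } else {
      wil <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    }
    ks <- suppressWarnings(ks.test(x, y))
    list(wilcoxon = list(statistic = unname(wil$statistic), p = wil$p.value),
         ks = list(D = unname(ks$statistic), p = ks$p.value),
         mean_ratio = mean(x) / mean(y))
  }
  structure(list(lambda = one(a$lambda, b$lambda),
                 mu = one(a$mu, b$mu),
                 r = one(a$r, b$r)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  for (nm in c("lambda", "mu", "r")) {
    v <- x[[nm]]
    cat(sprintf("%-6s mean ratio %.4g | Wilcoxon p %.3g | KS D %.3f p %.3g\n",
                nm, v$mean_ratio, v$wilcoxon$p, v$ks$D, v$ks$p))
  }
  invisible(x)
}

#' Write a posterior chain as an event-style TSV
#'
#' One row per stored sample and regime: generation, number of shifts, the
#' regime's node (NA for the root regime), lambda and mu.
#'
#' @param chain A `posterior_chain`.
#' @param file Output path.
#' @export
write_chain_tsv <- function(chain, file) {
  rows <- lapply(chain$samples, function(s) {
    nodes <- c(NA_integer_, s$shifts)
    data.frame(generation = s$generation, n_shifts = length(s$shifts),
               node = nodes, lambda = s$lambda, mu = s$mu,
               loglik = s$loglik, logpost = s$logpost)
  })
  df <- do.call(rbind, rows)
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
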