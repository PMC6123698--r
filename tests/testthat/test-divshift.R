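test_that("bd_loglik matches the pure-birth closed form", {
  # 3-tip tree with known node times
  tr <- parse_newick("((A:2,B:2):3,C:5);")
  lam <- 0.11
  expect_equal(bd_loglik(tr, shift_model(integer(0), lam, 0)),
               yule_loglik(tr, lam), tolerance = 1e-10)
  set.seed(3)
  for (i in 1:5) {
    tt <- sim_bd_tree(0.1, 0, n = sample(10:60, 1), seed = 40 + i)
    lam <- runif(1, 0.02, 0.3)
    expect_equal(bd_loglik(tt, shift_model(integer(0), lam, 0)),
                 yule_loglik(tt, lam), tolerance = 1e-8)
  }
})

test_that("bd_loglik matches numerical ODE integration of the E/D system", {
  # independent oracle: integrate dE/dt and dD/dt with deSolve per branch,
  # assemble with the same node-factor and conditioning convention
  library(deSolve)
  ode_loglik <- function(tree, lambda, mu, rho) {
    nt <- ape::Ntip(tree)
    E <- numeric(nt + tree$Nnode); logD <- numeric(nt + tree$Nnode)
    E[seq_len(nt)] <- 1 - rho
    logD[seq_len(nt)] <- log(rho)
    deriv <- function(t, y, parms) {
      list(c(parms$mu - (parms$lambda + parms$mu) * y[1] + parms$lambda * y[1]^2,
             -(parms$lambda + parms$mu) * y[2] +
               2 * parms$lambda * y[1] * y[2]))
    }
    po <- ape::postorder(tree)
    pending <- rep(0L, nt + tree$Nnode)
    for (e in po) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      out <- ode(c(E[ch], 1), c(0, tree$edge.length[e]), deriv,
                 parms = list(lambda = lambda, mu = mu),
                 rtol = 1e-12, atol = 1e-12)
      Etop <- out[2, 2]; Dfac <- out[2, 3]
      if (pending[p] == 0L) E[p] <- Etop else E[p] <- (E[p] + Etop) / 2
      pending[p] <- pending[p] + 1L
      logD[p] <- logD[p] + logD[ch] + log(Dfac)
    }
    root <- nt + 1L
    internals <- unique(tree$edge[, 1])
    nkids <- table(tree$edge[, 1])
    ll <- logD[root] + sum((nkids[as.character(setdiff(internals, root))] - 1)) *
      log(lambda)
    ll - 2 * log(1 - E[root])
  }
  set.seed(51)
  for (i in 1:8) {
    tt <- sim_bd_tree(0.1, 0.03, n = sample(8:25, 1), seed = 50 + i)
    lam <- runif(1, 0.05, 0.25); mu <- runif(1, 0, 0.8) * lam
    rho <- sample(c(1, 0.7, 0.4), 1)
    mine <- bd_loglik(tt, shift_model(integer(0), lam, mu,
                                      default_rho = rho))
    oracle <- ode_loglik(tt, lam, mu, rho)
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
})

test_that("degenerate rates are handled: lambda -> 0 impossible, lambda = mu finite", {
  tt <- sim_bd_tree(0.1, 0, n = 10, seed = 61)
  # likelihood falls without bound as lambda -> 0+ (speciations impossible)
  lls <- vapply(c(1e-2, 1e-6, 1e-12, 1e-50),
                function(l) bd_loglik(tt, shift_model(integer(0), l, 0)),
                numeric(1))
  expect_true(all(diff(lls) < 0))
  expect_lt(lls[4], -900)
  ll_crit <- bd_loglik(tt, shift_model(integer(0), 0.1, 0.1))
  expect_true(is.finite(ll_crit))
  # continuity across the critical line
  ll_near <- bd_loglik(tt, shift_model(integer(0), 0.1, 0.1 - 1e-9))
  expect_equal(ll_crit, ll_near, tolerance = 1e-5)
})

test_that("non-ultrametric trees are rejected", {
  tr <- parse_newick("((A:1,B:2):1,C:5);")
  expect_error(bd_loglik(tr, shift_model(integer(0), 0.1, 0)), "ultrametric")
})

test_that("rjMCMC is bit-reproducible and recovers the prior without data", {
  tt <- sim_bd_tree(0.1, 0, n = 40, seed = 71)
  cfgs <- list(generations = 5000, store = 500)
  c1 <- run_rjmcmc(tt, cfgs, seed = 9)
  c2 <- run_rjmcmc(tt, cfgs, seed = 9)
  expect_identical(c1$samples, c2$samples)

  # prior recovery: likelihood off, K ~ Poisson(1), lambda ~ Exp(0.1)
  ch <- run_rjmcmc(tt, config = list(generations = 1e5, store = 2000,
                                     likelihood_off = TRUE,
                                     lambda_prior_mean = 0.1,
                                     mu_prior_mean = 0.02), seed = 10)
  rs <- retained_samples(ch)
  K <- vapply(rs, function(s) length(s$shifts), integer(1))
  obs <- table(factor(pmin(K, 5), levels = 0:5))
  pexp <- dpois(0:4, 1); pexp <- c(pexp, 1 - sum(pexp))
  gof <- suppressWarnings(chisq.test(obs, p = pexp))
  expect_gt(gof$p.value, 0.01)
  lam <- vapply(rs, function(s) s$lambda[1], numeric(1))
  expect_lt(abs(mean(lam) - 0.1), 0.02)
})

test_that("rjMCMC warns and runs single-regime on tiny trees", {
  tt <- sim_bd_tree(0.2, 0, n = 4, seed = 81)
  expect_warning(ch <- run_rjmcmc(tt, list(generations = 2000, store = 200),
                                  seed = 1),
                 "no eligible")
  expect_true(all(vapply(retained_samples(ch),
                         function(s) length(s$shifts), integer(1)) == 0))
})

test_that("sampling fractions matter: rho-corrected estimates are closer", {
  # lambda = 0.1, mu = 0.03 trees with 40% of tips dropped uniformly
  wins <- 0; n_seed <- 6
  for (i in seq_len(n_seed)) {
    tt <- sim_bd_tree(0.1, 0.03, n = 150, seed = 90 + i)
    dr <- drop_tips(tt, retention = NULL, default_retention = 0.6,
                    seed = 90 + i)
    ml1 <- ml_bd_constant(dr$tree, rho = 1)
    ml2 <- ml_bd_constant(dr$tree, rho = 0.6)
    if (abs(ml2$lambda - 0.1) < abs(ml1$lambda - 0.1)) wins <- wins + 1
  }
  expect_gte(wins, n_seed - 1)
})

test_that("credible_shift_summary counts configurations and marginals", {
  fake <- structure(list(
    samples = list(
      list(generation = 1, shifts = integer(0), lambda = 0.1, mu = 0,
           loglik = 0, logpost = 0),
      list(generation = 2, shifts = 7L, lambda = c(0.1, 0.2), mu = c(0, 0),
           loglik = 0, logpost = 0),
      list(generation = 3, shifts = 7L, lambda = c(0.1, 0.2), mu = c(0, 0),
           loglik = 0, logpost = 0),
      list(generation = 4, shifts = c(7L, 9L), lambda = c(0.1, 0.2, 0.3),
           mu = c(0, 0, 0), loglik = 0, logpost = 0)),
    burnin = 0L), class = "posterior_chain")
  summ <- credible_shift_summary(fake)
  expect_equal(summ$configurations$frequency,
               c(0.5, 0.25, 0.25))
  expect_equal(summ$configurations$shift_nodes[1], "7")
  expect_equal(unname(summ$marginal["7"]), 0.75)
  expect_equal(unname(summ$marginal["9"]), 0.25)

  # all shift-free: single configuration at frequency 1
  fake0 <- fake; fake0$samples <- fake$samples[c(1, 1)]
  s0 <- credible_shift_summary(fake0)
  expect_equal(s0$configurations$frequency, 1)
})

test_that("clade_rates weights regimes by branch duration", {
  tt <- sim_bd_tree(0.1, 0, n = 40, seed = 95)
  cs <- caridiv:::clade_sets(tt)
  sizes <- lengths(cs)
  nd <- which(sizes > 11 & sizes < 35)[1]
  ab <- caridiv:::anchor_pair(tt, nd)
  clades <- data.frame(name = "c1", taxon_a = ab[1], taxon_b = ab[2],
                       category = "x", stringsAsFactors = FALSE)

  # single regime: clade rates equal the regime rates exactly
  fake <- structure(list(
    samples = list(list(generation = 1, shifts = integer(0), lambda = 0.17,
                        mu = 0.04, loglik = 0, logpost = 0)),
    burnin = 0L, tree = tt), class = "posterior_chain")
  rs <- clade_rates(fake, clades)
  expect_equal(rs$x$lambda, 0.17)
  expect_equal(rs$x$mu, 0.04)
  expect_equal(rs$x$r, 0.17 - 0.04)

  # a shift doubling lambda on a subclade: weighted mean interpolates
  td <- caridiv:::bd_tree_data(tt)
  sub <- tt$edge[tt$edge[, 1] == nd, 2][1]   # first child of the clade node
  if (sub > 40) {
    fake2 <- fake
    fake2$samples <- list(list(generation = 1, shifts = sub,
                               lambda = c(0.1, 0.2), mu = c(0, 0),
                               loglik = 0, logpost = 0))
    rs2 <- clade_rates(fake2, clades)
    desc <- setdiff(caridiv:::which_descendants(td, nd), nd)
    w <- td$edge_length[td$edge[, 2] %in% desc]
    inside <- caridiv:::which_descendants(td, sub)  # includes stem of sub
    frac <- sum(td$edge_length[td$edge[, 2] %in% inside]) / sum(w)
    expect_equal(rs2$x$lambda, 0.1 * (1 - frac) + 0.2 * frac,
                 tolerance = 1e-12)
  }

  # clades at or below the size threshold are rejected
  small_nd <- which(sizes >= 2 & sizes <= 10)[1]
  ab2 <- caridiv:::anchor_pair(tt, small_nd)
  bad <- data.frame(name = "tiny", taxon_a = ab2[1], taxon_b = ab2[2],
                    category = "x", stringsAsFactors = FALSE)
  expect_error(clade_rates(fake, bad), "tips")

  # two clades in one category: unweighted mean
  nd2 <- which(sizes > 11 & sizes < 35)
  if (length(nd2) >= 2) {
    ab3 <- caridiv:::anchor_pair(tt, nd2[2])
    two <- rbind(clades, data.frame(name = "c2", taxon_a = ab3[1],
                                    taxon_b = ab3[2], category = "x"))
    rs3 <- clade_rates(fake, two)
    expect_equal(rs3$x$lambda, 0.17)  # both clades sit in the same regime
  }
})

test_that("compare_categories reproduces closed-form behaviour", {
  n <- 9000
  a <- data.frame(sample = 1:n, lambda = rep(0.05, n), mu = rep(0.01, n),
                  r = rep(0.04, n))
  res_id <- compare_categories(a, a)
  expect_equal(res_id$lambda$wilcoxon$p, 1)
  expect_equal(res_id$lambda$ks$D, 0, ignore_attr = TRUE)
  expect_equal(res_id$r$mean_ratio, 1)

  set.seed(4)
  x <- rnorm(n, 0.05, 0.001)
  b <- data.frame(sample = 1:n, lambda = x, mu = rep(0.01, n), r = x - 0.01)
  c_ <- b; c_$lambda <- b$lambda + 0.01; c_$r <- c_$lambda - c_$mu
  res <- compare_categories(c_, b)
  expect_lt(res$lambda$wilcoxon$p, 1e-10)
  expect_equal(unname(res$lambda$ks$D), 1)  # disjoint supports
  expect_gt(res$lambda$mean_ratio, 1)

  expect_error(compare_categories(a, a[1:10, ]), "length")
})

test_that("r = lambda - mu holds exactly in emitted rate series", {
  tt <- sim_bd_tree(0.1, 0.02, n = 60, seed = 97)
  ch <- run_rjmcmc(tt, list(generations = 4000, store = 400), seed = 3)
  cs <- caridiv:::clade_sets(tt)
  nd <- which(lengths(cs) > 11)[2]
  ab <- caridiv:::anchor_pair(tt, nd)
  rs <- clade_rates(ch, data.frame(name = "c", taxon_a = ab[1],
                                   taxon_b = ab[2], category = "g"))
  expect_identical(rs$g$r, rs$g$lambda - rs$g$mu)
  expect_equal(nrow(rs$g), length(retained_samples(ch)))
})

test_that("multiple chains run and Geweke diagnostics are computable", {
  tt <- sim_bd_tree(0.1, 0, n = 30, seed = 98)
  chs <- run_rjmcmc(tt, list(generations = 4000, store = 400), seed = 5,
                    chains = 2)
  expect_s3_class(chs, "posterior_chains")
  expect_length(chs, 2)
  g <- geweke_logpost(chs[[1]])
  expect_true(is.finite(g$z))
  expect_true(g$p >= 0 && g$p <= 1)
})
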