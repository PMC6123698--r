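mk_src <- function(nwk, id = "s1", fp = id, w = 1) {
  s <- source_tree(parse_newick(nwk), study_id = id, year = 2000,
                   evidence = "molecular", fingerprint = fp, weight = w)
  s
}

test_that("Baum-Ragan coding follows the 1/0/? membership rule", {
  m1 <- encode_baum_ragan(list(mk_src("((A,B),C);")))
  expect_equal(ncol(m1$matrix), 1L)
  expect_equal(m1$matrix[, 1],
               c(A = 1L, B = 1L, C = 0L, MRP_outgroup = 0L))

  m2 <- encode_baum_ragan(list(mk_src("((A,B),C);", "s1"),
                               mk_src("((B,C),D);", "s2")))
  expect_equal(m2$matrix["A", ], c(1L, NA))
  expect_equal(m2$matrix["B", ], c(1L, 1L))
  expect_equal(m2$matrix["C", ], c(0L, 1L))
  expect_equal(m2$matrix["D", ], c(NA, 0L))
  expect_equal(m2$matrix["MRP_outgroup", ], c(0L, 0L))

  # duplicated source at half weight: identical characters, weights 1/2
  dup <- assign_independence_weights(list(mk_src("((A,B),C);", "a", "same"),
                                          mk_src("((A,B),C);", "b", "same")))
  m3 <- encode_baum_ragan(dup)
  expect_equal(m3$weights, c(0.5, 0.5))
  expect_equal(m3$matrix[, 1], m3$matrix[, 2])

  # star source contributes no characters
  expect_warning(
    expect_error(encode_baum_ragan(list(mk_src("(A,B,C);"))), "no informative"),
    "no non-root")
})

test_that("fitch_score matches hand examples and errors on missing taxa", {
  src <- list(mk_src("((A,B),(C,D));"))
  t_good <- parse_newick("(((A,B),(C,D)),MRP_outgroup);")
  t_bad <- parse_newick("(((A,C),(B,D)),MRP_outgroup);")
  # isolate the AB character (A=1,B=1,C=0,D=0) regardless of encoding order
  full <- encode_baum_ragan(src)
  ab <- which(colSums(full$matrix[c("A", "B"), , drop = FALSE] == 1) == 2)[1]
  full$matrix <- full$matrix[, ab, drop = FALSE]
  full$weights <- full$weights[ab]; full$source <- full$source[ab]
  expect_equal(fitch_score(t_good, full), 1)
  expect_equal(fitch_score(t_bad, full), 2)

  expect_error(fitch_score(parse_newick("((A,B),C);"), full), "absent")

  # all-? character contributes nothing
  allq <- full
  allq$matrix[] <- NA_integer_
  allq$matrix["MRP_outgroup", ] <- 0L  # outgroup stays 0
  expect_equal(fitch_score(t_good, allq), 0)
})

test_that("fitch_score equals brute force on 200 random cases with ?", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:7, 1)
    tr <- random_rooted_tree(n, lengths = FALSE)
    nchar_ <- sample(1:3, 1)
    m <- matrix(sample(c(0L, 1L, NA), n * nchar_, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)), n, nchar_,
                dimnames = list(tr$tip.label, NULL))
    w <- runif(nchar_, 0.2, 2)
    mm <- structure(list(matrix = m, weights = w,
                         source = rep("s", nchar_), outgroup = NULL),
                    class = "mrp_matrix")
    expect_equal(fitch_score(tr, mm), brute_force_parsimony(tr, m, w),
                 tolerance = 1e-12)
  }
})

test_that("duplicating a source at half weight leaves every score unchanged", {
  set.seed(5)
  true <- random_rooted_tree(8, lengths = FALSE)
  s1 <- mk_src(write_newick(true), "a", "f1")
  base <- encode_baum_ragan(list(s1))
  dup <- assign_independence_weights(list(mk_src(write_newick(true), "a", "f"),
                                          mk_src(write_newick(true), "b", "f")))
  doubled <- encode_baum_ragan(dup)
  for (i in 1:10) {
    cand <- ape::root(ape::rtree(9, tip.label = c(true$tip.label, "MRP_outgroup")),
                      outgroup = "MRP_outgroup", resolve.root = TRUE)
    expect_equal(fitch_score(cand, base), fitch_score(cand, doubled),
                 tolerance = 1e-9)
  }
})

test_that("heuristic_search recovers clean topologies and honours weights", {
  true <- parse_newick("((((A,B),C),D),E);")
  src <- lapply(1:2, function(i) mk_src(write_newick(true), paste0("s", i),
                                        paste0("f", i)))
  m <- encode_baum_ragan(src)
  ts <- heuristic_search(m, replicates = 4, seed = 2)
  expect_true(any(vapply(ts$trees, trees_isomorphic, logical(1), t2 = true)))
  # homoplasy-free score: one change per character
  expect_equal(ts$score, sum(m$weights))
  # exhaustive check: no 5-leaf rooted topology scores lower
  all5 <- phangorn::allTrees(5, rooted = TRUE, tip.label = true$tip.label)
  scores <- vapply(all5, function(t5) {
    t5og <- parse_newick(paste0("(", sub(";$", "", write_newick(t5)),
                                ",MRP_outgroup);"))
    fitch_score(t5og, m)
  }, numeric(1))
  expect_equal(min(scores), ts$score)

  # conflicting cherries with weights 1 vs 2: heavy cherry wins
  light <- mk_src("((A,B),(C,D));", "w1", "fa")
  heavy1 <- mk_src("((A,C),(B,D));", "w2", "fsame")
  heavy2 <- mk_src("((A,C),(B,D));", "w3", "fsame2")
  m2 <- encode_baum_ragan(list(light, heavy1, heavy2))
  ts2 <- heuristic_search(m2, replicates = 6, seed = 3)
  expect_true(all(vapply(ts2$trees, displays_clade, logical(1),
                         clade = c("A", "C"))))

  # determinism
  tsa <- heuristic_search(m2, replicates = 2, seed = 11)
  tsb <- heuristic_search(m2, replicates = 2, seed = 11)
  expect_equal(lapply(tsa$trees, write_newick), lapply(tsb$trees, write_newick))
  expect_equal(tsa$score, tsb$score)
})

test_that("MRP recovery: conflict-free corpora yield trees displaying all source clades", {
  set.seed(21)
  for (rep_i in 1:10) {
    true <- random_rooted_tree(sample(10:12, 1), lengths = FALSE)
    src <- sim_source_trees(true, m = 8, size_range = c(5, 9), nni_moves = 0,
                            seed = 400 + rep_i)
    mat <- encode_baum_ragan(src)
    ts <- heuristic_search(mat, replicates = 3, seed = rep_i)
    expect_equal(ts$score, sum(mat$weights))
    best <- ts$trees[[1]]
    for (s in src) {
      cls <- caridiv:::clade_sets(s$tree)
      nt <- ape::Ntip(s$tree)
      for (nd in seq(nt + 2L, nt + s$tree$Nnode)) {
        expect_true(displays_clade(best, cls[[nd]],
                                   context = s$tree$tip.label))
      }
    }
  }
})

test_that("strict consensus keeps exactly the shared clades", {
  a <- parse_newick("((A,B),C);")
  expect_true(trees_isomorphic(strict_consensus(list(a, a)), a))
  b <- parse_newick("((A,C),B);")
  star <- strict_consensus(list(a, b))
  expect_equal(star$Nnode, 1L)
  # two trees sharing only the AB clade
  t1 <- parse_newick("(((A,B),C),D);")
  t2 <- parse_newick("(((A,B),D),C);")
  cons <- strict_consensus(list(t1, t2))
  expect_true(displays_clade(cons, c("A", "B")))
  expect_false(displays_clade(cons, c("A", "B", "C")))
  expect_false(displays_clade(cons, c("A", "B", "D")))
})

test_that("mast is exact pairwise (oracle) and an agreement subtree generally", {
  a <- parse_newick("((A,B),C);"); b <- parse_newick("((A,C),B);")
  expect_true(trees_isomorphic(mast(list(a, a)), a))
  expect_equal(ape::Ntip(mast(list(a, b))), 2L)
  expect_error(mast(list(parse_newick("(A,B);"), parse_newick("(A,C);"))),
               "shared")

  set.seed(31)
  for (i in 1:30) {
    t1 <- random_rooted_tree(8, lengths = FALSE)
    t2 <- random_rooted_tree(8, lengths = FALSE)
    res <- mast(list(t1, t2))
    expect_equal(ape::Ntip(res), brute_force_mast_size(t1, t2))
    keep <- res$tip.label
    expect_true(trees_isomorphic(prune_to(t1, keep), prune_to(t2, keep)))
  }

  # multi-tree folding still returns an agreement subtree of all inputs
  set.seed(32)
  base <- random_rooted_tree(12, lengths = FALSE)
  trees <- list(base, caridiv:::rooted_nni(base), caridiv:::rooted_nni(base))
  res <- mast(trees)
  r1 <- prune_to(trees[[1]], res$tip.label)
  for (t_ in trees[-1])
    expect_true(trees_isomorphic(prune_to(t_, res$tip.label), r1))
})

test_that("remove_taxa prunes rogues and keeps clade restrictions", {
  tr <- parse_newick("(((A,B),C),D);")
  expect_true(trees_isomorphic(remove_taxa(tr, character(0)), tr))
  out <- remove_taxa(tr, "B")
  expect_true(trees_isomorphic(out, parse_newick("((A,C),D);")))
  expect_warning(out2 <- remove_taxa(tr, c("Z", "D")), "Z")
  expect_equal(sort(out2$tip.label), c("A", "B", "C"))

  set.seed(41)
  big <- random_rooted_tree(100, lengths = FALSE)
  rogues <- sample(big$tip.label, 5)
  pruned <- remove_taxa(big, rogues)
  expect_equal(ape::Ntip(pruned), 95L)
  cls <- caridiv:::clade_sets(pruned)
  keepset <- pruned$tip.label
  orig <- lapply(caridiv:::clade_sets(big), function(s) sort(intersect(s, keepset)))
  for (nd in seq(96L, 95L + pruned$Nnode)) {
    expect_true(any(vapply(orig, identical, logical(1), y = cls[[nd]])))
  }
})

test_that("flag_novel_clades reports only unsupported non-trivial clades", {
  src <- list(mk_src("((((A,B),C),D),E);"))
  st <- parse_newick("((((A,B),C),D),E);")
  expect_length(flag_novel_clades(st, src), 0)

  # supertree groups A with D against every source placing them apart
  s1 <- mk_src("(((A,B),C),D);", "s1")
  s2 <- mk_src("(((A,C),B),D);", "s2")
  s3 <- mk_src("((A,B),(C,D));", "s3")
  st2 <- parse_newick("(((A,D),B),C);")
  flags <- flag_novel_clades(st2, list(s1, s2, s3))
  expect_true(any(vapply(flags, identical, logical(1), y = c("A", "D"))))

  # clade trivial in every source is not flagged
  s4 <- mk_src("((A,B),C);", "s4")
  st3 <- parse_newick("(((X,Y),A),B);")
  flags3 <- flag_novel_clades(st3, list(s4))
  expect_false(any(vapply(flags3, identical, logical(1), y = c("X", "Y"))))
})

test_that("matrix writers emit well-formed NEXUS and TNT", {
  m <- encode_baum_ragan(list(mk_src("((A,B),C);"), mk_src("((B,C),D);", "s2")))
  f1 <- tempfile(fileext = ".nex"); write_nexus_data(m, f1)
  txt <- readLines(f1)
  expect_true(any(grepl("NTAX=5 NCHAR=2", txt)))
  expect_true(any(grepl("MATRIX", txt)))
  f2 <- tempfile(fileext = ".tnt"); write_tnt(m, f2)
  txt2 <- readLines(f2)
  expect_equal(txt2[1], "xread")
  expect_true(any(grepl("ccode", txt2)))
})
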