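## End-to-end pipeline: chains curation -> MRP encoding -> parsimony search
## -> MAST -> rogue pruning -> time scaling -> stochastic mapping ->
## diversification MCMC -> clade rates -> rate comparisons, with a run
## manifest (config, seeds, file hashes, timestamps) for reproducibility.

pipeline_defaults <- function() {
  list(
    out_dir = NULL, seed = 1,
    study_dir = NULL,
    sources_csv = NULL, synonyms_csv = NULL, higher_taxa_csv = NULL,
    calibrations_csv = NULL, traits_csv = NULL, sampling_csv = NULL,
    rogues_file = NULL, timescaled_tree = NULL,
    search = list(replicates = 10),
    timescale = list(min_branch = 0.1),
    asr = list(n_maps = 200, traits = c("habitat", "lifestyle")),
    divrates = list(generations = 5e4, store = 2000, min_clade_size = 5),
    clades = list(min_tips = 10)
  )
}

validate_config <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (sub in c("search", "timescale", "asr", "divrates", "clades")) {
    if (!is.null(config[[sub]])) {
      bad <- setdiff(names(config[[sub]]), names(defaults[[sub]]))
      if (length(bad))
        stop("unknown config key(s) in '", sub, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      defaults[[sub]] <- utils::modifyList(defaults[[sub]], config[[sub]])
      config[[sub]] <- NULL
    }
  }
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, logical(1))])
  if (is.null(cfg$out_dir)) stop("config must set out_dir", call. = FALSE)
  cfg
}

#' Run the full supertree-to-diversification pipeline
#'
#' Executes curate, encode, search, mast, prune, timescale, asr, divrates,
#' claderates and compare in order, skipping the tree-building stages when a
#' precomputed time-scaled tree is supplied. Every stage's configuration,
#' seed, and output file hashes are recorded in `manifest.json` under the
#' output directory; rerunning with an identical config and seed reproduces
#' identical outputs.
#'
#' @param config A YAML file path or a named list. Keys: `out_dir` (required),
#'   `seed`, `study_dir` (a [sim_study()]/[write_study()] layout) or explicit
#'   input paths (`sources_csv`, `synonyms_csv`, `higher_taxa_csv`,
#'   `calibrations_csv`, `traits_csv`, `sampling_csv`, `rogues_file`,
#'   `timescaled_tree`), and per-stage settings (`search$replicates`,
#'   `timescale$min_branch`, `asr$n_maps`, `asr$traits`,
#'   `divrates$generations` / `store` / `min_clade_size`, `clades$min_tips`).
#' @return The run manifest (list), invisibly; side effects under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$study_dir)) {
    sd <- cfg$study_dir
    take <- function(cur, f) if (!is.null(cur)) cur else {
      p <- file.path(sd, f); if (file.exists(p)) p else NULL
    }
    cfg$sources_csv <- take(cfg$sources_csv, "sources.csv")
    cfg$calibrations_csv <- take(cfg$calibrations_csv, "calibrations.csv")
    cfg$traits_csv <- take(cfg$traits_csv, "traits.csv")
    cfg$sampling_csv <- take(cfg$sampling_csv, "sampling.csv")
  }

  manifest <- list(package = "caridiv",
                   version = as.character(utils::packageVersion("caridiv")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = cfg$seed, stages = list())
  t_start <- NULL
  stage <- function(name, conf, fun) {
    t_start <<- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    files <- res$files
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, config = conf,
      started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = as.list(tools::md5sum(files)))
    res
  }

  traits <- if (!is.null(cfg$traits_csv)) read_traits(cfg$traits_csv) else
    stop("traits_csv (or a study_dir containing traits.csv) is required",
         call. = FALSE)

  if (is.null(cfg$timescaled_tree)) {
    if (is.null(cfg$sources_csv))
      stop("either sources_csv or timescaled_tree must be supplied", call. = FALSE)
    if (is.null(cfg$calibrations_csv))
      stop("calibrations_csv is required to time-scale the supertree", call. = FALSE)

    cur <- stage("curate", list(), function() {
      sources <- read_sources(cfg$sources_csv)
      tmap <- read_taxon_map(cfg$synonyms_csv, cfg$higher_taxa_csv)
      all_taxa <- lapply(sources, function(s) s$tree$tip.label)
      sources <- lapply(seq_along(sources), function(i) {
        observed <- unique(unlist(all_taxa[-i]))
        standardize_taxa(sources[[i]], tmap, observed)
      })
      sources <- assign_independence_weights(sources)
      ov <- check_overlap(sources)
      if (!ov$pass)
        stop("source trees lack sufficient taxonomic overlap (",
             ov$n_components, " components)", call. = FALSE)
      f <- file.path(out, "overlap_report.json")
      jsonlite::write_json(ov[c("pass", "n_components", "flagged")], f,
                           auto_unbox = TRUE)
      list(sources = sources, files = f)
    })

    enc <- stage("encode", list(), function() {
      m <- encode_baum_ragan(cur$sources)
      f1 <- file.path(out, "mrp_matrix.nex"); write_nexus_data(m, f1)
      f2 <- file.path(out, "mrp_matrix.tnt"); write_tnt(m, f2)
      list(matrix = m, files = c(f1, f2))
    })

    srch <- stage("search", cfg$search, function() {
      ts <- heuristic_search(enc$matrix, replicates = cfg$search$replicates,
                             seed = cfg$seed)
      f <- file.path(out, "mptrees.nwk")
      writeLines(vapply(ts$trees, write_newick, character(1)), f)
      list(treeset = ts, files = f)
    })

    mst <- stage("mast", list(), function() {
      if (length(srch$treeset$trees) >= 2) {
        tr <- mast(srch$treeset)
        cons <- strict_consensus(srch$treeset)
      } else {
        tr <- srch$treeset$trees[[1]]
        cons <- tr
      }
      f1 <- file.path(out, "mast.nwk"); writeLines(write_newick(tr), f1)
      f2 <- file.path(out, "strict_consensus.nwk")
      writeLines(write_newick(cons), f2)
      list(tree = tr, files = c(f1, f2))
    })

    prn <- stage("prune", list(), function() {
      rogues <- if (!is.null(cfg$rogues_file))
        readLines(cfg$rogues_file, warn = FALSE) else character(0)
      rogues <- rogues[nzchar(rogues)]
      tr <- remove_taxa(mst$tree, rogues)
      f <- file.path(out, "supertree_pruned.nwk")
      writeLines(write_newick(tr), f)
      list(tree = tr, files = f)
    })

    tsc <- stage("timescale", cfg$timescale, function() {
      cal <- read_calibrations(cfg$calibrations_csv)
      cal <- cal[cal$taxon_a %in% prn$tree$tip.label &
                   cal$taxon_b %in% prn$tree$tip.label, , drop = FALSE]
      cal <- filter_compatible_calibrations(prn$tree, calibration_table(cal),
                                            min_gap = cfg$timescale$min_branch)
      root <- ape::Ntip(prn$tree) + 1L
      hits_root <- any(vapply(seq_len(nrow(cal)), function(i)
        mrca_node(prn$tree, c(cal$taxon_a[i], cal$taxon_b[i])) == root,
        logical(1)))
      tr <- timescale_equal(prn$tree, cal,
                            min_branch = cfg$timescale$min_branch,
                            root_age = if (hits_root) NULL else
                              1.05 * max(cal$age_ma))
      f <- file.path(out, "supertree_timescaled.nwk")
      writeLines(write_newick(tr), f)
      list(tree = tr, files = f)
    })
    tree <- tsc$tree
  } else {
    txt <- paste(readLines(cfg$timescaled_tree, warn = FALSE), collapse = "")
    tree <- parse_newick(txt)
  }

  tree <- prune_to(tree, intersect(tree$tip.label, traits$species))

  asr_res <- stage("asr", cfg$asr, function() {
    files <- character(0)
    res <- list()
    for (tn in cfg$asr$traits) {
      states <- trait_states(traits, tn)[tree$tip.label]
      fit <- fit_q(tree, states)
      maps <- sample_histories(tree, states, fit, n_maps = cfg$asr$n_maps,
                               seed = cfg$seed)
      gains <- count_origins(maps, "01")
      losses <- count_origins(maps, "10")
      f <- file.path(out, paste0("asr_", tn, ".tsv"))
      write.table(data.frame(map = seq_along(gains$per_map),
                             count_01 = gains$per_map,
                             count_10 = losses$per_map),
                  f, sep = "\t", row.names = FALSE, quote = FALSE)
      fj <- file.path(out, paste0("asr_", tn, ".json"))
      jsonlite::write_json(list(q = fit$q, loglik = fit$loglik,
                                origins = gains$count,
                                reversals = losses$count),
                           fj, auto_unbox = TRUE, digits = NA)
      files <- c(files, f, fj)
      res[[tn]] <- list(fit = fit, gains = gains, losses = losses)
    }
    c(res, list(files = files))
  })

  sampling <- if (!is.null(cfg$sampling_csv))
    read.csv(cfg$sampling_csv, stringsAsFactors = FALSE) else NULL
  if (!is.null(sampling)) {
    present <- sampling$taxon_a %in% tree$tip.label &
      sampling$taxon_b %in% tree$tip.label
    if (any(!present))
      message(sum(!present), " sampling-fraction clade(s) lost their anchor",
              " taxa during tree building; dropped")
    sampling <- sampling[present, , drop = FALSE]
    if (nrow(sampling) == 0) sampling <- NULL
  }

  div <- stage("divrates", cfg$divrates, function() {
    chain <- run_rjmcmc(tree,
                        config = list(generations = cfg$divrates$generations,
                                      store = cfg$divrates$store,
                                      min_clade_size = cfg$divrates$min_clade_size,
                                      sampling = sampling),
                        seed = cfg$seed)
    f1 <- file.path(out, "divrates_chain.tsv"); write_chain_tsv(chain, f1)
    summ <- credible_shift_summary(chain)
    f2 <- file.path(out, "shift_configurations.json")
    jsonlite::write_json(list(configurations = summ$configurations,
                              marginal = as.list(summ$marginal)),
                         f2, auto_unbox = TRUE, digits = NA)
    list(chain = chain, files = c(f1, f2))
  })

  cr <- stage("claderates", cfg$clades, function() {
    states <- trait_states(traits, "habitat")[tree$tip.label]
    fresh <- trait_clades(tree, states, 1, min_tips = cfg$clades$min_tips)
    marine <- trait_clades(tree, states, 0, min_tips = cfg$clades$min_tips)
    if (nrow(fresh) == 0 || nrow(marine) == 0)
      stop("need at least one clade of each habitat with more than ",
           cfg$clades$min_tips, " tips", call. = FALSE)
    clades <- rbind(cbind(fresh, category = "freshwater"),
                    cbind(marine, category = "marine"))
    rs <- clade_rates(div$chain, clades, min_tips = cfg$clades$min_tips)
    files <- character(0)
    for (cat in names(rs)) {
      f <- file.path(out, paste0("rates_", cat, ".csv"))
      write.csv(rs[[cat]], f, row.names = FALSE)
      files <- c(files, f)
    }
    list(rates = rs, clades = clades, files = files)
  })

  cmp <- stage("compare", list(), function() {
    res <- compare_categories(cr$rates$freshwater, cr$rates$marine)
    f <- file.path(out, "comparison.json")
    jsonlite::write_json(
      lapply(res, function(v) list(wilcoxon_p = v$wilcoxon$p, ks_D = v$ks$D,
                                   ks_p = v$ks$p, mean_ratio = v$mean_ratio)),
      f, auto_unbox = TRUE, digits = NA)
    list(result = res, files = f)
  })

  mf <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
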