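# Pipeline orchestration: config, staged execution, report, CLI.

PIPELINE_STAGES <- c("simulate", "segment", "distances", "stats", "cluster",
                     "associate", "connectivity", "report")

#' Read a pipeline run configuration
#'
#' Flat INI-style text with sections `[pipeline]`, `[io]`, `[simulate]`,
#' `[segmentation]`, `[stats]`, `[clustering]`, `[association]`,
#' `[connectivity]`. Missing keys fall back to package defaults (see
#' [default_config()]).
#'
#' @param path config file path.
#' @return nested list of configuration sections.
#' @export
read_run_config <- function(path) {
  user <- parse_ini(path)
  cfg <- default_config()
  for (sec in names(user)) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- list()
    for (key in names(user[[sec]])) cfg[[sec]][[key]] <- user[[sec]][[key]]
  }
  cfg
}

#' Default pipeline configuration (bundled toy scene)
#'
#' A small synthetic scene that exercises every stage in well under a minute:
#' eight homotypes of 3-6 neurons threading three regions, plus planted
#' synapse tables for both interfaces.
#'
#' @return nested list of configuration sections.
#' @export
default_config <- function() {
  list(
    pipeline = list(outdir = "pnorg_run", seed = 20260910),
    io = list(unit_scale = 1, alias_map = TRUE),
    simulate = list(enabled = TRUE, n_homotypes = 8, neurons_min = 3,
                    neurons_max = 6, sigma = 1, nodes_per_region = 25,
                    anchor_spread = 20, n_partners = 12,
                    specific_fraction = 0.25, weight_mean = 5),
    segmentation = list(axis = 1, increment = 5, bin_width = 2, weight = 1,
                        prominence_frac = 0.05),
    stats = list(lambda_threshold = 0.4),
    clustering = list(min_cluster_size = 4, deep_split = 2, gap_B = 50),
    association = list(n_perm = 1000, alpha = 0.01),
    connectivity = list(threshold = 3, threshold_strict = 8)
  )
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

toy_homotypes <- function(n) {
  # alternate attractive and aversive glomeruli so valence tests have margins
  hv <- homotype_valences()
  att <- hv$homotype[hv$valence == "attractive"]
  avs <- hv$homotype[hv$valence == "aversive"]
  pool <- as.vector(rbind(att[seq_len(min(length(att), length(avs)))],
                          avs[seq_len(min(length(att), length(avs)))]))
  pool <- c(pool, setdiff(c(att, avs), pool))
  pool[seq_len(min(n, length(pool)))]
}

#' Run the analysis pipeline
#'
#' Executes the stages in order (selection, segmentation, distances,
#' homotype statistics, clustering, association, connectivity, report),
#' writing per-stage outputs under `outdir`. Rerunning with an unchanged
#' configuration is a no-op (the run manifest stores a content hash).
#' Stochastic stages draw their seeds deterministically from the global seed.
#'
#' @param config a config list from [read_run_config()] / [default_config()],
#'   or a path to a config file.
#' @param outdir output directory (overrides the config value).
#' @param seed global seed (overrides the config value).
#' @param last_stage run only up to this stage (simulate, segment, distances,
#'   stats, cluster, associate, connectivity, report); earlier stage outputs
#'   are bit-identical to a full run's.
#' @param force rerun even when the manifest hash matches.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL, seed = NULL,
                         last_stage = "report", force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  assert_that(last_stage %in% PIPELINE_STAGES, "unknown stage '%s'", last_stage)
  outdir <- outdir %||% config$pipeline$outdir
  seed <- as.integer(seed %||% config$pipeline$seed)
  config$pipeline$outdir <- outdir
  config$pipeline$seed <- seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  cfg_file <- tempfile(fileext = ".rds")
  on.exit(unlink(cfg_file), add = TRUE)
  hashed_cfg <- config
  hashed_cfg$pipeline$outdir <- NULL  # the output location must not defeat the no-op check
  saveRDS(list(hashed_cfg, last_stage, as.character(utils::packageVersion("pnorg"))),
          cfg_file, version = 2)
  hash <- unname(tools::md5sum(cfg_file))
  manifest_path <- file.path(outdir, "manifest.txt")
  report_path <- file.path(outdir, "report.txt")
  if (!force && file.exists(manifest_path) && file.exists(report_path)) {
    prev <- readLines(manifest_path, warn = FALSE)
    if (any(prev == paste0("config_hash = ", hash))) {
      message("configuration unchanged; outputs are current (no-op rerun)")
      return(invisible(NULL))
    }
  }
  results <- list(config = config)
  upto <- match(last_stage, PIPELINE_STAGES)

  # -- simulate / io ---------------------------------------------------------
  results <- stage_try("io", {
    if (isTRUE(config$simulate$enabled)) {
      sc <- config$simulate
      set.seed(seed)
      nh <- sc$n_homotypes
      specs <- bundle_spec(
        homotype = toy_homotypes(nh),
        n_neurons = sample(sc$neurons_min:sc$neurons_max, nh, replace = TRUE),
        sigma = rep(sc$sigma, nh),
        nodes_per_region = sc$nodes_per_region)
      pop <- generate_population(specs, seed = seed,
                                 anchor_spread = rep(sc$anchor_spread %||% 15, 3))
      write_population(pop, file.path(outdir, "population"))
      cspec <- connectivity_spec(specs$homotype, sc$n_partners, sc$specific_fraction)
      syn_kc <- generate_synapses(cspec, seed = seed + 1L, upn_map = pop$annotations,
                                  interface = "PN-KC", weight_mean = sc$weight_mean)
      syn_lhn <- generate_synapses(cspec, seed = seed + 2L, upn_map = pop$annotations,
                                   interface = "PN-LHN", weight_mean = sc$weight_mean)
      syn <- rbind(syn_kc$table, syn_lhn$table)
      utils::write.csv(syn, file.path(outdir, "synapses.csv"), row.names = FALSE,
                       quote = FALSE)
      c(results, list(population = pop, synapses = syn,
                      syn_truth = list(`PN-KC` = syn_kc$truth, `PN-LHN` = syn_lhn$truth)))
    } else {
      io <- config$io
      assert_that(!is.null(io$swc_dir), "config [io] needs swc_dir when simulation is off")
      assert_that(!is.null(io$annotation_path) && file.exists(io$annotation_path),
                  "annotation file not found: %s", io$annotation_path %||% "<missing>")
      files <- sort(list.files(io$swc_dir, pattern = "\\.swc$", full.names = TRUE))
      assert_that(length(files) > 0, "no SWC files under %s", io$swc_dir)
      skels <- lapply(files, read_swc, unit_scale = io$unit_scale)
      names(skels) <- vapply(skels, function(s) s$neuron_id, character(1))
      alias <- if (isTRUE(io$alias_map)) default_alias_map() else NULL
      ann <- read_annotations(io$annotation_path, alias_map = alias)
      syn <- NULL
      if (!is.null(io$synapse_path)) syn <- read_synapse_table(io$synapse_path)
      c(results, list(population = list(skeletons = skels, annotations = ann,
                                        ground_truth = NULL),
                      synapses = syn, syn_truth = NULL))
    }
  })
  if (upto < match("segment", PIPELINE_STAGES)) return(done_pipeline(results, manifest_path, hash, seed))

  # -- segment ---------------------------------------------------------------
  results <- stage_try("segment", {
    sg <- config$segmentation
    seg <- segment_scene(results$population$skeletons, axis = sg$axis,
                         increment = sg$increment, bin_width = sg$bin_width,
                         weight = sg$weight, prominence_frac = sg$prominence_frac)
    write_masks(seg$masks, file.path(outdir, "masks.tsv"))
    upns <- select_upns(results$population$annotations, seg$masks)
    writeLines(upns, file.path(outdir, "selected_upns.txt"))
    c(results, list(segmentation = seg, upns = upns))
  })
  if (upto < match("distances", PIPELINE_STAGES)) return(done_pipeline(results, manifest_path, hash, seed))

  # -- distances -------------------------------------------------------------
  results <- stage_try("distances", {
    skels <- results$population$skeletons[results$upns]
    dms <- lapply(NEUROPILS, function(np) {
      d <- distance_matrix(skels, masks = results$segmentation$masks, neuropil = np)
      write_distance_matrix(d, file.path(outdir, sprintf("dist_%s.csv", np)))
      d
    })
    names(dms) <- NEUROPILS
    c(results, list(distances = dms))
  })
  if (upto < match("stats", PIPELINE_STAGES)) return(done_pipeline(results, manifest_path, hash, seed))

  # -- stats -----------------------------------------------------------------
  results <- stage_try("stats", {
    thr <- config$stats$lambda_threshold
    hs <- lapply(NEUROPILS, function(np) {
      homotype_stats(results$distances[[np]], results$population$annotations,
                     lambda_threshold = thr)
    })
    names(hs) <- NEUROPILS
    all_stats <- do.call(rbind, hs)
    write_homotype_stats(all_stats, file.path(outdir, "homotype_stats.tsv"))
    summaries <- do.call(rbind, lapply(hs, population_summary))
    utils::write.table(summaries, file.path(outdir, "population_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lcorr <- tryCatch(lambda_correlation(hs$MB_calyx, hs$LH),
                      error = function(e) list(r = NA_real_, p = NA_real_,
                                               n = 0L, note = conditionMessage(e)))
    c(results, list(homotype_stats = hs, summaries = summaries,
                    lambda_corr_mb_lh = lcorr))
  })
  if (upto < match("cluster", PIPELINE_STAGES)) return(done_pipeline(results, manifest_path, hash, seed))

  # -- cluster ---------------------------------------------------------------
  results <- stage_try("cluster", {
    cl <- config$clustering
    trees <- list(); cuts <- list()
    for (np in NEUROPILS) {
      tree <- complete_linkage(results$distances[[np]])
      cut <- cut_dynamic_hybrid(tree, d = results$distances[[np]],
                                min_cluster_size = cl$min_cluster_size,
                                deep_split = cl$deep_split)
      dendrogram_newick(tree, file.path(outdir, sprintf("tree_%s.nwk", np)))
      write_assignments(cut, file.path(outdir, sprintf("clusters_%s.tsv", np)),
                        neuropil = np)
      trees[[np]] <- tree
      cuts[[np]] <- cut
    }
    c(results, list(trees = trees, clusters = cuts))
  })
  if (upto < match("associate", PIPELINE_STAGES)) return(done_pipeline(results, manifest_path, hash, seed))

  # -- associate -------------------------------------------------------------
  results <- stage_try("associate", {
    as_cfg <- config$association
    ann <- results$population$annotations
    assoc <- list()
    k <- 0L
    for (np in c("MB_calyx", "LH")) {
      cut <- results$clusters[[np]]
      meta <- ann[match(names(cut), ann$neuron_id), ]
      for (var in c("homotype", "odor_type", "valence")) {
        k <- k + 1L
        key <- sprintf("%s~%s", np, var)
        assoc[[key]] <- tryCatch(
          association_test(meta[[var]], as.integer(cut),
                           n_perm = as_cfg$n_perm, seed = seed + 100L + k,
                           alpha = as_cfg$alpha),
          error = function(e) list(note = conditionMessage(e)))
      }
    }
    lines <- vapply(names(assoc), function(key) {
      a <- assoc[[key]]
      if (!is.null(a$note)) return(sprintf("%s\tskipped: %s", key, a$note))
      sprintf("%s\tchi2=%.4f\tdof=%d\tp=%.4g\tV=%.4f\tMI=%.4f\tMI_p=%.4g",
              key, a$chi2, a$dof, a$p_value, a$cramers_v, a$mi, a$mi_p)
    }, character(1))
    writeLines(lines, file.path(outdir, "association.tsv"))
    c(results, list(association = assoc))
  })
  if (upto < match("connectivity", PIPELINE_STAGES)) return(done_pipeline(results, manifest_path, hash, seed))

  # -- connectivity ----------------------------------------------------------
  results <- stage_try("connectivity", {
    if (is.null(results$synapses)) {
      message("no synapse table supplied; connectivity stage skipped")
      c(results, list(connectivity = NULL))
    } else {
      cc <- config$connectivity
      ann <- results$population$annotations
      out <- list()
      for (iface in unique(results$synapses$interface)) {
        C <- binarize_synapses(results$synapses, threshold = cc$threshold,
                               homotype_map = ann, interface = iface)
        S <- common_synapses(C)
        spd <- specificity(C)
        tag <- sub("^PN-", "", iface)
        write_labelled_matrix(C, file.path(outdir, sprintf("C_%s.csv", tag)))
        write_labelled_matrix(S, file.path(outdir, sprintf("S_%s.csv", tag)))
        utils::write.table(spd, file.path(outdir, sprintf("specificity_%s.tsv", tag)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        Cu <- binarize_synapses(results$synapses, threshold = cc$threshold,
                                homotype_map = ann, interface = iface,
                                level = "upn")
        conn_tree <- connectivity_clustering(Cu)
        dendrogram_newick(conn_tree, file.path(outdir, sprintf("conn_tree_%s.nwk", tag)))
        np <- if (iface == "PN-KC") "MB_calyx" else "LH"
        spatial_tree <- results$trees[[np]]
        common <- intersect(spatial_tree$labels, conn_tree$labels)
        tangle <- NULL
        if (length(common) >= 3L) {
          t1 <- prune_hclust(spatial_tree, common)
          t2 <- prune_hclust(conn_tree, common)
          tangle <- tanglegram_stats(t1, t2)
        }
        out[[iface]] <- list(C = C, S = S, specificity = spd,
                             conn_tree = conn_tree, tanglegram = tangle)
      }
      tl <- vapply(names(out), function(iface) {
        tg <- out[[iface]]$tanglegram
        if (is.null(tg)) return(sprintf("%s\tNA", iface))
        sprintf("%s\tbakers_gamma=%.4f\tentanglement=%.4f\tcophenetic_r=%.4f",
                iface, tg$bakers_gamma, tg$entanglement, tg$cophenetic_r)
      }, character(1))
      writeLines(tl, file.path(outdir, "tanglegram.tsv"))
      c(results, list(connectivity = out))
    }
  })

  # -- report ----------------------------------------------------------------
  results <- stage_try("report", {
    rep <- c(
      sprintf("pnorg pipeline report (seed %d)", seed),
      sprintf("neurons selected (tri-neuropil): %d", length(results$upns)),
      "",
      "per-neuropil population summary:",
      utils::capture.output(print(results$summaries, row.names = FALSE)),
      "",
      sprintf("lambda correlation MB_calyx~LH: r=%.4f p=%.4g n=%d",
              results$lambda_corr_mb_lh$r, results$lambda_corr_mb_lh$p,
              results$lambda_corr_mb_lh$n),
      "",
      "clusters per neuropil (dynamic hybrid cut):",
      vapply(NEUROPILS, function(np) {
        sprintf("  %s: %d clusters / %d neurons", np,
                length(setdiff(unique(results$clusters[[np]]), 0L)),
                length(results$clusters[[np]]))
      }, character(1)),
      "",
      "association tests: see association.tsv",
      "connectivity: see C_*.csv, S_*.csv, specificity_*.tsv, tanglegram.tsv")
    writeLines(rep, report_path)
    results
  })
  done_pipeline(results, manifest_path, hash, seed)
}

done_pipeline <- function(results, manifest_path, hash, seed) {
  writeLines(c(sprintf("config_hash = %s", hash),
               sprintf("seed = %d", seed),
               sprintf("pnorg_version = %s", utils::packageVersion("pnorg")),
               sprintf("finished = %s", "true")),
             manifest_path)
  invisible(results)
}

# Restrict an hclust to a label subset by re-clustering the cophenetic
# distances of the retained leaves (exact for the induced subtree).
prune_hclust <- function(tree, keep) {
  cm <- as.matrix(stats::cophenetic(tree))[keep, keep]
  stats::hclust(stats::as.dist(cm), method = "complete")
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages: `simulate`, `segment`, `distances`,
#' `stats`, `cluster`, `associate`, `connectivity`, `report` (each runs the
#' pipeline up to that stage; stage outputs are bit-identical to a full run),
#' `run` (everything) and `reproduce-paper` (scripted re-analysis of the
#' public FAFB/hemibrain exports; requires a user-supplied download, never run
#' by tests). Flags: `--config PATH`, `--seed INT`, `--outdir PATH`,
#' `--force`, `--verbose`.
#'
#' @param args character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
pnorg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: pnorg <", paste(c(PIPELINE_STAGES, "run"), collapse = "|"),
                  "> [--config PATH] [--seed INT] [--outdir PATH] [--force]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(config = NULL, seed = NULL, outdir = NULL, force = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--force") { opts$force <- TRUE; i <- i + 1L }
    else if (a %in% c("--config", "--seed", "--outdir", "--threads", "--verbose")) {
      if (a == "--verbose") { i <- i + 1L; next }
      assert_that(i < length(args), "missing value for %s", a)
      key <- sub("^--", "", a)
      if (key != "threads") opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else stop_("unknown argument '%s'\n%s", a, usage)
  }
  if (cmd == "reproduce-paper") {
    stop_(paste("reproduce-paper needs the public FAFB/hemibrain exports on disk;",
                "download them (CATMAID / neuPrint), point [io] swc_dir,",
                "annotation_path and synapse_path at them, disable [simulate],",
                "and run 'pnorg run --config <your.ini>'."))
  }
  last <- if (cmd == "run") "report" else cmd
  assert_that(last %in% PIPELINE_STAGES, "unknown subcommand '%s'\n%s", cmd, usage)
  config <- if (is.null(opts$config)) default_config() else read_run_config(opts$config)
  run_pipeline(config, outdir = opts$outdir,
               seed = if (is.null(opts$seed)) NULL else as.integer(opts$seed),
               last_stage = last, force = opts$force)
  invisible(0L)
}
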