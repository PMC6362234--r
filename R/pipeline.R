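# End-to-end orchestration: synthetic input (or files on disk) ->
# similarity network -> clusters -> motif screen -> per-cluster
# alignment/filter/logos -> trees with bootstrap -> neighborhood
# analysis -> machine-readable report.

#' Pipeline configuration
#'
#' Exactly one of `world` (a [world_config()], for synthetic runs) or
#' `input_dir` (a directory holding `proteins.faa`, `features.tsv`,
#' `taxonomy.tsv` and optionally `truth.json`) must be given.  For
#' synthetic runs the world seed is derived from the pipeline seed, so
#' a single `seed` reproduces the whole run.
#'
#' @param world Optional [world_config()].
#' @param input_dir Optional input directory.
#' @param out_dir Output directory.
#' @param seed Integer master seed; every stage forks its own stream
#'   from it by stage name.
#' @param threshold Network alignment-score threshold (default 75).
#' @param kmer_prefilter Use the shared-4-mer prefilter in the network
#'   stage.
#' @param mode Motif-screen mode, `"strict"` or `"relaxed"`.
#' @param min_quality Alignment column-quality threshold (default 826).
#' @param bootstrap_replicates Bootstrap replicates per cluster tree
#'   (default 1000; test-scale runs use 100).
#' @param window_k Neighborhood window half-width (default 3).
#' @param min_taxa Neighbor selection threshold (default 30 genera).
#' @param exclusions Excluded neighbor labels (default PF07690,
#'   PF00005).
#' @param cooccur_min Windows required for a co-occurrence edge
#'   (default 2).
#' @param stages Stages to run after input, a subset of
#'   `c("network", "motif", "msa", "tree", "neighborhood")`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(world = NULL, input_dir = NULL,
                            out_dir = tempfile("caltscan_run_"),
                            seed = 1L, threshold = 75,
                            kmer_prefilter = TRUE,
                            mode = c("strict", "relaxed"),
                            min_quality = 826,
                            bootstrap_replicates = 1000L,
                            window_k = 3L, min_taxa = 30,
                            exclusions = c("PF07690", "PF00005"),
                            cooccur_min = 2L,
                            stages = c("network", "motif", "msa", "tree",
                                       "neighborhood")) {
  if (is.null(world) == is.null(input_dir)) {
    stop("exactly one of `world` or `input_dir` must be set", call. = FALSE)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(world = world, input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), threshold = threshold,
                 kmer_prefilter = isTRUE(kmer_prefilter),
                 mode = match.arg(mode), min_quality = min_quality,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 window_k = as.integer(window_k), min_taxa = min_taxa,
                 exclusions = exclusions,
                 cooccur_min = as.integer(cooccur_min), stages = stages),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (synthetic generation or input reading,
#' network, clusters, motif screen, per-cluster alignment + quality
#' filter + logos, per-cluster NJ tree with bootstrap, neighborhood
#' analysis, context flags) and writes all artifacts plus a
#' `report.json` into `config$out_dir`.  A stage failure aborts with
#' the stage name.  Reruns with an identical config are byte-identical
#' (the log file, which carries timings, is excluded from checksums).
#'
#' When planted truth is available, the report carries the adjusted
#' Rand index between network clusters and true protein families and
#' the precision/recall of the motif screen against true Cu-type
#' membership (ARI requires the mclust package).
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  cat(NULL, file = log_path)
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_line("stage=%s elapsed=%.2fs", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  report <- list(parameters = config[setdiff(names(config), "world")],
                 counts = list(), files = list(), skipped = character(0))
  report$parameters$world <- !is.null(config$world)

  ## input ------------------------------------------------------------------
  world <- run_stage("input", {
    if (!is.null(config$world)) {
      wc <- config$world
      wc$seed <- stage_seed(config$seed, "synthetic_data")
      w <- generate_world(wc)
      write_world(w, out)
      w
    } else {
      truth_path <- file.path(config$input_dir, "truth.json")
      list(proteins = read_fasta(file.path(config$input_dir, "proteins.faa")),
           features = read_feature_table(
             file.path(config$input_dir, "features.tsv")),
           taxonomy = read_taxonomy(
             file.path(config$input_dir, "taxonomy.tsv")),
           truth = if (file.exists(truth_path)) {
             jsonlite::read_json(truth_path)
           } else NULL)
    }
  })
  report$counts$proteins_in <- length(world$proteins)
  report$counts$genes_in <- nrow(world$features)

  clusters <- NULL; network <- NULL; members <- NULL
  cluster_msas <- list()

  ## network + clusters -----------------------------------------------------
  if ("network" %in% config$stages) {
    network <- run_stage("network", {
      build_network(world$proteins, threshold = config$threshold,
                    kmer_prefilter = config$kmer_prefilter)
    })
    clusters <- run_stage("clusters", extract_clusters(network))
    members <- cluster_proteins(network, clusters)
    write_edge_list(network, file.path(out, "network_edges.tsv"))
    node_attrs <- data.frame(node_id = names(network$nodes),
                             stringsAsFactors = FALSE)
    genome_of <- sub("_calT$", "", vapply(network$nodes, `[[`, character(1), 1))
    ti <- match(genome_of, world$taxonomy$species)
    node_attrs$taxonomy_class <- world$taxonomy$class[ti]
    node_attrs$cluster_id <- clusters$cluster_id[
      match(node_attrs$node_id, clusters$node_id)]
    cco <- cco_presence(world$features)
    ci <- match(genome_of, cco$genome_id)
    node_attrs$ccoN <- cco$ccoN[ci]
    node_attrs$ccoO <- cco$ccoO[ci]
    node_attrs$ccoP <- cco$ccoP[ci]
    write_network_graphml(network, file.path(out, "network.graphml"),
                          node_attrs)
    cl_tab <- data.frame(
      protein_id = unlist(members, use.names = FALSE),
      cluster_id = rep.int(as.integer(names(members)), lengths(members)))
    write.table(cl_tab, file.path(out, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$counts$nodes <- length(network$nodes)
    report$counts$edges <- nrow(network$edges)
    report$counts$clusters <- length(members)
  } else {
    report$skipped <- c(report$skipped, "network", "clusters")
  }

  ## motif screen -----------------------------------------------------------
  screen <- NULL
  if ("motif" %in% config$stages) {
    screen <- run_stage("motif_screen", {
      screen_cu_transporters(world$proteins, mode = config$mode)
    })
    write.table(screen, file.path(out, "cu_transporter_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    seqs <- as_seq_vector(world$proteins)
    topo_rows <- list(); hit_rows <- list()
    for (id in names(seqs)) {
      topo <- suppressWarnings(predict_tm_segments(seqs[[id]]))
      spans <- paste(sprintf("%d-%d", topo$segments$start,
                             topo$segments$end), collapse = ";")
      topo_rows[[id]] <- data.frame(protein_id = id,
                                    n_segments = topo$n_segments,
                                    segments = spans)
      hits <- scan_motifs(seqs[[id]], topo)
      if (nrow(hits)) hit_rows[[id]] <- cbind(protein_id = id, hits)
    }
    write.table(do.call(rbind, topo_rows), file.path(out, "tm_topology.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, hit_rows), file.path(out, "motif_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$counts$cu_candidates <- sum(screen$is_candidate)
  } else {
    report$skipped <- c(report$skipped, "motif_screen")
  }

  ## per-cluster MSA, quality filter, logos ---------------------------------
  if ("msa" %in% config$stages && !is.null(members)) {
    run_stage("msa_logo", {
      seqs <- as_seq_vector(world$proteins)
      for (cl in names(members)) {
        ids <- members[[cl]]
        if (length(ids) < 3) next
        msa <- center_star_align(seqs[ids])
        filtered <- tryCatch(
          filter_alignment(msa, min_quality = config$min_quality),
          error = function(e) NULL)
        quality_ok <- !is.null(filtered)
        # on divergent families the 0-1000 scale can empty an alignment
        # at a strict threshold; fall back to the gap filter alone
        if (!quality_ok) {
          filtered <- filter_alignment(msa, min_quality = 0)
        }
        write_msa_fasta(filtered, file.path(
          out, sprintf("cluster%s_alignment.faa", cl)))
        logo <- build_logo(filtered)
        write_logo_tsv(logo, file.path(out, sprintf("cluster%s_logo.tsv", cl)))
        cluster_msas[[cl]] <- list(msa = filtered, quality_ok = quality_ok)
      }
      invisible(NULL)
    })
    report$counts$clusters_aligned <- length(cluster_msas)
    report$counts$clusters_quality_filtered <-
      sum(vapply(cluster_msas, `[[`, logical(1), "quality_ok"))
  } else if ("msa" %in% config$stages) {
    report$skipped <- c(report$skipped, "msa_logo (needs network)")
  } else {
    report$skipped <- c(report$skipped, "msa_logo")
  }

  ## per-cluster trees with bootstrap ---------------------------------------
  if ("tree" %in% config$stages && length(cluster_msas)) {
    run_stage("tree", {
      for (cl in names(cluster_msas)) {
        msa <- cluster_msas[[cl]]$msa
        if (length(msa$rows) < 3) next
        tree <- bootstrap_support(
          msa, n_replicates = config$bootstrap_replicates,
          seed = stage_seed(config$seed, paste0("bootstrap_", cl)))
        write_tree_newick(tree, file.path(out, sprintf("cluster%s_tree.nwk",
                                                       cl)))
      }
      invisible(NULL)
    })
  } else if ("tree" %in% config$stages) {
    report$skipped <- c(report$skipped, "tree (needs msa)")
  } else {
    report$skipped <- c(report$skipped, "tree")
  }

  ## neighborhood analysis --------------------------------------------------
  if ("neighborhood" %in% config$stages) {
    run_stage("neighborhood", {
      focal <- world$features$gene_id[
        world$features$protein_id %in% names(world$proteins)]
      windows <- extract_windows(world$features, focal, k = config$window_k)
      counts <- count_taxon_conservation(windows, world$taxonomy)
      selected <- select_top_neighbors(counts, min_taxa = config$min_taxa,
                                       exclusions = config$exclusions)
      groups <- collapse_neighborhoods(selected, windows,
                                       min_cooccur = config$cooccur_min)
      flags <- flag_contexts(windows)
      cco <- cco_presence(world$features)
      write.table(counts, file.path(out, "neighbor_conservation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(selected, file.path(out, "neighbor_selection.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      grp_tab <- data.frame(
        group_id = rep.int(names(groups), lengths(groups)),
        domain_label = unlist(groups, use.names = FALSE))
      write.table(grp_tab, file.path(out, "neighborhood_groups.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(flags, file.path(out, "context_flags.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(cco, file.path(out, "cco_presence.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rep <- attr(selected, "report")
      report$counts$domains_counted <- nrow(counts)
      report$counts$domains_considered <- rep$n_considered
      report$counts$domains_above_threshold <- rep$n_above_threshold
      report$counts$domains_selected <- rep$n_selected
      report$counts$neighborhood_groups <- length(groups)
      invisible(NULL)
    })
  } else {
    report$skipped <- c(report$skipped, "neighborhood")
  }

  ## truth comparison -------------------------------------------------------
  if (!is.null(world$truth)) {
    metrics <- list()
    if (!is.null(members)) {
      fam <- unlist(world$truth$family_of_protein)
      pred <- rep.int(as.integer(names(members)), lengths(members))
      names(pred) <- unlist(members, use.names = FALSE)
      common <- intersect(names(fam), names(pred))
      if (requireNamespace("mclust", quietly = TRUE)) {
        metrics$cluster_ari <-
          mclust::adjustedRandIndex(fam[common], pred[common])
      }
    }
    if (!is.null(screen)) {
      cu_fams <- unlist(world$truth$cu_type_families)
      fam <- unlist(world$truth$family_of_protein)
      pos <- names(fam)[fam %in% cu_fams]
      called <- screen$protein_id[screen$is_candidate]
      tp <- length(intersect(called, pos))
      metrics$motif_precision <- if (length(called)) tp / length(called) else NA
      metrics$motif_recall <- if (length(pos)) tp / length(pos) else NA
    }
    report$truth_metrics <- metrics
  }

  ## checksums and report ----------------------------------------------------
  files <- setdiff(list.files(out),
                   c("pipeline.log", "report.json"))
  sums <- tools::md5sum(file.path(out, sort(files)))
  report$files <- as.list(setNames(unname(sums), sort(files)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
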