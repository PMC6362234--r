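# Synthetic pangenome generator with planted ground truth.  Worlds
# emulate the statistical structure the downstream analysis assumes:
# divergent protein families sharing (for Cu-type families) an MFS-like
# 12-transmembrane scaffold with MxxxM/HxxxM motifs planted in TM7/TM8,
# one focal calT-like gene per genome, and neighbor domain labels
# planted in the +-3-gene windows of controlled numbers of genera.

# Hydrophobic residues used inside planted TM segments, and the
# hydrophilic linker alphabet (no M or H, so planted motifs are the
# only M/H anchors outside mutational noise).
.tm_alphabet <- c("A", "I", "L", "M", "F", "V")
.linker_alphabet <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P")

#' Default neighbor plan
#'
#' Planted window-neighbor domains for the default world.  Labels echo
#' the domain families recurrent in CalT neighborhoods: a ribH-like
#' lumazine synthase (PF00885) co-occurring with a BamE-like factor
#' (PF04355), a FabG-like reductase (PF13561), an HMA Cu-chaperone
#' domain (PF00403), the large MFS_1 family (PF07690, later excluded),
#' two mid-frequency domains, and a CcoN-like oxidase subunit label
#' providing ccoNOQP context.  `group` names co-occurring sets; NA rows
#' are placed independently.  Three selectable domains sit at or above
#' the 30-genus selection threshold, PF07690 sits above it but is
#' excluded as a large family, two domains occupy the 3-29 band, and
#' window decoys are confined to at most two genera each.
#'
#' @return data.frame with columns `domain_label`, `n_genera`, `group`.
#' @export
default_neighbor_plan <- function() {
  data.frame(
    domain_label = c("PF00885", "PF04355", "PF13561", "PF00403",
                     "PF07690", "PF00730", "PF02230", "IPR004677"),
    n_genera = c(36L, 34L, 30L, 28L, 40L, 12L, 5L, 6L),
    group = c("grp_rbp", "grp_rbp", "grp_red", "grp_cu",
              NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Synthetic world configuration
#'
#' Defaults define the reference study conditions used throughout the
#' test-suite: 100 genomes over 2 orders x 5 families x 10 genera
#' (one species each), 5 protein families of 20 members at 0.2
#' within-family divergence, 3 of the 5 families Cu-type, and the
#' neighbor plan of [default_neighbor_plan()].
#'
#' @param seed Integer seed; the whole world derives from it.
#' @param n_orders,families_per_order,genera_per_family,species_per_genus
#'   Taxonomy shape (all >= 1); one genome per species.
#' @param n_protein_families Number of focal protein families.
#' @param within_family_divergence Per-site substitution probability
#'   from the family ancestor, in \[0, 1\].
#' @param cu_type_fraction Fraction of protein families carrying the
#'   12-TM scaffold with planted motifs.
#' @param neighbor_plan data.frame (`domain_label`, `n_genera`,
#'   `group`).
#' @param window_background_pool Decoy domain labels for filler genes.
#' @param genes_per_contig,contigs_per_genome Contig layout (the focal
#'   gene sits mid-contig unless `focal_edge_cases`).
#' @param tm_len,linker_len,n_tm Protein scaffold geometry (defaults
#'   give length 12*19 + 13*15 = 423, MFS scale).
#' @param cco_presence_fraction Fraction of genomes carrying the
#'   cbb3-oxidase subunit labels somewhere outside the focal window.
#' @param focal_edge_cases Place focal genes at contig edges.
#' @return A validated `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_orders = 2L, families_per_order = 5L,
                         genera_per_family = 10L, species_per_genus = 1L,
                         n_protein_families = 5L,
                         within_family_divergence = 0.2,
                         cu_type_fraction = 0.6,
                         neighbor_plan = default_neighbor_plan(),
                         window_background_pool = sprintf("PF99%03d", 1:20),
                         genes_per_contig = 11L, contigs_per_genome = 2L,
                         tm_len = 19L, linker_len = 15L, n_tm = 12L,
                         cco_presence_fraction = 0.8,
                         focal_edge_cases = FALSE) {
  cfg <- list(seed = as.integer(seed), n_orders = as.integer(n_orders),
              families_per_order = as.integer(families_per_order),
              genera_per_family = as.integer(genera_per_family),
              species_per_genus = as.integer(species_per_genus),
              n_protein_families = as.integer(n_protein_families),
              within_family_divergence = within_family_divergence,
              cu_type_fraction = cu_type_fraction,
              neighbor_plan = neighbor_plan,
              window_background_pool = window_background_pool,
              genes_per_contig = as.integer(genes_per_contig),
              contigs_per_genome = as.integer(contigs_per_genome),
              tm_len = as.integer(tm_len), linker_len = as.integer(linker_len),
              n_tm = as.integer(n_tm),
              cco_presence_fraction = cco_presence_fraction,
              focal_edge_cases = isTRUE(focal_edge_cases))
  counts <- c(cfg$n_orders, cfg$families_per_order, cfg$genera_per_family,
              cfg$species_per_genus, cfg$n_protein_families,
              cfg$genes_per_contig, cfg$contigs_per_genome)
  if (any(counts < 1L)) stop("all counts must be >= 1", call. = FALSE)
  if (within_family_divergence < 0 || within_family_divergence > 1) {
    stop("within_family_divergence must be in [0, 1]", call. = FALSE)
  }
  if (cu_type_fraction < 0 || cu_type_fraction > 1) {
    stop("cu_type_fraction must be in [0, 1]", call. = FALSE)
  }
  n_genera <- cfg$n_orders * cfg$families_per_order * cfg$genera_per_family
  if (nrow(neighbor_plan) &&
      any(neighbor_plan$n_genera > n_genera)) {
    stop(sprintf(
      "neighbor_plan requests more planted genera than exist (%d)", n_genera),
      call. = FALSE)
  }
  if (cfg$genes_per_contig < 7L) {
    stop("genes_per_contig must be >= 7 to host a full +-3 window",
         call. = FALSE)
  }
  structure(cfg, class = "world_config")
}

#' Substitute residues along a sequence
#'
#' Each unprotected site is substituted independently with probability
#' `divergence`; replacement residues are drawn uniformly from the
#' hydrophobic alphabet `{A,I,L,M,F,V}` inside planted TM segments and
#' from all 20 residues elsewhere (the draw may equal the original, so
#' at divergence 1 an expected 19/20 of all-residue sites differ).
#' Length is preserved; randomness comes from the R session RNG.
#'
#' @param parent Parent sequence (string).
#' @param divergence Per-site substitution probability in \[0, 1\].
#' @param protected Integer positions never substituted.
#' @param tm_positions Integer positions belonging to planted TM
#'   segments.
#' @return Mutated sequence (string).
#' @export
mutate_sequence <- function(parent, divergence, protected = integer(0),
                            tm_positions = integer(0)) {
  if (divergence < 0 || divergence > 1) {
    stop("divergence must be in [0, 1]", call. = FALSE)
  }
  chars <- strsplit(parent, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (length(protected) && (min(protected) < 1 || max(protected) > n)) {
    stop("protected positions outside parent", call. = FALSE)
  }
  hit <- stats::runif(n) < divergence
  hit[protected] <- FALSE
  in_tm <- seq_len(n) %in% tm_positions
  ntm <- sum(hit & in_tm)
  nother <- sum(hit & !in_tm)
  if (ntm) chars[hit & in_tm] <- sample(.tm_alphabet, ntm, replace = TRUE)
  if (nother) {
    chars[hit & !in_tm] <- sample(aa_alphabet(), nother, replace = TRUE)
  }
  paste(chars, collapse = "")
}

# Build one Cu-type ancestor: 13 hydrophilic linkers around 12
# hydrophobic TM segments; MxxxM planted mid-TM7, HxxxM mid-TM8
# (anchors at segment positions 8 and 12, inside the window-mean
# plateau of the hydropathy profile).  Each segment is resampled until
# its mean Kyte-Doolittle hydropathy — motif anchors included — reaches
# 2.5, and the whole ancestor is redrawn if hydropathy prediction does
# not recover the planted topology.  Returns the sequence plus segment
# spans, motif coordinates and the positions that stay
# protected/hydrophobic under mutation.
build_cu_ancestor <- function(tm_len, linker_len, n_tm) {
  kd <- kyte_doolittle()
  off <- 7L
  sample_tm <- function(anchors = NULL) {
    repeat {
      s <- sample(.tm_alphabet, tm_len, replace = TRUE)
      if (!is.null(anchors)) s[c(off + 1L, off + 5L)] <- anchors
      if (mean(kd[s]) >= 2.5) return(s)
    }
  }
  repeat {
    pieces <- character(0)
    seg <- data.frame(start = integer(n_tm), end = integer(n_tm))
    pos <- 0L
    for (k in seq_len(n_tm)) {
      pieces <- c(pieces, sample(.linker_alphabet, linker_len, replace = TRUE))
      pos <- pos + linker_len
      seg$start[k] <- pos + 1L
      anchors <- if (k == 7L) c("M", "M") else if (k == 8L) c("H", "M")
      pieces <- c(pieces, sample_tm(anchors))
      pos <- pos + tm_len
      seg$end[k] <- pos
    }
    pieces <- c(pieces, sample(.linker_alphabet, linker_len, replace = TRUE))
    sequence <- paste(pieces, collapse = "")
    m_start <- seg$start[7] + off
    h_start <- seg$start[8] + off
    topo <- predict_tm_segments(sequence)
    ok <- topo$n_segments == n_tm &&
      topo$segments$start[7] <= m_start &&
      topo$segments$end[7] >= m_start + 4L &&
      topo$segments$start[8] <= h_start &&
      topo$segments$end[8] >= h_start + 4L
    if (ok) {
      return(list(sequence = sequence, segments = seg,
                  m_start = m_start, h_start = h_start,
                  protected = c(m_start, m_start + 4L, h_start, h_start + 4L),
                  tm_positions = unlist(Map(seq, seg$start, seg$end))))
    }
  }
}

# Draw one Cu-type family member: substitutions per mutate_sequence(),
# but conditioned on the planted scaffold staying detectable — every
# planted segment keeps a mean hydropathy of at least 2.5, hydropathy
# prediction recovers exactly 12 segments, and the motif spans fall
# inside predicted segments 7 and 8.  This makes the generator's
# topology contract hold for every member, not just the ancestor.
draw_cu_member <- function(anc, divergence, max_tries = 1000L) {
  kd <- kyte_doolittle()
  seg <- anc$segments
  for (try in seq_len(max_tries)) {
    cand <- mutate_sequence(anc$sequence, divergence,
                            protected = anc$protected,
                            tm_positions = anc$tm_positions)
    chars <- strsplit(cand, "", fixed = TRUE)[[1]]
    means <- vapply(seq_len(nrow(seg)), function(k) {
      mean(kd[chars[seg$start[k]:seg$end[k]]])
    }, numeric(1))
    if (any(means < 2.5)) next
    topo <- predict_tm_segments(cand)
    if (topo$n_segments != nrow(seg)) next
    ok7 <- topo$segments$start[7] <= anc$m_start &&
      topo$segments$end[7] >= anc$m_start + 4L
    ok8 <- topo$segments$start[8] <= anc$h_start &&
      topo$segments$end[8] >= anc$h_start + 4L
    if (ok7 && ok8) return(cand)
  }
  stop("could not draw a valid Cu-type member; divergence too high?",
       call. = FALSE)
}

#' Generate a synthetic pangenome world
#'
#' Produces a taxonomy, per-genome gene feature tables, focal protein
#' sequences and a planted-truth record, all deterministically from
#' `config$seed` (identical configs are byte-identical on rerun).
#'
#' Guarantees: one focal calT-like gene per genome; Cu-type proteins
#' carry the 12-TM scaffold with motifs in segments 7/8, motif
#' positions protected at every divergence; each planned neighbor label
#' appears in the focal windows of exactly `n_genera` distinct genera;
#' labels sharing a plan `group` co-occur in the same windows while
#' distinct groups never share a window; decoy labels inside windows
#' are confined to at most 2 genera each.
#'
#' @param config A [world_config()].
#' @return List with `taxonomy`, `features`, `proteins`
#'   ([Biostrings::AAStringSet]) and `truth` (family labels, motif
#'   coordinates, TM spans, planted neighbor genera, planted groups,
#'   context flags, focal gene ids).
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  cfg <- config

  ## taxonomy -------------------------------------------------------------
  n_fam_tax <- cfg$n_orders * cfg$families_per_order
  n_gen <- n_fam_tax * cfg$genera_per_family
  n_sp <- n_gen * cfg$species_per_genus
  genus_ids <- sprintf("g%03d", seq_len(n_gen))
  taxonomy <- data.frame(
    species = sprintf("s%03d", seq_len(n_sp)),
    genus = rep(genus_ids, each = cfg$species_per_genus),
    family = rep(sprintf("f%02d", seq_len(n_fam_tax)),
                 each = cfg$genera_per_family * cfg$species_per_genus),
    order = rep(sprintf("o%02d", seq_len(cfg$n_orders)),
                each = cfg$families_per_order * cfg$genera_per_family *
                  cfg$species_per_genus),
    class = rep(sprintf("c%02d", seq_len(cfg$n_orders)),
                each = cfg$families_per_order * cfg$genera_per_family *
                  cfg$species_per_genus),
    stringsAsFactors = FALSE)
  genomes <- taxonomy$species
  genus_of <- setNames(taxonomy$genus, genomes)

  ## protein families ------------------------------------------------------
  npf <- cfg$n_protein_families
  if (n_sp < npf) stop("fewer genomes than protein families", call. = FALSE)
  fam_of_genome <- sort(rep_len(seq_len(npf), n_sp))
  n_cu <- round(cfg$cu_type_fraction * npf)
  cu_families <- seq_len(npf) <= n_cu
  total_len <- cfg$n_tm * cfg$tm_len + (cfg$n_tm + 1L) * cfg$linker_len

  ancestors <- vector("list", npf)
  for (f in seq_len(npf)) {
    if (cu_families[f]) {
      ancestors[[f]] <- build_cu_ancestor(cfg$tm_len, cfg$linker_len, cfg$n_tm)
    } else {
      ancestors[[f]] <- list(
        sequence = paste(sample(aa_alphabet(), total_len, replace = TRUE),
                         collapse = ""),
        segments = NULL, m_start = NA_integer_, h_start = NA_integer_,
        protected = integer(0), tm_positions = integer(0))
    }
  }

  protein_ids <- paste0(genomes, "_calT")
  proteins <- character(n_sp)
  for (i in seq_len(n_sp)) {
    f <- fam_of_genome[i]
    anc <- ancestors[[f]]
    if (cu_families[f]) {
      proteins[i] <- draw_cu_member(anc, cfg$within_family_divergence)
    } else {
      proteins[i] <- mutate_sequence(anc$sequence,
                                     cfg$within_family_divergence,
                                     protected = anc$protected,
                                     tm_positions = anc$tm_positions)
    }
  }
  names(proteins) <- protein_ids

  ## gene layout ------------------------------------------------------------
  G <- cfg$genes_per_contig
  focal_idx <- if (cfg$focal_edge_cases) 0L else G %/% 2L
  win_off <- setdiff(-3:3, 0)
  win_idx <- focal_idx + win_off
  win_idx <- win_idx[win_idx >= 0L & win_idx < G]

  ## neighbor planting -------------------------------------------------------
  plan <- cfg$neighbor_plan
  placements <- list()   # label -> character vector of genomes
  slot_labels <- list()  # genome -> labels to place in its window
  claimed <- setNames(rep(NA_character_, n_sp), genomes)  # genome -> group
  genomes_by_genus <- split(genomes, genus_of[genomes])

  if (nrow(plan)) {
    perm <- sample(genus_ids)
    named_groups <- unique(plan$group[!is.na(plan$group)])
    group_windows <- list()
    for (g in named_groups) {
      rows <- plan[!is.na(plan$group) & plan$group == g, , drop = FALSE]
      n_max <- max(rows$n_genera)
      wins <- character(0)
      for (gen in perm) {
        if (length(wins) >= n_max) break
        cand <- genomes_by_genus[[gen]]
        cand <- cand[is.na(claimed[cand])]
        if (!length(cand)) next
        pick <- sort(cand)[1]
        claimed[pick] <- g
        wins <- c(wins, pick)
      }
      if (length(wins) < n_max) {
        stop(sprintf(
          "cannot place group %s: need %d genera, only %d free windows",
          g, n_max, length(wins)), call. = FALSE)
      }
      group_windows[[g]] <- wins
      rows <- rows[order(-rows$n_genera, rows$domain_label), , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        tgt <- wins[seq_len(rows$n_genera[r])]
        lab <- rows$domain_label[r]
        placements[[lab]] <- tgt
        for (gm in tgt) slot_labels[[gm]] <- c(slot_labels[[gm]], lab)
      }
    }
    capacity <- length(win_idx)
    floating <- plan[is.na(plan$group), , drop = FALSE]
    for (r in seq_len(nrow(floating))) {
      lab <- floating$domain_label[r]
      need <- floating$n_genera[r]
      perm_f <- sample(genus_ids)
      tgt <- character(0)
      for (gen in perm_f) {
        if (length(tgt) >= need) break
        cand <- genomes_by_genus[[gen]]
        used <- vapply(cand, function(gm) {
          length(slot_labels[[gm]])
        }, integer(1))
        cand <- cand[used < capacity]
        if (!length(cand)) next
        pick <- sort(cand)[1]
        tgt <- c(tgt, pick)
        slot_labels[[pick]] <- c(slot_labels[[pick]], lab)
      }
      if (length(tgt) < need) {
        stop(sprintf("cannot place %s in %d distinct genera", lab, need),
             call. = FALSE)
      }
      placements[[lab]] <- tgt
    }
  }

  ## decoy restriction: each decoy label allowed in <= 2 genera
  pool <- cfg$window_background_pool
  decoy_genera <- lapply(seq_along(pool), function(i) sample(genus_ids, 2L))
  names(decoy_genera) <- pool
  decoys_by_genus <- lapply(setNames(genus_ids, genus_ids), function(g) {
    pool[vapply(decoy_genera, function(v) g %in% v, logical(1))]
  })

  ## assemble features -------------------------------------------------------
  feat <- vector("list", n_sp)
  cco_genomes <- character(0)
  ctx <- list()
  for (i in seq_len(n_sp)) {
    gm <- genomes[i]
    gen <- genus_of[[gm]]
    rows <- list()
    planted <- slot_labels[[gm]]
    if (is.null(planted)) planted <- character(0)
    if (length(planted) > length(win_idx)) {
      stop("window capacity exceeded for genome ", gm, call. = FALSE)
    }
    planted_at <- sample(win_idx, length(planted))
    plant_cco_here <- stats::runif(1) < cfg$cco_presence_fraction
    for (contig in seq_len(cfg$contigs_per_genome)) {
      for (idx in 0:(G - 1L)) {
        gene_id <- sprintf("%s_c%d_%02d", gm, contig, idx)
        labels <- character(0)
        protein <- ""
        if (contig == 1L && idx == focal_idx) {
          labels <- "CalT-like"
          protein <- protein_ids[i]
        } else if (contig == 1L && idx %in% planted_at) {
          labels <- planted[match(idx, planted_at)]
        } else if (contig == 1L && idx %in% win_idx) {
          avail <- decoys_by_genus[[gen]]
          nl <- sample(0:2, 1)
          if (nl > 0 && length(avail)) {
            labels <- sample(avail, min(nl, length(avail)))
          }
        } else if (plant_cco_here && contig == min(2L, cfg$contigs_per_genome) &&
                   contig != 1L && idx <= 2L) {
          labels <- c("IPR004677", "IPR003468", "IPR004678")[idx + 1L]
        } else {
          nl <- sample(0:2, 1)
          if (nl > 0) labels <- sample(pool, nl)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gm, contig_id = sprintf("%s_c%d", gm, contig),
          gene_index = idx, start = 1L + idx * 1200L, end = idx * 1200L + 1000L,
          strand = sample(c("+", "-"), 1), gene_id = gene_id,
          protein_id = protein,
          domain_labels = I(list(labels)), stringsAsFactors = FALSE)
      }
    }
    if (plant_cco_here && cfg$contigs_per_genome >= 2L) {
      cco_genomes <- c(cco_genomes, gm)
    }
    feat[[i]] <- do.call(rbind, rows)
    sets <- default_label_sets()
    ctx[[sprintf("%s_c1_%02d", gm, focal_idx)]] <- list(
      rbp = any(planted %in% sets$rbp),
      cu_homeostasis = any(planted %in% sets$cu_homeostasis),
      ccoNOQP = any(planted %in% sets$ccoNOQP))
  }
  features <- do.call(rbind, feat)
  rownames(features) <- NULL

  ## truth -------------------------------------------------------------------
  fam_labels <- sprintf("fam%02d", seq_len(npf))
  truth <- list(
    family_of_protein = setNames(fam_labels[fam_of_genome], protein_ids),
    cu_type_families = fam_labels[cu_families],
    motif_coords = setNames(lapply(seq_len(n_sp), function(i) {
      f <- fam_of_genome[i]
      if (cu_families[f]) {
        list(mxxxm_start = ancestors[[f]]$m_start,
             hxxxm_start = ancestors[[f]]$h_start)
      } else NULL
    }), protein_ids),
    tm_segments = setNames(lapply(seq_len(npf), function(f) {
      ancestors[[f]]$segments
    }), fam_labels),
    planted_neighbors = lapply(placements, function(gms) {
      sort(unique(unname(genus_of[gms])))
    }),
    planted_groups = if (nrow(plan)) {
      gs <- unique(plan$group[!is.na(plan$group)])
      setNames(lapply(gs, function(g) {
        sort(plan$domain_label[!is.na(plan$group) & plan$group == g])
      }), gs)
    } else list(),
    context_flags = ctx,
    focal_genes = setNames(sprintf("%s_c1_%02d", genomes, focal_idx), genomes),
    cco_genomes = sort(cco_genomes))

  list(taxonomy = taxonomy, features = features,
       proteins = Biostrings::AAStringSet(proteins), truth = truth)
}

#' Write a synthetic world to disk
#'
#' Writes `proteins.faa`, `features.tsv`, `taxonomy.tsv` and
#' `truth.json` into `dir`.
#'
#' @param world Result of [generate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$proteins, file.path(dir, "proteins.faa"))
  write_feature_table(world$features, file.path(dir, "features.tsv"))
  write_taxonomy(world$taxonomy, file.path(dir, "taxonomy.tsv"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(dir)
}
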