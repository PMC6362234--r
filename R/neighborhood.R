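# Gene-neighborhood conservation analysis: +-k gene windows around
# focal genes, distinct-taxon counts per domain label at the genus,
# family and order ranks, ranking/threshold/exclusion selection,
# co-occurrence collapsing into neighborhoods, and context flags.

#' Extract gene-index windows around focal genes
#'
#' Neighbors are the genes at gene-index offsets -k..-1 and +1..+k on
#' the focal gene's contig, truncated at contig edges.  Windows follow
#' gene order, not coordinates, and ignore strand.  A gene contributes
#' each of its domain labels; a gene with two or more labels also
#' contributes the fusion label (labels sorted, joined with `-`),
#' mirroring the "domains or domain fusions" convention.
#'
#' @param features Feature data.frame (see [read_feature_table()]).
#' @param focal_ids Gene ids of the focal genes; all must be present.
#' @param k Window half-width in genes (default 3).
#' @return data.frame with one row per window: `focal_gene_id`,
#'   `genome_id`, `n_neighbors`, and `labels`, a list-column with the
#'   multiset of neighbor domain labels (focal gene's own labels
#'   excluded).
#' @export
extract_windows <- function(features, focal_ids, k = 3L) {
  missing <- setdiff(focal_ids, features$gene_id)
  if (length(missing)) {
    stop("focal gene id(s) absent from features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fi <- match(focal_ids, features$gene_id)
  rows <- lapply(seq_along(focal_ids), function(t) {
    f <- features[fi[t], ]
    same <- features$genome_id == f$genome_id &
      features$contig_id == f$contig_id
    off <- features$gene_index - f$gene_index
    nb <- features[same & off != 0L & abs(off) <= k, , drop = FALSE]
    labs <- unlist(lapply(nb$domain_labels, gene_labels), use.names = FALSE)
    data.frame(focal_gene_id = f$gene_id, genome_id = f$genome_id,
               n_neighbors = nrow(nb),
               labels = I(list(if (is.null(labs)) character(0) else labs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Labels contributed by one gene: each label, plus the sorted fusion
# label when the gene carries more than one.
gene_labels <- function(labels) {
  labels <- sort(unique(labels))
  if (length(labels) >= 2) c(labels, paste(labels, collapse = "-"))
  else labels
}

#' Count distinct-taxon conservation per domain label
#'
#' For every domain label seen in any window, counts the number of
#' DISTINCT taxa at the genus, family and order ranks whose windows
#' contain it (presence per taxon: a genus counts once no matter how
#' many of its genomes or genes show the label), plus the number of
#' windows containing it.
#'
#' @param windows Windows from [extract_windows()].
#' @param taxonomy Taxonomy data.frame (species = genome id).
#' @return data.frame with columns `domain_label`, `n_genera`,
#'   `n_families`, `n_orders`, `n_windows`, sorted by decreasing
#'   `n_genera` then label.
#' @export
count_taxon_conservation <- function(windows, taxonomy) {
  ti <- match(windows$genome_id, taxonomy$species)
  if (anyNA(ti)) {
    stop("genome(s) missing from taxonomy: ",
         paste(unique(windows$genome_id[is.na(ti)]), collapse = ", "),
         call. = FALSE)
  }
  nlab <- lengths(lapply(windows$labels, unique))
  if (sum(nlab) == 0) {
    return(data.frame(domain_label = character(0), n_genera = integer(0),
                      n_families = integer(0), n_orders = integer(0),
                      n_windows = integer(0)))
  }
  long <- data.frame(
    domain_label = unlist(lapply(windows$labels, unique), use.names = FALSE),
    genus = rep(taxonomy$genus[ti], nlab),
    family = rep(taxonomy$family[ti], nlab),
    order = rep(taxonomy$order[ti], nlab),
    window = rep(seq_len(nrow(windows)), nlab),
    stringsAsFactors = FALSE)
  agg <- function(col) {
    tapply(long[[col]], long$domain_label, function(v) length(unique(v)))
  }
  g <- agg("genus"); f <- agg("family"); o <- agg("order"); w <- agg("window")
  out <- data.frame(domain_label = names(g), n_genera = as.integer(g),
                    n_families = as.integer(f[names(g)]),
                    n_orders = as.integer(o[names(g)]),
                    n_windows = as.integer(w[names(g)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_genera, out$domain_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top conserved neighbors
#'
#' Domains seen in fewer than two genera are never considered.  The
#' remainder are ranked by the distinct-taxon count at `rank`
#' (descending, ties by label), thresholded at `min_taxa`, and the
#' exclusion list (large multi-functional transporter families such as
#' PF07690/PF00005, plus any configured transcription-factor labels) is
#' removed.  `exclude_first` applies the exclusion list before the
#' threshold instead of after; both orders give the same selected set,
#' but the before/after counts in the report differ.
#'
#' @param counts Conservation table from [count_taxon_conservation()].
#' @param min_taxa Minimum distinct-taxon count (default 30).
#' @param rank `"genus"`, `"family"` or `"order"`.
#' @param exclusions Character vector of excluded labels.
#' @param exclude_first Apply exclusions before the threshold.
#' @return data.frame of selected rows (ranked), with attribute
#'   `"report"`: counts of domains considered (>= 2 genera), above the
#'   threshold, and remaining after exclusion.
#' @export
select_top_neighbors <- function(counts, min_taxa = 30,
                                 rank = c("genus", "family", "order"),
                                 exclusions = c("PF07690", "PF00005"),
                                 exclude_first = FALSE) {
  rank <- match.arg(rank)
  col <- c(genus = "n_genera", family = "n_families", order = "n_orders")[rank]
  pool <- counts[counts$n_genera >= 2, , drop = FALSE]
  n_considered <- nrow(pool)
  if (exclude_first) {
    pool <- pool[!pool$domain_label %in% exclusions, , drop = FALSE]
    above <- pool[pool[[col]] >= min_taxa, , drop = FALSE]
    selected <- above
    n_above <- nrow(above)
  } else {
    above <- pool[pool[[col]] >= min_taxa, , drop = FALSE]
    n_above <- nrow(above)
    selected <- above[!above$domain_label %in% exclusions, , drop = FALSE]
  }
  selected <- selected[order(-selected[[col]], selected$domain_label), ,
                       drop = FALSE]
  rownames(selected) <- NULL
  attr(selected, "report") <- list(rank = rank, min_taxa = min_taxa,
                                   n_considered = n_considered,
                                   n_above_threshold = n_above,
                                   n_selected = nrow(selected))
  selected
}

#' Collapse selected neighbors into neighborhoods
#'
#' Builds a co-occurrence graph on the selected domain labels (edge
#' when two labels co-occur in at least `min_cooccur` windows) and
#' reports its connected components as neighborhood groups N1, N2, ...
#' in decreasing summed conservation (sum of members' genus counts,
#' ties by smallest member label).
#'
#' @param selected Selection from [select_top_neighbors()].
#' @param windows Windows from [extract_windows()].
#' @param min_cooccur Minimum co-occurrence count for an edge
#'   (default 2).
#' @return Named list mapping group id (`"N1"`, ...) to sorted member
#'   labels.
#' @export
collapse_neighborhoods <- function(selected, windows, min_cooccur = 2L) {
  labs <- selected$domain_label
  if (!length(labs)) return(setNames(list(), character(0)))
  present <- lapply(windows$labels, function(v) intersect(labs, unique(v)))
  co <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (v in present) {
    if (length(v) >= 2) {
      idx <- match(v, labs)
      co[idx, idx] <- co[idx, idx] + 1L
    }
  }
  diag(co) <- 0L
  g <- igraph::graph_from_adjacency_matrix(co >= min_cooccur,
                                           mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(labs, comp$membership[labs])
  cons <- setNames(selected$n_genera, selected$domain_label)
  score <- vapply(groups, function(v) sum(cons[v]), numeric(1))
  first <- vapply(groups, function(v) min(v), character(1))
  groups <- groups[order(-score, first)]
  groups <- lapply(groups, sort)
  names(groups) <- paste0("N", seq_along(groups))
  groups
}

# Default label sets for context flagging: riboflavin-biosynthesis
# context (ribH-like lumazine synthase), Cu-homeostasis genes, and the
# cbb3-oxidase structural/biogenesis cassette (InterPro-style labels for
# CcoN, CcoO and CcoP).
default_label_sets <- function() {
  list(
    rbp = c("PF00885", "ribH"),
    cu_homeostasis = c("PF00403", "HMA", "copA", "csoR", "cueR", "mco"),
    ccoNOQP = c("ccoN", "ccoO", "ccoQ", "ccoP",
                "IPR004677", "IPR003468", "IPR004678", "IPR032858"))
}

#' Flag genomic contexts of focal genes
#'
#' Per focal gene, one boolean per configured label set: whether any
#' window label belongs to the set.  Defaults cover the riboflavin
#' biosynthesis context (`rbp`), Cu homeostasis genes
#' (`cu_homeostasis`: HMA/PF00403, copA, csoR, cueR, mco) and the
#' cbb3-oxidase cassette (`ccoNOQP`).
#'
#' @param windows Windows from [extract_windows()].
#' @param label_sets Named list of character vectors; defaults as above.
#' @return data.frame with `focal_gene_id`, `genome_id` and one logical
#'   column per label set.
#' @export
flag_contexts <- function(windows, label_sets = default_label_sets()) {
  if (is.null(names(label_sets)) || any(!nzchar(names(label_sets)))) {
    stop("label_sets must be a named list", call. = FALSE)
  }
  out <- windows[, c("focal_gene_id", "genome_id")]
  for (set in names(label_sets)) {
    out[[set]] <- vapply(windows$labels, function(v) {
      any(v %in% label_sets[[set]])
    }, logical(1))
  }
  rownames(out) <- NULL
  out
}

#' Per-genome presence of cbb3-oxidase subunit labels
#'
#' Scans whole genomes (all genes, not just windows) for the
#' InterPro-style subunit labels of the three largest cbb3-type
#' cytochrome c oxidase subunits: CcoN (IPR004677), CcoO (IPR003468)
#' and CcoP (IPR004678 or IPR032858).
#'
#' @param features Feature data.frame.
#' @return data.frame with `genome_id`, `ccoN`, `ccoO`, `ccoP` logical
#'   columns.
#' @export
cco_presence <- function(features) {
  genomes <- unique(features$genome_id)
  sets <- list(ccoN = "IPR004677", ccoO = "IPR003468",
               ccoP = c("IPR004678", "IPR032858"))
  out <- data.frame(genome_id = genomes, stringsAsFactors = FALSE)
  labs_by_genome <- tapply(features$domain_labels, features$genome_id,
                           function(l) unique(unlist(l, use.names = FALSE)))
  for (s in names(sets)) {
    out[[s]] <- vapply(genomes, function(g) {
      any(labs_by_genome[[g]] %in% sets[[s]])
    }, logical(1))
  }
  rownames(out) <- NULL
  out
}
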