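# Readers and writers for the plain-text formats the pipeline touches:
# FASTA protein sets, tab-separated feature and taxonomy tables, network
# edge lists, GraphML and Newick.  Tables are tab-separated UTF-8 with
# '#' comment lines; coordinates are 1-based inclusive both in files and
# internally.

#' Read a protein FASTA file
#'
#' Sequences are uppercased and trailing stop characters (`*`) stripped.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::AAStringSet] named by record id (the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(gsub("\\*", "", as.character(set)))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a protein FASTA file
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70L) {
  seqs <- as_seq_vector(proteins)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.feature_cols <- c("genome_id", "contig_id", "gene_index", "start", "end",
                   "strand", "gene_id", "protein_id", "domain_labels")

#' Read a gene feature table
#'
#' Expects a tab-separated file with header columns `genome_id`,
#' `contig_id`, `gene_index` (0-based position in contig gene order),
#' `start`, `end` (1-based inclusive), `strand` (`+`/`-`), `gene_id`,
#' `protein_id` (may be empty) and `domain_labels` (`;`-joined accession
#' labels, empties dropped).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per gene; `domain_labels` is a
#'   list-column of character vectors.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(.feature_cols, names(df))
  if (length(missing)) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, .feature_cols]
  df$gene_index <- as.integer(df$gene_index)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad)) {
    stop("unknown strand symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$start > df$end)) stop("feature with start > end", call. = FALSE)
  key <- paste(df$genome_id, df$contig_id, df$gene_index)
  if (anyDuplicated(key)) {
    stop("duplicate gene_index within a contig", call. = FALSE)
  }
  df$domain_labels <- split_labels(df$domain_labels)
  df
}

split_labels <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}

#' Write a gene feature table
#'
#' @param features Feature data.frame as returned by
#'   [read_feature_table()] (the `domain_labels` list-column is joined
#'   with `;`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features[, setdiff(.feature_cols, "domain_labels")]
  out$domain_labels <- vapply(features$domain_labels, paste,
                              character(1), collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.taxonomy_cols <- c("species", "genus", "family", "order", "class")

#' Read a taxonomy table
#'
#' Tab-separated, one row per species, columns `species`, `genus`,
#' `family`, `order`, `class`.  Species must be unique and no rank value
#' may be empty.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of taxonomy records.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(.taxonomy_cols, names(df))
  if (length(missing)) {
    stop("taxonomy table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, .taxonomy_cols]
  if (any(!nzchar(as.matrix(df))) || anyNA(df)) {
    stop("taxonomy table contains empty rank values", call. = FALSE)
  }
  if (anyDuplicated(df$species)) {
    stop("duplicate species in taxonomy table", call. = FALSE)
  }
  df
}

#' Write a taxonomy table
#' @param taxonomy Taxonomy data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy[, .taxonomy_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a network edge list
#'
#' Tab-separated columns `node_a`, `node_b`, `alignment_score`.
#'
#' @param network A `seq_network` object (see [build_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges[, c("node_a", "node_b", "alignment_score")]
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a similarity network as GraphML
#'
#' Node attributes (taxonomy class, cluster id, cco presence flags,
#' member count, ...) can be supplied as a data.frame keyed by `node_id`
#' and are exported so that downstream viewers can color nodes the same
#' way the network figures of the source analyses do.
#'
#' @param network A `seq_network` object.
#' @param path Output path.
#' @param node_attrs Optional data.frame with a `node_id` column plus
#'   attribute columns (logicals are exported as 0/1 integers).
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, node_attrs = NULL) {
  g <- network_igraph(network)
  if (!is.null(node_attrs)) {
    stopifnot("node_id" %in% names(node_attrs))
    ix <- match(igraph::V(g)$name, node_attrs$node_id)
    for (col in setdiff(names(node_attrs), "node_id")) {
      v <- node_attrs[[col]][ix]
      if (is.logical(v)) v <- as.integer(v)
      g <- igraph::set_vertex_attr(g, col, value = v)
    }
  }
  g <- igraph::set_vertex_attr(g, "member_count",
                               value = lengths(network$nodes)[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Bootstrap supports, when present as node labels, are written as
#' internal node labels.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}
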