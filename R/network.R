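# Protein sequence similarity network: Smith-Waterman local scoring,
# conversion of raw scores to -log10 E-value "alignment scores", network
# construction at a threshold, and connected-component clusters.

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under affine gap costs, where a gap of
#' length k costs `gap_open + k * gap_extend`.
#'
#' @param a,b Protein sequences (character strings over the 20-residue
#'   alphabet; lowercase accepted).
#' @param matrix Substitution matrix with residue dimnames
#'   (default BLOSUM62).
#' @param gap_open,gap_extend Non-negative penalties with
#'   `gap_open >= gap_extend`.
#' @return Non-negative numeric score; symmetric in `a` and `b`.
#' @export
smith_waterman_score <- function(a, b, matrix = blosum62(),
                                 gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0,
            gap_open >= gap_extend, gap_extend >= 0)
  sub <- align_matrix(matrix)
  .sw_score_c(encode_seq(a, "sequence a"), encode_seq(b, "sequence b"),
              sub, gap_open, gap_extend)
}

# Reorder an arbitrary residue-named substitution matrix onto the
# aa_alphabet() order expected by the C kernels.
align_matrix <- function(matrix) {
  ab <- aa_alphabet()
  if (is.null(dimnames(matrix)) || !all(ab %in% rownames(matrix))) {
    stop("substitution matrix must have dimnames covering the 20 residues",
         call. = FALSE)
  }
  storage.mode(matrix) <- "double"
  matrix[ab, ab]
}

#' Convert a raw local-alignment score to an alignment score
#'
#' The network edge weight follows the EFI-EST convention: the
#' Karlin-Altschul expected value of the local alignment,
#' `E = K * len_a * len_b * exp(-lambda * raw_score)`, is converted to
#' `-log10(E)`.  The default constants are the standard gapped BLOSUM62
#' parameterisation (lambda = 0.267, K = 0.041); both are configurable
#' because the network threshold is expressed on this scale.
#'
#' @param raw_score Non-negative Smith-Waterman score(s).
#' @param len_a,len_b Sequence lengths (> 0).
#' @param lambda,K Karlin-Altschul constants.
#' @return Alignment score(s), strictly increasing in `raw_score`.
#' @export
to_alignment_score <- function(raw_score, len_a, len_b,
                               lambda = 0.267, K = 0.041) {
  stopifnot(all(raw_score >= 0))
  if (any(len_a <= 0) || any(len_b <= 0)) {
    stop("sequence lengths must be positive", call. = FALSE)
  }
  (lambda * raw_score - log(K * len_a * len_b)) / log(10)
}

#' Build a protein similarity network
#'
#' All-against-all Smith-Waterman scoring, conversion to alignment
#' scores, and thresholding.  Identical sequences (100% identity, equal
#' length) are collapsed into one representative node when
#' `merge_identical` is on, so a node represents one or more proteins.
#' Every protein belongs to exactly one node; proteins without an edge at
#' the threshold remain as singleton nodes unless `drop_singletons`.
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @param threshold Minimum alignment score for an edge (default 75).
#' @param merge_identical Collapse identical sequences into one node.
#' @param drop_singletons Remove nodes with no retained edge (reporting
#'   filter; off by default).
#' @param kmer_prefilter Skip pairs sharing no 4-mer.  Candidate edges
#'   must be unaffected: any pair reaching the threshold shares many
#'   exact words, so the prefilter only prunes hopeless pairs.
#' @param matrix,gap_open,gap_extend,lambda,K Scoring parameters, see
#'   [smith_waterman_score()] and [to_alignment_score()].
#' @return A `seq_network` object: list with `nodes` (named list mapping
#'   node id to member protein ids), `edges` (data.frame `node_a`,
#'   `node_b`, `raw_score`, `alignment_score` with `node_a < node_b`),
#'   and `threshold`.
#' @export
build_network <- function(proteins, threshold = 75, merge_identical = TRUE,
                          drop_singletons = FALSE, kmer_prefilter = FALSE,
                          matrix = blosum62(), gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041) {
  seqs <- as_seq_vector(proteins)
  if (length(seqs) < 1) stop("need at least one protein", call. = FALSE)
  if (anyDuplicated(names(seqs))) stop("duplicate protein ids", call. = FALSE)

  if (merge_identical) {
    grp <- split(names(seqs), factor(seqs, levels = unique(seqs)))
    nodes <- lapply(unname(grp), function(m) sort(m))
    names(nodes) <- vapply(nodes, `[[`, character(1), 1L)
  } else {
    nodes <- as.list(names(seqs))
    names(nodes) <- names(seqs)
  }
  # deterministic node order
  nodes <- nodes[order(names(nodes))]
  rep_seq <- seqs[names(nodes)]

  n <- length(nodes)
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      raw_score = numeric(0), alignment_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (n >= 2) {
    pairs <- t(utils::combn(n, 2L))
    if (kmer_prefilter) {
      shared <- shared_kmer_counts(rep_seq, k = 4L)
      keep <- shared[pairs] >= 1L
      pairs <- pairs[keep, , drop = FALSE]
    }
    if (nrow(pairs)) {
      enc <- lapply(rep_seq, encode_seq)
      sub <- align_matrix(matrix)
      raw <- .sw_score_pairs_c(enc, pairs, sub, gap_open, gap_extend)
      la <- nchar(rep_seq)[pairs[, 1]]
      lb <- nchar(rep_seq)[pairs[, 2]]
      as <- to_alignment_score(raw, la, lb, lambda = lambda, K = K)
      keep <- as >= threshold
      if (any(keep)) {
        ida <- names(nodes)[pairs[keep, 1]]
        idb <- names(nodes)[pairs[keep, 2]]
        swap <- ida > idb
        tmp <- ida[swap]; ida[swap] <- idb[swap]; idb[swap] <- tmp
        edges <- data.frame(node_a = ida, node_b = idb,
                            raw_score = raw[keep],
                            alignment_score = as[keep],
                            stringsAsFactors = FALSE)
        edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
        rownames(edges) <- NULL
      }
    }
  }
  if (drop_singletons) {
    connected <- union(edges$node_a, edges$node_b)
    nodes <- nodes[names(nodes) %in% connected]
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "seq_network")
}

seq_kmers <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# n x n matrix of distinct shared k-mer counts, via a 0/1 incidence
# matrix over the union of observed k-mers.
shared_kmer_counts <- function(seqs, k = 4L) {
  kms <- lapply(seqs, seq_kmers, k = k)
  all_k <- unique(unlist(kms, use.names = FALSE))
  inc <- matrix(0, nrow = length(seqs), ncol = length(all_k))
  for (i in seq_along(kms)) inc[i, match(kms[[i]], all_k)] <- 1
  tcrossprod(inc)
}

#' @export
print.seq_network <- function(x, ...) {
  cat(sprintf(
    "seq_network: %d nodes (%d proteins), %d edges at alignment score >= %s\n",
    length(x$nodes), sum(lengths(x$nodes)), nrow(x$edges),
    format(x$threshold)))
  invisible(x)
}

# igraph view of a seq_network (all nodes, retained edges).
network_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes),
                            name = names(network$nodes))
  if (nrow(network$edges)) {
    el <- rbind(network$edges$node_a, network$edges$node_b)
    g <- igraph::add_edges(g, as.vector(el),
                           alignment_score = network$edges$alignment_score)
  }
  g
}

#' Extract network clusters (connected components)
#'
#' Connected components of the thresholded network, numbered 1..K in
#' decreasing member-protein count; ties broken by the lexicographically
#' smallest member protein id.
#'
#' @param network A `seq_network` object.
#' @return data.frame with columns `node_id` and `cluster_id`, plus an
#'   attribute `"clusters"`: a list mapping cluster id to member node
#'   ids.
#' @export
extract_clusters <- function(network) {
  g <- network_igraph(network)
  comp <- igraph::components(g)
  comp_of <- comp$membership  # named by node id
  groups <- split(names(comp_of), comp_of)
  sizes <- vapply(groups, function(ns) sum(lengths(network$nodes[ns])),
                  numeric(1))
  min_member <- vapply(groups, function(ns) {
    min(unlist(network$nodes[ns], use.names = FALSE))
  }, character(1))
  ord <- order(-sizes, min_member)
  groups <- groups[ord]
  names(groups) <- seq_along(groups)
  df <- data.frame(
    node_id = unlist(groups, use.names = FALSE),
    cluster_id = rep.int(as.integer(names(groups)), lengths(groups)),
    stringsAsFactors = FALSE)
  df <- df[order(df$cluster_id, df$node_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "clusters") <- lapply(groups, sort)
  df
}

#' Map clusters to member proteins
#'
#' @param network A `seq_network` object.
#' @param clusters Result of [extract_clusters()].
#' @return Named list: cluster id (character) to sorted member protein
#'   ids.
#' @export
cluster_proteins <- function(network, clusters) {
  cl <- attr(clusters, "clusters")
  lapply(cl, function(ns) sort(unlist(network$nodes[ns], use.names = FALSE)))
}
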