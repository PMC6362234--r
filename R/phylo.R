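# Distance-based phylogeny: p-distance matrices, Saitou-Nei neighbor
# joining with deterministic tie-breaks, bootstrap supports over
# resampled alignment columns, and placement of additional sequences
# into network clusters by alignment distance.

#' p-distance matrix from an alignment
#'
#' `d(i, j)` is the fraction of differing residues over columns where
#' neither row has a gap.  A pair with no mutually gap-free column is an
#' error.
#'
#' @param msa An `msa` object.
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\], dimnames = row ids.
#' @export
protein_distance_matrix <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  ids <- msa$ids
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0) {
        stop(sprintf("no comparable columns between %s and %s",
                     ids[i], ids[j]), call. = FALSE)
      }
      d <- sum(m[i, ok] != m[j, ok]) / nc
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix.  Ties in
#' the Q criterion are broken deterministically by the lexicographically
#' smallest pair of node labels (a node is labelled by the smallest leaf
#' id in its subtree).  Negative branch lengths are clamped to zero with
#' the deficit moved to the sister branch, conserving path lengths.
#'
#' @param D Symmetric distance matrix with id dimnames, >= 3 ids.
#' @return An unrooted [ape::phylo] tree.
#' @export
build_nj_tree <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  ids <- rownames(D)
  n <- length(ids)
  if (n < 3) stop("need at least 3 ids", call. = FALSE)
  D <- unname(D)
  labels <- ids           # smallest leaf id per active node
  nwk <- ids              # newick fragment per active node
  fmt <- function(x) sprintf("%.12g", x)

  while (length(labels) > 3) {
    N <- length(labels)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- min(Q)
    cand <- which(Q - best <= 1e-12 * max(1, abs(best)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      lab <- sort(c(labels[ij[1]], labels[ij[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj))
    new_lab <- min(labels[i], labels[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    labels <- c(labels[keep], new_lab)
    nwk <- c(nwk[keep], new_nwk)
  }
  # final trifurcation
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  v1 <- max((d12 + d13 - d23) / 2, 0)
  v2 <- max((d12 + d23 - d13) / 2, 0)
  v3 <- max((d13 + d23 - d12) / 2, 0)
  ord <- order(labels)
  b <- c(v1, v2, v3)[ord]
  s <- nwk[ord]
  text <- sprintf("(%s:%s,%s:%s,%s:%s);", s[1], fmt(b[1]),
                  s[2], fmt(b[2]), s[3], fmt(b[3]))
  ape::read.tree(text = text)
}

# Canonical keys for the non-trivial bipartitions of a tree: each
# internal edge splits the leaves in two; the side not containing the
# alphabetically smallest leaf, sorted and joined, identifies the split
# independent of rooting and tip order.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- min(tips)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_replicates`
#' times; an NJ tree is built per replicate and the support of each
#' internal edge of the original tree is the percentage of replicate
#' trees containing the same leaf bipartition.  Fully seeded and
#' reproducible.
#'
#' @param msa An `msa` object with >= 3 rows.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The NJ tree of the full alignment with `node.label` set to
#'   the support (0-100) of each internal edge (empty for the root and
#'   trivial splits).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(msa$rows) < 3) stop("need >= 3 rows", call. = FALSE)
  tree <- build_nj_tree(protein_distance_matrix(msa))
  keys <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(keys)), keys)
  m <- msa_matrix(msa)
  L <- ncol(m)
  set.seed(seed)
  for (rep in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_rows <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    names(rep_rows) <- names(msa$rows)
    rep_msa <- msa_from_rows(rep_rows)
    D <- tryCatch(protein_distance_matrix(rep_msa), error = function(e) NULL)
    if (is.null(D)) next  # a pair lost all comparable columns
    rk <- tree_bipartitions(build_nj_tree(D))
    hit <- intersect(rk, keys)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_replicates
  # attach supports as internal node labels
  tips <- tree$tip.label
  anchor <- min(tips)
  parts <- ape::prop.part(tree)
  labs <- character(length(parts))
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2) {
      labs[k] <- sprintf("%g", support[[paste(sort(side), collapse = "|")]])
    }
  }
  tree$node.label <- labs
  attr(tree, "support") <- support
  tree
}

#' Place additional sequences into network clusters
#'
#' Each extra sequence is merged into the alignment by a global
#' alignment to the alignment's center sequence (center-star extension;
#' residues inserted relative to the center fall outside shared columns
#' and do not contribute), then assigned to the cluster minimising the
#' mean p-distance to the cluster's member rows.  Ties go to the
#' smaller cluster id; the margin to the runner-up cluster is reported.
#'
#' @param extra Named character vector or `AAStringSet` of new
#'   sequences; ids must not collide with alignment row ids.
#' @param cluster_members Named list mapping cluster id to member
#'   protein ids (see [cluster_proteins()]); members absent from the
#'   alignment are ignored.
#' @param msa An `msa` object whose row ids are protein ids.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return data.frame with one row per extra sequence: `extra_id`,
#'   `cluster_id`, `mean_distance`, `runner_up`, `margin`.
#' @export
place_external_sequences <- function(extra, cluster_members, msa,
                                     matrix = blosum62(),
                                     gap_open = 11, gap_extend = 1) {
  seqs <- as_seq_vector(extra)
  clash <- intersect(names(seqs), msa$ids)
  if (length(clash)) {
    stop("extra id(s) already present in alignment: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  center_id <- if (!is.null(msa$center_id) && msa$center_id %in% msa$ids) {
    msa$center_id
  } else msa$ids[1]
  center_row <- strsplit(msa$rows[[center_id]], "")[[1]]
  center_cols <- which(center_row != "-")
  center_seq <- paste(center_row[center_cols], collapse = "")
  sub <- align_matrix(matrix)
  cen_enc <- encode_seq(center_seq)
  m <- msa_matrix(msa)
  gap <- m == "-"

  rows <- lapply(names(seqs), function(id) {
    al <- .nw_align_c(cen_enc, encode_seq(seqs[[id]]), sub,
                      gap_open, gap_extend)
    ext <- rep("-", ncol(m))
    chars <- strsplit(seqs[[id]], "")[[1]]
    for (col in seq_along(al$a)) {
      if (al$a[col] > 0L && al$b[col] > 0L) {
        ext[center_cols[al$a[col]]] <- chars[al$b[col]]
      }
    }
    ext_gap <- ext == "-"
    # mean p-distance to each cluster
    cl_ids <- names(cluster_members)
    means <- vapply(cl_ids, function(cl) {
      members <- intersect(cluster_members[[cl]], msa$ids)
      if (!length(members)) return(Inf)
      ds <- vapply(members, function(mid) {
        ri <- match(mid, msa$ids)
        ok <- !gap[ri, ] & !ext_gap
        if (!sum(ok)) return(NA_real_)
        sum(m[ri, ok] != ext[ok]) / sum(ok)
      }, numeric(1))
      mean(ds, na.rm = TRUE)
    }, numeric(1))
    ord <- order(means, suppressWarnings(as.numeric(cl_ids)), cl_ids)
    best <- ord[1]
    runner <- if (length(ord) > 1) ord[2] else NA_integer_
    data.frame(extra_id = id, cluster_id = cl_ids[best],
               mean_distance = means[best],
               runner_up = if (is.na(runner)) NA_character_ else cl_ids[runner],
               margin = if (is.na(runner)) NA_real_ else
                 means[runner] - means[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
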