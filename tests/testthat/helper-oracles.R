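# Independent oracles and shared fixtures.  Oracles are deliberately
# plain re-derivations (full-matrix R dynamic programming, queue-based
# BFS, nested-loop recounts) kept separate from the package's code
# paths.

# Brute-force affine-gap Smith-Waterman in R: full three-matrix DP,
# gap of length k costs go + k * ge.
sw_dp_oracle <- function(a, b, mat = blosum62(), go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Queue-based BFS connected components over an edge list.
bfs_components <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges$node_a[k]; b <- edges$node_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (s in nodes) {
    if (!is.na(comp[[s]])) next
    cid <- cid + 1L
    queue <- s
    comp[[s]] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[[w]])) { comp[[w]] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# Minimal seq_network object for cluster-extraction tests.
make_network <- function(nodes, edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        raw_score = numeric(0), alignment_score = numeric(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = setNames(as.list(nodes), nodes), edges = edges,
                 threshold = 75), class = "seq_network")
}

# Nested-loop recount: distinct taxa at a rank whose windows contain a
# label (presence per taxon).
recount_taxa <- function(windows, taxonomy, label, rank) {
  taxa <- character(0)
  for (i in seq_len(nrow(windows))) {
    if (label %in% windows$labels[[i]]) {
      t <- taxonomy[[rank]][taxonomy$species == windows$genome_id[i]]
      taxa <- union(taxa, t)
    }
  }
  length(taxa)
}

# Shared expensive fixtures, built once per test run.
.fixtures <- new.env()

default_world <- function() {
  if (is.null(.fixtures$world)) {
    .fixtures$world <- generate_world(world_config(seed = 1))
  }
  .fixtures$world
}

default_network <- function() {
  if (is.null(.fixtures$network)) {
    .fixtures$network <- build_network(default_world()$proteins,
                                       threshold = 75, kmer_prefilter = TRUE)
  }
  .fixtures$network
}

default_screen <- function() {
  if (is.null(.fixtures$screen)) {
    .fixtures$screen <- screen_cu_transporters(default_world()$proteins)
  }
  .fixtures$screen
}

# Named plain-character sequences for a subset of a world's proteins.
as_msa_input <- function(world, ids) {
  as.character(world$proteins)[ids]
}

# A small fast world without neighbor planting, for structural tests.
small_world <- function(seed = 3) {
  generate_world(world_config(
    seed = seed, n_orders = 1L, families_per_order = 2L,
    genera_per_family = 3L, species_per_genus = 2L,
    n_protein_families = 3L, cu_type_fraction = 0.5,
    neighbor_plan = data.frame(domain_label = character(0),
                               n_genera = integer(0), group = character(0),
                               stringsAsFactors = FALSE)))
}

# Alignment with two clades separated by diagnostic columns.
planted_clade_msa <- function(n_diag = 200, n_noise = 50, seed = 8) {
  set.seed(seed)
  ab <- aa_alphabet()
  base1 <- sample(ab, n_diag, replace = TRUE)
  base2 <- vapply(base1, function(r) sample(setdiff(ab, r), 1), character(1))
  noise <- function() sample(ab, n_noise, replace = TRUE)
  mk <- function(base) paste(c(base, noise()), collapse = "")
  rows <- c(a1 = mk(base1), a2 = mk(base1), a3 = mk(base1),
            b1 = mk(base2), b2 = mk(base2), b3 = mk(base2))
  msa_from_rows(rows)
}
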