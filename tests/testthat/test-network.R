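# Similarity network: local alignment scoring, E-value based alignment
# scores, network construction, clusters.

test_that("Smith-Waterman matches hand-derived values", {
  # perfect self-alignment of MKTM: diagonal BLOSUM62 5+5+5+5
  expect_equal(smith_waterman_score("MKTM", "MKTM"), 20)
  # all-negative substitution (W vs P = -4): empty local alignment wins
  expect_equal(smith_waterman_score("WWWWW", "PPPPP"), 0)
  expect_error(smith_waterman_score("MKB1", "MK"), "alphabet")
})

test_that("Smith-Waterman is symmetric and matches the DP oracle", {
  set.seed(41)
  ab <- aa_alphabet()
  for (i in 1:25) {
    a <- paste(sample(ab, sample(5:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(ab, sample(5:30, 1), replace = TRUE), collapse = "")
    s <- smith_waterman_score(a, b)
    expect_equal(s, smith_waterman_score(b, a))
    expect_equal(s, sw_dp_oracle(a, b))
  }
})

test_that("alignment score follows the Karlin-Altschul form", {
  lambda <- 0.267; K <- 0.041
  # raw score with E exactly 1
  raw1 <- log(K * 200 * 300) / lambda
  expect_equal(to_alignment_score(raw1, 200, 300), 0)
  # direct evaluation at raw 20, lengths 100
  expect_equal(to_alignment_score(20, 100, 100),
               -log10(0.041 * 1e4 * exp(-5.34)))
  # analytic slope: 1/lambda * ln 10 raw units per alignment-score unit
  step <- log(10) / lambda
  expect_equal(to_alignment_score(50 + step, 100, 100) -
                 to_alignment_score(50, 100, 100), 1)
  expect_error(to_alignment_score(10, 0, 10), "length")
})

test_that("identical sequences merge into one representative node", {
  net <- build_network(c(x = "MKTAYLV", y = "MKTAYLV"), threshold = 0)
  expect_length(net$nodes, 1)
  expect_equal(sort(net$nodes[[1]]), c("x", "y"))
  expect_equal(nrow(net$edges), 0)
  # merging off keeps both nodes
  net2 <- build_network(c(x = "MKTAYLV", y = "MKTAYLV"),
                        threshold = 0, merge_identical = FALSE)
  expect_length(net2$nodes, 2)
})

test_that("an infinite threshold leaves no edges", {
  net <- build_network(c(a = "MKTAYLVMKTAYLV", b = "MKTAYLVMKTAYLV",
                         c = "WWPPGGHH"), threshold = Inf)
  expect_equal(nrow(net$edges), 0)
  expect_length(net$nodes, 2)  # a and b still merge
})

test_that("synthetic families separate cleanly at threshold 75", {
  w <- generate_world(world_config(
    seed = 17, n_orders = 1L, families_per_order = 3L,
    genera_per_family = 5L, species_per_genus = 1L,
    n_protein_families = 3L, within_family_divergence = 0.2,
    neighbor_plan = data.frame(domain_label = character(0),
                               n_genera = integer(0), group = character(0))))
  seqs <- as.character(w$proteins)
  fam <- unlist(w$truth$family_of_protein)
  # brute-force all-pairs alignment scores
  ids <- names(seqs)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      raw <- smith_waterman_score(seqs[[i]], seqs[[j]])
      as <- to_alignment_score(raw, nchar(seqs[[i]]), nchar(seqs[[j]]))
      if (fam[[ids[i]]] == fam[[ids[j]]]) {
        expect_gte(as, 75)
      } else {
        expect_lt(as, 75)
      }
    }
  }
})

test_that("the k-mer prefilter never changes accepted edges", {
  w <- small_world(seed = 19)
  n1 <- build_network(w$proteins, kmer_prefilter = TRUE)
  n2 <- build_network(w$proteins, kmer_prefilter = FALSE)
  expect_identical(n1$edges, n2$edges)
})

test_that("clusters are components numbered by size with tie-breaks", {
  net <- make_network(c("a", "b", "c", "d"),
                      data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                                 raw_score = c(1, 1),
                                 alignment_score = c(80, 80)))
  cl <- extract_clusters(net)
  expect_equal(cl$cluster_id[match(c("a", "b", "c", "d"), cl$node_id)],
               c(1L, 1L, 1L, 2L))
  # partition: every node in exactly one cluster
  expect_setequal(cl$node_id, names(net$nodes))
  expect_false(anyDuplicated(cl$node_id) > 0)
})

test_that("components agree with a BFS oracle on random graphs", {
  set.seed(73)
  for (rep in 1:40) {
    n <- sample(3:14, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    npairs <- sample(0:(n * 2), 1)
    if (npairs > 0) {
      ii <- replicate(npairs, sort(sample(n, 2)))
      edges <- unique(data.frame(node_a = nodes[ii[1, ]],
                                 node_b = nodes[ii[2, ]],
                                 stringsAsFactors = FALSE))
      edges$raw_score <- 1; edges$alignment_score <- 80
    } else {
      edges <- NULL
    }
    net <- make_network(nodes, edges)
    cl <- extract_clusters(net)
    oracle <- bfs_components(nodes, net$edges)
    got <- setNames(cl$cluster_id, cl$node_id)[nodes]
    # same partition (labels may differ)
    expect_equal(length(unique(got)), length(unique(oracle)))
    expect_true(all(tapply(oracle, got, function(v) length(unique(v))) == 1))
  }
})

test_that("raising the threshold only refines clusters", {
  w <- small_world(seed = 23)
  lo <- extract_clusters(build_network(w$proteins, threshold = 40))
  hi <- extract_clusters(build_network(w$proteins, threshold = 120))
  lo_of <- setNames(lo$cluster_id, lo$node_id)
  hi_cl <- split(hi$node_id, hi$cluster_id)
  for (members in hi_cl) {
    expect_length(unique(lo_of[members]), 1)
  }
})

test_that("singleton dropping is a pure reporting filter", {
  net <- build_network(c(a = "MKTAYLVMKTAYLVWWRR", b = "MKTAYLVMKTAYLVWWRR",
                         c = "GGPPHHDDEE"), threshold = 10,
                       drop_singletons = TRUE)
  expect_false("c" %in% unlist(net$nodes))
})
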