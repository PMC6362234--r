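# p-distances, neighbor joining, bootstrap, external placement.

test_that("p-distances count mismatches over comparable columns", {
  msa <- msa_from_rows(c(a = "AAAA", b = "AAAV", c = "A-AA", d = "AVAA"))
  D <- protein_distance_matrix(msa)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "b"], 0.25)
  # a gap masks one column: c vs d compares 3 columns, all equal
  expect_equal(D["c", "d"], 0)
  expect_true(isSymmetric(D))
  bad <- msa_from_rows(c(x = "A--", y = "-AA", z = "AAA"))
  expect_error(protein_distance_matrix(bad), "comparable")
})

test_that("NJ recovers the 4-taxon additive matrix exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- build_nj_tree(D)
  expect_equal(tree_bipartitions(tree), "C|D")  # split AB|CD
  # path lengths reproduce the input matrix exactly
  expect_equal(cophenetic(tree)[LETTERS[1:4], LETTERS[1:4]], D)
  # leaf branch lengths 1, 2, 3, 4 and internal branch 1
  el <- setNames(tree$edge.length[tree$edge[, 2] <= 4],
                 tree$tip.label[tree$edge[tree$edge[, 2] <= 4, 2]])
  expect_equal(el[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))
  expect_error(build_nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b")))),
               "symmetric")
})

test_that("equidistant taxa give a zero-length internal resolution", {
  eps <- 0.1
  D <- matrix(2 * eps, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D) <- 0
  tree <- build_nj_tree(D)
  internal <- tree$edge.length[tree$edge[, 2] > 4]
  expect_true(all(abs(internal) < 1e-12))
  expect_true(all(tree$edge.length >= 0))
})

test_that("NJ recovers random additive trees (four-point oracle)", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- cophenetic(ref)
    ids <- sort(rownames(D))
    D <- D[ids, ids]
    tree <- build_nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(ref), tree), 0,
                 ignore_attr = TRUE)
    # additivity: output path lengths equal the input distances
    expect_equal(cophenetic(tree)[ids, ids], D, tolerance = 1e-8)
  }
})

test_that("NJ is invariant to input id order", {
  set.seed(56)
  ref <- ape::rtree(8, br = function(k) runif(k, 0.05, 1))
  D <- cophenetic(ref)
  t1 <- build_nj_tree(D)
  perm <- sample(nrow(D))
  t2 <- build_nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  expect_equal(cophenetic(t1)[rownames(D), rownames(D)],
               cophenetic(t2)[rownames(D), rownames(D)], tolerance = 1e-8)
})

test_that("bootstrap supports are seeded and certain for fixed splits", {
  msa <- planted_clade_msa()
  t1 <- bootstrap_support(msa, n_replicates = 100, seed = 7)
  t2 <- bootstrap_support(msa, n_replicates = 100, seed = 7)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  # the clade split is retained by every resample
  key <- paste(sort(c("b1", "b2", "b3")), collapse = "|")
  expect_equal(unname(attr(t1, "support")[key]), 100)
  # a single replicate can only give 0 or 100
  t3 <- bootstrap_support(msa, n_replicates = 1, seed = 9)
  expect_true(all(attr(t3, "support") %in% c(0, 100)))
  expect_error(bootstrap_support(msa, n_replicates = 0), "n_replicates")
})

test_that("external sequences place into the nearest cluster", {
  msa <- msa_from_rows(c(p1 = "AAAAAAAA", p2 = "AAAAAAAV",
                         q1 = "WWWWWWWW", q2 = "WWWWWWWV"))
  clusters <- list(`1` = c("p1", "p2"), `2` = c("q1", "q2"))
  hit <- place_external_sequences(c(x = "AAAAAAAA"), clusters, msa)
  expect_equal(hit$cluster_id, "1")
  expect_equal(hit$mean_distance, mean(c(0, 1 / 8)))
  expect_error(place_external_sequences(c(p1 = "AAAA"), clusters, msa),
               "already present")
})

test_that("equidistant extras go to the smaller cluster id with margin 0", {
  msa <- msa_from_rows(c(p1 = "AAAA", q1 = "WWWW"))
  clusters <- list(`2` = "q1", `1` = "p1")
  hit <- place_external_sequences(c(x = "AAWW"), clusters, msa)
  expect_equal(hit$cluster_id, "1")
  expect_equal(hit$margin, 0)
})

test_that("truncated synthetic variants place into their family cluster", {
  w <- default_world()
  net <- default_network()
  members <- cluster_proteins(net, extract_clusters(net))
  seqs <- as.character(w$proteins)
  # one representative per cluster in a joint alignment
  picks <- unlist(lapply(members, head, 4))
  msa <- center_star_align(seqs[picks])
  src <- members[["3"]][5]
  frag <- substr(seqs[[src]], 1, round(0.7 * nchar(seqs[[src]])))
  hit <- place_external_sequences(setNames(frag, "trunc"), members, msa)
  expect_equal(hit$cluster_id, "3")
})
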