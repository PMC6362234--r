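# Gene-neighborhood conservation: windows, distinct-taxon counts,
# selection, collapapsing, context flags.

# A hand-built feature table: one contig of n genes, labels as given.
toy_features <- function(genome, labels, contig = "c1") {
  n <- length(labels)
  data.frame(genome_id = genome, contig_id = paste0(genome, "_", contig),
             gene_index = 0:(n - 1), start = 1 + 0:(n - 1) * 1000,
             end = 900 + 0:(n - 1) * 1000, strand = "+",
             gene_id = sprintf("%s_%s_%d", genome, contig, 0:(n - 1)),
             protein_id = "",
             domain_labels = I(labels), stringsAsFactors = FALSE)
}

toy_taxonomy <- function(species, genus, family, order = "o1") {
  data.frame(species = species, genus = genus, family = family,
             order = order, class = "cl1", stringsAsFactors = FALSE)
}

test_that("windows truncate at contig edges and exclude the focal gene", {
  ft <- toy_features("s1", rep(list(character(0)), 10))
  focal <- ft$gene_id[3]  # gene_index 2
  win <- extract_windows(ft, focal, k = 3)
  expect_equal(win$n_neighbors, 5)  # indices 0,1,3,4,5
  # focal alone on a contig
  ft1 <- toy_features("s2", list("PFX"))
  expect_equal(extract_windows(ft1, ft1$gene_id[1], k = 3)$n_neighbors, 0)
  # k = 0 gives empty windows
  expect_equal(extract_windows(ft, focal, k = 0)$n_neighbors, 0)
  expect_error(extract_windows(ft, "nope", k = 3), "nope")
})

test_that("a gene's own labels never enter its window", {
  ft <- toy_features("s1", list("A", "FOCAL", "B"))
  win <- extract_windows(ft, ft$gene_id[2], k = 3)
  expect_setequal(win$labels[[1]], c("A", "B"))
})

test_that("multi-label genes contribute each domain plus the fusion", {
  ft <- toy_features("s1", list(c("PF00107", "PF08240"), "FOCAL"))
  win <- extract_windows(ft, ft$gene_id[2], k = 3)
  expect_setequal(win$labels[[1]],
                  c("PF00107", "PF08240", "PF00107-PF08240"))
})

test_that("distinct-taxon counts follow the rank hierarchy", {
  ft <- rbind(toy_features("s1", list("D", "FOCAL")),
              toy_features("s2", list("D", "FOCAL")),
              toy_features("s3", list("D", "FOCAL")))
  tx <- toy_taxonomy(c("s1", "s2", "s3"), c("g1", "g2", "g3"),
                     c("f1", "f1", "f2"))
  win <- extract_windows(ft, ft$gene_id[ft$gene_index == 1], k = 3)
  cnt <- count_taxon_conservation(win, tx)
  d <- cnt[cnt$domain_label == "D", ]
  expect_equal(c(d$n_genera, d$n_families, d$n_orders), c(3L, 2L, 1L))
  expect_equal(d$n_windows, 3L)
})

test_that("repeats inside one genome count a single taxon", {
  ft <- toy_features("s1", list("D", "D", "D", "FOCAL", "D", "D"))
  tx <- toy_taxonomy("s1", "g1", "f1")
  win <- extract_windows(ft, ft$gene_id[4], k = 3)
  cnt <- count_taxon_conservation(win, tx)
  expect_equal(cnt$n_genera[cnt$domain_label == "D"], 1L)
  # empty windows give an empty result
  ft0 <- toy_features("s1", list("FOCAL"))
  win0 <- extract_windows(ft0, ft0$gene_id[1], k = 3)
  expect_equal(nrow(count_taxon_conservation(win0, tx)), 0)
  expect_error(count_taxon_conservation(win, tx[0, ]), "missing")
})

toy_counts <- function() {
  data.frame(domain_label = c("D1", "D2", "D3", "PF07690"),
             n_genera = c(31L, 30L, 29L, 100L),
             n_families = c(10L, 9L, 9L, 40L),
             n_orders = c(2L, 2L, 2L, 10L),
             n_windows = c(40L, 35L, 30L, 120L), stringsAsFactors = FALSE)
}

test_that("selection ranks, thresholds and excludes as specified", {
  sel <- select_top_neighbors(toy_counts(), min_taxa = 30)
  expect_equal(sel$domain_label, c("D1", "D2"))
  rep <- attr(sel, "report")
  expect_equal(rep$n_above_threshold, 3)  # D1, D2, PF07690
  expect_equal(rep$n_selected, 2)
  # without threshold or exclusions: identity ordering by count
  sel0 <- select_top_neighbors(toy_counts(), min_taxa = 0,
                               exclusions = character(0))
  expect_equal(sel0$domain_label, c("PF07690", "D1", "D2", "D3"))
  # everything below threshold
  sel_hi <- select_top_neighbors(toy_counts(), min_taxa = 1000)
  expect_equal(nrow(sel_hi), 0)
  expect_equal(attr(sel_hi, "report")$n_above_threshold, 0)
})

test_that("domains below two genera are never considered", {
  cnt <- data.frame(domain_label = c("rare", "ok"), n_genera = c(1L, 2L),
                    n_families = c(1L, 2L), n_orders = c(1L, 1L),
                    n_windows = c(1L, 2L))
  sel <- select_top_neighbors(cnt, min_taxa = 0, exclusions = character(0))
  expect_equal(sel$domain_label, "ok")
})

test_that("raising min_taxa never adds a domain", {
  cnt <- count_taxon_conservation(
    extract_windows(default_world()$features,
                    unname(default_world()$truth$focal_genes), k = 3),
    default_world()$taxonomy)
  prev <- NULL
  for (t in c(5, 20, 30, 35)) {
    sel <- select_top_neighbors(cnt, min_taxa = t)$domain_label
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("collapsing groups always-co-occurring domains", {
  ft <- rbind(toy_features("s1", list("a", "b", "FOCAL", "c")),
              toy_features("s2", list("a", "b", "FOCAL")),
              toy_features("s3", list("c", "FOCAL")))
  win <- extract_windows(ft, ft$gene_id[grepl("FOCAL",
    vapply(ft$domain_labels, paste, character(1), collapse = ""))], k = 3)
  sel <- data.frame(domain_label = c("a", "b", "c"),
                    n_genera = c(2L, 2L, 2L))
  grp <- collapse_neighborhoods(sel, win, min_cooccur = 2)
  expect_equal(grp, list(N1 = c("a", "b"), N2 = "c"))
  # an infinite threshold isolates every domain
  grp_inf <- collapse_neighborhoods(sel, win, min_cooccur = Inf)
  expect_equal(lengths(grp_inf), c(N1 = 1L, N2 = 1L, N3 = 1L))
})

test_that("context flags re-derive from window labels", {
  ft <- rbind(toy_features("s1", list("ribH", "FOCAL")),
              toy_features("s2", list("PF00403", "FOCAL")),
              toy_features("s3", list("PF99001", "FOCAL")))
  focal <- ft$gene_id[ft$gene_index == 1]
  win <- extract_windows(ft, focal, k = 3)
  fl <- flag_contexts(win)
  expect_equal(fl$rbp, c(TRUE, FALSE, FALSE))
  expect_equal(fl$cu_homeostasis, c(FALSE, TRUE, FALSE))
  expect_equal(fl$ccoNOQP, c(FALSE, FALSE, FALSE))
  expect_error(flag_contexts(win, list(c("x"))), "named")
})

test_that("cco subunit presence is per genome with either CcoP label", {
  ft <- rbind(toy_features("s1", list("IPR004677", "IPR003468", "IPR032858")),
              toy_features("s2", list("PF99001")))
  cc <- cco_presence(ft)
  expect_equal(cc$ccoN, c(TRUE, FALSE))
  expect_equal(cc$ccoO, c(TRUE, FALSE))
  expect_equal(cc$ccoP, c(TRUE, FALSE))
})

test_that("rank consistency holds on the default world", {
  w <- default_world()
  win <- extract_windows(w$features, unname(w$truth$focal_genes), k = 3)
  cnt <- count_taxon_conservation(win, w$taxonomy)
  expect_true(all(cnt$n_orders <= cnt$n_families))
  expect_true(all(cnt$n_families <= cnt$n_genera))
  expect_true(all(cnt$n_genera <= cnt$n_windows))
})

test_that("a world with three co-occurrence groups collapses to three", {
  plan <- data.frame(
    domain_label = c("X1", "X2", "Y1", "Z1", "Z2"),
    n_genera = c(34L, 32L, 33L, 31L, 30L),
    group = c("gA", "gA", "gB", "gC", "gC"), stringsAsFactors = FALSE)
  w <- generate_world(world_config(seed = 29, neighbor_plan = plan))
  win <- extract_windows(w$features, unname(w$truth$focal_genes), k = 3)
  cnt <- count_taxon_conservation(win, w$taxonomy)
  sel <- select_top_neighbors(cnt, min_taxa = 30)
  grp <- collapse_neighborhoods(sel, win, min_cooccur = 2)
  expect_length(grp, 3)
  canon <- function(groups) {
    sort(unname(vapply(lapply(groups, sort), paste, character(1), collapse = "+")))
  }
  expect_equal(canon(grp), canon(w$truth$planted_groups))
})
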