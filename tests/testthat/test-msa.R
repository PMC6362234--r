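# Center-star alignment, column-quality filtering, sequence logos.

test_that("identical sequences align gap-free", {
  msa <- center_star_align(c(a = "MKTAY", b = "MKTAY", c = "MKTAY"))
  expect_true(all(!grepl("-", msa$rows)))
  expect_equal(unname(nchar(msa$rows)), rep(5L, 3))
})

test_that("two sequences reduce to their pairwise global alignment", {
  msa <- center_star_align(c(a = "MKTLLVW", b = "MKTLVW"))
  expect_equal(nchar(msa$rows[["a"]]), 7L)
  expect_equal(gsub("-", "", msa$rows[["b"]]), "MKTLVW")
  expect_equal(sum(strsplit(msa$rows[["b"]], "")[[1]] == "-"), 1L)
})

test_that("every row ungaps to its input sequence", {
  set.seed(31)
  ab <- aa_alphabet()
  seqs <- setNames(vapply(1:6, function(i) {
    paste(sample(ab, sample(20:40, 1), replace = TRUE), collapse = "")
  }, character(1)), paste0("s", 1:6))
  msa <- center_star_align(seqs)
  expect_equal(gsub("-", "", msa$rows), seqs)
  expect_length(unique(nchar(msa$rows)), 1)
  expect_error(center_star_align(seqs[1]), "at least 2")
})

test_that("column quality matches hand-computed BLOSUM62 values", {
  # col1 all W: s = 11 -> 1000; col2 half A half V:
  # s = .25*4 + .25*4 + .5*0 = 2 -> round(1000 * 6/15) = 400
  msa <- msa_from_rows(c(r1 = "WA", r2 = "WV", r3 = "WA", r4 = "WV"))
  expect_equal(column_quality(msa), c(1000L, 400L))
  f <- filter_alignment(msa, min_quality = 826)
  expect_equal(unname(f$rows), rep("W", 4))
  expect_equal(attr(f, "kept_columns"), 1L)
})

test_that("filtering is idempotent and errors when nothing survives", {
  msa <- msa_from_rows(c(r1 = "WWAC", r2 = "WWVC", r3 = "W-AC"))
  f1 <- filter_alignment(msa, min_quality = 500)
  f2 <- filter_alignment(f1, min_quality = 500)
  expect_equal(f1$rows, f2$rows)
  expect_error(filter_alignment(msa, min_quality = 1001), "lower min_quality")
})

test_that("gap-dominated columns are dropped", {
  msa <- msa_from_rows(c(r1 = "W-", r2 = "W-", r3 = "W-", r4 = "WW"))
  f <- filter_alignment(msa, min_quality = 0)
  expect_equal(unname(f$rows), c("W", "W", "W", "W"))
})

test_that("the motif row filter removes motif-less rows before scoring", {
  rows <- c(good = "MAAAMHAAAM", bad = "MAAAMAAAAA")
  msa <- msa_from_rows(rows)
  f <- filter_alignment(msa, min_quality = 0, require_motifs = TRUE)
  expect_equal(names(f$rows), "good")
  expect_error(filter_alignment(msa_from_rows(rows["bad"]), min_quality = 0,
                                require_motifs = TRUE), "motifs")
})

test_that("logo information content matches the closed form", {
  msa <- msa_from_rows(setNames(rep("M", 100), paste0("r", 1:100)))
  logo <- build_logo(msa)
  expect_equal(logo$R, log2(20) - (19 / 200) / log(2))
  expect_equal(unname(logo$heights["M", 1]), logo$R)
  # uniform column at large n approaches zero information
  msa_u <- msa_from_rows(setNames(rep(aa_alphabet(), 50),
                                  paste0("r", 1:1000)))
  expect_lt(build_logo(msa_u)$R, 0.02)
})

test_that("letter heights in every column sum to R", {
  w <- default_world()
  net <- default_network()
  members <- cluster_proteins(net, extract_clusters(net))
  ids <- members[[1]][1:8]
  msa <- center_star_align(as_msa_input(w, ids))
  logo <- build_logo(msa)
  expect_lt(max(abs(colSums(logo$heights) - logo$R)), 1e-9)
})

test_that("planted motif anchor columns survive and dominate", {
  w <- default_world()
  fam <- unlist(w$truth$family_of_protein)
  cu_fam <- unlist(w$truth$cu_type_families)[1]
  ids <- names(fam)[fam == cu_fam][1:10]
  msa <- center_star_align(as_msa_input(w, ids))
  mc <- w$truth$motif_coords[[ids[1]]]
  # conserved M self-scores 600, H 800 on the 0-1000 scale; filter there
  f <- filter_alignment(msa, min_quality = 600)
  # anchors are protected, so member coordinates equal ancestor ones;
  # the family aligns gap-free (no indels) and columns map 1:1
  kept <- attr(f, "kept_columns")
  for (col in c(mc$mxxxm_start, mc$mxxxm_start + 4, mc$hxxxm_start)) {
    expect_true(col %in% kept)
  }
  logo <- build_logo(f)
  m_col <- match(mc$mxxxm_start, kept)
  expect_equal(names(which.max(logo$heights[, m_col])), "M")
  h_col <- match(mc$hxxxm_start, kept)
  expect_equal(names(which.max(logo$heights[, h_col])), "H")
})

test_that("aligned FASTA round-trips", {
  msa <- msa_from_rows(c(a = "MK-TA", b = "MKQTA"))
  path <- tempfile(fileext = ".afa")
  write_msa_fasta(msa, path)
  back <- read_msa_fasta(path)
  expect_equal(back$rows, msa$rows)
})
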