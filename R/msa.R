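# Center-star multiple alignment, BLOSUM62 column-quality filtering and
# information-content sequence logos.

#' Center-star multiple sequence alignment
#'
#' The center is the sequence with the best summed global alignment
#' score against all others (equivalently, minimal summed alignment
#' distance; ties go to the lexicographically smallest id).  Every other
#' sequence is merged into the alignment by its pairwise global
#' affine-gap alignment to the center under the "once a gap, always a
#' gap" rule.
#'
#' @param sequences Named character vector or `AAStringSet`, length >= 2.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (a length-k gap costs
#'   `gap_open + k * gap_extend`).
#' @return An `msa` object: list with `ids`, `rows` (aligned strings of
#'   equal length over residues and `-`) and `center_id`.  Ungapping any
#'   row reproduces its input sequence.
#' @export
center_star_align <- function(sequences, matrix = blosum62(),
                              gap_open = 11, gap_extend = 1) {
  seqs <- as_seq_vector(sequences)
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(seqs)
  sub <- align_matrix(matrix)
  enc <- lapply(seqs, encode_seq)

  n <- length(seqs)
  tot <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- .nw_score_c(enc[[i]], enc[[j]], sub, gap_open, gap_extend)
      tot[i] <- tot[i] + s
      tot[j] <- tot[j] + s
    }
  }
  center <- which(tot == max(tot))
  center <- center[order(ids[center])][1]

  cen <- enc[[center]]
  L <- length(cen)
  others <- setdiff(seq_len(n), center)
  alns <- lapply(others, function(i) {
    .nw_align_c(cen, enc[[i]], sub, gap_open, gap_extend)
  })
  # ins[k+1] = columns inserted after center position k (k = 0..L)
  ins <- integer(L + 1L)
  per_ins <- lapply(alns, function(al) {
    v <- integer(L + 1L)
    last <- 0L
    for (col in seq_along(al$a)) {
      if (al$a[col] > 0L) last <- al$a[col]
      else v[last + 1L] <- v[last + 1L] + 1L
    }
    v
  })
  for (v in per_ins) ins <- pmax(ins, v)

  ncol_out <- L + sum(ins)
  # column index of center position k in the master alignment
  col_of <- if (L == 1L) ins[1L] + 1L else
    ins[1L] + cumsum(c(1L, ins[2:L] + 1L))
  ab <- aa_alphabet()
  rows <- character(n)
  # center row
  cen_row <- rep("-", ncol_out)
  cen_row[col_of] <- ab[cen + 1L]
  rows[center] <- paste(cen_row, collapse = "")
  # other rows: place residues aligned to center positions at col_of, and
  # insertion-run residues left-aligned in the reserved slots
  for (t in seq_along(others)) {
    al <- alns[[t]]
    oseq <- ab[enc[[others[t]]] + 1L]
    out <- rep("-", ncol_out)
    last <- 0L     # last consumed center position
    k_ins <- 0L    # residues already placed in the current insertion run
    for (col in seq_along(al$a)) {
      if (al$a[col] > 0L) {
        last <- al$a[col]
        k_ins <- 0L
        if (al$b[col] > 0L) out[col_of[last]] <- oseq[al$b[col]]
      } else {
        k_ins <- k_ins + 1L
        slot_base <- if (last == 0L) 0L else col_of[last]
        out[slot_base + k_ins] <- oseq[al$b[col]]
      }
    }
    rows[others[t]] <- paste(out, collapse = "")
  }
  structure(list(ids = ids, rows = setNames(rows, ids), center_id = ids[center]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (center %s)\n",
              length(x$rows), nchar(x$rows[[1]]), x$center_id))
  invisible(x)
}

#' Build an msa object from pre-aligned rows
#'
#' @param rows Named character vector of equal-length aligned rows.
#' @param center_id Optional id of the center sequence.
#' @return An `msa` object.
#' @export
msa_from_rows <- function(rows, center_id = NULL) {
  stopifnot(length(unique(nchar(rows))) == 1, !is.null(names(rows)))
  structure(list(ids = names(rows), rows = toupper(rows),
                 center_id = center_id), class = "msa")
}

# Character matrix view (rows = sequences, columns = alignment columns).
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
}

#' Per-column alignment quality scores
#'
#' Column quality on a 0-1000 scale: with gap-free residue frequencies
#' `p` of a column, the expected pairwise BLOSUM62 similarity
#' `s = sum_ab p_a p_b B(a,b)` is rescaled linearly from the matrix
#' range (-4, 11) to (0, 1000) and rounded, so a perfectly conserved
#' tryptophan column scores exactly 1000.  Columns with no gap-free
#' residues score NA.
#'
#' @param msa An `msa` object.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return Integer vector, one score per column.
#' @export
column_quality <- function(msa, matrix = blosum62()) {
  m <- msa_matrix(msa)
  sub <- align_matrix(matrix)
  rng <- range(sub)
  ab <- aa_alphabet()
  vapply(seq_len(ncol(m)), function(j) {
    res <- m[, j]
    res <- res[res %in% ab]
    if (!length(res)) return(NA_integer_)
    p <- as.vector(table(factor(res, levels = ab))) / length(res)
    s <- drop(t(p) %*% sub %*% p)
    as.integer(round(1000 * (s - rng[1]) / (rng[2] - rng[1])))
  }, integer(1))
}

#' Filter an alignment by column quality (and motif presence)
#'
#' Removes columns whose quality score (see [column_quality()]) is below
#' `min_quality` and columns with more than `max_gap_frac` gaps.  When
#' `require_motifs` is on, rows whose ungapped sequence lacks an
#' `M.{3}M` or lacks an `H.{3}M` match are removed before column scoring
#' — the row filter applied to the transporter alignments before tree
#' building.
#'
#' @param msa An `msa` object.
#' @param min_quality Minimum column quality (default 826).
#' @param require_motifs Remove motif-less rows first.
#' @param max_gap_frac Maximum tolerated gap fraction per column.
#' @param matrix Substitution matrix.
#' @return Filtered `msa` with attributes `kept_columns` (original
#'   column indices) and `column_quality` (scores of kept columns).
#' @export
filter_alignment <- function(msa, min_quality = 826, require_motifs = FALSE,
                             max_gap_frac = 0.5, matrix = blosum62()) {
  rows <- msa$rows
  if (require_motifs) {
    ungapped <- gsub("-", "", rows, fixed = TRUE)
    keep <- grepl("M.{3}M", ungapped) & grepl("H.{3}M", ungapped)
    if (!any(keep)) {
      stop("no rows contain both MxxxM and HxxxM motifs", call. = FALSE)
    }
    rows <- rows[keep]
    msa <- msa_from_rows(rows, msa$center_id)
  }
  q <- column_quality(msa, matrix)
  m <- msa_matrix(msa)
  gap_frac <- colMeans(m == "-")
  keep_cols <- which(!is.na(q) & q >= min_quality & gap_frac <= max_gap_frac)
  if (!length(keep_cols)) {
    stop("all columns removed by quality filter; lower min_quality",
         call. = FALSE)
  }
  new_rows <- apply(m[, keep_cols, drop = FALSE], 1, paste, collapse = "")
  names(new_rows) <- names(msa$rows)
  out <- msa_from_rows(new_rows, msa$center_id)
  attr(out, "kept_columns") <- keep_cols
  attr(out, "column_quality") <- q[keep_cols]
  out
}

#' Sequence logo heights from an alignment
#'
#' Per column, the information content is
#' `R = log2(20) - H - e_n` (floored at 0), where `H` is the Shannon
#' entropy of the gap-free residue frequencies and
#' `e_n = (19 / (2 n)) / ln(2)` is the small-sample correction for `n`
#' gap-free rows.  Letter heights are `p_a * R`, so heights in a column
#' sum to `R`.  Columns with no gap-free rows get `R = 0`.
#'
#' @param msa An `msa` object.
#' @return A `logo_matrix` object: list with `heights` (20 x n-column
#'   matrix, rows named by residue) and `R` (per-column information
#'   content in bits).
#' @export
build_logo <- function(msa) {
  m <- msa_matrix(msa)
  if (!ncol(m)) stop("alignment has no columns", call. = FALSE)
  ab <- aa_alphabet()
  heights <- matrix(0, nrow = 20, ncol = ncol(m), dimnames = list(ab, NULL))
  R <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    res <- m[, j]
    res <- res[res %in% ab]
    n <- length(res)
    if (!n) next
    p <- as.vector(table(factor(res, levels = ab))) / n
    H <- -sum(p[p > 0] * log2(p[p > 0]))
    e_n <- (19 / (2 * n)) / log(2)
    R[j] <- max(0, log2(20) - H - e_n)
    heights[, j] <- p * R[j]
  }
  structure(list(heights = heights, R = R), class = "logo_matrix")
}

#' Write a logo matrix as TSV
#'
#' Long-format columns: `column`, `residue`, `height`, `R`.  Zero
#' heights are omitted.
#'
#' @param logo A `logo_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  nz <- which(logo$heights > 0, arr.ind = TRUE)
  df <- data.frame(column = nz[, 2],
                   residue = rownames(logo$heights)[nz[, 1]],
                   height = logo$heights[nz],
                   R = logo$R[nz[, 2]])
  df <- df[order(df$column, -df$height, df$residue), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an alignment as FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  write_fasta_raw(msa$rows, path)
}

# FASTA writer that tolerates gap characters.
write_fasta_raw <- function(rows, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(rows)) {
    writeLines(paste0(">", names(rows)[i]), con)
    s <- rows[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file as an msa
#' @param path Path to aligned FASTA.
#' @return An `msa` object.
#' @export
read_msa_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  rows <- setNames(toupper(as.character(set)), ids)
  msa_from_rows(rows)
}
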