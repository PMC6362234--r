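# Transmembrane topology prediction (Kyte-Doolittle sliding window) and
# Cu-binding motif screening.  The screen implements the MxxxM-in-TM7 /
# HxxxM-in-TM8 signature of the CcoA-like transporter family.

#' Predict transmembrane segments by hydropathy
#'
#' Classical Kyte-Doolittle sliding-window prediction: a position is
#' flagged when the mean hydropathy of the window centered on it reaches
#' `kd_threshold`; flagged runs separated by fewer than `merge_gap`
#' unflagged positions are merged, and runs of at least `min_len`
#' positions are reported as segments, numbered 1..n from the
#' N-terminus.
#'
#' @param sequence Protein sequence (string). Residues outside the
#'   20-letter alphabet (e.g. `X`) contribute hydropathy 0.
#' @param window Window length (odd; default 19, the classical choice
#'   for membrane-spanning segments).
#' @param kd_threshold Mean-hydropathy cutoff (default 1.6).
#' @param min_len Minimum reported run length.
#' @param merge_gap Runs closer than this many positions are merged.
#' @return A `tm_topology` object: list with `segments`, a data.frame of
#'   1-based inclusive `start`, `end` per segment, and `n_segments`.
#' @export
predict_tm_segments <- function(sequence, window = 19L, kd_threshold = 1.6,
                                min_len = 8L, merge_gap = 3L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < window) {
    warning("sequence shorter than window; empty topology")
    return(structure(list(segments = data.frame(start = integer(0),
                                                end = integer(0)),
                          n_segments = 0L), class = "tm_topology"))
  }
  kd <- kyte_doolittle()
  vals <- kd[strsplit(sequence, "")[[1]]]
  vals[is.na(vals)] <- 0
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(vals))
  centers <- (half + 1L):(n - half)
  means <- (cs[centers + half + 1L] - cs[centers - half]) / window
  flagged <- centers[means >= kd_threshold]
  segments <- runs_from_positions(flagged, merge_gap, min_len)
  structure(list(segments = segments, n_segments = nrow(segments)),
            class = "tm_topology")
}

# Collapse a sorted vector of flagged positions into runs, merging runs
# whose gap is < merge_gap, then dropping runs shorter than min_len.
runs_from_positions <- function(pos, merge_gap, min_len) {
  if (!length(pos)) return(data.frame(start = integer(0), end = integer(0)))
  brk <- which(diff(pos) > 1L)
  start <- pos[c(1L, brk + 1L)]
  end <- pos[c(brk, length(pos))]
  # merge runs separated by < merge_gap unflagged positions
  i <- 1L
  while (i < length(start)) {
    if (start[i + 1L] - end[i] - 1L < merge_gap) {
      end[i] <- end[i + 1L]
      start <- start[-(i + 1L)]
      end <- end[-(i + 1L)]
    } else i <- i + 1L
  }
  keep <- (end - start + 1L) >= min_len
  data.frame(start = start[keep], end = end[keep])
}

#' @export
print.tm_topology <- function(x, ...) {
  cat(sprintf("tm_topology: %d segment(s)\n", x$n_segments))
  if (x$n_segments) print(x$segments)
  invisible(x)
}

#' Scan a sequence for Cu-binding motifs
#'
#' Finds all (overlapping) matches of `MxxxM` and `HxxxM`, where `x` is
#' any residue, and annotates each hit with the transmembrane segment
#' that fully contains it, if a topology is supplied.
#'
#' @param sequence Protein sequence (string).
#' @param topology Optional `tm_topology`; when given, a hit spanning
#'   positions `start..start+4` entirely inside segment k gets
#'   `containing_tm = k` (NA otherwise).
#' @return data.frame with columns `pattern` (`"MxxxM"`/`"HxxxM"`),
#'   `start` (1-based position of the first anchor) and `containing_tm`.
#' @export
scan_motifs <- function(sequence, topology = NULL) {
  sequence <- toupper(sequence)
  hits <- do.call(rbind, lapply(c(MxxxM = "(?=M.{3}M)", HxxxM = "(?=H.{3}M)"),
    function(re) {
      m <- gregexpr(re, sequence, perl = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      data.frame(start = as.integer(m))
    }))
  if (is.null(hits)) {
    hits <- data.frame(pattern = character(0), start = integer(0))
  } else {
    hits$pattern <- sub("\\..*$", "", rownames(hits))
    rownames(hits) <- NULL
    hits <- hits[order(hits$start, hits$pattern), c("pattern", "start")]
    rownames(hits) <- NULL
  }
  hits$containing_tm <- rep(NA_integer_, nrow(hits))
  if (!is.null(topology) && topology$n_segments > 0 && nrow(hits)) {
    seg <- topology$segments
    for (i in seq_len(nrow(hits))) {
      s <- hits$start[i]
      k <- which(seg$start <= s & seg$end >= s + 4L)
      if (length(k) == 1L) hits$containing_tm[i] <- k
    }
  }
  hits
}

#' Call a protein as a candidate Cu transporter
#'
#' Strict mode requires at least one `MxxxM` hit contained in predicted
#' segment 7 and one `HxxxM` hit contained in segment 8 — the TM7/TM8
#' signature of characterised CcoA-like Cu importers.  Relaxed mode,
#' intended for proteins whose predicted segment count is not 12,
#' requires each pattern to fall inside any predicted segment.
#'
#' @param topology A `tm_topology`.
#' @param hits Motif hits from [scan_motifs()] computed with the same
#'   topology.
#' @param mode `"strict"` or `"relaxed"`.
#' @return List with `is_candidate` (logical), `evidence` (the hit rows
#'   supporting the call) and `mode`.
#' @export
call_cu_transporter <- function(topology, hits, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    ev <- hits[(hits$pattern == "MxxxM" & !is.na(hits$containing_tm) &
                  hits$containing_tm == 7L) |
               (hits$pattern == "HxxxM" & !is.na(hits$containing_tm) &
                  hits$containing_tm == 8L), , drop = FALSE]
    ok <- any(ev$pattern == "MxxxM") && any(ev$pattern == "HxxxM")
  } else {
    ev <- hits[!is.na(hits$containing_tm), , drop = FALSE]
    ok <- any(ev$pattern == "MxxxM") && any(ev$pattern == "HxxxM")
  }
  if (!ok) ev <- ev[0, , drop = FALSE]
  list(is_candidate = ok, evidence = ev, mode = mode)
}

#' Screen a protein set for candidate Cu transporters
#'
#' Convenience wrapper running topology prediction, motif scanning and
#' the transporter call over a whole sequence set.
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @param mode Passed to [call_cu_transporter()].
#' @param ... Passed to [predict_tm_segments()].
#' @return data.frame with one row per protein: `protein_id`,
#'   `n_segments`, `is_candidate`, `mxxxm_tm` and `hxxxm_tm` (segment
#'   numbers of the first supporting hit, NA if none).
#' @export
screen_cu_transporters <- function(proteins, mode = "strict", ...) {
  seqs <- as_seq_vector(proteins)
  rows <- lapply(names(seqs), function(id) {
    topo <- suppressWarnings(predict_tm_segments(seqs[[id]], ...))
    hits <- scan_motifs(seqs[[id]], topo)
    call <- call_cu_transporter(topo, hits, mode)
    first_tm <- function(pat) {
      ev <- call$evidence
      v <- ev$containing_tm[ev$pattern == pat]
      if (length(v)) v[1] else NA_integer_
    }
    data.frame(protein_id = id, n_segments = topo$n_segments,
               is_candidate = call$is_candidate,
               mxxxm_tm = first_tm("MxxxM"), hxxxm_tm = first_tm("HxxxM"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
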