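# Shared constants and small helpers.

#' Standard amino-acid alphabet
#'
#' The twenty standard residues, in the conventional alphabetical
#' one-letter order used by substitution matrices.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used for sliding-window transmembrane
#' segment prediction.  Positive values are hydrophobic.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

# BLOSUM62 restricted to the 20 standard residues, rows/cols in
# aa_alphabet() order.  Cached per session.
.pkg_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix (20 standard residues)
#'
#' @return 20 x 20 integer matrix with dimnames in [aa_alphabet()] order.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ab <- aa_alphabet()
    .pkg_env$blosum62 <- e$BLOSUM62[ab, ab]
  }
  .pkg_env$blosum62
}

# Encode a protein string as 0-based indices into aa_alphabet();
# unknown residues error (callers decide how to pre-clean X's).
encode_seq <- function(x, context = "sequence") {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, aa_alphabet())
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(sprintf("%s contains residues outside the matrix alphabet: %s",
                 context, paste(bad, collapse = ", ")), call. = FALSE)
  }
  idx - 1L
}

# Coerce an AAStringSet or named character vector to a named character
# vector of uppercase sequences.
as_seq_vector <- function(proteins) {
  if (inherits(proteins, "XStringSet")) {
    out <- as.character(proteins)
  } else {
    out <- as.character(proteins)
    names(out) <- names(proteins)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("proteins must be named (protein ids)", call. = FALSE)
  }
  toupper(out)
}

# Deterministic 32-bit sub-seed derived from a base seed and a stage name,
# so that stage order never changes a stage's random stream.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483647)
}
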