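#' k-mer fragment frequencies over a peptide set
#'
#' Tallies all sliding-window fragments of length `k` (so `L - k + 1`
#' windows per length-`L` peptide) with multiplicity. With the default
#' `k = 4` on 15-mers, each peptide contributes 12 fragments.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param k Fragment length (default 4); must not exceed the peptide
#'   length.
#' @return Named integer vector of fragment counts, sorted by count
#'   descending then fragment.
#' @export
#' @examples
#' kmer_fragments("AAAAAAAAAAAAAAA")  # AAAA: 12
kmer_fragments <- function(peptides, k = 4L) {
  stopifnot(k >= 1)
  if (length(peptides) == 0) return(setNames(integer(0), character(0)))
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("all peptides must have equal length")
  if (k > L) stop("k = ", k, " exceeds peptide length ", L)
  frags <- unlist(lapply(seq_len(L - k + 1L), function(i) {
    substr(peptides, i, i + k - 1L)
  }), use.names = FALSE)
  tab <- table(frags)
  counts <- setNames(as.integer(tab), names(tab))
  counts[order(-counts, names(counts))]
}

#' Pairwise amino-acid co-occurrence matrix
#'
#' For each peptide, every unordered position pair (i < j) contributes
#' one count to the cell for its residue pair (and the mirror cell), so
#' a 15-mer contributes choose(15, 2) = 105 pairs and the
#' upper-triangle-plus-diagonal mass is 105 per sequence. This counting
#' is position-free: permuting residues within a peptide leaves the
#' matrix unchanged.
#'
#' `mode = "presence"` is an alternative rule counting each residue
#' pair at most once per sequence (cell \[a, b\] = number of sequences
#' containing both a and b; diagonal = number containing a).
#'
#' @param peptides Character vector of equal-length peptides.
#' @param mode "pairs" (default, position-pair counting) or "presence".
#' @return Object of class `cooccurrence_matrix`: list with `counts`
#'   (symmetric 20 x 20 matrix), `n_sequences`, `mode`, and `fraction`
#'   (counts normalized by total pair mass).
#' @export
#' @examples
#' m <- cooccurrence("ACACACACACACACA")
#' m$counts["A", "C"]  # 8 * 7 = 56
cooccurrence <- function(peptides, mode = c("pairs", "presence")) {
  mode <- match.arg(mode)
  n <- length(peptides)
  if (n == 0) stop("no peptides supplied")
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("all peptides must have equal length")
  # per-peptide residue count matrix (n x 20)
  M <- matrix(0L, nrow = n, ncol = 20L,
              dimnames = list(NULL, AA_STANDARD))
  for (p in seq_len(L)) {
    col <- substr(peptides, p, p)
    idx <- match(col, AA_STANDARD)
    if (anyNA(idx)) stop("non-standard residues in input")
    M[cbind(seq_len(n), idx)] <- M[cbind(seq_len(n), idx)] + 1L
  }
  if (mode == "pairs") {
    cross <- crossprod(M)                       # sum_i n_a * n_b
    diag(cross) <- (diag(cross) - colSums(M)) / 2  # sum_i choose(n_a, 2)
    counts <- cross
    mass <- n * choose(L, 2)
  } else {
    P <- (M > 0) * 1L
    counts <- crossprod(P)
    mass <- sum(counts[upper.tri(counts, diag = TRUE)])
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, n_sequences = n, mode = mode,
                 fraction = counts / mass),
            class = "cooccurrence_matrix")
}

#' Rank peptide sequences by frequency of occurrence
#'
#' Exact-string counting with multiplicity, sorted by count descending
#' with lexicographic tie-break, reporting each sequence's count and its
#' fraction of the input.
#'
#' @param peptides Character vector of peptides.
#' @param top_n Number of top sequences to return (default 100; capped
#'   at the number of distinct sequences).
#' @return data.frame: `rank`, `peptide`, `count`, `fraction`.
#' @export
rank_sequences <- function(peptides, top_n = 100L) {
  stopifnot(top_n >= 1)
  if (length(peptides) == 0) {
    return(data.frame(rank = integer(0), peptide = character(0),
                      count = integer(0), fraction = numeric(0)))
  }
  tab <- table(peptides)
  counts <- as.integer(tab)
  pep <- names(tab)
  ord <- order(-counts, pep)
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(rank = seq_along(keep), peptide = pep[keep],
             count = counts[keep],
             fraction = counts[keep] / length(peptides),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact-match overlap between two peptide sets
#'
#' Deduplicated intersection, ordered by first appearance in `set_a`.
#' Used to compare NGS top-ranked sequences against Sanger-sequenced
#' isolates (where a display experiment's diversity is high, the overlap
#' is typically empty).
#'
#' @param set_a,set_b Character vectors of peptides.
#' @return Character vector of shared peptides (possibly empty).
#' @export
overlap_peptides <- function(set_a, set_b) {
  a <- unique(set_a)
  a[a %in% set_b]
}

#' Position frequency matrix for logo tools
#'
#' Per-position residue fractions (columns sum to 1), the standard input
#' for sequence-logo renderers.
#'
#' @param profile A [composition()] profile.
#' @return 20 x L numeric matrix of per-position residue fractions.
#' @export
position_frequency_matrix <- function(profile) {
  sweep(profile$positional_counts, 2, profile$n_sequences, "/")
}
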