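#' Select valid 15-mer peptides from extraction records
#'
#' Only valid display peptides of exactly 15 residues enter the frequency
#' and motif analyses; shorter or longer valid peptides (truncations) and
#' all invalid classes are dropped. Input order and multiplicity are
#' preserved.
#'
#' @param records Extraction records data.frame (from [extract_all()]).
#' @param length_aa Required peptide length (default 15).
#' @return Character vector of peptides.
#' @export
select_15mers <- function(records, length_aa = 15L) {
  keep <- records$validity == "valid" &
    !is.na(records$length_aa) & records$length_aa == length_aa
  records$peptide[keep]
}

#' Amino-acid composition profile of a peptide set
#'
#' Accumulates the total occurrence of each of the 20 amino acids over
#' all peptides and normalizes by the total number of residues, and
#' tallies per-position counts (positions 1..15, N- to C-terminus).
#'
#' @param peptides Character vector of peptides, all the same length,
#'   standard residues only.
#' @param round_label Label for this library/sorting round.
#' @param length_aa Expected peptide length (default 15).
#' @return Object of class `composition_profile`: list with
#'   `round_label`, `n_sequences`, `total_residues`, `freq` (named
#'   fraction vector summing to 1) and `positional_counts` (20 x
#'   `length_aa` integer matrix, residues x positions).
#' @export
#' @examples
#' p <- composition(c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC"), "demo")
#' p$freq[c("A", "C")]  # 0.5 each
composition <- function(peptides, round_label = "round", length_aa = 15L) {
  n <- length(peptides)
  if (n == 0) stop("no peptides supplied")
  if (any(nchar(peptides) != length_aa)) {
    stop("all peptides must have length ", length_aa)
  }
  pos_counts <- matrix(0L, nrow = 20L, ncol = length_aa,
                       dimnames = list(AA_STANDARD, seq_len(length_aa)))
  for (p in seq_len(length_aa)) {
    col <- substr(peptides, p, p)
    bad <- setdiff(unique(col), AA_STANDARD)
    if (length(bad) > 0) {
      stop("non-standard residues in input: ", paste(bad, collapse = ", "))
    }
    pos_counts[, p] <- tabulate(match(col, AA_STANDARD), nbins = 20L)
  }
  total <- n * length_aa
  counts <- rowSums(pos_counts)
  structure(list(round_label = round_label,
                 n_sequences = n,
                 total_residues = total,
                 freq = counts / total,
                 positional_counts = pos_counts),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("Amino-acid composition profile:", x$round_label, "\n")
  cat("  sequences:", x$n_sequences, " residues:", x$total_residues, "\n")
  print(round(100 * x$freq, 2))
  invisible(x)
}

#' Aggregate a composition profile into chemical classes
#'
#' Sums residue fractions within each category of a class scheme
#' (hydrophobic, non-polar, polar, basic, acidic by default). Category
#' fractions sum to 1.
#'
#' @param profile A [composition()] profile.
#' @param scheme Named character vector residue -> category (default
#'   [aa_class_scheme()]).
#' @return Named numeric vector of category fractions.
#' @export
class_aggregate <- function(profile, scheme = aa_class_scheme()) {
  validate_class_scheme(scheme)
  tapply(profile$freq[AA_STANDARD], scheme[AA_STANDARD], sum)
}

#' Length distribution of valid display peptides
#'
#' Histogram of peptide lengths over valid records only (all lengths,
#' not just 15-mers), e.g. to show what share of a displayed library is
#' full-length.
#'
#' @param records Extraction records data.frame (from [extract_all()]).
#' @return data.frame with columns `length_aa` and `count`, sorted by
#'   length; zero rows when there are no valid records.
#' @export
length_distribution <- function(records) {
  lens <- records$length_aa[records$validity == "valid"]
  if (length(lens) == 0) {
    return(data.frame(length_aa = integer(0), count = integer(0)))
  }
  tab <- table(lens)
  data.frame(length_aa = as.integer(names(tab)),
             count = as.integer(tab), row.names = NULL)
}

#' Per-residue frequency deltas across sorting rounds
#'
#' Compares each profile to the first (the unsorted library, by
#' convention) and reports per-residue deltas in percentage points:
#' `100 * (freq_round - freq_first)`.
#'
#' @param profiles List of two or more [composition()] profiles, in
#'   round order; the first is the baseline.
#' @return data.frame with one row per residue: `residue`, one
#'   `freq_<label>` column per profile (percent), and one
#'   `delta_<label>` column per non-baseline profile (percentage
#'   points).
#' @export
compare_rounds <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two profiles")
  labels <- vapply(profiles, function(p) p$round_label, "")
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  freqs <- vapply(profiles, function(p) p$freq[AA_STANDARD],
                  numeric(20L))
  colnames(freqs) <- labels
  out <- data.frame(residue = AA_STANDARD, 100 * freqs,
                    check.names = FALSE, row.names = NULL)
  names(out)[-1] <- paste0("freq_", labels)
  for (j in 2:length(labels)) {
    out[[paste0("delta_", labels[j])]] <-
      100 * (freqs[, j] - freqs[, 1])
  }
  out
}
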