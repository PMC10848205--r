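#' @importFrom Biostrings DNAStringSet AAStringSet GENETIC_CODE
#'   reverseComplement vmatchPattern writeXStringSet readDNAStringSet
#'   readAAStringSet translate startIndex
#' @importFrom stats runif sd aggregate setNames
#' @importFrom utils read.delim write.table
#' @importFrom methods is
NULL

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This is the canonical residue
#' ordering used throughout the package (frequency vectors, positional
#' count matrices, co-occurrence matrices).
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codons grouped by the residue they encode (standard code, stops excluded)
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA_STANDARD]
})

#' Default chemical-class scheme for the 20 amino acids
#'
#' Maps every residue to one of five categories: hydrophobic, non-polar,
#' polar, basic, acidic. Histidine is placed with the polar residues,
#' consistent with its behaviour at physiological pH in surface-binding
#' contexts. The assignment is a convention, not a law; supply your own
#' mapping (or load one from YAML with [read_class_scheme()]) when a
#' different partition is appropriate.
#'
#' @return Named character vector: names are residues, values categories.
#' @export
#' @examples
#' scheme <- aa_class_scheme()
#' scheme[["H"]]  # "polar"
aa_class_scheme <- function() {
  c(A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
    I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
    W = "hydrophobic",
    G = "non-polar", P = "non-polar", C = "non-polar",
    S = "polar", T = "polar", Y = "polar", N = "polar", Q = "polar",
    H = "polar",
    K = "basic", R = "basic",
    D = "acidic", E = "acidic")[AA_STANDARD]
}

#' Read a chemical-class scheme from a YAML file
#'
#' The file maps either residue -> category or category -> residue vector;
#' both layouts are accepted.
#'
#' @param path Path to a YAML file.
#' @return Named character vector residue -> category covering all 20
#'   residues.
#' @export
read_class_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  if (all(lengths(raw) == 1L) && all(names(raw) %in% AA_STANDARD)) {
    scheme <- unlist(raw)
  } else {
    scheme <- unlist(lapply(names(raw), function(cat) {
      setNames(rep(cat, length(raw[[cat]])), unlist(raw[[cat]]))
    }))
  }
  validate_class_scheme(scheme)
  scheme[AA_STANDARD]
}

validate_class_scheme <- function(scheme) {
  missing <- setdiff(AA_STANDARD, names(scheme))
  if (length(missing) > 0) {
    stop("class scheme is missing residues: ", paste(missing, collapse = ", "))
  }
  invisible(scheme)
}

# validate a residue->probability map; returns probabilities in AA_STANDARD
# order
validate_aa_probs <- function(aa_probs) {
  if (is.null(names(aa_probs)) ||
      !setequal(names(aa_probs), AA_STANDARD) ||
      length(aa_probs) != 20L) {
    stop("aa_probs must be a named vector over exactly the 20 standard ",
         "amino acids")
  }
  p <- as.numeric(aa_probs[AA_STANDARD])
  if (any(p < 0)) stop("aa_probs must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) {
    stop("aa_probs must sum to 1 (got ", format(sum(p), digits = 12), ")")
  }
  setNames(p, AA_STANDARD)
}

#' Uniform residue probabilities with selected residues fixed
#'
#' Builds a residue-probability map where the residues named in `fixed`
#' get the stated probabilities and the remaining mass is spread uniformly
#' over the other residues. With `fixed = NULL` the result is the uniform
#' map (0.05 each).
#'
#' @param fixed Named numeric vector of residue probabilities to pin
#'   (e.g. `c(G = 0.066)`), or NULL.
#' @return Named numeric vector over the 20 standard residues, summing
#'   to 1.
#' @export
#' @examples
#' p <- uniform_aa_probs(c(H = 0.105))
#' sum(p)  # 1
uniform_aa_probs <- function(fixed = NULL) {
  p <- setNames(rep(0.05, 20L), AA_STANDARD)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% AA_STANDARD)) {
      stop("'fixed' must be named with standard residues")
    }
    rest <- setdiff(AA_STANDARD, names(fixed))
    p[names(fixed)] <- fixed
    p[rest] <- (1 - sum(fixed)) / length(rest)
  }
  validate_aa_probs(p)
}
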