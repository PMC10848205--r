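#' Anchor configuration for insert extraction
#'
#' The display-peptide insert in the eCPX amplicon is bounded by fixed
#' nucleotide anchors: a precursor (wild type GGCCAGTCTGGCCAG, translating
#' to GQSGQ) and a postcursor (wild type GGCTCGAGC, translating to GSS).
#' Extraction returns the substring strictly between the first precursor
#' occurrence and the first postcursor occurrence after it.
#'
#' @param precursor,postcursor Anchor nucleotide strings (uppercase
#'   A/C/G/T).
#' @param max_mismatches Maximum mismatches tolerated per anchor
#'   (default 0, exact matching).
#' @param search_both_strands If TRUE (default) a read with no forward
#'   match is searched again as its reverse complement; a read matching
#'   both strands is resolved as forward.
#' @return An object of class `anchor_config`.
#' @export
anchor_config <- function(precursor = "GGCCAGTCTGGCCAG",
                          postcursor = "GGCTCGAGC",
                          max_mismatches = 0L,
                          search_both_strands = TRUE) {
  if (!grepl("^[ACGT]+$", precursor) || !grepl("^[ACGT]+$", postcursor)) {
    stop("anchors must be non-empty uppercase A/C/G/T strings")
  }
  stopifnot(max_mismatches >= 0)
  structure(list(precursor = precursor, postcursor = postcursor,
                 max_mismatches = as.integer(max_mismatches),
                 search_both_strands = isTRUE(search_both_strands)),
            class = "anchor_config")
}

# locate inserts in a character vector of reads, one strand only.
# Returns character vector of inserts, NA where no anchor pair found.
locate_inserts <- function(reads, anchors) {
  n <- length(reads)
  insert <- rep(NA_character_, n)
  if (n == 0) return(insert)
  pre <- anchors$precursor
  post <- anchors$postcursor
  mm <- anchors$max_mismatches
  if (mm == 0L) {
    pre_pos <- regexpr(pre, reads, fixed = TRUE)
    hit <- pre_pos > 0L
    if (any(hit)) {
      after <- substr(reads[hit], pre_pos[hit] + nchar(pre),
                      nchar(reads[hit]))
      post_pos <- regexpr(post, after, fixed = TRUE)
      ok <- post_pos > 0L
      found <- which(hit)[ok]
      insert[found] <- substr(after[ok], 1L, post_pos[ok] - 1L)
    }
  } else {
    subj <- Biostrings::DNAStringSet(reads)
    pre_m <- Biostrings::vmatchPattern(pre, subj, max.mismatch = mm)
    post_m <- Biostrings::vmatchPattern(post, subj, max.mismatch = mm)
    pre_s <- Biostrings::startIndex(pre_m)
    post_s <- Biostrings::startIndex(post_m)
    for (i in seq_len(n)) {
      ps <- pre_s[[i]]
      if (is.null(ps) || length(ps) == 0) next
      p1 <- min(ps)
      end1 <- p1 + nchar(pre)        # first position after the precursor
      qs <- post_s[[i]]
      qs <- qs[qs >= end1]
      if (length(qs) == 0) next
      insert[i] <- substr(reads[i], end1, min(qs) - 1L)
    }
  }
  insert
}

#' Locate the anchor-bounded insert in a single read
#'
#' Searches the forward strand first; if nothing is found and
#' `search_both_strands` is set, the reverse complement is searched.
#'
#' @param read A nucleotide string (A/C/G/T/N).
#' @param anchors An [anchor_config()].
#' @return List with `insert_nt` (string, possibly empty; NA when no
#'   anchor pair is found) and `strand` ("forward", "reverse", or NA).
#' @export
#' @examples
#' r <- paste0("AA", "GGCCAGTCTGGCCAG", "CATCATCAT", "GGCTCGAGC", "TT")
#' find_anchored_insert(r, anchor_config())  # insert "CATCATCAT", forward
find_anchored_insert <- function(read, anchors = anchor_config()) {
  stopifnot(length(read) == 1L, nchar(read) > 0)
  ins <- locate_inserts(read, anchors)
  if (!is.na(ins)) {
    return(list(insert_nt = ins, strand = "forward"))
  }
  if (anchors$search_both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(read)))
    ins <- locate_inserts(rc, anchors)
    if (!is.na(ins)) {
      return(list(insert_nt = ins, strand = "reverse"))
    }
  }
  list(insert_nt = NA_character_, strand = NA_character_)
}

#' Translate insert nucleotides to peptides
#'
#' Standard-codon-table translation. Stop codons are rendered as `*`;
#' codons containing a non-ACGT base (e.g. N) as `X`. The first codon is
#' not treated as an initiator, so leading TTG/CTG translate as L, not M.
#'
#' @param insert_nt Character vector of nucleotide strings, each of
#'   length a multiple of 3 (callers must classify frame shifts first).
#' @return Character vector of peptide strings with `*`/`X` markers.
#' @export
#' @examples
#' translate_insert("GGCCAGTCTGGCCAG")  # "GQSGQ"
#' translate_insert("GGCTCGAGC")        # "GSS"
translate_insert <- function(insert_nt) {
  if (any(nchar(insert_nt) %% 3L != 0L)) {
    stop("insert length must be a multiple of 3; classify frame shifts ",
         "before translating")
  }
  out <- character(length(insert_nt))
  nonempty <- nchar(insert_nt) > 0L
  if (any(nonempty)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(insert_nt[nonempty]),
                                no.init.codon = TRUE,
                                if.fuzzy.codon = "X")
    out[nonempty] <- as.character(aa)
  }
  out
}

#' Classify extracted inserts
#'
#' Deterministic mapping from an insert nucleotide string to a validity
#' class, in this priority: `NA` (no anchor pair) -> `no_anchor`; empty
#' -> `blank`; length not a multiple of 3 -> `frame_shift`; translation
#' containing a stop -> `stop_codon`; translation containing an unknown
#' residue -> `unknown_residue`; otherwise `valid` with the translated
#' peptide. Stop codons take precedence over unknown residues when both
#' occur in one insert.
#'
#' @param insert_nt Character vector of insert nucleotide strings; NA
#'   means no anchor pair was found.
#' @return data.frame with columns `validity`, `peptide` (NA unless
#'   valid) and `length_aa` (NA unless valid).
#' @export
#' @examples
#' classify_insert(c("CATCAT", "CATCA", "", "CATTAACAT", NA))
classify_insert <- function(insert_nt) {
  n <- length(insert_nt)
  validity <- rep("valid", n)
  peptide <- rep(NA_character_, n)
  w <- nchar(insert_nt)
  validity[is.na(insert_nt)] <- "no_anchor"
  validity[!is.na(insert_nt) & w == 0L] <- "blank"
  validity[validity == "valid" & w %% 3L != 0L] <- "frame_shift"
  todo <- validity == "valid"
  if (any(todo)) {
    pep <- translate_insert(insert_nt[todo])
    has_stop <- grepl("*", pep, fixed = TRUE)
    has_unknown <- grepl("X", pep, fixed = TRUE)
    v <- rep("valid", sum(todo))
    v[has_unknown] <- "unknown_residue"
    v[has_stop] <- "stop_codon"   # stop outranks unknown
    validity[todo] <- v
    peptide[todo][v == "valid"] <- pep[v == "valid"]
  }
  data.frame(validity = validity, peptide = peptide,
             length_aa = ifelse(validity == "valid", nchar(peptide),
                                NA_integer_),
             stringsAsFactors = FALSE)
}

#' Extract and classify inserts from a whole FASTQ library
#'
#' Runs the full extraction procedure over every read: locate the
#' anchor-bounded insert (forward strand first, then reverse complement),
#' translate, and classify. Reads are processed in file order; duplicates
#' are kept (downstream analyses count sequence occurrences).
#'
#' @param reads A FASTQ/FASTQ.gz path, a character vector of read
#'   sequences (optionally named with read ids), or a
#'   [Biostrings::DNAStringSet].
#' @param anchors An [anchor_config()].
#' @return List with `records` (data.frame: read_id, strand, validity,
#'   insert_nt, peptide, length_aa — one row per read, input order) and
#'   `summary` (named integer vector of per-class counts, summing to the
#'   read count).
#' @export
extract_all <- function(reads, anchors = anchor_config()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    dss <- Biostrings::readDNAStringSet(reads, format = "fastq")
    ids <- sub(" .*", "", names(dss))
    seqs <- as.character(dss)
  } else if (methods::is(reads, "DNAStringSet")) {
    ids <- names(reads)
    seqs <- as.character(reads)
  } else if (is.character(reads)) {
    ids <- names(reads)
    seqs <- unname(reads)
  } else {
    stop("'reads' must be a FASTQ path, character vector, or DNAStringSet")
  }
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("read_%07d", seq_len(n))

  insert <- locate_inserts(seqs, anchors)
  strand <- ifelse(is.na(insert), NA_character_, "forward")
  if (anchors$search_both_strands && anyNA(insert)) {
    miss <- which(is.na(insert))
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[miss])))
    ins_rc <- locate_inserts(rc, anchors)
    got <- !is.na(ins_rc)
    insert[miss[got]] <- ins_rc[got]
    strand[miss[got]] <- "reverse"
  }

  cls <- classify_insert(insert)
  records <- data.frame(read_id = ids, strand = strand,
                        validity = cls$validity, insert_nt = insert,
                        peptide = cls$peptide, length_aa = cls$length_aa,
                        stringsAsFactors = FALSE)
  classes <- c("valid", "stop_codon", "frame_shift", "blank",
               "unknown_residue", "no_anchor")
  summary <- setNames(
    vapply(classes, function(k) sum(records$validity == k), 0L), classes)
  list(records = records, summary = summary)
}
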