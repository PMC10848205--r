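#' Configuration for the synthetic amplicon-read generator
#'
#' Describes a simulated sequencing library of single-end Illumina-style
#' amplicon reads carrying a `[precursor]-[insert]-[postcursor]` structure.
#' The generator is the ground-truth oracle for the extraction and
#' composition stages: every read's intended validity class, peptide and
#' strand are recorded alongside the FASTQ output.
#'
#' Corruption events are mutually exclusive per read, resolved in priority
#' order blank > frame shift > stop codon > ambiguous base, so each read
#' has exactly one intended class. Independent per-event draws are made
#' and the highest-priority event that fires wins; when only a single
#' rate is nonzero the realized class probability therefore equals that
#' rate.
#'
#' @param n_reads Number of reads to emit (positive integer).
#' @param insert_length_aa Distribution of insert lengths in residues:
#'   a named numeric vector mapping length -> probability (default a
#'   point mass at 15).
#' @param aa_probs Residue-probability map for insert composition
#'   (default uniform). Must be named over the 20 standard residues and
#'   sum to 1.
#' @param stop_codon_rate Probability per read that one codon of the
#'   insert is replaced by a stop codon.
#' @param frameshift_rate Probability per read of a single +/-1 nt indel
#'   at a uniform position inside the insert.
#' @param blank_rate Probability per read of an empty insert (precursor
#'   immediately followed by postcursor).
#' @param ambiguous_rate Probability per read that one insert base is
#'   replaced by 'N'.
#' @param revcomp_rate Probability per read of emission as the reverse
#'   complement.
#' @param read_length Read length in nt (default 151, iSeq-style).
#' @param flank_lengths Integer pair: fixed number of random context nt
#'   before the precursor and minimum after the postcursor; the read is
#'   padded with random nt to `read_length`.
#' @param precursor,postcursor Anchor nucleotide sequences flanking the
#'   insert.
#' @param seed Integer seed; identical configurations (including seed)
#'   produce byte-identical FASTQ output.
#'
#' @return An object of class `sim_config`.
#' @seealso [generate_fastq()]
#' @export
sim_config <- function(n_reads,
                       insert_length_aa = c("15" = 1),
                       aa_probs = uniform_aa_probs(),
                       stop_codon_rate = 0,
                       frameshift_rate = 0,
                       blank_rate = 0,
                       ambiguous_rate = 0,
                       revcomp_rate = 0,
                       read_length = 151L,
                       flank_lengths = c(10L, 10L),
                       precursor = "GGCCAGTCTGGCCAG",
                       postcursor = "GGCTCGAGC",
                       seed = 1L) {
  stopifnot(length(n_reads) == 1L, n_reads >= 1, n_reads == floor(n_reads))
  aa_probs <- validate_aa_probs(aa_probs)
  rates <- c(stop_codon_rate = stop_codon_rate,
             frameshift_rate = frameshift_rate,
             blank_rate = blank_rate,
             ambiguous_rate = ambiguous_rate,
             revcomp_rate = revcomp_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rate parameters must lie in [0, 1]")
  }
  len_p <- as.numeric(insert_length_aa)
  lens <- as.integer(names(insert_length_aa))
  if (anyNA(lens) || any(lens < 0) || any(len_p < 0) ||
      abs(sum(len_p) - 1) > 1e-9) {
    stop("insert_length_aa must map non-negative integer lengths to ",
         "probabilities summing to 1")
  }
  if (!grepl("^[ACGT]+$", precursor) || !grepl("^[ACGT]+$", postcursor)) {
    stop("anchors must be non-empty uppercase A/C/G/T strings")
  }
  # +1 nt: a frameshift insertion can lengthen the insert by one base
  max_anchored <- nchar(precursor) + 3L * max(lens) + 1L + nchar(postcursor)
  if (flank_lengths[1] + max_anchored > read_length) {
    stop("anchored region (", max_anchored, " nt at the longest insert) ",
         "plus leading flank does not fit in read_length = ", read_length)
  }
  structure(list(n_reads = as.integer(n_reads),
                 insert_length_aa = setNames(len_p, names(insert_length_aa)),
                 aa_probs = aa_probs,
                 stop_codon_rate = stop_codon_rate,
                 frameshift_rate = frameshift_rate,
                 blank_rate = blank_rate,
                 ambiguous_rate = ambiguous_rate,
                 revcomp_rate = revcomp_rate,
                 read_length = as.integer(read_length),
                 flank_lengths = as.integer(flank_lengths),
                 precursor = precursor,
                 postcursor = postcursor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a random peptide
#'
#' Draws `length` residues i.i.d. from a residue-probability map. Uses
#' the current RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param aa_probs Named probability vector over the 20 standard residues.
#' @param length Non-negative number of residues.
#' @return A peptide string (possibly empty).
#' @export
#' @examples
#' set.seed(1)
#' sample_peptide(uniform_aa_probs(), 15)
sample_peptide <- function(aa_probs, length) {
  p <- validate_aa_probs(aa_probs)
  stopifnot(length >= 0)
  if (length == 0) return("")
  paste(sample(AA_STANDARD, length, replace = TRUE, prob = p),
        collapse = "")
}

# concatenate a flat element vector into one string per group, where
# group i takes the next lens[i] elements; fast matrix path when all
# nonzero group sizes are equal
paste_groups <- function(x, lens) {
  out <- character(length(lens))
  L <- unique(lens[lens > 0])
  if (length(L) == 0L) return(out)
  if (length(L) == 1L) {
    m <- matrix(x, ncol = L, byrow = TRUE)
    out[lens > 0] <- do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
  } else {
    idx <- rep.int(seq_along(lens), lens)
    grp <- split.default(x, factor(idx, levels = unique(idx)))
    out[lens > 0] <- vapply(grp, paste, "", collapse = "")
  }
  out
}

# vectorized residue sampling: one string per entry of `lengths`
sample_peptides <- function(aa_probs, lengths) {
  res <- sample(AA_STANDARD, sum(lengths), replace = TRUE, prob = aa_probs)
  paste_groups(res, lengths)
}

#' Encode a peptide as nucleotides with random synonymous codons
#'
#' Inverse of translation under the standard codon table: each residue is
#' encoded by one of its synonymous codons chosen uniformly at random, so
#' `translate_insert(encode_insert(p))` recovers `p`. Uses the current
#' RNG stream.
#'
#' @param peptide Peptide string over the 20 standard residues (may be
#'   empty).
#' @return Nucleotide string of length `3 * nchar(peptide)`.
#' @export
#' @examples
#' encode_insert("M")  # "ATG" (methionine has a single codon)
encode_insert <- function(peptide) {
  stopifnot(length(peptide) == 1L)
  if (nchar(peptide) == 0) return("")
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (!all(res %in% AA_STANDARD)) {
    stop("peptide contains non-standard residues: ",
         paste(unique(setdiff(res, AA_STANDARD)), collapse = ", "))
  }
  paste(encode_residues(res), collapse = "")
}

# codon lookup matrix: row per residue, padded to the widest codon family
.codon_matrix <- local({
  w <- max(lengths(.codons_by_aa))
  m <- matrix(NA_character_, nrow = 20L, ncol = w,
              dimnames = list(AA_STANDARD, NULL))
  for (a in AA_STANDARD) m[a, seq_along(.codons_by_aa[[a]])] <- .codons_by_aa[[a]]
  m
})

# vectorized codon choice for a residue vector
encode_residues <- function(res) {
  if (length(res) == 0) return(character(0))
  ai <- match(res, AA_STANDARD)
  ncod <- lengths(.codons_by_aa)[ai]
  pick <- floor(runif(length(res)) * ncod) + 1L
  .codon_matrix[cbind(ai, pick)]
}

random_nt <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_nt_vec <- function(lens) {
  nt <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
  paste_groups(nt, lens)
}

#' Generate a synthetic FASTQ library with per-read ground truth
#'
#' Emits `config$n_reads` single-end reads, each built as random flank +
#' precursor + insert + postcursor + random padding to `read_length`,
#' with corruption events applied per the configured rates (see
#' [sim_config()] for the priority rule) and recorded as ground truth.
#' Reads selected for reverse-complement emission are flipped as whole
#' reads and flagged. Base quality is constant Q37 ('F'); the downstream
#' pipeline never consumes quality.
#'
#' A read whose sampled insert length is 0 is recorded as class `blank`
#' whatever corruption event was drawn: an empty insert can hold neither
#' a stop codon nor an indel.
#'
#' @param config A [sim_config()] object.
#' @param fastq_path Output FASTQ path; a `.gz` suffix triggers gzip
#'   compression. `NULL` skips writing and returns reads in memory.
#' @param ground_truth_path Optional TSV path for the ground-truth table.
#' @return List with elements `fastq` (path or NULL), `reads` (character
#'   vector of read sequences, named by read id) and `ground_truth`
#'   (data.frame: read_id, class, peptide, insert_nt, strand).
#' @export
generate_fastq <- function(config, fastq_path = NULL,
                           ground_truth_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n <- config$n_reads
  # per-event draws, resolved by priority blank > frameshift > stop > ambig
  ev_blank <- runif(n) < config$blank_rate
  ev_fs <- runif(n) < config$frameshift_rate
  ev_stop <- runif(n) < config$stop_codon_rate
  ev_amb <- runif(n) < config$ambiguous_rate
  class <- rep("valid", n)
  class[ev_amb] <- "unknown_residue"
  class[ev_stop] <- "stop_codon"
  class[ev_fs] <- "frame_shift"
  class[ev_blank] <- "blank"

  lens <- as.integer(names(config$insert_length_aa))
  len <- if (length(lens) == 1L) rep(lens, n) else {
    sample(lens, n, replace = TRUE, prob = config$insert_length_aa)
  }
  len[class == "blank"] <- 0L
  class[len == 0L] <- "blank"  # empty insert is blank whatever was drawn

  # build peptide/insert/forward-read for a batch of intents
  make_reads <- function(class, len) {
    m <- length(class)
    peptide <- sample_peptides(config$aa_probs, len)
    # encode all residues in one vectorized pass; read i owns codons
    # offset[i]+1 .. offset[i]+len[i] of the flat vector
    res_flat <- unlist(strsplit(peptide, "", fixed = TRUE),
                       use.names = FALSE)
    codon_flat <- encode_residues(res_flat)
    offset <- c(0L, cumsum(len))

    # stop-codon injection: replace one codon at a uniform position
    stops <- c("TAA", "TAG", "TGA")
    for (i in which(class == "stop_codon")) {
      pos <- sample.int(len[i], 1L)
      codon_flat[offset[i] + pos] <- stops[sample.int(3L, 1L)]
    }
    insert <- paste_groups(codon_flat, len)

    # frameshift: single +/-1 nt indel at a uniform insert position
    for (i in which(class == "frame_shift")) {
      s <- insert[i]
      w <- nchar(s)
      if (runif(1) < 0.5) {           # deletion
        pos <- sample.int(w, 1L)
        insert[i] <- paste0(substr(s, 1L, pos - 1L),
                            substr(s, pos + 1L, w))
      } else {                        # insertion after position `pos`
        pos <- sample.int(w + 1L, 1L) - 1L
        insert[i] <- paste0(substr(s, 1L, pos),
                            sample(c("A", "C", "G", "T"), 1L),
                            substr(s, pos + 1L, w))
      }
    }

    # ambiguous base: one insert position replaced by N
    for (i in which(class == "unknown_residue")) {
      s <- insert[i]
      pos <- sample.int(nchar(s), 1L)
      substr(s, pos, pos) <- "N"
      insert[i] <- s
    }

    anchored <- paste0(config$precursor, insert, config$postcursor)
    lead <- random_nt_vec(rep(config$flank_lengths[1], m))
    pad <- pmax(config$read_length - nchar(anchored) -
                  config$flank_lengths[1], 0L)
    trail <- random_nt_vec(pad)
    list(peptide = peptide, insert = insert,
         fwd = paste0(lead, anchored, trail))
  }

  rc <- runif(n) < config$revcomp_rate
  anch <- anchor_config(config$precursor, config$postcursor)

  # rejection sampling keeps the anchor pair unambiguous by construction:
  # a read is redrawn (same intended class/length/strand) if chance
  # placement of an anchor string in the insert or flanks would make the
  # extractor recover anything but the intended insert on the intended
  # strand
  batch <- make_reads(class, len)
  peptide <- batch$peptide; insert <- batch$insert; fwd <- batch$fwd
  for (iter in seq_len(50L)) {
    ins_f <- locate_inserts(fwd, anch)
    ok <- !is.na(ins_f) & ins_f == insert
    if (any(ok & rc)) {
      # reverse-emitted reads must not also match in emitted orientation
      idx <- which(ok & rc)
      emitted_rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fwd[idx])))
      ok[idx] <- is.na(locate_inserts(emitted_rc, anch))
    }
    if (all(ok)) break
    bad <- which(!ok)
    redo <- make_reads(class[bad], len[bad])
    peptide[bad] <- redo$peptide
    insert[bad] <- redo$insert
    fwd[bad] <- redo$fwd
  }
  if (!all(ok)) {
    stop("could not generate unambiguous reads for these anchors; ",
         "check that the anchors do not trivially occur in random context")
  }

  reads <- fwd
  if (any(rc)) {
    reads[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[rc])))
  }
  strand <- ifelse(rc, "reverse", "forward")

  read_id <- sprintf("sim_%07d", seq_len(n))
  names(reads) <- read_id
  gt <- data.frame(read_id = read_id, class = class,
                   peptide = peptide,
                   insert_nt = insert, strand = strand,
                   stringsAsFactors = FALSE)

  if (!is.null(fastq_path)) {
    con <- if (grepl("\\.gz$", fastq_path)) {
      gzfile(fastq_path, "wb")
    } else {
      file(fastq_path, "wb")
    }
    qual <- strrep("F", config$read_length)
    writeLines(paste0("@", read_id, "\n", reads, "\n+\n", qual), con,
               sep = "\n")
    close(con)
  }
  if (!is.null(ground_truth_path)) {
    write.table(gt, ground_truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(fastq = fastq_path, reads = reads, ground_truth = gt)
}
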