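PRE <- "GGCCAGTCTGGCCAG"
POST <- "GGCTCGAGC"

test_that("find_anchored_insert recovers the bounded insert on both strands", {
  read <- paste0("AA", PRE, "CATCATCAT", POST, "TT")
  hit <- find_anchored_insert(read)
  expect_identical(hit$insert_nt, "CATCATCAT")
  expect_identical(hit$strand, "forward")

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read)))
  hit_rc <- find_anchored_insert(rc)
  expect_identical(hit_rc$insert_nt, "CATCATCAT")
  expect_identical(hit_rc$strand, "reverse")

  # adjacent anchors: empty insert, still found on the forward strand
  blank <- find_anchored_insert(paste0(PRE, POST))
  expect_identical(blank$insert_nt, "")
  expect_identical(blank$strand, "forward")

  # no anchors at all
  miss <- find_anchored_insert(strrep("ACGT", 30))
  expect_true(is.na(miss$insert_nt))
})

test_that("single-strand search ignores reverse-complemented reads", {
  read <- paste0("AA", PRE, "CATCATCAT", POST, "TT")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read)))
  one <- anchor_config(search_both_strands = FALSE)
  expect_true(is.na(find_anchored_insert(rc, one)$insert_nt))
})

test_that("anchor matching honours the mismatch budget", {
  pre_mm <- sub("^GG", "GT", PRE)  # one mismatch in the precursor
  read <- paste0("AA", pre_mm, "CATCATCAT", POST, "TT")
  expect_true(is.na(find_anchored_insert(read)$insert_nt))
  fuzzy <- anchor_config(max_mismatches = 1)
  expect_identical(find_anchored_insert(read, fuzzy)$insert_nt, "CATCATCAT")
})

test_that("first-occurrence rule bounds the insert deterministically", {
  # two postcursor occurrences: the first one after the precursor wins
  read <- paste0(PRE, "AAATTT", POST, "CCC", POST)
  expect_identical(find_anchored_insert(read)$insert_nt, "AAATTT")
  # two precursor occurrences: the first one wins
  read2 <- paste0(PRE, "AAA", PRE, "TTTTTT", POST)
  expect_identical(find_anchored_insert(read2)$insert_nt,
                   paste0("AAA", PRE, "TTTTTT"))
})

test_that("translation follows the standard codon table with markers", {
  expect_identical(translate_insert(PRE), "GQSGQ")
  expect_identical(translate_insert(POST), "GSS")
  expect_identical(translate_insert("TAA"), "*")
  expect_identical(translate_insert("CATNATCAT"), "HXH")
  expect_identical(translate_insert(""), "")
  # leading TTG is leucine, not an initiator methionine
  expect_identical(translate_insert("TTGAAA"), "LK")
  expect_error(translate_insert("CATCA"), "multiple of 3")
})

test_that("classification maps inserts to the validity partition", {
  cls <- classify_insert(c(strrep("CAT", 15), "CATCA", "",
                           "CATTAACAT", NA, "CATNATCAT"))
  expect_identical(cls$validity,
                   c("valid", "frame_shift", "blank", "stop_codon",
                     "no_anchor", "unknown_residue"))
  expect_identical(cls$peptide[1], strrep("H", 15))
  expect_identical(cls$length_aa[1], 15L)
  expect_true(all(is.na(cls$peptide[-1])))
  # stop codon outranks unknown residue when both occur
  expect_identical(classify_insert("TAANNN")$validity, "stop_codon")
})

test_that("extract_all conserves reads across the class partition", {
  sim <- generate_fastq(clean_config(1000))
  ex <- extract_all(sim$reads)
  expect_identical(sum(ex$summary), 1000L)
  expect_identical(unname(ex$summary["valid"]), 1000L)

  blanks <- generate_fastq(sim_config(500, blank_rate = 1, seed = 21))
  exb <- extract_all(blanks$reads)
  expect_identical(unname(exb$summary["blank"]), 500L)
  expect_identical(unname(exb$summary["valid"]), 0L)
})

test_that("extraction agrees with simulator ground truth exactly", {
  cfg <- sim_config(n_reads = 5000, stop_codon_rate = 0.1,
                    frameshift_rate = 0.05, blank_rate = 0.05,
                    ambiguous_rate = 0.05, revcomp_rate = 0.5,
                    insert_length_aa = c("15" = 0.8, "12" = 0.2),
                    seed = 22)
  f <- withr::local_tempfile(fileext = ".fastq.gz")
  sim <- generate_fastq(cfg, fastq_path = f)
  ex <- extract_all(f)
  expect_identical(ex$records$validity, sim$ground_truth$class)
  expect_identical(ex$records$strand, sim$ground_truth$strand)
  expect_identical(ex$records$insert_nt, sim$ground_truth$insert_nt)
  valid <- sim$ground_truth$class == "valid"
  expect_identical(ex$records$peptide[valid], sim$ground_truth$peptide[valid])
})

test_that("reverse-complementing every read changes only the strand field", {
  sim <- generate_fastq(clean_config(300, seed = 23))
  ex_f <- extract_all(sim$reads)
  flipped <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sim$reads)))
  names(flipped) <- names(sim$reads)
  ex_r <- extract_all(flipped)
  expect_identical(ex_r$records$insert_nt, ex_f$records$insert_nt)
  expect_identical(ex_r$records$peptide, ex_f$records$peptide)
  expect_identical(ex_r$records$validity, ex_f$records$validity)
  expect_true(all(ex_f$records$strand == "forward"))
  expect_true(all(ex_r$records$strand == "reverse"))
})

test_that("extraction is idempotent and order-preserving", {
  sim <- generate_fastq(sim_config(200, revcomp_rate = 0.5, seed = 24))
  e1 <- extract_all(sim$reads)
  e2 <- extract_all(sim$reads)
  expect_identical(e1, e2)
  expect_identical(e1$records$read_id, sim$ground_truth$read_id)
})

test_that("extract_all round-trips through FASTQ and FASTQ.gz files", {
  cfg <- clean_config(100, seed = 25)
  plain <- withr::local_tempfile(fileext = ".fastq")
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  sim <- generate_fastq(cfg, fastq_path = plain)
  generate_fastq(cfg, fastq_path = gz)
  from_mem <- extract_all(sim$reads)
  from_plain <- extract_all(plain)
  from_gz <- extract_all(gz)
  expect_identical(from_plain, from_mem)
  expect_identical(from_gz, from_mem)
  expect_error(extract_all(list()), "must be")
})
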