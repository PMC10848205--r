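# independent brute-force oracles used to cross-check the motif statistics
brute_kmers <- function(peptides, k) {
  counts <- new.env()
  for (p in peptides) {
    for (i in seq_len(nchar(p) - k + 1)) {
      frag <- substr(p, i, i + k - 1)
      counts[[frag]] <- (if (is.null(counts[[frag]])) 0L else counts[[frag]]) + 1L
    }
  }
  out <- unlist(as.list(counts))
  out[order(-out, names(out))]
}

brute_cooccurrence <- function(peptides) {
  m <- matrix(0, 20, 20, dimnames = list(AA_STANDARD, AA_STANDARD))
  for (p in peptides) {
    res <- strsplit(p, "")[[1]]
    L <- length(res)
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        a <- res[i]; b <- res[j]
        m[a, b] <- m[a, b] + 1
        if (a != b) m[b, a] <- m[b, a] + 1
      }
    }
  }
  m
}

brute_rank <- function(peptides, top_n) {
  u <- sort(unique(peptides))
  cnt <- vapply(u, function(p) sum(peptides == p), 0L)
  ord <- order(-cnt, u)
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(peptide = u[keep], count = cnt[keep], row.names = NULL,
             stringsAsFactors = FALSE)
}

test_that("k-mer fragment counts obey the sliding-window rule", {
  expect_identical(kmer_fragments(strrep("A", 15)),
                   c(AAAA = 12L))
  expect_identical(length(kmer_fragments(character(0))), 0L)
  peps <- random_peptides(1000, seed = 51)
  tab <- kmer_fragments(peps, k = 4)
  expect_identical(sum(tab), 12000L)
  expect_error(kmer_fragments(peps, k = 16), "exceeds")
  # k = 1 degenerates to residue counting
  k1 <- kmer_fragments(peps[1:10], k = 1)
  expect_identical(sum(k1), 150L)
})

test_that("co-occurrence counting matches the combinatorial oracle", {
  m1 <- cooccurrence(strrep("H", 15))
  expect_identical(m1$counts["H", "H"], 105)
  expect_identical(sum(m1$counts), 105)

  # alternating 8 A's and 7 C's: 8*7 cross pairs, C(8,2) and C(7,2) within
  m2 <- cooccurrence(paste(rep(c("A", "C"), length.out = 15), collapse = ""))
  expect_identical(m2$counts["A", "C"], 56)
  expect_identical(m2$counts["C", "A"], 56)
  expect_identical(m2$counts["A", "A"], 28)
  expect_identical(m2$counts["C", "C"], 21)
})

test_that("co-occurrence is symmetric, position-free and mass-conserving", {
  peps <- random_peptides(300, seed = 52)
  m <- cooccurrence(peps)
  expect_identical(m$counts, t(m$counts))
  upper_mass <- sum(m$counts[upper.tri(m$counts, diag = TRUE)])
  expect_identical(upper_mass, 105 * 300)
  expect_equal(sum(m$fraction[upper.tri(m$fraction, diag = TRUE)]), 1,
               tolerance = 1e-12)

  # permuting residues within each peptide leaves the matrix unchanged
  set.seed(53)
  shuffled <- vapply(strsplit(peps, ""), function(r) {
    paste(sample(r), collapse = "")
  }, "")
  expect_identical(cooccurrence(shuffled)$counts, m$counts)
})

test_that("presence mode counts each residue pair once per sequence", {
  m <- cooccurrence(c("ACACACACACACACA", strrep("A", 15)),
                    mode = "presence")
  expect_identical(m$counts["A", "C"], 1)
  expect_identical(m$counts["A", "A"], 2)
  expect_identical(m$counts["C", "C"], 1)
})

test_that("sequence ranking counts exactly with deterministic tie-break", {
  a <- strrep("A", 15); c15 <- strrep("C", 15)
  rk <- rank_sequences(c(a, a, a, c15), top_n = 2)
  expect_identical(rk$peptide, c(a, c15))
  expect_identical(rk$count, c(3L, 1L))
  expect_equal(rk$fraction, c(0.75, 0.25))

  # all-unique input: ties broken lexicographically
  peps <- unique(random_peptides(50, seed = 54))
  rk5 <- rank_sequences(peps, top_n = 5)
  expect_identical(rk5$peptide, sort(peps)[1:5])
  expect_true(all(rk5$count == 1L))
})

test_that("a spiked sequence dominates the ranking at its spike rate", {
  spike <- strrep("W", 15)
  set.seed(55)
  background <- random_peptides(99000, seed = 55)
  peps <- sample(c(rep(spike, 1000), background))
  rk <- rank_sequences(peps, top_n = 10)
  expect_identical(rk$peptide[1], spike)
  expect_lt(abs(rk$count[1] - 1000), 5 * sqrt(1000))
})

test_that("motif statistics match brute-force enumeration on small sets", {
  for (s in 61:62) {
    peps <- c(random_peptides(18, seed = s), strrep("H", 15),
              strrep("H", 15))
    expect_identical(kmer_fragments(peps, 4), brute_kmers(peps, 4))
    expect_identical(cooccurrence(peps)$counts, brute_cooccurrence(peps))
    got <- rank_sequences(peps, top_n = 10)
    want <- brute_rank(peps, 10)
    expect_identical(got$peptide, want$peptide)
    expect_identical(got$count, want$count)
  }
})

test_that("overlap returns the deduplicated intersection in set-a order", {
  a <- random_peptides(40, seed = 63)
  b <- random_peptides(40, seed = 64)
  expect_identical(overlap_peptides(a, b), character(0))
  expect_identical(overlap_peptides(a, a), unique(a))

  planted <- random_peptides(7, seed = 65)
  set.seed(66)
  a2 <- sample(c(a, planted))
  b2 <- sample(c(b, planted))
  expect_setequal(overlap_peptides(a2, b2), planted)
  expect_identical(overlap_peptides(a2, b2),
                   unique(a2)[unique(a2) %in% planted])
})

test_that("position frequency matrix columns sum to one", {
  prof <- composition(random_peptides(80, seed = 67), "pfm")
  pfm <- position_frequency_matrix(prof)
  expect_equal(unname(colSums(pfm)), rep(1, 15))
  expect_identical(dim(pfm), c(20L, 15L))
})
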