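test_that("k-mer codes round-trip and reverse-complement correctly", {
  kmers <- c("AAA", "ACG", "TTT", "GAT")
  codes <- kmer_to_code(kmers)
  expect_identical(code_to_kmer(codes, 3), kmers)
  expect_identical(code_to_kmer(revcomp_code(codes, 3), 3),
                   c("TTT", "CGT", "AAA", "ATC"))
  expect_identical(revcomp(c("ACGT", "AANT")), c("ACGT", "ANTT"))
  # window codes skip non-ACGT windows
  b <- dna_to_base_codes("ACGNT")
  expect_true(all(is.na(window_codes(b, 3)[2:3])))
  expect_identical(code_to_kmer(window_codes(b, 2)[1], 2), "AC")
})

test_that("dedupe collapses exact duplicates and validates lengths", {
  lib <- selex_library(c("ACGTACGT", "ACGTACGT", "ACGTACGT", "TTTTAAAA"),
                       round = 4)
  dd <- dedupe_reads(lib)
  expect_equal(length(dd$reads), 2)
  expect_true(dd$deduplicated)
  expect_equal(attr(dd, "n_removed"), 2)
  # all-unique library unchanged
  lib2 <- selex_library(c("ACGT", "TTTT", "GGGG"))
  expect_equal(length(dedupe_reads(lib2)$reads), 3)
  # N reads with d duplicates leave N - d survivors
  set.seed(30)
  base <- replicate(40, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                              collapse = ""))
  dup_idx <- sample(40, 15, replace = FALSE)
  lib3 <- selex_library(c(base, base[dup_idx]))
  expect_equal(length(dedupe_reads(lib3)$reads), 40)
  expect_error(dedupe_reads(selex_library(c("ACGT", "ACG"))), "unequal length")
})

test_that("shuffling preserves per-read composition and the null distribution", {
  # homopolymer is unchanged; shuffles are anagrams
  lib <- selex_library(c("AAAAAAAA", "ACGTACGT", "GGGGCCCC"))
  sh <- shuffle_library(lib, seed = 3)
  expect_identical(sh$reads[1], "AAAAAAAA")
  for (i in 1:3) {
    expect_identical(sort(strsplit(sh$reads[i], "")[[1]]),
                     sort(strsplit(lib$reads[i], "")[[1]]))
  }
  expect_identical(shuffle_library(lib, seed = 3)$reads, sh$reads)
  # times > 1 replicates the library before shuffling
  sh3 <- shuffle_library(lib, seed = 3, times = 3)
  expect_equal(length(sh3$reads), 9)

  # dinucleotide option preserves dinucleotide counts
  din <- shuffle_library(lib, seed = 5, method = "dinucleotide")
  dicount <- function(r) table(substring(r, 1:(nchar(r) - 1), 2:nchar(r)))
  for (i in 1:3) expect_identical(dicount(din$reads[i]), dicount(lib$reads[i]))

  # shuffled 10-mer frequencies match the mononucleotide null (chi-square)
  set.seed(31)
  reads <- replicate(10000, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                  collapse = ""))
  sh2 <- shuffle_library(selex_library(reads), seed = 7)
  counts <- library_kmer_counts(selex_library(sh2$reads), 2)
  # dinucleotide counts of an iid shuffle are uniform over the 16 cells
  expected <- counts$total / 16
  chi <- sum((counts$counts - expected)^2 / expected)
  expect_lt(chi, qchisq(0.999, df = 15))
})

test_that("k-mer counting matches the naive substring oracle", {
  set.seed(32)
  reads <- replicate(100, paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                                collapse = ""))
  lib <- selex_library(reads)
  k <- 5
  counted <- library_kmer_counts(lib, k)
  oracle <- kmer_count_oracle(reads, k)
  nonzero <- which(counted$counts > 0)
  got <- setNames(counted$counts[nonzero], code_to_kmer(nonzero - 1, k))
  got <- got[order(names(got))]
  expect_equal(got, oracle)
  # window-count conservation: sum = reads * 2 * (len - k + 1)
  expect_equal(counted$total, 100 * 2 * (25 - k + 1))
})

test_that("enrichment is a pseudocounted frequency ratio with strand symmetry", {
  set.seed(33)
  reads <- replicate(300, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                                collapse = ""))
  lib <- selex_library(reads)
  # selected = null gives enrichment 1 everywhere
  ke_same <- kmer_enrichment(lib, lib, k = 4)
  expect_true(all(abs(ke_same$enrichment - 1) < 1e-12))

  null <- shuffle_library(lib, seed = 9)
  ke <- kmer_enrichment(lib, null, k = 4)
  # reverse-complement symmetry is exact under double-strand counting
  codes <- 0:(4^4 - 1)
  rc <- revcomp_code(codes, 4)
  expect_identical(ke$counts_sel, ke$counts_sel[rc + 1])
  expect_identical(ke$enrichment, ke$enrichment[rc + 1])
  # the ratio definition: (count + 1) scaled by totals
  w <- which.max(ke$enrichment)
  expect_equal(ke$enrichment[w],
               ((ke$counts_sel[w] + 1) / ke$total_sel) /
                 ((ke$counts_null[w] + 1) / ke$total_null))
  expect_error(kmer_enrichment(lib, null, k = 40), "exceeds")

  tk <- top_kmers(ke, 8)
  expect_equal(nrow(tk), 8)
  expect_true(all(diff(tk$enrichment) <= 0))
  expect_equal(kmer_rank(ke, tk$kmer[1]), 1L)
})

test_that("find_seeds returns local maxima and separates distinct motifs", {
  k <- 6
  enr <- rep(1, 4^k)
  m1 <- kmer_to_code("ACGTAC")
  m2 <- kmer_to_code("TTGGCC")
  enr[m1 + 1] <- 12
  enr[substitution_neighbors(m1, k) + 1] <- 6
  enr[m2 + 1] <- 9
  enr[substitution_neighbors(m2, k) + 1] <- 4
  ke <- structure(list(k = k, enrichment = enr,
                       counts_sel = round(enr), counts_null = rep(1, 4^k),
                       total_sel = 1, total_null = 1),
                  class = "kmer_enrichment")
  seeds <- find_seeds(ke, n = 3)
  canon <- function(w) code_to_kmer(pmin(kmer_to_code(w),
                                         revcomp_code(kmer_to_code(w), k)), k)
  expect_setequal(seeds, canon(c("ACGTAC", "TTGGCC")))
  # no signal at all raises the documented error
  ke_flat <- ke
  ke_flat$enrichment <- rep(1, 4^k)
  expect_error(find_seeds(ke_flat), "no signal")
})

test_that("build_motif turns a single-sequence library into a one-hot PWM", {
  # non-self-overlapping seed: its single-substitution variants must not
  # appear on the reverse strand of the read by construction
  seedw <- "ACGGTCATTG"
  read <- paste0("GG", seedw, "TT")
  lib <- selex_library(rep(read, 5))
  null <- selex_library(rep("GTCAGTCAGTCAGT", 5))
  ke <- kmer_enrichment(lib, null, k = 10)
  mo <- build_motif(ke, lib, null, seed = seedw, extend = 2)
  expect_equal(ncol(mo$pwm), 14)
  expect_equal(colSums(mo$pwm), rep(1, 14), tolerance = 1e-12)
  core <- substr(mo$consensus, 3, 12)
  expect_identical(core, seedw)
  expect_identical(substr(mo$consensus, 1, 2), "GG")
  expect_identical(substr(mo$consensus, 13, 14), "TT")
})

test_that("motif fold change separates planted from scrambled motifs", {
  set.seed(34)
  bg <- function(n, L) replicate(n, paste(sample(c("A", "C", "G", "T"), L,
                                                 TRUE), collapse = ""))
  site <- "TTACGTTACG"
  with_site <- vapply(bg(150, 30), function(r) {
    pos <- sample(1:21, 1)
    paste0(substr(r, 1, pos - 1), site, substr(r, pos + 10, 30))
  }, character(1))
  sel <- selex_library(unname(c(with_site, bg(150, 30))))
  null <- shuffle_library(sel, seed = 4)
  ke <- kmer_enrichment(sel, null, k = 10)
  mo <- build_motif(ke, sel, null, seed = site, extend = 0)
  fc <- motif_fold_change(mo, sel, null)
  expect_gt(as.numeric(fc), 2)
  # identical libraries give fold 1
  expect_equal(as.numeric(motif_fold_change(mo, null, null)), 1,
               tolerance = 1e-9)
  # a scrambled-column control motif scores lower
  scram <- mo
  perm <- c(4, 9, 2, 7, 1, 10, 5, 3, 8, 6)
  scram$pwm <- mo$pwm[, perm]
  expect_gt(as.numeric(fc), as.numeric(motif_fold_change(scram, sel, null)))
})

test_that("consensus match fractions respect IUPAC compatibility and offsets", {
  expect_equal(consensus_match_fraction("ACGTACGTAC", "ACGTACGTAC"), 1)
  expect_equal(consensus_match_fraction("RCGTWCGTAC", "ACGTACGTAC"), 1)
  # reverse strand and shifted alignments are found
  expect_equal(consensus_match_fraction(revcomp("ACGTACGTAC"), "ACGTACGTAC"), 1)
  expect_equal(consensus_match_fraction("NNACGTACGTACNN", "ACGTACGTAC"), 1)
  expect_lt(consensus_match_fraction("GGGGGGGGGG", "ACCTAACTTG"), 0.5)
})

test_that("SELEX FASTA/FASTQ round-trips through the readers", {
  reads <- c("ACGTACGTAATT", "TTGGCCAATTGG")
  fa <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(reads), c("r1", "r2")), fa)
  lib <- read_selex_reads(fa, round = 2)
  expect_identical(lib$reads, reads)
  expect_equal(lib$round, 2L)

  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", reads[1], "+", strrep("I", 12),
               "@r2", reads[2], "+", strrep("I", 12)), fq)
  expect_identical(read_selex_reads(fq)$reads, reads)
})
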