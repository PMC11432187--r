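# A designed enrichment table: every word scores 1 except chosen k-mers.
flat_enrichment <- function(k, boosts = c()) {
  enr <- rep(1, 4^k)
  for (w in names(boosts)) {
    code <- kmer_to_code(w)
    enr[code + 1] <- boosts[[w]]
    enr[revcomp_code(code, k) + 1] <- boosts[[w]]
  }
  structure(list(k = k, enrichment = enr,
                 counts_sel = integer(4^k), counts_null = integer(4^k),
                 total_sel = 1, total_null = 1),
            class = "kmer_enrichment")
}

test_that("score_genome takes the best strand and zeroes N windows", {
  ke <- flat_enrichment(4, c(ACGT = 9, TTAA = 5))
  # the genome is exactly one boosted word
  tr <- score_genome(c(chr1 = "ACGT"), ke)
  expect_equal(tr$tracks$chr1, 9)
  # reverse-complement occurrence scores the same
  expect_equal(score_genome(c(chr1 = "ACGT"), ke)$tracks$chr1,
               score_genome(c(chr1 = revcomp("ACGT")), ke)$tracks$chr1)
  # all-N sequence scores 0 everywhere
  expect_equal(score_genome(c(chr1 = strrep("N", 10)), ke)$tracks$chr1,
               rep(0, 7))
  # chromosome shorter than k yields an empty track
  expect_length(score_genome(c(chr1 = "AC"), ke)$tracks$chr1, 0)

  # planted occurrences give track maxima exactly at the planted offsets
  # (10-mers: chance background occurrences are effectively impossible)
  set.seed(40)
  w1 <- "ACGGTCATTG"; w2 <- "TTGACCGGAT"
  ke10 <- flat_enrichment(10, setNames(c(9, 5), c(w1, w2)))
  bg <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  g <- paste0(substr(bg, 1, 99), w1, substr(bg, 110, 300), w2,
              substr(bg, 311, 500))
  tr2 <- score_genome(c(chr1 = g), ke10)
  expect_equal(which(tr2$tracks$chr1 == 9), 100)
  expect_equal(which(tr2$tracks$chr1 == 5), 301)
})

test_that("scoring is strand-symmetric under genome reverse complement", {
  set.seed(41)
  g <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ke <- flat_enrichment(4, c(ACGT = 9, GGCC = 3))
  fwd <- score_genome(c(chr1 = g), ke)$tracks$chr1
  rev <- score_genome(c(chr1 = revcomp(g)), ke)$tracks$chr1
  expect_equal(rev, base::rev(fwd))
})

test_that("promoter windows respect strand, clipping and coordinate systems", {
  ann <- data.frame(gene_id = c("gp", "gm", "edge"),
                    chrom = "chr1", strand = c("+", "-", "+"),
                    tss = c(5001, 5001, 101))
  w <- promoter_windows(ann, span = 2000)
  expect_equal(w[w$gene_id == "gp", c("start", "end")],
               data.frame(start = 3000L, end = 5000L), ignore_attr = TRUE)
  expect_equal(w[w$gene_id == "gm", c("start", "end")],
               data.frame(start = 5000L, end = 7000L), ignore_attr = TRUE)
  expect_equal(w[w$gene_id == "edge", c("start", "end")],
               data.frame(start = 0L, end = 100L), ignore_attr = TRUE)
  # downstream and both modes
  wd <- promoter_windows(ann[1, ], span = 2000, mode = "downstream")
  expect_equal(c(wd$start, wd$end), c(5000L, 7000L))
  wb <- promoter_windows(ann[1, ], span = 2000, mode = "both")
  expect_equal(c(wb$start, wb$end), c(3000L, 7000L))
  expect_error(promoter_windows(data.frame(gene_id = "x", chrom = "chr1",
                                           strand = "*", tss = 10)),
               "strand")
})

test_that("GFF3 gene models round-trip into TSS tables", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=gA",
               "chr1\ttest\tgene\t5001\t6000\t.\t-\t.\tID=gB"), gff)
  ann <- read_gene_annotation(gff)
  expect_identical(ann$gene_id, c("gA", "gB"))
  expect_identical(ann$tss, c(1001L, 6000L))
  expect_identical(ann$strand, c("+", "-"))
})

test_that("call_sites keeps run maxima inside promoters above the quantile", {
  set.seed(42)
  bg <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  site <- "ACGTACGTAC"
  # plant in gene A's promoter (TSS 6001, +): promoter [4000, 6000)
  g <- paste0(substr(bg, 1, 4999), site, substr(bg, 5010, 10000))
  ke <- flat_enrichment(10, setNames(25, site))
  tr <- score_genome(c(chr1 = g), ke)
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    strand = "+", tss = c(6001, 9501))
  win <- promoter_windows(ann, span = 2000,
                          chrom_lengths = c(chr1 = nchar(g)))
  sites <- call_sites(tr, win, threshold_quantile = 0.999)
  expect_equal(nrow(sites), 1)
  expect_identical(sites$gene_id, "gA")
  expect_equal(sites$start, 4999)
  expect_equal(sites$end - sites$start, 10)
  expect_equal(sites$distance_to_tss, 4999 - 6000)
  # the same instance outside every promoter yields no sites
  g2 <- paste0(substr(bg, 1, 499), site, substr(bg, 510, 10000))
  sites2 <- call_sites(score_genome(c(chr1 = g2), ke), win, 0.999)
  expect_equal(nrow(sites2), 0)
  # a uniform track yields no sites at any quantile below 1
  flat <- score_genome(c(chr1 = substr(bg, 1, 3000)), flat_enrichment(10))
  expect_warning(s3 <- call_sites(flat, win[0, ], 0.99), "empty promoter")
  expect_equal(nrow(s3), 0)
  s4 <- call_sites(flat, win, 0.99)
  expect_equal(nrow(s4), 0)
})

test_that("overlapping above-threshold runs merge to their local maximum", {
  ke <- flat_enrichment(10, c(ACGTACGTAC = 20, CGTACGTACG = 30))
  # two overlapping boosted words: one run, the higher score wins
  g <- paste0(strrep("T", 200), "ACGTACGTACG", strrep("T", 200))
  tr <- score_genome(c(chr1 = g), ke)
  ann <- data.frame(gene_id = "gA", chrom = "chr1", strand = "-", tss = 150)
  win <- promoter_windows(ann, span = 150,
                          chrom_lengths = c(chr1 = nchar(g)))
  sites <- call_sites(tr, win, threshold_quantile = 0.99)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$score, 30)
  # every emitted site scores above the threshold quantile value
  expect_true(all(sites$score > attr(sites, "threshold")))
})

test_that("promoter ranking finds the planted promoters first", {
  set.seed(43)
  bg <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  site <- "ACGTACGTAC"
  g <- paste0(substr(bg, 1, 2999), site, substr(bg, 3010, 20000))
  ke <- flat_enrichment(10, setNames(40, site))
  tr <- score_genome(c(chr1 = g), ke)
  ann <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1", strand = "+",
                    tss = c(4001, 9001, 14001, 19001))
  win <- promoter_windows(ann, span = 2000,
                          chrom_lengths = c(chr1 = nchar(g)))
  rp <- rank_promoters(tr, win)
  expect_identical(rp$gene_id[1], "g1")
  expect_equal(rp$max_score[1], 40)
})
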