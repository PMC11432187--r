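# HT-SELEX read processing: deduplication, composition-preserving shuffles,
# 10-mer enrichment against the shuffled null, seed-based motif (PWM)
# construction and motif fold-change evaluation.

#' Construct a SELEX library
#'
#' @param reads Character vector of DNA reads (ligands), uniform length.
#' @param round Selection round (0 = input library).
#' @param deduplicated Whether PCR duplicates have been removed.
#' @return List of class `selex_library`.
#' @export
selex_library <- function(reads, round = 0L, deduplicated = FALSE) {
  stopifnot(is.character(reads), length(reads) > 0)
  structure(list(reads = reads, round = as.integer(round),
                 deduplicated = isTRUE(deduplicated)),
            class = "selex_library")
}

#' @export
print.selex_library <- function(x, ...) {
  cat(sprintf("selex_library: round %d, %d reads (%s)\n", x$round,
              length(x$reads),
              if (x$deduplicated) "deduplicated" else "raw"))
  invisible(x)
}

#' Read SELEX ligands from FASTA or FASTQ
#'
#' @param path File path; format is taken from the extension
#'   (`.fastq`/`.fq`, optionally gzipped, is read as FASTQ, anything else
#'   as FASTA).
#' @param round Selection round the file corresponds to.
#' @return A [selex_library()].
#' @export
read_selex_reads <- function(path, round = 0L) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  selex_library(unname(as.character(seqs)), round = round)
}

#' Remove exact PCR duplicates
#'
#' Collapses identical read sequences to a single copy and reports the
#' reduction.  Reads must have a uniform length.
#'
#' @param lib A [selex_library()].
#' @return Deduplicated `selex_library` with attributes `n_input` and
#'   `n_removed`.
#' @export
dedupe_reads <- function(lib) {
  lens <- nchar(lib$reads)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != stats::median(lens))
    stop("reads of unequal length after trimming: ",
         paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) sprintf(" ... (%d total)", length(off)) else "")
  }
  reads <- unique(lib$reads)
  out <- selex_library(reads, round = lib$round, deduplicated = TRUE)
  attr(out, "n_input") <- length(lib$reads)
  attr(out, "n_removed") <- length(lib$reads) - length(reads)
  out
}

#' Shuffle a library, preserving per-read composition
#'
#' The default mononucleotide shuffle permutes the bases of each read
#' independently, preserving its length and base composition exactly.  The
#' dinucleotide option preserves each read's dinucleotide composition
#' (successor-list shuffle with retry until an admissible walk is found).
#' With `times > 1` every read is shuffled that many independent times,
#' giving a deeper null library with the same composition — the k-mer
#' frequencies of the null are then estimated with proportionally less
#' sampling noise (enrichment normalizes by library size, so depth
#' cancels).
#'
#' @param lib A [selex_library()].
#' @param seed Integer seed (shuffles are deterministic given the seed).
#' @param method `"mononucleotide"` (default) or `"dinucleotide"`.
#' @param times Independent shuffles per read (default 1).
#' @return A shuffled `selex_library` with `times * length(reads)` reads.
#' @export
shuffle_library <- function(lib, seed, method = c("mononucleotide", "dinucleotide"),
                            times = 1) {
  method <- match.arg(method)
  if (missing(seed)) stop("shuffle_library requires an explicit seed")
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  reads <- rep(lib$reads, times)
  if (method == "mononucleotide") {
    L <- nchar(reads)
    b <- dna_to_base_codes(reads)
    read_id <- rep(seq_along(reads), L)
    perm <- order(read_id, stats::runif(length(b)))
    b <- b[perm]
    ends <- cumsum(L)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    chars <- c("A", "C", "G", "T")[b + 1L]
    shuffled <- vapply(seq_along(reads), function(i)
      paste(chars[starts[i]:ends[i]], collapse = ""), character(1))
  } else {
    shuffled <- vapply(reads, dinucleotide_shuffle_one, character(1),
                       USE.NAMES = FALSE)
  }
  selex_library(shuffled, round = lib$round, deduplicated = lib$deduplicated)
}

# Dinucleotide-preserving shuffle of a single read: shuffle the successor
# list of each base and retry until the walk consumes every edge.
dinucleotide_shuffle_one <- function(read, max_tries = 100) {
  b <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < 3 || length(unique(b)) == 1L) return(read)
  for (try in seq_len(max_tries)) {
    succ <- split(b[-1], b[-n])
    succ <- lapply(succ, sample)
    ptr <- stats::setNames(rep(1L, length(succ)), names(succ))
    out <- character(n)
    out[1] <- b[1]
    ok <- TRUE
    for (i in 2:n) {
      cur <- out[i - 1]
      s <- succ[[cur]]
      if (is.null(s) || ptr[[cur]] > length(s)) { ok <- FALSE; break }
      out[i] <- s[ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
    }
    if (ok) return(paste(out, collapse = ""))
  }
  # fall back to the exact original (composition trivially preserved)
  read
}

#' Count all k-mers of a read library
#'
#' Tallies every k-length window of every read on both strands into a
#' dense count vector indexed by k-mer code + 1 (see [kmer_to_code()]).
#' Reads are processed in chunks so large libraries stay in memory.
#'
#' @param lib A [selex_library()] (uniform read length).
#' @param k Word length.
#' @param chunk Reads per processing block (default 50,000).
#' @return List with `counts` (integer vector of length `4^k`) and
#'   `total` (number of counted windows).
#' @export
library_kmer_counts <- function(lib, k, chunk = 50000L) {
  reads <- lib$reads
  L <- unique(nchar(reads))
  if (length(L) != 1L) stop("uniform read length required for k-mer counting")
  if (k > L) stop("k exceeds the read length")
  counts <- integer(4^k)
  total <- 0L
  done <- 0L
  while (done < length(reads)) {
    idx <- (done + 1L):min(done + chunk, length(reads))
    b <- dna_to_base_codes(reads[idx])
    fwd <- window_codes(b, k)
    rc <- window_codes_rc(b, k)
    starts <- as.vector(outer(seq_len(L - k + 1L),
                              (seq_along(idx) - 1L) * L, "+"))
    codes <- c(fwd[starts], rc[starts])
    codes <- codes[!is.na(codes)]
    counts <- counts + tabulate(as.integer(codes) + 1L, nbins = 4^k)
    total <- total + length(codes)
    done <- done + length(idx)
  }
  list(counts = counts, total = total)
}

#' 10-mer enrichment of a selected library over a null library
#'
#' Counts every k-length window on both strands in both libraries and
#' scores each k-mer by the pseudocounted frequency ratio
#' `(f_sel + eps_sel) / (f_null + eps_null)`, the per-library pseudocount
#' defaulting to one window (`eps = 1 / total windows`), so the score
#' reduces to a (count + 1) ratio when both libraries have equal depth.
#' Double-strand counting makes the score identical for a k-mer and its
#' reverse complement.
#'
#' @param selected Selected-round [selex_library()].
#' @param null Null library (typically [shuffle_library()] of `selected`).
#' @param k Word length (default 10).
#' @param pseudocount Optional frequency pseudocount applied to both
#'   libraries; `NULL` (default) uses one window per library.
#' @return List of class `kmer_enrichment` with dense vectors
#'   `counts_sel`, `counts_null`, `enrichment` (indexed by code + 1),
#'   window totals, and `k`.
#' @export
kmer_enrichment <- function(selected, null, k = 10, pseudocount = NULL) {
  cs <- library_kmer_counts(selected, k)
  cn <- library_kmer_counts(null, k)
  eps_s <- if (is.null(pseudocount)) 1 / cs$total else pseudocount
  eps_n <- if (is.null(pseudocount)) 1 / cn$total else pseudocount
  enr <- (cs$counts / cs$total + eps_s) / (cn$counts / cn$total + eps_n)
  structure(list(k = k, counts_sel = cs$counts, counts_null = cn$counts,
                 total_sel = cs$total, total_null = cn$total,
                 enrichment = enr),
            class = "kmer_enrichment")
}

#' @export
print.kmer_enrichment <- function(x, ...) {
  cat(sprintf("kmer_enrichment: k = %d, %d / %d windows (selected / null)\n",
              x$k, x$total_sel, x$total_null))
  print(top_kmers(x, 5), row.names = FALSE)
  invisible(x)
}

#' Top enriched k-mers
#'
#' @param ke A [kmer_enrichment()] result.
#' @param n Number of k-mers to report.
#' @return Data frame with `kmer`, `count_sel`, `count_null`, `enrichment`,
#'   sorted by decreasing enrichment (a k-mer and its reverse complement
#'   both appear, with identical scores, as in double-strand counting).
#' @export
top_kmers <- function(ke, n = 10) {
  ord <- order(-ke$enrichment, seq_along(ke$enrichment))[seq_len(n)]
  data.frame(kmer = code_to_kmer(ord - 1, ke$k),
             count_sel = ke$counts_sel[ord],
             count_null = ke$counts_null[ord],
             enrichment = ke$enrichment[ord],
             stringsAsFactors = FALSE)
}

#' Enrichment rank of a k-mer
#'
#' Rank (1 = most enriched) of a word in the enrichment table.
#'
#' @param ke A [kmer_enrichment()].
#' @param kmer DNA word of length `ke$k`.
#' @return Integer rank (min rank across ties).
#' @export
kmer_rank <- function(ke, kmer) {
  code <- kmer_to_code(kmer)
  sum(ke$enrichment > ke$enrichment[code + 1]) + 1L
}

#' Locally maximal enriched seeds
#'
#' A seed is a k-mer whose enrichment exceeds 1 and is not exceeded by any
#' of its 3k single-substitution neighbours.  Seeds are reported in
#' decreasing enrichment; each reverse-complement pair is reported once
#' (the lexicographically smaller word), and seeds within one substitution
#' of a stronger seed are suppressed so that distinct motifs yield
#' distinct seeds.
#'
#' @param ke A [kmer_enrichment()].
#' @param n Maximum number of seeds to return.
#' @param candidates Number of top k-mers to inspect (default 2000).
#' @return Character vector of seed k-mers (possibly shorter than `n`).
#' @export
find_seeds <- function(ke, n = 3, candidates = 2000) {
  k <- ke$k
  ord <- order(-ke$enrichment, seq_along(ke$enrichment))[seq_len(candidates)]
  codes <- ord - 1
  enr <- ke$enrichment
  keep <- vapply(codes, function(code) {
    e <- enr[code + 1]
    if (e <= 1) return(FALSE)
    all(enr[substitution_neighbors(code, k) + 1] <= e)
  }, logical(1))
  seeds <- codes[keep]
  if (!length(seeds)) stop("no signal: no k-mer is locally maximal with enrichment > 1")
  # drop reverse-complement twins and near-duplicates of stronger seeds
  out <- numeric(0)
  for (s in seeds) {
    rc <- revcomp_code(s, k)
    nb <- c(substitution_neighbors(s, k), substitution_neighbors(rc, k), rc)
    if (!length(out) || !any(out %in% nb | out == s)) out <- c(out, s)
    if (length(out) >= n) break
  }
  out <- vapply(out, function(s) min(s, revcomp_code(s, k)), numeric(1))
  code_to_kmer(out, k)
}

# codes of all 3k single-substitution neighbours of a k-mer code
substitution_neighbors <- function(code, k) {
  out <- numeric(3 * k)
  idx <- 1L
  rem <- code
  for (j in seq_len(k)) {
    w <- 4^(k - j)
    d <- rem %/% w
    rem <- rem - d * w
    for (alt in setdiff(0:3, d)) {
      out[idx] <- code + (alt - d) * w
      idx <- idx + 1L
    }
  }
  out
}

iupac_codes <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Build a PWM motif from an enriched seed
#'
#' Autoseed-style seed-and-count construction.  The core `k` columns come
#' from the enrichment scores of the seed's single-substitution variants:
#' column `j`, base `b` is scored by the enrichment of the seed with
#' position `j` replaced by `b`, which corrects each variant count by its
#' abundance in the shuffled library.  `extend` flanking columns on each
#' side are tallied from the aligned seed occurrences in the selected
#' reads (oriented so the seed matches the forward strand) and corrected
#' by the null library's base composition.  Columns are normalized to
#' probabilities and a per-column IUPAC consensus is called from all bases
#' reaching `consensus_frac` of the column.
#'
#' @param ke A [kmer_enrichment()].
#' @param selected,null The libraries used for `ke`.
#' @param seed Seed k-mer; `NULL` takes the top seed from [find_seeds()].
#' @param extend Flanking columns on each side (default 2).
#' @param consensus_frac Minimum column probability for a base to enter
#'   the degenerate consensus (default 0.25).
#' @return List of class `selex_motif` with `pwm` (4 x L, column-
#'   stochastic), `seed`, `consensus`, `background`, `match_threshold`
#'   (log-odds 0 by default) and `core` (core column indices).
#' @export
build_motif <- function(ke, selected, null, seed = NULL, extend = 2,
                        consensus_frac = 0.25) {
  k <- ke$k
  if (is.null(seed)) seed <- find_seeds(ke, n = 1)[1]
  stopifnot(nchar(seed) == k)
  seed_code <- kmer_to_code(seed)
  if (ke$enrichment[seed_code + 1] <= 1)
    stop("no signal: seed enrichment does not exceed 1")
  # core columns from single-substitution enrichments
  core <- matrix(0, 4, k, dimnames = list(c("A", "C", "G", "T"), NULL))
  rem <- seed_code
  for (j in seq_len(k)) {
    w <- 4^(k - j)
    d <- rem %/% w
    rem <- rem - d * w
    variants <- seed_code + (0:3 - d) * w
    core[, j] <- ke$enrichment[variants + 1]
  }
  # flanking columns from aligned seed occurrences in the selected reads
  flank_left <- flank_right <- NULL
  if (extend > 0) {
    occ <- aligned_flanks(selected$reads, seed, extend)
    bg <- base_composition(null$reads)
    corr <- function(cnt) sweep(cnt + 1, 1, bg, "/")
    flank_left <- corr(occ$left)
    flank_right <- corr(occ$right)
  }
  pwm <- cbind(flank_left, core, flank_right)
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  colnames(pwm) <- NULL
  consensus <- paste(apply(pwm, 2, function(p) {
    bases <- names(p)[p >= consensus_frac]
    if (!length(bases)) bases <- names(p)[which.max(p)]
    iupac_codes[[paste(sort(bases), collapse = "")]]
  }), collapse = "")
  bg <- base_composition(null$reads)
  structure(list(pwm = pwm, seed = seed, consensus = consensus,
                 background = bg, match_threshold = 0,
                 core = (if (extend > 0) extend else 0) + seq_len(k)),
            class = "selex_motif")
}

#' @export
print.selex_motif <- function(x, ...) {
  cat(sprintf("selex_motif: seed %s, consensus %s (L = %d)\n",
              x$seed, x$consensus, ncol(x$pwm)))
  invisible(x)
}

# mononucleotide composition of a read set (A,C,G,T probabilities)
base_composition <- function(reads) {
  b <- dna_to_base_codes(reads)
  tab <- tabulate(b + 1L, nbins = 4L)
  stats::setNames(tab / sum(tab), c("A", "C", "G", "T"))
}

# base counts at the extend columns left/right of aligned seed matches
aligned_flanks <- function(reads, seed, extend) {
  k <- nchar(seed)
  rc_seed <- revcomp(seed)
  hit_f <- regexpr(seed, reads, fixed = TRUE)
  hit_r <- regexpr(rc_seed, reads, fixed = TRUE)
  use_r <- hit_f < 0 & hit_r > 0
  oriented <- reads
  oriented[use_r] <- revcomp(reads[use_r])
  pos <- ifelse(hit_f > 0, hit_f,
                ifelse(use_r, nchar(reads) - (hit_r + k - 1) + 1L, NA))
  keep <- !is.na(pos)
  oriented <- oriented[keep]
  pos <- pos[keep]
  left <- matrix(0L, 4, extend, dimnames = list(c("A", "C", "G", "T"), NULL))
  right <- matrix(0L, 4, extend, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (e in seq_len(extend)) {
    lpos <- pos - (extend - e + 1L)
    rpos <- pos + k + e - 1L
    lb <- substr(oriented, lpos, lpos)
    rb <- substr(oriented, rpos, rpos)
    left[, e] <- tabulate(match(lb, c("A", "C", "G", "T")), nbins = 4)
    right[, e] <- tabulate(match(rb, c("A", "C", "G", "T")), nbins = 4)
  }
  list(left = left, right = right, n = length(oriented))
}

# log-odds score of every window of each read against a PWM (forward
# orientation); returns the per-position scores as a list with valid starts
pwm_log_odds <- function(pwm, background) {
  log(sweep(pmax(pwm, 1e-12), 1, background, "/"))
}

# per-position best-strand PWM match indicator over a library; processed
# in read chunks so deep (multiply shuffled) libraries stay in memory
count_pwm_matches <- function(motif, lib, chunk = 50000L) {
  reads <- lib$reads
  L <- unique(nchar(reads))
  stopifnot(length(L) == 1L)
  w <- ncol(motif$pwm)
  if (w > L) return(list(matches = 0L, positions = 0L))
  lo <- pwm_log_odds(motif$pwm, motif$background)
  lo_rc <- lo[4:1, ncol(lo):1]           # reverse complement of the PWM
  matches <- 0L
  positions <- 0L
  done <- 0L
  while (done < length(reads)) {
    idx <- (done + 1L):min(done + chunk, length(reads))
    b <- dna_to_base_codes(reads[idx])
    m <- length(b) - w + 1L
    sf <- numeric(m); sr <- numeric(m)
    bb <- as.numeric(b)
    for (j in seq_len(w)) {
      col <- bb[j:(m + j - 1L)]
      sf <- sf + lo[cbind(col + 1, j)]
      sr <- sr + lo_rc[cbind(col + 1, j)]
    }
    starts <- as.vector(outer(seq_len(L - w + 1L),
                              (seq_along(idx) - 1L) * L, "+"))
    hit <- (sf[starts] > motif$match_threshold) |
      (sr[starts] > motif$match_threshold)
    matches <- matches + sum(hit, na.rm = TRUE)
    positions <- positions + length(starts)
    done <- done + length(idx)
  }
  list(matches = matches, positions = positions)
}

#' Motif fold change between selected and null libraries
#'
#' Counts the positions (both strands, once per position) whose PWM
#' log-odds score exceeds the motif's match threshold in each library and
#' returns `(matches_sel + eps) / (matches_null + eps)`.
#'
#' @param motif A [build_motif()] result.
#' @param selected,null Libraries of equal read length.
#' @param eps Pseudocount (default 1).
#' @return Fold change (single number), with match counts in attributes.
#' @export
motif_fold_change <- function(motif, selected, null, eps = 1) {
  ms <- count_pwm_matches(motif, selected)
  mn <- count_pwm_matches(motif, null)
  # correct for library depth when the two differ
  scale <- ms$positions / mn$positions
  fold <- (ms$matches + eps) / (mn$matches * scale + eps)
  structure(fold, matches_sel = ms$matches, matches_null = mn$matches)
}

#' Replicate agreement of two enrichment tables
#'
#' Pearson correlation of log enrichment over the k-mers with at least
#' `min_count` occurrences in both selected libraries — the abundance
#' filter removes words whose scores are dominated by sampling noise
#' (at a depth of 20,000 reads per library, counts below roughly 30 carry
#' Poisson noise comparable to the affinity signal).
#'
#' @param ke1,ke2 Two [kmer_enrichment()] results (same k).
#' @param min_count Minimum selected-library count in both replicates
#'   (default 30).
#' @return Correlation, with the number of k-mers used in attribute `n`.
#' @export
enrichment_replicate_cor <- function(ke1, ke2, min_count = 30) {
  stopifnot(ke1$k == ke2$k)
  keep <- ke1$counts_sel >= min_count & ke2$counts_sel >= min_count
  if (sum(keep) < 3) stop("fewer than 3 k-mers pass the abundance filter")
  r <- stats::cor(log(ke1$enrichment[keep]), log(ke2$enrichment[keep]))
  structure(r, n = sum(keep))
}

#' Fraction of IUPAC-compatible consensus columns
#'
#' Best ungapped alignment (either strand) of a discovered consensus
#' against a reference word; a column matches when the reference base is
#' covered by the discovered column's IUPAC code (or vice versa).  The
#' fraction is relative to the reference length.
#'
#' @param consensus Discovered IUPAC consensus string.
#' @param reference Reference word (e.g. the planted consensus).
#' @return Best match fraction in `[0, 1]`.
#' @export
consensus_match_fraction <- function(consensus, reference) {
  iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                     M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                     S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                     V = c("A", "C", "G"), H = c("A", "C", "T"),
                     D = c("A", "G", "T"), B = c("C", "G", "T"),
                     N = c("A", "C", "G", "T"))
  score_pair <- function(a, b) {
    sa <- iupac_sets[[a]]; sb <- iupac_sets[[b]]
    as.numeric(length(intersect(sa, sb)) > 0)
  }
  best <- 0
  for (cand in c(consensus, revcomp_iupac(consensus))) {
    ca <- strsplit(cand, "")[[1]]
    cb <- strsplit(reference, "")[[1]]
    for (off in -(length(ca) - 1):(length(cb) - 1)) {
      hits <- 0
      for (j in seq_along(cb)) {
        i <- j - off
        if (i >= 1 && i <= length(ca)) hits <- hits + score_pair(ca[i], cb[j])
      }
      best <- max(best, hits / length(cb))
    }
  }
  best
}

revcomp_iupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

#' Write a motif in minimal MEME text format
#'
#' @param motif A [build_motif()] result.
#' @param path Output file.
#' @param name Motif name (default the seed).
#' @return Invisibly, the path.
#' @export
write_meme <- function(motif, path, name = motif$seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", names(motif$background), motif$background),
                     collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d", ncol(motif$pwm))),
             con)
  utils::write.table(format(t(motif$pwm), digits = 6), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
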