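# Synthetic-data generators with known ground truth: an internode expression
# matrix with planted zones/clusters/modules, trait vectors with planted
# coupling, TF annotations, SELEX libraries evolved from a hidden PWM, and a
# toy genome with motif instances planted in annotated promoters.

#' Zone membership of the 19 study internodes
#'
#' The emulated design: Zone I holds the four earliest internodes (FS and
#' SS), Zone II the six basal internodes of the two later stages, Zone III
#' the seven upper internodes, and Zone IV the two fast-elongating
#' mid-stalk internodes of the last stage.
#'
#' @return Named character vector internode -> zone ("I".."IV").
#' @export
zone_map <- function() {
  des <- study_design()
  z <- c("I", "I", "I", "I",                 # FS, SS1-SS3
         "II", "II", "II",                   # TS1-TS3
         "III", "III", "III",                # TS4-TS6
         "II", "II", "II",                   # LS1-LS3
         "III",                              # LS4
         "IV", "IV",                         # LS5, LS6
         "III", "III", "III")                # LS7-LS9
  stats::setNames(z, des$internode)
}

#' Planted expression archetypes
#'
#' Cluster archetypes combine a zone-level weight pattern (mapped onto the
#' 19 internodes) with a small smooth positional component, and are
#' standardized to zero mean and unit variance.  The zone weights dominate,
#' so developmental zones are separable by column clustering, while the
#' positional component keeps the twelve archetypes mutually
#' distinguishable for gene clustering.  `kind = "modules3"` returns three
#' module archetypes used
#' by the network simulations: a Zone-IV elongation-like profile, a
#' monotone bottom-to-top decreasing profile, and an early-zone profile.
#'
#' @param kind `"clusters12"` (default) or `"modules3"`.
#' @return 19 x c matrix (internodes x archetypes), columns standardized.
#' @export
archetype_profiles <- function(kind = c("clusters12", "modules3")) {
  kind <- match.arg(kind)
  zm <- zone_map()
  zidx <- match(zm, c("I", "II", "III", "IV"))
  if (kind == "clusters12") {
    # zone-level weights (columns I..IV) with four distinct values per
    # cluster, plus a small smooth positional component that separates
    # clusters sharing similar zone patterns without breaking the
    # zone-dominated column structure
    w <- rbind(
      C1  = c( 1.0, -0.1, -0.7, -1.0),
      C2  = c(-0.9,  0.9, -0.1, -0.5),
      C3  = c( 1.0,  0.4, -0.6,  0.1),
      C4  = c( 0.9, -0.7,  0.6, -0.2),
      C5  = c(-0.8, -0.2,  1.0, -0.5),
      C6  = c( 0.3,  1.0, -0.1,  0.7),
      C7  = c(-1.0,  0.3,  0.8,  0.4),
      C8  = c(-0.2,  0.9,  0.5, -0.9),
      C9  = c(-0.4, -1.0,  0.5,  1.0),
      C10 = c( 0.6, -0.9, -0.3,  1.0),
      C11 = c(-0.9, -0.5,  0.2,  1.0),
      C12 = c( 0.9,  0.4,  0.0, -1.0))
    freq <- c(1, 2, 1, 2, 1, 2, 3, 1, 2, 3, 1, 1)
    phase <- pi * c(0, 1 / 3, 1 / 2, 1 / 2, 1, 1, 0, 3 / 2, 3 / 2, 1 / 2, 1 / 3, 1 / 6)
    pos <- seq_len(19)
    prof <- vapply(seq_len(12), function(i)
      w[i, zidx] + 0.35 * sin(2 * pi * freq[i] * pos / 19 + phase[i]),
      numeric(19))
    colnames(prof) <- rownames(w)
  } else {
    # near-orthogonal triple: an unsigned network (|cor|^beta) merges
    # strongly (anti-)correlated blocks, so module archetypes must be
    # mutually near-uncorrelated to stay distinct
    pos <- seq_len(19)
    elong <- c(-0.4, 0.3, -0.8, 1.0)[zidx] +        # Zone IV peak
      0.2 * sin(2 * pi * pos / 19)
    ramp <- -pos                                    # decreasing bottom to top
    osc <- sin(2 * pi * 2.5 * pos / 19 + 3 * pi / 4) +
      c(0.3, -0.3, 0.3, -0.3)[zidx]
    prof <- cbind(M1 = elong, M2 = ramp, M3 = osc)
  }
  rownames(prof) <- names(zm)
  scale(prof)[, , drop = FALSE]
}

#' Simulation configuration
#'
#' Bundles the generator parameters emulating the study conditions: 19
#' internodes x 2 replicates, 12 cluster archetypes across 4 zones,
#' Gaussian noise on the log2 scale calibrated so replicate correlation
#' exceeds 0.97, trait coupling of r = 0.9 (length) and 0.87 (diameter),
#' 4 SELEX rounds of 20,000 101-bp ligands selected from a hidden
#' 10-column PWM, and a 1-Mb toy genome with 20 annotated genes.
#'
#' @param n_genes Total simulated genes (clustered + background).
#' @param n_clusters Number of planted expression clusters.
#' @param cluster_sizes Genes per cluster (recycled; default equal split of
#'   90% of `n_genes`, the rest background noise genes).
#' @param noise_sd Per-replicate Gaussian noise SD on the log2 scale.
#' @param amplitude Archetype amplitude on the log2 scale.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression.
#' @param r_length,r_diameter Planted trait-module correlations.
#' @param trait_cluster_length,trait_cluster_diameter Index of the cluster
#'   archetype each trait couples to.
#' @param consensus Hidden SELEX motif consensus (10 bases).
#' @param consensus_prob Per-column probability of the consensus base
#'   (recycled to the motif length).  The default is heterogeneous, as for
#'   real transcription factors: columns of unequal information content
#'   give mismatch variants a genuine affinity gradient, which is what
#'   makes replicate enrichment tables correlate.
#' @param reads_per_round Sequenced reads per SELEX round.
#' @param pool_factor Initial ligand pool size as a multiple of
#'   `reads_per_round`.
#' @param rounds SELEX selection rounds.
#' @param ligand_length Ligand length in bp.
#' @param occupancy_tau,occupancy_margin Logistic occupancy scale (log-odds
#'   units) and the offset of the logistic midpoint below the mean
#'   single-mismatch score, in units of `tau` (negative values place the
#'   midpoint above it, sharpening selection).
#' @param genome_length,n_genes_annotated,n_planted_sites,promoter_span
#'   Toy genome parameters.
#' @param seed Master seed (mandatory).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 3600,
                       n_clusters = 12,
                       cluster_sizes = NULL,
                       noise_sd = 0.3,
                       amplitude = 2.5,
                       baseline_mean = 5,
                       baseline_sd = 1.5,
                       r_length = 0.9,
                       r_diameter = 0.87,
                       trait_cluster_length = NULL,
                       trait_cluster_diameter = NULL,
                       consensus = "ACCTAACTTG",
                       consensus_prob = c(0.97, 0.92, 0.85, 0.62, 0.78,
                                          0.70, 0.88, 0.58, 0.65, 0.94),
                       reads_per_round = 20000,
                       pool_factor = 30,
                       rounds = 4,
                       ligand_length = 101,
                       occupancy_tau = 2.0,
                       occupancy_margin = -0.5,
                       genome_length = 1e6,
                       n_genes_annotated = 20,
                       n_planted_sites = 3,
                       promoter_span = 2000,
                       seed) {
  if (missing(seed)) stop("sim_config requires a master seed")
  if (is.null(cluster_sizes)) {
    per <- floor(0.9 * n_genes / n_clusters)
    cluster_sizes <- rep(per, n_clusters)
  }
  if (sum(cluster_sizes) > n_genes)
    stop("cluster sizes exceed n_genes")
  cfg <- list(n_genes = n_genes, n_clusters = n_clusters,
              cluster_sizes = cluster_sizes, noise_sd = noise_sd,
              amplitude = amplitude, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, r_length = r_length,
              r_diameter = r_diameter,
              trait_cluster_length = trait_cluster_length,
              trait_cluster_diameter = trait_cluster_diameter,
              consensus = toupper(consensus),
              consensus_prob = consensus_prob,
              reads_per_round = reads_per_round, pool_factor = pool_factor,
              rounds = rounds, ligand_length = ligand_length,
              occupancy_tau = occupancy_tau,
              occupancy_margin = occupancy_margin,
              genome_length = genome_length,
              n_genes_annotated = n_genes_annotated,
              n_planted_sites = n_planted_sites,
              promoter_span = promoter_span,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the internode expression matrix
#'
#' Each planted gene is `baseline + amplitude * archetype + noise` on the
#' log2(TPM+1) scale, with independent noise per replicate; background
#' genes are baseline plus noise only.  Values are exported on the linear
#' TPM scale (`2^x - 1`, clipped at 0), as the pipeline re-applies the log
#' transform.
#'
#' @param cfg A [sim_config()].
#' @param archetypes Optional 19 x c archetype matrix (default
#'   [archetype_profiles()] matching `cfg$n_clusters` when 12 or 3).
#' @return List with `expr` (linear-scale [expr_matrix()], 38 columns),
#'   `meta` (sample metadata), `truth` (`cluster` gene labels with
#'   "background", `zone` internode labels, `archetypes`).
#' @export
simulate_expression <- function(cfg, archetypes = NULL) {
  old_seed <- local_seed(cfg$seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  if (is.null(archetypes)) {
    archetypes <- if (cfg$n_clusters == 3) archetype_profiles("modules3")
                  else if (cfg$n_clusters == 12) archetype_profiles("clusters12")
                  else stop("supply archetypes for n_clusters other than 12 or 3")
  }
  stopifnot(ncol(archetypes) >= cfg$n_clusters)
  archetypes <- archetypes[, seq_len(cfg$n_clusters), drop = FALSE]
  des <- study_design()
  n_int <- nrow(des)
  sizes <- cfg$cluster_sizes
  n_bg <- cfg$n_genes - sum(sizes)
  cluster_of <- c(rep(colnames(archetypes), sizes), rep("background", n_bg))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  names(cluster_of) <- gene_ids
  base <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  signal <- matrix(0, cfg$n_genes, n_int)
  planted <- cluster_of != "background"
  signal[planted, ] <- cfg$amplitude *
    t(archetypes[, cluster_of[planted], drop = FALSE])
  meta <- do.call(rbind, lapply(1:2, function(r) {
    d <- des
    d$replicate <- r
    d$sample_id <- paste0(d$internode, "_r", r)
    d
  }))
  rownames(meta) <- NULL
  logx <- matrix(0, cfg$n_genes, nrow(meta),
                 dimnames = list(gene_ids, meta$sample_id))
  for (i in seq_len(nrow(meta))) {
    j <- match(meta$internode[i], des$internode)
    logx[, i] <- base + signal[, j] + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
  }
  tpm <- pmax(2^logx - 1, 0)
  list(expr = expr_matrix(tpm, log_transformed = FALSE),
       meta = meta[, c("sample_id", "stage", "internode_index", "replicate", "internode")],
       truth = list(cluster = cluster_of, zone = zone_map(),
                    archetypes = archetypes))
}

#' Simulate internode traits coupled to planted archetypes
#'
#' Internode length couples to the Zone-IV elongation archetype and
#' diameter to the monotone bottom-to-top archetype (overridable), each as
#' `trait = r * archetype + sqrt(1 - r^2) * noise` before rescaling to
#' plausible units (length: cm, diameter: mm), so the planted population
#' correlation equals `r`.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_expression()] (for the archetype
#'   matrix).
#' @param seed Optional seed override (defaults to `cfg$seed + 1`).
#' @return Data frame `internode`, `length`, `diameter`.
#' @export
simulate_traits <- function(cfg, truth, seed = NULL) {
  old_seed <- local_seed(if (is.null(seed)) cfg$seed + 1L else seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  arch <- truth$archetypes
  pick <- function(pref, override) {
    if (!is.null(override)) return(override)
    hit <- match(pref, colnames(arch))
    hit[!is.na(hit)][1]
  }
  i_len <- pick(c("M1", "C11"), cfg$trait_cluster_length)
  i_dia <- pick(c("M2", "C2"), cfg$trait_cluster_diameter)
  n <- nrow(arch)
  mix <- function(profile, r) {
    z <- as.numeric(scale(profile))
    r * z + sqrt(1 - r^2) * stats::rnorm(n)
  }
  len <- pmax(10 + 3 * mix(arch[, i_len], cfg$r_length), 0.5)
  dia <- pmax(8 + 2 * mix(arch[, i_dia], cfg$r_diameter), 0.5)
  data.frame(internode = rownames(arch), length = len, diameter = dia,
             stringsAsFactors = FALSE)
}

#' Simulate a TF-family annotation table
#'
#' Assigns a sample of genes to common plant TF families, drawing from both
#' planted and background genes so family HVTF ratios vary.
#'
#' @param cfg A [sim_config()].
#' @param gene_ids Gene ids of the simulated matrix.
#' @param n_tfs Number of TF genes (default 10% of genes).
#' @return Data frame `gene_id`, `family`.
#' @export
simulate_tf_annotation <- function(cfg, gene_ids, n_tfs = NULL) {
  old_seed <- local_seed(cfg$seed + 2L)
  on.exit(restore_seed(old_seed), add = TRUE)
  if (is.null(n_tfs)) n_tfs <- max(20L, round(0.1 * length(gene_ids)))
  fams <- c("MYB", "NAC", "bHLH", "WRKY", "AP2/ERF-ERF", "GRAS", "C2H2",
            "MADS-M-type", "Whirly", "STAT")
  genes <- sample(gene_ids, n_tfs)
  data.frame(gene_id = genes,
             family = sample(fams, n_tfs, replace = TRUE,
                             prob = c(0.2, 0.15, 0.15, 0.12, 0.12, 0.08,
                                      0.08, 0.05, 0.03, 0.02)),
             stringsAsFactors = FALSE)
}

# The hidden PWM: per-column consensus probability p_j (recycled), the
# three other bases sharing (1 - p_j) equally.
truth_pwm <- function(consensus, p) {
  k <- nchar(consensus)
  p <- rep_len(p, k)
  pwm <- matrix(rep((1 - p) / 3, each = 4), 4, k,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  pwm[cbind(idx, seq_len(k))] <- p
  pwm
}

# best-window PWM log-odds score per read, both strands, from base codes
best_window_scores <- function(b, n_reads, L, lodds) {
  k <- ncol(lodds)
  m <- length(b) - k + 1L
  lo_rc <- lodds[4:1, k:1]
  sf <- numeric(m); sr <- numeric(m)
  bb <- as.numeric(b)
  for (j in seq_len(k)) {
    col <- bb[j:(m + j - 1L)]
    sf <- sf + lodds[cbind(col + 1, j)]
    sr <- sr + lo_rc[cbind(col + 1, j)]
  }
  s <- pmax(sf, sr)
  wpr <- L - k + 1L
  starts <- as.vector(outer(seq_len(wpr), (seq_len(n_reads) - 1L) * L, "+"))
  sm <- matrix(s[starts], nrow = wpr)
  sm[cbind(max.col(t(sm), ties.method = "first"), seq_len(n_reads))]
}

# draw n random reads of length L as a character vector
random_reads <- function(n, L) {
  b <- sample.int(4L, n * L, replace = TRUE)
  big <- rawToChar(as.raw(c(65L, 67L, 71L, 84L))[b])
  substring(big, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
}

#' Simulate SELEX selection rounds from a hidden PWM
#'
#' A pool of `pool_factor * reads_per_round` random ligands stands in for
#' the diverse synthesized initial library.  Each ligand's occupancy is a
#' logistic function of its best-window PWM log-odds score (both strands);
#' the round-t library is a multinomial sample of the pool with weights
#' `occupancy^t`, emulating t rounds of bind-wash-amplify followed by
#' sequencing at `reads_per_round` depth.  Round 0 is an unselected sample
#' of the pool.  Replicate experiments share the pool (one library
#' synthesis, as in the wet protocol) but draw their selections
#' independently: pass a different `seed` and keep `pool_seed` fixed.
#'
#' @param cfg A [sim_config()].
#' @param seed Selection/sequencing seed (defaults to `cfg$seed + 13`; use
#'   a different value for an independent replicate experiment).
#' @param pool_seed Seed of the ligand pool synthesis (defaults to
#'   `cfg$seed + 3`).
#' @return List with `libraries` (list of [selex_library()], rounds
#'   0..`rounds`) and `truth` (`pwm`, `consensus`, occupancy parameters).
#' @export
simulate_selex <- function(cfg, seed = NULL, pool_seed = NULL) {
  old_seed <- local_seed(if (is.null(pool_seed)) cfg$seed + 3L else pool_seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  k <- nchar(cfg$consensus)
  pwm <- truth_pwm(cfg$consensus, cfg$consensus_prob)
  lodds <- log(pwm / 0.25)
  smax <- sum(apply(lodds, 2, max))
  p <- rep_len(cfg$consensus_prob, k)
  penalty <- mean(log(p / ((1 - p) / 3)))     # mean single-mismatch cost
  s0 <- smax - penalty - cfg$occupancy_margin * cfg$occupancy_tau
  L <- cfg$ligand_length
  n_pool <- cfg$pool_factor * cfg$reads_per_round
  chunk <- 50000L
  pool <- character(n_pool)
  occ <- numeric(n_pool)
  done <- 0L
  while (done < n_pool) {
    n <- min(chunk, n_pool - done)
    reads <- random_reads(n, L)
    b <- dna_to_base_codes(reads)
    s <- best_window_scores(b, n, L, lodds)
    pool[done + seq_len(n)] <- reads
    occ[done + seq_len(n)] <- stats::plogis((s - s0) / cfg$occupancy_tau)
    done <- done + n
  }
  set.seed(if (is.null(seed)) cfg$seed + 13L else seed)
  libs <- vector("list", cfg$rounds + 1L)
  idx0 <- sample.int(n_pool, cfg$reads_per_round)
  libs[[1]] <- selex_library(pool[idx0], round = 0L)
  for (t in seq_len(cfg$rounds)) {
    idx <- sample.int(n_pool, cfg$reads_per_round, replace = TRUE,
                      prob = occ^t)
    libs[[t + 1L]] <- selex_library(pool[idx], round = t)
  }
  list(libraries = libs,
       truth = list(pwm = pwm, consensus = cfg$consensus, s0 = s0,
                    tau = cfg$occupancy_tau))
}

#' Simulate a toy genome with planted promoter sites
#'
#' An i.i.d. background sequence with `n_genes_annotated` genes placed on
#' random strands; the hidden consensus is planted inside the promoters of
#' the first `n_planted_sites` genes at known offsets.  Chance background
#' occurrences of the consensus or any single-mismatch variant (either
#' strand) outside the planted positions are removed by local re-drawing,
#' so the planted sites are the only motif instances.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed override (defaults to `cfg$seed + 4`).
#' @return List with `genome` (named character, one chromosome "chr1"),
#'   `annotation` (gene table as in [read_gene_annotation()]), `sites`
#'   (truth: planted site coordinates, 0-based half-open) and `gene_length`.
#' @export
simulate_genome <- function(cfg, seed = NULL) {
  old_seed <- local_seed(if (is.null(seed)) cfg$seed + 4L else seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  len <- as.integer(cfg$genome_length)
  n_gene <- cfg$n_genes_annotated
  span <- cfg$promoter_span
  gene_len <- 1000L
  k <- nchar(cfg$consensus)
  b <- sample.int(4L, len, replace = TRUE) - 1L
  # evenly spaced gene slots with jitter; each slot must fit promoter + body
  slot <- len %/% n_gene
  if (slot < gene_len + 2L * span + 100L) stop("genome too short for the annotation")
  offs <- round(stats::runif(n_gene, 0.35, 0.65) * slot)
  starts <- (seq_len(n_gene) - 1L) * slot + offs   # 1-based gene start
  strand <- sample(c("+", "-"), n_gene, replace = TRUE)
  gene_id <- sprintf("TG%02d", seq_len(n_gene))
  tss <- ifelse(strand == "+", starts, starts + gene_len - 1L)
  ann <- data.frame(gene_id = gene_id, chrom = "chr1", strand = strand,
                    tss = as.integer(tss), stringsAsFactors = FALSE)
  # plant the consensus in the promoters of the first n_planted_sites genes
  cons_b <- dna_to_base_codes(cfg$consensus)
  planted <- data.frame()
  keep_mask <- rep(FALSE, len)
  for (i in seq_len(cfg$n_planted_sites)) {
    off <- sample(50:(span - 50L - k), 1L)          # distance upstream of TSS
    if (strand[i] == "+") {
      site_start <- tss[i] - off - k + 1L           # 1-based
      word <- cons_b
    } else {
      site_start <- tss[i] + off
      word <- rev(3L - cons_b)
    }
    b[site_start:(site_start + k - 1L)] <- word
    keep_mask[site_start:(site_start + k - 1L)] <- TRUE
    planted <- rbind(planted, data.frame(
      chrom = "chr1", start = site_start - 1L, end = site_start - 1L + k,
      strand = strand[i], gene_id = gene_id[i], stringsAsFactors = FALSE))
  }
  # scrub chance near-consensus occurrences (Hamming <= 1, both strands)
  cons_code <- kmer_to_code(cfg$consensus)
  motif_codes <- unique(c(cons_code, substitution_neighbors(cons_code, k)))
  motif_codes <- unique(c(motif_codes, revcomp_code(motif_codes, k)))
  is_motif <- rep(FALSE, 4^k)
  is_motif[motif_codes + 1] <- TRUE
  repeat {
    codes <- window_codes(b, k)
    hits <- which(is_motif[as.integer(codes) + 1L])
    hits <- hits[!keep_mask[hits]]
    if (!length(hits)) break
    for (h in hits) {
      idx <- h:(h + k - 1L)
      redraw <- !keep_mask[idx]
      b[idx[redraw]] <- sample.int(4L, sum(redraw), replace = TRUE) - 1L
    }
  }
  genome <- stats::setNames(rawToChar(as.raw(c(65L, 67L, 71L, 84L))[b + 1L]), "chr1")
  list(genome = genome, annotation = ann, sites = planted,
       gene_length = gene_len)
}

#' Write a full synthetic data set to disk
#'
#' Generates every pipeline input with one master seed: expression matrix,
#' sample metadata, traits, TF families (TSV), SELEX rounds (FASTA), the
#' toy genome (FASTA) and its annotation (GFF3), plus ground-truth JSON
#' files under `truth/`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_all <- function(cfg, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(cfg)
  traits <- simulate_traits(cfg, sim$truth)
  ann <- simulate_tf_annotation(cfg, rownames(sim$expr))
  paths <- list()
  w <- function(x, name, ...) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE, ...)
    p
  }
  expr_df <- data.frame(gene_id = rownames(sim$expr),
                        as.data.frame(unclass(sim$expr), check.names = FALSE),
                        check.names = FALSE)
  paths$expr <- w(expr_df, "expr.tsv")
  paths$meta <- w(sim$meta, "meta.tsv")
  paths$traits <- w(traits, "traits.tsv")
  paths$tf <- w(ann, "tf_families.tsv")
  sx <- simulate_selex(cfg)
  paths$selex <- vapply(sx$libraries, function(lib) {
    p <- file.path(dir, sprintf("r%d.fasta", lib$round))
    Biostrings::writeXStringSet(
      stats::setNames(Biostrings::DNAStringSet(lib$reads),
                      sprintf("read%06d", seq_along(lib$reads))), p)
    p
  }, character(1))
  gn <- simulate_genome(cfg)
  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gn$genome), paths$genome)
  paths$gff <- file.path(dir, "genes.gff3")
  gr <- GenomicRanges::GRanges(
    seqnames = gn$annotation$chrom,
    ranges = IRanges::IRanges(
      start = ifelse(gn$annotation$strand == "+", gn$annotation$tss,
                     gn$annotation$tss - gn$gene_length + 1L),
      width = gn$gene_length),
    strand = gn$annotation$strand,
    type = "gene", ID = gn$annotation$gene_id)
  rtracklayer::export(gr, paths$gff, format = "gff3")
  truth <- list(cluster = as.list(sim$truth$cluster),
                zone = as.list(sim$truth$zone),
                consensus = sx$truth$consensus,
                pwm = sx$truth$pwm,
                planted_sites = gn$sites)
  paths$truth <- file.path(dir, "truth", "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
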