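# Genome-wide affinity scoring with SELEX 10-mer enrichments, strand-aware
# promoter window extraction from GFF3, and high-affinity site calling.

#' Score a genome with k-mer enrichment scores
#'
#' Slides a width-k window (step 1) over each chromosome and assigns every
#' start position the larger of the forward and reverse-complement 10-mer
#' enrichment — double-strand counting in the enrichment table makes the
#' two equal, but the maximum is taken so the track is correct for
#' single-strand tables too.  Windows containing a non-ACGT base score 0.
#'
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param ke A [kmer_enrichment()] table (k-mers never observed in either
#'   library carry their pseudocount-only score).
#' @return List of class `affinity_track`: per-chromosome numeric score
#'   vectors (length `nchar - k + 1`), plus `k`.
#' @export
score_genome <- function(genome, ke) {
  seqs <- as_genome_strings(genome)
  k <- ke$k
  tracks <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(numeric(0))
    b <- dna_to_base_codes(s)
    fwd <- window_codes(b, k)
    rc <- window_codes_rc(b, k)
    sc <- pmax(ke$enrichment[as.integer(fwd) + 1L],
               ke$enrichment[as.integer(rc) + 1L])
    sc[is.na(fwd)] <- 0
    sc
  })
  structure(list(tracks = tracks, k = k), class = "affinity_track")
}

as_genome_strings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome
}

#' @export
print.affinity_track <- function(x, ...) {
  cat(sprintf("affinity_track: %d chromosome(s), k = %d\n",
              length(x$tracks), x$k))
  invisible(x)
}

#' Read gene annotation (TSS table) from GFF3
#'
#' Uses gene-type records; the TSS is the start coordinate for `+` genes
#' and the end coordinate for `-` genes (1-based).
#'
#' @param gff Path to a GFF3 file, or a `GRanges` of genes.
#' @return Data frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(gff) {
  gr <- if (methods::is(gff, "GRanges")) gff else rtracklayer::import(gff)
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$gene_id
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("gene annotation with missing strand")
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             tss = ifelse(strand == "+", GenomicRanges::start(gr),
                          GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Strand-aware promoter windows
#'
#' For a `+` gene the promoter is the `span` bases upstream of the TSS,
#' `[tss - span, tss)` in 0-based half-open coordinates; for a `-` gene it
#' is `[tss, tss + span)`.  Windows are clipped to the chromosome bounds
#' when lengths are supplied.
#'
#' @param ann Gene annotation from [read_gene_annotation()] (or a GFF3
#'   path).
#' @param span Window size in bp (default 2000).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clipping.
#' @param mode `"upstream"` (default), `"downstream"` or `"both"` of the
#'   TSS.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `tss`.
#' @export
promoter_windows <- function(ann, span = 2000, chrom_lengths = NULL,
                             mode = c("upstream", "downstream", "both")) {
  mode <- match.arg(mode)
  if (!is.data.frame(ann)) ann <- read_gene_annotation(ann)
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss0 <- ann$tss - 1L                     # 0-based TSS position
  up <- ifelse(ann$strand == "+", tss0 - span, tss0)
  up_end <- ifelse(ann$strand == "+", tss0, tss0 + span)
  down <- ifelse(ann$strand == "+", tss0, tss0 + 1L - span)
  down_end <- ifelse(ann$strand == "+", tss0 + span, tss0 + 1L)
  start <- switch(mode, upstream = up, downstream = down,
                  both = pmin(up, down))
  end <- switch(mode, upstream = up_end, downstream = down_end,
                both = pmax(up_end, down_end))
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[ann$chrom])
    if (anyNA(len))
      stop("chrom_lengths missing for: ",
           paste(unique(ann$chrom[is.na(len)]), collapse = ", "))
    end <- pmin(end, len)
  }
  out <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = ann$strand, tss = ann$tss,
                    stringsAsFactors = FALSE)
  out[out$end > out$start, , drop = FALSE]
}

#' Call high-affinity binding sites in promoter windows
#'
#' Positions inside promoter windows whose affinity score strictly exceeds
#' the genome-wide `threshold_quantile` quantile of the track are
#' candidate sites; runs of overlapping above-threshold windows are merged
#' and only the local maximum of each run is kept.  Each site is annotated
#' with its owning gene and the signed distance of the site start to the
#' TSS (negative = upstream of the TSS on the gene's strand).
#'
#' @param track An [score_genome()] result.
#' @param windows Promoter windows from [promoter_windows()].
#' @param threshold_quantile Genome-wide score quantile (default 0.999).
#' @return Data frame of class `binding_sites` with `chrom`, `start`,
#'   `end` (0-based half-open, width k), `score`, `gene_id`,
#'   `distance_to_tss`, and the threshold in attribute `threshold`.
#' @export
call_sites <- function(track, windows, threshold_quantile = 0.999) {
  k <- track$k
  all_scores <- unlist(track$tracks, use.names = FALSE)
  thr <- stats::quantile(all_scores, threshold_quantile, names = FALSE)
  out <- list()
  if (nrow(windows) == 0L) {
    warning("empty promoter window set")
  } else {
    for (chrom in unique(windows$chrom)) {
      sc <- track$tracks[[chrom]]
      if (is.null(sc) || !length(sc)) next
      w <- windows[windows$chrom == chrom, , drop = FALSE]
      wr <- IRanges::IRanges(start = w$start + 1L, end = w$end)  # 1-based
      above <- which(sc > thr)
      if (!length(above)) next
      hit <- IRanges::findOverlaps(IRanges::IRanges(above, above), wr)
      if (!length(hit)) next
      pos <- above[S4Vectors::queryHits(hit)]
      widx <- S4Vectors::subjectHits(hit)
      # merge runs of overlapping above-threshold windows per promoter,
      # keeping the local maximum of each run
      df <- data.frame(pos = pos, widx = widx)
      df <- df[order(df$widx, df$pos), , drop = FALSE]
      run <- cumsum(c(TRUE, diff(df$pos) >= k | diff(df$widx) != 0))
      for (r in split(seq_len(nrow(df)), run)) {
        p <- df$pos[r]
        best <- p[which.max(sc[p])]
        wrow <- w[df$widx[r[1L]], ]
        d <- if (wrow$strand == "+") (best - 1L) - (wrow$tss - 1L)
             else (wrow$tss - 1L) - (best - 1L + k - 1L)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = best - 1L, end = best - 1L + k,
          score = sc[best], gene_id = wrow$gene_id,
          distance_to_tss = as.integer(d), stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               score = numeric(0), gene_id = character(0),
               distance_to_tss = integer(0), stringsAsFactors = FALSE)
  sites <- sites[order(-sites$score), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "threshold") <- thr
  class(sites) <- c("binding_sites", "data.frame")
  sites
}

#' Rank genes by their best promoter affinity
#'
#' The maximum track score inside each gene's promoter window, ranked
#' decreasing — useful for comparing promoters even below the site-calling
#' threshold.
#'
#' @param track An [score_genome()] result.
#' @param windows Promoter windows.
#' @return Data frame with `gene_id` and `max_score`, sorted decreasing.
#' @export
rank_promoters <- function(track, windows) {
  score_one <- function(i) {
    sc <- track$tracks[[windows$chrom[i]]]
    lo <- windows$start[i] + 1L
    hi <- min(windows$end[i], length(sc))
    if (is.null(sc) || hi < lo) return(NA_real_)
    max(sc[lo:hi])
  }
  out <- data.frame(gene_id = windows$gene_id,
                    max_score = vapply(seq_len(nrow(windows)), score_one, numeric(1)),
                    stringsAsFactors = FALSE)
  out[order(-out$max_score), , drop = FALSE]
}

#' Write called sites as BED6
#'
#' @param sites A [call_sites()] result.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$start, sites$end, sites$gene_id,
                    signif(sites$score, 6),
                    rep(".", nrow(sites)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
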