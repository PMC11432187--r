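# Transcription-factor family summaries over the HVG set, expression
# grouping of high-variation TFs and family overrepresentation per group.

#' Per-family HVTF counts and ratios
#'
#' For each annotated TF family, counts its TFs, the TFs passing the HVG
#' filter (HVTFs) and the ratio of the two; also reports the global HVTF
#' fraction across all families.
#'
#' @param hvgs An `hvg_set` from [select_hvgs()], or a character vector of
#'   HVG ids.
#' @param ann TF annotation data.frame (`gene_id`, `family`).
#' @return List of class `family_ratio_table` with `table` (family, n_tfs,
#'   n_hvtfs, ratio, sorted by decreasing ratio) and `global_fraction`.
#' @export
family_ratios <- function(hvgs, ann) {
  ids <- if (inherits(hvgs, "hvg_set")) hvgs$gene_ids else hvgs
  n_tfs <- table(ann$family)
  n_tfs <- n_tfs[n_tfs > 0]
  hv <- ann$gene_id %in% ids
  n_hvtfs <- tapply(hv, ann$family, sum)[names(n_tfs)]
  tab <- data.frame(family = names(n_tfs),
                    n_tfs = as.integer(n_tfs),
                    n_hvtfs = as.integer(n_hvtfs),
                    ratio = as.numeric(n_hvtfs / n_tfs),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$ratio, tab$family), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 global_fraction = sum(tab$n_hvtfs) / sum(tab$n_tfs)),
            class = "family_ratio_table")
}

#' @export
print.family_ratio_table <- function(x, ...) {
  print(utils::head(x$table, 10), row.names = FALSE)
  cat(sprintf("global HVTF fraction: %.1f%% (%d / %d)\n",
              100 * x$global_fraction, sum(x$table$n_hvtfs), sum(x$table$n_tfs)))
  invisible(x)
}

#' Group high-variation TFs by expression pattern
#'
#' Average-linkage hierarchical clustering (Euclidean distance) of the
#' per-gene standardized profiles, cut into `k` groups.  Groups are named
#' G1..Gk ordered by the mean position of each group's peak expression
#' along the internode columns, so group identities are stable across runs.
#'
#' @param m Log-scale expression matrix restricted to HVTFs.
#' @param k Number of groups (default 6).
#' @return Named character vector gene -> group id, with the hclust tree in
#'   attribute `tree`.
#' @export
group_hvtfs <- function(m, k = 6) {
  x <- unclass(m)
  if (k > nrow(x)) stop("k exceeds the number of HVTFs")
  zs <- standardize_genes(x)
  tree <- stats::hclust(stats::dist(zs), method = "average")
  grp <- stats::cutree(tree, k = k)
  peak <- max.col(zs, ties.method = "first")
  mean_peak <- tapply(peak, grp, mean)
  ord <- order(mean_peak)
  labels <- paste0("G", match(grp, ord))
  names(labels) <- rownames(x)
  attr(labels, "tree") <- tree
  labels
}

#' TF-family overrepresentation per expression group
#'
#' One-sided hypergeometric test of each family's count inside a group
#' against its count among all grouped HVTFs, with Benjamini-Hochberg
#' adjusted q-values.
#'
#' @param groups Named gene -> group vector from [group_hvtfs()].
#' @param ann TF annotation (`gene_id`, `family`).
#' @return Data frame with `group`, `family`, `in_group`, `group_size`,
#'   `in_family`, `p`, `q`.
#' @export
family_overrepresentation <- function(groups, ann) {
  fam <- stats::setNames(ann$family, ann$gene_id)[names(groups)]
  keep <- !is.na(fam)
  groups <- groups[keep]
  fam <- fam[keep]
  N <- length(groups)
  res <- expand.grid(group = sort(unique(groups)), family = sort(unique(fam)),
                     stringsAsFactors = FALSE)
  res$in_group <- mapply(function(g, f) sum(groups == g & fam == f),
                         res$group, res$family)
  res$group_size <- as.integer(table(groups)[res$group])
  res$in_family <- as.integer(table(fam)[res$family])
  # P(X >= in_group) for X ~ Hypergeom(in_family, N - in_family, group_size)
  res$p <- ifelse(res$in_group == 0, 1,
                  stats::phyper(res$in_group - 1, res$in_family,
                                N - res$in_family, res$group_size,
                                lower.tail = FALSE))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
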