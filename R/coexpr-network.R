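# Weighted gene co-expression network, implemented from scratch:
# soft-threshold selection by scale-free fit, topological overlap, module
# detection by average-linkage clustering with a simplified dynamic hybrid
# cut, module eigengenes, module-trait statistics and hub extraction.

module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet"
)

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` across samples, diagonal set to 1.
#' Constant genes have undefined correlations; these are set to 0 with a
#' warning.
#'
#' @param m Expression matrix, genes in rows (log scale).
#' @param beta Positive soft-threshold power.
#' @return Symmetric genes x genes adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(m, beta = 9) {
  x <- unclass(m)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s): correlations set to 0")
  }
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[is.na(cc)] <- 0
  a <- abs(cc)^beta
  diag(a) <- 1
  a
}

#' Connectivity of an adjacency matrix
#'
#' `k_i = sum_{j != i} a_ij`.
#'
#' @param adj Adjacency matrix.
#' @return Named numeric vector.
#' @export
connectivity <- function(adj) {
  rowSums(adj) - diag(adj)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into logarithmically spaced bins and returns the
#' squared correlation of log10(frequency) versus log10(mean bin
#' connectivity), i.e. the R^2 of a power-law fit to the degree
#' distribution.
#'
#' @param k Connectivity vector.
#' @param n_bins Number of bins (default 10).
#' @return List with `r_squared` and `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r_squared = NA_real_, slope = NA_real_))
  brks <- exp(seq(log(min(k)), log(max(k)), length.out = n_bins + 1))
  brks[1] <- brks[1] * (1 - 1e-8)
  bin <- cut(k, brks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(list(r_squared = NA_real_, slope = NA_real_))
  lx <- log10(kmean[ok])
  ly <- log10(freq[ok] / sum(freq[ok]))
  fit <- stats::lm(ly ~ lx)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]))
}

#' Scan candidate soft-threshold powers
#'
#' For each candidate power, builds the unsigned adjacency, measures the
#' scale-free fit R^2 and the mean connectivity, and picks the smallest
#' power with R^2 above `r2_min` and mean connectivity below `k_max`.
#' `k_max = 100` matches a network of about 20,000 genes; for smaller
#' simulated networks pass a proportionally smaller value (or use
#' `scale_k_max()`).
#'
#' @param m Expression matrix restricted to HVGs.
#' @param betas Candidate integer powers.
#' @param r2_min Scale independence criterion (default 0.85).
#' @param k_max Mean connectivity criterion (default 100).
#' @return List of class `power_scan`: `table` (beta, r_squared, slope,
#'   mean_k), `beta` (chosen power or NA).
#' @export
power_scan <- function(m, betas = 1:20, r2_min = 0.85, k_max = 100) {
  if (ncol(m) < 4) stop("need at least 4 samples for a meaningful correlation network")
  x <- unclass(m)
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[is.na(cc)] <- 0
  ac <- abs(cc)
  rows <- lapply(betas, function(b) {
    a <- ac^b
    diag(a) <- 1
    k <- connectivity(a)
    sf <- scale_free_fit(k)
    data.frame(beta = b, r_squared = sf$r_squared, slope = sf$slope,
               mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$r_squared) & tab$r_squared > r2_min & tab$mean_k < k_max
  beta <- if (any(ok)) tab$beta[which(ok)[1L]] else NA_integer_
  structure(list(table = tab, beta = beta, r2_min = r2_min, k_max = k_max),
            class = "power_scan")
}

#' @export
print.power_scan <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(if (is.na(x$beta)) "no power met the criteria\n"
      else sprintf("chosen power: %d (R^2 > %g, mean k < %g)\n",
                   x$beta, x$r2_min, x$k_max))
  invisible(x)
}

#' Rescale the connectivity criterion to a different network size
#'
#' The mean-connectivity cutoff of 100 refers to a network of roughly
#' 20,000 genes; for a simulated network of `n_genes` the cutoff is scaled
#' proportionally.
#'
#' @param n_genes Number of genes in the network.
#' @param k_max_ref Reference cutoff (default 100).
#' @param n_ref Reference gene count (default 19887).
#' @return Scaled cutoff.
#' @export
scale_k_max <- function(n_genes, k_max_ref = 100, n_ref = 19887) {
  k_max_ref * n_genes / n_ref
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is set to 1.
#'
#' @param adj Symmetric adjacency matrix with unit diagonal.
#' @return Symmetric TOM in `[0, 1]`.
#' @export
compute_tom <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a            # l_ij = sum_u a_iu a_uj over u != i (diag zeroed)
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by tree cutting
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a static
#' height; branches of at least `min_module_size` genes become modules
#' (named with the conventional color labels, largest first).  Module
#' membership is then pruned: a gene whose mean TOM to its own module
#' falls below `member_frac` times the module's median intramodular TOM
#' is moved to the unassigned "grey" pool — chance correlations over few
#' samples otherwise attach weakly connected genes to large branches.
#' Genes on sub-threshold branches are conversely adopted by the module
#' with the highest mean TOM when they pass the same membership
#' criterion.  This is a simplified form of the dynamic hybrid cut: a
#' static height split followed by TOM-proximity reassignment.
#'
#' @param tom Topological overlap matrix.
#' @param min_module_size Minimum genes per module (default 50).
#' @param cut_height Height at which the dendrogram is cut; default
#'   `0.99 * max(merge heights)`.
#' @param member_frac Fraction of the median intramodular TOM a gene must
#'   reach (mean TOM to the module) to be kept in or adopted by a module
#'   (default 0.5).
#' @return Named character vector gene -> module color ("grey" =
#'   unassigned), with the hclust tree in attribute `tree`.
#' @export
detect_modules <- function(tom, min_module_size = 50, cut_height = NULL,
                           member_frac = 0.5) {
  genes <- rownames(tom)
  if (is.null(genes)) {
    genes <- paste0("g", seq_len(nrow(tom)))
    dimnames(tom) <- list(genes, genes)
  }
  diss <- 1 - tom
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(tree$height)
  grp <- stats::cutree(tree, h = cut_height)
  sizes <- table(grp)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  if (length(big)) {
    # name modules by decreasing size using the conventional color series
    big <- big[order(-sizes[big])]
    pal <- c(module_palette,
             paste0("module", seq_len(max(0, length(big) - length(module_palette)))))
    for (i in seq_along(big)) labels[grp == as.integer(big[i])] <- pal[i]
    mods <- pal[seq_along(big)]
    med_intra <- vapply(mods, function(mod) {
      idx <- which(labels == mod)
      sub <- tom[idx, idx]
      stats::median(sub[upper.tri(sub)])
    }, numeric(1))
    # prune weakly connected members, then adopt qualifying outsiders
    mean_tom_to <- function(g, mod) {
      members <- setdiff(names(labels)[labels == mod], g)
      mean(tom[g, members])
    }
    for (g in genes[labels != "grey"]) {
      mod <- labels[[g]]
      if (mean_tom_to(g, mod) < member_frac * med_intra[[mod]])
        labels[g] <- "grey"
    }
    for (g in genes[labels == "grey"]) {
      mt <- vapply(mods, function(mod) mean_tom_to(g, mod), numeric(1))
      best <- which.max(mt)
      if (mt[best] >= member_frac * med_intra[best]) labels[g] <- mods[best]
    }
  }
  attr(labels, "tree") <- tree
  attr(labels, "cut_height") <- cut_height
  labels
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix
#' (samples as observations), with the sign fixed so the eigengene
#' correlates positively with the module's mean expression profile (when
#' the mean profile is degenerate, the first gene is used for alignment).
#'
#' @param m Expression matrix (genes x samples, log scale).
#' @param genes Genes of one module.
#' @return Numeric eigengene of length `ncol(m)`, with the fraction of
#'   module variance it explains in attribute `var_explained`.
#' @export
module_eigengene <- function(m, genes) {
  x <- unclass(m)[genes, , drop = FALSE]
  if (nrow(x) < 2) stop("a module eigengene needs at least 2 genes")
  zs <- standardize_genes(x)
  if (all(zs == 0)) {
    warning("degenerate (rank-0) module; eigengene set to zero")
    return(structure(stats::setNames(rep(0, ncol(x)), colnames(x)), var_explained = 0))
  }
  sv <- svd(t(zs), nu = 1, nv = 0)
  me <- drop(sv$u[, 1])
  ref <- colMeans(zs)
  alignment <- sum(me * ref)
  if (abs(alignment) < 1e-10) alignment <- sum(me * zs[1, ])
  if (alignment < 0) me <- -me
  names(me) <- colnames(x)
  structure(me, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes of all modules
#'
#' @param m Expression matrix.
#' @param module_labels Named gene -> module vector from [detect_modules()];
#'   the "grey" pool is skipped.
#' @return Modules x samples matrix.
#' @export
module_eigengenes <- function(m, module_labels) {
  mods <- setdiff(unique(module_labels), "grey")
  out <- t(vapply(mods, function(mod)
    as.numeric(module_eigengene(m, names(module_labels)[module_labels == mod])),
    numeric(ncol(m))))
  dimnames(out) <- list(mods, colnames(m))
  out
}

# two-sided p-value for a Pearson correlation via the Student t transform
cor_pvalue <- function(r, n) {
  if (n < 3) stop("correlation p-value needs n >= 3")
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Module-trait correlation, module membership and gene significance
#'
#' Pearson correlation of every module eigengene with every trait, with
#' two-sided p-values from the Student t transform on n - 2 degrees of
#' freedom; per-gene module membership (correlation with the own module's
#' eigengene) and gene significance (correlation with each trait).
#'
#' @param m Expression matrix (genes x samples).
#' @param eigengenes Modules x samples matrix from [module_eigengenes()].
#' @param traits Data.frame with an `internode` column matching the sample
#'   columns plus one numeric column per trait, or a numeric matrix with
#'   rownames matching samples.
#' @param module_labels Named gene -> module vector (for MM/GS; optional).
#' @return List of class `module_trait_result`: `stats` (module, trait, r,
#'   p), `mm` (gene, module, mm), `gs` (gene x trait matrix) where labels
#'   were supplied.
#' @export
module_trait <- function(m, eigengenes, traits, module_labels = NULL) {
  samples <- colnames(eigengenes)
  tr <- as_trait_matrix(traits, samples)
  n <- length(samples)
  if (n < 3) stop("module-trait correlation needs at least 3 samples")
  combos <- expand.grid(module = rownames(eigengenes), trait = colnames(tr),
                        stringsAsFactors = FALSE)
  combos$r <- mapply(function(mod, t)
    stats::cor(eigengenes[mod, ], tr[, t]), combos$module, combos$trait)
  combos$p <- cor_pvalue(combos$r, n)
  out <- list(stats = combos)
  if (!is.null(module_labels)) {
    x <- unclass(m)[names(module_labels), samples, drop = FALSE]
    assigned <- names(module_labels)[module_labels != "grey"]
    mm <- vapply(assigned, function(g)
      stats::cor(x[g, ], eigengenes[module_labels[[g]], ]), numeric(1))
    out$mm <- data.frame(gene = assigned, module = module_labels[assigned],
                         mm = unname(mm), stringsAsFactors = FALSE)
    gs <- suppressWarnings(stats::cor(t(x), tr))
    gs[is.na(gs)] <- 0
    out$gs <- gs
  }
  structure(out, class = "module_trait_result")
}

as_trait_matrix <- function(traits, samples) {
  if (is.matrix(traits)) {
    tr <- traits[samples, , drop = FALSE]
  } else {
    stopifnot(is.data.frame(traits))
    key <- if ("internode" %in% names(traits)) traits$internode else rownames(traits)
    idx <- match(samples, key)
    if (anyNA(idx)) stop("traits missing for: ", paste(samples[is.na(idx)], collapse = ", "))
    numcols <- names(traits)[vapply(traits, is.numeric, TRUE)]
    tr <- as.matrix(traits[idx, numcols, drop = FALSE])
    rownames(tr) <- samples
  }
  tr
}

#' Hub network of one module
#'
#' Intramodular connectivity `k_i = sum_{j in module} TOM_ij`; the node set
#' is the top `top_n` genes by connectivity plus any flagged genes in the
#' module; edges keep TOM weights above the `edge_quantile` quantile of the
#' node-pair weights.
#'
#' @param tom TOM matrix.
#' @param module_labels Named gene -> module vector.
#' @param module Module to extract.
#' @param top_n Number of top-connectivity genes (default 100).
#' @param flagged_genes Genes always included (e.g. TFs and target genes).
#' @param edge_quantile Quantile cutoff for edges (default 0.95).
#' @return List of class `hub_network`: `nodes` (gene, connectivity,
#'   flagged), `edges` (source, target, weight), `top_flagged` (the
#'   flagged gene with the highest connectivity, if any).
#' @export
hub_network <- function(tom, module_labels, module, top_n = 100,
                        flagged_genes = character(0), edge_quantile = 0.95) {
  members <- names(module_labels)[module_labels == module]
  if (!length(members)) stop("module not found: ", module)
  k <- rowSums(tom[members, members, drop = FALSE]) - 1
  names(k) <- members
  if (top_n > length(members)) {
    warning("top_n exceeds module size; using the whole module")
    top_n <- length(members)
  }
  top <- names(sort(k, decreasing = TRUE))[seq_len(top_n)]
  flagged <- intersect(flagged_genes, members)
  nodes <- union(top, flagged)
  nodes_df <- data.frame(gene = nodes, connectivity = k[nodes],
                         flagged = nodes %in% flagged,
                         row.names = NULL, stringsAsFactors = FALSE)
  sub <- tom[nodes, nodes, drop = FALSE]
  ut <- which(upper.tri(sub), arr.ind = TRUE)
  w <- sub[ut]
  thr <- stats::quantile(w, edge_quantile)
  keep <- w > thr
  edges <- data.frame(source = nodes[ut[keep, 1]], target = nodes[ut[keep, 2]],
                      weight = w[keep], stringsAsFactors = FALSE)
  top_flagged <- if (length(flagged)) flagged[which.max(k[flagged])] else NA_character_
  structure(list(nodes = nodes_df, edges = edges, module = module,
                 top_flagged = top_flagged),
            class = "hub_network")
}

#' @export
print.hub_network <- function(x, ...) {
  cat(sprintf("hub_network (%s): %d nodes, %d edges", x$module,
              nrow(x$nodes), nrow(x$edges)))
  if (!is.na(x$top_flagged))
    cat(sprintf("; highest-connectivity flagged gene: %s", x$top_flagged))
  cat("\n")
  invisible(x)
}

#' Pairwise expression correlation between two gene sets
#'
#' Pearson correlation on the (log-scale) expression across the internode
#' columns for every pair in `set_a` x `set_b`.
#'
#' @param m Expression matrix.
#' @param set_a,set_b Gene id vectors.
#' @return Data frame with `gene_a`, `gene_b`, `r`, sorted by decreasing r.
#' @export
gene_gene_correlation <- function(m, set_a, set_b) {
  x <- unclass(m)
  missing <- setdiff(c(set_a, set_b), rownames(x))
  if (length(missing)) stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  cc <- suppressWarnings(stats::cor(t(x[set_a, , drop = FALSE]),
                                    t(x[set_b, , drop = FALSE])))
  out <- expand.grid(gene_a = set_a, gene_b = set_b, stringsAsFactors = FALSE)
  out$r <- as.vector(cc)
  out[order(-out$r), , drop = FALSE]
}
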