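# High-variation gene selection, developmental-zone assignment and fuzzy
# c-means expression clustering.

#' Median absolute deviation per gene (unscaled)
#'
#' `MAD(g) = median_j |x_gj - median_j(x_gj)|`, without the 1.4826
#' normal-consistency factor: the plain definition on which the HVG cutoff
#' operates.
#'
#' @param m Numeric matrix, genes in rows.
#' @return Named numeric vector of per-gene MAD values.
#' @export
gene_mad <- function(m) {
  med <- apply(m, 1L, stats::median)
  apply(abs(m - med), 1L, stats::median)
}

#' Select high-variation genes by MAD cutoff
#'
#' @param m A log-transformed [expr_matrix()].
#' @param cutoff Genes with MAD strictly greater than this are retained
#'   (default 1).
#' @return List of class `hvg_set` with `gene_ids`, `mad` (all genes) and
#'   `cutoff`.
#' @export
select_hvgs <- function(m, cutoff = 1) {
  if (inherits(m, "expr_matrix") && !is_log_transformed(m))
    stop("select_hvgs expects a log-transformed matrix")
  mad_vals <- gene_mad(m)
  keep <- names(mad_vals)[mad_vals > cutoff]
  if (!length(keep)) warning("no genes pass the MAD cutoff")
  structure(list(gene_ids = keep, mad = mad_vals, cutoff = cutoff), class = "hvg_set")
}

#' @export
print.hvg_set <- function(x, ...) {
  cat(sprintf("hvg_set: %d of %d genes with MAD > %g\n",
              length(x$gene_ids), length(x$mad), x$cutoff))
  invisible(x)
}

#' Standardize gene profiles
#'
#' Centers and scales each row to zero mean and unit variance.  Rows with
#' zero variance are set to all-zero (with a warning), so that they cannot
#' dominate correlation- or distance-based steps.
#'
#' @param m Numeric matrix, genes in rows.
#' @return Matrix of the same shape.
#' @export
standardize_genes <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  flat <- sd == 0 | is.na(sd)
  if (any(flat)) {
    warning(sum(flat), " constant gene profile(s) set to zero after standardization")
    sd[flat] <- 1
  }
  out <- (m - mu) / sd
  out[flat, ] <- 0
  out
}

#' Assign internodes to developmental zones
#'
#' Standardizes each gene profile, clusters the internode columns by
#' average-linkage hierarchical clustering on Euclidean distance, cuts the
#' tree into `k` groups, and labels the groups Zone I..IV (Roman numerals)
#' ordered by the mean developmental stage of their members (ties broken by
#' mean position along the stalk ordering).  A PCA of the same matrix
#' reports per-component variance fractions.
#'
#' @param m Log-scale expression matrix restricted to HVGs (internode
#'   columns).
#' @param meta Optional data.frame mapping `internode` to `stage` and
#'   `internode_index` (defaults to [study_design()] when the columns match
#'   it).
#' @param k Number of zones (default 4).
#' @return List of class `zone_assignment` with `zones` (named character
#'   vector internode -> label), `tree` (hclust), `pca_variance_explained`.
#' @export
assign_zones <- function(m, meta = NULL, k = 4) {
  if (k > ncol(m)) stop("k exceeds the number of internode columns")
  zs <- standardize_genes(unclass(m))
  d <- stats::dist(t(zs))
  tree <- stats::hclust(d, method = "average")
  grp <- stats::cutree(tree, k = k)
  if (is.null(meta)) {
    des <- study_design()
    if (all(colnames(m) %in% des$internode)) meta <- des
  }
  if (!is.null(meta)) {
    stage_num <- match(meta$stage, c("FS", "SS", "TS", "LS"))
    names(stage_num) <- meta$internode
    pos <- seq_len(ncol(m))
    names(pos) <- colnames(m)
    mean_stage <- tapply(stage_num[colnames(m)], grp, mean)
    mean_pos <- tapply(pos[colnames(m)], grp, mean)
    ord <- order(mean_stage, mean_pos)
  } else {
    ord <- order(tapply(seq_len(ncol(m)), grp, mean))
  }
  relabel <- match(grp, ord)
  labels <- as.character(utils::as.roman(relabel))
  names(labels) <- colnames(m)
  pca <- stats::prcomp(t(zs), center = FALSE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(zones = labels, tree = tree,
                 pca_variance_explained = ve, pca = pca),
            class = "zone_assignment")
}

#' @export
print.zone_assignment <- function(x, ...) {
  cat("zone_assignment:\n")
  print(split(names(x$zones), x$zones))
  cat(sprintf("PC1+PC2 variance: %.1f%%\n", 100 * sum(x$pca_variance_explained[1:2])))
  invisible(x)
}

#' Heuristic fuzzifier for fuzzy c-means
#'
#' Dimension-based estimate of the fuzzifier m from the number of features
#' D and objects N (Schwaemmle-Jensen rule), suitable for expression
#' profiles where a hand-picked m is rarely available.
#'
#' @param n_genes Number of objects to be clustered.
#' @param n_samples Number of features (samples).
#' @return Fuzzifier m > 1.
#' @export
estimate_fuzzifier <- function(n_genes, n_samples) {
  D <- n_samples
  N <- n_genes
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering of gene expression profiles
#'
#' Standard fuzzy c-means with alternating updates of centroids
#' `v_i = sum_g u_gi^m x_g / sum_g u_gi^m` and memberships
#' `u_gi = 1 / sum_k (d_gi / d_gk)^(2/(m-1))`, run on per-gene standardized
#' profiles.  A gene coinciding exactly with a centroid receives membership
#' 1 for that centroid.  Initial memberships are drawn at random from the
#' given seed, so runs are reproducible.
#'
#' @param m Log-scale expression matrix restricted to HVGs.
#' @param c Number of clusters (default 12).
#' @param fuzzifier Fuzzifier m > 1; `NULL` (default) uses
#'   [estimate_fuzzifier()].
#' @param max_iter,tol Convergence controls: stop when the largest
#'   membership change drops below `tol` or after `max_iter` iterations.
#' @param seed Mandatory integer seed for the random initialization.
#' @param nstart Number of random restarts; the run with the lowest final
#'   objective is kept (default 5 — fuzzy c-means with many clusters is
#'   prone to local optima).
#' @param standardize Standardize gene rows first (default TRUE; set FALSE
#'   if the input is already standardized).
#' @return List of class `fuzzy_clustering` with `membership` (genes x c),
#'   `hard_labels`, `centroids` (c x samples), `fuzzifier`, `objective`
#'   (per-iteration objective values) and `iterations`.
#' @export
fuzzy_cmeans <- function(m, c = 12, fuzzifier = NULL, max_iter = 200,
                         tol = 1e-6, seed, nstart = 5, standardize = TRUE) {
  if (missing(seed)) stop("fuzzy_cmeans requires an explicit seed")
  x <- unclass(m)
  if (standardize) x <- standardize_genes(x)
  n <- nrow(x)
  if (c < 1 || c > n) stop("c must be between 1 and the number of genes")
  if (is.null(fuzzifier)) fuzzifier <- estimate_fuzzifier(n, ncol(x))
  if (fuzzifier <= 1) stop("fuzzifier must exceed 1")
  if (nstart > 1 && c > 1L) {
    fits <- lapply(seq_len(nstart), function(i)
      fuzzy_cmeans(x, c = c, fuzzifier = fuzzifier, max_iter = max_iter,
                   tol = tol, seed = seed + (i - 1L), nstart = 1,
                   standardize = FALSE))
    obj <- vapply(fits, function(f) utils::tail(f$objective, 1), numeric(1))
    return(fits[[which.min(obj)]])
  }
  if (c == 1L) {
    u <- matrix(1, n, 1, dimnames = list(rownames(x), "C1"))
    cent <- matrix(colMeans(x), 1, ncol(x), dimnames = list("C1", colnames(x)))
    return(structure(list(membership = u,
                          hard_labels = stats::setNames(rep("C1", n), rownames(x)),
                          centroids = cent, c = 1L, fuzzifier = fuzzifier,
                          objective = NA_real_, iterations = 0L),
                     class = "fuzzy_clustering"))
  }
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  u <- matrix(stats::runif(n * c), n, c)
  u <- u / rowSums(u)
  xsq <- rowSums(x^2)
  expo <- 2 / (fuzzifier - 1)
  obj <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^fuzzifier
    cent <- crossprod(um, x) / colSums(um)
    # squared Euclidean distances genes x centroids
    d2 <- outer(xsq, rowSums(cent^2), "+") - 2 * x %*% t(cent)
    d2[d2 < 0] <- 0
    obj <- c(obj, sum(um * d2))
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-expo / 2)
    u_new <- inv / rowSums(inv)
    if (any(zero)) {
      hit <- which(rowSums(zero) > 0)
      u_new[hit, ] <- 0
      u_new[cbind(hit, max.col(-d2[hit, , drop = FALSE]))] <- 1
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol || iter >= max_iter) break
  }
  dimnames(u) <- list(rownames(x), paste0("C", seq_len(c)))
  dimnames(cent) <- list(paste0("C", seq_len(c)), colnames(x))
  hard <- colnames(u)[max.col(u, ties.method = "first")]
  names(hard) <- rownames(x)
  structure(list(membership = u, hard_labels = hard, centroids = cent,
                 c = c, fuzzifier = fuzzifier, objective = obj,
                 iterations = iter),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("fuzzy_clustering: %d genes, c = %d, m = %.3f, %d iterations\n",
              nrow(x$membership), x$c, x$fuzzifier, x$iterations))
  print(table(x$hard_labels))
  invisible(x)
}

#' Membership-weighted mean cluster profiles
#'
#' @param fc A [fuzzy_cmeans()] result.
#' @param m The expression matrix it was fitted to (same genes).
#' @param standardize Standardize gene rows before averaging (default TRUE,
#'   matching the clustering input).
#' @return c x samples matrix of weighted mean standardized profiles.
#' @export
cluster_mean_profiles <- function(fc, m, standardize = TRUE) {
  x <- unclass(m)[rownames(fc$membership), , drop = FALSE]
  if (standardize) x <- standardize_genes(x)
  w <- fc$membership
  prof <- crossprod(w, x) / colSums(w)
  dimnames(prof) <- list(colnames(fc$membership), colnames(x))
  prof
}

# Seed handling: set the RNG seed for a reproducible section without
# clobbering the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
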