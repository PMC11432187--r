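# Shared helpers: independent oracles and small fixture builders.

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Brute-force TOM by triple loop, straight from the definition.
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# Naive quadratic k-mer counter over both strands (substring scan).
kmer_count_oracle <- function(reads, k) {
  counts <- new.env(parent = emptyenv())
  bump <- function(w) {
    assign(w, (if (exists(w, counts)) get(w, counts) else 0L) + 1L, counts)
  }
  for (r in c(reads, revcomp(reads))) {
    for (i in seq_len(nchar(r) - k + 1)) bump(substr(r, i, i + k - 1))
  }
  out <- vapply(ls(counts), get, numeric(1), envir = counts)
  out[order(names(out))]
}

# Exhaustive hypergeometric tail: P(X >= q) for a family of size m in a
# group of size s drawn from N genes, by enumerating all counts.
hyper_tail_oracle <- function(q, m, N, s) {
  ks <- max(0, s - (N - m)):min(m, s)
  p <- choose(m, ks) * choose(N - m, s - ks) / choose(N, s)
  sum(p[ks >= q])
}

# A small log-scale expression matrix with the 19-internode study columns.
toy_internode_matrix <- function(n_genes = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 19, 5, 1.5), n_genes, 19,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              study_design()$internode))
  expr_matrix(m, log_transformed = TRUE)
}

# A tiny replicate-structured TPM matrix plus matching metadata.
toy_replicated <- function(n_genes = 50, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  des <- study_design()
  meta <- do.call(rbind, lapply(1:2, function(r) {
    d <- des
    d$replicate <- r
    d$sample_id <- paste0(d$internode, "_r", r)
    d
  }))
  base <- matrix(rnorm(n_genes * 19, 5, 1), n_genes, 19)
  logx <- cbind(base, base) +
    matrix(rnorm(n_genes * 38, 0, noise_sd), n_genes, 38)
  dimnames(logx) <- list(sprintf("g%03d", seq_len(n_genes)), meta$sample_id)
  list(expr = expr_matrix(pmax(2^logx - 1, 0), log_transformed = FALSE),
       meta = meta)
}

write_expr_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
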