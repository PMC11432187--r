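# Reading and validating expression matrices, sample metadata, trait tables
# and TF-family annotations; replicate agreement and replicate collapsing.

#' Construct an expression matrix object
#'
#' A light container around a genes x samples numeric matrix of TPM values
#' (or log2-transformed TPM).  Gene and sample identifiers are carried as
#' dimnames and validated for uniqueness.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param log_transformed Logical; `TRUE` when values are on the log2 scale.
#' @return An object of class `expr_matrix` (the validated matrix with a
#'   `log_transformed` attribute).
#' @export
expr_matrix <- function(values, log_transformed = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!log_transformed && any(values < 0, na.rm = TRUE))
    stop("TPM values must be non-negative")
  structure(values, log_transformed = isTRUE(log_transformed), class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "log_transformed"))) "log2" else "linear TPM"))
  invisible(x)
}

#' Is the matrix log-transformed?
#' @param m An `expr_matrix`.
#' @return Logical.
#' @export
is_log_transformed <- function(m) isTRUE(attr(m, "log_transformed"))

#' Read a gene x sample TPM matrix from a TSV file
#'
#' The file must be tab-separated with a header row of sample ids and gene
#' ids in the first column.  With `log2_offset > 0` the values are
#' transformed to `log2(TPM + offset)` (offset 1 gives the usual
#' log2(TPM+1) scale) and the result is flagged as log-transformed.
#'
#' @param path Path to the TSV file.
#' @param log2_offset Non-negative offset; 0 keeps the linear TPM scale.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, log2_offset = 0) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression file needs a gene id column plus at least one sample")
  gene_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 gene_ids[bad[["row"]]], colnames(vals)[bad[["col"]]]))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  m <- expr_matrix(num, log_transformed = FALSE)
  if (log2_offset > 0) m <- log_transform(m, offset = log2_offset)
  m
}

#' Log2-transform a TPM matrix
#'
#' @param m An [expr_matrix()] on the linear scale.
#' @param offset Pseudo-TPM added before taking log2 (default 1).
#' @return A log-transformed `expr_matrix`.
#' @export
log_transform <- function(m, offset = 1) {
  if (is_log_transformed(m)) stop("matrix is already log-transformed")
  expr_matrix(log2(unclass(m) + offset), log_transformed = TRUE)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `stage` (FS/SS/TS/LS), `internode_index`
#' (1-based, bottom to top within stage) and `replicate`.  An optional
#' `zone` column is preserved.
#'
#' @param path TSV path.
#' @return A data.frame with one row per sample, plus an `internode` column
#'   (`stage` pasted with `internode_index`, e.g. "LS5"; the single FS
#'   internode is labelled "FS").
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_sample_meta(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df Data frame with `sample_id`, `stage`, `internode_index`,
#'   `replicate` columns.
#' @return The validated data.frame with a derived `internode` label.
#' @export
validate_sample_meta <- function(df) {
  need <- c("sample_id", "stage", "internode_index", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$stage %in% c("FS", "SS", "TS", "LS")))
    stop("stage must be one of FS, SS, TS, LS")
  if (any(df$internode_index < 1) || any(df$replicate < 1))
    stop("internode_index and replicate must be positive integers")
  key <- paste(df$stage, df$internode_index, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (stage, internode_index, replicate) combinations")
  df$internode <- internode_label(df$stage, df$internode_index)
  df
}

#' Canonical internode labels
#'
#' @param stage Stage codes (FS/SS/TS/LS).
#' @param index Internode index within stage.
#' @return Labels such as "SS2"; the single first-stage internode is "FS".
#' @export
internode_label <- function(stage, index) {
  ifelse(stage == "FS", "FS", paste0(stage, index))
}

#' The emulated study sampling design
#'
#' One internode at the first stage, three at the second, six at the third
#' and nine at the last stage, ordered bottom-to-top within stage and by
#' stage overall.
#'
#' @return Data frame with `internode`, `stage`, `internode_index` in
#'   canonical column order (19 rows).
#' @export
study_design <- function() {
  stage <- c("FS", rep("SS", 3), rep("TS", 6), rep("LS", 9))
  index <- c(1L, 1:3, 1:6, 1:9)
  data.frame(internode = internode_label(stage, index),
             stage = stage, internode_index = index,
             stringsAsFactors = FALSE)
}

#' Read a per-internode trait table
#'
#' @param path TSV with columns `internode`, `length`, `diameter`
#'   (cm and mm respectively).
#' @return Validated data.frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("internode", "length", "diameter")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$internode)) stop("duplicate internode rows in trait table")
  if (any(df$length <= 0) || any(df$diameter <= 0))
    stop("lengths and diameters must be strictly positive")
  df
}

#' Read a TF-family annotation table
#'
#' @param path TSV with columns `gene_id` and `family`.
#' @return Validated data.frame (each gene annotated at most once).
#' @export
read_tf_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "family")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TF annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("a gene maps to more than one TF family")
  df
}

#' Per-internode replicate correlation
#'
#' Pearson correlation between the two replicate columns of each internode,
#' computed on the log2 scale (the matrix is transformed with offset 1 if it
#' arrives on the linear scale).
#'
#' @param m An [expr_matrix()].
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @return Data frame with `internode` and `r`, ordered as in the design.
#' @export
replicate_correlation <- function(m, meta) {
  meta <- validate_sample_meta(meta)
  if (!is_log_transformed(m)) m <- log_transform(m, offset = 1)
  groups <- split(meta$sample_id, meta$internode)
  bad <- names(groups)[vapply(groups, length, 1L) != 2L]
  if (length(bad))
    stop("internodes without exactly two replicates: ", paste(bad, collapse = ", "))
  ord <- intersect(unique(meta$internode[order(match(meta$stage, c("FS", "SS", "TS", "LS")),
                                               meta$internode_index)]), names(groups))
  r <- vapply(ord, function(g) {
    s <- groups[[g]]
    stats::cor(m[, s[1L]], m[, s[2L]])
  }, numeric(1))
  data.frame(internode = ord, r = unname(r), stringsAsFactors = FALSE)
}

#' Collapse replicate columns to internode means
#'
#' Averages the replicates of each internode (arithmetic mean on the scale
#' of the input matrix) and orders the columns bottom-to-top within stage,
#' stages FS to LS.
#'
#' @inheritParams replicate_correlation
#' @return An `expr_matrix` with one column per internode.
#' @export
collapse_replicates <- function(m, meta) {
  meta <- validate_sample_meta(meta)
  missing_samples <- setdiff(meta$sample_id, colnames(m))
  if (length(missing_samples))
    stop("samples in metadata absent from matrix: ", paste(missing_samples, collapse = ", "))
  ord_meta <- meta[order(match(meta$stage, c("FS", "SS", "TS", "LS")), meta$internode_index), ]
  internodes <- unique(ord_meta$internode)
  out <- matrix(0, nrow(m), length(internodes),
                dimnames = list(rownames(m), internodes))
  for (g in internodes) {
    cols <- meta$sample_id[meta$internode == g]
    out[, g] <- rowMeans(m[, cols, drop = FALSE])
  }
  expr_matrix(out, log_transformed = is_log_transformed(m))
}
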