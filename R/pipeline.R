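# End-to-end orchestration: run every stage from a single configuration,
# writing per-stage outputs and JSON manifests so a run can be resumed.

#' Pipeline configuration
#'
#' Paths of the inputs plus the stage parameters, with defaults matching
#' the study analysis: MAD cutoff 1, 12 expression clusters, 4 zones,
#' soft power 9 (or `"auto"` to re-derive it from the power scan), minimum
#' module size 50, top-100 hub connectivity, 10-mer enrichment, 2-kb
#' promoter span.
#'
#' @param expr,meta,traits,tf Paths of the expression matrix, sample
#'   metadata, trait table and TF annotation TSVs.
#' @param selex_selected,selex_input Optional FASTA/FASTQ paths of the
#'   final-round and round-0 SELEX libraries.
#' @param genome,gff Optional genome FASTA and GFF3 paths.
#' @param out_dir Run directory for outputs and manifests.
#' @param mad_cutoff,clusters,zones,beta,min_module_size,top_n,k,span,
#'   quantile Stage parameters (see the stage functions).
#' @param seed Seed used by every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expr, meta, traits = NULL, tf = NULL,
                            selex_selected = NULL, selex_input = NULL,
                            genome = NULL, gff = NULL,
                            out_dir = "stalkscape_run",
                            mad_cutoff = 1, clusters = 12, zones = 4,
                            beta = 9, min_module_size = 50, top_n = 100,
                            k = 10, span = 2000, quantile = 0.999,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage <- function(out_dir, stage, outputs, params) {
  manifest <- list(stage = stage,
                   params = params,
                   outputs = outputs,
                   md5 = vapply(outputs, function(p) unname(tools::md5sum(p)),
                                character(1)),
                   package_version = as.character(utils::packageVersion("stalkscape")))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

stage_done <- function(out_dir, stage) {
  mf <- file.path(out_dir, paste0(stage, ".manifest.json"))
  if (!file.exists(mf)) return(FALSE)
  man <- jsonlite::read_json(mf)
  paths <- unlist(man$outputs)
  if (!all(file.exists(paths))) return(FALSE)
  all(vapply(seq_along(paths), function(i)
    unname(tools::md5sum(paths[i])) == man$md5[[i]], logical(1)))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — load, HVG selection, zone
#' assignment, fuzzy clustering, TF analysis, network construction,
#' module-trait statistics, hub extraction and (when SELEX/genome inputs
#' are configured) 10-mer enrichment and promoter scanning — writing each
#' stage's tables plus a JSON manifest (parameters, output checksums) to
#' the run directory.  With `resume = TRUE` stages whose manifests and
#' outputs are intact are skipped; a corrupt or missing intermediate
#' raises an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @param resume Skip completed stages (default FALSE).
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- cfg$out_dir

  # load ------------------------------------------------------------------
  expr <- read_expression(cfg$expr, log2_offset = 0)
  meta <- read_sample_meta(cfg$meta)
  rep_cor <- replicate_correlation(expr, meta)
  logm <- log_transform(collapse_replicates(expr, meta), offset = 1)
  if (!resume || !stage_done(od, "load")) {
    p <- write_tsv(rep_cor, file.path(od, "replicate_correlation.tsv"))
    write_stage(od, "load", list(rep_cor = p), list(log2_offset = 1))
  }

  # hvg -------------------------------------------------------------------
  hvgs <- select_hvgs(logm, cutoff = cfg$mad_cutoff)
  hvg_m <- logm[hvgs$gene_ids, , drop = FALSE]
  if (!resume || !stage_done(od, "hvg")) {
    p <- write_tsv(data.frame(gene = names(hvgs$mad), mad = hvgs$mad,
                              hvg = names(hvgs$mad) %in% hvgs$gene_ids),
                   file.path(od, "hvgs.tsv"))
    write_stage(od, "hvg", list(hvgs = p), list(mad_cutoff = cfg$mad_cutoff))
  }

  # zones -----------------------------------------------------------------
  za <- assign_zones(hvg_m, k = cfg$zones)
  if (!resume || !stage_done(od, "zones")) {
    p <- write_tsv(data.frame(internode = names(za$zones), zone = za$zones),
                   file.path(od, "zones.tsv"))
    write_stage(od, "zones", list(zones = p),
                list(k = cfg$zones,
                     pc12 = sum(za$pca_variance_explained[1:2])))
  }

  # cluster ---------------------------------------------------------------
  fc <- fuzzy_cmeans(hvg_m, c = cfg$clusters, seed = cfg$seed)
  if (!resume || !stage_done(od, "cluster")) {
    p1 <- write_tsv(data.frame(gene = rownames(fc$membership),
                               round(fc$membership, 6)),
                    file.path(od, "membership.tsv"))
    p2 <- write_tsv(data.frame(gene = names(fc$hard_labels),
                               cluster = fc$hard_labels,
                               max_membership = round(apply(fc$membership, 1, max), 6)),
                    file.path(od, "clusters.tsv"))
    write_stage(od, "cluster", list(membership = p1, clusters = p2),
                list(c = cfg$clusters, fuzzifier = fc$fuzzifier, seed = cfg$seed))
  }

  # tf --------------------------------------------------------------------
  if (!is.null(cfg$tf)) {
    ann <- read_tf_annotation(cfg$tf)
    fr <- family_ratios(hvgs, ann)
    hvtfs <- intersect(ann$gene_id, hvgs$gene_ids)
    if (length(hvtfs) >= 6) {
      groups <- group_hvtfs(logm[hvtfs, , drop = FALSE], k = 6)
      enr <- family_overrepresentation(groups, ann)
    } else {
      groups <- NULL
      enr <- NULL
    }
    if (!resume || !stage_done(od, "tf")) {
      outs <- list(ratios = write_tsv(fr$table, file.path(od, "tf_ratios.tsv")))
      if (!is.null(groups)) {
        outs$groups <- write_tsv(data.frame(gene = names(groups), group = groups),
                                 file.path(od, "tf_groups.tsv"))
        outs$enrichment <- write_tsv(enr, file.path(od, "tf_enrichment.tsv"))
      }
      write_stage(od, "tf", outs,
                  list(global_fraction = fr$global_fraction))
    }
  }

  # network ---------------------------------------------------------------
  beta <- cfg$beta
  if (identical(beta, "auto")) {
    ps <- power_scan(hvg_m, k_max = scale_k_max(nrow(hvg_m)))
    beta <- if (is.na(ps$beta)) 9 else ps$beta
  }
  adj <- adjacency_matrix(hvg_m, beta = beta)
  tom <- compute_tom(adj)
  labels <- detect_modules(tom, min_module_size = cfg$min_module_size)
  mes <- module_eigengenes(hvg_m, labels)
  if (!resume || !stage_done(od, "network")) {
    p1 <- write_tsv(data.frame(gene = names(labels), module = labels),
                    file.path(od, "modules.tsv"))
    p2 <- write_tsv(data.frame(module = rownames(mes), round(mes, 6)),
                    file.path(od, "eigengenes.tsv"))
    write_stage(od, "network", list(modules = p1, eigengenes = p2),
                list(beta = beta, min_module_size = cfg$min_module_size))
  }

  # module-trait ----------------------------------------------------------
  mt <- NULL
  if (!is.null(cfg$traits) && nrow(mes) > 0) {
    traits <- read_traits(cfg$traits)
    mt <- module_trait(hvg_m, mes, traits, labels)
    if (!resume || !stage_done(od, "module_trait")) {
      p <- write_tsv(mt$stats, file.path(od, "module_trait.tsv"))
      write_stage(od, "module_trait", list(module_trait = p), list())
    }
  }

  # hubs ------------------------------------------------------------------
  if (!is.null(mt) && nrow(mt$stats) > 0) {
    best <- mt$stats[which.max(abs(mt$stats$r)), ]
    hn <- hub_network(tom, labels, best$module,
                      top_n = min(cfg$top_n, sum(labels == best$module)))
    if (!resume || !stage_done(od, "hubs")) {
      p <- write_tsv(hn$edges, file.path(od, "hub_edges.tsv"))
      write_stage(od, "hubs", list(hub_edges = p),
                  list(module = best$module, top_n = cfg$top_n))
    }
  }

  # selex -----------------------------------------------------------------
  ke <- NULL
  if (!is.null(cfg$selex_selected)) {
    sel <- dedupe_reads(read_selex_reads(cfg$selex_selected, round = NA))
    null <- shuffle_library(sel, seed = cfg$seed)
    ke <- kmer_enrichment(sel, null, k = cfg$k)
    if (!resume || !stage_done(od, "selex")) {
      p <- write_tsv(top_kmers(ke, 1000), file.path(od, "kmers.tsv"))
      write_stage(od, "selex", list(kmers = p),
                  list(k = cfg$k, seed = cfg$seed))
    }
  }

  # scan ------------------------------------------------------------------
  if (!is.null(ke) && !is.null(cfg$genome) && !is.null(cfg$gff)) {
    track <- score_genome(cfg$genome, ke)
    win <- promoter_windows(cfg$gff, span = cfg$span,
                            chrom_lengths = vapply(track$tracks, length, 1L) +
                              track$k - 1L)
    sites <- call_sites(track, win, threshold_quantile = cfg$quantile)
    if (!resume || !stage_done(od, "scan")) {
      p <- file.path(od, "sites.bed")
      write_sites_bed(sites, p)
      write_stage(od, "scan", list(sites = p),
                  list(span = cfg$span, quantile = cfg$quantile,
                       threshold = attr(sites, "threshold")))
    }
  }

  invisible(od)
}
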