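# End-to-end orchestration: simulate (or read) -> normalize -> time-effect
# LRT -> polarization -> clustering -> enrichment, under one config with a
# single global seed fanned out to the stochastic stages by fixed offsets.

#' Pipeline configuration
#'
#' Collects the thresholds and stage settings of the full analysis. When
#' `counts_path` / `design_path` are `NULL` the synthetic-data generator
#' supplies the inputs (with the global `seed`); otherwise the TSVs are
#' read and validated. Stage seeds are derived from the global seed by
#' fixed offsets (simulation: `seed`; annotation: `seed + 1`; profile
#' permutations: `seed + 2` and `seed + 3` for the two sides).
#'
#' @param alpha_level BH-adjusted significance level for the DE call.
#' @param ccc_cutoff concordance cutoff for the low-concordance flag.
#' @param fold_threshold fold-change threshold of the trend rules.
#' @param pseudocount pseudocount for ratio/log2 computations.
#' @param transform CCC input scale, `"linear"` or `"log2p1"`.
#' @param cluster_k clusters for the cut of the gene dendrogram.
#' @param max_profiles model-profile cap for profile clustering.
#' @param n_permutations permutations for profile significance.
#' @param enrichment_background `"de"` (DE gene set, default) or `"all"`
#'   (every tested gene).
#' @param n_terms,enriched_term_fraction,term_size,odds_ratio synthetic
#'   annotation settings (ignored when `annotation_path` is given).
#' @param sim list of arguments to [simulation_config()] (seed is taken
#'   from the global `seed`).
#' @param counts_path,design_path,annotation_path optional input TSVs.
#' @param seed global integer seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_level = 0.05, ccc_cutoff = 0.6,
                            fold_threshold = 1.6, pseudocount = 1,
                            transform = "linear", cluster_k = 6L,
                            max_profiles = 20L, n_permutations = 200L,
                            enrichment_background = c("de", "all"),
                            n_terms = 100L, enriched_term_fraction = 0.1,
                            term_size = 50L, odds_ratio = 8,
                            sim = list(), counts_path = NULL,
                            design_path = NULL, annotation_path = NULL,
                            seed = 1L) {
  if (alpha_level < 0 || alpha_level > 1) stop("alpha_level must be in [0, 1]")
  if (fold_threshold <= 0) stop("fold_threshold must be positive")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  enrichment_background <- match.arg(enrichment_background)
  transform <- match.arg(transform, c("linear", "log2p1"))
  for (p in c(counts_path, design_path, annotation_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  structure(
    list(alpha_level = alpha_level, ccc_cutoff = ccc_cutoff,
         fold_threshold = fold_threshold, pseudocount = pseudocount,
         transform = transform, cluster_k = as.integer(cluster_k),
         max_profiles = as.integer(max_profiles),
         n_permutations = as.integer(n_permutations),
         enrichment_background = enrichment_background,
         n_terms = as.integer(n_terms),
         enriched_term_fraction = enriched_term_fraction,
         term_size = as.integer(term_size), odds_ratio = odds_ratio,
         sim = sim, counts_path = counts_path, design_path = design_path,
         annotation_path = annotation_path, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; the `sim` mapping
#' holds [simulation_config()] arguments.
#'
#' @param path YAML file.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

# small deterministic string hash for the run log (djb2 mod 2^31 - 1)
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 5381
  for (c_ in utf8ToInt(txt)) h <- (h * 33 + c_) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full two-sided time-course analysis
#'
#' Executes the stages in order, writes per-stage TSVs, a machine-readable
#' JSON summary and a run log into `out_dir`. Identical configuration and
#' seed give a byte-identical summary.
#'
#' @param config [pipeline_config()] object.
#' @param out_dir output directory (created if needed).
#' @return list of class `polarseq_run` with the summary, stage objects
#'   and file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be created by pipeline_config()")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("polarseq %s | %s",
                         as.character(utils::packageVersion("polarseq")),
                         R.version.string),
                 sprintf("seed: %d", config$seed),
                 sprintf("config hash: %s", config_hash(config)))
  stage <- function(name) log_lines <<- c(log_lines, paste("stage:", name))

  stage("input")
  truth <- NULL
  if (!is.null(config$counts_path)) {
    counts <- read_count_matrix(config$counts_path)
    design <- read_design(config$design_path, counts)
  } else {
    sim_cfg <- do.call(simulation_config,
                       c(config$sim, list(seed = config$seed)))
    sim <- simulate_counts(sim_cfg)
    counts <- sim$counts
    design <- sim$design
    truth <- sim$truth
    write_count_matrix(counts, file.path(out_dir, "counts.tsv"))
    write_tsv(design, file.path(out_dir, "design.tsv"))
    write_tsv(data.frame(gene = names(truth$class), class = truth$class,
                         dispersion = truth$dispersion,
                         baseline_mean = truth$baseline_mean,
                         row.names = NULL),
              file.path(out_dir, "ground_truth.tsv"))
  }

  stage("normalize")
  s <- size_factors(counts)
  q <- normalize_counts(counts, s)
  profiles <- side_profiles(q, design)
  write_tsv(data.frame(sample = names(s), size_factor = s, row.names = NULL),
            file.path(out_dir, "size_factors.tsv"))
  write_count_matrix(round(q, 4), file.path(out_dir, "normalized.tsv"))

  stage("detest")
  disp <- estimate_dispersions(counts, s, design)
  de <- lrt_time_effect(counts, s, design, disp,
                        alpha_level = config$alpha_level)
  write_tsv(de, file.path(out_dir, "detest.tsv"))

  stage("polarize")
  records <- polarize(profiles, de, cutoff = config$ccc_cutoff,
                      fold = config$fold_threshold,
                      pseudocount = config$pseudocount,
                      transform = config$transform)
  de_records <- records[records$de_flag, , drop = FALSE]
  write_results_table(de_records, file.path(out_dir, "polarization.tsv"))
  write_results_table(records, file.path(out_dir, "results.tsv"))
  de_genes <- de_records$gene
  ivl <- NULL

  stage("cluster")
  gene_clusters <- NULL
  sample_clusters <- NULL
  prof_clust <- list()
  if (length(de_genes) >= 2L) {
    z <- suppressWarnings(preprocess_for_clustering(
      q[de_genes, , drop = FALSE]))
    if (nrow(z) >= 2L) {
      k <- min(config$cluster_k, nrow(z))
      gene_clusters <- hierarchical_cluster(z, axis = "genes", k = k)
      write_tsv(data.frame(gene = rownames(z),
                           cluster = gene_clusters$clusters,
                           row.names = NULL),
                file.path(out_dir, "gene_clusters.tsv"))
      write_newick(gene_clusters, file.path(out_dir, "gene_tree.nwk"))
      sample_clusters <- hierarchical_cluster(z, axis = "samples")
      write_newick(sample_clusters, file.path(out_dir, "sample_tree.nwk"))
    }
    de_prof <- list(oral = profiles$oral[de_genes, , drop = FALSE],
                    physa = profiles$physa[de_genes, , drop = FALSE])
    prof_clust <- lapply(seq_along(de_prof), function(i) {
      profile_cluster(de_prof[[i]], max_profiles = config$max_profiles,
                      n_permutations = config$n_permutations,
                      seed = config$seed + 1L + i)
    })
    names(prof_clust) <- names(de_prof)
    for (sd in names(prof_clust)) {
      write_tsv(prof_clust[[sd]]$assignment,
                file.path(out_dir, paste0("profiles_", sd, ".tsv")))
    }
    ivl <- interval_changes(
      structure(list(oral = de_prof$oral, physa = de_prof$physa,
                     time_points = profiles$time_points),
                class = "expression_profiles"),
      fold = config$fold_threshold, pseudocount = config$pseudocount)
  }

  stage("enrich")
  enr <- NULL
  annotation <- NULL
  low_genes <- de_records$gene[de_records$low_concordance_flag %in% TRUE]
  if (!is.null(config$annotation_path)) {
    annotation <- list(map = read_category_map(config$annotation_path),
                       enriched_terms = character())
  } else if (!is.null(truth)) {
    annotation <- simulate_annotation(
      truth, n_terms = config$n_terms,
      enriched_term_fraction = config$enriched_term_fraction,
      seed = config$seed + 1L, term_size = config$term_size,
      odds_ratio = config$odds_ratio)
    write_tsv(annotation$map, file.path(out_dir, "annotation.tsv"))
  }
  if (!is.null(annotation) && length(low_genes)) {
    background <- if (config$enrichment_background == "de") de_genes
                  else de$gene[de$tested]
    enr <- enrich(low_genes, background, annotation$map,
                  alpha = config$alpha_level)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }

  stage("summary")
  trend_tab <- table(factor(de_records$side_trend_category,
                            levels = c("both", "oral_only", "physa_only")))
  ivl_counts <- list()
  if (!is.null(ivl)) {
    for (r in seq_len(nrow(ivl$counts))) {
      row <- ivl$counts[r, ]
      if (row$direction == "flat") next
      ivl_counts[[paste(row$side, row$interval, row$direction,
                        sep = ".")]] <- row$n
    }
  }
  summary_obj <- list(
    schema_version = "1",
    seed = config$seed,
    n_genes = nrow(counts),
    n_tested = sum(de$tested),
    n_untested = sum(!de$tested),
    n_de = sum(de$de_flag),
    n_not_significant = sum(de$tested & !de$de_flag),
    n_low_concordance = length(low_genes),
    trend_categories = as.list(stats::setNames(as.integer(trend_tab),
                                               names(trend_tab))),
    interval_changes = ivl_counts,
    largest_profile = lapply(prof_clust, function(pc) {
      i <- which.max(pc$counts)
      list(profile_id = names(pc$counts)[i],
           shape = pc$profiles$shape[i],
           n_genes = as.integer(pc$counts[i]))
    }),
    n_enriched_terms = if (is.null(enr)) 0L else sum(enr$significant))
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_obj, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(structure(list(summary = summary_obj, summary_path = summary_path,
                 out_dir = out_dir, counts = counts, design = design,
                 truth = truth, size_factors = s, profiles = profiles,
                 dispersions = disp, de = de, records = records,
                 gene_clusters = gene_clusters,
                 sample_clusters = sample_clusters,
                 profile_clusters = prof_clust, enrichment = enr),
            class = "polarseq_run"))
}

#' @export
print.polarseq_run <- function(x, ...) {
  s <- x$summary
  cat("polarseq pipeline run\n")
  cat(sprintf("  output: %s\n", x$out_dir))
  cat(sprintf("  genes: %d (tested %d, DE %d, low-concordance %d)\n",
              s$n_genes, s$n_tested, s$n_de, s$n_low_concordance))
  cat(sprintf("  enriched terms: %d\n", s$n_enriched_terms))
  invisible(x)
}
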