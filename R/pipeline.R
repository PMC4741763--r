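# End-to-end driver: (simulate | read) -> per-pair DMPs -> concordant
# signature -> gene mapping + enrichment -> overlap significance ->
# clustering -> expression integration -> report.

#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [simulation_config()]) or `paths` must be
#' given. `paths` is a list with elements `beta`, `annotation`, `samples`
#' (TSV paths) and `expression` (named list of per-tissue TSV paths).
#'
#' @param simulation Optional [simulation_config()].
#' @param paths Optional list of input paths.
#' @param delta_threshold Absolute delta-beta calling threshold (default 0.25).
#' @param p_threshold Methylation significance threshold (default 0.001).
#' @param calling_mode `"raw_p"` (default) or `"fdr"` (BH q < threshold,
#'   typically 0.05).
#' @param fold_threshold Expression linear fold threshold (default 2).
#' @param score_threshold Expression DiffScore threshold (default 13).
#' @param method Differential methylation test: `"moderated"` or `"welch"`.
#' @param n_permutations Permutations for the multi-way overlap test.
#' @param epsilon Beta clipping bound for the M transform.
#' @param seed Seed for the pipeline's own randomness (permutations).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            delta_threshold = 0.25, p_threshold = 0.001,
                            calling_mode = c("raw_p", "fdr"),
                            fold_threshold = 2, score_threshold = 13,
                            method = c("moderated", "welch"),
                            n_permutations = 1000L, epsilon = 1e-6,
                            seed = 1L) {
  calling_mode <- match.arg(calling_mode)
  method <- match.arg(method)
  if (is.null(simulation) == is.null(paths))
    stop("exactly one of simulation or paths must be given")
  if (!is.null(simulation)) validate_simulation_config(simulation)
  if (delta_threshold <= 0 || delta_threshold >= 1 ||
      p_threshold <= 0 || p_threshold >= 1)
    stop("methylation thresholds must be in (0, 1)")
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  structure(list(simulation = simulation, paths = paths,
                 delta_threshold = delta_threshold, p_threshold = p_threshold,
                 calling_mode = calling_mode, fold_threshold = fold_threshold,
                 score_threshold = score_threshold, method = method,
                 n_permutations = as.integer(n_permutations),
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "pipeline_config")
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes (simulate or read inputs) -> per-pair differential methylation ->
#' concordant signature -> gene mapping, promoter filtering, enhancer and
#' promoter enrichment -> multi-way overlap significance -> sample clustering
#' on the signature probes -> expression normalization, per-pair differential
#' expression, cross-pair intersection and promoter-hypomethylation /
#' upregulation overlap. The report carries every count and p-value together
#' with the thresholds and universes used, plus ground-truth recovery metrics
#' when running from a simulation. Identical config gives an identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, the signature BED /
#'   gene lists / JSON report, per-pair DMP tables, the dendrogram and the
#'   heatmap matrix are written there.
#' @return The report, an object of class `pipeline_report` (a nested list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$simulation)) {
    data <- generate_dataset(config$simulation)
  } else {
    p <- config$paths
    ann <- read_probe_annotation(p$annotation)
    samples <- read_sample_sheet(p$samples)
    expression <- lapply(p$expression, read_expression_matrix)
    data <- list(annotation = ann, beta = read_beta_matrix(p$beta),
                 samples = samples, truth = NULL,
                 expression = expression, truth_genes = NULL)
  }
  annotation <- data$annotation
  samples <- data$samples
  tissues <- unique(samples$tissue)

  # --- differential methylation per pair ---------------------------------
  tables <- list()
  calls <- list()
  universes <- list()
  for (t in tissues) {
    tab <- test_pair(data$beta, samples, t, epsilon = config$epsilon,
                     method = config$method,
                     delta_threshold = config$delta_threshold,
                     p_threshold = config$p_threshold,
                     mode = config$calling_mode)
    tables[[t]] <- tab
    calls[[t]] <- call_dmps(tab, config$delta_threshold, config$p_threshold,
                            config$calling_mode)
    universes[[t]] <- tab$probe_id
  }

  signature <- intersect_concordant(calls, universes)
  sig_probes <- c(signature$common_hyper, signature$common_hypo)

  # mean delta beta across pairs, for BED scores and reporting
  mean_delta <- if (length(sig_probes)) {
    rowMeans(vapply(tables, function(tab)
      tab$delta_beta[match(sig_probes, tab$probe_id)],
      numeric(length(sig_probes))))
  } else numeric(0)
  names(mean_delta) <- sig_probes

  # --- gene mapping and promoter subsets ---------------------------------
  hyper_genes <- probes_to_genes(signature$common_hyper, annotation)
  hypo_genes <- probes_to_genes(signature$common_hypo, annotation)
  hyper_promoter <- filter_promoter_probes(signature$common_hyper, annotation)
  hypo_promoter <- filter_promoter_probes(signature$common_hypo, annotation)
  hypo_promoter_genes <- probes_to_genes(hypo_promoter, annotation)$genes
  hyper_promoter_genes <- probes_to_genes(hyper_promoter, annotation)$genes

  # --- enrichment --------------------------------------------------------
  enr <- list(
    enhancer_hypo = category_enrichment(signature$common_hypo, "enhancer",
                                        signature$universe, annotation),
    enhancer_hyper = category_enrichment(signature$common_hyper, "enhancer",
                                         signature$universe, annotation),
    promoter_hypo = category_enrichment(
      hypo_promoter, filter_promoter_probes(signature$universe, annotation),
      signature$universe),
    promoter_hyper = category_enrichment(
      hyper_promoter, filter_promoter_probes(signature$universe, annotation),
      signature$universe)
  )

  overlap_hypo <- multiway_overlap_significance(
    lapply(calls, `[[`, "hypo"), signature$universe,
    n_permutations = config$n_permutations, seed = config$seed + 11L)
  overlap_hyper <- multiway_overlap_significance(
    lapply(calls, `[[`, "hyper"), signature$universe,
    n_permutations = config$n_permutations, seed = config$seed + 12L)

  # --- clustering on signature probes ------------------------------------
  clustering <- NULL
  if (length(sig_probes) >= 2L) {
    cl <- cluster_samples(data$beta, sig_probes)
    phen <- samples$phenotype[match(names(cl$cut2), samples$sample_id)]
    agree <- length(unique(cl$cut2[phen == "invasive"])) == 1L &&
      length(unique(cl$cut2[phen == "non_invasive"])) == 1L &&
      cl$cut2[phen == "invasive"][1L] != cl$cut2[phen == "non_invasive"][1L]
    clustering <- list(result = cl, phenotype_separation = agree)
  }

  # --- expression integration --------------------------------------------
  de_tables <- list()
  for (t in names(data$expression)) {
    norm <- quantile_normalize(data$expression[[t]])
    de_tables[[t]] <- call_de_pair(norm, samples, t,
                                   fold_threshold = config$fold_threshold,
                                   score_threshold = config$score_threshold,
                                   method = config$method)
  }
  de_common <- intersect_de_common(de_tables)
  meth_genes <- probes_to_genes(signature$universe, annotation)$genes
  expr_genes <- unique(unlist(lapply(data$expression, rownames), use.names = FALSE))
  shared_universe <- length(intersect(meth_genes, expr_genes))
  hypo_up <- gene_list_overlap(intersect(hypo_promoter_genes, expr_genes),
                               de_common$common_up, shared_universe)

  # --- ground-truth recovery (simulation mode only) ----------------------
  recovery <- NULL
  if (!is.null(data$truth)) {
    truth <- data$truth
    planted_hypo <- truth$probe_id[truth$class == "common_hypo"]
    planted_hyper <- truth$probe_id[truth$class == "common_hyper"]
    nulls <- intersect(truth$probe_id[truth$class == "null"], signature$universe)
    called_null <- intersect(sig_probes, nulls)
    planted_prom_genes <- data$truth_genes$gene[data$truth_genes$planted_promoter_hypo]
    recovery <- list(
      jaccard_common_hypo = .jaccard(signature$common_hypo, planted_hypo),
      jaccard_common_hyper = .jaccard(signature$common_hyper, planted_hyper),
      null_false_call_rate = length(called_null) / max(length(nulls), 1L),
      n_null_tested = length(nulls),
      concordance_recovered =
        length(intersect(hypo_up$overlap, planted_prom_genes)) /
          max(length(planted_prom_genes), 1L)
    )
  }

  report <- list(
    package_version = as.character(utils::packageVersion("methsig")),
    config_hash = .config_hash(config),
    seed = config$seed,
    thresholds = list(delta_beta = config$delta_threshold,
                      p = config$p_threshold, mode = config$calling_mode,
                      fold = config$fold_threshold,
                      diff_score = config$score_threshold,
                      method = config$method),
    pairs = lapply(tables, function(tab) list(
      pair = attr(tab, "pair"),
      n_tested = nrow(tab),
      n_excluded = attr(tab, "n_excluded"),
      n_hyper = sum(tab$direction == "hyper"),
      n_hypo = sum(tab$direction == "hypo"))),
    signature = list(
      n_common_hyper = length(signature$common_hyper),
      n_common_hypo = length(signature$common_hypo),
      n_universe = length(signature$universe),
      n_hyper_genes = length(hyper_genes$genes),
      n_hypo_genes = length(hypo_genes$genes),
      n_hyper_promoter = length(hyper_promoter),
      n_hypo_promoter = length(hypo_promoter),
      n_hyper_promoter_genes = length(hyper_promoter_genes),
      n_hypo_promoter_genes = length(hypo_promoter_genes)),
    enrichment = lapply(enr, function(e) list(
      hits = e$hits, subset_size = e$subset_size,
      category_size = e$category_size, universe_size = e$universe_size,
      fraction = e$fraction, background_fraction = e$background_fraction,
      fold_enrichment = e$fold_enrichment, log10_p = e$test$log10_p)),
    overlap = list(
      hypo = list(observed = overlap_hypo$observed,
                  expected = overlap_hypo$expected,
                  permutation_p = overlap_hypo$permutation_p),
      hyper = list(observed = overlap_hyper$observed,
                   expected = overlap_hyper$expected,
                   permutation_p = overlap_hyper$permutation_p)),
    clustering = if (is.null(clustering)) NULL else list(
      phenotype_separation = clustering$phenotype_separation,
      leaf_order = clustering$result$leaf_order),
    expression = list(
      pairs = lapply(de_tables, function(tab) list(
        pair = attr(tab, "pair"),
        n_up = sum(tab$call == "up"),
        n_down = sum(tab$call == "down"))),
      n_common_up = length(de_common$common_up),
      n_common_down = length(de_common$common_down),
      hypo_up_overlap = list(n_overlap = hypo_up$n_overlap,
                             n_hypo_promoter_genes = hypo_up$n_a,
                             n_common_up = hypo_up$n_b,
                             universe_size = hypo_up$universe_size,
                             log10_p = hypo_up$test$log10_p)),
    recovery = recovery
  )
  class(report) <- c("pipeline_report", "list")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_signature_outputs(signature, annotation, out_dir,
                            scores = mean_delta,
                            report = report[c("thresholds", "enrichment",
                                              "overlap", "expression")])
    for (t in names(tables))
      write_dmp_table(tables[[t]], file.path(out_dir, paste0("dmp_", t, ".tsv")))
    if (!is.null(clustering))
      export_tree_and_heatmap(clustering$result, data$beta, sig_probes, out_dir)
    jsonlite::write_json(unclass(report), file.path(out_dir, "pipeline_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }

  attr(report, "signature") <- signature
  attr(report, "tables") <- tables
  attr(report, "de_tables") <- de_tables
  attr(report, "data") <- data
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (seed %d): %d common hyper / %d common hypo CpGs; ",
              x$seed, x$signature$n_common_hyper, x$signature$n_common_hypo))
  cat(sprintf("%d common up / %d common down genes; hypo/up overlap %d (log10 p = %.3g)\n",
              x$expression$n_common_up, x$expression$n_common_down,
              x$expression$hypo_up_overlap$n_overlap,
              x$expression$hypo_up_overlap$log10_p))
  invisible(x)
}
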