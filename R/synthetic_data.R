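# Synthetic methylation + expression datasets with a planted cross-tissue
# invasiveness signature and full ground truth. The generator emulates the
# study design of three tissue pairs (invasive vs non-invasive lines, 2-3
# replicate cultures each) profiled on a 450K-style array: beta values arise
# from group-mean M-values plus Gaussian M-scale noise through the logistic,
# a planted set of CpGs is concordantly hypo-/hypermethylated across all
# three pairs, tissue-specific DMPs form background, ~21% of probes carry an
# enhancer flag, and a configurable fraction of planted promoter-hypo genes
# is >= 2-fold upregulated in the matching expression matrices.

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. Defaults mirror the
#' three-tissue invasive/non-invasive design: 3 replicates per line with one
#' duplicate-culture line, a planted concordant signature with |delta beta|
#' 0.40, M-scale replicate noise 0.5, a 21% enhancer background with 47%
#' enhancer prevalence among planted common-hypo CpGs, and 80% of planted
#' promoter-hypo genes upregulated at least two-fold.
#'
#' @param n_probes Number of array probes.
#' @param tissues Three tissue labels.
#' @param replicates Replicates per cell line.
#' @param low_rep_tissue Index of the tissue whose non-invasive line has
#'   `low_rep_n` replicates (duplicate-culture line); `NA` disables.
#' @param low_rep_n Replicates for that line.
#' @param n_common_hypo,n_common_hyper Planted concordant CpG counts.
#' @param n_tissue_specific Planted tissue-specific DMPs per tissue.
#' @param effect_delta_beta Target |delta beta| of planted effects, in (0, 0.5].
#' @param noise_sd_m Replicate noise SD on the M (log2) scale.
#' @param tissue_sd_m SD of the per-tissue M-scale deviation around the shared
#'   probe baseline (tissue identity signal).
#' @param enhancer_fraction Global fraction of enhancer-flagged probes.
#' @param enhancer_enrichment_in_hypo Enhancer rate among planted common-hypo
#'   probes.
#' @param promoter_fraction Fraction of gene-linked probe-gene relations with a
#'   5-prime (promoter) region label.
#' @param n_genes Number of genes; each receives >= 1 probe.
#' @param intergenic_fraction Fraction of probes with no gene annotation.
#' @param second_gene_fraction Fraction of gene-linked probes annotated to a
#'   second gene (multi-mapping).
#' @param concordance Fraction of planted promoter-hypo genes made >= 2-fold
#'   upregulated in invasive samples of every tissue.
#' @param effect_lfc Length-2 range of planted expression log2 fold changes.
#' @param expr_noise_sd Log2-scale expression replicate noise SD.
#' @param expr_baseline_log2 Mean and SD of per-gene baseline log2 intensity.
#' @param n_tissue_specific_expr Tissue-specific differentially expressed genes
#'   per tissue (background).
#' @param seed Master seed; stage seeds are derived by fixed offsets.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 20000L,
                              tissues = c("breast", "liver", "prostate"),
                              replicates = 3L,
                              low_rep_tissue = 3L,
                              low_rep_n = 2L,
                              n_common_hypo = 300L,
                              n_common_hyper = 300L,
                              n_tissue_specific = 200L,
                              effect_delta_beta = 0.40,
                              noise_sd_m = 0.5,
                              tissue_sd_m = 0.8,
                              enhancer_fraction = 0.21,
                              enhancer_enrichment_in_hypo = 0.47,
                              promoter_fraction = 0.40,
                              n_genes = 4000L,
                              intergenic_fraction = 0.10,
                              second_gene_fraction = 0.02,
                              concordance = 0.8,
                              effect_lfc = c(1.5, 2.5),
                              expr_noise_sd = 0.25,
                              expr_baseline_log2 = c(7, 1.5),
                              n_tissue_specific_expr = 100L,
                              seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), tissues = as.character(tissues),
              replicates = as.integer(replicates),
              low_rep_tissue = low_rep_tissue, low_rep_n = as.integer(low_rep_n),
              n_common_hypo = as.integer(n_common_hypo),
              n_common_hyper = as.integer(n_common_hyper),
              n_tissue_specific = as.integer(n_tissue_specific),
              effect_delta_beta = effect_delta_beta,
              noise_sd_m = noise_sd_m, tissue_sd_m = tissue_sd_m,
              enhancer_fraction = enhancer_fraction,
              enhancer_enrichment_in_hypo = enhancer_enrichment_in_hypo,
              promoter_fraction = promoter_fraction,
              n_genes = as.integer(n_genes),
              intergenic_fraction = intergenic_fraction,
              second_gene_fraction = second_gene_fraction,
              concordance = concordance, effect_lfc = effect_lfc,
              expr_noise_sd = expr_noise_sd,
              expr_baseline_log2 = expr_baseline_log2,
              n_tissue_specific_expr = as.integer(n_tissue_specific_expr),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

#' Validate a simulation configuration
#' @param cfg A `simulation_config`.
#' @return The config, or an error on infeasible settings.
#' @export
validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(cfg$tissues) != 3L || anyDuplicated(cfg$tissues))
    stop("exactly three distinct tissues are required")
  if (cfg$replicates < 2L || cfg$low_rep_n < 2L)
    stop("every cell line needs >= 2 replicates")
  planted <- cfg$n_common_hypo + cfg$n_common_hyper + 3L * cfg$n_tissue_specific
  if (planted > cfg$n_probes)
    stop("planted probe classes exceed n_probes")
  fr <- c(cfg$enhancer_fraction, cfg$enhancer_enrichment_in_hypo,
          cfg$promoter_fraction, cfg$intergenic_fraction,
          cfg$second_gene_fraction, cfg$concordance)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  if (cfg$effect_delta_beta <= 0 || cfg$effect_delta_beta > 0.5)
    stop("effect_delta_beta must be in (0, 0.5]")
  if (cfg$noise_sd_m < 0 || cfg$tissue_sd_m < 0 || cfg$expr_noise_sd < 0)
    stop("noise SDs must be non-negative")
  n_enh <- round(cfg$enhancer_fraction * cfg$n_probes)
  n_hypo_enh <- round(cfg$enhancer_enrichment_in_hypo * cfg$n_common_hypo)
  if (n_hypo_enh > n_enh)
    stop("enhancer fraction infeasible: planted enhancer count exceeds total")
  if (n_enh - n_hypo_enh > cfg$n_probes - cfg$n_common_hypo)
    stop("enhancer fraction infeasible for non-planted probes")
  n_intergenic <- round(cfg$intergenic_fraction * cfg$n_probes)
  if (cfg$n_probes - n_intergenic < cfg$n_genes)
    stop("fewer gene-linked probes than genes")
  if (n_intergenic > cfg$n_probes - planted)
    stop("intergenic fraction leaves no room for planted (gene-linked) probes")
  cfg
}

# planted class per probe, fixed block layout (probe identity is arbitrary)
.probe_classes <- function(cfg) {
  cls <- rep("null", cfg$n_probes)
  i <- 0L
  cls[seq_len(cfg$n_common_hypo)] <- "common_hypo"
  i <- cfg$n_common_hypo
  cls[i + seq_len(cfg$n_common_hyper)] <- "common_hyper"
  i <- i + cfg$n_common_hyper
  for (t in cfg$tissues) {
    cls[i + seq_len(cfg$n_tissue_specific)] <- paste0("tissue_specific_", t)
    i <- i + cfg$n_tissue_specific
  }
  cls
}

.probe_ids <- function(cfg) sprintf("cg%08d", seq_len(cfg$n_probes))
.gene_ids <- function(cfg) sprintf("GENE%05d", seq_len(cfg$n_genes))

#' Generate a probe annotation table
#'
#' Probes are assigned to genes (every gene receives at least one probe;
#' planted probes are always gene-linked), promoter/body region labels at the
#' configured promoter fraction, island-relation labels, and enhancer flags
#' such that the global enhancer fraction matches `enhancer_fraction` to
#' within one probe while planted common-hypo probes are flagged at rate
#' `enhancer_enrichment_in_hypo`. Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return Annotation data.frame as from [read_probe_annotation()], with an
#'   extra attribute `classes` giving the planted class per probe.
#' @export
generate_annotation <- function(cfg) {
  validate_simulation_config(cfg)
  .with_seed(cfg$seed + 101L, {
    n <- cfg$n_probes
    ids <- .probe_ids(cfg)
    cls <- .probe_classes(cfg)
    planted <- cls != "null"

    # intergenic probes drawn from the null block only
    n_intergenic <- round(cfg$intergenic_fraction * n)
    null_idx <- which(!planted)
    intergenic <- sort(sample(null_idx, n_intergenic))
    genic <- setdiff(seq_len(n), intergenic)

    # every gene gets one anchor probe; remaining genic probes sample genes
    genes <- .gene_ids(cfg)
    gene_of <- integer(n)
    anchors <- genic[seq_len(cfg$n_genes)]
    gene_of[anchors] <- seq_len(cfg$n_genes)
    rest <- setdiff(genic, anchors)
    gene_of[rest] <- sample.int(cfg$n_genes, length(rest), replace = TRUE)

    region_pool_promoter <- PROMOTER_REGIONS
    region_pool_body <- c("Body", "3UTR")
    draw_region <- function(m) {
      is_prom <- stats::runif(m) < cfg$promoter_fraction
      out <- character(m)
      out[is_prom] <- sample(region_pool_promoter, sum(is_prom), replace = TRUE)
      out[!is_prom] <- sample(region_pool_body, sum(!is_prom), replace = TRUE)
      out
    }

    gene_symbols <- vector("list", n)
    gene_region <- vector("list", n)
    gene_symbols[intergenic] <- list(character(0))
    gene_region[intergenic] <- list(character(0))
    first_region <- draw_region(length(genic))
    second <- genic[stats::runif(length(genic)) < cfg$second_gene_fraction]
    second_gene <- sample.int(cfg$n_genes, length(second), replace = TRUE)
    second_region <- draw_region(length(second))
    names(second_gene) <- names(second_region) <- as.character(second)
    for (j in seq_along(genic)) {
      i <- genic[j]
      gs <- genes[gene_of[i]]
      gr <- first_region[j]
      key <- as.character(i)
      if (!is.na(second_gene[key])) {
        gs <- c(gs, genes[second_gene[key]])
        gr <- c(gr, second_region[key])
      }
      gene_symbols[[i]] <- gs
      gene_region[[i]] <- gr
    }

    # enhancer flags: exact global count, planted-hypo rate as configured
    n_enh <- round(cfg$enhancer_fraction * n)
    hypo_idx <- which(cls == "common_hypo")
    n_hypo_enh <- round(cfg$enhancer_enrichment_in_hypo * length(hypo_idx))
    enhancer <- logical(n)
    enhancer[sample(hypo_idx, n_hypo_enh)] <- TRUE
    other <- setdiff(seq_len(n), hypo_idx)
    enhancer[sample(other, n_enh - n_hypo_enh)] <- TRUE

    ann <- data.frame(probe_id = ids,
                      chromosome = paste0("chr", sample(1:22, n, replace = TRUE)),
                      position = sample.int(2e8L, n, replace = TRUE),
                      island_relation = sample(ISLAND_RELATIONS, n, replace = TRUE,
                                               prob = c(0.31, 0.23, 0.10, 0.36)),
                      enhancer = enhancer,
                      stringsAsFactors = FALSE)
    ann$gene_symbols <- gene_symbols
    ann$gene_region <- gene_region
    attr(ann, "classes") <- cls
    ann
  })
}

# sample sheet implied by the config
.make_samples <- function(cfg) {
  rows <- list()
  for (ti in seq_along(cfg$tissues)) {
    t <- cfg$tissues[ti]
    for (phen in c("invasive", "non_invasive")) {
      nrep <- cfg$replicates
      if (phen == "non_invasive" && !is.na(cfg$low_rep_tissue) &&
          ti == cfg$low_rep_tissue)
        nrep <- cfg$low_rep_n
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = sprintf("%s_%s_%d", t, sub("_", "", phen), seq_len(nrep)),
                   tissue = t, phenotype = phen, replicate = seq_len(nrep),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# baseline beta for the unaffected group: planted probes draw from the
# extreme component that leaves room for the effect inside (0,1)
.draw_baseline <- function(cls, delta) {
  n <- length(cls)
  b <- numeric(n)
  comp <- sample(c("low", "high", "unif"), n, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  b[comp == "low"] <- stats::rbeta(sum(comp == "low"), 5, 45)
  b[comp == "high"] <- stats::rbeta(sum(comp == "high"), 45, 5)
  b[comp == "unif"] <- stats::runif(sum(comp == "unif"), 0.05, 0.95)
  pmin(pmax(b, 0.02), 0.98)
}

#' Generate a methylation dataset with planted ground truth
#'
#' Per probe, a shared baseline M-value plus a per-tissue Gaussian deviation
#' defines the tissue baseline; planted probes additionally separate their
#' invasive and non-invasive group-mean betas by the configured signed
#' |delta beta| (concordant across all tissues for common classes, one tissue
#' for tissue-specific classes). Replicate values are
#' `logistic(M_groupmean + Normal(0, noise_sd_m))`, hence strictly inside
#' (0, 1). Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `beta` (probes x samples matrix), `samples` (sample
#'   sheet), and `truth` (data.frame: probe_id, class, planted signed delta
#'   beta per tissue).
#' @export
generate_methylation_dataset <- function(cfg) {
  validate_simulation_config(cfg)
  .with_seed(cfg$seed + 202L, {
    n <- cfg$n_probes
    ids <- .probe_ids(cfg)
    cls <- .probe_classes(cfg)
    samples <- .make_samples(cfg)
    delta <- cfg$effect_delta_beta

    # signed planted effect per probe per tissue (invasive minus non-invasive)
    sign_of <- numeric(n)                       # direction for planted probes
    sign_of[cls == "common_hypo"] <- -1
    sign_of[cls == "common_hyper"] <- 1
    ts <- grepl("^tissue_specific_", cls)
    sign_of[ts] <- sample(c(-1, 1), sum(ts), replace = TRUE)
    effect <- matrix(0, n, length(cfg$tissues),
                     dimnames = list(ids, cfg$tissues))
    for (t in cfg$tissues) {
      act <- cls %in% c("common_hypo", "common_hyper") |
        cls == paste0("tissue_specific_", t)
      effect[act, t] <- sign_of[act] * delta
    }

    # shared baseline: unaffected-group beta; planted probes draw uniformly
    # over the range that keeps baseline and baseline +/- delta inside (0,1),
    # so both phenotypes retain probe-to-probe structure on signature CpGs
    b0 <- .draw_baseline(cls, delta)
    planted_neg <- sign_of < 0                   # invasive lower: baseline high
    planted_pos <- sign_of > 0                   # invasive higher: baseline low
    b0[planted_neg] <- stats::runif(sum(planted_neg), delta + 0.05, 0.95)
    b0[planted_pos] <- stats::runif(sum(planted_pos), 0.05, 0.95 - delta)
    m0 <- beta_to_m(b0)

    beta <- matrix(NA_real_, n, nrow(samples),
                   dimnames = list(ids, samples$sample_id))
    for (ti in seq_along(cfg$tissues)) {
      t <- cfg$tissues[ti]
      bt <- m_to_beta(m0 + stats::rnorm(n, 0, cfg$tissue_sd_m))
      # keep the planted effect inside (0,1) after the tissue deviation
      neg <- effect[, t] < 0
      pos <- effect[, t] > 0
      bt[neg] <- pmin(pmax(bt[neg], delta + 0.02), 0.98)
      bt[pos] <- pmin(pmax(bt[pos], 0.02), 0.98 - delta)
      mean_ni <- bt
      mean_inv <- bt + effect[, t]
      for (phen in c("invasive", "non_invasive")) {
        cols <- samples$sample_id[samples$tissue == t & samples$phenotype == phen]
        gm <- beta_to_m(if (phen == "invasive") mean_inv else mean_ni)
        for (s in cols)
          beta[, s] <- m_to_beta(gm + stats::rnorm(n, 0, cfg$noise_sd_m))
      }
    }

    truth <- data.frame(probe_id = ids, class = cls, stringsAsFactors = FALSE)
    for (t in cfg$tissues) truth[[paste0("delta_", t)]] <- effect[, t]
    list(beta = beta, samples = samples, truth = truth)
  })
}

#' Generate per-tissue expression matrices with planted concordance
#'
#' Gene baseline log2 intensities are Gaussian (log-normal intensities); a
#' fraction `concordance` of the genes whose promoter probes are planted
#' common-hypo receive a log2 fold change drawn from `effect_lfc` (>= 1, i.e.
#' at least two-fold) in the invasive samples of every tissue; a background of
#' tissue-specific expression changes is added among the remaining genes.
#' Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @param annotation Annotation from [generate_annotation()].
#' @param samples Sample sheet from [generate_methylation_dataset()].
#' @param truth Probe truth from [generate_methylation_dataset()].
#' @return List with `expression` (named list of genes x samples matrices,
#'   one per tissue) and `truth_genes` (data.frame: gene, concordant flag,
#'   planted log2 fold change per tissue).
#' @export
generate_expression_dataset <- function(cfg, annotation, samples, truth) {
  validate_simulation_config(cfg)
  .with_seed(cfg$seed + 303L, {
    genes <- .gene_ids(cfg)
    hypo_probes <- truth$probe_id[truth$class == "common_hypo"]
    prom <- filter_promoter_probes(hypo_probes, annotation)
    planted_genes <- probes_to_genes(prom, annotation)$genes
    n_conc <- round(cfg$concordance * length(planted_genes))
    concordant <- sort(sample(planted_genes, n_conc))

    lfc <- matrix(0, length(genes), length(cfg$tissues),
                  dimnames = list(genes, cfg$tissues))
    g_lfc <- stats::runif(length(concordant), cfg$effect_lfc[1], cfg$effect_lfc[2])
    lfc[concordant, ] <- g_lfc                  # same planted effect per tissue
    pool <- setdiff(genes, planted_genes)
    for (t in cfg$tissues) {
      ts_genes <- sample(pool, min(cfg$n_tissue_specific_expr, length(pool)))
      lfc[ts_genes, t] <- sample(c(-1, 1), length(ts_genes), replace = TRUE) *
        stats::runif(length(ts_genes), cfg$effect_lfc[1], cfg$effect_lfc[2])
    }

    base <- stats::rnorm(length(genes), cfg$expr_baseline_log2[1],
                         cfg$expr_baseline_log2[2])
    expression <- list()
    for (t in cfg$tissues) {
      cols <- samples[samples$tissue == t, , drop = FALSE]
      mat <- matrix(NA_real_, length(genes), nrow(cols),
                    dimnames = list(genes, cols$sample_id))
      for (j in seq_len(nrow(cols))) {
        eff <- if (cols$phenotype[j] == "invasive") lfc[, t] else 0
        mat[, j] <- 2^(base + eff + stats::rnorm(length(genes), 0, cfg$expr_noise_sd))
      }
      expression[[t]] <- mat
    }

    truth_genes <- data.frame(gene = genes,
                              planted_promoter_hypo = genes %in% planted_genes,
                              concordant = genes %in% concordant,
                              stringsAsFactors = FALSE)
    for (t in cfg$tissues) truth_genes[[paste0("lfc_", t)]] <- lfc[, t]
    list(expression = expression, truth_genes = truth_genes)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_annotation()],
#' [generate_methylation_dataset()] and [generate_expression_dataset()] in
#' order with their stage seeds derived from the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return List: `annotation`, `beta`, `samples`, `truth`, `expression`,
#'   `truth_genes`, `config`.
#' @export
generate_dataset <- function(cfg) {
  ann <- generate_annotation(cfg)
  meth <- generate_methylation_dataset(cfg)
  expr <- generate_expression_dataset(cfg, ann, meth$samples, meth$truth)
  list(annotation = ann, beta = meth$beta, samples = meth$samples,
       truth = meth$truth, expression = expr$expression,
       truth_genes = expr$truth_genes, config = cfg)
}
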