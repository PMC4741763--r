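# Cross-pair concordant intersection, CpG-to-gene collapapse, promoter
# filtering, genomic-context enrichment and multi-set overlap significance.

#' Intersect per-pair DMP calls into a concordant signature
#'
#' The common hypermethylated set is the intersection of the three per-pair
#' hyper sets (and likewise for hypo), so direction concordance across all
#' pairs is enforced by construction. The signature universe is the
#' intersection of the per-pair tested-probe sets.
#'
#' @param pair_calls List of >= 3 elements, each a list with character vectors
#'   `hyper` and `hypo` (disjoint within a pair), as from [call_dmps()].
#' @param universes List (same length) of tested-probe id vectors per pair.
#' @return Object of class `signature_set`: `common_hyper`, `common_hypo`,
#'   `universe`, `pairs` (names of the inputs).
#' @export
intersect_concordant <- function(pair_calls, universes) {
  if (length(pair_calls) < 3L)
    stop("at least three pairs are required")
  if (length(universes) != length(pair_calls))
    stop("one universe per pair is required")
  for (i in seq_along(pair_calls)) {
    pc <- pair_calls[[i]]
    if (!all(c("hyper", "hypo") %in% names(pc)))
      stop("each pair needs hyper and hypo sets")
    if (length(intersect(pc$hyper, pc$hypo)))
      stop("hyper and hypo sets overlap within pair ", i)
  }
  common_hyper <- Reduce(intersect, lapply(pair_calls, `[[`, "hyper"))
  common_hypo <- Reduce(intersect, lapply(pair_calls, `[[`, "hypo"))
  universe <- Reduce(intersect, universes)
  structure(list(common_hyper = common_hyper,
                 common_hypo = common_hypo,
                 universe = universe,
                 pairs = names(pair_calls)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d common hyper, %d common hypo CpGs (universe %d)\n",
              length(x$common_hyper), length(x$common_hypo), length(x$universe)))
  invisible(x)
}

#' Collapse a probe set to gene symbols
#'
#' Union of annotated gene symbols over the probes, deduplicated; probes with
#' no gene annotation contribute nothing and are counted as intergenic.
#'
#' @param probes Character vector of probe ids (all present in `annotation`).
#' @param annotation Probe annotation.
#' @return List: `genes` (sorted unique symbols), `per_gene_counts` (named
#'   integer: probes per gene), `intergenic` (count of unannotated probes).
#' @export
probes_to_genes <- function(probes, annotation) {
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    stop("unknown probe(s): ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  gene_lists <- annotation$gene_symbols[idx]
  per_probe <- lapply(gene_lists, unique)
  all_genes <- unlist(per_probe, use.names = FALSE)
  counts <- table(all_genes)
  list(genes = sort(unique(all_genes)),
       per_gene_counts = stats::setNames(as.integer(counts), names(counts)),
       intergenic = sum(lengths(gene_lists) == 0L))
}

#' Keep probes annotated 5-prime to a gene
#'
#' A probe passes if any of its gene relations carries a region label in
#' `regions` (default: TSS1500, TSS200, 5'UTR, first exon).
#'
#' @param probes Character vector of probe ids.
#' @param annotation Probe annotation.
#' @param regions Non-empty set of region labels.
#' @return The promoter subset of `probes` (original order).
#' @export
filter_promoter_probes <- function(probes, annotation,
                                   regions = PROMOTER_REGIONS) {
  if (!length(regions)) stop("regions must be non-empty")
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    stop("unknown probe(s): ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  keep <- vapply(annotation$gene_region[idx],
                 function(r) any(r %in% regions), logical(1))
  probes[keep]
}

#' Category enrichment of a probe subset against a universe
#'
#' Hypergeometric upper-tail test of how many subset probes fall in an
#' annotation category (e.g. enhancer probes), against the category's
#' prevalence in the universe. The log10 p-value is always populated, so
#' array-scale enrichments that underflow double precision remain exact.
#'
#' @param subset Character vector of probe ids, a subset of `universe`.
#' @param category Either the name of a logical annotation column (e.g.
#'   `"enhancer"`), a logical vector aligned with `annotation` rows, or a
#'   character vector of category member probe ids.
#' @param universe Character vector of probe ids.
#' @param annotation Probe annotation (needed unless `category` is a probe id
#'   vector).
#' @return Object of class `enrichment_result`: subset/category/universe
#'   sizes, hits, fraction, fold enrichment and a [tail_test()].
#' @export
category_enrichment <- function(subset, category, universe, annotation = NULL) {
  if (length(setdiff(subset, universe)))
    stop("subset must be contained in the universe")
  members <- if (is.character(category) && length(category) == 1L &&
                 !is.null(annotation) && category %in% colnames(annotation)) {
    annotation$probe_id[as.logical(annotation[[category]])]
  } else if (is.logical(category)) {
    if (is.null(annotation) || length(category) != nrow(annotation))
      stop("logical category must align with annotation rows")
    annotation$probe_id[category]
  } else {
    as.character(category)
  }
  N <- length(universe)
  K <- length(intersect(members, universe))
  n <- length(subset)
  k <- length(intersect(subset, members))
  test <- hypergeometric_tail(N, K, n, k)
  fold <- if (n == 0L || K == 0L) NA_real_ else (k / n) / (K / N)
  structure(list(subset_size = n, hits = k, category_size = K,
                 universe_size = N,
                 fraction = if (n > 0) k / n else NA_real_,
                 background_fraction = if (N > 0) K / N else NA_real_,
                 fold_enrichment = fold, test = test),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d/%d hits (%.1f%%) vs %d/%d background (%.1f%%), fold %.3g, log10 p = %.4g\n",
    x$hits, x$subset_size, 100 * x$fraction, x$category_size, x$universe_size,
    100 * x$background_fraction, x$fold_enrichment, x$test$log10_p))
  invisible(x)
}

#' Multi-set overlap significance by permutation
#'
#' Observed k-way overlap of the sets, the expectation under independence
#' (`|U| * prod(|set_i| / |U|)`), a seeded permutation p-value with add-one
#' correction (random same-size draws from the universe), and pairwise exact
#' hypergeometric upper-tail p-values.
#'
#' @param sets List of >= 2 character vectors, all subsets of `universe`.
#' @param universe Non-empty character vector.
#' @param n_permutations Number of random draws (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return List: `observed`, `expected`, `permutation_p`, `n_permutations`,
#'   `pairwise` (matrix of log10 p), `sizes`.
#' @export
multiway_overlap_significance <- function(sets, universe, n_permutations = 1000L,
                                          seed = 1L) {
  if (!length(universe)) stop("universe must be non-empty")
  if (length(sets) < 2L) stop("need at least two sets")
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  for (s in sets)
    if (length(setdiff(s, universe)))
      stop("all sets must be subsets of the universe")
  sizes <- lengths(sets)
  observed <- length(Reduce(intersect, sets))
  expected <- length(universe) * prod(sizes / length(universe))

  hits <- .with_seed(seed, {
    n_hit <- 0L
    for (b in seq_len(n_permutations)) {
      draws <- lapply(sizes, function(sz) sample(universe, sz))
      if (length(Reduce(intersect, draws)) >= observed) n_hit <- n_hit + 1L
    }
    n_hit
  })
  permutation_p <- (hits + 1) / (n_permutations + 1)

  k <- length(sets)
  pairwise <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    ov <- length(intersect(sets[[i]], sets[[j]]))
    pairwise[i, j] <- pairwise[j, i] <-
      hypergeometric_tail(length(universe), sizes[i], sizes[j], ov)$log10_p
  }
  list(observed = observed, expected = expected,
       permutation_p = permutation_p, n_permutations = n_permutations,
       pairwise_log10_p = pairwise, sizes = sizes)
}
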