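# Expression side of the pipeline: quantile normalization, per-pair two-fold /
# DiffScore differential expression, cross-pair intersection, and
# hypergeometric gene-list overlap (methylation-expression integration).

#' Quantile normalization
#'
#' Classic rank-average quantile normalization: each column is sorted, values
#' are averaged across columns at each rank, and the averages are assigned
#' back by rank. Tied entries receive the mean of the averages over their
#' rank range, so all column distributions become identical as multisets up
#' to tie-averaging.
#'
#' @param expr Features x samples matrix without missing values.
#' @return Normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(expr) {
  if (anyNA(expr)) stop("missing values are not supported")
  if (ncol(expr) < 2L) {
    warning("single-sample matrix returned unchanged")
    return(expr)
  }
  mu <- rowMeans(apply(expr, 2L, sort))
  out <- expr
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    if (all(lo == hi)) {
      out[, j] <- mu[lo]
    } else {
      out[, j] <- vapply(seq_along(x),
                         function(i) mean(mu[lo[i]:hi[i]]), numeric(1))
    }
  }
  out
}

#' Differential expression for one tissue pair
#'
#' Two-sided t on log2 intensities (limma empirical-Bayes moderated by
#' default, per-probe Welch as an option), DiffScore from the sign of the log
#' fold change and the p-value, and up/down calls combining a linear fold
#' change threshold (invasive / non-invasive orientation) with a DiffScore
#' threshold: up requires fold >= `fold_threshold` and DiffScore >
#' `score_threshold`; down is symmetric.
#'
#' @param expr Features x samples intensity matrix (quantile-normalize first
#'   for cross-sample comparability).
#' @param samples Sample sheet covering the matrix columns.
#' @param tissue Tissue label selecting the pair.
#' @param fold_threshold Linear fold-change threshold (default 2).
#' @param score_threshold DiffScore threshold (default 13, i.e. p ~ 0.05).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return A `data.frame` of class `de_table`: `feature_id`,
#'   `mean_invasive`, `mean_noninvasive`, `fold_change`, `log2_fold`,
#'   `p_value`, `diff_score`, `call`.
#' @export
call_de_pair <- function(expr, samples, tissue, fold_threshold = 2,
                         score_threshold = 13,
                         method = c("moderated", "welch")) {
  method <- match.arg(method)
  if (!tissue %in% samples$tissue)
    stop("unknown tissue: ", tissue)
  sheet <- samples[samples$tissue == tissue, , drop = FALSE]
  inv <- intersect(sheet$sample_id[sheet$phenotype == "invasive"], colnames(expr))
  ninv <- intersect(sheet$sample_id[sheet$phenotype == "non_invasive"], colnames(expr))
  if (length(inv) < 2L || length(ninv) < 2L)
    stop("tissue ", tissue, " needs >= 2 expression samples per phenotype")

  eps <- .Machine$double.eps
  L <- log2(pmax(expr[, c(inv, ninv), drop = FALSE], eps))
  A <- L[, seq_along(inv), drop = FALSE]
  B <- L[, length(inv) + seq_along(ninv), drop = FALSE]
  if (method == "moderated") {
    design <- cbind(Intercept = 1,
                    invasive = rep(c(1, 0), c(ncol(A), ncol(B))))
    fit <- limma::eBayes(limma::lmFit(L, design))
    p <- fit$p.value[, "invasive"]
  } else {
    p <- .row_welch(A, B)$p
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  mean_inv <- rowMeans(expr[, inv, drop = FALSE])
  mean_ninv <- rowMeans(expr[, ninv, drop = FALSE])
  fold <- mean_inv / pmax(mean_ninv, eps)
  log2_fold <- rowMeans(A) - rowMeans(B)
  dscore <- diff_score(sign(log2_fold), p)

  call <- rep("none", nrow(expr))
  call[fold >= fold_threshold & dscore > score_threshold] <- "up"
  call[fold <= 1 / fold_threshold & dscore < -score_threshold] <- "down"

  tab <- data.frame(feature_id = rownames(expr),
                    mean_invasive = mean_inv,
                    mean_noninvasive = mean_ninv,
                    fold_change = fold,
                    log2_fold = log2_fold,
                    p_value = p,
                    diff_score = dscore,
                    call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "pair") <- tissue
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' Intersect per-pair differential expression calls
#'
#' Features called up (respectively down) in every pair.
#'
#' @param tables List of `de_table` objects (one per tissue pair).
#' @return List with character vectors `common_up` and `common_down`.
#' @export
intersect_de_common <- function(tables) {
  ups <- lapply(tables, function(t) t$feature_id[t$call == "up"])
  downs <- lapply(tables, function(t) t$feature_id[t$call == "down"])
  list(common_up = Reduce(intersect, ups),
       common_down = Reduce(intersect, downs))
}

#' Hypergeometric overlap of two gene lists
#'
#' Upper-tail significance of the observed overlap of two gene sets drawn
#' from a common universe, e.g. promoter-hypomethylated genes against
#' upregulated genes, or a signature against an external cohort list. The
#' test is symmetric in the two lists.
#'
#' @param list_a,list_b Character vectors of gene identifiers.
#' @param universe_size Size of the common universe (>= both list sizes).
#' @return List: `overlap` (character vector), `n_overlap`, and `test`
#'   (a [tail_test()]).
#' @export
gene_list_overlap <- function(list_a, list_b, universe_size) {
  a <- unique(list_a)
  b <- unique(list_b)
  if (universe_size < length(a) || universe_size < length(b))
    stop("universe_size must be at least as large as each list")
  ov <- intersect(a, b)
  list(overlap = sort(ov), n_overlap = length(ov),
       n_a = length(a), n_b = length(b), universe_size = universe_size,
       test = hypergeometric_tail(universe_size, length(a), length(b),
                                  length(ov)))
}
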