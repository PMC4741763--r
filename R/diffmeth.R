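# Per-tissue-pair differential methylation: invasive vs non-invasive testing
# on M-values, delta beta on the beta scale, BH q-values, DiffScores and DMP
# calling. The default test is the limma empirical-Bayes moderated t, the
# standard choice for 450K-style designs with 2-3 replicates per line, where
# a per-probe test has too few degrees of freedom to resolve p < 0.001;
# a plain per-probe Welch t is available as method = "welch".

# vectorized NA-aware Welch t over matrix rows
.row_welch <- function(A, B, var_floor = 1e-12) {
  na_count <- rowSums(!is.na(A))
  nb_count <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE)
  mb <- rowMeans(B, na.rm = TRUE)
  va <- rowSums((A - ma)^2, na.rm = TRUE) / pmax(na_count - 1, 1) + var_floor
  vb <- rowSums((B - mb)^2, na.rm = TRUE) / pmax(nb_count - 1, 1) + var_floor
  se2 <- va / na_count + vb / nb_count
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_count)^2 / pmax(na_count - 1, 1) +
                 (vb / nb_count)^2 / pmax(nb_count - 1, 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Differential methylation for one tissue pair
#'
#' Tests every probe of the given tissue's invasive vs non-invasive groups.
#' Delta beta is the difference of group-mean betas (invasive minus
#' non-invasive, so hypomethylation in the invasive line is negative); the
#' p-value comes from a test on M-values; q-values are Benjamini-Hochberg
#' across all tested probes of the pair; DiffScores follow the
#' 10 * sign(delta) * (-log10 p) convention. Probes with fewer than two
#' non-missing values in either group are excluded and counted.
#'
#' @param beta Probes x samples beta matrix.
#' @param samples Sample sheet covering the matrix columns.
#' @param tissue Tissue label selecting the pair.
#' @param epsilon Clipping bound for the M transform.
#' @param method `"moderated"` (limma empirical-Bayes, default) or `"welch"`
#'   (per-probe Welch t).
#' @param delta_threshold,p_threshold,mode Calling parameters used to fill the
#'   `direction` column; see [call_dmps()].
#' @return A `data.frame` of class `dmp_table` with columns `probe_id`,
#'   `mean_beta_invasive`, `mean_beta_noninvasive`, `delta_beta`, `p_value`,
#'   `q_value`, `diff_score`, `direction`, `n_invasive`, `n_noninvasive`;
#'   attributes `pair`, `n_excluded`, `excluded_probes`, `method`.
#' @export
test_pair <- function(beta, samples, tissue, epsilon = 1e-6,
                      method = c("moderated", "welch"),
                      delta_threshold = 0.25, p_threshold = 0.001,
                      mode = c("raw_p", "fdr")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (!tissue %in% samples$tissue)
    stop("unknown tissue: ", tissue)
  sheet <- samples[samples$tissue == tissue, , drop = FALSE]
  inv <- sheet$sample_id[sheet$phenotype == "invasive"]
  ninv <- sheet$sample_id[sheet$phenotype == "non_invasive"]
  if (length(inv) < 2L || length(ninv) < 2L)
    stop("tissue ", tissue, " needs >= 2 samples per phenotype")
  missing_cols <- setdiff(c(inv, ninv), colnames(beta))
  if (length(missing_cols))
    stop("samples absent from beta matrix: ", paste(missing_cols, collapse = ", "))

  A <- beta[, inv, drop = FALSE]
  B <- beta[, ninv, drop = FALSE]
  n_inv <- rowSums(!is.na(A))
  n_ninv <- rowSums(!is.na(B))
  usable <- n_inv >= 2L & n_ninv >= 2L
  excluded <- rownames(beta)[!usable]
  A <- A[usable, , drop = FALSE]
  B <- B[usable, , drop = FALSE]

  mean_inv <- rowMeans(A, na.rm = TRUE)
  mean_ninv <- rowMeans(B, na.rm = TRUE)
  delta <- mean_inv - mean_ninv

  M <- beta_to_m(cbind(A, B), epsilon = epsilon)
  if (method == "moderated") {
    design <- cbind(Intercept = 1,
                    invasive = rep(c(1, 0), c(ncol(A), ncol(B))))
    fit <- limma::eBayes(limma::lmFit(M, design))
    p <- fit$p.value[, "invasive"]
    stat <- fit$t[, "invasive"]
  } else {
    w <- .row_welch(M[, seq_len(ncol(A)), drop = FALSE],
                    M[, ncol(A) + seq_len(ncol(B)), drop = FALSE])
    p <- w$p
    stat <- w$t
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  q <- bh_fdr(p)
  dscore <- diff_score(delta, p)

  crit <- if (mode == "raw_p") p else q
  direction <- rep("none", length(delta))
  direction[delta > delta_threshold & crit < p_threshold] <- "hyper"
  direction[delta < -delta_threshold & crit < p_threshold] <- "hypo"

  tab <- data.frame(probe_id = rownames(A),
                    mean_beta_invasive = mean_inv,
                    mean_beta_noninvasive = mean_ninv,
                    delta_beta = delta,
                    statistic = stat,
                    p_value = p,
                    q_value = q,
                    diff_score = dscore,
                    direction = direction,
                    n_invasive = n_inv[usable],
                    n_noninvasive = n_ninv[usable],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "pair") <- tissue
  attr(tab, "n_excluded") <- length(excluded)
  attr(tab, "excluded_probes") <- excluded
  attr(tab, "method") <- method
  attr(tab, "mode") <- mode
  class(tab) <- c("dmp_table", "data.frame")
  tab
}

#' Call differentially methylated positions from a pair table
#'
#' Strict thresholds matching the "> 25% difference, p < 0.001" convention:
#' hyper requires delta beta strictly above `delta_threshold` and p (or q in
#' FDR mode) strictly below `p_threshold`; hypo is symmetric.
#'
#' @param table A `dmp_table` from [test_pair()].
#' @param delta_threshold Absolute delta-beta threshold in (0, 1).
#' @param p_threshold Significance threshold in (0, 1); when `mode = "fdr"`
#'   it is applied to the BH q-value (typically 0.05).
#' @param mode `"raw_p"` (default) or `"fdr"`.
#' @return List with character vectors `hyper` and `hypo` of probe ids.
#' @export
call_dmps <- function(table, delta_threshold = 0.25, p_threshold = 0.001,
                      mode = c("raw_p", "fdr")) {
  mode <- match.arg(mode)
  if (delta_threshold <= 0 || delta_threshold >= 1 ||
      p_threshold <= 0 || p_threshold >= 1)
    stop("thresholds must be in (0, 1)")
  crit <- if (mode == "raw_p") table$p_value else table$q_value
  list(hyper = table$probe_id[table$delta_beta > delta_threshold & crit < p_threshold],
       hypo = table$probe_id[table$delta_beta < -delta_threshold & crit < p_threshold])
}

#' Write a DMP table as TSV
#'
#' @param table A `dmp_table`.
#' @param path Output path.
#' @export
write_dmp_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
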