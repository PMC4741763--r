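# Readers, writers and scale transforms for the tabular formats the pipeline
# consumes: beta-value matrices, probe annotation, sample sheets, expression
# matrices. All files are tab-delimited UTF-8 with a header row.

NA_TOKENS <- c("", "na", "nan", "null")

PROMOTER_REGIONS <- c("TSS1500", "TSS200", "5UTR", "1stExon")
GENE_REGIONS <- c(PROMOTER_REGIONS, "Body", "3UTR")
ISLAND_RELATIONS <- c("island", "shore", "shelf", "open_sea")

.read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, na.strings = NULL,
                    quote = "", comment.char = "")
}

.parse_numeric <- function(x) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  miss <- tolower(x) %in% NA_TOKENS
  val <- suppressWarnings(as.numeric(x[!miss]))
  if (anyNA(val)) {
    bad <- x[!miss][is.na(val)]
    stop("non-numeric value(s) in matrix: ", paste(utils::head(bad, 3), collapse = ", "))
  }
  out[!miss] <- val
  out
}

.check_unique <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate ", what, ": ", paste(utils::head(dup, 5), collapse = ", "))
  }
  invisible(ids)
}

.read_matrix_tsv <- function(path, what) {
  raw <- .read_tsv(path)
  if (ncol(raw) < 2L || nrow(raw) == 0L)
    stop("no ", what, "s found in ", path)
  ids <- raw[[1L]]
  .check_unique(ids, paste0(what, " id"))
  .check_unique(colnames(raw)[-1L], "sample id")
  vals <- vapply(raw[-1L], .parse_numeric, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, colnames(raw)[-1L]))
  vals
}

#' Read a beta-value matrix
#'
#' Reads a probes-by-samples TSV of methylation fractions (first column probe
#' id, remaining columns one per sample). Blank, `NA`, `NaN` and `null` cells
#' (case-insensitive) become missing values.
#'
#' @param path Path to a tab-delimited file.
#' @param strict If `TRUE`, any value outside \[0,1\] is an error naming the
#'   offending probe and sample; if `FALSE` such values are clipped into
#'   \[0,1\] with a warning and the count recorded in attribute `n_clipped`.
#' @return Numeric matrix with probe ids as rownames and sample ids as
#'   colnames; values in \[0,1\] or `NA`.
#' @export
read_beta_matrix <- function(path, strict = FALSE) {
  vals <- .read_matrix_tsv(path, "probe")
  out_of_range <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)
    offenders <- paste0(rownames(vals)[idx[, 1L]], "/", colnames(vals)[idx[, 2L]])
    if (strict) {
      stop("beta value(s) outside [0,1] at probe/sample: ",
           paste(utils::head(offenders, 5), collapse = ", "))
    }
    warning(sum(out_of_range), " beta value(s) outside [0,1] clipped")
    vals[vals < 0 & !is.na(vals)] <- 0
    vals[vals > 1 & !is.na(vals)] <- 1
  }
  attr(vals, "n_clipped") <- sum(out_of_range)
  vals
}

#' Write a numeric matrix as TSV
#'
#' Inverse of [read_beta_matrix()] / [read_expression_matrix()]: first column
#' holds the row ids under `id_col`, remaining columns one per sample.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Header for the id column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "probe_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Manifest-style annotation with columns `probe_id`, `chromosome`,
#' `position` (1-based), `gene_symbols` and `gene_region` (each
#' semicolon-joined and aligned index-wise), `island_relation`
#' (island/shore/shelf/open_sea) and `enhancer` (TRUE/FALSE; empty means
#' FALSE).
#'
#' @param path Path to a tab-delimited file.
#' @return A data.frame with list columns `gene_symbols` and `gene_region`,
#'   integer `position`, logical `enhancer`, one row per probe.
#' @export
read_probe_annotation <- function(path) {
  raw <- .read_tsv(path)
  need <- c("probe_id", "chromosome", "position", "gene_symbols",
            "gene_region", "island_relation", "enhancer")
  missing_cols <- setdiff(need, colnames(raw))
  if (length(missing_cols))
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  .check_unique(raw$probe_id, "probe id")
  pos <- suppressWarnings(as.integer(raw$position))
  if (anyNA(pos) || any(pos < 1L))
    stop("position must be an integer >= 1")
  split_field <- function(x) {
    x <- trimws(x)
    out <- strsplit(x, ";", fixed = TRUE)
    out[x == ""] <- list(character(0))
    out
  }
  genes <- split_field(raw$gene_symbols)
  regions <- split_field(raw$gene_region)
  bad <- which(lengths(genes) != lengths(regions))
  if (length(bad))
    stop("gene_symbols and gene_region have different lengths at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  enh <- trimws(raw$enhancer)
  enhancer <- toupper(enh) %in% c("TRUE", "T", "1")
  ann <- data.frame(probe_id = raw$probe_id,
                    chromosome = raw$chromosome,
                    position = pos,
                    island_relation = raw$island_relation,
                    enhancer = enhancer,
                    stringsAsFactors = FALSE)
  ann$gene_symbols <- genes
  ann$gene_region <- regions
  ann
}

#' Write a probe annotation table
#'
#' @param ann Annotation data.frame as returned by [read_probe_annotation()].
#' @param path Output path.
#' @export
write_probe_annotation <- function(ann, path) {
  df <- data.frame(probe_id = ann$probe_id,
                   chromosome = ann$chromosome,
                   position = ann$position,
                   gene_symbols = vapply(ann$gene_symbols, paste, "", collapse = ";"),
                   gene_region = vapply(ann$gene_region, paste, "", collapse = ";"),
                   island_relation = ann$island_relation,
                   enhancer = ifelse(ann$enhancer, "TRUE", "FALSE"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' Features-by-samples TSV of non-negative intensities; first column feature
#' id (gene symbol or platform probe id).
#'
#' @param path Path to a tab-delimited file.
#' @return Numeric matrix, features in rows.
#' @export
read_expression_matrix <- function(path) {
  vals <- .read_matrix_tsv(path, "feature")
  if (any(vals < 0, na.rm = TRUE)) {
    idx <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
    stop("negative intensity at feature/sample: ",
         paste(utils::head(paste0(rownames(vals)[idx[, 1L]], "/",
                                  colnames(vals)[idx[, 2L]]), 5), collapse = ", "))
  }
  vals
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `tissue`, `phenotype` (`invasive`/`non_invasive`),
#' `replicate`. Every tissue must carry at least two samples per phenotype.
#'
#' @param path Path to a tab-delimited file.
#' @return data.frame of samples.
#' @export
read_sample_sheet <- function(path) {
  raw <- .read_tsv(path)
  need <- c("sample_id", "tissue", "phenotype", "replicate")
  missing_cols <- setdiff(need, colnames(raw))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  sheet <- data.frame(sample_id = raw$sample_id,
                      tissue = raw$tissue,
                      phenotype = raw$phenotype,
                      replicate = as.integer(raw$replicate),
                      stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet
#'
#' @param sheet data.frame with sample_id, tissue, phenotype, replicate.
#' @return The sheet, invisibly validated (errors on violation).
#' @export
validate_sample_sheet <- function(sheet) {
  .check_unique(sheet$sample_id, "sample id")
  bad_phen <- setdiff(unique(sheet$phenotype), c("invasive", "non_invasive"))
  if (length(bad_phen))
    stop("unknown phenotype label(s): ", paste(bad_phen, collapse = ", "))
  counts <- table(sheet$tissue, sheet$phenotype)
  if (any(counts < 2L) || ncol(counts) < 2L)
    stop("every tissue needs >= 2 samples of each phenotype")
  sheet
}

#' Convert beta values to M-values
#'
#' M = log2(b / (1 - b)) with b clipped into \[epsilon, 1 - epsilon\] so the
#' result is bounded. Missing values stay missing.
#'
#' @param beta Numeric vector/matrix of methylation fractions in \[0,1\].
#' @param epsilon Clipping bound in (0, 0.5); default 1e-6.
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      !is.finite(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must be in (0, 0.5)")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M-values to beta values
#'
#' Inverse logistic of [beta_to_m()]: beta = 2^M / (1 + 2^M), always strictly
#' inside (0, 1) for finite M.
#'
#' @param m Numeric vector/matrix of M-values.
#' @return Beta values.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Export a signature as BED, gene lists and a JSON report
#'
#' Writes (a) a BED6 file of signature CpGs (0-based half-open single-base
#' intervals, name = probe id, score = round(1000 * |mean delta beta|)),
#' (b) sorted deduplicated gene lists (one symbol per line), and (c) a JSON
#' report with the counts and p-values carried by the signature object.
#'
#' @param signature A signature set from [intersect_concordant()].
#' @param annotation Probe annotation covering all signature probes.
#' @param out_dir Output directory (created if absent).
#' @param scores Optional named numeric vector of mean delta beta per probe
#'   used for the BED score column; probes without a score get 0.
#' @param report Optional list of extra fields merged into the JSON report.
#' @return Named character vector: manifest of written files.
#' @export
write_signature_outputs <- function(signature, annotation, out_dir,
                                    scores = NULL, report = list()) {
  stopifnot(inherits(signature, "signature_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probes <- c(signature$common_hyper, signature$common_hypo)
  unknown <- setdiff(probes, annotation$probe_id)
  if (length(unknown))
    stop("probe(s) missing from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  direction <- rep(c("hyper", "hypo"),
                   c(length(signature$common_hyper), length(signature$common_hypo)))

  bed_path <- file.path(out_dir, "signature_cpgs.bed")
  if (length(probes)) {
    idx <- match(probes, annotation$probe_id)
    sc <- if (is.null(scores)) rep(0, length(probes)) else {
      s <- scores[probes]
      s[is.na(s)] <- 0
      s
    }
    bed <- data.frame(chrom = annotation$chromosome[idx],
                      start = annotation$position[idx] - 1L,
                      end = annotation$position[idx],
                      name = probes,
                      score = as.integer(round(1000 * abs(sc))),
                      strand = ".",
                      stringsAsFactors = FALSE)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed_path)
  }

  gene_files <- c(hyper = file.path(out_dir, "genes_common_hyper.txt"),
                  hypo = file.path(out_dir, "genes_common_hypo.txt"))
  for (dir_lab in c("hyper", "hypo")) {
    p <- if (dir_lab == "hyper") signature$common_hyper else signature$common_hypo
    genes <- if (length(p)) probes_to_genes(p, annotation)$genes else character(0)
    writeLines(sort(genes), gene_files[[dir_lab]])
  }

  report_path <- file.path(out_dir, "signature_report.json")
  base_report <- list(
    n_common_hyper = length(signature$common_hyper),
    n_common_hypo = length(signature$common_hypo),
    n_universe = length(signature$universe)
  )
  jsonlite::write_json(c(base_report, report), report_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  c(bed = bed_path, genes_hyper = gene_files[["hyper"]],
    genes_hypo = gene_files[["hypo"]], report = report_path)
}
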