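# Shared fixtures: a reduced simulation for fast module tests, and a cached
# set of full-condition pipeline runs reused by the recovery checks.

small_config <- function(seed = 1, ...) {
  defaults <- list(n_probes = 4000, n_common_hypo = 150, n_common_hyper = 150,
                   n_tissue_specific = 50, n_genes = 1000, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

write_tsv_text <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# tiny hand-built annotation for io / signature unit tests
toy_annotation <- function() {
  ann <- data.frame(
    probe_id = c("cg01", "cg02", "cg03", "cg04", "cg05"),
    chromosome = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    position = c(100L, 250L, 50L, 75L, 900L),
    island_relation = c("island", "shore", "open_sea", "shelf", "island"),
    enhancer = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  ann$gene_symbols <- list(c("A", "A"), "A", c("A", "B"), "C", character(0))
  ann$gene_region <- list(c("TSS200", "5UTR"), "Body", c("TSS200", "Body"),
                          "1stExon", character(0))
  ann
}

# full-condition pipeline runs (the study conditions), cached across tests
.pipeline_cache <- new.env(parent = emptyenv())

full_condition_runs <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- lapply(seeds, function(s) {
      cfg <- simulation_config(seed = s)
      run_pipeline(pipeline_config(simulation = cfg, n_permutations = 300,
                                   seed = s))
    })
  }
  .pipeline_cache[[key]]
}
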