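# End-to-end orchestration: translate -> search -> join -> filter ->
# reduce -> resolve.

#' Pipeline run configuration
#'
#' Defaults reproduce the benchmark settings of the method: lenient
#' per-exon E-value 100, gene-call E-value cutoff 1e-4, target coverage
#' 0.6, fragments of at least 20 codons, exons of at least 10 aligned
#' aa, introns of 15-10,000 nt, up to 10 aa of target-side overlap
#' between joined exons. `preset = "large_metagenome"` switches to the
#' large-survey settings (`min_fragment_aa = 40`, `min_exon_aa = 20`).
#'
#' @param min_fragment_aa minimal translated fragment length (codons).
#' @param min_exon_aa minimal aligned exon length (aa).
#' @param max_exon_evalue maximal per-exon E-value.
#' @param max_call_evalue maximal gene-call E-value.
#' @param min_tcov minimal predicted-protein/target length ratio.
#' @param min_intron,max_intron intron length window (nt).
#' @param max_target_overlap allowed target overlap between joined
#'   exons (aa).
#' @param genetic_code NCBI genetic code id.
#' @param params scoring parameters from [score_params()].
#' @param prefilter_kmer shared-k-mer search prefilter length
#'   (see [search_fragments()]; 0 disables).
#' @param preset `"benchmark"` (default) or `"large_metagenome"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_fragment_aa = 20L, min_exon_aa = 10L,
                       max_exon_evalue = 100, max_call_evalue = 1e-4,
                       min_tcov = 0.6, min_intron = 15L, max_intron = 10000L,
                       max_target_overlap = 10L, genetic_code = "1",
                       params = score_params(), prefilter_kmer = 5L,
                       preset = c("benchmark", "large_metagenome")) {
  preset <- match.arg(preset)
  if (preset == "large_metagenome") {
    if (missing(min_fragment_aa)) min_fragment_aa <- 40L
    if (missing(min_exon_aa)) min_exon_aa <- 20L
  }
  stopifnot(min_fragment_aa >= 1L, min_exon_aa >= 1L, max_exon_evalue > 0,
            max_call_evalue > 0, min_tcov >= 0, min_intron >= 0,
            max_intron >= min_intron, max_target_overlap >= 0)
  structure(list(min_fragment_aa = as.integer(min_fragment_aa),
                 min_exon_aa = as.integer(min_exon_aa),
                 max_exon_evalue = max_exon_evalue,
                 max_call_evalue = max_call_evalue, min_tcov = min_tcov,
                 min_intron = as.integer(min_intron),
                 max_intron = as.integer(max_intron),
                 max_target_overlap = as.integer(max_target_overlap),
                 genetic_code = genetic_code, params = params,
                 prefilter_kmer = as.integer(prefilter_kmer),
                 preset = preset),
            class = "run_config")
}

#' Predict protein-coding genes on contigs
#'
#' Runs the full pipeline: six-frame fragment extraction, local search
#' of fragments against the reference, dynamic-programming joining of
#' putative exons into gene calls per (contig, strand, target), E-value
#' and target-coverage filtering, redundancy clustering with
#' representative selection, and same-strand overlap resolution.
#'
#' @param contigs named `DNAStringSet`, named character vector, or a
#'   FASTA path.
#' @param reference a [reference_db()], named `AAStringSet`/character
#'   vector of targets, or a FASTA path.
#' @param config [run_config()] object.
#' @param hits optional precomputed hits (data.table from
#'   [import_hits_m8()]); skips the built-in search.
#' @param invert run the inverted-fragment null model: fragment amino
#'   acids are reversed after extraction, so every resulting prediction
#'   is a false positive.
#' @param verbose print per-stage counts.
#' @return list of class `prediction_run`: `predictions` (`gene_calls`),
#'   `clusters`, `calls` (filtered calls), `fragments`, `stats`
#'   (per-stage counts), `config`, `ref`, `contigs`.
#' @export
predict_genes <- function(contigs, reference, config = run_config(),
                          hits = NULL, invert = FALSE, verbose = FALSE) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_fasta(contigs, "nt")
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  ref <- if (inherits(reference, "reference_db")) reference
         else if (is.character(reference) && length(reference) == 1L &&
                  file.exists(reference))
           reference_db(read_fasta(reference, "aa"))
         else reference_db(reference)
  say <- function(...) if (verbose) message(sprintf(...))

  fragments <- extract_fragments(contigs, config$genetic_code,
                                 config$min_fragment_aa)
  if (invert) fragments <- invert_fragments(fragments)
  say("fragments: %d", nrow(fragments))
  if (is.null(hits)) {
    hits <- search_fragments(fragments, ref, config$max_exon_evalue,
                             config$params, config$prefilter_kmer)
  }
  say("hits (E <= %g): %d", config$max_exon_evalue, nrow(hits))
  exons <- build_putative_exons(hits, fragments, config$min_exon_aa)
  say("putative exons (>= %d aa): %d", config$min_exon_aa, nrow(exons))
  calls <- join_exons(exons, fragments, ref, config$min_intron,
                      config$max_intron, config$max_target_overlap)
  say("gene calls: %d", nrow(calls$calls))
  calls <- filter_calls(calls, config$max_call_evalue, config$min_tcov)
  say("calls after E/tcov filter: %d", nrow(calls$calls))
  red <- reduce_calls(calls)
  say("clusters: %d; predictions after overlap resolution: %d",
      if (nrow(red$clusters)) max(red$clusters$cluster_id) else 0L,
      nrow(red$predictions$calls))
  stats <- list(n_fragments = nrow(fragments), n_hits = nrow(hits),
                n_exons = nrow(exons), n_calls_filtered = nrow(calls$calls),
                n_clusters = if (nrow(red$clusters))
                  max(red$clusters$cluster_id) else 0L,
                n_predictions = nrow(red$predictions$calls))
  structure(list(predictions = red$predictions, clusters = red$clusters,
                 calls = calls, fragments = fragments, stats = stats,
                 config = config, ref = ref, contigs = contigs),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("prediction_run: %d fragments -> %d hits -> %d exons",
                     " -> %d calls -> %d clusters -> %d predictions\n"),
              s$n_fragments, s$n_hits, s$n_exons, s$n_calls_filtered,
              s$n_clusters, s$n_predictions))
  invisible(x)
}
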