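# Shared fixtures, built once per test run and memoized.

.world_cache <- new.env(parent = emptyenv())

# small world: 10 genes / 60 kbp, mild divergence; cheap enough for
# module tests
small_world <- function() {
  if (is.null(.world_cache$small)) {
    .world_cache$small <- synth_world(
      synth_config(n_genes = 10L, genome_bp = 6e4, n_contigs = 2L,
                   decoy_targets = 3L),
      divergence = 0.1, seed = 101)
  }
  .world_cache$small
}

small_run <- function() {
  if (is.null(.world_cache$small_run)) {
    w <- small_world()
    .world_cache$small_run <- predict_genes(w$contigs, w$ref, run_config())
  }
  .world_cache$small_run
}

# acceptance world: the stated scale (1 Mbp, 200 multi-exon genes,
# reference at 20% divergence)
acceptance_world <- function(seed = 424242L) {
  key <- paste0("acc", seed)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- synth_world(synth_config(), divergence = 0.2,
                                       seed = seed)
  }
  .world_cache[[key]]
}

acceptance_run <- function(seed = 424242L) {
  key <- paste0("accrun", seed)
  if (is.null(.world_cache[[key]])) {
    w <- acceptance_world(seed)
    .world_cache[[key]] <- predict_genes(w$contigs, w$ref, run_config())
  }
  .world_cache[[key]]
}

# compact constructor for hand-built gene_calls objects
make_calls <- function(calls_spec) {
  # calls_spec: list of lists with fields contig, strand, target, exons
  # (list of c(SC, EC, ST, ET, bits)), exon_ids, evalue override optional
  calls_l <- list(); exons_l <- list()
  for (i in seq_along(calls_spec)) {
    cs <- calls_spec[[i]]
    exm <- do.call(rbind, cs$exons)
    k <- nrow(exm)
    ids <- if (!is.null(cs$exon_ids)) cs$exon_ids
           else sprintf("c%d_f%d", i, seq_len(k))
    ex <- data.table::data.table(
      call_id = i, exon_rank = seq_len(k), exon_id = ids,
      contig_id = cs$contig, strand = cs$strand, target_id = cs$target,
      SC = as.integer(exm[, 1]), EC = as.integer(exm[, 2]),
      ST = as.integer(exm[, 3]), ET = as.integer(exm[, 4]),
      bits = exm[, 5], e_value = 1,
      aa_len = as.integer(exm[, 4] - exm[, 3] + 1),
      qstart = 0L, qend = as.integer(exm[, 4] - exm[, 3] + 1))
    ex[, nt_start := pmin(SC, EC)]
    ex[, nt_end := pmax(SC, EC)]
    S_set <- if (!is.null(cs$S_set)) cs$S_set else sum(ex$bits)
    ev <- if (!is.null(cs$evalue)) cs$evalue else 2 * 1e4 * 2^(-S_set)
    prot <- if (!is.null(cs$protein)) cs$protein
            else paste(rep("A", sum(ex$aa_len)), collapse = "")
    calls_l[[i]] <- data.table::data.table(
      call_id = i, contig_id = cs$contig, strand = cs$strand,
      target_id = cs$target, n_exons = k, S_set = S_set, evalue = ev,
      span_start = min(ex$nt_start), span_end = max(ex$nt_end),
      protein = prot, target_len = sum(ex$aa_len),
      tcov = if (!is.null(cs$tcov)) cs$tcov else 1)
    exons_l[[i]] <- ex
  }
  structure(list(calls = data.table::rbindlist(calls_l),
                 exons = data.table::rbindlist(exons_l)),
            class = "gene_calls")
}
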