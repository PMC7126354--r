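# Stages 4-5: cluster redundant calls arising from homologous targets,
# keep the best-scoring member of each cluster as the prediction, and
# resolve same-strand overlaps by E-value.

#' Cluster gene calls that share an exon
#'
#' Greedy single pass per (contig, strand): calls are ordered by the
#' contig start of their first exon (sub-ordered by decreasing exon
#' count, then target id for determinism). The first unassigned call
#' seeds a cluster and acts as its tentative representative; each
#' following call whose start lies strictly before `m` (the last contig
#' position of the representative's last exon) joins the cluster iff it
#' shares an exon identifier with the tentative representative. The
#' highest-scoring member of each cluster becomes the cluster's
#' prediction (which may differ from the tentative representative).
#'
#' @param calls `gene_calls` object (typically after [filter_calls()]).
#' @return data.table: call_id, cluster_id, is_tentative_representative,
#'   is_prediction, cluster_size.
#' @export
cluster_calls <- function(calls) {
  cl <- copy(calls$calls)
  if (nrow(cl) == 0L)
    return(data.table(call_id = integer(), cluster_id = integer(),
                      is_tentative_representative = logical(),
                      is_prediction = logical(), cluster_size = integer()))
  exon_sets <- calls$exons[, .(ids = list(exon_id)), by = call_id]
  cl <- merge(cl, exon_sets, by = "call_id", sort = FALSE)
  setorder(cl, contig_id, strand, span_start, -n_exons, target_id, call_id)
  cl[, cluster_id := NA_integer_]
  next_cluster <- 0L
  for (grp in split(seq_len(nrow(cl)),
                    paste(cl$contig_id[seq_len(nrow(cl))],
                          cl$strand[seq_len(nrow(cl))]))) {
    assigned <- rep(FALSE, length(grp))
    for (a in seq_along(grp)) {
      if (assigned[a]) next
      next_cluster <- next_cluster + 1L
      ra <- grp[a]
      data.table::set(cl, ra, "cluster_id", next_cluster)
      assigned[a] <- TRUE
      rep_ids <- cl$ids[[ra]]
      m <- cl$span_end[ra]
      b <- a + 1L
      while (b <= length(grp) && cl$span_start[grp[b]] < m) {
        if (!assigned[b] && length(intersect(cl$ids[[grp[b]]], rep_ids))) {
          data.table::set(cl, grp[b], "cluster_id", next_cluster)
          assigned[b] <- TRUE
        }
        b <- b + 1L
      }
    }
  }
  cl[, is_tentative_representative := seq_len(.N) == 1L, by = cluster_id]
  # prediction = best score per cluster; ties: smaller E (same thing),
  # then target id, then call id
  setorder(cl, cluster_id, -S_set, target_id, call_id)
  cl[, is_prediction := seq_len(.N) == 1L, by = cluster_id]
  cl[, cluster_size := .N, by = cluster_id]
  out <- cl[, .(call_id, cluster_id, is_tentative_representative,
                is_prediction, cluster_size)]
  setorder(out, call_id)
  out[]
}

#' Resolve same-strand overlapping predictions
#'
#' Predictions on one contig and strand are scanned in order of
#' ascending E-value (ties: higher bit-score, then smaller span start,
#' then target id); a prediction is kept iff its contig span shares no
#' nucleotide with an already-kept span. Opposite-strand overlaps are
#' untouched.
#'
#' @param predictions `gene_calls` object of cluster representatives.
#' @return `gene_calls` object of retained predictions, ordered by
#'   contig position.
#' @export
resolve_overlaps <- function(predictions) {
  cl <- copy(predictions$calls)
  if (nrow(cl) == 0L) return(predictions)
  setorder(cl, contig_id, strand, evalue, -S_set, span_start, target_id)
  cl[, kept := FALSE]
  for (grp in split(seq_len(nrow(cl)), paste(cl$contig_id, cl$strand))) {
    kept_s <- integer(); kept_e <- integer()
    for (r in grp) {
      s <- cl$span_start[r]; e <- cl$span_end[r]
      if (!any(s < kept_e & e > kept_s)) {
        data.table::set(cl, r, "kept", TRUE)
        kept_s <- c(kept_s, s); kept_e <- c(kept_e, e)
      }
    }
  }
  keep_ids <- cl[kept == TRUE, call_id]
  out_calls <- predictions$calls[call_id %in% keep_ids]
  setorder(out_calls, contig_id, span_start, strand, target_id)
  structure(list(calls = out_calls,
                 exons = predictions$exons[call_id %in% keep_ids]),
            class = "gene_calls")
}

#' Reduce calls to final predictions
#'
#' Convenience wrapper: [cluster_calls()], keep each cluster's
#' prediction, then [resolve_overlaps()].
#'
#' @param calls `gene_calls` object (typically after [filter_calls()]).
#' @return list: `predictions` (`gene_calls`), `clusters` (the
#'   clustering table).
#' @export
reduce_calls <- function(calls) {
  clusters <- cluster_calls(calls)
  pred_ids <- clusters[is_prediction == TRUE, call_id]
  preds <- structure(list(calls = calls$calls[call_id %in% pred_ids],
                          exons = calls$exons[call_id %in% pred_ids]),
                     class = "gene_calls")
  list(predictions = resolve_overlaps(preds), clusters = clusters)
}

#' Collapse identical predicted proteins
#'
#' Downstream helper (not part of the core pipeline): keeps one
#' representative per distinct predicted protein string across contigs.
#'
#' @param predictions `gene_calls` object.
#' @return `gene_calls` with one call per unique protein (smallest
#'   E-value wins; ties by contig, position).
#' @export
collapse_identical_proteins <- function(predictions) {
  cl <- copy(predictions$calls)
  if (nrow(cl) == 0L) return(predictions)
  setorder(cl, protein, evalue, contig_id, span_start, target_id)
  keep <- cl[, call_id[1L], by = protein]$V1
  structure(list(calls = predictions$calls[call_id %in% keep],
                 exons = predictions$exons[call_id %in% keep]),
            class = "gene_calls")
}
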