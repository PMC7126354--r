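# Taxonomic assignment: best annotated hit per prediction with
# identity-dependent rank truncation, and per-contig label conferral.

.tax_ranks <- c("domain", "kingdom", "phylum", "class", "order", "family",
                "genus", "species")

# identity (fraction) -> deepest allowed rank; cutoffs are strict (">")
.rank_from_identity <- function(identity) {
  cuts <- c(species = 0.95, genus = 0.80, family = 0.65, order = 0.50,
            class = 0.40, phylum = 0.30, kingdom = 0.20)
  for (r in names(cuts)) if (identity > cuts[[r]]) return(r)
  "domain"
}

#' Read a lineage table
#'
#' Two-column TSV: target id, then semicolon-separated ranked labels
#' from domain downward (missing trailing ranks allowed).
#'
#' @param path TSV file.
#' @return named list of character vectors (one lineage per target).
#' @export
read_lineages <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("target_id", "lineage"))
  if (anyDuplicated(dt$target_id))
    stop("duplicate target id in lineage table", call. = FALSE)
  setNames(strsplit(dt$lineage, ";", fixed = TRUE), dt$target_id)
}

# truncate a lineage at the rank allowed by identity; lineages missing
# intermediate ranks are treated positionally (labels fill ranks from
# domain downward) and truncation falls back to the nearest present
# ancestor rank
.truncate_lineage <- function(lineage, identity) {
  rank <- .rank_from_identity(identity)
  depth <- match(rank, .tax_ranks)
  keep <- lineage[seq_len(min(depth, length(lineage)))]
  keep[nzchar(keep)]
}

#' Assign taxonomy to predictions
#'
#' For each prediction, the hit with the highest bit-score and an
#' E-value below `max_evalue` (default 1e-5) is selected (ties: smaller
#' E-value, then target id); its lineage is truncated at the rank
#' allowed by the alignment identity: >95% species, >80% genus, >65%
#' family, >50% order, >40% class, >30% phylum, >20% kingdom, lower
#' values domain. Predictions without a qualifying hit, or whose best
#' hit has no lineage, are unassigned.
#'
#' @param prediction_hits data.table: call_id, target_id, bits, evalue,
#'   identity (one or more annotated hits per prediction, e.g. the
#'   prediction's own call joined with [prediction_target_identity()],
#'   or hits of predicted proteins against an annotated database).
#' @param lineages named list from [read_lineages()].
#' @param max_evalue maximal hit E-value.
#' @return data.table: call_id, target_id, identity, rank, label
#'   (semicolon-joined truncated lineage; NA when unassigned).
#' @export
assign_prediction_taxonomy <- function(prediction_hits, lineages,
                                       max_evalue = 1e-5) {
  out <- data.table(call_id = unique(prediction_hits$call_id),
                    target_id = NA_character_, identity = NA_real_,
                    rank = NA_character_, label = NA_character_)
  h <- prediction_hits[evalue < max_evalue]
  if (nrow(h)) {
    setorder(h, call_id, -bits, evalue, target_id)
    best <- h[, .SD[1L], by = call_id]
    for (i in seq_len(nrow(best))) {
      b <- best[i]
      lin <- lineages[[b$target_id]]
      if (is.null(lin)) {
        warning("no lineage for target ", b$target_id, call. = FALSE)
        next
      }
      kept <- .truncate_lineage(lin, b$identity)
      if (length(kept) == 0L) next
      row <- which(out$call_id == b$call_id)
      data.table::set(out, row, "target_id", b$target_id)
      data.table::set(out, row, "identity", b$identity)
      data.table::set(out, row, "rank",
                      .tax_ranks[min(match(.rank_from_identity(b$identity),
                                           .tax_ranks), length(kept))])
      data.table::set(out, row, "label", paste(kept, collapse = ";"))
    }
  }
  setorder(out, call_id)
  out[]
}

#' Confer taxonomy to contigs
#'
#' Each contig takes the label of its best prediction: the labeled
#' prediction with the smallest E-value (ties: higher bit-score, then
#' call id). Contigs whose predictions are all unassigned stay
#' unassigned.
#'
#' @param predictions `gene_calls` object.
#' @param prediction_taxonomy data.table from
#'   [assign_prediction_taxonomy()].
#' @return data.table: contig_id, label, rank, call_id (the conferring
#'   prediction; NA when unassigned).
#' @export
assign_contig_taxonomy <- function(predictions, prediction_taxonomy) {
  pr <- merge(predictions$calls[, .(call_id, contig_id, evalue, S_set)],
              prediction_taxonomy, by = "call_id")
  res <- pr[, {
    lab <- .SD[!is.na(label)]
    if (nrow(lab)) {
      setorder(lab, evalue, -S_set, call_id)
      .(label = lab$label[1L], rank = lab$rank[1L], call_id = lab$call_id[1L])
    } else .(label = NA_character_, rank = NA_character_,
             call_id = NA_integer_)
  }, by = contig_id]
  setorder(res, contig_id)
  res[]
}

#' Krona-style path counts
#'
#' Plain-TSV summary: one row per distinct lineage path with the number
#' of contigs carrying it.
#'
#' @param contig_taxonomy data.table from [assign_contig_taxonomy()].
#' @param path optional output TSV.
#' @return data.table: label (path or "unassigned"), n.
#' @export
taxonomy_path_counts <- function(contig_taxonomy, path = NULL) {
  tab <- contig_taxonomy[, .(n = .N),
                         by = .(label = ifelse(is.na(label), "unassigned",
                                               label))]
  setorder(tab, -n, label)
  if (!is.null(path)) fwrite(tab, path, sep = "\t")
  tab[]
}
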