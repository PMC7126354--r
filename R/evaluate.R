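# Benchmark harness: map predictions to gold annotations, exon
# coverage, sensitivity under identity exclusion, precision-recall from
# E-values, split-gene rate, the inverted-fragment null model, and
# scaffold fragmentation into metagenome-like contig lengths.

# mismatch fraction of an end-gap-free global alignment of two proteins:
# mismatch columns (aligned, non-identical, non-gap) / total columns
.protein_mismatch_fraction <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  if (length(s1) == 0L) return(1)
  mism <- sum(s1 != s2 & s1 != "-" & s2 != "-")
  mism / length(s1)
}

#' Map predictions to annotated genes
#'
#' A prediction maps to an annotated protein when the overlap of their
#' global contig spans (lowest to highest CDS coordinate) is at least
#' `min_span_overlap` (default 0.8) of either party's span length, and
#' the end-gap-free alignment of their protein sequences has fewer than
#' `max_mismatch` (default 0.1) mismatch columns. One annotation may be
#' hit by several predictions; each prediction maps to at most one
#' annotation (largest span overlap wins).
#'
#' @param predictions `gene_calls` object.
#' @param annotations `annotation_set` with `proteins` attached.
#' @param min_span_overlap span-overlap fraction threshold.
#' @param max_mismatch maximal protein mismatch fraction.
#' @param same_strand require the annotation strand to match
#'   (default TRUE).
#' @return data.table of mappings: call_id, gene_id, overlap_bp,
#'   frac_pred, frac_gene, mismatch_fraction.
#' @export
map_predictions <- function(predictions, annotations,
                            min_span_overlap = 0.8, max_mismatch = 0.1,
                            same_strand = TRUE) {
  stopifnot(inherits(annotations, "annotation_set"),
            !is.null(annotations$proteins))
  pr <- predictions$calls
  gn <- annotations$genes
  empty <- data.table(call_id = integer(), gene_id = character(),
                      overlap_bp = integer(), frac_pred = numeric(),
                      frac_gene = numeric(), mismatch_fraction = numeric())
  if (nrow(pr) == 0L || nrow(gn) == 0L) return(empty)
  if (!any(pr$contig_id %in% gn$contig_id))
    stop("predictions and annotations share no contig id", call. = FALSE)
  cand <- merge(pr[, .(call_id, contig_id, strand, span_start, span_end,
                       protein)],
                gn[, .(gene_id, contig_id, gstrand = strand,
                       gstart = span_start, gend = span_end)],
                by = "contig_id", allow.cartesian = TRUE)
  if (same_strand) cand <- cand[strand == gstrand]
  cand[, overlap_bp := pmax(0L, pmin(span_end, gend) -
                                 pmax(span_start, gstart))]
  cand <- cand[overlap_bp > 0L]
  if (nrow(cand) == 0L) return(empty)
  cand[, frac_pred := overlap_bp / (span_end - span_start)]
  cand[, frac_gene := overlap_bp / (gend - gstart)]
  cand <- cand[pmax(frac_pred, frac_gene) >= min_span_overlap]
  if (nrow(cand) == 0L) return(empty)
  gprot <- as.character(annotations$proteins)
  cand[, mismatch_fraction := mapply(
    function(p, g) .protein_mismatch_fraction(p, gprot[[g]]),
    protein, gene_id)]
  cand <- cand[mismatch_fraction < max_mismatch]
  if (nrow(cand) == 0L) return(empty)
  # best annotation per prediction
  setorder(cand, call_id, -overlap_bp, gene_id)
  cand <- cand[, .SD[1L], by = call_id]
  out <- cand[, .(call_id, gene_id, overlap_bp, frac_pred, frac_gene,
                  mismatch_fraction)]
  setorder(out, call_id)
  out[]
}

#' Exon-level coverage of mapped annotations
#'
#' An annotated exon counts as covered when a single predicted exon
#' overlaps at least `min_exon_overlap` (default 0.8) of its contig
#' length.
#'
#' @param mappings data.table from [map_predictions()].
#' @param predictions `gene_calls` object.
#' @param annotations `annotation_set`.
#' @param min_exon_overlap per-exon coverage threshold.
#' @return list: `per_exon` (data.table: gene_id, call_id, start0, end0,
#'   covered), `per_gene` (gene_id, n_exons, n_covered, fraction),
#'   `overall` (fraction of annotated exons of mapped genes covered).
#' @export
exon_coverage <- function(mappings, predictions, annotations,
                          min_exon_overlap = 0.8) {
  if (nrow(mappings) == 0L)
    return(list(per_exon = data.table(), per_gene = data.table(),
                overall = NA_real_))
  pe_l <- vector("list", nrow(mappings))
  for (i in seq_len(nrow(mappings))) {
    mp <- mappings[i]
    acds <- annotations$cds[gene_id == mp$gene_id]
    pexons <- predictions$exons[call_id == mp$call_id]
    cov <- vapply(seq_len(nrow(acds)), function(j) {
      ov <- pmax(0L, pmin(acds$end0[j], pexons$nt_end) -
                      pmax(acds$start0[j], pexons$nt_start))
      any(ov >= min_exon_overlap * (acds$end0[j] - acds$start0[j]))
    }, logical(1))
    pe_l[[i]] <- data.table(gene_id = mp$gene_id, call_id = mp$call_id,
                            start0 = acds$start0, end0 = acds$end0,
                            covered = cov)
  }
  per_exon <- rbindlist(pe_l)
  # a gene's exon is covered if covered by any mapped prediction
  gene_exon <- per_exon[, .(covered = any(covered)),
                        by = .(gene_id, start0, end0)]
  per_gene <- gene_exon[, .(n_exons = .N, n_covered = sum(covered),
                            fraction = mean(covered)), by = gene_id]
  list(per_exon = per_exon, per_gene = per_gene,
       overall = mean(gene_exon$covered))
}

#' Sensitivity, with identity-based exclusion regimes
#'
#' Base sensitivity is the fraction of annotated proteins to which a
#' prediction was mapped. Increasing evolutionary distance is emulated
#' by excluding predictions whose alignment to their own target exceeds
#' an identity threshold, then recomputing the mapped fraction.
#'
#' @param mappings data.table from [map_predictions()].
#' @param predictions `gene_calls` object.
#' @param annotations `annotation_set`.
#' @param ref [reference_db()] (to align predictions to their targets).
#' @param identity_thresholds identity exclusion levels
#'   (default 0.9, 0.8, 0.6, 0.4).
#' @param params scoring parameters.
#' @return list: `table` (data.table: regime, max_identity, n_mapped,
#'   sensitivity), `prediction_identity` (per call).
#' @export
sensitivity <- function(mappings, predictions, annotations, ref,
                        identity_thresholds = c(0.9, 0.8, 0.6, 0.4),
                        params = score_params()) {
  n_ann <- nrow(annotations$genes)
  pid <- prediction_target_identity(predictions, ref, params)
  base <- data.table(regime = "base", max_identity = NA_real_,
                     n_mapped = length(unique(mappings$gene_id)),
                     sensitivity = length(unique(mappings$gene_id)) / n_ann)
  rows <- lapply(identity_thresholds, function(th) {
    keep <- pid[identity <= th, call_id]
    mp <- mappings[call_id %in% keep]
    data.table(regime = sprintf("identity<=%g", th), max_identity = th,
               n_mapped = length(unique(mp$gene_id)),
               sensitivity = length(unique(mp$gene_id)) / n_ann)
  })
  list(table = rbindlist(c(list(base), rows)), prediction_identity = pid)
}

#' Smith-Waterman identity of each prediction to its target
#'
#' @param predictions `gene_calls` object.
#' @param ref [reference_db()].
#' @param params scoring parameters.
#' @return data.table: call_id, identity, sw_raw, sw_bits.
#' @export
prediction_target_identity <- function(predictions, ref,
                                       params = score_params()) {
  pr <- predictions$calls
  if (nrow(pr) == 0L)
    return(data.table(call_id = integer(), identity = numeric(),
                      sw_raw = numeric(), sw_bits = numeric()))
  tg <- as.character(ref$targets)
  res <- lapply(seq_len(nrow(pr)), function(i) {
    a <- sw_align(pr$protein[i], tg[[pr$target_id[i]]], params)
    data.table(call_id = pr$call_id[i], identity = a$identity,
               sw_raw = a$raw, sw_bits = a$bits)
  })
  rbindlist(res)
}

#' Precision-recall curve over prediction E-values
#'
#' Predictions are ranked by ascending E-value (descending confidence);
#' equal E-values are processed as one step. The area under the curve
#' is the trapezoid over recall.
#'
#' @param evalues numeric vector of prediction E-values.
#' @param truth logical vector: was the prediction mapped to an
#'   annotation.
#' @return list: `curve` (data.table: evalue, tp, fp, precision,
#'   recall), `auc_pr`.
#' @export
precision_recall <- function(evalues, truth) {
  stopifnot(length(evalues) == length(truth))
  if (length(evalues) == 0L || !any(truth))
    return(list(curve = data.table(), auc_pr = NA_real_))
  o <- order(evalues)
  dt <- data.table(evalue = evalues[o], truth = truth[o])
  dt[, `:=`(tp = cumsum(truth), fp = cumsum(!truth))]
  dt <- dt[, .SD[.N], by = evalue]  # one point per distinct threshold
  dt[, precision := tp / (tp + fp)]
  dt[, recall := tp / sum(truth)]
  r <- c(0, dt$recall)
  p <- c(dt$precision[1L], dt$precision)
  auc <- sum(diff(r) * (head(p, -1L) + tail(p, -1L)) / 2)
  list(curve = dt[, .(evalue, tp, fp, precision, recall)], auc_pr = auc)
}

#' Fraction of annotated genes split across several predictions
#'
#' Computed on mapped genes only: the fraction to which two or more
#' predictions were mapped.
#'
#' @param mappings data.table from [map_predictions()].
#' @return list: `rate`, `table` (gene_id, n_predictions).
#' @export
split_gene_rate <- function(mappings) {
  if (nrow(mappings) == 0L)
    return(list(rate = NA_real_, table = data.table()))
  tab <- mappings[, .(n_predictions = .N), by = gene_id]
  list(rate = mean(tab$n_predictions >= 2L), table = tab)
}

#' Inverted-fragment null model
#'
#' Runs the full pipeline with fragment sequences character-reversed
#' after extraction. Every prediction on inverted fragments is a false
#' positive, giving an annotation-free precision bound at the same
#' reporting cutoffs.
#'
#' @param contigs named `DNAStringSet` or character vector.
#' @param ref [reference_db()].
#' @param config [run_config()].
#' @return list: `n_false_positives`, `per_mbp` (count per Mbp of
#'   contig sequence), `run` (the full `prediction_run`).
#' @export
inverted_null_run <- function(contigs, ref, config = run_config()) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  run <- predict_genes(contigs, ref, config, invert = TRUE)
  n <- nrow(run$predictions$calls)
  mbp <- sum(as.numeric(Biostrings::width(contigs))) / 1e6
  list(n_false_positives = n, per_mbp = if (mbp > 0) n / mbp else NA_real_,
       run = run)
}

#' Metagenome-like contig length sampler
#'
#' Shifted log-normal calibrated to typical metagenomic assemblies
#' (minimum ~5 kbp, median ~6.8 kbp, upper quartile ~9 kbp):
#' `min_bp + lognormal(meanlog, sdlog)`. The default quartile anchors
#' are min 5002, Q1 5661, median 6763, Q3 9020 bp.
#'
#' @param n number of lengths.
#' @param min_bp hard minimum length.
#' @param meanlog,sdlog log-normal parameters of the excess over
#'   `min_bp` (defaults fitted to the quartile anchors above).
#' @return integer vector of lengths.
#' @export
sample_contig_lengths <- function(n, min_bp = 5002, meanlog = 7.474,
                                  sdlog = 1.343) {
  as.integer(round(min_bp + exp(rnorm(n, meanlog, sdlog))))
}

#' Fragment scaffolds into metagenome-like contigs
#'
#' Cuts each scaffold left to right into contigs whose lengths are drawn
#' from `length_sampler`; the concatenation of the emitted contigs
#' reproduces the scaffold exactly, and per-contig offsets are recorded
#' so truth coordinates lift over. Deterministic given `seed`.
#'
#' @param scaffolds named `DNAStringSet` or character vector.
#' @param length_sampler function(n) returning candidate lengths.
#' @param seed integer seed.
#' @return list: `contigs` (`DNAStringSet`, ids
#'   `<scaffold>.p<part>`), `offsets` (data.table: contig_id,
#'   scaffold_id, offset, length).
#' @export
fragment_scaffolds <- function(scaffolds, length_sampler =
                                 sample_contig_lengths, seed = 1L) {
  if (is.character(scaffolds)) scaffolds <- Biostrings::DNAStringSet(scaffolds)
  set.seed(seed)
  seqs <- character(); ids <- character()
  off_l <- list()
  for (si in seq_along(scaffolds)) {
    sid <- names(scaffolds)[si]
    len <- Biostrings::width(scaffolds)[si]
    pos <- 0L; part <- 0L
    while (pos < len) {
      take <- min(length_sampler(1L), len - pos)
      part <- part + 1L
      cid <- sprintf("%s.p%03d", sid, part)
      ids <- c(ids, cid)
      seqs <- c(seqs, as.character(Biostrings::subseq(scaffolds[[si]],
                                                      pos + 1L, pos + take)))
      off_l[[length(off_l) + 1L]] <- data.table(
        contig_id = cid, scaffold_id = sid, offset = pos, length = take)
      pos <- pos + take
    }
  }
  list(contigs = Biostrings::DNAStringSet(setNames(seqs, ids)),
       offsets = rbindlist(off_l))
}

#' Lift annotations onto fragmented contigs
#'
#' Re-expresses truth CDS intervals in the coordinates of the contigs
#' produced by [fragment_scaffolds()]. A gene is lifted to every contig
#' it overlaps, with CDS intervals clipped to the contig; gene ids gain
#' the contig suffix when a gene is split.
#'
#' @param annotations `annotation_set` on the scaffolds.
#' @param offsets data.table from [fragment_scaffolds()].
#' @return `annotation_set` on the contigs (proteins carried over under
#'   the original gene id when the gene is intact on one contig).
#' @export
lift_annotations <- function(annotations, offsets) {
  cds <- annotations$cds
  out_l <- list()
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i]
    hit <- cds[contig_id == o$scaffold_id &
                 start0 < o$offset + o$length & end0 > o$offset]
    if (nrow(hit) == 0L) next
    hit <- copy(hit)
    hit[, `:=`(start0 = pmax(start0, o$offset) - o$offset,
               end0 = pmin(end0, o$offset + o$length) - o$offset,
               contig_id = o$contig_id)]
    out_l[[length(out_l) + 1L]] <- hit
  }
  if (length(out_l) == 0L)
    stop("no annotation overlaps any contig", call. = FALSE)
  cds2 <- rbindlist(out_l)
  # genes present on several contigs get distinct per-contig ids
  cds2[, gene_len := sum(end0 - start0), by = .(gene_id, contig_id)]
  multi <- cds2[, length(unique(contig_id)) > 1L, by = gene_id]
  split_genes <- multi[V1 == TRUE, gene_id]
  cds2[gene_id %in% split_genes,
       gene_id := paste0(gene_id, "@", contig_id)]
  cds2[, gene_len := NULL]
  setorder(cds2, gene_id, start0)
  genes <- cds2[, .(contig_id = contig_id[1L], strand = strand[1L],
                    span_start = min(start0), span_end = max(end0),
                    n_exons = .N), by = gene_id]
  setorder(genes, contig_id, span_start)
  prot <- annotations$proteins
  if (!is.null(prot)) prot <- prot[intersect(names(prot), genes$gene_id)]
  structure(list(genes = genes, cds = cds2, proteins = prot),
            class = "annotation_set")
}
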