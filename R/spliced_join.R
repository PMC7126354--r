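# Stages 2-3: putative exons, pairwise compatibility, and the dynamic
# program that recovers the highest-scoring compatible exon set per
# (contig, strand, target), with composite bit-score and E-value.
#
# Coordinate conventions for a putative exon:
#   ST/ET  target amino-acid coordinates, 1-based inclusive (first/last
#          aligned residue), so perfect adjacency gives ST_j - ET_i = 1.
#   SC/EC  plus-strand contig nucleotide coordinates of the translation
#          start/end of the aligned part; on '+' SC < EC (span [SC,EC)),
#          on '-' SC > EC (span [EC,SC)).

#' Build putative exons from hits
#'
#' The aligned part of each fragment against one target becomes a
#' putative exon; its contig coordinates derive from the fragment span
#' plus three times the fragment-internal amino-acid offsets. Hits whose
#' aligned fragment length falls below `min_exon_aa` (default 10, the
#' minimal exon length) are dropped.
#'
#' @param hits data.table from [search_fragments()] or
#'   [import_hits_m8()].
#' @param fragments data.table from [extract_fragments()].
#' @param min_exon_aa minimal aligned length in amino acids.
#' @return exons data.table: exon_id (= fragment_id), contig_id, strand,
#'   target_id, SC, EC, ST, ET, bits, e_value, aa_len, qstart, qend,
#'   nt_start, nt_end.
#' @export
build_putative_exons <- function(hits, fragments, min_exon_aa = 10L) {
  fr <- fragments[, .(fragment_id, contig_id, strand, contig_start,
                      contig_end, frag_aa = aa_len)]
  ex <- merge(hits, fr, by = "fragment_id", sort = FALSE)
  if (nrow(ex) < nrow(hits))
    stop("hit references unknown fragment", call. = FALSE)
  if (any(ex$qend > ex$frag_aa))
    stop("hit coordinates exceed fragment length", call. = FALSE)
  ex[, aa_len := qend - qstart]
  ex <- ex[aa_len >= min_exon_aa]
  ex[, `:=`(
    SC = ifelse(strand == "+", contig_start + 3L * qstart,
                contig_end - 3L * qstart),
    EC = ifelse(strand == "+", contig_start + 3L * qend,
                contig_end - 3L * qend),
    ST = tstart + 1L, ET = tend)]
  ex[, `:=`(nt_start = pmin(SC, EC), nt_end = pmax(SC, EC))]
  out <- ex[, .(exon_id = fragment_id, contig_id, strand, target_id,
                SC, EC, ST, ET, bits, e_value = evalue, aa_len,
                qstart, qend, nt_start, nt_end)]
  setorder(out, contig_id, strand, target_id, nt_start)
  out[]
}

#' Pairwise putative-exon compatibility
#'
#' Two putative exons from the same (contig, strand, target) group, with
#' `ST_i < ST_j`, can be joined when (plus strand) their contig order
#' matches their target order (`SC_i < SC_j`), the contig distance
#' between them can hold an intron (`15 <= SC_j - EC_i <= 10000`), and
#' their target matches do not overlap by more than a short allowance
#' (`ST_j - ET_i >= -10`). On the minus strand the contig conditions
#' flip to `SC_i > SC_j` and `15 <= EC_i - SC_j <= 10000`.
#'
#' @param exon_i,exon_j single-row exon data.tables (`exon_i` the one
#'   with the smaller target start).
#' @param min_intron,max_intron contig gap bounds in nt.
#' @param max_target_overlap allowed target-side overlap in aa.
#' @return logical.
#' @export
compatible <- function(exon_i, exon_j, min_intron = 15L, max_intron = 10000L,
                       max_target_overlap = 10L) {
  if (exon_i$contig_id != exon_j$contig_id ||
      exon_i$strand != exon_j$strand ||
      exon_i$target_id != exon_j$target_id)
    stop("exons are from different (contig, strand, target) groups",
         call. = FALSE)
  if (exon_i$ST >= exon_j$ST)
    stop("exon_i must have the smaller target start", call. = FALSE)
  if (exon_j$ST - exon_i$ET < -max_target_overlap) return(FALSE)
  if (exon_i$strand == "+") {
    if (exon_i$SC >= exon_j$SC) return(FALSE)
    gap <- exon_j$SC - exon_i$EC
  } else {
    if (exon_i$SC <= exon_j$SC) return(FALSE)
    gap <- exon_i$EC - exon_j$SC
  }
  gap >= min_intron && gap <= max_intron
}

#' Target-gap penalty C(l)
#'
#' `l` is the number of unmatched target residues between consecutive
#' exons under inclusive coordinates (`l = ST_{i+1} - ET_i`); negative
#' values denote overlap. Perfect adjacency (`l = 1`) is free; any other
#' value costs `|l|` bits.
#'
#' @param l integer vector of target gaps.
#' @return numeric vector of penalties in bits (non-positive).
#' @export
gap_penalty <- function(l) {
  ifelse(l == 1L, 0, -abs(l))
}

#' Composite bit-score of a compatible exon set
#'
#' Sums the per-exon Karlin-Altschul bit-scores, adds the target-gap
#' penalties between consecutive exons, and rewards the correct ordering
#' of the k exons with `log2(k!)`.
#'
#' @param exons exon data.table (one compatible set; any row order).
#' @param check verify pairwise compatibility of consecutive exons.
#' @return composite bit-score (numeric scalar).
#' @export
call_score <- function(exons, check = TRUE) {
  ex <- exons[order(ST)]
  k <- nrow(ex)
  stopifnot(k >= 1L)
  if (check && k > 1L) {
    for (i in seq_len(k - 1L)) {
      if (!compatible(ex[i], ex[i + 1L]))
        stop("exon set is not compatible", call. = FALSE)
    }
  }
  gaps <- if (k > 1L) ex$ST[-1L] - ex$ET[-k] else integer()
  sum(ex$bits) + sum(gap_penalty(gaps)) + lgamma(k + 1) / log(2)
}

#' E-value of a gene call
#'
#' `E = 2 * D * 2^(-S)`: at most one gene call is reported per strand
#' and target, so the expectation scales with the database size `D` (in
#' amino acids) and the two searched strands.
#'
#' @param S_set composite bit-score.
#' @param D total amino acids in the reference database.
#' @return numeric E-value.
#' @export
call_evalue <- function(S_set, D) {
  stopifnot(D >= 1)
  2 * D * 2^(-S_set)
}

# canonical in-group sort: translation order along the contig,
# deterministic tie-breaks
.sort_group <- function(ex) {
  if (ex$strand[1L] == "+") setorder(ex, SC, ET, exon_id)
  else setorder(ex, -SC, ET, exon_id)
  ex
}

#' Best compatible exon set for one (contig, strand, target) group
#'
#' Dynamic program over exons sorted by contig start (translation
#' order): the best chain ending at exon j extends a compatible
#' predecessor chain, paying the target-gap penalty and collecting the
#' ordering reward `log2(k+1)`. Because that reward depends on the
#' chain length, the state is layered over the exon count, which keeps
#' the recursion exactly equal to exhaustive enumeration over
#' compatible subsets. The optimum is recovered by backtracing from the
#' maximal entry. Ties prefer the earlier predecessor and, for the
#' global maximum, the chain whose first exon comes earliest in
#' translation order.
#'
#' @param exons exon data.table for a single group.
#' @param D database size for the E-value.
#' @param min_intron,max_intron,max_target_overlap compatibility bounds.
#' @return list: `call` (1-row data.table) and `exons` (member exons
#'   with exon_rank in translation order), or `NULL` when the group is
#'   empty.
#' @export
best_exon_set <- function(exons, D, min_intron = 15L, max_intron = 10000L,
                          max_target_overlap = 10L) {
  if (nrow(exons) == 0L) return(NULL)
  stopifnot(length(unique(exons$contig_id)) == 1L,
            length(unique(exons$strand)) == 1L,
            length(unique(exons$target_id)) == 1L)
  ex <- .sort_group(copy(exons))
  minus <- ex$strand[1L] == "-"
  dp <- .chain_exons_cpp(ex$SC, ex$EC, ex$ST, ex$ET, ex$bits, minus,
                         as.integer(min_intron), as.integer(max_intron),
                         as.integer(max_target_overlap))
  path <- dp$path
  members <- ex[path]
  members[, exon_rank := seq_len(.N)]
  S_set <- dp$S_set
  call <- data.table(
    contig_id = ex$contig_id[1L], strand = ex$strand[1L],
    target_id = ex$target_id[1L], n_exons = length(path),
    S_set = S_set, evalue = call_evalue(S_set, D),
    span_start = min(members$nt_start), span_end = max(members$nt_end))
  list(call = call, exons = members)
}

#' Join putative exons into gene calls
#'
#' Runs [best_exon_set()] for every (contig, strand, target) group, so
#' at most one call is produced per group. The call's protein is the
#' concatenation of the aligned fragment segments in translation order;
#' `tcov` is its length divided by the target length.
#'
#' @param exons data.table from [build_putative_exons()].
#' @param fragments data.table from [extract_fragments()] (provides the
#'   amino-acid segments).
#' @param ref [reference_db()] object.
#' @param min_intron,max_intron,max_target_overlap compatibility bounds.
#' @return object of class `gene_calls`: list with `calls` (one row per
#'   call: call_id, contig_id, strand, target_id, n_exons, S_set,
#'   evalue, span_start, span_end, protein, target_len, tcov) and
#'   `exons` (call members with exon_rank).
#' @export
join_exons <- function(exons, fragments, ref, min_intron = 15L,
                       max_intron = 10000L, max_target_overlap = 10L) {
  frag_seq <- setNames(fragments$aa_seq, fragments$fragment_id)
  empty <- structure(list(
    calls = data.table(call_id = integer(), contig_id = character(),
                       strand = character(), target_id = character(),
                       n_exons = integer(), S_set = numeric(),
                       evalue = numeric(), span_start = integer(),
                       span_end = integer(), protein = character(),
                       target_len = integer(), tcov = numeric()),
    exons = data.table(call_id = integer(), exon_rank = integer(),
                       exon_id = character(), contig_id = character(),
                       strand = character(), target_id = character(),
                       SC = integer(), EC = integer(), ST = integer(),
                       ET = integer(), bits = numeric(), e_value = numeric(),
                       aa_len = integer(), qstart = integer(),
                       qend = integer(), nt_start = integer(),
                       nt_end = integer())),
    class = "gene_calls")
  if (nrow(exons) == 0L) return(empty)
  groups <- split(exons,
                  by = c("contig_id", "strand", "target_id"), drop = TRUE)
  # deterministic group order
  groups <- groups[order(names(groups))]
  calls_l <- vector("list", length(groups))
  exons_l <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    res <- best_exon_set(groups[[g]], ref$D, min_intron, max_intron,
                         max_target_overlap)
    res$call[, call_id := g]
    res$exons[, call_id := g]
    calls_l[[g]] <- res$call
    exons_l[[g]] <- res$exons
  }
  calls <- rbindlist(calls_l)
  cexons <- rbindlist(exons_l)
  prot <- cexons[, .(protein = paste(substring(frag_seq[exon_id],
                                               qstart + 1L, qend),
                                     collapse = "")),
                 by = call_id]
  calls <- merge(calls, prot, by = "call_id", sort = FALSE)
  calls[, target_len := unname(ref$lengths[target_id])]
  calls[, tcov := nchar(protein) / target_len]
  setcolorder(cexons, c("call_id", "exon_rank"))
  setorder(calls, call_id)
  structure(list(calls = calls[], exons = cexons[]), class = "gene_calls")
}

#' @export
print.gene_calls <- function(x, ...) {
  cat(sprintf("gene_calls: %d calls (%d exon assignments)\n",
              nrow(x$calls), nrow(x$exons)))
  invisible(x)
}

#' Filter gene calls by E-value and target coverage
#'
#' Retains calls with `evalue <= max_call_evalue` (default 1e-4) and
#' predicted-protein-length / target-length at least `min_tcov`
#' (default 0.6).
#'
#' @param calls `gene_calls` object from [join_exons()].
#' @param max_call_evalue maximal gene-call E-value.
#' @param min_tcov minimal target coverage ratio (0 disables).
#' @return filtered `gene_calls` object.
#' @export
filter_calls <- function(calls, max_call_evalue = 1e-4, min_tcov = 0.6) {
  keep <- calls$calls[evalue <= max_call_evalue & tcov >= min_tcov, call_id]
  structure(list(calls = calls$calls[call_id %in% keep],
                 exons = calls$exons[call_id %in% keep]),
            class = "gene_calls")
}
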