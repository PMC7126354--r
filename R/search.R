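# Stage 2: local protein alignments between fragments and reference
# targets, with Karlin-Altschul bit-scores and E-values, plus a BLAST
# tabular (m8) adapter for externally computed hits.

#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under affine gap costs. The traceback is
#' deterministic (diagonal preferred over vertical over horizontal).
#' Coordinates are 0-based half-open on both sequences.
#'
#' @param query,target amino-acid strings (characters outside the
#'   matrix alphabet score as `X`).
#' @param params scoring parameters from [score_params()].
#' @return list: raw, bits, qstart, qend, tstart, tend, alnlen, matches,
#'   mismatches, gapopens, identity (matches / alignment columns).
#' @export
sw_align <- function(query, target, params = score_params()) {
  .assert_scalar_string(query, "query")
  .assert_scalar_string(target, "target")
  r <- .sw_pair_cpp(query, target, params$matrix, params$alphabet,
                    params$gap_open, params$gap_extend)
  r$bits <- .bits_from_raw(r$raw, params)
  r$identity <- if (r$alnlen > 0) r$matches / r$alnlen else 0
  r
}

.empty_hits <- function() {
  data.table(fragment_id = character(), target_id = character(),
             qstart = integer(), qend = integer(), tstart = integer(),
             tend = integer(), raw = integer(), bits = numeric(),
             evalue = numeric(), alnlen = integer(), matches = integer(),
             mismatches = integer(), gapopens = integer(),
             identity = numeric())
}

#' Search fragments against a reference database
#'
#' Smith-Waterman of fragments against targets (one best local
#' alignment per pair). A hit is reported when its E-value
#' `K * m * D * exp(-lambda * raw)` (m = fragment length, D = database
#' size in amino acids) is at most `max_exon_evalue`; the default 100 is
#' deliberately lenient because sub-significant exons can combine into
#' significant multi-exon calls.
#'
#' That leniency is calibrated to a staged search: candidate pairs must
#' first share one exact amino-acid k-mer (`prefilter_kmer`, default 5),
#' the analog of the k-mer prefilter of fast protein search tools.
#' Without it, a lenient E-value against a small database admits a large
#' fraction of all random fragment-target pairs and pure-noise exon
#' chains overwhelm the joining stage. Set `prefilter_kmer = 0` for the
#' exhaustive all-vs-all mode.
#'
#' @param fragments data.table from [extract_fragments()].
#' @param ref [reference_db()] object.
#' @param max_exon_evalue maximal per-exon E-value (default 100).
#' @param params scoring parameters from [score_params()].
#' @param prefilter_kmer length of the shared-k-mer prefilter
#'   (0 disables).
#' @return hits data.table: fragment_id, target_id, qstart, qend,
#'   tstart, tend (0-based half-open), raw, bits, evalue, alnlen,
#'   matches, mismatches, gapopens, identity.
#' @export
search_fragments <- function(fragments, ref, max_exon_evalue = 100,
                             params = score_params(), prefilter_kmer = 5L) {
  stopifnot(inherits(ref, "reference_db"), max_exon_evalue > 0)
  if (nrow(fragments) == 0L) return(.empty_hits())
  m <- nchar(fragments$aa_seq)
  # minimal raw score implied by the E-value cutoff (per fragment length)
  min_raw <- ceiling((log(params$K * m * ref$D) - log(max_exon_evalue)) /
                       params$lambda)
  h <- as.data.table(.sw_search_cpp(
    fragments$aa_seq, as.character(ref$targets), params$matrix,
    params$alphabet, params$gap_open, params$gap_extend,
    as.numeric(min_raw), as.integer(prefilter_kmer)))
  if (nrow(h) == 0L) return(.empty_hits())
  h[, fragment_id := fragments$fragment_id[qi]]
  h[, target_id := names(ref$targets)[ti]]
  h[, bits := .bits_from_raw(raw, params)]
  h[, evalue := .hit_evalue(raw, nchar(fragments$aa_seq)[qi], ref$D, params)]
  h <- h[evalue <= max_exon_evalue]
  h[, identity := matches / alnlen]
  h[, c("qi", "ti") := NULL]
  setcolorder(h, c("fragment_id", "target_id", "qstart", "qend", "tstart",
                   "tend", "raw", "bits", "evalue", "alnlen", "matches",
                   "mismatches", "gapopens", "identity"))
  setorder(h, fragment_id, target_id)
  h[]
}

#' Export hits in BLAST tabular (m8) format
#'
#' Columns: query, target, percent identity, alignment length,
#' mismatches, gap openings, qstart, qend, tstart, tend (1-based
#' inclusive), E-value, bit-score.
#'
#' @param hits hits data.table from [search_fragments()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_hits_m8 <- function(hits, path) {
  m8 <- hits[, .(fragment_id, target_id,
                 pident = sprintf("%.3f", 100 * identity),
                 alnlen, mismatches, gapopens,
                 qstart = qstart + 1L, qend = qend,
                 tstart = tstart + 1L, tend = tend,
                 evalue = sprintf("%.6e", evalue),
                 bits = sprintf("%.6f", bits))]
  fwrite(m8, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Import hits from BLAST tabular (m8) format
#'
#' Adapter so an external search tool (BLAST, MMseqs2) can replace the
#' built-in search at scale; query ids must equal fragment ids.
#' Coordinates are converted from the 1-based inclusive m8 convention to
#' internal half-open coordinates; bit-scores are taken as given.
#'
#' @param path m8 file (12 or more tab-separated columns).
#' @param fragments data.table from [extract_fragments()].
#' @param ref [reference_db()] object.
#' @return hits data.table as from [search_fragments()] (`raw` is `NA`
#'   for imported hits; `matches` is derived from identity and alignment
#'   length).
#' @export
import_hits_m8 <- function(path, fragments, ref) {
  h <- fread(path, header = FALSE, sep = "\t")
  if (ncol(h) < 12L) stop("m8 file needs at least 12 columns", call. = FALSE)
  h <- h[, 1:12]
  setnames(h, c("fragment_id", "target_id", "pident", "alnlen", "mismatches",
                "gapopens", "qstart", "qend", "tstart", "tend", "evalue",
                "bits"))
  bad <- setdiff(h$fragment_id, fragments$fragment_id)
  if (length(bad)) stop("m8 hit names unknown fragment: ", bad[1L], call. = FALSE)
  bad <- setdiff(h$target_id, names(ref$targets))
  if (length(bad)) stop("m8 hit names unknown target: ", bad[1L], call. = FALSE)
  if (any(h$qstart > h$qend) || any(h$tstart > h$tend))
    stop("reversed m8 coordinates are not supported", call. = FALSE)
  h[, `:=`(qstart = qstart - 1L, tstart = tstart - 1L,
           identity = pident / 100, raw = NA_integer_)]
  h[, matches := as.integer(round(identity * alnlen))]
  h[, pident := NULL]
  setcolorder(h, c("fragment_id", "target_id", "qstart", "qend", "tstart",
                   "tend", "raw", "bits", "evalue", "alnlen", "matches",
                   "mismatches", "gapopens", "identity"))
  setorder(h, fragment_id, target_id)
  h[]
}
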