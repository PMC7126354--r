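# Stage 1: six-frame extraction of stop-free putative protein fragments.

#' Extract six-frame translated fragments from contigs
#'
#' Every contig is scanned on both strands in all three frames; maximal
#' stop-free stretches of at least `min_fragment_aa` residues are
#' emitted. Stop codons are excluded from fragments; stretches abutting
#' contig ends (no bounding stop codon) are kept; trailing partial
#' codons are discarded. Minus-strand fragments are translated from the
#' reverse complement, with `contig_start`/`contig_end` reported as
#' plus-strand, 0-based, half-open coordinates. Codons containing a
#' non-ACGT base translate to `X`.
#'
#' Fragment identifiers are `"<contig>|<strand>|<frame>|<contig_start>"`
#' and double as exon identifiers downstream.
#'
#' @param contigs named `DNAStringSet` (or named character vector).
#' @param genetic_code NCBI genetic code id, default `"1"` (standard).
#' @param min_fragment_aa minimal fragment length in amino acids
#'   (default 20, i.e. `--min-length 20`).
#' @return data.table: fragment_id, contig_id, strand, frame, aa_seq,
#'   contig_start, contig_end, aa_len, inverted.
#' @export
extract_fragments <- function(contigs, genetic_code = "1",
                              min_fragment_aa = 20L) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  stopifnot(min_fragment_aa >= 1L)
  code <- Biostrings::getGeneticCode(genetic_code)  # errors on unknown id
  out <- vector("list", 6L * length(contigs))
  n <- 0L
  for (ci in seq_along(contigs)) {
    cid <- names(contigs)[ci]
    len <- Biostrings::width(contigs)[ci]
    if (len < 3L) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") contigs[[ci]]
           else Biostrings::reverseComplement(contigs[[ci]])
      for (frame in 0:2) {
        ncod <- (len - frame) %/% 3L
        if (ncod < 1L) next
        aa <- as.character(Biostrings::translate(
          Biostrings::subseq(s, frame + 1L, frame + 3L * ncod),
          genetic.code = code, if.fuzzy.codon = "X", no.init.codon = TRUE))
        runs <- gregexpr("[^*]+", aa)[[1L]]
        if (runs[1L] == -1L) next
        rl <- attr(runs, "match.length")
        keep <- rl >= min_fragment_aa
        if (!any(keep)) next
        p <- as.integer(runs[keep]); rl <- rl[keep]
        # strand-local nt span, then plus-strand coordinates
        ls <- frame + 3L * (p - 1L)
        le <- ls + 3L * rl
        if (strand == "+") {
          cs <- ls; ce <- le
        } else {
          cs <- len - le; ce <- len - ls
        }
        n <- n + 1L
        out[[n]] <- data.table(
          fragment_id = sprintf("%s|%s|%d|%d", cid, strand, frame, cs),
          contig_id = cid, strand = strand, frame = frame,
          aa_seq = substring(aa, p, p + rl - 1L),
          contig_start = cs, contig_end = ce, aa_len = rl)
      }
    }
  }
  frags <- if (n) rbindlist(out[seq_len(n)]) else data.table(
    fragment_id = character(), contig_id = character(), strand = character(),
    frame = integer(), aa_seq = character(), contig_start = integer(),
    contig_end = integer(), aa_len = integer())
  frags[, inverted := FALSE]
  setorder(frags, contig_id, strand, frame, contig_start)
  frags[]
}

#' Invert fragment sequences (null model)
#'
#' Character-reverses every fragment's amino-acid sequence (no
#' complementation) and flags the fragments as inverted; identifiers and
#' coordinates are retained. Running the full pipeline on inverted
#' fragments gives an annotation-free false-positive estimate, since any
#' resulting prediction is spurious by construction.
#'
#' @param fragments data.table from [extract_fragments()].
#' @return data.table of the same shape with reversed `aa_seq` and
#'   `inverted = TRUE`.
#' @export
invert_fragments <- function(fragments) {
  inv <- copy(fragments)
  inv[, aa_seq := .revstr(aa_seq)]
  inv[, inverted := !inverted]
  inv[]
}

#' Export fragments to FASTA
#'
#' Headers carry strand, frame and plus-strand coordinates so external
#' search tools can consume the fragments.
#'
#' @param fragments data.table from [extract_fragments()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
fragments_to_fasta <- function(fragments, path) {
  write_fasta(setNames(fragments$aa_seq, fragments$fragment_id), path)
}
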