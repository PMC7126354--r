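# FASTA / GFF3 input and output, and the coordinate conventions every
# other module follows.
#
# Conventions: internal coordinates are 0-based, half-open, always on the
# plus strand of the contig; GFF3 output is 1-based inclusive. 'N' is
# permitted in contigs; any codon containing a non-ACGT base translates
# to 'X'.

#' Read a FASTA file of contigs or proteins
#'
#' Records are returned in file order as a `DNAStringSet` (nucleotide
#' mode) or `AAStringSet` (amino-acid mode) named by the identifier
#' (first whitespace-separated token); the remainder of each header is
#' kept in `mcols(x)$desc`.
#'
#' @param path FASTA file.
#' @param type `"nt"` for contigs (alphabet ACGTN) or `"aa"` for
#'   proteins.
#' @return named `DNAStringSet` or `AAStringSet`.
#' @export
read_fasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  .assert_scalar_string(path, "path")
  raw <- Biostrings::readBStringSet(path)  # permissive read, then validate
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- names(raw)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(Biostrings::width(raw) == 0L))
    stop("zero-length FASTA record in ", path, call. = FALSE)
  seqs <- toupper(as.character(raw))
  pat <- if (type == "nt") "[^ACGTN]" else "[^ARNDCQEGHILKMFPSTWYVBJZXUO*]"
  bad <- regmatches(seqs, regexpr(pat, seqs))
  if (length(bad))
    stop("illegal ", if (type == "nt") "nucleotide" else "amino-acid",
         " character '", bad[1L], "' in ", path, call. = FALSE)
  x <- if (type == "nt") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  names(x) <- ids
  S4Vectors::mcols(x)$desc <- desc
  x
}

#' Write sequences to FASTA
#'
#' Deterministic output: records in input order, sequence wrapped at 60
#' columns.
#'
#' @param x named `XStringSet` or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all records must be named", call. = FALSE)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Build a reference database from target proteins
#'
#' Carries the targets plus `D`, the total number of amino acids in the
#' database, which scales gene-call E-values. Trailing stop symbols are
#' stripped; internal stops are an error.
#'
#' @param targets named `AAStringSet` or named character vector of
#'   target proteins.
#' @return object of class `reference_db`: list with `targets`
#'   (`AAStringSet`), `D` (total aa count) and `lengths` (named integer).
#' @export
reference_db <- function(targets) {
  if (is.character(targets)) targets <- Biostrings::AAStringSet(targets)
  if (length(targets) == 0L) stop("empty reference database", call. = FALSE)
  if (is.null(names(targets)) || anyDuplicated(names(targets)))
    stop("targets must carry unique names", call. = FALSE)
  seqs <- as.character(targets)
  seqs <- sub("\\*+$", "", seqs)
  if (any(grepl("*", seqs, fixed = TRUE)))
    stop("internal stop symbol in target protein", call. = FALSE)
  if (any(!nzchar(seqs))) stop("zero-length target protein", call. = FALSE)
  targets <- Biostrings::AAStringSet(setNames(seqs, names(targets)))
  lens <- setNames(Biostrings::width(targets), names(targets))
  structure(list(targets = targets, D = sum(as.numeric(lens)),
                 lengths = lens),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d targets, D = %.0f amino acids\n",
              length(x$targets), x$D))
  invisible(x)
}

#' Read gene annotations from GFF3
#'
#' Groups CDS features per gene (via their mRNA parents where present)
#' and converts coordinates to the internal convention (0-based,
#' half-open, plus strand). Optionally attaches annotated protein
#' sequences keyed by gene id.
#'
#' @param path GFF3 file with gene/mRNA/CDS features.
#' @param proteins optional named `AAStringSet` (or FASTA path) of the
#'   annotated proteins, named by gene id.
#' @return list of class `annotation_set`: `genes` (data.table: gene_id,
#'   contig_id, strand, span_start, span_end, n_exons), `cds`
#'   (data.table: gene_id, contig_id, strand, start0, end0, sorted), and
#'   `proteins` (`AAStringSet` or NULL).
#' @export
read_gff3 <- function(path, proteins = NULL) {
  .assert_scalar_string(path, "path")
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(structure(list(
      genes = data.table(gene_id = character(), contig_id = character(),
                         strand = character(), span_start = integer(),
                         span_end = integer(), n_exons = integer()),
      cds = data.table(gene_id = character(), contig_id = character(),
                       strand = character(), start0 = integer(),
                       end0 = integer()),
      proteins = NULL), class = "annotation_set"))
  }
  dt <- as.data.table(as.data.frame(gr))
  if (!"type" %in% names(dt)) stop("GFF3 without feature types", call. = FALSE)
  # map feature ID -> parent for resolving CDS -> mRNA -> gene
  ids <- if ("ID" %in% names(dt)) as.character(dt$ID) else rep(NA_character_, nrow(dt))
  parent_of <- function(p) {
    if (is.null(p) || length(p) == 0L) NA_character_ else as.character(p)[1L]
  }
  parents <- if ("Parent" %in% names(dt))
    vapply(dt$Parent, parent_of, character(1)) else rep(NA_character_, nrow(dt))
  type <- as.character(dt$type)
  gene_rows <- which(type == "gene")
  id2row <- setNames(seq_len(nrow(dt)), ids)
  resolve_gene <- function(par) {
    seen <- 0L
    while (!is.na(par) && par %in% names(id2row) && seen < 5L) {
      r <- id2row[[par]]
      if (type[r] == "gene") return(ids[r])
      par <- parents[r]
      seen <- seen + 1L
    }
    NA_character_
  }
  cds_rows <- which(type == "CDS")
  if (length(cds_rows) == 0L) stop("no CDS features in ", path, call. = FALSE)
  gene_ids <- vapply(parents[cds_rows], resolve_gene, character(1))
  if (anyNA(gene_ids))
    stop("CDS feature without resolvable gene parent in ", path, call. = FALSE)
  cds <- data.table(gene_id = gene_ids,
                    contig_id = as.character(dt$seqnames[cds_rows]),
                    strand = as.character(dt$strand[cds_rows]),
                    start0 = dt$start[cds_rows] - 1L,
                    end0 = dt$end[cds_rows])
  if (any(cds$end0 <= cds$start0))
    stop("malformed CDS coordinates (start > end)", call. = FALSE)
  setorder(cds, gene_id, start0)
  ov <- cds[, any(start0[-1L] < end0[-.N]), by = gene_id]$V1
  if (any(ov)) stop("overlapping CDS intervals within a gene", call. = FALSE)
  genes <- cds[, .(contig_id = contig_id[1L], strand = strand[1L],
                   span_start = min(start0), span_end = max(end0),
                   n_exons = .N), by = gene_id]
  setorder(genes, contig_id, span_start)
  if (!is.null(proteins)) {
    if (is.character(proteins) && length(proteins) == 1L)
      proteins <- read_fasta(proteins, "aa")
    missing <- setdiff(genes$gene_id, names(proteins))
    if (length(missing))
      stop("no protein sequence for gene(s): ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(genes = genes, cds = cds, proteins = proteins),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d CDS intervals\n",
              nrow(x$genes), nrow(x$cds)))
  invisible(x)
}

# 9-column GFF3 line formatter (1-based inclusive output coordinates)
.gff3_line <- function(seqid, source, type, start0, end0, score, strand,
                       phase, attrs) {
  paste(seqid, source, type, start0 + 1L, end0, score, strand, phase, attrs,
        sep = "\t")
}

#' Write predictions to GFF3 plus protein and codon FASTA
#'
#' One `gene` feature and one `CDS` feature per exon are written per
#' prediction. FASTA headers are pipe-delimited:
#' `target|contig|strand|score|evalue|n_exons` followed by per-exon
#' `[nt_start,nt_end)` contig coordinates in translation order. The
#' codon FASTA concatenates the exon nucleotide segments in translation
#' order (minus-strand segments reverse-complemented); the protein FASTA
#' is its translation.
#'
#' @param predictions a `gene_calls` object (see [join_exons()]),
#'   typically after [resolve_overlaps()].
#' @param contigs named `DNAStringSet` the predictions refer to.
#' @param gff3,protein_fasta,codon_fasta output paths (`NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_predictions <- function(predictions, contigs, gff3 = NULL,
                              protein_fasta = NULL, codon_fasta = NULL) {
  calls <- copy(predictions$calls)
  exons <- predictions$exons
  if (nrow(calls)) {
    unknown <- setdiff(unique(calls$contig_id), names(contigs))
    if (length(unknown))
      stop("prediction references unknown contig: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    setorder(calls, contig_id, span_start, span_end, target_id)
  }
  headers <- character(nrow(calls))
  codons <- character(nrow(calls))
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i]
    ex <- exons[call_id == cl$call_id][order(exon_rank)]
    attrs_id <- sprintf("%s_%s_%s_%d", cl$target_id, cl$contig_id,
                        ifelse(cl$strand == "+", "plus", "minus"),
                        cl$span_start)
    lines <- c(lines, .gff3_line(
      cl$contig_id, "splicecall", "gene", cl$span_start, cl$span_end,
      sprintf("%.3g", cl$evalue), cl$strand, ".",
      sprintf("ID=%s;target=%s;bitscore=%.2f;evalue=%.3g;n_exons=%d",
              attrs_id, cl$target_id, cl$S_set, cl$evalue, cl$n_exons)))
    ex_by_pos <- ex[order(nt_start)]
    for (j in seq_len(nrow(ex_by_pos))) {
      e <- ex_by_pos[j]
      lines <- c(lines, .gff3_line(
        cl$contig_id, "splicecall", "CDS", e$nt_start, e$nt_end,
        sprintf("%.2f", e$bits), cl$strand, ".",
        sprintf("ID=%s.cds%d;Parent=%s;exon_id=%s", attrs_id, j, attrs_id,
                e$exon_id)))
    }
    coords <- paste(sprintf("%d-%d", ex$nt_start, ex$nt_end), collapse = "|")
    headers[i] <- sprintf("%s|%s|%s|%.2f|%.3g|%d|%s", cl$target_id,
                          cl$contig_id, cl$strand, cl$S_set, cl$evalue,
                          cl$n_exons, coords)
    if (!is.null(codon_fasta)) {
      segs <- vapply(seq_len(nrow(ex)), function(j) {
        e <- ex[j]
        s <- Biostrings::subseq(contigs[[cl$contig_id]], e$nt_start + 1L,
                                e$nt_end)
        if (cl$strand == "-") s <- Biostrings::reverseComplement(s)
        as.character(s)
      }, character(1))
      codons[i] <- paste(segs, collapse = "")
    }
  }
  out <- list()
  if (!is.null(gff3)) {
    writeLines(lines, gff3)
    out$gff3 <- gff3
  }
  if (!is.null(protein_fasta)) {
    prot <- setNames(if (nrow(calls)) calls$protein else character(), headers)
    if (length(prot)) write_fasta(Biostrings::AAStringSet(prot), protein_fasta)
    else writeLines(character(), protein_fasta)
    out$protein_fasta <- protein_fasta
  }
  if (!is.null(codon_fasta)) {
    cod <- setNames(codons, headers)
    if (length(cod)) write_fasta(Biostrings::DNAStringSet(cod), codon_fasta)
    else writeLines(character(), codon_fasta)
    out$codon_fasta <- codon_fasta
  }
  invisible(out)
}
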