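# Synthetic multi-exon genomes with matched truth annotations and
# divergence-controlled reference proteins, so every pipeline stage and
# the benchmark harness run without downloads.

# Robinson & Robinson amino-acid background frequencies (the composition
# underlying BLOSUM statistics); used to draw random protein sequences.
.aa_background <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

# standard-code codons per amino acid (uniform synonymous choice)
.codon_table <- function() {
  code <- Biostrings::getGeneticCode("1")
  split(names(code), unname(code))
}

#' Synthetic genome configuration
#'
#' The defaults describe a desk-scale benchmark world: 200 multi-exon
#' genes on about 1 Mbp of contigs, exon and intron lengths inside the
#' compatibility window, and strands drawn evenly. Exon counts are
#' uniform on `exon_count_range`; exon lengths uniform on
#' `exon_aa_range`; intron lengths uniform on `intron_range` (which must
#' sit inside [15, 10000] nt, the joinable window).
#'
#' @param n_genes number of genes to implant.
#' @param genome_bp approximate total genome size; intergenic stretches
#'   are scaled so the contigs sum to this size.
#' @param n_contigs number of contigs to distribute genes over.
#' @param exon_count_range integer range of exons per gene.
#' @param exon_aa_range integer range of exon lengths (aa).
#' @param intron_range integer range of intron lengths (nt).
#' @param strand_prob probability a gene lies on the plus strand.
#' @param decoy_targets number of unrelated decoy proteins added to the
#'   reference database.
#' @param decoy_aa_range length range of decoy proteins (aa).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 200L, genome_bp = 1e6, n_contigs = 5L,
                         exon_count_range = c(2L, 5L),
                         exon_aa_range = c(30L, 150L),
                         intron_range = c(20L, 500L),
                         strand_prob = 0.5,
                         decoy_targets = 20L,
                         decoy_aa_range = c(100L, 400L)) {
  stopifnot(n_genes >= 1L, n_contigs >= 1L, n_genes >= n_contigs,
            exon_count_range[1L] >= 1L,
            exon_aa_range[1L] >= 10L,
            intron_range[1L] >= 15L, intron_range[2L] <= 10000L,
            strand_prob >= 0, strand_prob <= 1)
  structure(list(n_genes = as.integer(n_genes), genome_bp = genome_bp,
                 n_contigs = as.integer(n_contigs),
                 exon_count_range = as.integer(exon_count_range),
                 exon_aa_range = as.integer(exon_aa_range),
                 intron_range = as.integer(intron_range),
                 strand_prob = strand_prob,
                 decoy_targets = as.integer(decoy_targets),
                 decoy_aa_range = as.integer(decoy_aa_range)),
            class = "synth_config")
}

.random_protein <- function(n_aa) {
  paste(sample(names(.aa_background), n_aa, replace = TRUE,
               prob = .aa_background), collapse = "")
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# back-translate a protein with uniform synonymous codon choice
.back_translate <- function(protein, codons) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

# random intron carrying a stop codon in the reading frame that
# continues the upstream exon (phase = CDS nt emitted so far, mod 3),
# so a multi-exon gene cannot surface as one stop-free fragment
.random_intron <- function(len, phase) {
  nt <- .random_nt(len)
  stop_at <- ((3L - phase) %% 3L) + 1L  # 1-based offset of next in-frame codon
  if (stop_at + 2L <= len) {
    substr(nt, stop_at, stop_at + 2L) <- sample(c("TAA", "TAG", "TGA"), 1L)
  }
  nt
}

#' Generate a synthetic genome with implanted multi-exon genes
#'
#' Genes are placed left to right without same-strand overlap (in fact
#' without any overlap), separated by random intergenic stretches sized
#' so the genome reaches `config$genome_bp`. Exon nucleotide sequence is
#' the back-translated protein segment (uniform synonymous codons);
#' introns are random nucleotides carrying an in-frame stop so the
#' dynamic-programming joiner, not single-fragment matching, must
#' recover multi-exon genes. Minus-strand genes are reverse-complemented
#' into the contig. Deterministic given the RNG state.
#'
#' @param config [synth_config()] object.
#' @param seed optional integer seed (set for reproducibility).
#' @return list: `contigs` (`DNAStringSet`), `annotations`
#'   (`annotation_set` with truth CDS intervals), `proteins`
#'   (`AAStringSet` of true proteins, named by gene id).
#' @export
generate_genome <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  codons <- .codon_table()
  genes_per_contig <- diff(round(seq(0, config$n_genes,
                                     length.out = config$n_contigs + 1L)))
  # draw gene structures first so intergenic sizes can fill the budget
  n <- config$n_genes
  exon_counts <- sample(seq(config$exon_count_range[1L],
                            config$exon_count_range[2L]), n, replace = TRUE)
  exon_lens <- lapply(exon_counts, function(k)
    sample(seq(config$exon_aa_range[1L], config$exon_aa_range[2L]), k,
           replace = TRUE))
  intron_lens <- lapply(exon_counts, function(k)
    if (k > 1L) sample(seq(config$intron_range[1L], config$intron_range[2L]),
                       k - 1L, replace = TRUE) else integer())
  strands <- ifelse(runif(n) < config$strand_prob, "+", "-")
  gene_bp <- vapply(seq_len(n), function(i)
    3L * sum(exon_lens[[i]]) + sum(intron_lens[[i]]), numeric(1))
  n_gaps <- n + config$n_contigs  # one gap before and after genes per contig
  spare <- config$genome_bp - sum(gene_bp)
  if (spare < 50 * n_gaps)
    stop("genome_bp too small for the requested genes", call. = FALSE)
  gap_w <- runif(n_gaps, 0.5, 1.5)
  gap_lens <- pmax(30L, as.integer(round(spare * gap_w / sum(gap_w))))

  contig_seqs <- character(config$n_contigs)
  cds_l <- list(); prot <- character(); prot_ids <- character()
  gi <- 0L; gap_i <- 0L
  for (ci in seq_len(config$n_contigs)) {
    cid <- sprintf("ctg%02d", ci)
    parts <- character(); pos <- 0L
    for (g in seq_len(genes_per_contig[ci])) {
      gi <- gi + 1L; gap_i <- gap_i + 1L
      parts <- c(parts, .random_nt(gap_lens[gap_i]))
      pos <- pos + gap_lens[gap_i]
      gene_id <- sprintf("gene%03d", gi)
      k <- exon_counts[gi]
      p <- .random_protein(sum(exon_lens[[gi]]))
      segs <- character(2L * k - 1L)
      offs <- cumsum(c(0L, exon_lens[[gi]]))
      local_cds <- matrix(0L, nrow = k, ncol = 2L)  # gene-local [start,end)
      lpos <- 0L
      for (e in seq_len(k)) {
        aa_seg <- substring(p, offs[e] + 1L, offs[e + 1L])
        nt_seg <- .back_translate(aa_seg, codons)
        segs[2L * e - 1L] <- nt_seg
        local_cds[e, ] <- c(lpos, lpos + nchar(nt_seg))
        lpos <- lpos + nchar(nt_seg)
        if (e < k) {
          il <- intron_lens[[gi]][e]
          # exons are whole codons, so the continuing frame has phase 0
          segs[2L * e] <- .random_intron(il, 0L)
          lpos <- lpos + il
        }
      }
      gene_nt <- paste(segs, collapse = "")
      glen <- nchar(gene_nt)
      if (strands[gi] == "-") {
        gene_nt <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(gene_nt)))
        local_cds <- cbind(glen - local_cds[, 2L], glen - local_cds[, 1L])
      }
      cds_l[[gi]] <- data.table(
        gene_id = gene_id, contig_id = cid, strand = strands[gi],
        start0 = pos + local_cds[, 1L], end0 = pos + local_cds[, 2L])
      prot <- c(prot, p); prot_ids <- c(prot_ids, gene_id)
      parts <- c(parts, gene_nt)
      pos <- pos + glen
    }
    gap_i <- gap_i + 1L
    parts <- c(parts, .random_nt(gap_lens[gap_i]))
    contig_seqs[ci] <- paste(parts, collapse = "")
  }
  contigs <- Biostrings::DNAStringSet(setNames(contig_seqs,
                                               sprintf("ctg%02d",
                                                       seq_len(config$n_contigs))))
  cds <- rbindlist(cds_l)
  setorder(cds, gene_id, start0)
  genes <- cds[, .(contig_id = contig_id[1L], strand = strand[1L],
                   span_start = min(start0), span_end = max(end0),
                   n_exons = .N), by = gene_id]
  setorder(genes, contig_id, span_start)
  proteins <- Biostrings::AAStringSet(setNames(prot, prot_ids))
  annotations <- structure(list(genes = genes, cds = cds,
                                proteins = proteins),
                           class = "annotation_set")
  list(contigs = contigs, annotations = annotations, proteins = proteins)
}

#' Diverge proteins into a reference database
#'
#' Substitutes each site independently with probability `divergence`;
#' the replacement residue is drawn among the other 19 amino acids with
#' weight `exp(BLOSUM62[a, b] / 2)`, so substitutions follow plausible
#' exchange preferences rather than a uniform choice. The realized
#' identity is reported per protein.
#'
#' @param proteins named `AAStringSet` or named character vector.
#' @param divergence per-site substitution probability in \[0, 1\].
#' @param suffix appended to sequence names (default `"_ref"`), so
#'   target ids differ from gene ids.
#' @return list: `targets` (named character), `realized_identity`
#'   (named numeric).
#' @export
diverge_proteins <- function(proteins, divergence, suffix = "_ref") {
  stopifnot(divergence >= 0, divergence <= 1)
  if (!is.character(proteins)) proteins <- as.character(proteins)
  b <- .blosum62()
  aas <- names(.aa_background)
  wts <- lapply(setNames(aas, aas), function(a) {
    w <- exp(b[a, aas] / 2)
    w[a] <- 0
    w / sum(w)
  })
  out <- character(length(proteins))
  ident <- numeric(length(proteins))
  for (i in seq_along(proteins)) {
    aa <- strsplit(proteins[[i]], "")[[1]]
    hit <- which(runif(length(aa)) < divergence)
    for (j in hit) {
      a <- aa[j]
      if (a %in% aas) aa[j] <- sample(aas, 1L, prob = wts[[a]])
    }
    out[i] <- paste(aa, collapse = "")
    ident[i] <- 1 - length(hit) / length(aa)
  }
  names(out) <- paste0(names(proteins), suffix)
  names(ident) <- names(out)
  list(targets = out, realized_identity = ident)
}

#' Random decoy proteins
#'
#' Background-composition proteins with no ancestry to any implanted
#' gene; at default cutoffs they should attract (next to) no gene calls.
#'
#' @param n number of decoys.
#' @param aa_range length range in amino acids.
#' @return named character vector (`decoy001`, ...).
#' @export
decoy_proteins <- function(n, aa_range = c(100L, 400L)) {
  if (n == 0L) return(setNames(character(), character()))
  lens <- sample(seq(aa_range[1L], aa_range[2L]), n, replace = TRUE)
  setNames(vapply(lens, .random_protein, character(1)),
           sprintf("decoy%03d", seq_len(n)))
}

#' Build a synthetic benchmark world
#'
#' One call produces contigs, truth annotations, and a reference
#' database of diverged true proteins plus decoys.
#'
#' @param config [synth_config()] object.
#' @param divergence per-site substitution rate for the reference
#'   targets (default 0.2).
#' @param seed integer seed driving all randomness.
#' @return list: `contigs`, `annotations`, `proteins`, `ref`
#'   (`reference_db`), `realized_identity`.
#' @export
synth_world <- function(config = synth_config(), divergence = 0.2,
                        seed = 1L) {
  set.seed(seed)
  gen <- generate_genome(config)
  div <- diverge_proteins(gen$proteins, divergence)
  decoys <- decoy_proteins(config$decoy_targets, config$decoy_aa_range)
  ref <- reference_db(c(div$targets, decoys))
  c(gen, list(ref = ref, realized_identity = div$realized_identity))
}
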