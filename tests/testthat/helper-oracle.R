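# Independent oracles, deliberately implemented apart from the package
# internals (plain R, no shared code paths with src/).

.oracle_blosum <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Brute-force local alignment score by enumeration of all monotone
# matchings of residue pairs (aligned pairs may mismatch; unmatched
# residues between consecutive pairs are charged as affine gaps:
# open + extend * length per side). Exact for tiny sequences.
oracle_sw_score <- function(q, t, go = 11, ge = 1, mat = .oracle_blosum) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  best <- 0
  recurse <- function(pi, pj, score) {
    if (pi >= n || pj >= m) return(invisible(NULL))
    for (i in (pi + 1):n) {
      for (j in (pj + 1):m) {
        add <- mat[qs[i], ts[j]]
        if (pi > 0) {
          di <- i - pi - 1L; dj <- j - pj - 1L
          if (di > 0) add <- add - (go + ge * di)
          if (dj > 0) add <- add - (go + ge * dj)
        }
        s2 <- score + add
        if (s2 > best) best <<- s2
        recurse(i, j, s2)
      }
    }
  }
  recurse(0L, 0L, 0)
  best
}

# Exhaustive best compatible exon subset (independent re-statement of
# the compatibility conditions and the composite score). Pairwise
# predicates are precomputed so the 2^n subset sweep stays fast.
oracle_best_subset <- function(ex, min_intron = 15, max_intron = 10000,
                               max_overlap = 10) {
  n <- nrow(ex)
  minus <- ex$strand[1] == "-"
  ST <- ex$ST; ET <- ex$ET; SC <- ex$SC; EC <- ex$EC; bits <- ex$bits
  ok <- matrix(FALSE, n, n)
  pen <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || ST[i] >= ST[j]) next
    if (ST[j] - ET[i] < -max_overlap) next
    g <- if (!minus) {
      if (SC[i] >= SC[j]) next
      SC[j] - EC[i]
    } else {
      if (SC[i] <= SC[j]) next
      EC[i] - SC[j]
    }
    if (g < min_intron || g > max_intron) next
    ok[i, j] <- TRUE
    l <- ST[j] - ET[i]
    pen[i, j] <- if (l == 1) 0 else -abs(l)
  }
  sto <- order(ST, ET, ex$exon_id)
  pw <- 2^(seq_len(n) - 1L)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- sto[bitwAnd(mask, pw[sto]) > 0L]
    k <- length(idx)
    sc <- sum(bits[idx]) + lgamma(k + 1) / log(2)
    if (k > 1L) {
      i <- idx[-k]; j <- idx[-1L]
      if (!all(ok[cbind(i, j)])) next
      sc <- sc + sum(pen[cbind(i, j)])
    }
    if (sc > best) best <- sc
  }
  best
}

# Random putative-exon group for the chaining tests: coordinates are
# drawn so that compatible chains exist but are not guaranteed.
random_exon_group <- function(n, strand = sample(c("+", "-"), 1L),
                              contig_len = 30000L) {
  aa <- sample(10:40, n, replace = TRUE)
  ST <- sample(1:150, n, replace = TRUE)
  pos <- sort(sample(seq(0L, contig_len, by = 3L), n))
  if (strand == "+") {
    SC <- pos
    EC <- SC + 3L * aa
  } else {
    SC <- rev(pos) + 3L * aa
    EC <- SC - 3L * aa
  }
  data.table::data.table(
    exon_id = sprintf("f%02d", seq_len(n)), contig_id = "c1",
    strand = strand, target_id = "t1", SC = SC, EC = EC,
    ST = ST, ET = ST + aa - 1L, bits = round(runif(n, 5, 60), 3),
    e_value = 1, aa_len = aa, qstart = 0L, qend = aa,
    nt_start = pmin(SC, EC), nt_end = pmax(SC, EC))
}

# independent six-frame translation of a contig span (for fragment
# verification)
oracle_translate_span <- function(contig_seq, start0, end0, strand) {
  s <- Biostrings::subseq(Biostrings::DNAString(contig_seq), start0 + 1L,
                          end0)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(Biostrings::translate(s, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}
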