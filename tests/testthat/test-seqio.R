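test_that("FASTA round-trip is the identity on random records", {
  set.seed(11)
  n <- 100L
  nt <- vapply(sample(20:200, n, replace = TRUE), function(L)
    paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                 prob = c(rep(0.24, 4), 0.04)), collapse = ""), character(1))
  names(nt) <- sprintf("rec%03d", seq_len(n))
  f <- tempfile(fileext = ".fna")
  write_fasta(nt, f)
  back <- read_fasta(f, "nt")
  expect_identical(names(back), names(nt))
  expect_identical(unname(as.character(back)), unname(nt))

  aa <- vapply(sample(15:120, n, replace = TRUE), function(L)
    paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], L,
                 replace = TRUE), collapse = ""), character(1))
  names(aa) <- sprintf("p%03d", seq_len(n))
  fa <- tempfile(fileext = ".faa")
  write_fasta(aa, fa)
  back <- read_fasta(fa, "aa")
  expect_identical(unname(as.character(back)), unname(aa))
})

test_that("read_fasta validates records", {
  f <- tempfile()
  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), f)
  expect_error(read_fasta(f, "nt"), "duplicate")
  writeLines(c(">c1 some description", "ACGT"), f)
  x <- read_fasta(f, "nt")
  expect_identical(names(x), "c1")
  expect_identical(S4Vectors::mcols(x)$desc, "some description")
  writeLines(c(">c1", "ACGUX"), f)
  expect_error(read_fasta(f, "nt"), "illegal")
  writeLines(character(), f)
  expect_error(read_fasta(f, "nt"), "empty|read")
})

test_that("reference_db computes D and rejects internal stops", {
  ref <- reference_db(c(t1 = "MKLV", t2 = "ACDEFGHIKL*"))
  expect_equal(ref$D, 14)  # trailing stop stripped
  expect_equal(unname(ref$lengths), c(4L, 10L))
  expect_error(reference_db(c(t1 = "MK*LV")), "internal stop")
  expect_error(reference_db(c("MKLV")), "names")
  expect_error(reference_db(character()), "empty")
})

test_that("read_gff3 converts coordinates and groups CDS per gene", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t100\t250\t.\t+\t.\tID=g1",
    "c1\tsrc\tmRNA\t100\t250\t.\t+\t.\tID=g1.t1;Parent=g1",
    "c1\tsrc\tCDS\t100\t150\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
    "c1\tsrc\tCDS\t200\t250\t.\t+\t0\tID=g1.c2;Parent=g1.t1",
    "c1\tsrc\tgene\t400\t500\t.\t-\t.\tID=g2",
    "c1\tsrc\tmRNA\t400\t500\t.\t-\t.\tID=g2.t1;Parent=g2",
    "c1\tsrc\tCDS\t400\t500\t.\t-\t0\tID=g2.c1;Parent=g2.t1"), f)
  ann <- read_gff3(f)
  expect_equal(nrow(ann$genes), 2L)
  g1 <- ann$cds[gene_id == "g1"]
  expect_equal(g1$start0, c(99L, 199L))
  expect_equal(g1$end0, c(150L, 250L))
  g2 <- ann$cds[gene_id == "g2"]
  expect_identical(g2$strand, "-")
  expect_equal(c(g2$start0, g2$end0), c(399L, 500L))

  # header-only file -> empty collection
  writeLines("##gff-version 3", f)
  empty <- read_gff3(f)
  expect_equal(nrow(empty$genes), 0L)

  # CDS without resolvable parent
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t10\t60\t.\t+\t0\tID=x;Parent=nope"), f)
  expect_error(read_gff3(f), "parent")
})

test_that("write_predictions emits GFF3 conventions and strand-aware FASTAs", {
  # contig with a known minus-strand two-exon gene
  set.seed(5)
  prot <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  p1 <- substr(prot, 1, 20); p2 <- substr(prot, 21, nchar(prot))
  cod <- splicecall:::.codon_table()
  nt1 <- splicecall:::.back_translate(p1, cod)
  nt2 <- splicecall:::.back_translate(p2, cod)
  intron <- strrep("T", 60)
  gene <- paste0(nt1, intron, nt2)
  grc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gene)))
  contig <- paste0(strrep("A", 100), grc, strrep("A", 50))
  glen <- nchar(gene)
  # plus-strand coords of the two exons after revcomp (exon 1 is at the
  # high end)
  e2 <- c(100L, 100L + nchar(nt2))                      # second exon (low)
  e1 <- c(100L + nchar(nt2) + 60L, 100L + glen)         # first exon (high)
  calls <- make_calls(list(list(
    contig = "c1", strand = "-", target = "t1",
    exons = list(c(e1[2], e1[1], 1, 20, 50),
                 c(e2[2], e2[1], 21, 33, 40)),
    protein = prot)))
  paths <- list(gff3 = tempfile(), prot = tempfile(), cod = tempfile())
  write_predictions(calls, Biostrings::DNAStringSet(c(c1 = contig)),
                    gff3 = paths$gff3, protein_fasta = paths$prot,
                    codon_fasta = paths$cod)
  lines <- readLines(paths$gff3)
  expect_identical(lines[1], "##gff-version 3")
  cds <- strsplit(grep("\tCDS\t", lines, value = TRUE), "\t")
  # CDS lines in increasing contig coordinate, 1-based inclusive
  starts <- as.integer(vapply(cds, `[`, "", 4L))
  ends <- as.integer(vapply(cds, `[`, "", 5L))
  expect_equal(starts, c(e2[1] + 1L, e1[1] + 1L))
  expect_equal(ends, c(e2[2], e1[2]))
  # codon FASTA translates back to the protein, exons in target order
  codseq <- as.character(read_fasta(paths$cod, "nt"))
  expect_identical(
    as.character(Biostrings::translate(Biostrings::DNAString(codseq))),
    prot)
  protseq <- read_fasta(paths$prot, "aa")
  expect_identical(as.character(protseq)[[1]], prot)
  expect_match(names(protseq), "^t1\\|c1\\|-\\|")

  # single-exon plus-strand convention: internal [300,330) -> 301 330
  one <- make_calls(list(list(contig = "c1", strand = "+", target = "t2",
                              exons = list(c(300, 330, 1, 10, 30)))))
  write_predictions(one, Biostrings::DNAStringSet(c(c1 = contig)),
                    gff3 = paths$gff3)
  cds <- strsplit(grep("\tCDS\t", readLines(paths$gff3), value = TRUE),
                  "\t")[[1]]
  expect_equal(as.integer(cds[4:5]), c(301L, 330L))

  # empty prediction set -> valid header-only GFF3
  empty <- make_calls(list())
  write_predictions(empty, Biostrings::DNAStringSet(c(c1 = contig)),
                    gff3 = paths$gff3, protein_fasta = paths$prot)
  expect_identical(readLines(paths$gff3), "##gff-version 3")
  # unknown contig is an error
  expect_error(
    write_predictions(one, Biostrings::DNAStringSet(c(other = "ACGT")),
                      gff3 = paths$gff3),
    "unknown contig")
})

test_that("internal -> GFF3 -> internal is the identity on intervals", {
  w <- small_world()
  f <- tempfile(fileext = ".gff3")
  splicecall:::.write_truth_gff3(w$annotations, f)
  back <- read_gff3(f)
  a <- w$annotations$cds[order(gene_id, start0),
                         .(gene_id, contig_id, strand, start0, end0)]
  b <- back$cds[order(gene_id, start0),
                .(gene_id, contig_id, strand, start0, end0)]
  expect_equal(a, b, ignore_attr = TRUE)
})
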