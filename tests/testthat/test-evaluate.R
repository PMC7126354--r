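# minimal annotation_set constructor
make_ann <- function(genes) {
  cds_l <- list()
  prot <- character()
  for (g in genes) {
    cds_l[[g$id]] <- data.table::data.table(
      gene_id = g$id, contig_id = g$contig, strand = g$strand,
      start0 = as.integer(vapply(g$cds, `[`, 0, 1L)),
      end0 = as.integer(vapply(g$cds, `[`, 0, 2L)))
    prot[g$id] <- g$protein
  }
  cds <- data.table::rbindlist(cds_l)
  data.table::setorder(cds, gene_id, start0)
  gn <- cds[, .(contig_id = contig_id[1], strand = strand[1],
                span_start = min(start0), span_end = max(end0),
                n_exons = .N), by = gene_id]
  structure(list(genes = gn, cds = cds,
                 proteins = Biostrings::AAStringSet(prot)),
            class = "annotation_set")
}

rand_prot <- function(n) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV",
                                               "")[[1]], n,
                                      replace = TRUE), collapse = "")

test_that("global mapping applies the span and mismatch rules", {
  set.seed(67)
  p <- rand_prot(300)
  ann <- make_ann(list(list(id = "g1", contig = "c1", strand = "+",
                            cds = list(c(150, 1050)), protein = p)))
  # prediction [100,1000): overlap 850 of 900 (94.4%) -> mapped
  pred <- make_calls(list(list(contig = "c1", strand = "+", target = "t",
                               exons = list(c(100, 1000, 1, 300, 200)),
                               protein = p)))
  mp <- map_predictions(pred, ann)
  expect_equal(nrow(mp), 1L)
  expect_equal(mp$frac_pred, 850 / 900)
  expect_equal(mp$mismatch_fraction, 0)

  # 50% span overlap: not mapped regardless of protein identity
  pred50 <- make_calls(list(list(contig = "c1", strand = "+", target = "t",
                                 exons = list(c(600, 1500, 1, 300, 200)),
                                 protein = p)))
  expect_equal(nrow(map_predictions(pred50, ann)), 0L)

  # identical spans but 15% mismatching columns: not mapped
  p2 <- strsplit(p, "")[[1]]
  swap <- sample(300, 45)
  p2[swap] <- vapply(p2[swap], function(a)
    sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], a), 1),
    character(1))
  predmm <- make_calls(list(list(contig = "c1", strand = "+", target = "t",
                                 exons = list(c(150, 1050, 1, 300, 200)),
                                 protein = paste(p2, collapse = ""))))
  expect_equal(nrow(map_predictions(predmm, ann)), 0L)

  # the 80%-of-either rule is symmetric: a short prediction inside a
  # long gene maps through its own span
  short <- make_calls(list(list(contig = "c1", strand = "+", target = "t",
                                exons = list(c(150, 400, 1, 80, 100)),
                                protein = substr(p, 1, 83))))
  mp2 <- map_predictions(short, ann)
  expect_equal(nrow(mp2), 1L)
  expect_lt(mp2$frac_gene, 0.8)
  expect_gte(mp2$frac_pred, 0.8)

  # contig mismatch errors
  annX <- make_ann(list(list(id = "g1", contig = "other", strand = "+",
                             cds = list(c(150, 1050)), protein = p)))
  expect_error(map_predictions(pred, annX), "share no contig")
})

test_that("exon coverage uses the 80% single-exon rule", {
  p <- rand_prot(100)
  ann <- make_ann(list(list(id = "g1", contig = "c1", strand = "+",
                            cds = list(c(100, 200), c(300, 400),
                                       c(500, 600)),
                            protein = p)))
  mk_pred <- function(e2) make_calls(list(list(
    contig = "c1", strand = "+", target = "t",
    exons = list(c(100, 200, 1, 33, 60), c(e2[1], e2[2], 34, 60, 50)),
    protein = p)))
  mp <- data.table::data.table(call_id = 1L, gene_id = "g1",
                               overlap_bp = 100L, frac_pred = 1,
                               frac_gene = 1, mismatch_fraction = 0)
  # [300,380) covers exactly 80% of [300,400)
  cov <- exon_coverage(mp, mk_pred(c(300, 380)), ann)
  expect_equal(cov$per_gene$n_covered, 2L)
  expect_equal(cov$per_gene$fraction, 2 / 3)
  # 79% is not covered
  cov79 <- exon_coverage(mp, mk_pred(c(300, 379)), ann)
  expect_equal(cov79$per_gene$n_covered, 1L)
  expect_equal(cov79$overall, 1 / 3)
})

test_that("precision-recall behaves at the extremes and under transforms", {
  # all predictions true
  pr <- precision_recall(c(1e-9, 1e-7, 1e-5), c(TRUE, TRUE, TRUE))
  expect_equal(pr$auc_pr, 1)
  # single true prediction with the best E-value among 10
  ev <- c(1e-20, sort(runif(9, 1e-6, 1e-4)))
  truth <- c(TRUE, rep(FALSE, 9))
  pr2 <- precision_recall(ev, truth)
  expect_equal(pr2$curve$precision[1], 1)
  # random scores vs labels: AUC-PR approaches prevalence
  set.seed(71)
  n <- 4000
  ev3 <- runif(n)
  lab <- runif(n) < 0.3
  pr3 <- precision_recall(ev3, lab)
  expect_equal(pr3$auc_pr, 0.3, tolerance = 0.05)
  # invariant under strictly monotone transform of the scores
  pr4 <- precision_recall(log10(ev3 + 1), lab)
  expect_equal(pr4$auc_pr, pr3$auc_pr, tolerance = 1e-12)
})

test_that("split-gene rate counts multiply-mapped genes only", {
  expect_equal(split_gene_rate(data.table::data.table(
    call_id = 1:3, gene_id = c("a", "b", "c")))$rate, 0)
  mp <- data.table::data.table(call_id = 1:11,
                               gene_id = c(rep("g1", 2),
                                           sprintf("g%d", 2:10)))
  expect_equal(split_gene_rate(mp)$rate, 0.1)
  # computed on mapped genes only: unmapped genes are not in the table
  expect_equal(nrow(split_gene_rate(mp)$table), 10L)
})

test_that("scaffold fragmentation partitions the scaffold deterministically", {
  set.seed(73)
  scaf <- Biostrings::DNAStringSet(c(
    s1 = paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
               collapse = ""),
    s2 = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")))
  fr <- fragment_scaffolds(scaf, seed = 9L)
  fr2 <- fragment_scaffolds(scaf, seed = 9L)
  expect_identical(as.character(fr$contigs), as.character(fr2$contigs))
  # concatenation reproduces each scaffold; offsets strictly increase
  for (sid in names(scaf)) {
    o <- fr$offsets[scaffold_id == sid]
    expect_equal(o$offset, cumsum(c(0L, head(o$length, -1L))))
    expect_identical(
      paste(as.character(fr$contigs)[o$contig_id], collapse = ""),
      as.character(scaf[[sid]]))
  }
  # scaffold shorter than any sampled length -> one contig
  expect_equal(nrow(fr$offsets[scaffold_id == "s2"]), 1L)
  # sampler reproduces its stated median at large n
  set.seed(2)
  med <- median(sample_contig_lengths(30000))
  expect_equal(med, 6763, tolerance = 0.06)
})

test_that("lifted annotations preserve CDS content", {
  w <- small_world()
  fr <- fragment_scaffolds(w$contigs, length_sampler = function(n)
    rep(20000L, n), seed = 3L)
  lifted <- lift_annotations(w$annotations, fr$offsets)
  expect_equal(sum(lifted$cds$end0 - lifted$cds$start0),
               sum(w$annotations$cds$end0 - w$annotations$cds$start0))
  expect_true(all(lifted$cds$start0 >= 0))
  mx <- merge(lifted$cds, fr$offsets, by = "contig_id")
  expect_true(all(mx$end0 <= mx$length))
})
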