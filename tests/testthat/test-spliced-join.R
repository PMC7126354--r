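test_that("putative exon coordinates derive from fragment spans", {
  frag <- data.table::data.table(
    fragment_id = c("fp", "fm"), contig_id = "c1", strand = c("+", "-"),
    frame = 0L, aa_seq = strrep("K", 30), contig_start = c(300L, 300L),
    contig_end = c(390L, 390L), aa_len = 30L, inverted = FALSE)
  hits <- data.table::data.table(
    fragment_id = c("fp", "fm"), target_id = "t1",
    qstart = 5L, qend = 15L, tstart = 0L, tend = 10L,
    raw = 50L, bits = c(23.9, 23.9), evalue = 1e-3, alnlen = 10L,
    matches = 10L, mismatches = 0L, gapopens = 0L, identity = 1)
  ex <- build_putative_exons(hits, frag, min_exon_aa = 10L)
  plus <- ex[exon_id == "fp"]
  expect_equal(c(plus$SC, plus$EC), c(315L, 345L))
  expect_equal(c(plus$ST, plus$ET), c(1L, 10L))
  minus <- ex[exon_id == "fm"]
  expect_gt(minus$SC, minus$EC)
  expect_equal(c(minus$SC, minus$EC), c(390L - 15L, 390L - 45L))

  # aligned length 9 with min_exon_aa = 10 is dropped
  hits9 <- data.table::copy(hits)[, `:=`(qend = 14L, tend = 9L,
                                         alnlen = 9L, matches = 9L)]
  expect_equal(nrow(build_putative_exons(hits9, frag, min_exon_aa = 10L)),
               0L)
  # unknown fragment is an error
  bad <- data.table::copy(hits)[1, fragment_id := "nope"]
  expect_error(build_putative_exons(bad, frag), "unknown fragment")
})

test_that("compatibility boundaries classify exactly as printed", {
  mk <- function(SC, EC, ST, ET, strand = "+")
    data.table::data.table(contig_id = "c1", strand = strand,
                           target_id = "t1", SC = SC, EC = EC, ST = ST,
                           ET = ET, bits = 20, exon_id = "x")
  # plus strand, contig gap: 15 and 10000 compatible; 14 and 10001 not
  i <- mk(100L, 400L, 1L, 100L)
  expect_true(compatible(i, mk(415L, 700L, 101L, 150L)))    # gap 15
  expect_false(compatible(i, mk(414L, 700L, 101L, 150L)))   # gap 14
  expect_true(compatible(i, mk(10400L, 10700L, 101L, 150L)))  # gap 10000
  expect_false(compatible(i, mk(10401L, 10700L, 101L, 150L))) # gap 10001
  # target overlap: -10 allowed, -11 not
  expect_true(compatible(i, mk(415L, 700L, 90L, 150L)))     # l = -10
  expect_false(compatible(i, mk(415L, 700L, 89L, 150L)))    # l = -11
  # contig order must match target order
  expect_false(compatible(mk(500L, 800L, 1L, 100L),
                          mk(100L, 400L, 101L, 150L)))
  # minus strand: SC_i > SC_j, gap = EC_i - SC_j
  im <- mk(20900L, 20600L, 1L, 100L, "-")
  expect_true(compatible(im, mk(20585L, 20300L, 101L, 150L, "-")))  # 15
  expect_false(compatible(im, mk(20586L, 20300L, 101L, 150L, "-"))) # 14
  expect_true(compatible(im, mk(10600L, 10300L, 101L, 150L, "-")))  # 10000
  expect_false(compatible(im, mk(10599L, 10300L, 101L, 150L, "-"))) # 10001
  expect_false(compatible(im, mk(20950L, 20920L, 101L, 150L, "-"))) # order
  # misuse errors
  expect_error(compatible(i, mk(415L, 700L, 101L, 150L, "-")),
               "different")
  expect_error(compatible(mk(100L, 400L, 50L, 100L),
                          mk(415L, 700L, 40L, 60L)),
               "smaller target start")
})

test_that("gap penalty and composite score follow the formulas", {
  expect_equal(gap_penalty(1L), 0)
  expect_equal(gap_penalty(4L), -4)
  expect_equal(gap_penalty(-3L), -3)
  expect_equal(gap_penalty(0L), 0)
  expect_equal(gap_penalty(c(1L, 5L, -2L)), c(0, -5, -2))

  two <- make_calls(list(list(
    contig = "c1", strand = "+", target = "t1",
    exons = list(c(100, 400, 1, 100, 30), c(415, 700, 101, 150, 25)))))
  expect_equal(call_score(two$exons), 30 + 25 + log2(2), tolerance = 1e-12)
  one <- make_calls(list(list(contig = "c1", strand = "+", target = "t1",
                              exons = list(c(100, 400, 1, 100, 30)))))
  expect_equal(call_score(one$exons), 30)
  three <- make_calls(list(list(
    contig = "c1", strand = "+", target = "t1",
    exons = list(c(100, 400, 1, 100, 20), c(415, 700, 101, 195, 20),
                 c(715, 1000, 200, 260, 20)))))
  expect_equal(call_score(three$exons), 60 - 5 + log2(6), tolerance = 1e-12)
  # incompatible set errors
  bad <- make_calls(list(list(
    contig = "c1", strand = "+", target = "t1",
    exons = list(c(100, 400, 1, 100, 30), c(405, 700, 101, 150, 25)))))
  expect_error(call_score(bad$exons), "not compatible")

  expect_equal(call_evalue(50, 2^20), 2^-29)
  expect_equal(call_evalue(0, 1), 2)
  expect_equal(call_evalue(33.7, 2e5) / call_evalue(33.7, 1e5), 2)
})

test_that("best_exon_set base cases", {
  one <- random_exon_group(1L, strand = "+")
  one[, bits := 30]
  res <- best_exon_set(one, D = 1e4)
  expect_equal(res$call$n_exons, 1L)
  expect_equal(res$call$S_set, 30)
  expect_equal(res$call$evalue, call_evalue(30, 1e4))

  # two mutually incompatible exons: the better one wins
  ex <- data.table::data.table(
    exon_id = c("a", "b"), contig_id = "c1", strand = "+",
    target_id = "t1", SC = c(100L, 103L), EC = c(400L, 403L),
    ST = c(1L, 2L), ET = c(100L, 101L), bits = c(30, 40), e_value = 1,
    aa_len = 100L, qstart = 0L, qend = 100L,
    nt_start = c(100L, 103L), nt_end = c(400L, 403L))
  res <- best_exon_set(ex, D = 1e4)
  expect_equal(res$call$n_exons, 1L)
  expect_equal(res$exons$exon_id, "b")
  expect_equal(res$call$S_set, 40)
  expect_null(best_exon_set(ex[0], D = 1e4))
})

test_that("chaining equals exhaustive subset enumeration (spot check)", {
  set.seed(53)
  for (i in 1:60) {
    n <- sample(2:9, 1)
    ex <- random_exon_group(n)
    res <- best_exon_set(ex, D = 1e4)
    expect_equal(res$call$S_set, oracle_best_subset(ex), tolerance = 1e-9,
                 info = paste("instance", i))
    # self-consistency: members pairwise compatible, score reproducible
    mem <- res$exons[order(exon_rank)]
    if (nrow(mem) > 1L) {
      for (a in seq_len(nrow(mem) - 1L))
        expect_true(compatible(mem[a], mem[a + 1L]))
    }
    expect_equal(call_score(mem), res$call$S_set, tolerance = 1e-9)
  }
})

test_that("adding exons never decreases the optimum", {
  set.seed(59)
  for (i in 1:20) {
    ex <- random_exon_group(sample(3:8, 1))
    base <- best_exon_set(ex, D = 1e4)$call$S_set
    extra <- random_exon_group(2L, strand = ex$strand[1])
    extra[, exon_id := paste0("z", exon_id)]
    grown <- best_exon_set(rbind(ex, extra), D = 1e4)$call$S_set
    expect_gte(grown, base - 1e-9)
  }
})

test_that("filter_calls applies E-value and coverage cutoffs", {
  calls <- make_calls(list(
    list(contig = "c1", strand = "+", target = "t1",
         exons = list(c(0, 300, 1, 100, 30)), evalue = 1e-3, tcov = 1),
    list(contig = "c1", strand = "+", target = "t2",
         exons = list(c(400, 700, 1, 100, 60)), evalue = 1e-5, tcov = 0.5),
    list(contig = "c1", strand = "+", target = "t3",
         exons = list(c(800, 1100, 1, 100, 60)), evalue = 1e-5, tcov = 0.6)))
  kept <- filter_calls(calls)
  expect_equal(kept$calls$target_id, "t3")
  # tcov = 0 disables coverage filtering
  kept2 <- filter_calls(calls, min_tcov = 0)
  expect_setequal(kept2$calls$target_id, c("t2", "t3"))
  # stricter E keeps nothing
  expect_equal(nrow(filter_calls(calls, max_call_evalue = 1e-6)$calls), 0L)
})

test_that("reverse-complementing contigs mirrors calls exactly", {
  w <- small_world()
  cfg <- run_config()
  run_fwd <- predict_genes(w$contigs[1], w$ref, cfg)
  rc <- Biostrings::reverseComplement(w$contigs[1])
  names(rc) <- names(w$contigs)[1]
  run_rc <- predict_genes(rc, w$ref, cfg)
  a <- run_fwd$calls$calls[order(target_id, strand)]
  b <- data.table::copy(run_rc$calls$calls)
  b[, strand := chartr("+-", "-+", strand)]
  b <- b[order(target_id, strand)]
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$S_set, b$S_set, tolerance = 1e-9)
  expect_identical(a$target_id, b$target_id)
  expect_identical(a$strand, b$strand)
  expect_identical(a$protein, b$protein)
})
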