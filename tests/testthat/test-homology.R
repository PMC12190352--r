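test_that("built-in aligner finds exact substrings at full identity", {
  set.seed(13)
  target <- random_dna(5000)
  q <- substr(target, 2001, 2300)
  h <- alignLocal(q, target)
  expect_gte(nrow(h), 1L)
  expect_identical(h$tstart[1], 2000L)
  expect_identical(h$tend[1], 2300L)
  expect_identical(h$qstart[1], 0L)
  expect_identical(h$qend[1], 300L)
  expect_equal(h$pident[1], 100)
})

test_that("a single mismatch in 20 nt reports 95% identity", {
  set.seed(14)
  target <- random_dna(2000)
  q <- substr(target, 501, 520)
  substr(q, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                               substr(q, 10, 10))[1]
  h <- alignLocal(q, target, word_size = 7, min_score = 5)
  h <- h[h$tstart == 500L, ]
  expect_equal(h$pident[1], 95)
})

test_that("exact planted genes are found on both strands symmetrically", {
  fx <- fix_small_locus()
  contig <- fx$plant$contig[[1]]
  hits <- searchHits(fx$ref$refset, contig, "c")
  v1 <- fx$ref$refset[[1]]
  hv <- hits[hits$gene == v1@name, ]
  expect_gte(nrow(hv), 1L)
  expect_equal(max(hv$pident), 100)
  expect_identical(max(hv$qend - hv$qstart), nchar(v1@seq_full))
  # mirrored contig gives mirrored coordinates, same scores
  L <- nchar(contig)
  hits_rc <- searchHits(fx$ref$refset, revComp(contig), "c")
  flip <- c("+" = "-", "-" = "+")
  k1 <- sort(paste(hits$gene, flip[hits$strand], L - hits$tend,
                   L - hits$tstart, round(hits$score, 6)))
  k2 <- sort(paste(hits_rc$gene, hits_rc$strand, hits_rc$tstart,
                   hits_rc$tend, round(hits_rc$score, 6)))
  expect_identical(k2, k1)
})

test_that("pure background yields zero hits at default gates", {
  fx <- fix_small_locus()
  set.seed(15)
  bg <- random_dna(30000)
  hits <- searchHits(fx$ref$refset, bg, "bg")
  hits <- hits[hits$segment_type != "D", ]  # D gated downstream by RSS
  expect_identical(nrow(hits), 0L)
})

test_that("hits separated by an intron-sized gap chain into one model", {
  # two exon hits 300 nt apart on the target
  h <- makeHits(qstart = c(0L, 120L), qend = c(100L, 250L),
                tstart = c(1000L, 1400L), tend = c(1100L, 1530L),
                bitscore = c(90, 110))
  fx <- fix_small_locus()
  cg <- fx$ref$refset[[length(fx$ref$refset)]]  # the C gene
  chains <- chainHits(h, cg)
  expect_identical(length(chains), 1L)
  expect_identical(nrow(chains[[1]]@hits), 2L)
  # the same two hits 20 kb apart stay separate
  h2 <- h; h2$tstart[2] <- 21100L; h2$tend[2] <- 21230L
  h2$blocks[[2]]$ts <- 21100L; h2$blocks[[2]]$te <- 21230L
  chains2 <- chainHits(h2, cg)
  expect_identical(length(chains2), 2L)
})

test_that("chaining equals exhaustive co-linear maximization", {
  fx <- fix_small_locus()
  cg <- fx$ref$refset[[length(fx$ref$refset)]]
  qlen <- nchar(cg@seq_full)
  set.seed(16)
  for (rep in 1:15) {
    n <- sample(3:8, 1)
    qs <- sort(sample(0:(qlen - 60), n))
    qe <- pmin(qs + sample(30:200, n, TRUE), qlen)
    ts <- sort(sample(0:50000, n)) + sample(c(0L, 0L, 30000L), n, TRUE)
    te <- ts + (qe - qs)
    h <- makeHits(qs, qe, ts, te, bitscore = sample(20:120, n, TRUE))
    chains <- chainHits(h, cg)
    expect_equal(chains[[1]]@score, bruteBestChainScore(h),
                 tolerance = 1e-9)
  }
  # a target-out-of-order middle hit is excluded from the best chain
  h <- makeHits(qstart = c(0L, 50L, 120L), qend = c(40L, 100L, 200L),
                tstart = c(1000L, 5000L, 1500L), tend = c(1040L, 5050L, 1580L),
                bitscore = c(50, 40, 80))
  chains <- chainHits(h, cg)
  expect_equal(chains[[1]]@score, bruteBestChainScore(h))
  expect_identical(nrow(chains[[1]]@hits), 2L)
})

test_that("candidate selection is greedy, tie-broken, order-invariant", {
  fx <- fix_small_locus()
  cg <- fx$ref$refset[[1]]
  mk <- function(gene, ts, te, bits) {
    h <- makeHits(0L, te - ts, ts, te, bits, gene = gene, type = "V")
    chainHits(h, cg)[[1]]
  }
  # same interval, two alleles: only the higher-scoring one survives
  a <- mk("IGHV1-1", 100L, 500L, 200)
  b <- mk("IGHV1-2", 100L, 500L, 150)
  sel <- selectCandidates(list(a, b))
  expect_identical(length(sel), 1L)
  expect_identical(sel[[1]]@gene, "IGHV1-1")
  # exact tie: ascending name wins
  b2 <- mk("IGHV1-0", 100L, 500L, 200)
  sel2 <- selectCandidates(list(a, b2))
  expect_identical(sel2[[1]]@gene, "IGHV1-0")
  # disjoint candidates are all kept; overlap below the 50% limit too
  c1 <- mk("IGHV1-3", 2000L, 2400L, 100)
  d1 <- mk("IGHV1-4", 2300L, 2700L, 90)   # ~25% coding overlap
  sel3 <- selectCandidates(list(a, c1, d1))
  expect_identical(length(sel3), 3L)
  # permutation invariance
  perm <- selectCandidates(list(d1, a, b, c1, b2))
  perm2 <- selectCandidates(list(b2, c1, b, a, d1))
  expect_identical(vapply(perm, function(x) x@gene, character(1)),
                   vapply(perm2, function(x) x@gene, character(1)))
})

test_that("builtin and blastn engines agree on top hit intervals", {
  fx <- fix_small_locus()
  contig <- fx$plant$contig[[1]]
  hb <- searchHits(fx$ref$refset, contig, "c", engine = "builtin")
  hx <- searchHits(fx$ref$refset, contig, "c", engine = "blastn")
  for (g in unique(hb$gene)) {
    b <- hb[hb$gene == g, ]; b <- b[which.max(b$score), ]
    x <- hx[hx$gene == g, ]
    expect_gte(nrow(x), 1L)
    x <- x[which.max(x$score), ]
    expect_lte(abs(b$tstart - x$tstart), 2L)
    expect_lte(abs(b$tend - x$tend), 2L)
    expect_identical(b$strand, x$strand)
  }
})
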