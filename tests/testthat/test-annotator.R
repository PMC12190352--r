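# minimal hand-built V candidate on the plus strand, coding end at `cend`
fakeV <- function(cend = 500L, cstart = 100L) {
  h <- makeHits(0L, cend - cstart, cstart, cend, 100, gene = "VX",
                type = "V")
  new("ChainedCandidate", gene = "VX", allele = "01", segment_type = "V",
      strand = "+", span = GenomicInterval("c", cstart, cend, "+"),
      hits = h, blocks = h$blocks[[1]],
      exon_map = data.frame(label = "V-REGION", start = cstart,
                            end = cend, qstart = 0L,
                            qend = cend - cstart),
      completeness = 1, gap_overlap = 0L, score = 100)
}

rssRow <- function(start, class = 23L, strand = "+", score = -5) {
  w <- 16L + class
  data.frame(contig = "c", start = start, end = start + w,
             strand = strand, spacer_class = class, score = score,
             heptamer_boundary = if (strand == "+") start else start + w,
             stringsAsFactors = FALSE)
}

test_that("RSS matching honors adjacency, tolerance, class and ties", {
  rules <- locusRules("IGH")
  cand <- fakeV(cend = 500L)
  expect_identical(matchRss(cand, rssRow(500L), rules)$three$match$start,
                   500L)
  expect_identical(matchRss(cand, rssRow(502L), rules,
                            tolerance = 3)$three$match$start, 502L)
  expect_null(matchRss(cand, rssRow(550L), rules)$three$match)
  # wrong spacer class is not accepted for a V flank in IGH
  expect_null(matchRss(cand, rssRow(500L, class = 12L), rules)$three$match)
  # higher score wins; exact tie goes to the smaller start
  two <- rbind(rssRow(499L, score = -8), rssRow(501L, score = -2))
  expect_identical(matchRss(cand, two, rules)$three$match$start, 501L)
  tie <- rbind(rssRow(501L, score = -2), rssRow(499L, score = -2))
  expect_identical(matchRss(cand, tie, rules)$three$match$start, 499L)
})

test_that("splice verification reads canonical and GC donors", {
  # exons [100,150) and [250,300); intron GT...AG
  intron_ok <- paste0("GT", random_dna(96), "AG")
  contig <- paste0(random_dna(100), random_dna(50), intron_ok,
                   random_dna(50), random_dna(100))
  h <- makeHits(0L, 200L, 100L, 300L, 100, type = "C")
  cand <- new("ChainedCandidate", gene = "CX", allele = "01",
              segment_type = "C", strand = "+",
              span = GenomicInterval("c", 100L, 300L, "+"), hits = h,
              blocks = h$blocks[[1]],
              exon_map = data.frame(label = c("CH1", "CH2"),
                                    start = c(100L, 250L),
                                    end = c(150L, 300L),
                                    qstart = c(0L, 150L),
                                    qend = c(50L, 200L)),
              completeness = 1, gap_overlap = 0L, score = 100)
  v <- verifySplice(cand, contig)
  expect_true(v$ok)
  expect_identical(v$introns$donor, "GT")
  expect_identical(v$introns$acceptor, "AG")
  gc_contig <- contig
  substr(gc_contig, 152, 152) <- "C"   # GT -> GC at the donor
  v2 <- verifySplice(cand, gc_contig)
  expect_false(v2$ok)
  expect_identical(v2$introns$donor, "GC")
  # single-exon candidates pass vacuously
  expect_true(verifySplice(fakeV(), contig)$ok)
})

test_that("classification precedence is a pure function of the report", {
  pass_rss <- list(five = NULL,
                   three = list(required = TRUE, match = rssRow(1L)))
  fail_rss <- list(five = NULL, three = list(required = TRUE, match = NULL))
  pass_splice <- list(ok = TRUE, introns = data.frame())
  fail_splice <- list(ok = FALSE, introns = data.frame())
  coding_ok <- list(start_codon_ok = TRUE, internal_stop = FALSE,
                    frameshift = FALSE,
                    conserved_ok = c(first_cys = TRUE, second_cys = TRUE))
  expect_identical(
    classifyFunctionality(pass_rss, pass_splice, coding_ok, "V"),
    list(functionality = "functional", reasons = character(0)))
  r <- classifyFunctionality(fail_rss, pass_splice, coding_ok, "V")
  expect_identical(r$functionality, "ORF")
  expect_identical(r$reasons, "RSS_MISSING")
  coding_stop <- coding_ok; coding_stop$internal_stop <- TRUE
  r2 <- classifyFunctionality(fail_rss, pass_splice, coding_stop, "V")
  expect_identical(r2$functionality, "pseudogene")
  expect_setequal(r2$reasons, c("INTERNAL_STOP", "RSS_MISSING"))
  # same report, same call, regardless of how often it is asked
  expect_identical(classifyFunctionality(fail_rss, fail_splice,
                                         coding_stop, "V"),
                   classifyFunctionality(fail_rss, fail_splice,
                                         coding_stop, "V"))
  coding_nostart <- coding_ok; coding_nostart$start_codon_ok <- FALSE
  expect_identical(classifyFunctionality(pass_rss, pass_splice,
                                         coding_nostart, "V")$functionality,
                   "pseudogene")
  coding_nocys <- coding_ok
  coding_nocys$conserved_ok["second_cys"] <- FALSE
  r3 <- classifyFunctionality(pass_rss, pass_splice, coding_nocys, "V")
  expect_identical(r3$functionality, "ORF")
  expect_identical(r3$reasons, "MISSING_CONSERVED_CYS")
})

test_that("allele naming: exact match, hash suffix, collisions", {
  fx <- fix_small_locus()
  set <- fx$ref$refset
  g <- set[[1]]
  exact <- assignName(referenceCodingSeq(g), set@allele_index, g@name)
  expect_identical(exact$name, paste0(g@name, "*", g@allele))
  expect_false(exact$novel)
  novel_seq <- paste0("AC", referenceCodingSeq(g))
  nv <- assignName(novel_seq, set@allele_index, g@name)
  expect_true(nv$novel)
  expect_identical(nv$name,
                   paste0(g@name, "*", substr(sha1Hex(novel_seq), 1, 4)))
  # cross-check the digest against an independent SHA-1 implementation
  oracle <- as.character(openssl::sha1(novel_seq))
  expect_identical(sha1Hex(novel_seq), oracle)
  # distinct novel sequences get distinct names (collision -> _2 suffix)
  used <- setNames("SOMEOTHERSEQ", nv$name)
  nv2 <- assignName(novel_seq, set@allele_index, g@name, used)
  expect_identical(nv2$name, paste0(nv$name, "_2"))
  expect_error(assignName("", set@allele_index, "X"), "empty")
})

test_that("planted loci annotate to functional genes at exact coordinates", {
  fx <- fix_small_locus()
  res <- annotateLocus(fx$ref$refset, fx$plant$contig[[1]],
                       names(fx$plant$contig), fx$rss)
  expect_identical(length(res$features), length(fx$ref$refset))
  expect_identical(nrow(res$withheld), 0L)
  expect_true(all(vapply(res$features, function(f) f@functionality,
                         character(1)) == "functional"))
  cc <- coordCheck(res$features, fx$plant$truth)
  expect_identical(unname(cc["exact"]), length(res$features))
  expect_identical(unname(cc["unmatched"]), 0L)
  # exact rediscoveries resolve to the reference allele names
  expect_setequal(vapply(res$features, function(f) f@assigned_name,
                         character(1)),
                  geneNames(fx$ref$refset))
  # GFF document carries gene, exon, CDS and RSS features
  expect_true(all(c("exon", "CDS", "V_gene_segment",
                    "recombination_signal_sequence") %in% res$gff$type))
  f <- withr::local_tempfile()
  writeGff3(res$gff, f,
            seqlens = setNames(nchar(fx$plant$contig),
                               names(fx$plant$contig)))
  expect_identical(readLines(f)[1], "##gff-version 3")
})

test_that("mutation operators map to their expected classifications", {
  spec <- locusSpec("IGH", n_v = 5L, n_d = 1L, n_j = 2L, n_c = 1L,
                    seed = 77L, intergenic = c(300L, 1500L))
  ref <- generateReference(spec)
  mut <- c("IGHV1-1*01" = "introduce_stop", "IGHV1-2*01" = "delete_start",
           "IGHV1-3*01" = "frameshift_del1", "IGHV1-4*01" = "scramble_rss",
           "IGHV1-5*01" = "gc_donor", "IGHJ1*01" = "introduce_stop",
           "IGHC1*01" = "insert_n_gap")
  m <- fix_models()
  pl <- plantLocus(spec, ref$refset, mutations = mut,
                   rss_windows = m$pools)
  rss <- scanRss(m$m12, m$m23, pl$contig[[1]], names(pl$contig))
  res <- annotateLocus(ref$refset, pl$contig[[1]], names(pl$contig), rss)
  calls <- vapply(seq_len(nrow(pl$truth)), function(i) {
    tr <- pl$truth[i, ]
    j <- which(vapply(res$features, function(f)
      f@candidate@segment_type == tr$segment_type &&
        start(f@candidate@span) < tr$span_end &&
        end(f@candidate@span) > tr$span_start, logical(1)))
    if (length(j)) res$features[[j[1]]]@functionality
    else if (any(res$withheld$segment_type == tr$segment_type &
                 res$withheld$start < tr$span_end &
                 res$withheld$end > tr$span_start)) "withheld"
    else "missing"
  }, character(1))
  expect_identical(calls, pl$truth$expected)
  # reason codes match the operator classes
  feats_by_truth <- function(nm) {
    tr <- pl$truth[pl$truth$name == nm, ]
    j <- which(vapply(res$features, function(f)
      f@candidate@segment_type == tr$segment_type &&
        start(f@candidate@span) < tr$span_end &&
        end(f@candidate@span) > tr$span_start, logical(1)))
    res$features[[j[1]]]
  }
  expect_identical(feats_by_truth("IGHV1-1*01")@reasons, "INTERNAL_STOP")
  expect_identical(feats_by_truth("IGHV1-2*01")@reasons, "NO_START")
  expect_true("FRAMESHIFT" %in% feats_by_truth("IGHV1-3*01")@reasons)
  expect_identical(feats_by_truth("IGHV1-4*01")@reasons, "RSS_MISSING")
  expect_identical(feats_by_truth("IGHV1-5*01")@reasons,
                   "NONCANONICAL_SPLICE")
  expect_identical(res$withheld$cause, "ASSEMBLY_GAP")
})

test_that("annotating the reverse-complemented contig mirrors the result", {
  fx <- fix_small_locus()
  contig <- fx$plant$contig[[1]]
  L <- nchar(contig)
  m <- fix_models()
  res <- annotateLocus(fx$ref$refset, contig, "c", fx$rss)
  rss_rc <- scanRss(m$m12, m$m23, revComp(contig), "c")
  res_rc <- annotateLocus(fx$ref$refset, revComp(contig), "c", rss_rc)
  key <- function(r, L = NULL) sort(vapply(r$features, function(f) {
    s <- start(f@candidate@span); e <- end(f@candidate@span)
    if (!is.null(L)) { tmp <- s; s <- L - e; e <- L - tmp }
    paste(f@assigned_name, s, e, f@functionality)
  }, character(1)))
  expect_identical(key(res_rc, L), key(res))
})
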