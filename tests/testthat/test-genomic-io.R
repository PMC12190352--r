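test_that("readFasta normalizes case and RNA, keeps file order", {
  f <- withr::local_tempfile(lines = c(">a first", "acgu", ">b", "ACGTN"))
  x <- readFasta(f)
  expect_equal(unname(x), c("ACGT", "ACGTN"), ignore_attr = TRUE)
  expect_identical(names(x), c("a", "b"))
  expect_identical(unname(attr(x, "description")["a"]), "first")
})

test_that("readFasta rejects duplicates, bad characters, empty files", {
  f <- withr::local_tempfile(lines = c(">a", "ACGT", ">a", "GGGG"))
  expect_error(readFasta(f), "duplicate.*a")
  f2 <- withr::local_tempfile(lines = c(">bad", "ACRT"))
  expect_error(readFasta(f2), "bad")
  expect_equal(unname(readFasta(f2, ambig_to_n = TRUE)), "ACNT",
               ignore_attr = TRUE)
  f3 <- withr::local_tempfile(lines = character(0))
  expect_error(readFasta(f3), "empty")
})

test_that("FASTA write/read round trip is an identity", {
  set.seed(1)
  seqs <- setNames(c(random_dna(150), random_dna(37)), c("s1", "s2"))
  f <- withr::local_tempfile()
  writeFasta(seqs, f, width = 60)
  back <- readFasta(f)
  expect_equal(unname(back), unname(seqs), ignore_attr = TRUE)
  expect_identical(names(back), names(seqs))
})

test_that("revComp complements, reverses, and is an involution", {
  expect_identical(revComp("ACGTN"), "NACGT")
  expect_error(revComp(""), "empty")
  set.seed(2)
  for (i in 1:20) {
    s <- random_dna(sample(1:200, 1))
    expect_identical(revComp(revComp(s)), s)
    expect_identical(nchar(revComp(s)), nchar(s))
  }
})

test_that("translateDna follows the standard table, N and frame rules", {
  expect_identical(translateDna("ATGTAA"), "M*")
  expect_identical(translateDna("ATGNAA"), "MX")
  expect_identical(translateDna("ATGAAA", 1), "*")  # TGA, trailing AA dropped
  expect_identical(translateDna("AT"), "")
  expect_error(translateDna("ATG", 3), "frame")
})

test_that("reverse-strand translation equals a brute-force codon walk", {
  codon_walk <- function(s) {
    # walk the minus strand 5'->3' explicitly, codon by codon
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ch <- rev(unname(comp[strsplit(s, "")[[1]]]))
    out <- ""
    i <- 1
    while (i + 2 <= length(ch)) {
      out <- paste0(out, translateDna(paste(ch[i:(i + 2)], collapse = "")))
      i <- i + 3
    }
    out
  }
  set.seed(3)
  for (i in 1:20) {
    s <- random_dna(sample(10:100, 1))
    expect_identical(translateDna(revComp(s)), codon_walk(s))
  }
})

test_that("BED6 output is tab-separated, 0-based, sorted, clamped", {
  f <- withr::local_tempfile()
  writeBed(GenomicInterval("c1", 0, 7), "h", 0, f)
  expect_identical(readLines(f), "c1\t0\t7\th\t0\t+")
  writeBed(GenomicInterval(c("c2", "c1"), c(5, 1), c(9, 4)),
           c("x", "y"), c(2000, -5), f)
  expect_identical(readLines(f), c("c1\t1\t4\ty\t0\t+", "c2\t5\t9\tx\t1000\t+"))
  expect_error(GenomicInterval("c1", 5, 5), "end must be > start")
})

test_that("BED round trip is an identity on sorted random intervals", {
  set.seed(4)
  n <- 10L
  starts <- sort(sample(0:10000, n))
  iv <- GenomicInterval("ctg", starts, starts + sample(1:500, n),
                        sample(c("+", "-"), n, TRUE))
  f <- withr::local_tempfile()
  writeBed(iv, sprintf("f%02d", seq_len(n)), seq_len(n), f)
  back <- readBed(f)
  expect_identical(as.data.frame(back$intervals), as.data.frame(iv))
  expect_identical(back$name, sprintf("f%02d", seq_len(n)))
  expect_identical(back$score, as.numeric(seq_len(n)))
})

test_that("readBed defaults, tolerated lines, and error reporting", {
  f <- withr::local_tempfile(lines = c("track name=x", "# note",
                                       "c1\t10\t38\trss12\t0\t-",
                                       "c1\t10\t38"))
  b <- readBed(f)
  expect_identical(strand(b$intervals), c("-", "+"))
  expect_identical(b$name, c("rss12", "."))
  f2 <- withr::local_tempfile(lines = "c1\tten\t38")
  expect_error(readBed(f2), "line 1")
})

test_that("GFF3 writer converts coordinates and escapes attributes", {
  set.seed(5)
  starts <- sample(0:100000, 200)
  iv <- GenomicInterval("c1", starts, starts + sample(1:999, 200))
  feats <- gff3Features(iv, "region", sprintf("id%03d", 1:200))
  f <- withr::local_tempfile()
  writeGff3(feats, f, seqlens = c(c1 = 200000L))
  lines <- grep("^[^#]", readLines(f), value = TRUE)
  cols <- do.call(rbind, strsplit(lines, "\t"))
  o <- order(starts)
  expect_identical(as.integer(cols[, 4]), starts[o] + 1L)
  expect_identical(as.integer(cols[, 5]), end(iv)[o])
  # escaping
  f2 <- withr::local_tempfile()
  feats2 <- gff3Features(GenomicInterval("c1", 0, 7), "gene", "g1",
                         attrs = list(c(Name = "IGHV1-1*01;x")))
  writeGff3(feats2, f2)
  expect_match(readLines(f2)[3], "Name=IGHV1-1\\*01%3Bx", fixed = FALSE)
  expect_identical(readGff3(f2)$attrs[[1]][["Name"]], "IGHV1-1*01;x")
})

test_that("GFF3 round trip is an identity on a 3-level feature tree", {
  iv <- GenomicInterval("c1", c(100, 100, 100, 250, 600),
                        c(900, 200, 220, 380, 900), "-")
  feats <- gff3Features(iv, c("gene", "exon", "CDS", "exon", "exon"),
                        c("g1", "g1.e1", "g1.c1", "g1.e2", "g1.e3"),
                        c(NA, "g1", "g1.e1", "g1", "g1"),
                        phase = c(NA, NA, 0L, NA, NA),
                        attrs = list(c(Name = "x"), character(0),
                                     character(0), character(0),
                                     character(0)))
  f <- withr::local_tempfile()
  writeGff3(feats, f, seqlens = c(c1 = 1000L))
  back <- readGff3(f)
  attr(back, "seqlens") <- NULL
  expect_equal(back, feats, ignore_attr = "row.names")
  # re-emission is byte identical
  f2 <- withr::local_tempfile()
  writeGff3(readGff3(f), f2, seqlens = c(c1 = 1000L))
  expect_identical(readLines(f), readLines(f2))
})

test_that("GFF3 reader enforces pragma, column count, parent links", {
  f <- withr::local_tempfile(lines = c("#comment", "c1\t.\tgene\t1\t7\t.\t+\t.\tID=g1"))
  expect_error(readGff3(f), "gff-version")
  f2 <- withr::local_tempfile(lines = c("##gff-version 3", "c1\tgene\t1\t7"))
  expect_error(readGff3(f2), "line 2")
  feats <- gff3Features(GenomicInterval("c1", 0, 7), "exon", "e1", "ghost")
  expect_error(writeGff3(feats, withr::local_tempfile()), "dangling")
  cds <- gff3Features(GenomicInterval("c1", 0, 9), "CDS", "c1")
  expect_error(writeGff3(cds, withr::local_tempfile()), "phase")
})

test_that("emitted GFF3 is parseable by an independent reader", {
  iv <- GenomicInterval("c1", c(10, 10, 60), c(100, 40, 100))
  feats <- gff3Features(iv, c("gene", "exon", "exon"),
                        c("g1", "g1.e1", "g1.e2"), c(NA, "g1", "g1"))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeGff3(feats, f, seqlens = c(c1 = 200L))
  gr <- rtracklayer::import(f)
  expect_identical(length(gr), 3L)
  # rtracklayer reports 1-based inclusive coordinates
  expect_identical(sort(BiocGenerics::start(gr)), c(11L, 11L, 61L))
  expect_identical(sort(BiocGenerics::end(gr)), c(40L, 100L, 100L))
})
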