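flat_fixture <- function() c(
  "ID   TEST0001; SV 1; linear; genomic DNA; STD; SYN; 400 BP.",
  "FH   Key             Location/Qualifiers",
  "FT   V-REGION        101..196",
  "FT                   /IMGT_allele=\"IGHV9-1*01\"",
  "FT   J-REGION        complement(250..300)",
  "FT                   /IMGT_allele=\"IGHJ9*01\"",
  paste0("SQ   Sequence 400 BP;"),
  paste0("     ", paste(rep("acgt", 15), collapse = "")),
  "//")

test_that("flat-file locations parse with conversion to 0-based", {
  pf <- parseFlatfile(flat_fixture())
  expect_identical(pf$accession, "TEST0001")
  ft <- pf$features
  expect_identical(ft$start, c(100L, 249L))
  expect_identical(ft$end, c(196L, 300L))
  expect_identical(ft$strand, c("+", "-"))
})

test_that("location grammar handles join, complement, nesting, fuzz", {
  p <- parseFlatfile(c("FT   C-REGION        join(10..20,50..70)",
                       "FT                   /gene=\"X\""))
  expect_identical(nrow(p$features$parts[[1]]), 2L)
  expect_identical(p$features$parts[[1]]$start, c(9L, 49L))
  p2 <- parseFlatfile("FT   J-REGION        complement(join(5..9,30..40))")
  expect_identical(p2$features$strand, "-")
  expect_identical(p2$features$parts[[1]]$end, c(9L, 40L))
  p3 <- parseFlatfile("FT   V-REGION        <101..396")
  expect_true(p3$features$partial)
  expect_identical(p3$features$start, 100L)
  expect_error(parseFlatfile("FT   V-REGION        join(1..5"),
               "unbalanced")
  expect_error(parseFlatfile("FT   V-REGION        10..x"), "V-REGION")
})

test_that("buildGeneSet groups features and extracts sequences", {
  genome <- paste(rep("ACGT", 100), collapse = "")
  pf <- parseFlatfile(flat_fixture())
  gs <- buildGeneSet(pf, setNames(genome, "TEST0001"), "IGH")
  expect_s4_class(gs, "ReferenceGeneSet")
  expect_identical(length(gs), 2L)
  v <- gs[[1]]
  expect_identical(v@segment_type, "V")
  expect_identical(v@seq_full, substr(genome, 101, 196))
  j <- gs[[2]]
  expect_identical(j@segment_type, "J")
  expect_identical(j@seq_full, revComp(substr(genome, 250, 300)))
})

test_that("unknown labels are logged and skipped, never fatal", {
  bad <- c("FT   V-REGOIN        101..196",
           "FT                   /IMGT_allele=\"IGHV9-1*01\"",
           "FT   J-REGION        250..300",
           "FT                   /IMGT_allele=\"IGHJ9*01\"")
  genome <- setNames(paste(rep("ACGT", 100), collapse = ""), "x")
  gs <- buildGeneSet(parseFlatfile(bad), genome, "IGH")
  expect_identical(length(gs), 1L)
  expect_match(attr(gs, "parse_log"), "IGHV9-1")
  # fuzzed labels parse without aborting
  set.seed(6)
  for (i in 1:20) {
    lab <- paste(sample(LETTERS, 8), collapse = "")
    txt <- c(sprintf("FT   %-15s 11..40", lab),
             "FT                   /IMGT_allele=\"Z*01\"")
    expect_no_error(buildGeneSet(parseFlatfile(txt), genome, "IGH"))
  }
})

test_that("join() exons concatenate to per-part substring extraction", {
  set.seed(7)
  genome <- setNames(random_dna(800), "g")
  txt <- c("FT   C-REGION        join(11..110,201..310,401..490,601..690)",
           "FT                   /IMGT_allele=\"IGHC9*01\"")
  gs <- buildGeneSet(parseFlatfile(txt), genome, "IGH")
  g <- gs[[1]]
  expect_identical(start(g@full_span), 10L)
  expect_identical(end(g@full_span), 690L)
  direct <- paste(substr(genome, 11, 110), substr(genome, 201, 310),
                  substr(genome, 401, 490), substr(genome, 601, 690),
                  sep = "")
  expect_identical(referenceCodingSeq(g), direct)
})

test_that("synthetic flat file reconstructs the generated reference", {
  spec <- locusSpec("TRB", n_v = 3L, n_d = 2L, n_j = 2L, n_c = 1L,
                    seed = 11L, intergenic = c(300L, 800L))
  ref <- generateReference(spec)
  gs <- buildGeneSet(parseFlatfile(ref$flatfile), locus = "TRB")
  expect_identical(length(gs), length(ref$refset))
  for (i in seq_along(ref$refset@genes)) {
    a <- ref$refset[[i]]; b <- gs[[i]]
    expect_identical(b@seq_full, a@seq_full)
    expect_identical(b@exons$start, a@exons$start)
    expect_identical(b@exons$end, a@exons$end)
    expect_identical(strand(b@full_span), strand(a@full_span))
    expect_identical(length(b@conserved), length(a@conserved))
    if (length(a@conserved))
      expect_identical(b@conserved[names(a@conserved)], a@conserved)
  }
})

test_that("allele_index maps every extracted sequence to its own gene", {
  fx <- fix_small_locus()
  set <- fx$ref$refset
  for (g in set@genes) {
    key <- paste0(g@name, "*", g@allele)
    expect_identical(unname(set@allele_index[g@seq_full]), key)
    expect_identical(unname(set@allele_index[referenceCodingSeq(g)]), key)
  }
})

test_that("geneSetToBed emits exon and span records that round trip", {
  fx <- fix_small_locus()
  bed <- geneSetToBed(fx$ref$refset)
  n_exons <- sum(vapply(fx$ref$refset@genes, function(g) nrow(g@exons),
                        integer(1)))
  expect_identical(length(bed$name), n_exons + length(fx$ref$refset))
  expect_identical(sum(grepl("\\|span$", bed$name)),
                   length(fx$ref$refset))
  f <- withr::local_tempfile()
  writeBed(bed$intervals, bed$name, bed$score, f)
  back <- readBed(f)
  expect_identical(sort(paste(contigId(back$intervals),
                              start(back$intervals), end(back$intervals))),
                   sort(paste(contigId(bed$intervals),
                              start(bed$intervals), end(bed$intervals))))
  # empty set gives an empty, header-free BED
  empty <- new("ReferenceGeneSet", genes = list(), source_accession = "x",
               locus = "IGH", allele_index = character(0))
  bed0 <- geneSetToBed(empty)
  writeBed(bed0$intervals, bed0$name, bed0$score, f)
  expect_identical(length(readLines(f)), 0L)
})
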