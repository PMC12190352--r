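#' @include annotator.R
NULL

# canonical RSS consensus elements; spacers are fixed arbitrary sequences so
# trained models have a well-defined consensus
.RSS_HEPTAMER <- "CACAGTG"
.RSS_NONAMER <- "ACAAAAACC"
.RSS_SPACER12 <- "ACTGGAACAAAA"
.RSS_SPACER23 <- "GTGAGGACTTCACAGCCCTTAAC"

#' Consensus RSS window for a spacer class
#' @param spacer_class 12 or 23.
#' @return heptamer + spacer + nonamer string (28 or 39 nt).
#' @export
rssConsensus <- function(spacer_class) {
  sp <- switch(as.character(spacer_class), "12" = .RSS_SPACER12,
               "23" = .RSS_SPACER23, stop("spacer_class must be 12 or 23"))
  paste0(.RSS_HEPTAMER, sp, .RSS_NONAMER)
}

.BASES <- c("A", "C", "G", "T")
.randSeq <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

.SENSE_CODONS <- local({
  all <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                         .BASES, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})
.randCodons <- function(n) paste(sample(.SENSE_CODONS, n, replace = TRUE),
                                 collapse = "")

# substitute positions of `seq` i.i.d. at `rate` (uniform over other bases)
.mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate & ch %in% .BASES)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate RSS training windows around the consensus
#'
#' Windows are sampled by substituting the consensus i.i.d. at `noise` in
#' the spacer and at the lower `core_noise` in the heptamer and nonamer
#' (the biologically conserved elements).
#'
#' @param spacer_class 12 or 23.
#' @param n number of windows.
#' @param noise per-position substitution rate in the spacer (default 0.1).
#' @param seed RNG seed.
#' @param core_noise substitution rate in heptamer/nonamer
#'   (default `noise / 5`).
#' @return character vector of `n` windows of length 16 + spacer_class.
#' @export
generateRssTraining <- function(spacer_class, n, noise = 0.1, seed = 1L,
                                core_noise = noise / 5) {
  set.seed(seed)
  sp <- switch(as.character(spacer_class), "12" = .RSS_SPACER12,
               "23" = .RSS_SPACER23, stop("spacer_class must be 12 or 23"))
  vapply(seq_len(n), function(i) {
    paste0(.mutateSeq(.RSS_HEPTAMER, core_noise),
           .mutateSeq(sp, noise),
           .mutateSeq(.RSS_NONAMER, core_noise))
  }, character(1))
}

#' Specification for a synthetic locus
#'
#' Length ranges mirror the anatomy of real IG/TR loci: short V genes with
#' a leader exon (L-PART1) split from the V exon by a small intron, very
#' short D genes, short J genes, and multi-exon C genes with up to
#' kilobase-scale introns.
#'
#' @param locus locus code (determines RSS spacer rules and D presence).
#' @param n_v,n_d,n_j,n_c segment counts (n_d forced to 0 for loci
#'   without D genes).
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @param gc background GC content (default 0.5, i.i.d. bases).
#' @param intergenic c(min, max) intergenic spacing (default 500-5000).
#' @return list of class "locus_spec".
#' @export
locusSpec <- function(locus = "IGH", n_v = 8L, n_d = 4L, n_j = 6L,
                      n_c = 2L, seed = 1L, gc = 0.5,
                      intergenic = c(500L, 5000L)) {
  rules <- locusRules(locus)
  if (!rules$has_d) n_d <- 0L
  structure(list(locus = locus, n_v = n_v, n_d = n_d, n_j = n_j, n_c = n_c,
                 seed = seed, gc = gc, intergenic = intergenic,
                 v_coding = c(270L, 309L), l_part1 = c(45L, 60L),
                 v_intron = c(80L, 150L), d_len = c(10L, 35L),
                 j_len = c(45L, 63L), c_exon = c(102L, 330L),
                 c_intron = c(100L, 2000L), c_nexon = c(2L, 4L)),
            class = "locus_spec")
}

# build the internal layout of one gene: a list of pieces (label, seq,
# role in "exon"/"intron") in gene orientation, plus conserved offsets
.makeGeneLayout <- function(type, name, spec) {
  if (type == "V") {
    lp1 <- sample(seq(spec$l_part1[1], spec$l_part1[2], by = 3L), 1L)
    ncod <- sample((spec$v_coding[1] %/% 3L):(spec$v_coding[2] %/% 3L), 1L)
    c1 <- 40L; c2 <- ncod - 11L   # 0-based codon indices
    codons <- strsplit(.randCodons(ncod), "(?<=...)", perl = TRUE)[[1]]
    codons[1] <- "ATG"
    codons[c1 + 1L] <- sample(c("TGT", "TGC"), 1L)
    codons[c2 + 1L] <- sample(c("TGT", "TGC"), 1L)
    coding <- paste(codons, collapse = "")
    intron_len <- sample(spec$v_intron[1]:spec$v_intron[2], 1L)
    pieces <- list(
      list(label = "L-PART1", role = "exon",
           seq = substr(coding, 1L, lp1)),
      list(label = "intron", role = "intron",
           seq = paste0("GT", .randSeq(intron_len - 4L, spec$gc), "AG")),
      list(label = "V-EXON", role = "exon",
           seq = substring(coding, lp1 + 1L)))
    list(type = type, name = name, pieces = pieces,
         conserved = c(first_cys = 3L * c1, second_cys = 3L * c2))
  } else if (type == "D") {
    len <- sample(spec$d_len[1]:spec$d_len[2], 1L)
    list(type = type, name = name,
         pieces = list(list(label = "D-REGION", role = "exon",
                            seq = .randSeq(len, spec$gc))),
         conserved = integer(0))
  } else if (type == "J") {
    len <- sample(seq(spec$j_len[1], spec$j_len[2], by = 3L), 1L)
    ncod <- len %/% 3L
    codons <- strsplit(.randCodons(ncod), "(?<=...)", perl = TRUE)[[1]]
    wf <- ncod - 10L
    codons[wf + 1L] <- "TGG"
    list(type = type, name = name,
         pieces = list(list(label = "J-REGION", role = "exon",
                            seq = paste(codons, collapse = ""))),
         conserved = c(j_trp_phe = 3L * wf))
  } else {
    nex <- sample(spec$c_nexon[1]:spec$c_nexon[2], 1L)
    lens <- sample(seq(spec$c_exon[1], spec$c_exon[2], by = 3L), nex,
                   replace = TRUE)
    coding <- .randCodons(sum(lens) %/% 3L)
    pieces <- list()
    off <- 0L
    for (i in seq_len(nex)) {
      pieces[[length(pieces) + 1L]] <-
        list(label = paste0("CH", i), role = "exon",
             seq = substr(coding, off + 1L, off + lens[i]))
      off <- off + lens[i]
      if (i < nex) {
        il <- sample(spec$c_intron[1]:spec$c_intron[2], 1L)
        pieces[[length(pieces) + 1L]] <-
          list(label = "intron", role = "intron",
               seq = paste0("GT", .randSeq(il - 4L, spec$gc), "AG"))
      }
    }
    list(type = type, name = name, pieces = pieces, conserved = integer(0))
  }
}

.layoutSeq <- function(layout)
  paste(vapply(layout$pieces, `[[`, character(1), "seq"), collapse = "")

#' Generate a synthetic reference gene set and its flat file
#'
#' Synthesizes canonical gene structures (ATG-initiated leader, GT/AG
#' introns, conserved cysteine/tryptophan codons), lays them on a reference
#' sequence with mixed strands, and renders both the in-memory
#' [ReferenceGeneSet-class] and an IMGT-style EMBL flat file describing it
#' (with `1st-CYST`/`2nd-CYST`/`J-TRP` labels and `IMGT_allele`
#' qualifiers), so the flat-file parser can be validated against known
#' ground truth.
#'
#' @param spec a [locusSpec()].
#' @return list: `refset` ([ReferenceGeneSet-class]), `flatfile` (character
#'   vector of lines), `genome` (named reference sequence).
#' @export
generateReference <- function(spec) {
  set.seed(spec$seed)
  locus <- spec$locus
  layouts <- c(
    lapply(seq_len(spec$n_v), function(i)
      .makeGeneLayout("V", paste0(locus, "V1-", i), spec)),
    lapply(seq_len(spec$n_d), function(i)
      .makeGeneLayout("D", paste0(locus, "D1-", i), spec)),
    lapply(seq_len(spec$n_j), function(i)
      .makeGeneLayout("J", paste0(locus, "J", i), spec)),
    lapply(seq_len(spec$n_c), function(i)
      .makeGeneLayout("C", paste0(locus, "C", i), spec)))
  strands <- sample(c("+", "-"), length(layouts), replace = TRUE)
  acc <- paste0("SYN", toupper(locus), sprintf("%04d", spec$seed %% 10000L))
  genome_parts <- character(0)
  pos <- 0L
  genes <- list()
  ft <- character(0)
  idx <- character(0)
  for (gi in seq_along(layouts)) {
    lay <- layouts[[gi]]
    spacer <- .randSeq(100L, spec$gc)
    genome_parts <- c(genome_parts, spacer)
    pos <- pos + nchar(spacer)
    unit <- .layoutSeq(lay)
    minus <- strands[gi] == "-"
    placed <- if (minus) revComp(unit) else unit
    gstart <- pos
    gend <- pos + nchar(unit)
    # per-piece genomic intervals (contig-forward)
    off <- 0L
    exdf <- NULL
    cons_genomic <- integer(0)
    for (p in lay$pieces) {
      w <- nchar(p$seq)
      iv <- if (!minus) c(gstart + off, gstart + off + w)
            else c(gend - off - w, gend - off)
      if (p$role == "exon")
        exdf <- rbind(exdf, data.frame(label = p$label, start = iv[1],
                                       end = iv[2],
                                       stringsAsFactors = FALSE))
      off <- off + w
    }
    # conserved coding offsets -> genomic codon positions for FT labels
    for (w in names(lay$conserved)) {
      co <- lay$conserved[[w]]
      cum <- 0L; gpos <- NA_integer_
      for (p in lay$pieces) {
        if (p$role != "exon") next
        pw <- nchar(p$seq)
        prow <- exdf[exdf$label == p$label, ]
        if (co < cum + pw) {
          within <- co - cum
          gpos <- if (!minus) prow$start + within
                  else prow$end - 1L - within
          break
        }
        cum <- cum + pw
      }
      cons_genomic[w] <- gpos
    }
    genome_parts <- c(genome_parts, placed)
    pos <- gend
    allele <- "01"
    key <- paste0(lay$name, "*", allele)
    span <- GenomicInterval(acc, gstart, gend, strands[gi])
    exdf <- exdf[order(exdf$start, decreasing = minus), , drop = FALSE]
    rownames(exdf) <- NULL
    seq_ex <- stats::setNames(
      vapply(lay$pieces[vapply(lay$pieces, `[[`, character(1), "role") ==
                          "exon"], `[[`, character(1), "seq"),
      vapply(lay$pieces[vapply(lay$pieces, `[[`, character(1), "role") ==
                          "exon"], `[[`, character(1), "label"))
    g <- new("ReferenceGene", name = lay$name, allele = allele,
             segment_type = lay$type, locus = locus, exons = exdf,
             full_span = span, seq_full = unit, seq_exons = seq_ex,
             conserved = vapply(lay$conserved, as.integer, integer(1)),
             functionality_label = "functional", notes = character(0))
    genes[[length(genes) + 1L]] <- g
    idx[unit] <- key
    coding <- paste(seq_ex, collapse = "")
    if (!coding %in% names(idx)) idx[coding] <- key
    # flat-file FT lines (1-based inclusive; complement() on minus)
    loc <- function(s, e) {
      if (!minus) sprintf("%d..%d", s + 1L, e)
      else sprintf("complement(%d..%d)", s + 1L, e)
    }
    addft <- function(label, s, e) {
      ft <<- c(ft,
        sprintf("FT   %-15s %s", label, loc(s, e)),
        sprintf("FT                   /IMGT_allele=\"%s\"", key))
    }
    addft(paste0(lay$type, "-GENE"), gstart, gend)
    for (r in seq_len(nrow(exdf))) addft(exdf$label[r], exdf$start[r],
                                         exdf$end[r])
    cons_label <- c(first_cys = "1st-CYST", second_cys = "2nd-CYST",
                    j_trp_phe = "J-TRP")
    for (w in names(cons_genomic)) {
      gp <- cons_genomic[[w]]
      if (!minus) addft(cons_label[[w]], gp, gp + 3L)
      else addft(cons_label[[w]], gp - 2L, gp + 1L)
    }
  }
  genome_parts <- c(genome_parts, .randSeq(100L, spec$gc))
  genome <- paste(genome_parts, collapse = "")
  refset <- new("ReferenceGeneSet", genes = genes, source_accession = acc,
                locus = locus, allele_index = idx)
  validObject(refset)
  sq <- paste0("     ",
               substring(tolower(genome),
                         seq(1L, nchar(genome), by = 60L),
                         pmin(seq(1L, nchar(genome), by = 60L) + 59L,
                              nchar(genome))))
  flat <- c(sprintf("ID   %s; SV 1; linear; genomic DNA; STD; SYN; %d BP.",
                    acc, nchar(genome)),
            "XX",
            sprintf("DE   synthetic %s locus reference", locus),
            "XX",
            "FH   Key             Location/Qualifiers",
            "FH",
            ft,
            "XX",
            sprintf("SQ   Sequence %d BP;", nchar(genome)),
            sq,
            "//")
  list(refset = refset, flatfile = flat,
       genome = stats::setNames(genome, acc))
}
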