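#' @include synthetic.R
NULL

# one RSS window sampled around the consensus using the current RNG stream
.rssWindow <- function(spacer_class, noise = 0.1, core_noise = noise / 5) {
  sp <- if (spacer_class == 12L) .RSS_SPACER12 else .RSS_SPACER23
  paste0(.mutateSeq(.RSS_HEPTAMER, core_noise), .mutateSeq(sp, noise),
         .mutateSeq(.RSS_NONAMER, core_noise))
}

# coding-piece bookkeeping for mutation operators --------------------------
.codingPieces <- function(pieces) {
  which(vapply(pieces, function(p) p$role == "exon", logical(1)))
}

# pick a codon-aligned coding offset in the middle of the largest exon,
# avoiding the start codon and conserved codons
.pickCodingCodon <- function(pieces, conserved) {
  idx <- .codingPieces(pieces)
  lens <- vapply(pieces[idx], function(p) nchar(p$seq), integer(1))
  big <- idx[which.max(lens)]
  cum <- 0L
  for (i in idx) {
    if (i == big) break
    cum <- cum + nchar(pieces[[i]]$seq)
  }
  w <- nchar(pieces[[big]]$seq)
  off <- cum + w %/% 2L
  off <- off - off %% 3L
  forbidden <- c(0L, unname(conserved))
  while (off %in% forbidden || off < cum || off + 3L > cum + w)
    off <- off + 3L
  list(piece = big, local = off - cum, global = off)
}

# apply one mutation operator to a gene's piece list (gene orientation)
.applyOperator <- function(pieces, conserved, op, n_len = 200L) {
  if (op == "introduce_stop") {
    k <- .pickCodingCodon(pieces, conserved)
    s <- pieces[[k$piece]]$seq
    substr(s, k$local + 1L, k$local + 3L) <- "TAA"
    pieces[[k$piece]]$seq <- s
  } else if (op == "delete_start") {
    i <- .codingPieces(pieces)[1]
    s <- pieces[[i]]$seq
    substr(s, 1L, 1L) <- "C"   # ATG -> CTG
    pieces[[i]]$seq <- s
  } else if (op == "frameshift_del1") {
    k <- .pickCodingCodon(pieces, conserved)
    s <- pieces[[k$piece]]$seq
    pieces[[k$piece]]$seq <- paste0(substr(s, 1L, k$local),
                                    substring(s, k$local + 2L))
  } else if (op == "scramble_rss") {
    ri <- which(vapply(pieces, function(p) p$role == "rss", logical(1)))
    if (!length(ri)) stop("scramble_rss: gene has no RSS")
    s <- pieces[[ri[1]]]$seq
    pieces[[ri[1]]]$seq <- .randSeq(nchar(s))
    pieces[[ri[1]]]$scrambled <- TRUE
  } else if (op == "gc_donor") {
    ii <- which(vapply(pieces, function(p) p$role == "intron", logical(1)))
    if (!length(ii)) stop("gc_donor: gene has no intron")
    s <- pieces[[ii[1]]]$seq
    substr(s, 2L, 2L) <- "C"   # GT -> GC
    pieces[[ii[1]]]$seq <- s
  } else if (op == "insert_n_gap") {
    idx <- .codingPieces(pieces)
    big <- idx[which.max(vapply(pieces[idx], function(p) nchar(p$seq),
                                integer(1)))]
    s <- pieces[[big]]$seq
    mid <- nchar(s) %/% 2L
    pieces[[big]]$seq <- paste0(substr(s, 1L, mid), strrep("N", n_len),
                                substring(s, mid + 1L))
  } else stop("unknown mutation operator: ", op)
  pieces
}

.EXPECTED_CALL <- c(none = "functional", introduce_stop = "pseudogene",
                    delete_start = "pseudogene",
                    frameshift_del1 = "pseudogene",
                    scramble_rss = "ORF", gc_donor = "ORF",
                    insert_n_gap = "withheld")

#' Plant a reference gene set into a synthetic target contig
#'
#' Genes are placed in reference order, each with its required flanking RSS
#' (spacer classes per the locus rules, heptamer abutting the coding
#' boundary), separated by i.i.d. background of the spec's composition, on
#' a randomly chosen strand per gene. Mutation operators — each applying
#' exactly one change — emulate the defect classes an annotator must
#' recognize: `introduce_stop`, `delete_start`, `frameshift_del1`,
#' `scramble_rss` (one flank), `gc_donor`, `insert_n_gap`.
#'
#' @param spec the [locusSpec()] the reference was generated from.
#' @param refset [ReferenceGeneSet-class] to plant.
#' @param mutations named character vector: gene*allele -> operator.
#' @param seed RNG seed (default spec seed + 1000).
#' @param rss_noise substitution rate used when sampling planted RSS from
#'   the consensus (used when no `rss_windows` pool is given).
#' @param rss_windows optional named list ("12", "23") of window pools —
#'   typically the very training sets the scan models were fitted on.
#'   Planted RSS are then resampled from the pool, which guarantees they
#'   score at or above the minimum training score and hence above the
#'   default threshold (minimum minus margin). Fresh consensus-noise draws
#'   (the default) carry a small tail risk of scoring below threshold.
#' @param n_gap_len N-run length for `insert_n_gap` (default 200).
#' @return list: `contig` (named sequence), `truth` (data.frame with one
#'   row per planted gene: name, segment_type, strand, operator, expected
#'   call, span and exon coordinates in list-columns `exons`, `rss`),
#'   `gff` (truth feature table for [writeGff3()]), `rss_truth`
#'   (data.frame of planted RSS windows).
#' @export
plantLocus <- function(spec, refset, mutations = character(0),
                       seed = spec$seed + 1000L, rss_noise = 0.1,
                       rss_windows = NULL, n_gap_len = 200L) {
  set.seed(seed)
  rules <- locusRules(spec$locus)
  draw_rss <- function(spacer) {
    pool <- rss_windows[[as.character(spacer)]]
    if (is.null(pool)) .rssWindow(spacer, rss_noise)
    else pool[[sample.int(length(pool), 1L)]]
  }
  contig_id <- paste0("tig", spec$seed)
  parts <- character(0)
  pos <- 0L
  truth <- list()
  rss_rows <- list()
  mutations <- unlist(mutations)
  strands <- sample(c("+", "-"), length(refset@genes), replace = TRUE)
  for (gi in seq_along(refset@genes)) {
    g <- refset@genes[[gi]]
    key <- paste0(g@name, "*", g@allele)
    op <- if (key %in% names(mutations)) unname(mutations[key]) else "none"
    bg <- .randSeq(sample(spec$intergenic[1]:spec$intergenic[2], 1L),
                   spec$gc)
    parts <- c(parts, bg); pos <- pos + nchar(bg)
    # pieces in gene orientation: exon/intron pieces from the reference
    # layout, plus flanking RSS pieces
    offs <- .exonOffsets(g)
    pieces <- list()
    if (g@segment_type == "J")
      pieces[[1]] <- list(label = "rss5", role = "rss",
                          seq = revComp(draw_rss(rules$j_spacer)),
                          spacer = rules$j_spacer, flank = "five")
    if (g@segment_type == "D" && rules$has_d)
      pieces[[length(pieces) + 1L]] <-
        list(label = "rss5", role = "rss",
             seq = revComp(draw_rss(rules$d_spacers[1])),
             spacer = rules$d_spacers[1], flank = "five")
    prev_end <- 0L
    for (i in seq_len(nrow(offs))) {
      if (offs$qstart[i] > prev_end)
        pieces[[length(pieces) + 1L]] <-
          list(label = "intron", role = "intron",
               seq = substr(g@seq_full, prev_end + 1L, offs$qstart[i]))
      pieces[[length(pieces) + 1L]] <-
        list(label = offs$label[i], role = "exon",
             seq = substr(g@seq_full, offs$qstart[i] + 1L, offs$qend[i]))
      prev_end <- offs$qend[i]
    }
    if (g@segment_type == "V")
      pieces[[length(pieces) + 1L]] <-
        list(label = "rss3", role = "rss",
             seq = draw_rss(rules$v_spacer),
             spacer = rules$v_spacer, flank = "three")
    if (g@segment_type == "D" && rules$has_d)
      pieces[[length(pieces) + 1L]] <-
        list(label = "rss3", role = "rss",
             seq = draw_rss(rules$d_spacers[2]),
             spacer = rules$d_spacers[2], flank = "three")
    if (op != "none")
      pieces <- .applyOperator(pieces, g@conserved, op, n_gap_len)
    unit <- paste(vapply(pieces, `[[`, character(1), "seq"), collapse = "")
    minus <- strands[gi] == "-"
    placed <- if (minus) revComp(unit) else unit
    ustart <- pos; uend <- pos + nchar(unit)
    # piece intervals on the contig (contig-forward)
    off <- 0L
    exdf <- NULL; rssdf <- NULL
    for (p in pieces) {
      w <- nchar(p$seq)
      iv <- if (!minus) c(ustart + off, ustart + off + w)
            else c(uend - off - w, uend - off)
      if (p$role == "exon")
        exdf <- rbind(exdf, data.frame(label = p$label, start = iv[1],
                                       end = iv[2],
                                       stringsAsFactors = FALSE))
      if (p$role == "rss" && !isTRUE(p$scrambled)) {
        # contig strand of the RSS reading direction
        rs <- if (p$flank == "three") strands[gi]
              else if (minus) "+" else "-"
        rssdf <- rbind(rssdf, data.frame(
          start = iv[1], end = iv[2], strand = rs,
          spacer_class = p$spacer, flank = p$flank,
          stringsAsFactors = FALSE))
      }
      off <- off + w
    }
    parts <- c(parts, placed); pos <- uend
    exdf <- exdf[order(exdf$start), , drop = FALSE]
    rownames(exdf) <- NULL
    truth[[length(truth) + 1L]] <- data.frame(
      name = key, segment_type = g@segment_type, strand = strands[gi],
      operator = op, expected = unname(.EXPECTED_CALL[op]),
      span_start = min(exdf$start), span_end = max(exdf$end),
      stringsAsFactors = FALSE)
    truth[[length(truth)]]$exons <- list(exdf)
    truth[[length(truth)]]$rss <- list(rssdf)
    if (!is.null(rssdf)) {
      rssdf$gene <- key
      rss_rows[[length(rss_rows) + 1L]] <- rssdf
    }
  }
  tail_bg <- .randSeq(sample(spec$intergenic[1]:spec$intergenic[2], 1L),
                      spec$gc)
  contig <- paste(c(parts, tail_bg), collapse = "")
  truth_df <- do.call(rbind, truth)
  rss_truth <- if (length(rss_rows)) do.call(rbind, rss_rows)
    else data.frame(start = integer(0), end = integer(0),
                    strand = character(0), spacer_class = integer(0),
                    flank = character(0), gene = character(0))
  gff <- .truthGff(truth_df, rss_truth, contig_id)
  list(contig = stats::setNames(contig, contig_id), truth = truth_df,
       gff = gff, rss_truth = rss_truth)
}

.truthGff <- function(truth_df, rss_truth, contig_id) {
  rows <- list()
  for (i in seq_len(nrow(truth_df))) {
    tr <- truth_df[i, ]
    gid <- sprintf("truth%03d", i)
    rows[[length(rows) + 1L]] <- gff3Features(
      GenomicInterval(contig_id, tr$span_start, tr$span_end, tr$strand),
      .SO_TYPE[[tr$segment_type]], gid, NA_character_, "truth",
      attrs = list(c(Name = tr$name, expected = tr$expected,
                     operator = tr$operator)))
    ex <- tr$exons[[1]]
    rows[[length(rows) + 1L]] <- gff3Features(
      GenomicInterval(contig_id, ex$start, ex$end, tr$strand), "exon",
      sprintf("%s.exon%d", gid, seq_len(nrow(ex))), gid, "truth")
  }
  if (nrow(rss_truth)) {
    rows[[length(rows) + 1L]] <- gff3Features(
      GenomicInterval(contig_id, rss_truth$start, rss_truth$end,
                      rss_truth$strand),
      "recombination_signal_sequence",
      sprintf("truthrss%03d", seq_len(nrow(rss_truth))), NA_character_,
      "truth",
      attrs = lapply(seq_len(nrow(rss_truth)), function(i)
        c(spacer_length = as.character(rss_truth$spacer_class[i]),
          associated_gene = rss_truth$gene[i])))
  }
  do.call(rbind, rows)
}

#' Apply divergence to a reference set
#'
#' Substitutes reference sequences i.i.d. at `rate`, emulating annotation
#' transfer from an increasingly distant donor species. Mutation sets are
#' nested across rates for a fixed seed: each position carries one uniform
#' draw, and is substituted (to one pre-drawn alternative base) whenever
#' the draw falls below `rate` — so the r = 0.10 reference contains every
#' change of the r = 0.05 one.
#'
#' @param refset [ReferenceGeneSet-class].
#' @param rate per-position substitution rate in `[0, 1)`.
#' @param seed RNG seed (fix it across rates to get nested mutation sets).
#' @return a new [ReferenceGeneSet-class] with mutated sequences
#'   (coordinates and conserved positions unchanged).
#' @export
divergeReferenceSet <- function(refset, rate, seed = 1L) {
  set.seed(seed)
  genes <- lapply(refset@genes, function(g) {
    L <- nchar(g@seq_full)
    u <- stats::runif(L)
    alt <- sample(3L, L, replace = TRUE)
    ch <- strsplit(g@seq_full, "", fixed = TRUE)[[1]]
    hit <- which(u < rate & ch %in% .BASES)
    for (i in hit) ch[i] <- setdiff(.BASES, ch[i])[alt[i]]
    g@seq_full <- paste(ch, collapse = "")
    offs <- .exonOffsets(g)
    g@seq_exons <- stats::setNames(
      vapply(seq_len(nrow(offs)), function(i)
        substr(g@seq_full, offs$qstart[i] + 1L, offs$qend[i]),
        character(1)),
      offs$label)
    g
  })
  idx <- character(0)
  for (g in genes) {
    if (!g@seq_full %in% names(idx))
      idx[g@seq_full] <- paste0(g@name, "*", g@allele)
  }
  new("ReferenceGeneSet", genes = genes,
      source_accession = paste0(refset@source_accession, "-div"),
      locus = refset@locus, allele_index = idx)
}
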