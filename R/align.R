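#' @include imgt.R
NULL

# Karlin-Altschul parameters for the +1/-2 (gap 5/2) nucleotide scoring
# used by the built-in aligner; good enough for an e-value style gate.
.KA_LAMBDA <- 1.28
.KA_K <- 0.46

.subMatrix <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- -2; m[, "N"] <- -2
  m
})

.bitScore <- function(raw) (.KA_LAMBDA * raw - log(.KA_K)) / log(2)
.eValue <- function(raw, m, n) m * n * 2^(-.bitScore(raw))

# k-mer index of a target sequence: data.table(kmer, tpos) (1-based tpos)
.kmerIndex <- function(target, k) {
  L <- nchar(target)
  if (L < k) return(data.table::data.table(kmer = character(0),
                                           tpos = integer(0)))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(target, starts, starts + k - 1L)
  dt <- data.table::data.table(kmer = kmers, tpos = starts)
  dt[!grepl("N", kmer, fixed = TRUE)]
}

# gap-free alignment blocks from a pairwise alignment (0-based half-open,
# query/target absolute offsets supplied by the caller)
.alignmentBlocks <- function(pat_chars, sub_chars, q0, t0) {
  qi <- q0; ti <- t0
  qs <- integer(0); qe <- integer(0); ts <- integer(0); te <- integer(0)
  open <- FALSE
  matches <- 0L
  for (k in seq_along(pat_chars)) {
    pg <- pat_chars[k] == "-"; sg <- sub_chars[k] == "-"
    if (!pg && !sg) {
      if (!open) {
        qs <- c(qs, qi); ts <- c(ts, ti); open <- TRUE
      }
      if (pat_chars[k] == sub_chars[k]) matches <- matches + 1L
      qi <- qi + 1L; ti <- ti + 1L
    } else {
      if (open) { qe <- c(qe, qi); te <- c(te, ti); open <- FALSE }
      if (!pg) qi <- qi + 1L
      if (!sg) ti <- ti + 1L
    }
  }
  if (open) { qe <- c(qe, qi); te <- c(te, ti) }
  list(blocks = data.frame(qs = qs, qe = qe, ts = ts, te = te),
       matches = matches, ncol = length(pat_chars))
}

#' Local alignment of a query against a target (built-in engine)
#'
#' Seed-and-extend local aligner: exact k-mer seeds are clustered by
#' diagonal, and each cluster is refined by Smith-Waterman with affine gaps
#' (via `Biostrings::pairwiseAlignment`). Multi-exon genes whose introns
#' diverge produce one local hit per conserved block, which downstream
#' chaining reassembles. Significance is reported as an approximate
#' Karlin-Altschul e-value so the same gates apply as for an external
#' engine.
#'
#' @param query query sequence (character scalar).
#' @param target target sequence (character scalar).
#' @param word_size exact seed length (default 11).
#' @param max_evalue report hits with e-value at or below this (default 10).
#' @param min_score minimum raw alignment score (default 2 * word_size).
#' @param target_index optional precomputed k-mer index of `target` (from
#'   repeated searches against one contig).
#' @return data.frame with columns qstart, qend, tstart, tend (0-based
#'   half-open), pident, length, score, bitscore, evalue, and a `blocks`
#'   list-column of gap-free aligned segments.
#' @export
alignLocal <- function(query, target, word_size = 11L, max_evalue = 10,
                       min_score = 2L * word_size, target_index = NULL) {
  qlen <- nchar(query); tlen <- nchar(target)
  empty <- data.frame(qstart = integer(0), qend = integer(0),
                      tstart = integer(0), tend = integer(0),
                      pident = numeric(0), length = integer(0),
                      score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0))
  empty$blocks <- list()
  if (qlen < word_size || tlen < word_size) return(empty)
  tidx <- if (is.null(target_index)) .kmerIndex(target, word_size)
          else target_index
  qstarts <- seq_len(qlen - word_size + 1L)
  qk <- data.table::data.table(
    kmer = substring(query, qstarts, qstarts + word_size - 1L),
    qpos = qstarts)
  seeds <- tidx[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(seeds) == 0L) return(empty)
  seeds[, diag := tpos - qpos]
  data.table::setorder(seeds, diag, tpos)
  band <- 40L; max_seed_gap <- 250L
  grp <- cumsum(c(1L, (diff(seeds$diag) > band) |
                      (abs(diff(seeds$tpos)) > max_seed_gap)))
  seeds[, cluster := grp]
  hits <- list()
  for (cl in split(seq_len(nrow(seeds)), grp)) {
    sqpos <- seeds$qpos[cl]; stpos <- seeds$tpos[cl]
    qlo <- min(sqpos); qhi <- max(sqpos) + word_size - 1L
    tlo <- min(stpos); thi <- max(stpos) + word_size - 1L
    # exact full-query shortcut: single diagonal, query fully matched
    d <- unique(seeds$diag[cl])
    if (length(d) == 1L) {
      t_start_full <- 1L + d
      if (t_start_full >= 1L && t_start_full + qlen - 1L <= tlen &&
          substring(target, t_start_full, t_start_full + qlen - 1L) == query) {
        hits[[length(hits) + 1L]] <- list(
          qstart = 0L, qend = qlen, tstart = t_start_full - 1L,
          tend = t_start_full - 1L + qlen, pident = 100,
          length = qlen, score = qlen,
          blocks = data.frame(qs = 0L, qe = qlen,
                              ts = t_start_full - 1L,
                              te = t_start_full - 1L + qlen))
        next
      }
    }
    # align only the query neighborhood of the seed cluster; a stray seed
    # far from any true hit then costs a small alignment, not a full SW
    pad <- 30L; pad_q <- 150L
    qs_w <- max(1L, qlo - pad_q)
    qe_w <- min(qlen, qhi + pad_q)
    ts <- max(1L, tlo - (qlo - qs_w) - pad)
    te <- min(tlen, thi + (qe_w - qhi) + pad)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substring(query, qs_w, qe_w)),
      Biostrings::DNAString(substring(target, ts, te)),
      type = "local", substitutionMatrix = .subMatrix,
      gapOpening = 5, gapExtension = 2)
    raw <- Biostrings::score(al)
    if (raw < min_score) next
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    q0 <- qs_w - 1L + Biostrings::start(Biostrings::pattern(al)) - 1L
    t0 <- ts - 1L + Biostrings::start(Biostrings::subject(al)) - 1L
    bl <- .alignmentBlocks(pat, sub, q0, t0)
    if (nrow(bl$blocks) == 0L) next
    hits[[length(hits) + 1L]] <- list(
      qstart = bl$blocks$qs[1], qend = bl$blocks$qe[nrow(bl$blocks)],
      tstart = bl$blocks$ts[1], tend = bl$blocks$te[nrow(bl$blocks)],
      pident = 100 * bl$matches / bl$ncol,
      length = bl$ncol, score = raw, blocks = bl$blocks)
  }
  if (!length(hits)) return(empty)
  df <- data.frame(
    qstart = vapply(hits, `[[`, integer(1), "qstart"),
    qend = vapply(hits, `[[`, integer(1), "qend"),
    tstart = vapply(hits, `[[`, integer(1), "tstart"),
    tend = vapply(hits, `[[`, integer(1), "tend"),
    pident = vapply(hits, `[[`, numeric(1), "pident"),
    length = vapply(hits, `[[`, integer(1), "length"),
    score = vapply(hits, `[[`, numeric(1), "score"))
  df$blocks <- lapply(hits, `[[`, "blocks")
  df <- df[!duplicated(df[, c("qstart", "qend", "tstart", "tend")]), ,
           drop = FALSE]
  df$bitscore <- .bitScore(df$score)
  df$evalue <- .eValue(df$score, qlen, tlen)
  df <- df[df$evalue <= max_evalue, , drop = FALSE]
  df <- df[order(-df$score, df$tstart), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# default per-segment-type search parameters
.defaultSearchParams <- function() {
  list(V = list(evalue = 1e-10, word = 11L, min_pident = 60, min_cov = 0,
                min_score = 22L),
       J = list(evalue = 1e-10, word = 11L, min_pident = 60, min_cov = 0,
                min_score = 22L),
       C = list(evalue = 1e-10, word = 11L, min_pident = 60, min_cov = 0,
                min_score = 22L),
       # D genes can be 10 nt: the raw-score floor must sit below a
       # perfect short match; e-value, identity, coverage and the
       # downstream D-without-RSS rule carry the specificity
       D = list(evalue = 10, word = 7L, min_pident = 80, min_cov = 0.9,
                min_score = 8L))
}

# flip hit query coordinates (and blocks) from revcomp(query) space back to
# the original query, and record minus strand; target coords stay forward.
.flipHitsToMinus <- function(hits, qlen) {
  if (nrow(hits) == 0L) return(hits)
  new_qstart <- qlen - hits$qend
  new_qend <- qlen - hits$qstart
  hits$blocks <- lapply(hits$blocks, function(b) {
    nb <- data.frame(qs = qlen - b$qe, qe = qlen - b$qs,
                     ts = b$ts, te = b$te)
    nb[order(nb$qs), , drop = FALSE]
  })
  hits$qstart <- new_qstart
  hits$qend <- new_qend
  hits$strand <- "-"
  hits
}

#' Homology search of a reference gene set against a contig
#'
#' Each reference gene's full genomic span (introns included) is the query.
#' Both strands are searched. D genes use short-sequence parameters (small
#' word size, relaxed e-value, near-full coverage required); V, J and C use
#' stringent e-values.
#'
#' @param refset a [ReferenceGeneSet-class].
#' @param contig_seq contig sequence (character scalar).
#' @param contig_id contig name.
#' @param params per-type parameter list; see `vdjloci:::.defaultSearchParams`.
#' @param engine "builtin" (default) or "blastn" (requires BLAST+ on PATH).
#' @return data.frame of local hits: gene, allele, segment_type, strand,
#'   qstart, qend, tstart, tend, pident, length, score, bitscore, evalue,
#'   blocks (list-column).
#' @export
searchHits <- function(refset, contig_seq, contig_id = "contig",
                       params = NULL, engine = c("builtin", "blastn")) {
  engine <- match.arg(engine)
  p <- .defaultSearchParams()
  if (!is.null(params)) for (ty in names(params))
    p[[ty]] <- utils::modifyList(p[[ty]], params[[ty]])
  if (engine == "blastn")
    return(.searchBlastn(refset, contig_seq, contig_id, p))
  idx <- list()
  out <- list()
  for (g in refset@genes) {
    pp <- p[[g@segment_type]]
    wkey <- as.character(pp$word)
    if (is.null(idx[[wkey]])) idx[[wkey]] <- .kmerIndex(contig_seq, pp$word)
    qlen <- nchar(g@seq_full)
    for (str in c("+", "-")) {
      q <- if (str == "+") g@seq_full else revComp(g@seq_full)
      h <- alignLocal(q, contig_seq, word_size = pp$word,
                      max_evalue = pp$evalue, min_score = pp$min_score,
                      target_index = idx[[wkey]])
      if (nrow(h) == 0L) next
      h$strand <- str
      if (str == "-") h <- .flipHitsToMinus(h, qlen)
      h <- h[h$pident >= pp$min_pident, , drop = FALSE]
      if (pp$min_cov > 0)
        h <- h[(h$qend - h$qstart) / qlen >= pp$min_cov, , drop = FALSE]
      if (nrow(h) == 0L) next
      h$gene <- g@name; h$allele <- g@allele
      h$segment_type <- g@segment_type
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) {
    e <- alignLocal("A", "A")  # typed empty frame
    e$strand <- character(0); e$gene <- character(0)
    e$allele <- character(0); e$segment_type <- character(0)
    return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# external engine: blastn with tabular output; blocks recomputed locally so
# exon projection has gap-free segments to work with
.searchBlastn <- function(refset, contig_seq, contig_id, p) {
  blastn <- Sys.which("blastn")
  if (blastn == "") stop("blastn not found on PATH")
  td <- tempfile("blast"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  tfa <- file.path(td, "target.fa")
  writeFasta(stats::setNames(contig_seq, contig_id), tfa)
  out <- list()
  for (ty in c("V", "D", "J", "C")) {
    genes <- Filter(function(g) g@segment_type == ty, refset@genes)
    if (!length(genes)) next
    qfa <- file.path(td, paste0("q", ty, ".fa"))
    qs <- stats::setNames(vapply(genes, function(g) g@seq_full, character(1)),
                          vapply(genes, function(g)
                            paste0(g@name, "*", g@allele), character(1)))
    writeFasta(qs, qfa)
    pp <- p[[ty]]
    args <- c("-query", qfa, "-subject", tfa, "-outfmt",
              shQuote("6 qseqid pident length qstart qend sstart send evalue bitscore score"),
              "-evalue", format(pp$evalue, scientific = TRUE),
              "-word_size", pp$word, "-dust", "no",
              if (ty == "D") c("-task", "blastn-short"))
    res <- suppressWarnings(system2(blastn, args, stdout = TRUE,
                                    stderr = TRUE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0L)
      stop("blastn failed: ", paste(res, collapse = "\n"))
    res <- res[nzchar(res)]
    if (!length(res)) next
    tab <- utils::read.table(text = res, sep = "\t", stringsAsFactors = FALSE)
    names(tab) <- c("qseqid", "pident", "length", "qstart", "qend",
                    "sstart", "send", "evalue", "bitscore", "score")
    for (r in seq_len(nrow(tab))) {
      minus <- tab$sstart[r] > tab$send[r]
      t0 <- (if (minus) tab$send[r] else tab$sstart[r]) - 1L
      t1 <- if (minus) tab$sstart[r] else tab$send[r]
      nm <- strsplit(tab$qseqid[r], "*", fixed = TRUE)[[1]]
      g <- genes[[match(tab$qseqid[r], names(qs))]]
      qlen <- nchar(g@seq_full)
      q0 <- tab$qstart[r] - 1L; q1 <- tab$qend[r]
      # re-derive gap-free blocks for this hit region
      qsub <- substring(g@seq_full, q0 + 1L, q1)
      tsub <- substring(contig_seq, t0 + 1L, t1)
      if (minus) tsub <- revComp(tsub)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(qsub), Biostrings::DNAString(tsub),
        type = "global", substitutionMatrix = .subMatrix,
        gapOpening = 5, gapExtension = 2)
      bl <- .alignmentBlocks(
        strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
        strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]],
        q0, 0L)
      blocks <- bl$blocks
      if (minus) {
        # blocks currently in revcomp(target-sub) space; map to forward
        w <- t1 - t0
        blocks <- data.frame(qs = blocks$qs, qe = blocks$qe,
                             ts = t0 + (w - blocks$te),
                             te = t0 + (w - blocks$ts))
      } else {
        blocks$ts <- blocks$ts + t0
        blocks$te <- blocks$te + t0
      }
      row <- data.frame(qstart = q0, qend = q1, tstart = t0, tend = t1,
                        pident = tab$pident[r], length = tab$length[r],
                        score = tab$score[r], bitscore = tab$bitscore[r],
                        evalue = tab$evalue[r],
                        strand = if (minus) "-" else "+",
                        gene = nm[1], allele = nm[2],
                        segment_type = ty, stringsAsFactors = FALSE)
      row$blocks <- list(blocks)
      pp2 <- p[[ty]]
      if (tab$pident[r] < pp2$min_pident) next
      if (pp2$min_cov > 0 && (q1 - q0) / qlen < pp2$min_cov) next
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    e <- alignLocal("A", "A")
    e$strand <- character(0); e$gene <- character(0)
    e$allele <- character(0); e$segment_type <- character(0)
    return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
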