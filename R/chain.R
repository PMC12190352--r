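#' @include align.R
NULL

#' ChainedCandidate: a chained homology hit forming one gene model
#'
#' Co-linear local hits to one reference gene, assembled into a candidate
#' gene model spanning introns, with reference exon boundaries projected
#' onto the target contig.
#'
#' @slot gene,allele reference gene identity.
#' @slot segment_type V, D, J or C.
#' @slot strand candidate strand on the contig.
#' @slot span [GenomicInterval-class] from first to last hit.
#' @slot hits data.frame of member local hits.
#' @slot blocks data.frame of gap-free aligned segments (query offsets in
#'   the reference full span, gene orientation; targets contig-forward).
#' @slot exon_map data.frame: label, start, end (contig-forward),
#'   qstart, qend (reference full-span offsets).
#' @slot completeness fraction of reference coding positions covered by
#'   aligned blocks.
#' @slot gap_overlap number of N bases inside the projected coding region.
#' @slot score summed bit score of the member hits.
#' @export
setClass("ChainedCandidate",
  representation(gene = "character", allele = "character",
                 segment_type = "character", strand = "character",
                 span = "GenomicInterval", hits = "data.frame",
                 blocks = "data.frame", exon_map = "data.frame",
                 completeness = "numeric", gap_overlap = "integer",
                 score = "numeric"))

setValidity("ChainedCandidate", function(object) {
  if (object@completeness < 0 || object@completeness > 1)
    return("completeness must be in [0, 1]")
  if (nrow(object@hits) < 1L) return("candidate must contain >= 1 hit")
  TRUE
})

setMethod("show", "ChainedCandidate", function(object) {
  cat(sprintf(
    "ChainedCandidate %s*%s [%s] %s:%d-%d(%s) %d hit(s), %.1f bits, %.0f%% complete\n",
    object@gene, object@allele, object@segment_type,
    contigId(object@span), start(object@span), end(object@span),
    object@strand, nrow(object@hits), object@score,
    100 * object@completeness))
})

# exon offsets within the full span, gene orientation, ordered 5'->3'
.exonOffsets <- function(gene) {
  sp <- gene@full_span
  minus <- strand(sp) == "-"
  ex <- gene@exons   # already ordered along the gene strand
  if (!minus) {
    qs <- ex$start - start(sp); qe <- ex$end - start(sp)
  } else {
    qs <- end(sp) - ex$end; qe <- end(sp) - ex$start
  }
  data.frame(label = ex$label, qstart = qs, qend = qe,
             stringsAsFactors = FALSE)
}

# project a query offset (base position) to a contig-forward position.
# blocks: data.frame(qs,qe,ts,te); cand_minus: candidate on contig minus
# strand (query ascending maps to target descending).
.projectPos <- function(q, blocks, cand_minus) {
  inb <- which(q >= blocks$qs & q < blocks$qe)
  if (length(inb)) {
    b <- blocks[inb[1], ]
    return(if (!cand_minus) b$ts + (q - b$qs) else b$te - 1L - (q - b$qs))
  }
  # nearest aligned query position, then linear interpolation
  cand_q <- c(blocks$qs, blocks$qe - 1L)
  near <- cand_q[which.min(abs(cand_q - q))]
  b <- blocks[which(near >= blocks$qs & near < blocks$qe)[1], ]
  t_near <- if (!cand_minus) b$ts + (near - b$qs) else b$te - 1L - (near - b$qs)
  if (!cand_minus) t_near + (q - near) else t_near - (q - near)
}

# nudge an exon boundary (in unaligned territory) onto a canonical GT/AG
# splice site within +/- adjust nt; positions are gene-oriented query
# offsets already projected to target coordinates.
.spliceAdjust <- function(tpos, kind, contig_seq, cand_minus, adjust = 6L) {
  L <- nchar(contig_seq)
  base_at <- function(p) substring(contig_seq, p + 1L, p + 2L)
  want <- if (!cand_minus) {
    if (kind == "donor") "GT" else "AG"
  } else {
    if (kind == "donor") "AC" else "CT"   # revcomp of GT / AG
  }
  # donor: first 2 intron bases; acceptor: last 2 intron bases
  probe <- function(p) {
    at <- switch(paste(kind, if (cand_minus) "-" else "+"),
      "donor +" = p, "acceptor +" = p - 2L,
      "donor -" = p - 2L, "acceptor -" = p)
    if (at < 0L || at + 2L > L) return(FALSE)
    base_at(at) == want
  }
  if (probe(tpos)) return(tpos)
  for (d in seq_len(adjust)) {
    if (probe(tpos + d)) return(tpos + d)
    if (probe(tpos - d)) return(tpos - d)
  }
  tpos
}

#' Chain co-linear local hits into candidate gene models
#'
#' Dynamic-programming chaining of hits that share one reference gene and
#' strand: chains maximize summed bit score over strictly co-linear hits
#' (increasing in query and in strand-normalized target coordinates) whose
#' consecutive target gaps do not exceed `max_intron` and query gaps do not
#' exceed `query_gap_slack`. Each hit joins at most one chain; chains are
#' peeled off best-first. Reference exon boundaries are projected onto the
#' target through the chain's aligned blocks, with nearest-aligned-position
#' interpolation inside unaligned gaps and a GT/AG nearest-splice-site
#' adjustment (within 6 nt) for boundaries landing in unaligned territory.
#'
#' @param hits data.frame of local hits for one reference gene and strand
#'   (rows of [searchHits()] output).
#' @param ref_gene the [ReferenceGene-class] the hits refer to.
#' @param contig_seq contig sequence; enables the splice-site adjustment
#'   and N-gap counting (may be NULL).
#' @param contig_id contig name.
#' @param max_intron maximum target gap between consecutive hits (default
#'   16000 nt, sized for kilobase-scale C-gene introns).
#' @param query_gap_slack maximum query gap between consecutive hits
#'   (default 50 nt).
#' @return list of [ChainedCandidate-class], best chain first.
#' @export
chainHits <- function(hits, ref_gene, contig_seq = NULL,
                      contig_id = "contig", max_intron = 16000L,
                      query_gap_slack = 50L) {
  if (nrow(hits) == 0L) return(list())
  if (length(unique(hits$strand)) != 1L)
    stop("chainHits expects hits on a single strand")
  minus <- hits$strand[1] == "-"
  # strand-normalized target keys: v ascending along the gene
  vs <- if (!minus) hits$tstart else -hits$tend
  ve <- if (!minus) hits$tend else -hits$tstart
  chains <- list()
  remaining <- seq_len(nrow(hits))
  while (length(remaining)) {
    h <- hits[remaining, , drop = FALSE]
    hvs <- vs[remaining]; hve <- ve[remaining]
    o <- order(h$qstart, hvs)
    n <- length(o)
    best <- h$bitscore[o]
    prev <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1L)) {
        a <- o[i]; b <- o[j]
        if (h$qend[a] > h$qstart[b]) next
        if (hve[a] > hvs[b]) next
        if (hvs[b] - hve[a] > max_intron) next
        if (h$qstart[b] - h$qend[a] > query_gap_slack) next
        cand <- best[i] + h$bitscore[o[j]]
        if (cand > best[j]) { best[j] <- cand; prev[j] <- i }
      }
    }
    jbest <- which.max(best)
    path <- integer(0); j <- jbest
    while (!is.na(j)) { path <- c(j, path); j <- prev[j] }
    members <- remaining[o[path]]
    chains[[length(chains) + 1L]] <- members
    remaining <- setdiff(remaining, members)
  }
  lapply(chains, function(members) {
    .buildCandidate(hits[members, , drop = FALSE], ref_gene, contig_seq,
                    contig_id)
  })
}

.buildCandidate <- function(h, ref_gene, contig_seq, contig_id) {
  minus <- h$strand[1] == "-"
  blocks <- do.call(rbind, h$blocks)
  blocks <- blocks[order(blocks$qs), , drop = FALSE]
  rownames(blocks) <- NULL
  offs <- .exonOffsets(ref_gene)
  covered_in <- function(q) any(q >= blocks$qs & q < blocks$qe)
  em <- lapply(seq_len(nrow(offs)), function(i) {
    q0 <- offs$qstart[i]; q1 <- offs$qend[i] - 1L
    t_first <- .projectPos(q0, blocks, minus)
    t_last <- .projectPos(q1, blocks, minus)
    if (!minus) { ts <- t_first; te <- t_last + 1L }
    else { ts <- t_last; te <- t_first + 1L }
    # splice adjustment only for boundaries interpolated into unaligned gaps
    if (!is.null(contig_seq) && nrow(offs) > 1L) {
      if (i < nrow(offs) && !covered_in(q1)) {
        # exon 3' end -> intron donor just after (gene orientation)
        if (!minus) te <- .spliceAdjust(te, "donor", contig_seq, minus)
        else ts <- .spliceAdjust(ts, "donor", contig_seq, minus)
      }
      if (i > 1L && !covered_in(q0)) {
        if (!minus) ts <- .spliceAdjust(ts, "acceptor", contig_seq, minus)
        else te <- .spliceAdjust(te, "acceptor", contig_seq, minus)
      }
    }
    data.frame(label = offs$label[i], start = ts, end = te,
               qstart = offs$qstart[i], qend = offs$qend[i],
               stringsAsFactors = FALSE)
  })
  exon_map <- do.call(rbind, em)
  # completeness: coding positions covered by aligned blocks
  tot <- 0L; cov <- 0L
  for (i in seq_len(nrow(offs))) {
    qq <- seq(offs$qstart[i], offs$qend[i] - 1L)
    tot <- tot + length(qq)
    for (bi in seq_len(nrow(blocks)))
      qq <- qq[!(qq >= blocks$qs[bi] & qq < blocks$qe[bi])]
    cov <- cov + (offs$qend[i] - offs$qstart[i] - length(qq))
  }
  gap_n <- 0L
  if (!is.null(contig_seq)) {
    for (i in seq_len(nrow(exon_map))) {
      s <- substring(contig_seq, exon_map$start[i] + 1L, exon_map$end[i])
      gap_n <- gap_n + sum(strsplit(s, "", fixed = TRUE)[[1]] == "N")
    }
  }
  span <- GenomicInterval(contig_id, min(h$tstart), max(h$tend),
                          h$strand[1])
  new("ChainedCandidate", gene = h$gene[1], allele = h$allele[1],
      segment_type = h$segment_type[1], strand = h$strand[1], span = span,
      hits = h, blocks = blocks, exon_map = exon_map,
      completeness = if (tot > 0L) cov / tot else 0,
      gap_overlap = as.integer(gap_n), score = sum(h$bitscore))
}

# total overlap between a candidate's coding projection and a set of
# accepted intervals, as a fraction of the candidate's coding length
.codingOverlapFrac <- function(cand, accepted) {
  if (!length(accepted)) return(0)
  own <- cand@exon_map
  own_len <- sum(own$end - own$start)
  ov <- 0L
  for (a in accepted) {
    if (contigId(a@span)[1] != contigId(cand@span)[1]) next
    am <- a@exon_map
    for (i in seq_len(nrow(own))) for (j in seq_len(nrow(am)))
      ov <- ov + max(0L, min(own$end[i], am$end[j]) -
                         max(own$start[i], am$start[j]))
  }
  ov / own_len
}

#' Select non-redundant candidates per segment type
#'
#' Greedy selection: candidates are ranked by (summed bit score desc,
#' completeness desc, reference name asc) and accepted unless their coding
#' projection overlaps an already accepted candidate of the same segment
#' type by more than `overlap_frac` of their own coding length. The result
#' is deterministic and invariant to input order.
#'
#' @param chains list of [ChainedCandidate-class] (any mix of genes and
#'   types).
#' @param overlap_frac maximum tolerated coding overlap fraction
#'   (default 0.5).
#' @return list of accepted [ChainedCandidate-class], in ranking order.
#' @export
selectCandidates <- function(chains, overlap_frac = 0.5) {
  if (!length(chains)) return(list())
  key <- order(
    -vapply(chains, function(x) x@score, numeric(1)),
    -vapply(chains, function(x) x@completeness, numeric(1)),
    vapply(chains, function(x) paste0(x@gene, "*", x@allele), character(1)),
    vapply(chains, function(x) start(x@span), integer(1)))
  accepted <- list()
  for (i in key) {
    cand <- chains[[i]]
    same <- Filter(function(a) a@segment_type == cand@segment_type,
                   accepted)
    if (.codingOverlapFrac(cand, same) <= overlap_frac)
      accepted[[length(accepted) + 1L]] <- cand
  }
  accepted
}
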