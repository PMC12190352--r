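#' @include chain.R ric.R gff3.R
NULL

# per-locus RSS spacer requirements (12/23 rule); user-overridable
.LOCUS_RULES <- list(
  IGH = list(v = 23L, d = c(12L, 12L), j = 23L),
  IGK = list(v = 12L, d = NULL, j = 23L),
  IGL = list(v = 23L, d = NULL, j = 12L),
  TRA = list(v = 23L, d = NULL, j = 12L),
  TRB = list(v = 23L, d = c(12L, 23L), j = 12L),
  TRD = list(v = 23L, d = c(12L, 23L), j = 12L),
  TRG = list(v = 23L, d = NULL, j = 12L))

#' Per-locus RSS spacer rules
#'
#' Returns the spacer classes expected for each required RSS flank at a
#' locus: V genes carry an RSS 3' of the coding end, J genes 5' of the
#' coding start, and D genes (IGH, TRB, TRD) both. The table encodes the
#' 12/23 rule and can be overridden field by field.
#'
#' @param locus one of IGH, IGK, IGL, TRA, TRB, TRG, TRD.
#' @param overrides named list overriding `v_spacer`, `j_spacer`,
#'   `d_spacers` or `has_d`.
#' @return list with locus, v_spacer, j_spacer, d_spacers (length-2 integer
#'   c(five, three) or NULL), has_d.
#' @export
locusRules <- function(locus, overrides = NULL) {
  if (!locus %in% names(.LOCUS_RULES)) stop("unknown locus: ", locus)
  r <- .LOCUS_RULES[[locus]]
  rules <- list(locus = locus, v_spacer = r$v, j_spacer = r$j,
                d_spacers = r$d, has_d = !is.null(r$d))
  if (!is.null(overrides)) rules <- utils::modifyList(rules, overrides)
  if (rules$has_d && is.null(rules$d_spacers))
    stop("has_d locus needs d_spacers")
  rules
}

# contig coordinate of the candidate's coding start / end boundary
.codingBoundary <- function(cand, which = c("start", "end")) {
  which <- match.arg(which)
  em <- cand@exon_map
  minus <- cand@strand == "-"
  if (which == "start") {
    if (!minus) em$start[1] else em$end[1]
  } else {
    if (!minus) em$end[nrow(em)] else em$start[nrow(em)]
  }
}

#' Match predicted RSS to a candidate gene's flanks
#'
#' For each flank the segment type requires (V: 3' of the coding end;
#' J: 5' of the coding start; D: both), the highest-scoring candidate RSS
#' of the correct spacer class and orientation whose heptamer edge lies
#' within `tolerance` nt of the gene boundary is selected; ties go to the
#' smaller start coordinate. No match is a classification input, not an
#' error. C genes require no RSS.
#'
#' @param cand a [ChainedCandidate-class].
#' @param rss RSS candidate data.frame from [scanRss()] (or
#'   [bedToCandidates()]).
#' @param rules locus rules from [locusRules()].
#' @param tolerance maximum heptamer-to-boundary distance in nt (default 3).
#' @return named list of flanks ("five"/"three"), each NULL (flank not
#'   required), or a list(required=TRUE, match=<rss row or NULL>).
#' @export
matchRss <- function(cand, rss, rules, tolerance = 3L) {
  ty <- cand@segment_type
  res <- list(five = NULL, three = NULL)
  wanted <- switch(ty,
    V = list(three = rules$v_spacer),
    J = list(five = rules$j_spacer),
    D = if (rules$has_d) list(five = rules$d_spacers[1],
                              three = rules$d_spacers[2]) else list(),
    C = list())
  for (flank in names(wanted)) {
    spacer <- wanted[[flank]]
    # heptamer must point toward the gene: 3' flank RSS reads on the gene
    # strand, 5' flank RSS on the opposite strand
    need_strand <- if (flank == "three") cand@strand
                   else if (cand@strand == "+") "-" else "+"
    boundary <- if (flank == "three") .codingBoundary(cand, "end")
                else .codingBoundary(cand, "start")
    hitset <- rss[rss$spacer_class == spacer & rss$strand == need_strand &
                  abs(rss$heptamer_boundary - boundary) <= tolerance, ,
                  drop = FALSE]
    match <- NULL
    if (nrow(hitset)) {
      hitset <- hitset[order(-hitset$score, hitset$start), , drop = FALSE]
      match <- hitset[1, , drop = FALSE]
    }
    res[[flank]] <- list(required = TRUE, match = match)
  }
  res
}

#' Verify splice sites of a multi-exon candidate
#'
#' Every intron implied by the exon map is checked for the canonical donor
#' "GT" at its first two bases and acceptor "AG" at its last two (read in
#' gene orientation). Single-exon candidates pass vacuously.
#'
#' @param cand a [ChainedCandidate-class].
#' @param contig_seq contig sequence.
#' @return list(ok = logical, introns = data.frame(donor, acceptor, ok)).
#' @export
verifySplice <- function(cand, contig_seq) {
  em <- cand@exon_map
  n <- nrow(em)
  if (n < 2L)
    return(list(ok = TRUE, introns = data.frame(donor = character(0),
                                                acceptor = character(0),
                                                ok = logical(0))))
  minus <- cand@strand == "-"
  rows <- lapply(seq_len(n - 1L), function(i) {
    if (!minus) { s <- em$end[i]; e <- em$start[i + 1L] }
    else { s <- em$end[i + 1L]; e <- em$start[i] }
    if (e - s < 4L)
      return(data.frame(donor = "", acceptor = "", ok = FALSE))
    iv <- GenomicInterval(contigId(cand@span), s, e, cand@strand)
    iseq <- intervalSeq(iv, stats::setNames(contig_seq,
                                            contigId(cand@span)))
    donor <- substr(iseq, 1L, 2L)
    acceptor <- substr(iseq, nchar(iseq) - 1L, nchar(iseq))
    data.frame(donor = donor, acceptor = acceptor,
               ok = donor == "GT" & acceptor == "AG",
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, rows)
  list(ok = all(introns$ok), introns = introns)
}

# candidate coding sequence: coding exons concatenated in gene orientation
.candidateCodingSeq <- function(cand, contig_seq) {
  em <- cand@exon_map
  em <- em[!em$label %in% .C_NONCODING, , drop = FALSE]
  seqs <- intervalSeq(
    GenomicInterval(contigId(cand@span), em$start, em$end, cand@strand),
    stats::setNames(contig_seq, contigId(cand@span)))
  paste(seqs, collapse = "")
}

# map a reference coding offset to a candidate coding offset through the
# aligned blocks; NA when the position is unaligned
.refCodingToCandCoding <- function(ref_off, ref_gene, cand) {
  offs <- .exonOffsets(ref_gene)
  offs <- offs[!offs$label %in% .C_NONCODING, , drop = FALSE]
  # coding offset -> full-span query offset
  cum <- 0L; q <- NA_integer_
  for (i in seq_len(nrow(offs))) {
    w <- offs$qend[i] - offs$qstart[i]
    if (ref_off < cum + w) { q <- offs$qstart[i] + (ref_off - cum); break }
    cum <- cum + w
  }
  if (is.na(q)) return(NA_integer_)
  b <- cand@blocks
  inb <- which(q >= b$qs & q < b$qe)
  if (!length(inb)) return(NA_integer_)
  minus <- cand@strand == "-"
  tpos <- if (!minus) b$ts[inb[1]] + (q - b$qs[inb[1]])
          else b$te[inb[1]] - 1L - (q - b$qs[inb[1]])
  # contig position -> candidate coding offset
  em <- cand@exon_map
  em <- em[!em$label %in% .C_NONCODING, , drop = FALSE]
  cum <- 0L
  for (i in seq_len(nrow(em))) {
    if (tpos >= em$start[i] && tpos < em$end[i]) {
      within <- if (!minus) tpos - em$start[i] else em$end[i] - 1L - tpos
      return(cum + within)
    }
    cum <- cum + em$end[i] - em$start[i]
  }
  NA_integer_
}

#' Check coding integrity of a candidate against its reference
#'
#' Assembles the spliced coding sequence from the exon map and checks: the
#' start codon (V genes: first codon must be ATG), internal stop codons,
#' reading-frame conservation (coding-length difference vs the reference
#' must be a multiple of 3), and the conserved residues (V: both cysteines;
#' J: the tryptophan/phenylalanine) at positions projected from the
#' reference through the alignment.
#'
#' @param cand a [ChainedCandidate-class].
#' @param contig_seq contig sequence.
#' @param ref_gene the matched [ReferenceGene-class].
#' @return list: coding_seq, start_codon_ok (NA unless V), internal_stop,
#'   first_stop (0-based codon index or NA), frameshift, conserved_ok
#'   (named logical), frame.
#' @export
checkCoding <- function(cand, contig_seq, ref_gene) {
  coding <- .candidateCodingSeq(cand, contig_seq)
  ty <- cand@segment_type
  frame <- 0L
  if (ty == "J" && "j_trp_phe" %in% names(ref_gene@conserved))
    frame <- ref_gene@conserved[["j_trp_phe"]] %% 3L
  start_ok <- if (ty == "V") substr(coding, 1L, 3L) == "ATG" else NA
  if (ty == "D") {
    # D segments have no intrinsic reading frame (set by rearrangement);
    # stop and frameshift checks do not apply
    internal_stop <- FALSE; first_stop <- NA_integer_; frameshift <- FALSE
  } else {
    aa <- translateDna(coding, frame)
    stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
    internal_stop <- stops[1] != -1L
    first_stop <- if (internal_stop) stops[1] - 1L else NA_integer_
    ref_coding <- referenceCodingSeq(ref_gene)
    frameshift <- (nchar(coding) - nchar(ref_coding)) %% 3L != 0L
  }
  conserved_ok <- logical(0)
  for (w in names(ref_gene@conserved)) {
    co <- .refCodingToCandCoding(ref_gene@conserved[[w]], ref_gene, cand)
    ok <- FALSE
    if (!is.na(co)) {
      codon_aa <- translateDna(substr(coding, co + 1L, co + 3L))
      ok <- if (w == "j_trp_phe") codon_aa %in% c("W", "F")
            else codon_aa == "C"
    }
    conserved_ok[w] <- ok
  }
  list(coding_seq = coding, start_codon_ok = start_ok,
       internal_stop = internal_stop, first_stop = first_stop,
       frameshift = frameshift, conserved_ok = conserved_ok, frame = frame)
}

#' Classify functionality from a verification report
#'
#' Pseudogene-class defects: internal stop codon, frameshift, missing start
#' codon (V). ORF-class defects: missing required RSS, non-canonical splice
#' motifs, missing conserved residues. Any pseudogene-class code forces
#' "pseudogene"; otherwise any ORF-class code gives "ORF"; otherwise the
#' gene is "functional". Incomplete candidates are withheld upstream of
#' this call.
#'
#' @param rss_res result of [matchRss()].
#' @param splice_res result of [verifySplice()].
#' @param coding_res result of [checkCoding()].
#' @param segment_type V, D, J or C.
#' @return list(functionality, reasons).
#' @export
classifyFunctionality <- function(rss_res, splice_res, coding_res,
                                  segment_type) {
  reasons <- character(0)
  if (coding_res$internal_stop) reasons <- c(reasons, "INTERNAL_STOP")
  if (coding_res$frameshift) reasons <- c(reasons, "FRAMESHIFT")
  if (segment_type == "V" && isFALSE(coding_res$start_codon_ok))
    reasons <- c(reasons, "NO_START")
  for (flank in c("five", "three")) {
    f <- rss_res[[flank]]
    if (!is.null(f) && f$required && is.null(f$match))
      reasons <- c(reasons, "RSS_MISSING")
  }
  if (!splice_res$ok) reasons <- c(reasons, "NONCANONICAL_SPLICE")
  cns <- coding_res$conserved_ok
  if (any(!cns[names(cns) %in% c("first_cys", "second_cys")]))
    reasons <- c(reasons, "MISSING_CONSERVED_CYS")
  if (any(!cns[names(cns) == "j_trp_phe"]))
    reasons <- c(reasons, "MISSING_CONSERVED_WF")
  reasons <- unique(reasons)
  pseudo <- c("INTERNAL_STOP", "FRAMESHIFT", "NO_START")
  functionality <- if (any(reasons %in% pseudo)) "pseudogene"
    else if (length(reasons)) "ORF" else "functional"
  list(functionality = functionality, reasons = reasons)
}

#' SHA-1 hex digest of a sequence string
#' @param s character scalar.
#' @return 40-character lowercase hex digest.
#' @export
sha1Hex <- function(s) digest::digest(s, algo = "sha1", serialize = FALSE)

#' Assign a gene*allele name to a candidate sequence
#'
#' An exact match of the coding nucleotide sequence in the reference allele
#' index returns that gene*allele name. A novel sequence is named after the
#' best-matching reference gene with an allele suffix made of the first
#' four lowercase hex characters of the SHA-1 digest of the sequence; a
#' prefix collision between distinct sequences is disambiguated by
#' appending "_2", "_3", ...
#'
#' @param seq uppercase ungapped coding nucleotide sequence.
#' @param allele_index named map (sequence -> "gene*allele") from the
#'   [ReferenceGeneSet-class].
#' @param base_gene base gene name of the best-scoring reference hit.
#' @param used named character of names already assigned in this run
#'   (name -> sequence), for collision handling.
#' @return list(name, novel).
#' @export
assignName <- function(seq, allele_index, base_gene, used = character(0)) {
  if (!nzchar(seq)) stop("cannot name an empty sequence")
  if (seq %in% names(allele_index))
    return(list(name = unname(allele_index[seq]), novel = FALSE))
  nm <- paste0(base_gene, "*", substr(sha1Hex(seq), 1L, 4L))
  k <- 2L
  base <- nm
  while (nm %in% names(used) && used[[nm]] != seq) {
    nm <- paste0(base, "_", k)
    k <- k + 1L
  }
  list(name = nm, novel = TRUE)
}

.SO_TYPE <- c(V = "V_gene_segment", D = "D_gene_segment",
              J = "J_gene_segment", C = "C_gene_segment")

#' AnnotatedFeature: a classified, named gene annotation
#'
#' @slot candidate the underlying [ChainedCandidate-class].
#' @slot functionality "functional", "ORF" or "pseudogene".
#' @slot reasons machine-readable defect codes (empty when functional).
#' @slot assigned_name gene*allele name.
#' @slot matched_rss data.frame of matched RSS candidates (0 rows if none).
#' @slot report verification details (rss/splice/coding results).
#' @export
setClass("AnnotatedFeature",
  representation(candidate = "ChainedCandidate", functionality = "character",
                 reasons = "character", assigned_name = "character",
                 matched_rss = "data.frame", report = "list"))

setValidity("AnnotatedFeature", function(object) {
  pseudo <- c("INTERNAL_STOP", "FRAMESHIFT", "NO_START")
  f <- object@functionality
  if (!f %in% c("functional", "ORF", "pseudogene"))
    return("functionality must be functional/ORF/pseudogene")
  if (f == "functional" && length(object@reasons))
    return("functional features must have no reason codes")
  if (f == "pseudogene" && !any(object@reasons %in% pseudo))
    return("pseudogene requires a pseudogene-class reason code")
  if (f == "ORF" && (!length(object@reasons) ||
                     any(object@reasons %in% pseudo)))
    return("ORF requires ORF-class reason codes only")
  TRUE
})

setMethod("show", "AnnotatedFeature", function(object) {
  cat(sprintf("AnnotatedFeature %s [%s] %s:%d-%d(%s) %s%s\n",
              object@assigned_name, object@candidate@segment_type,
              contigId(object@candidate@span),
              start(object@candidate@span), end(object@candidate@span),
              object@candidate@strand, object@functionality,
              if (length(object@reasons))
                paste0(" (", paste(object@reasons, collapse = ","), ")")
              else ""))
})

#' Annotate a locus on a novel contig
#'
#' Runs the full annotation: homology search, chaining and candidate
#' selection per segment type in the order V, D, J, C; then per candidate
#' RSS matching, splice verification, coding checks, functionality
#' classification, and allele naming. Candidates that are incomplete
#' (aligned coverage of the reference coding region below
#' `completeness_min`, or any N inside the projected coding region) are
#' withheld from the output and logged. D candidates with no matched RSS on
#' either flank are likewise withheld: a D segment is defined by its
#' flanking RSS pair, and unanchored short matches are indistinguishable
#' from background.
#'
#' @param refset [ReferenceGeneSet-class] reference annotation.
#' @param contig_seq novel contig sequence (character scalar).
#' @param contig_id contig name.
#' @param rss RSS candidate data.frame (from [scanRss()] or
#'   [bedToCandidates()]).
#' @param rules locus rules from [locusRules()]; defaults to the reference
#'   set's locus.
#' @param params optional per-type search parameter overrides.
#' @param engine "builtin" or "blastn".
#' @param rss_tolerance heptamer-to-boundary tolerance in nt (default 3).
#' @param completeness_min minimum covered coding fraction (default 0.95).
#' @param max_intron,query_gap_slack chaining limits (see [chainHits()]).
#' @param overlap_frac candidate-selection overlap limit.
#' @param source GFF3 source column value.
#' @return list: `features` (list of [AnnotatedFeature-class]), `gff`
#'   (GFF3 feature table incl. exon/CDS children and RSS features),
#'   `withheld` (data.frame log of suppressed candidates).
#' @export
annotateLocus <- function(refset, contig_seq, contig_id = "contig",
                          rss, rules = NULL, params = NULL,
                          engine = c("builtin", "blastn"),
                          rss_tolerance = 3L, completeness_min = 0.95,
                          max_intron = 16000L, query_gap_slack = 50L,
                          overlap_frac = 0.5, source = "vdjloci") {
  engine <- match.arg(engine)
  if (!is.character(contig_seq) || !nzchar(contig_seq))
    stop("contig_seq must be a non-empty sequence string")
  if (length(refset@genes) == 0L) stop("reference gene set is empty")
  if (is.null(rules)) rules <- locusRules(refset@locus)
  hits <- searchHits(refset, contig_seq, contig_id, params, engine)
  ref_by_name <- stats::setNames(refset@genes, geneNames(refset))
  withheld <- list()
  features <- list()
  used_names <- character(0)
  accepted_all <- list()
  for (ty in c("V", "D", "J", "C")) {
    th <- hits[hits$segment_type == ty, , drop = FALSE]
    chains <- list()
    if (nrow(th)) {
      keys <- paste0(th$gene, "*", th$allele, "/", th$strand)
      for (k in unique(keys)) {
        sub <- th[keys == k, , drop = FALSE]
        rg <- ref_by_name[[paste0(sub$gene[1], "*", sub$allele[1])]]
        chains <- c(chains, chainHits(sub, rg, contig_seq, contig_id,
                                      max_intron, query_gap_slack))
      }
    }
    accepted_all <- c(accepted_all, selectCandidates(chains, overlap_frac))
  }
  for (cand in accepted_all) {
    rg <- ref_by_name[[paste0(cand@gene, "*", cand@allele)]]
    if (cand@completeness < completeness_min || cand@gap_overlap > 0L) {
      withheld[[length(withheld) + 1L]] <- data.frame(
        gene = cand@gene, allele = cand@allele,
        segment_type = cand@segment_type,
        start = start(cand@span), end = end(cand@span),
        cause = if (cand@gap_overlap > 0L) "ASSEMBLY_GAP" else "INCOMPLETE",
        stringsAsFactors = FALSE)
      next
    }
    rss_res <- matchRss(cand, rss, rules, rss_tolerance)
    n_matched <- sum(vapply(rss_res, function(f)
      !is.null(f) && !is.null(f$match), logical(1)))
    if (cand@segment_type == "D" && n_matched == 0L) {
      withheld[[length(withheld) + 1L]] <- data.frame(
        gene = cand@gene, allele = cand@allele, segment_type = "D",
        start = start(cand@span), end = end(cand@span),
        cause = "D_WITHOUT_RSS", stringsAsFactors = FALSE)
      next
    }
    splice_res <- verifySplice(cand, contig_seq)
    coding_res <- checkCoding(cand, contig_seq, rg)
    cls <- classifyFunctionality(rss_res, splice_res, coding_res,
                                 cand@segment_type)
    nm <- assignName(coding_res$coding_seq, refset@allele_index,
                     cand@gene, used_names)
    used_names[nm$name] <- coding_res$coding_seq
    matched <- do.call(rbind, Filter(Negate(is.null),
      lapply(rss_res, function(f) if (!is.null(f)) f$match)))
    if (is.null(matched))
      matched <- data.frame(contig = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            spacer_class = integer(0), score = numeric(0),
                            heptamer_boundary = integer(0))
    features[[length(features) + 1L]] <- new("AnnotatedFeature",
      candidate = cand, functionality = cls$functionality,
      reasons = cls$reasons, assigned_name = nm$name,
      matched_rss = matched,
      report = list(rss = rss_res, splice = splice_res,
                    coding = coding_res))
  }
  gff <- .featuresToGff(features, contig_id, nchar(contig_seq), source)
  withheld_df <- if (length(withheld)) do.call(rbind, withheld)
    else data.frame(gene = character(0), allele = character(0),
                    segment_type = character(0), start = integer(0),
                    end = integer(0), cause = character(0))
  list(features = features, gff = gff, withheld = withheld_df)
}

# render annotated features (plus their RSS) as a GFF3 feature table
.featuresToGff <- function(features, contig_id, contig_len, source) {
  rows <- list()
  rss_seen <- character(0)
  for (i in seq_along(features)) {
    f <- features[[i]]
    cand <- f@candidate
    gid <- sprintf("gene%03d", i)
    em <- cand@exon_map
    gene_iv <- GenomicInterval(contig_id, min(em$start), max(em$end),
                               cand@strand)
    rows[[length(rows) + 1L]] <- gff3Features(
      gene_iv, .SO_TYPE[[cand@segment_type]], gid, NA_character_, source,
      attrs = list(c(Name = f@assigned_name,
                     functionality = f@functionality,
                     if (length(f@reasons))
                       c(notes = paste(f@reasons, collapse = ",")))))
    o <- order(em$start)
    emo <- em[o, , drop = FALSE]
    ex_iv <- GenomicInterval(contig_id, emo$start, emo$end, cand@strand)
    rows[[length(rows) + 1L]] <- gff3Features(
      ex_iv, "exon", sprintf("%s.exon%d", gid, seq_len(nrow(emo))), gid,
      source)
    # CDS children with phase, in gene orientation
    emg <- em[!em$label %in% .C_NONCODING, , drop = FALSE]
    lens <- emg$end - emg$start
    cum <- c(0L, cumsum(lens))[seq_len(nrow(emg))]
    phase <- (3L - (cum %% 3L)) %% 3L
    cds_iv <- GenomicInterval(contig_id, emg$start, emg$end, cand@strand)
    rows[[length(rows) + 1L]] <- gff3Features(
      cds_iv, "CDS", sprintf("%s.cds%d", gid, seq_len(nrow(emg))), gid,
      source, phase = phase)
    if (nrow(f@matched_rss)) {
      for (r in seq_len(nrow(f@matched_rss))) {
        m <- f@matched_rss[r, ]
        rid <- sprintf("rss_%d_%d_%s", m$start, m$spacer_class, m$strand)
        if (rid %in% rss_seen) next
        rss_seen <- c(rss_seen, rid)
        rows[[length(rows) + 1L]] <- gff3Features(
          GenomicInterval(contig_id, m$start, m$end, m$strand),
          "recombination_signal_sequence", rid, NA_character_, source,
          score = round(m$score, 3),
          attrs = list(c(spacer_length = as.character(m$spacer_class),
                         associated_gene = f@assigned_name)))
      }
    }
  }
  if (!length(rows))
    return(gff3Features(GenomicInterval(character(0), integer(0),
                                        integer(0)),
                        character(0), character(0)))
  do.call(rbind, rows)
}
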