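#' @include GenomicInterval-class.R
NULL

#' ReferenceGene: one reference IG/TR gene segment
#'
#' Holds a reference segment (V, D, J or C) with its exon substructure,
#' extracted sequences, and conserved-residue positions. Coordinates are
#' contig-forward 0-based half-open on the source reference sequence; the
#' full span runs from the first exon start to the last exon end, introns
#' included — the full genomic span, not just the coding exons, is what
#' seeds the homology search in a novel contig.
#'
#' @slot name gene name, e.g. "IGHV1-1".
#' @slot allele allele designation, e.g. "01".
#' @slot segment_type "V", "D", "J" or "C".
#' @slot locus locus code (IGH, IGK, IGL, TRA, TRB, TRG, TRD).
#' @slot exons data.frame with columns label, start, end (contig-forward,
#'   ordered along the gene strand).
#' @slot full_span [GenomicInterval-class] of length 1.
#' @slot seq_full full-span nucleotide sequence (gene orientation).
#' @slot seq_exons named character vector of per-exon sequences.
#' @slot conserved named integer: 0-based nucleotide offsets of codons in
#'   the coding sequence (`first_cys`, `second_cys`, `j_trp_phe`); may be
#'   empty.
#' @slot functionality_label functionality string from the source file, or NA.
#' @slot notes passthrough notes (unrecognized labels etc.).
#' @export
setClass("ReferenceGene",
  representation(name = "character", allele = "character",
                 segment_type = "character", locus = "character",
                 exons = "data.frame", full_span = "GenomicInterval",
                 seq_full = "character", seq_exons = "character",
                 conserved = "integer", functionality_label = "character",
                 notes = "character"))

setValidity("ReferenceGene", function(object) {
  if (!object@segment_type %in% c("V", "D", "J", "C"))
    return("segment_type must be one of V, D, J, C")
  ex <- object@exons
  if (nrow(ex) < 1L) return("gene must have at least one exon")
  o <- order(ex$start)
  if (any(ex$end[o][-nrow(ex)] > ex$start[o][-1]))
    return("exons overlap")
  if (start(object@full_span) > min(ex$start) ||
      end(object@full_span) < max(ex$end))
    return("full_span does not contain every exon")
  if (object@segment_type == "V" &&
      sum(ex$label == "L-PART1") > 1L)
    return("V gene with more than one L-PART1")
  TRUE
})

setMethod("show", "ReferenceGene", function(object) {
  cat(sprintf("ReferenceGene %s*%s [%s, %s] %s:%d-%d(%s) %d exon(s)\n",
              object@name, object@allele, object@segment_type, object@locus,
              contigId(object@full_span), start(object@full_span),
              end(object@full_span), strand(object@full_span),
              nrow(object@exons)))
})

#' ReferenceGeneSet: a locus worth of reference genes
#'
#' @slot genes list of [ReferenceGene-class].
#' @slot source_accession accession of the source annotation.
#' @slot locus locus code.
#' @slot allele_index named character vector mapping exact uppercase
#'   full-span sequence to "gene*allele".
#' @export
setClass("ReferenceGeneSet",
  representation(genes = "list", source_accession = "character",
                 locus = "character", allele_index = "character"))

setValidity("ReferenceGeneSet", function(object) {
  if (!all(vapply(object@genes, is, logical(1), "ReferenceGene")))
    return("genes must all be ReferenceGene objects")
  loci <- vapply(object@genes, function(g) g@locus, character(1))
  if (length(loci) && !all(loci == object@locus))
    return("every gene must belong to the declared locus")
  if (anyDuplicated(names(object@allele_index)))
    return("allele_index keys must be mutually distinct")
  TRUE
})

#' @export
setMethod("length", "ReferenceGeneSet", function(x) length(x@genes))

#' @export
setMethod("[[", "ReferenceGeneSet", function(x, i) x@genes[[i]])

setMethod("show", "ReferenceGeneSet", function(object) {
  types <- vapply(object@genes, function(g) g@segment_type, character(1))
  cat(sprintf("ReferenceGeneSet (%s, %s): %d genes [%s]\n",
              object@locus, object@source_accession, length(object@genes),
              paste(sprintf("%s:%d", names(table(types)), table(types)),
                    collapse = " ")))
})

#' Names of the genes in a reference set
#' @param set a [ReferenceGeneSet-class].
#' @return character vector "gene*allele".
#' @export
geneNames <- function(set) {
  vapply(set@genes, function(g) paste0(g@name, "*", g@allele), character(1))
}

# ---- EMBL/IMGT location expression grammar -------------------------------
# n..m | complement(expr) | join(expr, ...) | order(expr, ...) | n
# fuzzy markers < > are stripped and recorded as partial.
.parseLocation <- function(expr, label = "?") {
  partial <- grepl("[<>]", expr)
  s <- gsub("[<> ]", "", expr)
  if (nchar(gsub("[^(]", "", s)) != nchar(gsub("[^)]", "", s)))
    stop("unbalanced parentheses in location of feature ", label)
  rec <- function(s, minus) {
    if (grepl("^complement\\(", s)) {
      inner <- substr(s, 12L, nchar(s) - 1L)
      return(rec(inner, !minus))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\(", "", s)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      # split on commas at depth 0
      chars <- strsplit(inner, "", fixed = TRUE)[[1]]
      depth <- cumsum((chars == "(") - (chars == ")"))
      cuts <- which(chars == "," & depth == 0L)
      bounds <- c(0L, cuts, length(chars) + 1L)
      parts <- vapply(seq_len(length(bounds) - 1L), function(i)
        paste(chars[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = ""),
        character(1))
      return(do.call(rbind, lapply(parts, rec, minus = minus)))
    }
    m <- regmatches(s, regexec("^(\\d+)\\.\\.(\\d+)$", s))[[1]]
    if (length(m) == 3L) {
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (is.na(a) || is.na(b) || a > b)
        stop("bad location bounds in feature ", label, ": ", s)
      return(data.frame(start = a - 1L, end = b,
                        strand = if (minus) "-" else "+"))
    }
    if (grepl("^\\d+$", s)) {
      a <- as.integer(s)
      return(data.frame(start = a - 1L, end = a,
                        strand = if (minus) "-" else "+"))
    }
    stop("cannot parse location of feature ", label, ": ", s)
  }
  parts <- rec(s, FALSE)
  parts <- parts[order(parts$start), , drop = FALSE]
  rownames(parts) <- NULL
  list(parts = parts, strand = parts$strand[1], partial = partial)
}

#' Parse an EMBL/IMGT flat file
#'
#' Reads the `FT` feature-table block of an IMGT/LIGM-DB style flat file.
#' Locations support `n..m`, `complement(...)`, `join(...)`/`order(...)`,
#' nesting, and fuzzy `<`/`>` markers (stripped and recorded as a partial
#' flag). 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. The `SQ` block, when present, is returned
#' as the normalized sequence.
#'
#' @param text flat-file content: a single string or a character vector of
#'   lines (or a file path to read).
#' @return list with elements `features` (data.frame: label, start, end,
#'   strand, partial, plus list-columns `parts` and `qualifiers`),
#'   `accession`, and `sequence` (NA if no SQ block).
#' @export
parseFlatfile <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  accession <- NA_character_
  idl <- grep("^ID   ", text, value = TRUE)
  if (length(idl))
    accession <- sub(";.*$", "", sub("^ID   +", "", idl[1]))
  ft <- text[grepl("^FT ", text)]
  feats <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    loc <- .parseLocation(cur$loc, cur$label)
    feats[[length(feats) + 1L]] <<- list(
      label = cur$label, parts = loc$parts, strand = loc$strand,
      partial = loc$partial, qualifiers = cur$quals)
    cur <<- NULL
  }
  for (line in ft) {
    key <- trimws(substr(line, 6L, 20L))
    rest <- trimws(substr(line, 21L, nchar(line)))
    if (nzchar(key)) {
      flush()
      cur <- list(label = key, loc = rest, quals = character(0))
    } else if (is.null(cur)) {
      next
    } else if (grepl("^/", rest)) {
      m <- regmatches(rest, regexec('^/([A-Za-z0-9_]+)(="?(.*?)"?)?$', rest))[[1]]
      q <- stats::setNames(if (length(m) >= 4L) m[4] else "", m[2])
      cur$quals <- c(cur$quals, q)
    } else {
      cur$loc <- paste0(cur$loc, rest)   # wrapped location
    }
  }
  flush()
  seq <- NA_character_
  sq_at <- grep("^SQ ", text)
  if (length(sq_at)) {
    end_at <- grep("^//", text)
    end_at <- if (length(end_at)) end_at[1] else length(text) + 1L
    body <- text[(sq_at[1] + 1L):(end_at - 1L)]
    seq <- .normalizeSeq(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  features <- data.frame(
    label = vapply(feats, `[[`, character(1), "label"),
    start = vapply(feats, function(f) min(f$parts$start), integer(1)),
    end = vapply(feats, function(f) max(f$parts$end), integer(1)),
    strand = vapply(feats, `[[`, character(1), "strand"),
    partial = vapply(feats, `[[`, logical(1), "partial"),
    stringsAsFactors = FALSE)
  features$parts <- lapply(feats, `[[`, "parts")
  features$qualifiers <- lapply(feats, `[[`, "qualifiers")
  list(features = features, accession = accession, sequence = seq)
}

# label lexicon: which FT labels mean which segment type / role
.V_CODING <- c("L-PART1", "L-PART2", "V-EXON", "V-REGION")
.C_CODING <- c("C-REGION", "CH1", "H", "H1", "H2", "CH2", "CH3", "CH4",
               "CH-S", "M", "M1", "M2", "EX1", "EX2", "EX3", "EX4")
.C_NONCODING <- c("EX4UTR")
.CONSERVED <- c("1st-CYST", "2nd-CYST", "J-TRP", "J-PHE")
.GENE_CONTAINERS <- c("V-GENE", "D-GENE", "J-GENE", "C-GENE")
.RSS_LABELS <- c("V-RS", "J-RS", "D-RS", "5'D-RS", "3'D-RS",
                 "V-HEPTAMER", "V-NONAMER", "V-SPACER",
                 "J-HEPTAMER", "J-NONAMER", "J-SPACER")

.segTypeOf <- function(labels) {
  if (any(labels %in% c("V-EXON", "V-REGION", "L-PART1", "L-PART2"))) "V"
  else if (any(labels == "D-REGION")) "D"
  else if (any(labels == "J-REGION")) "J"
  else if (any(labels %in% c(.C_CODING, .C_NONCODING))) "C"
  else NA_character_
}

# genomic position (contig-forward) -> 0-based offset in the coding sequence
# exons: ordered along gene strand
.genomicToCoding <- function(pos, exons, minus) {
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i]
    if (!minus) {
      if (pos >= exons$start[i] && pos < exons$end[i])
        return(off + (pos - exons$start[i]))
    } else {
      if (pos >= exons$start[i] && pos < exons$end[i])
        return(off + (exons$end[i] - 1L - pos))
    }
    off <- off + w
  }
  NA_integer_
}

#' Build a reference gene set from a parsed flat file
#'
#' Groups feature-table entries into genes by their `IMGT_allele` (or
#' `gene`/`allele`) qualifiers, extracts per-exon and full-span sequences
#' (reverse-complemented for minus-strand genes), and records conserved
#' cysteine / tryptophan-phenylalanine codon positions from the
#' `1st-CYST` / `2nd-CYST` / `J-TRP` / `J-PHE` labels when present. Unknown
#' labels are kept as passthrough notes and never abort the parse; genes
#' with zero locatable exons are skipped and reported in the parse log
#' (`attr(, "parse_log")`).
#'
#' @param parsed result of [parseFlatfile()], or a feature data.frame.
#' @param genome_seq reference sequence as a single (optionally named)
#'   character string; defaults to the flat file's own SQ block.
#' @param locus locus code for the set.
#' @return a [ReferenceGeneSet-class]; skipped-gene messages in
#'   `attr(, "parse_log")`.
#' @export
buildGeneSet <- function(parsed, genome_seq = NULL, locus) {
  if (is.data.frame(parsed)) parsed <- list(features = parsed,
                                            accession = NA_character_,
                                            sequence = NA_character_)
  if (is.null(genome_seq)) {
    if (is.na(parsed$sequence)) stop("no genome sequence available")
    genome_seq <- parsed$sequence
  }
  contig <- names(genome_seq) %||% parsed$accession %||% "ref"
  if (is.na(contig)) contig <- "ref"
  genome <- stats::setNames(unname(genome_seq), contig)
  ft <- parsed$features
  log <- character(0)

  qual <- function(i, keys) {
    q <- ft$qualifiers[[i]]
    for (k in keys) if (k %in% names(q)) return(unname(q[k]))
    NA_character_
  }
  # group key: IMGT_allele ("GENE*01") or gene+allele quals
  keys <- vapply(seq_len(nrow(ft)), function(i) {
    a <- qual(i, "IMGT_allele")
    if (!is.na(a)) return(a)
    g <- qual(i, "gene")
    if (!is.na(g)) {
      al <- qual(i, "allele")
      return(paste0(g, "*", if (is.na(al)) "01" else al))
    }
    NA_character_
  }, character(1))
  # orphan features (no gene qualifier) get deterministic per-label names
  orphan <- is.na(keys) & !ft$label %in% c(.GENE_CONTAINERS, .RSS_LABELS)
  if (any(orphan)) {
    ords <- stats::ave(seq_len(nrow(ft)), ft$label, FUN = seq_along)
    keys[orphan] <- paste0(ft$label[orphan], "-", ords[orphan], "*01")
  }

  genes <- list()
  idx <- character(0)
  for (key in unique(keys[!is.na(keys)])) {
    rows <- which(keys == key)
    labels <- ft$label[rows]
    st <- .segTypeOf(labels)
    known_coding <- switch(st,
      V = .V_CODING, D = "D-REGION", J = "J-REGION", C = .C_CODING, character(0))
    # V genes annotated with both V-EXON and V-REGION: V-REGION is contained
    # in V-EXON; prefer the exon-level labels
    if (!is.na(st) && st == "V" && "V-EXON" %in% labels)
      known_coding <- setdiff(known_coding, "V-REGION")
    ex_rows <- rows[labels %in% known_coding]
    unknown <- setdiff(labels,
      c(known_coding, "V-REGION", .C_NONCODING, .CONSERVED,
        .GENE_CONTAINERS, .RSS_LABELS))
    notes <- if (length(unknown))
      paste0("unrecognized label(s): ", paste(unique(unknown), collapse = ","))
      else character(0)
    if (is.na(st) || length(ex_rows) == 0L) {
      log <- c(log, paste0("skipped '", key, "': no locatable exons (labels: ",
                           paste(labels, collapse = ","), ")"))
      next
    }
    # expand join() parts into individual exon rows
    exdf <- do.call(rbind, lapply(ex_rows, function(i) {
      p <- ft$parts[[i]]
      data.frame(label = if (nrow(p) > 1L)
                   paste0(ft$label[i], ".", seq_len(nrow(p)))
                 else ft$label[i],
                 start = p$start, end = p$end, stringsAsFactors = FALSE)
    }))
    minus <- ft$strand[rows[1]] == "-"
    exdf <- exdf[order(exdf$start, decreasing = minus), , drop = FALSE]
    rownames(exdf) <- NULL
    span <- GenomicInterval(contig, min(exdf$start), max(exdf$end),
                            if (minus) "-" else "+")
    exon_iv <- GenomicInterval(contig, exdf$start, exdf$end,
                               if (minus) "-" else "+")
    seq_full <- intervalSeq(span, genome)
    seq_ex <- stats::setNames(intervalSeq(exon_iv, genome), exdf$label)
    coding <- paste(seq_ex, collapse = "")
    # conserved residue codons, from explicit labels
    cons <- integer(0)
    for (i in rows[labels %in% .CONSERVED]) {
      pos0 <- if (minus) ft$end[i] - 1L else ft$start[i]
      offs <- .genomicToCoding(pos0, exdf, minus)
      if (is.na(offs)) next
      aa <- translateDna(substr(coding, offs + 1L, offs + 3L))
      slot_name <- switch(ft$label[i],
        "1st-CYST" = "first_cys", "2nd-CYST" = "second_cys",
        "J-TRP" = "j_trp_phe", "J-PHE" = "j_trp_phe")
      ok <- switch(slot_name, first_cys = , second_cys = aa == "C",
                   j_trp_phe = aa %in% c("W", "F"))
      if (isTRUE(ok)) cons[slot_name] <- offs
      else notes <- c(notes, paste0(ft$label[i], " codon does not translate ",
                                    "to the expected residue; ignored"))
    }
    nm_allele <- strsplit(key, "*", fixed = TRUE)[[1]]
    g <- new("ReferenceGene", name = nm_allele[1],
             allele = if (length(nm_allele) > 1L) nm_allele[2] else "01",
             segment_type = st, locus = locus, exons = exdf,
             full_span = span, seq_full = seq_full, seq_exons = seq_ex,
             conserved = cons,
             functionality_label = {
               f <- vapply(rows, function(i) qual(i, "functional") %||%
                             qual(i, "IMGT_functionality") %||% NA_character_,
                           character(1))
               f <- f[!is.na(f)]
               if (length(f)) f[1] else NA_character_
             },
             notes = notes)
    genes[[length(genes) + 1L]] <- g
    # index both the full span and the spliced coding sequence, so exact
    # re-discoveries resolve to the reference allele either way
    if (!seq_full %in% names(idx)) idx[seq_full] <- key
    else log <- c(log, paste0("duplicate full-span sequence: '", key,
                              "' not indexed (kept '", idx[seq_full], "')"))
    if (!coding %in% names(idx)) idx[coding] <- key
  }
  # conserved-position fallback: borrow via translated alignment from the
  # closest same-type gene that has them
  genes <- .fillConservedByAlignment(genes, log_env = environment())
  set <- new("ReferenceGeneSet", genes = genes,
             source_accession = parsed$accession %||% "synthetic",
             locus = locus, allele_index = idx)
  validObject(set)
  attr(set, "parse_log") <- log
  set
}

# For genes missing conserved positions, align the translated coding
# sequence to the closest same-type gene that has them and project the
# offsets through the alignment. Leaves them unset when no donor exists.
.fillConservedByAlignment <- function(genes, log_env) {
  types <- vapply(genes, function(g) g@segment_type, character(1))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (!g@segment_type %in% c("V", "J")) next
    want <- if (g@segment_type == "V") c("first_cys", "second_cys")
            else "j_trp_phe"
    if (all(want %in% names(g@conserved))) next
    donors <- which(types == g@segment_type &
                    vapply(genes, function(d)
                      all(want %in% names(d@conserved)), logical(1)))
    donors <- setdiff(donors, i)
    if (!length(donors)) next
    aa_g <- translateDna(referenceCodingSeq(g))
    best <- NULL; best_score <- -Inf
    for (d in donors) {
      aa_d <- translateDna(referenceCodingSeq(genes[[d]]))
      al <- Biostrings::pairwiseAlignment(aa_d, aa_g, type = "global-local",
                                          gapOpening = 10, gapExtension = 1)
      if (Biostrings::score(al) > best_score) {
        best_score <- Biostrings::score(al); best <- list(d = d, al = al)
      }
    }
    if (is.null(best)) next
    dgene <- genes[[best$d]]
    for (w in setdiff(want, names(g@conserved))) {
      aa_pos_d <- dgene@conserved[[w]] %/% 3L + 1L
      mapped <- .mapAlignedPosition(best$al, aa_pos_d)
      if (is.na(mapped)) next
      codon <- substr(referenceCodingSeq(g), (mapped - 1L) * 3L + 1L,
                      (mapped - 1L) * 3L + 3L)
      aa <- translateDna(codon)
      ok <- if (w == "j_trp_phe") aa %in% c("W", "F") else aa == "C"
      if (ok) {
        cons <- g@conserved
        cons[w] <- (mapped - 1L) * 3L
        g@conserved <- cons
      }
    }
    genes[[i]] <- g
  }
  genes
}

# map a 1-based pattern position through a pairwise alignment to the subject
.mapAlignedPosition <- function(al, ppos) {
  pr <- Biostrings::aligned(Biostrings::pattern(al))
  sr <- Biostrings::aligned(Biostrings::subject(al))
  p <- strsplit(as.character(pr), "")[[1]]
  s <- strsplit(as.character(sr), "")[[1]]
  pi <- Biostrings::start(Biostrings::pattern(al)) - 1L
  si <- Biostrings::start(Biostrings::subject(al)) - 1L
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-" && pi == ppos)
      return(if (s[k] != "-") si else NA_integer_)
  }
  NA_integer_
}

#' Concatenated coding sequence of a reference gene
#' @param gene a [ReferenceGene-class].
#' @return character scalar (exons concatenated in gene orientation).
#' @export
referenceCodingSeq <- function(gene) paste(gene@seq_exons, collapse = "")

#' Convert a reference gene set to BED records
#'
#' One record per exon plus one per full gene span; names encode
#' `gene|allele|label` (label "span" for the full span).
#'
#' @param set a [ReferenceGeneSet-class].
#' @return list(intervals, name, score) suitable for [writeBed()].
#' @export
geneSetToBed <- function(set) {
  ivs <- list(); nms <- character(0)
  for (g in set@genes) {
    strand <- strand(g@full_span)
    ex_iv <- GenomicInterval(contigId(g@full_span), g@exons$start,
                             g@exons$end, strand)
    ivs[[length(ivs) + 1L]] <- ex_iv
    nms <- c(nms, paste(g@name, g@allele, g@exons$label, sep = "|"))
    ivs[[length(ivs) + 1L]] <- g@full_span
    nms <- c(nms, paste(g@name, g@allele, "span", sep = "|"))
  }
  if (!length(ivs))
    return(list(intervals = GenomicInterval(character(0), integer(0),
                                            integer(0)),
                name = character(0), score = numeric(0)))
  list(intervals = do.call(c, ivs), name = nms,
       score = rep(0, length(nms)))
}
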