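#' @name gff3
#' @title GFF3 reading and writing
#'
#' @description
#' Features are represented as a data.frame with columns `contig`, `start`,
#' `end` (0-based half-open), `strand`, `type` (Sequence Ontology term),
#' `source`, `score` (numeric or NA), `phase` (0/1/2 or NA), `ID`, `Parent`
#' (NA for roots), and a list-column `attrs` of additional named attribute
#' vectors. Coordinates are converted to the 1-based inclusive GFF3
#' convention only at the file boundary.
#'
#' The writer emits `##gff-version 3` first, one `##sequence-region` pragma
#' per contig, percent-encodes the reserved characters in attribute values,
#' places children after their parents, and orders features
#' deterministically by (contig, start, ID). CDS features must carry a
#' phase; a dangling `Parent` reference is an error.
NULL

#' Construct a GFF3 feature table
#'
#' @param intervals [GenomicInterval-class] vector.
#' @param type SO feature types (recycled).
#' @param ID unique feature identifiers.
#' @param Parent parent IDs (NA for top-level features).
#' @param source source column (default "vdjloci").
#' @param score numeric or NA.
#' @param phase integer 0/1/2 or NA; required for CDS.
#' @param attrs list of named character vectors of extra attributes.
#' @return data.frame as described in [gff3].
#' @export
gff3Features <- function(intervals, type, ID, Parent = NA_character_,
                         source = "vdjloci", score = NA_real_,
                         phase = NA_integer_, attrs = NULL) {
  stopifnot(is(intervals, "GenomicInterval"))
  n <- length(intervals)
  if (is.null(attrs)) attrs <- rep(list(character(0)), n)
  df <- data.frame(contig = contigId(intervals), start = start(intervals),
                   end = end(intervals), strand = strand(intervals),
                   type = rep_len(type, n), source = rep_len(source, n),
                   score = rep_len(score, n),
                   phase = rep_len(as.integer(phase), n),
                   ID = rep_len(ID, n),
                   Parent = rep_len(Parent, n),
                   stringsAsFactors = FALSE)
  df$attrs <- attrs
  df
}

# reserved characters in attribute values; % first so encoding is idempotent
.gffEscape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

.gffUnescape <- function(x) {
  vapply(x, function(s) utils::URLdecode(s), character(1), USE.NAMES = FALSE)
}

.checkGffFrame <- function(features) {
  need <- c("contig", "start", "end", "strand", "type", "source", "score",
            "phase", "ID", "Parent", "attrs")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(features$ID[!is.na(features$ID)]))
    stop("duplicate feature ID: ",
         features$ID[duplicated(features$ID) & !is.na(features$ID)][1])
  dangling <- !is.na(features$Parent) &
    !(features$Parent %in% features$ID)
  if (any(dangling))
    stop("dangling Parent reference: ", features$Parent[dangling][1])
  cds_nophase <- features$type == "CDS" & is.na(features$phase)
  if (any(cds_nophase))
    stop("CDS feature without phase: ", features$ID[cds_nophase][1])
  invisible(features)
}

# parent-first, (contig, start, ID)-sorted traversal order
.gffOrder <- function(features) {
  n <- nrow(features)
  ord <- order(features$contig, features$start, features$ID)
  children <- split(seq_len(n), factor(features$Parent, exclude = NULL))
  roots <- ord[is.na(features$Parent[ord])]
  out <- integer(0)
  stack <- rev(roots)
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, i)
    kids <- children[[features$ID[i]]]
    if (!is.null(kids) && length(kids)) {
      kids <- kids[order(features$contig[kids], features$start[kids],
                         features$ID[kids])]
      stack <- c(stack, rev(kids))
    }
  }
  out
}

#' Write features as GFF3
#'
#' @param features feature table as produced by [gff3Features()].
#' @param seqlens named integer vector of contig lengths for the
#'   `##sequence-region` pragmas; derived from feature extents when NULL.
#' @param path output path.
#' @seealso [readGff3()]
#' @export
writeGff3 <- function(features, path, seqlens = NULL) {
  .checkGffFrame(features)
  if (nrow(features) &&
      (any(features$start < 0) | any(features$end <= features$start)))
    stop("invalid interval in feature table")
  contigs <- sort(unique(features$contig))
  if (is.null(seqlens)) {
    seqlens <- vapply(contigs, function(cg)
      max(features$end[features$contig == cg]), numeric(1))
  }
  ord <- .gffOrder(features)
  if (length(ord) != nrow(features))
    stop("feature parent graph is not a forest (cycle or orphan)")
  f <- features[ord, , drop = FALSE]
  attr_str <- vapply(seq_len(nrow(f)), function(i) {
    parts <- character(0)
    if (!is.na(f$ID[i])) parts <- paste0("ID=", .gffEscape(f$ID[i]))
    if (!is.na(f$Parent[i]))
      parts <- c(parts, paste0("Parent=", .gffEscape(f$Parent[i])))
    a <- f$attrs[[i]]
    if (length(a))
      parts <- c(parts, paste0(names(a), "=", .gffEscape(unname(a))))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }, character(1))
  lines <- c("##gff-version 3",
             paste("##sequence-region", contigs, 1L,
                   as.integer(seqlens[contigs])),
             paste(f$contig, f$source, f$type,
                   f$start + 1L, f$end,
                   ifelse(is.na(f$score), ".", format(f$score, trim = TRUE,
                                                      scientific = FALSE)),
                   f$strand,
                   ifelse(is.na(f$phase), ".", as.character(f$phase)),
                   attr_str, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file
#'
#' Requires the `##gff-version 3` pragma on the first line; fails with the
#' line number on malformed rows (column count != 9). Coordinates are
#' back-converted to 0-based half-open; percent-encoded attribute values are
#' decoded; `Parent` references are checked against the IDs present.
#'
#' @param path GFF3 file path.
#' @return feature table in the layout of [gff3Features()], plus a
#'   `seqlens` attribute with the `##sequence-region` lengths.
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0L || !grepl("^##gff-version(\\s+3)?\\s*$", raw[1]))
    stop("missing ##gff-version 3 pragma on line 1")
  seq_re <- "^##sequence-region\\s+(\\S+)\\s+(\\d+)\\s+(\\d+)"
  sr <- regmatches(raw, regexec(seq_re, raw))
  sr <- sr[lengths(sr) == 4L]
  seqlens <- stats::setNames(
    as.integer(vapply(sr, `[`, character(1), 4L)),
    vapply(sr, `[`, character(1), 2L))
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  rows <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 9L))
    stop("GFF3 line ", lineno[which(nf != 9L)[1]],
         ": expected 9 tab-separated columns, found ", nf[nf != 9L][1])
  col <- function(i) vapply(rows, `[`, character(1), i)
  s1 <- suppressWarnings(as.integer(col(4)))
  e1 <- suppressWarnings(as.integer(col(5)))
  badc <- is.na(s1) | is.na(e1)
  if (any(badc))
    stop("GFF3 line ", lineno[which(badc)[1]], ": non-integer coordinates")
  attrs_raw <- col(9)
  parsed <- lapply(attrs_raw, function(a) {
    if (a == ".") return(character(0))
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- vapply(kv, function(p)
      .gffUnescape(if (length(p) >= 2L) p[2] else ""), character(1))
    names(vals) <- vapply(kv, `[`, character(1), 1L)
    vals
  })
  getattr <- function(key) vapply(parsed, function(a)
    if (key %in% names(a)) unname(a[[key]]) else NA_character_, character(1))
  ID <- getattr("ID"); Parent <- getattr("Parent")
  extras <- lapply(parsed, function(a) {
    ex <- a[setdiff(names(a), c("ID", "Parent"))]
    if (!length(ex)) character(0) else ex
  })
  score_chr <- col(6)
  phase_chr <- col(8)
  df <- data.frame(contig = col(1), start = s1 - 1L, end = e1,
                   strand = col(7), type = col(3), source = col(2),
                   score = ifelse(score_chr == ".", NA_real_,
                                  suppressWarnings(as.numeric(score_chr))),
                   phase = ifelse(phase_chr == ".", NA_integer_,
                                  suppressWarnings(as.integer(phase_chr))),
                   ID = ID, Parent = Parent, stringsAsFactors = FALSE)
  df$attrs <- extras
  .checkGffFrame(df)
  attr(df, "seqlens") <- seqlens
  df
}
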