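#' Read a FASTA file
#'
#' Sequences are uppercased and U is mapped to T on ingest. Records are
#' returned in file order as a named character vector with a `description`
#' attribute (the header text after the first whitespace).
#'
#' Fails on: an empty file, duplicate record ids, or characters outside
#' \{A,C,G,T,N\} (the offending record id is named). Ambiguity codes beyond
#' N are rejected by default; `ambig_to_n = TRUE` maps the IUPAC ambiguity
#' letters to N instead.
#'
#' @param path file path.
#' @param ambig_to_n map IUPAC ambiguity codes (R,Y,S,W,K,M,B,D,H,V) to N
#'   instead of failing. Default FALSE.
#' @return named character vector of sequences; `attr(,"description")` holds
#'   per-record descriptions.
#' @export
readFasta <- function(path, ambig_to_n = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not FASTA: first non-empty line is not a header")
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA header with empty id")
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- vapply(split(lines[!hdr], factor(idx[!hdr], levels = seq_along(ids))),
                 function(x) paste(x, collapse = ""), character(1))
  seqs <- .normalizeSeq(gsub("[ \t]", "", seqs))
  if (ambig_to_n) seqs <- chartr("RYSWKMBDHV", strrep("N", 10), seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}")
  empty <- !nzchar(seqs)
  if (any(empty)) stop("record '", ids[which(empty)[1]], "' has no sequence")
  names(seqs) <- ids
  attr(seqs, "description") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector; names become record ids.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  desc <- attr(seqs, "description")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    d <- if (!is.null(desc) && nzchar(desc[id] %||% "")) paste0(" ", desc[id]) else ""
    writeLines(paste0(">", id, d), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
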