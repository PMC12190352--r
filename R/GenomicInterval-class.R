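#' GenomicInterval: contig-anchored spans in 0-based half-open coordinates
#'
#' `GenomicInterval` is the coordinate currency of the package: a vector of
#' contig-anchored spans stored 0-based, half-open (`start` inclusive, `end`
#' exclusive), with an explicit strand. All internal computation uses this
#' convention; conversion to the 1-based inclusive convention happens only
#' when writing GFF3 (see [writeGff3()]).
#'
#' Minus-strand intervals store contig-forward coordinates (`start < end`
#' always); sequence extraction applies reverse complementation.
#'
#' @slot contig character, contig identifiers.
#' @slot start integer, 0-based inclusive starts (>= 0).
#' @slot end integer, exclusive ends (> start).
#' @slot strand character, "+" or "-".
#'
#' @aliases GenomicInterval-class
#' @export
setClass("GenomicInterval",
  representation(contig = "character", start = "integer",
                 end = "integer", strand = "character"))

setValidity("GenomicInterval", function(object) {
  n <- length(object@contig)
  if (length(object@start) != n || length(object@end) != n ||
      length(object@strand) != n)
    return("contig, start, end, strand must have equal lengths")
  if (any(is.na(object@start)) || any(is.na(object@end)))
    return("start/end must not be NA")
  if (any(object@start < 0L))
    return("start must be >= 0 (coordinates are 0-based)")
  if (any(object@end <= object@start))
    return("end must be > start (half-open intervals are non-empty)")
  if (!all(object@strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  TRUE
})

#' Construct genomic intervals
#'
#' @param contig character vector of contig ids.
#' @param start integer-like, 0-based inclusive start.
#' @param end integer-like, exclusive end; must exceed `start`.
#' @param strand "+" (default) or "-", recycled.
#' @return A [GenomicInterval-class] object.
#' @examples
#' gi <- GenomicInterval("chr1", 0, 7)
#' width(gi)  # 7
#' @export
GenomicInterval <- function(contig, start, end, strand = "+") {
  n <- max(length(contig), length(start), length(end))
  new("GenomicInterval",
      contig = rep_len(as.character(contig), n),
      start  = rep_len(as.integer(start), n),
      end    = rep_len(as.integer(end), n),
      strand = rep_len(as.character(strand), n))
}

#' @describeIn GenomicInterval number of intervals.
#' @param x a `GenomicInterval`.
#' @export
setMethod("length", "GenomicInterval", function(x) length(x@contig))

#' @export
setMethod("start", "GenomicInterval", function(x, ...) x@start)

#' @export
setMethod("end", "GenomicInterval", function(x, ...) x@end)

#' @export
setMethod("width", "GenomicInterval", function(x) x@end - x@start)

#' @export
setMethod("strand", "GenomicInterval", function(x, ...) x@strand)

#' Contig identifiers of an interval vector
#' @param x a `GenomicInterval`.
#' @return character vector.
#' @export
contigId <- function(x) {
  stopifnot(is(x, "GenomicInterval"))
  x@contig
}

#' @export
setMethod("[", "GenomicInterval", function(x, i, j, ..., drop = TRUE) {
  new("GenomicInterval", contig = x@contig[i], start = x@start[i],
      end = x@end[i], strand = x@strand[i])
})

#' @export
setMethod("c", "GenomicInterval", function(x, ...) {
  args <- c(list(x), list(...))
  new("GenomicInterval",
      contig = unlist(lapply(args, function(a) a@contig)),
      start  = unlist(lapply(args, function(a) a@start)),
      end    = unlist(lapply(args, function(a) a@end)),
      strand = unlist(lapply(args, function(a) a@strand)))
})

setMethod("show", "GenomicInterval", function(object) {
  n <- length(object)
  cat("GenomicInterval with", n, if (n == 1L) "interval\n" else "intervals\n")
  if (n > 0L) {
    show_n <- min(n, 8L)
    df <- as.data.frame(object[seq_len(show_n)])
    print(df)
    if (n > show_n) cat("...", n - show_n, "more\n")
  }
})

#' @export
as.data.frame.GenomicInterval <- function(x, ...) {
  data.frame(contig = x@contig, start = x@start, end = x@end,
             strand = x@strand, stringsAsFactors = FALSE)
}

#' Resolve an interval vector against a sequence set
#'
#' Checks that every interval fits on its named contig; errors otherwise.
#' @param x a `GenomicInterval`.
#' @param seqs named character vector (or list) of contig sequences.
#' @return `x`, invisibly, after validation.
#' @export
resolveIntervals <- function(x, seqs) {
  lens <- vapply(seqs, nchar, integer(1))
  missing <- setdiff(unique(x@contig), names(lens))
  if (length(missing))
    stop("interval references unknown contig(s): ",
         paste(missing, collapse = ", "))
  bad <- x@end > lens[x@contig]
  if (any(bad))
    stop("interval end exceeds contig length for: ",
         paste(unique(x@contig[bad]), collapse = ", "))
  invisible(x)
}

#' Extract interval sequences
#'
#' Substrings are taken contig-forward; minus-strand intervals are
#' reverse-complemented, so the result reads 5' to 3' on the feature strand.
#'
#' @param x a `GenomicInterval`.
#' @param seqs named character vector of contig sequences.
#' @return character vector of sequences, one per interval.
#' @export
intervalSeq <- function(x, seqs) {
  resolveIntervals(x, seqs)
  out <- unname(substring(unlist(seqs)[x@contig], x@start + 1L, x@end))
  minus <- x@strand == "-"
  if (any(minus)) out[minus] <- vapply(out[minus], revComp, character(1),
                                       USE.NAMES = FALSE)
  out
}
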