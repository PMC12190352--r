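#' Write intervals as BED6
#'
#' Lines are tab-separated, 0-based half-open, sorted by (contig, start).
#' Scores are clamped to integers in [0, 1000].
#'
#' @param intervals a [GenomicInterval-class] vector.
#' @param name character vector of feature names (recycled).
#' @param score numeric scores (recycled; default 0).
#' @param path output path.
#' @export
writeBed <- function(intervals, name, score = 0, path) {
  stopifnot(is(intervals, "GenomicInterval"))
  validObject(intervals)
  n <- length(intervals)
  name <- rep_len(as.character(name), n)
  score <- pmin(pmax(round(rep_len(score, n)), 0L), 1000L)
  o <- order(intervals@contig, intervals@start, intervals@end, name)
  lines <- paste(intervals@contig[o], intervals@start[o], intervals@end[o],
                 name[o], as.integer(score[o]), intervals@strand[o],
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file (BED3 to BED6)
#'
#' Track and comment lines are skipped. Strand defaults to "+" when column 6
#' is absent; name defaults to "." and score to 0. Non-integer coordinates
#' fail with the offending line number.
#'
#' @param path BED file path.
#' @return list with `intervals` ([GenomicInterval-class]), `name` and
#'   `score` vectors, in file order.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw)) & !grepl("^(track|browser|#)", raw)
  lineno <- which(keep)
  lines <- raw[keep]
  if (length(lines) == 0L)
    return(list(intervals = GenomicInterval(character(0), integer(0),
                                            integer(0)),
                name = character(0), score = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", lineno[which(nf < 3L)[1]], ": fewer than 3 columns")
  get <- function(i, default) vapply(seq_along(fields), function(j) {
    if (nf[j] >= i) fields[[j]][i] else default
  }, character(1))
  contig <- get(1L, "")
  s_chr <- get(2L, ""); e_chr <- get(3L, "")
  s <- suppressWarnings(as.integer(s_chr))
  e <- suppressWarnings(as.integer(e_chr))
  bad <- is.na(s) | is.na(e) | s_chr != as.character(s) | e_chr != as.character(e)
  if (any(bad))
    stop("BED line ", lineno[which(bad)[1]], ": non-integer coordinates")
  nm <- get(4L, ".")
  sc <- suppressWarnings(as.numeric(get(5L, "0")))
  sc[is.na(sc)] <- 0
  st <- get(6L, "+")
  st[!st %in% c("+", "-")] <- "+"
  list(intervals = GenomicInterval(contig, s, e, st), name = nm, score = sc)
}
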