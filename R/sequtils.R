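#' Reverse complement of a DNA string
#'
#' Complements A/T, C/G and N, then reverses. Input must be a non-empty
#' uppercase string over \{A,C,G,T,N\}; the operation is an involution.
#'
#' @param seq character scalar.
#' @return character scalar of the same length.
#' @examples
#' revComp("ACGTN")  # "NACGT"
#' @export
revComp <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("seq must be a single character string")
  if (nchar(seq) == 0L) stop("cannot reverse-complement an empty sequence")
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# codon -> amino acid lookup, standard nuclear code; built once at load
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- names(gc)
  tab
})

#' Translate DNA in a fixed frame
#'
#' Standard nuclear codon table. The trailing partial codon is dropped; any
#' codon containing N translates to `X`; stop codons are rendered `*`.
#'
#' @param seq character scalar over \{A,C,G,T,N\}.
#' @param frame 0, 1 or 2 — number of bases skipped before the first codon.
#' @return amino-acid string (possibly empty).
#' @examples
#' translateDna("ATGTAA")      # "M*"
#' translateDna("ATGAAA", 1)   # "*"  (TGA, trailing AA dropped)
#' @export
translateDna <- function(seq, frame = 0L) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("seq must be a single character string")
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  s <- substring(seq, frame + 1L)
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}

# uppercase + RNA->DNA on ingest; used by readFasta and flat-file SQ blocks
.normalizeSeq <- function(s) chartr("U", "T", toupper(s))
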