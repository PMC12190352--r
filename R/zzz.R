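#' vdjloci: annotation transfer for IG/TR genomic loci
#'
#' Automated annotation of immunoglobulin and T cell receptor loci on novel
#' genomic contigs, by transfer from a curated reference: flat-file
#' reference parsing ([parseFlatfile()], [buildGeneSet()]), RSS scanning
#' with RIC models ([trainRic()], [scanRss()]), homology search and hit
#' chaining ([searchHits()], [chainHits()]), verification and
#' classification ([annotateLocus()]), and a synthetic-locus generator for
#' validation ([generateReference()], [plantLocus()]).
#'
#' @keywords internal
#' @import methods
#' @importFrom BiocGenerics start end width strand
#' @importFrom digest digest
#' @importFrom stats setNames runif ave
#' @importFrom utils modifyList read.table URLdecode
"_PACKAGE"

.datatable.aware <- TRUE
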