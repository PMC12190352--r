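Package: vdjloci
Title: Annotation Transfer for Immunoglobulin and T Cell Receptor Loci
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated annotation of immunoglobulin (IG) and T cell receptor
    (TR) genomic loci by transfer from a curated reference. Parses
    IMGT/LIGM-DB EMBL-style flat files into a reference gene set, scans
    contigs for candidate recombination signal sequences (RSS) with
    position-conditional log-probability (recombination information content)
    models, locates V, D, J and C gene segments by homology search with
    co-linear hit chaining across kilobase-scale introns, verifies splice
    sites, coding integrity and conserved residues, classifies functionality
    (functional / ORF / pseudogene), names novel alleles by sequence hash,
    and emits standards-compliant BED and GFF3. Includes a synthetic-locus
    generator that produces reference sets, RSS training data, and target
    contigs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    jsonlite,
    data.table,
    digest
Suggests:
    testthat (>= 3.0.0),
    openssl,
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Annotation, SequenceMatching, Alignment, Immunology
Collate: 
    'GenomicInterval-class.R'
    'imgt.R'
    'align.R'
    'gff3.R'
    'ric.R'
    'chain.R'
    'annotator.R'
    'bed.R'
    'fasta.R'
    'synthetic.R'
    'plant.R'
    'sequtils.R'
    'zzz.R'
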