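# shared fixtures, memoized so expensive objects are built once per run
.fx <- new.env(parent = emptyenv())

fix_models <- function(n = 400L) {
  if (is.null(.fx$models)) {
    w12 <- generateRssTraining(12, n, 0.1, seed = 101L)
    w23 <- generateRssTraining(23, n, 0.1, seed = 102L)
    .fx$models <- list(m12 = trainRic(w12, 12), m23 = trainRic(w23, 23),
                       pools = list("12" = w12, "23" = w23))
  }
  .fx$models
}

# a small annotated locus (3 V, 2 D, 2 J, 1 C) used by several test files
fix_small_locus <- function() {
  if (is.null(.fx$small)) {
    spec <- locusSpec("IGH", n_v = 3L, n_d = 2L, n_j = 2L, n_c = 1L,
                      seed = 42L, intergenic = c(300L, 1500L))
    ref <- generateReference(spec)
    m <- fix_models()
    pl <- plantLocus(spec, ref$refset, rss_windows = m$pools)
    rss <- scanRss(m$m12, m$m23, pl$contig[[1]], names(pl$contig))
    .fx$small <- list(spec = spec, ref = ref, plant = pl, rss = rss)
  }
  .fx$small
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# independent brute-force RIC scorer: explicit loop over positions and
# conditioning contexts, sharing nothing with the package scan path
bruteRicScore <- function(model, window) {
  chars <- strsplit(window, "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(code)) return(-Inf)
  total <- 0
  for (i in seq_along(code)) {
    k <- min(model@order, i - 1L)
    ctx <- 1L
    t <- 1L
    while (t <= k) {
      ctx <- ctx + (code[i - t] - 1L) * 4L^(t - 1L)
      t <- t + 1L
    }
    total <- total + model@log_probs[[i]][ctx, code[i]]
  }
  total
}

# exhaustive chaining oracle: enumerate every subset of hits, keep those
# strictly co-linear under the gap limits, return the best summed bitscore
bruteBestChainScore <- function(hits, max_intron = 16000L,
                                query_gap_slack = 50L) {
  n <- nrow(hits)
  minus <- hits$strand[1] == "-"
  vs <- if (!minus) hits$tstart else -hits$tend
  ve <- if (!minus) hits$tend else -hits$tstart
  best <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(sel)) next
    o <- sel[order(hits$qstart[sel], vs[sel])]
    ok <- TRUE
    if (length(o) > 1L) {
      for (i in seq_len(length(o) - 1L)) {
        a <- o[i]; b <- o[i + 1L]
        if (hits$qend[a] > hits$qstart[b] || ve[a] > vs[b] ||
            vs[b] - ve[a] > max_intron ||
            hits$qstart[b] - hits$qend[a] > query_gap_slack) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, sum(hits$bitscore[o]))
  }
  best
}

# build a synthetic hit table (for chaining tests) with trivial blocks
makeHits <- function(qstart, qend, tstart, tend, bitscore,
                     strand = "+", gene = "G1", type = "C") {
  df <- data.frame(qstart = qstart, qend = qend, tstart = tstart,
                   tend = tend, pident = 100,
                   length = qend - qstart, score = bitscore,
                   bitscore = bitscore, evalue = 0, strand = strand,
                   gene = gene, allele = "01", segment_type = type,
                   stringsAsFactors = FALSE)
  df$blocks <- lapply(seq_len(nrow(df)), function(i)
    data.frame(qs = qstart[i], qe = qend[i], ts = tstart[i], te = tend[i]))
  df
}

# count recovered planted genes: output features overlapping a truth span
# of the same segment type
countRecovered <- function(features, truth) {
  sum(vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    any(vapply(features, function(f)
      f@candidate@segment_type == tr$segment_type &&
        start(f@candidate@span) < tr$span_end &&
        end(f@candidate@span) > tr$span_start, logical(1)))
  }, logical(1)))
}

# exact-coordinate check of every output feature against truth exon maps;
# returns c(n_exact, n_features, n_unmatched_output)
coordCheck <- function(features, truth) {
  exact <- 0L; unmatched <- 0L
  for (f in features) {
    i <- which(truth$segment_type ==
                 f@candidate@segment_type &
               truth$span_start < end(f@candidate@span) &
               truth$span_end > start(f@candidate@span))
    if (length(i) != 1L) { unmatched <- unmatched + 1L; next }
    te <- truth$exons[[i]]
    em <- f@candidate@exon_map
    if (nrow(em) == nrow(te) &&
        all(sort(em$start) == sort(te$start)) &&
        all(sort(em$end) == sort(te$end)))
      exact <- exact + 1L
  }
  c(exact = exact, n = length(features), unmatched = unmatched)
}
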