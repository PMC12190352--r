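#' @include GenomicInterval-class.R
NULL

# base coding A=1 C=2 G=3 T=4; N -> NA
.BASE4 <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.seqToCodes <- function(seq) {
  unname(.BASE4[strsplit(seq, "", fixed = TRUE)[[1]]])
}

#' RicModel: recombination information content model for one spacer class
#'
#' A position-conditional log-probability model over fixed-length RSS
#' windows (heptamer + spacer + nonamer; 28 nt for 12-spacer, 39 nt for
#' 23-spacer). Position `i` conditions on the `order` immediately preceding
#' positions within the window (order 0 is a plain position weight matrix).
#' The score of a window is the summed log conditional probability of its
#' bases, so the consensus of a noise-free model scores 0 and scores are
#' non-positive log-likelihoods.
#'
#' @slot spacer_class 12 or 23.
#' @slot window_length 16 + spacer_class (28 or 39).
#' @slot order non-negative integer, conditioning depth.
#' @slot log_probs list (one element per position) of matrices
#'   `[4^k contexts x 4 bases]` of log probabilities, `k = min(order, i-1)`.
#' @slot pseudocount additive pseudocount used at training.
#' @slot threshold minimum reportable score (log scale, typically <= 0).
#' @slot training_n number of training windows.
#' @export
setClass("RicModel",
  representation(spacer_class = "integer", window_length = "integer",
                 order = "integer", log_probs = "list",
                 pseudocount = "numeric", threshold = "numeric",
                 training_n = "integer"))

setValidity("RicModel", function(object) {
  if (!object@spacer_class %in% c(12L, 23L))
    return("spacer_class must be 12 or 23")
  if (object@window_length != 16L + object@spacer_class)
    return("window_length must equal 16 + spacer_class")
  if (length(object@log_probs) != object@window_length)
    return("log_probs must have one entry per window position")
  for (i in seq_along(object@log_probs)) {
    m <- object@log_probs[[i]]
    k <- min(object@order, i - 1L)
    if (!is.matrix(m) || nrow(m) != 4L^k || ncol(m) != 4L)
      return(sprintf("log_probs[[%d]] must be a %d x 4 matrix", i, 4L^k))
    sums <- rowSums(exp(m))
    seen <- apply(is.finite(m), 1L, any)
    if (any(abs(sums[seen] - 1) > 1e-9))
      return(sprintf("probabilities at position %d do not sum to 1", i))
  }
  TRUE
})

setMethod("show", "RicModel", function(object) {
  cat(sprintf(
    "RicModel: %d-spacer (window %d nt), order %d, pseudocount %g\n",
    object@spacer_class, object@window_length, object@order,
    object@pseudocount))
  cat(sprintf("  trained on %d windows; threshold %.3f\n",
              object@training_n, object@threshold))
})

# context index (1-based) of position i given window codes; k = depth used
.ctxIndex <- function(codes_mat, i, k) {
  # codes_mat: n x w integer matrix
  if (k == 0L) return(rep(1L, nrow(codes_mat)))
  ctx <- rep(1L, nrow(codes_mat))
  for (t in seq_len(k))
    ctx <- ctx + (codes_mat[, i - t] - 1L) * 4L^(t - 1L)
  ctx
}

#' Train a RIC model from aligned RSS windows
#'
#' Log probabilities are estimated per position and conditioning context by
#' relative frequency with an additive pseudocount. The default reporting
#' threshold is the minimum training-window score minus `margin` (so every
#' training window would be recovered by a scan).
#'
#' @param windows character vector of equal-length training windows over
#'   \{A,C,G,T\}, each of length 16 + spacer_class.
#' @param spacer_class 12 or 23.
#' @param order conditioning depth (default 1; 0 gives a PWM).
#' @param pseudocount additive pseudocount (default 1).
#' @param margin nats subtracted from the minimum training score to set the
#'   threshold (default 5).
#' @param threshold explicit threshold overriding the margin rule.
#' @return a [RicModel-class].
#' @export
trainRic <- function(windows, spacer_class, order = 1L, pseudocount = 1,
                     margin = 5, threshold = NULL) {
  spacer_class <- as.integer(spacer_class)
  if (!spacer_class %in% c(12L, 23L)) stop("spacer_class must be 12 or 23")
  w <- 16L + spacer_class
  if (length(windows) < 1L) stop("at least one training window is required")
  if (any(nchar(windows) != w))
    stop("all training windows must have length ", w)
  if (any(grepl("[^ACGT]", windows)))
    stop("training windows must be over {A,C,G,T}")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  order <- as.integer(order)
  n <- length(windows)
  codes <- t(vapply(windows, .seqToCodes, integer(w), USE.NAMES = FALSE))
  log_probs <- vector("list", w)
  for (i in seq_len(w)) {
    k <- min(order, i - 1L)
    nctx <- 4L^k
    counts <- matrix(0, nctx, 4L)
    ctx <- .ctxIndex(codes, i, k)
    for (r in seq_len(n))
      counts[ctx[r], codes[r, i]] <- counts[ctx[r], codes[r, i]] + 1
    counts <- counts + pseudocount
    tot <- rowSums(counts)
    probs <- counts / ifelse(tot == 0, 1, tot)  # all-zero rows stay 0
    log_probs[[i]] <- log(probs)
  }
  m <- new("RicModel", spacer_class = spacer_class, window_length = w,
           order = order, log_probs = log_probs,
           pseudocount = as.numeric(pseudocount), threshold = 0,
           training_n = n)
  train_scores <- vapply(windows, function(x) ricScore(m, x), numeric(1))
  m@threshold <- if (is.null(threshold)) min(train_scores) - margin
                 else threshold
  validObject(m)
  m
}

#' Score one window under a RIC model
#'
#' Sum over positions of log P(base | preceding `order` bases). A window
#' containing N scores `-Inf` (never reportable). Length mismatch is an
#' error.
#'
#' @param model a [RicModel-class].
#' @param window character scalar of length `window_length`.
#' @return numeric score (log probability, <= 0).
#' @export
ricScore <- function(model, window) {
  if (nchar(window) != model@window_length)
    stop("window length ", nchar(window), " != model window_length ",
         model@window_length)
  codes <- .seqToCodes(window)
  if (anyNA(codes)) return(-Inf)
  s <- 0
  for (i in seq_len(model@window_length)) {
    k <- min(model@order, i - 1L)
    ctx <- 1L
    if (k > 0L)
      for (t in seq_len(k)) ctx <- ctx + (codes[i - t] - 1L) * 4L^(t - 1L)
    s <- s + model@log_probs[[i]][ctx, codes[i]]
  }
  s
}

# vectorized window scores over all start positions of a coded sequence
.scanScores <- function(model, codes) {
  L <- length(codes)
  w <- model@window_length
  nwin <- L - w + 1L
  if (nwin < 1L) return(numeric(0))
  na <- is.na(codes)
  codes0 <- ifelse(na, 1L, codes)
  total <- numeric(nwin)
  has_na <- logical(nwin)
  idx0 <- seq_len(nwin)
  for (j in seq_len(w)) {
    pos <- idx0 + j - 1L
    has_na <- has_na | na[pos]
    k <- min(model@order, j - 1L)
    ctx <- rep(1L, nwin)
    if (k > 0L)
      for (t in seq_len(k))
        ctx <- ctx + (codes0[pos - t] - 1L) * 4L^(t - 1L)
    total <- total + model@log_probs[[j]][cbind(ctx, codes0[pos])]
  }
  total[has_na] <- -Inf
  total
}

#' Scan a contig for candidate RSS
#'
#' Every window position on both strands is scored against the 12- and
#' 23-spacer models; windows scoring at or above each model's threshold are
#' reported. Candidate strand records the reading direction of the
#' heptamer-spacer-nonamer layout: the `heptamer_boundary` column gives the
#' contig coordinate of the heptamer edge that abuts a gene segment
#' (window start for "+", window end for "-").
#'
#' @param model12,model23 [RicModel-class] objects (either may be NULL to
#'   scan one class only).
#' @param contig_seq contig sequence (character scalar over \{A,C,G,T,N\}).
#' @param contig_id contig identifier for reporting.
#' @return data.frame: contig, start, end, strand, spacer_class, score,
#'   heptamer_boundary; sorted by (start, strand, spacer_class).
#' @export
scanRss <- function(model12, model23, contig_seq, contig_id = "contig") {
  models <- Filter(Negate(is.null), list(model12, model23))
  if (!length(models)) stop("at least one model is required")
  L <- nchar(contig_seq)
  codes_f <- .seqToCodes(contig_seq)
  codes_r <- .seqToCodes(revComp(contig_seq))
  out <- list()
  for (m in models) {
    w <- m@window_length
    if (L < w) next
    sf <- .scanScores(m, codes_f)
    keep <- which(sf >= m@threshold)
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        contig = contig_id, start = keep - 1L, end = keep - 1L + w,
        strand = "+", spacer_class = m@spacer_class, score = sf[keep],
        stringsAsFactors = FALSE)
    sr <- .scanScores(m, codes_r)
    keep <- which(sr >= m@threshold)
    if (length(keep)) {
      st <- L - (keep - 1L) - w   # contig-forward start of the rc window
      out[[length(out) + 1L]] <- data.frame(
        contig = contig_id, start = st, end = st + w,
        strand = "-", spacer_class = m@spacer_class, score = sr[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      spacer_class = integer(0), score = numeric(0),
                      heptamer_boundary = integer(0)))
  df <- do.call(rbind, out)
  df$heptamer_boundary <- ifelse(df$strand == "+", df$start, df$end)
  df <- df[order(df$start, df$strand, df$spacer_class), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Convert RSS candidates to/from BED
#'
#' BED names are `RSS12`/`RSS23`; the BED score is the RIC score rescaled
#' affinely from `[threshold, 0]` to `[0, 1000]` (and clamped), so a
#' threshold-scoring candidate maps to 0 and a perfect consensus to 1000.
#' `bedToCandidates` inverts the map given the same thresholds, which also
#' lets third-party RSS predictions enter the pipeline as plain BED.
#'
#' @param candidates candidate data.frame from [scanRss()].
#' @param thresholds named numeric, thresholds for classes "12" and "23".
#' @return `candidatesToBed`: list(intervals, name, score) for [writeBed()];
#'   `bedToCandidates`: candidate data.frame (scores quantized by the BED
#'   integer rescaling).
#' @export
candidatesToBed <- function(candidates, thresholds) {
  thr <- thresholds[as.character(candidates$spacer_class)]
  bscore <- ifelse(is.finite(thr) & thr < 0,
                   1000 * (1 - candidates$score / thr), 1000)
  list(intervals = GenomicInterval(candidates$contig, candidates$start,
                                   candidates$end, candidates$strand),
       name = paste0("RSS", candidates$spacer_class),
       score = unname(pmin(pmax(bscore, 0), 1000)))
}

#' @rdname candidatesToBed
#' @param bed list(intervals, name, score) as returned by [readBed()];
#'   names must be RSS12/RSS23.
#' @export
bedToCandidates <- function(bed, thresholds) {
  if (!all(grepl("^RSS(12|23)$", bed$name)))
    stop("BED names must be RSS12 or RSS23")
  cls <- as.integer(sub("^RSS", "", bed$name))
  thr <- thresholds[as.character(cls)]
  score <- thr * (1 - bed$score / 1000)
  iv <- bed$intervals
  data.frame(contig = contigId(iv), start = start(iv), end = end(iv),
             strand = strand(iv), spacer_class = cls, score = score,
             heptamer_boundary = ifelse(strand(iv) == "+", start(iv),
                                        end(iv)),
             stringsAsFactors = FALSE)
}

#' Serialize a RIC model to versioned JSON
#'
#' @param model a [RicModel-class].
#' @param path output path.
#' @export
writeRicModel <- function(model, path) {
  obj <- list(format = "vdjloci-ric", version = 1L,
              spacer_class = model@spacer_class,
              window_length = model@window_length,
              order = model@order, pseudocount = model@pseudocount,
              threshold = model@threshold, training_n = model@training_n,
              log_probs = lapply(model@log_probs, function(m)
                unname(apply(m, 1L, as.numeric, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRicModel
#' @return `readRicModel`: the restored [RicModel-class].
#' @export
readRicModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "vdjloci-ric"))
    stop("not a RIC model file: ", path)
  lp <- lapply(obj$log_probs, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r)
      vapply(r, function(x) if (is.null(x)) -Inf else as.numeric(x),
             numeric(1))))
    unname(m)
  })
  m <- new("RicModel", spacer_class = as.integer(obj$spacer_class),
           window_length = as.integer(obj$window_length),
           order = as.integer(obj$order),
           log_probs = lp, pseudocount = as.numeric(obj$pseudocount),
           threshold = as.numeric(obj$threshold),
           training_n = as.integer(obj$training_n))
  validObject(m)
  m
}
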