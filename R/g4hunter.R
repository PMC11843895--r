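#' G4Hunter propensity scores for an amplicon
#'
#' Per-base G4Hunter scoring: every base inside a run of k consecutive G
#' scores `+min(k, 4)`, every base inside a run of k consecutive C scores
#' `-min(k, 4)`, and A/T score 0. Window scores are arithmetic means of the
#' base scores over a sliding window. Positive windows flag G-richness (G4
#' propensity on the stored strand), negative windows flag C-richness (G4
#' propensity on the complementary strand).
#'
#' @param amp An [amplicon()].
#' @param window Sliding-window width in nt; default 25 (the conventional
#'   G4Hunter window). Must satisfy `1 <= window <= nchar(seq)`.
#' @return An object of class `pqs_track`: list with `base_scores` (length =
#'   sequence length, integers in `[-4, 4]`), `window_scores` (length =
#'   sequence length - window + 1), `window`, `seq_length`, `amplicon_id`.
#' @examples
#' g4hunter_scores(amplicon("ACGT", numbering_offset = 1))$base_scores
#' @export
g4hunter_scores <- function(amp, window = 25L) {
  stopifnot(inherits(amp, "amplicon"))
  n <- nchar(amp$seq)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window > n)
    stop("'window' must be between 1 and the sequence length (", n, ")",
         call. = FALSE)
  base_scores <- g4hunter_base_scores(amp$seq)
  cs <- c(0, cumsum(base_scores))
  starts <- seq_len(n - window + 1L)
  window_scores <- (cs[starts + window] - cs[starts]) / window
  structure(
    list(base_scores = base_scores, window_scores = window_scores,
         window = window, seq_length = n, amplicon_id = amp$id),
    class = "pqs_track"
  )
}

g4hunter_base_scores <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  val <- integer(length(r$values))
  val[r$values == "G"] <- pmin(r$lengths[r$values == "G"], 4L)
  val[r$values == "C"] <- -pmin(r$lengths[r$values == "C"], 4L)
  rep(val, r$lengths)
}

#' @export
print.pqs_track <- function(x, ...) {
  cat(sprintf("pqs_track on '%s': %d nt, window %d, %d window score(s)\n",
              x$amplicon_id, x$seq_length, x$window,
              length(x$window_scores)))
  invisible(x)
}

#' Call PQS intervals from a G4Hunter track
#'
#' A window qualifies when `|window score| >= threshold`. Maximal runs of
#' consecutive qualifying windows of constant sign are merged and expanded
#' to base coordinates (the union of the qualifying windows). If expansion
#' makes an interval overlap the previous one (opposite-sign runs closer
#' than one window), the later interval is clipped at the earlier one's end
#' so that returned intervals are disjoint and sorted.
#'
#' @param track A [g4hunter_scores()] track.
#' @param threshold Positive score cutoff; default 1.2 (the conventional
#'   G4Hunter threshold).
#' @param min_width Minimum interval width in nt after expansion; default 1.
#' @return A data.frame with 0-based half-open `start`, `end`, `strand`
#'   (`"+"` = G-rich on the stored strand, `"-"` = C-rich) and `score` (mean
#'   window score over the run's qualifying windows). Zero rows when nothing
#'   qualifies.
#' @export
call_pqs <- function(track, threshold = 1.2, min_width = 1L) {
  stopifnot(inherits(track, "pqs_track"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be > 0", call. = FALSE)
  if (min_width < 1L) stop("'min_width' must be >= 1", call. = FALSE)
  ws <- track$window_scores
  W <- track$window
  qual <- abs(ws) >= threshold
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0))
  if (!any(qual)) return(empty)
  idx <- which(qual)
  sign_q <- ifelse(ws[idx] > 0, "+", "-")
  # break runs where window indices are non-consecutive or sign changes
  brk <- c(TRUE, diff(idx) != 1L | sign_q[-1] != sign_q[-length(sign_q)])
  run <- cumsum(brk)
  out <- do.call(rbind, lapply(split(seq_along(idx), run), function(i) {
    w <- idx[i]
    data.frame(start = w[1] - 1L, end = w[length(w)] - 1L + W,
               strand = sign_q[i[1]], score = mean(ws[w]))
  }))
  # clip overlaps between adjacent opposite-sign runs
  if (nrow(out) > 1L) for (k in 2:nrow(out)) {
    if (out$start[k] < out$end[k - 1L]) out$start[k] <- out$end[k - 1L]
  }
  out <- out[out$end - out$start >= min_width, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label CpG sites by PQS overlap
#'
#' A CpG site is labeled `"PQS"` when its C position or the paired G
#' position (C position + 1) lies within any called interval, else
#' `"non-PQS"`.
#'
#' @param intervals A data.frame from [call_pqs()] (or any data.frame with
#'   0-based half-open `start`/`end` on the same amplicon).
#' @param cpg_index A [find_cpg_sites()] index.
#' @return Character vector parallel to `cpg_index$positions`, values
#'   `"PQS"` / `"non-PQS"`, named by site number.
#' @export
pqs_cpg_overlap <- function(intervals, cpg_index) {
  stopifnot(inherits(cpg_index, "cpg_index"))
  if (nrow(intervals)) {
    if (any(intervals$start < 0L) ||
        any(intervals$end > cpg_index$seq_length))
      stop("PQS interval out of sequence bounds", call. = FALSE)
  }
  pos <- cpg_index$positions
  lab <- rep("non-PQS", length(pos))
  for (k in seq_len(nrow(intervals))) {
    s <- intervals$start[k]; e <- intervals$end[k]
    lab[(pos >= s & pos < e) | (pos + 1L >= s & pos + 1L < e)] <- "PQS"
  }
  names(lab) <- cpg_index$site_numbers
  lab
}

#' Write PQS intervals as 6-column BED
#'
#' BED score is the mean window score times 100, rounded.
#'
#' @param intervals Data.frame from [call_pqs()].
#' @param path Output path.
#' @param chrom Chromosome/sequence name column value (amplicon id).
#' @export
write_bed <- function(intervals, path, chrom) {
  bed <- data.frame(chrom = chrom, start = intervals$start,
                    end = intervals$end, name = "PQS",
                    score = round(intervals$score * 100),
                    strand = intervals$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write G4Hunter window scores as bedGraph
#'
#' One row per window start position (value = window mean score).
#'
#' @param track A [g4hunter_scores()] track.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track$window_scores)
  bg <- data.frame(chrom = track$amplicon_id,
                   start = seq_len(n) - 1L, end = seq_len(n),
                   value = track$window_scores)
  utils::write.table(bg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
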