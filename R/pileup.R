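#' Per-read modification-call table
#'
#' The native container for per-read cytosine modification-probability
#' calls: one row per read x CpG site with the probability triple
#' `(p_c, p_m, p_h)` for canonical C, 5mC and 5hmC. Calls from the template
#' (G-rich, `"-"`) strand are stored against the coding-strand C position of
#' their site, so the same `site_pos` keys both strands of one
#' strand-symmetric CpG site.
#'
#' @param df A data.frame with columns `read_id` (character), `strand`
#'   (`"+"` coding / `"-"` template), `site_pos` (0-based C position on the
#'   coding strand), `p_c`, `p_m`, `p_h` (each in `[0,1]`, summing to 1
#'   within `tol`).
#' @param tol Tolerance on `p_c + p_m + p_h - 1`; default `1e-6`.
#' @return A `mod_calls` object (a `data.table` with validated columns).
#' @export
mod_calls <- function(df, tol = 1e-6) {
  req <- c("read_id", "strand", "site_pos", "p_c", "p_m", "p_h")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("mod_calls: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(df)[, req, with = FALSE]
  dt[, `:=`(read_id = as.character(read_id), strand = as.character(strand),
            site_pos = as.integer(site_pos))]
  bad <- setdiff(unique(dt$strand), c("+", "-"))
  if (length(bad))
    stop("mod_calls: unknown strand symbol(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  p <- dt[, c(p_c, p_m, p_h)]
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("mod_calls: probabilities must be finite and in [0, 1]",
         call. = FALSE)
  dev <- abs(dt$p_c + dt$p_m + dt$p_h - 1)
  if (any(dev > tol))
    stop(sprintf(
      "mod_calls: %d row(s) with probability triple not summing to 1 (max deviation %.3g)",
      sum(dev > tol), max(dev)), call. = FALSE)
  data.table::setattr(dt, "class", c("mod_calls", class(dt)))
  dt[]
}

#' Read a per-read modification-call TSV
#'
#' Native dialect: tab-separated with header
#' `read_id  strand  site_pos  p_c  p_m  p_h`; lines starting with `#` are
#' comments; `site_pos` is 0-based; `strand` is `+` or `-`.
#'
#' @param path Path to the TSV.
#' @return A [mod_calls()] table (possibly zero rows).
#' @export
read_call_table <- function(path) {
  if (!file.exists(path))
    stop("call table not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("read_id", "strand")))
  if (nrow(dt) == 0L)
    return(mod_calls(data.frame(read_id = character(0),
                                strand = character(0),
                                site_pos = integer(0), p_c = numeric(0),
                                p_m = numeric(0), p_h = numeric(0))))
  mod_calls(dt)
}

#' Write a per-read modification-call TSV
#'
#' @param calls A [mod_calls()] table.
#' @param path Output path.
#' @export
write_call_table <- function(calls, path) {
  out <- data.table::copy(data.table::as.data.table(calls))
  for (col in c("p_c", "p_m", "p_h"))
    data.table::set(out, j = col, value = sprintf("%.8g", out[[col]]))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Classify probability triples at a confidence threshold
#'
#' Single-pass semantics: the winning state is the argmax of
#' `(p_c, p_m, p_h)` and the call is retained iff the winning probability is
#' at least `threshold`, otherwise it is `filtered`. Ties are broken
#' deterministically in favor of canonical, then 5mC.
#'
#' @param p_c,p_m,p_h Numeric vectors (recycled to common length) forming
#'   valid probability triples.
#' @param threshold Confidence cutoff in `(1/3, 1]`; default 0.65. Values at
#'   or below 1/3 would retain every call and are rejected unless
#'   `allow_low_threshold = TRUE`.
#' @param allow_low_threshold Permit thresholds <= 1/3 (e.g. 0 to disable
#'   filtering explicitly).
#' @return A data.frame with `state` (factor: canonical, 5mC, 5hmC,
#'   filtered) and `max_prob` (the winning probability).
#' @export
classify_call <- function(p_c, p_m, p_h, threshold = 0.65,
                          allow_low_threshold = FALSE) {
  if (threshold <= 1/3 && !allow_low_threshold)
    stop("'threshold' <= 1/3 retains every call; set allow_low_threshold = TRUE to override",
         call. = FALSE)
  if (threshold > 1) stop("'threshold' must be <= 1", call. = FALSE)
  n <- max(length(p_c), length(p_m), length(p_h))
  p <- cbind(rep_len(p_c, n), rep_len(p_m, n), rep_len(p_h, n))
  # max.col(ties.method = "first") implements canonical > 5mC > 5hmC
  win <- max.col(p, ties.method = "first")
  max_prob <- p[cbind(seq_len(n), win)]
  state <- c("canonical", "5mC", "5hmC")[win]
  state[max_prob < threshold] <- "filtered"
  data.frame(state = factor(state,
                            levels = c("canonical", "5mC", "5hmC", "filtered")),
             max_prob = max_prob)
}

#' Strand-resolved methylation pileup
#'
#' Aggregates per-read calls into per-(site, strand) counts after
#' confidence-threshold classification (see [classify_call()]). Methylation
#' fractions are computed over retained calls only; `mean_p_c` and the
#' derived `accuracy_pct` use all calls unfiltered (see [site_accuracy()]).
#'
#' @param calls A [mod_calls()] table.
#' @param cpg_index A [find_cpg_sites()] index; every `site_pos` in `calls`
#'   must be a known CpG position.
#' @param threshold Confidence cutoff passed to [classify_call()].
#' @param ... Passed on to [classify_call()].
#' @return A `meth_pileup`: a `data.table` with one row per (site, strand)
#'   ordered by position then strand, columns `site_pos`, `site_number`,
#'   `strand`, `coverage_total`, `n_canonical`, `n_5mC`, `n_5hmC`,
#'   `n_filtered`, `n_retained`, `frac_5mC`, `frac_5hmC`, `pct_5mC`,
#'   `mean_p_c`, `accuracy_pct`. Fractions are `NA` where no call survives
#'   filtering. The threshold is attached as attribute `threshold`.
#' @export
pileup <- function(calls, cpg_index, threshold = 0.65, ...) {
  stopifnot(inherits(cpg_index, "cpg_index"))
  dt <- data.table::as.data.table(calls)
  unknown <- setdiff(unique(dt$site_pos), cpg_index$positions)
  if (length(unknown))
    stop("pileup: call site position(s) not in CpG index: ",
         paste(utils::head(sort(unknown), 5), collapse = ", "),
         call. = FALSE)
  cls <- classify_call(dt$p_c, dt$p_m, dt$p_h, threshold = threshold, ...)
  dt <- data.table::copy(dt)[, state := cls$state]
  agg <- dt[, .(
    coverage_total = .N,
    n_canonical = sum(state == "canonical"),
    n_5mC = sum(state == "5mC"),
    n_5hmC = sum(state == "5hmC"),
    n_filtered = sum(state == "filtered"),
    mean_p_c = mean(p_c)
  ), by = .(site_pos, strand)]
  agg[, n_retained := coverage_total - n_filtered]
  agg[, frac_5mC := ifelse(n_retained > 0, n_5mC / n_retained, NA_real_)]
  agg[, frac_5hmC := ifelse(n_retained > 0, n_5hmC / n_retained, NA_real_)]
  agg[, pct_5mC := 100 * frac_5mC]
  agg[, accuracy_pct := accuracy_from_mean_pc(mean_p_c)]
  agg[, site_number := cpg_index$site_numbers[
    match(site_pos, cpg_index$positions)]]
  data.table::setorder(agg, site_pos, strand)
  data.table::setcolorder(agg, c("site_pos", "site_number", "strand",
                                 "coverage_total", "n_canonical", "n_5mC",
                                 "n_5hmC", "n_filtered", "n_retained",
                                 "frac_5mC", "frac_5hmC", "pct_5mC",
                                 "mean_p_c", "accuracy_pct"))
  data.table::setattr(agg, "threshold", threshold)
  data.table::setattr(agg, "class", c("meth_pileup", class(agg)))
  agg[]
}

#' Modification-calling accuracy statistic
#'
#' Accuracy is the rescaled mean canonical-cytosine probability across all
#' reads covering a site (no confidence filtering is applied):
#' `100 * (mean(p_c) - 1/3) / (2/3)`. By construction it is 100% when every
#' read is certain of canonical C, 0% when the three states are
#' equiprobable, and it may go negative (no clamping) when the caller
#' systematically favors a modified state at an unmethylated site.
#'
#' @param calls A [mod_calls()] table.
#' @param site_pos 0-based coding-strand C position of the site.
#' @param strand `"+"` or `"-"`.
#' @return Accuracy in percent (scalar).
#' @export
site_accuracy <- function(calls, site_pos, strand) {
  dt <- data.table::as.data.table(calls)
  p <- dt$p_c[dt$site_pos == site_pos & dt$strand == strand]
  if (length(p) == 0L)
    stop("site_accuracy: no calls at site_pos ", site_pos, " strand ",
         strand, call. = FALSE)
  accuracy_from_mean_pc(mean(p))
}

accuracy_from_mean_pc <- function(mean_p_c) {
  100 * (mean_p_c - 1/3) / (2/3)
}

#' Per-site accuracy track
#'
#' [site_accuracy()] evaluated at every covered (site, strand), using all
#' calls without filtering.
#'
#' @param calls A [mod_calls()] table.
#' @param cpg_index Optional [find_cpg_sites()] index used to attach site
#'   numbers.
#' @return A `data.table` with `site_pos`, `strand`, `n_reads`, `mean_p_c`,
#'   `accuracy_pct`, plus `site_number` when an index is given.
#' @export
accuracy_track <- function(calls, cpg_index = NULL) {
  dt <- data.table::as.data.table(calls)
  out <- dt[, .(n_reads = .N, mean_p_c = mean(p_c)),
            by = .(site_pos, strand)]
  out[, accuracy_pct := accuracy_from_mean_pc(mean_p_c)]
  if (!is.null(cpg_index))
    out[, site_number := cpg_index$site_numbers[
      match(site_pos, cpg_index$positions)]]
  data.table::setorder(out, site_pos, strand)
  out[]
}

#' Global modification levels from a pileup
#'
#' Pools retained calls over all sites and strands: the 5mC level is the
#' number of retained 5mC calls over all retained calls (likewise 5hmC).
#'
#' @param pileup A [pileup()] result.
#' @return Named numeric vector `c(level_5mC =, level_5hmC =)`.
#' @export
global_modification_levels <- function(pileup) {
  tot <- sum(pileup$n_retained)
  if (tot == 0L)
    stop("global_modification_levels: no retained calls", call. = FALSE)
  c(level_5mC = sum(pileup$n_5mC) / tot,
    level_5hmC = sum(pileup$n_5hmC) / tot)
}

bedmethyl_cols <- c("chrom", "start", "end", "site_number", "strand",
                    "coverage_total", "n_retained", "n_5mC", "n_5hmC",
                    "n_filtered", "pct_5mC", "accuracy_pct")

#' Write a pileup as a bedMethyl-like TSV
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open, `end = start + 1`),
#' `site_number`, `strand`, `coverage_total`, `n_retained`, `n_5mC`,
#' `n_5hmC`, `n_filtered`, `pct_5mC`, `accuracy_pct`. Rows are ordered by
#' position then strand; the write/read pair round-trips counts exactly.
#'
#' @param pileup A [pileup()] result.
#' @param path Output path.
#' @param chrom Sequence name (amplicon id).
#' @export
write_bedmethyl <- function(pileup, path, chrom = "amplicon") {
  dt <- data.table::as.data.table(pileup)
  out <- data.table::data.table(
    chrom = chrom, start = dt$site_pos, end = dt$site_pos + 1L,
    site_number = dt$site_number, strand = dt$strand,
    coverage_total = dt$coverage_total, n_retained = dt$n_retained,
    n_5mC = dt$n_5mC, n_5hmC = dt$n_5hmC, n_filtered = dt$n_filtered,
    pct_5mC = sprintf("%.6g", dt$pct_5mC),
    accuracy_pct = sprintf("%.6g", dt$accuracy_pct))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a bedMethyl-like TSV written by [write_bedmethyl()]
#'
#' @param path Input path.
#' @return A `data.table` with the bedMethyl columns (numeric `pct_5mC`,
#'   `accuracy_pct`).
#' @export
read_bedmethyl <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "strand")))
  miss <- setdiff(bedmethyl_cols, names(dt))
  if (length(miss))
    stop("bedMethyl file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dt[]
}
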