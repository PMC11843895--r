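#' Welch's unequal-variance t-test
#'
#' Two-sided t-test without the equal-variance assumption: the statistic is
#' `(mean(a) - mean(b)) / sqrt(va/n1 + vb/n2)` with Welch-Satterthwaite
#' degrees of freedom, and the two-tailed p-value comes from the central
#' t-distribution.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return An object of class `welch_test`: list with `t_statistic`, `df`
#'   (real-valued), `p_two_tailed`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test: each sample needs n >= 2", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0)
    stop("welch_t_test: both samples have zero variance", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  se2 <- va / n1 + vb / n2
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / n1)^2 / (n1 - 1) + (vb / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  structure(list(t_statistic = t_stat, df = df, p_two_tailed = p,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = n1, n_b = n2),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4g, df = %.4g, two-tailed p = %s\n",
              x$t_statistic, x$df, format_p(x$p_two_tailed)))
  invisible(x)
}

format_p <- function(p) {
  ifelse(p < 1e-4, "< 0.0001", sprintf("%.4g", p))
}

#' Region x strand methylation summary
#'
#' The unit of replication is the CpG site: for each (region, strand) cell
#' the per-site `pct_5mC` values are summarized as mean +/- SEM
#' (`sd / sqrt(n_sites)`). Sites lacking coverage on either strand are
#' excluded from both strands' summaries (their count is attached as
#' attribute `n_excluded_sites`).
#'
#' @param pileup A [pileup()] result covering both strands.
#' @param site_labels Character vector of `"PQS"` / `"non-PQS"` labels named
#'   or ordered by the pileup's site positions: either the output of
#'   [pqs_cpg_overlap()] (one label per CpG site of the index, in position
#'   order) or a vector named by `site_pos`.
#' @param site_positions 0-based positions parallel to `site_labels`;
#'   required when `site_labels` carries no usable names. When
#'   `site_labels` comes from [pqs_cpg_overlap()], pass the matching
#'   `cpg_index$positions`.
#' @return A data.frame with `region`, `strand`, `n_sites`, `mean_pct_5mC`,
#'   `sem_pct_5mC`; one row per non-empty cell. A cell with zero sites is an
#'   error.
#' @export
region_strand_summary <- function(pileup, site_labels,
                                  site_positions = NULL) {
  dt <- data.table::as.data.table(pileup)
  if (is.null(site_positions)) {
    if (is.null(names(site_labels)))
      stop("provide 'site_positions' or a named 'site_labels'",
           call. = FALSE)
    stop("'site_labels' names are site numbers; pass 'site_positions' explicitly",
         call. = FALSE)
  }
  lab_map <- data.table::data.table(site_pos = as.integer(site_positions),
                                    region = as.character(site_labels))
  dt <- merge(dt, lab_map, by = "site_pos")
  if (nrow(dt) == 0L)
    stop("no pileup rows match the labeled sites", call. = FALSE)
  # keep only sites observed (with retained calls) on both strands
  ok_sites <- dt[!is.na(pct_5mC), data.table::uniqueN(strand),
                 by = site_pos][V1 == 2L, site_pos]
  n_excluded <- length(setdiff(unique(dt$site_pos), ok_sites))
  dt <- dt[site_pos %in% ok_sites & !is.na(pct_5mC)]
  cells <- dt[, .(n_sites = .N, mean_pct_5mC = mean(pct_5mC),
                  sem_pct_5mC = if (.N > 1L)
                    stats::sd(pct_5mC) / sqrt(.N) else 0),
              by = .(region, strand)]
  expected <- data.table::CJ(region = unique(lab_map$region),
                             strand = c("+", "-"))
  missing <- expected[!cells, on = c("region", "strand")]
  if (nrow(missing))
    stop("region x strand cell(s) with zero sites: ",
         paste(sprintf("%s/%s", missing$region, missing$strand),
               collapse = ", "), call. = FALSE)
  out <- as.data.frame(cells[order(region, strand)])
  attr(out, "n_excluded_sites") <- n_excluded
  out
}

#' Differential strand-methylation report
#'
#' Builds the four (region x strand) summaries and the two planned strand
#' contrasts: C-rich (`+`) vs G-rich (`-`) per-site `pct_5mC`, inside and
#' outside the primary PQS region, each by [welch_t_test()].
#'
#' The region can be given either as a reported-site-number range
#' (`region_sites`, default 47-72, requiring `cpg_index`) or as explicit
#' per-site labels (`site_labels` + `site_positions`, e.g. derived from
#' [call_pqs()] + [pqs_cpg_overlap()]).
#'
#' @param pileup A [pileup()] result covering both strands.
#' @param cpg_index A [find_cpg_sites()] index (needed for
#'   `region_sites`).
#' @param region_sites Length-2 integer vector: first and last reported CpG
#'   site number of the PQS region (inclusive). Default `c(47, 72)`.
#' @param site_labels,site_positions Alternative explicit labeling; see
#'   [region_strand_summary()].
#' @return An object of class `differential_report`: list with `summary`
#'   (4-row data.frame), `tests` (data.frame with one row per region:
#'   `region`, `mean_g`, `sem_g`, `mean_c`, `sem_c`, `t_statistic`, `df`,
#'   `p_two_tailed`), and `region_definition` (text).
#' @export
differential_report <- function(pileup, cpg_index = NULL,
                                region_sites = c(47L, 72L),
                                site_labels = NULL,
                                site_positions = NULL) {
  if (is.null(site_labels)) {
    if (is.null(cpg_index))
      stop("provide 'cpg_index' (for region_sites) or explicit site_labels",
           call. = FALSE)
    sn <- cpg_index$site_numbers
    site_labels <- ifelse(sn >= region_sites[1] & sn <= region_sites[2],
                          "PQS", "non-PQS")
    site_positions <- cpg_index$positions
    region_definition <- sprintf("CpG site numbers %d-%d",
                                 region_sites[1], region_sites[2])
  } else {
    if (is.null(site_positions))
      stop("'site_positions' required with explicit 'site_labels'",
           call. = FALSE)
    region_definition <- "explicit PQS site labels"
  }
  for (rg in c("PQS", "non-PQS"))
    if (!rg %in% site_labels)
      stop("region '", rg, "' has zero sites under this definition",
           call. = FALSE)
  summ <- region_strand_summary(pileup, site_labels, site_positions)
  dt <- data.table::as.data.table(pileup)
  lab_map <- data.table::data.table(site_pos = as.integer(site_positions),
                                    region = as.character(site_labels))
  dt <- merge(dt, lab_map, by = "site_pos")
  ok_sites <- dt[!is.na(pct_5mC), data.table::uniqueN(strand),
                 by = site_pos][V1 == 2L, site_pos]
  dt <- dt[site_pos %in% ok_sites & !is.na(pct_5mC)]
  tests <- do.call(rbind, lapply(c("PQS", "non-PQS"), function(rg) {
    g <- dt[region == rg & strand == "-", pct_5mC]
    cc <- dt[region == rg & strand == "+", pct_5mC]
    wt <- welch_t_test(g, cc)
    data.frame(region = rg,
               mean_g = mean(g), sem_g = stats::sd(g) / sqrt(length(g)),
               mean_c = mean(cc), sem_c = stats::sd(cc) / sqrt(length(cc)),
               t_statistic = wt$t_statistic, df = wt$df,
               p_two_tailed = wt$p_two_tailed)
  }))
  structure(list(summary = summ, tests = tests,
                 region_definition = region_definition),
            class = "differential_report")
}

#' @export
print.differential_report <- function(x, ...) {
  cat("Differential strand methylation (G-rich '-' vs C-rich '+')\n")
  cat("Region definition:", x$region_definition, "\n")
  for (k in seq_len(nrow(x$tests))) {
    r <- x$tests[k, ]
    cat(sprintf(
      "  %-8s G-rich %0.f%% ± %0.f%% vs C-rich %0.f%% ± %0.f%%, p value %s\n",
      r$region, r$mean_g, r$sem_g, r$mean_c, r$sem_c,
      format_p(r$p_two_tailed)))
  }
  invisible(x)
}

#' Write a differential report as TSV
#'
#' Two sections separated by comment headers: the four region x strand
#' summaries and the two Welch contrasts. The region definition is echoed
#' in the header for provenance.
#'
#' @param report A [differential_report()].
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# region definition: %s", report$region_definition),
             con)
  writeLines("# section: region_strand_summary", con)
  utils::write.table(report$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("# section: welch_contrasts", con)
  utils::write.table(report$tests, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
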