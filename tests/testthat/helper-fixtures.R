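# Shared fixtures and independent oracles for the test suite.

mgmt_amplicon <- function() {
  load_fasta(system.file("extdata", "mgmt752.fa", package = "quadmeth"),
             numbering_offset = 3L)
}

oligo_seq <- function(name) {
  set <- Biostrings::readBStringSet(
    system.file("extdata", "oligos.fa", package = "quadmeth"))
  ids <- sub("\\s.*$", "", names(set))
  as.character(set[[match(name, ids)]])
}

# A small amplicon with many evenly spaced CpG sites, convenient for
# simulation tests: each "AACGTT" block carries one CpG.
toy_cpg_amplicon <- function(n_sites = 40L) {
  amplicon(paste(rep("AACGTT", n_sites), collapse = ""), id = "toy",
           numbering_offset = 1L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_calls <- function(read_id, strand, site_pos, p_c, p_m, p_h) {
  mod_calls(data.frame(read_id = read_id, strand = strand,
                       site_pos = site_pos, p_c = p_c, p_m = p_m,
                       p_h = p_h))
}

# noise configuration that makes the emitter deterministic:
# confident point-mass calls only
noise_off <- function() {
  list(high_conf_concentration = Inf, low_conf_concentration = 3,
       p_low_conf_inside_pqs = 0, p_low_conf_outside = 0,
       false_mod_rate = 0)
}

truth_uniform <- function(p, site_sd = 0) {
  list(means = matrix(p, 2, 2,
                      dimnames = list(c("+", "-"), c("PQS", "non-PQS"))),
       site_sd = c("PQS" = site_sd, "non-PQS" = site_sd))
}

## ---- independent oracles ----------------------------------------------

# Welch test from first principles: statistic/df by the direct formula,
# p-value by numerical integration of the t density (no pt()).
oracle_welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- sum(a) / n1; m2 <- sum(b) / n2
  v1 <- sum((a - m1)^2) / (n1 - 1)
  v2 <- sum((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  dens <- function(x)
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) /
      sqrt(df * pi) * (1 + x^2 / df)^(-(df + 1) / 2)
  tail <- stats::integrate(dens, abs(t_stat), Inf,
                           rel.tol = 1e-10)$value
  list(t_statistic = t_stat, df = df, p_two_tailed = 2 * tail)
}

# Brute-force per-read tally: scalar loop, explicit argmax with the
# canonical > 5mC > 5hmC tie-break, no shared code with pileup().
oracle_pileup <- function(calls, threshold) {
  df <- as.data.frame(calls)
  keys <- unique(df[, c("site_pos", "strand")])
  out <- NULL
  for (k in seq_len(nrow(keys))) {
    rows <- df[df$site_pos == keys$site_pos[k] &
                 df$strand == keys$strand[k], ]
    counts <- c(canonical = 0L, `5mC` = 0L, `5hmC` = 0L, filtered = 0L)
    for (r in seq_len(nrow(rows))) {
      p <- c(rows$p_c[r], rows$p_m[r], rows$p_h[r])
      best <- 1L
      if (p[2] > p[best]) best <- 2L
      if (p[3] > p[best]) best <- 3L
      if (p[best] < threshold) {
        counts["filtered"] <- counts["filtered"] + 1L
      } else {
        counts[best] <- counts[best] + 1L
      }
    }
    out <- rbind(out, data.frame(
      site_pos = keys$site_pos[k], strand = keys$strand[k],
      coverage_total = nrow(rows),
      n_canonical = counts[["canonical"]], n_5mC = counts[["5mC"]],
      n_5hmC = counts[["5hmC"]], n_filtered = counts[["filtered"]]))
  }
  out[order(out$site_pos, out$strand), ]
}

# random valid probability triples
random_triples <- function(n) {
  g <- matrix(stats::rgamma(n * 3, shape = 1), ncol = 3)
  g / rowSums(g)
}

## ---- SAM fixture -------------------------------------------------------

# Write a small SAM file aligned to an amplicon; reads is a list of
# character vectors of SAM fields.
write_sam <- function(amp, reads, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", amp$id, nchar(amp$seq)))
  body <- vapply(reads, paste, character(1), collapse = "\t")
  writeLines(c(hdr, body), path)
  path
}
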