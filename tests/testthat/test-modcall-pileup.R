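test_that("read_call_table parses, validates and round-trips", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("read_id\tstrand\tsite_pos\tp_c\tp_m\tp_h",
               "r1\t+\t12\t1.0\t0.0\t0.0"), tsv)
  calls <- read_call_table(tsv)
  expect_s3_class(calls, "mod_calls")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$site_pos, 12L)

  writeLines(c("read_id\tstrand\tsite_pos\tp_c\tp_m\tp_h",
               "r1\t+\t12\t0.5\t0.6\t0.2"), tsv)
  expect_error(read_call_table(tsv), "summing to 1")

  writeLines("read_id\tstrand\tsite_pos\tp_c\tp_m\tp_h", tsv)
  expect_equal(nrow(read_call_table(tsv)), 0L)

  writeLines(c("read_id\tstrand\tsite_pos\tp_c\tp_m\tp_h",
               "r1\t*\t12\t1\t0\t0"), tsv)
  expect_error(read_call_table(tsv), "strand")
  expect_error(read_call_table(tempfile()), "not found")

  withr::with_seed(5, {
    tri <- random_triples(50)
    calls <- make_calls(sprintf("r%d", rep(1:10, 5)),
                        sample(c("+", "-"), 50, TRUE),
                        rep(c(1L, 5L, 9L, 13L, 17L), each = 10),
                        tri[, 1], tri[, 2], tri[, 3])
    out <- tempfile(fileext = ".tsv")
    write_call_table(calls, out)
    back <- read_call_table(out)
    expect_equal(as.data.frame(back)[order(back$read_id, back$site_pos,
                                           back$strand), ],
                 as.data.frame(calls)[order(calls$read_id, calls$site_pos,
                                            calls$strand), ],
                 tolerance = 1e-7, ignore_attr = TRUE)
  })
})

test_that("classify_call: argmax, threshold, ties, and guard rails", {
  expect_equal(as.character(classify_call(1, 0, 0)$state), "canonical")
  expect_equal(as.character(classify_call(0.2, 0.7, 0.1)$state), "5mC")
  expect_equal(as.character(classify_call(0.4, 0.35, 0.25)$state),
               "filtered")  # max 0.4 < 0.65
  # deterministic tie-breaks: canonical > 5mC > 5hmC
  expect_equal(as.character(classify_call(0.5, 0.5, 0, 0.5)$state),
               "canonical")
  expect_equal(as.character(classify_call(0, 0.5, 0.5, 0.5)$state), "5mC")
  expect_error(classify_call(1, 0, 0, threshold = 1/3), "1/3")
  expect_error(classify_call(1, 0, 0, threshold = 1.2), "<= 1")
  expect_equal(as.character(classify_call(0.4, 0.35, 0.25, threshold = 0.2,
                                          allow_low_threshold = TRUE)$state),
               "canonical")
})

test_that("raising the threshold never un-filters a call", {
  withr::with_seed(13, {
    tri <- random_triples(300)
    th <- sort(runif(5, 0.4, 1))
    states <- lapply(th, function(t)
      as.character(classify_call(tri[, 1], tri[, 2], tri[, 3], t)$state))
    for (k in 2:length(th)) {
      was_filtered <- states[[k - 1]] == "filtered"
      expect_true(all(states[[k]][was_filtered] == "filtered"))
      # retained calls keep their state when they survive
      kept <- states[[k]] != "filtered"
      expect_equal(states[[k]][kept], states[[k - 1]][kept])
    }
  })
})

test_that("pileup counts, conserves coverage, and orders output", {
  amp <- amplicon("ACGTACGT", numbering_offset = 1)
  idx <- find_cpg_sites(amp)   # positions 1, 5
  calls <- make_calls(sprintf("r%d", 1:10), "+", 1L, 1, 0, 0)
  pu <- pileup(calls, idx)
  expect_equal(pu$n_canonical, 10L)
  expect_equal(pu$frac_5mC, 0)
  expect_equal(pu$site_number, 1L)

  # 4 of 10 confidently methylated
  calls <- make_calls(sprintf("r%d", 1:10), "+", 1L,
                      c(rep(0.1, 4), rep(0.9, 6)),
                      c(rep(0.9, 4), rep(0.1, 6)), 0)
  pu <- pileup(calls, idx)
  expect_equal(pu$frac_5mC, 0.4)
  expect_equal(pu$pct_5mC, 40)

  # mixed strands and filtered calls: conservation and NA handling
  calls <- make_calls(sprintf("r%d", 1:9),
                      c("+", "+", "+", "-", "-", "-", "+", "+", "+"),
                      rep(c(1L, 5L, 5L), each = 3),
                      c(1, 1, 1, 0.4, 0.4, 0.4, 0, 0, 0),
                      c(0, 0, 0, 0.35, 0.35, 0.35, 1, 1, 1),
                      c(0, 0, 0, 0.25, 0.25, 0.25, 0, 0, 0))
  pu <- pileup(calls, idx)
  expect_equal(sum(pu$n_filtered), 3L)
  expect_true(all(pu$n_canonical + pu$n_5mC + pu$n_5hmC + pu$n_filtered ==
                    pu$coverage_total))
  expect_true(is.na(pu[pu$strand == "-" & pu$site_pos == 5L]$frac_5mC))
  expect_equal(pu$site_pos, sort(pu$site_pos))

  expect_error(pileup(make_calls("r", "+", 2L, 1, 0, 0), idx),
               "not in CpG index")
})

test_that("pileup equals a brute-force tally on random instances", {
  amp <- amplicon(strrep("TACGGA", 5), numbering_offset = 1)
  idx <- find_cpg_sites(amp)   # 5 sites
  withr::with_seed(99, {
    for (rep_i in 1:8) {
      n_reads <- sample(3:20, 1)
      rows <- expand.grid(read = seq_len(n_reads),
                          site = sample(idx$positions,
                                        sample(2:5, 1)))
      tri <- random_triples(nrow(rows))
      calls <- make_calls(sprintf("r%02d", rows$read),
                          sample(c("+", "-"), nrow(rows), TRUE),
                          rows$site, tri[, 1], tri[, 2], tri[, 3])
      th <- runif(1, 0.4, 0.9)
      got <- as.data.frame(pileup(calls, idx, threshold = th))
      want <- oracle_pileup(calls, threshold = th)
      for (col in c("coverage_total", "n_canonical", "n_5mC", "n_5hmC",
                    "n_filtered"))
        expect_equal(got[[col]], want[[col]],
                     info = sprintf("col %s rep %d", col, rep_i))
    }
  })
})

test_that("site_accuracy matches its anchors and is affine + permutation-invariant", {
  calls <- make_calls(sprintf("r%d", 1:5), "+", 1L, 1, 0, 0)
  expect_equal(site_accuracy(calls, 1L, "+"), 100)
  calls <- make_calls(sprintf("r%d", 1:5), "+", 1L, 1/3, 1/3, 1/3)
  expect_equal(site_accuracy(calls, 1L, "+"), 0)
  calls <- make_calls(sprintf("r%d", 1:5), "+", 1L, 2/3, 1/6, 1/6)
  expect_equal(site_accuracy(calls, 1L, "+"), 50)
  expect_error(site_accuracy(calls, 2L, "+"), "no calls")

  withr::with_seed(3, {
    tri <- random_triples(40)
    calls <- make_calls(sprintf("r%d", 1:40), "+", 7L,
                        tri[, 1], tri[, 2], tri[, 3])
    a1 <- site_accuracy(calls, 7L, "+")
    # affine in mean p_c
    expect_equal(a1, 100 * (mean(tri[, 1]) - 1/3) / (2/3))
    shuf <- calls[sample(nrow(calls)), ]
    expect_equal(site_accuracy(mod_calls(shuf), 7L, "+"), a1)
  })
  # below-zero accuracies are reported, not clamped
  calls <- make_calls(sprintf("r%d", 1:4), "-", 1L, 0.1, 0.8, 0.1)
  expect_lt(site_accuracy(calls, 1L, "-"), 0)
})

test_that("accuracy_track covers every (site, strand) with all calls", {
  calls <- rbind(
    make_calls(sprintf("a%d", 1:3), "+", 1L, 1, 0, 0),
    make_calls(sprintf("b%d", 1:3), "-", 1L, 1/3, 1/3, 1/3))
  tr <- accuracy_track(mod_calls(calls))
  expect_equal(nrow(tr), 2L)
  expect_equal(tr[tr$strand == "+", ]$accuracy_pct, 100)
  expect_equal(tr[tr$strand == "-", ]$accuracy_pct, 0, tolerance = 1e-9)
})

test_that("global_modification_levels pools retained calls", {
  amp <- amplicon("ACGT", numbering_offset = 1)
  idx <- find_cpg_sites(amp)
  all_c <- make_calls(sprintf("r%d", 1:10), "+", 1L, 1, 0, 0)
  expect_equal(unname(global_modification_levels(pileup(all_c, idx))),
               c(0, 0))
  all_m <- make_calls(sprintf("r%d", 1:10), "+", 1L, 0, 1, 0)
  expect_equal(unname(global_modification_levels(pileup(all_m, idx))),
               c(1, 0))
  half <- make_calls(sprintf("r%d", 1:100), "+", 1L,
                     rep(c(1, 0), 50), rep(c(0, 1), 50), 0)
  expect_equal(unname(global_modification_levels(pileup(half, idx))),
               c(0.5, 0))
  none <- make_calls("r1", "+", 1L, 0.4, 0.35, 0.25)
  expect_error(global_modification_levels(pileup(none, idx)),
               "no retained")
})

test_that("bedMethyl writer round-trips counts and keeps strand order", {
  amp <- mgmt_amplicon()
  idx <- find_cpg_sites(amp)
  withr::with_seed(17, {
    pre <- preset_truth("dnmt3a")
    lab <- rep(c("PQS", "non-PQS"), length.out = length(idx$positions))
    calls <- simulate_reads(amp, idx, lab, pre$truth, pre$noise,
                            n_reads_per_strand = 20, seed = 1)
  })
  pu <- pileup(calls, idx)
  path <- tempfile(fileext = ".tsv")
  write_bedmethyl(pu, path, chrom = amp$id)
  back <- read_bedmethyl(path)
  expect_equal(back$start, pu$site_pos)
  expect_equal(back$end, pu$site_pos + 1L)
  expect_equal(back$n_5mC, pu$n_5mC)
  expect_equal(back$n_filtered, pu$n_filtered)
  expect_equal(back$coverage_total, pu$coverage_total)
  expect_true(all(back$strand %in% c("+", "-")))
  expect_equal(back$pct_5mC, pu$pct_5mC, tolerance = 1e-5)

  # empty pileup -> header-only file
  empty <- pu[0, ]
  p2 <- tempfile(fileext = ".tsv")
  write_bedmethyl(empty, p2, chrom = amp$id)
  expect_equal(nrow(read_bedmethyl(p2)), 0L)
})
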