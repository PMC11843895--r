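test_that("load_fasta normalizes case, keeps ids, rejects bad alphabets", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">x some description", "acgt"), fa)
  amp <- load_fasta(fa, numbering_offset = 1)
  expect_s3_class(amp, "amplicon")
  expect_equal(amp$id, "x")
  expect_equal(amp$seq, "ACGT")

  writeLines(c(">x", "ACGNT"), fa)
  expect_error(load_fasta(fa), "N")
  writeLines(c(">x", "ACGU"), fa)
  expect_error(load_fasta(fa), "U")
  writeLines(character(0), fa)
  expect_error(load_fasta(fa))
  expect_error(load_fasta(tempfile()), "not found")

  # multi-record: first by default, others addressable by index or name
  writeLines(c(">a", "AAAA", ">b", "CCGG"), fa)
  expect_equal(load_fasta(fa, numbering_offset = 1)$id, "a")
  expect_equal(load_fasta(fa, record = "b", numbering_offset = 1)$seq,
               "CCGG")
  expect_error(load_fasta(fa, record = 3), "out of range")
})

test_that("packaged study sequences have the documented dimensions", {
  amp <- mgmt_amplicon()
  expect_equal(nchar(amp$seq), 752L)
  idx <- find_cpg_sites(amp)
  # 95 CG dinucleotides; numbering 3..97 with the default offset
  expect_length(idx$positions, 95L)
  expect_equal(range(idx$site_numbers), c(3L, 97L))

  expect_equal(nchar(oligo_seq("MGMT-G4")), 24L)
  expect_equal(nchar(oligo_seq("MGMT-C")), 24L)
  expect_equal(nchar(oligo_seq("MGMT-ds1-top")), 22L)
})

test_that("reverse_complement: palindrome, duplex partners, involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  # the two strands of the G/C-rich 24-mer duplex are complementary
  expect_equal(reverse_complement(oligo_seq("MGMT-G4")),
               oligo_seq("MGMT-C"))
  expect_error(reverse_complement("ACGX"), "non-ACGT")
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- random_dna(sample(1:80, 1))
      expect_equal(reverse_complement(reverse_complement(s)), s)
    }
  })
})

test_that("find_cpg_sites indexes CG dinucleotides with site numbers", {
  amp <- amplicon("ACGT", numbering_offset = 1)
  idx <- find_cpg_sites(amp)
  expect_equal(idx$positions, 1L)
  expect_equal(idx$site_numbers, 1L)
  expect_true(all(vapply(idx$positions, function(p)
    substr(amp$seq, p + 1, p + 2) == "CG", logical(1))))

  # a single central CpG in the 22-mer duplex top strand
  ds1 <- amplicon(oligo_seq("MGMT-ds1-top"), numbering_offset = 1)
  expect_length(find_cpg_sites(ds1)$positions, 1L)
  # the CpG-free control oligo
  ctrl <- amplicon(oligo_seq("non-specific-control"), numbering_offset = 1)
  expect_length(find_cpg_sites(ctrl)$positions, 0L)

  expect_equal(site_number_to_position(idx, 1L), 1L)
  expect_error(site_number_to_position(idx, 99L), "unknown")
})

test_that("CpG count is strand-symmetric (palindromy)", {
  withr::with_seed(7, {
    for (i in 1:30) {
      s <- random_dna(sample(2:120, 1))
      a <- amplicon(s, numbering_offset = 1)
      b <- amplicon(reverse_complement(s), numbering_offset = 1)
      expect_length(find_cpg_sites(b)$positions,
                    length(find_cpg_sites(a)$positions))
    }
  })
})

test_that("g4hunter_scores applies the run-length rules", {
  expect_equal(g4hunter_scores(amplicon("ACGT", numbering_offset = 1),
                               window = 1)$base_scores,
               c(0, -1, 1, 0))
  tr <- g4hunter_scores(amplicon("GGGGG", numbering_offset = 1),
                        window = 5)
  expect_equal(tr$base_scores, rep(4, 5))   # runs >= 4 cap at 4
  expect_equal(tr$window_scores, 4)

  # 24-mer G4 oligo: run scores sum to 44, single window mean 44/24
  g4 <- amplicon(oligo_seq("MGMT-G4"), numbering_offset = 1)
  tr24 <- g4hunter_scores(g4, window = 24)
  expect_equal(sum(tr24$base_scores), 44)
  expect_equal(tr24$window_scores, 44 / 24)

  expect_error(g4hunter_scores(g4, window = 25), "window")
  expect_error(g4hunter_scores(g4, window = 0), "window")
  expect_equal(length(g4hunter_scores(mgmt_amplicon())$window_scores),
               752 - 25 + 1)
})

test_that("base scores are antisymmetric under reverse complement", {
  withr::with_seed(21, {
    for (i in 1:30) {
      s <- random_dna(sample(5:100, 1))
      a <- g4hunter_scores(amplicon(s, numbering_offset = 1),
                           window = 1)$base_scores
      b <- g4hunter_scores(amplicon(reverse_complement(s),
                                    numbering_offset = 1),
                           window = 1)$base_scores
      expect_equal(b, rev(-a))
    }
  })
})

test_that("window means bounded; extending a G-run never lowers its window", {
  withr::with_seed(31, {
    for (i in 1:15) {
      n <- sample(25:80, 1)
      s <- random_dna(n)
      tr <- g4hunter_scores(amplicon(s, numbering_offset = 1))
      expect_true(all(abs(tr$window_scores) <= 4))
      expect_true(all(abs(tr$base_scores) <= 4))
      # replace a random non-G base by G next to an existing G (extends or
      # creates a run): the first window containing it cannot decrease
      gpos <- which(strsplit(s, "")[[1]] != "G")
      j <- sample(gpos, 1)
      s2 <- paste0(substr(s, 1, j - 1), "G", substr(s, j + 1, n))
      tr2 <- g4hunter_scores(amplicon(s2, numbering_offset = 1))
      w <- max(1, j - 24):min(j, length(tr$window_scores))
      expect_true(all(tr2$window_scores[w] >= tr$window_scores[w]))
    }
  })
})

test_that("call_pqs: trivial cases and the G4 oligo", {
  polyA <- g4hunter_scores(amplicon(strrep("A", 40),
                                    numbering_offset = 1))
  expect_equal(nrow(call_pqs(polyA)), 0L)

  g4 <- g4hunter_scores(amplicon(oligo_seq("MGMT-G4"),
                                 numbering_offset = 1), window = 24)
  iv <- call_pqs(g4, threshold = 1.2)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$strand, "+")
  expect_equal(c(iv$start, iv$end), c(0L, 24L))

  # scores are bounded by 4, so threshold 5 yields nothing anywhere
  expect_equal(nrow(call_pqs(g4hunter_scores(mgmt_amplicon()),
                             threshold = 5)), 0L)
  expect_error(call_pqs(g4, threshold = 0), "> 0")
})

test_that("call_pqs intervals are disjoint/sorted; threshold is monotone", {
  withr::with_seed(41, {
    for (i in 1:25) {
      s <- random_dna(sample(40:200, 1))
      tr <- g4hunter_scores(amplicon(s, numbering_offset = 1))
      lo <- call_pqs(tr, threshold = 0.8)
      hi <- call_pqs(tr, threshold = 1.5)
      expect_lte(nrow(hi), nrow(lo))
      if (nrow(lo) > 1) {
        expect_true(all(diff(lo$start) > 0))
        expect_true(all(lo$start[-1] >= lo$end[-nrow(lo)]))
      }
      # every base covered at the high threshold is covered at the low one
      cover <- function(iv) unlist(mapply(seq, iv$start, iv$end - 1,
                                          SIMPLIFY = FALSE))
      if (nrow(hi)) expect_true(all(cover(hi) %in% cover(lo)))
    }
  })
})

test_that("pqs_cpg_overlap labels by C-or-G containment", {
  amp <- amplicon("TTACGTTTTTCGTT", numbering_offset = 1)  # C at 3, 10
  idx <- find_cpg_sites(amp)
  none <- data.frame(start = integer(0), end = integer(0),
                     strand = character(0), score = numeric(0))
  expect_equal(unname(pqs_cpg_overlap(none, idx)),
               rep("non-PQS", 2))
  all_iv <- data.frame(start = 0L, end = 14L, strand = "+", score = 2)
  expect_equal(unname(pqs_cpg_overlap(all_iv, idx)), rep("PQS", 2))
  # interval [5, 12) misses C3/G4 but catches the site at 10
  mid <- data.frame(start = 5L, end = 12L, strand = "+", score = 2)
  expect_equal(unname(pqs_cpg_overlap(mid, idx)), c("non-PQS", "PQS"))
  # paired-G containment: interval [4, 5) covers only G of site 3
  gonly <- data.frame(start = 4L, end = 5L, strand = "+", score = 2)
  expect_equal(unname(pqs_cpg_overlap(gonly, idx)), c("PQS", "non-PQS"))
  out <- data.frame(start = 0L, end = 99L, strand = "+", score = 2)
  expect_error(pqs_cpg_overlap(out, idx), "bounds")
})

test_that("BED and bedGraph writers emit well-formed tracks", {
  amp <- mgmt_amplicon()
  tr <- g4hunter_scores(amp)
  iv <- call_pqs(tr)
  bed <- tempfile(fileext = ".bed")
  write_bed(iv, bed, chrom = amp$id)
  got <- read.table(bed, sep = "\t")
  expect_equal(nrow(got), nrow(iv))
  expect_equal(got$V2, iv$start)
  expect_equal(got$V5, round(iv$score * 100))
  expect_true(all(got$V6 %in% c("+", "-")))

  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, bg)
  gotbg <- read.table(bg, sep = "\t")
  expect_equal(nrow(gotbg), length(tr$window_scores))
  expect_equal(gotbg$V4, tr$window_scores, tolerance = 1e-12)
})

test_that("amplicon constructor validates its invariants", {
  expect_error(amplicon(""), "empty")
  expect_error(amplicon("ACGT", numbering_offset = 0), "numbering_offset")
  expect_error(amplicon("ACRT"), "non-ACGT")
  expect_equal(amplicon("acgt")$seq, "ACGT")
})
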