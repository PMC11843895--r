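#' Construct an amplicon sequence object
#'
#' An `amplicon` is the reference object for every downstream track: a named,
#' uppercase DNA sequence over the strict alphabet `{A, C, G, T}` together
#' with the site-numbering convention used when reporting CpG sites. The
#' stored strand is by convention the coding (C-rich) strand; the template
#' (G-rich) strand is its reverse complement.
#'
#' @param seq Single DNA string. Lowercase input is accepted and uppercased;
#'   any character outside `ACGT` (including IUPAC ambiguity codes and `U`)
#'   is rejected with an error naming the offending characters.
#' @param id Text label for the sequence.
#' @param numbering_offset Integer >= 1: the reported site number of the
#'   first CpG site in the amplicon. The default `3` matches an amplicon
#'   whose first CpG is site 3 of its parent CpG island.
#' @return An object of class `amplicon` with fields `id`, `seq`, and
#'   `numbering_offset`.
#' @examples
#' amp <- amplicon("ACGTTACG", id = "toy")
#' nchar(amp$seq)
#' @export
amplicon <- function(seq, id = "amplicon", numbering_offset = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (nchar(seq) == 0L)
    stop("amplicon sequence is empty", call. = FALSE)
  check_dna_alphabet(seq)
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 1L)
    stop("'numbering_offset' must be an integer >= 1", call. = FALSE)
  structure(
    list(id = as.character(id), seq = seq,
         numbering_offset = numbering_offset),
    class = "amplicon"
  )
}

check_dna_alphabet <- function(seq) {
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]),
                 c("A", "C", "G", "T"))
  if (length(bad))
    stop("sequence contains non-ACGT character(s): ",
         paste(bad, collapse = ", "),
         " (ambiguity codes and RNA bases are not accepted)", call. = FALSE)
  invisible(seq)
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("amplicon '%s': %d nt, first CpG numbered %d\n",
              x$id, nchar(x$seq), x$numbering_offset))
  invisible(x)
}

#' Load an amplicon from a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file and returns one record as an
#' [amplicon()]. DNA only: `U` and ambiguity codes are rejected.
#'
#' @param path Path to a FASTA file.
#' @param record Which record to take (index or record name); default the
#'   first record.
#' @inheritParams amplicon
#' @return An `amplicon`.
#' @export
load_fasta <- function(path, record = 1L, numbering_offset = 3L) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  if (is.character(record)) {
    if (!record %in% names(set))
      stop("no FASTA record named '", record, "' in ", path, call. = FALSE)
  } else if (record < 1L || record > length(set)) {
    stop("FASTA record index out of range: ", record, call. = FALSE)
  }
  rec <- set[record]
  id <- sub("\\s.*$", "", names(rec))
  amplicon(as.character(rec[[1]]), id = id,
           numbering_offset = numbering_offset)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement over the strict `ACGT` alphabet.
#'
#' @param seq A single DNA string (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("ACGT")  # palindrome
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  check_dna_alphabet(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Index the CpG sites of an amplicon
#'
#' Finds every CG dinucleotide on the stored (coding) strand and attaches
#' reported site numbers via the amplicon's `numbering_offset`. A CpG site is
#' strand-symmetric: the C at position `p` on the coding strand pairs with
#' the G-strand cytosine opposite position `p + 1`.
#'
#' @param amp An [amplicon()].
#' @return An object of class `cpg_index`: a list with `positions` (0-based
#'   positions of the C of each CG, strictly increasing), `site_numbers`
#'   (rank + `numbering_offset`), and the amplicon `id` and length. An empty
#'   index is allowed.
#' @export
find_cpg_sites <- function(amp) {
  stopifnot(inherits(amp, "amplicon"))
  pos <- gregexpr("(?=CG)", amp$seq, perl = TRUE)[[1]]
  pos <- if (pos[1] == -1L) integer(0) else as.integer(pos) - 1L  # 0-based
  structure(
    list(positions = pos,
         site_numbers = if (length(pos)) seq_along(pos) - 1L +
           amp$numbering_offset else integer(0),
         amplicon_id = amp$id,
         seq_length = nchar(amp$seq)),
    class = "cpg_index"
  )
}

#' @export
print.cpg_index <- function(x, ...) {
  n <- length(x$positions)
  cat(sprintf("cpg_index on '%s': %d CpG site(s)", x$amplicon_id, n))
  if (n) cat(sprintf(", numbered %d-%d", x$site_numbers[1],
                     x$site_numbers[n]))
  cat("\n")
  invisible(x)
}

#' Translate reported site numbers to 0-based C positions
#'
#' @param cpg_index A [find_cpg_sites()] index.
#' @param site_numbers Integer vector of reported site numbers.
#' @return Integer vector of 0-based positions.
#' @export
site_number_to_position <- function(cpg_index, site_numbers) {
  idx <- match(site_numbers, cpg_index$site_numbers)
  if (anyNA(idx))
    stop("unknown CpG site number(s): ",
         paste(site_numbers[is.na(idx)], collapse = ", "), call. = FALSE)
  cpg_index$positions[idx]
}
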