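#' Read per-read modification calls from a modBAM/SAM file
#'
#' Decodes SAM/BAM base-modification tags (`MM`/`ML`, legacy `Mm`/`Ml`) for
#' 5mC (`C+m`) and 5hmC (`C+h`) on reads aligned to a single amplicon. Each
#' ML byte `b` is decoded as the probability `(b + 0.5) / 256`;
#' `p_c = 1 - p_m - p_h`. Calls from reverse-strand alignments are assigned
#' to the paired G-strand cytosine of the CpG site and stored against the
#' coding-strand C position with `strand = "-"` (see [mod_calls()]).
#'
#' Only positions listed in the MM tag yield calls (the `?` skip semantics);
#' calls landing outside a CpG site of the amplicon (e.g. CpH cytosines)
#' are dropped and counted. Unaligned reads are skipped and counted.
#'
#' @param path Path to a BAM (or SAM, converted on the fly) file.
#' @param amp The [amplicon()] the reads are aligned to.
#' @return A [mod_calls()] table with attributes `n_unaligned` and
#'   `n_off_site` (dropped call count).
#' @export
read_modbam <- function(path, amp) {
  stopifnot(inherits(amp, "amplicon"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    path <- bam
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq"),
    tag = c("MM", "ML", "Mm", "Ml"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(b$qname)
  idx <- find_cpg_sites(amp)
  cpg_pos <- idx$positions
  rows <- vector("list", n)
  n_unaligned <- 0L
  n_off_site <- 0L
  for (i in seq_len(n)) {
    flag <- b$flag[i]
    if (bitwAnd(flag, 4L) || is.na(b$pos[i])) {
      n_unaligned <- n_unaligned + 1L
      next
    }
    mm <- b$tag$MM[[i]]
    if (is.null(mm) || is.na(mm)) mm <- b$tag$Mm[[i]]
    ml <- b$tag$ML[[i]]
    if (is.null(ml) || all(is.na(ml))) ml <- b$tag$Ml[[i]]
    if (is.null(mm) || is.na(mm) || is.null(ml) || all(is.na(ml)))
      stop("read '", b$qname[i], "' lacks MM/ML base-modification tags",
           call. = FALSE)
    seq_chars <- strsplit(as.character(b$seq[i]), "", fixed = TRUE)[[1]]
    reverse <- bitwAnd(flag, 16L) > 0L
    probs <- decode_mm_ml(mm, as.integer(ml), seq_chars, reverse,
                          read_id = b$qname[i])
    if (nrow(probs) == 0L) next
    q2r <- cigar_query_to_ref(b$cigar[i], b$pos[i], length(seq_chars))
    ref_pos1 <- q2r[probs$query_pos]          # 1-based reference position
    keep <- !is.na(ref_pos1)
    probs <- probs[keep, , drop = FALSE]
    ref_pos1 <- ref_pos1[keep]
    if (reverse) {
      site_pos <- ref_pos1 - 2L               # G at ref -> coding C at G-1
      strand <- "-"
    } else {
      site_pos <- ref_pos1 - 1L
      strand <- "+"
    }
    ok <- site_pos %in% cpg_pos
    n_off_site <- n_off_site + sum(!ok)
    if (!any(ok)) next
    p_m <- probs$p_m[ok]; p_h <- probs$p_h[ok]
    if (any(p_m + p_h > 1 + 1e-9))
      stop("read '", b$qname[i],
           "': decoded p_5mC + p_5hmC exceeds 1", call. = FALSE)
    rows[[i]] <- data.frame(read_id = b$qname[i], strand = strand,
                            site_pos = site_pos[ok], p_m = p_m, p_h = p_h)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- mod_calls(data.frame(read_id = character(0),
                                strand = character(0),
                                site_pos = integer(0), p_c = numeric(0),
                                p_m = numeric(0), p_h = numeric(0)))
  } else {
    df <- do.call(rbind, rows)
    df$p_c <- 1 - df$p_m - df$p_h
    out <- mod_calls(df[, c("read_id", "strand", "site_pos",
                            "p_c", "p_m", "p_h")])
  }
  data.table::setattr(out, "n_unaligned", n_unaligned)
  data.table::setattr(out, "n_off_site", n_off_site)
  out
}

#' @noRd
#' Decode one read's MM/ML tags into per-query-position (p_m, p_h).
#' Returns data.frame(query_pos [1-based, in stored/aligned orientation],
#' p_m, p_h). Handles subtags C+m / C+h (with optional '?'/'.' flag) and
#' combined codes (e.g. C+mh). For reverse-strand alignments the original
#' read's C residues appear as G in the stored sequence and are counted
#' from the 3' end.
decode_mm_ml <- function(mm, ml, seq_chars, reverse, read_id = "?") {
  subtags <- strsplit(sub(";$", "", mm), ";", fixed = TRUE)[[1]]
  if (reverse) {
    c_query <- rev(which(seq_chars == "G"))
  } else {
    c_query <- which(seq_chars == "C")
  }
  out <- list()
  ml_off <- 0L
  seen_c <- FALSE
  for (st in subtags) {
    head <- sub(",.*$", "", st)
    m <- regmatches(head,
                    regexec("^([A-Z])([-+])([a-z0-9]+)([.?]?)$", head))[[1]]
    if (length(m) == 0L)
      stop("read '", read_id, "': malformed MM subtag '", st, "'",
           call. = FALSE)
    base <- m[2]; codes <- strsplit(m[4], "", fixed = TRUE)[[1]]
    deltas <- if (grepl(",", st)) {
      as.integer(strsplit(sub("^[^,]*,", "", st), ",", fixed = TRUE)[[1]])
    } else integer(0)
    n_ml <- length(deltas) * length(codes)
    ml_i <- ml[ml_off + seq_len(n_ml)]
    ml_off <- ml_off + n_ml
    if (base != "C") next
    if (!all(codes %in% c("m", "h"))) next
    seen_c <- TRUE
    if (length(deltas) == 0L) next
    ranks <- cumsum(deltas + 1L)   # which C (5'->3' of the read) is called
    if (max(ranks) > length(c_query))
      stop("read '", read_id,
           "': MM tag references more C bases than the read contains",
           call. = FALSE)
    qpos <- c_query[ranks]
    # ML bytes for a multi-code subtag are per position, codes in order
    pm <- matrix(ml_i, nrow = length(codes))
    for (k in seq_along(codes)) {
      p <- (pm[k, ] + 0.5) / 256
      key <- codes[k]
      out[[length(out) + 1L]] <-
        data.frame(query_pos = qpos, code = key, p = p)
    }
  }
  if (!seen_c)
    stop("read '", read_id, "': no C+m/C+h subtag in MM", call. = FALSE)
  if (length(out) == 0L)
    return(data.frame(query_pos = integer(0), p_m = numeric(0),
                      p_h = numeric(0)))
  long <- do.call(rbind, out)
  wide <- data.frame(query_pos = sort(unique(long$query_pos)))
  for (key in c("m", "h")) {
    v <- rep(0, nrow(wide))
    sel <- long$code == key
    v[match(long$query_pos[sel], wide$query_pos)] <- long$p[sel]
    wide[[if (key == "m") "p_m" else "p_h"]] <- v
  }
  wide
}

#' @noRd
#' Map 1-based query positions to 1-based reference positions through a
#' CIGAR string. Inserted/clipped query bases map to NA.
cigar_query_to_ref <- function(cigar, pos, qlen) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  type <- sub("^[0-9]+", "", ops)
  map <- rep(NA_integer_, qlen)
  q <- 1L; r <- pos
  for (k in seq_along(ops)) {
    L <- lens[k]
    if (type[k] %in% c("M", "=", "X")) {
      map[q + 0:(L - 1L)] <- r + 0:(L - 1L)
      q <- q + L; r <- r + L
    } else if (type[k] %in% c("I", "S")) {
      q <- q + L
    } else if (type[k] %in% c("D", "N")) {
      r <- r + L
    }                                        # H, P consume nothing here
  }
  map
}

#' Encode a probability as an ML byte
#'
#' Inverse of the standard decoding `(b + 0.5)/256`: the byte whose bin
#' contains `p`. Round-tripping changes a probability by less than 1/256.
#'
#' @param p Probability vector in `[0, 1]`.
#' @return Integer vector of ML bytes in `0:255`.
#' @export
ml_byte <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  pmin(pmax(as.integer(floor(p * 256)), 0L), 255L)
}
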