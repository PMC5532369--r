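#' DNA sequence record for guide design
#'
#' Normalises a DNA sequence (uppercase, alphabet ACGTN) and attaches an
#' identifier and topology. Circular records (plasmids) are scanned with
#' origin wrap-around.
#'
#' @param seq A character scalar or `Biostrings::DNAString`.
#' @param id Record identifier.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `"seq_record"` with fields `id`, `seq`,
#'   `topology`, `length`.
#' @export
seq_record <- function(seq, id = "seq", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  if (!grepl("^[ACGTN]*$", seq)) {
    stop("sequence may contain only A, C, G, T, N")
  }
  structure(list(id = id, seq = seq, topology = topology,
                 length = nchar(seq)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Read FASTA records for scanning
#'
#' @param path FASTA file path.
#' @param circular Logical scalar or vector (recycled): topology of each
#'   record.
#' @return A list of [seq_record()] objects.
#' @export
read_fasta_records <- function(path, circular = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  circular <- rep_len(circular, length(x))
  ids <- sub("\\s.*$", "", names(x))
  lapply(seq_along(x), function(i) {
    seq_record(as.character(x[[i]]), id = ids[i],
               topology = if (circular[i]) "circular" else "linear")
  })
}

# wrap a (possibly out-of-range) 1-based position onto a circle of length L
.wrap_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

.record_chars <- function(record) strsplit(record$seq, "", fixed = TRUE)[[1]]

.comp_chars <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' Reverse complement of a DNA string
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# extract bases at raw (unwrapped) positions start..end on the given strand;
# positions are wrapped for circular records, and must be in range for
# linear ones
.extract <- function(record, start, end, strand = "+") {
  pos <- start:end
  if (record$topology == "circular") {
    pos <- .wrap_pos(pos, record$length)
  } else if (any(pos < 1L | pos > record$length)) {
    stop("positions out of range for linear record")
  }
  ch <- .record_chars(record)[pos]
  if (strand == "-") ch <- rev(.comp_chars(ch))
  paste(ch, collapse = "")
}

#' Enumerate NGG PAM sites with available 20-nt protospacers
#'
#' Scans both strands for 5'-NGG-3' PAMs (S. pyogenes dCas9). A PAM is
#' reported only if the full 20-nt protospacer immediately 5' of it fits
#' on the record (always true on a circular record of length >= 23). `N`
#' bases in the input never match any PAM position. Coordinates are
#' 1-based on the forward strand; for circular records intervals may
#' extend past the ends (wrap implied) but `pam_start` is always in
#' `1..L`.
#'
#' @param record A [seq_record()].
#' @return A data.frame with columns `strand` (+/-), `pam_start`,
#'   `pam_end`, `proto_start`, `proto_end` (raw, wrap implied when
#'   outside `1..L`), `pam`, `protospacer` (sequences on the PAM's own
#'   strand), sorted by `pam_start`.
#' @export
find_pams <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  L <- record$length
  empty <- data.frame(strand = character(), pam_start = integer(),
                      pam_end = integer(), proto_start = integer(),
                      proto_end = integer(), pam = character(),
                      protospacer = character(), stringsAsFactors = FALSE)
  if (L < 23L) return(empty)
  ch <- .record_chars(record)
  circ <- record$topology == "circular"
  # doubled lookup for wrap-around trinucleotides
  ch2 <- if (circ) c(ch, ch[seq_len(min(L, 2L))]) else ch
  is_real <- function(x) x %in% c("A", "C", "G", "T")

  out <- list()
  # + strand: NGG at [i, i+2], protospacer [i-20, i-1]
  imax <- if (circ) L else L - 2L
  i <- seq_len(imax)
  ok <- is_real(ch2[i]) & ch2[i + 1L] == "G" & ch2[i + 2L] == "G"
  if (!circ) ok <- ok & (i >= 21L)
  plus <- i[ok]
  if (length(plus)) {
    out$plus <- data.frame(
      strand = "+", pam_start = plus, pam_end = plus + 2L,
      proto_start = plus - 20L, proto_end = plus - 1L,
      stringsAsFactors = FALSE)
  }
  # - strand: forward CCN at [i, i+2]; PAM 3' end at i, protospacer
  # forward [i+3, i+22]
  ok <- ch2[i] == "C" & ch2[i + 1L] == "C" & is_real(ch2[i + 2L])
  if (!circ) ok <- ok & (i + 22L <= L)
  minus <- i[ok]
  if (length(minus)) {
    out$minus <- data.frame(
      strand = "-", pam_start = minus, pam_end = minus + 2L,
      proto_start = minus + 3L, proto_end = minus + 22L,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$pam_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res$pam <- vapply(seq_len(nrow(res)), function(k) {
    .extract(record, res$pam_start[k], res$pam_end[k], res$strand[k])
  }, character(1))
  res$protospacer <- vapply(seq_len(nrow(res)), function(k) {
    .extract(record, res$proto_start[k], res$proto_end[k], res$strand[k])
  }, character(1))
  res
}

#' Enumerate CpG dinucleotides
#'
#' Every CpG is palindromic: the forward-strand C at `c_forward_pos` pairs
#' with a reverse-strand C opposite the G at `c_reverse_pos =
#' c_forward_pos + 1` (wrapped to 1 for an origin-spanning CpG on a
#' circular record).
#'
#' @param record A [seq_record()].
#' @return data.frame with columns `c_forward_pos`, `c_reverse_pos`.
#' @export
find_cpgs <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  ch <- .record_chars(record)
  L <- record$length
  if (L < 2L) {
    return(data.frame(c_forward_pos = integer(), c_reverse_pos = integer()))
  }
  i <- seq_len(L - 1L)
  pos <- i[ch[i] == "C" & ch[i + 1L] == "G"]
  rev <- pos + 1L
  if (record$topology == "circular" && ch[L] == "C" && ch[1L] == "G") {
    pos <- c(pos, L)
    rev <- c(rev, 1L)
  }
  data.frame(c_forward_pos = as.integer(pos), c_reverse_pos = as.integer(rev))
}

#' Gap length between a PAM and a CpG site
#'
#' The gap is the number of bases strictly between the PAM's 3'-terminal
#' base and the cis-strand C of the CpG, counted along the cis
#' (PAM-carrying) strand moving away from the protospacer. Returns `NA`
#' when the CpG lies on the protospacer side of the PAM (linear records)
#' or overlaps the guide footprint (circular records, where every CpG is
#' otherwise "downstream" going around the circle).
#'
#' @param pam One row of [find_pams()] output (data.frame or list).
#' @param cpg One row of [find_cpgs()] output.
#' @param record The [seq_record()] both came from.
#' @return Integer gap in bp, or `NA_integer_`.
#' @export
gap_length <- function(pam, cpg, record) {
  stopifnot(inherits(record, "seq_record"))
  L <- record$length
  circ <- record$topology == "circular"
  if (pam$strand == "+") {
    raw <- cpg$c_forward_pos - (pam$pam_start + 2L) - 1L
  } else {
    raw <- pam$pam_start - cpg$c_reverse_pos - 1L
  }
  if (!circ) {
    if (raw < 0L) return(NA_integer_)
    return(as.integer(raw))
  }
  g <- as.integer(raw %% L)
  # exclude CpGs overlapping the 23-bp protospacer+PAM footprint
  fp <- if (pam$strand == "+") {
    (pam$pam_start - 20L):(pam$pam_start + 2L)
  } else {
    pam$pam_start:(pam$pam_start + 22L)
  }
  fp <- .wrap_pos(fp, L)
  if (any(c(cpg$c_forward_pos, cpg$c_reverse_pos) %in% fp)) {
    return(NA_integer_)
  }
  g
}

#' Enumerate candidate target sites (PAM x CpG pairs) within a gap window
#'
#' Pairs every PAM with every CpG whose gap falls in
#' `[min_gap, max_gap]` and records which cytosine of the CpG lies on
#' the cis strand (the PAM/protospacer strand) and which on the trans
#' strand. Cytosines are addressed by the forward coordinate of their
#' own base and a strand: the forward-strand C is `(c_forward_pos, +)`,
#' the reverse-strand C sits opposite the G at `(c_reverse_pos, -)`.
#'
#' @param record A [seq_record()].
#' @param min_gap,max_gap Gap window in bp (default 8--25, the
#'   empirically targetable window).
#' @return data.frame with one row per candidate: `record_id`, `strand`,
#'   `pam_start`, `pam_end`, `proto_start`, `proto_end`, `protospacer`,
#'   `c_forward_pos`, `c_reverse_pos`, `gap`, `cis_pos`, `cis_strand`,
#'   `trans_pos`, `trans_strand`.
#' @export
enumerate_target_sites <- function(record, min_gap = 8L, max_gap = 25L) {
  stopifnot(inherits(record, "seq_record"), min_gap <= max_gap)
  pams <- find_pams(record)
  cpgs <- find_cpgs(record)
  out <- list()
  if (nrow(pams) && nrow(cpgs)) {
    for (k in seq_len(nrow(pams))) {
      pam <- pams[k, ]
      gaps <- vapply(seq_len(nrow(cpgs)), function(j) {
        g <- gap_length(pam, cpgs[j, ], record)
        if (is.na(g)) NA_integer_ else g
      }, integer(1))
      keep <- which(!is.na(gaps) & gaps >= min_gap & gaps <= max_gap)
      if (!length(keep)) next
      cp <- cpgs[keep, , drop = FALSE]
      plus_pam <- pam$strand == "+"
      out[[length(out) + 1L]] <- data.frame(
        record_id = record$id,
        strand = pam$strand,
        pam_start = pam$pam_start, pam_end = pam$pam_end,
        proto_start = pam$proto_start, proto_end = pam$proto_end,
        protospacer = pam$protospacer,
        c_forward_pos = cp$c_forward_pos,
        c_reverse_pos = cp$c_reverse_pos,
        gap = gaps[keep],
        cis_pos = if (plus_pam) cp$c_forward_pos else cp$c_reverse_pos,
        cis_strand = if (plus_pam) "+" else "-",
        trans_pos = if (plus_pam) cp$c_reverse_pos else cp$c_forward_pos,
        trans_strand = if (plus_pam) "-" else "+",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(record_id = character(), strand = character(),
                      pam_start = integer(), pam_end = integer(),
                      proto_start = integer(), proto_end = integer(),
                      protospacer = character(), c_forward_pos = integer(),
                      c_reverse_pos = integer(), gap = integer(),
                      cis_pos = integer(), cis_strand = character(),
                      trans_pos = integer(), trans_strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$pam_start, res$strand, res$gap), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a candidate target-site table
#'
#' Tab-delimited, 1-based inclusive coordinates.
#'
#' @param sites Output of [enumerate_target_sites()].
#' @param path Output file.
#' @export
write_target_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export guide footprints (protospacer + PAM) as BED6
#'
#' BED uses 0-based half-open intervals; scores hold the gap length.
#'
#' @param sites Output of [enumerate_target_sites()].
#' @param record The scanned [seq_record()] (for interval clamping).
#' @param path Output file.
#' @export
write_footprint_bed <- function(sites, record, path) {
  if (!nrow(sites)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  start1 <- ifelse(sites$strand == "+", sites$proto_start, sites$pam_start)
  end1 <- ifelse(sites$strand == "+", sites$pam_end, sites$proto_end)
  bed <- data.frame(
    chrom = sites$record_id,
    start = pmax(start1 - 1L, 0L),
    end = pmin(end1, record$length),
    name = sprintf("%s_%d%s_gap%d", sites$record_id, sites$pam_start,
                   sites$strand, sites$gap),
    score = sites$gap,
    strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
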