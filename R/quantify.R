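#' Toy-scale three-letter bisulfite alignment
#'
#' Places each read against the C-to-T-converted top strand and the
#' C-to-T-converted bottom strand of a small reference, exhaustively at
#' every offset, after converting the read's own Cs to T. Converting
#' both read and reference makes C/T mismatches at reference cytosines
#' invisible to the mismatch count (the essence of three-letter
#' alignment), so methylation state does not penalise placement. The
#' best placement with at most `max_mismatches` is kept; reads whose
#' best placement is not unique are marked ambiguous and discarded from
#' downstream calling, and unalignable reads are counted, not fatal.
#'
#' This exhaustive scan is exactly testable and dependency-free but is
#' intended for references of at most a few tens of kb; it is not a
#' genome-scale aligner.
#'
#' @param reads data.frame with `name`, `seq` ([sample_reads()] /
#'   [read_fastq()] output).
#' @param record The reference [seq_record()] (circular references are
#'   handled with origin wrap).
#' @param max_mismatches Maximum effective mismatches (default 2).
#' @return data.frame of class `"bs_placements"`: `name`, `seq`,
#'   `strand` (`"top"`/`"bottom"`/`NA`), `start` (1-based in the
#'   assigned strand's own coordinates), `mismatches`, `status`
#'   (`unique` / `ambiguous` / `unaligned`). The record is attached as
#'   attribute `record`.
#' @export
align_bisulfite <- function(reads, record, max_mismatches = 2L) {
  stopifnot(is.data.frame(reads), all(c("name", "seq") %in% names(reads)),
            inherits(record, "seq_record"))
  L <- record$length
  circ <- record$topology == "circular"
  maxlen <- if (nrow(reads)) max(nchar(reads$seq)) else 0L
  if (maxlen > L) stop("reads longer than the reference")

  top <- record$seq
  bot <- revcomp(record$seq)
  if (circ && maxlen > 1L) {
    top_e <- paste0(top, substr(top, 1L, maxlen - 1L))
    bot_e <- paste0(bot, substr(bot, 1L, maxlen - 1L))
  } else {
    top_e <- top
    bot_e <- bot
  }
  ct <- function(x) chartr("C", "T", x)
  res <- cpp_align_reads(ct(reads$seq), ct(top_e), ct(bot_e),
                         as.integer(max_mismatches), L, circ)
  status <- ifelse(res$n_best == 0L, "unaligned",
                   ifelse(res$n_best > 1L, "ambiguous", "unique"))
  out <- data.frame(
    name = reads$name, seq = reads$seq,
    strand = c(NA, "top", "bottom")[res$strand + 1L],
    start = res$start, mismatches = res$mismatches, status = status,
    stringsAsFactors = FALSE)
  out$strand[status != "unique"] <- NA
  attr(out, "record") <- record
  class(out) <- c("bs_placements", "data.frame")
  out
}

#' Per-cytosine strand-specific methylation calling
#'
#' At every reference cytosine position covered by a uniquely placed
#' read on the matching strand, a read base C is a methylated call and T
#' an unmethylated call (other bases give no call). Calls are aggregated
#' per cytosine and strand and annotated with CpG / non-CpG context.
#' Cytosines with zero coverage report `fraction = NA` (never 0).
#'
#' @param placements Output of [align_bisulfite()].
#' @param record The reference [seq_record()]; defaults to the record
#'   attached to `placements`.
#' @return data.frame of class `"methylation_table"`: `pos` (forward
#'   coordinate of the cytosine's own base), `strand` (`"+"` forward C,
#'   `"-"` reverse C), `context` (`"CpG"`/`"CpH"`), `meth`, `unmeth`,
#'   `coverage`, `fraction`.
#' @export
call_methylation <- function(placements, record = attr(placements, "record")) {
  stopifnot(inherits(record, "seq_record"))
  L <- record$length
  circ <- record$topology == "circular"
  maxlen <- if (nrow(placements)) max(nchar(placements$seq)) else 0L
  top <- record$seq
  bot <- revcomp(record$seq)
  if (circ && maxlen > 1L) {
    top_e <- paste0(top, substr(top, 1L, maxlen - 1L))
    bot_e <- paste0(bot, substr(bot, 1L, maxlen - 1L))
  } else {
    top_e <- top
    bot_e <- bot
  }
  usable <- placements$status == "unique"
  strand_code <- ifelse(usable & placements$strand == "top", 1L,
                        ifelse(usable & placements$strand == "bottom",
                               2L, 0L))
  strand_code[is.na(strand_code)] <- 0L
  start <- placements$start
  start[is.na(start)] <- 1L
  counts <- cpp_count_calls(placements$seq, strand_code, start,
                            top_e, bot_e, L, circ)

  ch <- .record_chars(record)
  nxt <- function(p) if (circ) .wrap_pos(p + 1L, L) else p + 1L
  prv <- function(p) if (circ) .wrap_pos(p - 1L, L) else p - 1L

  # forward-strand cytosines
  fpos <- which(ch == "C")
  fctx <- vapply(fpos, function(p) {
    q <- nxt(p)
    if (!is.na(q) && q >= 1L && q <= L && ch[q] == "G") "CpG" else "CpH"
  }, character(1))
  # reverse-strand cytosines sit opposite forward Gs; bottom coordinate
  # of forward position p is L - p + 1
  rpos <- which(ch == "G")
  rctx <- vapply(rpos, function(p) {
    q <- prv(p)
    if (!is.na(q) && q >= 1L && q <= L && ch[q] == "C") "CpG" else "CpH"
  }, character(1))

  tab <- rbind(
    data.frame(pos = fpos, strand = "+", context = fctx,
               meth = counts$meth_top[fpos],
               unmeth = counts$unmeth_top[fpos],
               stringsAsFactors = FALSE),
    data.frame(pos = rpos, strand = "-", context = rctx,
               meth = counts$meth_bot[L - rpos + 1L],
               unmeth = counts$unmeth_bot[L - rpos + 1L],
               stringsAsFactors = FALSE))
  tab$coverage <- tab$meth + tab$unmeth
  tab$fraction <- ifelse(tab$coverage > 0, tab$meth / tab$coverage, NA_real_)
  tab <- tab[order(tab$pos, tab$strand), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("methylation_table", "data.frame")
  tab
}

#' Fold preference of the target over the median off-target site
#'
#' The specificity metric of the system: the (maximum) target-cytosine
#' methylation fraction divided by the median fraction across
#' sufficiently covered off-target CpG cytosines. A pseudo-floor
#' (default `1 / (2 * total off-target calls)`) bounds the denominator
#' away from zero on finite samples.
#'
#' @param table A [call_methylation()] table.
#' @param targets data.frame with columns `pos`, `strand` naming the
#'   target cytosines.
#' @param pseudo_floor Optional explicit denominator floor.
#' @param min_coverage Minimum calls for a site to enter the statistics
#'   (default 10; lower-covered sites are excluded as unstable).
#' @return A single positive ratio.
#' @export
fold_preference <- function(table, targets, pseudo_floor = NULL,
                            min_coverage = 10L) {
  stopifnot(is.data.frame(table), all(c("pos", "strand") %in% names(targets)))
  tab <- table[table$context == "CpG" & table$coverage >= min_coverage, ,
               drop = FALSE]
  key <- paste(tab$pos, tab$strand)
  tkey <- paste(targets$pos, targets$strand)
  is_t <- key %in% tkey
  if (!any(is_t)) stop("no covered target cytosine")
  if (!any(!is_t)) stop("no covered off-target cytosine")
  target_frac <- max(tab$fraction[is_t])
  off <- tab$fraction[!is_t]
  if (is.null(pseudo_floor)) {
    pseudo_floor <- 1 / (2 * sum(tab$coverage[!is_t]))
  }
  target_frac / max(stats::median(off), pseudo_floor)
}

#' Squared Pearson correlation between two methylation profiles
#'
#' Computed over the cytosines covered (at `min_coverage` or deeper) in
#' both tables, optionally restricted to given positions. Returns `NA`
#' with a warning when either profile has zero variance over the shared
#' sites.
#'
#' @param a,b [call_methylation()] tables over the same reference.
#' @param positions Optional data.frame (`pos`, `strand`) restricting
#'   the comparison.
#' @param min_coverage Minimum coverage in both tables.
#' @return Squared Pearson correlation in `[0, 1]`, or `NA`.
#' @export
compare_profiles <- function(a, b, positions = NULL, min_coverage = 10L) {
  ka <- paste(a$pos, a$strand)
  kb <- paste(b$pos, b$strand)
  shared <- intersect(ka[a$coverage >= min_coverage],
                      kb[b$coverage >= min_coverage])
  if (!is.null(positions)) {
    shared <- intersect(shared, paste(positions$pos, positions$strand))
  }
  if (length(shared) < 3L) stop("need at least 3 shared covered cytosines")
  fa <- a$fraction[match(shared, ka)]
  fb <- b$fraction[match(shared, kb)]
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    warning("zero variance in a profile; correlation undefined")
    return(NA_real_)
  }
  stats::cor(fa, fb)^2
}

#' Same-molecule co-methylation matrix
#'
#' For simulated reads (whose names encode the source molecule), builds
#' the pairwise fraction of molecules methylated at both of two
#' cytosines, among molecules informative for both; the diagonal is the
#' per-site marginal. This mirrors the clonal (per-molecule) bisulfite
#' view that population-level profiles cannot give.
#'
#' @param placements [align_bisulfite()] output on simulated reads.
#' @param positions data.frame (`pos`, `strand`) of cytosines to cross.
#' @param record Reference, defaulting to the attached one.
#' @return Numeric matrix (named `pos:strand`) with `NA` where no
#'   molecule covers both sites; attribute `n` holds the molecule counts.
#' @export
comethylation_matrix <- function(placements, positions,
                                 record = attr(placements, "record")) {
  stopifnot(inherits(record, "seq_record"), nrow(positions) >= 1L)
  L <- record$length
  circ <- record$topology == "circular"
  pl <- placements[placements$status == "unique", , drop = FALSE]
  prov <- parse_read_names(pl$name)

  k <- nrow(positions)
  labels <- paste0(positions$pos, ":", positions$strand)
  # strand-space coordinate of each queried cytosine
  scoord <- ifelse(positions$strand == "+", positions$pos,
                   L - positions$pos + 1L)
  swant <- ifelse(positions$strand == "+", "top", "bottom")

  calls <- matrix(NA_real_, nrow = 0L, ncol = k)
  mols <- sort(unique(prov$molecule))
  call_rows <- lapply(mols, function(m) {
    rows <- which(prov$molecule == m)
    out <- rep(NA_real_, k)
    for (q in seq_len(k)) {
      rr <- rows[pl$strand[rows] == swant[q]]
      if (!length(rr)) next
      votes <- c()
      for (r in rr) {
        len <- nchar(pl$seq[r])
        off <- if (circ) (scoord[q] - pl$start[r]) %% L else
          scoord[q] - pl$start[r]
        if (is.na(off) || off < 0L || off >= len) next
        base <- substr(pl$seq[r], off + 1L, off + 1L)
        if (base == "C") votes <- c(votes, 1) else
          if (base == "T") votes <- c(votes, 0)
      }
      if (length(votes)) {
        mu <- mean(votes)
        out[q] <- if (mu == 0.5) NA_real_ else as.numeric(mu > 0.5)
      }
    }
    out
  })
  calls <- do.call(rbind, call_rows)
  joint <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  nmat <- matrix(0L, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- !is.na(calls[, i]) & !is.na(calls[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (any(ok)) {
        joint[i, j] <- joint[j, i] <-
          mean(calls[ok, i] == 1 & calls[ok, j] == 1)
      }
    }
  }
  attr(joint, "n") <- nmat
  joint
}

#' Label a methylation table with target / off-target status
#'
#' @param table A [call_methylation()] table.
#' @param targets data.frame (`pos`, `strand`) of target cytosines.
#' @return The table with a logical `target` column.
#' @export
label_targets <- function(table, targets) {
  table$target <- paste(table$pos, table$strand) %in%
    paste(targets$pos, targets$strand)
  table
}

#' Write a methylation table (TSV) or per-strand bedGraph tracks
#'
#' @param table A [call_methylation()] table.
#' @param path Output TSV path.
#' @export
write_methylation_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation_table
#' @param record The reference record (for the track chromosome name).
#' @param prefix Output path prefix; `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph` are written (0-based half-open intervals,
#'   uncovered cytosines omitted).
#' @export
write_bedgraph <- function(table, record, prefix) {
  for (s in c("+", "-")) {
    sub <- table[table$strand == s & !is.na(table$fraction), , drop = FALSE]
    path <- paste0(prefix, if (s == "+") ".plus" else ".minus",
                   ".bedGraph")
    bg <- data.frame(chrom = record$id, start = sub$pos - 1L,
                     end = sub$pos, value = sub$fraction)
    utils::write.table(bg, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}
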