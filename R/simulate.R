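#' Build a synthetic plasmid-like reporter reference
#'
#' Constructs a random reference emulating the structure of a reporter
#' plasmid used to characterise RNA-guided methylation: one planted
#' PAM + protospacer cassette per requested target gap, whose target CpG
#' is embedded in an FspI site (TGCGCA, CpG at internal positions 3--4)
#' so the restriction-protection assay applies; at least two FspI sites
#' overall; and a requested number of additional background ("off-target")
#' CpG sites. The background sequence is CpG-free outside planted sites,
#' so the scanner finds exactly the planted CpGs.
#'
#' The returned methylation specification assigns every CpG cytosine
#' (both strands) a ground-truth methylation probability: off-target
#' cytosines draw independently from a Beta background (default
#' Beta(0.5, 99.5), mean 0.5%, matching the observed sub-1% off-target
#' regime); target cytosines start at 0 and are set explicitly with
#' [set_site_probability()]. An optional proximity mode inflates
#' background probabilities within a window of the target protospacer to
#' emulate topology-driven off-target methylation concentrated within a
#' few hundred bp of the bound site.
#'
#' @param n_offtarget_cpgs Number of background CpG sites to plant.
#' @param target_gaps Integer vector of PAM-to-CpG gaps, one planted
#'   target cassette each (gaps must be >= 2 so the FspI site clears the
#'   PAM).
#' @param topology `"circular"` (plasmid-like, default) or `"linear"`.
#' @param seed Optional RNG seed for reproducible construction.
#' @param offtarget_shape Two Beta shape parameters for the background.
#' @param proximity_window If > 0, background CpGs within this many bp of
#'   a target PAM draw from an inflated background.
#' @param proximity_mean Mean of the inflated background Beta (shape1
#'   fixed at 0.5).
#' @return List of class `"synthetic_reference"`: `record`
#'   ([seq_record()]), `spec` (data.frame: `pos`, `strand`, `prob`,
#'   `target`), `targets` (data.frame: `pam_start`, `strand`, `gap`,
#'   `c_forward_pos`, `fspi_start`), `fspi_starts`.
#' @export
build_reference <- function(n_offtarget_cpgs = 240L, target_gaps = 12L,
                            topology = c("circular", "linear"), seed = NULL,
                            offtarget_shape = c(0.5, 99.5),
                            proximity_window = 0L, proximity_mean = 0.05) {
  topology <- match.arg(topology)
  stopifnot(n_offtarget_cpgs >= 0L)
  if (length(target_gaps) && any(target_gaps < 2L)) {
    stop("target gaps must be >= 2 bp (FspI site must clear the PAM)")
  }
  if (!is.null(seed)) set.seed(seed)

  # CpG-free random block with A/T first and last base, so no CpG, PAM or
  # FspI site can be created across a junction with a planted element
  rand_block <- function(n) {
    if (n <= 0L) return(character(0))
    x <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    x[1L] <- sample(c("A", "T"), 1L)
    x[n] <- sample(c("A", "T"), 1L)
    if (n >= 2L) {
      i <- which(x[-n] == "C" & x[-1L] == "G")
      if (length(i)) x[i + 1L] <- "A"
    }
    x
  }

  pieces <- list(rand_block(60L))
  cursor <- 60L
  targets <- list()
  fspi_starts <- integer(0)
  target_cpg_fwd <- integer(0)

  for (g in target_gaps) {
    proto <- rand_block(20L)
    cassette <- c(proto, c("A", "G", "G"), rand_block(g - 2L),
                  strsplit("TGCGCA", "")[[1]], rand_block(30L))
    pam_start <- cursor + 21L          # leftmost base of AGG
    pam_end <- cursor + 23L
    fspi_start <- pam_end + (g - 2L) + 1L
    c_fwd <- fspi_start + 2L
    targets[[length(targets) + 1L]] <- data.frame(
      pam_start = pam_start, strand = "+", gap = as.integer(g),
      c_forward_pos = c_fwd, fspi_start = fspi_start)
    fspi_starts <- c(fspi_starts, fspi_start)
    target_cpg_fwd <- c(target_cpg_fwd, c_fwd)
    pieces[[length(pieces) + 1L]] <- cassette
    cursor <- cursor + length(cassette)
  }

  # guarantee >= 2 FspI sites; extras carry off-target CpGs
  extra_fspi_cpg <- integer(0)
  n_extra <- max(0L, 2L - length(target_gaps))
  for (k in seq_len(n_extra)) {
    cassette <- c(rand_block(12L), strsplit("TGCGCA", "")[[1]],
                  rand_block(12L))
    fspi_start <- cursor + 13L
    fspi_starts <- c(fspi_starts, fspi_start)
    extra_fspi_cpg <- c(extra_fspi_cpg, fspi_start + 2L)
    pieces[[length(pieces) + 1L]] <- cassette
    cursor <- cursor + length(cassette)
  }

  off_cpg_fwd <- extra_fspi_cpg
  n_body <- n_offtarget_cpgs - length(extra_fspi_cpg)
  for (k in seq_len(max(0L, n_body))) {
    spacer <- rand_block(sample(5:12, 1L))
    pieces[[length(pieces) + 1L]] <- c(spacer, c("C", "G"))
    off_cpg_fwd <- c(off_cpg_fwd, cursor + length(spacer) + 1L)
    cursor <- cursor + length(spacer) + 2L
  }
  pieces[[length(pieces) + 1L]] <- rand_block(40L)

  seq <- paste(unlist(pieces), collapse = "")
  record <- seq_record(seq, id = "synthetic_reporter", topology = topology)

  all_cpg <- sort(c(target_cpg_fwd, off_cpg_fwd))
  is_target <- all_cpg %in% target_cpg_fwd
  spec <- data.frame(
    pos = as.integer(c(rbind(all_cpg, all_cpg + 1L))),
    strand = rep(c("+", "-"), length(all_cpg)),
    prob = 0,
    target = rep(is_target, each = 2L),
    stringsAsFactors = FALSE)
  off_rows <- which(!spec$target)
  spec$prob[off_rows] <- stats::rbeta(length(off_rows), offtarget_shape[1],
                                      offtarget_shape[2])
  if (proximity_window > 0L && length(targets)) {
    pam_pos <- vapply(targets, `[[`, integer(1), "pam_start")
    near <- vapply(spec$pos, function(p) {
      any(abs(p - pam_pos) <= proximity_window)
    }, logical(1))
    hot <- which(near & !spec$target)
    if (length(hot)) {
      s1 <- 0.5
      s2 <- s1 * (1 - proximity_mean) / proximity_mean
      spec$prob[hot] <- stats::rbeta(length(hot), s1, s2)
    }
  }

  targets <- if (length(targets)) do.call(rbind, targets) else
    data.frame(pam_start = integer(), strand = character(),
               gap = integer(), c_forward_pos = integer(),
               fspi_start = integer())
  structure(list(record = record, spec = spec, targets = targets,
                 fspi_starts = sort(fspi_starts)),
            class = "synthetic_reference")
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat(sprintf("<synthetic_reference> %d bp (%s), %d target site(s), %d CpG cytosines, %d FspI site(s)\n",
              x$record$length, x$record$topology, nrow(x$targets),
              nrow(x$spec), length(x$fspi_starts)))
  invisible(x)
}

#' Set a ground-truth methylation probability in a specification
#'
#' @param spec The `spec` data.frame of a [build_reference()] result.
#' @param pos Forward coordinate of the cytosine's own base.
#' @param strand `"+"` (forward C) or `"-"` (reverse C, the base
#'   opposite the forward G at `pos`).
#' @param prob Methylation probability in `[0, 1]`.
#' @return The modified spec.
#' @export
set_site_probability <- function(spec, pos, strand, prob) {
  stopifnot(prob >= 0, prob <= 1)
  hit <- spec$pos == pos & spec$strand == strand
  if (!any(hit)) stop("no such cytosine in the specification")
  spec$prob[hit] <- prob
  spec
}

#' Sample per-molecule methylation states
#'
#' Each cytosine of each molecule is methylated independently with its
#' specified probability (Bernoulli per site and strand).
#'
#' @param spec Specification data.frame (`pos`, `strand`, `prob`).
#' @param n_molecules Number of molecules (>= 1).
#' @param seed Optional RNG seed.
#' @return Integer 0/1 matrix, `n_molecules` x `nrow(spec)`; columns
#'   follow the spec rows.
#' @export
sample_molecules <- function(spec, n_molecules, seed = NULL) {
  stopifnot(n_molecules >= 1L)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(spec)
  m <- matrix(stats::runif(n_molecules * k), n_molecules, k)
  states <- (m < matrix(rep(spec$prob, each = n_molecules),
                        n_molecules, k)) * 1L
  storage.mode(states) <- "integer"
  states
}

#' Bisulfite-convert molecules
#'
#' Emulates bisulfite chemistry on both strands of each molecule:
#' unmethylated cytosines deaminate and read as T, methylated cytosines
#' (CpG context, per the molecule's state) are protected and remain C.
#' Non-CpG cytosines are always converted (the MTase is CpG-specific, so
#' they are never methylated). `conversion` < 1 leaves an unmethylated
#' CpG cytosine unconverted (still read as C) with probability
#' `1 - conversion`.
#'
#' @param states Matrix from [sample_molecules()].
#' @param record The reference [seq_record()].
#' @param spec The specification data.frame the states were sampled from.
#' @param conversion Conversion efficiency in `[0, 1]` (default 1:
#'   idealised complete conversion).
#' @param seed Optional RNG seed (used only when `conversion < 1`).
#' @return List with character vectors `top` and `bottom`: the two
#'   converted strand sequences (each written 5' to 3' on its own
#'   strand) per molecule.
#' @export
bisulfite_convert <- function(states, record, spec, conversion = 1,
                              seed = NULL) {
  stopifnot(inherits(record, "seq_record"), ncol(states) == nrow(spec),
            conversion >= 0, conversion <= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- record$length
  ch <- .record_chars(record)
  bch <- rev(.comp_chars(ch))
  top_t <- ch; top_t[top_t == "C"] <- "T"
  bot_t <- bch; bot_t[bot_t == "C"] <- "T"
  top_template <- paste(top_t, collapse = "")
  bot_template <- paste(bot_t, collapse = "")

  plus <- spec$strand == "+"
  top_idx <- spec$pos            # top-strand index of each + cytosine
  bot_idx <- L - spec$pos + 1L   # bottom-strand index of each - cytosine

  n <- nrow(states)
  top <- character(n)
  bottom <- character(n)
  for (i in seq_len(n)) {
    keep_c <- states[i, ] == 1L
    if (conversion < 1) {
      fail <- stats::runif(nrow(spec)) > conversion
      keep_c <- keep_c | fail
    }
    s <- top_template
    for (j in which(keep_c & plus)) {
      substr(s, top_idx[j], top_idx[j]) <- "C"
    }
    top[i] <- s
    s <- bot_template
    for (j in which(keep_c & !plus)) {
      substr(s, bot_idx[j], bot_idx[j]) <- "C"
    }
    bottom[i] <- s
  }
  list(top = top, bottom = bottom)
}

#' Sample bisulfite short reads from converted molecules
#'
#' Single-end reads with uniform start positions (wrapping across the
#' origin for circular records), drawn from randomly chosen molecules
#' and strands, with independent substitution errors. Read names encode
#' the ground truth as `mol<id>|<top|bottom>|<start>` where `start` is
#' the 1-based start in the source strand's own coordinates.
#'
#' @param converted Output of [bisulfite_convert()].
#' @param record The reference [seq_record()].
#' @param read_length Read length in nt (<= reference length).
#' @param depth Target mean per-base coverage; the number of reads is
#'   `round(depth * L / read_length)`.
#' @param error_rate Per-base substitution error probability.
#' @param seed Optional RNG seed.
#' @return data.frame of class `"sim_reads"` with columns `name`, `seq`.
#' @export
sample_reads <- function(converted, record, read_length = 75L, depth = 500,
                         error_rate = 0, seed = NULL) {
  stopifnot(inherits(record, "seq_record"),
            read_length <= record$length, depth > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- record$length
  circ <- record$topology == "circular"
  n_mol <- length(converted$top)
  n_reads <- max(1L, round(depth * L / read_length))

  ext <- function(x) if (circ) paste0(x, substr(x, 1L, read_length - 1L)) else x
  tops <- ext(converted$top)
  bots <- ext(converted$bottom)

  mol <- sample.int(n_mol, n_reads, replace = TRUE)
  strand <- sample(c("top", "bottom"), n_reads, replace = TRUE)
  start <- if (circ) sample.int(L, n_reads, replace = TRUE) else
    sample.int(L - read_length + 1L, n_reads, replace = TRUE)

  seqs <- character(n_reads)
  it <- strand == "top"
  seqs[it] <- substring(tops[mol[it]], start[it],
                        start[it] + read_length - 1L)
  seqs[!it] <- substring(bots[mol[!it]], start[!it],
                         start[!it] + read_length - 1L)

  if (error_rate > 0) {
    nerr <- stats::rbinom(n_reads, read_length, error_rate)
    bases <- c("A", "C", "G", "T")
    for (r in which(nerr > 0L)) {
      pos <- sample.int(read_length, nerr[r])
      s <- seqs[r]
      for (p in pos) {
        old <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(bases, old), 1L)
      }
      seqs[r] <- s
    }
  }
  structure(data.frame(
    name = sprintf("mol%06d|%s|%d", mol, strand, start),
    seq = seqs, stringsAsFactors = FALSE),
    class = c("sim_reads", "data.frame"))
}

#' Parse simulated read names back into their ground-truth provenance
#'
#' @param names Character vector of `mol<id>|<strand>|<start>` names.
#' @return data.frame with `molecule`, `strand`, `start`.
#' @export
parse_read_names <- function(names) {
  parts <- strsplit(names, "|", fixed = TRUE)
  data.frame(
    molecule = as.integer(sub("^mol", "", vapply(parts, `[`, "", 1L))),
    strand = vapply(parts, `[`, "", 2L),
    start = as.integer(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE)
}

#' Write / read simulated reads as FASTQ
#'
#' @param reads data.frame with `name`, `seq` ([sample_reads()] output).
#' @param path FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$name
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' @rdname write_fastq
#' @return [read_fastq()]: data.frame with `name`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(name = names(x), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the ground-truth methylation specification
#'
#' Tab-delimited: `pos`, `strand`, `prob`, `target`.
#'
#' @param spec Specification data.frame.
#' @param path Output file.
#' @export
write_truth_table <- function(spec, path) {
  utils::write.table(spec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Find FspI recognition sites (TGCGCA)
#'
#' @param record A [seq_record()]; circular records are scanned across
#'   the origin.
#' @return Integer vector of 1-based start positions (in `1..L`).
#' @export
find_fspi_sites <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  s <- record$seq
  L <- record$length
  if (record$topology == "circular" && L >= 6L) {
    s <- paste0(s, substr(record$seq, 1L, 5L))
  }
  hits <- gregexpr("(?=TGCGCA)", s, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  sort(unique(.wrap_pos(as.integer(hits), L)))
}

#' Simulated FspI restriction-protection assay
#'
#' FspI cuts bluntly between positions 3 and 4 of TGCGCA unless the CpG
#' embedded at positions 3--4 is methylated on either strand, which
#' protects the site. Digesting each molecule of a population therefore
#' converts the per-molecule methylation states into fragment patterns;
#' the protected fraction across site copies mirrors the methylation
#' level.
#'
#' @param states Matrix from [sample_molecules()].
#' @param record The reference [seq_record()].
#' @param spec The specification data.frame matching `states`.
#' @return List: `fragments` (per-molecule integer vectors of fragment
#'   lengths; a circular molecule with no cut yields one full-length
#'   fragment), `protected_fraction` (overall fraction of site copies
#'   protected), `per_site` (named per-site protected fractions),
#'   `cut_after` (cut positions used, per site).
#' @export
digest_fspi <- function(states, record, spec) {
  stopifnot(inherits(record, "seq_record"), ncol(states) == nrow(spec))
  L <- record$length
  circ <- record$topology == "circular"
  sites <- find_fspi_sites(record)
  n <- nrow(states)
  if (!length(sites)) {
    return(list(
      fragments = replicate(n, L, simplify = FALSE),
      protected_fraction = NA_real_,
      per_site = numeric(0), cut_after = integer(0)))
  }
  c_fwd <- .wrap_pos(sites + 2L, L)
  col_plus <- match(paste(c_fwd, "+"), paste(spec$pos, spec$strand))
  col_minus <- match(paste(.wrap_pos(sites + 3L, L), "-"),
                     paste(spec$pos, spec$strand))
  protected <- sapply(seq_along(sites), function(k) {
    p <- if (!is.na(col_plus[k])) states[, col_plus[k]] else
      rep(0L, n)
    m <- if (!is.na(col_minus[k])) states[, col_minus[k]] else
      rep(0L, n)
    (p | m) * 1L
  })
  protected <- matrix(protected, nrow = n)
  cut_after <- .wrap_pos(sites + 2L, L)  # blunt cut after 3rd base
  fragments <- lapply(seq_len(n), function(i) {
    cuts <- sort(cut_after[protected[i, ] == 0L])
    if (!length(cuts)) return(L)
    if (circ) {
      if (length(cuts) == 1L) return(L)
      as.integer(diff(c(cuts, cuts[1] + L)))
    } else {
      as.integer(diff(c(0L, cuts, L)))
    }
  })
  list(fragments = fragments,
       protected_fraction = mean(protected),
       per_site = stats::setNames(colMeans(protected),
                                  paste0("fspi_", sites)),
       cut_after = cut_after)
}
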