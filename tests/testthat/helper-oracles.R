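# Independent brute-force oracles and fixture builders. These stay
# deliberately naive (window loops, textbook formulas) so they can
# cross-check the package implementations.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# every NGG PAM with a full 20-nt protospacer, by scanning all windows
oracle_pams <- function(record) {
  ch <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  circ <- record$topology == "circular"
  at <- function(p) ch[((p - 1) %% L) + 1]
  real <- c("A", "C", "G", "T")
  out <- data.frame(strand = character(), pam_start = integer())
  if (L < 23) return(out)
  for (i in 1:L) {
    if (!circ && i + 2 > L) next
    tri <- vapply(i:(i + 2), at, character(1))
    if (tri[1] %in% real && tri[2] == "G" && tri[3] == "G" &&
        (circ || i - 20 >= 1)) {
      out <- rbind(out, data.frame(strand = "+", pam_start = i))
    }
    if (tri[1] == "C" && tri[2] == "C" && tri[3] %in% real &&
        (circ || i + 22 <= L)) {
      out <- rbind(out, data.frame(strand = "-", pam_start = i))
    }
  }
  out[order(out$pam_start, out$strand), , drop = FALSE]
}

# every CG dinucleotide, by substring scan
oracle_cpgs <- function(record) {
  ch <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  pos <- integer(0)
  for (i in seq_len(L - 1)) {
    if (ch[i] == "C" && ch[i + 1] == "G") pos <- c(pos, i)
  }
  if (record$topology == "circular" && L >= 2 &&
      ch[L] == "C" && ch[1] == "G") {
    pos <- c(pos, L)
  }
  pos
}

# independent gap arithmetic for a PAM/CpG pair under the documented
# convention (bases strictly between the PAM 3' end and the cis C)
oracle_gap <- function(strand, pam_start, c_fwd, L, circ) {
  raw <- if (strand == "+") c_fwd - (pam_start + 2) - 1 else
    pam_start - (c_fwd + 1) - 1
  if (!circ) {
    if (raw < 0) return(NA_integer_)
    return(as.integer(raw))
  }
  g <- raw %% L
  fp <- if (strand == "+") (pam_start - 20):(pam_start + 2) else
    pam_start:(pam_start + 22)
  fp <- ((fp - 1) %% L) + 1
  crv <- ((c_fwd) %% L) + 1
  if (c_fwd %in% fp || crv %in% fp) return(NA_integer_)
  as.integer(g)
}

oracle_gap_multiset <- function(record, min_gap = 8, max_gap = 25) {
  p <- oracle_pams(record)
  cg <- oracle_cpgs(record)
  gaps <- integer(0)
  if (nrow(p) && length(cg)) {
    for (i in seq_len(nrow(p))) {
      for (cf in cg) {
        g <- oracle_gap(p$strand[i], p$pam_start[i], cf,
                        record$length, record$topology == "circular")
        if (!is.na(g) && g >= min_gap && g <= max_gap) gaps <- c(gaps, g)
      }
    }
  }
  sort(gaps)
}

# textbook Pearson correlation (no stats::cor)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# --- multiplex fixture builder: A/T background with planted elements ---

at_background <- function(len) rep(c("A", "T"), length.out = len)

plant_pam <- function(ch, pam_start, strand) {
  ch[pam_start + 0:2] <- if (strand == "+") c("A", "G", "G") else
    c("C", "C", "A")
  ch
}

plant_cpg <- function(ch, c_fwd) {
  ch[c_fwd + 0:1] <- c("C", "G")
  ch
}

# builds a record holding two guides (by pam_start/strand) each with one
# target CpG at gap 12, all coordinates shiftable for translation tests
pair_fixture <- function(pamA, strandA, pamB, strandB, len = 220,
                         shift = 0, gap = 12) {
  ch <- at_background(len)
  cpg_for <- function(pam, strand) {
    if (strand == "+") pam + 2 + gap + 1 else pam - gap - 2
  }
  cA <- cpg_for(pamA + shift, strandA)
  cB <- cpg_for(pamB + shift, strandB)
  ch <- plant_pam(ch, pamA + shift, strandA)
  ch <- plant_pam(ch, pamB + shift, strandB)
  ch <- plant_cpg(ch, cA)
  ch <- plant_cpg(ch, cB)
  rec <- seq_record(paste(ch, collapse = ""), id = "fixture")
  list(record = rec,
       a = guide_candidate(rec, pamA + shift, strandA, id = "A"),
       b = guide_candidate(rec, pamB + shift, strandB, id = "B"))
}
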