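#' Guide candidate for multiplex compatibility checking
#'
#' A guide is described by its PAM position and strand on a record; its
#' 23-bp footprint (20-nt protospacer + 3-nt PAM, the DNA occupied by
#' bound dCas9) and the CpG sites it can target within the profile's gap
#' window are derived from the record.
#'
#' @param record A [seq_record()].
#' @param pam_start Forward 1-based coordinate of the PAM trinucleotide's
#'   leftmost base (as reported by [find_pams()]).
#' @param strand `"+"` or `"-"`.
#' @param id Optional guide name.
#' @param min_gap,max_gap Gap window for its targeted CpGs (defaults: the
#'   targetable window 8--25).
#' @return Object of class `"guide_candidate"`.
#' @export
guide_candidate <- function(record, pam_start, strand = c("+", "-"),
                            id = NULL, min_gap = 8L, max_gap = 25L) {
  stopifnot(inherits(record, "seq_record"))
  strand <- match.arg(strand)
  pams <- find_pams(record)
  hit <- pams$pam_start == pam_start & pams$strand == strand
  if (!any(hit)) {
    stop(sprintf("no NGG PAM with a full protospacer at %d (%s) on '%s'",
                 pam_start, strand, record$id))
  }
  footprint <- if (strand == "+") {
    c(pam_start - 20L, pam_start + 2L)
  } else {
    c(pam_start, pam_start + 22L)
  }
  sites <- enumerate_target_sites(record, min_gap, max_gap)
  own <- sites[sites$pam_start == pam_start & sites$strand == strand, ,
               drop = FALSE]
  structure(
    list(id = if (is.null(id)) sprintf("g%d%s", pam_start, strand) else id,
         record_id = record$id, record_length = record$length,
         topology = record$topology,
         pam_start = as.integer(pam_start), strand = strand,
         footprint = as.integer(footprint), targets = own),
    class = "guide_candidate")
}

#' @export
print.guide_candidate <- function(x, ...) {
  cat(sprintf("<guide_candidate> %s: PAM %d (%s), footprint [%d, %d], %d target CpG(s)\n",
              x$id, x$pam_start, x$strand, x$footprint[1], x$footprint[2],
              nrow(x$targets)))
  invisible(x)
}

# distance (bp) from positions to a footprint interval; 0 when inside
.dist_to_interval <- function(pos, fp, L, topology) {
  if (topology == "circular") {
    fpset <- .wrap_pos(fp[1]:fp[2], L)
    vapply(pos, function(p) {
      if (p %in% fpset) return(0L)
      d <- pmin((p - fpset) %% L, (fpset - p) %% L)
      min(d)
    }, integer(1))
  } else {
    ifelse(pos < fp[1], fp[1] - pos, ifelse(pos > fp[2], pos - fp[2], 0L))
  }
}

.footprints_overlap <- function(a, b) {
  if (a$topology == "circular") {
    length(intersect(.wrap_pos(a$footprint[1]:a$footprint[2], a$record_length),
                     .wrap_pos(b$footprint[1]:b$footprint[2], b$record_length))) > 0
  } else {
    a$footprint[1] <= b$footprint[2] && b$footprint[1] <= a$footprint[2]
  }
}

# targeted CpGs of `a` obstructed by `b`'s footprint: blocked when the
# nearer cytosine of the CpG is inside, or within block_margin bp of,
# the partner's 23-bp footprint
.blocked_cpgs <- function(a, b, block_margin) {
  if (!nrow(a$targets)) {
    return(data.frame(guide = character(), c_forward_pos = integer(),
                      blocked_by = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  d <- vapply(seq_len(nrow(a$targets)), function(k) {
    min(.dist_to_interval(
      c(a$targets$c_forward_pos[k], a$targets$c_reverse_pos[k]),
      b$footprint, a$record_length, a$topology))
  }, integer(1))
  keep <- which(d <= block_margin)
  data.frame(guide = rep(a$id, length(keep)),
             c_forward_pos = a$targets$c_forward_pos[keep],
             blocked_by = rep(b$id, length(keep)), distance = d[keep],
             stringsAsFactors = FALSE)
}

#' Pairwise interference status of two guides
#'
#' Encodes the demonstrated multiplexing rules: a targeted CpG lying
#' inside, or within `block_margin` bp of, the partner guide's 23-bp
#' footprint cannot be methylated (dCas9 obstruction) and is flagged
#' `blocked`; guides with overlapping footprints but unobstructed target
#' CpGs merely compete for binding (`competing`, near-full efficiency
#' via complex exchange); guides with disjoint footprints and
#' unobstructed CpGs are `compatible` (independence was demonstrated at
#' a 33-bp same-strand separation).
#'
#' @param a,b [guide_candidate()] objects on the same record.
#' @param block_margin Obstruction margin in bp around a footprint
#'   (default 4, the largest distance at which blocking was demonstrated;
#'   the true threshold between 4 and 33 bp is unmeasured, so treat
#'   intermediate distances with care).
#' @return Object of class `"pair_status"`: list with `status` (one of
#'   `compatible`, `competing`, `blocked`), `blocked` (data.frame of
#'   obstructed CpGs with blocking guide and distance), `overlap`
#'   (logical), `reason`.
#' @export
check_pair <- function(a, b, block_margin = 4L) {
  stopifnot(inherits(a, "guide_candidate"), inherits(b, "guide_candidate"))
  if (!identical(a$record_id, b$record_id) ||
      a$record_length != b$record_length) {
    stop("guides must come from the same record")
  }
  blocked <- rbind(.blocked_cpgs(a, b, block_margin),
                   .blocked_cpgs(b, a, block_margin))
  overlap <- .footprints_overlap(a, b)
  if (nrow(blocked)) {
    status <- "blocked"
    reason <- sprintf("%d target CpG(s) obstructed by the partner footprint (margin %d bp)",
                      nrow(blocked), block_margin)
  } else if (overlap) {
    status <- "competing"
    reason <- "footprints overlap; guides exchange at the shared site with minimal interference"
  } else {
    status <- "compatible"
    reason <- "disjoint footprints, no obstructed target CpG"
  }
  structure(list(status = status, blocked = blocked, overlap = overlap,
                 reason = reason, block_margin = as.integer(block_margin)),
            class = "pair_status")
}

#' @export
print.pair_status <- function(x, ...) {
  cat(sprintf("<pair_status> %s: %s\n", x$status, x$reason))
  if (nrow(x$blocked)) print(x$blocked)
  invisible(x)
}

#' Compatibility matrix and warnings for a multiplexed guide set
#'
#' Evaluates all unordered pairs; each CpG obstructed by any partner is
#' reported once per blocking guide. The set verdict is the worst pair
#' status (`compatible < competing < blocked`).
#'
#' @param guides List of [guide_candidate()]s (length >= 1).
#' @param block_margin See [check_pair()].
#' @return List with `matrix` (character, guide ids as dimnames),
#'   `warnings` (data.frame of blocked CpGs), `verdict`.
#' @export
check_set <- function(guides, block_margin = 4L) {
  stopifnot(is.list(guides), length(guides) >= 1L)
  ids <- vapply(guides, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("guide ids must be unique")
  n <- length(guides)
  m <- matrix("compatible", n, n, dimnames = list(ids, ids))
  diag(m) <- "self"
  warnings <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ps <- check_pair(guides[[i]], guides[[j]], block_margin)
        m[i, j] <- m[j, i] <- ps$status
        if (nrow(ps$blocked)) warnings[[length(warnings) + 1L]] <- ps$blocked
      }
    }
  }
  warnings <- if (length(warnings)) {
    w <- do.call(rbind, warnings)
    w[!duplicated(w[c("guide", "c_forward_pos", "blocked_by")]), ,
      drop = FALSE]
  } else {
    data.frame(guide = character(), c_forward_pos = integer(),
               blocked_by = character(), distance = integer(),
               stringsAsFactors = FALSE)
  }
  lvl <- c(self = 0, compatible = 1, competing = 2, blocked = 3)
  worst <- max(lvl[unique(as.vector(m))])
  verdict <- if (worst <= 1) "compatible" else names(lvl)[lvl == worst]
  list(matrix = m, warnings = warnings, verdict = verdict)
}

#' Predicted per-cytosine methylation for a multiplexed guide set
#'
#' Per targeted CpG cytosine: 0 if its CpG is obstructed by any guide's
#' footprint; otherwise the maximum single-guide profile prediction
#' among unblocked guides targeting it (competing guides exchange, so
#' multiplexed efficiency matches the best single guide rather than
#' summing).
#'
#' @param guides List of [guide_candidate()]s.
#' @param profile A [gap_profile()].
#' @param block_margin See [check_pair()].
#' @return data.frame with columns `pos`, `strand` (cytosine address),
#'   `c_forward_pos` (its CpG), `predicted`, `blocked`, `guide` (best
#'   unblocked guide, `NA` if blocked).
#' @export
effective_prediction <- function(guides, profile, block_margin = 4L) {
  if (!length(guides)) {
    return(data.frame(pos = integer(), strand = character(),
                      c_forward_pos = integer(), predicted = numeric(),
                      blocked = logical(), guide = character(),
                      stringsAsFactors = FALSE))
  }
  cs <- check_set(guides, block_margin)
  blocked_key <- unique(paste(cs$warnings$guide, cs$warnings$c_forward_pos))
  rows <- list()
  for (g in guides) {
    t <- g$targets
    if (!nrow(t)) next
    scored <- score_target_sites(t, profile)
    for (k in seq_len(nrow(t))) {
      is_blocked <- paste(g$id, t$c_forward_pos[k]) %in% blocked_key
      rows[[length(rows) + 1L]] <- data.frame(
        pos = c(scored$cis_pos[k], scored$trans_pos[k]),
        strand = c(scored$cis_strand[k], scored$trans_strand[k]),
        c_forward_pos = t$c_forward_pos[k],
        predicted = if (is_blocked) c(0, 0) else
          c(scored$p_cis[k], scored$p_trans[k]),
        blocked = is_blocked, guide = g$id, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pos = integer(), strand = character(),
                      c_forward_pos = integer(), predicted = numeric(),
                      blocked = logical(), guide = character(),
                      stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, rows)
  # a CpG obstructed for any guide is physically obstructed for all
  cpg_blocked <- unique(all$c_forward_pos[all$blocked])
  all$blocked <- all$c_forward_pos %in% cpg_blocked
  all$predicted[all$blocked] <- 0
  # per cytosine: best unblocked guide
  key <- paste(all$pos, all$strand)
  out <- do.call(rbind, lapply(split(all, key), function(d) {
    best <- which.max(d$predicted)
    data.frame(pos = d$pos[1], strand = d$strand[1],
               c_forward_pos = d$c_forward_pos[1],
               predicted = d$predicted[best],
               blocked = d$blocked[1],
               guide = if (d$blocked[1]) NA_character_ else d$guide[best],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
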