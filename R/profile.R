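#' Gap-to-efficiency profile
#'
#' A per-gap, per-strand table of predicted methylation fractions for a
#' target CpG as a function of its PAM gap. The packaged default (see
#' [default_gap_profile()]) encodes the empirically established shape of
#' the gap scan: no methylation below 8 bp or above 25 bp, oscillation
#' with the helical period, a first-turn optimum at 12 bp and a
#' second-turn optimum at 22--23 bp, and the trans strand methylated
#' better than the cis strand throughout. Profiles can be replaced from
#' user calibration data via [read_gap_profile()].
#'
#' @param entries data.frame with integer column `gap` (unique) and
#'   columns `p_cis`, `p_trans` in `[0, 1]`.
#' @param provenance Free-text label describing where the numbers come
#'   from.
#' @return Object of class `"gap_profile"`.
#' @export
gap_profile <- function(entries, provenance = "user") {
  stopifnot(is.data.frame(entries),
            all(c("gap", "p_cis", "p_trans") %in% names(entries)))
  if (any(entries$gap != round(entries$gap)) || anyDuplicated(entries$gap)) {
    stop("`gap` must be unique integers")
  }
  p <- c(entries$p_cis, entries$p_trans)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  entries <- entries[order(entries$gap),
                     c("gap", "p_cis", "p_trans"), drop = FALSE]
  entries$gap <- as.integer(entries$gap)
  rownames(entries) <- NULL
  structure(list(entries = entries, provenance = provenance),
            class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  nz <- x$entries[x$entries$p_cis > 0 | x$entries$p_trans > 0, ]
  cat(sprintf("<gap_profile> %d gaps (%d with nonzero efficiency)\n",
              nrow(x$entries), nrow(nz)))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Packaged default gap-efficiency profile
#'
#' A smooth raised-cosine parameterisation of the gap scan shape: for
#' gaps g in 8..25,
#' `p_trans(g) = 0.30 * (0.5 + 0.5 * cos(2*pi*(g - 12) / 10.5))` and
#' `p_cis = 0.55 * p_trans`, rounded to 4 decimals; zero elsewhere in
#' 2..42. The 10.5 bp period matches the 34.3 deg/bp helical twist, the
#' maximum sits at gap 12, and the second-turn raised-cosine crest falls
#' symmetrically between 22 and 23 so both are reported as tied peaks.
#' These numeric values are a packaged configuration artifact satisfying
#' the established qualitative constraints, not measured data; calibrate
#' your own profile for quantitative predictions.
#'
#' @return A [gap_profile()] covering gaps 2..42.
#' @export
default_gap_profile <- function() {
  g <- 2:42
  shape <- 0.5 + 0.5 * cos(2 * pi * (g - 12) / 10.5)
  inside <- g >= 8 & g <= 25
  gap_profile(
    data.frame(gap = g,
               p_cis = ifelse(inside, round(0.165 * shape, 4), 0),
               p_trans = ifelse(inside, round(0.30 * shape, 4), 0)),
    provenance = "packaged default (raised-cosine, period 10.5 bp)")
}

#' Predicted single-strand methylation fraction at a gap
#'
#' Gaps absent from the profile (including anything outside 2..42 for
#' the default) predict 0. Vectorised over `gap`.
#'
#' @param profile A [gap_profile()].
#' @param gap Integer gap(s) in bp.
#' @param strand `"trans"` or `"cis"` role of the cytosine.
#' @return Fraction(s) in `[0, 1]`.
#' @export
predict_strand <- function(profile, gap, strand = c("trans", "cis")) {
  stopifnot(inherits(profile, "gap_profile"))
  strand <- match.arg(strand)
  if (any(gap != round(gap))) stop("`gap` must be whole base-pair counts")
  col <- if (strand == "trans") "p_trans" else "p_cis"
  idx <- match(as.integer(gap), profile$entries$gap)
  out <- profile$entries[[col]][idx]
  out[is.na(idx)] <- 0
  out
}

#' Probability of methylation on at least one strand
#'
#' Combines the two per-strand fractions assuming strand-specific
#' methylation events are independent: `1 - (1 - p_cis) * (1 - p_trans)`.
#'
#' @param p_cis,p_trans Fractions in `[0, 1]` (vectorised).
#' @return Fraction(s).
#' @export
combine_any_strand <- function(p_cis, p_trans) {
  stopifnot(all(p_cis >= 0 & p_cis <= 1), all(p_trans >= 0 & p_trans <= 1))
  1 - (1 - p_cis) * (1 - p_trans)
}

#' At-least-one-strand prediction at a gap
#'
#' @param profile A [gap_profile()].
#' @param gap Integer gap(s).
#' @return Fraction(s).
#' @export
predict_any_strand <- function(profile, gap) {
  combine_any_strand(predict_strand(profile, gap, "cis"),
                     predict_strand(profile, gap, "trans"))
}

#' Targetable gap window of a profile
#'
#' @param profile A [gap_profile()].
#' @return `c(min_gap, max_gap)`: smallest and largest gap with a
#'   nonzero at-least-one-strand prediction. Errors on an all-zero
#'   profile.
#' @export
targetable_window <- function(profile) {
  stopifnot(inherits(profile, "gap_profile"))
  g <- profile$entries$gap
  p <- predict_any_strand(profile, g)
  nz <- g[p > 0]
  if (!length(nz)) stop("profile predicts zero efficiency everywhere")
  c(min_gap = min(nz), max_gap = max(nz))
}

#' Peak gaps (argmax of the at-least-one-strand prediction)
#'
#' Ties are all returned, sorted ascending: the second-turn optimum of
#' the default profile is a genuine two-gap peak.
#'
#' @param profile A [gap_profile()].
#' @param gaps Integer vector of gaps to search over (e.g. `8:15` for
#'   the first helical turn).
#' @return Sorted integer vector of maximising gaps.
#' @export
peak_gaps <- function(profile, gaps) {
  stopifnot(length(gaps) >= 1L)
  p <- predict_any_strand(profile, gaps)
  sort(as.integer(gaps[p >= max(p) - 1e-12]))
}

#' Classify a methylation fraction into transfer classes
#'
#' Classes follow the E. coli to human transfer analysis: `low` (< 5%),
#' `medium` (5--20%, closed on both ends), `high` (> 20%). The mapping is
#' monotone in the fraction.
#'
#' @param fraction Fraction(s) in `[0, 1]`.
#' @return Ordered factor with levels `low < medium < high`.
#' @export
classify_efficiency <- function(fraction) {
  if (anyNA(fraction) || any(fraction < 0 | fraction > 1)) {
    stop("`fraction` must lie in [0, 1]")
  }
  cls <- ifelse(fraction < 0.05, "low",
                ifelse(fraction <= 0.20, "medium", "high"))
  factor(cls, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Score candidate target sites against a profile
#'
#' Appends per-strand predictions for the two cytosines of each site's
#' CpG, the at-least-one-strand combination, and their transfer classes.
#'
#' @param sites Output of [enumerate_target_sites()] (any subset of rows).
#' @param profile A [gap_profile()].
#' @return `sites` with added columns `p_cis`, `p_trans`, `p_any`,
#'   `class_cis`, `class_trans`, `class_any`.
#' @export
score_target_sites <- function(sites, profile) {
  stopifnot(is.data.frame(sites), "gap" %in% names(sites))
  sites$p_cis <- predict_strand(profile, sites$gap, "cis")
  sites$p_trans <- predict_strand(profile, sites$gap, "trans")
  sites$p_any <- combine_any_strand(sites$p_cis, sites$p_trans)
  sites$class_cis <- classify_efficiency(sites$p_cis)
  sites$class_trans <- classify_efficiency(sites$p_trans)
  sites$class_any <- classify_efficiency(sites$p_any)
  sites
}

#' Read / write gap-efficiency profiles
#'
#' Tab-delimited with header columns `gap`, `p_cis`, `p_trans`;
#' validated on load.
#'
#' @param path File path.
#' @param provenance Label for the loaded profile.
#' @return [read_gap_profile()]: a [gap_profile()].
#' @export
read_gap_profile <- function(path, provenance = path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gap_profile(df, provenance = provenance)
}

#' @rdname read_gap_profile
#' @param profile A [gap_profile()] to write.
#' @export
write_gap_profile <- function(profile, path) {
  stopifnot(inherits(profile, "gap_profile"))
  utils::write.table(profile$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
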