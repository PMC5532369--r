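#' B-DNA helical geometry model for the dCas9--MTase fusion point
#'
#' The split-methyltransferase fusion strategy places the N-terminus of the
#' MC fragment at an angular position around the DNA axis, relative to the
#' C-terminus of dCas9, that depends on the gap between the PAM and the
#' target CpG. Each added base pair of gap rotates the fusion point by the
#' B-DNA twist. The model is anchored at a reference gap where the angles
#' for the two strand roles were measured on a structural model: at a gap
#' of 8 bp the angle is 20 degrees when the MTase methylates the trans
#' strand and 290 degrees for the cis strand.
#'
#' The sense of rotation with increasing gap is not determined by the
#' anchors alone; `rotation_sign` selects it (+1 by default, angle grows
#' with gap). Efficiency prediction does not consume the sign (see
#' [predict_strand()]), so it only affects polar visualisation.
#'
#' @param twist_per_bp Helical twist in degrees per base pair. The default
#'   34.3 corresponds to ideal B-DNA (10.5 bp/turn). Must lie in (0, 360).
#' @param anchor_gap Gap (bp) at which the anchor angles were measured.
#' @param anchor_angle_trans,anchor_angle_cis Anchor angles in degrees,
#'   in `[0, 360)`, for the MTase bound to the trans (sgRNA-complementary)
#'   or cis (PAM-carrying) strand.
#' @param rotation_sign +1 or -1; direction of rotation per added bp.
#' @return An object of class `"helical_model"`.
#' @seealso [angle_at_gap()], [helical_period()], [polar_profile()]
#' @examples
#' m <- helical_model()
#' angle_at_gap(m, 8, "trans")   # 20
#' angle_at_gap(m, 12, "cis")    # anchor + 4 twists, mod 360
#' @export
helical_model <- function(twist_per_bp = 34.3, anchor_gap = 8L,
                          anchor_angle_trans = 20, anchor_angle_cis = 290,
                          rotation_sign = 1) {
  if (!is.numeric(twist_per_bp) || length(twist_per_bp) != 1L ||
      !is.finite(twist_per_bp) || twist_per_bp <= 0 || twist_per_bp >= 360) {
    stop("`twist_per_bp` must be a single number in (0, 360)")
  }
  if (!is.numeric(anchor_gap) || length(anchor_gap) != 1L ||
      anchor_gap < 0 || anchor_gap != round(anchor_gap)) {
    stop("`anchor_gap` must be a single non-negative integer")
  }
  for (a in c(anchor_angle_trans, anchor_angle_cis)) {
    if (!is.numeric(a) || !is.finite(a) || a < 0 || a >= 360) {
      stop("anchor angles must lie in [0, 360)")
    }
  }
  if (!rotation_sign %in% c(-1, 1)) {
    stop("`rotation_sign` must be +1 or -1")
  }
  structure(
    list(twist_per_bp = twist_per_bp,
         anchor_gap = as.integer(anchor_gap),
         anchor_angle_trans = anchor_angle_trans,
         anchor_angle_cis = anchor_angle_cis,
         rotation_sign = rotation_sign),
    class = "helical_model"
  )
}

#' @export
print.helical_model <- function(x, ...) {
  cat("Helical geometry model\n")
  cat(sprintf("  twist: %.2f deg/bp (period %.3f bp)\n",
              x$twist_per_bp, helical_period(x)))
  cat(sprintf("  anchors at gap %d: trans %.1f deg, cis %.1f deg\n",
              x$anchor_gap, x$anchor_angle_trans, x$anchor_angle_cis))
  cat(sprintf("  rotation sign: %+d\n", x$rotation_sign))
  invisible(x)
}

#' Angular position of the MTase fusion point at a given gap
#'
#' Computes `anchor + rotation_sign * twist_per_bp * (gap - anchor_gap)`
#' reduced modulo 360, where the anchor is the strand-role-specific anchor
#' angle of the model. Vectorised over `gap`.
#'
#' @param model A [helical_model()].
#' @param gap Integer gap length(s) in bp between the PAM and the CpG;
#'   must be non-negative whole numbers (gaps are base-pair counts, so
#'   fractional values are rejected rather than interpolated).
#' @param strand `"trans"` or `"cis"` strand role of the methylated C.
#' @return Angle(s) in degrees, in `[0, 360)`.
#' @export
angle_at_gap <- function(model, gap, strand = c("trans", "cis")) {
  stopifnot(inherits(model, "helical_model"))
  strand <- match.arg(strand)
  if (!is.numeric(gap) || length(gap) == 0L || anyNA(gap) ||
      any(!is.finite(gap))) {
    stop("`gap` must be finite numeric")
  }
  if (any(gap < 0)) stop("`gap` must be non-negative")
  if (any(gap != round(gap))) stop("`gap` must be whole base-pair counts")
  anchor <- if (strand == "trans") model$anchor_angle_trans else
    model$anchor_angle_cis
  (anchor + model$rotation_sign * model$twist_per_bp *
      (gap - model$anchor_gap)) %% 360
}

#' Separation of an angle from 0 degrees
#'
#' Distance (in degrees, `[0, 180]`) of an angle from the reference 0
#' direction, i.e. from the dCas9 C-terminus side of the helix. Small
#' values mean the fusion points sit on the same side of the DNA.
#'
#' @param angle Angle(s) in degrees (any finite value).
#' @return Value(s) in `[0, 180]`.
#' @export
angular_separation <- function(angle) {
  if (!is.numeric(angle) || anyNA(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric")
  }
  a <- angle %% 360
  pmin(a, 360 - a)
}

#' Helical period implied by the model twist
#'
#' @param model A [helical_model()].
#' @return Period in bp (360 / twist), e.g. 10.496 bp for 34.3 deg/bp,
#'   consistent with the ~11 bp oscillation of methylation efficiency.
#' @export
helical_period <- function(model) {
  stopifnot(inherits(model, "helical_model"))
  360 / model$twist_per_bp
}

#' Tabulated polar profile of fusion-point angles over a gap range
#'
#' @param model A [helical_model()].
#' @param gaps Integer vector of gaps (default 2:42, the measured range).
#' @return A data.frame with columns `gap`, `strand`, `angle`.
#' @export
polar_profile <- function(model, gaps = 2:42) {
  data.frame(
    gap = rep(gaps, 2L),
    strand = rep(c("trans", "cis"), each = length(gaps)),
    angle = c(angle_at_gap(model, gaps, "trans"),
              angle_at_gap(model, gaps, "cis")),
    stringsAsFactors = FALSE
  )
}
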