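# Idealized curved B-DNA geometry.
#
# The two half-sites of the promoter IR are ~34 bp apart center-to-center
# (about three helical turns of 10.5 bp, so nearly on the same helical
# face), while the two wHTH motifs of a dimer span roughly 10-11 nm. On a
# straight helix the centers would be 34 * 0.34 = 11.56 nm apart; a planar
# circular arc with a constant per-bp bend shortens the chord, and the
# bend that brings the chord into the dimer span is the geometric
# feasibility condition for a dimer contacting both half-sites.

#' B-DNA helix model parameters
#'
#' @param rise helical rise, nm/bp (default 0.34).
#' @param bp_per_turn bp per helical turn (default 10.5).
#' @param bend_per_step planar bend per bp step, degrees (default 0 =
#'   straight).
#' @return list of class `helix_model`.
#' @export
helix_model <- function(rise = 0.34, bp_per_turn = 10.5, bend_per_step = 0) {
  stopifnot(rise > 0, bp_per_turn > 0, bend_per_step >= 0)
  structure(list(rise = rise, bp_per_turn = bp_per_turn,
                 bend_per_step = bend_per_step),
            class = "helix_model")
}

#' Total curvature of a bent fragment
#'
#' `bend_per_step * length`, using the N-steps-for-N-bp convention (a
#' 3 degree/bp bend over a 40-bp fragment gives 120 degrees). A strict
#' step count of N-1 is available via `convention = "n-1"`.
#'
#' @param bend_per_step degrees per bp.
#' @param length_bp fragment length, bp.
#' @param convention `"n"` (default) or `"n-1"` bend steps for an N-bp
#'   fragment.
#' @return total curvature in degrees.
#' @export
total_curvature <- function(bend_per_step, length_bp,
                            convention = c("n", "n-1")) {
  convention <- match.arg(convention)
  steps <- if (convention == "n") length_bp else length_bp - 1
  bend_per_step * steps
}

#' Chord distance between two points on a planar DNA arc
#'
#' Contour `L = sep_bp * rise`; arc angle `theta = sep_bp * bend_per_step`
#' (in radians); chord `= L` for a straight helix, otherwise
#' `2 * (L / theta) * sin(theta / 2)` (planar circular arc).
#'
#' @param center_sep_bp separation between the two motif centers, bp.
#' @param model a `helix_model` (its `bend_per_step` is used).
#' @return chord distance, nm.
#' @examples
#' chord_distance(34, helix_model(bend_per_step = 3)) # ~10.09 nm
#' @export
chord_distance <- function(center_sep_bp, model = helix_model()) {
  stopifnot(inherits(model, "helix_model"), center_sep_bp > 0)
  contour <- center_sep_bp * model$rise
  theta <- center_sep_bp * model$bend_per_step * pi / 180
  if (theta >= 2 * pi) {
    stop("total arc angle must be below 360 degrees (theta >= 2*pi)")
  }
  if (theta == 0) contour else 2 * (contour / theta) * sin(theta / 2)
}

#' Helical-face offset between two positions
#'
#' Angular offset around the helix axis between two bp positions:
#' `phi = (sep mod bp_per_turn) / bp_per_turn * 360`, folded to
#' `[0, 180]`. Two sites are "on the same face" when the offset is at or
#' below the threshold (default 90 degrees; the criterion is qualitative).
#'
#' @param center_sep_bp separation, bp (fractional values allowed).
#' @param bp_per_turn bp per helical turn (default 10.5).
#' @param same_face_threshold degrees (default 90).
#' @return list: `offset_deg` in `[0, 180]` and `same_face` flag.
#' @export
face_offset <- function(center_sep_bp, bp_per_turn = 10.5,
                        same_face_threshold = 90) {
  stopifnot(bp_per_turn > 0)
  phi <- (center_sep_bp %% bp_per_turn) / bp_per_turn * 360
  offset <- min(phi, 360 - phi)
  list(offset_deg = offset, same_face = offset <= same_face_threshold)
}

#' Scan per-bp bend angles for compatibility with a dimer span
#'
#' Evaluates the arc chord between motif centers over a grid of per-bp
#' bend angles and reports which bends bring the chord inside the span
#' window of the protein dimer, plus the feasible bend whose chord is
#' closest to the window midpoint. Deterministic.
#'
#' @param center_sep_bp motif center separation, bp.
#' @param span_range `(min, max)` acceptable chord, nm (default
#'   `c(10, 11)`, the dimer wHTH span).
#' @param model `helix_model` providing rise (its own bend is ignored).
#' @param grid bend grid in degrees/bp (default 0 to 5 by 0.25).
#' @return list of class `bend_scan`: `table` (data.frame `bend_deg`,
#'   `chord_nm`, `feasible`), `feasible_bends`, `best_bend` (NA when the
#'   feasible set is empty) and `best_chord`.
#' @export
scan_bend_for_span <- function(center_sep_bp, span_range = c(10, 11),
                               model = helix_model(),
                               grid = seq(0, 5, by = 0.25)) {
  if (length(grid) == 0L) stop("bend grid must be non-empty")
  stopifnot(span_range[1] <= span_range[2])
  chord <- vapply(grid, function(b) {
    chord_distance(center_sep_bp,
                   helix_model(model$rise, model$bp_per_turn, b))
  }, numeric(1))
  feasible <- chord >= span_range[1] & chord <= span_range[2]
  tab <- data.frame(bend_deg = grid, chord_nm = chord, feasible = feasible)
  if (any(feasible)) {
    mid <- mean(span_range)
    k <- which(feasible)[which.min(abs(chord[feasible] - mid))]
    best_bend <- grid[k]
    best_chord <- chord[k]
  } else {
    best_bend <- NA_real_
    best_chord <- NA_real_
  }
  structure(list(table = tab, feasible_bends = grid[feasible],
                 best_bend = best_bend, best_chord = best_chord,
                 span_range = span_range, center_sep_bp = center_sep_bp),
            class = "bend_scan")
}

#' @export
print.bend_scan <- function(x, ...) {
  cat(sprintf("Bend scan over %d angles, centers %g bp apart:\n",
              nrow(x$table), x$center_sep_bp))
  if (length(x$feasible_bends)) {
    cat(sprintf("  feasible bends (chord in [%g, %g] nm): %s deg/bp\n",
                x$span_range[1], x$span_range[2],
                paste(x$feasible_bends, collapse = ", ")))
    cat(sprintf("  best: %g deg/bp (chord %.2f nm)\n", x$best_bend,
                x$best_chord))
  } else {
    cat("  no feasible bend in the grid\n")
  }
  invisible(x)
}

# Numerical polyline construction of the bent axis: center_sep_bp segments
# of length `rise`, each rotated by bend_per_step degrees in the plane.
# Independent cross-check for the closed-form chord; also exportable as a
# curved-axis trace.
polyline_chord <- function(center_sep_bp, model = helix_model()) {
  n <- center_sep_bp
  ang <- model$bend_per_step * pi / 180
  pos <- c(0, 0)
  for (i in seq_len(n)) {
    # heading of segment i: rotate by the per-step bend after each segment,
    # with half the bend applied at each end so the chord of the polyline
    # matches the inscribed arc chord
    heading <- (i - 0.5) * ang
    pos <- pos + model$rise * c(cos(heading), sin(heading))
  }
  sqrt(sum(pos^2))
}
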