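#' Describe an elevated maze
#'
#' Builds the geometry record used throughout the pipeline. Two maze kinds
#' are supported: the elevated linear maze (ELM), a 120 x 8 cm track with
#' reward zones at both ends and removable sidewalls, and the elevated plus
#' maze (EPM) with two closed and two open 9 x 50 cm arms.
#'
#' ELM configurations: `CC` (all sidewalls in place), `CO` (walls removed
#' from one half, creating an anxiogenic open half), `CT` (walls kept but
#' texture/visual cues changed on one half) and `CC2` (the closed-closed
#' epoch preceding CT). By convention linear position 0 cm is the left
#' (never-changing) reward end and the changing half is `[middle,
#' track_length]`.
#'
#' @param kind `"ELM"` or `"EPM"`.
#' @param configuration For ELM: one of `"CC"`, `"CO"`, `"CT"`, `"CC2"`.
#' @param track_length,track_width ELM track dimensions (cm).
#' @param reward_zone_length Length of each end reward zone (cm).
#' @param centre_zone_width Total width of the centre band (cm); the band
#'   spans `middle +/- centre_zone_width/2`. Set
#'   `centre_zone_is_halfwidth = TRUE` to interpret the value as the
#'   half-width instead.
#' @param centre_zone_is_halfwidth Interpretation toggle for
#'   `centre_zone_width` (default `FALSE`: total width).
#' @param epm_arm_length,epm_arm_width EPM arm dimensions (cm).
#' @return A list of class `maze_spec`.
#' @examples
#' maze_spec("ELM", "CO")
#' @export
maze_spec <- function(kind = c("ELM", "EPM"),
                      configuration = c("CC", "CO", "CT", "CC2"),
                      track_length = 120, track_width = 8,
                      reward_zone_length = 10,
                      centre_zone_width = 11.5,
                      centre_zone_is_halfwidth = FALSE,
                      epm_arm_length = 50, epm_arm_width = 9) {
  kind <- match.arg(kind)
  configuration <- if (kind == "ELM") match.arg(configuration) else NA_character_
  middle <- track_length / 2
  if (kind == "ELM") {
    if (reward_zone_length <= 0 || reward_zone_length >= middle)
      abort("`reward_zone_length` must lie in (0, track_length/2).",
            class = "elmaze_parameter_error")
    cw <- if (centre_zone_is_halfwidth) 2 * centre_zone_width else centre_zone_width
    if (cw >= track_length)
      abort("centre zone wider than the track.", class = "elmaze_parameter_error")
  }
  structure(list(
    kind = kind, configuration = configuration,
    track_length = track_length, track_width = track_width,
    middle = middle, reward_zone_length = reward_zone_length,
    centre_zone_width = if (centre_zone_is_halfwidth) 2 * centre_zone_width else centre_zone_width,
    epm_arm_length = epm_arm_length, epm_arm_width = epm_arm_width
  ), class = "maze_spec")
}

#' @export
print.maze_spec <- function(x, ...) {
  if (x$kind == "ELM") {
    cat(sprintf("<maze_spec> ELM %s: %.0f x %.0f cm, middle %.0f cm, reward zones %.0f cm, centre band %.1f cm\n",
                x$configuration, x$track_length, x$track_width, x$middle,
                x$reward_zone_length, x$centre_zone_width))
  } else {
    cat(sprintf("<maze_spec> EPM: arms %.0f x %.0f cm\n",
                x$epm_arm_length, x$epm_arm_width))
  }
  invisible(x)
}

#' Elevated-plus-maze geometry
#'
#' Defines the centre square and the four arm rectangles with their
#' directional vectors. Arms run along the axes from the centre square:
#' closed arms on +x / -x, open arms on +y / -y. Linear coordinates on an
#' arm are obtained by projecting a position P onto the arm's directional
#' vector D: `(P . D) / ||D||`.
#'
#' @param arm_length,arm_width Arm dimensions (cm).
#' @return A list of class `epm_geometry` with per-arm unit direction
#'   vectors and the centre half-width.
#' @export
epm_geometry <- function(arm_length = 50, arm_width = 9) {
  hw <- arm_width / 2
  arms <- list(
    closed1 = c(1, 0), closed2 = c(-1, 0),
    open1 = c(0, 1), open2 = c(0, -1)
  )
  structure(list(arms = arms, arm_length = arm_length, arm_width = arm_width,
                 centre_halfwidth = hw), class = "epm_geometry")
}

#' Project a 2D point onto an arm's directional vector
#'
#' `(P . D_arm) / ||D_arm||`: the linear coordinate of position `p` along
#' the arm, in cm.
#'
#' @param x,y Position coordinates (cm); vectors allowed.
#' @param d_arm Length-2 directional vector of the arm (any non-zero
#'   magnitude).
#' @return Numeric vector of projections.
#' @examples
#' project_onto_arm(3, 4, c(1, 0)) # 3
#' project_onto_arm(3, 4, c(3, 4)) # 5
#' @export
project_onto_arm <- function(x, y, d_arm) {
  nrm <- sqrt(sum(d_arm^2))
  if (nrm == 0) abort("arm directional vector is zero.", class = "elmaze_geometry_error")
  (x * d_arm[1] + y * d_arm[2]) / nrm
}

# Which EPM region each sample falls in: one of the arm names, "centre", or
# NA when outside the maze footprint.
epm_region <- function(x, y, geom) {
  hw <- geom$centre_halfwidth
  len <- geom$arm_length
  region <- rep(NA_character_, length(x))
  region[abs(x) <= hw & abs(y) <= hw] <- "centre"
  region[x > hw & x <= hw + len & abs(y) <= hw] <- "closed1"
  region[x < -hw & x >= -hw - len & abs(y) <= hw] <- "closed2"
  region[y > hw & y <= hw + len & abs(x) <= hw] <- "open1"
  region[y < -hw & y >= -hw - len & abs(x) <= hw] <- "open2"
  region
}

# Half-open linear bin edges over [0, L]; last bin closed at L.
linear_bin_edges <- function(track_length, bin_width) {
  n <- ceiling(track_length / bin_width - 1e-9)
  c(seq(0, by = bin_width, length.out = n), track_length)[1:(n + 1)]
}

# Assign positions to 0-based? No: 1-based bin indices, half-open [lo, hi),
# last bin closed.
bin_index <- function(pos, edges) {
  idx <- findInterval(pos, edges, rightmost.closed = TRUE, all.inside = TRUE)
  idx
}

# ELM zone label per linear position: non-changing arm [0, middle - cw/2),
# centre band, changing arm.
elm_zone <- function(pos, maze) {
  half <- maze$centre_zone_width / 2
  lo <- maze$middle - half
  hi <- maze$middle + half
  ifelse(pos < lo, "non_changing_arm", ifelse(pos <= hi, "centre", "changing_arm"))
}
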