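#' Parametric 82-point hip contour template
#'
#' Builds the default parametric template standing in for an annotated
#' anteroposterior hip contour: 30 points on a circular femoral-head arc,
#' 7 points on a blending arc at the head-neck junction, 15 lateral-neck /
#' greater-trochanter points and 8 medial-neck points on cubic Bezier
#' segments, and 22 acetabular-rim points on an arc concentric with the
#' head. Coordinates are millimetres in a y-up frame; the centroid of the
#' 82 points is translated to the origin.
#'
#' The male template uses a femoral-head radius of 25 mm, the female
#' template 22 mm; the acetabular-rim radius is 28 mm for both. Neck
#' segment control points are fixed offsets from the head-edge anchor
#' points so both sexes produce smooth, connected polylines.
#'
#' @param sex `"male"` or `"female"`.
#' @return An object of class `hip_template`: a list with `points`
#'   (82 x 2 numeric matrix, columns `x`, `y`), `segment_labels`
#'   (length-82 character vector), `sex`, and `head_radius` (mm).
#' @examples
#' tpl <- make_template("male")
#' nrow(tpl$points)         # 82
#' colMeans(tpl$points)     # ~ (0, 0)
#' @export
make_template <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  r <- if (sex == "male") 25 else 22

  deg <- pi / 180

  ## femoral head: 30 points, angles 200 deg -> -20 deg about the head centre
  th_head <- seq(200, -20, length.out = 30) * deg
  head_pts <- cbind(r * cos(th_head), r * sin(th_head))

  ## head-neck junction: 7 points on a concave blending arc of radius 9 mm
  ## centred radially outward from the lateral head edge (creates the
  ## head-neck "waist" whose filling-in constitutes cam morphology)
  p_lat <- c(r * cos(-20 * deg), r * sin(-20 * deg))
  rj <- 9
  cj <- p_lat + rj * c(cos(-20 * deg), sin(-20 * deg))
  th_j <- seq(150, 95, length.out = 7) * deg
  junction_pts <- cbind(cj[1] + rj * cos(th_j), cj[2] + rj * sin(th_j))

  ## lateral neck + greater trochanter: cubic Bezier from the junction end,
  ## bulging superolaterally (trochanter) then descending along the shaft
  a <- junction_pts[7, ]
  lateral_pts <- bezier_points(
    p0 = a,
    p1 = a + c(6, 11),
    p2 = c(a[1] + 12, 3),
    p3 = c(a[1] + 13, -24),
    n = 15
  )

  ## medial neck: cubic Bezier from the medial head edge down toward the
  ## lesser trochanter / medial shaft
  p_med <- c(r * cos(200 * deg), r * sin(200 * deg))
  medial_pts <- bezier_points(
    p0 = p_med,
    p1 = p_med + c(2, -11),
    p2 = c(p_med[1] + 7, p_med[2] - 22),
    p3 = c(p_med[1] + 9, p_med[2] - 33),
    n = 8
  )

  ## acetabular rim: 22 points, radius 28 mm concentric with the head,
  ## angles 30 deg -> 150 deg (superior coverage)
  th_rim <- seq(30, 150, length.out = 22) * deg
  rim_pts <- cbind(28 * cos(th_rim), 28 * sin(th_rim))

  pts <- rbind(head_pts, junction_pts, lateral_pts, medial_pts, rim_pts)
  labels <- c(
    rep("head_arc", 30),
    rep("headneck_junction", 7),
    rep("lateral_neck", 15),
    rep("medial_neck", 8),
    rep("acetabular_rim", 22)
  )

  pts <- sweep(pts, 2, colMeans(pts))
  colnames(pts) <- c("x", "y")

  structure(
    list(points = pts, segment_labels = labels, sex = sex, head_radius = r),
    class = "hip_template"
  )
}

## n points along a cubic Bezier, including both endpoints
bezier_points <- function(p0, p1, p2, p3, n) {
  t <- seq(0, 1, length.out = n)
  b <- outer((1 - t)^3, p0) + outer(3 * (1 - t)^2 * t, p1) +
    outer(3 * (1 - t) * t^2, p2) + outer(t^3, p3)
  b
}

#' Flatten / unflatten landmark configurations
#'
#' Shapes are stored internally as length-164 vectors in stacked order
#' `(x1..x82, y1..y82)`.
#'
#' @param points An n_points x 2 matrix.
#' @return `flatten_points()`: a numeric vector of length `2 * n_points`;
#'   `unflatten_points()`: an `n_points x 2` matrix.
#' @keywords internal
#' @export
flatten_points <- function(points) {
  c(points[, 1], points[, 2])
}

#' @rdname flatten_points
#' @param v A flattened coordinate vector of even length.
#' @export
unflatten_points <- function(v) {
  k <- length(v) / 2L
  m <- cbind(x = v[seq_len(k)], y = v[k + seq_len(k)])
  m
}
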