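# Simulator layout and fistula-axis calibration.
#
# The simulator bed holds four fistulas arranged radially, each with a
# vibration motor at its anastomosis point. Location metrics are planar:
# calibration traces are z-projected to the bed plane (x, y in mm, origin
# at the bed centre) before fitting. Motor locations come from the layout,
# not from the axis fit; the fitted axis direction is exposed for
# completeness (e.g. future fistula-orientation metrics) but no metric
# consumes it.

#' Fit a fistula central axis by orthogonal least squares
#'
#' Total-least-squares line through a planar point cloud: the line through
#' the centroid along the principal eigenvector of the covariance matrix,
#' which minimises the summed squared perpendicular distances. The
#' direction sign is chosen so the coordinate with the larger spread is
#' positive.
#'
#' @param points Two-column matrix (or data.frame) of x, y in mm.
#' @return List with `anchor` (centroid, mm), `direction` (unit vector),
#'   and `rms` (root-mean-square perpendicular residual, mm).
#' @export
fit_fistula_axis <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2L) stop_palp("degenerate_input", "points must have x and y")
  pts <- pts[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(unique(pts)) < 2L)
    stop_palp("degenerate_input", "need at least 2 distinct points")
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  cv <- crossprod(d) / nrow(d)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (sqrt(lam[1]) < 1.05 * sqrt(lam[2]))
    stop_palp("isotropic_cloud",
              "no dominant direction (principal-axis ratio %.3f < 1.05)",
              sqrt(lam[1] / max(lam[2], .Machine$double.eps)))
  dir <- eg$vectors[, 1L]
  dir <- dir / sqrt(sum(dir^2))
  # sign: the coordinate with larger spread points positive
  spread <- apply(pts, 2, function(x) diff(range(x)))
  lead <- if (spread[1] >= spread[2]) 1L else 2L
  if (dir[lead] < 0) dir <- -dir
  perp <- d[, 1] * (-dir[2]) + d[, 2] * dir[1]
  list(anchor = unname(ctr), direction = unname(dir),
       rms = sqrt(mean(perp^2)))
}

#' Construct a simulator layout
#'
#' @param fistulas List of four entries (one per fistula id 1..4), each a
#'   list with `anchor` (mm), `direction` (unit vector) and `motor`
#'   (c(x, y) mm, the anastomosis / vibration-motor location).
#' @param bed_radius Bed radius in mm.
#' @return Object of class `simulator_layout`.
#' @export
simulator_layout <- function(fistulas, bed_radius = 150) {
  if (length(fistulas) != 4L)
    stop_palp("schema", "layout must describe exactly 4 fistulas")
  for (i in seq_along(fistulas)) {
    f <- fistulas[[i]]
    if (is.null(f$motor) || length(f$motor) != 2L || anyNA(f$motor) ||
        any(!is.finite(f$motor)))
      stop_palp("schema", "fistula %d: motor location must be finite c(x, y)", i)
    if (!is.null(f$direction)) {
      if (abs(sqrt(sum(f$direction^2)) - 1) > 1e-9)
        stop_palp("schema", "fistula %d: direction must be unit-norm", i)
    }
  }
  structure(list(fistulas = fistulas, bed_radius = bed_radius,
                 schema_version = 1L),
            class = "simulator_layout")
}

#' Default simulator layout
#'
#' Four fistulas placed radially at 45, 135, 225 and 315 degrees, motors
#' (anastomosis points) 60 mm from the bed centre, axes pointing radially
#' outward, bed radius 150 mm.
#'
#' @return A [simulator_layout()].
#' @export
default_layout <- function() {
  ang <- c(45, 135, 225, 315) * pi / 180
  fistulas <- lapply(ang, function(a) {
    u <- c(cos(a), sin(a))
    list(anchor = 60 * u, direction = u, motor = 60 * u)
  })
  simulator_layout(fistulas, bed_radius = 150)
}

#' Motor (anastomosis) location of one fistula
#'
#' @param layout A [simulator_layout()].
#' @param fistula_id Integer 1..4.
#' @return Numeric `c(x, y)` in mm.
#' @export
motor_location <- function(layout, fistula_id) {
  if (!fistula_id %in% 1:4) stop_palp("schema", "fistula_id must be 1..4")
  as.numeric(layout$fistulas[[fistula_id]]$motor)
}

#' Write / read a simulator layout as JSON
#'
#' @param layout A [simulator_layout()].
#' @param path File path for `layout.json`.
#' @return `path` / the layout, invisibly / visibly.
#' @export
write_layout <- function(layout, path) {
  write_json_file(list(
    schema_version = layout$schema_version,
    bed_radius = layout$bed_radius,
    fistulas = lapply(layout$fistulas, function(f)
      list(anchor = f$anchor, direction = f$direction, motor = f$motor))
  ), path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  fist <- lapply(j$fistulas, function(f)
    list(anchor = as.numeric(f$anchor),
         direction = as.numeric(f$direction),
         motor = as.numeric(f$motor)))
  simulator_layout(fist, bed_radius = j$bed_radius)
}
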