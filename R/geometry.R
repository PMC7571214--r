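# Unit conventions, asserted here once and relied on everywhere else:
#   * pixel coordinates x, y and the focal length f are in pixels; x is a
#     continuous offset from the principal point growing to the right
#     (columns), y grows downward (rows);
#   * light positions (xi, eta, zeta), surface depths z and gradients are in
#     mm; visible scene points have z < 0;
#   * the perspective map is M(x, y) = (-x z / f, -y z / f, z) in the camera
#     frame, which makes the mixed forms xi*f/z + x (pixels) and
#     xi + x*z/f (mm) dimensionally consistent.
# Under the z < 0 convention the illumination vector l and the surface normal
# n both come out flipped relative to their physical directions; all dot
# products used as shading terms are therefore positive for illuminated
# geometry and are clamped where noise could push them outside [0, 1].

#' Pinhole camera model
#'
#' Intrinsics of the endoscopic camera.  Pixel centres sit at integer
#' (column, row) positions starting at 1; the continuous image coordinates
#' used throughout the package are `x = col - cx`, `y = row - cy`.
#'
#' @param f Focal length in pixels (> 0).
#' @param width,height Image size in pixels.
#' @param cx,cy Principal point in pixel units; the default `(width/2,
#'   height/2)` puts the optical axis on a pixel centre for even image
#'   sizes, so a symmetric rig has its mirror points on pixel centres.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(f = 565, width = 640, height = 480)
#' @export
camera_model <- function(f, width, height,
                         cx = width / 2, cy = height / 2) {
  stopifnot(is.numeric(f), f > 0, width >= 1, height >= 1)
  structure(
    list(f = f, cx = cx, cy = cy,
         width = as.integer(width), height = as.integer(height)),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> f = %g px, %d x %d, principal point (%g, %g)\n",
              x$f, x$width, x$height, x$cx, x$cy))
  invisible(x)
}

#' Convert between pixel indices and image coordinates
#'
#' @param cam A [camera_model()].
#' @param col,row 1-based pixel column/row indices (may be fractional).
#' @param x,y Continuous image coordinates (pixels from the principal point).
#' @return A list with components `x`, `y` (or `col`, `row`).
#' @export
pixel_to_xy <- function(cam, col, row) {
  list(x = col - cam$cx, y = row - cam$cy)
}

#' @rdname pixel_to_xy
#' @export
xy_to_pixel <- function(cam, x, y) {
  list(col = x + cam$cx, row = y + cam$cy)
}

#' Full-frame image coordinate grids
#'
#' @param cam A [camera_model()].
#' @return List of two `height x width` matrices `x` and `y`.
#' @export
pixel_grid <- function(cam) {
  h <- cam$height; w <- cam$width
  list(
    x = matrix(rep(seq_len(w) - cam$cx, each = h), h, w),
    y = matrix(rep(seq_len(h) - cam$cy, times = w), h, w)
  )
}

#' Near-point light source
#'
#' A surface-mounted LED at a finite distance: illumination direction and
#' attenuation vary per surface point.  The principal direction is the axis of
#' maximal emission; radial attenuation follows the cosine of the angle from
#' it.  `intensity` is a dimensionless relative radiant scale (the default rig
#' assumes equal illuminance across the four LEDs).
#'
#' @param position Numeric length 3, mm in the camera frame.
#' @param principal_direction Numeric length 3; normalised internally.
#'   Default `(0, 0, -1)`, pointing into the scene.
#' @param intensity Relative radiant scale, > 0.
#' @return An object of class `light_source`.
#' @export
light_source <- function(position, principal_direction = c(0, 0, -1),
                         intensity = 1) {
  stopifnot(length(position) == 3, length(principal_direction) == 3,
            intensity > 0)
  nrm <- sqrt(sum(principal_direction^2))
  if (nrm == 0) stop("principal_direction must be a nonzero vector")
  structure(
    list(position = as.numeric(position),
         principal_direction = as.numeric(principal_direction) / nrm,
         intensity = as.numeric(intensity)),
    class = "light_source"
  )
}

#' Photometric-stereo rig: one camera plus its light sources
#'
#' @param camera A [camera_model()].
#' @param lights A list of [light_source()] objects (four for the standard
#'   capsule rig).
#' @return An object of class `ps_rig`.
#' @export
ps_rig <- function(camera, lights) {
  stopifnot(inherits(camera, "camera_model"),
            all(vapply(lights, inherits, logical(1), "light_source")))
  structure(list(camera = camera, lights = lights), class = "ps_rig")
}

#' The default capsule-endoscope rig
#'
#' A 640 x 480 pinhole camera with f = 565 px and four LEDs in the camera
#' plane at 5.5 mm centrifugal distance (+x, -x, +y, -y), principal
#' directions along -z, equal intensity -- the simulated configuration of the
#' capsule robot.
#'
#' @param f Focal length in pixels.
#' @param width,height Image size.
#' @param light_distance LED centrifugal distance in mm.
#' @return A [ps_rig()].
#' @export
default_rig <- function(f = 565, width = 640, height = 480,
                        light_distance = 5.5) {
  cam <- camera_model(f, width, height)
  d <- light_distance
  lights <- list(
    light_source(c( d, 0, 0)),
    light_source(c(-d, 0, 0)),
    light_source(c(0,  d, 0)),
    light_source(c(0, -d, 0))
  )
  ps_rig(cam, lights)
}

#' Illumination direction terms for a near-point source
#'
#' For pixels (x, y) at depth z and source S = (xi, eta, zeta), returns the
#' unnormalised illumination vector
#' `lbar = (xi f/z + x, eta f/z + y, zeta f/z - f)`, its modulus `q`, and the
#' unit vector `l = lbar / q`.  `lbar` is `(f/z) (S - M)`, i.e. antiparallel
#' to the surface-to-source vector for visible points (z < 0).
#'
#' @param x,y Image coordinates (pixels from the principal point); arrays.
#' @param z Depth in mm (z < 0 in front of the camera); recycled with x, y.
#' @param light A [light_source()].
#' @param cam A [camera_model()].
#' @return List with `lbar_x`, `lbar_y`, `lbar_z`, `q`, `l_x`, `l_y`, `l_z`,
#'   all shaped like the broadcast of the inputs.
#' @export
light_direction <- function(x, y, z, light, cam) {
  if (any(z == 0, na.rm = TRUE)) stop("degenerate geometry: z = 0")
  f <- cam$f
  p <- light$position
  lx <- p[1] * f / z + x
  ly <- p[2] * f / z + y
  lz <- p[3] * f / z - f
  q <- sqrt(lx^2 + ly^2 + lz^2)
  if (any(q == 0, na.rm = TRUE)) {
    stop("degenerate geometry: light source coincides with surface point")
  }
  list(lbar_x = lx, lbar_y = ly, lbar_z = lz, q = q,
       l_x = lx / q, l_y = ly / q, l_z = lz / q)
}

#' Illuminance attenuation factors
#'
#' Distance attenuation `a_d = f^2 / (z^2 q^2)` (inverse square of the
#' source-to-point distance), radial attenuation `a_r = |cos theta|` between
#' the illumination vector and the source's principal direction (clamped to
#' \[0, 1\]), and their product `a`.  For a source in the camera plane
#' (zeta = 0) with principal direction (0, 0, -1) the product reduces to
#' `f^3 / (z^2 q^3)`.
#'
#' @inheritParams light_direction
#' @return List with components `a_d` (mm^-2), `a_r` (dimensionless), `a`.
#' @export
attenuation <- function(x, y, z, light, cam) {
  ld <- light_direction(x, y, z, light, cam)
  f <- cam$f
  a_d <- f^2 / (z^2 * ld$q^2)
  pd <- light$principal_direction
  a_r <- pmin(1, abs(ld$l_x * pd[1] + ld$l_y * pd[2] + ld$l_z * pd[3]))
  list(a_d = a_d, a_r = a_r, a = a_d * a_r)
}

#' Surface normal from the depth gradient
#'
#' The unnormalised outgoing normal of the graph M(x, y) under perspective,
#' `nbar = (z/f)^2 (f zx, f zy, z + x zx + y zy)`, and its unit version.
#' Under the z < 0 convention `nbar` is flipped relative to the physical
#' outward normal (a fronto-parallel plane has n = (0, 0, -1)), matching the
#' flipped illumination vectors so that shading dot products are positive.
#'
#' @inheritParams light_direction
#' @param zx,zy Depth gradient in mm per pixel.
#' @return List with `nbar_x`, `nbar_y`, `nbar_z`, `norm`, `n_x`, `n_y`,
#'   `n_z`.
#' @export
surface_normal <- function(x, y, z, zx, zy, cam) {
  f <- cam$f
  s <- (z / f)^2
  nx <- s * f * zx
  ny <- s * f * zy
  nz <- s * (z + x * zx + y * zy)
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  if (any(nrm == 0, na.rm = TRUE)) stop("degenerate normal: |nbar| = 0")
  list(nbar_x = nx, nbar_y = ny, nbar_z = nz, norm = nrm,
       n_x = nx / nrm, n_y = ny / nrm, n_z = nz / nrm)
}

#' Read or write a rig configuration (JSON)
#'
#' The file holds the camera intrinsics and the list of light sources
#' (position in mm, principal direction, relative intensity).
#'
#' @param path File path.
#' @param rig A [ps_rig()].
#' @return `read_rig()` returns a [ps_rig()]; `write_rig()` returns `path`
#'   invisibly.
#' @export
write_rig <- function(rig, path) {
  cam <- rig$camera
  obj <- list(
    camera = list(f = cam$f, cx = cam$cx, cy = cam$cy,
                  width = cam$width, height = cam$height),
    lights = lapply(rig$lights, function(s) {
      list(position_mm = s$position,
           principal_direction = s$principal_direction,
           intensity = s$intensity)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rig
#' @export
read_rig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cam <- camera_model(obj$camera$f, obj$camera$width, obj$camera$height,
                      obj$camera$cx, obj$camera$cy)
  lights <- purrr::pmap(obj$lights, function(position_mm,
                                             principal_direction, intensity) {
    light_source(unlist(position_mm), unlist(principal_direction), intensity)
  })
  ps_rig(cam, lights)
}
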