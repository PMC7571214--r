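# Synthetic endoscopic scenes: analytic polyp-like surfaces rendered under
# the rig's four near-point lights with Blinn-Phong reflectance, dark
# environment, no shadows or interreflection.  The renderer and the
# reconstruction share the same light/normal model, so on noiseless
# Lambertian renders the photometric irradiance equations hold to machine
# precision -- the renderer doubles as the package's oracle for them.

#' Analytic surface specification
#'
#' The simulated object is a plane at `base_depth` optionally carrying a
#' spherical cap of height `cap_height` cut from a sphere of radius
#' `cap_radius` -- a sessile-polyp-like bump whose apex sits `cap_height` mm
#' closer to the camera.  The default radius (10.17 mm, with height 4 mm) is
#' calibrated so that the ideal mirror point of a light at 5.5 mm lies at
#' -17.4188 mm, the printed ground-truth centroid depth of the reference
#' simulation; `cap_radius = cap_height` gives a hemisphere.  Reflectance is
#' Blinn-Phong: per-channel albedo `albedo`, diffuse and specular weights
#' `k_d`, `k_s` and shininess `shininess`.  The specular lobe carries the
#' illuminant colour (dichromatic convention), which is what makes
#' highlights low-saturation on a saturated mucosa.
#'
#' @param kind `"sphere_cap_on_plane"`, `"plane"` or `"hemisphere"` (cap
#'   without the plane; rays that miss are invalid).
#' @param base_depth Plane depth in mm, negative. Default -21.37, the
#'   camera-to-surface distance of the simulated capsule rig.
#' @param cap_radius Radius of the sphere the cap is cut from, mm.
#' @param cap_height Height of the cap above the plane, mm (<= cap_radius);
#'   the apex depth is `base_depth + cap_height` (-17.37 mm by default).
#' @param cap_center_px Pixel (x, y) offset of the cap apex from the
#'   principal point.
#' @param albedo Per-channel reflectance in \[0, 1\]; length 1 renders
#'   grayscale.  Default a mucosa pink.
#' @param k_d,k_s Diffuse/specular weights in \[0, 1\].
#' @param shininess Blinn-Phong exponent; larger = tighter highlight.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(kind = c("sphere_cap_on_plane", "plane", "hemisphere"),
                         base_depth = -21.37, cap_radius = 10.17,
                         cap_height = min(4, cap_radius),
                         cap_center_px = c(0, 0),
                         albedo = c(0.80, 0.52, 0.48),
                         k_d = 0.8, k_s = 0.4, shininess = 300) {
  kind <- match.arg(kind)
  if (kind == "hemisphere") cap_height <- cap_radius
  stopifnot(base_depth < 0, cap_radius > 0, cap_height > 0,
            cap_height <= cap_radius,
            all(albedo >= 0 & albedo <= 1),
            k_d >= 0, k_d <= 1, k_s >= 0, k_s <= 1, shininess > 0)
  structure(
    list(kind = kind, base_depth = base_depth, cap_radius = cap_radius,
         cap_height = cap_height, cap_center_px = cap_center_px,
         albedo = albedo, k_d = k_d, k_s = k_s, shininess = shininess),
    class = "surface_spec"
  )
}

#' @rdname surface_spec
#' @param ... Overrides passed to [surface_spec()].
#' @export
polyp_scene <- function(...) surface_spec("sphere_cap_on_plane", ...)

#' @rdname surface_spec
#' @export
plane_scene <- function(...) surface_spec("plane", ...)

# Sphere centre in camera-frame mm for the cap kinds.
sphere_center <- function(spec, cam) {
  za <- spec$base_depth + spec$cap_height  # apex depth
  c(-spec$cap_center_px[1] * za / cam$f,
    -spec$cap_center_px[2] * za / cam$f,
    za - spec$cap_radius)
}

#' Depth-map container
#'
#' @param z `height x width` matrix of depths in mm (negative in front of
#'   the camera; `NA` where invalid).
#' @param mask Logical validity matrix (defaults to finite z).
#' @param cam The [camera_model()] the map is sampled on.
#' @param delta Grid step in pixels (1 for native resolution).
#' @param seed Optional list `(col, row, depth)` recording the boundary
#'   condition a reconstruction started from.
#' @return An object of class `depth_map`.
#' @export
depth_map <- function(z, mask = is.finite(z), cam = NULL, delta = 1,
                      seed = NULL) {
  stopifnot(is.matrix(z), identical(dim(z), dim(mask)))
  structure(list(z = z, mask = mask, cam = cam, delta = delta, seed = seed),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  rng <- range(x$z[x$mask])
  cat(sprintf("<depth_map> %d x %d px, %d valid, z in [%.4f, %.4f] mm\n",
              ncol(x$z), nrow(x$z), sum(x$mask), rng[1], rng[2]))
  invisible(x)
}

#' Analytic ground-truth depth of a scene
#'
#' Per-pixel depth by exact ray-surface intersection (nearest hit along the
#' pixel ray).  Plane pixels are exactly at `base_depth`; cap pixels take the
#' near root of the ray-sphere quadratic.
#'
#' @param spec A [surface_spec()].
#' @param cam A [camera_model()].
#' @return A [depth_map()]; pixels whose ray misses the surface (possible
#'   only for `kind = "hemisphere"`) are invalid.
#' @export
analytic_depth <- function(spec, cam) {
  g <- pixel_grid(cam)
  if (spec$kind == "plane") {
    z <- matrix(spec$base_depth, cam$height, cam$width)
    return(depth_map(z, cam = cam))
  }
  ctr <- sphere_center(spec, cam)
  u <- -g$x / cam$f
  v <- -g$y / cam$f
  # |(u z, v z, z) - ctr|^2 = R^2, quadratic in z
  A <- u^2 + v^2 + 1
  B <- -2 * (u * ctr[1] + v * ctr[2] + ctr[3])
  C <- sum(ctr^2) - spec$cap_radius^2
  disc <- B^2 - 4 * A * C
  hit <- disc >= 0
  z_sph <- matrix(NA_real_, cam$height, cam$width)
  z_sph[hit] <- (-B[hit] + sqrt(disc[hit])) / (2 * A[hit])  # near root
  if (spec$kind == "hemisphere") {
    ok <- hit & z_sph >= spec$base_depth
    z <- ifelse(ok, z_sph, NA_real_)
    return(depth_map(z, mask = !is.na(z), cam = cam))
  }
  on_cap <- hit & !is.na(z_sph) & z_sph > spec$base_depth
  z <- ifelse(on_cap, z_sph, spec$base_depth)
  depth_map(z, cam = cam)
}

#' Analytic depth gradient of a scene
#'
#' Exact gradient (mm per pixel) of the analytic depth field, by implicit
#' differentiation of the ray-sphere equation on cap pixels and zero on the
#' plane.
#'
#' @inheritParams analytic_depth
#' @param x,y,z Optional image coordinates and depths to evaluate at
#'   (defaults: full frame and the analytic depth).
#' @return List of matrices `zx`, `zy`.
#' @export
analytic_gradient <- function(spec, cam, x = NULL, y = NULL, z = NULL) {
  if (is.null(x)) {
    g <- pixel_grid(cam)
    x <- g$x; y <- g$y
  }
  if (is.null(z)) z <- analytic_depth(spec, cam)$z
  zx <- z * 0
  zy <- z * 0
  if (spec$kind != "plane") {
    ctr <- sphere_center(spec, cam)
    on_cap <- is.finite(z) & (z > spec$base_depth + 1e-12 |
                                spec$kind == "hemisphere")
    u <- -x / cam$f
    v <- -y / cam$f
    P <- u * z - ctr[1]
    Q <- v * z - ctr[2]
    W <- z - ctr[3]
    den <- P * u + Q * v + W
    zx[on_cap] <- (P * z / cam$f / den)[on_cap]
    zy[on_cap] <- (Q * z / cam$f / den)[on_cap]
  }
  list(zx = zx, zy = zy)
}

#' Render a scene under the rig's lights
#'
#' One image per active light: per pixel,
#' `I_c = Phi * a * (k_d * rho_c * max(0, l.n) + k_s * max(0, h.n)^alpha)`
#' where `a` is the combined near-point attenuation, `l` the illumination
#' direction, `h` the half vector of `l` and the view direction, and `n` the
#' surface normal -- all in the package's flipped z < 0 frame.  Dark
#' environment: no shadows, no interreflection, no ambient term.  Rendering
#' is in linear radiometry (float); quantisation happens only on explicit
#' export ([save_render()]).
#'
#' @param spec A [surface_spec()].
#' @param rig A [ps_rig()].
#' @param noise_sd Additive zero-mean Gaussian noise, in linear units as a
#'   fraction of the noiseless maximum over the stack.  Default 0.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param active Indices of the lights to render (one image each).
#' @return An object of class `ps_render`: `images` (list of
#'   `height x width x channels` arrays), `illuminance` (list of luminance
#'   matrices, channel mean), `ground_truth` ([depth_map()]), plus the scene
#'   and rig.
#' @export
render_scene <- function(spec, rig, noise_sd = 0, seed = NULL,
                         active = seq_along(rig$lights)) {
  cam <- rig$camera
  g <- pixel_grid(cam)
  gt <- analytic_depth(spec, cam)
  z <- gt$z
  valid <- gt$mask
  zs <- ifelse(valid, z, -1)  # placeholder depth for invalid rays
  grad <- analytic_gradient(spec, cam, g$x, g$y, zs)
  nrm <- surface_normal(g$x, g$y, zs, grad$zx, grad$zy, cam)
  # flipped unit view direction (x, y, -f)/b
  b <- sqrt(g$x^2 + g$y^2 + cam$f^2)
  vx <- g$x / b; vy <- g$y / b; vz <- -cam$f / b
  nch <- length(spec$albedo)
  images <- vector("list", length(active))
  for (k in seq_along(active)) {
    li <- rig$lights[[active[k]]]
    ld <- light_direction(g$x, g$y, zs, li, cam)
    at <- attenuation(g$x, g$y, zs, li, cam)
    diff_cos <- pmax(0, ld$l_x * nrm$n_x + ld$l_y * nrm$n_y + ld$l_z * nrm$n_z)
    hx <- ld$l_x + vx; hy <- ld$l_y + vy; hz <- ld$l_z + vz
    hn <- sqrt(hx^2 + hy^2 + hz^2)
    hn[hn == 0] <- 1
    spec_cos <- pmax(0, (hx * nrm$n_x + hy * nrm$n_y + hz * nrm$n_z) / hn)
    spec_term <- spec$k_s * spec_cos^spec$shininess
    img <- array(0, c(cam$height, cam$width, nch))
    base <- li$intensity * at$a
    for (ch in seq_len(nch)) {
      plane <- base * (spec$k_d * spec$albedo[ch] * diff_cos + spec_term)
      plane[!valid] <- 0
      img[, , ch] <- plane
    }
    images[[k]] <- img
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    peak <- max(vapply(images, max, numeric(1)))
    images <- lapply(images, function(im) {
      im + stats::rnorm(length(im), sd = noise_sd * peak)
    })
  }
  structure(
    list(images = images, illuminance = lapply(images, luminance),
         ground_truth = gt, rig = rig, spec = spec,
         active = active, noise_sd = noise_sd),
    class = "ps_render"
  )
}

#' @export
print.ps_render <- function(x, ...) {
  cat(sprintf("<ps_render> %d image(s), %d x %d, lights {%s}, noise_sd = %g\n",
              length(x$images), ncol(x$illuminance[[1]]),
              nrow(x$illuminance[[1]]),
              paste(x$active, collapse = ","), x$noise_sd))
  invisible(x)
}

#' Channel-mean luminance of an image array
#'
#' @param img `h x w` matrix or `h x w x c` array.
#' @return `h x w` matrix.
#' @export
luminance <- function(img) {
  if (length(dim(img)) == 3) {
    out <- img[, , 1]
    nch <- dim(img)[3]
    if (nch > 1) for (ch in 2:nch) out <- out + img[, , ch]
    out / nch
  } else {
    img
  }
}

#' Ideal specular (mirror) point of a scene for one light
#'
#' Independent geometric oracle: the surface point where the incident angle
#' exactly equals the reflected angle for the given source and the camera at
#' the origin.  For a fronto-parallel plane the solution is closed form (the
#' half-offset point between the source and the camera's mirror image); for
#' the spherical cap it is found by numerically minimising the tangential
#' residual of the mirror condition over the sphere, using only vector
#' geometry -- none of the reconstruction formulas.
#'
#' @param spec A [surface_spec()].
#' @param light A [light_source()].
#' @param cam A [camera_model()].
#' @return List with `col`, `row` (continuous pixel position), `x`, `y`, `z`,
#'   `M` (camera-frame mm), `residual` and `found`.  `found = FALSE` when the
#'   mirror point is outside the field of view or off the cap.
#' @export
mirror_point <- function(spec, light, cam) {
  S <- light$position
  mk <- function(M, residual) {
    x <- -M[1] * cam$f / M[3]
    y <- -M[2] * cam$f / M[3]
    px <- xy_to_pixel(cam, x, y)
    found <- residual < 1e-8 &&
      px$col >= 1 && px$col <= cam$width &&
      px$row >= 1 && px$row <= cam$height
    list(col = px$col, row = px$row, x = x, y = y, z = M[3], M = M,
         residual = residual, found = found)
  }
  if (spec$kind == "plane") {
    M <- c(S[1] / 2, S[2] / 2, spec$base_depth)
    # exact when the source lies in the camera plane (zeta = 0)
    if (S[3] != 0) {
      M <- c(S[1:2] * spec$base_depth / (2 * spec$base_depth - S[3]),
             spec$base_depth)
    }
    return(mk(M, 0))
  }
  ctr <- sphere_center(spec, cam)
  R <- spec$cap_radius
  obj <- function(par) {
    th <- par[1]; ph <- par[2]
    n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    M <- ctr + R * n
    u <- -M / sqrt(sum(M^2)) + (S - M) / sqrt(sum((S - M)^2))
    e <- u - sum(u * n) * n
    sum(e^2)
  }
  init <- c(0.3, atan2(S[2], S[1]))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 2000))
  # Nelder-Mead stalls near machine precision; restarting rebuilds the
  # simplex and typically gains several orders of magnitude
  for (k in 1:3) {
    if (fit$value < 1e-24) break
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 2000))
  }
  th <- fit$par[1]; ph <- fit$par[2]
  n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  M <- ctr + R * n
  out <- mk(M, sqrt(fit$value))
  if (spec$kind == "sphere_cap_on_plane" && M[3] <= spec$base_depth) {
    out$found <- FALSE
  }
  out
}
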