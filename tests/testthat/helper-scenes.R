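# Shared fixtures, all generated in code.  Expensive renders are cached per
# session; every scene derives from the stated rig (f = 565 px equivalent
# field of view, lights at 5.5 mm, surface at -21.37 mm with a 4 mm cap).

.scene_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .scene_cache)) {
    assign(name, force(expr), envir = .scene_cache)
  }
  get(name, envir = .scene_cache)
}

# 32 x 32 close-up of the cap apex: gentle slopes, used for solver oracles
mini_rig <- function() default_rig(f = 150, width = 32, height = 32)

mini_lambert <- function() cached("mini_lambert", {
  render_scene(polyp_scene(k_s = 0), mini_rig())
})

# 160 x 120 version of the full scene (same field of view as 640 x 480)
mid_rig <- function() default_rig(f = 141, width = 160, height = 120)

mid_render <- function() cached("mid_render", {
  render_scene(polyp_scene(), mid_rig())
})

mid_lambert <- function() cached("mid_lambert", {
  render_scene(polyp_scene(k_s = 0), mid_rig())
})

mid_plane_lambert <- function() cached("mid_plane_lambert", {
  render_scene(plane_scene(albedo = 0.6, k_s = 0), mid_rig())
})

mid_pipeline <- function() cached("mid_pipeline", {
  ps_pipeline(polyp_scene(), mid_rig())
})

# the full 640 x 480 reference pipeline (acceptance tests)
full_pipeline <- function() cached("full_pipeline", {
  ps_pipeline(polyp_scene(), default_rig())
})

# analytic Lambertian irradiance at a continuous image point (the model the
# renderer implements, evaluated directly -- used to build ideal inputs)
lambert_value <- function(k, x, y, z, zx, zy, rig, rho = 0.6, k_d = 1) {
  cam <- rig$camera
  li <- rig$lights[[k]]
  at <- attenuation(x, y, z, li, cam)
  ld <- light_direction(x, y, z, li, cam)
  nn <- surface_normal(x, y, z, zx, zy, cam)
  li$intensity * at$a * k_d * rho *
    (ld$l_x * nn$n_x + ld$l_y * nn$n_y + ld$l_z * nn$n_z)
}

# a 3x3 stack whose centre pixel sits exactly at the mirror point of light
# `sigma`, with ideal Lambertian values in the other images
ideal_mirror_fixture <- function(sigma = 1, spec = polyp_scene(),
                                 base_rig = default_rig()) {
  cam0 <- base_rig$camera
  mp <- mirror_point(spec, base_rig$lights[[sigma]], cam0)
  cam <- camera_model(cam0$f, 3, 3, cx = 2 - mp$x, cy = 2 - mp$y)
  rig <- ps_rig(cam, base_rig$lights)
  gr <- analytic_gradient(spec, cam0, mp$x, mp$y, matrix(mp$z, 1, 1))
  stack <- lapply(seq_along(rig$lights), function(k) {
    v <- if (k == sigma) 1 else {
      lambert_value(k, mp$x, mp$y, mp$z, gr$zx[1], gr$zy[1], base_rig)
    }
    matrix(v, 3, 3)
  })
  mask <- matrix(FALSE, 3, 3)
  mask[2, 2] <- TRUE
  region <- list(mask = mask, source = sigma, centroid_col = 2L,
                 centroid_row = 2L)
  list(stack = stack, region = region, rig = rig, z_true = mp$z,
       zx = gr$zx[1], zy = gr$zy[1], mp = mp)
}
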