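test_that("analytic depth: plane, apex, and ray-sphere oracle", {
  cam <- camera_model(565, 640, 480)
  dm <- analytic_depth(plane_scene(), cam)
  expect_true(all(dm$z == -21.37))

  spec <- polyp_scene()
  gt <- analytic_depth(spec, cam)
  # apex on the optical axis: base_depth + cap_height
  expect_equal(gt$z[240, 320], -17.37, tolerance = 1e-10)
  # independent oracle: root of the implicit ray-sphere function along a ray
  ctr <- endodepth:::sphere_center(spec, cam)
  for (px in list(c(380, 255), c(330, 300), c(250, 200))) {
    xy <- pixel_to_xy(cam, px[1], px[2])
    gfun <- function(z) {
      (-xy$x * z / cam$f - ctr[1])^2 + (-xy$y * z / cam$f - ctr[2])^2 +
        (z - ctr[3])^2 - spec$cap_radius^2
    }
    root <- stats::uniroot(gfun, c(-21.37, -7.2), tol = 1e-12)$root
    expect_equal(gt$z[px[2], px[1]], root, tolerance = 1e-8)
  }
  # continuity across the cap seam: depth steps stay bounded by the local
  # slope (no jumps)
  dz_col <- abs(diff(gt$z[240, ]))
  expect_lt(max(dz_col), 0.12)
  expect_true(all(is.finite(gt$z)))
})

test_that("renderer matches the pure-Lambertian closed form when k_s = 0", {
  rig <- mid_rig()
  cam <- rig$camera
  ren <- mid_plane_lambert()
  g <- pixel_grid(cam)
  for (k in c(1, 3)) {
    # independent closed form: a * rho * k_d * (l.n), plane normal (0,0,-1)
    li <- rig$lights[[k]]
    at <- attenuation(g$x, g$y, -21.37, li, cam)
    ld <- light_direction(g$x, g$y, -21.37, li, cam)
    expected <- at$a * 0.6 * 0.8 * (-ld$l_z)
    expect_equal(ren$illuminance[[k]], expected, tolerance = 1e-12)
  }
})

test_that("rendered irradiance satisfies the Lambertian model identity", {
  # I * q^4 * z^2 * |nbar| / (f^3 * (lbar . nbar)) is the constant albedo
  # factor at every pixel of a noiseless k_s = 0 render
  ren <- mid_lambert()
  rig <- mid_rig()
  cam <- rig$camera
  g <- pixel_grid(cam)
  gt <- ren$ground_truth
  gr <- analytic_gradient(ren$spec, cam)
  nn <- surface_normal(g$x, g$y, gt$z, gr$zx, gr$zy, cam)
  k <- 2
  ld <- light_direction(g$x, g$y, gt$z, rig$lights[[k]], cam)
  ln <- ld$lbar_x * nn$nbar_x + ld$lbar_y * nn$nbar_y + ld$lbar_z * nn$nbar_z
  ratio <- ren$illuminance[[k]] * ld$q^4 * gt$z^2 * nn$norm / (cam$f^3 * ln)
  rho_eff <- mean(ren$spec$albedo) * ren$spec$k_d
  expect_equal(max(abs(ratio - rho_eff)), 0, tolerance = 1e-10)
})

test_that("render invariances: albedo/intensity product and symmetry", {
  rig <- mid_rig()
  spec1 <- polyp_scene(albedo = 0.3, k_s = 0)
  rig2 <- ps_rig(rig$camera, lapply(rig$lights, function(s) {
    light_source(s$position, s$principal_direction, s$intensity * 3)
  }))
  spec2 <- polyp_scene(albedo = 0.1, k_s = 0)
  r1 <- render_scene(spec1, rig)
  r2 <- render_scene(spec2, rig2)
  expect_equal(r1$illuminance[[1]], r2$illuminance[[1]], tolerance = 1e-12)

  # four renders of the centred cap are image-plane mirror images
  ren <- mid_render()
  I <- ren$illuminance
  w <- ncol(I[[1]]); h <- nrow(I[[1]])
  # lights 1/2 oppose in x: I2(r, c) = I1(r, w - c), pixel-exact
  expect_equal(I[[2]][, 1:(w - 1)], I[[1]][, (w - 1):1])
  expect_equal(I[[4]][1:(h - 1), ], I[[3]][(h - 1):1, ])
})

test_that("specular lobe tightens as shininess grows", {
  rig <- mid_rig()
  areas <- vapply(c(10, 100, 1000), function(alpha) {
    ren <- render_scene(polyp_scene(shininess = alpha), rig, active = 1)
    v <- luminance(ren$images[[1]])
    sum(v > 0.9 * max(v))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("mirror point oracle: retroreflection and plane half-offset", {
  cam <- camera_model(565, 640, 480)
  # camera and light co-located: specular point where the normal meets the
  # view ray head-on; for a fronto-parallel plane that is the principal point
  mp <- mirror_point(plane_scene(), light_source(c(0, 0, 0)), cam)
  expect_equal(mp$x, 0)
  expect_equal(mp$y, 0)
  # plane mirror symmetry: surface point at half the source offset
  mp <- mirror_point(plane_scene(), light_source(c(5.5, 0, 0)), cam)
  expect_equal(mp$M[1], 5.5 / 2)
  expect_equal(mp$z, -21.37)
  # sphere cap: the oracle satisfies the mirror condition to high accuracy
  mp <- mirror_point(polyp_scene(), light_source(c(5.5, 0, 0)), cam)
  expect_true(mp$found)
  expect_lt(mp$residual, 1e-8)
  expect_equal(mp$z, -17.4188, tolerance = 1e-4)
})

test_that("noise option is seedable and off by default", {
  rig <- mini_rig()
  r1 <- render_scene(polyp_scene(), rig, noise_sd = 0.01, seed = 5, active = 1)
  r2 <- render_scene(polyp_scene(), rig, noise_sd = 0.01, seed = 5, active = 1)
  r3 <- render_scene(polyp_scene(), rig, active = 1)
  expect_identical(r1$images[[1]], r2$images[[1]])
  expect_false(identical(r1$images[[1]], r3$images[[1]]))
  expect_identical(r3$images[[1]],
                   render_scene(polyp_scene(), rig, active = 1)$images[[1]])
})
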