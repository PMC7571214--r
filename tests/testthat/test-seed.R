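test_that("ratio coefficients: antisymmetry, symmetry, and PDE residual", {
  rig <- default_rig()
  cam <- rig$camera
  # swapping the pair negates every component
  co <- ratio_coefficients(50, -30, -20, 0.4, 0.3,
                           rig$lights[[1]], rig$lights[[3]], cam)
  sw <- ratio_coefficients(50, -30, -20, 0.3, 0.4,
                           rig$lights[[3]], rig$lights[[1]], cam)
  expect_equal(co$F_xi, -sw$F_xi)
  expect_equal(co$F_eta, -sw$F_eta)
  expect_equal(co$F_zeta, -sw$F_zeta)

  # mirror-symmetric pair (+x / -x lights), equal illuminance, on-axis pixel
  co <- ratio_coefficients(0, 0, -21, 0.5, 0.5,
                           rig$lights[[1]], rig$lights[[2]], cam)
  expect_equal(co$F_eta, 0)
  expect_equal(co$F_zeta, 0)

  # the PDE holds at the true depth/gradient of noiseless matte renders
  for (ren in list(mid_plane_lambert(), mid_lambert())) {
    rigm <- mid_rig()
    gt <- ren$ground_truth
    gr <- analytic_gradient(ren$spec, rigm$camera)
    g <- pixel_grid(rigm$camera)
    set.seed(21)
    idx <- sample(length(gt$z), 1000)
    for (pair in list(c(1, 2), c(2, 3))) {
      co <- ratio_coefficients(g$x[idx], g$y[idx], gt$z[idx],
                               ren$illuminance[[pair[1]]][idx],
                               ren$illuminance[[pair[2]]][idx],
                               rigm$lights[[pair[1]]],
                               rigm$lights[[pair[2]]], rigm$camera)
      resid <- co$F_xi * gr$zx[idx] + co$F_eta * gr$zy[idx] - co$s
      scale <- abs(co$F_xi * gr$zx[idx]) + abs(co$F_eta * gr$zy[idx]) +
        abs(co$s) + co$scale * 1e-6
      expect_lt(max(abs(resid / scale)), 1e-6)
    }
  }
})

test_that("specular gradient solves the mirror condition in closed form", {
  rig <- default_rig()
  cam <- rig$camera
  # co-located camera and light: retroreflection, normal along the view ray
  sg <- specular_gradient(100, -50, -21.37, light_source(c(0, 0, 0)), cam)
  nn <- surface_normal(100, -50, -21.37, sg$zx, sg$zy, cam)
  v <- c(100, -50, -565)
  v <- v / sqrt(sum(v^2))
  cross <- c(nn$n_y * v[3] - nn$n_z * v[2],
             nn$n_z * v[1] - nn$n_x * v[3],
             nn$n_x * v[2] - nn$n_y * v[1])
  expect_lt(max(abs(cross)), 1e-12)

  # fronto-parallel plane mirror pixel: flat gradient
  mp <- mirror_point(plane_scene(), rig$lights[[1]], cam)
  sg <- specular_gradient(mp$x, mp$y, mp$z, rig$lights[[1]], cam)
  expect_lt(abs(sg$zx), 1e-8)
  expect_lt(abs(sg$zy), 1e-8)

  # sphere-cap mirror pixel: analytic sphere gradient recovered
  mp <- mirror_point(polyp_scene(), rig$lights[[1]], cam)
  sg <- specular_gradient(mp$x, mp$y, mp$z, rig$lights[[1]], cam)
  gr <- analytic_gradient(polyp_scene(), cam, mp$x, mp$y,
                          matrix(mp$z, 1, 1))
  expect_equal(sg$zx, gr$zx[1], tolerance = 1e-6)
  expect_equal(sg$zy, gr$zy[1], tolerance = 1e-6)

  # at any (pixel, depth) the returned gradient satisfies the reflection
  # equation: view + illumination unit sum parallel to the implied normal
  set.seed(5)
  for (i in 1:50) {
    x <- runif(1, -250, 250); y <- runif(1, -180, 180)
    z <- runif(1, -40, -8)
    li <- rig$lights[[sample(4, 1)]]
    sg <- specular_gradient(x, y, z, li, cam)
    nn <- surface_normal(x, y, z, sg$zx, sg$zy, cam)
    b <- sqrt(x^2 + y^2 + cam$f^2)
    ld <- light_direction(x, y, z, li, cam)
    wv <- c(x / b + ld$l_x, y / b + ld$l_y, -cam$f / b + ld$l_z)
    nb <- c(nn$n_x, nn$n_y, nn$n_z)
    cross <- c(wv[2] * nb[3] - wv[3] * nb[2],
               wv[3] * nb[1] - wv[1] * nb[3],
               wv[1] * nb[2] - wv[2] * nb[1])
    expect_lt(max(abs(cross)) / sqrt(sum(wv^2)), 1e-8)
  }
})

test_that("seed energy vanishes at the true depth of ideal mirror inputs", {
  fx <- ideal_mirror_fixture(sigma = 1)
  rig <- fx$rig
  cam <- rig$camera
  # informative Lambertian pairs (the +y/-y pair is degenerate on the
  # symmetry axis and identically zero)
  for (pair in list(c(2, 3), c(2, 4))) {
    e <- seed_energy(fx$mp$x, fx$mp$y, fx$z_true,
                     fx$stack[[pair[1]]][2, 2], fx$stack[[pair[2]]][2, 2],
                     rig$lights[[pair[1]]], rig$lights[[pair[2]]],
                     rig$lights[[1]], cam)
    expect_lt(abs(e$E) / e$scale, 1e-6)
    # continuity: increments vanish as the grid step shrinks, and the
    # energy changes sign across the true depth
    egrid <- function(step) {
      zg <- fx$z_true + seq(-0.5, 0.5, by = step)
      seed_energy(fx$mp$x, fx$mp$y, zg,
                  fx$stack[[pair[1]]][2, 2], fx$stack[[pair[2]]][2, 2],
                  rig$lights[[pair[1]]], rig$lights[[pair[2]]],
                  rig$lights[[1]], cam)$E
    }
    coarse <- egrid(0.01)
    fine <- egrid(0.001)
    expect_lt(max(abs(diff(fine))), 0.2 * max(abs(diff(coarse))))
    expect_lt(utils::head(coarse, 1) * utils::tail(coarse, 1), 0)
  }
})

test_that("seed estimator: exact recovery, grid oracle, scale invariance", {
  fx <- ideal_mirror_fixture(sigma = 1)
  est <- estimate_seed_depth(fx$stack, fx$region, fx$rig)
  cen <- est[est$is_centroid, ]
  expect_equal(cen$status, "converged")
  expect_lt(abs(cen$z_hat - fx$z_true), 1e-3)

  # brute-force 1e5-point grid search of the same objective
  zg <- seq(-100, -3, length.out = 1e5)
  obj <- 0
  pairs <- list(c(2, 3), c(2, 4), c(3, 4))
  for (pr in pairs) {
    e <- seed_energy(fx$mp$x, fx$mp$y, zg,
                     fx$stack[[pr[1]]][2, 2], fx$stack[[pr[2]]][2, 2],
                     fx$rig$lights[[pr[1]]], fx$rig$lights[[pr[2]]],
                     fx$rig$lights[[1]], fx$rig$camera)
    obj <- obj + e$E^2
  }
  z_grid <- zg[which.min(obj)]
  expect_lt(abs(cen$z_hat - z_grid), max(2e-4, diff(zg[1:2]) * 1.5))

  # global illumination scale cancels in the ratios
  est2 <- estimate_seed_depth(lapply(fx$stack, `*`, 37.5), fx$region, fx$rig)
  expect_equal(est2$z_hat, est$z_hat, tolerance = 1e-9)
})

test_that("estimation error grows away from the region centroid", {
  res <- mid_pipeline()
  seeds <- res$seeds
  gt <- res$render$ground_truth
  ok <- seeds$status == "converged"
  expect_gt(sum(ok), 10)
  err <- abs(seeds$z_hat - gt$z[cbind(seeds$row, seeds$col)])
  rho <- stats::cor(err[ok], seeds$dist_centroid[ok], method = "spearman")
  expect_gt(rho, 0.5)
  # and the centroid pixel is among the most accurate
  expect_lt(err[seeds$is_centroid][1], stats::quantile(err[ok], 0.25))
})
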