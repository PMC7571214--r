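test_that("upwind update: fixed point and bisection oracle", {
  ren <- mid_plane_lambert()
  rig <- mid_rig()
  # both upwind neighbours at the true plane depth and s(z0) = 0: fixed point
  nb <- c(w = -21.37, e = -21.37, n = -21.37, s = -21.37)
  up <- upwind_update(100, 40, nb, c(1, 2), ren$illuminance, rig,
                      z_init = -21.0)
  expect_true(up$converged)
  expect_lt(abs(up$z + 21.37), 1e-5)

  # on the cap, the converged update is the root of the scalar equation
  renc <- mid_lambert()
  gt <- renc$ground_truth$z
  col <- 95; row <- 66; pair <- c(1, 3)
  nbr <- c(w = gt[row, col - 1], e = gt[row, col + 1],
           n = gt[row - 1, col], s = gt[row + 1, col],
           nw = gt[row - 1, col - 1], ne = gt[row - 1, col + 1],
           sw = gt[row + 1, col - 1], se = gt[row + 1, col + 1])
  up <- upwind_update(col, row, nbr, pair, renc$illuminance, rig,
                      z_init = gt[row, col] + 0.4)
  expect_true(up$converged)
  # residual of the discrete equation, with the same orientation/stencil
  cam <- rig$camera
  xy <- pixel_to_xy(cam, col, row)
  gres <- function(z) {
    co <- ratio_coefficients(xy$x, xy$y, z,
                             renc$illuminance[[pair[1]]][row, col],
                             renc$illuminance[[pair[2]]][row, col],
                             rig$lights[[pair[1]]], rig$lights[[pair[2]]],
                             cam)
    o <- up$orient
    Fxi <- o * co$F_xi; Feta <- o * co$F_eta; s <- o * co$s
    if (up$stencil == "axial") {
      zx <- if (Fxi > 0) nbr["w"] else nbr["e"]
      zy <- if (Feta > 0) nbr["n"] else nbr["s"]
      abs(Fxi) * (z - zx) + abs(Feta) * (z - zy) - s
    } else {
      F1 <- (Fxi + Feta) / sqrt(2); F2 <- (Fxi - Feta) / sqrt(2)
      z1 <- if (F1 > 0) nbr["nw"] else nbr["se"]
      z2 <- if (F2 > 0) nbr["sw"] else nbr["ne"]
      abs(F1) * (z - z1) + abs(F2) * (z - z2) - sqrt(2) * s
    }
  }
  root <- stats::uniroot(gres, c(up$z - 0.2, up$z + 0.2), tol = 1e-9)$root
  expect_lt(abs(up$z - root), 1e-5)
  expect_lt(abs(up$z - gt[row, col]), 0.05)
})

test_that("pair selection: brightest two, mask gate, geometric sectors", {
  ren <- mid_render()
  st <- ren$illuminance
  us <- usable_masks(st)
  # far +x pixels see light 1 best; far -x light 2; etc.
  expect_true(1 %in% select_pair(st, 155, 60, us))
  expect_true(2 %in% select_pair(st, 5, 60, us))
  expect_true(3 %in% select_pair(st, 80, 115, us))
  expect_true(4 %in% select_pair(st, 80, 5, us))
  # ordered by source index
  pr <- select_pair(st, 155, 60, us)
  expect_equal(pr, sort(pr))
  # mask gate beats brightness
  masks <- lapply(1:4, function(i) matrix(FALSE, 120, 160))
  masks[[pr[1]]][60, 155] <- TRUE
  us2 <- usable_masks(st, masks, guard = FALSE)
  expect_false(pr[1] %in% select_pair(st, 155, 60, us2))
  # fewer than two usable images: unreconstructable
  masks_all <- lapply(1:4, function(i) matrix(TRUE, 120, 160))
  us3 <- usable_masks(st, masks_all, guard = FALSE)
  expect_null(select_pair(st, 80, 60, us3))
})

test_that("noiseless plane with exact seed is recovered everywhere", {
  ren <- mid_plane_lambert()
  rig <- mid_rig()
  rec <- fast_march(ren$illuminance, rig, 80, 60, -21.37)
  expect_true(all(rec$depth$mask))
  expect_lt(max(abs(rec$depth$z + 21.37)), 1e-3)
  ev <- evaluate_depth(rec, ren$ground_truth)
  expect_lt(ev$rel_rmse, 0.005)
})

test_that("march is deterministic and honours the seed exactly", {
  ren <- mid_render()
  rig <- mid_rig()
  r1 <- fast_march(ren$illuminance, rig, 88, 60, -17.4188)
  r2 <- fast_march(ren$illuminance, rig, 88, 60, -17.4188)
  expect_identical(r1$depth$z, r2$depth$z)
  expect_identical(r1$status, r2$status)
  expect_identical(r1$depth$z[60, 88], -17.4188)
  expect_equal(r1$status[60, 88], 0L)
})

test_that("fast march agrees with a Gauss-Seidel solve of its equations", {
  ren <- mini_lambert()
  rig <- mini_rig()
  gt <- ren$ground_truth
  rec <- fast_march(ren$illuminance, rig, 16, 16, gt$z[16, 16])
  gs <- gauss_seidel_reference(ren$illuminance, rig, 16, 16, gt$z[16, 16],
                               equations = rec)
  expect_lt(max(abs(rec$depth$z - gs$z)), 1e-3)
  # and both stay close to the analytic surface on this gentle crop
  expect_lt(max(abs(rec$depth$z - gt$z)), 0.05)
})

test_that("reconstruction error is monotone in the seed error", {
  res <- mid_pipeline()
  rig <- mid_rig()
  gt <- res$render$ground_truth
  cen <- res$seeds[res$seeds$is_centroid, ]
  z0 <- gt$z[cen$row, cen$col]
  rmse_at <- function(off) {
    rec <- fast_march(res$illuminance, rig, cen$col, cen$row, z0 + off,
                      masks = res$masks)
    evaluate_depth(rec, gt)$rmse
  }
  up <- vapply(c(0, 0.25, 0.5, 1), rmse_at, numeric(1))
  dn <- vapply(c(0, -0.25, -0.5, -1), rmse_at, numeric(1))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) > 0))
})

test_that("halving the grid resolution increases the error (first order)", {
  rmse_at_scale <- function(sc) {
    rig <- default_rig(f = 141 / sc, width = 160 / sc, height = 120 / sc)
    ren <- render_scene(polyp_scene(k_s = 0), rig)
    gt <- ren$ground_truth
    seed <- c(round(88 / sc), round(60 / sc))
    rec <- fast_march(ren$illuminance, rig, seed[1], seed[2],
                      gt$z[seed[2], seed[1]])
    evaluate_depth(rec, gt)$rmse
  }
  expect_lt(rmse_at_scale(1), rmse_at_scale(2))
})

test_that("evaluation: closed forms and the summation oracle", {
  z <- matrix(runif(200, -25, -15), 10)
  truth <- depth_map(z)
  expect_equal(evaluate_depth(depth_map(z), truth)$rmse, 0)
  expect_equal(evaluate_depth(depth_map(z), truth)$rel_rmse, 0)

  z0 <- matrix(-20, 10, 20)
  off <- evaluate_depth(depth_map(z0 + 0.7), depth_map(z0))
  expect_equal(off$rmse, 0.7)
  expect_equal(off$rel_rmse, 0.7 / 20)

  set.seed(13)
  pert <- z + matrix(rnorm(200, sd = 0.3), 10)
  ev <- evaluate_depth(depth_map(pert), truth)
  expect_equal(ev$rmse, sqrt(sum((pert - z)^2) / 200), tolerance = 1e-12)
  expect_equal(ev$rel_rmse,
               sqrt(sum(((pert - z) / z)^2) / 200), tolerance = 1e-12)
})
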