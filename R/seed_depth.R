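# Depth of the specular highlight.  Ratios of Lambertian irradiance
# equations cancel albedo and the common radiometric scale, leaving a PDE
#   F_xi * zx + F_eta * zy = z * F_zeta
# in the depth z and its gradient.  At the specular point the mirror
# constraint gives the gradient in closed form as a function of z alone
# (G terms), so substituting it turns the PDE into a scalar energy
#   E(z) = F_xi G_xi + F_eta G_eta + F_zeta G_zeta
# whose root/minimum is the highlight depth.  All functions here are
# vectorised over pixels and candidate depths simultaneously.

#' Image-ratio PDE coefficients for a Lambertian pair
#'
#' For an ordered pair of Lambertian-lit images (delta1, delta2) with
#' illuminances `I1`, `I2` at the pixel, the coefficients of
#' `F_xi zx + F_eta zy = z F_zeta`:
#' `F_xi = I1 q1^4 (xi2 f + zeta2 x) - I2 q2^4 (xi1 f + zeta1 x)` and its
#' eta analogue, `F_zeta = I2 q2^4 (zeta1 - z) - I1 q1^4 (zeta2 - z)`.
#' Swapping the pair negates all three components.  `s = z F_zeta` is the
#' source term used by the upwind integration.
#'
#' @param x,y Image coordinates (pixels from the principal point).
#' @param z Candidate depth(s), mm (broadcast against x, y).
#' @param I1,I2 Illuminance of the pixel in the two images (> 0).
#' @param light1,light2 The two [light_source()]s.
#' @param cam A [camera_model()].
#' @return List with `F_xi`, `F_eta`, `F_zeta`, `s`.
#' @export
ratio_coefficients <- function(x, y, z, I1, I2, light1, light2, cam) {
  f <- cam$f
  p1 <- light1$position; p2 <- light2$position
  q1 <- light_direction(x, y, z, light1, cam)$q
  q2 <- light_direction(x, y, z, light2, cam)$q
  c1 <- I1 * q1^4
  c2 <- I2 * q2^4
  F_xi <- c1 * (p2[1] * f + p2[3] * x) - c2 * (p1[1] * f + p1[3] * x)
  F_eta <- c1 * (p2[2] * f + p2[3] * y) - c2 * (p1[2] * f + p1[3] * y)
  F_zeta <- c2 * (p1[3] - z) - c1 * (p2[3] - z)
  list(F_xi = F_xi, F_eta = F_eta, F_zeta = F_zeta, s = z * F_zeta,
       scale = c1 + c2)
}

#' Closed-form depth gradient at a specular pixel
#'
#' From the mirror constraint (incident angle = reflected angle) for the
#' specular source, the gradient at depth z is
#' `zx = -z G_xi / G_zeta`, `zy = -z G_eta / G_zeta` with
#' `G_xi = x z q + (x z + xi f) b`, `G_eta = y z q + (y z + eta f) b`,
#' `G_zeta = z q b^2 + z b^3 + f (x xi + y eta - f zeta) b`, and
#' `b = sqrt(x^2 + y^2 + f^2)`.
#'
#' @inheritParams ratio_coefficients
#' @param light The specular (sigma) [light_source()].
#' @return List with `zx`, `zy`, `G_xi`, `G_eta`, `G_zeta`, `b`.
#' @export
specular_gradient <- function(x, y, z, light, cam) {
  f <- cam$f
  p <- light$position
  b <- sqrt(x^2 + y^2 + f^2)
  q <- light_direction(x, y, z, light, cam)$q
  G_xi <- x * z * q + (x * z + p[1] * f) * b
  G_eta <- y * z * q + (y * z + p[2] * f) * b
  G_zeta <- z * q * b^2 + z * b^3 + f * (x * p[1] + y * p[2] - f * p[3]) * b
  if (any(G_zeta == 0, na.rm = TRUE)) {
    stop("degenerate specular geometry: vanishing gradient denominator")
  }
  list(zx = -z * G_xi / G_zeta, zy = -z * G_eta / G_zeta,
       G_xi = G_xi, G_eta = G_eta, G_zeta = G_zeta, b = b)
}

#' Specular-seed energy for one Lambertian pair
#'
#' `E(z) = F_xi G_xi + F_eta G_eta + F_zeta G_zeta`; zero exactly when the
#' candidate depth satisfies both the image-ratio PDE and the mirror
#' constraint.  `scale` is the sum of the three term magnitudes, a natural
#' normaliser for relative residuals.
#'
#' @inheritParams ratio_coefficients
#' @param sigma_light The specular source.
#' @return List with `E` and `scale`.
#' @export
seed_energy <- function(x, y, z, I1, I2, light1, light2, sigma_light, cam) {
  Fc <- ratio_coefficients(x, y, z, I1, I2, light1, light2, cam)
  G <- specular_gradient(x, y, z, sigma_light, cam)
  t1 <- Fc$F_xi * G$G_xi
  t2 <- Fc$F_eta * G$G_eta
  t3 <- Fc$F_zeta * G$G_zeta
  list(E = t1 + t2 + t3, scale = abs(t1) + abs(t2) + abs(t3))
}

# Interior local minima of a numeric vector (strict on the left, non-strict
# right, so plateaus count once).
local_minima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n]) + 1L
}

#' Estimate the depth of every pixel in a specular-highlight region
#'
#' Per pixel, the (combined) squared seed energy is minimised over the
#' working-depth interval by a coarse grid scan followed by local
#' refinement.  With `pair_mode = "combined"` the objective is the sum of
#' squared energies over all usable Lambertian pairs; `"single"` uses the
#' one pair formed by the two brightest Lambertian images at the pixel.
#' Pixels whose minimum sits at the interval edge are flagged `"edge"`, and
#' pixels with two well-separated grid minima of comparable squared energy
#' are flagged `"ambiguous"`; both are excluded from region statistics.
#'
#' @param stack List of illuminance matrices, one per light (e.g.
#'   `render$illuminance`).
#' @param region A one-row `highlight_regions` tibble (or a list with
#'   `mask`, `source`, `centroid_col`, `centroid_row`).
#' @param rig A [ps_rig()].
#' @param masks Optional list of per-light highlight masks; a light's image
#'   is not used at pixels inside its own mask.
#' @param search Depth interval in mm, default `c(-100, -3)` -- the
#'   capsule camera's working range.
#' @param n_grid Coarse grid size (default 512).
#' @param tol Refinement tolerance in mm (default 1e-4).
#' @param pair_mode `"combined"` (default) or `"single"`.
#' @param ambiguity_ratio Two grid minima within this factor in squared
#'   energy (and separated by `min_separation` grid steps) flag the pixel.
#' @param min_separation Grid-step separation for the ambiguity test.
#' @return An object of class `seed_estimates`: a tibble with one row per
#'   region pixel (`col`, `row`, `z_hat`, `objective`, `residual_rel`,
#'   `status`, `is_centroid`, `dist_centroid`) carrying the search settings
#'   as attributes.  The centroid row is the recommended boundary condition
#'   for [fast_march()].
#' @export
estimate_seed_depth <- function(stack, region, rig, masks = NULL,
                                search = c(-100, -3), n_grid = 512,
                                tol = 1e-4,
                                pair_mode = c("combined", "single"),
                                ambiguity_ratio = 1.1, min_separation = 10) {
  pair_mode <- match.arg(pair_mode)
  cam <- rig$camera
  if (inherits(region, "tbl_df")) {
    stopifnot(nrow(region) == 1)
    region <- list(mask = region$mask[[1]], source = region$source[[1]],
                   centroid_col = region$centroid_col[[1]],
                   centroid_row = region$centroid_row[[1]])
  }
  sigma <- region$source
  delta_all <- setdiff(seq_along(stack), sigma)
  idx <- which(region$mask)
  if (length(idx) == 0) stop("empty highlight region")
  h <- nrow(stack[[1]])
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  xy <- pixel_to_xy(cam, cols, rows)
  zg <- seq(search[1], search[2], length.out = n_grid)

  n <- length(idx)
  est <- numeric(n); obj_min <- numeric(n); resid <- numeric(n)
  status <- character(n)
  sigma_light <- rig$lights[[sigma]]

  for (i in seq_len(n)) {
    px <- idx[i]
    lit <- delta_all[vapply(delta_all, function(k) stack[[k]][px] > 0,
                            logical(1))]
    usable <- lit[vapply(lit, function(k) {
      is.null(masks) || !masks[[k]][px]
    }, logical(1))]
    if (length(usable) < 2) {
      # coverage guard, as in the reconstruction: restore the dimmest
      # masked delta images (least specular contamination) up to two
      excl <- setdiff(lit, usable)
      excl <- excl[order(vapply(excl, function(k) stack[[k]][px],
                                numeric(1)))]
      usable <- sort(c(usable, utils::head(excl, 2 - length(usable))))
    }
    if (length(usable) < 2) {
      est[i] <- NA_real_; obj_min[i] <- NA_real_; resid[i] <- NA_real_
      status[i] <- "unusable"
      next
    }
    pairs <- if (pair_mode == "single") {
      bright <- usable[order(-vapply(usable, function(k) stack[[k]][px],
                                     numeric(1)), usable)]
      list(sort(bright[1:2]))
    } else {
      utils::combn(usable, 2, simplify = FALSE)
    }
    objective <- function(z) {
      tot <- 0
      sc <- 0
      for (pr in pairs) {
        e <- seed_energy(xy$x[i], xy$y[i], z,
                         stack[[pr[1]]][px], stack[[pr[2]]][px],
                         rig$lights[[pr[1]]], rig$lights[[pr[2]]],
                         sigma_light, cam)
        tot <- tot + e$E^2
        sc <- sc + e$scale
      }
      list(obj = tot, scale = sc)
    }
    og <- objective(zg)$obj
    k0 <- which.min(og)
    if (k0 == 1 || k0 == n_grid) {
      est[i] <- zg[k0]; obj_min[i] <- og[k0]; resid[i] <- NA_real_
      status[i] <- "edge"
      next
    }
    mins <- local_minima(og)
    amb <- FALSE
    if (length(mins) >= 2) {
      vals <- og[mins]
      o <- order(vals)
      best <- mins[o[1]]
      rivals <- mins[abs(mins - best) >= min_separation]
      if (length(rivals) > 0 &&
          min(og[rivals]) <= ambiguity_ratio * og[best] &&
          min(og[rivals]) > 0 && og[best] > 0) {
        amb <- TRUE
      }
    }
    opt <- stats::optimize(function(z) objective(z)$obj,
                           c(zg[k0 - 1], zg[k0 + 1]), tol = tol)
    est[i] <- opt$minimum
    obj_min[i] <- opt$objective
    sc <- objective(opt$minimum)$scale
    resid[i] <- sqrt(max(opt$objective, 0)) / max(sc, .Machine$double.xmin)
    status[i] <- if (amb) "ambiguous" else "converged"
  }

  dc <- sqrt((cols - region$centroid_col)^2 + (rows - region$centroid_row)^2)
  out <- tibble::tibble(
    col = cols, row = rows, x = xy$x, y = xy$y,
    z_hat = est, objective = obj_min, residual_rel = resid,
    status = status,
    is_centroid = cols == region$centroid_col & rows == region$centroid_row,
    dist_centroid = dc
  )
  structure(out,
            class = c("seed_estimates", class(out)),
            sigma_source = sigma, search = search, tol = tol,
            pair_mode = pair_mode,
            centroid = c(col = region$centroid_col,
                         row = region$centroid_row))
}
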