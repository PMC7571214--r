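# Whole-surface integration.  The image-ratio PDE holds at every Lambertian
# pixel for any usable image pair; discretised with a first-order upwind
# stencil it becomes a per-pixel scalar equation linking a depth to its
# upwind neighbours.  A fast-marching front grows the solution outward from
# the specular seed, each pixel choosing the brightest usable image pair and
# the directional stencil (axial or diagonal) whose upwind neighbours are
# already accepted.  The compiled core does the march; the R functions here
# implement the same per-pixel equations independently for testing
# (upwind_update, gauss_seidel_reference) and provide the user-facing
# wrapper and evaluation.

#' Per-pixel usability masks for a stack
#'
#' An image is usable at a pixel when the pixel is outside that image's own
#' (dilated) highlight mask and its illuminance is above a relative floor.
#' With `guard = TRUE`, pixels left with fewer than two usable images --
#' possible where the dilated exclusion zones of several highlights overlap
#' -- get their dimmest masked images restored until two are usable (near
#' such pixels the dimmest image carries the least specular contamination).
#'
#' @param stack List of illuminance matrices.
#' @param masks Optional list of per-light highlight masks.
#' @param floor_rel Illuminance floor as a fraction of each image's maximum.
#' @param guard Keep every pixel reconstructable (see above).
#' @return List of logical matrices.
#' @export
usable_masks <- function(stack, masks = NULL, floor_rel = 1e-6,
                         guard = TRUE) {
  us <- purrr::imap(stack, function(im, k) {
    u <- im > floor_rel * max(im)
    if (!is.null(masks)) u <- u & !masks[[k]]
    u
  })
  if (guard && !is.null(masks)) {
    floors <- vapply(stack, function(im) floor_rel * max(im), numeric(1))
    cnt <- Reduce(`+`, lapply(us, `*`, 1))
    for (p in which(cnt < 2)) {
      iv <- vapply(stack, function(im) im[p], numeric(1))
      need <- 2 - cnt[p]
      for (k in order(iv)) {
        if (need == 0) break
        if (!us[[k]][p] && iv[k] > floors[k]) {
          us[[k]][p] <- TRUE
          need <- need - 1
        }
      }
    }
  }
  us
}

#' Select the Lambertian image pair at a pixel
#'
#' The two usable images with the highest illuminance at the pixel, ordered
#' by source index.
#'
#' @param stack List of illuminance matrices.
#' @param col,row Pixel indices.
#' @param usable List of logical usability matrices (see [usable_masks()]).
#' @return Integer vector of length 2, or `NULL` when fewer than two images
#'   are usable (pixel unreconstructable).
#' @export
select_pair <- function(stack, col, row, usable = usable_masks(stack)) {
  ok <- which(vapply(usable, function(u) u[row, col], logical(1)))
  if (length(ok) < 2) return(NULL)
  vals <- vapply(ok, function(k) stack[[k]][row, col], numeric(1))
  sort(ok[order(-vals, ok)][1:2])
}

# Shared scalar fixed-point solve, the R twin of the compiled core.
# neighbors: named numeric vector with entries among
#   w, e, n, s, nw, ne, sw, se  (NA = not accepted).
# Both orientations of the pair are admissible (swapping the pair negates F
# and s, turning the one-sided differences around); the option differencing
# toward the most accepted weight wins.  `force` pins orientation/stencil
# (used by the Gauss-Seidel oracle to iterate the very equations the march
# chose).
upwind_solve <- function(x, y, I1, I2, light1, light2, cam, neighbors,
                         z_init, delta = 1, zrange = c(-100, -3),
                         tol = 1e-6, maxit = 50, strict = FALSE,
                         force = NULL) {
  getn <- function(nm) {
    v <- neighbors[[nm]] %||% NA_real_
    if (is.null(v) || is.na(v)) NA_real_ else v
  }
  z <- z_init
  prev <- Inf
  damp <- 1
  sqrt2 <- sqrt(2)
  chosen <- NULL
  for (it in seq_len(maxit)) {
    co <- ratio_coefficients(x, y, z, I1, I2, light1, light2, cam)
    csum <- co$scale
    if (abs(co$F_xi) + abs(co$F_eta) <= 1e-10 * csum * cam$f) {
      return(list(z = NA_real_, converged = FALSE, reason = "degenerate"))
    }
    thr <- 1e-13 * csum * cam$f
    build <- function(Fa, Fb, upa, upb, step, orient, stencil) {
      w <- numeric(0); zn <- numeric(0); miss <- 0
      for (tm in list(list(Fa, upa), list(Fb, upb))) {
        Fv <- tm[[1]]
        if (abs(Fv) <= thr) next
        znb <- if (Fv > 0) getn(tm[[2]][1]) else getn(tm[[2]][2])
        if (is.na(znb)) miss <- miss + abs(Fv)
        else { w <- c(w, abs(Fv)); zn <- c(zn, znb) }
      }
      list(w = w, zn = zn, miss = miss, step = step, orient = orient,
           stencil = stencil, usable = length(w) > 0)
    }
    F1 <- (co$F_xi + co$F_eta) / sqrt2
    F2 <- (co$F_xi - co$F_eta) / sqrt2
    opts <- list(
      build(co$F_xi, co$F_eta, c("w", "e"), c("n", "s"), delta, 1, "axial"),
      build(-co$F_xi, -co$F_eta, c("w", "e"), c("n", "s"), delta, -1, "axial"),
      build(F1, F2, c("nw", "se"), c("sw", "ne"), delta * sqrt2, 1,
            "diagonal"),
      build(-F1, -F2, c("nw", "se"), c("sw", "ne"), delta * sqrt2, -1,
            "diagonal")
    )
    if (!is.null(force)) {
      opts <- purrr::keep(opts, function(o) {
        o$orient == force$orient && o$stencil == force$stencil
      })
    }
    opts <- purrr::keep(opts, "usable")
    if (length(opts) == 0) {
      return(list(z = NA_real_, converged = FALSE, reason = "no upwind"))
    }
    frac <- vapply(opts, function(o) o$miss / (o$miss + sum(o$w)), numeric(1))
    o <- opts[[which.min(frac)]]
    if (strict && min(frac) > 0) {
      return(list(z = NA_real_, converged = FALSE, reason = "partial"))
    }
    W <- sum(o$w)
    znew <- (sum(o$w * o$zn) + o$step * o$orient * co$s) / W
    znew <- min(max(znew, zrange[1]), zrange[2])
    dz <- znew - z
    chosen <- o
    if (abs(dz) < tol) {
      edge <- znew <= zrange[1] + tol || znew >= zrange[2] - tol
      return(list(z = znew, converged = !edge, iterations = it,
                  stencil = o$stencil, orient = o$orient,
                  reason = if (edge) "edge" else "ok"))
    }
    if (abs(dz) > prev) damp <- max(0.1, damp / 2)
    prev <- abs(dz)
    z <- z + damp * dz
  }
  list(z = z, converged = FALSE, reason = "maxit",
       stencil = chosen$stencil, orient = chosen$orient)
}

#' One forward upwind update at a pixel
#'
#' Solves the discretised image-ratio PDE
#' `Z (|F_xi| + |F_eta|) = |F_xi| Z_upx + |F_eta| Z_upy + delta * s(Z)`
#' for the centre depth by damped fixed-point iteration, with the upwind
#' neighbours selected by the signs of the coefficients (diagonal stencils
#' use step `delta * sqrt(2)`).  This is the reference R implementation of
#' the compiled march's inner solve.
#'
#' @param col,row Pixel indices.
#' @param neighbors Named numeric vector of accepted neighbour depths among
#'   `w, e, n, s, nw, ne, sw, se` (NA or absent = not accepted).
#' @param pair Integer pair of image indices.
#' @param stack List of illuminance matrices.
#' @param rig A [ps_rig()].
#' @param z_init Starting depth (default: mean of supplied neighbours).
#' @param delta Grid step in pixels.
#' @param zrange Working depth range, mm.
#' @param tol,maxit Fixed-point tolerance (mm) and iteration cap.
#' @return List with `z`, `converged`, `stencil`, `reason`.
#' @export
upwind_update <- function(col, row, neighbors, pair, stack, rig,
                          z_init = mean(unlist(neighbors), na.rm = TRUE),
                          delta = 1, zrange = c(-100, -3),
                          tol = 1e-6, maxit = 50) {
  cam <- rig$camera
  xy <- pixel_to_xy(cam, col, row)
  upwind_solve(xy$x, xy$y,
               stack[[pair[1]]][row, col], stack[[pair[2]]][row, col],
               rig$lights[[pair[1]]], rig$lights[[pair[2]]], cam,
               as.list(neighbors), z_init, delta, zrange, tol, maxit)
}

#' Fast-marching depth-map integration from a seed
#'
#' Propagates depth outward from the seed pixel over 8-connected neighbours.
#' Pixels are finalised once, in a deterministic order (most accepted
#' neighbours first, then Chebyshev distance from the seed, then pixel
#' index); each uses the brightest usable image pair at that pixel and the
#' directional stencil whose upwind neighbours are already accepted.  Pixels
#' where every pair fails (degenerate characteristic direction or
#' non-convergence) are revisited after the front exhausts and, as a last
#' resort, assigned the mean of their accepted neighbours (status 2).
#' Unreached or unusable pixels are masked (status 3).
#'
#' @param stack List of 4 illuminance matrices.
#' @param rig A [ps_rig()].
#' @param seed_col,seed_row Seed pixel.
#' @param seed_depth Seed depth in mm (the output reproduces it exactly).
#' @param masks Optional per-light highlight masks (see
#'   [highlight_masks()]); an image is never used inside its own highlight.
#' @param delta Grid step in pixels (default 1).
#' @param zrange Working depth range, mm.
#' @param floor_rel Illuminance usability floor.
#' @param tol,maxit Per-pixel fixed-point controls.
#' @return An object of class `depth_recon`: `depth` (a [depth_map()]),
#'   `status` (integer matrix: 0 seed, 1 marched, 2 fallback, 3 unreached),
#'   `pair` (list of the two chosen-source matrices), and the seed.
#' @export
fast_march <- function(stack, rig, seed_col, seed_row, seed_depth,
                       masks = NULL, delta = 1, zrange = c(-100, -3),
                       floor_rel = 1e-6, tol = 1e-6, maxit = 50) {
  stopifnot(length(stack) == 4)
  usable <- usable_masks(stack, masks, floor_rel)
  lights <- t(vapply(rig$lights, `[[`, numeric(3), "position"))
  res <- .fm_march(stack, usable, lights,
                   rig$camera$f, rig$camera$cx, rig$camera$cy,
                   as.integer(seed_col), as.integer(seed_row), seed_depth,
                   delta, zrange[1], zrange[2], tol, as.integer(maxit))
  dm <- depth_map(res$z, mask = res$mask, cam = rig$camera, delta = delta,
                  seed = list(col = seed_col, row = seed_row,
                              depth = seed_depth))
  structure(
    list(depth = dm, status = res$status,
         pair = list(a = res$pair_a, b = res$pair_b),
         orient = res$orient, stencil = res$stencil,
         seed = dm$seed, rig = rig),
    class = "depth_recon"
  )
}

#' @export
print.depth_recon <- function(x, ...) {
  st <- table(factor(x$status, levels = 0:3,
                     labels = c("seed", "marched", "fallback", "unreached")))
  cat(sprintf("<depth_recon> seed (%d, %d) @ %.4f mm; %s\n",
              x$seed$col, x$seed$row, x$seed$depth,
              paste(names(st), st, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Gauss-Seidel reference solution of the same discrete equations
#'
#' Brute-force iterative oracle for [fast_march()]: every pixel repeatedly
#' re-solved from its current neighbours (all treated as available) in
#' alternating raster sweeps until the largest update falls below `tol`.
#' Intended for small crops; quadratic cost.
#'
#' @inheritParams fast_march
#' @param sweeps Maximum number of full sweeps.
#' @param tol Convergence threshold on the largest per-sweep change (mm).
#' @param equations Optional `depth_recon` whose per-pixel equation choices
#'   (image pair, orientation, stencil) are iterated; the oracle then solves
#'   exactly the discrete system the march assembled, by a different method.
#'   Without it each pixel uses the brightest usable pair and free
#'   orientation/stencil choice.
#' @return A [depth_map()].
#' @export
gauss_seidel_reference <- function(stack, rig, seed_col, seed_row, seed_depth,
                                   masks = NULL, delta = 1,
                                   zrange = c(-100, -3), floor_rel = 1e-6,
                                   sweeps = 500, tol = 1e-7,
                                   equations = NULL) {
  usable <- usable_masks(stack, masks, floor_rel)
  h <- nrow(stack[[1]]); w <- ncol(stack[[1]])
  Z <- matrix(seed_depth, h, w)
  cam <- rig$camera
  nbr_of <- function(r, c) {
    gv <- function(rr, cc) {
      if (rr < 1 || rr > h || cc < 1 || cc > w) NA_real_ else Z[rr, cc]
    }
    list(w = gv(r, c - 1), e = gv(r, c + 1), n = gv(r - 1, c),
         s = gv(r + 1, c), nw = gv(r - 1, c - 1), ne = gv(r - 1, c + 1),
         sw = gv(r + 1, c - 1), se = gv(r + 1, c + 1))
  }
  order_fwd <- expand.grid(row = seq_len(h), col = seq_len(w))
  order_bwd <- order_fwd[rev(seq_len(nrow(order_fwd))), ]
  for (it in seq_len(sweeps)) {
    ord <- if (it %% 2 == 1) order_fwd else order_bwd
    dmax <- 0
    for (k in seq_len(nrow(ord))) {
      r <- ord$row[k]; c <- ord$col[k]
      if (r == seed_row && c == seed_col) next
      force <- NULL
      if (!is.null(equations)) {
        if (equations$status[r, c] != 1L) next
        pr <- c(equations$pair$a[r, c], equations$pair$b[r, c])
        force <- list(orient = equations$orient[r, c],
                      stencil = c("axial", "diagonal")[
                        equations$stencil[r, c] + 1L])
      } else {
        pr <- select_pair(stack, c, r, usable)
        if (is.null(pr)) next
      }
      xy <- pixel_to_xy(cam, c, r)
      sol <- upwind_solve(xy$x, xy$y, stack[[pr[1]]][r, c],
                          stack[[pr[2]]][r, c],
                          rig$lights[[pr[1]]], rig$lights[[pr[2]]], cam,
                          nbr_of(r, c), Z[r, c], delta, zrange,
                          force = force)
      if (!is.na(sol$z) && sol$converged) {
        dmax <- max(dmax, abs(sol$z - Z[r, c]))
        Z[r, c] <- sol$z
      }
    }
    if (dmax < tol) break
  }
  depth_map(Z, cam = cam, delta = delta,
            seed = list(col = seed_col, row = seed_row, depth = seed_depth))
}

#' Compare a reconstructed depth map with ground truth
#'
#' RMSE in mm and relative RMSE (per-pixel `|error| / |truth|`, aggregated
#' as a root mean square) over the common valid mask, plus error maps.
#'
#' @param pred A [depth_map()] or `depth_recon`.
#' @param truth A [depth_map()].
#' @return An object of class `depth_eval` with `rmse`, `rel_rmse`
#'   (fraction), `n`, `error` and `rel_error` matrices and the common
#'   `mask`.
#' @export
evaluate_depth <- function(pred, truth) {
  if (inherits(pred, "depth_recon")) pred <- pred$depth
  stopifnot(identical(dim(pred$z), dim(truth$z)))
  mask <- pred$mask & truth$mask
  if (!any(mask)) stop("empty common valid mask")
  err <- pred$z - truth$z
  rel <- abs(err) / abs(truth$z)
  err[!mask] <- NA_real_
  rel[!mask] <- NA_real_
  structure(
    list(rmse = sqrt(mean(err[mask]^2)),
         rel_rmse = sqrt(mean(rel[mask]^2)),
         n = sum(mask), error = err, rel_error = rel, mask = mask),
    class = "depth_eval"
  )
}

#' @export
print.depth_eval <- function(x, ...) {
  cat(sprintf("<depth_eval> RMSE %.4f mm, relative RMSE %.4f%% over %d px\n",
              x$rmse, 100 * x$rel_rmse, x$n))
  invisible(x)
}
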