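# Specular-highlight detection.  Highlights are low-saturation (the lobe
# carries the illuminant colour) and high-intensity; pixels passing both
# gates are grouped by 8-connectivity and summarised per region.  Grayscale
# inputs fall back to the intensity gate alone.

# 8-connected component labelling of a logical matrix; returns an integer
# matrix (0 = background).  Plain BFS on pixel indices.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx_all <- which(mask)
  queue <- integer(length(idx_all))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (dc in -1:1) {
        nc <- cc + dc
        if (nc < 1L || nc > w) next
        for (dr in -1:1) {
          if (dr == 0L && dc == 0L) next
          nr <- r + dr
          if (nr < 1L || nr > h) next
          np <- (nc - 1L) * h + nr
          if (mask[np] && lab[np] == 0L) {
            lab[np] <- cur
            tail <- tail + 1L
            queue[tail] <- np
          }
        }
      }
    }
  }
  lab
}

#' Detect specular-highlight regions in one image
#'
#' RGB inputs: a pixel is a highlight candidate when its HSV saturation is
#' below `saturation_max` **and** its value (max channel) exceeds
#' `intensity_min` times the image maximum.  Grayscale inputs use the
#' intensity gate only.  Candidates are grouped by 8-connectivity, regions
#' below `min_area` pixels are dropped, and each region's centroid is the
#' intensity-weighted mean pixel, rounded to the nearest pixel.  Both
#' thresholds are relative, so detection is invariant to a global positive
#' scaling of all channels.
#'
#' The centroid is meant to locate the specular lobe (it seeds the depth
#' reconstruction), so its weights are the most specular pixels' specular
#' content, not raw brightness: on RGB inputs the diffuse component of a
#' homogeneous dielectric surface is proportional to `V - min(channel)`
#' (the specular lobe carries the illuminant colour and cancels in the
#' difference), so the per-pixel specular excess is
#' `w = V - beta * (V - min)`, with `beta` estimated as the median of
#' `V / (V - min)` over a diffuse ring just outside the region.  The
#' centroid is the `w`-weighted mean over the pixels where `w` exceeds
#' `intensity_min` of its own maximum -- gating `w` at the same relative
#' level as the detector, so neither the weights nor their support are
#' tilted by the diffuse baseline.  Grayscale inputs fall back to weighting
#' by the intensity excess over the gate level.
#'
#' @param img `h x w` matrix or `h x w x 3` array, linear values >= 0.
#' @param saturation_max Saturation gate (ignored for grayscale).
#' @param intensity_min Intensity gate as a fraction of the image maximum.
#' @param min_area Minimum region area in pixels.
#' @param source Index of the light that lit this image (carried through).
#' @return A tibble of class `highlight_regions`: one row per region with
#'   `source`, `region`, `area`, `centroid_col`, `centroid_row` and the
#'   logical `mask` in a list column.  Zero rows when nothing is found.
#' @export
detect_highlights <- function(img, saturation_max = 0.3, intensity_min = 0.9,
                              min_area = 5, source = NA_integer_) {
  rgb <- length(dim(img)) == 3
  if (rgb) {
    v <- pmax(img[, , 1], img[, , 2], img[, , 3])
    mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
    sat <- ifelse(v > 0, (v - mn) / v, 0)
  } else {
    v <- img
  }
  peak <- max(v)
  cand <- v > intensity_min * peak
  if (rgb) cand <- cand & (sat < saturation_max)
  empty <- tibble::tibble(
    source = integer(), region = integer(), area = integer(),
    centroid_col = integer(), centroid_row = integer(), mask = list()
  )
  if (!any(cand)) return(structure(empty, class = c("highlight_regions",
                                                    class(empty))))
  lab <- label_components(cand)
  h <- nrow(lab)
  w_spec <- NULL
  if (rgb) {
    # dichromatic specular excess; diffuse is proportional to v - mn on a
    # homogeneous surface, with the scale taken from specular-free pixels
    dif <- v - mn
    ratio <- ifelse(dif > 1e-3 * peak, v / dif, NA_real_)
    w_spec <- function(idx) {
      r <- ((idx - 1L) %% h) + 1L
      cc <- ((idx - 1L) %/% h) + 1L
      ctr <- c(mean(range(cc)), mean(range(r)))
      rad <- max(max(cc) - min(cc), max(r) - min(r)) / 2
      gall <- expand.grid(row = seq_len(h), col = seq_len(ncol(v)))
      dd <- sqrt((gall$col - ctr[1])^2 + (gall$row - ctr[2])^2)
      ring <- which(dd > 2 * rad + 5 & dd < 4 * rad + 15 & !cand)
      beta <- stats::median(ratio[ring], na.rm = TRUE)
      if (!is.finite(beta)) return(NULL)
      w <- v - beta * dif
      pmax(w, 0)
    }
  }
  regs <- purrr::map(seq_len(max(lab)), function(k) {
    idx <- which(lab == k)
    if (length(idx) < min_area) return(NULL)
    r <- ((idx - 1L) %% h) + 1L
    cc <- ((idx - 1L) %/% h) + 1L
    wgt <- NULL
    if (rgb) {
      w <- w_spec(idx)
      if (!is.null(w) && max(w[idx]) > 0) {
        keep <- w[idx] > intensity_min * max(w[idx])
        if (sum(keep) >= 1) {
          idx_w <- idx[keep]
          r <- ((idx_w - 1L) %% h) + 1L
          cc <- ((idx_w - 1L) %/% h) + 1L
          wgt <- w[idx_w]
        }
      }
    }
    if (is.null(wgt)) {
      wgt <- v[idx] - intensity_min * peak  # excess over the gate level
      r <- ((idx - 1L) %% h) + 1L
      cc <- ((idx - 1L) %/% h) + 1L
    }
    idx <- which(lab == k)
    m <- lab == k
    tibble::tibble(
      source = as.integer(source), region = k, area = length(idx),
      centroid_col = as.integer(round(sum(cc * wgt) / sum(wgt))),
      centroid_row = as.integer(round(sum(r * wgt) / sum(wgt))),
      mask = list(m)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(regs))
  if (nrow(out) == 0) out <- empty
  out$region <- seq_len(nrow(out))
  structure(out, class = c("highlight_regions", class(empty)))
}

#' Detect highlights in a full photometric-stereo stack
#'
#' Runs [detect_highlights()] on each image of a render (or list of images),
#' tagging regions with the index of the light that was active.
#'
#' @param x A `ps_render` or a list of image arrays (one per light).
#' @param ... Passed to [detect_highlights()].
#' @return A `highlight_regions` tibble over all images.
#' @export
detect_highlights_stack <- function(x, ...) {
  imgs <- if (inherits(x, "ps_render")) x$images else x
  out <- purrr::imap(imgs, function(im, i) {
    detect_highlights(im, source = i, ...)
  })
  out <- dplyr::bind_rows(out)
  structure(out, class = c("highlight_regions", class(tibble::tibble())))
}

#' Choose the seed region and the Lambertian light set
#'
#' The largest-area region across all images becomes the specular (sigma)
#' region; ties break to the lowest source index.  The remaining lights form
#' the delta set, whose images provide the Lambertian ratio equations.
#' Every image's own highlight mask is excluded from its Lambertian use
#' downstream.
#'
#' @param regions A `highlight_regions` tibble.
#' @param n_lights Total number of lights in the rig.
#' @return List with `sigma` (one-row tibble), `sigma_source`, and `delta`
#'   (integer vector of the other source indices).
#' @export
select_seed_region <- function(regions, n_lights = 4) {
  if (nrow(regions) == 0) {
    stop("seed unavailable: no specular highlight detected in any image")
  }
  ord <- order(-regions$area, regions$source, regions$region)
  sigma <- regions[ord[1], ]
  list(sigma = sigma, sigma_source = sigma$source[[1]],
       delta = setdiff(seq_len(n_lights), sigma$source[[1]]))
}

# Dilate a compact region mask by r pixels (Euclidean disc), exactly, via
# min distance to the region inside an expanded bounding box.
dilate_mask <- function(m, r) {
  if (r <= 0 || !any(m)) return(m)
  h <- nrow(m); w <- ncol(m)
  idx <- which(m)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  r0 <- max(1L, min(rr) - r); r1 <- min(h, max(rr) + r)
  c0 <- max(1L, min(cc) - r); c1 <- min(w, max(cc) + r)
  br <- seq.int(r0, r1); bc <- seq.int(c0, c1)
  # min squared distance from every bbox pixel to the region
  d2 <- matrix(Inf, length(br), length(bc))
  for (k in seq_along(idx)) {
    d2 <- pmin(d2, outer((br - rr[k])^2, (bc - cc[k])^2, `+`))
  }
  out <- m
  out[br, bc] <- out[br, bc] | (d2 <= r^2)
  out
}

#' Per-image highlight exclusion masks for a stack
#'
#' Union of all detected region masks per source, dilated, as needed by the
#' reconstruction (a light's image is never used as Lambertian evidence in
#' or near its own highlight).  The specular lobe extends well beyond the
#' detected core: the intensity gate keeps only pixels above
#' `intensity_min` of the peak, where the lobe still carries most of its
#' height, and the wings bias the Lambertian image ratios far outside it.
#' Each region is therefore dilated by `dilate` times its equivalent radius
#' `sqrt(area/pi)`, which for the default gates reaches the ~1% level of
#' the lobe.  Coverage is preserved downstream by [usable_masks()]'s guard.
#'
#' @param regions A `highlight_regions` tibble.
#' @param dim_hw Integer `c(height, width)`.
#' @param n_lights Number of lights.
#' @param dilate Dilation radius in units of each region's equivalent
#'   radius (0 disables).
#' @return List of logical matrices, one per light.
#' @export
highlight_masks <- function(regions, dim_hw, n_lights = 4, dilate = 3) {
  purrr::map(seq_len(n_lights), function(i) {
    m <- matrix(FALSE, dim_hw[1], dim_hw[2])
    rows <- which(regions$source == i)
    for (r in rows) {
      rad <- round(dilate * sqrt(regions$area[r] / pi))
      m <- m | dilate_mask(regions$mask[[r]], rad)
    }
    m
  })
}
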