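# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @method tidy depth_map
#' @export
tidy.depth_map <- function(x, ...) {
  h <- nrow(x$z); w <- ncol(x$z)
  tibble::tibble(
    col = rep(seq_len(w), each = h),
    row = rep(seq_len(h), times = w),
    z = as.vector(x$z),
    valid = as.vector(x$mask)
  )
}

#' @method glance depth_map
#' @export
glance.depth_map <- function(x, ...) {
  tibble::tibble(
    width = ncol(x$z), height = nrow(x$z), n_valid = sum(x$mask),
    z_min = min(x$z[x$mask]), z_max = max(x$z[x$mask]),
    delta_px = x$delta
  )
}

#' @method tidy depth_eval
#' @export
tidy.depth_eval <- function(x, ...) {
  h <- nrow(x$error); w <- ncol(x$error)
  out <- tibble::tibble(
    col = rep(seq_len(w), each = h),
    row = rep(seq_len(h), times = w),
    error = as.vector(x$error),
    rel_error = as.vector(x$rel_error)
  )
  dplyr::filter(out, !is.na(.data$error))
}

#' @method glance depth_eval
#' @export
glance.depth_eval <- function(x, ...) {
  tibble::tibble(rmse_mm = x$rmse, rel_rmse_pct = 100 * x$rel_rmse, n = x$n)
}

#' @method tidy seed_estimates
#' @export
tidy.seed_estimates <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance seed_estimates
#' @export
glance.seed_estimates <- function(x, ...) {
  ok <- x[x$status == "converged", ]
  cen <- x[x$is_centroid, ]
  tibble::tibble(
    n_pixels = nrow(x), n_converged = nrow(ok),
    sigma_source = attr(x, "sigma_source"),
    centroid_z = if (nrow(cen) == 1) cen$z_hat else NA_real_,
    pair_mode = attr(x, "pair_mode")
  )
}

#' @method glance depth_recon
#' @export
glance.depth_recon <- function(x, ...) {
  st <- tabulate(as.vector(x$status) + 1L, nbins = 4)
  tibble::tibble(
    n_seed = st[1], n_marched = st[2], n_fallback = st[3],
    n_unreached = st[4], seed_col = x$seed$col, seed_row = x$seed$row,
    seed_depth = x$seed$depth
  )
}

raster_plot <- function(df, fill, legend) {
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = {{ fill }})) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = legend) +
    ggplot2::theme_minimal()
}

#' Plot methods for depth maps, evaluations and renders
#'
#' `autoplot.depth_map` shows the depth raster (mm), `autoplot.depth_eval`
#' the signed error map, and `autoplot.ps_render` the four illuminance maps
#' in facets.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot depth_map
#' @export
autoplot.depth_map <- function(object, ...) {
  df <- tidy(object)
  df$z[!df$valid] <- NA_real_
  raster_plot(df, .data$z, "depth (mm)")
}

#' @rdname autoplot.depth_map
#' @method autoplot depth_recon
#' @export
autoplot.depth_recon <- function(object, ...) {
  autoplot(object$depth, ...)
}

#' @rdname autoplot.depth_map
#' @method autoplot depth_eval
#' @export
autoplot.depth_eval <- function(object, ...) {
  raster_plot(tidy(object), .data$error, "error (mm)")
}

#' @rdname autoplot.depth_map
#' @method autoplot ps_render
#' @export
autoplot.ps_render <- function(object, ...) {
  dfs <- purrr::imap(object$illuminance, function(m, k) {
    d <- tidy(depth_map(m, mask = is.finite(m)))
    d$source <- paste("light", object$active[k])
    d
  })
  df <- dplyr::bind_rows(dfs)
  raster_plot(df, .data$z, "illuminance") +
    ggplot2::facet_wrap(~source)
}
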