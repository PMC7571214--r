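#' End-to-end reconstruction pipeline
#'
#' Render (or take) a four-image stack, detect specular highlights, estimate
#' the centroid seed depth by energy minimisation, fast-march the full depth
#' map and, when ground truth is available, evaluate it.
#'
#' @param spec A [surface_spec()] (ignored when `stack` is supplied).
#' @param rig A [ps_rig()].
#' @param stack Optional pre-computed list of 4 image arrays (RGB or
#'   grayscale, linear); rendered from `spec` when `NULL`.
#' @param ground_truth Optional [depth_map()] for evaluation (taken from the
#'   render when available).
#' @param seed_depth Optional override of the seed depth in mm (e.g. a
#'   perturbed ground-truth depth); defaults to the estimated centroid
#'   depth.
#' @param response A [response_model()] applied to the stack images.
#' @param noise_sd,seed Renderer options, see [render_scene()].
#' @param detect_args,seed_args,march_args Lists of extra arguments for
#'   [detect_highlights_stack()], [estimate_seed_depth()] and
#'   [fast_march()].
#' @return A list of class `ps_pipeline` with elements `render`, `regions`,
#'   `selection`, `seeds`, `seed` (the boundary condition used),
#'   `reconstruction`, and `evaluation` (NULL without ground truth).
#' @examples
#' \donttest{
#' rig <- default_rig(f = 141, width = 160, height = 120)
#' res <- ps_pipeline(polyp_scene(shininess = 100), rig)
#' glance(res$evaluation)
#' }
#' @export
ps_pipeline <- function(spec = polyp_scene(), rig = default_rig(),
                        stack = NULL, ground_truth = NULL, seed_depth = NULL,
                        response = response_model("linear"),
                        noise_sd = 0, seed = NULL,
                        detect_args = list(), seed_args = list(),
                        march_args = list()) {
  render <- NULL
  if (is.null(stack)) {
    render <- render_scene(spec, rig, noise_sd = noise_sd, seed = seed)
    images <- render$images
    if (is.null(ground_truth)) ground_truth <- render$ground_truth
  } else {
    images <- stack
  }
  images <- lapply(images, to_illuminance, model = response)
  illum <- lapply(images, luminance)

  regions <- do.call(detect_highlights_stack, c(list(images), detect_args))
  selection <- select_seed_region(regions, n_lights = length(rig$lights))
  masks <- highlight_masks(regions, dim(illum[[1]]),
                           n_lights = length(rig$lights))

  seeds <- do.call(estimate_seed_depth,
                   c(list(illum, selection$sigma, rig, masks = masks),
                     seed_args))
  centroid <- seeds[seeds$is_centroid, ]
  if (nrow(centroid) == 0 || centroid$status[[1]] != "converged") {
    # centroid outside the mask or flagged: fall back to the converged pixel
    # closest to the centroid
    ok <- seeds[seeds$status == "converged", ]
    if (nrow(ok) == 0) stop("no usable seed estimate in the highlight region")
    centroid <- ok[order(ok$dist_centroid, ok$col, ok$row)[1], ]
  }
  used_depth <- seed_depth %||% centroid$z_hat[[1]]
  boundary <- list(col = centroid$col[[1]], row = centroid$row[[1]],
                   depth = used_depth)

  recon <- do.call(fast_march,
                   c(list(illum, rig, boundary$col, boundary$row,
                          boundary$depth, masks = masks), march_args))
  evaluation <- if (!is.null(ground_truth)) {
    evaluate_depth(recon, ground_truth)
  }
  structure(
    list(render = render, illuminance = illum, regions = regions,
         selection = selection, masks = masks, seeds = seeds,
         seed = boundary, reconstruction = recon, evaluation = evaluation,
         rig = rig),
    class = "ps_pipeline"
  )
}

#' @export
print.ps_pipeline <- function(x, ...) {
  cat(sprintf("<ps_pipeline> sigma source %d, seed (%d, %d) @ %.4f mm\n",
              x$selection$sigma_source, x$seed$col, x$seed$row, x$seed$depth))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
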