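# File interfaces: 8/16-bit PNG images (png package), float depth maps as
# TSV, and JSON manifests/configs.  Rendering and reconstruction are float
# end to end; quantisation to integer rasters happens only here.

#' Read or write an image as PNG
#'
#' Thin wrappers over the png package keeping this package's array layout
#' (`height x width[ x channels]`, linear values in \[0, 1\]).  The installed
#' png writer is 8-bit; [save_render()] therefore also stores exact float
#' channels as TSV so stacks round-trip losslessly.
#'
#' @param path File path.
#' @param img Matrix or 3-channel array with values in \[0, 1\].
#' @return `read_image_png()` returns a matrix or array; `write_image_png()`
#'   returns `path` invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' Write or read a float depth map as TSV
#'
#' Plain-text raster: one row per image row, tab-separated mm values,
#' `NA` where invalid.
#'
#' @param dm A [depth_map()] or bare matrix.
#' @param path File path.
#' @return `read_depth_tsv()` returns a [depth_map()]; the writer returns
#'   `path` invisibly.
#' @export
write_depth_tsv <- function(dm, path) {
  z <- if (inherits(dm, "depth_map")) {
    out <- dm$z
    out[!dm$mask] <- NA_real_
    out
  } else {
    dm
  }
  utils::write.table(z, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  z <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(z) <- NULL
  depth_map(z)
}

#' Save or load a rendered photometric-stereo stack
#'
#' Writes, per light, an 8-bit PNG preview and the exact float luminance as
#' TSV, plus the ground-truth depth map (TSV) and a JSON manifest recording
#' the scene, rig and the linear scale used for quantisation, so the float
#' illuminance is recovered exactly on load.
#'
#' @param render A `ps_render` from [render_scene()].
#' @param dir Output directory (created if missing).
#' @return `save_render()` returns `dir` invisibly; `load_render()` returns
#'   a list with `images` (linear float arrays), `illuminance`,
#'   `ground_truth` and `rig`.
#' @export
save_render <- function(render, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(vapply(render$images, max, numeric(1)))
  paths <- character(length(render$images))
  lum_paths <- character(length(render$images))
  for (k in seq_along(render$images)) {
    paths[k] <- file.path(dir, sprintf("image_%02d.png", render$active[k]))
    lum_paths[k] <- file.path(dir,
                              sprintf("illuminance_%02d.tsv", render$active[k]))
    write_image_png(render$images[[k]] / scale, paths[k])
    write_depth_tsv(luminance(render$images[[k]]), lum_paths[k])
  }
  write_depth_tsv(render$ground_truth, file.path(dir, "ground_truth.tsv"))
  write_rig(render$rig, file.path(dir, "rig.json"))
  spec <- render$spec
  manifest <- list(
    images = basename(paths), illuminance = basename(lum_paths),
    active = render$active, scale = scale,
    noise_sd = render$noise_sd,
    scene = list(kind = spec$kind, base_depth = spec$base_depth,
                 cap_radius = spec$cap_radius,
                 cap_center_px = spec$cap_center_px, albedo = spec$albedo,
                 k_d = spec$k_d, k_s = spec$k_s, shininess = spec$shininess)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_render
#' @export
load_render <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  images <- lapply(manifest$images, function(p) {
    read_image_png(file.path(dir, p)) * manifest$scale
  })
  illum <- lapply(manifest$illuminance, function(p) {
    read_depth_tsv(file.path(dir, p))$z
  })
  gt_path <- file.path(dir, "ground_truth.tsv")
  gt <- if (file.exists(gt_path)) read_depth_tsv(gt_path) else NULL
  rig <- read_rig(file.path(dir, "rig.json"))
  list(images = images, illuminance = illum,
       ground_truth = gt, rig = rig, active = manifest$active,
       manifest = manifest)
}
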