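#' Ordered colormap for ApEn topographies
#'
#' A fixed perceptually-ordered (dark blue to yellow) colormap.  A fixed map
#' over a fixed scale keeps images comparable across patients and
#' conditions; per-image autoscaling would destroy the class signal.
#'
#' @param n Number of colors.
#' @return n x 3 matrix of RGB values in \[0, 1\].
#' @export
apen_colormap <- function(n = 256) {
  anchors <- matrix(c(
    0.267, 0.005, 0.329,
    0.283, 0.141, 0.458,
    0.254, 0.265, 0.530,
    0.207, 0.372, 0.553,
    0.164, 0.471, 0.558,
    0.128, 0.567, 0.551,
    0.135, 0.659, 0.518,
    0.267, 0.749, 0.441,
    0.478, 0.821, 0.318,
    0.741, 0.873, 0.150,
    0.993, 0.906, 0.144), ncol = 3, byrow = TRUE)
  pos <- seq(0, 1, length.out = nrow(anchors))
  out <- seq(0, 1, length.out = n)
  cbind(approx(pos, anchors[, 1], out)$y,
        approx(pos, anchors[, 2], out)$y,
        approx(pos, anchors[, 3], out)$y)
}

# cache of per-(layout, size, method) interpolation operators: the TPS/IDW
# interpolant is linear in the node values, so the whole in-disk field is a
# single precomputed matrix times the 16 channel values
.topo_cache <- new.env(parent = emptyenv())

topo_operator <- function(layout, size, method) {
  key <- paste(method, size[1], size[2],
               paste(signif(c(layout$x, layout$y), 10), collapse = ","),
               sep = "|")
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  h <- size[1]; w <- size[2]
  R <- min(h, w) / 2 - 1
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  px <- (rep(seq_len(w), each = h) - cx) / R
  py <- (cy - rep(seq_len(h), times = w)) / R
  inside <- which(px^2 + py^2 <= 1)
  px <- px[inside]; py <- py[inside]
  if (method == "tps") {
    n <- nrow(layout)
    d <- sqrt(outer(layout$x, layout$x, "-")^2 +
                outer(layout$y, layout$y, "-")^2)
    K <- ifelse(d > 0, d^2 * log(d), 0)
    P <- cbind(1, layout$x, layout$y)
    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
    dg <- sqrt(outer(px, layout$x, "-")^2 + outer(py, layout$y, "-")^2)
    U <- ifelse(dg > 0, dg^2 * log(dg), 0)
    B <- cbind(U, 1, px, py) %*% solve(A)[, seq_len(n), drop = FALSE]
  } else {
    d2 <- outer(px, layout$x, "-")^2 + outer(py, layout$y, "-")^2
    wgt <- 1 / (d2 + 1e-12)
    B <- wgt / rowSums(wgt)
  }
  # pixel (row, col) nearest each electrode, snapped to the exact value
  erow <- pmin(pmax(round(cy - layout$y * R), 1), h)
  ecol <- pmin(pmax(round(layout$x * R + cx), 1), w)
  op <- list(inside = inside, B = B, epix = (ecol - 1) * h + erow)
  .topo_cache[[key]] <- op
  op
}

# thin-plate spline fit/evaluation on scattered 2-D nodes; exact at nodes
tps_fit <- function(x, y, v) {
  n <- length(x)
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  K <- ifelse(d > 0, d^2 * log(d), 0)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(v, rep(0, 3)))
  list(x = x, y = y, w = sol[1:n], a = sol[n + 1:3])
}

tps_eval <- function(fit, px, py) {
  d <- sqrt(outer(px, fit$x, "-")^2 + outer(py, fit$y, "-")^2)
  U <- ifelse(d > 0, d^2 * log(d), 0)
  as.numeric(U %*% fit$w + fit$a[1] + fit$a[2] * px + fit$a[3] * py)
}

idw_eval <- function(x, y, v, px, py, power = 2) {
  d2 <- outer(px, x, "-")^2 + outer(py, y, "-")^2
  w <- 1 / (d2 + 1e-12)^(power / 2)
  as.numeric((w %*% v) / rowSums(w))
}

#' Render one ApEn frame as a head-disk topography
#'
#' Scattered interpolation of the 16 channel values over the unit head disk
#' (thin-plate spline by default, inverse-distance weighting as an option),
#' colored with the fixed [apen_colormap()] over `scale`.  The interpolant
#' is exact at the electrode positions; the pixel nearest each electrode is
#' additionally snapped to the exact channel value.  Out-of-disk pixels are
#' background.  Values outside `scale` are clipped with a warning.
#'
#' @param frame An `apen_frame` (named 16-vector) or named numeric vector.
#' @param layout Electrode layout from [project_montage()].
#' @param scale `c(lo, hi)` ApEn color scale (fixed across images).
#' @param size `c(height, width)` of the raster in pixels.
#' @param method `"tps"` or `"idw"`.
#' @param background Background RGB.
#' @return `height x width x 3` array in \[0, 1\].
#' @export
render_topomap <- function(frame, layout = project_montage(),
                           scale = c(0, 1.2), size = c(128, 102),
                           method = c("tps", "idw"),
                           background = c(1, 1, 1)) {
  method <- match.arg(method)
  if (scale[1] >= scale[2]) stop("scale must satisfy lo < hi")
  v <- as.numeric(frame)[match(layout$label, names(frame))]
  if (any(is.na(v))) stop("frame is missing channels present in the layout")
  if (any(v < scale[1] | v > scale[2])) {
    warning("frame values outside the color scale were clipped")
    v <- pmin(pmax(v, scale[1]), scale[2])
  }
  h <- size[1]; w <- size[2]
  op <- topo_operator(layout, size, method)
  field <- rep(NA_real_, h * w)
  field[op$inside] <- op$B %*% v
  # snap the pixel nearest each electrode to the exact channel value
  field[op$epix] <- v
  field <- pmin(pmax(field, scale[1]), scale[2])

  cmap <- apen_colormap()
  idx <- round((field - scale[1]) / (scale[2] - scale[1]) *
                 (nrow(cmap) - 1)) + 1
  img <- array(rep(background, each = h * w), dim = c(h, w, 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ok] <- cmap[idx[ok], ch]
    img[, , ch] <- plane
  }
  img
}

#' Decode the ApEn value at an electrode's pixel
#'
#' Inverts the fixed colormap at the raster pixel nearest the given
#' electrode; used to verify electrode-exactness of rendered maps.
#'
#' @param img Raster from [render_topomap()].
#' @param label Electrode label.
#' @param layout,scale As used for rendering.
#' @return Decoded ApEn value (quantized to the colormap resolution).
#' @export
decode_electrode_value <- function(img, label, layout = project_montage(),
                                   scale = c(0, 1.2)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  R <- min(h, w) / 2 - 1
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  i <- match(label, layout$label)
  if (is.na(i)) stop("unknown electrode label: ", label)
  r <- pmin(pmax(round(cy - layout$y[i] * R), 1), h)
  c_ <- pmin(pmax(round(layout$x[i] * R + cx), 1), w)
  rgb_ <- img[r, c_, ]
  cmap <- apen_colormap()
  idx <- which.min(colSums((t(cmap) - rgb_)^2))
  scale[1] + (idx - 1) / (nrow(cmap) - 1) * (scale[2] - scale[1])
}

#' Tile 20 topographies into one 512 x 512 image
#'
#' Deterministic 4-row x 5-column grid of 128 x 102 cells on a white
#' 512 x 512 canvas (one-pixel margins absorb the 510-pixel grid width).
#'
#' @param maps List of exactly 20 rasters of identical size
#'   (default 128 x 102 x 3).
#' @return 512 x 512 x 3 array.
#' @export
tile_images <- function(maps) {
  if (length(maps) != 20)
    stop("layout error: exactly 20 topographies per image, got ",
         length(maps))
  dims <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), dims), logical(1))))
    stop("layout error: all maps must share the same dimensions")
  ch <- dims[1]; cw <- dims[2]
  nrow_ <- 4L; ncol_ <- 5L
  H <- 512L; W <- 512L
  if (nrow_ * ch > H || ncol_ * cw > W)
    stop("layout error: cells do not fit the 512 x 512 canvas")
  r0 <- (H - nrow_ * ch) %/% 2
  c0 <- (W - ncol_ * cw) %/% 2
  out <- array(1, dim = c(H, W, 3))
  for (i in seq_along(maps)) {
    gr <- (i - 1) %/% ncol_
    gc <- (i - 1) %% ncol_
    rows <- (r0 + gr * ch + 1):(r0 + (gr + 1) * ch)
    cols <- (c0 + gc * cw + 1):(c0 + (gc + 1) * cw)
    out[rows, cols, ] <- maps[[i]]
  }
  out
}

#' Central crop of an image
#'
#' @param img `h x w x 3` array, both dimensions >= `out`.
#' @param out Output side length in pixels.
#' @return `out x out x 3` array, pixel-identical to the central source
#'   region.
#' @export
crop_center <- function(img, out = 256L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < out || w < out)
    stop(sprintf("dimension error: input %d x %d smaller than crop %d",
                 h, w, out))
  r0 <- (h - out) %/% 2
  c0 <- (w - out) %/% 2
  img[(r0 + 1):(r0 + out), (c0 + 1):(c0 + out), , drop = FALSE]
}

#' Downscale an image by block averaging
#'
#' Used by the reduced desk profile (e.g. 256 -> 64 with `factor = 4`).
#'
#' @param img `h x w x 3` array with both dimensions divisible by `factor`.
#' @param factor Integer reduction factor.
#' @return Downscaled array.
#' @export
downscale_image <- function(img, factor) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h %% factor != 0 || w %% factor != 0)
    stop("image dimensions must be divisible by the downscale factor")
  ho <- h %/% factor; wo <- w %/% factor
  out <- array(0, dim = c(ho, wo, 3))
  for (ch in 1:3) {
    m <- img[, , ch]
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = ho)
    m <- t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = wo))
    out[, , ch] <- m
  }
  out
}

#' Build the per-patient image set from ApEn frames
#'
#' Consumes 60 frames per condition in epoch order, 20 per image, giving 3
#' images per condition and 6 per patient (120 topographies).  If a
#' condition has fewer frames than needed (after artifact screening), the
#' last available frame is repeated to fill the tail and the repetition is
#' recorded in the image's provenance; fewer than 20 frames in a condition
#' is an error.
#'
#' @param frames_by_condition Named list (`resting`, `music`; either may be
#'   absent) of lists of `apen_frame` objects.
#' @param n_per_image Topographies per image.
#' @param images_per_condition Images built per condition.
#' @param layout,scale,size,method Rendering options, see
#'   [render_topomap()].
#' @param reduce How to bring the 512 x 512 tiling to 256 x 256: `"crop"`
#'   (central crop, the default -- discards outer tile regions) or
#'   `"resize"` (2x block averaging, preserving all 20 topographies).
#' @return List of `topo_image` objects: `raster` (256 x 256 x 3),
#'   `patient_id`, `condition`, `epochs` (source epoch indices, repeats
#'   visible), `padded`.
#' @export
images_per_patient <- function(frames_by_condition, n_per_image = 20L,
                               images_per_condition = 3L,
                               layout = project_montage(),
                               scale = c(0, 1.2), size = c(128, 102),
                               method = "tps",
                               reduce = c("crop", "resize")) {
  reduce <- match.arg(reduce)
  out <- list()
  for (cond in names(frames_by_condition)) {
    frames <- frames_by_condition[[cond]]
    need <- n_per_image * images_per_condition
    if (length(frames) < n_per_image)
      stop(sprintf(
        "insufficiency error: %d frames in condition '%s' (< %d needed)",
        length(frames), cond, n_per_image))
    padded <- length(frames) < need
    if (padded) {
      message(sprintf(
        "padding %s frames %d -> %d by repeating the last frame",
        cond, length(frames), need))
      frames <- c(frames, rep(frames[length(frames)],
                              need - length(frames)))
    }
    for (j in seq_len(images_per_condition)) {
      sel <- ((j - 1) * n_per_image + 1):(j * n_per_image)
      maps <- lapply(frames[sel], render_topomap, layout = layout,
                     scale = scale, size = size, method = method)
      tiled <- tile_images(maps)
      epochs <- vapply(frames[sel],
                       function(f) as.integer(attr(f, "epoch") %||% NA),
                       integer(1))
      reduced <- if (reduce == "crop") crop_center(tiled, 256L)
                 else downscale_image(tiled, 2L)
      out[[length(out) + 1]] <- structure(
        list(raster = reduced,
             patient_id = attr(frames[[1]], "patient_id"),
             condition = cond, epochs = epochs, padded = padded),
        class = "topo_image")
    }
  }
  out
}

#' Write a topo image as PNG with a JSON manifest
#'
#' @param img A `topo_image`.
#' @param path PNG output path; the manifest is written next to it with a
#'   `.json` extension.
#' @param scale Color scale recorded in the manifest.
#' @return Invisibly, `path`.
#' @export
save_topo_image <- function(img, path, scale = c(0, 1.2)) {
  png::writePNG(img$raster, path)
  manifest <- list(patient_id = img$patient_id, condition = img$condition,
                   epochs = img$epochs, padded = img$padded,
                   scale = scale, grid = c(4, 5),
                   size = dim(img$raster)[1:2])
  jsonlite::write_json(manifest, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}
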