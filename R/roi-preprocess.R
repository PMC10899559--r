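#' CT display windows
#'
#' A window specification maps the Hounsfield interval
#' `[level - width/2, level + width/2]` linearly onto `[0, 1]`. Two presets
#' are used throughout: the lung window (level -400 HU, width 1500 HU) for
#' lung lesions and the abdominal window (level 50 HU, width 350 HU) for all
#' other sites.
#'
#' @param level Window level (centre) in HU.
#' @param width Window width in HU; must be positive.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(level, width) {
  if (!is.numeric(level) || !is.numeric(width) || width <= 0) {
    abort("`width` must be a positive number.")
  }
  structure(list(level = level, width = width), class = "window_spec")
}

#' @rdname window_spec
#' @param site Anatomic site string (e.g. `"lung"`, `"liver"`).
#' @details `site_window()` assigns the lung window to lung lesions and the
#'   abdominal window to every other site.
#' @export
site_window <- function(site) {
  if (identical(tolower(site), "lung")) {
    window_spec(-400, 1500)
  } else {
    window_spec(50, 350)
  }
}

window_min <- function(spec) spec$level - spec$width / 2

#' Map HU values to the unit interval under a display window
#'
#' Linear map of `[level - width/2, level + width/2]` to `[0, 1]`, clipping
#' values outside the window. Monotone non-decreasing in HU.
#'
#' @param hu Numeric array of HU values (any shape).
#' @param spec A [window_spec()].
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
apply_window <- function(hu, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (any(!is.finite(hu))) abort("HU values must be finite.")
  out <- (hu - (spec$level - spec$width / 2)) / spec$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Expand a bounding box about its centre
#'
#' Boxes are `c(x, y, width, height)` in pixel units, 0-based, `(x, y)` the
#' top-left corner, half-open extents (`[x, x + width)`). The expanded box
#' keeps the centre and multiplies both sides by `factor`, then is clipped to
#' the image bounds (which may shift the centre at the image edge).
#'
#' @param box Numeric vector `c(x, y, width, height)`.
#' @param factor Linear expansion factor (default 1.5, one and a half times
#'   the annotated box).
#' @param image_bounds Optional `c(nx, ny)` image size for clipping.
#' @return Expanded (and possibly clipped) box `c(x, y, width, height)`.
#' @export
expand_box <- function(box, factor = 1.5, image_bounds = NULL) {
  box <- as.numeric(box)
  if (length(box) != 4 || box[3] <= 0 || box[4] <= 0) {
    abort("`box` must be c(x, y, width, height) with positive sides.")
  }
  cx <- box[1] + box[3] / 2
  cy <- box[2] + box[4] / 2
  w <- box[3] * factor
  h <- box[4] * factor
  x0 <- cx - w / 2
  y0 <- cy - h / 2
  x1 <- x0 + w
  y1 <- y0 + h
  if (!is.null(image_bounds)) {
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    x1 <- min(x1, image_bounds[1]); y1 <- min(y1, image_bounds[2])
  }
  c(x = x0, y = y0, width = x1 - x0, height = y1 - y0)
}

# Integer pixel extent of a (possibly fractional) half-open box on a grid of
# size n: 1-based inclusive indices.
box_px_range <- function(start, len, n) {
  i0 <- max(1L, as.integer(floor(start)) + 1L)
  i1 <- min(as.integer(n), as.integer(ceiling(start + len)))
  c(i0, i1)
}

crop_box <- function(slice, box) {
  xr <- box_px_range(box[1], box[3], nrow(slice))
  yr <- box_px_range(box[2], box[4], ncol(slice))
  slice[xr[1]:xr[2], yr[1]:yr[2], drop = FALSE]
}

#' Symmetrically pad a rectangular ROI to its minimum circumscribed square
#'
#' The output side is `max(nrow, ncol)`; padding is split equally between the
#' two sides of the short dimension, with the extra pixel (odd total padding)
#' going to the trailing side.
#'
#' @param roi Numeric matrix.
#' @param fill Pad value; defaults to `min(roi)`. When windowed later, the
#'   window minimum renders as air/dark and introduces no bright artifact.
#' @return A square matrix of side `max(dim(roi))`.
#' @export
pad_to_square <- function(roi, fill = min(roi)) {
  if (!is.matrix(roi) || length(roi) == 0) abort("`roi` must be a nonempty matrix.")
  n1 <- nrow(roi); n2 <- ncol(roi)
  side <- max(n1, n2)
  out <- matrix(fill, side, side)
  off1 <- (side - n1) %/% 2
  off2 <- (side - n2) %/% 2
  out[(off1 + 1):(off1 + n1), (off2 + 1):(off2 + n2)] <- roi
  out
}

resize_bilinear <- function(mat, out_size) {
  if (all(dim(mat) == out_size)) return(mat)
  as.matrix(EBImage::resize(EBImage::Image(mat), w = out_size, h = out_size))
}

#' Build the model-ready 3-channel patch for one annotated lesion
#'
#' Applies the four preprocessing steps to the annotated slice and its two
#' neighbours: (1) extract 1.5-fold the annotated bounding box; (2) pad the
#' rectangular ROI symmetrically to its minimum circumscribed square and
#' resample to `out_size` x `out_size`; (3) window the HU values with the
#' site-appropriate display window (lung window for lung lesions, abdominal
#' window otherwise); (4) stack slices `slice_index - 1`, `slice_index`,
#' `slice_index + 1` as three channels. At a volume boundary the missing
#' neighbour is replaced by the central slice.
#'
#' @param volume 3-D HU array indexed `[x, y, slice]`.
#' @param annotation One-row data frame (or list) with `lesion_id`, `site`,
#'   `timepoint`, `slice_index` (1-based) and box fields `x`, `y`, `width`,
#'   `height` (0-based pixel units, see [expand_box()]).
#' @param out_size Output side in pixels (default 224).
#' @param expand Box expansion factor fed to [expand_box()].
#' @return An `image_patch`: list with `array` (`out_size x out_size x 3`,
#'   values in `[0, 1]`), `lesion_id`, `timepoint`, `site`.
#' @export
build_patch <- function(volume, annotation, out_size = 224, expand = 1.5) {
  stopifnot(length(dim(volume)) == 3)
  ann <- as.list(annotation)
  s <- as.integer(ann$slice_index)
  nz <- dim(volume)[3]
  if (s < 1 || s > nz) abort("annotation slice_index outside volume.")
  spec <- site_window(ann$site)
  box <- expand_box(c(ann$x, ann$y, ann$width, ann$height),
                    factor = expand, image_bounds = dim(volume)[1:2])
  slices <- c(s - 1L, s, s + 1L)
  slices[slices < 1L | slices > nz] <- s
  arr <- array(0, c(out_size, out_size, 3))
  for (k in 1:3) {
    roi <- crop_box(volume[, , slices[k]], box)
    sq <- pad_to_square(roi, fill = window_min(spec))
    arr[, , k] <- resize_bilinear(apply_window(sq, spec), out_size)
  }
  arr[arr < 0] <- 0; arr[arr > 1] <- 1
  structure(list(array = arr, lesion_id = ann$lesion_id,
                 timepoint = ann$timepoint, site = ann$site),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch> lesion %s, timepoint %s, site %s, %d x %d x %d\n",
              x$lesion_id, x$timepoint, x$site,
              dim(x$array)[1], dim(x$array)[2], dim(x$array)[3]))
  invisible(x)
}

# Bilinear rotation about the patch centre; out-of-frame pixels -> fill.
rotate_bilinear <- function(mat, angle_deg, fill) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  th <- angle_deg * pi / 180
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  g <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  # inverse mapping: rotate output coords by -theta into input space
  di <- g$i - c1; dj <- g$j - c2
  si <- cos(th) * di + sin(th) * dj + c1
  sj <- -sin(th) * di + cos(th) * dj + c2
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    v <- rep(fill, length(ii))
    v[ok] <- mat[cbind(ii[ok], jj[ok])]
    v
  }
  out <- (1 - fi) * (1 - fj) * val(i0, j0) +
    fi * (1 - fj) * val(i0 + 1, j0) +
    (1 - fi) * fj * val(i0, j0 + 1) +
    fi * fj * val(i0 + 1, j0 + 1)
  matrix(out, n1, n2)
}

#' Random rotation augmentation for training patches
#'
#' Rotates all three channels jointly by one angle drawn uniformly from
#' \[-30, 30\] degrees, with bilinear resampling; pixels rotated in from
#' outside the frame are filled with the patch minimum. Augmentation is a
#' training-time operation and refuses to run in validation mode.
#'
#' @param patch An `image_patch` (see [build_patch()]).
#' @param angle Optional fixed angle in degrees; by default drawn uniformly
#'   from `[-30, 30]` using the current RNG state.
#' @param training Must be `TRUE`; calling with `FALSE` is an error.
#' @return The rotated `image_patch` (same shape).
#' @export
augment_rotation <- function(patch, angle = NULL, training = TRUE) {
  stopifnot(inherits(patch, "image_patch"))
  if (!isTRUE(training)) abort("augment_rotation() is a training-time operation.")
  if (is.null(angle)) angle <- runif(1, -30, 30)
  fill <- min(patch$array)
  for (k in seq_len(dim(patch$array)[3])) {
    patch$array[, , k] <- rotate_bilinear(patch$array[, , k], angle, fill)
  }
  patch
}
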