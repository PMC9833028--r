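# Synthetic chip renderer and ROI intensity pipeline.
#
# The camera view is modelled as an 8-bit RGB array under uniform
# transillumination. A developed droplet attenuates the blue channel in
# Beer-Lambert fashion, 255-scale background * 10^(-OD * gain); the
# whitish superhydrophobic coating scatters slightly so coated regions sit
# a little below the clear observation windows. Readings are plain
# per-channel means over a region of interest (ROI); the quantity carried
# forward is the inverse blue intensity 255 - mean(B).

#' Construct an image frame
#'
#' @param pixels height x width x 3 integer array, values 0-255 (R, G, B).
#' @param time_s Acquisition time in seconds (metadata).
#' @param rois Optional named list of [circle_roi()] objects.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, time_s = NA_real_, rois = list()) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, time_s = as.numeric(time_s),
                 rois = rois),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_frame> %d x %d px, t = %s s, %d ROI(s)\n",
              d[2], d[1], format(x$time_s), length(x$rois)))
  invisible(x)
}

#' Circular region of interest
#'
#' @param cx,cy Center in pixel coordinates (column, row).
#' @param radius Radius in pixels (> 0).
#' @param unit,well Optional labels tying the ROI to a chip location.
#' @return An object of class `roi`.
#' @export
circle_roi <- function(cx, cy, radius, unit = NA, well = NA) {
  stopifnot(radius > 0)
  structure(list(shape = "circle", cx = cx, cy = cy, radius = radius,
                 unit = unit, well = well),
            class = "roi")
}

# linear indices of a frame matrix covered by the ROI
roi_pixel_indices <- function(roi, height, width) {
  if (!inherits(roi, "roi")) stop("not an roi object")
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rows <- matrix(seq_len(height), height, width)
  inside <- (cols - roi$cx)^2 + (rows - roi$cy)^2 <= roi$radius^2
  which(inside)
}

#' ROI for a well of a layout, in rendered-frame pixels
#'
#' @param layout A [chip_layout()].
#' @param unit Unit index.
#' @param well Well id.
#' @param px_per_mm Render scale used by [render_chip()].
#' @param radius_frac ROI radius as a fraction of the well radius; kept
#'   below 1 so the ROI sits inside the droplet.
#' @return A [circle_roi()].
#' @export
well_roi <- function(layout, unit, well, px_per_mm = 2,
                     radius_frac = 0.6) {
  u <- layout$units[[unit]]
  w <- unit_well(u, well)
  if (is.null(w)) stop("unknown well ", well, " in unit ", unit)
  ctr <- well_center_global(u, well) * px_per_mm
  circle_roi(ctr[1], ctr[2], radius_frac * w$diameter_mm / 2 * px_per_mm,
             unit = unit, well = well)
}

#' Render a chip image
#'
#' Draws the chip under uniform transillumination: coated background at
#' `level * coating_factor`, clear observation windows at `level`, wells as
#' faint rings, and each droplet as a disc whose blue channel is attenuated
#' by its optical density (`level * 10^(-od * gain)`); red and green stay
#' at the illumination level, so developed droplets render yellow.
#' Optional Gaussian sensor noise is applied to all channels and the frame
#' is quantized to 8 bits. Deterministic for a given seed.
#'
#' @param state A [chip_state()], or a data frame with columns `unit`,
#'   `well`, `od`, `volume_ul` describing the droplets to draw.
#' @param layout A [chip_layout()].
#' @param illumination List overriding defaults: `level` (background, 235),
#'   `gain` (OD gain, 1), `noise_sd` (sensor noise, 0),
#'   `coating_factor` (0.96).
#' @param seed RNG seed for sensor noise.
#' @param px_per_mm Render scale (pixels per mm).
#' @return An [image_frame()] with one ROI per drawn droplet, named
#'   `"u<unit>w<well>"`.
#' @export
render_chip <- function(state, layout, illumination = list(), seed = 1,
                        px_per_mm = 2) {
  il <- utils::modifyList(
    list(level = 235, gain = 1, noise_sd = 0, coating_factor = 0.96),
    illumination)
  droplets <- if (inherits(state, "chip_state")) {
    do.call(rbind, lapply(seq_along(state$units), function(i) {
      u <- state$units[[i]]
      if (!length(u$droplets)) return(NULL)
      data.frame(unit = i,
                 well = as.integer(names(u$droplets)),
                 od = vapply(u$droplets, function(d) d$od, numeric(1)),
                 volume_ul = vapply(u$droplets, function(d) d$volume_ul,
                                    numeric(1)),
                 row.names = NULL)
    }))
  } else {
    as.data.frame(state)
  }
  width <- ceiling(layout$footprint[1] * px_per_mm)
  height <- ceiling(layout$footprint[2] * px_per_mm)
  base <- matrix(il$level * il$coating_factor, height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rows <- matrix(seq_len(height), height, width)
  r <- base; g <- base; b <- base
  for (u in layout$units) {
    for (w in u$wells) {
      ctr <- well_center_global(u, w$id) * px_per_mm
      rad <- w$diameter_mm / 2 * px_per_mm
      d2 <- (cols - ctr[1])^2 + (rows - ctr[2])^2
      if (w$observation_window) {
        win <- d2 <= (rad * 1.2)^2
        r[win] <- il$level; g[win] <- il$level; b[win] <- il$level
      }
      rim <- d2 <= rad^2 & d2 >= (rad - 1)^2
      r[rim] <- r[rim] * 0.9; g[rim] <- g[rim] * 0.9; b[rim] <- b[rim] * 0.9
    }
  }
  if (!is.null(droplets) && nrow(droplets)) {
    for (k in seq_len(nrow(droplets))) {
      u <- layout$units[[droplets$unit[k]]]
      ctr <- well_center_global(u, droplets$well[k]) * px_per_mm
      dia <- droplet_footprint_diameter(droplets$volume_ul[k])
      rad <- max(2, dia / 2 * px_per_mm)
      disc <- (cols - ctr[1])^2 + (rows - ctr[2])^2 <= rad^2
      lvl <- if (unit_well(u, droplets$well[k])$observation_window) {
        il$level
      } else {
        il$level * il$coating_factor
      }
      r[disc] <- lvl
      g[disc] <- lvl
      b[disc] <- lvl * 10^(-droplets$od[k] * il$gain)
    }
  }
  px <- array(0, dim = c(height, width, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  if (il$noise_sd > 0) {
    set.seed(seed)
    px <- px + stats::rnorm(length(px), 0, il$noise_sd)
  }
  px <- pmin(pmax(round(px), 0), 255)  # pmin/pmax keep dims of 1st arg
  rois <- list()
  if (!is.null(droplets) && nrow(droplets)) {
    for (k in seq_len(nrow(droplets))) {
      rois[[sprintf("u%dw%d", droplets$unit[k], droplets$well[k])]] <-
        well_roi(layout, droplets$unit[k], droplets$well[k], px_per_mm)
    }
  }
  image_frame(px, rois = rois)
}

#' Read droplet channel means from an ROI
#'
#' Arithmetic means of the R, G and B channels over the ROI pixels, plus
#' the inverse blue intensity `255 - mean(B)`.
#'
#' @param frame An [image_frame()].
#' @param roi A [circle_roi()] (or the name of an ROI stored in the frame).
#' @return A one-row data frame: `unit`, `well`, `mean_r`, `mean_g`,
#'   `mean_b`, `inv_b`, `n_px`.
#' @export
droplet_reading <- function(frame, roi) {
  if (is.character(roi)) {
    if (is.null(frame$rois[[roi]])) stop("frame has no ROI named ", roi)
    roi <- frame$rois[[roi]]
  }
  d <- dim(frame$pixels)
  idx <- roi_pixel_indices(roi, d[1], d[2])
  if (!length(idx)) stop("ROI covers no pixels")
  plane <- d[1] * d[2]
  mr <- mean(frame$pixels[idx])
  mg <- mean(frame$pixels[idx + plane])
  mb <- mean(frame$pixels[idx + 2 * plane])
  data.frame(unit = roi$unit, well = roi$well,
             mean_r = mr, mean_g = mg, mean_b = mb,
             inv_b = 255 - mb, n_px = length(idx))
}

#' Mixing curve from an image sequence
#'
#' Computes the blue-channel mixing index of every frame's ROI and rescales
#' it to homogeneity against two reference frames: an unmixed droplet
#' (M_i) and a fully mixed droplet (M_f).
#'
#' @param frames List of [image_frame()] objects (>= 1) with `time_s` set.
#' @param roi A [circle_roi()] applied to every frame.
#' @param mi_frame Reference frame of the unmixed droplet.
#' @param mf_frame Reference frame of the fully mixed droplet.
#' @return A data frame with columns `time_s`, `m_c`, `h`, carrying the
#'   reference indices as attributes `m_i` and `m_f`.
#' @export
mixing_curve_from_images <- function(frames, roi, mi_frame, mf_frame) {
  if (!length(frames)) stop("no frames supplied")
  roi_blue <- function(frame) {
    d <- dim(frame$pixels)
    idx <- roi_pixel_indices(roi, d[1], d[2])
    frame$pixels[idx + 2 * d[1] * d[2]]
  }
  m_i <- mixing_index(roi_blue(mi_frame))
  m_f <- mixing_index(roi_blue(mf_frame))
  if (m_i == m_f) stop("degenerate references: M_i equals M_f")
  m_c <- vapply(frames, function(f) mixing_index(roi_blue(f)), numeric(1))
  out <- data.frame(
    time_s = vapply(frames, function(f) f$time_s, numeric(1)),
    m_c = m_c,
    h = vapply(m_c, homogeneity, numeric(1), m_i = m_i, m_f = m_f))
  attr(out, "m_i") <- m_i
  attr(out, "m_f") <- m_f
  out
}

#' PNG input/output for image frames
#'
#' @param frame An [image_frame()].
#' @param path File path.
#' @param time_s Acquisition time to attach when reading.
#' @return `write_frame_png()` returns `path` invisibly;
#'   `read_frame_png()` returns an [image_frame()].
#' @name frame_io
NULL

#' @rdname frame_io
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame$pixels / 255, path)
  invisible(path)
}

#' @rdname frame_io
#' @export
read_frame_png <- function(path, time_s = NA_real_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) {
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  }
  image_frame(round(px[, , 1:3] * 255), time_s = time_s)
}
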