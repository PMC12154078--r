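# Scratch-assay wound-width detection (texture energy + Otsu + morphology,
# orientation-independent) and migration-rate summaries.

#' Detect the wound band in a scratch-assay image
#'
#' Stages: (1) band-pass texture energy — difference of Gaussians, absolute
#' response, local smoothing — so textured cell regions score high regardless
#' of mean intensity; (2) Otsu threshold on the energy gives a cell mask;
#' (3) morphological closing then opening (disk) bridges sparse cell texture
#' and removes debris; (4) the wound axis is the principal axis of the largest
#' background component; (5) the mask is rotated so the wound is vertical and
#' the per-row width is the widest background run; the summary width is the
#' median over rows (robust to boundary spurs).
#'
#' @param image single-channel numeric matrix containing one wound band.
#' @param pixel_size micrometres per pixel.
#' @param dog_sigma `c(low, high)` Gaussian sigmas of the band-pass (px).
#' @param smooth_sigma sigma of the local energy smoothing (px).
#' @param close_radius disk radius (px) of the closing that bridges sparse
#'   cell texture.
#' @param open_radius disk radius (px) of the opening that removes debris; a
#'   small radius avoids deepening boundary bays left by missing cells.
#' @param min_span minimum fraction of the image the background band must span
#'   along its axis for a wound to be declared.
#' @return object of class `wound_frame`: `width_um`, `width_px`, `angle_deg`
#'   (wound axis), `per_row_px`, `mask` (logical cell mask), `pixel_size`.
#' @export
detect_wound <- function(image, pixel_size = 1, dog_sigma = c(0.8, 2),
                         smooth_sigma = 2, close_radius = 6, open_radius = 2,
                         min_span = 0.8) {
  stop_if_not(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  img <- rescale01(image)
  g1 <- as.matrix(EBImage::gblur(img, sigma = dog_sigma[1]))
  g2 <- as.matrix(EBImage::gblur(img, sigma = dog_sigma[2]))
  energy <- as.matrix(EBImage::gblur(abs(g1 - g2), sigma = smooth_sigma))
  energy <- rescale01(energy)
  thr <- EBImage::otsu(energy, range = c(0, 1))
  cellmask <- energy > thr
  cellmask <- EBImage::closing(cellmask,
                               EBImage::makeBrush(2 * close_radius + 1, "disc"))
  cellmask <- EBImage::opening(cellmask,
                               EBImage::makeBrush(2 * open_radius + 1, "disc")) > 0
  if (mean(cellmask) < 0.05) stop("no wound detected", call. = FALSE)
  bg <- !cellmask
  lab <- EBImage::bwlabel(bg * 1)
  if (max(lab) == 0) stop("no wound detected", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  pix <- which(lab == big, arr.ind = TRUE)
  if (nrow(pix) < 0.02 * length(image)) stop("no wound detected", call. = FALSE)
  # principal axis of the background band
  ctr <- colMeans(pix)
  cv <- stats::cov(pix)
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]  # (row, col) direction of greatest extent
  angle <- atan2(v[1], v[2])  # from the x (column) axis
  # span of the band along its axis must cover most of the image
  proj <- pix[, 2] * cos(angle) + pix[, 1] * sin(angle)
  if (diff(range(proj)) < min_span * min(dim(image)))
    stop("no wound detected", call. = FALSE)
  # rotate so the wound axis becomes vertical (columns constant along band)
  rot_deg <- (angle * 180 / pi) - 90
  rmask <- EBImage::rotate(cellmask * 1, rot_deg, bg.col = 1) > 0.5
  rband <- EBImage::rotate((lab == big) * 1, rot_deg, bg.col = 0) > 0.5
  rows_stats <- t(apply(rmask, 1, function(rr) {
    z <- rle(!rr)
    if (!any(z$values)) return(c(0L, 0L))
    ends <- cumsum(z$lengths)
    starts <- ends - z$lengths + 1L
    gaps <- which(z$values)
    wmax <- which.max(z$lengths[gaps])
    c(z$lengths[gaps][wmax], starts[gaps][wmax])
  }))
  widths <- rows_stats[, 1]
  # the wound must be a coherent band: most rows carry a gap whose position
  # overlaps the rotated background component
  band_rows <- vapply(seq_len(nrow(rmask)), function(i) {
    w <- widths[i]
    if (w == 0L) return(FALSE)
    s <- rows_stats[i, 2]
    any(rband[i, s:(s + w - 1L)])
  }, logical(1))
  if (mean(band_rows) < 0.8) stop("no wound detected", call. = FALSE)
  widths <- widths[band_rows & widths > 0]
  if (length(widths) == 0L) stop("no wound detected", call. = FALSE)
  width_px <- stats::median(widths)
  structure(list(width_um = width_px * pixel_size, width_px = width_px,
                 angle_deg = (angle * 180 / pi) %% 180, per_row_px = widths,
                 mask = cellmask, pixel_size = pixel_size),
            class = "wound_frame")
}

#' @export
print.wound_frame <- function(x, ...) {
  cat(sprintf("wound: width %.1f um (%.1f px, median of %d rows), axis %.1f deg\n",
              x$width_um, x$width_px, length(x$per_row_px), x$angle_deg))
  invisible(x)
}

#' Migration rate from wound widths
#'
#' `rate = (width_t0 - width_t) / elapsed_h` in um/h (total gap closure per
#' unit time). Negative rates (wound widening) are permitted and flagged.
#'
#' @param width_t0,width_t wound widths in micrometres at baseline and at the
#'   later time point.
#' @param elapsed_h elapsed time in hours (> 0).
#' @return list with `rate_um_h` and logical `widened`.
#' @export
migration_rate <- function(width_t0, width_t, elapsed_h) {
  stop_if_not(elapsed_h > 0, "elapsed_h must be > 0")
  rate <- (width_t0 - width_t) / elapsed_h
  list(rate_um_h = rate, widened = rate < 0)
}

#' Normalize migration rates to the control condition
#'
#' @param rates numeric vector of rates in um/h, one per condition.
#' @param conditions condition labels matching `rates`.
#' @param control name of the control condition (must have rate > 0).
#' @return data.frame of class `wound_series`: condition, rate and
#'   `normalized_rate` (control maps to 1 by construction).
#' @export
normalize_rates <- function(rates, conditions, control = "control") {
  stop_if_not(length(rates) == length(conditions), "rates/conditions length mismatch")
  stop_if_not(control %in% conditions, "control condition missing")
  cr <- rates[match(control, conditions)]
  if (cr <= 0) stop("control rate must be > 0", call. = FALSE)
  out <- data.frame(condition = conditions, rate_um_h = rates,
                    normalized_rate = rates / cr)
  class(out) <- c("wound_series", class(out))
  out
}
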