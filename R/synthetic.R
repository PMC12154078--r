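# Synthetic-data generators. Every generator emits its ground truth alongside
# the generated object, so each pipeline stage can be tested against known
# values without any external recordings.

#' Specification of a synthetic fiber field
#'
#' Describes a phalloidin-like image of straight actin filaments over an uneven
#' background: a set of anti-aliased line segments with Gaussian cross-profile,
#' a linear background gradient, and additive Gaussian noise. The generator's
#' signal-to-noise ratio is `fiber_intensity / noise_sd`.
#'
#' @param image_size side of the square image in pixels.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param n_fibers number of filaments to draw (>= 0).
#' @param length_dist `c(mean, sd)` of filament length in micrometres.
#' @param orientation_mode modal orientation in radians, in \[0, pi).
#' @param orientation_concentration axial von Mises concentration kappa >= 0;
#'   0 is isotropic, large values give parallel filaments.
#' @param fiber_intensity peak filament intensity (arbitrary units).
#' @param background `c(offset, slope)`: constant offset plus a linear gradient
#'   of total amplitude `slope` across the field (models uneven illumination).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param min_gap minimum distance in pixels kept between filament centerlines
#'   (filaments are placed without overlap).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return object of class `fiber_field_spec`.
#' @export
fiber_field_spec <- function(image_size = 256, pixel_size = 0.25, n_fibers = 12,
                             length_dist = c(18, 4), orientation_mode = pi / 3,
                             orientation_concentration = 3, fiber_intensity = 1,
                             background = c(0.08, 0.05), noise_sd = 0.2,
                             min_gap = 8, seed = 1L) {
  stop_if_not(n_fibers >= 0, "n_fibers must be >= 0")
  stop_if_not(orientation_concentration >= 0, "kappa must be >= 0")
  stop_if_not(pixel_size > 0, "pixel_size must be > 0")
  stop_if_not(length(length_dist) == 2 && length_dist[1] > 0 && length_dist[2] >= 0,
              "length_dist must be c(mean > 0, sd >= 0)")
  diag_um <- sqrt(2) * image_size * pixel_size
  if (length_dist[1] > diag_um)
    stop("mean fiber length exceeds the image diagonal (", round(diag_um, 1), " um)",
         call. = FALSE)
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 n_fibers = as.integer(n_fibers), length_dist = length_dist,
                 orientation_mode = orientation_mode %% pi,
                 orientation_concentration = orientation_concentration,
                 fiber_intensity = fiber_intensity, background = background,
                 noise_sd = noise_sd, min_gap = min_gap, seed = as.integer(seed)),
            class = "fiber_field_spec")
}

# stamp an anti-aliased segment (Gaussian cross-profile, sd ~0.7 px) into img
draw_segment <- function(img, x0, y0, x1, y1, intensity, profile_sd = 0.7) {
  n <- nrow(img)
  rmin <- max(1L, floor(min(y0, y1) - 3)); rmax <- min(n, ceiling(max(y0, y1) + 3))
  cmin <- max(1L, floor(min(x0, x1) - 3)); cmax <- min(n, ceiling(max(x0, x1) + 3))
  rows <- rmin:rmax; cols <- cmin:cmax
  yy <- matrix(rows, length(rows), length(cols))
  xx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  tt <- pmin(1, pmax(0, ((xx - x0) * vx + (yy - y0) * vy) / len2))
  d2 <- (xx - (x0 + tt * vx))^2 + (yy - (y0 + tt * vy))^2
  img[rows, cols] <- img[rows, cols] + intensity * exp(-d2 / (2 * profile_sd^2)) * (d2 <= 9)
  img
}

#' Generate a synthetic fiber-field image with ground truth
#'
#' Draws `n_fibers` non-overlapping anti-aliased line segments over a graded
#' background with additive Gaussian noise. Orientations are drawn from an
#' axial von Mises distribution ([raxial_vonmises()]); lengths from a truncated
#' normal. The returned truth record lists every filament's orientation,
#' length, and centerline pixels, plus the polarity of the orientation set.
#'
#' @param spec a [fiber_field_spec()].
#' @return list with `image` (numeric matrix), `truth` (list: `fibers`
#'   data.frame with `orientation`, `length_um`, `length_px`; `centerlines`
#'   list of pixel coordinate matrices; `polarity`), and `spec`.
#' @export
gen_fiber_image <- function(spec) {
  stop_if_not(inherits(spec, "fiber_field_spec"), "spec must be a fiber_field_spec")
  set.seed(spec$seed)
  n <- spec$image_size
  xnorm <- matrix(seq(0, 1, length.out = n), n, n, byrow = TRUE)
  img <- spec$background[1] + spec$background[2] * xnorm
  diag_px <- sqrt(2) * n
  occupied <- matrix(FALSE, n, n)
  ori <- len_um <- numeric(0)
  centerlines <- list()
  if (spec$n_fibers > 0) {
    ori <- raxial_vonmises(spec$n_fibers, spec$orientation_mode,
                           spec$orientation_concentration)
    for (i in seq_len(spec$n_fibers)) {
      placed <- FALSE
      for (try in 1:300) {
        l_um <- stats::rnorm(1, spec$length_dist[1], spec$length_dist[2])
        if (l_um < 2 * spec$pixel_size) next
        l_px <- l_um / spec$pixel_size
        if (l_px > diag_px) next
        dx <- l_px / 2 * cos(ori[i]); dy <- l_px / 2 * sin(ori[i])
        lo_x <- 3 + abs(dx); hi_x <- n - 2 - abs(dx)
        lo_y <- 3 + abs(dy); hi_y <- n - 2 - abs(dy)
        if (lo_x >= hi_x || lo_y >= hi_y) next
        cx <- stats::runif(1, lo_x, hi_x); cy <- stats::runif(1, lo_y, hi_y)
        ts <- seq(-l_px / 2, l_px / 2, by = 0.5)
        px <- round(cx + ts * cos(ori[i])); py <- round(cy + ts * sin(ori[i]))
        keep <- !duplicated(cbind(py, px))
        py <- py[keep]; px <- px[keep]
        if (any(occupied[cbind(py, px)])) next
        img <- draw_segment(img, cx - dx, cy - dy, cx + dx, cy + dy, spec$fiber_intensity)
        # block a min_gap-radius neighborhood around the new centerline
        g <- ceiling(spec$min_gap)
        for (k in seq_along(px)) {
          rr <- max(1, py[k] - g):min(n, py[k] + g)
          cc <- max(1, px[k] - g):min(n, px[k] + g)
          occupied[rr, cc] <- TRUE
        }
        len_um[i] <- l_um
        centerlines[[i]] <- cbind(row = py, col = px)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place fiber ", i, " without overlap; reduce n_fibers or min_gap",
             call. = FALSE)
    }
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  truth <- list(
    fibers = data.frame(orientation = ori, length_um = len_um,
                        length_px = len_um / spec$pixel_size),
    centerlines = centerlines,
    polarity = if (length(ori)) orientation_polarity(ori)$polarity else NA_real_
  )
  list(image = img, truth = truth, spec = spec)
}

#' Specification of a synthetic calcium transient
#'
#' A triangular (piecewise-linear) Fura-2 ratio transient: flat baseline until
#' `stimulus_time + latency`, linear rise over `rise_time` to
#' `baseline + amplitude`, then linear fall over `fall_time` back to baseline.
#' Every shape parameter therefore has a closed-form ground truth.
#'
#' @param baseline resting I340/I380 ratio.
#' @param amplitude peak height above baseline (ratio units).
#' @param latency stimulus-to-onset delay in seconds.
#' @param rise_time onset-to-peak time `a` in seconds.
#' @param fall_time peak-to-return time `b` in seconds.
#' @param stimulus_time stimulus application time in seconds.
#' @param sampling_interval sampling step in seconds (must be < `rise_time`).
#' @param noise_sd additive Gaussian noise (ratio units).
#' @param total_duration record length in seconds; defaults to the transient
#'   end plus a 10 s tail.
#' @param seed integer seed.
#' @export
transient_spec <- function(baseline = 1, amplitude = 1, latency = 2,
                           rise_time = 2, fall_time = 6, stimulus_time = 30,
                           sampling_interval = 0.1, noise_sd = 0,
                           total_duration = NULL, seed = 1L) {
  for (f in c(latency, rise_time, fall_time, stimulus_time, sampling_interval))
    stop_if_not(f > 0, "all time fields must be > 0")
  stop_if_not(sampling_interval < rise_time, "sampling_interval must be < rise_time")
  total_duration <- total_duration %||% (stimulus_time + latency + rise_time + fall_time + 10)
  structure(list(baseline = baseline, amplitude = amplitude, latency = latency,
                 rise_time = rise_time, fall_time = fall_time,
                 stimulus_time = stimulus_time, sampling_interval = sampling_interval,
                 noise_sd = noise_sd, total_duration = total_duration,
                 seed = as.integer(seed)),
            class = "transient_spec")
}

#' Generate a synthetic calcium trace with known shape parameters
#'
#' @param spec a [transient_spec()].
#' @return a `calcium_trace` (see [calcium_trace()]) whose `truth` element
#'   holds the generating parameters: baseline, amplitude, latency, `a`, `b`,
#'   duration (`latency + a + b`, measured from the stimulus), area
#'   (`(a + b) * amplitude / 2`), rising velocity (`amplitude / a`) and
#'   asymmetry (`b / a`).
#' @export
gen_calcium_trace <- function(spec) {
  stop_if_not(inherits(spec, "transient_spec"), "spec must be a transient_spec")
  set.seed(spec$seed)
  tm <- seq(0, spec$total_duration, by = spec$sampling_interval)
  onset <- spec$stimulus_time + spec$latency
  peak <- onset + spec$rise_time
  ret <- peak + spec$fall_time
  r <- rep(spec$baseline, length(tm))
  rising <- tm > onset & tm <= peak
  r[rising] <- spec$baseline + spec$amplitude * (tm[rising] - onset) / spec$rise_time
  falling <- tm > peak & tm < ret
  r[falling] <- spec$baseline + spec$amplitude * (1 - (tm[falling] - peak) / spec$fall_time)
  if (spec$noise_sd > 0) r <- r + stats::rnorm(length(tm), 0, spec$noise_sd)
  tr <- calcium_trace(time = tm, ratio = r, stimulus_time = spec$stimulus_time)
  tr$truth <- list(baseline = spec$baseline, amplitude = spec$amplitude,
                   latency = spec$latency, a = spec$rise_time, b = spec$fall_time,
                   duration = spec$latency + spec$rise_time + spec$fall_time,
                   area = (spec$rise_time + spec$fall_time) * spec$amplitude / 2,
                   rising_velocity = spec$amplitude / spec$rise_time,
                   asymmetry = spec$fall_time / spec$rise_time)
  tr$spec <- spec
  tr
}

#' Specification of a synthetic wound (scratch) field
#'
#' Two speckle-textured cell regions separated by a low-intensity band of known
#' width at an arbitrary orientation; `cell_sparsity` removes random texture
#' patches to emulate sparse monolayers.
#'
#' @param image_size side of the square image in pixels.
#' @param gap_width wound width in pixels, measured perpendicular to the band.
#' @param gap_orientation wound axis angle in degrees (90 = vertical band).
#' @param texture_grain speckle grain size in pixels.
#' @param cell_sparsity fraction in \[0, 1) of cell-region texture removed in
#'   random patches.
#' @param intensity texture intensity (arbitrary units).
#' @param noise_sd additive Gaussian noise.
#' @param seed integer seed.
#' @export
wound_field_spec <- function(image_size = 256, gap_width = 100, gap_orientation = 90,
                             texture_grain = 3, cell_sparsity = 0, intensity = 1,
                             noise_sd = 0.05, seed = 1L) {
  stop_if_not(gap_width > 0 && gap_width < image_size,
              "gap_width must be in (0, image_size)")
  stop_if_not(cell_sparsity >= 0 && cell_sparsity < 1, "cell_sparsity must be in [0, 1)")
  structure(list(image_size = as.integer(image_size), gap_width = gap_width,
                 gap_orientation = gap_orientation, texture_grain = as.integer(texture_grain),
                 cell_sparsity = cell_sparsity, intensity = intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "wound_field_spec")
}

#' Generate a synthetic wound-field image with known gap width
#'
#' @param spec a [wound_field_spec()].
#' @return list with `image`, `truth` (`gap_width` in px, `orientation` in
#'   degrees), and `spec`.
#' @export
gen_wound_image <- function(spec) {
  stop_if_not(inherits(spec, "wound_field_spec"), "spec must be a wound_field_spec")
  set.seed(spec$seed)
  n <- spec$image_size
  g <- max(1L, spec$texture_grain)
  nc <- ceiling(n / g)
  coarse <- matrix(stats::runif(nc * nc) > 0.5, nc, nc)
  idx <- rep(seq_len(nc), each = g)[seq_len(n)]
  speckle <- coarse[idx, idx] * 1
  # signed perpendicular distance from the band axis through the image center
  phi <- spec$gap_orientation * pi / 180
  ctr <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- -(xx - ctr) * sin(phi) + (yy - ctr) * cos(phi)
  cell <- abs(d) > spec$gap_width / 2
  tex <- speckle * cell
  if (spec$cell_sparsity > 0) {
    target <- spec$cell_sparsity * sum(cell)
    removed <- 0
    while (removed < target) {
      r0 <- stats::runif(1, 1, n); c0 <- stats::runif(1, 1, n)
      rad <- stats::runif(1, 2 * g, 6 * g)
      rr <- max(1, floor(r0 - rad)):min(n, ceiling(r0 + rad))
      cc <- max(1, floor(c0 - rad)):min(n, ceiling(c0 + rad))
      sub_y <- matrix(rr, length(rr), length(cc))
      sub_x <- matrix(cc, length(rr), length(cc), byrow = TRUE)
      disk <- (sub_y - r0)^2 + (sub_x - c0)^2 <= rad^2
      patch_cells <- sum(cell[rr, cc][disk] & tex[rr, cc][disk] >= 0)
      tex[rr, cc][disk] <- 0
      removed <- removed + sum(cell[rr, cc][disk])
    }
  }
  img <- spec$intensity * tex
  if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  list(image = img,
       truth = list(gap_width = spec$gap_width, orientation = spec$gap_orientation),
       spec = spec)
}

#' Generate a synthetic plate table with known group effects
#'
#' Gaussian replicates per condition; the first condition is the control.
#'
#' @param group_means,group_sds equal-length numeric vectors (sds >= 0).
#' @param n_per_group replicates per condition (>= 2).
#' @param seed integer seed.
#' @param conditions optional condition labels; defaults to `names(group_means)`
#'   or `control`, `cond2`, ...
#' @param assay assay kind tag stored on the table.
#' @return an `assay_table` (data.frame: `condition`, `replicate`, `value`)
#'   with the generating means/sds attached as `attr(, "truth")`.
#' @export
gen_plate_table <- function(group_means, group_sds, n_per_group, seed = 1L,
                            conditions = NULL, assay = "generic") {
  stop_if_not(length(group_means) == length(group_sds),
              "group_means and group_sds must have equal length")
  stop_if_not(all(group_sds >= 0), "negative sd rejected")
  stop_if_not(n_per_group >= 2, "n_per_group must be >= 2")
  k <- length(group_means)
  conditions <- conditions %||% names(group_means) %||%
    c("control", if (k > 1) paste0("cond", 2:k))
  set.seed(seed)
  df <- data.frame(
    condition = factor(rep(conditions, each = n_per_group), levels = conditions),
    replicate = rep(seq_len(n_per_group), times = k),
    value = unlist(lapply(seq_len(k), function(i)
      stats::rnorm(n_per_group, group_means[i], group_sds[i])))
  )
  tab <- assay_table(df, assay = assay)
  attr(tab, "truth") <- list(means = group_means, sds = group_sds)
  tab
}

#' Generate a synthetic nuclei raster with a uniform signal channel
#'
#' A simple disk raster of non-overlapping nuclei plus a spatially uniform
#' signal channel, used to test per-nucleus normalization of total
#' fluorescence.
#'
#' @param n_nuclei number of disks.
#' @param image_size side in pixels.
#' @param radius disk radius in pixels.
#' @param signal_per_pixel uniform signal intensity per pixel.
#' @param seed integer seed.
#' @return list with `nuclei` (binary matrix), `signal` (numeric matrix),
#'   `truth` (`n_nuclei`, `total_signal`).
#' @export
gen_nuclei_image <- function(n_nuclei = 10, image_size = 128, radius = 5,
                             signal_per_pixel = 1, seed = 1L) {
  stop_if_not(n_nuclei >= 1, "n_nuclei must be >= 1")
  set.seed(seed)
  n <- image_size
  nuc <- matrix(0, n, n)
  centers <- matrix(NA_real_, 0, 2)
  for (i in seq_len(n_nuclei)) {
    for (try in 1:500) {
      cx <- stats::runif(1, radius + 1, n - radius)
      cy <- stats::runif(1, radius + 1, n - radius)
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2 > (2 * radius + 2)^2)) {
        centers <- rbind(centers, c(cy, cx))
        break
      }
      if (try == 500) stop("could not place nuclei without overlap", call. = FALSE)
    }
    rr <- max(1, floor(centers[i, 1] - radius)):min(n, ceiling(centers[i, 1] + radius))
    cc <- max(1, floor(centers[i, 2] - radius)):min(n, ceiling(centers[i, 2] + radius))
    yy <- matrix(rr, length(rr), length(cc))
    xx <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    nuc[rr, cc][(yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <= radius^2] <- 1
  }
  signal <- matrix(signal_per_pixel, n, n)
  list(nuclei = nuc, signal = signal,
       truth = list(n_nuclei = n_nuclei, total_signal = signal_per_pixel * n * n))
}
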