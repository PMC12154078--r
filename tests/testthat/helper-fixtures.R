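# shared fixtures, all built in code

# a single anti-aliased line of given length/angle centered in a dark field
make_line_image <- function(angle_deg = 18, len_px = 30, size = 96,
                            intensity = 1) {
  img <- matrix(0, size, size)
  th <- angle_deg * pi / 180
  ctr <- (size + 1) / 2
  dx <- len_px / 2 * cos(th); dy <- len_px / 2 * sin(th)
  endoquant:::draw_segment(img, ctr - dx, ctr - dy, ctr + dx, ctr + dy, intensity)
}

# construct a fiber_map directly with given per-pixel orientations
make_fiber_map <- function(orientations, size = 32) {
  mask <- matrix(FALSE, size, size)
  ori <- matrix(NA_real_, size, size)
  idx <- seq_along(orientations)
  mask[idx] <- TRUE
  ori[idx] <- orientations
  structure(list(fiber_index = ifelse(mask, 1, 0), orientation = ori,
                 mask = mask, params = fiberscore_params(),
                 bank_angles = (0:9) * pi / 10),
            class = "fiber_map")
}

# random smooth blob mask for thinning property tests
random_blob_mask <- function(seed, size = 64) {
  set.seed(seed)
  z <- matrix(stats::rnorm(size * size), size, size)
  s <- as.matrix(EBImage::gblur(z, sigma = 4))
  s > stats::quantile(s, 0.75)
}
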