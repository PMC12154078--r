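#' Fiberscore-style detection parameters
#'
#' Parameter set for oriented-template filament detection. Defaults are the
#' values tuned for bEnd.3 endothelial cells: kernel half-length `L = 6`
#' (13 x 13 windows), `K = 10` orientations, correlation threshold
#' `TC = 0.55`, along-fiber coefficient-of-variation threshold `M = 0.3`,
#' cross/along CV ratio threshold `N = 2.1`, and pixel-intensity threshold
#' `T = 0.25` on min-max normalized images.
#'
#' @param L kernel half-length in pixels (window side is `2L + 1`). A
#'   `full_size` interpretation, where `L` is the full window side, is
#'   available via `kernel = "full"`.
#' @param K number of template orientations, spaced `180 / K` degrees apart.
#' @param TC Pearson correlation threshold in (0, 1).
#' @param M threshold on the coefficient of variation (sd/mean) of intensities
#'   sampled along the best-matching oriented segment; fiber pixels are
#'   homogeneous lengthwise, so acceptance requires `CV_along <= M`.
#' @param N threshold on `CV_cross / CV_along` (>= 1); a ridge varies more
#'   across than along, so acceptance requires the ratio `>= N`.
#' @param T pixel-intensity threshold in \[0, 1) applied after min-max
#'   normalization.
#' @param kernel `"half"` (default) reads `L` as half-length; `"full"` reads it
#'   as the full window side (rounded up to odd).
#' @param smooth Gaussian sigma (px) of the matched pre-filter applied to both
#'   the image and the templates before correlation (0 disables). Blurring
#'   both sides with the same kernel makes the binary line template's profile
#'   match the diffraction-widened ridge profile of real filaments and
#'   suppresses pixel noise without biasing the correlation.
#' @return object of class `fiberscore_params`.
#' @export
fiberscore_params <- function(L = 6, K = 10, TC = 0.55, M = 0.3, N = 2.1,
                              T = 0.25, kernel = c("half", "full"), smooth = 1) {
  kernel <- match.arg(kernel)
  if (kernel == "full") {
    side <- as.integer(L)
    if (side %% 2L == 0L) side <- side + 1L
    L <- (side - 1L) / 2L
  }
  stop_if_not(L >= 1, "L must be >= 1")
  stop_if_not(K >= 1, "K must be >= 1")
  stop_if_not(TC > 0 && TC < 1, "TC must be in (0, 1)")
  stop_if_not(M > 0, "M must be > 0")
  stop_if_not(N >= 1, "N must be >= 1")
  stop_if_not(T >= 0 && T < 1, "T must be in [0, 1)")
  stop_if_not(smooth >= 0, "smooth must be >= 0")
  structure(list(L = as.integer(L), K = as.integer(K), TC = TC, M = M, N = N,
                 T = T, smooth = smooth),
            class = "fiberscore_params")
}

#' @export
print.fiberscore_params <- function(x, ...) {
  cat(sprintf("fiberscore params: L=%d (window %dx%d), K=%d, TC=%.3g, M=%.3g, N=%.3g, T=%.3g\n",
              x$L, 2 * x$L + 1, 2 * x$L + 1, x$K, x$TC, x$M, x$N, x$T))
  invisible(x)
}

# rasterize a centered line segment of half-length L at angle theta into a
# (2L+1) x (2L+1) binary window (Bresenham-style symmetric rasterization)
rasterize_segment <- function(L, theta) {
  w <- matrix(0, 2 * L + 1, 2 * L + 1)
  ct <- cos(theta); st <- sin(theta)
  if (abs(ct) >= abs(st)) {
    steps <- -L:L
    cols <- steps
    rows <- round(steps * st / ct)
  } else {
    steps <- -L:L
    rows <- steps
    cols <- round(steps * ct / st)
  }
  w[cbind(rows + L + 1, cols + L + 1)] <- 1
  w
}

#' Build the oriented line-template bank
#'
#' `K` binary templates, each a centered line segment of `2L + 1` pixels
#' rasterized in a `(2L + 1) x (2L + 1)` window, at orientations
#' `k * 180 / K` degrees for `k = 0, ..., K - 1`.
#'
#' @param params a [fiberscore_params()].
#' @return list with `templates` (list of binary matrices), `angles`
#'   (radians, in \[0, pi)), and `L`.
#' @export
build_template_bank <- function(params) {
  stop_if_not(inherits(params, "fiberscore_params"), "params must be fiberscore_params")
  angles <- (seq_len(params$K) - 1) * pi / params$K
  templates <- lapply(angles, function(a) rasterize_segment(params$L, a))
  list(templates = templates, angles = angles, L = params$L)
}
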