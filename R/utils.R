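#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Rescale an image to [0, 1]
#'
#' Min-max rescaling applied before any intensity threshold so that thresholds
#' on the unit scale (such as the pixel-intensity threshold `T`) are meaningful
#' regardless of camera bit depth. A constant image maps to all zeros.
#'
#' @param img numeric matrix.
#' @return numeric matrix with values in \[0, 1\].
#' @export
rescale01 <- function(img) {
  stop_if_not(is.numeric(img) && is.matrix(img), "img must be a numeric matrix")
  rng <- range(img, finite = TRUE)
  if (diff(rng) <= 0) return(img * 0)
  (img - rng[1]) / diff(rng)
}

# trapezoidal integral of y over x (uniform or not)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Von Mises sampler (Best-Fisher rejection method)
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return angles in \[0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  stop_if_not(kappa >= 0, "kappa must be >= 0")
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- (mu + sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Axial von Mises sampler for undirected orientations
#'
#' Fibers are axial data (theta and theta + pi are the same line), so
#' orientations are drawn by sampling the doubled angle from a von Mises
#' distribution and halving, giving values in \[0, pi).
#'
#' @inheritParams rvonmises
#' @param mode modal orientation in \[0, pi).
#' @export
raxial_vonmises <- function(n, mode, kappa) {
  (rvonmises(n, 2 * mode, kappa) / 2) %% pi
}

#' Polarity (axial resultant length) of a set of orientations
#'
#' Polarity is the length of the mean resultant vector of the doubled angles:
#' `Dx = mean(cos 2*theta)`, `Dy = mean(sin 2*theta)`,
#' `polarity = sqrt(Dx^2 + Dy^2)`. It is 1 when all orientations coincide and
#' 0 for an isotropic set; antiparallel orientations reinforce rather than
#' cancel because the angle is doubled.
#'
#' @param theta orientations in radians (axial, i.e. modulo pi).
#' @return list with `Dx`, `Dy`, `polarity`.
#' @export
orientation_polarity <- function(theta) {
  stop_if_not(length(theta) >= 1L, "no orientations supplied")
  dx <- mean(cos(2 * theta))
  dy <- mean(sin(2 * theta))
  list(Dx = dx, Dy = dy, polarity = sqrt(dx^2 + dy^2))
}

# significance star codes: * p<0.05, ** p<0.01, *** p<0.001
star_code <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*" else "ns"
  }, character(1))
}
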