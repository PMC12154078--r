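# Oriented-template filament detection: per-pixel Pearson correlation against
# a bank of line templates, coefficient-of-variation tests along/across the
# best orientation, thinning to skeletons, and per-cell metrics.

dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

#' Detect fiber pixels by oriented template correlation
#'
#' For every pixel above the intensity threshold `T` (on the min-max
#' normalized image) and every bank orientation, computes the Pearson
#' correlation between the pixel's square neighborhood and the centered line
#' template, together with the coefficient of variation (sd/mean) of
#' intensities sampled along the oriented segment (`CV_along`) and along the
#' perpendicular segment (`CV_cross`). A pixel is a core fiber pixel at its
#' best orientation iff the best correlation is `>= TC`, `CV_along <= M`, and
#' `CV_cross / CV_along >= N`. Because the along-segment CV test necessarily
#' rejects filament tips (the sampling line is half on, half off the
#' filament), pixels with correlation `>= TC` that are 8-connected to the core
#' are then reclaimed by geodesic reconstruction, restoring filament ends
#' without admitting isolated noise. Constant (zero-variance) windows yield
#' correlation 0, never NaN. The computation is fully deterministic.
#'
#' @param image single-channel numeric matrix; rescaled internally to \[0, 1\].
#' @param params a [fiberscore_params()].
#' @return object of class `fiber_map`: `fiber_index` (best correlation at
#'   accepted pixels, 0 elsewhere), `orientation` (radians in \[0, pi), NA off
#'   the mask), `mask` (logical), plus the parameters and bank angles.
#' @export
correlate_fibers <- function(image, params = fiberscore_params()) {
  stop_if_not(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  stop_if_not(inherits(params, "fiberscore_params"), "params must be fiberscore_params")
  img0 <- rescale01(image)
  img <- if (params$smooth > 0)
    rescale01(as.matrix(EBImage::gblur(img0, sigma = params$smooth))) else img0
  bank <- build_template_bank(params)
  L <- params$L
  side <- 2L * L + 1L
  n_w <- side^2
  npix <- side  # pixels per line template
  box <- matrix(1 / n_w, side, side)
  mean_w <- as.matrix(EBImage::filter2(img, box, boundary = "replicate"))
  mean_w2 <- as.matrix(EBImage::filter2(img^2, box, boundary = "replicate"))
  var_w <- pmax(mean_w2 - mean_w^2, 0)
  sd_w <- sqrt(var_w)
  best_corr <- matrix(-Inf, nrow(img), ncol(img))
  best_k <- matrix(0L, nrow(img), ncol(img))
  sums1 <- vector("list", params$K)
  sums2 <- vector("list", params$K)
  corr_stack <- vector("list", params$K)
  for (k in seq_len(params$K)) {
    tk <- bank$templates[[k]]
    # matched filter: correlate against the template seen through the same
    # blur as the image, so the template profile matches the ridge profile
    tb <- if (params$smooth > 0)
      as.matrix(EBImage::gblur(tk, sigma = params$smooth)) else tk
    t_mean <- mean(tb)
    t_sd <- sqrt(mean(tb^2) - t_mean^2)
    s1 <- as.matrix(EBImage::filter2(img, tk, boundary = "replicate"))
    s2 <- as.matrix(EBImage::filter2(img^2, tk, boundary = "replicate"))
    sums1[[k]] <- s1
    sums2[[k]] <- s2
    sb <- as.matrix(EBImage::filter2(img, tb, boundary = "replicate"))
    covar <- sb / n_w - mean_w * t_mean
    corr <- ifelse(sd_w > 1e-12 & t_sd > 1e-12, covar / (sd_w * t_sd), 0)
    corr_stack[[k]] <- corr
    upd <- corr > best_corr
    best_corr[upd] <- corr[upd]
    best_k[upd] <- k
  }
  # CV along best orientation and across it (perpendicular segment)
  cv_from_sums <- function(s1, s2) {
    m <- s1 / npix
    v <- pmax(s2 / npix - m^2, 0)
    ifelse(m > 1e-12, sqrt(v) / m, Inf)
  }
  cv_along <- cv_cross <- matrix(NA_real_, nrow(img), ncol(img))
  perp_cache <- list()
  for (k in seq_len(params$K)) {
    sel <- best_k == k
    if (!any(sel)) next
    ca <- cv_from_sums(sums1[[k]], sums2[[k]])
    perp_angle <- (bank$angles[k] + pi / 2) %% pi
    kp <- which(abs(bank$angles - perp_angle) < 1e-9)
    if (length(kp) == 1L) {
      cx <- cv_from_sums(sums1[[kp]], sums2[[kp]])
    } else {
      key <- sprintf("%.9f", perp_angle)
      if (is.null(perp_cache[[key]])) {
        tp <- rasterize_segment(L, perp_angle)
        perp_cache[[key]] <- list(
          s1 = as.matrix(EBImage::filter2(img, tp, boundary = "replicate")),
          s2 = as.matrix(EBImage::filter2(img^2, tp, boundary = "replicate")))
      }
      cx <- cv_from_sums(perp_cache[[key]]$s1, perp_cache[[key]]$s2)
    }
    cv_along[sel] <- ca[sel]
    cv_cross[sel] <- cx[sel]
  }
  above_T <- img > params$T
  candidate <- above_T & best_corr >= params$TC
  ratio <- ifelse(cv_along <= 1e-12, Inf, cv_cross / cv_along)
  core <- candidate & cv_along <= params$M & ratio >= params$N
  core[is.na(core)] <- FALSE
  candidate[is.na(candidate)] <- FALSE
  # geodesic reconstruction of the core within the candidate set
  mask <- core
  repeat {
    grown <- dilate3(mask) & candidate
    if (identical(grown, mask)) break
    mask <- grown
  }
  # sub-bin orientation: parabolic interpolation of the correlation over the
  # best bank angle and its two angular neighbors (periodic in pi); a line
  # exactly at a bank angle stays at that angle by symmetry
  orientation <- matrix(NA_real_, nrow(img), ncol(img))
  bin <- pi / params$K
  sel_all <- which(mask)
  if (length(sel_all)) {
    kbest <- best_k[sel_all]
    kprev <- ((kbest - 2L) %% params$K) + 1L
    knext <- (kbest %% params$K) + 1L
    cb <- best_corr[sel_all]
    cp <- vapply(seq_along(sel_all), function(i) corr_stack[[kprev[i]]][sel_all[i]],
                 numeric(1))
    cn <- vapply(seq_along(sel_all), function(i) corr_stack[[knext[i]]][sel_all[i]],
                 numeric(1))
    den <- cp - 2 * cb + cn
    dth <- ifelse(abs(den) > 1e-12, 0.5 * (cp - cn) / den, 0)
    dth <- pmin(0.5, pmax(-0.5, dth))
    orientation[sel_all] <- (bank$angles[kbest] + dth * bin) %% pi
    # local axial consensus: doubled-angle vector averaging over the 5x5
    # masked neighborhood suppresses isolated misassigned orientations
    u <- v <- w <- matrix(0, nrow(img), ncol(img))
    u[sel_all] <- cos(2 * orientation[sel_all])
    v[sel_all] <- sin(2 * orientation[sel_all])
    w[sel_all] <- 1
    box5 <- matrix(1, 5, 5)
    us <- as.matrix(EBImage::filter2(u, box5, boundary = 0))
    vs <- as.matrix(EBImage::filter2(v, box5, boundary = 0))
    orientation[sel_all] <- (atan2(vs[sel_all], us[sel_all]) / 2) %% pi
  }
  fiber_index <- matrix(0, nrow(img), ncol(img))
  fiber_index[mask] <- pmax(best_corr[mask], 0)
  structure(list(fiber_index = fiber_index, orientation = orientation,
                 mask = mask, params = params, bank_angles = bank$angles),
            class = "fiber_map")
}

#' @export
print.fiber_map <- function(x, ...) {
  cat(sprintf("fiber map: %d x %d, %d fiber pixels (%.2f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Thin a fiber map to one-pixel-wide skeletons
#'
#' Binarizes the fiber mask (removing intensity dependence) and applies
#' Guo-Hall homotopic thinning, then labels 8-connected skeleton components
#' and measures each component's path length: 1 px per 4-neighbor step,
#' sqrt(2) per diagonal step, converted to micrometres by `pixel_size`.
#'
#' @param map a `fiber_map` (or a logical mask matrix).
#' @param pixel_size micrometres per pixel.
#' @return object of class `fiber_skeleton`: `skeleton` (logical matrix),
#'   `components` (data.frame: `id`, `n_pixels`, `length_px`, `length_um`),
#'   `labels` (integer matrix), `pixel_size`.
#' @export
thin_fiber_map <- function(map, pixel_size = 1) {
  mask <- if (inherits(map, "fiber_map")) map$mask else map != 0
  skel <- thin_binary(mask)
  comp <- skeleton_components(skel)
  comp$components$length_um <- comp$components$length_px * pixel_size
  structure(list(skeleton = skel, components = comp$components,
                 labels = comp$labels, pixel_size = pixel_size),
            class = "fiber_skeleton")
}

#' @export
print.fiber_skeleton <- function(x, ...) {
  cat(sprintf("fiber skeleton: %d components, %d skeleton pixels\n",
              nrow(x$components), sum(x$skeleton)))
  invisible(x)
}

#' Filament count and mean length above a minimum length
#'
#' Skeleton components with path length below `min_length` are discarded;
#' the survivors' count and mean length are returned. An optional
#' `max_length` restricts to a length window (used by the parameter scan).
#'
#' @param skeleton a `fiber_skeleton` from [thin_fiber_map()].
#' @param min_length minimum filament length in micrometres (default 5).
#' @param max_length optional maximum length in micrometres.
#' @return list of class `filament_metrics`: `n_filaments`, `mean_length`
#'   (um; 0 with `no_filaments = TRUE` when nothing survives), `lengths_um`.
#' @export
measure_filaments <- function(skeleton, min_length = 5, max_length = Inf) {
  stop_if_not(inherits(skeleton, "fiber_skeleton"), "skeleton must be a fiber_skeleton")
  stop_if_not(min_length >= 0, "min_length must be >= 0")
  len <- skeleton$components$length_um
  keep <- len >= min_length & len <= max_length
  n <- sum(keep)
  structure(list(n_filaments = n,
                 mean_length = if (n > 0) mean(len[keep]) else 0,
                 no_filaments = n == 0L,
                 lengths_um = len[keep]),
            class = "filament_metrics")
}

#' @export
print.filament_metrics <- function(x, ...) {
  if (x$no_filaments) cat("no filaments above the minimum length\n")
  else cat(sprintf("%d filaments, mean length %.2f um\n", x$n_filaments, x$mean_length))
  invisible(x)
}

#' Restrict a fiber map to components containing accepted filaments
#'
#' Keeps only mask pixels belonging to 8-connected mask components whose
#' skeleton path length reaches `min_length`; short noise blobs — already
#' excluded from filament counts by the same rule — are thereby excluded
#' from polarity as well, so polarity is measured along detected filaments
#' only.
#'
#' @param map a `fiber_map`.
#' @param skeleton the matching `fiber_skeleton` from [thin_fiber_map()].
#' @param min_length minimum filament length in micrometres.
#' @return a `fiber_map` with the mask (and orientation / fiber index)
#'   restricted to accepted components.
#' @export
filter_fiber_map <- function(map, skeleton, min_length = 5) {
  stop_if_not(inherits(map, "fiber_map"), "map must be a fiber_map")
  stop_if_not(inherits(skeleton, "fiber_skeleton"), "skeleton must be a fiber_skeleton")
  keep_comp <- skeleton$components$id[skeleton$components$length_um >= min_length]
  if (length(keep_comp) == 0L) {
    map$mask[] <- FALSE
    map$orientation[] <- NA_real_
    map$fiber_index[] <- 0
    return(map)
  }
  # grow the surviving skeleton components back onto their mask components
  seed <- matrix(FALSE, nrow(map$mask), ncol(map$mask))
  seed[skeleton$labels %in% keep_comp & skeleton$skeleton] <- TRUE
  grown <- seed
  repeat {
    nxt <- dilate3(grown) & map$mask
    if (identical(nxt, grown)) break
    grown <- nxt
  }
  map$mask <- grown
  map$orientation[!grown] <- NA_real_
  map$fiber_index[!grown] <- 0
  map
}

#' Filament polarity from a fiber map
#'
#' Over all fiber pixels with orientation `theta(p)`:
#' `Dx = mean(cos 2*theta)`, `Dy = mean(sin 2*theta)`,
#' `polarity = sqrt(Dx^2 + Dy^2)` in \[0, 1\] (doubled-angle convention for
#' axial data). Polarity 1 means perfectly parallel filaments; 0, isotropic.
#'
#' @param map a `fiber_map`.
#' @return list with `Dx`, `Dy`, `polarity`.
#' @export
compute_polarity <- function(map) {
  stop_if_not(inherits(map, "fiber_map"), "map must be a fiber_map")
  th <- map$orientation[map$mask]
  if (length(th) == 0L) stop("no fibers detected", call. = FALSE)
  orientation_polarity(th)
}

#' Histogram and FWHM of per-cell polarity values
#'
#' Fixed-width histogram over \[0, 1\]; the full width at half maximum is
#' computed on the histogram profile by linear interpolation around the modal
#' bin. A degenerate distribution concentrated in one bin has FWHM equal to
#' one bin width. Tail summaries report the fraction of cells below 0.25 and
#' above 0.75.
#'
#' @param polarities per-cell polarity values in \[0, 1\].
#' @param binwidth histogram bin width (default 0.05).
#' @return object of class `polarity_distribution`: `breaks`, `counts`,
#'   `mids`, `fwhm`, `mode`, `tails` (`lower`, `upper`), `n`.
#' @export
polarity_distribution <- function(polarities, binwidth = 0.05) {
  stop_if_not(length(polarities) >= 1L, "at least one cell required")
  stop_if_not(all(polarities >= 0 & polarities <= 1), "polarity must be in [0, 1]")
  breaks <- seq(0, 1, by = binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- graphics::hist(polarities, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  imode <- which.max(counts)
  half <- counts[imode] / 2
  # left crossing
  left <- breaks[imode]  # default: left edge of the modal bin region
  if (imode > 1) {
    i <- imode
    while (i > 1 && counts[i - 1] >= half) i <- i - 1
    left <- if (i == 1) mids[1] - binwidth / 2 else
      mids[i - 1] + (half - counts[i - 1]) / (counts[i] - counts[i - 1]) * binwidth
  } else left <- mids[1] - binwidth / 2
  if (imode < length(counts)) {
    i <- imode
    while (i < length(counts) && counts[i + 1] >= half) i <- i + 1
    right <- if (i == length(counts)) mids[length(counts)] + binwidth / 2 else
      mids[i] + (counts[i] - half) / (counts[i] - counts[i + 1]) * binwidth
  } else right <- mids[length(mids)] + binwidth / 2
  fwhm <- max(right - left, binwidth)
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 fwhm = fwhm, mode = mids[imode],
                 tails = list(lower = mean(polarities < 0.25),
                              upper = mean(polarities > 0.75)),
                 n = length(polarities)),
            class = "polarity_distribution")
}

#' @export
print.polarity_distribution <- function(x, ...) {
  cat(sprintf("polarity distribution over %d cells: mode %.2f, FWHM %.3f\n",
              x$n, x$mode, x$fwhm))
  invisible(x)
}

#' Full filament analysis of one image
#'
#' Convenience wrapper running detection ([correlate_fibers()]), thinning
#' ([thin_fiber_map()]), filament measurement ([measure_filaments()]) and
#' polarity ([compute_polarity()]), optionally per cell via a label mask
#' (integer matrix; 0 = background), replacing interactive cell
#' individualization.
#'
#' @param image single-channel numeric matrix.
#' @param params a [fiberscore_params()].
#' @param pixel_size micrometres per pixel.
#' @param min_length minimum filament length in micrometres.
#' @param labels optional integer label-mask matrix assigning pixels to cells.
#' @return object of class `fiberscore`: the `fiber_map`, `fiber_skeleton`,
#'   global `metrics` and `polarity`, and a per-cell data.frame `cells`
#'   (`cell_id`, `n_filaments`, `mean_length_um`, `Dx`, `Dy`, `polarity`).
#' @export
fiberscore <- function(image, params = fiberscore_params(), pixel_size = 1,
                       min_length = 5, labels = NULL) {
  map <- correlate_fibers(image, params)
  skel <- thin_fiber_map(map, pixel_size)
  metrics <- measure_filaments(skel, min_length)
  fmap <- filter_fiber_map(map, skel, min_length)
  pol <- if (any(fmap$mask)) compute_polarity(fmap) else
    list(Dx = NA_real_, Dy = NA_real_, polarity = NA_real_)
  cells <- NULL
  if (!is.null(labels)) {
    stop_if_not(is.matrix(labels) && all(dim(labels) == dim(image)),
                "labels must be a matrix matching the image")
    ids <- sort(setdiff(unique(as.integer(labels)), 0L))
    cells <- do.call(rbind, lapply(ids, function(id) {
      sel <- labels == id
      submap <- map
      submap$mask <- map$mask & sel
      submap$orientation[!submap$mask] <- NA_real_
      subskel <- thin_fiber_map(submap, pixel_size)
      m <- measure_filaments(subskel, min_length)
      subpol <- fmap
      subpol$mask <- fmap$mask & sel
      subpol$orientation[!subpol$mask] <- NA_real_
      p <- if (any(subpol$mask)) compute_polarity(subpol) else
        list(Dx = NA_real_, Dy = NA_real_, polarity = NA_real_)
      data.frame(cell_id = id, n_filaments = m$n_filaments,
                 mean_length_um = m$mean_length, Dx = p$Dx, Dy = p$Dy,
                 polarity = p$polarity)
    }))
  }
  structure(list(map = map, skeleton = skel, metrics = metrics, polarity = pol,
                 cells = cells, pixel_size = pixel_size, min_length = min_length,
                 params = params),
            class = "fiberscore")
}

#' @export
print.fiberscore <- function(x, ...) {
  cat("Oriented-template filament analysis\n")
  print(x$params)
  cat(sprintf("  filaments >= %.3g um: %d, mean length %.2f um\n",
              x$min_length, x$metrics$n_filaments, x$metrics$mean_length))
  if (!is.na(x$polarity$polarity))
    cat(sprintf("  polarity: %.3f (Dx %.3f, Dy %.3f)\n",
                x$polarity$polarity, x$polarity$Dx, x$polarity$Dy))
  if (!is.null(x$cells)) cat(sprintf("  %d cells analyzed\n", nrow(x$cells)))
  invisible(x)
}

#' @export
summary.fiberscore <- function(object, ...) {
  out <- data.frame(n_filaments = object$metrics$n_filaments,
                    mean_length_um = object$metrics$mean_length,
                    Dx = object$polarity$Dx, Dy = object$polarity$Dy,
                    polarity = object$polarity$polarity)
  if (!is.null(object$cells)) attr(out, "cells") <- object$cells
  out
}

#' @export
plot.fiberscore <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(x$map$fiber_index)[, nrow(x$map$fiber_index):1],
                  col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                  main = "fiber index")
  graphics::image(t(x$skeleton$skeleton * 1)[, nrow(x$skeleton$skeleton):1],
                  col = c("black", "white"), axes = FALSE, main = "skeleton")
  invisible(x)
}

#' Parameter-space scan of detected filament counts
#'
#' Runs the full detection over a grid of threshold values and records, for
#' each grid point, the number of filaments with length inside
#' `min_length_range` (default 5-30 um). Returns the full contour table and
#' the argmax grid point.
#'
#' @param images a list of single-channel matrices (or a single matrix).
#' @param grid named list with any of `M`, `N`, `TC`, `T`, each a numeric
#'   vector of values to scan; omitted parameters stay at `base_params`.
#' @param base_params a [fiberscore_params()] supplying non-scanned values.
#' @param min_length_range length window in micrometres.
#' @param pixel_size micrometres per pixel.
#' @return list of class `fiber_param_scan`: `table` (one row per grid point
#'   with the summed filament count across images) and `best` (the row with
#'   the highest count).
#' @export
optimize_parameters <- function(images, grid, base_params = fiberscore_params(),
                                min_length_range = c(5, 30), pixel_size = 1) {
  if (is.matrix(images)) images <- list(images)
  stop_if_not(length(images) >= 1L, "at least one image required")
  stop_if_not(is.list(grid) && length(grid) >= 1L && all(lengths(grid) >= 1L),
              "empty grid rejected")
  stop_if_not(all(names(grid) %in% c("M", "N", "TC", "T")),
              "grid names must be among M, N, TC, T")
  gg <- do.call(expand.grid, grid)
  counts <- vapply(seq_len(nrow(gg)), function(i) {
    p <- base_params
    for (nm in names(gg)) p[[nm]] <- gg[i, nm]
    p <- fiberscore_params(L = p$L, K = p$K, TC = p$TC, M = p$M, N = p$N,
                           T = p$T, smooth = p$smooth)
    sum(vapply(images, function(im) {
      sk <- thin_fiber_map(correlate_fibers(im, p), pixel_size)
      measure_filaments(sk, min_length_range[1], min_length_range[2])$n_filaments
    }, numeric(1)))
  }, numeric(1))
  tab <- cbind(gg, n_filaments = counts)
  structure(list(table = tab, best = tab[which.max(counts), , drop = FALSE]),
            class = "fiber_param_scan")
}

#' @export
print.fiber_param_scan <- function(x, ...) {
  cat(sprintf("parameter scan over %d grid points; best:\n", nrow(x$table)))
  print(x$best, row.names = FALSE)
  invisible(x)
}
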