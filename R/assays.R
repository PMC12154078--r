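# Plate-assay computations: normalization to control, per-nucleus ROS,
# Transwell apparent permeability, and the ANOVA + post hoc significance
# layer shared by all endpoints.

#' Construct a condition x replicate assay table
#'
#' @param data data.frame with columns `condition` and `value` (and optionally
#'   `replicate`); the first condition level is the control.
#' @param assay assay kind tag (e.g. "viability", "ros", "adhesion").
#' @param control optional control label; reorders the condition levels so the
#'   control is first.
#' @return data.frame of class `assay_table`.
#' @export
assay_table <- function(data, assay = "generic", control = NULL) {
  stop_if_not(is.data.frame(data) && all(c("condition", "value") %in% names(data)),
              "data must have columns condition and value")
  data$condition <- as.factor(data$condition)
  if (!is.null(control)) {
    stop_if_not(control %in% levels(data$condition), "control level not found")
    data$condition <- stats::relevel(data$condition, ref = control)
  }
  counts <- table(data$condition)
  stop_if_not(all(counts >= 2), "every condition needs >= 2 replicates")
  if (!"replicate" %in% names(data))
    data$replicate <- stats::ave(seq_len(nrow(data)), data$condition, FUN = seq_along)
  attr(data, "assay") <- assay
  class(data) <- c("assay_table", "data.frame")
  data
}

control_level <- function(tab) levels(tab$condition)[1]

#' Normalize condition means to the control
#'
#' Per-condition mean and SD expressed relative to the control mean: 100% for
#' the control in percent mode (viability), 1.0 in ratio mode (adhesion and
#' other ratio assays).
#'
#' @param tab an [assay_table()]; the first condition level is the control.
#' @param percent if TRUE report percent of control, else a ratio.
#' @return data.frame: condition, mean, sd, `normalized` (and the control row
#'   exactly 100 or 1).
#' @export
normalize_to_control <- function(tab, percent = TRUE) {
  stop_if_not(inherits(tab, "assay_table"), "tab must be an assay_table")
  agg <- do.call(rbind, lapply(split(tab$value, tab$condition), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v))))
  agg$condition <- factor(rownames(agg), levels = levels(tab$condition))
  agg <- agg[order(agg$condition), c("condition", "mean", "sd")]
  cm <- agg$mean[1]
  if (cm <= 0) stop("control mean must be > 0", call. = FALSE)
  scale <- if (percent) 100 else 1
  agg$normalized <- agg$mean / cm * scale
  agg$normalized_sd <- agg$sd / cm * scale
  rownames(agg) <- NULL
  agg
}

#' Mean per-cell intensity from total fluorescence and nuclei count
#'
#' @param total_intensity summed fluorescence intensity over the field.
#' @param nuclei_count number of nuclei (>= 1).
#' @return total intensity divided by the number of nuclei.
#' @export
ros_per_cell <- function(total_intensity, nuclei_count) {
  stop_if_not(nuclei_count >= 1, "nuclei_count must be >= 1")
  total_intensity / nuclei_count
}

#' Count nuclei in a binary nuclei raster
#'
#' Thresholds at 0.5 and counts connected components.
#'
#' @param nuclei numeric matrix (e.g. from [gen_nuclei_image()]).
#' @return integer count.
#' @export
count_nuclei <- function(nuclei) {
  stop_if_not(is.matrix(nuclei), "nuclei must be a matrix")
  max(EBImage::bwlabel((nuclei > 0.5) * 1))
}

#' Apparent permeability coefficient from Transwell sampling
#'
#' The flux `dQ/dt` is the least-squares slope through the cumulative
#' basolateral amounts `Q(t)`; the apparent permeability is
#' `Papp = (dQ/dt) / (A * C0)` with units reconciled to cm/s (times in
#' minutes, `Q` in ug, `C0` in ug/mL = ug/cm^3, `A` in cm^2). Non-monotone
#' `Q` is permitted (the fit proceeds); a non-positive fitted slope is
#' flagged and yields `Papp = 0` when the slope is exactly 0.
#'
#' @param times_min sampling times in minutes (strictly increasing, >= 2).
#' @param Q_ug cumulative basolateral amounts in micrograms.
#' @param C0_ug_ml apical (donor) concentration in ug/mL (> 0).
#' @param area_cm2 membrane area in cm^2 (> 0).
#' @param control_papp optional control Papp for normalization.
#' @return list of class `permeability`: `slope_ug_min`, `papp_cm_s`,
#'   `normalized` (NA without a control), `negative_slope` flag.
#' @export
permeability_coefficient <- function(times_min, Q_ug, C0_ug_ml, area_cm2,
                                     control_papp = NULL) {
  stop_if_not(length(times_min) >= 2L, "at least 2 time points required")
  stop_if_not(all(diff(times_min) > 0), "times must be strictly increasing")
  stop_if_not(C0_ug_ml > 0 && area_cm2 > 0, "C0 and A must be > 0")
  fit <- stats::lm(Q_ug ~ times_min)
  slope <- unname(stats::coef(fit)[2])  # ug/min
  papp <- (slope / 60) / (area_cm2 * C0_ug_ml)  # cm/s
  if (slope == 0) papp <- 0
  structure(list(slope_ug_min = slope, papp_cm_s = papp,
                 normalized = if (is.null(control_papp)) NA_real_ else papp / control_papp,
                 negative_slope = slope < 0),
            class = "permeability")
}

#' @export
print.permeability <- function(x, ...) {
  cat(sprintf("Papp = %.4g cm/s (flux %.4g ug/min)%s\n", x$papp_cm_s,
              x$slope_ug_min, if (x$negative_slope) " [negative slope]" else ""))
  if (!is.na(x$normalized)) cat(sprintf("  normalized to control: %.3g\n", x$normalized))
  invisible(x)
}

#' One-way ANOVA with post hoc comparisons against the control
#'
#' Omnibus one-way ANOVA followed by pairwise t tests of every condition
#' against the control on the pooled error term (df = N - k). Bonferroni
#' multiplies each raw p by the number of comparisons (capped at 1);
#' Fisher's LSD reports the raw p gated on a significant omnibus test
#' (non-significant omnibus suppresses the stars). Star codes: * p < 0.05,
#' ** p < 0.01, *** p < 0.001.
#'
#' @param tab an [assay_table()] with >= 2 conditions, >= 2 replicates each.
#' @param posthoc `"bonferroni"` or `"fisher_lsd"`.
#' @param alpha omnibus significance level used to gate Fisher's LSD.
#' @return object of class `significance_report`: `f_value`, `p_omnibus`,
#'   `df`, and `comparisons` (condition, estimate, p_raw, p_adjusted, stars).
#' @export
anova_posthoc <- function(tab, posthoc = c("bonferroni", "fisher_lsd"),
                          alpha = 0.05) {
  stop_if_not(inherits(tab, "assay_table"), "tab must be an assay_table")
  posthoc <- match.arg(posthoc)
  k <- nlevels(tab$condition)
  stop_if_not(k >= 2, "at least 2 conditions required")
  if (all(tapply(tab$value, tab$condition, function(v) diff(range(v))) == 0))
    stop("zero within-group variance", call. = FALSE)
  fit <- stats::aov(value ~ condition, data = tab)
  dfe <- fit$df.residual
  mse <- sum(stats::residuals(fit)^2) / dfe
  an <- summary(fit)[[1]]
  f_value <- an[1, "F value"]
  p_omni <- an[1, "Pr(>F)"]
  means <- tapply(tab$value, tab$condition, mean)
  ns <- tapply(tab$value, tab$condition, length)
  ctrl <- control_level(tab)
  others <- setdiff(levels(tab$condition), ctrl)
  m <- length(others)
  cmp <- do.call(rbind, lapply(others, function(g) {
    est <- means[g] - means[ctrl]
    se <- sqrt(mse * (1 / ns[g] + 1 / ns[ctrl]))
    tval <- est / se
    p_raw <- 2 * stats::pt(-abs(tval), dfe)
    data.frame(condition = g, estimate = unname(est), t = unname(tval),
               p_raw = unname(p_raw))
  }))
  if (posthoc == "bonferroni") {
    cmp$p_adjusted <- pmin(cmp$p_raw * m, 1)
    cmp$stars <- star_code(cmp$p_adjusted)
  } else {
    cmp$p_adjusted <- cmp$p_raw
    cmp$stars <- if (p_omni < alpha) star_code(cmp$p_raw) else rep("ns", m)
  }
  structure(list(f_value = unname(f_value), p_omnibus = unname(p_omni),
                 df = c(k - 1, dfe), posthoc = posthoc, alpha = alpha,
                 comparisons = cmp, control = ctrl),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g; post hoc: %s vs %s\n",
              x$df[1], x$df[2], x$f_value, x$p_omnibus, x$posthoc, x$control))
  df <- x$comparisons
  df$p_raw <- signif(df$p_raw, 3); df$p_adjusted <- signif(df$p_adjusted, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
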