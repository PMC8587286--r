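#' @title ROI-based image quality metrics
#' @description
#' All statistics are population statistics (divide by N, not N-1): the
#' background and ROI definitions treat the voxel set as the complete
#' population of the region, matching standard phantom quality-control
#' practice.
#' @name metrics
NULL

pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

coerce_mask <- function(mask, d) {
  if (inherits(mask, "mso_volume")) mask <- mask$values
  if (is.matrix(mask)) mask <- array(rep(mask, d[3]), d)
  if (!is.array(mask) || !identical(dim(mask), d))
    stop("mask grid does not match the volume grid", call. = FALSE)
  mask != 0
}

#' Per-slice background statistics
#'
#' For every slice, the mean and population standard deviation of the
#' voxels inside the background mask; the summary "mean background STD" is
#' the average of the per-slice standard deviations over the counted
#' slices. Slices whose background mask is empty are skipped with a
#' warning and the slice count adjusted.
#'
#' @param vol An `mso_volume` (or array).
#' @param background Logical/0-1 array on the volume grid (a matrix is
#'   replicated across slices).
#' @return A list: `per_slice` (data frame with `slice`, `n`, `mean`,
#'   `sd`), `mean_sd` (the search objective), `mean_mean`,
#'   `n_slices_used`.
#' @examples
#' v <- volume(array(c(1, 3, 5, 7), c(2, 2, 1)))
#' background_stats(v, array(TRUE, c(2, 2, 1)))$per_slice$sd  # sqrt(5)
#' @export
background_stats <- function(vol, background) {
  vol <- as_volume(vol)
  d <- dim(vol$values)
  bg <- coerce_mask(background, d)
  res <- data.frame(slice = seq_len(d[3]), n = NA_integer_,
                    mean = NA_real_, sd = NA_real_)
  for (z in seq_len(d[3])) {
    vals <- vol$values[, , z][bg[, , z]]
    res$n[z] <- length(vals)
    if (length(vals) == 0L) next
    res$mean[z] <- mean(vals)
    res$sd[z] <- pop_sd(vals)
  }
  used <- !is.na(res$sd)
  if (!any(used))
    stop("background mask is empty on every slice", call. = FALSE)
  if (!all(used))
    warning(sprintf("%d slice(s) with empty background skipped",
                    sum(!used)))
  list(per_slice = res,
       mean_sd = mean(res$sd[used]),
       mean_mean = mean(res$mean[used]),
       n_slices_used = sum(used))
}

#' Mean background standard deviation
#'
#' Shorthand for `background_stats(vol, background)$mean_sd` -- the
#' quantity the operator search minimises.
#'
#' @inheritParams background_stats
#' @return A single number.
#' @export
mean_background_std <- function(vol, background) {
  background_stats(vol, background)$mean_sd
}

#' ROI signal-to-noise ratio
#'
#' Pools all voxels inside the ROI across slices; SNR is the ROI mean
#' divided by the ROI population standard deviation. A constant ROI has no
#' defined SNR and raises an error (class `mso_degenerate_error`) rather
#' than returning infinity.
#'
#' @param vol An `mso_volume` (or array).
#' @param roi Logical/0-1 array on the volume grid.
#' @return A list: `mean`, `sd`, `snr`, `n`.
#' @export
roi_snr <- function(vol, roi) {
  vol <- as_volume(vol)
  d <- dim(vol$values)
  m <- coerce_mask(roi, d)
  vals <- vol$values[m]
  if (length(vals) == 0L) stop("ROI is empty", call. = FALSE)
  mu <- mean(vals)
  s <- pop_sd(vals)
  if (s == 0)
    stop(structure(class = c("mso_degenerate_error", "error", "condition"),
                   list(message = "ROI is constant: SNR undefined",
                        call = sys.call(-1))))
  list(mean = mu, sd = s, snr = mu / s, n = length(vals))
}

#' Contrast ratio
#'
#' Mean ROI intensity divided by mean background intensity.
#'
#' @param vol An `mso_volume` (or array).
#' @param roi,background Logical/0-1 arrays on the volume grid.
#' @return A single number.
#' @export
contrast_ratio <- function(vol, roi, background) {
  vol <- as_volume(vol)
  d <- dim(vol$values)
  rv <- vol$values[coerce_mask(roi, d)]
  bv <- vol$values[coerce_mask(background, d)]
  if (length(rv) == 0L || length(bv) == 0L)
    stop("ROI and background must be non-empty", call. = FALSE)
  mb <- mean(bv)
  if (mb == 0)
    stop(structure(class = c("mso_degenerate_error", "error", "condition"),
                   list(message = "background mean is zero: CR undefined",
                        call = sys.call(-1))))
  mean(rv) / mb
}

#' Percentage change between a raw and a processed value
#'
#' The two report conventions used for denoising tables:
#' `"reduction"` is `(before - after) / before * 100` (noise reduction),
#' `"increase"` is `(after - before) / before * 100` (SNR or CR gain).
#' Values are returned unrounded; report writers round noise/SNR
#' percentages to one decimal and CR percentages to two.
#'
#' @param before Baseline (raw) value, non-zero.
#' @param after Value after processing.
#' @param direction `"reduction"` or `"increase"`.
#' @return Percentage as a plain number (85.3 means 85.3%).
#' @examples
#' pct_change(750.59, 110.64, "reduction")  # ~85.3
#' @export
pct_change <- function(before, after,
                       direction = c("reduction", "increase")) {
  direction <- match.arg(direction)
  if (!is.finite(before) || !is.finite(after))
    stop("inputs must be finite", call. = FALSE)
  if (before == 0) stop("baseline value is zero", call. = FALSE)
  if (direction == "reduction") (before - after) / before * 100
  else (after - before) / before * 100
}

#' Extract a line profile from a slice
#'
#' Samples the image along a straight segment at half-voxel steps using
#' bilinear interpolation. Physical coordinates put the centre of voxel
#' `(row 0, col 0)` at `(0, 0)` mm, with x along columns and y along rows.
#'
#' @param vol An `mso_volume` (or array).
#' @param slice 1-based slice index.
#' @param from_mm,to_mm Numeric length-2 `(x, y)` endpoints in mm; both
#'   must lie inside the slice.
#' @return A `line_profile` object: list with `samples`, `positions_mm`
#'   (distance from the first endpoint) and `spacing_mm`.
#' @export
extract_line_profile <- function(vol, slice, from_mm, to_mm) {
  vol <- as_volume(vol)
  d <- dim(vol$values)
  if (slice < 1L || slice > d[3]) stop("slice index out of range",
                                       call. = FALSE)
  sp <- vol$spacing_mm
  img <- vol$values[, , slice]
  lim_x <- (d[2] - 1) * sp[2]
  lim_y <- (d[1] - 1) * sp[1]
  for (p in list(from_mm, to_mm))
    if (length(p) != 2L || p[1] < 0 || p[1] > lim_x ||
        p[2] < 0 || p[2] > lim_y)
      stop("profile endpoints must lie inside the slice", call. = FALSE)
  dist <- sqrt(sum((to_mm - from_mm)^2))
  step <- min(sp[1:2]) / 2
  n <- max(3L, as.integer(round(dist / step)) + 1L)
  tseq <- seq(0, 1, length.out = n)
  xs <- from_mm[1] + tseq * (to_mm[1] - from_mm[1])
  ys <- from_mm[2] + tseq * (to_mm[2] - from_mm[2])
  samples <- interp_bilinear(img, ys / sp[1] + 1, xs / sp[2] + 1)
  structure(list(samples = samples, positions_mm = tseq * dist,
                 spacing_mm = if (n > 1) dist / (n - 1) else 0),
            class = "line_profile")
}

#' Full width at half maximum of a line profile
#'
#' The baseline is the median of the outer 20% of samples (10% from each
#' end); the extremum is the profile maximum (`"peak"`) or minimum
#' (`"dip"`); the half level lies midway between baseline and extremum.
#' The two half-level crossings are located by linear interpolation
#' between the bracketing samples, scanning outward from the extremum, and
#' the FWHM is their separation in mm.
#'
#' @param profile A `line_profile` (or a list with `samples` and
#'   `positions_mm`).
#' @param polarity `"dip"` (default: cold rods in a hot background) or
#'   `"peak"`.
#' @return Width in mm.
#' @export
fwhm <- function(profile, polarity = c("dip", "peak")) {
  polarity <- match.arg(polarity)
  y <- profile$samples
  x <- profile$positions_mm
  n <- length(y)
  if (n < 3L) stop("profile too short", call. = FALSE)
  k <- max(1L, floor(0.1 * n))
  baseline <- stats::median(c(y[seq_len(k)], y[seq(n - k + 1L, n)]))
  if (polarity == "peak") {
    iext <- which.max(y)
  } else {
    iext <- which.min(y)
  }
  ext <- y[iext]
  if ((polarity == "peak" && ext <= baseline) ||
      (polarity == "dip" && ext >= baseline))
    stop("aperture unresolved: no extremum relative to baseline",
         call. = FALSE)
  half <- baseline + (ext - baseline) / 2
  # signed deviation: positive on the extremum side of the half level
  s <- if (polarity == "peak") y - half else half - y
  cross_out <- function(dir) {
    i <- iext
    while (i + dir >= 1L && i + dir <= n) {
      j <- i + dir
      if (s[j] <= 0) {
        # linear interpolation between samples i and j
        f <- s[i] / (s[i] - s[j])
        return(x[i] + f * (x[j] - x[i]))
      }
      i <- j
    }
    NA_real_
  }
  left <- cross_out(-1L)
  right <- cross_out(1L)
  if (is.na(left) || is.na(right))
    stop("aperture unresolved: half-level crossings not found",
         call. = FALSE)
  abs(right - left)
}
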