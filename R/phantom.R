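#' Digital Jaszczak-style phantom specification
#'
#' Describes a cylindrical quality-control phantom: a uniform hot cylinder
#' containing six 60-degree pie sectors of cold rods with graded diameters.
#' Defaults mirror a Deluxe Jaszczak phantom imaged on a clinical PET
#' scanner: a 168 x 168 in-plane grid over a 700 mm field of view
#' (4.1667 mm voxels) and rod diameters 31.80, 25.40, 19.10, 15.90, 12.70
#' and 9.50 mm. Slices are identical copies of the rod section, giving a
#' compact multi-slice volume for 3D operator search.
#'
#' @param grid_size In-plane voxels per axis (square grid, >= 32).
#' @param n_slices Number of identical slices (default 8).
#' @param fov_mm Field of view in mm (default 700).
#' @param rod_diameters_mm Six cold-rod diameters in mm, one per sector.
#' @param cylinder_radius_mm Radius of the hot cylinder (default 108 mm,
#'   a 216 mm diameter Jaszczak-class cylinder).
#' @param activity_level Mean voxel value (arbitrary count units) in the
#'   hot region; scales the Poisson noise level of simulated projections.
#'   The default gives FBP backgrounds whose streak standard deviation is
#'   a realistic 10-20% of the hot-region mean at 84 projection angles.
#' @param seed Integer RNG seed used by the simulation wrapper.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 168L, n_slices = 8L, fov_mm = 700,
                         rod_diameters_mm = c(31.80, 25.40, 19.10,
                                              15.90, 12.70, 9.50),
                         cylinder_radius_mm = 108,
                         activity_level = 4,
                         seed = 1L) {
  grid_size <- as.integer(grid_size)
  n_slices <- as.integer(n_slices)
  if (grid_size < 32L) stop("grid_size must be >= 32", call. = FALSE)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  if (fov_mm <= 0) stop("fov_mm must be positive", call. = FALSE)
  if (any(rod_diameters_mm <= 0))
    stop("rod diameters must be positive", call. = FALSE)
  if (any(rod_diameters_mm >= 2 * cylinder_radius_mm))
    stop("rod diameters must be smaller than the cylinder diameter",
         call. = FALSE)
  if (activity_level < 0)
    stop("activity_level must be non-negative", call. = FALSE)
  vox <- fov_mm / grid_size
  if (cylinder_radius_mm > fov_mm / 2)
    stop("cylinder does not fit in the field of view", call. = FALSE)
  structure(list(grid_size = grid_size, n_slices = n_slices,
                 fov_mm = fov_mm, rod_diameters_mm = rod_diameters_mm,
                 cylinder_radius_mm = cylinder_radius_mm,
                 activity_level = activity_level,
                 voxel_spacing_mm = vox, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rod centres for one sector: hexagonal packing with centre-to-centre
# pitch = 2 x diameter (standard Jaszczak convention), rows stacked along
# the sector bisector.  Returns an n x 2 matrix of (x, y) mm.
sector_rod_centers <- function(diam, theta1, theta2, R, margin) {
  pitch <- 2 * diam
  phi <- (theta1 + theta2) / 2
  u <- c(cos(phi), sin(phi))
  v <- c(-sin(phi), cos(phi))
  w1 <- c(cos(theta1), sin(theta1))
  w2 <- c(cos(theta2), sin(theta2))
  half <- diam / 2 + margin
  centers <- NULL
  jmax <- ceiling(R / (pitch * sqrt(3) / 2)) + 1L
  kmax <- ceiling(R / pitch) + 1L
  for (j in 0:jmax) {
    rad <- pitch + j * pitch * sqrt(3) / 2
    for (k in -kmax:kmax) {
      t <- (k + (j %% 2) / 2) * pitch
      p <- rad * u + t * v
      if (sqrt(sum(p^2)) + half > R) next
      # signed distances to the two sector boundary rays through the origin
      d1 <- w1[1] * p[2] - w1[2] * p[1]   # positive inside (ccw of w1)
      d2 <- w2[2] * p[1] - w2[1] * p[2]   # positive inside (cw of w2)
      if (d1 < half || d2 < half) next
      centers <- rbind(centers, p)
    }
  }
  centers
}

phantom_layout <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  margin <- spec$voxel_spacing_mm / 2
  rods <- list()
  for (a in 1:6) {
    th1 <- (a - 1) * pi / 3
    th2 <- a * pi / 3
    ctr <- sector_rod_centers(spec$rod_diameters_mm[a], th1, th2,
                              spec$cylinder_radius_mm, margin)
    if (is.null(ctr))
      stop(sprintf(
        "rod layout infeasible: no %.2f mm rod fits in sector %d",
        spec$rod_diameters_mm[a], a), call. = FALSE)
    rods[[a]] <- ctr
  }
  # cross-check: rods must not overlap (they cannot, by construction, but
  # a malformed spec is rejected here rather than silently rasterised)
  all_c <- do.call(rbind, rods)
  all_d <- rep(spec$rod_diameters_mm, vapply(rods, nrow, 1L))
  if (nrow(all_c) > 1L) {
    dd <- as.matrix(stats::dist(all_c))
    lim <- outer(all_d, all_d, "+") / 2
    diag(dd) <- Inf
    if (any(dd < lim))
      stop("rod layout infeasible: rods overlap", call. = FALSE)
  }
  rods
}

#' Generate the ground-truth phantom volume
#'
#' Rasterises the phantom: voxels inside the cylinder take the value
#' `activity_level`, voxels inside any cold rod take 0, voxels outside the
#' cylinder take 0. All slices are identical. Deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @return An `mso_volume` of dimension
#'   `grid_size x grid_size x n_slices`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_label_slice(spec)
  sl <- ifelse(lab >= 0 & lab < 10, spec$activity_level, 0)
  sl[lab >= 10] <- 0  # cold rods
  vol <- array(rep(sl, spec$n_slices),
               c(spec$grid_size, spec$grid_size, spec$n_slices))
  volume(vol, spacing_mm = rep(spec$voxel_spacing_mm, 3))
}

# Label slice: -1 outside cylinder, 0 hot region, 10 + sector for rod voxels
phantom_label_slice <- function(spec) {
  n <- spec$grid_size
  vox <- spec$voxel_spacing_mm
  cc <- (n - 1) / 2
  x <- ((seq_len(n) - 1) - cc) * vox
  X <- matrix(x, n, n, byrow = TRUE)   # col coordinate
  Y <- matrix(x, n, n)                 # row coordinate
  lab <- matrix(-1, n, n)
  lab[X^2 + Y^2 <= spec$cylinder_radius_mm^2] <- 0
  rods <- phantom_layout(spec)
  for (a in 1:6) {
    r2 <- (spec$rod_diameters_mm[a] / 2)^2
    for (i in seq_len(nrow(rods[[a]]))) {
      p <- rods[[a]][i, ]
      inside <- (X - p[1])^2 + (Y - p[2])^2 <= r2
      lab[inside & lab == 0] <- 10 + a
    }
  }
  lab
}

#' Ground-truth masks for a phantom
#'
#' Builds the label volumes used by the quality metrics: the cylinder
#' support, the hot signal region (cylinder interior away from rods and
#' from the cylinder wall), the streak-bearing background annulus outside
#' the cylinder, and per-sector rod labels.
#'
#' @param spec A [phantom_spec()].
#' @return A list of volumes/arrays on the phantom grid: `cylinder`,
#'   `roi`, `background` (logical 3D arrays) and `rod_labels` (integer 3D
#'   array, 0 = none, 1..6 = sector).
#' @export
phantom_masks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  vox <- spec$voxel_spacing_mm
  cc <- (n - 1) / 2
  x <- ((seq_len(n) - 1) - cc) * vox
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(x, n, n)
  R2 <- X^2 + Y^2
  lab <- phantom_label_slice(spec)
  cyl <- lab >= 0
  # hot ROI: inside the cylinder, clear of the wall and of every rod by
  # one rod-radius worth of margin
  roi <- cyl & R2 <= (spec$cylinder_radius_mm - 2 * vox)^2 & lab == 0
  rods <- phantom_layout(spec)
  for (a in 1:6) {
    grow2 <- (spec$rod_diameters_mm[a] / 2 + 2 * vox)^2
    for (i in seq_len(nrow(rods[[a]]))) {
      p <- rods[[a]][i, ]
      roi[(X - p[1])^2 + (Y - p[2])^2 <= grow2] <- FALSE
    }
  }
  bg <- make_background_slice(n, vox, spec$cylinder_radius_mm)
  rod <- matrix(0L, n, n)
  rod[lab >= 10] <- lab[lab >= 10] - 10L
  rep_slice <- function(m) array(rep(m, spec$n_slices),
                                 c(n, n, spec$n_slices))
  list(cylinder = rep_slice(cyl), roi = rep_slice(roi),
       background = rep_slice(bg), rod_labels = rep_slice(rod))
}

# Background annulus: outside the (dilated) cylinder, inside the usable
# part of the reconstruction circle, eroded so that padding effects and
# the exactly-zero corners outside the scan circle are excluded.
make_background_slice <- function(n, vox, cyl_radius_mm) {
  cc <- (n - 1) / 2
  x <- ((seq_len(n) - 1) - cc) * vox
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(x, n, n)
  R2 <- X^2 + Y^2
  outer_r <- 0.95 * (n / 2) * vox - 2 * vox
  inner_r <- cyl_radius_mm + 2 * vox
  R2 > inner_r^2 & R2 < outer_r^2
}

#' Background mask for an arbitrary volume
#'
#' Convenience builder for volumes not produced by the simulator: the
#' background is everything outside a central disc of radius
#' `object_radius_mm`, restricted to the usable reconstruction circle and
#' eroded by two voxels, replicated across slices.
#'
#' @param vol An `mso_volume`.
#' @param object_radius_mm Radius of the object to exclude, in mm.
#' @return A logical 3D array on the volume grid.
#' @export
make_background_mask <- function(vol, object_radius_mm) {
  vol <- as_volume(vol)
  d <- dim(vol$values)
  if (d[1] != d[2])
    stop("background helper expects a square in-plane grid", call. = FALSE)
  sl <- make_background_slice(d[1], vol$spacing_mm[1], object_radius_mm)
  array(rep(sl, d[3]), d)
}

## ---- projection and reconstruction ---------------------------------------

#' Forward projection of a slice (discrete Radon transform)
#'
#' Computes parallel-beam line-integral projections by rotate-and-sum:
#' for each angle the slice is resampled (bilinear) on a rotated grid and
#' summed along the ray direction. Distances are in pixel units, so the
#' total of each projection equals the slice sum up to discretisation at
#' the grid edge.
#'
#' @param slice Numeric matrix (one slice) or an `mso_volume`, in which
#'   case each slice is projected and a list of sinograms is returned.
#' @param n_angles Number of projection angles (>= 1).
#' @param angle_span_deg Angular span; angles are evenly spaced over
#'   `[0, angle_span_deg)` (default 180, the parallel-beam half-turn).
#' @param detector_spacing_mm Physical detector bin spacing recorded in
#'   the sinogram (defaults to the voxel spacing for volumes, 1 for bare
#'   matrices).
#' @return A `sinogram` object: list with `values`
#'   (`n_angles x n_detector_bins`), `angles_deg`, `detector_spacing_mm`.
#' @export
forward_project <- function(slice, n_angles, angle_span_deg = 180,
                            detector_spacing_mm = NULL) {
  if (inherits(slice, "mso_volume")) {
    sp <- slice$spacing_mm[1]
    return(lapply(seq_len(dim(slice$values)[3]), function(z)
      forward_project(slice$values[, , z], n_angles, angle_span_deg,
                      detector_spacing_mm %||% sp)))
  }
  if (!is.matrix(slice) || length(slice) == 0L)
    stop("`slice` must be a non-empty matrix", call. = FALSE)
  n_angles <- as.integer(n_angles)
  if (n_angles < 1L) stop("n_angles must be >= 1", call. = FALSE)
  n <- nrow(slice)
  if (ncol(slice) != n) stop("slice must be square", call. = FALSE)
  angles <- seq(0, angle_span_deg, length.out = n_angles + 1L)[seq_len(n_angles)]
  ctr <- (n + 1) / 2
  tgrid <- seq_len(n) - ctr
  TT <- matrix(tgrid, n, n, byrow = TRUE)  # detector coordinate, by column
  SS <- matrix(tgrid, n, n)                # ray coordinate, by row
  out <- matrix(0, n_angles, n)
  for (ai in seq_len(n_angles)) {
    th <- angles[ai] * pi / 180
    Xc <- TT * cos(th) - SS * sin(th)
    Yc <- TT * sin(th) + SS * cos(th)
    vals <- interp_bilinear(slice, Yc + ctr, Xc + ctr)
    out[ai, ] <- colSums(matrix(vals, n, n))
  }
  structure(list(values = out, angles_deg = angles,
                 detector_spacing_mm = detector_spacing_mm %||% 1),
            class = "sinogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add Poisson counting noise to a sinogram
#'
#' Each bin is replaced by a Poisson draw with mean equal to the bin
#' value. Reproducible given the seed; the caller's RNG state is left
#' untouched.
#'
#' @param sino A `sinogram` (bins must be non-negative; values within
#'   floating-point jitter below zero are clamped to 0).
#' @param seed Integer seed.
#' @return A `sinogram` with integer-valued bins.
#' @export
add_poisson_noise <- function(sino, seed) {
  stopifnot(inherits(sino, "sinogram"))
  v <- sino$values
  if (any(v < -1e-8 * max(abs(v), 1)))
    stop("sinogram has negative bins; Poisson noise undefined",
         call. = FALSE)
  v[v < 0] <- 0
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  noisy <- matrix(stats::rpois(length(v), as.vector(v)),
                  nrow(v), ncol(v))
  out <- sino
  out$values <- noisy
  out
}

# Ram-Lak ramp filter in the Fourier domain, built from its real-space
# response to avoid the DC bias of the naive |f| ramp.
ramp_filter_fourier <- function(npad, window = c("none", "hann")) {
  window <- match.arg(window)
  f <- numeric(npad)
  f[1] <- 0.25
  kk <- seq(1, npad / 2, by = 2)
  f[kk + 1] <- -1 / (pi * kk)^2
  f[npad - kk + 1] <- -1 / (pi * kk)^2
  filt <- 2 * Re(stats::fft(f))
  if (window == "hann") {
    fr <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / npad
    filt <- filt * 0.5 * (1 + cos(2 * pi * fr))
  }
  filt
}

#' Filtered back-projection of a sinogram
#'
#' Reconstructs one slice on the original grid: each projection is ramp
#' filtered (Ram-Lak; optional Hann apodisation) in the Fourier domain and
#' smeared back across the image at its acquisition angle. With few angles
#' and Poisson noise the reconstruction shows the radial streak artifacts
#' characteristic of angularly undersampled FBP.
#'
#' @param sino A `sinogram` from [forward_project()].
#' @param filter `"ramp"` (default; maximises streak contrast) or
#'   `"hann"`.
#' @return A numeric matrix (`n x n`, `n` = detector bin count).
#' @export
fbp_reconstruct <- function(sino, filter = c("ramp", "hann")) {
  stopifnot(inherits(sino, "sinogram"))
  filter <- match.arg(filter)
  P <- sino$values
  n_angles <- nrow(P)
  if (n_angles < 1L) stop("sinogram has no angles", call. = FALSE)
  n <- ncol(P)
  npad <- max(64L, 2L^ceiling(log2(2 * n)))
  filt <- ramp_filter_fourier(npad,
                              if (filter == "hann") "hann" else "none")
  Q <- matrix(0, n_angles, n)
  for (ai in seq_len(n_angles)) {
    p <- c(P[ai, ], numeric(npad - n))
    q <- Re(stats::fft(stats::fft(p) * filt, inverse = TRUE)) / npad
    Q[ai, ] <- q[seq_len(n)]
  }
  ctr <- (n + 1) / 2
  tgrid <- seq_len(n) - ctr
  X <- matrix(tgrid, n, n, byrow = TRUE)
  Y <- matrix(tgrid, n, n)
  rec <- matrix(0, n, n)
  for (ai in seq_len(n_angles)) {
    th <- sino$angles_deg[ai] * pi / 180
    tt <- X * cos(th) + Y * sin(th) + ctr
    i0 <- floor(tt)
    fr <- tt - i0
    inside <- i0 >= 1 & i0 < n
    q <- Q[ai, ]
    contrib <- matrix(0, n, n)
    contrib[inside] <- q[i0[inside]] * (1 - fr[inside]) +
      q[i0[inside] + 1L] * fr[inside]
    rec <- rec + contrib
  }
  rec * pi / (2 * n_angles)
}

#' Simulate an FBP-reconstructed phantom with streak artifacts
#'
#' End-to-end simulation: rasterise the phantom, forward project each
#' slice over `n_angles` parallel-beam angles, add Poisson counting noise
#' (slice `z` uses seed `spec$seed + z - 1`), and reconstruct by filtered
#' back-projection. The default 84 angles with an unapodised ramp filter
#' produce pronounced radial streaks in the background.
#'
#' @param spec A [phantom_spec()].
#' @param n_angles Number of projection angles (default 84).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param filter Reconstruction filter, `"ramp"` or `"hann"`.
#' @return A list: `ground_truth` (`mso_volume`), `recon` (`mso_volume`),
#'   `masks` (from [phantom_masks()]), `sinograms` (list, one per slice),
#'   `spec`, `n_angles`.
#' @export
simulate_fbp_phantom <- function(spec, n_angles = 84L,
                                 noise = c("poisson", "none"),
                                 filter = c("ramp", "hann")) {
  stopifnot(inherits(spec, "phantom_spec"))
  noise <- match.arg(noise)
  filter <- match.arg(filter)
  truth <- make_phantom(spec)
  n <- spec$grid_size
  # all ground-truth slices are identical: project once, noise per slice
  clean <- forward_project(truth$values[, , 1], n_angles,
                           detector_spacing_mm = spec$voxel_spacing_mm)
  sinos <- vector("list", spec$n_slices)
  rec <- array(0, dim(truth$values))
  for (z in seq_len(spec$n_slices)) {
    s <- if (noise == "poisson")
      add_poisson_noise(clean, seed = spec$seed + z - 1L) else clean
    sinos[[z]] <- s
    rec[, , z] <- fbp_reconstruct(s, filter = filter)
  }
  list(ground_truth = truth,
       recon = volume(rec, rep(spec$voxel_spacing_mm, 3)),
       masks = phantom_masks(spec),
       sinograms = sinos, spec = spec, n_angles = n_angles)
}
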