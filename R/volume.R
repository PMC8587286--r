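#' PET volume container
#'
#' A lightweight container for a 3D scalar image together with its voxel
#' spacing. Values are stored as a base-R array indexed
#' `values[row, col, slice]`; physical coordinates are assigned to voxel
#' centres, with the centre of voxel `(i, j)` (0-based) of a slice at
#' `(i * spacing, j * spacing)` mm. A 2D matrix is promoted to a
#' single-slice volume. All processing is done in 64-bit floating point.
#'
#' @param values Numeric matrix or 3D array of voxel values. Must be finite.
#' @param spacing_mm Per-axis voxel spacing in mm, length 3
#'   (row, col, slice) or a single number recycled to all axes.
#' @return An object of class `mso_volume`: a list with elements `values`
#'   (3D array) and `spacing_mm` (length-3 numeric).
#' @examples
#' v <- volume(array(rnorm(8 * 8 * 2), c(8, 8, 2)), spacing_mm = 700 / 168)
#' dim(v$values)
#' @export
volume <- function(values, spacing_mm = c(1, 1, 1)) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a matrix or a 3D array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume contains non-finite voxel values", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm)),
            class = "mso_volume")
}

#' Coerce to a PET volume
#'
#' @param x An `mso_volume`, matrix or 3D array.
#' @param spacing_mm Spacing used when `x` is a bare array.
#' @return An `mso_volume`.
#' @export
as_volume <- function(x, spacing_mm = c(1, 1, 1)) {
  if (inherits(x, "mso_volume")) return(x)
  volume(x, spacing_mm)
}

#' @export
print.mso_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mso_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 5), collapse = " x ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Read a volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An `mso_volume` with spacing taken from the NIfTI header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input volume not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))  # strip NIfTI attributes
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3L - length(sp)))
  volume(arr, spacing_mm = sp[1:3])
}

#' Write a volume to a NIfTI file
#'
#' @param vol An `mso_volume` (or array coercible to one).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Reflect an out-of-range 1-based index into [1, n] (edge-inclusive mirror:
# ... c b a | a b c ... | c b a).  Vectorised.
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  m <- (j - 1L) %% (2L * n)
  m <- ifelse(m < 0L, m + 2L * n, m)
  as.integer(ifelse(m < n, m + 1L, 2L * n - m))
}

# Shift a 3D array by integer offset d (length 3): out[x] = arr[x + d],
# with reflect or zero padding at the borders.
shift_array <- function(arr, d, padding = c("reflect", "zero")) {
  padding <- match.arg(padding)
  dm <- dim(arr)
  idx <- vector("list", 3L)
  ok <- vector("list", 3L)
  for (a in 1:3) {
    j <- seq_len(dm[a]) + d[a]
    if (padding == "reflect") {
      idx[[a]] <- reflect_index(j, dm[a])
      ok[[a]] <- rep(TRUE, dm[a])
    } else {
      valid <- j >= 1L & j <= dm[a]
      idx[[a]] <- ifelse(valid, j, 1L)
      ok[[a]] <- valid
    }
  }
  out <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (padding == "zero") {
    bad <- !(outer(outer(ok[[1]], ok[[2]], "&"), ok[[3]], "&"))
    if (any(bad)) out[bad] <- 0
  }
  out
}

# Bilinear interpolation of a matrix at fractional (row, col) 1-based
# coordinates; points outside the grid evaluate to 0.  Vectorised.
interp_bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  val <- numeric(length(row))
  # gather the four neighbours with zero outside
  pick <- function(ri, ci) {
    inside <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    if (any(inside))
      v[inside] <- img[cbind(ri[inside], ci[inside])]
    v
  }
  v00 <- pick(r0,      c0)
  v01 <- pick(r0,      c0 + 1)
  v10 <- pick(r0 + 1L, c0)
  v11 <- pick(r0 + 1L, c0 + 1)
  val <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
         v10 * fr       * (1 - fc) + v11 * fr       * fc
  val
}
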