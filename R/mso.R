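#' @title Binary morphological structure operators
#' @description
#' A morphological structure operator (MSO) is a small binary mask: 1 marks
#' a neighbour whose signal is kept ("reserved signal"), 0 marks a position
#' excluded from the local operation ("denoising structure"). Supported mask
#' shapes have every dimension in 1..3, covering the 2D families 2x2, 2x3,
#' 3x2, 3x3 and all eight 3D families from 2x2x2 up to 3x3x3. A mask with
#' L elements is identified by an integer code in `[1, 2^L - 1]`: element
#' `e` (0-based, row-major with the column index fastest and the slab index
#' slowest) corresponds to bit `e` of the code. The all-zero mask is
#' excluded: it selects no neighbours and its local mean is undefined.
#' @name mso
NULL

.supported_dim <- function(d) all(d >= 1L & d <= 3L)

check_shape <- function(shape) {
  shape <- as.integer(shape)
  if (!(length(shape) %in% 2:3) || !.supported_dim(shape))
    stop(sprintf("unsupported mask shape (%s): each dimension must be 1-3",
                 paste(shape, collapse = "x")), call. = FALSE)
  shape
}

#' Number of operator combinations in a mask family
#'
#' A family of shape `r x c` (or `r x c x s`) contains `2^(r*c)` (or
#' `2^(r*c*s)`) binary masks, counting the all-zero mask. The 2D families
#' 2x2, 2x3, 3x2 and 3x3 therefore hold 16, 64, 64 and 512 combinations,
#' and the 3D families range from 256 (2x2x2) to 134,217,728 (3x3x3).
#'
#' @param shape Integer vector of length 2 or 3, each entry in 1..3.
#' @return The family size `2^L` as a double (exact: `L <= 27`).
#' @examples
#' family_size(c(3, 3))       # 512
#' family_size(c(3, 3, 3))    # 134217728
#' @export
family_size <- function(shape) {
  shape <- check_shape(shape)
  2^prod(shape)
}

#' Construct a structuring element
#'
#' @param shape Mask shape, length 2 or 3, dimensions in 1..3.
#' @param code Integer code in `[1, 2^L - 1]`; bit `e` (0-based) sets mask
#'   element `e` in row-major order (column fastest, slab slowest).
#' @param bits Alternatively, a 0/1 matrix or array of dimension `shape`
#'   (supply either `code` or `bits`).
#' @return An object of class `structuring_element` with fields `shape`,
#'   `bits` (0/1 array), `code` and `popcount`.
#' @examples
#' se <- structuring_element(c(2, 2), code = 15)  # all-ones 2x2
#' se$popcount
#' @export
structuring_element <- function(shape, code = NULL, bits = NULL) {
  shape <- check_shape(shape)
  L <- prod(shape)
  if (is.null(code) == is.null(bits))
    stop("supply exactly one of `code` or `bits`", call. = FALSE)
  if (!is.null(bits)) {
    bits <- as.array(bits)
    if (!identical(as.integer(dim(bits)), shape) && !(length(shape) == 2L &&
        identical(as.integer(dim(as.matrix(bits))), shape)))
      stop("`bits` dimension does not match `shape`", call. = FALSE)
    bits <- array(as.numeric(bits), dim = shape)
    if (!all(bits %in% c(0, 1)))
      stop("`bits` must contain only 0 and 1", call. = FALSE)
    code <- sum(bits * 2^(element_index(shape)))
  } else {
    code <- as.numeric(code)
    if (length(code) != 1L || !is.finite(code) || code != floor(code) ||
        code < 1 || code > 2^L - 1)
      stop(sprintf("`code` must be an integer in [1, %s]",
                   format(2^L - 1, big.mark = ",")), call. = FALSE)
    b <- bits_of_code(code, L)
    eidx <- element_index(shape)
    bits <- array(b[as.vector(eidx) + 1L], dim = shape)
  }
  p <- sum(bits)
  if (p < 1) stop("the all-zero mask is excluded", call. = FALSE)
  structure(list(shape = shape, bits = bits, code = code, popcount = p),
            class = "structuring_element")
}

# element index e (0-based) for each array cell: row-major, column fastest,
# slab slowest; returned as an array of dim `shape`.
element_index <- function(shape) {
  if (length(shape) == 2L) {
    r <- shape[1]; cc <- shape[2]
    outer(seq_len(r) - 1L, seq_len(cc) - 1L, function(i, j) i * cc + j)
  } else {
    r <- shape[1]; cc <- shape[2]; s <- shape[3]
    e <- array(0, dim = shape)
    for (k in seq_len(s))
      e[, , k] <- outer(seq_len(r) - 1L, seq_len(cc) - 1L,
                        function(i, j) (k - 1L) * r * cc + i * cc + j)
    e
  }
}

# bit vector of a code: entry e + 1 holds bit e (0-based)
bits_of_code <- function(code, L) {
  b <- numeric(L)
  for (e in seq_len(L)) {
    b[e] <- code %% 2
    code <- code %/% 2
  }
  b
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> %s, code %s, popcount %d\n",
              paste(x$shape, collapse = "x"),
              format(x$code, scientific = FALSE), x$popcount))
  for (k in seq_len(if (length(x$shape) == 3L) x$shape[3] else 1L)) {
    m <- if (length(x$shape) == 3L) x$bits[, , k] else x$bits
    if (length(x$shape) == 3L) cat(sprintf(" slab %d:\n", k))
    for (i in seq_len(nrow(m)))
      cat("  ", paste(m[i, ], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize / deserialize a structuring element
#'
#' Masks are exchanged as JSON records `{"shape": [r, c, s], "code": n}`.
#'
#' @param se A `structuring_element`.
#' @param txt A JSON string produced by `se_to_json()`.
#' @return `se_to_json()` a JSON string; `se_from_json()` a
#'   `structuring_element`.
#' @export
se_to_json <- function(se) {
  stopifnot(inherits(se, "structuring_element"))
  jsonlite::toJSON(list(shape = se$shape, code = se$code),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname se_to_json
#' @export
se_from_json <- function(txt) {
  rec <- jsonlite::fromJSON(txt)
  structuring_element(rec$shape, code = rec$code)
}

## ---- ordered enumeration -------------------------------------------------

# Rank r (0-based) among the C(L, p) codes with popcount p, in ascending
# numeric code order (equivalently colexicographic order of the bit sets).
# Returns the 0-based bit positions.
unrank_popcount_class <- function(r, p, L) {
  pos <- integer(p)
  for (q in p:1) {
    cc <- q - 1
    while (cc + 1 <= L - 1 && choose(cc + 1, q) <= r) cc <- cc + 1
    pos[q] <- cc
    r <- r - choose(cc, q)
  }
  pos
}

#' Mask at a position on the ordered candidate axis
#'
#' The search modules order every non-zero mask of a family along a single
#' axis: ascending popcount first, ascending code within a popcount class.
#' This ordering makes the background-smoothing objective quasi-smooth along
#' the axis (smoothing strength is driven primarily by popcount), which the
#' interval-refinement search relies on. `mask_at()` maps an axis index to
#' its mask without materialising the family, so the 3x3x3 family
#' (134,217,727 non-zero masks) can be indexed lazily.
#'
#' @param shape Mask shape.
#' @param i Axis index in `[1, 2^L - 1]`.
#' @return A `structuring_element`.
#' @examples
#' mask_at(c(2, 2), 1)$popcount   # first mask on the axis has popcount 1
#' @export
mask_at <- function(shape, i) {
  shape <- check_shape(shape)
  L <- prod(shape)
  N <- 2^L - 1
  i <- as.numeric(i)
  if (length(i) != 1L || !is.finite(i) || i != floor(i) || i < 1 || i > N)
    stop(sprintf("axis index must be in [1, %s]",
                 format(N, big.mark = ",")), call. = FALSE)
  # locate the popcount class
  p <- 1L
  below <- 0
  while (i > below + choose(L, p)) {
    below <- below + choose(L, p)
    p <- p + 1L
  }
  pos <- unrank_popcount_class(i - below - 1, p, L)
  code <- sum(2^pos)
  structuring_element(shape, code = code)
}

#' Axis index of a mask under the (popcount, code) ordering
#'
#' Inverse of [mask_at()].
#'
#' @param se A `structuring_element`.
#' @return The 1-based axis index.
#' @export
axis_index <- function(se) {
  stopifnot(inherits(se, "structuring_element"))
  L <- prod(se$shape)
  p <- se$popcount
  below <- if (p > 1) sum(choose(L, seq_len(p - 1))) else 0
  pos <- sort(which(bits_of_code(se$code, L) == 1)) - 1L
  r <- sum(choose(pos, seq_along(pos)))
  below + r + 1
}

#' Enumerate every non-zero mask of a small family
#'
#' Materialises the full family in (popcount, code) ascending axis order.
#' Intended for families up to a few thousand masks; for the large 3D
#' families use [mask_at()] for lazy indexed access.
#'
#' @param shape Mask shape.
#' @param limit Safety cap on the family size (default `2^16`).
#' @return A list of `structuring_element` objects of length
#'   `family_size(shape) - 1`.
#' @export
enumerate_masks <- function(shape, limit = 2^16) {
  shape <- check_shape(shape)
  N <- family_size(shape) - 1
  if (N + 1 > limit)
    stop(sprintf(
      "family %s has %s masks; enumerate_masks() materialises the family, use mask_at() instead",
      paste(shape, collapse = "x"), format(N, big.mark = ",")), call. = FALSE)
  lapply(seq_len(N), function(i) mask_at(shape, i))
}

## ---- application ---------------------------------------------------------

# Convolution offsets for a mask: element e at position k (0-based, per
# axis) contributes the voxel at x - k + anchor, anchor = floor((n-1)/2).
# Returns an L x 3 matrix of offsets d such that the contribution of
# element e is shift_array(V, d[e, ])[x] = V[x + d[e, ]].
mso_offsets <- function(shape) {
  shape <- check_shape(shape)
  dims3 <- c(shape, if (length(shape) == 2L) 1L)
  anchor <- (dims3 - 1L) %/% 2L
  L <- prod(shape)
  eidx <- element_index(shape)
  off <- matrix(0L, L, 3L)
  it <- expand.grid(r = seq_len(dims3[1]) - 1L,
                    c = seq_len(dims3[2]) - 1L,
                    s = seq_len(dims3[3]) - 1L)
  for (n in seq_len(nrow(it))) {
    k <- c(it$r[n], it$c[n], it$s[n])
    e <- if (length(shape) == 2L) eidx[k[1] + 1L, k[2] + 1L]
         else eidx[k[1] + 1L, k[2] + 1L, k[3] + 1L]
    off[e + 1L, ] <- as.integer(anchor - k)
  }
  off
}

#' Apply a morphological structure operator to a volume
#'
#' Two readings of the binary-mask operation are provided. The default,
#' `"normalized_convolution"`, is the masked local mean: each output voxel
#' is the mean of the input voxels selected by the mask's 1-positions,
#' applied with the convolution (flipped-kernel) convention, so image
#' intensity scale is preserved regardless of how many positions the mask
#' keeps. `"opening"` is the classical grayscale morphological opening
#' (erosion followed by dilation) with the mask as flat structuring
#' element. 2D masks are applied slice by slice; 3D masks smooth across
#' neighbouring slices as well.
#'
#' Odd mask dimensions anchor at their centre; even dimensions anchor at
#' the lower index of the central pair (offset `floor((n-1)/2)`). Borders
#' use edge-inclusive mirror padding by default; zero padding is available
#' but darkens the rim and is not recommended when background statistics
#' are read off the result.
#'
#' @param vol An `mso_volume` (or array).
#' @param mask A `structuring_element`.
#' @param mode `"normalized_convolution"` (masked local mean, default) or
#'   `"opening"`.
#' @param padding `"reflect"` (default) or `"zero"`.
#' @return An `mso_volume` on the same grid and spacing as the input.
#' @examples
#' v <- volume(matrix(c(0, 4, 2, 6), 2, 2))
#' m <- structuring_element(c(2, 2), code = 15)
#' apply_mso(v, m)$values[2, 2, 1]  # mean of the four voxels = 3
#' @export
apply_mso <- function(vol, mask,
                      mode = c("normalized_convolution", "opening"),
                      padding = c("reflect", "zero")) {
  vol <- as_volume(vol)
  mode <- match.arg(mode)
  padding <- match.arg(padding)
  stopifnot(inherits(mask, "structuring_element"))
  if (mask$popcount < 1) stop("all-zero mask", call. = FALSE)
  if (!all(is.finite(vol$values)))
    stop("volume contains non-finite voxel values", call. = FALSE)
  if (length(mask$shape) == 3L && dim(vol$values)[3] < 1L)
    stop("3D mask requires a 3D volume", call. = FALSE)

  off <- mso_offsets(mask$shape)
  sel <- which(as.vector(aperm_bits(mask)) == 1)
  if (mode == "normalized_convolution") {
    acc <- NULL
    for (e in sel) {
      sh <- shift_array(vol$values, off[e, ], padding)
      acc <- if (is.null(acc)) sh else acc + sh
    }
    out <- acc / mask$popcount
  } else {
    # opening: erosion uses the mask as-is (element k probes x + (k - a),
    # i.e. offset -d), dilation uses the reflected mask (offset +d)
    ero <- NULL
    for (e in sel) {
      sh <- shift_array(vol$values, -off[e, ], padding)
      ero <- if (is.null(ero)) sh else pmin(ero, sh)
    }
    out <- NULL
    for (e in sel) {
      sh <- shift_array(ero, off[e, ], padding)
      out <- if (is.null(out)) sh else pmax(out, sh)
    }
  }
  volume(out, vol$spacing_mm)
}

# bits arranged so that as.vector() order matches element index order
# (element e at vector position e + 1)
aperm_bits <- function(mask) {
  b <- numeric(prod(mask$shape))
  eidx <- element_index(mask$shape)
  b[as.vector(eidx) + 1L] <- as.vector(mask$bits)
  b
}

#' Average the outputs of a set of structuring elements
#'
#' Applies each mask to the volume and returns the voxelwise arithmetic
#' mean of the results. This is the final denoising step of the search
#' pipeline: the top-ranked masks (typically five) are averaged into one
#' output volume.
#'
#' @param vol An `mso_volume` (or array).
#' @param masks Non-empty list of `structuring_element`s of one shape.
#' @inheritParams apply_mso
#' @return An `mso_volume`.
#' @export
apply_mask_set_average <- function(vol, masks,
                                   mode = c("normalized_convolution",
                                            "opening"),
                                   padding = c("reflect", "zero")) {
  vol <- as_volume(vol)
  mode <- match.arg(mode)
  padding <- match.arg(padding)
  if (!is.list(masks) || length(masks) == 0L)
    stop("`masks` must be a non-empty list of structuring elements",
         call. = FALSE)
  shp <- masks[[1]]$shape
  for (m in masks) {
    stopifnot(inherits(m, "structuring_element"))
    if (!identical(m$shape, shp))
      stop("all masks in a set must share one shape", call. = FALSE)
  }
  acc <- NULL
  for (m in masks) {
    out <- apply_mso(vol, m, mode = mode, padding = padding)$values
    acc <- if (is.null(acc)) out else acc + out
  }
  volume(acc / length(masks), vol$spacing_mm)
}
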