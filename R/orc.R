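#' Response curve between successive objective values
#'
#' The soft comparison `exp(g*e_curr) / (exp(g*e_curr) + exp(g*e_prev))`,
#' computed in log space so large objectives cannot overflow. It equals
#' 0.5 when the two objectives are equal (or as `gamma` tends to 0) and
#' approaches 0 or 1 as they separate; the search logs it per refinement
#' round as a convergence diagnostic and can optionally use its distance
#' from 0.5 as an early-stop signal.
#'
#' @param e_curr,e_prev Objective values (finite).
#' @param gamma Deviation parameter, > 0.
#' @return A value in (0, 1).
#' @examples
#' response_curve(1, 0, gamma = 1)  # 1 / (1 + exp(-1)) ~ 0.7311
#' @export
response_curve <- function(e_curr, e_prev, gamma = 1) {
  if (!is.finite(e_curr) || !is.finite(e_prev))
    stop("objective values must be finite", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma must be positive", call. = FALSE)
  stats::plogis(gamma * (e_curr - e_prev))
}

#' Search objective: mean background STD after applying one mask
#'
#' Applies the mask to the volume and returns the mean per-slice
#' population standard deviation of the background. The function is pure
#' (no shared mutable state), so evaluations of different masks may be
#' scheduled concurrently or in any order with bit-identical results.
#'
#' @param vol An `mso_volume` (or array).
#' @param mask A `structuring_element`.
#' @param background Logical/0-1 array on the volume grid.
#' @inheritParams apply_mso
#' @return A single number.
#' @export
evaluate_objective <- function(vol, mask, background,
                               mode = c("normalized_convolution",
                                        "opening"),
                               padding = c("reflect", "zero")) {
  mode <- match.arg(mode)
  padding <- match.arg(padding)
  mean_background_std(apply_mso(vol, mask, mode = mode, padding = padding),
                      background)
}

## ---- fast objective for the masked-mean mode ------------------------------
#
# For normalized convolution the denoised value at voxel x is
# (1/p) * sum_e bits_e * S_e(x), where S_e is the input shifted by the
# element-e convolution offset.  Per-slice mean and variance over the
# background are then quadratic forms in the bit vector, so we precompute,
# once per (volume, shape, background):
#   n_z            background voxel count per slice
#   A  (S x L)     per-slice sums of each shifted field over the background
#   G_z (L x L)    per-slice Gram matrices of the shifted fields
# after which each mask evaluation costs O(S * L^2).  The generic
# evaluate_objective() path is retained as the independent route and the
# two are checked against each other in the test suite.
objective_stats <- function(vol, shape, background, padding = "reflect") {
  vol <- as_volume(vol)
  d <- dim(vol$values)
  bg <- coerce_mask(background, d)
  off <- mso_offsets(shape)
  L <- nrow(off)
  slice_id <- rep(seq_len(d[3]), each = d[1] * d[2])[as.vector(bg)]
  idx <- which(bg)
  M <- matrix(0, length(idx), L)
  for (e in seq_len(L))
    M[, e] <- shift_array(vol$values, off[e, ], padding)[idx]
  n_z <- as.vector(table(factor(slice_id, levels = seq_len(d[3]))))
  keep <- n_z > 0
  A <- rowsum(M, slice_id)              # per-slice column sums
  G <- lapply(which(keep), function(z) crossprod(M[slice_id == z, ,
                                                   drop = FALSE]))
  list(A = A, G = G, n_z = n_z[keep], L = L)
}

objective_from_stats <- function(st, bits) {
  p <- sum(bits)
  sds <- vapply(seq_along(st$G), function(k) {
    n <- st$n_z[k]
    s1 <- sum(st$A[k, ] * bits) / p
    q <- as.numeric(crossprod(bits, st$G[[k]] %*% bits)) / p^2
    v <- q / n - (s1 / n)^2
    sqrt(max(v, 0))
  }, numeric(1))
  mean(sds)
}

make_objective_fn <- function(vol, shape, background, mode, padding) {
  if (mode == "normalized_convolution") {
    st <- objective_stats(vol, shape, background, padding)
    function(se) objective_from_stats(st, aperm_bits(se))
  } else {
    function(se) evaluate_objective(vol, se, background, mode = mode,
                                    padding = padding)
  }
}

rank_evaluated <- function(codes, objectives, shape, k) {
  ord <- order(objectives, codes)
  top <- ord[seq_len(min(k, length(ord)))]
  list(top = data.frame(code = codes[top], objective = objectives[top]),
       masks = lapply(codes[top],
                      function(cd) structuring_element(shape, code = cd)))
}

new_search_result <- function(shape, mode, ranked, n_evaluated, pool,
                              rounds = NULL, method = "exhaustive") {
  structure(list(shape = shape, mode = mode, top = ranked$top,
                 top_masks = ranked$masks, n_evaluated = n_evaluated,
                 pool = pool, rounds = rounds, method = method),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s family, %s, %d objective evaluations\n",
              paste(x$shape, collapse = "x"), x$method, x$n_evaluated))
  df <- x$top
  df$popcount <- vapply(x$top_masks, function(m) m$popcount, numeric(1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Exhaustive structuring-element search
#'
#' Evaluates every non-zero mask of the family and returns the `k` masks
#' with the lowest mean background standard deviation. Ties are broken by
#' the smaller mask code. Refuses families larger than `cap` (use
#' [orc_search()] there).
#'
#' @param vol An `mso_volume` (or array).
#' @param shape Mask family shape.
#' @param background Logical/0-1 array on the volume grid.
#' @inheritParams apply_mso
#' @param k Number of top masks to return (default 5).
#' @param cap Largest family size this function will enumerate
#'   (default `2^12`).
#' @return A `search_result`: ranked `top` data frame, `top_masks` list,
#'   `n_evaluated`, `pool` (all evaluated codes).
#' @export
exhaustive_search <- function(vol, shape, background,
                              mode = c("normalized_convolution",
                                       "opening"),
                              k = 5, cap = 2^12,
                              padding = c("reflect", "zero")) {
  mode <- match.arg(mode)
  padding <- match.arg(padding)
  shape <- check_shape(shape)
  N <- family_size(shape) - 1
  if (N + 1 > cap)
    stop(sprintf(
      "family %s has %s masks, above the exhaustive cap; use orc_search()",
      paste(shape, collapse = "x"), format(N + 1, big.mark = ",")),
      call. = FALSE)
  f <- make_objective_fn(vol, shape, background, mode, padding)
  codes <- numeric(N)
  objs <- numeric(N)
  for (i in seq_len(N)) {
    se <- mask_at(shape, i)
    codes[i] <- se$code
    objs[i] <- f(se)
  }
  ranked <- rank_evaluated(codes, objs, shape, k)
  new_search_result(shape, mode, ranked, n_evaluated = N, pool = codes,
                    method = "exhaustive")
}

#' Interval-refinement minimisation over an ordered candidate axis
#'
#' The generic engine behind [orc_search()], usable with any black-box
#' objective over indices `1..N`. Each round samples up to
#' `samples_per_round` evenly spaced indices across the current intervals
#' (interval endpoints always included), evaluates the objective at each
#' (with caching), keeps the two sampled indices with the lowest values,
#' and replaces the intervals by the spans between each kept index's
#' flanking sampled neighbours. Refinement stops when the remaining
#' candidate count is at most `pool_target`; the final pool is then
#' evaluated exhaustively. Fully deterministic: no randomness, ties broken
#' by the smaller index.
#'
#' @param N Number of candidates on the axis.
#' @param f Objective: function of a single index, returning a finite
#'   number. Must be pure.
#' @param samples_per_round Samples per refinement round (default 100).
#' @param pool_target Refine until at most this many candidates remain
#'   (default 200).
#' @param gamma Response-curve deviation parameter for the per-round
#'   convergence diagnostic (default 1).
#' @param early_stop If `TRUE`, stop refining once the response curve
#'   between successive round minima is within `early_stop_tol` of 0.5.
#' @param early_stop_tol Tolerance for `early_stop` (default 1e-3).
#' @return A list: `evaluated` (data frame `index`, `objective`), `pool`
#'   (indices of the final pool), `rounds` (per-round diagnostics),
#'   `n_evaluated`.
#' @export
orc_refine <- function(N, f, samples_per_round = 100, pool_target = 200,
                       gamma = 1, early_stop = FALSE,
                       early_stop_tol = 1e-3) {
  N <- as.numeric(N)
  stopifnot(N >= 1, samples_per_round >= 4, pool_target >= 2)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(i) {
    key <- ikey(i)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- f(i)
    if (!is.finite(v)) stop("objective returned a non-finite value",
                            call. = FALSE)
    cache[[key]] <- v
    v
  }
  intervals <- matrix(c(1, N), 1)   # rows: lo, hi (inclusive)
  total_len <- function(iv) sum(iv[, 2] - iv[, 1] + 1)
  rounds <- list()
  best_prev <- NA_real_
  round_no <- 0L
  repeat {
    len <- total_len(intervals)
    if (len <= pool_target) break
    round_no <- round_no + 1L
    # allocate samples across intervals proportional to their lengths
    lens <- intervals[, 2] - intervals[, 1] + 1
    alloc <- pmax(2, round(samples_per_round * lens / sum(lens)))
    alloc <- pmin(alloc, lens)
    samp <- list()
    for (r in seq_len(nrow(intervals))) {
      s <- unique(round(seq(intervals[r, 1], intervals[r, 2],
                            length.out = alloc[r])))
      samp[[r]] <- s
    }
    all_s <- sort(unique(unlist(samp)))
    if (length(all_s) < 2L) break   # intervals collapsed: finalize early
    objs <- vapply(all_s, evaluate, numeric(1))
    ord <- order(objs, all_s)
    kept <- all_s[ord[seq_len(min(2L, length(all_s)))]]
    # new intervals: span between each kept index's flanking neighbours
    # within its own interval's sample set
    new_iv <- NULL
    for (ki in kept) {
      r <- which(intervals[, 1] <= ki & intervals[, 2] >= ki)[1]
      s <- samp[[r]]
      pos <- match(ki, s)
      lo <- if (pos > 1L) s[pos - 1L] else s[1L]
      hi <- if (pos < length(s)) s[pos + 1L] else s[length(s)]
      new_iv <- rbind(new_iv, c(lo, hi))
    }
    new_iv <- merge_intervals(new_iv)
    best <- objs[ord[1]]
    rc <- if (is.na(best_prev)) NA_real_
          else response_curve(best, best_prev, gamma)
    rounds[[round_no]] <- data.frame(
      round = round_no, n_sampled = length(all_s),
      best_index = kept[1], best_objective = best,
      second_index = if (length(kept) > 1L) kept[2] else NA_real_,
      remaining = total_len(new_iv), response_curve = rc)
    stop_now <- early_stop && !is.na(rc) && abs(rc - 0.5) < early_stop_tol
    if (total_len(new_iv) >= len) {
      # no shrink: trim deterministically to the pool target and stop
      pool_iv <- thin_intervals(new_iv, pool_target)
      intervals <- pool_iv
      break
    }
    intervals <- new_iv
    best_prev <- best
    if (stop_now) {
      intervals <- thin_intervals(intervals, pool_target)
      break
    }
  }
  pool <- unlist(apply(intervals, 1, function(iv) seq(iv[1], iv[2]),
                       simplify = FALSE))
  if (length(pool) > pool_target)
    pool <- unique(round(seq(min(pool), max(pool),
                             length.out = pool_target)))
  for (i in pool) evaluate(i)
  keys <- ls(cache)
  idx <- as.numeric(keys)
  list(evaluated = data.frame(index = idx,
                              objective = vapply(keys, function(k)
                                cache[[k]], numeric(1))),
       pool = sort(pool),
       rounds = if (length(rounds)) do.call(rbind, rounds) else NULL,
       n_evaluated = length(keys))
}

# scalar index -> stable cache key (no scientific notation, no padding)
ikey <- function(i) format(i, scientific = FALSE, trim = TRUE)

merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (r in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[r, 1] <= out[last, 2] + 1) {
      out[last, 2] <- max(out[last, 2], iv[r, 2])
    } else {
      out <- rbind(out, iv[r, ])
    }
  }
  out
}

# deterministic even thinning of interval indices down to at most `target`
thin_intervals <- function(iv, target) {
  all_i <- unlist(apply(iv, 1, function(r) seq(r[1], r[2]),
                        simplify = FALSE))
  if (length(all_i) <= target) return(iv)
  keep <- unique(round(seq(1, length(all_i), length.out = target)))
  kept <- sort(all_i[keep])
  cbind(kept, kept)
}

#' Optimal-response-curve search over a large mask family
#'
#' Minimises the mean background standard deviation over a mask family too
#' large to enumerate (for 3x3x3, 134,217,727 candidates) by interval
#' refinement along the (popcount, code)-ordered candidate axis: sample
#' `samples_per_round` evenly spaced candidates, keep the two lowest, zoom
#' into the spans around them, and repeat until at most `pool_target`
#' candidates remain; the final pool is evaluated exhaustively. A few
#' hundred objective evaluations replace the full enumeration. Families
#' already at or below `pool_target` degenerate to [exhaustive_search()]
#' with an identical result.
#'
#' @inheritParams exhaustive_search
#' @inheritParams orc_refine
#' @return A `search_result` with per-round `rounds` diagnostics
#'   (including the response-curve value between successive round minima)
#'   and the final `pool` of axis indices.
#' @export
orc_search <- function(vol, shape, background,
                       mode = c("normalized_convolution", "opening"),
                       samples_per_round = 100, pool_target = 200, k = 5,
                       gamma = 1, early_stop = FALSE,
                       padding = c("reflect", "zero")) {
  mode <- match.arg(mode)
  padding <- match.arg(padding)
  shape <- check_shape(shape)
  N <- family_size(shape) - 1
  if (N <= pool_target) {
    res <- exhaustive_search(vol, shape, background, mode = mode, k = k,
                             cap = pool_target + 1, padding = padding)
    res$method <- "orc (degenerate: exhaustive)"
    return(res)
  }
  f_mask <- make_objective_fn(vol, shape, background, mode, padding)
  code_of <- new.env(parent = emptyenv())
  f <- function(i) {
    se <- mask_at(shape, i)
    assign(ikey(i), se$code, envir = code_of)
    f_mask(se)
  }
  ref <- orc_refine(N, f, samples_per_round = samples_per_round,
                    pool_target = pool_target, gamma = gamma,
                    early_stop = early_stop)
  codes <- vapply(ref$evaluated$index,
                  function(i) get(ikey(i), envir = code_of), numeric(1))
  ranked <- rank_evaluated(codes, ref$evaluated$objective, shape, k)
  new_search_result(shape, mode, ranked, n_evaluated = ref$n_evaluated,
                    pool = ref$pool, rounds = ref$rounds, method = "orc")
}
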