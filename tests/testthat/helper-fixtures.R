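# Shared fixtures, memoised for the duration of the test run.

fixture_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(grid = 64, slices = 8, seed = 7, angles = 84) {
    key <- paste(grid, slices, seed, angles, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_fbp_phantom(
        phantom_spec(grid_size = grid, n_slices = slices, seed = seed),
        n_angles = angles)
    cache[[key]]
  }
})

# a small fixed noisy slice stack (not a phantom) for operator unit tests
fixture_noise_volume <- function(dims = c(16, 16, 4), seed = 11) {
  set.seed(seed)
  volume(array(rnorm(prod(dims), mean = 10, sd = 2), dims))
}

# Independent brute-force oracle for the masked-mean operation: explicit
# loops over voxels and mask elements, flipped-kernel convention, with
# edge-inclusive mirror padding.  Deliberately slow and simple.
oracle_masked_mean <- function(vals, bits) {
  d3 <- dim(vals)
  kd <- dim(bits)
  if (length(kd) == 2L) kd <- c(kd, 1L)
  bits <- array(bits, kd)
  anchor <- (kd - 1L) %/% 2L
  refl <- function(j, n) {
    while (j < 1L || j > n) {
      if (j < 1L) j <- 1L - j          # edge-inclusive mirror: 0 -> 1
      if (j > n) j <- 2L * n - j + 1L  # n + 1 -> n
    }
    j
  }
  out <- array(0, d3)
  p <- sum(bits)
  for (x in seq_len(d3[1])) for (y in seq_len(d3[2]))
    for (z in seq_len(d3[3])) {
      acc <- 0
      for (i in seq_len(kd[1])) for (j in seq_len(kd[2]))
        for (s in seq_len(kd[3])) {
          if (bits[i, j, s] == 0) next
          # element at 0-based position k contributes voxel x - k + anchor
          xi <- refl(x - (i - 1L) + anchor[1], d3[1])
          yj <- refl(y - (j - 1L) + anchor[2], d3[2])
          zs <- refl(z - (s - 1L) + anchor[3], d3[3])
          acc <- acc + vals[xi, yj, zs]
        }
      out[x, y, z] <- acc / p
    }
  out
}
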