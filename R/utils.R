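# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Deterministic per-subject seed from a master seed; stays below 2^31.
child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 16807) %% 2147483629L)
}

# ---- spectra ---------------------------------------------------------------

# One-sided periodogram of a demeaned series: frequencies k/(n*tr), k = 1..n/2.
periodogram <- function(x, tr_seconds) {
  n <- length(x)
  x <- x - mean(x)
  xf <- stats::fft(x)
  k <- seq_len(floor(n / 2))
  list(freq = k / (n * tr_seconds), power = Mod(xf[k + 1L])^2)
}

# Fraction of periodogram power falling in [lo, hi) Hz.
band_power_fraction <- function(x, tr_seconds, lo, hi) {
  pg <- periodogram(x, tr_seconds)
  tot <- sum(pg$power)
  if (tot <= 0) return(0)
  sum(pg$power[pg$freq >= lo & pg$freq < hi]) / tot
}

# ---- 3D connected components (26-connectivity) -----------------------------

# Label TRUE voxels of a logical 3D array; returns an integer array, 0 = background.
# Union-find over the 13 forward neighbour offsets.
label_components_3d <- function(mask) {
  .assert(is.logical(mask) && length(dim(mask)) == 3L, "mask must be a logical 3D array")
  dims <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  out <- array(0L, dims)
  if (n == 0L) return(out)
  pos <- arrayInd(idx, dims)
  # map linear voxel index -> 1..n id
  id <- integer(prod(dims))
  id[idx] <- seq_len(n)

  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    np <- pos + matrix(offs[o, ], n, 3, byrow = TRUE)
    ok <- np[, 1] >= 1 & np[, 1] <= dims[1] &
      np[, 2] >= 1 & np[, 2] <= dims[2] &
      np[, 3] >= 1 & np[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- np[ok, 1] + (np[ok, 2] - 1L) * dims[1] + (np[ok, 3] - 1L) * dims[1] * dims[2]
    nb <- id[lin]
    hit <- which(nb > 0L)
    src <- which(ok)[hit]
    for (j in seq_along(hit)) {
      ra <- find(src[j]); rb <- find(nb[hit[j]])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out[idx] <- match(roots, unique(roots))
  out
}

# Sizes of labelled components (named integer vector, label -> voxel count).
component_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0L])
  stats::setNames(tab, seq_along(tab))
}

# ---- Gaussian smoothing (separable, replicate edges) -----------------------

fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# n x n one-dimensional smoothing operator with out-of-range kernel mass
# folded onto the nearest edge sample (replicate padding).  Rows sum to 1.
smoothing_matrix_1d <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + (-r:r)
    jc <- pmin(pmax(j, 1L), n)
    for (m in seq_along(j)) S[i, jc[m]] <- S[i, jc[m]] + k[m]
  }
  S
}

# Smooth a 3D array with an isotropic-in-mm Gaussian, per-axis sigma in voxels.
gaussian_smooth_array <- function(arr, fwhm_mm, voxel_mm) {
  dims <- dim(arr)
  .assert(length(dims) == 3L, "arr must be 3D")
  if (fwhm_mm <= 0) return(arr)
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_mm
  Sx <- smoothing_matrix_1d(dims[1], sig[1])
  Sy <- smoothing_matrix_1d(dims[2], sig[2])
  Sz <- smoothing_matrix_1d(dims[3], sig[3])
  # axis 1
  m <- matrix(arr, dims[1], dims[2] * dims[3])
  arr <- array(Sx %*% m, dims)
  # axis 2
  a <- aperm(arr, c(2, 1, 3))
  m <- matrix(a, dims[2], dims[1] * dims[3])
  arr <- aperm(array(Sy %*% m, c(dims[2], dims[1], dims[3])), c(2, 1, 3))
  # axis 3
  a <- aperm(arr, c(3, 1, 2))
  m <- matrix(a, dims[3], dims[1] * dims[2])
  aperm(array(Sz %*% m, c(dims[3], dims[1], dims[2])), c(2, 3, 1))
}

# Per-voxel standard deviation of gaussian_smooth_array() applied to unit white
# noise: outer product of row sums of squares of the separable 1D operators.
smoothed_noise_sd <- function(dims, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(array(1, dims))
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_mm
  rs <- lapply(seq_len(3), function(a) {
    rowSums(smoothing_matrix_1d(dims[a], sig[a])^2)
  })
  array(sqrt(outer(outer(rs[[1]], rs[[2]]), rs[[3]])), dims)
}

# ---- misc ------------------------------------------------------------------

# Sample skewness / excess kurtosis (moment estimators).
moment_skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
moment_kurtosis <- function(x) {
  mean((x - mean(x))^4) / (mean((x - mean(x))^2))^2 - 3
}

# Shannon entropy (nats) of a 64-bin equal-width histogram.
histogram_entropy <- function(x, bins = 64L) {
  rg <- range(x)
  .assert(diff(rg) > 0, "cannot compute histogram entropy of a constant signal")
  cuts <- seq(rg[1], rg[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE, all.inside = TRUE), bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log(p))
}
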