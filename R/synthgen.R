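# Ground-truth phantom generator.
#
# Each phantom run is a linear mixture of latent spatial sources:
#   * network      - the "neuronal" target network: 14 disjoint spherical blobs
#                    whose shared time course is band-limited to 0.01-0.05 Hz;
#   * anti_network - 6 blobs expressed with the exact sign-flipped network
#                    course (the anticorrelated regions the selection step
#                    keys on);
#   * global       - strictly positive everywhere (scanner-wide signal);
#   * drift        - slow monotone scanner drift on a spatial gradient;
#   * spike        - motion-like transient expressed on the volume rim;
#   * physio       - high-frequency (0.15 Hz) physiological oscillation
# plus i.i.d. Gaussian voxel noise.  The "patient" condition additionally
# couples the network time course into designated extra regions, emulating
# increased connectivity beyond the core network.

SOURCE_LABELS <- c("network", "anti_network", "global", "drift", "spike", "physio")

# amplitudes (time-course sd multipliers) of each source in the mixture
.SOURCE_AMPLITUDE <- c(network = 1.0, anti_network = 1.0, global = 0.7,
                       drift = 0.45, spike = 0.5, physio = 0.6)
.PATIENT_COUPLING_GAIN <- 1.0
.TARGET_BLOB_RADIUS <- 2.5   # voxels (7.5 mm at 3 mm voxels)
.ANTI_BLOB_RADIUS <- 2.5
.EXTRA_BLOB_RADIUS <- 2.8

sphere_mask <- function(dims, center, radius) {
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3]))
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  array(d2 <= radius^2, dims)
}

smooth_noise_field <- function(dims, sigma_vox) {
  f <- gaussian_smooth_array(array(stats::rnorm(prod(dims)), dims),
                             fwhm_mm = sigma_vox * sqrt(8 * log(2)), voxel_mm = c(1, 1, 1))
  (f - mean(f)) / stats::sd(f)
}

#' Build the latent source bank of a phantom cohort
#'
#' Places 14 target network blobs, 6 anticorrelated blobs and
#' \code{n_extra_regions} patient-coupling blobs on a jittered lattice so that
#' all blobs are pairwise disjoint, and constructs the artifact source maps
#' (global, drift, spike, physiological).
#'
#' @param grid_shape integer length-3 grid dimensions (each \eqn{\ge} 16).
#' @param n_extra_regions number of extra regions receiving patient-condition
#'   coupling.
#' @param seed integer; fully determines the bank.
#' @return An object of class \code{component_bank}: named spatial maps
#'   (\code{network}, \code{anti_network}, \code{global}, \code{drift},
#'   \code{spike}, \code{physio}), per-source temporal descriptors, blob
#'   centers (voxel ijk) and extra-region masks.
#' @export
make_component_bank <- function(grid_shape = c(24, 24, 24), n_extra_regions = 3, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  .assert(length(grid_shape) == 3L && all(grid_shape >= 16L),
          "each grid dimension must be at least 16")
  .assert(n_extra_regions >= 0, "n_extra_regions must be non-negative")
  # lattice of candidate blob centers: spacing 6 keeps the blobs disjoint,
  # and the 6-voxel edge margin keeps every blob fully inside the grid even
  # after the +/-2 voxel subject jitter (no clipping)
  slots <- expand.grid(
    i = seq(6L, grid_shape[1] - 6L, by = 6L),
    j = seq(6L, grid_shape[2] - 6L, by = 6L),
    k = seq(6L, grid_shape[3] - 6L, by = 6L)
  )
  need <- 14L + 6L + n_extra_regions
  .assert(nrow(slots) >= need,
          "grid too small to place %d disjoint blobs (only %d slots)", need, nrow(slots))
  set.seed(seed)
  slots <- as.matrix(slots[sample.int(nrow(slots)), , drop = FALSE])
  target_centers <- slots[1:14, , drop = FALSE]
  anti_centers <- slots[15:20, , drop = FALSE]
  extra_centers <- if (n_extra_regions > 0)
    slots[20L + seq_len(n_extra_regions), , drop = FALSE] else matrix(numeric(0), 0, 3)

  blob_union <- function(centers, radius) {
    m <- array(FALSE, grid_shape)
    for (r in seq_len(nrow(centers))) m <- m | sphere_mask(grid_shape, centers[r, ], radius)
    m
  }
  net_mask <- blob_union(target_centers, .TARGET_BLOB_RADIUS)
  anti_mask <- blob_union(anti_centers, .ANTI_BLOB_RADIUS)
  extra_masks <- lapply(seq_len(nrow(extra_centers)), function(r)
    sphere_mask(grid_shape, extra_centers[r, ], .EXTRA_BLOB_RADIUS))

  # artifact maps are deliberately spatially non-Gaussian (skewed / sparse):
  # spatial ICA separates sources by map non-Gaussianity, as real artifacts do
  glob <- 0.3 + 0.5 * smooth_noise_field(grid_shape, 3)^2   # positive, right-skewed
  gr <- (slice.index(array(0, grid_shape), 1) / grid_shape[1] +
         slice.index(array(0, grid_shape), 2) / grid_shape[2] +
         slice.index(array(0, grid_shape), 3) / grid_shape[3]) / 3
  drift_map <- (gr - mean(gr)) / stats::sd(gr)
  rim <- array(FALSE, grid_shape)             # motion-like: opposite-face slabs
  rim[c(1, 2, grid_shape[1] - 1, grid_shape[1]), , ] <- TRUE
  physio_centers <- cbind(sample(4:(grid_shape[1] - 3), 5, replace = TRUE),
                          sample(4:(grid_shape[2] - 3), 5, replace = TRUE),
                          sample(4:(grid_shape[3] - 3), 5, replace = TRUE))
  physio_map <- array(FALSE, grid_shape)      # blobby, e.g. vascular/CSF foci
  for (r in 1:5) physio_map <- physio_map | sphere_mask(grid_shape, physio_centers[r, ], 3)
  physio_map <- physio_map * 1.0

  structure(list(
    spatial_maps = list(
      network = net_mask * 1.0,
      anti_network = anti_mask * 1.0,
      global = glob,
      drift = drift_map,
      spike = rim * 1.0,
      physio = physio_map
    ),
    labels = SOURCE_LABELS,
    time_specs = list(
      network = list(kind = "bandlimited", band = c(0.01, 0.05)),
      anti_network = list(kind = "anti_tied"),
      global = list(kind = "bandlimited", band = c(0.01, 0.05)),
      drift = list(kind = "poly", order = 1L),
      spike = list(kind = "spike", onset_frac = stats::runif(1, 0.35, 0.65), width = 3L),
      physio = list(kind = "sinusoid", freq_hz = 0.15)
    ),
    amplitudes = .SOURCE_AMPLITUDE,
    target_centers = target_centers,
    anti_centers = anti_centers,
    extra_centers = extra_centers,
    extra_masks = extra_masks,
    grid_shape = grid_shape,
    seed = seed
  ), class = "component_bank")
}

#' @export
print.component_bank <- function(x, ...) {
  cat(sprintf("<component_bank> %s grid, 14 target + 6 anti blobs, %d extra regions, seed %s\n",
              paste(x$grid_shape, collapse = "x"), length(x$extra_masks),
              format(x$seed)))
  invisible(x)
}

# The spatial pattern spatial ICA actually recovers for the network source:
# positive target blobs minus the (tied, sign-flipped) anticorrelated blobs.
truth_network_map <- function(truth) {
  bank <- if (inherits(truth, "component_bank")) truth else truth$bank
  bank$spatial_maps$network - bank$spatial_maps$anti_network
}

# Band-limited Gaussian course: white noise with all Fourier mass outside
# [band] zeroed; unit sd.
band_limited_course <- function(n, tr_seconds, band) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  j <- 0:(n - 1)
  freq <- pmin(j, n - j) / (n * tr_seconds)
  f[!(freq >= band[1] & freq <= band[2])] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

make_course <- function(spec, n, tr_seconds) {
  x <- switch(spec$kind,
    bandlimited = band_limited_course(n, tr_seconds, spec$band),
    poly = seq(-1, 1, length.out = n),
    spike = {
      s <- numeric(n)
      onset <- max(2L, round(spec$onset_frac * n))
      s[onset:min(n, onset + spec$width - 1L)] <- 1
      s
    },
    sinusoid = sin(2 * pi * spec$freq_hz * tr_seconds * (seq_len(n) - 1) +
                     stats::runif(1, 0, 2 * pi)),
    stop("unknown time spec kind: ", spec$kind)
  )
  (x - mean(x)) / stats::sd(x)
}

#' Simulate one phantom subject
#'
#' @param bank a \code{\link{make_component_bank}} result.
#' @param condition \code{"control"} or \code{"patient"}; patients receive
#'   additional coupling of the network time course into the bank's extra
#'   regions (gain 1.0 x network amplitude).
#' @param n_volumes number of volumes (\eqn{\ge} 60); default 300.
#' @param tr_seconds repetition time in seconds; default 2.
#' @param snr ratio of noiseless-signal RMS to noise SD; \code{Inf} gives a
#'   noise-free run.
#' @param seed integer; fully determines the realization.
#' @return list with elements \code{run} (a \code{\link{bold_run}}) and
#'   \code{truth} (mixing matrix, bank, condition, seed, noise SD).
#' @export
simulate_subject <- function(bank, condition = c("control", "patient"),
                             n_volumes = 300, tr_seconds = 2, snr = 2, seed = 1) {
  condition <- match.arg(condition)
  .assert(n_volumes >= 60, "n_volumes must be at least 60")
  .assert(is.numeric(snr) && snr > 0, "snr must be positive")
  set.seed(seed)
  n <- as.integer(n_volumes)
  courses <- matrix(0, n, length(SOURCE_LABELS),
                    dimnames = list(NULL, SOURCE_LABELS))
  courses[, "network"] <- make_course(bank$time_specs$network, n, tr_seconds)
  courses[, "anti_network"] <- -courses[, "network"]
  for (s in c("global", "drift", "spike", "physio"))
    courses[, s] <- make_course(bank$time_specs[[s]], n, tr_seconds)
  mixing <- sweep(courses, 2, bank$amplitudes[SOURCE_LABELS], `*`)

  S <- do.call(rbind, lapply(bank$spatial_maps, as.vector))
  noiseless <- mixing %*% S
  # noise level is set by the base mixture, so matched control/patient
  # realizations share both the noise draw and its scale
  sigma <- if (is.finite(snr)) stats::sd(as.vector(noiseless)) / snr else 0
  if (condition == "patient" && length(bank$extra_masks)) {
    extra <- Reduce(`|`, bank$extra_masks)
    noiseless <- noiseless + .PATIENT_COUPLING_GAIN * bank$amplitudes[["network"]] *
      tcrossprod(courses[, "network"], as.numeric(extra))
  }
  data <- noiseless
  if (sigma > 0) data <- data + stats::rnorm(length(data), sd = sigma)
  arr <- array(t(data), c(bank$grid_shape, n))
  run <- bold_run(arr, tr_seconds)
  truth <- structure(list(mixing = mixing, bank = bank, condition = condition,
                          seed = seed, noise_sd = sigma,
                          coupling_gain = if (condition == "patient") .PATIENT_COUPLING_GAIN else 0),
                     class = "ground_truth")
  list(run = run, truth = truth)
}

# Translate a 3D array by an integer offset, zero-filling vacated voxels.
shift_array <- function(arr, off) {
  d <- dim(arr)
  out <- array(if (is.logical(arr)) FALSE else 0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    src[[a]] <- max(1, 1 - off[a]):min(d[a], d[a] - off[a])
    dst[[a]] <- src[[a]] + off[a]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Apply a subject-level rigid integer translation to the blob-based maps
# (network, anti_network, extra regions), emulating residual misalignment.
jitter_bank <- function(bank, offset) {
  bank$spatial_maps$network <- shift_array(bank$spatial_maps$network, offset)
  bank$spatial_maps$anti_network <- shift_array(bank$spatial_maps$anti_network, offset)
  bank$extra_masks <- lapply(bank$extra_masks, shift_array, off = offset)
  bank$target_centers <- sweep(bank$target_centers, 2, offset, `+`)
  bank$anti_centers <- sweep(bank$anti_centers, 2, offset, `+`)
  if (nrow(bank$extra_centers)) bank$extra_centers <- sweep(bank$extra_centers, 2, offset, `+`)
  bank$jitter <- offset
  bank
}

#' Simulate a two-group phantom cohort
#'
#' Per-subject seeds and blob jitters (integer translations, uniform on
#' \{-2..2\} per axis) are derived deterministically from the master seed.
#'
#' @param n_controls,n_patients group sizes (defaults 15 and 13).
#' @param params optional overrides: \code{grid_shape}, \code{n_extra_regions},
#'   \code{n_volumes}, \code{tr_seconds}, \code{snr}, \code{jitter_vox},
#'   \code{bank_seed} (defaults to \code{seed}; set it to share one latent
#'   anatomy between a reference and a study cohort drawn with different
#'   master seeds).
#' @param seed master seed.
#' @return An object of class \code{phantom_cohort}: the shared
#'   \code{component_bank} plus one \code{list(id, group, run, truth)} per
#'   subject (controls first).
#' @export
make_cohort <- function(n_controls = 15, n_patients = 13, params = list(), seed = 1) {
  .assert(n_controls >= 1 && n_patients >= 0, "need at least one control subject")
  p <- utils::modifyList(list(grid_shape = c(24, 24, 24), n_extra_regions = 3,
                              n_volumes = 300, tr_seconds = 2, snr = 2,
                              jitter_vox = 2, bank_seed = seed), params)
  bank <- make_component_bank(p$grid_shape, p$n_extra_regions, seed = p$bank_seed)
  groups <- c(rep("control", n_controls), rep("patient", n_patients))
  subjects <- lapply(seq_along(groups), function(i) {
    set.seed(child_seed(seed, i))
    off <- sample(seq(-p$jitter_vox, p$jitter_vox), 3, replace = TRUE)
    sb <- jitter_bank(bank, off)
    sim <- simulate_subject(sb, groups[i], n_volumes = p$n_volumes,
                            tr_seconds = p$tr_seconds, snr = p$snr,
                            seed = child_seed(seed, i + 10000L))
    list(id = sprintf("%s%02d", substr(groups[i], 1, 4), i),
         group = groups[i], run = sim$run, truth = sim$truth)
  })
  structure(list(subjects = subjects, bank = bank, seed = seed, params = p),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  g <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<phantom_cohort> %d subjects (%s), seed %d\n",
              length(x$subjects),
              paste(sprintf("%d %s", g, names(g)), collapse = ", "), x$seed))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Each run becomes a 4D NIfTI plus a JSON sidecar (seed, condition, tr); the
#' cohort manifest is a TSV with columns subject_id, group, nifti_path, seed.
#'
#' @param cohort a \code{\link{make_cohort}} result.
#' @param dir output directory (created if missing).
#' @return path of the manifest TSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    path <- file.path(dir, paste0(s$id, ".nii.gz"))
    write_bold_nifti(s$run, path, sidecar = FALSE)
    jsonlite::write_json(list(seed = s$truth$seed, condition = s$truth$condition,
                              tr_seconds = s$run$tr_seconds),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    data.frame(subject_id = s$id, group = s$group, nifti_path = path,
               seed = s$truth$seed, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
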