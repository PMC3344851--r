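# Component fingerprints: spatial, temporal and spectral descriptors used to
# weigh components by neuronal likeness.  Eleven features: map skewness,
# kurtosis, 64-bin spatial entropy, "clusterness" (fraction of |z|>2 voxels
# sitting in 26-connected clusters of >= 10 voxels), one-lag autocorrelation
# and 64-bin temporal entropy of the course, and periodogram band-power
# fractions in 0-0.008, 0.008-0.02, 0.02-0.05, 0.05-0.1 and 0.1-Nyquist Hz.

FINGERPRINT_BANDS <- c(0, 0.008, 0.02, 0.05, 0.1)
FINGERPRINT_VERSION <- "rsnica-fp-1"

fingerprint_feature_names <- function() {
  c("skewness", "kurtosis", "spatial_entropy", "clusterness",
    "one_lag_autocorr", "temporal_entropy",
    paste0("band_", c("0.000_0.008", "0.008_0.020", "0.020_0.050",
                      "0.050_0.100", "0.100_nyq")))
}

#' Fingerprint of one ICA component
#'
#' @param map 3D spatial map (z-scored) or in-mask value vector.
#' @param course the paired time course (length \eqn{\ge} 64).
#' @param tr_seconds repetition time in seconds.
#' @param mask optional logical 3D array restricting the map features.
#' @return object of class \code{fingerprint}: a named feature vector plus
#'   metadata.  Spectral band fractions sum to 1.
#' @export
fingerprint <- function(map, course, tr_seconds, mask = NULL) {
  vals <- if (is.array(map) && !is.null(mask)) map[mask] else as.numeric(map)
  .assert(length(course) >= 64, "course must have at least 64 samples")
  .assert(stats::sd(vals) > 0, "degenerate (constant) spatial map")
  .assert(stats::sd(course) > 0, "degenerate (constant) time course")

  z <- (vals - mean(vals)) / stats::sd(vals)
  clusterness <- {
    supra <- abs(z) > 2
    if (!any(supra)) 0 else {
      # cluster on the 3D grid when available, else treat values as a 1D run
      m3 <- if (is.array(map) && length(dim(map)) == 3L) {
        msk <- if (is.null(mask)) array(TRUE, dim(map)) else mask
        zz <- array(0, dim(map))
        zz[msk] <- z
        lab <- label_components_3d(abs(zz) > 2 & msk)
        sizes <- component_sizes(lab)
        sum(sizes[sizes >= 10]) / sum(supra)
      } else {
        r <- rle(supra)
        sum(r$lengths[r$values & r$lengths >= 10]) / sum(supra)
      }
      m3
    }
  }

  pg <- periodogram(course, tr_seconds)
  nyq <- 1 / (2 * tr_seconds)
  edges <- c(FINGERPRINT_BANDS, Inf)
  bp <- vapply(seq_len(5), function(b)
    sum(pg$power[pg$freq >= edges[b] & pg$freq < edges[b + 1]]), 0)
  bp <- bp / sum(pg$power)

  cc <- course - mean(course)
  feats <- c(
    skewness = moment_skewness(vals),
    kurtosis = moment_kurtosis(vals),
    spatial_entropy = histogram_entropy(vals),
    clusterness = clusterness,
    one_lag_autocorr = sum(cc[-1] * cc[-length(cc)]) / sum(cc^2),
    temporal_entropy = histogram_entropy(course),
    stats::setNames(bp, fingerprint_feature_names()[7:11])
  )
  structure(list(features = feats, tr_seconds = tr_seconds, nyquist_hz = nyq,
                 version = FINGERPRINT_VERSION), class = "fingerprint")
}

# Feature vector used for distances: sign-invariant (|skewness|).
fingerprint_vector <- function(fp) {
  f <- fp$features
  f["skewness"] <- abs(f["skewness"])
  f
}

#' Reference fingerprint from a set of component fingerprints
#'
#' Per-feature mean and robust spread: the median absolute deviation scaled
#' by 1.4826, floored at 10 percent of the feature's absolute mean (and
#' 1e-3 absolute).  The relative floor keeps the standardized distance
#' meaningful when a homogeneous reference cohort drives the MAD of a
#' feature toward zero, which would otherwise veto any component whose
#' fingerprint deviates at all.  Skewness enters as its absolute value so
#' the reference is invariant to ICA sign indeterminacy.
#'
#' @param fps list of \code{\link{fingerprint}} objects (\eqn{\ge} 2).
#' @return object of class \code{reference_fingerprint} with \code{mean},
#'   \code{scale} and \code{n_sources}.
#' @export
reference_fingerprint <- function(fps) {
  .assert(length(fps) >= 2, "need at least 2 fingerprints for a reference")
  M <- do.call(rbind, lapply(fps, fingerprint_vector))
  mu <- colMeans(M)
  structure(list(mean = mu,
                 scale = pmax(apply(M, 2, stats::mad), 0.1 * abs(mu), 1e-3),
                 n_sources = length(fps),
                 version = fps[[1]]$version), class = "reference_fingerprint")
}

#' Neuronal-likeness weight of a component
#'
#' \eqn{w_F = \exp(-d/k)} where d is the Euclidean distance between the
#' scale-standardized fingerprint and the reference mean and k the number of
#' features.  Close to 1 for components resembling the neuronal reference,
#' close to 0 for artifactual ones.
#'
#' @param fp a \code{\link{fingerprint}}.
#' @param ref a \code{\link{reference_fingerprint}}.
#' @return scalar in (0, 1].
#' @export
fingerprint_weight <- function(fp, ref) {
  v <- fingerprint_vector(fp)
  .assert(identical(names(v), names(ref$mean)), "fingerprint feature sets do not match")
  d <- sqrt(sum(((v - ref$mean) / ref$scale)^2))
  exp(-d / length(v))
}

#' Write fingerprints as a TSV table
#'
#' @param fps list of \code{\link{fingerprint}} objects (one per component).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fingerprints_tsv <- function(fps, path) {
  M <- do.call(rbind, lapply(fps, function(f) f$features))
  df <- data.frame(component = seq_along(fps), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
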