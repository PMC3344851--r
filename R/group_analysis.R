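# Group-level statistics: residualized component beta maps per subject,
# random-effects one- and two-sample T maps, Benjamini-Hochberg FDR masking,
# and Monte-Carlo cluster-extent thresholding (3D randomization of smoothed
# null maps, 26-connectivity).

#' Residualize a run against all non-selected component courses
#'
#' Per in-mask voxel, the OLS residual after regressing the BOLD course on an
#' intercept plus the time courses of every component except the selected
#' one.  The residual is the activity attributable to the selected component
#' (plus noise).
#'
#' @param run a preprocessed \code{\link{bold_run}}.
#' @param courses t x n_components matrix of ICA time courses.
#' @param selected index (1-based) of the component of interest.
#' @return a \code{bold_run} of residuals.
#' @export
residualize <- function(run, courses, selected) {
  .assert(selected >= 1 && selected <= ncol(courses), "selected component out of range")
  X <- cbind(1, courses[, -selected, drop = FALSE])
  qx <- qr(X)
  .assert(qx$rank == ncol(X), "rank-deficient nuisance design")
  M <- run_matrix(run)
  matrix_to_run(M - qr.fitted(qx, M), run)
}

#' Partial out the nuisance components from the selected course
#'
#' Residual of the selected component's time course after regressing on an
#' intercept plus all other courses.  Using this as the predictor on a
#' \code{\link{residualize}}d run makes the voxelwise slope equal to the
#' full-model partial regression coefficient (Frisch-Waugh).
#'
#' @param courses t x n_components matrix.
#' @param selected index of the component of interest.
#' @return numeric vector of length t.
#' @export
residual_course <- function(courses, selected) {
  .assert(selected >= 1 && selected <= ncol(courses), "selected component out of range")
  X <- cbind(1, courses[, -selected, drop = FALSE])
  stats::lm.fit(X, courses[, selected])$residuals
}

#' Voxelwise beta map of the selected component
#'
#' OLS slope of each in-mask residual voxel course on an intercept plus the
#' selected component's time course.
#'
#' @param residual the \code{\link{residualize}} output.
#' @param selected_course the selected component's time course.
#' @param subject_id label stored with the map.
#' @return object of class \code{beta_map}: \code{values} (3D array, zero
#'   out-of-mask), \code{mask}, \code{subject_id}.
#' @export
component_beta_map <- function(residual, selected_course, subject_id = "subject") {
  .assert(length(selected_course) == n_volumes(residual),
          "course length does not match the run")
  c0 <- selected_course - mean(selected_course)
  ss <- sum(c0^2)
  .assert(ss > 0, "constant selected course")
  M <- run_matrix(residual)                   # t x v
  beta <- as.numeric(crossprod(M - rep(colMeans(M), each = nrow(M)), c0) / ss)
  vals <- array(0, dim(residual$data)[1:3])
  vals[residual$mask] <- beta
  structure(list(values = vals, mask = residual$mask,
                 voxel_mm = residual$voxel_mm, subject_id = subject_id),
            class = "beta_map")
}

beta_stack <- function(maps) {
  vapply(maps, function(m) m$values[m$mask], numeric(sum(maps[[1]]$mask)))
}

new_stat_map <- function(tvec, template_mask, dof, kind, voxel_mm,
                         zero_variance = 0L) {
  tv <- array(0, dim(template_mask))
  tv[template_mask] <- tvec
  structure(list(tvalues = tv, mask = template_mask, dof = as.integer(dof),
                 kind = kind, voxel_mm = voxel_mm,
                 n_zero_variance = as.integer(zero_variance)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, dof %d, max |t| = %.2f\n",
              x$kind, x$dof, max(abs(x$tvalues[x$mask]))))
  invisible(x)
}

#' One-sample random-effects T map
#'
#' Voxelwise one-sample t statistic of the subject beta maps against zero;
#' dof = n - 1.  Zero-variance voxels get t = 0 and are counted in
#' \code{n_zero_variance}.
#'
#' @param maps list of \code{\link{component_beta_map}} results (\eqn{\ge} 3).
#' @return a \code{stat_map} of kind \code{one_sample}.
#' @export
rfx_one_sample <- function(maps) {
  .assert(length(maps) >= 3, "one-sample analysis needs at least 3 subjects")
  B <- beta_stack(maps)
  n <- ncol(B)
  mu <- rowMeans(B)
  sdv <- sqrt(rowSums((B - mu)^2) / (n - 1))
  tvec <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
  new_stat_map(tvec, maps[[1]]$mask, n - 1L, "one_sample", maps[[1]]$voxel_mm,
               sum(sdv == 0))
}

#' Two-sample (pooled-variance) contrast T map
#'
#' Voxelwise t of group 1 minus group 2 with pooled variance;
#' dof = n1 + n2 - 2.
#'
#' @param g1,g2 lists of \code{\link{component_beta_map}} results
#'   (\eqn{\ge} 2 each).
#' @return a \code{stat_map} of kind \code{two_sample}.
#' @export
two_sample_contrast <- function(g1, g2) {
  .assert(length(g1) >= 2 && length(g2) >= 2, "each group needs at least 2 subjects")
  B1 <- beta_stack(g1); B2 <- beta_stack(g2)
  n1 <- ncol(B1); n2 <- ncol(B2)
  m1 <- rowMeans(B1); m2 <- rowMeans(B2)
  sp2 <- (rowSums((B1 - m1)^2) + rowSums((B2 - m2)^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tvec <- ifelse(se > 0, (m1 - m2) / se, 0)
  new_stat_map(tvec, g1[[1]]$mask, n1 + n2 - 2L, "two_sample", g1[[1]]$voxel_mm,
               sum(se == 0))
}

#' FDR-controlling voxel mask
#'
#' Benjamini-Hochberg step-up over the in-mask two-sided p values; returns the
#' logical 3D mask of surviving voxels.
#'
#' @param stat a \code{stat_map}.
#' @param q FDR level (default 0.05).
#' @return logical 3D array.
#' @export
fdr_mask <- function(stat, q = 0.05) {
  .assert(q > 0 && q < 1, "q must be in (0,1)")
  tv <- stat$tvalues[stat$mask]
  p <- 2 * stats::pt(-abs(tv), df = stat$dof)
  keep <- stats::p.adjust(p, method = "BH") <= q
  out <- array(FALSE, dim(stat$tvalues))
  out[stat$mask] <- keep
  out
}

# max suprathreshold cluster size (26-connectivity, signs labelled separately)
max_cluster_size <- function(tmap, mask, thr) {
  mx <- 0L
  for (sgn in c(1, -1)) {
    supra <- (sgn * tmap > thr) & mask
    if (!any(supra)) next
    sizes <- component_sizes(label_components_3d(supra))
    mx <- max(mx, max(sizes))
  }
  mx
}

#' Monte-Carlo estimate of the minimum cluster-size threshold
#'
#' Simulates \code{n_iterations} null maps (white Gaussian noise smoothed to
#' \code{smoothness_mm} FWHM, standardized exactly per voxel and mapped
#' monotonically to a t field with the given dof), thresholds two-sided at
#' \code{voxel_t_threshold}, and records the largest suprathreshold
#' 26-connected cluster per iteration.  Returns the smallest size k whose
#' exceedance fraction is at most \code{alpha}: clusters of at least k voxels
#' then occur with cluster-level false-positive rate \eqn{\le alpha}.
#'
#' @param grid logical 3D mask (or integer length-3 dimensions, taken as a
#'   full-grid mask).
#' @param voxel_t_threshold voxel-level |t| threshold (e.g. the t for
#'   two-sided p = 0.01 at the map's dof).
#' @param dof degrees of freedom of the map the threshold will be applied to.
#' @param smoothness_mm spatial smoothness (Gaussian FWHM, mm) of the null
#'   maps; match it to the analyzed maps (see \code{\link{estimate_fwhm_mm}}).
#' @param n_iterations number of null maps (\eqn{\ge} 100; default 1000).
#' @param alpha cluster-level false-positive rate (default 0.05).
#' @param seed RNG seed.
#' @param voxel_mm voxel size in mm.
#' @return minimum cluster size in voxels (integer, \eqn{\ge} 1); the
#'   simulated max-cluster-size distribution is attached as attribute
#'   \code{"max_sizes"}.
#' @export
cluster_size_threshold <- function(grid, voxel_t_threshold, dof, smoothness_mm,
                                   n_iterations = 1000, alpha = 0.05, seed = 1,
                                   voxel_mm = c(3, 3, 3)) {
  .assert(n_iterations >= 100, "need at least 100 iterations")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  mask <- if (is.logical(grid)) grid else array(TRUE, grid)
  dims <- dim(mask)
  # the z <-> t map is monotone, so threshold in z space: same clusters
  z_thr <- stats::qnorm(stats::pt(voxel_t_threshold, df = dof))
  sd_field <- smoothed_noise_sd(dims, smoothness_mm, voxel_mm)
  set.seed(seed)
  mx <- vapply(seq_len(n_iterations), function(i) {
    z <- gaussian_smooth_array(array(stats::rnorm(prod(dims)), dims),
                               smoothness_mm, voxel_mm) / sd_field
    max_cluster_size(z, mask, z_thr)
  }, 0L)
  k <- 1L
  while (mean(mx >= k) > alpha) k <- k + 1L
  structure(k, max_sizes = mx)
}

#' Held-out cluster-level false-positive rate
#'
#' Fraction of freshly simulated null maps (same model as
#' \code{\link{cluster_size_threshold}}) containing a suprathreshold cluster
#' of at least \code{min_size} voxels.
#'
#' @inheritParams cluster_size_threshold
#' @param min_size the cluster-size threshold to evaluate.
#' @return scalar rate in [0, 1].
#' @export
cluster_fpr <- function(grid, voxel_t_threshold, dof, smoothness_mm, min_size,
                        n_iterations = 1000, seed = 2, voxel_mm = c(3, 3, 3)) {
  mask <- if (is.logical(grid)) grid else array(TRUE, grid)
  dims <- dim(mask)
  z_thr <- stats::qnorm(stats::pt(voxel_t_threshold, df = dof))
  sd_field <- smoothed_noise_sd(dims, smoothness_mm, voxel_mm)
  set.seed(seed)
  mean(vapply(seq_len(n_iterations), function(i) {
    z <- gaussian_smooth_array(array(stats::rnorm(prod(dims)), dims),
                               smoothness_mm, voxel_mm) / sd_field
    max_cluster_size(z, mask, z_thr) >= min_size
  }, logical(1)))
}

#' Estimate the spatial smoothness of a set of maps
#'
#' Fits a Gaussian autocorrelation model along each axis from neighbouring
#' voxel correlations (\eqn{\rho(\Delta) = \exp(-\Delta^2 / 4\sigma^2)} for a
#' field smoothed with kernel sd \eqn{\sigma}) and returns the mean FWHM in
#' mm.  Used to match the null-map smoothness of the cluster-size estimator
#' to the analyzed beta maps.
#'
#' @param maps list of \code{beta_map} (or \code{stat_map}) objects.
#' @param voxel_mm voxel size in mm.
#' @return scalar FWHM in mm.
#' @export
estimate_fwhm_mm <- function(maps, voxel_mm = c(3, 3, 3)) {
  vals <- lapply(maps, function(m) if (!is.null(m$values)) m$values else m$tvalues)
  est_axis <- function(a) {
    rhos <- vapply(vals, function(v) {
      d <- dim(v)
      idx1 <- lapply(seq_len(3), function(ax) seq_len(d[ax] - (ax == a)))
      idx2 <- lapply(seq_len(3), function(ax) seq_len(d[ax]) [if (ax == a) -1 else TRUE])
      x <- v[idx1[[1]], idx1[[2]], idx1[[3]]]
      y <- v[idx2[[1]], idx2[[2]], idx2[[3]]]
      stats::cor(as.vector(x), as.vector(y))
    }, 0)
    rho <- mean(rhos)
    if (!is.finite(rho) || rho <= 0) return(0)
    sigma_vox <- sqrt(-voxel_mm[a]^2 / (4 * log(rho)))
    sigma_vox * sqrt(8 * log(2))
  }
  mean(vapply(1:3, est_axis, 0))
}

#' Label suprathreshold clusters of a stat map
#'
#' Suprathreshold voxels (both signs, labelled separately) are grouped by
#' 26-connectivity; clusters smaller than \code{min_size} are dropped.
#'
#' @param stat a \code{stat_map}.
#' @param voxel_t_threshold voxel-level |t| threshold.
#' @param min_size minimum surviving cluster size in voxels (\eqn{\ge} 1).
#' @return a \code{cluster_table} data.frame with columns cluster_id,
#'   size_voxels, peak_t, peak_i, peak_j, peak_k, sign; the voxel membership
#'   is attached as attribute \code{"voxels"} (list of ijk matrices).
#' @export
apply_cluster_threshold <- function(stat, voxel_t_threshold, min_size = 1) {
  .assert(min_size >= 1, "min_size must be at least 1")
  rows <- list(); vox <- list(); cid <- 0L
  for (sgn in c(1, -1)) {
    supra <- (sgn * stat$tvalues > voxel_t_threshold) & stat$mask
    if (!any(supra)) next
    lab <- label_components_3d(supra)
    for (lv in seq_len(max(lab))) {
      idx <- which(lab == lv)
      if (length(idx) < min_size) next
      cid <- cid + 1L
      pos <- arrayInd(idx, dim(lab))
      tv <- stat$tvalues[idx]
      pk <- which.max(abs(tv))
      rows[[cid]] <- data.frame(cluster_id = cid, size_voxels = length(idx),
                                peak_t = tv[pk], peak_i = pos[pk, 1],
                                peak_j = pos[pk, 2], peak_k = pos[pk, 3],
                                sign = if (sgn > 0) "positive" else "negative",
                                stringsAsFactors = FALSE)
      vox[[cid]] <- pos
    }
  }
  out <- if (cid > 0) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), size_voxels = integer(0),
               peak_t = numeric(0), peak_i = integer(0), peak_j = integer(0),
               peak_k = integer(0), sign = character(0), stringsAsFactors = FALSE)
  class(out) <- c("cluster_table", class(out))
  attr(out, "voxels") <- vox
  attr(out, "min_size") <- min_size
  attr(out, "voxel_t_threshold") <- voxel_t_threshold
  out
}

#' Write a cluster table as TSV
#'
#' @param tab a \code{cluster_table}.
#' @param path output path.
#' @param voxel_mm voxel size used to add peak mm coordinates.
#' @return \code{path}, invisibly.
#' @export
write_cluster_tsv <- function(tab, path, voxel_mm = c(3, 3, 3)) {
  df <- as.data.frame(tab)
  if (nrow(df)) {
    mm <- ijk_to_mm(as.matrix(df[, c("peak_i", "peak_j", "peak_k")]), voxel_mm)
    df$peak_x_mm <- mm[, 1]; df$peak_y_mm <- mm[, 2]; df$peak_z_mm <- mm[, 3]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a stat map as NIfTI
#'
#' @param stat a \code{stat_map}.
#' @param path output NIfTI path.
#' @return \code{path}, invisibly.
#' @export
write_stat_nifti <- function(stat, path) {
  img <- RNifti::asNifti(stat$tvalues, pixdim = stat$voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}
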