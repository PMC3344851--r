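# Spatial ICA, cross-subject component clustering, and ROI derivation.
#
# The decomposition is the classic two-stage estimator: PCA reduction of the
# time dimension followed by fixed-point ICA (logcosh contrast, symmetric
# decorrelation) maximizing non-Gaussianity of the *spatial* maps.  Maps are
# z-scored over the mask; the paired time courses absorb the scale so that
# maps %*% courses reconstructs the retained subspace of the data.

#' Spatial independent component analysis of a BOLD run
#'
#' @param run a preprocessed \code{\link{bold_run}}.
#' @param n_components number of components (default 30); must be smaller than
#'   the number of volumes.
#' @param seed integer seed for the random orthogonal initialization; the
#'   decomposition is deterministic given the seed.
#' @param max_iter,tol fixed-point iteration cap and convergence tolerance.
#' @param subject_id label stored with the decomposition.
#' @return An object of class \code{ica_decomposition}: \code{maps} (4D array
#'   x,y,z,component, z-scored over the mask, zero outside), \code{courses}
#'   (t x n_components, columns mean zero), \code{mask}, \code{converged},
#'   \code{subject_id}, \code{seed}.
#' @export
spatial_ica <- function(run, n_components = 30, seed = 1, max_iter = 1000, tol = 1e-4,
                        subject_id = "subject") {
  .assert(inherits(run, "bold_run"), "run must be a bold_run")
  nt <- n_volumes(run)
  .assert(n_components < nt, "n_components must be smaller than the number of volumes")
  X <- run_matrix(run)                       # t x v
  X <- X - rowMeans(X)                       # center each volume spatially
  X <- X - rep(colMeans(X), each = nt)       # and each voxel temporally
  v <- ncol(X)

  # PCA on the time dimension via the small t x t Gram matrix
  G <- tcrossprod(X) / v
  eg <- eigen(G, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-12)
  .assert(length(keep) >= n_components,
          "rank after reduction (%d) is below n_components (%d)", length(keep), n_components)
  d <- sqrt(eg$values[seq_len(n_components)])
  U <- eg$vectors[, seq_len(n_components), drop = FALSE]
  Z <- crossprod(U, X) / d                   # n x v whitened spatial PCs (rows: var 1)

  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  set.seed(seed)
  W <- sym_orth(matrix(stats::rnorm(n_components^2), n_components))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    gwx <- tanh(WX)
    W1 <- gwx %*% t(Z) / v - diag(rowMeans(1 - gwx^2)) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("fixed-point ICA did not converge in %d iterations; returning partial result",
                    max_iter))
  S <- W %*% Z                               # n x v spatial sources, rows ~ var 1
  courses <- X %*% t(S) / v                  # t x n mixing (rows of S orthonormal * sqrt(v))
  # enforce exact map normalization, pushing scale into the courses
  mu <- rowMeans(S)
  sdv <- sqrt(rowMeans((S - mu)^2))
  S <- (S - mu) / sdv
  courses <- sweep(courses, 2, sdv, `*`)
  courses <- sweep(courses, 2, colMeans(courses))

  d4 <- c(dim(run$data)[1:3], n_components)
  maps <- matrix(0, prod(d4[1:3]), n_components)
  maps[which(run$mask), ] <- t(S)
  structure(list(maps = array(maps, d4), courses = courses,
                 n_components = as.integer(n_components), mask = run$mask,
                 voxel_mm = run$voxel_mm, tr_seconds = run$tr_seconds,
                 converged = converged, subject_id = subject_id, seed = seed),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %s: %d components, %d volumes%s\n",
              x$subject_id, x$n_components, nrow(x$courses),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Write a decomposition to disk
#'
#' Spatial maps as a 4D NIfTI (\code{<prefix>_maps.nii.gz}) and time courses
#' as TSV (\code{<prefix>_courses.tsv}, one column per component).
#'
#' @param dec a \code{\link{spatial_ica}} result.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_decomposition <- function(dec, prefix) {
  maps_path <- paste0(prefix, "_maps.nii.gz")
  tc_path <- paste0(prefix, "_courses.tsv")
  RNifti::writeNifti(RNifti::asNifti(dec$maps, pixdim = c(dec$voxel_mm, 1)), maps_path)
  df <- as.data.frame(dec$courses)
  names(df) <- sprintf("IC%02d", seq_len(ncol(df)))
  utils::write.table(df, tc_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(maps_path, tc_path))
}

# In-mask map vectors as a v x n matrix.
decomposition_map_matrix <- function(dec) {
  d <- dim(dec$maps)
  matrix(dec$maps, prod(d[1:3]), d[4])[which(dec$mask), , drop = FALSE]
}

#' Cluster spatially similar components across subjects
#'
#' Groups the components of several subjects into \code{n_clusters} clusters
#' of spatially similar maps (similarity = |spatial correlation|) under the
#' constraint that a cluster holds at most one component per subject.
#'
#' The algorithm is deterministic reference matching: the subject whose maps
#' best match the rest of the cohort seeds the clusters with its components;
#' every other subject (in decreasing order of cohort similarity, ties by
#' subject id) then assigns its components to clusters by repeatedly taking
#' the globally best remaining |correlation| with the running sign-aligned
#' cluster means.  This yields exactly \code{n_clusters} clusters, each with
#' one component per subject, independent of the input order.
#'
#' @param decomps list of \code{\link{spatial_ica}} results (\eqn{\ge} 2
#'   subjects, same grid).
#' @param n_clusters target number of clusters; default: the component count.
#' @return list of \code{component_cluster} objects, each with \code{members}
#'   (data.frame subject_id, subject, component, sign), \code{mean_map} (3D
#'   array, the sign-aligned voxelwise average) and the mean within-cluster
#'   similarity; sorted by decreasing size and tightness.
#' @export
cluster_components <- function(decomps, n_clusters = NULL) {
  .assert(length(decomps) >= 2, "need at least 2 subjects to cluster components")
  ncomp <- decomps[[1]]$n_components
  n_clusters <- n_clusters %||% ncomp
  .assert(n_clusters <= ncomp, "n_clusters cannot exceed components per subject")
  ids <- vapply(decomps, `[[`, "", "subject_id")
  mats <- lapply(decomps, decomposition_map_matrix)
  ns <- length(decomps)

  # deterministic subject order: mean best-match |r| to all other subjects
  cohort_fit <- vapply(seq_len(ns), function(s) {
    best <- rep(0, ncomp)
    for (o in seq_len(ns)) {
      if (o == s) next
      best <- pmax(best, apply(abs(stats::cor(mats[[s]], mats[[o]])), 1, max))
    }
    mean(best)
  }, 0)
  ord <- order(-cohort_fit, ids)
  seed <- ord[1]

  # seed the clusters with the reference subject's components (its best
  # cohort-matching components first when n_clusters < ncomp)
  seed_rank <- order(-apply(abs(stats::cor(
    mats[[seed]], do.call(cbind, mats[-seed]))), 1, max))
  seed_comps <- sort(seed_rank[seq_len(n_clusters)])
  sums <- mats[[seed]][, seed_comps, drop = FALSE]   # running aligned sums
  counts <- rep(1L, n_clusters)
  members <- lapply(seq_len(n_clusters), function(k)
    data.frame(subject_id = ids[seed], subject = seed,
               component = seed_comps[k], sign = 1, stringsAsFactors = FALSE))

  for (s in ord[-1]) {
    means <- sweep(sums, 2, counts, `/`)
    C <- stats::cor(mats[[s]], means)                # ncomp x n_clusters
    A <- abs(C)
    for (step in seq_len(n_clusters)) {
      i <- which.max(A)
      row <- (i - 1L) %% nrow(A) + 1L
      col <- (i - 1L) %/% nrow(A) + 1L
      sgn <- if (C[row, col] < 0) -1 else 1
      members[[col]] <- rbind(members[[col]],
        data.frame(subject_id = ids[s], subject = s, component = row,
                   sign = sgn, stringsAsFactors = FALSE))
      sums[, col] <- sums[, col] + sgn * mats[[s]][, row]
      counts[col] <- counts[col] + 1L
      A[row, ] <- -Inf
      A[, col] <- -Inf
    }
  }

  grid <- dim(decomps[[1]]$maps)[1:3]
  mk <- which(decomps[[1]]$mask)
  out <- lapply(seq_len(n_clusters), function(k) {
    mem <- members[[k]]
    m <- vapply(seq_len(nrow(mem)), function(r)
      mem$sign[r] * mats[[mem$subject[r]]][, mem$component[r]],
      numeric(length(mk)))
    mean_map <- array(0, grid)
    mean_map[mk] <- rowMeans(m)
    within <- if (nrow(mem) > 1) {
      rr <- abs(stats::cor(m))
      mean(rr[upper.tri(rr)])
    } else 1
    structure(list(members = mem, mean_map = mean_map,
                   within_similarity = within), class = "component_cluster")
  })
  out[order(-vapply(out, function(cl) nrow(cl$members), 0L),
            -vapply(out, `[[`, 0, "within_similarity"))]
}

#' Derive target and anticorrelated ROIs from a mean network map
#'
#' Each ROI starts as an axis-aligned cube of side \code{cube_mm} centered on
#' the supplied mm coordinate and keeps only the voxels exceeding
#' \code{map_threshold} in the mean map (positive side for targets, negative
#' side for anti ROIs).  Voxel membership is voxel-center-in-cube with
#' half-open upper bounds.
#'
#' @param mean_map 3D array (z units) from the selected network cluster.
#' @param target_centers_mm,anti_centers_mm matrices (14 x 3 and 6 x 3) of mm
#'   coordinates (mm = (ijk - 1) * voxel_mm).
#' @param cube_mm cube side in mm; default 10.
#' @param map_threshold |z| threshold a voxel must exceed; default 1.
#' @param voxel_mm voxel size; default 3 mm isotropic.
#' @param mask logical 3D array; ROI voxels must be in-mask.
#' @return An object of class \code{roi_set}: named lists \code{targets} and
#'   \code{anti} of voxel-index matrices (ijk rows), plus polarity metadata.
#' @export
derive_rois <- function(mean_map, target_centers_mm, anti_centers_mm,
                        cube_mm = 10, map_threshold = 1, voxel_mm = c(3, 3, 3),
                        mask = NULL) {
  .assert(nrow(target_centers_mm) == 14L, "exactly 14 target centers required")
  .assert(nrow(anti_centers_mm) == 6L, "exactly 6 anti centers required")
  .assert(cube_mm > max(voxel_mm), "cube_mm must exceed the voxel size")
  dims <- dim(mean_map)
  if (is.null(mask)) mask <- array(TRUE, dims)

  roi_voxels <- function(center, polarity, name) {
    rng <- lapply(1:3, function(a) {
      coords <- (seq_len(dims[a]) - 1) * voxel_mm[a]
      which(coords >= center[a] - cube_mm / 2 & coords < center[a] + cube_mm / 2)
    })
    cube <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
    .assert(nrow(cube) > 0, "ROI %s: cube contains no voxel centers", name)
    vals <- mean_map[cube]
    keep <- if (polarity > 0) vals > map_threshold else vals < -map_threshold
    keep <- keep & mask[cube]
    .assert(any(keep),
            "ROI %s is empty: no in-mask voxel exceeds the map threshold (%s side)",
            name, if (polarity > 0) "positive" else "negative")
    cube[keep, , drop = FALSE]
  }

  targets <- lapply(seq_len(14), function(r)
    roi_voxels(target_centers_mm[r, ], +1, sprintf("T%02d", r)))
  names(targets) <- sprintf("T%02d", 1:14)
  anti <- lapply(seq_len(6), function(r)
    roi_voxels(anti_centers_mm[r, ], -1, sprintf("A%02d", r)))
  names(anti) <- sprintf("A%02d", 1:6)

  lin <- function(m) m[, 1] + (m[, 2] - 1) * dims[1] + (m[, 3] - 1) * dims[1] * dims[2]
  all_lin <- unlist(lapply(c(targets, anti), lin))
  .assert(!anyDuplicated(all_lin), "ROIs are not pairwise disjoint")

  structure(list(targets = targets, anti = anti, cube_mm = cube_mm,
                 map_threshold = map_threshold, voxel_mm = as.numeric(voxel_mm),
                 grid_shape = dims), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> 14 targets (%d voxels), 6 anti (%d voxels), cube %g mm, threshold %g\n",
              sum(vapply(x$targets, nrow, 0L)), sum(vapply(x$anti, nrow, 0L)),
              x$cube_mm, x$map_threshold))
  invisible(x)
}

#' Serialize / read an ROI set as JSON
#'
#' @param rois a \code{\link{derive_rois}} result.
#' @param path output JSON path.  Voxel indices are written 0-based.
#' @return \code{write_roi_json} returns \code{path} invisibly;
#'   \code{read_roi_json} returns a \code{roi_set}.
#' @export
write_roi_json <- function(rois, path) {
  enc <- function(lst, polarity) lapply(names(lst), function(nm) {
    m <- lst[[nm]]
    list(name = nm, polarity = polarity,
         center_mm = as.numeric(colMeans(ijk_to_mm(m, rois$voxel_mm))),
         voxel_ijk = unname(as.matrix(m) - 1L))
  })
  jsonlite::write_json(list(cube_mm = rois$cube_mm, map_threshold = rois$map_threshold,
                            voxel_mm = rois$voxel_mm, grid_shape = rois$grid_shape,
                            rois = c(enc(rois$targets, "target"), enc(rois$anti, "anti"))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  split_rois <- function(pol) {
    sel <- j$rois[j$rois$polarity == pol, ]
    out <- lapply(seq_len(nrow(sel)), function(i) {
      m <- sel$voxel_ijk[[i]] + 1L
      colnames(m) <- c("i", "j", "k")
      m
    })
    names(out) <- sel$name
    out
  }
  structure(list(targets = split_rois("target"), anti = split_rois("anti"),
                 cube_mm = j$cube_mm, map_threshold = j$map_threshold,
                 voxel_mm = j$voxel_mm, grid_shape = j$grid_shape),
            class = "roi_set")
}
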