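# Configuration and the two-stage study workflow: a reference cohort defines
# the ROIs and the reference fingerprint; the study cohort is then analyzed
# per subject (ICA + automatic selection + beta map) and at the group level
# (random-effects maps, FDR, contrast with cluster-extent correction).

#' Pipeline configuration
#'
#' All tunable parameters of the chain with their defaults.  Unknown keys are
#' rejected.
#'
#' @param ... overrides of: \code{preproc.highpass_hz} (0.005),
#'   \code{preproc.fwhm_mm} (8), \code{ica.n_components} (30),
#'   \code{selection.alpha} (0.05), \code{roi.cube_mm} (10),
#'   \code{roi.map_threshold} (1), \code{group.q_fdr} (0.05),
#'   \code{group.voxel_p} (0.01), \code{group.n_iterations} (1000),
#'   \code{group.alpha_cluster} (0.05), \code{seed} (1).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    preproc.highpass_hz = 0.005, preproc.fwhm_mm = 8,
    ica.n_components = 30, selection.alpha = 0.05,
    roi.cube_mm = 10, roi.map_threshold = 1,
    group.q_fdr = 0.05, group.voxel_p = 0.01,
    group.n_iterations = 1000, group.alpha_cluster = 0.05,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  .assert(length(unknown) == 0, "unknown config keys: %s", paste(unknown, collapse = ", "))
  structure(utils::modifyList(defaults, over), class = "pipeline_config")
}

config_hash <- function(config) {
  s <- paste(names(config), unlist(config), sep = "=", collapse = ";")
  # small stable polynomial hash, hex string
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a cohort manifest written by \code{\link{write_cohort}}
#'
#' @param path manifest TSV (subject_id, group, nifti_path, seed).
#' @return list of \code{list(id, group, run, seed)} entries.
#' @export
read_cohort_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$nifti_path[i]
    if (!file.exists(p)) p <- file.path(dirname(path), basename(p))
    list(id = df$subject_id[i], group = df$group[i],
         run = read_bold_nifti(p), seed = df$seed[i])
  })
}

.as_subject_list <- function(cohort) {
  if (inherits(cohort, "phantom_cohort")) cohort$subjects
  else if (is.character(cohort)) read_cohort_manifest(cohort)
  else cohort
}

#' Reference run: derive ROIs and the reference fingerprint
#'
#' Preprocesses and decomposes every reference subject, clusters components
#' across subjects, identifies the network cluster (by maximal correlation of
#' its mean map with the phantom ground-truth network map, or by
#' \code{reference_cluster} for real data), derives the 14 target + 6 anti
#' ROIs from its mean map, and averages the member fingerprints into the
#' reference fingerprint.
#'
#' @param cohort a \code{phantom_cohort}, manifest path, or list of
#'   \code{list(id, run, ...)} entries (\eqn{\ge} 2 subjects).
#' @param config a \code{\link{pipeline_config}}.
#' @param target_centers_mm,anti_centers_mm ROI centers in mm; default: taken
#'   from the phantom ground truth.
#' @param reference_cluster optional explicit cluster index overriding the
#'   automatic network-cluster identification.
#' @return list with \code{rois}, \code{reference_fp}, \code{clusters},
#'   \code{network_cluster}, \code{decompositions}, \code{config}.
#' @export
run_reference <- function(cohort, config = pipeline_config(),
                          target_centers_mm = NULL, anti_centers_mm = NULL,
                          reference_cluster = NULL) {
  subjects <- .as_subject_list(cohort)
  .assert(length(subjects) >= 2, "the reference run needs at least 2 subjects")
  pp <- preproc_params(config$preproc.highpass_hz, config$preproc.fwhm_mm)
  decomps <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    run <- preprocess_run(s$run, pp)
    spatial_ica(run, config$ica.n_components,
                seed = child_seed(config$seed, i), subject_id = s$id)
  })
  clusters <- cluster_components(decomps, config$ica.n_components)

  if (is.null(reference_cluster)) {
    truth_map <- NULL
    if (inherits(cohort, "phantom_cohort")) truth_map <- truth_network_map(cohort$bank)
    else if (!is.null(subjects[[1]]$truth)) truth_map <- truth_network_map(subjects[[1]]$truth)
    .assert(!is.null(truth_map),
            "no ground truth available: supply reference_cluster explicitly")
    sims <- vapply(clusters, function(cl)
      abs(stats::cor(as.vector(cl$mean_map), as.vector(truth_map))), 0)
    reference_cluster <- which.max(sims)
  }
  netcl <- clusters[[reference_cluster]]

  vm <- subjects[[1]]$run$voxel_mm
  if (is.null(target_centers_mm)) {
    bank <- if (inherits(cohort, "phantom_cohort")) cohort$bank else subjects[[1]]$truth$bank
    .assert(!is.null(bank), "no ground truth available: supply ROI centers explicitly")
    target_centers_mm <- ijk_to_mm(bank$target_centers, vm)
    anti_centers_mm <- ijk_to_mm(bank$anti_centers, vm)
  }
  # orient the cluster mean map so target centers sit on the positive side
  cidx <- round(sweep(target_centers_mm, 2, vm, `/`)) + 1
  if (mean(netcl$mean_map[cidx]) < 0) netcl$mean_map <- -netcl$mean_map
  mm_z <- netcl$mean_map / stats::sd(netcl$mean_map[subjects[[1]]$run$mask])
  rois <- derive_rois(mm_z, target_centers_mm, anti_centers_mm,
                      cube_mm = config$roi.cube_mm,
                      map_threshold = config$roi.map_threshold,
                      voxel_mm = vm, mask = subjects[[1]]$run$mask)

  fps <- lapply(seq_len(nrow(netcl$members)), function(r) {
    dec <- decomps[[netcl$members$subject[r]]]
    k <- netcl$members$component[r]
    fingerprint(dec$maps[, , , k], dec$courses[, k], dec$tr_seconds, mask = dec$mask)
  })
  ref_fp <- reference_fingerprint(fps)

  list(rois = rois, reference_fp = ref_fp, clusters = clusters,
       network_cluster = reference_cluster, decompositions = decomps,
       config = config, config_hash = config_hash(config))
}

#' Study run: per-subject selection, beta maps and group statistics
#'
#' For every study subject: preprocess, spatial ICA, automatic network
#' selection, residualization against the non-selected components and the
#' component beta map.  Group level: one-sample random-effects T maps per
#' group with FDR masking, the control-vs-patient contrast, and a
#' cluster-extent-corrected contrast cluster table (null smoothness estimated
#' from the subject beta maps).
#'
#' @param cohort a \code{phantom_cohort}, manifest path, or list of subjects.
#' @param rois,ref_fp from \code{\link{run_reference}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param exclude_failed if TRUE, subjects whose selection found no network
#'   component are reported and dropped; by default any such subject aborts
#'   the run.
#' @return list with \code{selections}, \code{beta_maps}, \code{groups},
#'   \code{group_maps} (one-sample stat maps + FDR masks per group),
#'   \code{contrast} (stat map, patients minus controls), \code{min_cluster_size},
#'   \code{cluster_table}, \code{smoothness_mm}, \code{config}.
#' @export
run_study <- function(cohort, rois, ref_fp, config = pipeline_config(),
                      exclude_failed = FALSE) {
  subjects <- .as_subject_list(cohort)
  .assert(length(subjects) >= 3, "the study run needs at least 3 subjects")
  pp <- preproc_params(config$preproc.highpass_hz, config$preproc.fwhm_mm)
  per_subject <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    run <- preprocess_run(s$run, pp)
    dec <- spatial_ica(run, config$ica.n_components,
                       seed = child_seed(config$seed, 1000L + i), subject_id = s$id)
    sel <- select_network_component(run, dec, rois, ref_fp,
                                    alpha = config$selection.alpha)
    bm <- NULL
    if (!sel$no_network_found) {
      # a winning negative-sign graph means the component expresses the
      # network with flipped sign; orient the course so network loading is
      # positive, making beta maps comparable across subjects
      flip <- if (sel$scores$sign[sel$scores$selected] == "negative") -1 else 1
      resid <- residualize(run, dec$courses, sel$selected)
      # partial out the nuisance courses from the predictor as well, so the
      # slope equals the full-model (Frisch-Waugh) partial coefficient; with
      # z-scored maps the betas are then in comparable units across subjects
      course <- residual_course(dec$courses, sel$selected)
      bm <- component_beta_map(resid, flip * course, subject_id = s$id)
    }
    list(id = s$id, group = s$group, selection = sel, beta_map = bm)
  })
  failed <- vapply(per_subject, function(x) is.null(x$beta_map), logical(1))
  if (any(failed)) {
    msg <- sprintf("no network component found for subject(s): %s",
                   paste(vapply(per_subject[failed], `[[`, "", "id"), collapse = ", "))
    if (!exclude_failed) stop(msg, call. = FALSE) else message(msg, " - excluded")
    per_subject <- per_subject[!failed]
  }
  groups <- vapply(per_subject, `[[`, "", "group")
  beta_maps <- lapply(per_subject, `[[`, "beta_map")

  group_maps <- lapply(unique(groups), function(g) {
    maps <- beta_maps[groups == g]
    if (length(maps) < 3) return(NULL)
    sm <- rfx_one_sample(maps)
    list(group = g, stat = sm, fdr_mask = fdr_mask(sm, config$group.q_fdr))
  })
  names(group_maps) <- unique(groups)

  contrast <- min_size <- tab <- fw <- NULL
  if (all(c("control", "patient") %in% groups) &&
      sum(groups == "control") >= 2 && sum(groups == "patient") >= 2) {
    contrast <- two_sample_contrast(beta_maps[groups == "patient"],
                                    beta_maps[groups == "control"])
    t_thr <- stats::qt(1 - config$group.voxel_p / 2, df = contrast$dof)
    # null smoothness from group-demeaned, voxelwise-standardized maps: the
    # null model is a unit-variance correlated field, so its FWHM must match
    # the residuals' spatial *correlation*; demeaning removes the shared
    # network structure and standardization stops high-variance regions from
    # dominating the estimate
    demeaned <- beta_maps
    for (g in unique(groups)) {
      idx <- which(groups == g)
      gm <- Reduce(`+`, lapply(beta_maps[idx], `[[`, "values")) / length(idx)
      for (i in idx) demeaned[[i]]$values <- beta_maps[[i]]$values - gm
    }
    sd_vox <- sqrt(Reduce(`+`, lapply(demeaned, function(m) m$values^2)) /
                     (length(demeaned) - 1))
    sd_vox[sd_vox == 0] <- 1
    for (i in seq_along(demeaned)) demeaned[[i]]$values <- demeaned[[i]]$values / sd_vox
    fw <- estimate_fwhm_mm(demeaned, voxel_mm = beta_maps[[1]]$voxel_mm)
    min_size <- cluster_size_threshold(contrast$mask, t_thr, contrast$dof, fw,
                                       n_iterations = config$group.n_iterations,
                                       alpha = config$group.alpha_cluster,
                                       seed = child_seed(config$seed, 999L),
                                       voxel_mm = beta_maps[[1]]$voxel_mm)
    tab <- apply_cluster_threshold(contrast, t_thr, as.integer(min_size))
  } else {
    message("contrast skipped: need both groups with >= 2 subjects each")
  }

  list(selections = lapply(per_subject, `[[`, "selection"),
       subject_ids = vapply(per_subject, `[[`, "", "id"),
       groups = groups, beta_maps = beta_maps, group_maps = group_maps,
       contrast = contrast, min_cluster_size = if (!is.null(min_size)) as.integer(min_size),
       cluster_table = tab, smoothness_mm = fw,
       config = config, config_hash = config_hash(config))
}
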