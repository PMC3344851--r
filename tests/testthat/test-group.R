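test_that("residualization removes spanned signal and matches partial regression", {
  set.seed(2)
  nt <- 64; nx <- 5
  courses <- matrix(rnorm(nt * 6), nt, 6)
  # data exactly spanned by the non-selected courses -> residual 0
  w <- matrix(rnorm(5 * nx^3), 5, nx^3)
  dat <- courses[, -3] %*% w
  run <- bold_run(array(t(dat), c(nx, nx, nx, nt)), tr_seconds = 2)
  res <- residualize(run, courses, selected = 3)
  expect_lt(max(abs(res$data)), 1e-8)
  # orthogonal design: data = selected course only -> untouched
  # (columns orthogonal to each other and to the intercept)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(nt * 6), nt, 6))))[, -1]
  dat2 <- tcrossprod(Q[, 3], rep(1, nx^3))
  run2 <- bold_run(array(t(dat2), c(nx, nx, nx, nt)), tr_seconds = 2)
  res2 <- residualize(run2, Q, selected = 3)
  # residual retains the selected-course signal (intercept removal aside)
  expect_equal(res2$data, run2$data, tolerance = 1e-8)
  # Frisch-Waugh: two-step beta (residualized data + partialled course)
  # equals the full-model partial coefficient
  set.seed(3)
  dat3 <- matrix(rnorm(nt * nx^3), nt, nx^3)
  run3 <- bold_run(array(t(dat3), c(nx, nx, nx, nt)), tr_seconds = 2)
  res3 <- residualize(run3, courses, selected = 3)
  bm <- component_beta_map(res3, residual_course(courses, 3))
  full_beta <- coef(lm(dat3 ~ courses))["courses3", ]
  expect_equal(as.vector(bm$values), unname(full_beta), tolerance = 1e-8)
})

test_that("beta maps scale with the true loading and find phantom blobs", {
  set.seed(4)
  nt <- 100; nx <- 6
  course <- rnorm(nt)
  dat <- array(rep(2 * course, each = nx^3), c(nx, nx, nx, nt))
  run <- bold_run(dat, tr_seconds = 2)
  bm <- component_beta_map(run, course)
  expect_equal(unname(bm$values[3, 3, 3]), 2, tolerance = 1e-10)
  # pure-noise voxels: beta distribution centered at zero
  noise <- noise_run(nx = 10, nt = 100, seed = 5)
  bmn <- component_beta_map(noise, course)
  expect_lt(abs(mean(bmn$values)), 3 / sqrt(1000 * nt))
  expect_error(component_beta_map(run, rep(1, nt)), "constant")

  # phantom: betas concentrate in the network blobs (ground-truth contrast)
  fx <- fixture_subject()
  truth <- fx$sim$truth
  keep <- setdiff(colnames(truth$mixing), "anti_network")
  courses <- truth$mixing[, keep]
  seln <- which(keep == "network")
  resid <- residualize(fx$pp, courses, seln)
  bmp <- component_beta_map(resid, courses[, seln])
  blobs <- truth$bank$spatial_maps$network > 0
  background <- !(blobs | truth$bank$spatial_maps$anti_network > 0)
  expect_gte(mean(abs(bmp$values[blobs])), 5 * mean(abs(bmp$values[background])))
})

test_that("one-sample RFX t maps match the textbook formula", {
  mk <- function(vals) {
    v <- array(vals, c(2, 2, 2))
    structure(list(values = v, mask = array(TRUE, c(2, 2, 2)),
                   voxel_mm = c(3, 3, 3), subject_id = "s"), class = "beta_map")
  }
  # hand-computed oracle on a printed 5-subject column: 1,2,3,4,5
  # mean 3, sd sqrt(2.5), t = 3 / (sqrt(2.5)/sqrt(5)) = 4.2426
  maps <- lapply(1:5, function(i) mk(i))
  sm <- rfx_one_sample(maps)
  expect_equal(sm$dof, 4)
  expect_equal(sm$tvalues[1, 1, 1], 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(sm$kind, "one_sample")
  # identical positive betas with tiny jitter -> huge t
  set.seed(6)
  maps2 <- lapply(1:15, function(i) mk(1 + rnorm(8, sd = 1e-6)))
  sm2 <- rfx_one_sample(maps2)
  expect_equal(sm2$dof, 14)
  expect_gt(min(sm2$tvalues), 1e4)
  # zero-variance voxels are zeroed and counted
  sm3 <- rfx_one_sample(lapply(1:4, function(i) mk(7)))
  expect_equal(max(abs(sm3$tvalues)), 0)
  expect_equal(sm3$n_zero_variance, 8)
})

test_that("two-sample contrasts match hand computation and are antisymmetric", {
  mk <- function(vals) {
    v <- array(vals, c(2, 2, 2))
    structure(list(values = v, mask = array(TRUE, c(2, 2, 2)),
                   voxel_mm = c(3, 3, 3), subject_id = "s"), class = "beta_map")
  }
  # printed 3 vs 3 toy table: group A = 1,2,3; group B = 4,6,8
  # meanA 2, meanB 6, pooled var = (2 + 8)/4 = 2.5, se = sqrt(2.5*2/3)
  gA <- lapply(c(1, 2, 3), mk); gB <- lapply(c(4, 6, 8), mk)
  ct <- two_sample_contrast(gA, gB)
  expect_equal(ct$dof, 4)
  expect_equal(ct$tvalues[1, 1, 1], (2 - 6) / sqrt(2.5 * (2 / 3)), tolerance = 1e-12)
  # antisymmetry under group swap
  ct2 <- two_sample_contrast(gB, gA)
  expect_equal(ct2$tvalues, -ct$tvalues)
  # 15 vs 13 subjects -> dof 26
  set.seed(8)
  g1 <- lapply(1:15, function(i) mk(rnorm(8)))
  g2 <- lapply(1:13, function(i) mk(rnorm(8)))
  expect_equal(two_sample_contrast(g1, g2)$dof, 26)
  # identical groups -> t = 0 everywhere
  expect_equal(max(abs(two_sample_contrast(gA, gA)$tvalues)), 0)
})

test_that("FDR masking equals the step-up definition and is nested in p<0.05", {
  mk_stat <- function(tv, dof) {
    structure(list(tvalues = tv, mask = array(TRUE, dim(tv)), dof = dof,
                   kind = "one_sample", voxel_mm = c(3, 3, 3)),
              class = "stat_map")
  }
  # all p = 1 -> empty; one tiny p among 10^4 -> that voxel survives
  z <- array(0, c(20, 25, 20))
  expect_false(any(fdr_mask(mk_stat(z, 10), 0.05)))
  z[3, 3, 3] <- 50
  m <- fdr_mask(mk_stat(z, 10), 0.05)
  expect_equal(which(m), which(z == 50))
  # brute-force step-up enumeration on 20 p values
  set.seed(10)
  dof <- 12
  tv <- array(rt(20, dof) * sample(c(1, 3), 20, TRUE), c(20, 1, 1))
  stat <- mk_stat(tv, dof)
  p <- 2 * pt(-abs(as.vector(tv)), dof)
  q <- 0.05
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= q * seq_along(p) / length(p))))
  oracle <- rep(FALSE, 20)
  if (k > 0) oracle[ord[seq_len(k)]] <- TRUE
  expect_equal(as.vector(fdr_mask(stat, q)), oracle)
  # FDR survivors always sit inside the uncorrected p<0.05 mask
  for (seed in 1:5) {
    set.seed(seed)
    tv2 <- array(rt(1000, dof) * 2, c(10, 10, 10))
    st <- mk_stat(tv2, dof)
    fm <- fdr_mask(st, 0.05)
    un <- 2 * pt(-abs(tv2), dof) < 0.05
    expect_true(all(!fm | un))
  }
})

test_that("connected-component labelling agrees with a flood-fill oracle", {
  set.seed(12)
  for (rep in 1:3) {
    mask <- array(runif(10 * 10 * 10) < 0.2, c(10, 10, 10))
    lab <- rsnica:::label_components_3d(mask)
    oracle <- oracle_flood_fill(mask)
    # same partition: label images equal up to renumbering
    expect_equal(max(lab), max(oracle))
    expect_equal(lab > 0, oracle > 0)
    key1 <- split(which(mask), lab[mask])
    key2 <- split(which(mask), oracle[mask])
    expect_setequal(unname(vapply(key1, paste, "", collapse = ",")),
                    unname(vapply(key2, paste, "", collapse = ",")))
  }
})

test_that("cluster tables respect threshold, size boundary and signs", {
  tv <- array(0, c(12, 12, 12))
  stat <- structure(list(tvalues = tv, mask = array(TRUE, c(12, 12, 12)),
                         dof = 26, kind = "two_sample", voxel_mm = c(3, 3, 3)),
                    class = "stat_map")
  expect_equal(nrow(apply_cluster_threshold(stat, 2.772, 1)), 0)
  # one 10-voxel blob: dropped at min_size 11, kept at 10
  tv[2:6, 3, 3] <- 5; tv[2:6, 4, 3] <- 5
  stat$tvalues <- tv
  expect_equal(nrow(apply_cluster_threshold(stat, 2.772, 11)), 0)
  tab <- apply_cluster_threshold(stat, 2.772, 10)
  expect_equal(tab$size_voxels, 10)
  expect_equal(tab$sign, "positive")
  expect_equal(tab$peak_t, 5)
  # negative clusters labelled separately
  tv[9:11, 9:11, 9:11] <- -6
  stat$tvalues <- tv
  tab2 <- apply_cluster_threshold(stat, 2.772, 5)
  expect_setequal(tab2$sign, c("positive", "negative"))
})

test_that("the cluster-size threshold estimator behaves as a null calibrator", {
  # independent voxels at an extreme threshold: only isolated voxels pass
  k <- cluster_size_threshold(c(16, 16, 16), voxel_t_threshold = 6, dof = 26,
                              smoothness_mm = 0, n_iterations = 100, seed = 3)
  expect_equal(as.integer(k), 1L)
  # monotone: harsher voxel thresholds never need larger clusters
  ks <- vapply(c(2.0, 2.8, 3.5), function(th)
    as.integer(cluster_size_threshold(c(16, 16, 16), th, dof = 26,
                                      smoothness_mm = 6, n_iterations = 200,
                                      seed = 4)), 0L)
  expect_true(all(diff(ks) <= 0))
  # the returned size controls the empirical exceedance in the same sample
  k2 <- cluster_size_threshold(c(16, 16, 16), 2.8, dof = 26, smoothness_mm = 6,
                               n_iterations = 200, seed = 5)
  mx <- attr(k2, "max_sizes")
  expect_lte(mean(mx >= as.integer(k2)), 0.05)
  expect_gt(mean(mx >= as.integer(k2) - 1L), 0.05)
})

test_that("smoothness estimation recovers the applied kernel width", {
  set.seed(13)
  maps <- lapply(1:6, function(i) {
    v <- rsnica:::gaussian_smooth_array(array(rnorm(24^3), c(24, 24, 24)), 8, c(3, 3, 3))
    structure(list(values = v, mask = array(TRUE, c(24, 24, 24)),
                   voxel_mm = c(3, 3, 3)), class = "beta_map")
  })
  est <- estimate_fwhm_mm(maps)
  expect_equal(est, 8, tolerance = 0.15)
})
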