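make_reg <- function(tvalues, dof = 269, n_targets = 14, n_anti = 6) {
  structure(list(betas = tvalues, tvalues = tvalues, dof = as.integer(dof),
                 roi_order = c(sprintf("T%02d", seq_len(n_targets)),
                               sprintf("A%02d", seq_len(n_anti)))),
            class = "roi_regression")
}

test_that("ROI time courses are exact voxel means", {
  run <- noise_run(nx = 8, nt = 64, seed = 4)
  vox <- as.matrix(expand.grid(i = 2:6, j = 3:6, k = 2:6))[1:100, ]
  rois <- structure(list(
    targets = c(list(one = matrix(c(2, 2, 2), 1, 3), hundred = vox),
                lapply(3:14, function(r) matrix(c(r %% 6 + 1, 7, 7), 1, 3))),
    anti = lapply(1:6, function(r) matrix(c(r, 8, 8), 1, 3))), class = "roi_set")
  names(rois$targets) <- c("one", "hundred", sprintf("T%02d", 3:14))
  tc <- roi_timecourses(run, rois)
  expect_equal(dim(tc), c(64, 20))
  # single-voxel ROI equals that voxel's course
  expect_equal(tc[, "one"], run$data[2, 2, 2, ])
  # 100-voxel ROI equals the brute-force per-voxel loop mean
  oracle <- rowMeans(vapply(seq_len(nrow(vox)), function(r)
    run$data[vox[r, 1], vox[r, 2], vox[r, 3], ], numeric(64)))
  expect_equal(tc[, "hundred"], oracle)
  # two opposite courses cancel
  run2 <- run
  run2$data[3, 2, 2, ] <- -run2$data[2, 2, 2, ]
  rois$targets$one <- rbind(c(2, 2, 2), c(3, 2, 2))
  expect_equal(max(abs(roi_timecourses(run2, rois)[, "one"])), 0)
})

test_that("component regression recovers coefficients with correct dof", {
  set.seed(9)
  nt <- 300
  courses <- matrix(rnorm(nt * 30), nt, 30)
  # perfect fit: roi course = course 7
  tc <- cbind(courses[, 7], matrix(rnorm(nt * 19), nt, 19))
  colnames(tc) <- c(sprintf("T%02d", 1:14), sprintf("A%02d", 1:6))
  reg <- regress_components(tc, courses)
  expect_equal(reg$dof, 269)
  expect_equal(unname(reg$betas[1, 7]), 1, tolerance = 1e-8)
  expect_gt(abs(reg$tvalues[1, 7]), 1e6)
  expect_lt(max(abs(reg$betas[1, -7])), 1e-8)
  # orthonormal design + noise: recovery within 3 sigma / sqrt(t)
  Q <- qr.Q(qr(matrix(rnorm(nt * 30), nt, 30)))
  beta_true <- rnorm(30)
  sigma <- 0.5
  y <- Q %*% beta_true + rnorm(nt, sd = sigma)
  tc2 <- matrix(rep(y, 20), nt, 20)
  colnames(tc2) <- colnames(tc)
  reg2 <- regress_components(tc2, Q)
  expect_true(all(abs(reg2$betas[1, ] - beta_true) < 3 * sigma))
  # collinear design errors
  bad <- courses
  bad[, 2] <- bad[, 1]
  expect_error(regress_components(tc, bad), "collinear")
})

test_that("possible-edge counts match exhaustive pair enumeration", {
  expect_equal(n_possible_edges(14), 91)
  expect_equal(n_possible_edges(2), 1)
  expect_equal(n_possible_edges(30), nrow(t(combn(30, 2))))
  expect_error(n_possible_edges(1), "at least 2")
})

test_that("the edge threshold matches an independent inverse-CDF computation", {
  T_th <- edge_threshold(0.05, 14, dof = 267)
  # independent oracle: bisection on the numerically integrated t density
  t_density <- function(x, v) {
    exp(lgamma((v + 1) / 2) - lgamma(v / 2)) / sqrt(v * pi) *
      (1 + x^2 / v)^(-(v + 1) / 2)
  }
  upper_p <- function(q, v) stats::integrate(t_density, q, Inf, v = v,
                                             rel.tol = 1e-10)$value
  target <- 0.05 / 91
  oracle <- stats::uniroot(function(q) upper_p(q, 267) - target,
                           c(2, 6), tol = 1e-10)$root
  expect_equal(T_th, oracle, tolerance = 1e-6)
  # near alpha = 1 with a single node pair the threshold collapses toward 0
  expect_lt(edge_threshold(0.999, 2, dof = 50), 0.01)
  # dof increase approaches the normal quantile monotonically from above
  dofs <- c(10, 30, 100, 1000, 1e5)
  ths <- vapply(dofs, function(v) edge_threshold(0.05, 14, v), 0)
  zq <- qnorm(1 - 0.05 / 91)
  expect_true(all(diff(ths) < 0))
  expect_true(all(ths > zq))
  expect_equal(ths[5], zq, tolerance = 1e-3)
})

test_that("graph edge counts equal brute-force clique counts for all sign patterns", {
  T_th <- 3
  set.seed(14)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), 14)))
  patterns <- patterns[c(1, nrow(patterns), sample(2:(nrow(patterns) - 1), 1022)), ]
  tv <- t(patterns) * (T_th + 1)              # 14 x 1024, each column a pattern
  tv <- rbind(tv, matrix(0, 6, ncol(tv)))     # anti ROIs neutral
  reg <- make_reg(tv)
  graphs <- build_graphs(reg, T_th)
  expect_length(graphs, 2 * ncol(tv))
  brute <- function(pass) sum(outer(pass, pass, `&`)[upper.tri(diag(14))])
  for (g in sample(seq_along(graphs), 200)) {
    gr <- graphs[[g]]
    pass <- if (gr$sign == "positive") tv[1:14, gr$component] > T_th
            else tv[1:14, gr$component] < -T_th
    expect_equal(gr$E, brute(pass))
    expect_equal(nrow(gr$edges), gr$E)
  }
  # closed form over every sampled pattern
  k <- rowSums(patterns == 1)
  E_pos <- vapply(graphs[seq_len(ncol(tv))], `[[`, 0, "E")
  expect_equal(E_pos, unname(k * (k - 1) / 2))
  # no suprathreshold ROI -> E = 0; all 14 -> E = 91
  expect_equal(graphs[[which(k == 0)[1]]]$E, 0)
  expect_equal(graphs[[which(k == 14)[1]]]$E, 91)
})

test_that("anticorrelation weight counts opposite-signed anti ROIs", {
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  tv <- rbind(matrix(5, 14, 64), t(patterns) * 4)
  reg <- make_reg(tv)
  for (comp in seq_len(64)) {
    w <- anticorrelation_weight(reg, comp, "positive")
    expect_equal(w, mean(patterns[comp, ] == -1))
    w_neg <- anticorrelation_weight(reg, comp, "negative")
    expect_equal(w_neg, mean(patterns[comp, ] == 1))
  }
})

test_that("scoring obeys the global-component and zero-edge contracts", {
  # component 1: global-like, everything positive -> w = 0 -> score 0
  # component 2: network-like, anti ROIs negative
  # component 3: nothing suprathreshold -> E = 0 -> score 0
  tv <- cbind(c(rep(9, 14), rep(6, 6)),
              c(rep(9, 14), rep(-6, 6)),
              c(rep(0.1, 14), rep(-0.2, 6)))
  reg <- make_reg(tv)
  graphs <- build_graphs(reg, T_th = 3)
  set.seed(11)
  fps <- lapply(1:3, function(i) fingerprint(rnorm(2000), rnorm(128), 2))
  ref <- reference_fingerprint(fps)
  res <- score_and_select(reg, graphs, fps, ref)
  sc <- res$scores
  expect_equal(sc$score[sc$component == 1 & sc$sign == "positive"], 0)
  expect_equal(sc$E[sc$component == 1 & sc$sign == "positive"], 91)
  expect_equal(sc$score[sc$component == 3], c(0, 0))
  expect_equal(res$selected, 2)
  expect_equal(sc$w[sc$component == 2 & sc$sign == "positive"], 1)
  # all-zero scores are flagged, not arbitrarily resolved
  tv0 <- matrix(0.1, 20, 3)
  reg0 <- make_reg(tv0)
  res0 <- score_and_select(reg0, build_graphs(reg0, 3), fps, ref)
  expect_true(res0$no_network_found)
  expect_true(is.na(res0$selected))
})

test_that("selection is invariant to component sign flips", {
  fx <- fixture_subject()
  fxr <- fixture_reference()
  sel <- select_network_component(fx$pp, fx$dec, fxr$ref$rois, fxr$ref$reference_fp)
  expect_false(sel$no_network_found)
  flipped <- fx$dec
  set.seed(21)
  flip <- sample(c(-1, 1), 30, replace = TRUE)
  flip[sel$selected] <- -1                    # force-flip the winner too
  flipped$maps <- sweep(flipped$maps, 4, flip, `*`)
  flipped$courses <- sweep(flipped$courses, 2, flip, `*`)
  sel2 <- select_network_component(fx$pp, flipped, fxr$ref$rois, fxr$ref$reference_fp)
  expect_equal(sel2$selected, sel$selected)
  # the winning graph swaps between the positive and negative family
  expect_false(sel2$scores$sign[sel2$scores$selected] ==
                 sel$scores$sign[sel$scores$selected])
  # score bound: 0 <= score <= 91
  expect_true(all(sel$scores$score >= 0 & sel$scores$score <= 91))
})
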