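# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# One standard phantom bank (default study grid).
fixture_bank <- function() {
  if (is.null(.fixtures$bank)) .fixtures$bank <- make_component_bank(seed = 42)
  .fixtures$bank
}

# One control phantom subject at snr 2 with its preprocessed run and ICA.
fixture_subject <- function() {
  if (is.null(.fixtures$subject)) {
    sim <- simulate_subject(fixture_bank(), "control", snr = 2, seed = 7)
    pp <- preprocess_run(sim$run)
    dec <- spatial_ica(pp, 30, seed = 7)
    .fixtures$subject <- list(sim = sim, pp = pp, dec = dec)
  }
  .fixtures$subject
}

# A 12-subject reference run (ROIs + reference fingerprint), as a reference
# control group would provide.
fixture_reference <- function() {
  if (is.null(.fixtures$reference)) {
    refc <- make_cohort(12, 0, params = list(snr = 2, bank_seed = 42), seed = 101)
    .fixtures$reference <- list(
      cohort = refc,
      ref = run_reference(refc, pipeline_config(seed = 3))
    )
  }
  .fixtures$reference
}

# Small unstructured run for algebraic identities (cheap).
noise_run <- function(nx = 8, nt = 64, seed = 1, tr = 2) {
  set.seed(seed)
  bold_run(array(rnorm(nx^3 * nt), c(nx, nx, nx, nt)), tr_seconds = tr)
}

# Gaussian-smoothed ground-truth map, as it appears in preprocessed data.
smoothed_truth <- function(map, fwhm = 8, voxel_mm = c(3, 3, 3)) {
  rsnica:::gaussian_smooth_array(map, fwhm, voxel_mm)
}

# Independent periodogram band-fraction oracle built on stats::spec.pgram.
oracle_band_fraction <- function(x, tr, lo, hi) {
  sp <- stats::spec.pgram(x, taper = 0, detrend = FALSE, plot = FALSE)
  f <- sp$freq / tr
  sum(sp$spec[f >= lo & f < hi]) / sum(sp$spec)
}

# Recursive flood-fill 26-connectivity labelling oracle (slow, obvious).
oracle_flood_fill <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(start, dims)[1, ])
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > dims)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}
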