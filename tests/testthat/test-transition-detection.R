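# Rip/zip detection, hopping detection, extension measurement, hysteresis.

test_that("a pure elastic ramp yields no events", {
  ph <- make_line_phase(n = 3000, noise = 0.3, seed = 7)
  expect_identical(nrow(detect_rips(ph, min_drop = 1.5)), 0L)
})

test_that("detector warns when the threshold dips below 3 sigma", {
  ph <- make_line_phase(n = 500, noise = 0.3, seed = 7)
  expect_warning(detect_rips(ph, min_drop = 0.5), "false-positive")
})

test_that("a constructed rip is found with the right force and size", {
  set.seed(11)
  n <- 3000
  x <- 300 + 0.05 * seq_len(n)
  f <- 0.15 * x - 15
  drop_at <- 1800
  f[drop_at:n] <- f[drop_at:n] - 2.0  # abrupt 2 pN drop
  ph <- data.frame(time_s = seq_len(n) * 1e-3, trap_position_nm = x,
                   force_pN = f + rnorm(n, 0, 0.3))
  ev <- detect_rips(ph, min_drop = 1.5, stiffness = 0.156)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "RIP")
  expect_lt(abs(ev$time_s - drop_at * 1e-3), 0.02)
  expect_lt(abs(ev$force_pN - (0.15 * x[drop_at] - 15)), 0.4)
  expect_lt(abs(ev$force_drop_pN - 2.0), 0.4)
  expect_equal(ev$extension_change_nm, ev$force_drop_pN / 0.156)
})

test_that("square-wave hopping between two branches is detected", {
  b_lo <- structure(list(slope = 0.15, intercept = -15,
                         window = c(40, 60), resid_sd = 0.3, n = 100),
                    class = "branch_fit")
  b_hi <- structure(list(slope = 0.15, intercept = -15 - 0.15 * 10,
                         window = c(40, 60), resid_sd = 0.3, n = 100),
                    class = "branch_fit")
  set.seed(3)
  n <- 1100
  x <- 400 + 0.05 * seq_len(n)
  state <- rep(rep(c(0, 1), length.out = 11), each = 100)[1:n]
  pos <- x + state * 10
  ph <- data.frame(time_s = seq_len(n) * 1e-3,
                   trap_position_nm = pos,
                   force_pN = 0.15 * x - 15 + rnorm(n, 0, 0.3))
  res <- detect_hopping(ph, b_lo, b_hi, min_switches = 10)
  expect_identical(nrow(res$segments), 1L)
  expect_identical(res$segments$n_switches, 10L)
  expect_false(res$upper_isolated)  # square wave returns to the lower branch
  # single-branch noise-only data: nothing to find
  ph0 <- ph; ph0$trap_position_nm <- x
  res0 <- detect_hopping(ph0, b_lo, b_hi, min_switches = 4)
  expect_identical(nrow(res0$segments), 0L)
  # overlapping branches are undetectable
  b_close <- b_hi; b_close$intercept <- b_lo$intercept - 0.15 * 0.5
  expect_warning(res2 <- detect_hopping(ph, b_lo, b_close), "3 sigma")
  expect_identical(nrow(res2$segments), 0L)
})

test_that("hopping in simulated peeling overlaps the logged interval", {
  spec <- spec_of("5AT", "1M")
  prot <- default_protocol(spec)
  found <- FALSE
  for (seed in 101:105) {
    cy <- simulate_cycle(spec, prot, seed = seed)
    hops <- cy$events[cy$events$event %in% c("HOP_UP", "HOP_DOWN"), ]
    if (nrow(hops) < 6) next
    segs <- segment_cycles(cy$trajectory)
    pull <- segs[[1]]$pull
    melt_t <- cy$events$time_s[cy$events$event == "MELT"]
    pre <- pull[pull$time_s < melt_t - 0.05, ]
    b_lo <- branch_fit(pre, c(40, 53))
    b_hi <- b_lo
    b_hi$intercept <- b_lo$intercept - b_lo$slope * 4  # 4 nm longer state
    res <- detect_hopping(pre, b_lo, b_hi, min_switches = 4)
    if (!nrow(res$segments)) next
    overlap <- res$segments$start_s <= max(hops$time_s) &
      res$segments$end_s >= min(hops$time_s)
    if (any(overlap)) found <- TRUE
  }
  expect_true(found)
})

test_that("measure_extension is a signed, antisymmetric branch separation", {
  b_lo <- structure(list(slope = 0.15, intercept = -15,
                         window = c(15, 65), resid_sd = 0.1, n = 50),
                    class = "branch_fit")
  b_hi <- b_lo
  b_hi$intercept <- -15 - 0.15 * 14.7  # parallel, 14.7 nm longer
  for (f in c(20, 45, 61.5))
    expect_equal(measure_extension(b_lo, b_hi, f), 14.7, tolerance = 1e-12)
  expect_equal(measure_extension(b_hi, b_lo, 50),
               -measure_extension(b_lo, b_hi, 50))
  expect_error(measure_extension(b_lo, b_lo, 50), "degenerate")
  expect_warning(measure_extension(b_lo, b_hi, 80), "extrapolating")
})

test_that("an identical relax phase is classified reversible", {
  ph <- make_line_phase(n = 2000, noise = 0)
  relax <- ph[rev(seq_len(nrow(ph))), ]
  relax$time_s <- ph$time_s + max(ph$time_s)
  hc <- classify_hysteresis(ph, relax)
  expect_identical(hc$verdict, "REVERSIBLE")
  expect_lt(hc$max_gap_pN, 1e-9)
})

test_that("abrupt internal melting at low salt is detected at the logged force", {
  spec <- spec_of("35AT", "5mM")
  prot <- default_protocol(spec)
  for (seed in 1:3) {
    cy <- simulate_cycle(spec, prot, seed = seed)
    segs <- segment_cycles(cy$trajectory)
    rips <- suppressWarnings(
      detect_rips(segs[[1]]$pull, min_drop = 1.0, phase_label = "PULL"))
    rips <- rips[rips$kind == "RIP", ]
    zips <- suppressWarnings(
      detect_rips(segs[[1]]$relax, min_drop = 0.8, phase_label = "RELAX"))
    zips <- zips[zips$kind == "ZIP", ]
    expect_identical(nrow(rips), 1L)
    expect_identical(nrow(zips), 1L)
    log_m <- cy$events$force_pN[cy$events$event == "MELT"]
    log_z <- cy$events$force_pN[cy$events$event == "REZIP"]
    expect_lt(abs(rips$force_pN - log_m), 0.5)
    expect_lt(abs(zips$force_pN - log_z), 0.5)
  }
})

test_that("peeling cycles are hysteretic with accurate event forces", {
  spec <- spec_of("5AT", "1M")
  prot <- default_protocol(spec)
  mol <- simulate_molecule(spec, prot, n_cycles = 8, seed = 61)
  df <- analyze_peeling(mol)
  log_m <- vapply(mol$cycles, function(cy)
    cy$events$force_pN[cy$events$event == "MELT"], numeric(1))
  log_z <- vapply(mol$cycles, function(cy)
    cy$events$force_pN[cy$events$event == "REZIP"], numeric(1))
  expect_true(all(!is.na(df$melt_force_pN)))
  expect_true(all(abs(df$melt_force_pN - log_m) < 0.75))
  expect_true(all(abs(df$rezip_force_pN - log_z) < 0.75, na.rm = TRUE))
  expect_true(all(df$verdict == "HYSTERETIC"))
  expect_true(all(df$rezip_force_pN < df$melt_force_pN, na.rm = TRUE))
  # the branch separation at the melt force recovers the calibrated 14.7 nm
  expect_lt(abs(mean(df$extension_nm, na.rm = TRUE) - 14.7), 0.5)
})
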