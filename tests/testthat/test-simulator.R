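# Bell-Evans kinetics, calibration, and the kinetic Monte-Carlo cycles.

test_that("bell_rate has the textbook limits", {
  kbt <- kbt_at()
  expect_equal(bell_rate(2.5, 3, 0, kbt), 2.5)
  expect_equal(bell_rate(1, 2, kbt / 2, kbt), exp(1))
  expect_error(bell_rate(-1, 2, 1, kbt), "positive")
})

test_that("the Evans-Ritchie closed form matches direct integration", {
  kbt <- kbt_at()
  for (pars in list(c(1e-12, 2, 7.8), c(1e-4, 1.1, 7.8), c(0.5, 4, 20))) {
    expect_equal(evans_ritchie_mean_force(pars[1], pars[2], pars[3], kbt),
                 er_mean_force_integral(pars[1], pars[2], pars[3], kbt),
                 tolerance = 1e-7)
  }
})

test_that("Monte-Carlo rupture forces agree with the closed form", {
  kbt <- kbt_at()
  k0 <- 1e-10; x <- 2; r <- 7.8
  m_theory <- evans_ritchie_mean_force(k0, x, r, kbt)
  sd_theory <- pi / sqrt(6) * kbt / x
  set.seed(4321)
  n <- 10000
  dt <- 0.002
  alive <- rep(TRUE, n)
  rupt <- rep(NA_real_, n)
  t <- 0
  while (any(alive)) {
    t <- t + dt
    f <- r * t
    p <- bell_rate(k0, x, f, kbt) * dt
    hit <- alive & (runif(n) < p)
    rupt[hit] <- f
    alive <- alive & !hit
    if (f > 200) break
  }
  se <- sd_theory / sqrt(n)
  # allow for the O(k dt) discretization of the time-stepped reference
  expect_lt(abs(mean(rupt, na.rm = TRUE) - m_theory), 3 * se + 0.05)
})

test_that("calibrate_k0 inverts the closed form and behaves monotonically", {
  kbt <- kbt_at()
  for (k0 in c(1e-13, 1e-6, 0.05)) {
    m <- evans_ritchie_mean_force(k0, 2, 7.8, kbt)
    expect_equal(calibrate_k0(m, 7.8, 2, kbt) / k0, 1, tolerance = 1e-6)
  }
  # doubling the loading rate raises the implied mean rupture force
  m1 <- evans_ritchie_mean_force(1e-8, 2, 7.8, kbt)
  m2 <- evans_ritchie_mean_force(1e-8, 2, 15.6, kbt)
  expect_gt(m2, m1)
  # very large transition distance drives the mean rupture force toward zero
  expect_lt(evans_ritchie_mean_force(1, 500, 7.8, kbt), 0.5)
})

test_that("rezip calibration round-trips through the falling-ramp mean", {
  kbt <- kbt_at()
  for (k0 in c(1e6, 1e9)) {
    m <- mean_rezip_force(k0, -4, 7.8, 70, kbt)
    expect_equal(calibrate_rezip_k0(m, 7.8, -4, 70, kbt) / k0, 1,
                 tolerance = 1e-6)
  }
})

test_that("an elastic-only cycle shows no events and no hysteresis", {
  spec <- spec_of("5AT", "1M")
  prot <- default_protocol(spec)
  cy <- simulate_cycle(spec, prot, kinetics = dead_kinetics(spec, prot),
                       seed = 5)
  expect_identical(nrow(cy$events), 0L)
  segs <- segment_cycles(cy$trajectory)
  hc <- classify_hysteresis(segs[[1]]$pull, segs[[1]]$relax)
  expect_identical(hc$verdict, "REVERSIBLE")
  expect_lt(hc$max_gap_pN, 0.8)
})

test_that("peeling cycles melt once on pull and rezip once on relax", {
  spec <- spec_of("5AT", "1M")
  prot <- default_protocol(spec)
  for (seed in 1:4) {
    cy <- simulate_cycle(spec, prot, seed = seed)
    melts <- cy$events[cy$events$event == "MELT", ]
    rezips <- cy$events[cy$events$event == "REZIP", ]
    expect_identical(nrow(melts), 1L)
    expect_identical(nrow(rezips), 1L)
    expect_gt(melts$force_pN, rezips$force_pN)
    expect_identical(cy$pathway, "HYSTERETIC")
  }
})

test_that("force jumps at events equal stiffness times the extension change", {
  spec <- spec_of("5AT", "1M")
  spec$noise_sd <- 0
  prot <- default_protocol(spec)
  kbt <- prot$kbt
  k <- prot$trap_stiffness
  cy <- simulate_cycle(spec, prot, seed = 9)
  tr <- cy$trajectory
  # melting (B/I -> peeled) must drop the force at (nearly) fixed trap motion;
  # the sample at the event time already carries the post-transition state
  i_m <- which.min(abs(tr$time_s - cy$events$time_s[cy$events$event == "MELT"]))
  expect_lt(tr$force_pN[i_m] - tr$force_pN[i_m - 1], -0.5)
  # rezip (peeled -> B): the realized force rise equals stiffness times the
  # model's extension change between the two states at their respective forces
  i_z <- which.min(abs(tr$time_s - cy$events$time_s[cy$events$event == "REZIP"]))
  f_old <- tr$force_pN[i_z]; f_new <- tr$force_pN[i_z + 1]
  expect_gt(f_new, f_old)  # shortening raises the force
  dxt <- tr$trap_position_nm[i_z + 1] - tr$trap_position_nm[i_z]
  st_b <- list(segment_state("at_core", 64, "B_FORM"))
  st_p <- list(segment_state("at_core", 64, "PEELED_SS"))
  dext_model <- construct_extension(spec, st_b, f_new, kbt) -
    construct_extension(spec, st_p, f_old, kbt)
  dext_observed <- dxt - (f_new - f_old) / k
  expect_equal(dext_observed, dext_model, tolerance = 1e-3)
})

test_that("cycles are bit-for-bit reproducible under a seed", {
  spec <- spec_of("5AT", "1M")
  prot <- default_protocol(spec)
  a <- simulate_cycle(spec, prot, seed = 77)
  b <- simulate_cycle(spec, prot, seed = 77)
  expect_identical(a$trajectory$force_pN, b$trajectory$force_pN)
  expect_identical(a$events, b$events)
  c <- simulate_cycle(spec, prot, seed = 78)
  expect_false(identical(a$trajectory$force_pN, c$trajectory$force_pN))
  # different seeds decorrelate event times
  expect_false(isTRUE(all.equal(a$events$time_s, c$events$time_s)))
})

test_that("gradual internal melting produces no rips in the log", {
  spec <- spec_of("35AT", "1M")
  prot <- default_protocol(spec)
  mol <- simulate_molecule(spec, prot, n_cycles = 2, seed = 21,
                           hysteretic_pathway_probability = 0)
  for (cy in mol$cycles) {
    expect_identical(nrow(cy$events), 0L)
    segs <- segment_cycles(cy$trajectory)
    pull <- segs[[1]]$pull
    # transition spreads over many pN: no abrupt force changes anywhere
    expect_identical(nrow(detect_rips(pull, min_drop = 1.5)), 0L)
    expect_gt(max(pull$force_pN) - min(pull$force_pN), 40)
  }
})

test_that("pathway probability 0 and 1 are honored", {
  spec <- spec_of("35AT", "1M")
  prot <- default_protocol(spec)
  m0 <- simulate_molecule(spec, prot, n_cycles = 4, seed = 3,
                          hysteretic_pathway_probability = 0)
  expect_true(all(m0$pathways == "REVERSIBLE"))
  m1 <- simulate_molecule(spec, prot, n_cycles = 4, seed = 3,
                          hysteretic_pathway_probability = 1)
  expect_true(all(m1$pathways == "HYSTERETIC"))
})

test_that("the partial-peel intermediate always hangs off the B-form branch", {
  spec <- spec_of("5AT", "1M")
  prot <- default_protocol(spec)
  found_hop <- FALSE
  for (seed in 11:14) {
    cy <- simulate_cycle(spec, prot, seed = seed)
    st <- cy$state_seq
    runs <- rle(st)
    iI <- which(runs$values == "I")
    if (length(iI)) found_hop <- TRUE
    for (j in iI) {
      expect_gt(j, 1)  # never the initial state
      expect_identical(runs$values[j - 1], "B")  # entered from B
      if (j < length(runs$values))
        expect_true(runs$values[j + 1] %in% c("B", "MELTED"))
    }
  }
  expect_true(found_hop)
})

test_that("hysteretic cycles enclose non-negative pull-relax area", {
  for (nm in list(c("5AT", "1M"), c("35AT", "5mM"))) {
    spec <- spec_of(nm[1], nm[2])
    cy <- simulate_cycle(spec, default_protocol(spec), seed = 31)
    segs <- segment_cycles(cy$trajectory)
    pull <- segs[[1]]$pull; relax <- segs[[1]]$relax
    trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
    a_pull <- trapz(pull$trap_position_nm, pull$force_pN)
    o <- order(relax$trap_position_nm)
    a_relax <- trapz(relax$trap_position_nm[o], relax$force_pN[o])
    expect_gt(a_pull - a_relax, 0)
  }
})
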