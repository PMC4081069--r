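# Branch fits, reaction extent, two-state and three-state equilibrium fits.

test_that("branch_fit recovers exact linear data and rejects bad input", {
  ph <- make_line_phase(n = 400, slope = 0.147, intercept = -16, noise = 0)
  b <- branch_fit(ph, range(ph$force_pN) + c(-1, 1))
  expect_equal(b$slope, 0.147, tolerance = 1e-10)
  expect_equal(b$intercept, -16, tolerance = 1e-8)
  expect_lt(b$resid_sd, 1e-9)
  expect_error(branch_fit(ph, c(1000, 1001)), "fewer than 10")
  flat <- ph; flat$trap_position_nm <- 300
  expect_error(branch_fit(flat, range(ph$force_pN) + c(-1, 1)), "singular")
})

test_that("branch_fit under noise stays within three standard errors", {
  ph <- make_line_phase(n = 500, slope = 0.15, intercept = -15, noise = 0.3,
                        seed = 12)
  b <- branch_fit(ph, range(ph$force_pN) + c(-2, 2))
  d <- ph
  se_slope <- 0.3 / (sd(d$trap_position_nm) * sqrt(nrow(d)))
  expect_lt(abs(b$slope - 0.15), 3 * se_slope)
})

test_that("reaction extent is 0 / 1 / 0.5 on, above and between branches", {
  b_lo <- structure(list(slope = 0.15, intercept = -15, window = c(30, 50),
                         resid_sd = 0.01, n = 50), class = "branch_fit")
  b_hi <- structure(list(slope = 0.15, intercept = -15 - 0.15 * 10,
                         window = c(70, 80), resid_sd = 0.01, n = 50),
                    class = "branch_fit")
  mk <- function(offset) data.frame(
    time_s = 1:60 * 1e-3,
    trap_position_nm = (55 + seq(0, 5.9, by = 0.1) + 15) / 0.15 + offset,
    force_pN = 55 + seq(0, 5.9, by = 0.1))
  expect_lt(max(reaction_extent(mk(0), b_lo, b_hi)$extent), 1e-9)
  expect_gt(min(reaction_extent(mk(10), b_lo, b_hi)$extent), 1 - 1e-9)
  expect_equal(reaction_extent(mk(5), b_lo, b_hi)$extent,
               rep(0.5, 60), tolerance = 1e-9)
})

test_that("two-state fit recovers noise-free parameters to 1e-6", {
  kbt <- kbt_at()
  f <- seq(60, 76, by = 0.05)
  phi <- 1 / (1 + exp(-2.6 * (f - 67.8) / kbt))
  fit <- fit_two_state(data.frame(force = f, extent = phi), kbt)
  expect_equal(fit$ftr, 67.8, tolerance = 1e-6)
  expect_equal(fit$delta, 2.6, tolerance = 1e-6)
  # width identity: F(0.95) - F(0.05) = 2 ln(19) kBT / delta, about 9.3 pN
  width <- 2 * log(19) * kbt / fit$delta
  expect_equal(width, 9.26, tolerance = 0.01)
  f05 <- uniroot(function(x) fit$model(x) - 0.05, c(50, 67.8))$root
  f95 <- uniroot(function(x) fit$model(x) - 0.95, c(67.8, 90))$root
  expect_equal(f95 - f05, width, tolerance = 1e-6)
})

test_that("antisymmetric extent data pins the midpoint exactly", {
  kbt <- kbt_at()
  f0 <- 65
  df <- seq(-8, 8, by = 0.1)
  phi <- 1 / (1 + exp(-1.8 * df / kbt))  # antisymmetric about f0
  fit <- fit_two_state(data.frame(force = f0 + df, extent = phi), kbt)
  expect_equal(fit$ftr, f0, tolerance = 1e-8)
})

test_that("two-state fit rejects data that never spans the transition", {
  kbt <- kbt_at()
  f <- seq(60, 64, by = 0.1)
  phi <- 1 / (1 + exp(-2.6 * (f - 67.8) / kbt))  # all below 0.2
  expect_error(fit_two_state(data.frame(force = f, extent = phi), kbt),
               "span")
})

test_that("state assignment labels by proximity with a declared tie-break", {
  branches <- lapply(c(-15, -15 - 0.15 * 8, -15 - 0.15 * 20), function(ic)
    structure(list(slope = 0.15, intercept = ic, window = c(40, 70),
                   resid_sd = 0.3, n = 50), class = "branch_fit"))
  f <- rep(60, 5)
  x_b <- (f - (-15)) / 0.15
  # on branch 1, on branch 2, on branch 3, midway 1-2 (tie), near branch 2
  pos <- x_b + c(0, 8, 20, 4, 9)
  ph <- data.frame(time_s = 1:5 * 1e-3, trap_position_nm = pos, force_pN = f)
  lab <- assign_states(ph, branches)
  expect_identical(as.integer(lab), c(1L, 2L, 3L, 1L, 2L))
})

test_that("population curves normalize and drop sparse bins", {
  set.seed(5)
  forces <- runif(400, 60, 64)
  labels <- 1L + (forces > 62)
  pops <- population_curves(labels, forces, bin_width = 0.5, n_states = 2)
  expect_true(all(abs(pops$P1 + pops$P2 - 1) < 1e-12))
  one <- population_curves(rep(1L, 50), runif(50, 60, 61), n_states = 1)
  expect_true(all(one$P1 == 1))
  sparse <- population_curves(c(rep(1L, 100), 2L),
                              c(runif(100, 60, 61), 99), n_states = 2)
  expect_true(99.25 %in% attr(sparse, "dropped"))
})

test_that("three-state fit recovers noise-free populations and closed forms", {
  kbt <- kbt_at()
  g_i <- 62.1 * 8; x_i <- 8
  g_s <- g_i + 65.9 * 11.9; x_s <- 19.9
  f <- seq(56, 72, by = 0.25)
  P <- forcemelt:::.three_state_P(f, g_i, x_i, g_s, x_s, kbt)
  pops <- data.frame(force = f, P1 = P[, 1], P2 = P[, 2], P3 = P[, 3],
                     n = rep(1000L, length(f)))
  fit <- fit_three_state(pops, kbt)
  expect_equal(fit$g_i / g_i, 1, tolerance = 1e-6)
  expect_equal(fit$x_i / x_i, 1, tolerance = 1e-6)
  expect_equal(fit$g_s / g_s, 1, tolerance = 1e-6)
  expect_equal(fit$x_s / x_s, 1, tolerance = 1e-6)
  expect_equal(fit$ftr_I, fit$ftr_I_num, tolerance = 1e-8)
  expect_equal(fit$ftr_II, fit$ftr_II_num, tolerance = 1e-8)
  expect_equal(fit$ftr, fit$ftr_num, tolerance = 1e-6)
  expect_true(fit$ftr_I < fit$ftr && fit$ftr < fit$ftr_II)
  expect_false(fit$degenerate)
})

test_that("a symmetric three-state model puts F_tr midway between crossings", {
  kbt <- kbt_at()
  x_i <- 6; x_s <- 12           # x_I = x_S / 2
  g_i <- 60 * x_i; g_s <- g_i + 64 * x_i  # symmetric rung energies
  f <- seq(52, 72, by = 0.25)
  P <- forcemelt:::.three_state_P(f, g_i, x_i, g_s, x_s, kbt)
  fit <- fit_three_state(data.frame(force = f, P1 = P[, 1], P2 = P[, 2],
                                    P3 = P[, 3], n = rep(500L, length(f))),
                         kbt)
  expect_equal(fit$ftr, (fit$ftr_I + fit$ftr_II) / 2, tolerance = 1e-6)
})

test_that("a never-dominant intermediate flags the fit as degenerate", {
  kbt <- kbt_at()
  # crossings out of order: the intermediate is always a minority state
  g_i <- 66 * 8; x_i <- 8
  g_s <- g_i + 62 * 11.9; x_s <- 19.9
  f <- seq(55, 72, by = 0.25)
  P <- forcemelt:::.three_state_P(f, g_i, x_i, g_s, x_s, kbt)
  expect_warning(
    fit <- fit_three_state(data.frame(force = f, P1 = P[, 1], P2 = P[, 2],
                                      P3 = P[, 3], n = rep(500L, length(f))),
                           kbt),
    "degenerate")
  expect_true(fit$degenerate)
  expect_true(is.finite(fit$ftr_I) && is.finite(fit$ftr_II))
})

test_that("assigned states agree with the simulator's ground truth", {
  spec <- spec_of("ATGC", "1M")
  prot <- default_protocol(spec)
  cy <- simulate_cycle(spec, prot, seed = 17)
  res <- analyze_composite(list(cy), spec)
  segs <- segment_cycles(cy$trajectory)
  pull <- segs[[1]]$pull
  sel <- pull$force_pN > 58 & pull$force_pN < 70
  ph <- pull[sel, ]
  truth <- cy$state_seq[ph$.row]
  lab <- assign_states(ph, res$branches)
  truth_int <- match(truth, c("B", "I", "S"))
  expect_gt(mean(lab == truth_int), 0.95)
})
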