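# Kinetic Monte-Carlo simulator of constant-velocity pull-relax cycles.
#
# Each construct x salt condition is realized as a small state machine over
# conformational states (B-form, partially peeled intermediate(s), S-form,
# fully molten), with bistable hopping sampled by Gillespie steps within each
# sampling interval, abrupt ruptures/rezips as Bell processes along the force
# ramp, and the non-cooperative internal melting of the double-sealed duplex
# as a deterministic equilibrium molten fraction. The trap force balance is
# resolved through per-state force-vs-trap-position lookup tables built from
# the polymer models.

# ---------------------------------------------------------------------------
# Bell-Evans kinetics

#' Bell rate at a given force
#'
#' `k(F) = k0 * exp(F * x_dagger / kBT)`. The transition distance is signed:
#' positive if force accelerates the transition (rupture), negative if force
#' decelerates it (rezipping).
#'
#' @param k0 rate at zero force, 1/s (> 0).
#' @param x_dagger transition distance in nm (signed).
#' @param force force in pN (vectorized).
#' @param kbt thermal energy in pN nm.
#' @return rate in 1/s.
#' @examples
#' bell_rate(1, 2, 0, kbt_at())        # k0
#' bell_rate(1, 2, kbt_at() / 2, kbt_at())  # k0 * e
#' @export
bell_rate <- function(k0, x_dagger, force, kbt = kbt_at()) {
  if (any(k0 <= 0)) stop("k0 must be positive")
  k0 * exp(force * x_dagger / kbt)
}

# exp(a) * E1(a), stable for all a > 0
.e1exp <- function(a) {
  if (a < 50) exp(a) * pracma::expint_E1(a)
  else (1 - 1 / a + 2 / a^2 - 6 / a^3 + 24 / a^4) / a
}

#' Mean rupture force under a constant loading rate (Evans-Ritchie)
#'
#' For a Bell process `k(F) = k0 exp(F x / kBT)` under a force ramp
#' `F = r t`, the survival probability is
#' `S(F) = exp(-(k0 kBT / (r x)) (exp(F x / kBT) - 1))` and the mean rupture
#' force has the closed form `(kBT/x) e^a E1(a)` with `a = k0 kBT / (r x)`.
#'
#' @param k0 zero-force rate, 1/s.
#' @param x_dagger transition distance, nm (> 0).
#' @param loading_rate ramp rate in pN/s (> 0).
#' @param kbt thermal energy in pN nm.
#' @return mean rupture force in pN.
#' @export
evans_ritchie_mean_force <- function(k0, x_dagger, loading_rate,
                                     kbt = kbt_at()) {
  stopifnot(k0 > 0, x_dagger > 0, loading_rate > 0)
  a <- k0 * kbt / (loading_rate * x_dagger)
  (kbt / x_dagger) * .e1exp(a)
}

#' Calibrate a zero-force Bell rate against a target mean rupture force
#'
#' Inverts the Evans-Ritchie closed form: returns the `k0` for which a Bell
#' process with transition distance `x_dagger` under a `loading_rate` ramp
#' ruptures at `target_mean_rupture_force` on average.
#'
#' @param target_mean_rupture_force target mean rupture force, pN (> 0).
#' @param loading_rate ramp rate, pN/s (> 0).
#' @param x_dagger transition distance, nm (> 0).
#' @param kbt thermal energy in pN nm.
#' @return k0 in 1/s.
#' @export
calibrate_k0 <- function(target_mean_rupture_force, loading_rate, x_dagger,
                         kbt = kbt_at()) {
  stopifnot(target_mean_rupture_force > 0, loading_rate > 0, x_dagger > 0)
  g <- function(la) {
    a <- 10^la
    (kbt / x_dagger) * .e1exp(a) - target_mean_rupture_force
  }
  lo <- -300; hi <- 12
  if (g(lo) < 0)
    stop("calibrate_k0: target mean force too high to invert at this ",
         "loading rate / transition distance")
  la <- uniroot(g, c(lo, hi), tol = 1e-13)$root
  10^la * loading_rate * x_dagger / kbt
}

#' Mean rezip force under a falling force ramp
#'
#' For a Bell process with negative transition distance (rate grows as force
#' falls), starting fully converted at `force_start` and ramping the force
#' down at `loading_rate`, returns the mean force at which the reverse
#' transition fires (survival-function integral, computed numerically).
#'
#' @param k0 zero-force rate, 1/s.
#' @param x_dagger signed transition distance in nm (negative for a reverse
#'   transition that force decelerates).
#' @param loading_rate magnitude of the downward ramp, pN/s (> 0).
#' @param force_start force at the start of the relax ramp, pN.
#' @param kbt thermal energy in pN nm.
#' @return mean rezip force in pN.
#' @export
mean_rezip_force <- function(k0, x_dagger, loading_rate, force_start,
                             kbt = kbt_at()) {
  stopifnot(k0 > 0, x_dagger < 0, loading_rate > 0, force_start > 0)
  xa <- -x_dagger
  b <- k0 * kbt / (loading_rate * xa)
  # S(f): probability of still being in the extended state when the falling
  # ramp reaches force f; E[F_z] = int_0^f0 (1 - S(f)) df
  surv <- function(f)
    exp(-b * (exp(-f * xa / kbt) - exp(-force_start * xa / kbt)))
  integrate(function(f) 1 - surv(f), 0, force_start, rel.tol = 1e-10,
            subdivisions = 500L)$value
}

#' Calibrate the zero-force rate of a rezip transition
#'
#' @inheritParams mean_rezip_force
#' @param target_mean_force target mean rezip force, pN.
#' @return k0 in 1/s.
#' @export
calibrate_rezip_k0 <- function(target_mean_force, loading_rate, x_dagger,
                               force_start, kbt = kbt_at()) {
  stopifnot(target_mean_force > 0, target_mean_force < force_start)
  g <- function(lk) mean_rezip_force(10^lk, x_dagger, loading_rate,
                                     force_start, kbt) - target_mean_force
  10^uniroot(g, c(-18, 28), tol = 1e-13)$root
}

#' Transition distance implied by a rupture-force standard deviation
#'
#' The Evans-Ritchie rupture-force distribution approaches a Gumbel form whose
#' standard deviation is `(pi / sqrt(6)) kBT / x`; inverting it converts a
#' measured force dispersion into an effective Bell transition distance.
#'
#' @param sd_force rupture-force standard deviation, pN.
#' @param kbt thermal energy in pN nm.
#' @return transition distance in nm.
#' @export
bell_x_from_sd <- function(sd_force, kbt = kbt_at()) {
  stopifnot(sd_force > 0)
  pi / sqrt(6) * kbt / sd_force
}

# ---------------------------------------------------------------------------
# Kinetic parameter sets

#' Derive the kinetic parameter set of a construct
#'
#' Converts the configured transition-force means and standard deviations of a
#' [construct_spec] into Bell parameters (transition distance from the force
#' dispersion, `k0` from the mean via [calibrate_k0] / [calibrate_rezip_k0] at
#' the nominal loading rate), plus the hopping and equilibrium parameters of
#' the scheme.
#'
#' @param spec a [construct_spec].
#' @param protocol a [trap_protocol] (supplies the relax start force).
#' @return a list of class `kinetic_params`.
#' @export
derive_kinetics <- function(spec, protocol = default_protocol(spec)) {
  cfg <- spec$config
  kbt <- protocol$kbt
  r <- spec$loading_rate
  kin <- list(scheme = spec$scheme)
  mk_rupture <- function(mean_key, sd_key) {
    x <- bell_x_from_sd(.cfg_get(cfg, sd_key), kbt)
    list(k0 = calibrate_k0(.cfg_get(cfg, mean_key), r, x, kbt), x = x,
         target = .cfg_get(cfg, mean_key))
  }
  mk_rezip <- function(mean_key, sd_key) {
    x <- -bell_x_from_sd(.cfg_get(cfg, sd_key), kbt)
    list(k0 = calibrate_rezip_k0(.cfg_get(cfg, mean_key), r, x,
                                 protocol$force_max, kbt),
         x = x, target = .cfg_get(cfg, mean_key))
  }
  if (spec$scheme == "peeling") {
    kin$melt <- mk_rupture("melt_force_pN", "melt_force_sd_pN")
    kin$rezip <- mk_rezip("rezip_force_pN", "rezip_force_sd_pN")
    kin$hop <- list(mid = .cfg_get(cfg, "hop_midpoint_pN"),
                    dx = .cfg_get(cfg, "hop_extension_nm"),
                    attempt = .cfg_get(cfg, "hop_attempt_rate_hz"))
  } else if (spec$scheme == "two_state_rupture") {
    kin$melt <- mk_rupture("melt_force_pN", "melt_force_sd_pN")
    kin$rezip <- mk_rezip("rezip_force_pN", "rezip_force_sd_pN")
  } else if (spec$scheme == "internal_eq") {
    kin$eq <- list(ftr = .cfg_get(cfg, "ftr_pN"),
                   delta = .cfg_get(cfg, "delta_nm"),
                   equilibrium_mode = TRUE)
    kin$hyst_prob <- .cfg_get(cfg, "hysteretic_probability")
    kin$rezip <- mk_rezip("hyst_rezip_force_pN", "hyst_rezip_force_sd_pN")
  } else if (spec$scheme == "composite") {
    att <- .cfg_get(cfg, "hop_attempt_rate_hz")
    kin$ladder <- list(
      list(mid = .cfg_get(cfg, "ftr1_pN"), dx = .cfg_get(cfg, "dx1_nm"),
           attempt = att, up = "B_TO_I", down = "I_TO_B"),
      list(mid = spec$extras$ftr2_pN, dx = .cfg_get(cfg, "dx2_nm"),
           attempt = att, up = "I_TO_S", down = "S_TO_I"))
  } else if (spec$scheme == "composite_low") {
    att <- .cfg_get(cfg, "hop_attempt_rate_hz")
    kin$ladder <- list(
      list(mid = .cfg_get(cfg, "t1_pN"), dx = .cfg_get(cfg, "dx1_nm"),
           attempt = att, up = "B_TO_I1", down = "I1_TO_B"),
      list(mid = .cfg_get(cfg, "t2_pN"), dx = .cfg_get(cfg, "dx2_nm"),
           attempt = att, up = "I1_TO_I2", down = "I2_TO_I1"),
      list(mid = .cfg_get(cfg, "t3_pN"), dx = .cfg_get(cfg, "dx3_nm"),
           attempt = att, up = "I2_TO_S", down = "S_TO_I2"))
    kin$melt <- mk_rupture("melt_force_pN", "melt_force_sd_pN")
    kin$rezip <- mk_rezip("rezip_force_pN", "rezip_force_sd_pN")
  } else stop("unknown scheme: ", spec$scheme)
  class(kin) <- "kinetic_params"
  kin
}

# ---------------------------------------------------------------------------
# Simulation context: per-state extension functions and force lookup tables

.lookup_grid_step <- 0.01

.make_lookup <- function(Xfun, stiffness, f_hi) {
  F <- seq(0.02, f_hi, by = .lookup_grid_step)
  xt <- Xfun(F) + F / stiffness
  list(F = F, xt = xt, k = stiffness)
}

.F_of_xt <- function(lk, xt) {
  i <- findInterval(xt, lk$xt, all.inside = TRUE)
  w <- (xt - lk$xt[i]) / (lk$xt[i + 1] - lk$xt[i])
  lk$F[i] + w * .lookup_grid_step
}

.xt_of_F <- function(lk, f) {
  i <- pmin(pmax(floor((f - lk$F[1]) / .lookup_grid_step) + 1, 1),
            length(lk$F) - 1)
  w <- (f - lk$F[i]) / .lookup_grid_step
  lk$xt[i] + w * (lk$xt[i + 1] - lk$xt[i])
}

.sim_context <- function(spec, protocol, kinetics = NULL) {
  stopifnot(inherits(spec, "construct_spec"), inherits(protocol, "trap_protocol"))
  kin <- if (is.null(kinetics)) derive_kinetics(spec, protocol) else kinetics
  kbt <- protocol$kbt
  el <- spec$elastic
  k <- protocol$trap_stiffness
  rel <- function(p, f) wlc_relative_extension(f, p$persistence_length, kbt,
                                               p$stretch_modulus)
  seg_ext <- function(p, n) function(f) n * p$contour_length_per_unit * rel(p, f)
  handle <- seg_ext(el$HANDLE_SS, 1)
  n_bp <- spec$duplex_bp
  states <- NULL

  if (spec$scheme %in% c("peeling")) {
    h <- .cfg_get(spec$config, "hop_peel_bp")
    ds_all <- seg_ext(el$B_FORM, n_bp)
    ds_part <- seg_ext(el$B_FORM, n_bp - h)
    ss_part <- seg_ext(el$PEELED_SS, h)
    ss_all <- seg_ext(el$PEELED_SS, n_bp)
    states <- list(
      B = function(f) ds_all(f) + handle(f),
      I = function(f) ds_part(f) + ss_part(f) + handle(f),
      MELTED = function(f) ss_all(f) + handle(f))
  } else if (spec$scheme == "two_state_rupture") {
    ds_all <- seg_ext(el$B_FORM, n_bp)
    m_all <- seg_ext(el$MELTED_SHARED, n_bp)
    states <- list(B = function(f) ds_all(f) + handle(f),
                   MELTED = function(f) m_all(f) + handle(f))
  } else if (spec$scheme == "internal_eq") {
    ds_all <- seg_ext(el$B_FORM, n_bp)
    m_all <- seg_ext(el$MELTED_SHARED, n_bp)
    ftr <- kin$eq$ftr; delta <- kin$eq$delta
    phi <- function(f) 1 / (1 + exp(-delta * (f - ftr) / kbt))
    states <- list(
      EQ = function(f) {
        xb <- ds_all(f) + handle(f)
        xb + phi(f) * (m_all(f) - ds_all(f))
      },
      MELTED = function(f) m_all(f) + handle(f))
  } else if (spec$scheme == "composite") {
    n_at <- spec$segments$n_bp[1]; n_gc <- spec$segments$n_bp[2]
    at_ds <- seg_ext(el$B_FORM, n_at); gc_ds <- seg_ext(el$B_FORM, n_gc)
    at_ss <- seg_ext(el$PEELED_SS, n_at)
    gc_s <- seg_ext(el$S_FORM, n_gc)
    f1 <- .cfg_get(spec$config, "ftr1_pN")
    ce <- spec$extras$intermediate_extra_compliance
    states <- list(
      B = function(f) at_ds(f) + gc_ds(f) + handle(f),
      I = function(f) at_ss(f) + gc_ds(f) + handle(f) +
        ce * pmax(f - f1, -3),
      S = function(f) at_ss(f) + gc_s(f) + handle(f))
  } else if (spec$scheme == "composite_low") {
    n_at <- spec$segments$n_bp[1]; n_gc <- spec$segments$n_bp[2]
    h <- n_at %/% 2
    at_ds <- seg_ext(el$B_FORM, n_at)
    at_half_ds <- seg_ext(el$B_FORM, n_at - h)
    at_half_ss <- seg_ext(el$PEELED_SS, h)
    at_ss <- seg_ext(el$PEELED_SS, n_at)
    gc_ds <- seg_ext(el$B_FORM, n_gc)
    gc_s <- seg_ext(el$S_FORM, n_gc)
    gc_m <- seg_ext(el$MELTED_SHARED, n_gc)
    states <- list(
      B = function(f) at_ds(f) + gc_ds(f) + handle(f),
      I1 = function(f) at_half_ds(f) + at_half_ss(f) + gc_ds(f) + handle(f),
      I2 = function(f) at_ss(f) + gc_ds(f) + handle(f),
      S = function(f) at_ss(f) + gc_s(f) + handle(f),
      MELTED = function(f) at_ss(f) + gc_m(f) + handle(f))
  } else stop("unknown scheme: ", spec$scheme)

  f_hi <- protocol$force_max + 8
  lks <- lapply(states, .make_lookup, stiffness = k, f_hi = f_hi)
  if (protocol$force_max + 2 > f_hi)
    stop("force_max unreachable within the lookup range")
  ctx <- list(spec = spec, protocol = protocol, kin = kin, kbt = kbt,
              states = states, lks = lks, state_names = names(states),
              dt = 1 / protocol$sample_rate,
              v = protocol$trap_velocity, k = k, noise_sd = spec$noise_sd)
  # For the peeling scheme the rupture proceeds from whichever state (B-form
  # or partial-peel intermediate) the molecule occupies, and the intermediate
  # branch carries a slightly lower force at the same trap position. With the
  # default kinetics, refine k0 so that the mean rupture force of the full
  # state machine along the actual trap path (not of a bare Bell ramp)
  # equals the configured target.
  if (is.null(kinetics) && spec$scheme == "peeling")
    ctx$kin$melt$k0 <- .calibrate_peeling_k0(ctx)
  ctx
}

.calibrate_peeling_k0 <- function(ctx) {
  p <- ctx$protocol; kin <- ctx$kin; kbt <- ctx$kbt
  dt <- ctx$dt
  lkB <- ctx$lks$B; lkI <- ctx$lks$I
  xt <- seq(.xt_of_F(lkB, p$force_min), .xt_of_F(lkB, p$force_max),
            by = ctx$v * dt)
  fB <- .F_of_xt(lkB, xt)
  fI <- .F_of_xt(lkI, xt)
  # intermediate occupancy along the ramp: the hopping dynamics lag behind
  # the stationary distribution, so integrate the two-state master equation
  # (exponential Euler) instead of assuming instantaneous equilibrium
  k_up <- kin$hop$attempt * exp((fB - kin$hop$mid) * kin$hop$dx / (2 * kbt))
  k_dn <- kin$hop$attempt * exp(-(fI - kin$hop$mid) * kin$hop$dx / (2 * kbt))
  R <- k_up + k_dn
  peq <- k_up / R
  decay <- exp(-R * dt)
  pI <- numeric(length(fB))
  pI[1] <- peq[1] * (1 - decay[1])
  for (i in seq_along(pI)[-1])
    pI[i] <- peq[i] + (pI[i - 1] - peq[i]) * decay[i]
  target <- kin$melt$target
  x <- kin$melt$x
  eB <- exp(fB * x / kbt); eI <- exp(fI * x / kbt)
  g <- function(lk0) {
    k0 <- 10^lk0
    hB <- (1 - pI) * k0 * eB
    hI <- pI * k0 * eI
    h <- hB + hI
    S <- exp(-c(0, cumsum(h[-length(h)])) * dt)
    pr <- S * h * dt
    sum(S * (hB * fB + hI * fI) * dt) / sum(pr) - target
  }
  l0 <- log10(kin$melt$k0)
  10^uniroot(g, c(l0 - 6, l0 + 6), tol = 1e-12)$root
}

# first index at which a hazard (rate path, per-sample) fires, or NA
.hazard_event_index <- function(rates, dt) {
  if (!length(rates)) return(NA_integer_)
  H <- cumsum(rates) * dt
  E <- rexp(1)
  j <- findInterval(E, H) + 1L
  if (j > length(rates)) NA_integer_ else j
}

# ---------------------------------------------------------------------------
# Gillespie ladder loop: discrete hopping states (+ optional rupture channel)
# between window_lo and the loop exit. Records one sample per dt.

.ladder_loop <- function(ctx, lk_idx, trans, state, xt, dir, window_lo,
                         window_hi, f_stop, rupture = NULL, t0 = 0,
                         require_edge_state = TRUE) {
  dt <- ctx$dt; v <- ctx$v; kbt <- ctx$kbt
  n_states <- length(lk_idx)
  cap <- ceiling(abs(window_hi - window_lo + 10) / (ctx$k * v * dt) *
                 (1 + ctx$k * 3)) + 2000L
  xt_v <- numeric(cap); F_v <- numeric(cap); st_v <- integer(cap)
  ev_t <- numeric(0); ev_nm <- character(0); ev_f <- numeric(0)
  ev_x <- numeric(0)
  ruptured <- FALSE
  i <- 0L
  repeat {
    xt <- xt + dir * v * dt
    f <- .F_of_xt(ctx$lks[[lk_idx[state]]], xt)
    tnow <- t0 + i * dt
    # Gillespie substeps within this sampling interval
    tau <- 0
    repeat {
      r_up <- if (state < n_states)
        trans[[state]]$attempt *
          exp((f - trans[[state]]$mid) * trans[[state]]$dx / (2 * kbt))
      else 0
      r_dn <- if (state > 1)
        trans[[state - 1]]$attempt *
          exp(-(f - trans[[state - 1]]$mid) * trans[[state - 1]]$dx / (2 * kbt))
      else 0
      r_rupt <- if (!is.null(rupture) && state %in% rupture$from)
        bell_rate(rupture$k0, rupture$x, f, kbt) else 0
      R <- r_up + r_dn + r_rupt
      if (R <= 0) break
      w <- rexp(1, R)
      if (tau + w > dt) break
      tau <- tau + w
      u <- runif(1) * R
      if (u < r_rupt) {
        ev_t <- c(ev_t, tnow); ev_nm <- c(ev_nm, rupture$name)
        ev_f <- c(ev_f, f); ev_x <- c(ev_x, xt)
        ruptured <- TRUE
        break
      } else if (u < r_rupt + r_up) {
        ev_t <- c(ev_t, tnow); ev_nm <- c(ev_nm, trans[[state]]$up)
        ev_f <- c(ev_f, f); ev_x <- c(ev_x, xt)
        state <- state + 1L
      } else {
        ev_t <- c(ev_t, tnow); ev_nm <- c(ev_nm, trans[[state - 1]]$down)
        ev_f <- c(ev_f, f); ev_x <- c(ev_x, xt)
        state <- state - 1L
      }
      f <- .F_of_xt(ctx$lks[[lk_idx[state]]], xt)
    }
    if (ruptured) break
    i <- i + 1L
    if (i > cap) stop("ladder loop exceeded its sample budget")
    xt_v[i] <- xt; F_v[i] <- f; st_v[i] <- state
    if (dir > 0 && f >= f_stop) break
    if (dir > 0 && f >= window_hi &&
        (!require_edge_state || state == n_states)) break
    if (dir < 0 && f <= f_stop) break
    if (dir < 0 && f <= window_lo &&
        (!require_edge_state || state == 1L)) break
  }
  list(xt = xt_v[seq_len(i)], F = F_v[seq_len(i)], state = st_v[seq_len(i)],
       final_state = state, final_xt = xt, ruptured = ruptured,
       events = data.frame(time_s = ev_t, event = ev_nm, force_pN = ev_f,
                           trap_position_nm = ev_x,
                           stringsAsFactors = FALSE),
       n = i)
}

# deterministic span on one branch from xt_from (exclusive) towards force
# f_to; returns per-sample xt and F
.det_span <- function(ctx, lk, xt_from, f_to, dir) {
  dt <- ctx$dt; v <- ctx$v
  xt_to <- .xt_of_F(lk, f_to)
  n <- floor((xt_to - xt_from) / (dir * v * dt))
  if (n <= 0)
    return(list(xt = numeric(0), F = numeric(0), n = 0L,
                final_xt = xt_from))
  xt <- xt_from + dir * v * dt * seq_len(n)
  list(xt = xt, F = .F_of_xt(lk, xt), n = as.integer(n),
       final_xt = xt[n])
}

# ---------------------------------------------------------------------------
# Cycle simulation

#' Simulate one pull-relax cycle
#'
#' Runs the construct's state machine along a constant-velocity pull from the
#' lower to the upper force limit and back. Every lengthening event appears in
#' the trajectory as a drop in force (the bead relaxes toward the trap
#' center), every shortening event as a rise. Gaussian measurement noise is
#' added to the force channel. Identical seeds give identical output.
#'
#' @param spec a [construct_spec].
#' @param protocol a [trap_protocol]; default [default_protocol] of the spec.
#' @param kinetics a `kinetic_params` list; default [derive_kinetics].
#' @param seed integer seed fixing all randomness of the cycle.
#' @return an object of class `fm_cycle`: a list with `trajectory` (an
#'   [fm_trajectory]), `events` (the ground-truth log), `pathway`
#'   (`"REVERSIBLE"` or `"HYSTERETIC"`), `state_seq` (per-sample ground-truth
#'   state labels) and `n_pull` (number of pull-phase samples).
#' @export
simulate_cycle <- function(spec, protocol = default_protocol(spec),
                           kinetics = NULL, seed = 1L) {
  ctx <- .sim_context(spec, protocol, kinetics)
  .simulate_cycle_ctx(ctx, seed)
}

.simulate_cycle_ctx <- function(ctx, seed) {
  set.seed(seed)
  out <- switch(ctx$kin$scheme,
                peeling = .sim_peeling(ctx),
                two_state_rupture = .sim_two_state_rupture(ctx),
                internal_eq = .sim_internal_eq(ctx),
                composite = .sim_composite(ctx),
                composite_low = .sim_composite_low(ctx))
  n <- length(out$F)
  noise <- rnorm(n, 0, ctx$noise_sd)
  p <- ctx$protocol
  meta <- list(construct = ctx$spec$name, salt = ctx$spec$salt,
               temperature_C = p$temperature, seed = seed,
               trap_velocity_nm_s = p$trap_velocity,
               trap_stiffness_pN_nm = p$trap_stiffness,
               sample_rate_hz = p$sample_rate,
               force_min_pN = p$force_min, force_max_pN = p$force_max)
  traj <- fm_trajectory(data.frame(time_s = (seq_len(n) - 1) * ctx$dt,
                                   trap_position_nm = out$xt,
                                   force_pN = out$F + noise),
                        metadata = meta)
  structure(list(trajectory = traj,
                 events = out$events,
                 pathway = out$pathway,
                 state_seq = ctx$state_names[out$state],
                 n_pull = out$n_pull),
            class = "fm_cycle")
}

.bind_events <- function(...) {
  evs <- list(...)
  evs <- evs[vapply(evs, function(e) !is.null(e) && nrow(e) > 0, logical(1))]
  if (!length(evs))
    return(data.frame(time_s = numeric(0), event = character(0),
                      force_pN = numeric(0), trap_position_nm = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, evs)
}

.event_row <- function(t, name, f, xt) {
  data.frame(time_s = t, event = name, force_pN = f, trap_position_nm = xt,
             stringsAsFactors = FALSE)
}

# -- 5'AT-type peeling (also used for any one-end-sealed AT duplex) ---------
.sim_peeling <- function(ctx) {
  kin <- ctx$kin; p <- ctx$protocol
  lkB <- ctx$lks$B; lkM <- ctx$lks$MELTED
  dt <- ctx$dt; v <- ctx$v; kbt <- ctx$kbt
  cfg <- ctx$spec$config
  hop_lo <- kin$hop$mid - 7 * kbt / kin$hop$dx
  loop_lo <- min(hop_lo,
                 .cfg_get(cfg, "melt_force_pN") -
                   7 * .cfg_get(cfg, "melt_force_sd_pN"))
  loop_lo <- max(loop_lo, p$force_min + 0.5)

  # pull: deterministic B-branch span with exact melt hazard, then the
  # hopping/rupture window, then the melted branch up to force_max
  xt0 <- .xt_of_F(lkB, p$force_min)
  spanA <- .det_span(ctx, lkB, xt0, loop_lo, +1)
  hazA <- bell_rate(kin$melt$k0, kin$melt$x, spanA$F, kbt)
  jA <- .hazard_event_index(hazA, dt)
  xt <- c(); F <- c(); st <- c(); ev <- NULL
  melted <- FALSE
  if (!is.na(jA)) {
    xt <- spanA$xt[seq_len(jA)]; F <- spanA$F[seq_len(jA)]
    st <- rep(1L, jA)
    ev <- .event_row((jA - 1) * dt, "MELT", spanA$F[jA], spanA$xt[jA])
    melted <- TRUE
    last_xt <- spanA$xt[jA]
  } else {
    xt <- spanA$xt; F <- spanA$F; st <- rep(1L, spanA$n)
    loop <- .ladder_loop(
      ctx, lk_idx = c(1L, 2L), state = 1L,
      trans = list(list(mid = kin$hop$mid, dx = kin$hop$dx,
                        attempt = kin$hop$attempt,
                        up = "HOP_UP", down = "HOP_DOWN")),
      xt = spanA$final_xt, dir = +1,
      window_lo = loop_lo, window_hi = p$force_max, f_stop = p$force_max,
      rupture = list(k0 = kin$melt$k0, x = kin$melt$x, from = c(1L, 2L),
                     name = "MELT"),
      t0 = spanA$n * dt, require_edge_state = FALSE)
    loop$events$time_s <- loop$events$time_s  # already absolute
    xt <- c(xt, loop$xt); F <- c(F, loop$F); st <- c(st, loop$state)
    ev <- loop$events
    melted <- loop$ruptured
    last_xt <- loop$final_xt
  }
  if (melted) {
    spanB <- .det_span(ctx, lkM, last_xt, p$force_max, +1)
    xt <- c(xt, spanB$xt); F <- c(F, spanB$F)
    st <- c(st, rep(3L, spanB$n))
    last_xt <- spanB$final_xt
  }
  n_pull <- length(xt)

  # relax: melted branch down with rezip hazard, then B branch to force_min
  t_relax0 <- n_pull * dt
  if (melted) {
    xt_end <- .xt_of_F(lkB, p$force_min)
    nR <- max(floor((last_xt - xt_end) / (v * dt)), 0L)
    xtR <- last_xt - v * dt * seq_len(nR)
    FM <- .F_of_xt(lkM, xtR)
    haz <- bell_rate(kin$rezip$k0, kin$rezip$x, FM, kbt)
    j <- .hazard_event_index(haz, dt)
    FR <- FM; stR <- rep(3L, nR)
    evR <- NULL
    if (!is.na(j)) {
      if (j < nR) {
        idx <- (j + 1):nR
        FR[idx] <- .F_of_xt(lkB, xtR[idx])
        stR[idx] <- 1L
      }
      evR <- .event_row(t_relax0 + (j - 1) * dt, "REZIP", FM[j], xtR[j])
    }
    keep <- seq_len(nR)
    xt <- c(xt, xtR[keep]); F <- c(F, FR[keep]); st <- c(st, stR[keep])
    ev <- .bind_events(ev, evR)
  } else {
    spanR <- .det_span(ctx, lkB, last_xt, p$force_min, -1)
    xt <- c(xt, spanR$xt); F <- c(F, spanR$F)
    st <- c(st, rep(1L, spanR$n))
  }
  list(xt = xt, F = F, state = st, events = .bind_events(ev),
       pathway = if (melted) "HYSTERETIC" else "REVERSIBLE",
       n_pull = n_pull)
}

# -- 3'5'AT low salt: single abrupt internal melt + hysteretic rezip --------
.sim_two_state_rupture <- function(ctx) {
  kin <- ctx$kin; p <- ctx$protocol
  lkB <- ctx$lks$B; lkM <- ctx$lks$MELTED
  dt <- ctx$dt; v <- ctx$v; kbt <- ctx$kbt
  xt0 <- .xt_of_F(lkB, p$force_min)
  span <- .det_span(ctx, lkB, xt0, p$force_max, +1)
  haz <- bell_rate(kin$melt$k0, kin$melt$x, span$F, kbt)
  j <- .hazard_event_index(haz, dt)
  ev <- NULL
  if (!is.na(j)) {
    xt <- span$xt[seq_len(j)]; F <- span$F[seq_len(j)]
    st <- rep(1L, j)
    ev <- .event_row((j - 1) * dt, "MELT", span$F[j], span$xt[j])
    spanB <- .det_span(ctx, lkM, span$xt[j], p$force_max, +1)
    xt <- c(xt, spanB$xt); F <- c(F, spanB$F); st <- c(st, rep(2L, spanB$n))
    melted <- TRUE
    last_xt <- spanB$final_xt
  } else {
    xt <- span$xt; F <- span$F; st <- rep(1L, span$n)
    melted <- FALSE
    last_xt <- span$final_xt
  }
  n_pull <- length(xt)
  t0 <- n_pull * dt
  if (melted) {
    xt_end <- .xt_of_F(lkB, p$force_min)
    nR <- max(floor((last_xt - xt_end) / (v * dt)), 0L)
    xtR <- last_xt - v * dt * seq_len(nR)
    FM <- .F_of_xt(lkM, xtR)
    haz <- bell_rate(kin$rezip$k0, kin$rezip$x, FM, kbt)
    j <- .hazard_event_index(haz, dt)
    FR <- FM; stR <- rep(2L, nR)
    evR <- NULL
    if (!is.na(j)) {
      if (j < nR) {
        idx <- (j + 1):nR
        FR[idx] <- .F_of_xt(lkB, xtR[idx])
        stR[idx] <- 1L
      }
      evR <- .event_row(t0 + (j - 1) * dt, "REZIP", FM[j], xtR[j])
    }
    xt <- c(xt, xtR); F <- c(F, FR); st <- c(st, stR)
    ev <- .bind_events(ev, evR)
  } else {
    spanR <- .det_span(ctx, lkB, last_xt, p$force_min, -1)
    xt <- c(xt, spanR$xt); F <- c(F, spanR$F); st <- c(st, rep(1L, spanR$n))
  }
  list(xt = xt, F = F, state = st, events = .bind_events(ev),
       pathway = if (melted) "HYSTERETIC" else "REVERSIBLE",
       n_pull = n_pull)
}

# -- 3'5'AT high salt: gradual equilibrium internal melting -----------------
.sim_internal_eq <- function(ctx, hyst_prob = NULL) {
  kin <- ctx$kin; p <- ctx$protocol
  lkE <- ctx$lks$EQ; lkM <- ctx$lks$MELTED
  dt <- ctx$dt; v <- ctx$v; kbt <- ctx$kbt
  if (is.null(hyst_prob)) hyst_prob <- kin$hyst_prob
  hysteretic <- runif(1) < hyst_prob

  xt0 <- .xt_of_F(lkE, p$force_min)
  span <- .det_span(ctx, lkE, xt0, p$force_max, +1)
  xt <- span$xt; F <- span$F; st <- rep(1L, span$n)
  n_pull <- length(xt)
  last_xt <- span$final_xt
  t0 <- n_pull * dt
  ev <- NULL
  if (!hysteretic) {
    spanR <- .det_span(ctx, lkE, last_xt, p$force_min, -1)
    xt <- c(xt, spanR$xt); F <- c(F, spanR$F); st <- c(st, rep(1L, spanR$n))
  } else {
    xt_end <- .xt_of_F(lkE, p$force_min)
    nR <- max(floor((last_xt - xt_end) / (v * dt)), 0L)
    xtR <- last_xt - v * dt * seq_len(nR)
    FM <- .F_of_xt(lkM, xtR)
    haz <- bell_rate(kin$rezip$k0, kin$rezip$x, FM, kbt)
    j <- .hazard_event_index(haz, dt)
    FR <- FM; stR <- rep(2L, nR)
    if (!is.na(j)) {
      if (j < nR) {
        idx <- (j + 1):nR
        FR[idx] <- .F_of_xt(lkE, xtR[idx])
        stR[idx] <- 1L
      }
      ev <- .event_row(t0 + (j - 1) * dt, "REZIP", FM[j], xtR[j])
    }
    xt <- c(xt, xtR); F <- c(F, FR); st <- c(st, stR)
  }
  list(xt = xt, F = F, state = st, events = .bind_events(ev),
       pathway = if (hysteretic) "HYSTERETIC" else "REVERSIBLE",
       n_pull = n_pull)
}

# -- ATGC high salt: reversible three-state ladder B <-> I <-> S ------------
.sim_composite <- function(ctx) {
  kin <- ctx$kin; p <- ctx$protocol
  dt <- ctx$dt; kbt <- ctx$kbt
  lkB <- ctx$lks$B; lkS <- ctx$lks$S
  w_lo <- kin$ladder[[1]]$mid - 7 * kbt / kin$ladder[[1]]$dx
  w_hi <- kin$ladder[[2]]$mid + 7 * kbt / kin$ladder[[2]]$dx
  w_lo <- max(w_lo, p$force_min + 0.5)
  w_hi <- min(w_hi, p$force_max - 0.5)

  xt0 <- .xt_of_F(lkB, p$force_min)
  spanA <- .det_span(ctx, lkB, xt0, w_lo, +1)
  loopU <- .ladder_loop(ctx, lk_idx = 1:3, trans = kin$ladder, state = 1L,
                        xt = spanA$final_xt, dir = +1, window_lo = w_lo,
                        window_hi = w_hi, f_stop = p$force_max,
                        t0 = spanA$n * dt)
  spanB <- .det_span(ctx, ctx$lks[[loopU$final_state]], loopU$final_xt,
                     p$force_max, +1)
  xt <- c(spanA$xt, loopU$xt, spanB$xt)
  F <- c(spanA$F, loopU$F, spanB$F)
  st <- c(rep(1L, spanA$n), loopU$state, rep(loopU$final_state, spanB$n))
  n_pull <- length(xt)

  spanC <- .det_span(ctx, ctx$lks[[loopU$final_state]], spanB$final_xt,
                     w_hi, -1)
  loopD <- .ladder_loop(ctx, lk_idx = 1:3, trans = kin$ladder,
                        state = loopU$final_state,
                        xt = spanC$final_xt, dir = -1, window_lo = w_lo,
                        window_hi = w_hi, f_stop = p$force_min,
                        t0 = (n_pull + spanC$n) * dt)
  spanD <- .det_span(ctx, ctx$lks[[loopD$final_state]], loopD$final_xt,
                     p$force_min, -1)
  xt <- c(xt, spanC$xt, loopD$xt, spanD$xt)
  F <- c(F, spanC$F, loopD$F, spanD$F)
  st <- c(st, rep(loopU$final_state, spanC$n), loopD$state,
          rep(loopD$final_state, spanD$n))
  list(xt = xt, F = F, state = st,
       events = .bind_events(loopU$events, loopD$events),
       pathway = "REVERSIBLE", n_pull = n_pull)
}

# -- ATGC low salt: four-state ladder + irreversible full melt --------------
.sim_composite_low <- function(ctx) {
  kin <- ctx$kin; p <- ctx$protocol
  dt <- ctx$dt; v <- ctx$v; kbt <- ctx$kbt
  lkB <- ctx$lks$B
  lkM <- ctx$lks$MELTED
  w_lo <- kin$ladder[[1]]$mid - 7 * kbt / kin$ladder[[1]]$dx
  w_hi <- kin$ladder[[3]]$mid + 7 * kbt / kin$ladder[[3]]$dx
  w_lo <- max(w_lo, p$force_min + 0.5)
  rupture <- list(k0 = kin$melt$k0, x = kin$melt$x, from = 4L,
                  name = "FULL_MELT")

  xt0 <- .xt_of_F(lkB, p$force_min)
  spanA <- .det_span(ctx, lkB, xt0, w_lo, +1)
  loopU <- .ladder_loop(ctx, lk_idx = 1:4, trans = kin$ladder, state = 1L,
                        xt = spanA$final_xt, dir = +1, window_lo = w_lo,
                        window_hi = w_hi, f_stop = p$force_max,
                        rupture = rupture, t0 = spanA$n * dt)
  xt <- c(spanA$xt, loopU$xt)
  F <- c(spanA$F, loopU$F)
  st <- c(rep(1L, spanA$n), loopU$state)
  melted <- loopU$ruptured
  ev <- loopU$events
  last_state <- if (melted) 5L else loopU$final_state
  last_xt <- loopU$final_xt
  if (!melted) {
    # deterministic span on S with the full-melt hazard still active
    spanB <- .det_span(ctx, ctx$lks[[last_state]], last_xt, p$force_max, +1)
    haz <- bell_rate(kin$melt$k0, kin$melt$x, spanB$F, kbt)
    j <- .hazard_event_index(haz, dt)
    if (!is.na(j)) {
      xt <- c(xt, spanB$xt[seq_len(j)]); F <- c(F, spanB$F[seq_len(j)])
      st <- c(st, rep(last_state, j))
      ev <- .bind_events(ev, .event_row((length(xt) - 1) * dt, "FULL_MELT",
                                        spanB$F[j], spanB$xt[j]))
      melted <- TRUE
      spanM <- .det_span(ctx, lkM, spanB$xt[j], p$force_max, +1)
      xt <- c(xt, spanM$xt); F <- c(F, spanM$F); st <- c(st, rep(5L, spanM$n))
      last_xt <- spanM$final_xt
      last_state <- 5L
    } else {
      xt <- c(xt, spanB$xt); F <- c(F, spanB$F)
      st <- c(st, rep(last_state, spanB$n))
      last_xt <- spanB$final_xt
    }
  } else {
    spanM <- .det_span(ctx, lkM, last_xt, p$force_max, +1)
    xt <- c(xt, spanM$xt); F <- c(F, spanM$F); st <- c(st, rep(5L, spanM$n))
    last_xt <- spanM$final_xt
  }
  n_pull <- length(xt)
  t0 <- n_pull * dt

  if (melted) {
    xt_end <- .xt_of_F(lkB, p$force_min)
    nR <- max(floor((last_xt - xt_end) / (v * dt)), 0L)
    xtR <- last_xt - v * dt * seq_len(nR)
    FM <- .F_of_xt(lkM, xtR)
    haz <- bell_rate(kin$rezip$k0, kin$rezip$x, FM, kbt)
    j <- .hazard_event_index(haz, dt)
    FR <- FM; stR <- rep(5L, nR)
    if (!is.na(j)) {
      if (j < nR) {
        idx <- (j + 1):nR
        FR[idx] <- .F_of_xt(lkB, xtR[idx])
        stR[idx] <- 1L
      }
      ev <- .bind_events(ev, .event_row(t0 + (j - 1) * dt, "REZIP",
                                        FM[j], xtR[j]))
    }
    xt <- c(xt, xtR); F <- c(F, FR); st <- c(st, stR)
    pathway <- "HYSTERETIC"
  } else {
    spanC <- .det_span(ctx, ctx$lks[[last_state]], last_xt, w_hi, -1)
    loopD <- .ladder_loop(ctx, lk_idx = 1:4, trans = kin$ladder,
                          state = last_state, xt = spanC$final_xt, dir = -1,
                          window_lo = w_lo, window_hi = w_hi,
                          f_stop = p$force_min,
                          t0 = (n_pull + spanC$n) * dt)
    spanD <- .det_span(ctx, ctx$lks[[loopD$final_state]], loopD$final_xt,
                       p$force_min, -1)
    xt <- c(xt, spanC$xt, loopD$xt, spanD$xt)
    F <- c(F, spanC$F, loopD$F, spanD$F)
    st <- c(st, rep(last_state, spanC$n), loopD$state,
            rep(loopD$final_state, spanD$n))
    ev <- .bind_events(ev, loopD$events)
    pathway <- "REVERSIBLE"
  }
  list(xt = xt, F = F, state = st, events = .bind_events(ev),
       pathway = pathway, n_pull = n_pull)
}

# ---------------------------------------------------------------------------

#' Simulate repeated pull-relax cycles of one molecule
#'
#' @inheritParams simulate_cycle
#' @param n_cycles number of pull-relax cycles.
#' @param hysteretic_pathway_probability probability that a relax phase of the
#'   gradually melting double-sealed construct follows the hysteretic
#'   (one-step rezip) pathway instead of relaxing reversibly; default from the
#'   construct configuration. Ignored by schemes whose pathway is not drawn.
#' @return an object of class `fm_molecule`: list of [simulate_cycle] results
#'   plus the drawn pathway per cycle.
#' @export
simulate_molecule <- function(spec, protocol = default_protocol(spec),
                              kinetics = NULL, n_cycles = 5, seed = 1L,
                              hysteretic_pathway_probability = NULL) {
  stopifnot(n_cycles >= 1)
  ctx <- .sim_context(spec, protocol, kinetics)
  if (!is.null(hysteretic_pathway_probability)) {
    stopifnot(hysteretic_pathway_probability >= 0,
              hysteretic_pathway_probability <= 1)
    ctx$kin$hyst_prob <- hysteretic_pathway_probability
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_cycles)
  cycles <- lapply(seeds, function(s) .simulate_cycle_ctx(ctx, s))
  structure(list(cycles = cycles,
                 pathways = vapply(cycles, `[[`, character(1), "pathway"),
                 spec = ctx$spec),
            class = "fm_molecule")
}

#' @export
print.fm_cycle <- function(x, ...) {
  cat("<fm_cycle>", nrow(x$trajectory), "samples,", nrow(x$events),
      "events, pathway:", x$pathway, "\n")
  invisible(x)
}

#' @export
print.fm_molecule <- function(x, ...) {
  cat("<fm_molecule>", length(x$cycles), "cycles of", x$spec$name, "at",
      x$spec$salt, "\n")
  invisible(x)
}
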