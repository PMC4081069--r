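# Independent oracles and small fixture builders used across the suite.

# Bisection inversion of the (inextensible) Marko-Siggia interpolation:
# F(l) = kBT/Lp * (1/(4(1-l)^2) - 1/4 + l). Independent of the package's
# Newton solver.
ms_bisect_rel_ext <- function(force, lp, kbt, tol = 1e-12) {
  fwd <- function(l) kbt / lp * (0.25 / (1 - l)^2 - 0.25 + l)
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fwd(mid) < force) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# mean Evans-Ritchie rupture force by direct numerical integration of the
# survival function (independent of the exponential-integral closed form)
er_mean_force_integral <- function(k0, x, r, kbt) {
  a <- k0 * kbt / (r * x)
  surv <- function(f) exp(-a * (exp(f * x / kbt) - 1))
  integrate(surv, 0, 400, rel.tol = 1e-10, subdivisions = 1000L)$value
}

# exhaustive grid-search fit of the two-state model (SSE objective)
grid_two_state <- function(points, kbt, ftr_range, delta_range,
                           ftr_step = 0.02, delta_step = 0.02) {
  ftrs <- seq(ftr_range[1], ftr_range[2], by = ftr_step)
  deltas <- seq(delta_range[1], delta_range[2], by = delta_step)
  best <- c(NA, NA); best_sse <- Inf
  for (d in deltas) {
    pred <- outer(points$force, ftrs, function(f, m)
      1 / (1 + exp(-d * (f - m) / kbt)))
    sse <- colSums((pred - points$extent)^2)
    j <- which.min(sse)
    if (sse[j] < best_sse) {
      best_sse <- sse[j]
      best <- c(ftrs[j], d)
    }
  }
  list(ftr = best[1], delta = best[2], sse = best_sse,
       steps = c(ftr_step, delta_step))
}

# synthetic single-branch phase: force = slope * x + intercept + noise
make_line_phase <- function(n = 2000, slope = 0.15, intercept = -15,
                            x0 = 300, v = 0.05, noise = 0, seed = 1) {
  set.seed(seed)
  x <- x0 + v * seq_len(n)
  data.frame(time_s = seq_len(n) * 1e-3, trap_position_nm = x,
             force_pN = slope * x + intercept + rnorm(n, 0, noise))
}

# cached construct specs (built once per test run)
.spec_cache <- new.env(parent = emptyenv())
spec_of <- function(construct, salt) {
  key <- paste(construct, salt, sep = "_")
  if (is.null(.spec_cache[[key]]))
    .spec_cache[[key]] <- construct_spec(construct, salt)
  .spec_cache[[key]]
}

# kinetics with every transition effectively switched off (elastic-only)
dead_kinetics <- function(spec, protocol = default_protocol(spec)) {
  kin <- derive_kinetics(spec, protocol)
  for (nm in intersect(names(kin), c("melt", "rezip")))
    kin[[nm]]$k0 <- 1e-300
  if (!is.null(kin$hop)) kin$hop$attempt <- 1e-300
  if (!is.null(kin$ladder))
    kin$ladder <- lapply(kin$ladder, function(tr) {
      tr$attempt <- 1e-300
      tr
    })
  if (!is.null(kin$hyst_prob)) kin$hyst_prob <- 0
  kin
}
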