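# High-level analysis wrappers: from simulated (or read) cycles to per-cycle
# transition measurements and equilibrium fits. These are the building blocks
# the reporting layer and the command-line interface aggregate.

.cycle_phases <- function(cycle) {
  if (inherits(cycle, "fm_cycle")) {
    segs <- segment_cycles(cycle$trajectory)
    return(segs[[1]])
  }
  if (is.list(cycle) && !is.null(cycle$pull)) return(cycle)
  stop("expected an fm_cycle or a list(pull=, relax=)")
}

.cycle_list <- function(x) {
  if (inherits(x, "fm_molecule")) x$cycles
  else if (inherits(x, "fm_cycle")) list(x)
  else x
}

#' Effective loading rate of a phase
#'
#' Linear slope of force versus time over a force range (pN/s).
#'
#' @param phase data frame of one phase.
#' @param force_range length-2 force window, pN.
#' @return loading rate in pN/s (negative for relax phases).
#' @export
loading_rate <- function(phase, force_range) {
  df <- .phase_df(phase)
  sel <- df$force_pN >= force_range[1] & df$force_pN <= force_range[2]
  if (sum(sel) < 10) stop("too few samples in force range")
  unname(coef(lm(force_pN ~ time_s, data = df[sel, ]))[2])
}

#' Per-cycle peeling analysis
#'
#' For an abrupt peeling construct: locates the melt rip on the pull and the
#' rezip on the relax, fits the B-form and peeled branches around each event,
#' measures the transition extension/contraction as the branch separation at
#' the event force, and classifies the cycle's hysteresis.
#'
#' @param cycle an `fm_cycle` or `list(pull=, relax=)` of phase data frames.
#' @param stiffness trap stiffness pN/nm (default from trajectory metadata).
#' @param min_drop_pull,min_drop_relax event thresholds in pN.
#' @param window detector window, samples.
#' @param cycle_id identifier for the output row.
#' @return one-row data frame: `cycle`, `melt_force_pN`, `rezip_force_pN`,
#'   `extension_nm`, `contraction_nm`, `verdict`, `max_gap_pN`.
#' @export
analyze_peeling_cycle <- function(cycle, stiffness = NULL,
                                  min_drop_pull = 1.0, min_drop_relax = 0.8,
                                  window = 30, cycle_id = 1L) {
  ph <- .cycle_phases(cycle)
  if (is.null(stiffness) && inherits(cycle, "fm_cycle"))
    stiffness <- trajectory_metadata(cycle$trajectory)$trap_stiffness_pN_nm
  pull <- ph$pull; relax <- ph$relax
  out <- data.frame(cycle = cycle_id, melt_force_pN = NA_real_,
                    rezip_force_pN = NA_real_, extension_nm = NA_real_,
                    contraction_nm = NA_real_, verdict = NA_character_,
                    max_gap_pN = NA_real_, stringsAsFactors = FALSE)
  rips <- detect_rips(pull, min_drop = min_drop_pull, window = window,
                      stiffness = stiffness, phase_label = "PULL")
  rips <- rips[rips$kind == "RIP", , drop = FALSE]
  if (nrow(rips)) {
    rip <- rips[which.min(rips$time_s), ]
    fm <- rip$force_pN
    out$melt_force_pN <- fm
    pre <- pull[pull$time_s < rip$time_s - 0.1, , drop = FALSE]
    post <- pull[pull$time_s > rip$time_s + 0.05, , drop = FALSE]
    ext <- tryCatch({
      # provisional B-form line from below the bistable region, then refit on
      # the B-assigned samples near the rip so the curved branch is not
      # extrapolated over many pN
      b_lo0 <- branch_fit(pre, c(fm - 20, fm - 9))
      near <- pre[pre$force_pN > fm - 12, , drop = FALSE]
      resid <- near$trap_position_nm - .branch_position(b_lo0, near$force_pN)
      b_lo <- branch_fit(near[resid < 2, , drop = FALSE],
                         c(fm - 12, fm - 0.2))
      b_hi <- branch_fit(post, c(fm - 1.5, max(post$force_pN) + 1))
      suppressWarnings(measure_extension(b_lo, b_hi, fm))
    }, error = function(e) NA_real_)
    out$extension_nm <- ext
  }
  if (!is.null(relax)) {
    # the relax phases carry no bistable hopping, so a threshold slightly
    # below the 3-sigma advisory is safe there (the jump statistic averages
    # the noise down by an order of magnitude)
    zips <- suppressWarnings(
      detect_rips(relax, min_drop = min_drop_relax, window = window,
                  stiffness = stiffness, phase_label = "RELAX"))
    zips <- zips[zips$kind == "ZIP", , drop = FALSE]
    if (nrow(zips)) {
      zip <- zips[which.max(zips$force_drop_pN), ]
      fr <- zip$force_pN
      out$rezip_force_pN <- fr
      pre <- relax[relax$time_s < zip$time_s - 0.05, , drop = FALSE]
      post <- relax[relax$time_s > zip$time_s + 0.05, , drop = FALSE]
      contraction <- tryCatch({
        b_m <- branch_fit(pre, c(fr + 2, fr + 14))
        b_b <- branch_fit(post, c(max(min(post$force_pN) + 0.2, fr - 8),
                                  fr - 0.8))
        suppressWarnings(measure_extension(b_b, b_m, fr))
      }, error = function(e) NA_real_)
      out$contraction_nm <- contraction
    }
    hc <- classify_hysteresis(pull, relax, min_drop = min_drop_relax,
                              window = window, cycle_id = cycle_id)
    out$verdict <- hc$verdict
    out$max_gap_pN <- hc$max_gap_pN
  }
  out
}

#' Peeling analysis over many cycles
#'
#' @param cycles an `fm_molecule`, an `fm_cycle` or a list of either.
#' @param ... passed to [analyze_peeling_cycle].
#' @return data frame with one row per cycle.
#' @export
analyze_peeling <- function(cycles, ...) {
  cl <- .cycle_list(cycles)
  do.call(rbind, lapply(seq_along(cl), function(i)
    analyze_peeling_cycle(cl[[i]], cycle_id = i, ...)))
}

#' Two-state analysis of gradual internal melting
#'
#' Pools the pull phases (and the reversible relax phases) of a molecule's
#' cycles, fits the linear branches below and above the transition region,
#' computes the reaction extent and fits the two-state model.
#'
#' @param cycles an `fm_molecule` or list of `fm_cycle`s of the gradually
#'   melting construct.
#' @param spec the [construct_spec] (supplies kBT and default windows from
#'   its configured midpoint and cooperative length).
#' @param low_window,high_window force windows (pN) for the branch fits;
#'   defaults bracket the configured transition so that the molten fraction
#'   is below 1% / above 98% inside them.
#' @param gap_threshold hysteresis gap threshold (pN) used to exclude
#'   hysteretic relax phases from the pooled equilibrium data.
#' @return list: `fit` (a [fit_two_state] result), `branches`,
#'   `extent` (pooled points), `extension_at_ftr_nm`, `verdicts` (per cycle).
#' @export
analyze_internal_melting <- function(cycles, spec, low_window = NULL,
                                     high_window = NULL, gap_threshold = 0.8) {
  cl <- .cycle_list(cycles)
  kbt <- spec$kbt
  cfg <- spec$config
  ftr0 <- .cfg_get(cfg, "ftr_pN"); delta0 <- .cfg_get(cfg, "delta_nm")
  w01 <- kbt * log(99) / delta0  # distance from midpoint to 1% / 99% extent
  fmin <- .cfg_get(cfg, "force_min_pN"); fmax <- .cfg_get(cfg, "force_max_pN")
  # keep the branch windows close to the transition region: the worm-like
  # chain branches are curved, and long extrapolations of a straight-line fit
  # bias the branch positions at the midpoint
  if (is.null(low_window))
    low_window <- c(ftr0 - w01 - 8, ftr0 - w01 - 0.3)
  # the high window is open at the top: the pull apex overshoots force_max by
  # the noise amplitude, and clipping inside the apex data would truncate on
  # a noisy criterion and attenuate the fitted slope
  if (is.null(high_window))
    high_window <- c(ftr0 + 0.92 * w01, fmax + 8)
  pooled <- list(); verdicts <- character(length(cl))
  for (i in seq_along(cl)) {
    ph <- .cycle_phases(cl[[i]])
    pooled[[length(pooled) + 1L]] <- ph$pull
    if (!is.null(ph$relax)) {
      hc <- classify_hysteresis(ph$pull, ph$relax,
                                gap_threshold = gap_threshold, cycle_id = i)
      verdicts[i] <- hc$verdict
      if (hc$verdict == "REVERSIBLE")
        pooled[[length(pooled) + 1L]] <- ph$relax
    } else verdicts[i] <- NA_character_
  }
  cols <- c("time_s", "trap_position_nm", "force_pN")
  pooled <- do.call(rbind, lapply(pooled, function(d) as.data.frame(d)[cols]))
  b_lo <- branch_fit(pooled, low_window)
  b_hi <- branch_fit(pooled, high_window)
  extent <- reaction_extent(pooled, b_lo, b_hi)
  fit <- fit_two_state(extent, kbt)
  # Self-consistent refinement: the worm-like-chain branches are curved, so
  # straight lines fitted far from the midpoint misplace the branch positions
  # there and bias the apparent width of the transition. Subtract the fitted
  # molten fraction from each sample to linearize the two branches, refit
  # them on windows adjacent to the midpoint (short extrapolation), and
  # recompute the extent.
  extent_range <- c(ftr0 - w01, ftr0 + 0.92 * w01)
  for (iter in 1:2) {
    sep <- function(f) .branch_position(b_hi, f) - .branch_position(b_lo, f)
    fs <- .smooth_series(pooled$force_pN, 21L)
    phi <- fit$model(fs)
    d_lo <- pooled; d_lo$trap_position_nm <-
      pooled$trap_position_nm - phi * sep(fs)
    d_hi <- pooled; d_hi$trap_position_nm <-
      pooled$trap_position_nm + (1 - phi) * sep(fs)
    b_lo <- branch_fit(d_lo, c(fit$ftr - 10, fit$ftr - 2))
    b_hi <- branch_fit(d_hi, c(fit$ftr + 2, fit$ftr + 10))
    extent <- reaction_extent(pooled, b_lo, b_hi, force_range = extent_range)
    fit <- fit_two_state(extent, kbt)
  }
  ext_mid <- suppressWarnings(measure_extension(b_lo, b_hi, fit$ftr))
  list(fit = fit, branches = list(low = b_lo, high = b_hi), extent = extent,
       extension_at_ftr_nm = ext_mid, verdicts = verdicts)
}

#' Three-state analysis of a composite (peel + B-to-S) construct
#'
#' Pools all phases, fits the B-form and fully stretched branches in their
#' pure force windows, extracts an initial intermediate branch from the
#' samples between them, refines it by state assignment, computes per-state
#' populations versus force and fits the three-state model.
#'
#' @param cycles an `fm_molecule` or list of `fm_cycle`s.
#' @param spec the [construct_spec].
#' @param bin_width population bin width, pN.
#' @return list: `branches` (B, I, S), `populations`, `fit` (a
#'   [fit_three_state] result), `total_extension_nm` (B to S branch
#'   separation at the fitted overall transition force).
#' @export
analyze_composite <- function(cycles, spec, bin_width = 0.5) {
  cl <- .cycle_list(cycles)
  kbt <- spec$kbt
  cfg <- spec$config
  f1 <- .cfg_get(cfg, "ftr1_pN")
  f2 <- spec$extras$ftr2_pN
  fmin <- .cfg_get(cfg, "force_min_pN"); fmax <- .cfg_get(cfg, "force_max_pN")
  cols <- c("time_s", "trap_position_nm", "force_pN")
  pooled <- do.call(rbind, lapply(cl, function(cy) {
    ph <- .cycle_phases(cy)
    rbind(as.data.frame(ph$pull)[cols],
          if (!is.null(ph$relax)) as.data.frame(ph$relax)[cols])
  }))
  # the S window is open at the top so the pull apex is not clipped on a
  # noisy criterion; the B window stays close to the transition to limit the
  # extrapolation of the curved branch
  b_B <- branch_fit(pooled, c(max(fmin + 1, f1 - 10), f1 - 2.5))
  b_S <- branch_fit(pooled, c(f2 + 2.6, fmax + 8))
  # provisional intermediate branch: samples between the outer branches
  mid <- pooled[pooled$force_pN >= f1 - 1 & pooled$force_pN <= f2 + 1, ]
  xB <- .branch_position(b_B, mid$force_pN)
  xS <- .branch_position(b_S, mid$force_pN)
  frac <- (mid$trap_position_nm - xB) / (xS - xB)
  seed_I <- mid[frac > 0.2 & frac < 0.65, , drop = FALSE]
  if (nrow(seed_I) < 10) stop("no intermediate branch detectable")
  b_I <- branch_fit(seed_I, range(seed_I$force_pN) + c(-0.01, 0.01))
  # one refinement round: reassign and refit the intermediate
  tr <- pooled[pooled$force_pN >= f1 - 4 & pooled$force_pN <= f2 + 4, ]
  lab <- assign_states(tr, list(b_B, b_I, b_S))
  ref_I <- tr[lab == 2L, , drop = FALSE]
  if (nrow(ref_I) >= 10)
    b_I <- branch_fit(ref_I, range(ref_I$force_pN) + c(-0.01, 0.01))
  lab <- assign_states(tr, list(b_B, b_I, b_S))
  pops <- population_curves(lab, tr$force_pN, bin_width = bin_width,
                            n_states = 3)
  fit <- fit_three_state(pops, kbt)
  total <- suppressWarnings(measure_extension(b_B, b_S, fit$ftr))
  list(branches = list(B = b_B, I = b_I, S = b_S), populations = pops,
       fit = fit, total_extension_nm = total)
}
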