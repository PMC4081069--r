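# Detection of abrupt rips/zips, bistable hopping and hysteresis in
# force-vs-trap-position phases.
#
# Event convention: the reported event force is the force immediately before
# the jump (median of the trailing window, projected to the event sample along
# the local loading slope), matching how a melting force is read off the apex
# of the pull curve.

.phase_df <- function(phase) {
  df <- as.data.frame(phase)
  stopifnot(all(c("time_s", "trap_position_nm", "force_pN") %in% names(df)))
  df
}

# robust trailing slope per sample: difference of two successive trailing
# window medians one window apart, per sample. Immune to a jump inside the
# leading data that would wreck an OLS slope.
.rolling_slope <- function(med, w, half) {
  n <- length(med)
  out <- rep(NA_real_, n)
  i <- (2 * w):n
  out[i] <- (med[i - half] - med[i - half - w]) / w
  out
}

#' Detect abrupt force rips and zips in one phase
#'
#' Scans a pull or relax phase for changes of the force by at least `min_drop`
#' against the local loading baseline within `window` samples. The jump
#' statistic compares the medians of the leading and trailing windows after
#' removing the expected ramp (trailing-window linear fit), which makes the
#' detector robust both to the loading ramp and to telegraph-like hopping.
#'
#' @param phase data frame of one phase (columns `time_s`,
#'   `trap_position_nm`, `force_pN`).
#' @param min_drop minimum force change in pN (default 1.5, five times the
#'   default measurement noise).
#' @param window window length in samples (default 30, i.e. 30 ms at 1 kHz).
#' @param stiffness trap stiffness in pN/nm; if given, the extension change of
#'   each event is reported as `force_drop / stiffness` (the bead relaxation
#'   at fixed trap position), signed positive for a rip and negative for a
#'   zip.
#' @param noise_sd measurement noise SD used only to warn when `min_drop` is
#'   below 3 sigma.
#' @param phase_label optional `"PULL"`/`"RELAX"` tag copied to the output.
#' @return data frame of events: `kind` (`"RIP"` force drop / `"ZIP"` force
#'   rise), `phase`, `time_s`, `force_pN` (pre-event force),
#'   `trap_position_nm`, `force_drop_pN` (unsigned), `extension_change_nm`.
#' @export
detect_rips <- function(phase, min_drop = 1.5, window = 30, stiffness = NULL,
                        noise_sd = 0.3, phase_label = NA_character_) {
  df <- .phase_df(phase)
  w <- as.integer(window)
  if (w %% 2 == 0) w <- w + 1L
  n <- nrow(df)
  if (n < 2 * w) stop("phase too short: need at least 2*window samples")
  if (min_drop < 3 * noise_sd)
    warning("min_drop below 3x noise sigma: high false-positive risk")
  f <- df$force_pN
  half <- (w - 1L) %/% 2L
  med <- runmed(f, w, endrule = "median")
  slope <- .rolling_slope(med, w, half)
  # in bistable (telegraph) regions the local slope estimate absorbs part of
  # a jump; the loading ramp is smooth, so keep the local estimate within a
  # band around the phase-wide robust slope
  g <- median(slope, na.rm = TRUE)
  band <- sort(c(0.5 * g, 1.5 * g))
  slope <- pmin(pmax(slope, band[1]), band[2])
  idx <- seq.int(2L * w, n - half - 1L)
  J <- rep(NA_real_, n)
  J[idx] <- med[idx + half + 1L] - med[idx - half] - slope[idx] * w
  cand <- which(!is.na(J) & abs(J) >= min_drop)
  empty <- data.frame(kind = character(0), phase = character(0),
                      time_s = numeric(0), force_pN = numeric(0),
                      trap_position_nm = numeric(0),
                      force_drop_pN = numeric(0),
                      extension_change_nm = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  # cluster candidates, keep the strongest index per cluster
  breaks <- c(0, which(diff(cand) > half), length(cand))
  picks <- integer(0)
  for (b in seq_len(length(breaks) - 1)) {
    cl <- cand[(breaks[b] + 1):breaks[b + 1]]
    picks <- c(picks, cl[which.max(abs(J[cl]))])
  }
  # enforce a minimum separation of one window, keeping larger jumps
  picks <- picks[order(-abs(J[picks]))]
  kept <- integer(0)
  for (p in picks)
    if (!length(kept) || all(abs(kept - p) >= w)) kept <- c(kept, p)
  kept <- sort(kept)
  # Event force: median of the trailing-window samples that lie on the
  # pre-event side of the jump. Classifying samples against the midpoint of
  # the two window medians makes the estimate robust both to a few samples of
  # localization error and to bistable hopping earlier in the window.
  ev_force <- vapply(kept, function(i) {
    tw <- f[max(i - w + 1L, 1L):min(i + half, n)]
    pre_med <- med[i - half]; post_med <- med[i + half + 1L]
    midpt <- (pre_med + post_med) / 2
    pre <- if (pre_med > post_med) tw[tw > midpt] else tw[tw < midpt]
    if (!length(pre)) pre <- tw
    median(pre) + slope[i] * half
  }, numeric(1))
  kind <- ifelse(J[kept] < 0, "RIP", "ZIP")
  drop <- abs(J[kept])
  ext <- if (is.null(stiffness)) rep(NA_real_, length(kept))
         else ifelse(kind == "RIP", 1, -1) * drop / stiffness
  data.frame(kind = kind, phase = phase_label, time_s = df$time_s[kept],
             force_pN = ev_force, trap_position_nm = df$trap_position_nm[kept],
             force_drop_pN = drop, extension_change_nm = ext,
             stringsAsFactors = FALSE)
}

# trap position of a branch at a force (branch: force = slope * x + intercept)
.branch_position <- function(branch, force) {
  (force - branch$intercept) / branch$slope
}

#' Detect bistable hopping between two fitted branches
#'
#' Assigns each sample to the nearer branch (smallest position residual at its
#' force) and reports contiguous regions where the assignment alternates at
#' least `min_switches` times.
#'
#' @param phase data frame of one phase.
#' @param branch_low,branch_high [branch_fit] objects for the shorter and
#'   longer state.
#' @param min_switches minimum number of branch switches for a region to count
#'   as hopping.
#' @param max_gap_s maximum time between switches within one hopping region.
#' @param min_dwell dwells shorter than this many samples are treated as
#'   noise-induced assignment flips and merged into their neighbors before
#'   switches are counted.
#' @return a list with `segments` (data frame: `start_s`, `end_s`,
#'   `n_switches`, `dwell_low`, `dwell_high`), and `upper_isolated`: whether
#'   the longer state ever appears without returning to the lower branch
#'   (i.e. at the start or end of the phase). Overlapping branches (separation
#'   under 3 sigma) are undetectable and yield an empty result with a warning.
#' @export
detect_hopping <- function(phase, branch_low, branch_high, min_switches = 4,
                           max_gap_s = 0.5, min_dwell = 3L, smooth = 7L) {
  df <- .phase_df(phase)
  # light smoothing of the force channel: hopping dwells are long compared to
  # the sample interval, so this cuts the assignment noise without blurring
  # genuine switches
  fs <- .smooth_series(df$force_pN, smooth)
  sep <- abs(.branch_position(branch_high, median(df$force_pN)) -
             .branch_position(branch_low, median(df$force_pN)))
  sigma_pos <- max(branch_low$resid_sd / abs(branch_low$slope),
                   branch_high$resid_sd / abs(branch_high$slope)) /
    sqrt(max(smooth, 1))
  empty <- list(segments = data.frame(start_s = numeric(0), end_s = numeric(0),
                                      n_switches = integer(0),
                                      dwell_low = integer(0),
                                      dwell_high = integer(0)),
                upper_isolated = FALSE)
  if (sep < 3 * sigma_pos) {
    warning("branch separation below 3 sigma: hopping undetectable")
    return(empty)
  }
  r_lo <- abs(df$trap_position_nm - .branch_position(branch_low, fs))
  r_hi <- abs(df$trap_position_nm - .branch_position(branch_high, fs))
  upper <- r_hi < r_lo
  # debounce single-sample assignment flips caused by measurement noise
  for (it in 1:50) {
    r <- rle(upper)
    short <- which(r$lengths < min_dwell)
    if (!length(short) || length(r$lengths) == 1) break
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    idx <- (ends[j] - r$lengths[j] + 1L):ends[j]
    upper[idx] <- !r$values[j]
  }
  sw <- which(diff(upper) != 0)  # switch between sample sw and sw+1
  segments <- empty$segments
  if (length(sw) >= min_switches) {
    t_sw <- df$time_s[sw]
    cl_break <- c(0, which(diff(t_sw) > max_gap_s), length(sw))
    for (b in seq_len(length(cl_break) - 1)) {
      cl <- sw[(cl_break[b] + 1):cl_break[b + 1]]
      if (length(cl) >= min_switches) {
        rows <- cl[1]:(cl[length(cl)] + 1L)
        segments <- rbind(segments, data.frame(
          start_s = df$time_s[cl[1]], end_s = df$time_s[cl[length(cl)] + 1L],
          n_switches = length(cl),
          dwell_low = sum(!upper[rows]), dwell_high = sum(upper[rows])))
      }
    }
  }
  # the longer state "appears in isolation" if the phase ends in it without
  # returning to the lower branch
  runs <- rle(upper)
  upper_isolated <- isTRUE(runs$values[length(runs$values)])
  list(segments = segments, upper_isolated = upper_isolated)
}

#' Relative extension between two branches at a force
#'
#' The difference in trap position of the two fitted branches evaluated at a
#' common force: positive when `branch_high` is the longer state; antisymmetric
#' under branch exchange.
#'
#' @param branch_low,branch_high [branch_fit] objects.
#' @param at_force force in pN at which to compare (extrapolation beyond a
#'   branch's fitted window is permitted but flagged with a warning).
#' @return extension difference in nm.
#' @export
measure_extension <- function(branch_low, branch_high, at_force) {
  for (b in list(branch_low, branch_high))
    if (!is.finite(b$slope) || b$slope == 0)
      stop("degenerate branch fit: zero or non-finite slope")
  if (isTRUE(all.equal(branch_low$slope, branch_high$slope)) &&
      isTRUE(all.equal(branch_low$intercept, branch_high$intercept)))
    stop("degenerate branches: identical position at every force")
  outside <- function(b) !is.null(b$window) &&
    (at_force < b$window[1] || at_force > b$window[2])
  if (outside(branch_low) || outside(branch_high))
    warning("extrapolating branch fit beyond its force window")
  .branch_position(branch_high, at_force) -
    .branch_position(branch_low, at_force)
}

#' Classify a pull-relax cycle as reversible or hysteretic
#'
#' Compares the pull and relax curves at matched trap positions over their
#' common range (after light smoothing of the force channel): if the maximum
#' force gap stays at or below `gap_threshold` the cycle is reversible;
#' otherwise it is hysteretic and the rezip force is taken from the
#' relax-phase ZIP event.
#'
#' @param pull,relax data frames of the two phases of one cycle.
#' @param gap_threshold maximum tolerated pull-relax force gap in pN.
#' @param min_drop,window passed to [detect_rips] for the rezip event.
#' @param smooth smoothing window (samples) applied to the force before the
#'   gap computation.
#' @param cycle_id identifier copied into the result.
#' @return a list of class `hysteresis_call`: `cycle`, `verdict`
#'   (`"REVERSIBLE"` / `"HYSTERETIC"`), `rezip_force_pN` (NA when reversible
#'   or no zip found), `max_gap_pN`.
#' @export
classify_hysteresis <- function(pull, relax, gap_threshold = 0.8,
                                min_drop = 0.8, window = 30, smooth = 25,
                                cycle_id = NA) {
  pull <- .phase_df(pull); relax <- .phase_df(relax)
  lo <- max(min(pull$trap_position_nm), min(relax$trap_position_nm))
  hi <- min(max(pull$trap_position_nm), max(relax$trap_position_nm))
  if (lo >= hi) stop("pull and relax phases share no trap-position range")
  sm <- function(f, k) {
    k <- min(k, length(f))
    if (k < 2) return(f)
    y <- as.numeric(stats::filter(f, rep(1 / k, k), sides = 2))
    ok <- !is.na(y)
    y[!ok] <- f[!ok]
    y
  }
  # clip the edges of the common range: near the turning point the two phases
  # share few samples and the interpolated gap is dominated by noise
  margin <- 0.03 * (hi - lo)
  grid <- seq(lo + margin, hi - margin, length.out = 300)
  fp <- approx(pull$trap_position_nm, sm(pull$force_pN, smooth),
               xout = grid, ties = mean)$y
  fr <- approx(relax$trap_position_nm, sm(relax$force_pN, smooth),
               xout = grid, ties = mean)$y
  gap <- max(fp - fr, na.rm = TRUE)
  if (gap <= gap_threshold)
    return(structure(list(cycle = cycle_id, verdict = "REVERSIBLE",
                          rezip_force_pN = NA_real_, max_gap_pN = gap),
                     class = "hysteresis_call"))
  zips <- suppressWarnings(detect_rips(relax, min_drop = min_drop,
                                       window = window,
                                       phase_label = "RELAX"))
  zips <- zips[zips$kind == "ZIP", , drop = FALSE]
  rezip <- if (nrow(zips)) zips$force_pN[which.max(zips$force_drop_pN)]
           else NA_real_
  structure(list(cycle = cycle_id, verdict = "HYSTERETIC",
                 rezip_force_pN = rezip, max_gap_pN = gap),
            class = "hysteresis_call")
}

#' @export
print.hysteresis_call <- function(x, ...) {
  cat("<hysteresis_call>", x$verdict,
      if (!is.na(x$rezip_force_pN))
        sprintf("(rezip %.1f pN)", x$rezip_force_pN) else "",
      sprintf("max gap %.2f pN", x$max_gap_pN), "\n")
  invisible(x)
}
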