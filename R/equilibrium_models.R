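# Inference core: least-squares linear branch fits, reaction extent, the
# two-state equilibrium fit (midpoint force and cooperative length) and the
# three-state population fit (B-form / intermediate / fully stretched).

# centred running mean used to select samples by force without the selection
# bias the measurement noise would otherwise introduce
.smooth_series <- function(f, k = 21L) {
  k <- min(as.integer(k), length(f))
  if (k < 2) return(f)
  y <- as.numeric(stats::filter(f, rep(1 / k, k), sides = 2))
  y[is.na(y)] <- f[is.na(y)]
  y
}

#' Least-squares linear fit of one conformational branch
#'
#' Ordinary least squares of force on trap position over a force window.
#'
#' @param phase data frame with `trap_position_nm` and `force_pN` columns.
#' @param force_window numeric length-2: force window (pN) selecting the
#'   samples to fit.
#' @return an object of class `branch_fit`: `slope` (pN/nm), `intercept` (pN),
#'   `window`, `resid_sd` (pN), `n`.
#' @details Samples are selected by a lightly smoothed force signal (the raw
#'   values are fitted): selecting directly on the noisy force truncates the
#'   response inside a narrow window and attenuates the fitted slope.
#' @export
branch_fit <- function(phase, force_window) {
  df <- .phase_df(phase)
  stopifnot(length(force_window) == 2, force_window[1] < force_window[2])
  fs <- .smooth_series(df$force_pN, 21L)
  sel <- fs >= force_window[1] & fs <= force_window[2]
  d <- df[sel, , drop = FALSE]
  if (nrow(d) < 10)
    stop("branch window [", force_window[1], ", ", force_window[2],
         "] pN contains fewer than 10 samples")
  if (sd(d$trap_position_nm) == 0)
    stop("singular design: constant trap position in branch window")
  fit <- lm(force_pN ~ trap_position_nm, data = d)
  # suppress lm's advisory on exactly linear (noise-free) input
  sig <- suppressWarnings(summary(fit)$sigma)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 window = as.numeric(force_window),
                 resid_sd = sig,
                 n = nrow(d)),
            class = "branch_fit")
}

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("<branch_fit> slope %.4f pN/nm, intercept %.2f pN, n=%d, resid sd %.3f pN\n",
              x$slope, x$intercept, x$n, x$resid_sd))
  invisible(x)
}

#' Fit several branches over a set of force windows
#'
#' @param phase data frame of samples.
#' @param windows list of length-2 force windows.
#' @return list of [branch_fit] objects.
#' @export
fit_branches <- function(phase, windows) {
  lapply(windows, function(w) branch_fit(phase, w))
}

#' Reaction extent between two branches
#'
#' For every sample in the transition region, the relative distance of the
#' data point to the linear force-position behaviors below and above the
#' transition: `phi = (x - x_low(F)) / (x_high(F) - x_low(F))`, clamped to
#' `[0, 1]`.
#'
#' @param phase data frame of samples.
#' @param branch_low,branch_high [branch_fit] objects below and above the
#'   transition region.
#' @param force_range length-2 force range of the transition region; default:
#'   between the upper end of the low window and the lower end of the high
#'   window.
#' @return data frame with columns `force` (pN) and `extent`.
#' @export
reaction_extent <- function(phase, branch_low, branch_high,
                            force_range = NULL) {
  df <- .phase_df(phase)
  if (is.null(force_range))
    force_range <- c(branch_low$window[2], branch_high$window[1])
  # The extent abscissa and the branch positions use the smoothed force: the
  # raw per-sample noise enters phi and the force coordinate with correlated
  # sign and would tilt (flatten) the fitted transition.
  fs <- .smooth_series(df$force_pN, 21L)
  sel <- fs >= force_range[1] & fs <= force_range[2]
  d <- df[sel, , drop = FALSE]
  d$force_pN <- fs[sel]
  x_lo <- .branch_position(branch_low, d$force_pN)
  x_hi <- .branch_position(branch_high, d$force_pN)
  sep <- x_hi - x_lo
  sigma_pos <- max(branch_low$resid_sd / abs(branch_low$slope),
                   branch_high$resid_sd / abs(branch_high$slope))
  if (mean(abs(sep)) < 3 * sigma_pos)
    warning("branch separation below 3x residual SD: extent is noisy")
  phi <- pmin(pmax((d$trap_position_nm - x_lo) / sep, 0), 1)
  data.frame(force = d$force_pN, extent = phi)
}

#' Two-state equilibrium fit of the reaction extent
#'
#' Fits the equilibrium two-state force law
#' `phi(F) = 1 / (1 + exp(-delta (F - F_tr) / kBT))`
#' by (weighted) least squares: `F_tr` is the midpoint force of the
#' transition, `delta` the cooperative length that sets its force width
#' (`F(0.95) - F(0.05) = 2 ln(19) kBT / delta`).
#'
#' @param points data frame from [reaction_extent] (columns `force`,
#'   `extent`).
#' @param kbt thermal energy, pN nm.
#' @param weights optional per-point weights.
#' @return an object of class `two_state_fit`: `ftr` (pN), `delta` (nm),
#'   `cov` (2x2 covariance of (ftr, delta)), `gof` (list: rss, sigma, n),
#'   `model` (function of force returning the fitted extent).
#' @export
fit_two_state <- function(points, kbt = kbt_at(), weights = NULL) {
  stopifnot(all(c("force", "extent") %in% names(points)))
  if (min(points$extent) > 0.2 || max(points$extent) < 0.8)
    stop("extent points must span the transition (below 0.2 to above 0.8)")
  # starting values from a logit regression on the clamped extent
  eps <- 1e-3
  phi_c <- pmin(pmax(points$extent, eps), 1 - eps)
  lg <- lm(log(phi_c / (1 - phi_c)) ~ points$force)
  delta0 <- max(unname(coef(lg)[2]) * kbt, 0.1)
  ftr0 <- -unname(coef(lg)[1]) / unname(coef(lg)[2])
  if (!is.finite(ftr0)) ftr0 <- median(points$force)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      extent ~ 1 / (1 + exp(-delta * (force - ftr) / kbt)),
      data = points, start = list(ftr = ftr0, delta = delta0),
      weights = if (is.null(weights)) rep(1, nrow(points)) else weights,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e)
      stop("two-state fit failed to converge (last start: ftr=",
           signif(ftr0, 4), ", delta=", signif(delta0, 4), "): ",
           conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["delta"]] <= 0) stop("two-state fit returned non-positive delta")
  if (cf[["ftr"]] < min(points$force) || cf[["ftr"]] > max(points$force))
    warning("fitted midpoint lies outside the observed force range")
  structure(list(ftr = unname(cf[["ftr"]]), delta = unname(cf[["delta"]]),
                 cov = vcov(fit),
                 gof = list(rss = sum(resid(fit)^2),
                            sigma = summary(fit)$sigma, n = nrow(points)),
                 kbt = kbt,
                 model = function(f)
                   1 / (1 + exp(-cf[["delta"]] * (f - cf[["ftr"]]) / kbt))),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  se <- sqrt(diag(x$cov))
  cat(sprintf("<two_state_fit> F_tr = %.2f +/- %.2f pN, delta = %.2f +/- %.2f nm\n",
              x$ftr, se[1], x$delta, se[2]))
  invisible(x)
}

#' Assign samples to conformational states by branch proximity
#'
#' Each sample is labeled by the branch minimizing the absolute position
#' residual at the sample's force; ties break toward the lower-extension
#' state.
#'
#' @param phase data frame of samples.
#' @param branches list of [branch_fit] objects (any number >= 2); internally
#'   ordered by extension (position at the median force), label 1 = shortest.
#' @return integer vector of state labels (1 = lowest extension), with
#'   attribute `order` giving the permutation applied to `branches`.
#' @export
assign_states <- function(phase, branches) {
  df <- .phase_df(phase)
  stopifnot(length(branches) >= 2)
  fmid <- median(df$force_pN)
  ord <- order(vapply(branches, .branch_position, numeric(1), force = fmid))
  branches <- branches[ord]
  res <- vapply(branches, function(b)
    abs(df$trap_position_nm - .branch_position(b, df$force_pN)),
    numeric(nrow(df)))
  res <- matrix(res, nrow = nrow(df))
  labels <- max.col(-res, ties.method = "first")
  attr(labels, "order") <- ord
  labels
}

#' Per-state population versus force
#'
#' @param labels integer state labels (e.g. from [assign_states]).
#' @param forces force of each sample, pN.
#' @param bin_width force bin width in pN.
#' @param min_count bins with fewer samples are dropped (and reported in the
#'   `dropped` attribute).
#' @param n_states number of states (defaults to `max(labels)`).
#' @return data frame: `force` (bin center), `P1..Pk`, `n`; populations sum
#'   to 1 in every bin.
#' @export
population_curves <- function(labels, forces, bin_width = 0.5, min_count = 5,
                              n_states = max(labels)) {
  stopifnot(bin_width > 0, length(labels) == length(forces))
  lo <- floor(min(forces) / bin_width) * bin_width
  bins <- floor((forces - lo) / bin_width)
  centers <- lo + (sort(unique(bins)) + 0.5) * bin_width
  tab <- table(factor(bins), factor(labels, levels = seq_len(n_states)))
  counts <- matrix(as.numeric(tab), nrow = nrow(tab))
  n <- rowSums(counts)
  P <- sweep(counts, 1, n, "/")
  out <- data.frame(force = centers, P, n = n)
  names(out) <- c("force", paste0("P", seq_len(n_states)), "n")
  keep <- out$n >= min_count
  dropped <- out$force[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

# three-state Boltzmann populations: weights w_i = exp((F x_i - G_i)/kBT),
# with G_B = 0, x_B = 0
.three_state_P <- function(f, g_i, x_i, g_s, x_s, kbt) {
  e1 <- rep(0, length(f))
  e2 <- (f * x_i - g_i) / kbt
  e3 <- (f * x_s - g_s) / kbt
  m <- pmax(e1, e2, e3)
  w1 <- exp(e1 - m); w2 <- exp(e2 - m); w3 <- exp(e3 - m)
  tot <- w1 + w2 + w3
  cbind(P1 = w1 / tot, P2 = w2 / tot, P3 = w3 / tot)
}

#' Three-state Boltzmann population fit
#'
#' Fits the populations of the B-form (1), intermediate (2) and fully
#' stretched (3) states as `P_i(F) = w_i / sum_j w_j` with
#' `w_i = exp(-(G_i - F x_i)/kBT)`, `G_B = 0`, `x_B = 0`. The derived
#' transition forces are: `F_tr_I` where `P_B = P_I` (closed form `G_I/x_I`),
#' `F_tr_II` where `P_I = P_S` (closed form `(G_S - G_I)/(x_S - x_I)`), and
#' `F_tr`, the maximum of the fitted intermediate population (closed form
#' `(G_S + kBT log(x_I/(x_S - x_I))) / x_S`). The numerically located
#' crossings/maximum are also reported and must agree with the closed forms.
#'
#' @param populations data frame from [population_curves] with columns
#'   `force`, `P1`, `P2`, `P3`, `n`.
#' @param kbt thermal energy, pN nm.
#' @return object of class `three_state_fit` with elements `g_i`, `x_i`,
#'   `g_s`, `x_s`, `ftr_I`, `ftr`, `ftr_II` (closed forms), `ftr_I_num`,
#'   `ftr_num`, `ftr_II_num` (numeric), `populations` (function of force),
#'   `degenerate` (TRUE when the fitted intermediate never dominates both
#'   other states).
#' @export
fit_three_state <- function(populations, kbt = kbt_at()) {
  stopifnot(all(c("force", "P1", "P2", "P3", "n") %in% names(populations)))
  d <- populations
  # initial values from pairwise logit regressions
  eps <- 1e-4
  ok12 <- d$P1 > eps & d$P2 > eps
  ok23 <- d$P2 > eps & d$P3 > eps
  if (sum(ok12) < 3 || sum(ok23) < 3)
    stop("not enough populated force bins to initialize the three-state fit")
  l12 <- lm(log(d$P2[ok12] / d$P1[ok12]) ~ d$force[ok12])
  l23 <- lm(log(d$P3[ok23] / d$P2[ok23]) ~ d$force[ok23])
  x_i0 <- max(unname(coef(l12)[2]) * kbt, 0.5)
  g_i0 <- -unname(coef(l12)[1]) * kbt
  dx0 <- max(unname(coef(l23)[2]) * kbt, 0.5)
  g_s0 <- g_i0 - unname(coef(l23)[1]) * kbt
  x_s0 <- x_i0 + dx0
  # weighted least squares over all three population curves
  w <- rep(d$n, 3) / (c(d$P1, d$P2, d$P3) * (1 - c(d$P1, d$P2, d$P3)) + 0.02)
  obs <- c(d$P1, d$P2, d$P3)
  objective <- function(par) {
    P <- .three_state_P(d$force, par[1], par[2], par[3], par[4], kbt)
    sum(w * (obs - c(P[, 1], P[, 2], P[, 3]))^2)
  }
  opt <- optim(c(g_i0, x_i0, g_s0, x_s0), objective, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  opt <- optim(opt$par, objective, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  g_i <- opt$par[1]; x_i <- opt$par[2]; g_s <- opt$par[3]; x_s <- opt$par[4]
  if (!(x_s > x_i && x_i > 0))
    stop("three-state fit violated x_S > x_I > 0")
  Pfun <- function(f) .three_state_P(f, g_i, x_i, g_s, x_s, kbt)
  ftr_I <- g_i / x_i
  ftr_II <- (g_s - g_i) / (x_s - x_i)
  ftr <- (g_s + kbt * log(x_i / (x_s - x_i))) / x_s
  span <- range(d$force) + c(-10, 10)
  ftr_I_num <- tryCatch(
    uniroot(function(f) { P <- Pfun(f); P[, 1] - P[, 2] },
            c(span[1], ftr_II), tol = 1e-10)$root, error = function(e) NA_real_)
  ftr_II_num <- tryCatch(
    uniroot(function(f) { P <- Pfun(f); P[, 2] - P[, 3] },
            c(ftr_I, span[2]), tol = 1e-10)$root, error = function(e) NA_real_)
  ftr_num <- optimize(function(f) Pfun(f)[, 2], interval = span,
                      maximum = TRUE, tol = 1e-10)$maximum
  Pmax <- Pfun(ftr)
  degenerate <- !(Pmax[, 2] >= Pmax[, 1] && Pmax[, 2] >= Pmax[, 3])
  if (degenerate)
    warning("intermediate population never dominates: degenerate three-state fit")
  structure(list(g_i = g_i, x_i = x_i, g_s = g_s, x_s = x_s,
                 ftr_I = ftr_I, ftr = ftr, ftr_II = ftr_II,
                 ftr_I_num = ftr_I_num, ftr_num = ftr_num,
                 ftr_II_num = ftr_II_num,
                 populations = Pfun, degenerate = degenerate,
                 sse = opt$value, kbt = kbt),
            class = "three_state_fit")
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat(sprintf("<three_state_fit> F_tr^I = %.2f, F_tr = %.2f, F_tr^II = %.2f pN%s\n",
              x$ftr_I, x$ftr, x$ftr_II,
              if (x$degenerate) " (degenerate)" else ""))
  cat(sprintf("  x_I = %.2f nm, x_S = %.2f nm, G_I = %.1f, G_S = %.1f pN nm\n",
              x$x_i, x$x_s, x$g_i, x$g_s))
  invisible(x)
}
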