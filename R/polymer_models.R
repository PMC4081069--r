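# Force-extension relations for the conformational states of a construct and
# the construct-trap mechanical series.

#' Elastic parameters of a chain conformation
#'
#' Bundles the parameters of the (extensible) worm-like-chain law used for one
#' conformational state: double-stranded B-form and S-form DNA are WLCs with
#' long and intermediate persistence lengths, single strands are WLCs with a
#' short (~0.75 nm) persistence length, which at the forces of interest
#' behaves like a freely-jointed chain.
#'
#' @param contour_length_per_unit contour length per monomer unit, nm per bp
#'   (duplex states) or nm per nt (single-stranded states).
#' @param persistence_length persistence length in nm.
#' @param stretch_modulus enthalpic stretch modulus in pN, or `NULL` for an
#'   inextensible chain (extension then stays below the contour length at all
#'   finite force).
#' @return an object of class `elastic_params`.
#' @examples
#' elastic_params(0.34, 50, 1200)
#' @export
elastic_params <- function(contour_length_per_unit, persistence_length,
                           stretch_modulus = NULL) {
  stopifnot(is.numeric(contour_length_per_unit), contour_length_per_unit > 0,
            is.numeric(persistence_length), persistence_length > 0)
  if (!is.null(stretch_modulus))
    stopifnot(is.numeric(stretch_modulus), stretch_modulus > 0)
  structure(list(contour_length_per_unit = contour_length_per_unit,
                 persistence_length = persistence_length,
                 stretch_modulus = if (is.null(stretch_modulus)) Inf
                                   else stretch_modulus),
            class = "elastic_params")
}

#' One segment of a construct in a given conformation
#'
#' @param segment_id character identifier, matching a segment of the construct.
#' @param n_units number of monomer units (bp or nt), at least 1.
#' @param conformation one of `"B_FORM"`, `"S_FORM"`, `"PEELED_SS"`,
#'   `"MELTED_SHARED"`, `"HANDLE_SS"`.
#' @return an object of class `segment_state`.
#' @export
segment_state <- function(segment_id, n_units, conformation) {
  conformation <- match.arg(conformation, .CONFORMATIONS)
  stopifnot(is.numeric(n_units), n_units >= 1)
  structure(list(segment_id = as.character(segment_id),
                 n_units = as.integer(n_units),
                 conformation = conformation),
            class = "segment_state")
}

.CONFORMATIONS <- c("B_FORM", "S_FORM", "PEELED_SS", "MELTED_SHARED",
                    "HANDLE_SS")

#' Trap movement protocol
#'
#' Constant-velocity pull-relax protocol of the optical trap. The defaults
#' reproduce the emulated measurement conditions: 50 nm/s trap velocity,
#' 1 kHz sampling, and a trap stiffness of 0.156 pN/nm so that the loading
#' rate in the stiff part of the force range is ~7.8 pN/s.
#'
#' @param trap_velocity trap velocity in nm/s (> 0).
#' @param trap_stiffness trap stiffness in pN/nm (> 0).
#' @param force_min,force_max lower and upper force limits of a cycle in pN;
#'   the lower limit must keep the construct hybridized, the upper must allow
#'   the studied transitions to complete.
#' @param sample_rate sampling frequency in Hz.
#' @param temperature temperature in degrees Celsius.
#' @return an object of class `trap_protocol`.
#' @examples
#' trap_protocol(force_min = 15, force_max = 70)
#' @export
trap_protocol <- function(trap_velocity = 50, trap_stiffness = 0.156,
                          force_min = 10, force_max = 70,
                          sample_rate = 1000, temperature = 22.8) {
  stopifnot(trap_velocity > 0, trap_stiffness > 0, sample_rate > 0,
            force_min < force_max, force_min >= 0)
  structure(list(trap_velocity = trap_velocity,
                 trap_stiffness = trap_stiffness,
                 force_min = force_min, force_max = force_max,
                 sample_rate = sample_rate, temperature = temperature,
                 kbt = kbt_at(temperature)),
            class = "trap_protocol")
}

# Relative extension x/L of an extensible Marko-Siggia worm-like chain.
# With u = x/L - F/K the interpolation formula reads
#   F * Lp / kBT = 1/(4 (1-u)^2) - 1/4 + u,
# i.e. with y = 1 - u:  y^3 + (f - 3/4) y^2 - 1/4 = 0,  f = F Lp / kBT.
# g(y) is convex and increasing on (0, 1] with g(1) >= 0, so Newton from
# y = 1 converges monotonically to the unique physical root. Vectorized in F.
wlc_relative_extension <- function(force, persistence_length, kbt,
                                   stretch_modulus = Inf) {
  if (any(force < 0)) stop("force must be non-negative")
  f <- force * persistence_length / kbt
  b <- f - 0.75
  y <- rep(1, length(f))
  for (it in 1:100) {
    g <- y^3 + b * y^2 - 0.25
    dg <- 3 * y^2 + 2 * b * y
    step <- g / dg
    y <- y - step
    if (max(abs(step)) < 1e-15) break
  }
  u <- 1 - y
  if (is.finite(stretch_modulus)) u <- u + force / stretch_modulus
  u[force == 0] <- 0
  u
}

#' Extension of a single segment at a given force
#'
#' Evaluates the worm-like-chain force-extension law of the segment's
#' conformation. For an inextensible chain the extension is strictly below
#' `n_units * contour_length_per_unit` at all finite forces and approaches it
#' asymptotically.
#'
#' @param params an [elastic_params] object for the segment's conformation.
#' @param state a [segment_state] (only `n_units` is used here; the caller maps
#'   conformations to parameter sets).
#' @param force applied force in pN (>= 0; vectorized).
#' @param kbt thermal energy in pN nm.
#' @return extension in nm, strictly increasing in force, 0 at zero force.
#' @examples
#' p <- elastic_params(0.34, 50)
#' s <- segment_state("duplex", 64, "B_FORM")
#' segment_extension(p, s, force = 10, kbt = kbt_at())
#' @export
segment_extension <- function(params, state, force, kbt = kbt_at()) {
  stopifnot(inherits(params, "elastic_params"), inherits(state, "segment_state"))
  if (any(force < 0)) stop("force must be non-negative")
  L <- state$n_units * params$contour_length_per_unit
  L * wlc_relative_extension(force, params$persistence_length, kbt,
                             params$stretch_modulus)
}

# map a conformation to the elastic parameter set of a construct spec
.conformation_params <- function(spec, conformation) {
  p <- spec$elastic[[conformation]]
  if (is.null(p)) stop("no elastic parameters for conformation ", conformation)
  p
}

#' Total extension of a construct in a given set of segment states
#'
#' Sums the segment extensions plus the single-stranded handle extension.
#' A segment in the `PEELED_SS` conformation contributes only its
#' tension-bearing strand (the relaxed complementary strand contributes zero),
#' so its extension is that of `n_units` nucleotides of single-stranded DNA.
#'
#' @param spec a [construct_spec] object.
#' @param states list of [segment_state] covering every segment of `spec`
#'   exactly once.
#' @param force force in pN (vectorized).
#' @param kbt thermal energy in pN nm.
#' @return extension in nm.
#' @export
construct_extension <- function(spec, states, force, kbt = kbt_at()) {
  stopifnot(inherits(spec, "construct_spec"))
  ids <- vapply(states, function(s) s$segment_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate segment state for segment(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(spec$segments$segment_id, ids)
  if (length(missing))
    stop("missing segment state for segment(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(ids, spec$segments$segment_id)
  if (length(extra))
    stop("unknown segment(s): ", paste(extra, collapse = ", "))
  ext <- 0
  for (s in states) {
    p <- .conformation_params(spec, s$conformation)
    ext <- ext + segment_extension(p, s, force, kbt)
  }
  handle <- segment_state("handle", 1L, "HANDLE_SS")
  ext + segment_extension(spec$elastic$HANDLE_SS, handle, force, kbt)
}

#' Solve the force balance of the construct-trap series
#'
#' Finds the unique force satisfying
#' `F = stiffness * (trap_position - construct_extension(F))`: the bead sits
#' where the trap load equals the chain tension. A state change to a longer
#' conformation at fixed trap position strictly lowers the force (the bead
#' relaxes toward the trap center).
#'
#' @param trap_position trap position in nm, measured from the point where the
#'   construct is at rest (must be >= the construct rest extension, i.e. >= 0).
#' @param spec a [construct_spec].
#' @param states list of [segment_state] (see [construct_extension]).
#' @param protocol a [trap_protocol] (supplies stiffness and temperature).
#' @param tol absolute solver tolerance on the force balance, nm.
#' @return force in pN.
#' @export
solve_force <- function(trap_position, spec, states, protocol, tol = 1e-9) {
  stopifnot(inherits(protocol, "trap_protocol"))
  k <- protocol$trap_stiffness
  kbt <- protocol$kbt
  if (any(trap_position < 0)) stop("trap_position below rest extension")
  one <- function(xt) {
    g <- function(f) k * (xt - construct_extension(spec, states, f, kbt)) - f
    if (xt == 0) return(0)
    hi <- max(k * xt, 1)
    it <- 0
    while (g(hi) > 0) {
      hi <- hi * 2
      it <- it + 1
      if (it > 60) stop("solve_force: no bracketing solution for trap ",
                        "position ", xt, " nm (force balance never closes)")
    }
    uniroot(g, c(0, hi), tol = tol)$root
  }
  vapply(trap_position, one, numeric(1))
}
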