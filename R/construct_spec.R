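# Construct specifications: designed duplexes, their segment layout, salt
# condition, calibrated elastic parameter sets and kinetic targets. Parameters
# are read from plain-text key = value configuration files shipped with the
# package (one per construct x salt condition).

.CONSTRUCT_NAMES <- c("FIVE_PRIME_AT", "THREE_FIVE_PRIME_AT", "ATGC")
.SALT_NAMES <- c("HIGH_1M", "LOW_5MM")

.construct_alias <- function(x) {
  up <- toupper(gsub("[^0-9A-Za-z]", "", x))
  switch(up,
         "5AT" = , "FIVEPRIMEAT" = , "FIVE_PRIME_AT" = "FIVE_PRIME_AT",
         "35AT" = , "THREEFIVEPRIMEAT" = "THREE_FIVE_PRIME_AT",
         "ATGC" = "ATGC",
         if (x %in% .CONSTRUCT_NAMES) x else
           stop("unknown construct: ", x))
}

.salt_alias <- function(x) {
  up <- toupper(gsub("[^0-9A-Za-z]", "", x))
  switch(up,
         "1M" = , "HIGH1M" = , "HIGH" = "HIGH_1M",
         "5MM" = , "LOW5MM" = , "LOW" = "LOW_5MM",
         if (x %in% .SALT_NAMES) x else stop("unknown salt condition: ", x))
}

.config_basename <- function(construct, salt) {
  cn <- c(FIVE_PRIME_AT = "5AT", THREE_FIVE_PRIME_AT = "35AT", ATGC = "ATGC")
  sn <- c(HIGH_1M = "1M", LOW_5MM = "5mM")
  paste0(cn[[construct]], "_", sn[[salt]], ".cfg")
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that parse as
#' numbers are converted.
#'
#' @param path path to the configuration file.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("malformed config line: '", ln, "'")
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

.cfg_get <- function(cfg, key) {
  if (is.null(cfg[[key]])) stop("config key missing: ", key)
  cfg[[key]]
}

# solve a contour length per unit so that the extension difference between a
# "long" state and a reference extension equals `target` at force `f`
.calibrate_contour <- function(n_units, persistence, stretch_modulus,
                               reference_ext, target, f, kbt) {
  fn <- function(cpu) {
    n_units * cpu * wlc_relative_extension(f, persistence, kbt,
                                           stretch_modulus) -
      reference_ext - target
  }
  uniroot(fn, c(0.05, 3), tol = 1e-12)$root
}

#' Build a construct specification
#'
#' Loads the configuration for one construct and salt condition, calibrates the
#' single-stranded / S-form contour lengths against the configured extension
#' targets, and derives the Bell kinetic parameters from the configured mean
#' transition forces and their standard deviations (via the Evans-Ritchie
#' rupture-force distribution at the nominal loading rate).
#'
#' @param construct one of `"FIVE_PRIME_AT"` (alias `"5AT"`),
#'   `"THREE_FIVE_PRIME_AT"` (alias `"35AT"`), `"ATGC"`.
#' @param salt `"HIGH_1M"` (alias `"1M"`) or `"LOW_5MM"` (alias `"5mM"`).
#' @param config_file optional path to a configuration file overriding the
#'   packaged one.
#' @param temperature temperature in degrees C used for kBT during calibration.
#' @return an object of class `construct_spec`.
#' @examples
#' spec <- construct_spec("5AT", "1M")
#' spec$duplex_bp
#' @export
construct_spec <- function(construct, salt, config_file = NULL,
                           temperature = 22.8) {
  construct <- .construct_alias(construct)
  salt <- .salt_alias(salt)
  if (is.null(config_file))
    config_file <- system.file("extdata", "configs",
                               .config_basename(construct, salt),
                               package = "forcemelt", mustWork = TRUE)
  cfg <- read_config(config_file)
  kbt <- kbt_at(temperature)

  segments <- .parse_segments(.cfg_get(cfg, "segments"))
  duplex_bp <- .cfg_get(cfg, "duplex_bp")
  if (sum(segments$n_bp) != duplex_bp)
    stop("segment lengths do not sum to duplex_bp")
  linker <- .cfg_get(cfg, "linker_config")
  if (construct == "FIVE_PRIME_AT" && linker != "ONE_END")
    stop("FIVE_PRIME_AT requires linker_config = ONE_END")
  if (construct == "THREE_FIVE_PRIME_AT" && linker != "BOTH_ENDS")
    stop("THREE_FIVE_PRIME_AT requires linker_config = BOTH_ENDS")
  if (construct == "ATGC" &&
      !(nrow(segments) == 2 && segments$class[1] == "AT_RICH" &&
        segments$class[2] == "GC_RICH"))
    stop("ATGC requires two segments, AT_RICH then GC_RICH")

  ds <- elastic_params(.cfg_get(cfg, "ds_rise_nm"),
                       .cfg_get(cfg, "ds_persistence_nm"),
                       .cfg_get(cfg, "ds_stretch_modulus_pN"))
  ss_lp <- .cfg_get(cfg, "ss_persistence_nm")
  ss_k <- .cfg_get(cfg, "ss_stretch_modulus_pN")
  handle <- elastic_params(.cfg_get(cfg, "handle_contour_nm"), ss_lp, ss_k)

  scheme <- .cfg_get(cfg, "scheme")
  fcal <- .cfg_get(cfg, "calib_force_pN")
  rel_ds_cal <- function(f) wlc_relative_extension(f, ds$persistence_length,
                                                   kbt, ds$stretch_modulus)
  rel_ss_cal <- function(f) wlc_relative_extension(f, ss_lp, kbt, ss_k)

  elastic <- list(B_FORM = ds, HANDLE_SS = handle)
  extras <- list()

  if (scheme %in% c("peeling", "composite", "composite_low")) {
    # single-stranded contour per nt so that peeling the configured number of
    # bp yields the configured extension gain at the calibration force
    n_peel <- if (is.null(cfg$n_peel_bp)) duplex_bp else cfg$n_peel_bp
    target <- .cfg_get(cfg, "calib_extension_nm")
    ref <- n_peel * ds$contour_length_per_unit * rel_ds_cal(fcal)
    cpu <- .calibrate_contour(n_peel, ss_lp, ss_k, ref, target, fcal, kbt)
    elastic$PEELED_SS <- elastic_params(cpu, ss_lp, ss_k)
  }
  if (scheme %in% c("internal_eq", "two_state_rupture")) {
    # internally molten duplex: both strands share the tension; effective
    # single chain with contour calibrated to the midpoint extension
    target <- .cfg_get(cfg, "calib_extension_nm")
    ref <- duplex_bp * ds$contour_length_per_unit * rel_ds_cal(fcal)
    cpu <- .calibrate_contour(duplex_bp, ss_lp, ss_k, ref, target, fcal, kbt)
    elastic$MELTED_SHARED <- elastic_params(cpu, ss_lp, ss_k)
  }
  if (scheme == "composite") {
    # intermediate extra compliance (split intermediate: its branch has a
    # smaller force-position gradient than the flanking branches)
    f1 <- .cfg_get(cfg, "ftr1_pN")
    ftr <- .cfg_get(cfg, "ftr_pN")
    x1 <- .cfg_get(cfg, "dx1_nm")
    x2 <- .cfg_get(cfg, "dx2_nm")
    f2 <- ftr + (x1 * (ftr - f1) - kbt * log(x1 / x2)) / x2
    c_extra <- .cfg_get(cfg, "intermediate_extra_nm") / (f2 - f1)
    extras$ftr2_pN <- f2
    extras$intermediate_extra_compliance <- c_extra
    # S-form rise so that the total B -> stretched separation equals the
    # configured value at the overall transition force ftr. The stretched
    # state retains the extension the split intermediate gained, so the
    # intermediate's extra compliance is not subtracted here.
    n_at <- segments$n_bp[1]; n_gc <- segments$n_bp[2]
    ss <- elastic$PEELED_SS
    peel_gain <- n_at * (ss$contour_length_per_unit * rel_ss_cal(ftr) -
                         ds$contour_length_per_unit * rel_ds_cal(ftr))
    target_gc <- .cfg_get(cfg, "calib_total_extension_nm") - peel_gain
    s_lp <- .cfg_get(cfg, "sform_persistence_nm")
    s_k <- .cfg_get(cfg, "sform_stretch_modulus_pN")
    ref <- n_gc * ds$contour_length_per_unit * rel_ds_cal(ftr)
    cps <- .calibrate_contour(n_gc, s_lp, s_k, ref, target_gc, ftr, kbt)
    elastic$S_FORM <- elastic_params(cps, s_lp, s_k)
  }
  if (scheme == "composite_low") {
    n_gc <- segments$n_bp[2]
    s_lp <- .cfg_get(cfg, "sform_persistence_nm")
    s_k <- .cfg_get(cfg, "sform_stretch_modulus_pN")
    f3 <- .cfg_get(cfg, "t3_pN")
    ref <- n_gc * ds$contour_length_per_unit * rel_ds_cal(f3)
    cps <- .calibrate_contour(n_gc, s_lp, s_k, ref,
                              .cfg_get(cfg, "dx3_nm"), f3, kbt)
    elastic$S_FORM <- elastic_params(cps, s_lp, s_k)
    # fully molten GC part (irreversible full-melt channel)
    fmelt <- .cfg_get(cfg, "melt_force_pN")
    ref_s <- n_gc * cps * wlc_relative_extension(fmelt, s_lp, kbt, s_k)
    cpm <- .calibrate_contour(n_gc, ss_lp, ss_k, ref_s,
                              .cfg_get(cfg, "full_melt_extra_nm"), fmelt, kbt)
    elastic$MELTED_SHARED <- elastic_params(cpm, ss_lp, ss_k)
  }

  structure(list(name = construct, salt = salt, duplex_bp = duplex_bp,
                 segments = segments, linker_config = linker,
                 scheme = scheme, elastic = elastic, extras = extras,
                 config = cfg, kbt = kbt,
                 noise_sd = .cfg_get(cfg, "noise_sd_pN"),
                 loading_rate = .cfg_get(cfg, "loading_rate_pN_s")),
            class = "construct_spec")
}

.parse_segments <- function(txt) {
  parts <- strsplit(strsplit(txt, ",")[[1]], ":")
  df <- data.frame(
    segment_id = vapply(parts, `[`, character(1), 1),
    n_bp = as.integer(vapply(parts, `[`, character(1), 2)),
    class = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE)
  stopifnot(all(df$class %in% c("AT_RICH", "GC_RICH")), all(df$n_bp >= 1))
  df
}

#' Default pull-relax protocol for a construct
#'
#' @param spec a [construct_spec]; force limits come from its configuration.
#' @param ... overrides passed to [trap_protocol].
#' @return a [trap_protocol].
#' @export
default_protocol <- function(spec, ...) {
  stopifnot(inherits(spec, "construct_spec"))
  args <- list(force_min = .cfg_get(spec$config, "force_min_pN"),
               force_max = .cfg_get(spec$config, "force_max_pN"))
  over <- list(...)
  args[names(over)] <- over
  do.call(trap_protocol, args)
}

#' @export
print.construct_spec <- function(x, ...) {
  cat("<construct_spec>", x$name, "|", x$salt, "|", x$duplex_bp, "bp |",
      "scheme:", x$scheme, "\n")
  invisible(x)
}
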