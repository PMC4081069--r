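# Ensemble reporting: unit conversions at the printed precision, per-construct
# summaries and force histograms.

#' Per-base-pair extension
#'
#' @param extension extension in nm.
#' @param n_bp number of base pairs (>= 1).
#' @return nm/bp, rounded half-up to 3 decimals (the reporting precision).
#' @examples
#' per_bp_extension(14.7, 64)   # 0.230
#' per_bp_extension(24.7, 122)  # 0.202
#' @export
per_bp_extension <- function(extension, n_bp) {
  if (any(n_bp < 1)) stop("n_bp must be at least 1")
  round_half_up(extension / n_bp, 3)
}

#' B-form contour length
#'
#' @param n_bp number of base pairs.
#' @param rise helix rise per bp in nm (0.34 by default).
#' @return contour length in nm.
#' @examples
#' bform_contour(60)  # 20.4
#' @export
bform_contour <- function(n_bp, rise = 0.34) {
  if (any(n_bp < 1)) stop("n_bp must be at least 1")
  n_bp * rise
}

#' Cooperative length in base pairs
#'
#' Converts the cooperative length of the two-state fit into base pairs using
#' the measured per-bp extension at the transition midpoint.
#'
#' @param delta cooperative length in nm (> 0).
#' @param per_bp_midpoint per-bp extension at the midpoint, nm/bp (> 0;
#'   default 0.166, the measured midpoint extension per bp of the
#'   double-sealed 64 bp duplex).
#' @return number of base pairs (nearest integer).
#' @examples
#' cooperative_length_bp(2.6, 0.166)  # 16
#' @export
cooperative_length_bp <- function(delta, per_bp_midpoint = 0.166) {
  stopifnot(delta > 0, per_bp_midpoint > 0)
  as.integer(round_half_up(delta / per_bp_midpoint))
}

#' Extension of the intermediate between its two crossing forces
#'
#' Decomposes the total B-form to fully-stretched extension into the extension
#' gained at the first transition, the growth of the intermediate branch
#' between the two crossing forces, and the extension gained at the second
#' transition: returns `total - first - second`.
#'
#' @param total_extension total extension, nm.
#' @param first_extension extension at the first transition (B to
#'   intermediate, at the lower crossing force), nm.
#' @param second_extension extension at the second transition (intermediate to
#'   stretched, at the upper crossing force), nm.
#' @return intermediate extension in nm.
#' @examples
#' intermediate_extension(24.7, 8.0, 11.9)  # 4.8
#' @export
intermediate_extension <- function(total_extension, first_extension,
                                   second_extension) {
  total_extension - first_extension - second_extension
}

#' Aggregate per-cycle measurements into per-construct summaries
#'
#' @param measurements data frame with one row per analysed cycle; required
#'   columns `construct`, `salt`, `molecule`, `duplex_bp`; optional metric
#'   columns `melt_force_pN`, `rezip_force_pN`, `extension_nm`, `ftr_pN`,
#'   `verdict` (`"REVERSIBLE"`/`"HYSTERETIC"`).
#' @param histogram_bin_width histogram bin width in pN (default 1).
#' @return a list with `summary` (one row per construct x salt: counts, means,
#'   SDs, per-bp extension, hysteretic fraction) and `histograms` (per group,
#'   melt/rezip force histograms as returned by [graphics::hist], not
#'   plotted).
#' @export
aggregate_results <- function(measurements, histogram_bin_width = 1) {
  m <- as.data.frame(measurements)
  if (!nrow(m)) stop("no measurements to aggregate")
  stopifnot(all(c("construct", "salt", "molecule", "duplex_bp") %in% names(m)))
  key <- interaction(m$construct, m$salt, drop = TRUE)
  mean_sd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) c(NA_real_, NA_real_)
    else c(mean(x), if (length(x) > 1) sd(x) else 0)
  }
  groups <- split(m, key)
  summary <- do.call(rbind, lapply(groups, function(g) {
    fm <- mean_sd(g$melt_force_pN); fr <- mean_sd(g$rezip_force_pN)
    ex <- mean_sd(g$extension_nm); ft <- mean_sd(g$ftr_pN)
    data.frame(construct = g$construct[1], salt = g$salt[1],
               n_molecules = length(unique(g$molecule)),
               n_cycles = nrow(g),
               mean_melt_force_pN = fm[1], sd_melt_force_pN = fm[2],
               mean_rezip_force_pN = fr[1], sd_rezip_force_pN = fr[2],
               mean_extension_nm = ex[1], sd_extension_nm = ex[2],
               per_bp_extension_nm = if (is.na(ex[1])) NA_real_
                 else per_bp_extension(ex[1], g$duplex_bp[1]),
               mean_ftr_pN = ft[1], sd_ftr_pN = ft[2],
               hysteretic_fraction = if (is.null(g$verdict)) NA_real_
                 else mean(g$verdict == "HYSTERETIC", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  histo <- lapply(groups, function(g) {
    mk <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NULL)
      br <- seq(floor(min(x)), ceiling(max(x)) + histogram_bin_width,
                by = histogram_bin_width)
      graphics::hist(x, breaks = br, plot = FALSE)
    }
    list(melt = mk(g$melt_force_pN), rezip = mk(g$rezip_force_pN))
  })
  list(summary = summary, histograms = histo)
}

#' Write a summary table as TSV
#'
#' Numeric columns are written at full precision; the file is deterministic
#' for identical inputs.
#'
#' @param summary data frame (e.g. `aggregate_results(...)$summary`).
#' @param path output file path.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
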