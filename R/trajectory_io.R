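# Plain-text trajectory format and pull/relax segmentation.
#
# Dialect: UTF-8 TSV with '.' decimal separator; `# key = value` metadata
# lines, then a header line `time_s  trap_position_nm  force_pN` and one row
# per sample. Ground-truth event logs use a companion TSV with columns
# `cycle  time_s  event  force_pN  trap_position_nm`.

.REQUIRED_META <- c("construct", "salt", "temperature_C", "seed",
                    "trap_velocity_nm_s", "trap_stiffness_pN_nm",
                    "sample_rate_hz")

.TRAJ_COLS <- c("time_s", "trap_position_nm", "force_pN")

#' Construct a trajectory object
#'
#' @param samples data frame with columns `time_s`, `trap_position_nm`,
#'   `force_pN`; time must be strictly increasing and all values finite.
#' @param metadata named list of recording metadata; must contain at least
#'   construct, salt, temperature_C, seed, trap_velocity_nm_s,
#'   trap_stiffness_pN_nm and sample_rate_hz.
#' @return an object of class `fm_trajectory` (a data frame with a
#'   `metadata` attribute).
#' @export
fm_trajectory <- function(samples, metadata) {
  stopifnot(is.data.frame(samples), all(.TRAJ_COLS %in% names(samples)))
  samples <- samples[, .TRAJ_COLS]
  if (nrow(samples) > 1 && any(diff(samples$time_s) <= 0))
    stop("time must be strictly increasing")
  if (!all(is.finite(as.matrix(samples))))
    stop("trajectory contains non-finite values")
  miss <- setdiff(.REQUIRED_META, names(metadata))
  if (length(miss))
    stop("missing metadata key(s): ", paste(miss, collapse = ", "))
  structure(samples, metadata = metadata,
            class = c("fm_trajectory", "data.frame"))
}

#' Trajectory metadata
#' @param traj an [fm_trajectory].
#' @return the named metadata list.
#' @export
trajectory_metadata <- function(traj) attr(traj, "metadata")

#' Write a trajectory to the plain-text format
#'
#' @param traj an [fm_trajectory].
#' @param destination file path.
#' @return `destination`, invisibly.
#' @export
write_trajectory <- function(traj, destination) {
  stopifnot(inherits(traj, "fm_trajectory"))
  meta <- trajectory_metadata(traj)
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    paste0("# ", k, " = ",
           if (is.numeric(v)) sprintf("%.15g", v) else as.character(v))
  }, character(1))
  rows <- sprintf("%.15g\t%.15g\t%.15g", traj$time_s, traj$trap_position_nm,
                  traj$force_pN)
  writeLines(c(hdr, paste(.TRAJ_COLS, collapse = "\t"), rows), destination)
  invisible(destination)
}

#' Read a trajectory from the plain-text format
#'
#' @param source file path.
#' @return an [fm_trajectory]. Malformed headers or ragged rows raise a format
#'   error naming the offending line.
#' @export
read_trajectory <- function(source) {
  if (!file.exists(source)) stop("file not found: ", source)
  lines <- readLines(source, warn = FALSE)
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta) - 1L
  if (is.na(n_meta)) n_meta <- length(lines)
  meta <- list()
  for (i in seq_len(n_meta)) {
    m <- regmatches(lines[i],
                    regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3)
      stop("format error at line ", i, ": malformed metadata line")
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    meta[[m[2]]] <- if (!is.na(num)) num else val
  }
  if (length(lines) <= n_meta)
    stop("format error: no column header found")
  header <- strsplit(lines[n_meta + 1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header, .TRAJ_COLS))
    stop("format error at line ", n_meta + 1L, ": expected header '",
         paste(.TRAJ_COLS, collapse = "\t"), "'")
  data_lines <- lines[seq.int(n_meta + 2L, length.out =
                                length(lines) - n_meta - 1L)]
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("format error at line ", n_meta + 1L + bad[1],
         ": expected 3 tab-separated fields, found ",
         lengths(fields)[bad[1]])
  vals <- as.numeric(unlist(fields, use.names = FALSE))
  if (anyNA(vals)) {
    bad_row <- which(apply(matrix(is.na(vals), ncol = 3, byrow = TRUE), 1, any))[1]
    stop("format error at line ", n_meta + 1L + bad_row,
         ": non-numeric field")
  }
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  fm_trajectory(data.frame(time_s = m[, 1], trap_position_nm = m[, 2],
                           force_pN = m[, 3]),
                metadata = meta)
}

#' Write / read a ground-truth event log
#'
#' Companion TSV with columns `cycle  time_s  event  force_pN
#' trap_position_nm`.
#'
#' @param log data frame with the columns above (`cycle` added if absent).
#' @param destination,source file path.
#' @return the path / the log data frame.
#' @export
write_truth_log <- function(log, destination) {
  if (is.null(log$cycle)) log$cycle <- 1L
  log <- log[, c("cycle", "time_s", "event", "force_pN", "trap_position_nm")]
  out <- c(paste(names(log), collapse = "\t"),
           sprintf("%d\t%.15g\t%s\t%.15g\t%.15g", log$cycle, log$time_s,
                   log$event, log$force_pN, log$trap_position_nm))
  writeLines(out, destination)
  invisible(destination)
}

#' @rdname write_truth_log
#' @export
read_truth_log <- function(source) {
  read.table(source, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Segment a trajectory into pull and relax phases
#'
#' Phase boundaries are placed at sign changes of the trap velocity, smoothed
#' over a configurable window to suppress noise-induced sign flips. Each cycle
#' is one PULL phase plus the following RELAX phase. Segmentation is
#' idempotent and the concatenation of the segmented phases reproduces the
#' original sample order.
#'
#' @param traj an [fm_trajectory] (or plain data frame with the trajectory
#'   columns).
#' @param smooth_window smoothing window for the velocity sign, in samples
#'   (default 50, i.e. 50 ms at 1 kHz).
#' @return a list of cycles; each cycle is a list with elements `pull` and
#'   `relax`, data frames carrying the trajectory columns plus `.row` (the row
#'   index in `traj`). A trailing pull without a relax gets `relax = NULL`;
#'   a trajectory with no direction change yields a single-phase warning.
#' @export
segment_cycles <- function(traj, smooth_window = 50) {
  df <- as.data.frame(traj)
  n <- nrow(df)
  if (n < 2) stop("trajectory too short to segment")
  v <- diff(df$trap_position_nm)
  w <- max(1L, min(as.integer(smooth_window), length(v)))
  vs <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  # fill filter NAs at the edges with the nearest smoothed value
  first_ok <- which(!is.na(vs))[1]
  last_ok <- tail(which(!is.na(vs)), 1)
  vs[seq_len(first_ok - 1)] <- vs[first_ok]
  if (last_ok < length(vs)) vs[(last_ok + 1):length(vs)] <- vs[last_ok]
  sgn <- sign(vs)
  sgn[sgn == 0] <- NA
  # carry the previous sign through flat stretches
  for (i in seq_along(sgn)) if (is.na(sgn[i]) && i > 1) sgn[i] <- sgn[i - 1]
  if (anyNA(sgn)) sgn[is.na(sgn)] <- 1
  phase <- c(sgn[1], sgn)  # per sample
  r <- rle(phase)
  # merge runs shorter than the window into the preceding run
  if (length(r$lengths) > 1) {
    keep_l <- r$lengths; keep_v <- r$values
    i <- 2L
    while (i <= length(keep_l)) {
      if (keep_l[i] < w) {
        keep_l[i - 1] <- keep_l[i - 1] + keep_l[i]
        keep_l <- keep_l[-i]; keep_v <- keep_v[-i]
      } else if (keep_v[i] == keep_v[i - 1]) {
        keep_l[i - 1] <- keep_l[i - 1] + keep_l[i]
        keep_l <- keep_l[-i]; keep_v <- keep_v[-i]
      } else i <- i + 1L
    }
    r <- list(lengths = keep_l, values = keep_v)
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  phases <- lapply(seq_along(starts), function(i) {
    d <- df[starts[i]:ends[i], , drop = FALSE]
    d$.row <- starts[i]:ends[i]
    attr(d, "phase") <- if (r$values[i] > 0) "PULL" else "RELAX"
    d
  })
  labels <- vapply(phases, attr, character(1), "phase")
  if (all(labels == labels[1])) {
    warning("single-phase trajectory: no trap direction change found")
    if (labels[1] == "PULL")
      return(list(list(pull = phases[[1]], relax = NULL)))
    return(list(list(pull = NULL, relax = phases[[1]])))
  }
  cycles <- list()
  i <- 1L
  while (i <= length(phases)) {
    if (labels[i] == "PULL") {
      relax <- if (i + 1 <= length(phases) && labels[i + 1] == "RELAX") {
        i <<- i  # no-op for clarity
        phases[[i + 1]]
      } else NULL
      cycles[[length(cycles) + 1L]] <- list(pull = phases[[i]], relax = relax)
      i <- i + if (is.null(relax)) 1L else 2L
    } else {
      # leading relax without a pull: skip
      i <- i + 1L
    }
  }
  cycles
}
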