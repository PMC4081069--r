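# Plain-text trajectory format and pull/relax segmentation.

meta_stub <- function(seed = 1) {
  list(construct = "FIVE_PRIME_AT", salt = "HIGH_1M", temperature_C = 22.8,
       seed = seed, trap_velocity_nm_s = 50, trap_stiffness_pN_nm = 0.156,
       sample_rate_hz = 1000)
}

triangle_traj <- function(n_cycles = 1, n_half = 400, seed = 1) {
  x <- rep(c(seq_len(n_half), rev(seq_len(n_half))), n_cycles) * 0.05 + 100
  fm_trajectory(data.frame(time_s = seq_along(x) * 1e-3,
                           trap_position_nm = x,
                           force_pN = 0.15 * x),
                metadata = meta_stub(seed))
}

test_that("write and read round-trip samples and metadata", {
  tr <- fm_trajectory(
    data.frame(time_s = c(0, 0.001, 0.002),
               trap_position_nm = c(100.123456789, 100.2, 100.25),
               force_pN = c(5.000000001, 5.01, 4.99)),
    metadata = meta_stub())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  expect_identical(trajectory_metadata(back)$construct, "FIVE_PRIME_AT")
  expect_equal(trajectory_metadata(back)$trap_stiffness_pN_nm, 0.156)
})

test_that("malformed files raise format errors naming the line", {
  tr <- triangle_traj()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  lines <- readLines(path)
  # drop a required metadata key
  writeLines(lines[-1], path)
  expect_error(read_trajectory(path), "missing metadata")
  # ragged row
  bad <- lines
  bad[20] <- "1.0\t2.0"
  writeLines(bad, path)
  expect_error(read_trajectory(path), "line 20")
  # corrupted header
  bad <- lines
  bad[8] <- "time\tposition\tforce"
  writeLines(bad, path)
  expect_error(read_trajectory(path), "header")
})

test_that("truth logs round-trip through their TSV companion format", {
  log <- data.frame(cycle = c(1L, 1L), time_s = c(1.5, 8.25),
                    event = c("MELT", "REZIP"),
                    force_pN = c(61.2, 21.9),
                    trap_position_nm = c(520.5, 250.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_log(log, path)
  expect_equal(read_truth_log(path), log)
})

test_that("segmentation finds the expected cycles", {
  expect_length(segment_cycles(triangle_traj(1)), 1)
  cyc9 <- segment_cycles(triangle_traj(9))
  expect_length(cyc9, 9)
  expect_true(all(vapply(cyc9, function(cy) !is.null(cy$relax), logical(1))))
  # monotone ramp: one pull, no relax, with a single-phase warning
  up <- fm_trajectory(data.frame(time_s = 1:500 * 1e-3,
                                 trap_position_nm = 100 + 1:500 * 0.05,
                                 force_pN = 5 + 1:500 * 0.01),
                      metadata = meta_stub())
  expect_warning(res <- segment_cycles(up), "single-phase")
  expect_length(res, 1)
  expect_null(res[[1]]$relax)
  expect_identical(nrow(res[[1]]$pull), 500L)
})

test_that("segmentation is idempotent and preserves sample order", {
  tr <- triangle_traj(3)
  cyc <- segment_cycles(tr)
  rows <- unlist(lapply(cyc, function(cy) c(cy$pull$.row, cy$relax$.row)))
  expect_identical(rows, seq_len(nrow(tr)))
  # re-segmenting a single extracted phase leaves it intact
  pull1 <- cyc[[1]]$pull
  expect_warning(again <- segment_cycles(pull1), "single-phase")
  expect_identical(nrow(again[[1]]$pull), nrow(pull1))
})

test_that("a simulated cycle survives a file round trip with phases intact", {
  spec <- spec_of("5AT", "1M")
  cy <- simulate_cycle(spec, default_protocol(spec), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(cy$trajectory, path)
  back <- read_trajectory(path)
  s1 <- segment_cycles(cy$trajectory)
  s2 <- segment_cycles(back)
  expect_length(s2, length(s1))
  expect_identical(nrow(s2[[1]]$pull), nrow(s1[[1]]$pull))
  expect_identical(nrow(s2[[1]]$relax), nrow(s1[[1]]$relax))
  expect_equal(trajectory_metadata(back)$seed, 2)
})
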