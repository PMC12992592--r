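test_that("PDB and plain-frames round trips are lossless within precision", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 3,
                                              n_frames = 4, seed = 2))
  for (fmt in c("pdb_multimodel", "plain_frames")) {
    path <- tempfile()
    write_trajectory(sim$trajectory, path, fmt)
    back <- load_trajectory(path, fmt)
    tol <- if (fmt == "pdb_multimodel") 1.1e-3 else 1e-6
    expect_equal(dim(back$coords), dim(sim$trajectory$coords))
    expect_lt(max(abs(back$coords - sim$trajectory$coords)), tol)
    expect_equal(back$box[1, ], unname(sim$trajectory$box[1, ]),
                 tolerance = 1e-3)
  }
})

test_that("an atom-count mismatch names the offending frame", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 2,
                                              n_frames = 3, seed = 2))
  path <- tempfile()
  write_trajectory(sim$trajectory, path, "pdb_multimodel")
  lines <- readLines(path)
  atom_in_second <- which(grepl("^ATOM", lines))
  drop <- atom_in_second[length(atom_in_second) %/% 2L]  # in frame 2
  writeLines(lines[-drop], path)
  expect_error(load_trajectory(path, "pdb_multimodel"),
               "atom count mismatch at frame 2")
  path2 <- tempfile()
  write_trajectory(sim$trajectory, path2, "plain_frames")
  lines2 <- readLines(path2)
  writeLines(lines2[-3L], path2)
  expect_error(load_trajectory(path2, "plain_frames"), "frame 1")
})

test_that("topology round trips and validates enums", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 2,
                                              n_frames = 1))
  path <- tempfile(fileext = ".csv")
  write_topology(sim$topology, path)
  back <- load_topology(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$topology)[names(back)])
  bad <- utils::read.csv(path)
  bad$role[1] <- "headd"
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(load_topology(path), "unknown role")
})

test_that("missing terminal-tail flags are auto-flagged with a warning", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 1,
                                              n_frames = 1))
  topo <- sim$topology
  topo$is_terminal_tail <- FALSE
  path <- tempfile(fileext = ".csv")
  write_topology(topo, path)
  w <- capture_warnings(back <- load_topology(path))
  expect_match(w, "auto-flagged", all = TRUE)
  expect_length(w, 2L)  # one warning per lipid
  expect_equal(sum(back$is_terminal_tail), 2L)  # one per lipid, two lipids
})

test_that("ionizable lipids without head atoms are a topology error", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 1,
                                              n_frames = 1))
  topo <- sim$topology
  topo$role[topo$lipid_id == 1] <- "tail"
  path <- tempfile(fileext = ".csv")
  write_topology(topo, path)
  expect_error(suppressWarnings(load_topology(path)), "no head atoms")
})

test_that("leaflet assignment is mirrored and translation invariant", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 6,
                                              n_frames = 1, seed = 3))
  leaf <- assign_leaflets(sim$trajectory, sim$topology, 1)
  expect_equal(sum(leaf == "upper"), 6L)
  expect_equal(sum(leaf == "lower"), 6L)
  shifted <- sim$trajectory
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 50
  expect_identical(assign_leaflets(shifted, sim$topology, 1), leaf)
})

test_that("analysis-frame selection takes the final window at the stride", {
  traj <- new_trajectory(array(0, c(1, 3, 1500)), time = 1:1500)
  idx <- select_analysis_frames(traj, window_ns = 500, stride_ns = 1)
  expect_length(idx, 500L)
  expect_equal(range(idx), c(1001L, 1500L))
  expect_equal(max(idx), 1500L)  # inclusive of the last frame
  idx2 <- select_analysis_frames(traj, window_ns = 500, stride_ns = 2)
  expect_length(idx2, 250L)
  expect_error(select_analysis_frames(traj, window_ns = 2000), "range error")
})
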