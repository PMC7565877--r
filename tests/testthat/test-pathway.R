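test_that("clearance is the signed distance to the nearest atom surface", {
  one <- molecular_structure(1, "C", "C", "UNK", 1, "A",
                             matrix(c(0, 0, 0), 1), vdw_radius = 1.7)
  expect_identical(clearance(c(1.7, 0, 0), one), 0)
  expect_identical(clearance(c(0, 0, 0), one), -1.7)
  # on the axis of a cylindrical phantom: R - r within the ring
  # discretization error
  ph <- make_channel_phantom(channel_phantom_spec(
    length = 20, shape = "straight", wall_radius = 4, atom_radius = 1.5))
  for (z in c(3, 10.3, 17)) {
    expect_equal(clearance(c(0, 0, z), ph$structure), 2.5,
                 tolerance = 0.05 / 2.5)
    expect_identical(clearance(c(0, 0, z), ph$structure),
                     oracle_clearance(c(0, 0, z), ph$structure))
  }
})

test_that("adding an atom never increases any clearance (monotone degradation)", {
  ph <- make_channel_phantom(channel_phantom_spec(
    length = 12, shape = "straight", wall_radius = 4))
  st <- ph$structure
  set.seed(42)
  pts <- cbind(runif(25, -2, 2), runif(25, -2, 2), runif(25, 0, 12))
  before <- apply(pts, 1, clearance, structure = st)
  extra <- rbind(st, st[1, ])
  extra$atom_id[nrow(extra)] <- nrow(extra)
  extra[nrow(extra), c("x", "y", "z")] <- c(0.5, 0.5, 6)
  class(extra) <- class(st)
  after <- apply(pts, 1, clearance, structure = extra)
  expect_true(all(after <= before + 1e-12))
})

test_that("find_path follows the axis of a straight hollow cylinder", {
  ph <- make_channel_phantom(channel_phantom_spec(
    length = 30, shape = "straight", wall_radius = 4))
  spec <- pathway_spec(ph$start, ph$target, step_length = 1,
                       search_radius = 2)
  ax <- find_path(ph$structure, spec, seed = 1)
  expect_identical(ax$status, "reached")
  # by symmetry the z-axis is the unique clearance maximizer
  expect_true(all(sqrt(ax$points[, 1]^2 + ax$points[, 2]^2) < 0.5))
  # spacing invariant and progress invariant
  seg <- sqrt(rowSums(diff(ax$points)^2))
  expect_true(all(seg >= 0.5 * spec$step_length - 1e-9))
  expect_true(all(seg <= 1.5 * spec$step_length + 1e-9))
  dist_t <- sqrt(rowSums(sweep(ax$points, 2, spec$target_point)^2))
  expect_true(all(diff(dist_t) <= -0.25 * spec$step_length + 1e-9))
  # every stored clearance equals the brute-force scan bit-for-bit
  for (i in seq_len(nrow(ax$points)))
    expect_identical(ax$clearance[i],
                     oracle_clearance(ax$points[i, ], ph$structure))
})

test_that("find_path flags a blocked path at an occluding plug", {
  plugged <- wall_constriction(base = 4, min_wall = 0.4, at = 15,
                               width = 1.5)
  expect_warning(
    ph <- make_channel_phantom(channel_phantom_spec(
      length = 30, shape = "straight", wall_radius = plugged)),
    "sealed channel")
  spec <- pathway_spec(ph$start, ph$target, step_length = 1,
                       search_radius = 2)
  ax <- find_path(ph$structure, spec, seed = 1)
  expect_identical(ax$status, "blocked")
  # the partial axis ends before the plug and stays in open channel
  expect_true(max(ax$points[, 3]) < 15)
  expect_true(all(ax$clearance > 0))
})

test_that("find_path errors on a buried start point", {
  ph <- make_channel_phantom(channel_phantom_spec(
    length = 20, shape = "straight", wall_radius = 4))
  spec <- pathway_spec(c(0, 4, 10), ph$target, step_length = 1,
                       search_radius = 2)
  expect_error(find_path(ph$structure, spec), "buried")
})

test_that("min_radius_profile recovers a constant-width phantom and applies the entry trim", {
  ph <- make_channel_phantom(channel_phantom_spec(
    length = 30, shape = "straight", wall_radius = 4))
  spec <- pathway_spec(ph$start, ph$target, step_length = 1,
                       search_radius = 2)
  ax <- find_path(ph$structure, spec, seed = 1)
  pr <- min_radius_profile(ax, ph$structure, trim_start = 6)
  expect_s3_class(pr, "RadiusProfile")
  expect_true(all(abs(pr$values - 2.5) <= 0.1))
  expect_true(all(is.finite(pr$values)))
  expect_true(all(diff(pr$bin_centers) > 0))
  # first reported bin is >= 6 A from the entry end
  expect_true(all(pr$total_length - pr$bin_centers >= 6 - 1e-9))
  # untrimmed profile reaches closer to the entry
  pr0 <- min_radius_profile(ax, ph$structure, trim_start = 0)
  expect_gt(length(pr0$bin_centers), length(pr$bin_centers))
})

test_that("min_radius_profile rejects a topology mismatch", {
  ph <- make_channel_phantom(channel_phantom_spec(
    length = 20, shape = "straight", wall_radius = 4))
  ax <- find_path(ph$structure,
                  pathway_spec(ph$start, ph$target, step_length = 1,
                               search_radius = 2), seed = 1)
  other <- toy_two_region_topology()
  expect_error(min_radius_profile(ax, other), "topology mismatch")
})

test_that("constriction_report finds minima and ranks temporal variance", {
  # constant two-frame profile: minimum equals the constant, variance 0
  const <- structure(list(
    bin_centers = seq(0.5, 9.5, 1),
    values = matrix(3, 10, 2), trim_start = 0, total_length = 10,
    frame_times = 0:1), class = "RadiusProfile")
  rep1 <- constriction_report(const)
  expect_identical(rep1$per_frame$min_radius, c(3, 3))
  expect_identical(rep1$bin_variance$variance, rep(0, 10))
  # one bin drops 3.0 -> 0.5 across frames: maximal temporal variance there
  v <- matrix(3, 10, 2)
  v[4, 2] <- 0.5
  drop1 <- structure(list(
    bin_centers = seq(0.5, 9.5, 1), values = v, trim_start = 0,
    total_length = 10, frame_times = 0:1), class = "RadiusProfile")
  rep2 <- constriction_report(drop1)
  expect_identical(which.max(rep2$bin_variance$variance), 4L)
  expect_identical(rep2$per_frame$min_radius[2], 0.5)
})
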