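test_that("tubulin dimer has the cryo-derived footprint and is convex", {
  s <- fx("tubulin")
  expect_true(validate_convex_shape(s))
  ext <- apply(s$vertices, 2, function(v) diff(range(v)))
  expect_lt(abs(ext[1] - 8), 0.5)        # axial
  expect_equal(unname(ext[2]), 5.0, tolerance = 0.1)
  expect_equal(unname(ext[3]), 4.5, tolerance = 0.1)
  expect_length(grep("^corner_", names(s$anchors)), 4)
})

test_that("polyhedron volume matches a Monte-Carlo rejection oracle", {
  s <- fx("tubulin")
  set.seed(71)
  lo <- apply(s$vertices, 2, min); hi <- apply(s$vertices, 2, max)
  n <- 1e6
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  inside <- rep(TRUE, n)
  for (fi in seq_along(s$faces)) {
    nrm <- s$face_normals[fi, ]
    d <- sum(nrm * s$vertices[s$faces[[fi]][1], ])
    inside <- inside & (pts %*% nrm <= d)
  }
  vol_mc <- mean(inside) * prod(hi - lo)
  expect_equal(shape_volume(s), vol_mc, tolerance = 0.02)
})

test_that("binder has ~4 nm diameter and mode-specific anchors", {
  bp <- fx("binder_pocket")
  expect_lt(abs(2 * effective_radius(bp) - 4), 0.5)
  expect_length(grep("^iface_", names(bp$anchors)), 4)
  bf <- fx("binder_face")
  expect_length(grep("^iface", names(bf$anchors)), 1)
  expect_equal(bf$anchor_normals$binding, c(0, 0, -1))
})

test_that("pocket-mode binder mates exactly into a complete pocket", {
  mt <- fx("mt_blunt"); sites <- fx("sites_blunt")
  b <- fx("binder_pocket")
  df <- as.data.frame(sites)
  i4 <- which(df$k == 4 & !df$seam)[15]
  st <- sites[[i4]]
  mp <- mated_pose(st, b)
  aw <- transform_points(mp, pocket_anchor_matrix(b, st$roles))
  res <- sqrt(rowSums((aw - st$interface_centers)^2))
  expect_true(all(res < 1e-6))
  # and the mated pose is collision free
  ma <- mtarrival:::.mt_arrays(mt, fx("tubulin"))
  d <- mtarrival:::cpp_scene_distance(ma$V, ma$R, ma$t, b$vertices,
                                      quat_to_matrix(mp), mp$position)
  expect_gt(d$distance, 0)
})

test_that("degenerate shapes are rejected loudly", {
  flat <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0), ncol = 3,
                 byrow = TRUE)
  expect_error(convex_shape(flat, list(c(1, 2, 4, 3), c(1, 3, 4, 2))),
               "degenerate")
})

test_that("closest_distance reproduces simple closed-form cases", {
  cube <- unit_cube()
  cd <- closest_distance(cube, pose(c(0, 0, 0)), cube, pose(c(3, 0, 0)))
  expect_equal(cd$distance, 2, tolerance = 1e-9)
  expect_equal(cd$feature_a$type, "face")
  expect_equal(cd$feature_b$type, "face")
  # witness points realise the distance
  expect_equal(sqrt(sum((cd$point_a - cd$point_b)^2)), cd$distance,
               tolerance = 1e-9)
  # overlapping pair reports penetration
  ov <- closest_distance(cube, pose(c(0, 0, 0)), cube, pose(c(0.5, 0, 0)))
  expect_lte(ov$distance, 0)
})

test_that("closest_distance agrees with brute-force oracles on random poses", {
  set.seed(42)
  s <- fx("tubulin"); b <- fx("binder_pocket")
  worst <- 0; nov <- 0
  for (i in 1:150) {
    pp <- random_pose_pair()
    cd <- closest_distance(s, pp$pa, b, pp$pb)
    if (sat_overlap(s, pp$pa, b, pp$pb)) {
      nov <- nov + 1
      expect_lte(cd$distance, 1e-9)
    } else {
      bd <- brute_convex_distance(s, pp$pa, b, pp$pb)
      worst <- max(worst, abs(cd$distance - bd))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("closest_distance matches the surface-sampling oracle", {
  set.seed(43)
  s <- fx("tubulin"); b <- fx("binder_pocket")
  for (i in 1:25) {
    pp <- random_pose_pair()
    cd <- closest_distance(s, pp$pa, b, pp$pb)
    if (cd$distance <= 0.5) next
    so <- sampling_distance_oracle(s, pp$pa, b, pp$pb, density = 25)
    expect_lt(abs(cd$distance - so), 0.05)
  }
})

test_that("distance is symmetric and translation invariant", {
  set.seed(44)
  s <- fx("tubulin"); b <- fx("binder_pocket")
  for (i in 1:40) {
    pp <- random_pose_pair()
    d1 <- closest_distance(s, pp$pa, b, pp$pb)$distance
    d2 <- closest_distance(b, pp$pb, s, pp$pa)$distance
    sh <- rnorm(3) * 40
    d3 <- closest_distance(
      s, pose(pp$pa$position + sh, pp$pa$quaternion),
      b, pose(pp$pb$position + sh, pp$pb$quaternion))$distance
    expect_equal(d1, d2, tolerance = 1e-9)
    expect_equal(d1, d3, tolerance = 1e-8)
  }
})

test_that("warm starts are accepted and do not change the result", {
  set.seed(45)
  s <- fx("tubulin"); b <- fx("binder_pocket")
  pp <- random_pose_pair()
  cold <- closest_distance(s, pp$pa, b, pp$pb)
  warm <- closest_distance(s, pp$pa, b, pp$pb, warm_start = cold)
  expect_equal(warm$distance, cold$distance, tolerance = 1e-9)
})

test_that("broad phase returns a superset of the exact candidate set", {
  set.seed(46)
  mt <- fx("mt_small")
  s <- fx("tubulin"); b <- fx("binder_pocket")
  idx <- broad_phase_index(mt)
  for (i in 1:60) {
    p <- pose(mt$centroid + rnorm(3) * 25, random_quaternion(1)[1, ])
    radius <- runif(1, 0.5, 6)
    cand <- broad_phase_candidates(idx, p, radius,
                                   mol_radius = effective_radius(b) * 1.3)
    # exhaustive narrow phase
    true_set <- which(vapply(seq_len(mt$n_dimers), function(j) {
      closest_distance(b, p, s, mt$poses[[j]])$distance <= radius
    }, logical(1)))
    expect_true(all(true_set %in% cand))
  }
  # far query is empty, own-centre query contains the dimer
  expect_length(broad_phase_candidates(idx, pose(c(2500, 0, 0)), 1), 0)
  p1 <- pose(mt$poses[[5]]$position)
  expect_true(5 %in% broad_phase_candidates(idx, p1, 1))
})

test_that("OBJ export and import round-trip a shape", {
  s <- fx("tubulin")
  f <- tempfile(fileext = ".obj")
  write_obj(s, f)
  s2 <- read_obj(f, name = "reimport")
  expect_equal(s2$vertices, unname(s$vertices), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(shape_volume(s2), shape_volume(s), tolerance = 1e-9)
})
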