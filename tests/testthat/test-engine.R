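test_that("Stokes-Einstein coefficients match direct arithmetic", {
  co <- diffusion_coefficients(2.0e-9, 298, 8.9e-4)
  expect_equal(co$dc, 1.226e-10, tolerance = 0.005)
  expect_equal(co$dc_rot, 2.30e7, tolerance = 0.01)
  # scaling laws
  co2 <- diffusion_coefficients(4.0e-9, 298, 8.9e-4)
  expect_equal(co2$dc, co$dc / 2, tolerance = 1e-12)
  expect_equal(co2$dc_rot, co$dc_rot / 8, tolerance = 1e-12)
})

test_that("dynamic time-step rule reproduces the stated regimes", {
  mod <- diffusion_model(radius_nm = 2.0)
  # close to the lattice: ~4e-12 s
  p1 <- plan_timestep(1, mod)
  expect_equal(p1$dx, 0.05)
  expect_lt(abs(log(p1$dt / 4e-12)), log(1.5))
  # far: five steps away
  p100 <- plan_timestep(100, mod)
  expect_equal(p100$dx, 20)
  expect_equal(p100$dt, 20^2 / (6 * mod$dc_nm))
  # monotone non-decreasing over a grid
  dts <- vapply(c(0.1, 0.5, 1, 2, 5, 20, 50, 100, 400, 1000),
                function(d) plan_timestep(d, mod)$dt, numeric(1))
  expect_true(all(diff(dts) >= 0))
  # near-site override gives the fixed 0.05 nm step
  pns <- plan_timestep(50, mod, near_binding_site = TRUE)
  expect_equal(pns$dx, 0.05)
  expect_equal(pns$regime, "near-site")
})

test_that("sampled steps have the prescribed moments", {
  mod <- fx("model_pocket")
  plan <- plan_timestep(10, mod)
  set.seed(20)
  n <- 2e5
  d <- matrix(rnorm(3 * n, 0, sqrt(2 * mod$dc_nm * plan$dt)), ncol = 3)
  # the generator draws through sample_step; check a direct batch first,
  # then spot-check sample_step itself uses the same law
  set.seed(21)
  ss <- replicate(2000, sample_step(plan, mod)$displacement)
  v_target <- 2 * mod$dc_nm * plan$dt
  expect_equal(var(as.numeric(ss)), v_target, tolerance = 0.1)
  expect_lt(abs(mean(ss)), 3 * sqrt(v_target / length(ss)))
  expect_equal(var(as.numeric(d)), v_target, tolerance = 0.01)
  # zero time step: no motion
  p0 <- plan
  p0$dt <- 0
  st <- sample_step(p0, mod)
  expect_equal(st$displacement, c(0, 0, 0))
  expect_equal(st$rotation, c(1, 0, 0, 0))
})

test_that("free-diffusion MSD follows the Einstein relation", {
  mod <- fx("model_pocket")
  dt <- 1e-9
  msd <- mtarrival:::cpp_free_msd(4000L, 60L, dt, mod$dc_nm, 77)
  t <- (1:60) * dt
  rel <- msd / (6 * mod$dc_nm * t)
  expect_lt(max(abs(rel - 1)), 0.03)
})

test_that("rotational decorrelation decays as exp(-2 Dc_rot t)", {
  mod <- fx("model_pocket")
  dt <- 2e-10
  ac <- mtarrival:::cpp_rot_autocorr(4000L, 50L, dt, mod$dc_rot, 78)
  t <- (1:50) * dt
  expect_lt(max(abs(ac / exp(-2 * mod$dc_rot * t) - 1)), 0.05)
})

test_that("hitting probability matches the absorbing-sphere closed form", {
  mod <- fx("model_pocket")
  a <- 20; r0 <- 500; R <- 2000
  p_true <- (1 / r0 - 1 / R) / (1 / a - 1 / R)
  n <- 6000L
  hits <- mtarrival:::cpp_sphere_hitting(n, a, r0, R, mod$dc_nm, 79)
  expect_equal(hits[1] + hits[2], n)
  p_hat <- hits[1] / n
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 2 * se + 1e-12)
})

test_that("attempt_move never returns a penetrating pose", {
  mt <- fx("mt_small")
  b <- fx("binder_pocket"); mod <- fx("model_pocket")
  ma <- mtarrival:::.mt_arrays(mt, fx("tubulin"))
  set.seed(30)
  # wedge the molecule right against a dimer face and push into it
  i <- 20
  n <- quat_to_matrix(mt$poses[[i]])[, 3]
  start <- mt$poses[[i]]$position +
    n * (mt$constants$dimer_radial / 2 + effective_radius(b) + 0.35)
  st <- molecule_state(pose(start, random_quaternion(1)[1, ]))
  d0 <- mtarrival:::cpp_scene_distance(ma$V, ma$R, ma$t, b$vertices,
                                       quat_to_matrix(st$pose),
                                       st$pose$position)
  expect_gt(d0$distance, 0)
  plan <- plan_timestep(max(d0$distance, 0.05), mod)
  for (k in 1:25) {
    st <- attempt_move(st, mt, b, mod, plan)
    d <- mtarrival:::cpp_scene_distance(ma$V, ma$R, ma$t, b$vertices,
                                        quat_to_matrix(st$pose),
                                        st$pose$position)
    expect_gt(d$distance, 0)
  }
  expect_equal(st$steps_taken, 25L)
})

test_that("check_arrival is stereospecific", {
  sites <- fx("sites_blunt")
  b <- fx("binder_pocket")
  df <- as.data.frame(sites)
  i4 <- which(df$k == 4 & !df$seam)[25]
  st <- sites[[i4]]
  mp <- mated_pose(st, b)
  expect_equal(check_arrival(mp, sites, b), st$id)
  # rotate 180 degrees about the outward normal: anchors no longer match
  flip <- quat_from_rotvec(pi * st$site_normal)
  mp180 <- pose(mp$position, quat_multiply(flip, mp$quaternion))
  expect_null(check_arrival(mp180, sites, b))
  # far away: no arrival
  expect_null(check_arrival(pose(c(500, 0, 0)), sites, b))
})

test_that("single-anchor sites cannot be bound upside down", {
  sites <- fx("sites_single")
  b <- fx("binder_pocket")
  st <- sites[[1]]
  mp <- mated_pose(st, b)
  expect_equal(check_arrival(mp, sites, b), 1L)
  # flip the binder so its binding face points away: anchor can coincide
  # but the orientation rule must reject it
  flip <- quat_from_rotvec(pi * st$frame[, 1])
  ctr_anchor <- b$anchors$iface_ll
  Rf <- quat_to_matrix(quat_multiply(flip, mp$quaternion))
  posf <- as.numeric(st$interface_centers[1, ] - Rf %*% ctr_anchor)
  mpf <- pose(posf, quat_multiply(flip, mp$quaternion))
  # anchor distance is zero by construction, yet no arrival
  awf <- transform_points(mpf, rbind(ctr_anchor))
  expect_lt(sqrt(sum((awf - st$interface_centers[1, ])^2)), 1e-9)
  expect_null(check_arrival(mpf, sites, b))
})

test_that("pose-sampling acceptance is higher at k=2 than k=4 sites", {
  set.seed(31)
  sites <- fx("sites_blunt")
  b <- fx("binder_pocket")
  df <- as.data.frame(sites)
  acc <- function(st, n = 40000) {
    A <- pocket_anchor_matrix(b, st$roles)
    ctr <- st$site_center + 2.1 * st$site_normal
    hits <- 0
    for (j in seq_len(n)) {
      R <- quat_to_matrix(random_quaternion(1)[1, ])
      p <- ctr + runif(3, -2, 2)
      aw <- t(R %*% t(A)) + rep(p, each = nrow(A))
      if (all(sqrt(rowSums((aw - st$interface_centers)^2)) <= 1))
        hits <- hits + 1
    }
    hits / n
  }
  a2 <- acc(sites[[which(df$k == 2)[2]]])
  a4 <- acc(sites[[which(df$k == 4 & !df$seam)[30]]])
  expect_gt(a2, a4)
})

test_that("trajectories are deterministic and streams are mergeable", {
  mt <- fx("mt_single")
  sites <- fx("sites_single")
  b <- fx("binder_pocket"); mod <- fx("model_pocket")
  cfg <- simulation_config(seed = 5, max_steps = 1e6)
  t1 <- run_ensemble(mt, sites, b, mod, cfg, n_molecules = 40,
                     replicates = 1:2)
  t2 <- run_ensemble(mt, sites, b, mod, cfg, n_molecules = 40,
                     replicates = 1:2)
  expect_identical(t1$status, t2$status)
  expect_identical(t1$n_steps, t2$n_steps)
  # disjoint replicate ranges merge to the same table as one call
  ta <- run_ensemble(mt, sites, b, mod, cfg, n_molecules = 40,
                     replicates = 1L)
  tb <- run_ensemble(mt, sites, b, mod, cfg, n_molecules = 40,
                     replicates = 2L)
  merged <- rbind(ta, tb)
  expect_equal(merged$status, t1$status)
  expect_equal(merged$n_steps, t1$n_steps)
  # outcome bookkeeping is complete
  expect_equal(sum(t1$status %in% c("arrived", "escaped", "censored")),
               nrow(t1))
})

test_that("escape radius equal to start radius escapes immediately", {
  mt <- fx("mt_single")
  sites <- fx("sites_single")
  b <- fx("binder_pocket"); mod <- fx("model_pocket")
  cfg <- simulation_config(start_radius = 500, escape_radius = 500, seed = 6)
  tab <- run_ensemble(mt, sites, b, mod, cfg, n_molecules = 20)
  expect_true(all(tab$status == "escaped"))
  expect_true(all(tab$n_steps == 0))
})

test_that("no interpenetration over a debug-mode ensemble", {
  mt <- fx("mt_small")
  sites <- enumerate_sites(mt, "pocket")
  b <- fx("binder_pocket"); mod <- fx("model_pocket")
  cfg <- simulation_config(seed = 7, max_steps = 2e5, debug_check = TRUE)
  tab <- run_ensemble(mt, sites, b, mod, cfg, n_molecules = 60)
  expect_gte(attr(tab, "min_separation"), 0)
})

test_that("per-replicate arrival counts are binomially dispersed", {
  mt <- fx("mt_single")
  sites <- fx("sites_single")
  b <- fx("binder_pocket"); mod <- fx("model_pocket")
  cfg <- simulation_config(seed = 8, max_steps = 1e6)
  tab <- run_ensemble(mt, sites, b, mod, cfg, n_molecules = 400,
                      replicates = 1:10)
  counts <- tapply(tab$status == "arrived", tab$replicate, sum)
  expect_gt(sum(counts), 0)
  # index of dispersion test against binomial sampling
  n <- 400
  p <- mean(counts) / n
  disp <- var(counts) / (n * p * (1 - p))
  # chi-square bounds for 9 degrees of freedom at alpha = 0.01
  expect_gt(disp, qchisq(0.005, 9) / 9)
  expect_lt(disp, qchisq(0.995, 9) / 9)
})
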