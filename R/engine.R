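#' Stokes-Einstein diffusion coefficients
#'
#' Translational coefficient \eqn{D_c = k_B T / (6 \pi \rho r)} and
#' rotational coefficient \eqn{D_{rot} = k_B T / (8 \pi \rho r^3)} for a
#' sphere of effective radius \code{r}.
#'
#' @param r Molecule effective radius, m.
#' @param temperature Temperature, K.
#' @param viscosity Solvent viscosity, Pa s.
#' @return List with \code{dc} (m^2/s) and \code{dc_rot} (rad^2/s).
#' @export
diffusion_coefficients <- function(r, temperature = 298,
                                   viscosity = 8.9e-4) {
  stopifnot(r > 0, temperature > 0, viscosity > 0)
  list(dc = .kB * temperature / (6 * pi * viscosity * r),
       dc_rot = .kB * temperature / (8 * pi * viscosity * r^3))
}

#' Physical model of the diffusing molecule
#'
#' Bundles the physical constants of the simulation: temperature, water
#' viscosity, the binder's effective radius (mean vertex radius of its
#' shape) and the derived Stokes-Einstein coefficients.
#'
#' @param binder The binder \code{convex_shape} (sets the radius), or NULL
#'   to pass \code{radius_nm} directly.
#' @param radius_nm Effective radius in nm (used when \code{binder} is
#'   NULL).
#' @param temperature Temperature, K.
#' @param viscosity Viscosity, Pa s.
#' @return An object of class \code{"diffusion_model"} with fields
#'   \code{r} (m), \code{dc}, \code{dc_rot}, \code{dc_nm} (nm^2/s),
#'   \code{temperature}, \code{viscosity}, \code{dimensionality}.
#' @export
diffusion_model <- function(binder = NULL, radius_nm = NULL,
                            temperature = 298, viscosity = 8.9e-4) {
  if (is.null(radius_nm)) {
    if (is.null(binder)) binder <- build_binder_shape("pocket")
    radius_nm <- effective_radius(binder)
  }
  r <- radius_nm * 1e-9
  co <- diffusion_coefficients(r, temperature, viscosity)
  structure(list(r = r, radius_nm = radius_nm,
                 temperature = temperature, viscosity = viscosity,
                 dc = co$dc, dc_rot = co$dc_rot,
                 dc_nm = co$dc * 1e18, dimensionality = 3L),
            class = "diffusion_model")
}

#' Dynamic time-step plan
#'
#' The time step follows \eqn{\langle\Delta x^2\rangle = 2 d D_c \Delta t}
#' with a target step length set by the current separation \code{dist}
#' between the molecule and the microtubule: \code{dist/5} when at least
#' 100 nm away, \code{dist/20} when within 1 nm, with the divisor
#' interpolating linearly in between.  Within the binding distance of a
#' site centre a fixed time step giving a typical 0.05 nm displacement is
#' used instead.
#'
#' @param dist Current closest separation, nm (>= 0).
#' @param model A \code{diffusion_model}.
#' @param near_binding_site Logical; molecule within the binding distance
#'   of a site centre.
#' @return List of class \code{"step_plan"}: \code{dist}, \code{dx} (nm),
#'   \code{dt} (s), \code{regime}.
#' @export
plan_timestep <- function(dist, model, near_binding_site = FALSE) {
  stopifnot(dist >= 0)
  if (near_binding_site) {
    dx <- 0.05
    regime <- "near-site"
  } else {
    divisor <- if (dist >= 100) 5
               else if (dist <= 1) 20
               else 20 - 15 * (dist - 1) / 99
    dx <- max(dist / divisor, 1e-6)
    regime <- if (dist >= 100) "far" else "scaled"
  }
  dt <- dx^2 / (2 * model$dimensionality * model$dc_nm)
  structure(list(dist = dist, dx = dx, dt = dt, regime = regime),
            class = "step_plan")
}

#' Sample one Brownian step
#'
#' Each translational component is Normal(0, 2 Dc dt) and each body-axis
#' rotation angle Normal(0, 2 Dc_rot dt).  Uses R's RNG, so it is
#' deterministic under \code{set.seed}.
#'
#' @param plan A \code{step_plan}.
#' @param model A \code{diffusion_model}.
#' @return List with \code{displacement} (nm 3-vector), \code{rotvec}
#'   (radians 3-vector) and \code{rotation} (unit quaternion).
#' @export
sample_step <- function(plan, model) {
  sig_t <- sqrt(2 * model$dc_nm * plan$dt)
  sig_r <- sqrt(2 * model$dc_rot * plan$dt)
  d <- stats::rnorm(3, 0, sig_t)
  rv <- stats::rnorm(3, 0, sig_r)
  list(displacement = d, rotvec = rv, rotation = quat_from_rotvec(rv))
}

#' Simulation configuration
#'
#' @param start_radius Start-sphere radius, nm.
#' @param escape_radius Outer absorbing radius, nm.
#' @param binding_distance Arrival tolerance per anchor pair, nm.
#' @param seed Master seed; one independent RNG stream is derived per
#'   (replicate, molecule).
#' @param max_steps Step cap per molecule; exhaustion is recorded as a
#'   censored outcome, never dropped.
#' @param retry_cap Collision retries at constant step before the time
#'   step is halved.
#' @param debug_check Assert a positive separation after every accepted
#'   move and record the minimum separation seen.
#' @return List of class \code{"simulation_config"}.
#' @export
simulation_config <- function(start_radius = 500, escape_radius = 2000,
                              binding_distance = 1, seed = 1,
                              max_steps = 1e8, retry_cap = 100,
                              debug_check = FALSE) {
  stopifnot(escape_radius >= start_radius, binding_distance > 0)
  structure(list(start_radius = start_radius,
                 escape_radius = escape_radius,
                 binding_distance = binding_distance, seed = seed,
                 max_steps = max_steps, retry_cap = retry_cap,
                 near_step_nm = 0.05,
                 debug_check = debug_check),
            class = "simulation_config")
}

# flatten a binding_site_list for the compiled engine
.site_arrays <- function(sites, binder) {
  mode <- attr(sites, "mode")
  if (mode == "pocket") {
    anames <- c("iface_ll", "iface_ul", "iface_lr", "iface_ur")
    role_of <- c(ll = 1L, ul = 2L, lr = 3L, ur = 4L)
  } else {
    anames <- "iface"
    role_of <- c(face = 1L)
  }
  anchors <- t(vapply(anames, function(a) binder$anchors[[a]], numeric(3)))
  n <- length(sites)
  k <- vapply(sites, `[[`, integer(1), "k")
  aidx <- matrix(-1L, n, 4)
  iface <- matrix(0, n, 12)
  ctr <- matrix(0, n, 3)
  nrm <- matrix(0, n, 3)
  rule <- integer(n)
  for (i in seq_len(n)) {
    s <- sites[[i]]
    for (j in seq_along(s$roles)) {
      aidx[i, j] <- role_of[[s$roles[j]]] - 1L
      iface[i, (3 * j - 2):(3 * j)] <- s$interface_centers[j, ]
    }
    ctr[i, ] <- s$site_center
    nrm[i, ] <- s$site_normal
    rule[i] <- as.integer(s$mode == "face" || s$k == 1L)
  }
  list(anchors = anchors, k = as.integer(k), aidx = aidx, iface = iface,
       center = ctr, normal = nrm, rule = rule,
       binding_normal = binder$anchor_normals$binding)
}

.mt_arrays <- function(mt, dimer_shape) {
  R <- t(vapply(mt$poses, function(p) as.numeric(t(quat_to_matrix(p))),
                numeric(9)))
  list(V = dimer_shape$vertices, R = R, t = mt$centers)
}

#' Run an ensemble of diffusion-to-capture trajectories
#'
#' Each molecule starts at a uniformly random point on the start sphere
#' (centred on the model centroid) with uniformly random orientation, and
#' diffuses with the dynamic time step until it either escapes beyond the
#' escape radius, arrives (all anchor pairs of some binding site
#' simultaneously within the binding distance, with the orientation rule
#' for single-anchor sites), or exhausts the step cap (censored).  Each
#' (replicate, molecule) pair has its own RNG stream derived from the
#' master seed, so results are independent of execution order and
#' ensembles with disjoint replicate sets can be merged.
#'
#' @param mt A \code{microtubule_model}.
#' @param sites A \code{binding_site_list} from \code{enumerate_sites}.
#' @param binder Binder \code{convex_shape} matching the site mode.
#' @param model A \code{diffusion_model}.
#' @param config A \code{simulation_config}.
#' @param n_molecules Molecules per replicate.
#' @param replicates Integer vector of replicate ids.
#' @param dimer_shape Dimer \code{convex_shape}.
#' @return An arrival table (class \code{"arrival_table"}): data.frame
#'   with columns replicate, molecule, status
#'   (arrived/escaped/censored), site_id, site_class, k, n_steps.
#'   Attributes: \code{sites} summary, \code{config}, \code{provenance}.
#' @export
run_ensemble <- function(mt, sites, binder, model, config,
                         n_molecules = 1000L, replicates = 1L,
                         dimer_shape = build_tubulin_shape(mt$constants)) {
  sa <- .site_arrays(sites, binder)
  ma <- .mt_arrays(mt, dimer_shape)
  cfg <- list(start_radius = config$start_radius,
              escape_radius = config$escape_radius,
              binding_distance = config$binding_distance,
              dc_nm = model$dc_nm, dc_rot = model$dc_rot,
              near_step_nm = config$near_step_nm,
              max_steps = config$max_steps, retry_cap = config$retry_cap,
              seed = as.double(config$seed),
              n_molecules = as.integer(n_molecules),
              replicates = as.integer(replicates),
              debug_check = isTRUE(config$debug_check))
  res <- cpp_run_ensemble(ma$V, ma$R, ma$t, binder$vertices,
                          sa$anchors, sa$binding_normal,
                          sa$k, sa$aidx, sa$iface, sa$center, sa$normal,
                          sa$rule, mt$centroid, cfg)
  status <- c("free", "arrived", "escaped", "censored")[res$status + 1L]
  site_id <- res$site
  cls <- vapply(sites, `[[`, character(1), "classification")
  kk <- vapply(sites, `[[`, integer(1), "k")
  tab <- data.frame(
    replicate = res$replicate, molecule = res$molecule, status = status,
    site_id = site_id,
    site_class = ifelse(is.na(site_id), NA_character_, cls[site_id]),
    k = ifelse(is.na(site_id), NA_integer_, kk[site_id]),
    n_steps = res$n_steps, stringsAsFactors = FALSE)
  structure(tab, class = c("arrival_table", "data.frame"),
            sites = as.data.frame(sites), config = config,
            model = model[c("radius_nm", "temperature", "viscosity")],
            geometry = mt$config,
            min_separation = res$min_separation)
}

#' Run a single trajectory
#'
#' Convenience wrapper over \code{\link{run_ensemble}} with one molecule.
#'
#' @inheritParams run_ensemble
#' @param molecule Molecule index within the replicate (selects the RNG
#'   stream).
#' @param replicate Replicate id.
#' @return One-row arrival table.
#' @export
run_trajectory <- function(mt, sites, binder, model, config,
                           replicate = 1L, molecule = 1L) {
  # streams are indexed from 0 by molecule order; shift so that the
  # requested molecule's stream is used
  tab <- run_ensemble(mt, sites, binder, model, config,
                      n_molecules = molecule, replicates = replicate)
  tab[molecule, , drop = FALSE]
}

#' One Brownian move with collision rejection (reference implementation)
#'
#' Proposes a translation + rotation from \code{plan}; if the proposed
#' pose overlaps any dimer the move is rejected and resampled with the
#' same time step, halving the time step after \code{retry_cap} failures.
#' The returned pose never penetrates the lattice.  This R-level routine
#' mirrors the compiled trajectory engine step-for-step and is used for
#' validation; ensembles should use \code{\link{run_ensemble}}.
#'
#' @param state List with \code{pose} (an \code{mt_pose}) and
#'   \code{status} (\code{"free"}); see \code{\link{molecule_state}}.
#' @param mt A \code{microtubule_model}.
#' @param binder Binder shape.
#' @param model A \code{diffusion_model}.
#' @param plan A \code{step_plan}.
#' @param retry_cap Retries before step halving.
#' @param dimer_shape Dimer shape.
#' @return Updated state; \code{steps_taken} incremented, pose replaced
#'   by a collision-free pose.
#' @export
attempt_move <- function(state, mt, binder, model, plan, retry_cap = 100,
                         dimer_shape = build_tubulin_shape(mt$constants)) {
  stopifnot(state$status == "free")
  ma <- .mt_arrays(mt, dimer_shape)
  scale <- 1
  attempts <- 0
  repeat {
    st <- sample_step(plan, model)
    q_new <- quat_multiply(quat_from_rotvec(st$rotvec * scale),
                           state$pose$quaternion)
    p_new <- pose(state$pose$position + st$displacement * scale, q_new)
    d <- cpp_scene_distance(ma$V, ma$R, ma$t, binder$vertices,
                            quat_to_matrix(p_new), p_new$position)
    if (d$distance > 0) {
      state$pose <- p_new
      state$steps_taken <- (state$steps_taken %||% 0L) + 1L
      state$attempts <- attempts
      return(state)
    }
    attempts <- attempts + 1
    if (attempts %% retry_cap == 0) scale <- scale / sqrt(2)
    if (attempts > 100 * retry_cap)
      stop("attempt_move: no collision-free proposal found (geometry bug?)")
  }
}

#' Molecule state
#'
#' @param pose An \code{mt_pose}.
#' @param status One of \code{"free"}, \code{"arrived"}, \code{"escaped"},
#'   \code{"censored"}.  Transitions out of \code{"free"} are terminal.
#' @return A list of class \code{"molecule_state"}.
#' @export
molecule_state <- function(pose, status = "free") {
  structure(list(pose = pose, status = status, arrival_site = NULL,
                 steps_taken = 0L), class = "molecule_state")
}

#' Stereospecific arrival test (reference implementation)
#'
#' Returns the id of a site whose anchor pairs are all simultaneously
#' within the binding distance of the binder's corresponding interface
#' anchors, or NULL.  Single-anchor sites (isolated dimers, face sites)
#' additionally require the binder's binding normal to oppose the site
#' normal, so that the molecule cannot bind "upside down".
#'
#' @param pose Binder \code{mt_pose}.
#' @param sites A \code{binding_site_list}.
#' @param binder Binder shape matching the site mode.
#' @param config A \code{simulation_config} (uses
#'   \code{binding_distance}).
#' @return Site id (integer) or NULL.
#' @export
check_arrival <- function(pose, sites, binder, config = simulation_config()) {
  sa <- .site_arrays(sites, binder)
  aw <- transform_points(pose, sa$anchors)
  wn <- as.numeric(quat_to_matrix(pose) %*% sa$binding_normal)
  bd <- config$binding_distance
  for (i in seq_along(sites)) {
    ok <- TRUE
    for (j in 1:4) {
      ai <- sa$aidx[i, j]
      if (ai < 0) next
      if (sqrt(sum((aw[ai + 1, ] - sa$iface[i, (3 * j - 2):(3 * j)])^2)) > bd) {
        ok <- FALSE; break
      }
    }
    if (ok && sa$rule[i] == 1L && sum(wn * sa$normal[i, ]) >= 0) ok <- FALSE
    if (ok) return(sites[[i]]$id)
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
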