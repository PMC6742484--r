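#' Pose of a dimer at a lattice position
#'
#' Places a dimer on the canonical 13-protofilament B-lattice: protofilament
#' \code{p} sits at angle \code{p * 2*pi/13} around the microtubule axis
#' (world z), offset axially by the 3-start helical rise; layer \code{l}
#' advances one 8 nm dimer repeat.  The dimer body frame maps x to the
#' axial direction, z to the outward radial and y tangentially.
#'
#' @param p Protofilament index (0-based).
#' @param l Layer index (0-based).
#' @param constants Constant set.
#' @return An \code{mt_pose}.
#' @export
dimer_lattice_pose <- function(p, l, constants = mt_constants()) {
  th <- 2 * pi * p / constants$n_protofilaments
  ctr <- c(constants$lattice_radius * cos(th),
           constants$lattice_radius * sin(th),
           constants$axial_repeat * l + constants$helical_rise * p)
  R <- cbind(c(0, 0, 1),                      # body x -> axial
             c(sin(th), -cos(th), 0),         # body y -> tangential
             c(cos(th), sin(th), 0))          # body z -> radial (outward)
  pose_from_matrix(ctr, R)
}

#' Default monotone taper profile
#'
#' Protofilament lengths forming a monotone ramp of width 13 layers that
#' sums to \code{n_dimers}, used for the tapered ("disrupted-structure")
#' configuration.
#'
#' @param n_dimers Total dimer count.
#' @return Integer vector of 13 protofilament lengths.
#' @export
default_taper_profile <- function(n_dimers = 207L) {
  npf <- 13L
  base <- n_dimers %/% npf
  len <- base + seq(-6L, 6L)
  if (any(len < 1L)) stop("n_dimers too small for the default taper profile")
  rem <- n_dimers - sum(len)
  if (rem > 0) {
    idx <- (npf - rem + 1L):npf
    len[idx] <- len[idx] + 1L
  } else if (rem < 0) {
    idx <- 1L:(-rem)
    len[idx] <- len[idx] - 1L
  }
  as.integer(len)
}

#' Build a microtubule model
#'
#' Places tubulin dimers on the canonical lattice (13 protofilaments,
#' B-lattice, one seam, 8 nm axial repeat, 12/13 nm helical rise, 12.5 nm
#' radius to dimer centres) in one of four configurations:
#' \describe{
#'   \item{blunt}{All protofilaments as equal as possible (lengths differ
#'     by at most one when \code{n_dimers} is not divisible by 13); the
#'     "closed" condition.}
#'   \item{tapered}{A monotone protofilament-length ramp with the same
#'     total dimer count; the "disrupted-structure" condition.}
#'   \item{sheet}{An open sheet: same cylindrical placement but no lateral
#'     bond between the first and last protofilament, exposing two lateral
#'     edges.}
#'   \item{single_dimer}{One isolated dimer at the origin.}
#' }
#'
#' @param config Configuration tag.
#' @param n_dimers Total dimer count (default 207, giving an average
#'   protofilament length of ~16 dimers).
#' @param taper_profile Optional integer vector of 13 protofilament
#'   lengths; must sum to \code{n_dimers}.
#' @param constants Constant set.
#' @return An object of class \code{"microtubule_model"}.
#' @export
build_microtubule <- function(config = c("blunt", "tapered", "sheet",
                                         "single_dimer"),
                              n_dimers = 207L, taper_profile = NULL,
                              constants = mt_constants()) {
  config <- match.arg(config)
  npf <- constants$n_protofilaments
  if (config == "single_dimer") {
    placements <- data.frame(protofilament = 0L, layer = 0L)
    poses <- list(pose())
    pf_lengths <- c(1L, rep(0L, npf - 1L))
  } else {
    if (n_dimers < 1L) stop("n_dimers must be >= 1")
    if (config == "tapered") {
      pf_lengths <- if (is.null(taper_profile)) default_taper_profile(n_dimers)
                    else as.integer(taper_profile)
      if (length(pf_lengths) != npf || sum(pf_lengths) != n_dimers)
        stop("taper profile lengths must be 13 values summing to n_dimers")
    } else {
      base <- n_dimers %/% npf
      extra <- n_dimers %% npf
      # balanced split: `extra` protofilaments get one extra layer
      pf_lengths <- as.integer(rep(base, npf) + c(rep(1L, extra),
                                                  rep(0L, npf - extra)))
    }
    placements <- do.call(rbind, lapply(seq_len(npf) - 1L, function(p) {
      if (pf_lengths[p + 1L] == 0L) return(NULL)
      data.frame(protofilament = p, layer = seq_len(pf_lengths[p + 1L]) - 1L)
    }))
    rownames(placements) <- NULL
    poses <- lapply(seq_len(nrow(placements)), function(i)
      dimer_lattice_pose(placements$protofilament[i], placements$layer[i],
                         constants))
  }
  centers <- t(vapply(poses, function(p) p$position, numeric(3)))
  model <- structure(list(
    config = config,
    n_dimers = nrow(placements),
    placements = placements,
    poses = poses,
    centers = centers,
    pf_lengths = pf_lengths,
    centroid = colMeans(centers),
    axis_origin = c(0, 0, 0),
    axis_dir = c(0, 0, 1),
    constants = constants
  ), class = "microtubule_model")
  model
}

#' @export
print.microtubule_model <- function(x, ...) {
  cat(sprintf("<microtubule_model: %s, %d dimers, protofilament lengths %s>\n",
              x$config, x$n_dimers, paste(x$pf_lengths, collapse = "/")))
  invisible(x)
}

# is dimer (p, l) present; returns its row index or NA
.placement_index <- function(mt, p, l) {
  hit <- which(mt$placements$protofilament == p & mt$placements$layer == l)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Enumerate and classify binding sites
#'
#' Pocket mode enumerates one candidate site per inter-protofilament,
#' inter-layer pocket position.  Each site records the dimers actually
#' present among the four that would surround a complete pocket (roles
#' \code{ll, ul, lr, ur} = lower/upper layer of the left/right
#' protofilament), their contact-anchor positions (the interface centres),
#' the site centre (mean of the interface centres) and the outward normal.
#' Classification follows the adjacent-dimer count k: k = 2 sites are
#' "edge" sites (protofilament ends and exposed lateral edges), k = 4
#' sites are "lattice" sites, and k = 1 or 3 sites are tagged "excluded"
#' (they exist, can receive arrivals, but are left out of the edge/lattice
#' comparison).  Face mode returns exactly one site per dimer, centred on
#' its outward face.
#'
#' Sites at the seam junction (between the last and first protofilament,
#' where the 3-start helix leaves a ~4 nm lateral mismatch) are flagged
#' \code{seam = TRUE} and can be dropped with \code{include_seam = FALSE}.
#'
#' @param mt A \code{microtubule_model}.
#' @param mode \code{"pocket"} or \code{"face"}.
#' @param include_seam Keep sites at the seam junction (default TRUE).
#' @return A list of class \code{"binding_site_list"}; each element has
#'   fields \code{id, mode, k, classification, roles, dimers,
#'   interface_centers, site_center, site_normal, frame, seam}.
#' @export
enumerate_sites <- function(mt, mode = c("pocket", "face"),
                            include_seam = TRUE) {
  mode <- match.arg(mode)
  cst <- mt$constants
  if (mode == "face") {
    sites <- lapply(seq_len(mt$n_dimers), function(i) {
      ps <- mt$poses[[i]]
      R <- quat_to_matrix(ps)
      ctr <- as.numeric(transform_points(ps, build_tubulin_anchor("face", cst)))
      list(id = i, mode = "face", k = 1L, classification = "face",
           roles = "face", dimers = i,
           interface_centers = rbind(ctr), site_center = ctr,
           site_normal = as.numeric(R[, 3]),
           frame = cbind(R[, 1], R[, 2], R[, 3]), seam = FALSE)
    })
    return(structure(sites, class = "binding_site_list", mode = "face"))
  }

  if (mt$config == "single_dimer") {
    ps <- mt$poses[[1L]]
    R <- quat_to_matrix(ps)
    ctr <- as.numeric(transform_points(ps, build_tubulin_anchor("corner_pm",
                                                                cst)))
    site <- list(id = 1L, mode = "pocket", k = 1L, classification = "excluded",
                 roles = "ll", dimers = 1L,
                 interface_centers = rbind(ctr), site_center = ctr,
                 site_normal = as.numeric(R[, 3]),
                 frame = cbind(R[, 1], R[, 2], R[, 3]), seam = FALSE)
    return(structure(list(site), class = "binding_site_list", mode = "pocket"))
  }

  npf <- cst$n_protofilaments
  closed <- mt$config != "sheet"
  junctions <- if (closed) {
    lapply(seq_len(npf) - 1L, function(j)
      list(pL = j, pR = (j + 1L) %% npf, open = NA_character_))
  } else {
    c(list(list(pL = NA_integer_, pR = 0L, open = "left")),
      lapply(seq_len(npf - 1L) - 1L, function(j)
        list(pL = j, pR = j + 1L, open = NA_character_)),
      list(list(pL = npf - 1L, pR = NA_integer_, open = "right")))
  }
  role_anchor <- c(ll = "corner_pm", ul = "corner_mm",
                   lr = "corner_pp", ur = "corner_mp")
  sites <- list()
  sid <- 0L
  for (jn in junctions) {
    pL <- jn$pL; pR <- jn$pR
    # layer offset of the right protofilament relative to the left (non-zero
    # only across the seam, where the helix start mismatch is ~1.5 layers)
    zoffL <- if (!is.na(pL)) cst$helical_rise * pL else 0
    zoffR <- if (!is.na(pR)) cst$helical_rise * pR else 0
    shift <- if (!is.na(pL) && !is.na(pR))
      as.integer(round((zoffL - zoffR) / cst$axial_repeat)) else 0L
    is_seam <- closed && !is.na(pL) && pL == npf - 1L
    lmax <- max(mt$placements$layer)
    for (l in seq(-1L - abs(shift), lmax + abs(shift))) {
      cand <- list(
        ll = if (!is.na(pL)) c(pL, l) else NULL,
        ul = if (!is.na(pL)) c(pL, l + 1L) else NULL,
        lr = if (!is.na(pR)) c(pR, l + shift) else NULL,
        ur = if (!is.na(pR)) c(pR, l + 1L + shift) else NULL)
      roles <- character(0); dimers <- integer(0)
      for (rl in names(cand)) {
        pc <- cand[[rl]]
        if (is.null(pc)) next
        idx <- .placement_index(mt, pc[1], pc[2])
        if (!is.na(idx)) { roles <- c(roles, rl); dimers <- c(dimers, idx) }
      }
      k <- length(roles)
      if (k == 0L) next
      if (is_seam && !include_seam) next
      centers <- t(vapply(seq_along(roles), function(i) {
        as.numeric(transform_points(mt$poses[[dimers[i]]],
                                    build_tubulin_anchor(role_anchor[roles[i]],
                                                         cst)))
      }, numeric(3)))
      ctr <- colMeans(centers)
      fr <- site_frame(ctr, mt$axis_origin %||% c(0, 0, 0),
                       mt$axis_dir %||% c(0, 0, 1))
      sid <- sid + 1L
      sites[[sid]] <- list(
        id = sid, mode = "pocket", k = k, layer = l,
        junction = if (!is.na(pL)) pL else -1L,
        classification = if (k == 2L) "edge" else if (k == 4L) "lattice"
                         else "excluded",
        roles = roles, dimers = dimers,
        interface_centers = centers, site_center = ctr,
        site_normal = as.numeric(fr[, 3]), frame = fr, seam = is_seam)
    }
  }
  structure(sites, class = "binding_site_list", mode = "pocket")
}

#' @export
print.binding_site_list <- function(x, ...) {
  k <- vapply(x, `[[`, integer(1), "k")
  cat(sprintf("<binding_site_list: %d sites (%s mode); k counts: %s>\n",
              length(x), attr(x, "mode"),
              paste(sprintf("k=%d:%d", sort(unique(k)),
                            as.integer(table(k))), collapse = ", ")))
  invisible(x)
}

#' Summarise a binding-site list as a data frame
#' @param x A \code{binding_site_list}.
#' @param ... Unused.
#' @return data.frame with one row per site.
#' @export
as.data.frame.binding_site_list <- function(x, ...) {
  do.call(rbind, lapply(x, function(s) data.frame(
    id = s$id, mode = s$mode, k = s$k, classification = s$classification,
    layer = if (is.null(s$layer)) NA_integer_ else s$layer,
    junction = if (is.null(s$junction)) NA_integer_ else s$junction,
    x = s$site_center[1], y = s$site_center[2], z = s$site_center[3],
    seam = s$seam)))
}

#' Mated pose of the binder at a site
#'
#' The rigid pose that registers the binder's interface anchors with the
#' site's interface centres: a least-squares (Kabsch) alignment of the
#' corresponding anchor sets, using the site frame to resolve the
#' remaining degrees of freedom when fewer than three anchor pairs exist.
#' At a complete interior pocket the anchor patterns are congruent and all
#' four anchor-pair distances vanish.
#'
#' @param site One element of a \code{binding_site_list}.
#' @param binder The binder \code{convex_shape}.
#' @return An \code{mt_pose}.
#' @export
mated_pose <- function(site, binder) {
  fr <- site$frame
  drop <- -binder$anchors[[1]][3]  # anchor drop below the body origin
  if (site$mode == "face") {
    ctr <- site$site_center
  } else {
    # ideal pose from the site frame: binder z axis along the outward
    # normal, x along the microtubule axis
    role_anchor_names <- c(ll = "iface_ll", ul = "iface_ul",
                           lr = "iface_lr", ur = "iface_ur")
    anchors_body <- t(vapply(site$roles, function(rl)
      binder$anchors[[role_anchor_names[rl]]], numeric(3)))
    if (site$k >= 3L) {
      fit <- kabsch(anchors_body, site$interface_centers)
      return(pose_from_matrix(fit$translation, fit$rotation))
    }
    ctr <- site$site_center
    # for k < 3, place via the frame then translate so that the first
    # anchor pair coincides
    ps0 <- pose_from_matrix(ctr + fr[, 3] * drop, fr)
    w <- transform_points(ps0, anchors_body)
    off <- colMeans(site$interface_centers) - colMeans(rbind(w))
    return(pose_from_matrix(ps0$position + off, fr))
  }
  pose_from_matrix(ctr + fr[, 3] * drop, fr)
}


#' Apply a rigid transform to a whole model
#'
#' Rotates and translates every dimer pose, the centroid and the model
#' axis; site enumeration on the transformed model yields identically
#' transformed site centres and normals (equivariance).
#'
#' @param mt A \code{microtubule_model}.
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector, nm.
#' @return The transformed model.
#' @export
transform_model <- function(mt, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  q <- quat_from_matrix(rotation)
  mt$poses <- lapply(mt$poses, function(p)
    pose(as.numeric(rotation %*% p$position) + translation,
         quat_multiply(q, p$quaternion)))
  mt$centers <- t(vapply(mt$poses, function(p) p$position, numeric(3)))
  mt$centroid <- colMeans(mt$centers)
  mt$axis_origin <- as.numeric(rotation %*% (mt$axis_origin %||% c(0, 0, 0))) +
    translation
  mt$axis_dir <- as.numeric(rotation %*% (mt$axis_dir %||% c(0, 0, 1)))
  mt
}
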