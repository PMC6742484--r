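#' Closest distance between two posed convex shapes
#'
#' Exact convex-convex separation computed with a support-function (GJK)
#' method.  Returns the signed separation (negative means the solids
#' overlap; penetration depth is not computed -- any non-positive value is
#' a collision), the witness points realising the distance, and the
#' supporting vertex sets on each shape, from which the closest feature
#' type (vertex / edge / face) follows.
#'
#' @param shape_a,shape_b \code{convex_shape} objects.
#' @param pose_a,pose_b \code{mt_pose} objects.
#' @param warm_start Optional result of a previous call; its witness
#'   separation direction is used as the initial search direction.  The
#'   result does not depend on it.
#' @return A list of class \code{"closest_feature_pair"} with elements
#'   \code{distance} (nm), \code{point_a}, \code{point_b} (world nm),
#'   \code{feature_a}, \code{feature_b} (list: \code{type},
#'   \code{vertices}).
#' @export
closest_distance <- function(shape_a, pose_a, shape_b, pose_b,
                             warm_start = NULL) {
  validate_convex_shape(shape_a)
  validate_convex_shape(shape_b)
  dir0 <- c(0, 0, 0)
  if (!is.null(warm_start) && is.finite(warm_start$distance) &&
      warm_start$distance > 0)
    dir0 <- warm_start$point_a - warm_start$point_b
  res <- cpp_convex_distance(shape_a$vertices, quat_to_matrix(pose_a),
                             pose_a$position, shape_b$vertices,
                             quat_to_matrix(pose_b), pose_b$position, dir0)
  feat <- function(shape, ps, axis, tol = 1e-7) {
    # supporting vertex set along the separation axis
    w <- transform_points(ps, shape$vertices)
    pr <- as.numeric(w %*% axis)
    ids <- which(pr >= max(pr) - tol)
    type <- if (length(ids) == 1) "vertex" else if (length(ids) == 2) "edge"
            else "face"
    list(type = type, vertices = sort(ids))
  }
  if (res$distance > 0) {
    u <- (res$point_b - res$point_a) / res$distance
    fa <- feat(shape_a, pose_a, u)
    fb <- feat(shape_b, pose_b, -u)
  } else {
    fa <- fb <- list(type = "penetration", vertices = integer(0))
  }
  structure(list(
    distance = res$distance,
    point_a = res$point_a, point_b = res$point_b,
    feature_a = fa, feature_b = fb
  ), class = "closest_feature_pair")
}

#' Broad-phase index over the placed dimers
#'
#' A hierarchical binary tree of axis-aligned bounding boxes of the placed
#' dimers.  Queries return a superset of the dimers within a given closest
#' distance of the molecule.
#'
#' @param mt A \code{microtubule_model}.
#' @param shape The dimer \code{convex_shape} (defaults to
#'   \code{build_tubulin_shape()}).
#' @param margin Query margin, nm; defaults to the binder diameter + 1 nm.
#' @return An object of class \code{"broad_phase_index"}.
#' @export
broad_phase_index <- function(mt, shape = build_tubulin_shape(mt$constants),
                              margin = NULL) {
  if (is.null(margin))
    margin <- 2 * effective_radius(build_binder_shape("pocket",
                                                      mt$constants)) + 1
  boxes <- lapply(seq_len(mt$n_dimers), function(i) {
    v <- transform_points(mt$poses[[i]], shape$vertices)
    rbind(lo = apply(v, 2, min), hi = apply(v, 2, max))
  })
  lo <- t(vapply(boxes, function(b) b["lo", ], numeric(3)))
  hi <- t(vapply(boxes, function(b) b["hi", ], numeric(3)))
  structure(list(tree = cpp_aabb_tree(lo, hi), lo = lo, hi = hi,
                 margin = margin, n = mt$n_dimers),
            class = "broad_phase_index")
}

#' Broad-phase candidate dimers near a molecule pose
#'
#' Superset guarantee: the result contains every dimer whose true closest
#' distance to the molecule (any shape whose vertices lie within
#' \code{mol_radius} of the pose position) is at most \code{radius}.
#'
#' @param index A \code{broad_phase_index}.
#' @param pose Molecule \code{mt_pose}.
#' @param radius Query radius, nm.
#' @param mol_radius Bounding radius of the molecule, nm.
#' @return Integer vector of dimer indices (1-based).
#' @export
broad_phase_candidates <- function(index, pose, radius,
                                   mol_radius = index$margin) {
  r <- radius + mol_radius + index$margin
  p <- pose$position
  sort(cpp_aabb_query(index$tree, p - r, p + r))
}
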