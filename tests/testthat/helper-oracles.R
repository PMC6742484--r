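# Independent geometry oracles used by the tests.  These deliberately use
# different algorithms from the package internals: exhaustive feature-pair
# enumeration and dense surface sampling instead of support-function
# iteration, and separating-axis tests instead of simplex containment.

seg_seg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-300 && e <= 1e-300) return(sqrt(sum(r * r)))
  if (a <= 1e-300) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    cc <- sum(d1 * r)
    if (e <= 1e-300) {
      t <- 0; s <- min(max(-cc / a, 0), 1)
    } else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > 1e-300) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

point_tri_dist <- function(p, a, b, cc) {
  ab <- b - a; ac <- cc - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3); return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - cc; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - cc)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6); return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (cc - b)))^2)))
  }
  den <- va + vb + vc
  v <- vb / den; w <- vc / den
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

shape_world_vertices <- function(shape, pose) transform_points(pose, shape$vertices)

shape_world_triangles <- function(shape, pose) {
  v <- shape_world_vertices(shape, pose)
  tris <- list()
  for (f in shape$faces)
    for (i in 2:(length(f) - 1))
      tris[[length(tris) + 1]] <- list(v[f[1], ], v[f[i], ], v[f[i + 1], ])
  tris
}

# exhaustive feature-pair distance (exact for disjoint convex solids)
brute_convex_distance <- function(sa, pa, sb, pb) {
  va <- shape_world_vertices(sa, pa); vb <- shape_world_vertices(sb, pb)
  best <- Inf
  ta <- shape_world_triangles(sa, pa); tb <- shape_world_triangles(sb, pb)
  for (i in seq_len(nrow(va)))
    for (tr in tb)
      best <- min(best, point_tri_dist(va[i, ], tr[[1]], tr[[2]], tr[[3]]))
  for (i in seq_len(nrow(vb)))
    for (tr in ta)
      best <- min(best, point_tri_dist(vb[i, ], tr[[1]], tr[[2]], tr[[3]]))
  for (i in seq_len(nrow(sa$edges)))
    for (j in seq_len(nrow(sb$edges))) {
      e1 <- sa$edges[i, ]; e2 <- sb$edges[j, ]
      best <- min(best, seg_seg_dist(va[e1[1], ], va[e1[2], ],
                                     vb[e2[1], ], vb[e2[2], ]))
    }
  best
}

# separating axis test for convex-convex overlap (face normals + edge
# cross products)
sat_overlap <- function(sa, pa, sb, pb) {
  va <- shape_world_vertices(sa, pa); vb <- shape_world_vertices(sb, pb)
  Ra <- quat_to_matrix(pa); Rb <- quat_to_matrix(pb)
  axes <- rbind(t(Ra %*% t(sa$face_normals)), t(Rb %*% t(sb$face_normals)))
  for (i in seq_len(nrow(sa$edges)))
    for (j in seq_len(nrow(sb$edges))) {
      ea <- va[sa$edges[i, 2], ] - va[sa$edges[i, 1], ]
      eb <- vb[sb$edges[j, 2], ] - vb[sb$edges[j, 1], ]
      cx <- c(ea[2] * eb[3] - ea[3] * eb[2], ea[3] * eb[1] - ea[1] * eb[3],
              ea[1] * eb[2] - ea[2] * eb[1])
      if (sqrt(sum(cx^2)) > 1e-9) axes <- rbind(axes, cx)
    }
  for (k in seq_len(nrow(axes))) {
    ax <- axes[k, ]
    prja <- va %*% ax; prjb <- vb %*% ax
    if (max(prja) < min(prjb) - 1e-12 || max(prjb) < min(prja) - 1e-12)
      return(FALSE)
  }
  TRUE
}

# dense stratified surface sample of a posed shape (points per nm^2);
# vertices and subdivided edges are included so that vertex- and
# edge-realised minima are not undersampled
surface_sample <- function(shape, pose, density = 25) {
  vw <- shape_world_vertices(shape, pose)
  pts <- list(vw)
  for (i in seq_len(nrow(shape$edges))) {
    a <- vw[shape$edges[i, 1], ]; b <- vw[shape$edges[i, 2], ]
    tt <- seq(0, 1, length.out = 12)
    pts[[length(pts) + 1]] <- cbind(a[1] + tt * (b[1] - a[1]),
                                    a[2] + tt * (b[2] - a[2]),
                                    a[3] + tt * (b[3] - a[3]))
  }
  for (tr in shape_world_triangles(shape, pose)) {
    a <- tr[[1]]; b <- tr[[2]]; cc <- tr[[3]]
    e1 <- b - a; e2 <- cc - a
    cx <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    ar <- 0.5 * sqrt(sum(cx^2))
    n <- max(3L, ceiling(ar * density))
    u <- stats::runif(n); v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    pts[[length(pts) + 1]] <-
      cbind(a[1] + u * (b[1] - a[1]) + v * (cc[1] - a[1]),
            a[2] + u * (b[2] - a[2]) + v * (cc[2] - a[2]),
            a[3] + u * (b[3] - a[3]) + v * (cc[3] - a[3]))
  }
  do.call(rbind, pts)
}

# exact distance from world points to a posed convex solid (outside points)
points_to_shape_dist <- function(pts, shape, pose) {
  tris <- shape_world_triangles(shape, pose)
  apply(pts, 1, function(p) {
    best <- Inf
    for (tr in tris) best <- min(best, point_tri_dist(p, tr[[1]], tr[[2]],
                                                      tr[[3]]))
    best
  })
}

# surface-sampling distance oracle: sampled points on each surface vs the
# exact point-to-solid distance to the other solid (upper bound on truth,
# bias bounded by the sampling density)
sampling_distance_oracle <- function(sa, pa, sb, pb, density = 25) {
  p1 <- surface_sample(sa, pa, density)
  p2 <- surface_sample(sb, pb, density)
  min(min(points_to_shape_dist(p1, sb, pb)),
      min(points_to_shape_dist(p2, sa, pa)))
}

random_pose_pair <- function(gap_range = c(0.5, 8)) {
  qa <- random_quaternion(1)[1, ]; qb <- random_quaternion(1)[1, ]
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  d <- stats::runif(1, 8, 16)
  list(pa = pose(c(0, 0, 0), qa), pb = pose(dir * d, qb))
}
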