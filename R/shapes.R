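#' Construct a convex polyhedron
#'
#' The two solids of the simulation -- the tubulin dimer and the diffusing
#' binder -- are convex polyhedra.  A shape stores vertices (body frame, nm),
#' faces as vertex-index cycles with outward normals, the edge/face
#' adjacency used by closest-feature queries, and named anchor points
#' (binding-interface centres and binding normals).
#'
#' @param vertices n x 3 numeric matrix, body frame, nm.
#' @param faces List of integer vectors; each face is a vertex cycle.  Face
#'   winding is corrected automatically so normals point outward.
#' @param anchors Named list of body-frame 3-vectors.
#' @param anchor_normals Named list of body-frame unit 3-vectors.
#' @param name Character label.
#' @return An object of class \code{"convex_shape"}.
#' @export
convex_shape <- function(vertices, faces, anchors = list(),
                         anchor_normals = list(), name = "shape") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  centroid <- colMeans(vertices)
  # orient every face outward
  faces <- lapply(faces, function(f) {
    f <- as.integer(f)
    n <- face_newell_normal(vertices[f, , drop = FALSE])
    fc <- colMeans(vertices[f, , drop = FALSE])
    if (sum(n * (fc - centroid)) < 0) rev(f) else f
  })
  normals <- t(vapply(faces, function(f) {
    n <- face_newell_normal(vertices[f, , drop = FALSE])
    n / sqrt(sum(n^2))
  }, numeric(3)))
  ef <- edge_face_table(faces)
  shape <- structure(list(
    vertices = vertices, faces = faces, face_normals = normals,
    edges = ef$edges, edge_faces = ef$edge_faces,
    anchors = anchors, anchor_normals = anchor_normals,
    centroid = centroid, name = name
  ), class = "convex_shape")
  validate_convex_shape(shape)
  shape
}

face_newell_normal <- function(pts) {
  n <- c(0, 0, 0)
  k <- nrow(pts)
  for (i in seq_len(k)) {
    a <- pts[i, ]; b <- pts[if (i == k) 1 else i + 1, ]
    n <- n + c((a[2] - b[2]) * (a[3] + b[3]),
               (a[3] - b[3]) * (a[1] + b[1]),
               (a[1] - b[1]) * (a[2] + b[2]))
  }
  n
}

edge_face_table <- function(faces) {
  keys <- character(0); e1 <- integer(0); e2 <- integer(0)
  fa <- list()
  for (fi in seq_along(faces)) {
    f <- faces[[fi]]
    k <- length(f)
    for (i in seq_len(k)) {
      a <- f[i]; b <- f[if (i == k) 1 else i + 1]
      key <- paste(min(a, b), max(a, b))
      j <- match(key, keys)
      if (is.na(j)) {
        keys <- c(keys, key); e1 <- c(e1, min(a, b)); e2 <- c(e2, max(a, b))
        fa[[length(keys)]] <- fi
      } else {
        fa[[j]] <- c(fa[[j]], fi)
      }
    }
  }
  list(edges = cbind(e1, e2),
       edge_faces = t(vapply(fa, function(x) {
         if (length(x) != 2) c(x[1], NA_integer_) else x
       }, integer(2))))
}

#' Validate the convexity and topology invariants of a shape
#'
#' Checks that every vertex lies on or inside every face half-space
#' (tolerance 1e-9 nm), that face normals point outward, and that every
#' edge borders exactly two faces.  Degenerate shapes (all vertices
#' coplanar, zero volume) fail loudly.
#'
#' @param shape A \code{convex_shape}.
#' @param tol Half-space tolerance, nm.
#' @return Invisibly \code{TRUE}; stops on violation.
#' @export
validate_convex_shape <- function(shape, tol = 1e-9) {
  v <- shape$vertices
  if (shape_volume(shape) < 1e-9)
    stop("degenerate shape: zero volume (all vertices coplanar?)")
  for (fi in seq_along(shape$faces)) {
    f <- shape$faces[[fi]]
    n <- shape$face_normals[fi, ]
    d <- sum(n * v[f[1], ])
    if (any(v %*% n - d > tol))
      stop(sprintf("shape '%s' is not convex at face %d", shape$name, fi))
    if (sum(n * (colMeans(v[f, , drop = FALSE]) - shape$centroid)) < 0)
      stop(sprintf("face %d normal points inward", fi))
  }
  if (any(is.na(shape$edge_faces)))
    stop("inconsistent feature graph: an edge does not border exactly 2 faces")
  invisible(TRUE)
}

#' Volume of a convex polyhedron
#'
#' Divergence-theorem sum over fan-triangulated faces.
#'
#' @param shape A \code{convex_shape}.
#' @return Volume in nm^3.
#' @export
shape_volume <- function(shape) {
  v <- shape$vertices
  vol <- 0
  for (fi in seq_along(shape$faces)) {
    f <- shape$faces[[fi]]
    for (i in 2:(length(f) - 1)) {
      a <- v[f[1], ]; b <- v[f[i], ]; cc <- v[f[i + 1], ]
      vol <- vol + sum(a * c(b[2] * cc[3] - b[3] * cc[2],
                             b[3] * cc[1] - b[1] * cc[3],
                             b[1] * cc[2] - b[2] * cc[1])) / 6
    }
  }
  abs(vol)
}

#' Effective radius of a shape
#'
#' Mean distance of the vertices from the body-frame origin; the binder's
#' effective radius sets its Stokes-Einstein diffusion coefficients.
#'
#' @param shape A \code{convex_shape}.
#' @return Radius in nm.
#' @export
effective_radius <- function(shape) {
  mean(sqrt(rowSums(shape$vertices^2)))
}

#' Build the tubulin-dimer solid
#'
#' A chamfered octagonal prism approximating the cryo-EM envelope of the
#' alpha-beta tubulin heterodimer: 7.6 nm axial x 5 nm tangential x 4.5 nm
#' radial, with the four axial edges chamfered.  Body frame: x = axial
#' (toward the plus end), y = tangential, z = radial (outward).  Carries
#' four pocket contact anchors at the mid-height corner edges (named
#' \code{corner_<sx><sy>} with \code{p}/\code{m} for the sign of the axial
#' and tangential coordinate) and one outward \code{face} anchor at the
#' centre of the outer surface.  Deterministic; no RNG.
#'
#' @param constants Constant set, see \code{\link{mt_constants}}.
#' @return A \code{convex_shape}.
#' @export
build_tubulin_shape <- function(constants = mt_constants()) {
  hx <- constants$dimer_axial / 2
  hy <- constants$dimer_tangential / 2
  hz <- constants$dimer_radial / 2
  c0 <- constants$dimer_chamfer
  oct <- rbind(
    c( hy,  hz - c0), c( hy - c0,  hz), c(-(hy - c0),  hz), c(-hy,  hz - c0),
    c(-hy, -(hz - c0)), c(-(hy - c0), -hz), c( hy - c0, -hz), c( hy, -(hz - c0)))
  v <- rbind(cbind(hx, oct), cbind(-hx, oct))
  faces <- c(
    list(1:8, 9:16),
    lapply(1:8, function(i) {
      j <- if (i == 8) 1 else i + 1
      c(i, j, j + 8, i + 8)
    }))
  ax <- constants$anchor_axial
  ay <- constants$anchor_tangential
  az <- constants$anchor_radial
  anchors <- list(
    corner_pp = c( ax,  ay, az), corner_pm = c( ax, -ay, az),
    corner_mp = c(-ax,  ay, az), corner_mm = c(-ax, -ay, az),
    face = c(0, 0, hz))
  convex_shape(v, faces, anchors = anchors,
               anchor_normals = list(face = c(0, 0, 1)),
               name = "tubulin_dimer")
}

#' Build the diffusing binder solid
#'
#' A square frustum of overall diameter about 4 nm (twice the mean vertex
#' radius), tapering toward its binding face at body -z.  In pocket mode
#' the shape carries four interface anchors arranged congruently with the
#' four contact-anchor positions of a complete interior lattice pocket, so
#' that a rigid mated pose brings all four anchor pairs to coincidence; in
#' face mode it carries a single interface anchor on the binding axis.
#' Both modes store the binding normal (body -z).
#'
#' @param mode \code{"pocket"} or \code{"face"}.
#' @param constants Constant set, see \code{\link{mt_constants}}.
#' @return A \code{convex_shape}.
#' @export
build_binder_shape <- function(mode = c("pocket", "face"),
                               constants = mt_constants()) {
  mode <- match.arg(mode)
  b <- constants$binder_bottom_halfwidth
  tt <- constants$binder_top_halfwidth
  zb <- constants$binder_bottom_z
  zt <- constants$binder_top_z
  v <- rbind(
    c( b,  b, zb), c(-b,  b, zb), c(-b, -b, zb), c( b, -b, zb),
    c( tt,  tt, zt), c(-tt,  tt, zt), c(-tt, -tt, zt), c( tt, -tt, zt))
  faces <- list(1:4, 5:8, c(1, 2, 6, 5), c(2, 3, 7, 6), c(3, 4, 8, 7),
                c(4, 1, 5, 8))
  drop <- constants$binder_anchor_drop
  if (mode == "pocket") {
    pat <- canonical_pocket_pattern(constants)
    anchors <- list(
      iface_ll = c(pat["ll", 1:2], pat["ll", 3] - drop),
      iface_ul = c(pat["ul", 1:2], pat["ul", 3] - drop),
      iface_lr = c(pat["lr", 1:2], pat["lr", 3] - drop),
      iface_ur = c(pat["ur", 1:2], pat["ur", 3] - drop))
    anchors <- lapply(anchors, unname)
  } else {
    anchors <- list(iface = c(0, 0, -drop))
  }
  convex_shape(v, faces, anchors = anchors,
               anchor_normals = list(binding = c(0, 0, -1)),
               name = paste0("binder_", mode))
}

#' Contact-anchor pattern of an interior lattice pocket
#'
#' World positions of the four dimer contact anchors surrounding one
#' interior (non-seam) pocket, expressed in the pocket's site frame
#' (x = microtubule axis, z = outward radial at the site centre).  Rows
#' \code{ll, ul, lr, ur} order the adjacent dimers as (lower layer, left
#' protofilament), (upper, left), (lower, right), (upper, right).
#'
#' @param constants Constant set.
#' @return 4 x 3 matrix with rownames \code{ll, ul, lr, ur}.
#' @export
canonical_pocket_pattern <- function(constants = mt_constants()) {
  # anchors of the pocket between protofilaments 0/1, layers 0/1
  pts <- rbind(
    ll = dimer_anchor_world(0L, 0L, "corner_pm", constants),
    ul = dimer_anchor_world(0L, 1L, "corner_mm", constants),
    lr = dimer_anchor_world(1L, 0L, "corner_pp", constants),
    ur = dimer_anchor_world(1L, 1L, "corner_mp", constants))
  ctr <- colMeans(pts)
  fr <- site_frame(ctr)
  sweep(pts, 2, ctr) %*% fr
}

# world position of one named dimer anchor for lattice position (p, l)
dimer_anchor_world <- function(p, l, anchor, constants = mt_constants()) {
  ps <- dimer_lattice_pose(p, l, constants)
  as.numeric(transform_points(ps, build_tubulin_anchor(anchor, constants)))
}

build_tubulin_anchor <- function(anchor, constants) {
  ax <- constants$anchor_axial; ay <- constants$anchor_tangential
  az <- constants$anchor_radial
  switch(anchor,
    corner_pp = c( ax,  ay, az), corner_pm = c( ax, -ay, az),
    corner_mp = c(-ax,  ay, az), corner_mm = c(-ax, -ay, az),
    face = c(0, 0, constants$dimer_radial / 2),
    stop("unknown anchor"))
}

# site frame at a point: columns are world directions of the frame axes
# (x = microtubule axis, z = outward radial, y = z cross x)
site_frame <- function(center, axis_origin = c(0, 0, 0),
                       axis_dir = c(0, 0, 1)) {
  xf <- axis_dir / sqrt(sum(axis_dir^2))
  rel <- center - axis_origin
  n <- rel - sum(rel * xf) * xf
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) {
    n <- if (abs(xf[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- n - sum(n * xf) * xf
    n <- n / sqrt(sum(n^2))
  } else n <- n / nn
  yf <- c(n[2] * xf[3] - n[3] * xf[2],
          n[3] * xf[1] - n[1] * xf[3],
          n[1] * xf[2] - n[2] * xf[1])
  cbind(xf, yf, n)
}

#' Export a shape (or shape assembly) as Wavefront OBJ
#'
#' @param shapes A \code{convex_shape} or list of them.
#' @param poses Optional list of \code{mt_pose} (one per shape).
#' @param path Output file.
#' @return Invisibly \code{path}.
#' @export
write_obj <- function(shapes, path, poses = NULL) {
  if (inherits(shapes, "convex_shape")) shapes <- list(shapes)
  con <- file(path, "w")
  on.exit(close(con))
  off <- 0L
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    v <- s$vertices
    if (!is.null(poses)) v <- transform_points(poses[[i]], v)
    writeLines(sprintf("o %s_%d", s$name, i), con)
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    for (f in s$faces)
      writeLines(paste("f", paste(f + off, collapse = " ")), con)
    off <- off + nrow(v)
  }
  invisible(path)
}

#' Read a Wavefront OBJ file as a convex shape
#'
#' Only vertex (\code{v}) and face (\code{f}) records are interpreted;
#' multi-object files are merged.
#'
#' @param path OBJ file path.
#' @param name Shape label.
#' @return A \code{convex_shape}.
#' @export
read_obj <- function(path, name = "obj") {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"), function(x)
    as.integer(sub("/.*", "", x)))
  convex_shape(v, faces, name = name)
}
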