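#' Braided stent design vector
#'
#' A design is four per-quadrant wire counts plus a winding factor; the
#' wire radius is held fixed.  Each quadrant count lies in \{3..7\} and
#' the winding factor in \{20, 25, 30, 35\}, giving 5^4 x 4 = 2500
#' possible designs with 24 to 56 wires in total (two wires, one per
#' handedness, are braided from every start position).
#'
#' @param n Integer vector of length 4: wires per quadrant (3..7).
#' @param winding_factor Integer in \{20, 25, 30, 35\}.
#' @param wire_radius_um Wire radius (micrometers, default 60).
#' @return An object of class \code{stent_design}.
#' @export
#' @examples
#' d <- stent_design(c(5, 3, 5, 4), 25)
#' wire_count(d)  # 34
stent_design <- function(n, winding_factor = 25, wire_radius_um = 60) {
  n <- as.integer(n)
  if (length(n) != 4L || any(n < 3L) || any(n > 7L))
    stop("wire counts must be four integers in 3..7")
  winding_factor <- as.integer(winding_factor)
  if (!winding_factor %in% c(20L, 25L, 30L, 35L))
    stop("winding factor must be one of 20, 25, 30, 35")
  stopifnot(wire_radius_um > 0)
  structure(list(n = n, winding_factor = winding_factor,
                 wire_radius_um = wire_radius_um),
            class = "stent_design")
}

#' Total number of wires in a design
#' @param design A \code{stent_design}.
#' @return Integer: 2 * sum of the quadrant counts.
#' @export
wire_count <- function(design) 2L * sum(design$n)

#' Write / read a design vector as JSON
#' @param design A \code{stent_design}.
#' @param path File path.
#' @return \code{read_design} returns a \code{stent_design};
#'   \code{write_design} returns \code{path} invisibly.
#' @export
write_design <- function(design, path) {
  jsonlite::write_json(
    list(n1 = design$n[1], n2 = design$n[2], n3 = design$n[3],
         n4 = design$n[4], winding_factor = design$winding_factor,
         wire_radius_um = design$wire_radius_um),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stent_design(c(x$n1, x$n2, x$n3, x$n4), x$winding_factor, x$wire_radius_um)
}

#' Generate the braided wire set of a design
#'
#' Start positions are uniformly distributed within each quadrant of the
#' proximal end section (quadrants labelled counter-clockwise, quadrant 1
#' spanning azimuths [0, 90) degrees, the upper-outer torus quadrant).
#' From each start position two helical wires are braided, one clockwise
#' and one counter-clockwise, their azimuth evolving as
#' theta(s) = theta0 +/- 2 pi k s / L_ref.  Polylines are sampled densely
#' enough that the chord error stays below 1 micrometer (and at least 200
#' points per envelope revolution).
#'
#' @param design A \code{stent_design}.
#' @param env An \code{envelope_spec}.
#' @return An object of class \code{wire_set}: a list with \code{wires}
#'   (each a list with \code{points} n x 3 mm matrix, \code{handedness},
#'   \code{quadrant}, \code{theta0}) and \code{radius_um}.
#' @export
generate_wires <- function(design, env) {
  stopifnot(inherits(design, "stent_design"), inherits(env, "envelope_spec"))
  k <- design$winding_factor
  rate <- 2 * pi * k / env$reference_pitch_length   # d(theta)/ds, rad/mm
  revolutions <- abs(rate) * env$l / (2 * pi)
  # sampling: >= 200 pts/revolution and chord error < 1 um on both the
  # azimuthal circle (radius <= max minor radius) and the centerline arc
  rmax <- max(env$r_prox, env$r_dist)
  ds_theta <- if (rate > 0) sqrt(8e-3 / rmax) / rate else Inf
  ds_arc <- sqrt(8e-3 * env$R)
  ds <- min(ds_theta, ds_arc, env$l / (200 * max(1, revolutions)))
  npts <- max(51L, as.integer(ceiling(env$l / ds)) + 1L)
  s <- seq(0, env$l, length.out = npts)

  wires <- list()
  for (q in 1:4) {
    nq <- design$n[q]
    theta0s <- (q - 1) * pi / 2 + (seq_len(nq) - 0.5) * (pi / 2) / nq
    for (t0 in theta0s) {
      for (hand in c("ccw", "cw")) {
        sgn <- if (hand == "ccw") 1 else -1
        theta <- t0 + sgn * rate * s
        wires[[length(wires) + 1L]] <- list(
          points = envelope_point(env, theta, s),
          handedness = hand, quadrant = q, theta0 = t0)
      }
    }
  }
  structure(list(wires = wires, radius_um = design$wire_radius_um,
                 envelope = env, design = design),
            class = "wire_set")
}

#' Average braiding angle of a wire set
#'
#' The braiding angle is the angle between the tangents of the two
#' opposite-handedness wire families where they cross.  It is measured
#' here from finite-difference tangents as twice the angle each family
#' makes with the local centerline direction, averaged over the envelope.
#' For a constant-radius, slender envelope this equals
#' 2 arctan(r |dtheta/ds|).
#'
#' @param ws A \code{wire_set} containing both handedness families.
#' @param env The generating \code{envelope_spec} (defaults to the one
#'   stored in the wire set).
#' @return Braiding angle in degrees.
#' @export
braiding_angle <- function(ws, env = ws$envelope) {
  hands <- vapply(ws$wires, function(w) w$handedness, character(1))
  if (length(unique(hands)) < 2L)
    stop("undefined braiding angle: both handedness families are required")
  half_angle <- function(w) {
    p <- w$points
    n <- nrow(p)
    tan_vec <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
    mid <- (p[-1, , drop = FALSE] + p[-n, , drop = FALSE]) / 2
    # local centerline (axial) direction at the midpoint azimuth
    phi <- atan2(mid[, 2], mid[, 1])
    ax <- cbind(-sin(phi), cos(phi), 0)
    ct <- rowSums(tan_vec * ax) /
      sqrt(rowSums(tan_vec^2))
    mean(acos(pmin(1, abs(ct))))
  }
  mean(vapply(ws$wires, half_angle, numeric(1))) * 2 * 180 / pi
}

#' Porosity and pore density of the pre-deployment cylindrical structure
#'
#' Functional metrics are estimated on the unrolled reference cylinder
#' with a planar rhombic unit-cell model: the two wire families run at
#' +/- beta/2 from the cylinder axis with same-family perpendicular
#' spacing p = (2 pi R_c / N) cos(beta/2).  With per-family line coverage
#' f = d/p the wire-free fraction of the unit cell is (1 - f)^2 (the
#' crossing-overlap correction is exactly f^2 per cell), and the pore
#' count per unit area is sin(beta) / p^2.  Per-quadrant (ROI) values
#' restrict the census to each quadrant's n_j wires; the global values
#' are the quadrant means.
#'
#' @param design A \code{stent_design}.
#' @param cylinder_radius Reference cylinder radius R_c (mm).
#' @param reference_pitch_length Pitch calibration constant (mm);
#'   defaults to the standard 75-degree calibration.
#' @return A list of class \code{stent_metrics} with fields
#'   \code{braiding_angle} (degrees), \code{porosity} (percent),
#'   \code{pore_density} (pores/mm^2) and \code{by_quadrant}.
#' @export
porosity_pore_density <- function(design, cylinder_radius = 1.75,
                                  reference_pitch_length =
                                    calibrate_pitch()) {
  stopifnot(inherits(design, "stent_design"))
  d <- 2 * design$wire_radius_um * 1e-3   # wire diameter, mm
  if (cylinder_radius <= d / 2)
    stop("cylinder radius must exceed the wire radius")
  rate <- 2 * pi * design$winding_factor / reference_pitch_length
  beta <- 2 * atan(cylinder_radius * rate)
  quarter <- 2 * pi * cylinder_radius / 4
  c_j <- quarter / design$n                 # same-family circumferential spacing
  p_j <- c_j * cos(beta / 2)                # perpendicular spacing
  f_j <- pmin(1, d / p_j)                   # per-family coverage fraction
  if (any(d / p_j >= 1))
    warning("wire coverage reaches full occlusion in at least one quadrant")
  por_j <- (1 - f_j)^2 * 100
  pd_j <- ifelse(f_j < 1, sin(beta) / p_j^2, 0)
  structure(list(
    braiding_angle = beta * 180 / pi,
    porosity = mean(por_j),
    pore_density = mean(pd_j),
    by_quadrant = data.frame(quadrant = 1:4, n = design$n,
                             porosity = por_j, pore_density = pd_j)),
    class = "stent_metrics")
}

#' Plane specification for wire sectioning
#'
#' @param point A point on the plane (mm, length-3).
#' @param normal Plane normal (length-3, normalized internally).
#' @param u_axis In-plane direction defining the first 2-D coordinate;
#'   its component along the normal is removed.
#' @return A list of class \code{plane_spec} with orthonormal axes.
#' @export
plane_spec <- function(point, normal, u_axis) {
  n <- normal / sqrt(sum(normal^2))
  u <- u_axis - sum(u_axis * n) * n
  if (sum(u^2) < 1e-12) stop("u_axis is parallel to the plane normal")
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  structure(list(point = point, normal = n, u = u, v = v),
            class = "plane_spec")
}

#' Section a wire set with a plane
#'
#' Each transversal crossing of a wire centerline through the plane
#' yields one disc whose area equals the elliptical cross-section of the
#' oblique cylinder cut: radius = wire_radius / sqrt(|cos alpha|), with
#' alpha the angle between the wire tangent and the plane normal.
#' Crossings grazing the plane at less than 5 degrees incidence are
#' skipped (the elliptical section degenerates).
#'
#' @param ws A \code{wire_set}.
#' @param plane A \code{plane_spec}.
#' @param min_angle_deg Minimum incidence angle from the plane (degrees).
#' @return A data frame with one row per crossing: in-plane coordinates
#'   \code{u}, \code{v} (mm), \code{radius_um}, \code{wire} index and
#'   \code{incidence_deg}.  Empty when the plane misses the stent.
#' @export
section_obstacles <- function(ws, plane, min_angle_deg = 5) {
  stopifnot(inherits(ws, "wire_set"), inherits(plane, "plane_spec"))
  out <- list()
  skipped <- 0L
  for (iw in seq_along(ws$wires)) {
    p <- ws$wires[[iw]]$points
    dist <- (p[, 1] - plane$point[1]) * plane$normal[1] +
            (p[, 2] - plane$point[2]) * plane$normal[2] +
            (p[, 3] - plane$point[3]) * plane$normal[3]
    n <- length(dist)
    cross <- which(dist[-n] * dist[-1] < 0 | (dist[-n] == 0 & dist[-1] != 0))
    for (i in cross) {
      t <- dist[i] / (dist[i] - dist[i + 1])
      pt <- p[i, ] + t * (p[i + 1, ] - p[i, ])
      tv <- p[i + 1, ] - p[i, ]
      tv <- tv / sqrt(sum(tv^2))
      ca <- abs(sum(tv * plane$normal))       # cos(angle tangent-normal)
      incidence <- asin(min(1, ca)) * 180 / pi  # angle from the plane
      if (incidence < min_angle_deg) {
        skipped <- skipped + 1L
        next
      }
      rel <- pt - plane$point
      out[[length(out) + 1L]] <- data.frame(
        u = sum(rel * plane$u), v = sum(rel * plane$v),
        radius_um = ws$radius_um / sqrt(ca),
        wire = iw, incidence_deg = incidence)
    }
  }
  if (skipped > 0L)
    message(skipped, " grazing wire crossing(s) skipped")
  if (length(out) == 0L)
    return(data.frame(u = numeric(0), v = numeric(0), radius_um = numeric(0),
                      wire = integer(0), incidence_deg = numeric(0)))
  do.call(rbind, out)
}

# parallel-transport orthonormal frames along a polyline
.transport_frames <- function(p) {
  n <- nrow(p)
  tans <- rbind(p[2, ] - p[1, ],
                (p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]) / 2,
                p[n, ] - p[n - 1, ])
  tans <- tans / sqrt(rowSums(tans^2))
  e1 <- matrix(0, n, 3)
  ref <- if (abs(tans[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * tans[1, ]) * tans[1, ]
  e1[1, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) {
    v <- e1[i - 1, ] - sum(e1[i - 1, ] * tans[i, ]) * tans[i, ]
    e1[i, ] <- v / sqrt(sum(v^2))
  }
  e2 <- cbind(tans[, 2] * e1[, 3] - tans[, 3] * e1[, 2],
              tans[, 3] * e1[, 1] - tans[, 1] * e1[, 3],
              tans[, 1] * e1[, 2] - tans[, 2] * e1[, 1])
  list(tangent = tans, e1 = e1, e2 = e2)
}

.tube_mesh <- function(p, radius_mm, facets) {
  n <- nrow(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  turn <- numeric(0)
  if (n > 2) {
    a <- p[-c(n - 1, n), , drop = FALSE]; b <- p[-c(1, n), , drop = FALSE]
    cc <- p[-c(1, 2), , drop = FALSE]
    u <- b - a; v <- cc - b
    cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    turn <- acos(pmin(1, pmax(-1, cosang)))
    # curvature radius ~ seg / turn; extrusion self-intersects when the
    # tube radius exceeds it
    bad <- turn > 1e-8 & radius_mm >= pmin(seg[-1], seg[-length(seg)]) / turn
    if (any(bad)) return(NULL)
  }
  fr <- .transport_frames(p)
  ang <- 2 * pi * (0:(facets - 1)) / facets
  verts <- matrix(0, n * facets, 3)
  for (i in 1:n) {
    ring <- p[rep(i, facets), , drop = FALSE] +
      radius_mm * (outer(cos(ang), fr$e1[i, ]) + outer(sin(ang), fr$e2[i, ]))
    verts[((i - 1) * facets + 1):(i * facets), ] <- ring
  }
  tri <- list()
  for (i in 1:(n - 1)) {
    a <- (i - 1) * facets + (1:facets)
    b <- i * facets + (1:facets)
    a2 <- a[c(2:facets, 1)]; b2 <- b[c(2:facets, 1)]
    tri[[i]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  # end caps (fans around the end centroids)
  verts <- rbind(verts, p[1, ], p[n, ])
  c1 <- nrow(verts) - 1L; c2 <- nrow(verts)
  a <- 1:facets; a2 <- a[c(2:facets, 1)]
  b <- (n - 1) * facets + (1:facets); b2 <- b[c(2:facets, 1)]
  tri[[length(tri) + 1L]] <- rbind(cbind(a2, a, c1), cbind(b, b2, c2))
  list(vertices = verts, triangles = do.call(rbind, tri))
}

#' Export wire surface meshes
#'
#' Extrudes a circular profile along every wire centerline and writes the
#' resulting watertight tube surfaces to an ASCII STL file (one solid,
#' one connected component per wire) or to a legacy-ASCII VTK polydata
#' file.  The format follows the file extension (.stl or .vtk).
#'
#' @param ws A \code{wire_set}.
#' @param path Output path ending in .stl or .vtk.
#' @param facets Circumferential facet count (>= 8).
#' @return Invisibly, a list with total vertex and triangle counts.
#' @export
export_wire_mesh <- function(ws, path, facets = 16L) {
  stopifnot(inherits(ws, "wire_set"), facets >= 8L)
  radius_mm <- ws$radius_um * 1e-3
  meshes <- vector("list", length(ws$wires))
  for (i in seq_along(ws$wires)) {
    m <- .tube_mesh(ws$wires[[i]]$points, radius_mm, facets)
    if (is.null(m))
      stop("self-intersecting extrusion at a sharp kink in wire ", i)
    meshes[[i]] <- m
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") .write_stl(meshes, path)
  else if (ext == "vtk") .write_vtk_poly(meshes, path)
  else stop("unsupported mesh format: .", ext)
  invisible(list(
    vertices = sum(vapply(meshes, function(m) nrow(m$vertices), numeric(1))),
    triangles = sum(vapply(meshes, function(m) nrow(m$triangles), numeric(1)))))
}

.write_stl <- function(meshes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid wires", con)
  for (m in meshes) {
    v <- m$vertices; tr <- m$triangles
    p1 <- v[tr[, 1], , drop = FALSE]
    p2 <- v[tr[, 2], , drop = FALSE]
    p3 <- v[tr[, 3], , drop = FALSE]
    u <- p2 - p1; w <- p3 - p1
    nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    txt <- paste0(
      "facet normal ", nrm[, 1], " ", nrm[, 2], " ", nrm[, 3], "\n",
      " outer loop\n",
      "  vertex ", p1[, 1], " ", p1[, 2], " ", p1[, 3], "\n",
      "  vertex ", p2[, 1], " ", p2[, 2], " ", p2[, 3], "\n",
      "  vertex ", p3[, 1], " ", p3[, 2], " ", p3[, 3], "\n",
      " endloop\nendfacet")
    writeLines(txt, con)
  }
  writeLines("endsolid wires", con)
}

.write_vtk_poly <- function(meshes, path) {
  nv <- vapply(meshes, function(m) nrow(m$vertices), numeric(1))
  off <- cumsum(c(0, nv[-length(nv)]))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  tris <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$triangles + off[i]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fdstent wire surfaces",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(verts), "double")), con)
  writeLines(paste(verts[, 1], verts[, 2], verts[, 3]), con)
  writeLines(paste("POLYGONS", nrow(tris), 4 * nrow(tris)), con)
  writeLines(paste(3, tris[, 1] - 1, tris[, 2] - 1, tris[, 3] - 1), con)
}

#' Export wire centerlines as VTK polylines
#' @param ws A \code{wire_set}.
#' @param path Output .vtk path.
#' @return \code{path}, invisibly.
#' @export
export_wire_centerlines <- function(ws, path) {
  np <- vapply(ws$wires, function(w) nrow(w$points), numeric(1))
  off <- cumsum(c(0, np[-length(np)]))
  pts <- do.call(rbind, lapply(ws$wires, `[[`, "points"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fdstent wire centerlines",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(pts), "double")), con)
  writeLines(paste(pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(paste("LINES", length(np), sum(np + 1)), con)
  for (i in seq_along(np))
    writeLines(paste(c(np[i], off[i] + seq_len(np[i]) - 1), collapse = " "),
               con)
  invisible(path)
}

#' Read back a triangulated surface written by \code{export_wire_mesh}
#'
#' Minimal reader used for round-trip checks: returns vertex and
#' triangle counts for ASCII STL and legacy VTK polydata files.
#' @param path Mesh file path.
#' @return List with \code{vertices} and \code{triangles} counts.
#' @export
read_surface_counts <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "stl") {
    nf <- sum(grepl("^facet normal", lines))
    list(vertices = 3L * nf, triangles = nf)
  } else if (ext == "vtk") {
    ip <- grep("^POINTS", lines)[1]
    it <- grep("^POLYGONS", lines)[1]
    list(vertices = as.integer(strsplit(lines[ip], " ")[[1]][2]),
         triangles = as.integer(strsplit(lines[it], " ")[[1]][2]))
  } else stop("unsupported format")
}
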