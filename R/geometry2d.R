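#' Idealized 2-D sidewall-aneurysm geometry
#'
#' Desk-scale stand-in for a patient lumen: a straight parent-vessel
#' channel of width \code{parent_width} with a circular sac attached to
#' the upper wall through a neck opening.  The sac is the portion of a
#' disc of radius \code{sac_radius} lying above the wall line, positioned
#' so that the chord along the wall has length \code{neck_width}.
#' Setting \code{sac_radius = NULL} gives a plain channel (used for
#' Poiseuille verification).
#'
#' @param parent_width Channel width H (mm).
#' @param parent_length Channel length L (mm).
#' @param sac_radius Sac radius (mm) or \code{NULL} for a plain channel.
#' @param neck_width Neck opening width (mm), < 2 * sac_radius.
#' @param sac_offset Axial position of the sac center (mm; default L/2).
#' @param target_edge_size Nominal mesh edge length (mm).
#' @param neck_refine Edge-size division factor near the neck and sac.
#' @param wall_refine Wall-normal grading factor in the channel.
#' @return An object of class \code{aneurysm_geometry}.
#' @export
aneurysm_geometry <- function(parent_width = 4, parent_length = 24,
                              sac_radius = 2.2, neck_width = 3,
                              sac_offset = parent_length / 2,
                              target_edge_size = 0.35,
                              neck_refine = 3, wall_refine = 3) {
  stopifnot(parent_width > 0, parent_length > 0, target_edge_size > 0,
            neck_refine >= 1, wall_refine >= 1)
  if (!is.null(sac_radius)) {
    stopifnot(sac_radius > 0, neck_width > 0)
    if (neck_width >= 2 * sac_radius)
      stop("neck width must be smaller than the sac diameter")
    if (neck_width >= parent_length)
      stop("neck width must be smaller than the parent length")
    if (sac_offset - neck_width / 2 <= 0 ||
        sac_offset + neck_width / 2 >= parent_length)
      stop("sac neck must lie strictly inside the channel")
  }
  structure(list(parent_width = parent_width,
                 parent_length = parent_length,
                 sac_radius = sac_radius, neck_width = neck_width,
                 sac_offset = sac_offset,
                 target_edge_size = target_edge_size,
                 neck_refine = neck_refine, wall_refine = wall_refine),
            class = "aneurysm_geometry")
}

# symmetric two-sided graded subdivision of [0, len]: spacing at the ends
# is ~1/factor of the interior spacing
.graded_seq <- function(len, h, factor) {
  n <- max(4L, as.integer(ceiling(len / h * (1 + (factor - 1) / 2))))
  xi <- seq(0, 1, length.out = n + 1)
  A <- 1 - 1 / factor
  len * (xi - A * sin(2 * pi * xi) / (2 * pi))
}

#' Build a conforming triangular mesh of the geometry
#'
#' The channel is meshed with a structured, wall-graded grid split into
#' triangles; the sac (a convex circular segment) is meshed with a
#' transfinite blend between the neck chord and the arc, conforming to
#' the channel nodes along the neck.  Boundary edges are tagged
#' \code{inlet}, \code{outlet}, \code{wall} or \code{sac_wall}
#' (the sac arc, a subset of the wall).
#'
#' @param g An \code{aneurysm_geometry}.
#' @return An object of class \code{mesh2d}: a list with \code{nodes}
#'   (N x 2, mm), \code{tri} (M x 3, positively oriented),
#'   \code{boundary_edges} (data frame n1, n2, tag), \code{chi}
#'   (obstacle indicator per node, initialized to 0) and the generating
#'   geometry.
#' @export
build_geometry <- function(g) {
  stopifnot(inherits(g, "aneurysm_geometry"))
  H <- g$parent_width; L <- g$parent_length
  h <- g$target_edge_size
  hf <- h / g$neck_refine

  has_sac <- !is.null(g$sac_radius)
  if (has_sac) {
    x0n <- g$sac_offset - g$neck_width / 2
    x1n <- g$sac_offset + g$neck_width / 2
    pad <- min(g$neck_width / 2, x0n / 2, (L - x1n) / 2)
    ns <- max(4L, as.integer(ceiling(g$neck_width / hf)))
    npad <- max(1L, as.integer(ceiling(pad / hf)))
    xs <- c(seq(0, x0n - pad, length.out =
                  max(2L, as.integer(ceiling((x0n - pad) / h)) + 1L)),
            seq(x0n - pad, x0n, length.out = npad + 1L),
            seq(x0n, x1n, length.out = ns + 1L),
            seq(x1n, x1n + pad, length.out = npad + 1L),
            seq(x1n + pad, L, length.out =
                  max(2L, as.integer(ceiling((L - x1n - pad) / h)) + 1L)))
    xs <- sort(unique(round(xs, 10)))
  } else {
    xs <- seq(0, L, length.out = max(2L, as.integer(ceiling(L / h)) + 1L))
  }
  ys <- .graded_seq(H, h, g$wall_refine)

  nx <- length(xs); ny <- length(ys)
  nodes <- cbind(rep(xs, each = ny), rep(ys, nx))
  idx <- function(i, j) (i - 1L) * ny + j   # i along x, j along y

  tri <- vector("list", 2L * (nx - 1L) * (ny - 1L))
  tcount <- 0L
  for (i in 1:(nx - 1L)) for (j in 1:(ny - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    tcount <- tcount + 1L; tri[[tcount]] <- c(a, b, c2)
    tcount <- tcount + 1L; tri[[tcount]] <- c(a, c2, d)
  }
  tri <- do.call(rbind, tri[seq_len(tcount)])

  be <- list()
  add_edges <- function(n1, n2, tag)
    data.frame(n1 = n1, n2 = n2, tag = tag, stringsAsFactors = FALSE)
  be[[1]] <- add_edges(idx(1L, 1:(ny - 1L)), idx(1L, 2:ny), "inlet")
  be[[2]] <- add_edges(idx(nx, 1:(ny - 1L)), idx(nx, 2:ny), "outlet")
  be[[3]] <- add_edges(idx(1:(nx - 1L), 1L), idx(2:nx, 1L), "wall")
  # top wall; neck interval edges stay open when a sac is present
  top1 <- idx(1:(nx - 1L), ny); top2 <- idx(2:nx, ny)
  if (has_sac) {
    xm <- (nodes[top1, 1] + nodes[top2, 1]) / 2
    keep <- xm < x0n - 1e-9 | xm > x1n + 1e-9
    be[[4]] <- add_edges(top1[keep], top2[keep], "wall")
  } else {
    be[[4]] <- add_edges(top1, top2, "wall")
  }

  if (has_sac) {
    a <- g$sac_radius; w <- g$neck_width
    m <- sqrt(a^2 - (w / 2)^2)
    cx <- g$sac_offset; cy <- H + m
    phiL <- atan2(-m, -w / 2)
    phiR <- atan2(-m, w / 2)
    dphi <- (phiR - 2 * pi) - phiL          # < 0, major arc

    i_neck <- which(abs(nodes[, 1] - cx) <= w / 2 + 1e-9 &
                    abs(nodes[, 2] - H) < 1e-9)
    i_neck <- i_neck[order(nodes[i_neck, 1])]
    stopifnot(length(i_neck) == ns + 1L)
    u <- (nodes[i_neck, 1] - x0n) / w

    nt <- max(4L, as.integer(ceiling((a + m) / hf)))
    txi <- seq(0, 1, length.out = nt + 1L)
    A <- 1 - 1 / g$neck_refine
    tgr <- txi - A * sin(2 * pi * txi) / (2 * pi)

    sac_id <- matrix(0L, ns + 1L, nt + 1L)
    sac_id[, 1] <- i_neck
    sac_id[1, ] <- i_neck[1]
    sac_id[ns + 1L, ] <- i_neck[ns + 1L]
    new_nodes <- list()
    nextid <- nrow(nodes)
    for (ii in 2:ns) for (jj in 2:(nt + 1L)) {
      phi <- phiL + u[ii] * dphi
      arcp <- c(cx + a * cos(phi), cy + a * sin(phi))
      t <- tgr[jj]
      p <- (1 - t) * c(nodes[i_neck[ii], 1], H) + t * arcp
      nextid <- nextid + 1L
      sac_id[ii, jj] <- nextid
      new_nodes[[length(new_nodes) + 1L]] <- p
    }
    nodes <- rbind(nodes, do.call(rbind, new_nodes))

    sac_tri <- list()
    for (ii in 1:ns) for (jj in 1:nt) {
      qa <- sac_id[ii, jj]; qb <- sac_id[ii + 1L, jj]
      qc <- sac_id[ii + 1L, jj + 1L]; qd <- sac_id[ii, jj + 1L]
      for (tt in list(c(qa, qb, qc), c(qa, qc, qd))) {
        if (length(unique(tt)) == 3L)
          sac_tri[[length(sac_tri) + 1L]] <- tt
      }
    }
    tri <- rbind(tri, do.call(rbind, sac_tri))

    arc_row <- sac_id[, nt + 1L]
    be[[5]] <- add_edges(arc_row[1:ns], arc_row[2:(ns + 1L)], "sac_wall")
  }

  # enforce positive orientation, drop degenerate slivers
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- area2 < 0
  tri[flip, ] <- tri[flip, c(1L, 3L, 2L)]
  hmin <- min(abs(area2[abs(area2) > 0]))
  keep <- abs(area2) > 1e-8 * max(abs(area2))
  tri <- tri[keep, , drop = FALSE]

  boundary_edges <- do.call(rbind, be)
  structure(list(nodes = nodes, tri = tri,
                 boundary_edges = boundary_edges,
                 chi = numeric(nrow(nodes)),
                 geometry = g),
            class = "mesh2d")
}

#' Nodes on the sac wall (intra-saccular boundary)
#'
#' The delta_sac mask in 2-D: boundary nodes on the sac arc strictly
#' above the neck line.
#' @param mesh A \code{mesh2d}.
#' @return Integer node indices (empty when the geometry has no sac).
#' @export
sac_wall_nodes <- function(mesh) {
  be <- mesh$boundary_edges
  ids <- unique(c(be$n1[be$tag == "sac_wall"], be$n2[be$tag == "sac_wall"]))
  H <- mesh$geometry$parent_width
  ids[mesh$nodes[ids, 2] > H + 1e-9]
}

#' Immerse obstacle discs into a mesh
#'
#' Builds the penalization indicator.  Each disc carries a
#' \code{solidity} in (0, 1] (defaulting to 1 = solid): nodes inside the
#' disc receive indicator values equal to the solidity (sub-grid discs
#' deposit onto their nearest node), with fully solid coverage also
#' recorded in the binary \code{obstacle} flag.  The indicator is then
#' smoothed over one element layer.  The flow solver applies hard
#' Brinkman penalization on solid nodes and a finite porous-screen drag
#' scaled by the indicator on partially covered nodes.
#'
#' @param mesh A \code{mesh2d}.
#' @param discs Data frame with columns \code{x}, \code{y} (mm),
#'   \code{radius_um} and optionally \code{solidity}; an empty frame
#'   clears the indicator.
#' @return The mesh with updated \code{chi} (continuous indicator),
#'   \code{obstacle} (raw 0/1 solid flag) and \code{wire_d_mm} (wire
#'   diameter used by the screen-drag model, from
#'   \code{attr(discs, "wire_d_mm")} when present).
#' @export
immerse_obstacles <- function(mesh, discs) {
  stopifnot(inherits(mesh, "mesh2d"))
  n <- nrow(mesh$nodes)
  raw <- numeric(n)
  chi <- numeric(n)
  if (nrow(discs) > 0) {
    sol <- if (is.null(discs$solidity)) rep(1, nrow(discs)) else discs$solidity
    stopifnot(all(sol > 0), all(sol <= 1))
    xr <- range(mesh$nodes[, 1])
    rmm <- discs$radius_um * 1e-3
    if (any(discs$x - rmm < xr[1] - 1e-9) || any(discs$x + rmm > xr[2] + 1e-9))
      stop("obstacle disc overlaps the inlet or outlet boundary")
    for (i in seq_len(nrow(discs))) {
      r <- rmm[i]
      d2 <- (mesh$nodes[, 1] - discs$x[i])^2 + (mesh$nodes[, 2] - discs$y[i])^2
      inside <- d2 <= r^2
      if (sol[i] >= 0.999) raw[inside] <- 1
      targets <- if (any(inside)) which(inside) else which.min(d2)
      chi[targets] <- pmax(chi[targets], sol[i])
    }
  }
  chi <- pmin(1, pmax(raw, chi))
  # one diffusion pass over the element graph: spreads the indicator one
  # layer without inflating the total blocked area
  a1 <- c(mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3])
  a2 <- c(mesh$tri[, 2], mesh$tri[, 3], mesh$tri[, 1])
  acc <- numeric(n); cnt <- numeric(n)
  for (e in list(cbind(a1, a2), cbind(a2, a1))) {
    s <- rowsum(chi[e[, 2]], e[, 1])
    k <- rowsum(rep(1, nrow(e)), e[, 1])
    ids <- as.integer(rownames(s))
    acc[ids] <- acc[ids] + s[, 1]
    cnt[ids] <- cnt[ids] + k[, 1]
  }
  nb_mean <- ifelse(cnt > 0, acc / cnt, 0)
  sm <- (2 / 3) * chi + (1 / 3) * nb_mean
  mesh$chi <- pmin(1, pmax(raw, sm))
  mesh$obstacle <- raw
  wd <- attr(discs, "wire_d_mm")
  mesh$wire_d_mm <- if (is.null(wd)) 0.12 else wd
  mesh
}

# lumped nodal areas (1/3 of adjacent element areas), mm^2
.lumped_area <- function(mesh) {
  t <- mesh$tri
  x1 <- mesh$nodes[t[, 1], 1]; y1 <- mesh$nodes[t[, 1], 2]
  x2 <- mesh$nodes[t[, 2], 1]; y2 <- mesh$nodes[t[, 2], 2]
  x3 <- mesh$nodes[t[, 3], 1]; y3 <- mesh$nodes[t[, 3], 2]
  A <- 0.5 * abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  m <- numeric(nrow(mesh$nodes))
  for (kk in 1:3) {
    agg <- rowsum(A / 3, t[, kk])
    ids <- as.integer(rownames(agg))
    m[ids] <- m[ids] + agg[, 1]
  }
  m
}
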