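# Conforming quadratic tetrahedral meshing of the two-region cell
# (cytoplasm + nucleus) plus analytic fixtures.
#
# Strategy for the cell: the axisymmetric cross-section (r, z) is
# decomposed by rays fanning out from the nucleus centre -- the domain is
# star-shaped with respect to it -- giving an inner "polar" mesh of the
# nucleus half-ellipse and graded layers between the ellipse and the outer
# boundary (substrate, lateral edge, dome). The triangulated cross-section
# is revolved into wedges over azimuthal sectors and split into tetrahedra
# with a rotation-invariant diagonal rule, so the mesh has the exact
# discrete rotational symmetry of its sector count. Mid-edge nodes on the
# nuclear interface, dome and lateral surfaces are snapped onto the true
# curved surfaces, which makes region volumes fourth-order accurate in the
# sector angle.

AXTOL <- 1e-9

new_cs_mesh <- function(nodes, tet10, region, node_sets,
                        element_meta = NULL) {
  structure(list(nodes = nodes, tet10 = tet10, region = region,
                 tru3 = NULL, fiber_network = NULL, fiber_spec = NULL,
                 ties = NULL, slaved_nodes = integer(0),
                 node_sets = node_sets,
                 element_sets = list(near_attachment = integer(0)),
                 element_meta = element_meta,
                 length_unit = "um"),
            class = "cs_mesh")
}

#' @method print cs_mesh
#' @export
print.cs_mesh <- function(x, ...) {
  cat(sprintf("cs_mesh: %d nodes, %d tet10 (%d cytoplasm, %d nucleus), %d truss\n",
              nrow(x$nodes), nrow(x$tet10), sum(x$region == 1L),
              sum(x$region == 2L),
              if (is.null(x$tru3)) 0L else nrow(x$tru3)))
  invisible(x)
}

region_names <- c("cytoplasm", "nucleus")

# signed 6*volume of straight corner tets, vectorized
signed_vol6 <- function(nodes, conn4) {
  a <- nodes[conn4[, 2], , drop = FALSE] - nodes[conn4[, 1], , drop = FALSE]
  b <- nodes[conn4[, 3], , drop = FALSE] - nodes[conn4[, 1], , drop = FALSE]
  d <- nodes[conn4[, 4], , drop = FALSE] - nodes[conn4[, 1], , drop = FALSE]
  cx <- b[, 2] * d[, 3] - b[, 3] * d[, 2]
  cy <- b[, 3] * d[, 1] - b[, 1] * d[, 3]
  cz <- b[, 1] * d[, 2] - b[, 2] * d[, 1]
  a[, 1] * cx + a[, 2] * cy + a[, 3] * cz
}

orient_tets <- function(nodes, conn4) {
  v <- signed_vol6(nodes, conn4)
  flip <- v < 0
  if (any(flip)) {
    tmp <- conn4[flip, 3]
    conn4[flip, 3] <- conn4[flip, 4]
    conn4[flip, 4] <- tmp
  }
  if (any(abs(signed_vol6(nodes, conn4)) < 1e-14))
    stopf("degenerate (zero-volume) tetrahedron generated")
  conn4
}

# expand linear tets to tet10; returns conn10 and edge bookkeeping
tet4_to_tet10 <- function(nodes, conn4) {
  edge_local <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  nel <- nrow(conn4)
  ea <- matrix(0L, nel * 6, 2)
  for (m in 1:6) {
    idx <- seq_len(nel) + (m - 1) * nel
    ea[idx, 1] <- conn4[, edge_local[m, 1]]
    ea[idx, 2] <- conn4[, edge_local[m, 2]]
  }
  lo <- pmin(ea[, 1], ea[, 2]); hi <- pmax(ea[, 1], ea[, 2])
  key <- lo * (nrow(nodes) + 1) + hi
  ukey <- unique(key)
  mid_id <- nrow(nodes) + match(key, ukey)
  conn10 <- cbind(conn4, matrix(mid_id, nel, 6))
  first <- match(ukey, key)
  edges <- cbind(lo[first], hi[first])
  mids <- (nodes[edges[, 1], , drop = FALSE] +
           nodes[edges[, 2], , drop = FALSE]) / 2
  list(conn10 = conn10, edges = edges, mids = mids)
}

#' Generate the two-region cell mesh
#'
#' Builds a watertight, conforming quadratic tetrahedral mesh of the
#' cytoplasm and nucleus. The basal surface is exactly planar (z = 0); the
#' nuclear interface, dome and lateral surfaces are curved through their
#' mid-edge nodes. The azimuthal sector count is a multiple of 8 so meshes
#' always possess exact 45-degree discrete rotational symmetry, matching
#' the fiber network. Deterministic for fixed arguments.
#'
#' @param geom A \code{\link{cell_geometry_spec}}.
#' @param nucleus A \code{\link{nucleus_spec}}.
#' @param target_edge Nominal element edge length in micrometres,
#'   in \code{[0.1, 2]}; 0.8 gives roughly 5,000 elements.
#' @param sectors,rays,layers,rings Optional explicit resolution overrides
#'   (azimuthal sectors -- must be a multiple of 8 --, ray intervals over the
#'   meridian, layers between nucleus and boundary, rings inside the
#'   nucleus). Mainly for small test fixtures.
#' @return A \code{cs_mesh}.
#' @export
generate_cell_mesh <- function(geom, nucleus, target_edge = 0.8,
                               sectors = NULL, rays = NULL, layers = NULL,
                               rings = NULL) {
  if (target_edge < 0.1 || target_edge > 2)
    stopf("target_edge must lie in [0.1, 2] um")
  scale <- 0.8 / target_edge
  S <- if (is.null(sectors)) 8L * max(2L, as.integer(round(2 * scale)))
       else as.integer(sectors)
  if (S %% 8L != 0L) stopf("sectors must be a multiple of 8")
  nphi <- if (is.null(rays)) max(10L, as.integer(round(14 * scale)))
          else as.integer(rays)
  nlay <- if (is.null(layers)) max(2L, as.integer(round(3 * scale)))
          else as.integer(layers)
  nring <- if (is.null(rings)) max(2L, as.integer(round(2 * scale)))
           else as.integer(rings)

  R <- geom$radius
  a <- nucleus$equatorial_diameter / 2
  c_ <- nucleus$polar_diameter / 2
  zc <- nucleus$center_height
  if (nucleus_clearance(geom, nucleus) < 0.25)
    stopf("nucleus must clear the cytoplasm boundary by >= 0.25 um")
  hR <- profile_height(R, geom)

  # --- rays in sheared coordinates (r, zeta = z / h(r)) ------------------
  # In these coordinates the cross-section is exactly the rectangle
  # [0, R] x [0, 1], which is star-shaped from the (sheared) nucleus
  # centre for any dome profile; rays fan from there to the rectangle.
  zeta_c <- zc / profile_height(0, geom)
  to_real <- function(r, zeta) cbind(r, zeta * profile_height(r, geom))

  # Outer boundary sampled by (real) arclength so that ray endpoints are
  # evenly spaced on the physical boundary: substrate (0,0)->(R,0), lateral
  # edge (R,0)->(R,hR), dome (R,hR)->(0,H). The rim corners are sample
  # points. Ray angles are the sheared angles of these samples; monotone
  # because the rectangle is convex around the interior centre.
  rg <- seq(R, 0, length.out = 2001)
  zg <- profile_height(rg, geom)
  sdome <- c(0, cumsum(sqrt(diff(rg)^2 + diff(zg)^2)))
  Ldome <- sdome[length(sdome)]
  spacing <- (R + hR + Ldome) / nphi
  n_bot <- max(3L, as.integer(round(R / spacing)))
  n_side <- max(1L, as.integer(round(hR / spacing)))
  n_dome <- max(4L, as.integer(round(Ldome / spacing)))
  rb <- seq(0, R, length.out = n_bot + 1)
  zb <- seq(0, hR, length.out = n_side + 1)[-1]
  sd <- seq(0, Ldome, length.out = n_dome + 1)[-1]
  rd <- stats::approx(sdome, rg, xout = sd)$y
  rd[length(rd)] <- 0
  bpts <- rbind(cbind(rb, 0, 1),                      # bottom (surf code 1)
                cbind(R, zb, 2),                      # side (2)
                cbind(rd, profile_height(rd, geom), 3))  # dome (3)
  bsurf <- c("bottom", "side", "dome")[bpts[, 3]]
  bsurf[abs(bpts[, 1] - R) < 1e-9] <- "side"          # rim corners: side
  bzeta <- ifelse(bsurf == "dome", 1,
                  bpts[, 2] / profile_height(bpts[, 1], geom))
  bzeta[bsurf == "bottom"] <- 0
  th <- atan2(bzeta - zeta_c, bpts[, 1])
  ord <- order(th)
  th <- th[ord]; bsurf <- bsurf[ord]; bzeta <- bzeta[ord]
  br <- bpts[ord, 1]
  keep <- c(TRUE, diff(th) > 1e-6)
  th <- th[keep]; bsurf <- bsurf[keep]; bzeta <- bzeta[keep]
  br <- br[keep]
  nray <- length(th)
  t_out <- sqrt(br^2 + (bzeta - zeta_c)^2)
  osurf <- bsurf

  # nucleus-surface crossing along each sheared ray (the sheared ellipse
  # is a smooth closed curve around the centre)
  t_ell <- vapply(seq_len(nray), function(ri) {
    ell_f <- function(t) {
      p <- to_real(t * cos(th[ri]), zeta_c + t * sin(th[ri]))
      (p[1] / a)^2 + ((p[2] - zc) / c_)^2 - 1
    }
    uniroot(ell_f, c(1e-9, t_out[ri]), tol = 1e-13)$root
  }, 0)

  # --- 2D node table -----------------------------------------------------
  L <- nring + nlay
  n2d <- 1L + L * nray
  id2 <- function(lev, i) 1L + (lev - 1L) * nray + i
  x2 <- numeric(n2d); z2 <- numeric(n2d)
  x2[1] <- 0; z2[1] <- zc
  on_ell <- logical(n2d); psi2 <- rep(NA_real_, n2d)
  outer_surf <- rep(NA_character_, n2d); rprof2 <- rep(NA_real_, n2d)
  for (lev in 1:L) {
    tt <- if (lev <= nring) t_ell * lev / nring
          else t_ell + (t_out - t_ell) * (lev - nring) / nlay
    ids <- id2(lev, seq_len(nray))
    p <- to_real(tt * cos(th), zeta_c + tt * sin(th))
    x2[ids] <- p[, 1]
    z2[ids] <- p[, 2]
    if (lev == nring) {
      on_ell[ids] <- TRUE
      psi2[ids] <- atan2((z2[ids] - zc) / c_, x2[ids] / a)
    }
    if (lev == L) {
      outer_surf[ids] <- osurf
      z2[ids[osurf == "bottom"]] <- 0          # exact substrate plane
      side_i <- osurf == "side"
      x2[ids[side_i]] <- R
      z2[ids[side_i]] <- pmax(pmin(z2[ids[side_i]], hR), 0)
      rprof2[ids] <- x2[ids]
    }
  }
  x2[abs(x2) < AXTOL] <- 0

  # --- 2D triangles with region tags -------------------------------------
  tri <- matrix(0L, 0, 3); treg <- integer(0)
  add <- function(m, r) {
    tri <<- rbind(tri, m); treg <<- c(treg, rep.int(r, nrow(m)))
  }
  fan <- cbind(1L, id2(1L, seq_len(nray - 1L)), id2(1L, seq_len(nray - 1L) + 1L))
  add(fan, 2L)
  for (lev in 1:(L - 1L)) {
    A <- id2(lev, seq_len(nray - 1L));      B <- id2(lev, seq_len(nray - 1L) + 1L)
    C <- id2(lev + 1L, seq_len(nray - 1L) + 1L); D <- id2(lev + 1L, seq_len(nray - 1L))
    r <- if (lev + 1L <= nring) 2L else 1L
    add(cbind(A, B, C), r)
    add(cbind(A, C, D), r)
  }

  # --- revolve: 3D corner nodes ------------------------------------------
  axis2 <- x2 == 0
  alpha <- 2 * pi * (0:(S - 1)) / S
  id3 <- matrix(0L, n2d, S)
  coords <- matrix(0, 0, 3)
  nid <- 0L
  # interleave so ids grow with sector within each 2D node (rule below only
  # uses 2D ids, so 3D numbering is free)
  nodes_list <- vector("list", n2d)
  for (m in seq_len(n2d)) {
    if (axis2[m]) {
      nid <- nid + 1L
      id3[m, ] <- nid
      nodes_list[[m]] <- c(0, 0, z2[m])
    } else {
      id3[m, ] <- nid + seq_len(S)
      nid <- nid + S
      nodes_list[[m]] <- cbind(x2[m] * cos(alpha), x2[m] * sin(alpha), z2[m])
    }
  }
  coords <- do.call(rbind, nodes_list)

  # corner metadata for mid-edge snapping
  nnode <- nrow(coords)
  n_axis <- rep(FALSE, nnode); n_ell <- rep(FALSE, nnode)
  n_surf <- rep(NA_character_, nnode)
  n_psi <- rep(NA_real_, nnode); n_rprof <- rep(NA_real_, nnode)
  n_az <- rep(NA_real_, nnode)
  for (m in seq_len(n2d)) {
    ids <- unique(id3[m, ])
    n_axis[ids] <- axis2[m]
    n_ell[ids] <- on_ell[m]
    n_surf[ids] <- outer_surf[m]
    n_psi[ids] <- psi2[m]
    n_rprof[ids] <- rprof2[m]
    if (!axis2[m]) n_az[id3[m, ]] <- alpha
  }

  # --- wedges -> tets (rotation-invariant split) --------------------------
  ntri <- nrow(tri)
  conn_list <- vector("list", ntri * S)
  meta_list <- vector("list", ntri * S)
  ct <- 0L
  for (tix in seq_len(ntri)) {
    v <- sort(tri[tix, ])                 # ascending 2D ids drive the rule
    ax <- axis2[v]
    na <- sum(ax)
    for (s in seq_len(S)) {
      sn <- if (s == S) 1L else s + 1L
      b <- id3[v, s]; tp <- id3[v, sn]
      if (na == 0L) {
        tets <- rbind(c(b[1], b[2], b[3], tp[3]),
                      c(b[1], b[2], tp[3], tp[2]),
                      c(b[1], tp[2], tp[3], tp[1]))
      } else if (na == 1L) {
        A <- b[ax][1]
        u <- v[!ax][1]; w <- v[!ax][2]   # u < w
        ub <- id3[u, s]; wb <- id3[w, s]; ut <- id3[u, sn]; wt <- id3[w, sn]
        tets <- rbind(c(A, ub, wb, wt),
                      c(A, ub, wt, ut))
      } else {
        A1 <- b[ax][1]; A2 <- b[ax][2]
        u <- v[!ax][1]
        tets <- rbind(c(A1, A2, id3[u, s], id3[u, sn]))
      }
      ct <- ct + 1L
      conn_list[[ct]] <- tets
      meta_list[[ct]] <- cbind(tix, s, seq_len(nrow(tets)))
    }
  }
  conn4 <- do.call(rbind, conn_list)
  meta <- do.call(rbind, meta_list)
  nsub <- vapply(conn_list, nrow, 1L)
  region <- rep(rep(treg, each = 0L), 0L) # placeholder
  region <- rep.int(rep(treg, times = rep(S, ntri)), nsub)
  conn4 <- orient_tets(coords, conn4)

  # --- quadratic expansion + surface snapping ----------------------------
  q <- tet4_to_tet10(coords, conn4)
  em <- q$edges; mids <- q$mids
  e1 <- em[, 1]; e2 <- em[, 2]
  mean_az <- function(a1, a2) {
    a1[is.na(a1)] <- a2[is.na(a1)]
    a2[is.na(a2)] <- a1[is.na(a2)]
    atan2(sin(a1) + sin(a2), cos(a1) + cos(a2))
  }
  snapped_ell <- rep(FALSE, nrow(em))
  snap_s <- !is.na(n_surf[e1]) & !is.na(n_surf[e2]) &
    n_surf[e1] == "side" & n_surf[e2] == "side"
  snap_d <- !is.na(n_surf[e1]) & !is.na(n_surf[e2]) &
    ((n_surf[e1] == "dome" & n_surf[e2] %in% c("dome", "side")) |
     (n_surf[e1] == "side" & n_surf[e2] == "dome"))
  snap_d <- snap_d & !snap_s
  snap_e <- n_ell[e1] & n_ell[e2]
  both_axis <- n_axis[e1] & n_axis[e2]
  snap_s <- snap_s & !both_axis; snap_d <- snap_d & !both_axis
  snap_e <- snap_e & !both_axis
  if (any(snap_e)) {
    psib <- (n_psi[e1[snap_e]] + n_psi[e2[snap_e]]) / 2
    azb <- mean_az(n_az[e1[snap_e]], n_az[e2[snap_e]])
    mids[snap_e, ] <- cbind(a * cos(psib) * cos(azb),
                            a * cos(psib) * sin(azb),
                            zc + c_ * sin(psib))
    snapped_ell[snap_e] <- TRUE
  }
  if (any(snap_s)) {
    azb <- mean_az(n_az[e1[snap_s]], n_az[e2[snap_s]])
    zb <- (coords[e1[snap_s], 3] + coords[e2[snap_s], 3]) / 2
    mids[snap_s, ] <- cbind(R * cos(azb), R * sin(azb), zb)
  }
  if (any(snap_d)) {
    rp <- (pmin(n_rprof[e1[snap_d]], R) + pmin(n_rprof[e2[snap_d]], R)) / 2
    azb <- mean_az(n_az[e1[snap_d]], n_az[e2[snap_d]])
    mids[snap_d, ] <- cbind(rp * cos(azb), rp * sin(azb),
                            profile_height(rp, geom))
  }
  nodes <- rbind(coords, mids)
  conn10 <- q$conn10

  # guard: revert snapped mid-edges of any inverted element
  met <- .cs_tet10_metrics(nodes, conn10)
  bad <- which(met$min_detj <= 0)
  if (length(bad)) {
    bad_mid <- unique(as.vector(conn10[bad, 5:10])) - nrow(coords)
    bad_mid <- bad_mid[bad_mid > 0]
    nodes[nrow(coords) + bad_mid, ] <-
      (nodes[em[bad_mid, 1], ] + nodes[em[bad_mid, 2], ]) / 2
    snapped_ell[bad_mid] <- FALSE
    met <- .cs_tet10_metrics(nodes, conn10)
    if (any(met$min_detj <= 0))
      stopf("mesh generation failed: %d inverted elements remain",
            sum(met$min_detj <= 0))
  }

  nmid <- nrow(mids)
  basal <- which(abs(nodes[, 3]) < 1e-9)
  axisn <- which(nodes[, 1]^2 + nodes[, 2]^2 < AXTOL)
  interface <- c(which(n_ell), nrow(coords) + which(snapped_ell))
  node_sets <- list(basal = basal, axis = axisn, interface = interface,
                    sf_foot_anchors = integer(0),
                    sf_nucleus_anchors = integer(0))
  mesh <- new_cs_mesh(nodes, conn10, region, node_sets,
                      element_meta = data.frame(tri2d = meta[, 1],
                                                sector = meta[, 2],
                                                sub = meta[, 3]))
  mesh$sectors <- S
  mesh
}

#' Attach stress-fiber truss elements to a cell mesh
#'
#' Each fiber becomes one 3-node quadratic truss whose end nodes are tied to
#' the nearest mesh node on the target surface (basal plane / nuclear
#' interface) at the fiber's azimuth; because the tie is a node identity the
#' connection transmits translations only -- a pin joint. The mid node is
#' slaved to the ends (static condensation of a straight quadratic truss),
#' so no transverse-singular degrees of freedom are introduced.
#'
#' @param mesh A \code{cs_mesh} from \code{\link{generate_cell_mesh}}.
#' @param network A \code{\link{build_fiber_network}} result (or \code{NULL}
#'   / empty for no-op).
#' @param tolerance Maximum allowed distance (um) between a fiber endpoint
#'   and its tied surface node.
#' @return The mesh with truss elements, tie records and anchor node sets.
#' @export
attach_fiber_elements <- function(mesh, network, tolerance = 2.0) {
  if (is.null(network) || nrow(network) == 0) return(mesh)
  nodes <- mesh$nodes
  near_az <- function(cands, az_rad) {
    azn <- atan2(nodes[cands, 2], nodes[cands, 1])
    d <- abs(atan2(sin(azn - az_rad), cos(azn - az_rad)))
    r <- sqrt(nodes[cands, 1]^2 + nodes[cands, 2]^2)
    cands[d < 1e-6 | r < 1e-6]
  }
  ties <- NULL
  ends <- matrix(0L, nrow(network), 2)
  for (i in seq_len(nrow(network))) {
    az <- network$azimuth_deg[i] * pi / 180
    p0 <- c(network$x0[i], network$y0[i], network$z0[i])
    p1 <- c(network$x1[i], network$y1[i], network$z1[i])
    cb <- near_az(mesh$node_sets$basal, az)
    if (!length(cb)) stopf("no basal nodes found at azimuth %g deg",
                           network$azimuth_deg[i])
    db <- sqrt(colSums((t(nodes[cb, , drop = FALSE]) - p0)^2))
    nb <- cb[which.min(db)]
    ci <- near_az(mesh$node_sets$interface, az)
    if (!length(ci)) stopf("no interface nodes found at azimuth %g deg",
                           network$azimuth_deg[i])
    di <- sqrt(colSums((t(nodes[ci, , drop = FALSE]) - p1)^2))
    ni <- ci[which.min(di)]
    if (min(db) > tolerance || min(di) > tolerance)
      stopf("fiber %d endpoint is %.2f um from the nearest surface node (tolerance %g um)",
            i, max(min(db), min(di)), tolerance)
    ends[i, ] <- c(nb, ni)
    ties <- rbind(ties,
                  data.frame(fiber = i, end = c("foot", "nucleus"),
                             node = c(nb, ni), misfit_um = c(min(db), min(di))))
  }
  mids <- (nodes[ends[, 1], , drop = FALSE] + nodes[ends[, 2], , drop = FALSE]) / 2
  mid_ids <- nrow(nodes) + seq_len(nrow(network))
  mesh$nodes <- rbind(nodes, mids)
  mesh$tru3 <- cbind(ends[, 1], mid_ids, ends[, 2])
  mesh$fiber_network <- network
  mesh$fiber_spec <- attr(network, "spec")
  mesh$ties <- ties
  mesh$slaved_nodes <- mid_ids
  mesh$node_sets$sf_foot_anchors <- unique(ends[, 1])
  mesh$node_sets$sf_nucleus_anchors <- unique(ends[, 2])
  mesh
}

#' Rectangular slab fixture
#'
#' Single-region slab with its basal plane at z = 0, centred on the axis,
#' used as an analytic oracle (plane-stress equibiaxial loading, patch
#' tests). Structured grid, six tetrahedra per box cell.
#'
#' @param side In-plane side length, micrometres.
#' @param thickness Slab thickness, micrometres (should be much less than
#'   \code{side}).
#' @param target_edge Nominal edge length, micrometres.
#' @return A \code{cs_mesh} with a single \code{cytoplasm} region.
#' @export
make_slab_fixture <- function(side = 10, thickness = 1, target_edge = 1) {
  if (thickness >= side) stopf("slab fixture expects thickness < side")
  nx <- max(2L, as.integer(round(side / target_edge)))
  nz <- max(1L, as.integer(round(thickness / target_edge)))
  xs <- seq(-side / 2, side / 2, length.out = nx + 1)
  zs <- seq(0, thickness, length.out = nz + 1)
  nid <- function(i, j, k) {
    (k - 1L) * (nx + 1L)^2 + (j - 1L) * (nx + 1L) + i
  }
  grid <- expand.grid(i = seq_len(nx + 1), j = seq_len(nx + 1),
                      k = seq_len(nz + 1))
  nodes <- cbind(xs[grid$i], xs[grid$j], zs[grid$k])
  kuhn <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  cells <- expand.grid(i = seq_len(nx), j = seq_len(nx), k = seq_len(nz))
  corner <- cbind(nid(cells$i,     cells$j,     cells$k),
                  nid(cells$i + 1, cells$j,     cells$k),
                  nid(cells$i,     cells$j + 1, cells$k),
                  nid(cells$i + 1, cells$j + 1, cells$k),
                  nid(cells$i,     cells$j,     cells$k + 1),
                  nid(cells$i + 1, cells$j,     cells$k + 1),
                  nid(cells$i,     cells$j + 1, cells$k + 1),
                  nid(cells$i + 1, cells$j + 1, cells$k + 1))
  conn4 <- do.call(rbind, lapply(seq_len(6), function(t)
    cbind(corner[, kuhn[t, 1]], corner[, kuhn[t, 2]],
          corner[, kuhn[t, 3]], corner[, kuhn[t, 4]])))
  conn4 <- orient_tets(nodes, conn4)
  q <- tet4_to_tet10(nodes, conn4)
  nodes <- rbind(nodes, q$mids)
  basal <- which(abs(nodes[, 3]) < 1e-12)
  new_cs_mesh(nodes, q$conn10, rep.int(1L, nrow(conn4)),
              list(basal = basal, axis = integer(0), interface = integer(0),
                   sf_foot_anchors = integer(0),
                   sf_nucleus_anchors = integer(0)))
}

#' Single quadratic tetrahedron fixture
#'
#' One unit-size tet10 element (region cytoplasm), for constitutive and
#' element-level unit tests.
#' @return A \code{cs_mesh} with one element.
#' @export
make_single_element_fixture <- function() {
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  conn4 <- matrix(1:4, 1)
  q <- tet4_to_tet10(corners, conn4)
  nodes <- rbind(corners, q$mids)
  basal <- which(abs(nodes[, 3]) < 1e-12)
  new_cs_mesh(nodes, q$conn10, 1L,
              list(basal = basal, axis = integer(0), interface = integer(0),
                   sf_foot_anchors = integer(0),
                   sf_nucleus_anchors = integer(0)))
}

#' Mesh metrics
#'
#' Element counts, per-region quadrature volumes (accounting for curved
#' element boundaries) and the worst scaled Jacobian (min/max quadrature
#' Jacobian ratio per element; 1 for straight elements, must be positive).
#'
#' @param mesh A \code{cs_mesh}.
#' @return A list with \code{n_tets}, \code{n_truss}, \code{region_volumes}
#'   (named, cubic micrometres), \code{total_volume} and
#'   \code{min_scaled_jacobian}.
#' @export
mesh_metrics <- function(mesh) {
  met <- .cs_tet10_metrics(mesh$nodes, mesh$tet10)
  rv <- vapply(1:2, function(r) sum(met$volume[mesh$region == r]), 0)
  names(rv) <- region_names
  list(n_tets = nrow(mesh$tet10),
       n_truss = if (is.null(mesh$tru3)) 0L else nrow(mesh$tru3),
       region_volumes = rv,
       total_volume = sum(rv),
       min_scaled_jacobian = min(met$scaled_jacobian),
       element_volumes = met$volume)
}

#' Check mesh conformity
#'
#' Verifies that every interior face (corner-node triple) is shared by
#' exactly two tetrahedra and classifies interface faces (cytoplasm on one
#' side, nucleus on the other).
#'
#' @param mesh A \code{cs_mesh}.
#' @return List with counts and a \code{conforming} flag.
#' @export
check_mesh_conformity <- function(mesh) {
  conn <- mesh$tet10[, 1:4, drop = FALSE]
  faces_local <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  nel <- nrow(conn)
  f <- do.call(rbind, lapply(1:4, function(k) {
    m <- conn[, faces_local[k, ], drop = FALSE]
    t(apply(m, 1, sort))
  }))
  eid <- rep(seq_len(nel), 4)
  key <- paste(f[, 1], f[, 2], f[, 3], sep = "/")
  cnt <- table(key)
  ok <- all(cnt <= 2)
  shared <- names(cnt)[cnt == 2]
  idx <- split(eid, key)
  inter <- vapply(idx[shared], function(e)
    length(unique(mesh$region[e])) == 2, TRUE)
  list(conforming = ok,
       n_boundary_faces = sum(cnt == 1),
       n_interior_faces = sum(cnt == 2),
       n_interface_faces = sum(inter))
}
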