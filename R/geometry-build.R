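# 3D capsomer-lattice construction: isometric shells by projection of the
# hexagonal net onto the circumscribing sphere, prolate shells as two
# icosahedral end caps joined by a rolled hexagonal tube. Adjacency is
# derived combinatorially (isometric: on the folded polyhedron, where net
# distances are preserved well within the first/second-neighbour gap;
# prolate: in the flat net with seam identifications), so it is exact and
# independent of the curved embedding.

ICO_POLAR <- atan(2)                     # polar angle of the vertex ring, 63.4349 deg
ICO_CIRCUMRADIUS_PER_EDGE <- sqrt(10 + 2 * sqrt(5)) / 4  # 0.9510565...

hex_basis <- function() {
  cbind(a1 = c(1, 0), a2 = c(0.5, sqrt(3) / 2))
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# all hexagonal lattice points inside (or on) the triangle (A, B, C), given
# as 2-column coordinates; returns cartesian points and barycentric coords
lattice_points_in_triangle <- function(A, B, C, eps = 1e-9) {
  Bs <- hex_basis()
  rng <- ceiling(max(abs(c(A, B, C)))) + 1L
  grid <- expand.grid(n1 = -rng:rng, n2 = -rng:rng)
  pts <- cbind(grid$n1 + 0.5 * grid$n2, grid$n2 * sqrt(3) / 2)
  M <- cbind(B - A, C - A)
  vw <- t(solve(M, t(pts) - A))
  u <- 1 - vw[, 1] - vw[, 2]
  keep <- u >= -eps & vw[, 1] >= -eps & vw[, 2] >= -eps
  list(xy = pts[keep, , drop = FALSE],
       bary = cbind(u = u[keep], v = vw[keep, 1], w = vw[keep, 2]))
}

icosahedron_vertices <- function() {
  r <- 2 / sqrt(5); zr <- 1 / sqrt(5)
  up <- t(sapply(0:4, function(t) c(r * cos(2 * pi * t / 5),
                                    r * sin(2 * pi * t / 5), zr)))
  lo <- t(sapply(0:4, function(t) c(r * cos(2 * pi * (t + 0.5) / 5),
                                    r * sin(2 * pi * (t + 0.5) / 5), -zr)))
  rbind(top = c(0, 0, 1), up, lo, bottom = c(0, 0, -1))
}

icosahedron_faces <- function(verts) {
  U <- function(t) 2L + (t %% 5L)
  L <- function(t) 7L + (t %% 5L)
  f <- list()
  for (t in 0:4) {
    f[[length(f) + 1L]] <- c(1L, U(t), U(t + 1))
    f[[length(f) + 1L]] <- c(U(t), L(t), U(t + 1))
    f[[length(f) + 1L]] <- c(L(t), U(t + 1), L(t + 1))
    f[[length(f) + 1L]] <- c(12L, L(t + 1), L(t))
  }
  # enforce counter-clockwise orientation seen from outside, so that a
  # chiral lattice keeps one consistent handedness on every face
  lapply(f, function(idx) {
    v <- verts[idx, ]
    n <- crossprod3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    if (sum(n * colMeans(v)) < 0) idx[c(1, 3, 2)] else idx
  })
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

point_key <- function(p, scale) {
  apply(round(p / scale, 4), 1, paste, collapse = "/")
}

adjacency_from_coords <- function(coords, cutoff) {
  d <- as.matrix(stats::dist(coords))
  idx <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  cbind(from = idx[, 1], to = idx[, 2])
}

new_capsomer_lattice <- function(architecture, capsomers, edges, lattice_constant) {
  rownames(capsomers) <- NULL
  structure(list(architecture = architecture,
                 capsomers = capsomers,
                 edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
                 lattice_constant = lattice_constant,
                 axis = c(0, 0, 1)),
            class = "capsomer_lattice")
}

#' @export
print.capsomer_lattice <- function(x, ...) {
  k <- table(x$capsomers$kind)
  cat(sprintf("capsomer lattice: %s, T_end = %d, T_mid = %d, a = %.2f A\n",
              x$architecture$shape, x$architecture$t_end, x$architecture$t_mid,
              x$lattice_constant))
  cat(sprintf("  %d capsomers (%s), %d adjacencies\n", nrow(x$capsomers),
              paste(names(k), as.integer(k), sep = ": ", collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Adjacency graph of a capsomer lattice
#'
#' @param lat A `capsomer_lattice`.
#' @return An [igraph::graph] whose vertex names are capsomer ids.
#' @export
lattice_graph <- function(lat) {
  stopifnot(inherits(lat, "capsomer_lattice"))
  g <- igraph::graph_from_edgelist(cbind(as.character(lat$edges[, 1]),
                                         as.character(lat$edges[, 2])),
                                   directed = FALSE)
  igraph::permute(g, match(igraph::V(g)$name, as.character(lat$capsomers$id)))
}

#' Build a 3D isometric (icosahedral) capsomer lattice
#'
#' Capsomer centres are obtained by tiling the twenty icosahedral net
#' triangles defined by the lattice walk `(h, k)` with the hexagonal
#' capsomer lattice and projecting the folded net radially onto the
#' circumscribing sphere. Pentamers sit at the 12 icosahedral vertices;
#' all other lattice points are hexamers. Adjacency is computed on the
#' folded (pre-projection) polyhedron where net distances are preserved.
#'
#' @param h,k Lattice walk between adjacent five-fold vertices.
#' @param lattice_constant Hexamer centre-to-centre spacing in Angstrom.
#' @param portal If `TRUE` the pentamer at the bottom (-z) vertex is
#'   replaced by a portal.
#' @param adjacency_factor Two capsomers are adjacent when their net
#'   distance is below `adjacency_factor * lattice_constant` (midway
#'   between the first and second neighbour shells by default).
#' @return A `capsomer_lattice`.
#' @examples
#' lat <- build_icosahedral_lattice(2, 0)
#' table(lat$capsomers$kind)
#' @export
build_icosahedral_lattice <- function(h, k, lattice_constant = 110.85,
                                      portal = FALSE, adjacency_factor = 1.35) {
  check_hk(h, k)
  if (lattice_constant <= 0) stop("lattice_constant must be > 0", call. = FALSE)
  a <- lattice_constant
  T <- t_number(h, k)
  R <- a * sqrt(T) * ICO_CIRCUMRADIUS_PER_EDGE
  verts <- icosahedron_vertices() * R
  faces <- icosahedron_faces(verts)

  Bv <- c(h + k / 2, k * sqrt(3) / 2)    # net in units of the lattice constant
  Cv <- as.vector(rot2(60) %*% Bv)
  tri <- lattice_points_in_triangle(c(0, 0), Bv, Cv)

  keys <- character(); coords <- NULL; is_pent <- logical()
  for (f in faces) {
    V <- verts[f, ]
    p3 <- tri$bary %*% V
    kk <- point_key(p3, a)
    new <- !(kk %in% keys)
    if (any(new)) {
      keys <- c(keys, kk[new])
      coords <- rbind(coords, p3[new, , drop = FALSE])
      bb <- tri$bary[new, , drop = FALSE]
      is_pent <- c(is_pent, apply(bb, 1, max) > 1 - 1e-9)
    }
  }
  n <- nrow(coords)
  stopifnot(n == 10L * T + 2L, sum(is_pent) == 12L)

  edges <- adjacency_from_coords(coords, adjacency_factor * a)
  centers <- coords / sqrt(rowSums(coords^2)) * R
  normals <- centers / R

  kind <- ifelse(is_pent, "pentamer", "hexamer")
  if (portal) {
    bottom <- which(is_pent)[which.min(centers[is_pent, 3])]
    kind[bottom] <- "portal"
  }
  capsomers <- data.frame(
    id = seq_len(n), kind = kind,
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    nx = normals[, 1], ny = normals[, 2], nz = normals[, 3],
    region = ifelse(centers[, 3] < 0, "cap_bottom", "cap_top"),
    ring_index = NA_integer_
  )
  arch <- architecture_counts(lattice_vectors(h, k), has_portal = portal)
  new_capsomer_lattice(arch, capsomers, edges, a)
}

# --- prolate construction --------------------------------------------------

# net points of one end cap (wedge of five T = h1^2 sectors around the apex),
# excluding the outer (junction) edge which belongs to the tube bookkeeping.
cap_net_points <- function(h1) {
  pts <- list(); keys <- character()
  add <- function(xy, sector, bary) {
    # the wedge covers 0..300 deg; its 300-deg radial edge is glued to the
    # 0-deg edge, so seam points (sector 4, zero weight on P_4) are
    # canonicalized by a +60 deg rotation onto the already-enumerated copy
    if (sector == 4L && bary[["v"]] < 1e-9 && bary[["u"]] < 1 - 1e-9) {
      key <- paste(round(as.vector(rot2(60) %*% xy), 4), collapse = "/")
    } else {
      key <- paste(round(xy, 4), collapse = "/")
    }
    if (key %in% keys) return(invisible())
    keys <<- c(keys, key)
    pts[[length(pts) + 1L]] <<- list(xy = xy, sector = sector, bary = bary)
  }
  for (t in 0:4) {
    P1 <- h1 * c(cos(t * pi / 3), sin(t * pi / 3))
    P2 <- h1 * c(cos((t + 1) * pi / 3), sin((t + 1) * pi / 3))
    tri <- lattice_points_in_triangle(c(0, 0), P1, P2)
    on_outer <- tri$bary[, "u"] < 1e-9          # junction edge: tube bookkeeping
    for (i in which(!on_outer)) {
      add(tri$xy[i, ], t, tri$bary[i, ])        # bary = (apex, P_t, P_t+1)
    }
  }
  pts
}

#' Build a 3D prolate capsomer lattice
#'
#' Constructs the five-fold prolate shell: two icosahedral end caps with
#' `T_end = h1^2` (achiral caps, `k1 = 0`) joined by a cylindrical
#' midsection whose hexagonal lattice is rolled so that the tube
#' circumference equals `5*h1` hexamer spacings and the two junction
#' pentamer rings are separated by `h2 + k2` lattice rows (`k2` sets the
#' azimuthal skew of the top ring; `k2 = 0` gives the achiral stacked-ring
#' tube). Cap capsomers (including the junction rings) are projected onto
#' the end-cap spheres, midsection capsomers onto the cylinder. Adjacency
#' is derived in the flat net with seam identifications, so it is exact.
#'
#' @param v A [lattice_vectors()] object with `k1 = 0`.
#' @param lattice_constant Hexamer centre-to-centre spacing in Angstrom.
#' @param portal If `TRUE` the bottom apex pentamer is replaced by a portal.
#' @param adjacency_factor Net-distance adjacency cutoff in units of
#'   `lattice_constant`.
#' @return A `capsomer_lattice`.
#' @examples
#' lat <- build_prolate_lattice(lattice_vectors(2, 0, 7, 0), portal = TRUE)
#' table(lat$capsomers$kind, lat$capsomers$region)
#' @export
build_prolate_lattice <- function(v, lattice_constant = 110.85, portal = FALSE,
                                  adjacency_factor = 1.35) {
  stopifnot(inherits(v, "lattice_vectors"))
  if (v$k1 != 0L) {
    stop("unsupported cap/tube seam: prolate construction requires an ",
         "achiral end cap (k1 = 0)", call. = FALSE)
  }
  if (lattice_constant <= 0) stop("lattice_constant must be > 0", call. = FALSE)
  arch <- architecture_counts(v, has_portal = portal)
  a <- lattice_constant
  h1 <- v$h1
  cc <- 5L * h1                       # tube circumference, hexamer spacings
  M <- v$h2 + v$k2                    # lattice rows between junction rings
  skew <- v$k2 %% cc
  rise <- sqrt(3) / 2                 # row spacing, units of a
  Rt <- cc / (2 * pi)                 # tube radius, units of a
  Rs <- Rt / sin(ICO_POLAR)           # end-cap sphere radius, units of a
  zM <- M * rise
  cap_bot <- cap_net_points(h1)
  cap_top <- cap_net_points(h1)

  # --- node table (net/tube bookkeeping) -----------------------------------
  nodes <- list()
  tube_id <- matrix(NA_integer_, nrow = M + 1L, ncol = cc) # [m+1, j+1]
  add_node <- function(info) {
    nodes[[length(nodes) + 1L]] <<- info
    length(nodes)
  }
  bot_cap_ids <- integer(length(cap_bot))
  for (i in seq_along(cap_bot)) {
    bot_cap_ids[i] <- add_node(c(list(type = "cap", cap = "bottom"), cap_bot[[i]]))
  }
  for (m in 0:M) for (j in 0:(cc - 1L)) {
    tube_id[m + 1L, j + 1L] <- add_node(list(type = "tube", m = m, j = j))
  }
  top_cap_ids <- integer(length(cap_top))
  for (i in seq_along(cap_top)) {
    top_cap_ids[i] <- add_node(c(list(type = "cap", cap = "top"), cap_top[[i]]))
  }
  n <- length(nodes)

  # --- kinds ---------------------------------------------------------------
  kind <- rep("hexamer", n)
  apex_of <- function(pts) which(vapply(pts, function(p) sum(abs(p$xy)), 0) < 1e-9)
  apex_bot <- bot_cap_ids[apex_of(cap_bot)]
  apex_top <- top_cap_ids[apex_of(cap_top)]
  kind[apex_bot] <- if (portal) "portal" else "pentamer"
  kind[apex_top] <- "pentamer"
  for (t in 0:4) {
    kind[tube_id[1L, (h1 * t) %% cc + 1L]] <- "pentamer"
    kind[tube_id[M + 1L, (skew + h1 * t) %% cc + 1L]] <- "pentamer"
  }

  # --- adjacency -----------------------------------------------------------
  edges <- new.env(); nedge <- 0L
  add_edge <- function(i, j) {
    if (i == j) return(invisible())
    key <- paste(min(i, j), max(i, j))
    if (!is.null(edges[[key]])) return(invisible())
    edges[[key]] <- c(min(i, j), max(i, j))
  }
  # tube: within-row and row-to-row neighbours
  for (m in 0:M) for (j in 0:(cc - 1L)) {
    id <- tube_id[m + 1L, j + 1L]
    add_edge(id, tube_id[m + 1L, (j + 1L) %% cc + 1L])
    if (m < M) {
      add_edge(id, tube_id[m + 2L, j + 1L])
      add_edge(id, tube_id[m + 2L, (j - 1L) %% cc + 1L])
    }
  }
  # caps: flat-net distances with the 300-degree cone seam identified.
  # junction nodes participate with their tube ids.
  cap_adjacency <- function(cap_ids, cap_pts, junction_row, j_of_l) {
    xy <- do.call(rbind, lapply(cap_pts, function(p) p$xy))
    ids <- cap_ids
    for (t in 0:4) for (l in 0:(h1 - 1L)) {       # junction lattice points
      P1 <- h1 * c(cos(t * pi / 3), sin(t * pi / 3))
      P2 <- h1 * c(cos((t + 1) * pi / 3), sin((t + 1) * pi / 3))
      xy <- rbind(xy, P1 + (l / h1) * (P2 - P1))
      ids <- c(ids, tube_id[junction_row, j_of_l(t, l) + 1L])
    }
    # net distance on the cone: the flat wedge spans 300 degrees, so the
    # distance is the shorter of the direct chord and the chord obtained by
    # closing the wedge across the glued seam (angular span 300 - dtheta)
    ang <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
    rad <- sqrt(rowSums(xy^2))
    cut2 <- adjacency_factor^2
    for (i in seq_len(nrow(xy) - 1L)) for (jj in (i + 1L):nrow(xy)) {
      dth <- abs(ang[i] - ang[jj])
      seam <- 5 * pi / 3 - dth
      dd <- min(sum((xy[i, ] - xy[jj, ])^2),
                rad[i]^2 + rad[jj]^2 - 2 * rad[i] * rad[jj] * cos(seam))
      if (dd < cut2) add_edge(ids[i], ids[jj])
    }
  }
  cap_adjacency(bot_cap_ids, cap_bot, 1L, function(t, l) (h1 * t + l) %% cc)
  cap_adjacency(top_cap_ids, cap_top, M + 1L,
                function(t, l) (skew + h1 * t + l) %% cc)

  # --- embedding (units of a; scaled at the end) ---------------------------
  pos <- matrix(NA_real_, n, 3); nrm <- matrix(NA_real_, n, 3)
  theta_of <- function(x) 2 * pi * x / cc
  # midsection rows on the cylinder
  for (m in 0:M) for (j in 0:(cc - 1L)) {
    th <- theta_of(j + m / 2)
    id <- tube_id[m + 1L, j + 1L]
    pos[id, ] <- c(Rt * cos(th), Rt * sin(th), m * rise)
    nrm[id, ] <- c(cos(th), sin(th), 0)
  }
  # end caps: barycentric map of each net sector onto the cap pyramid, then
  # radial projection onto the cap sphere; junction rings are re-embedded on
  # the cap sphere so the whole cap has icosahedral-cap geometry.
  embed_cap <- function(top) {
    zring <- if (top) zM else 0
    zc <- zring + (if (top) -1 else 1) * Rs * cos(ICO_POLAR)
    apexz <- zc + (if (top) 1 else -1) * Rs
    base_theta <- function(t) {
      if (top) theta_of(skew + h1 * t + M / 2) else theta_of(h1 * t)
    }
    Vt <- function(t) c(Rt * cos(base_theta(t)), Rt * sin(base_theta(t)), zring)
    A <- c(0, 0, apexz)
    proj <- function(q) {
      Cc <- c(0, 0, zc)
      d <- q - Cc
      p <- Cc + d / sqrt(sum(d^2)) * Rs
      list(pos = p, nrm = (p - Cc) / Rs)
    }
    list(A = A, Vt = Vt, proj = proj)
  }
  for (side in c("bottom", "top")) {
    cap <- embed_cap(side == "top")
    ids <- if (side == "bottom") bot_cap_ids else top_cap_ids
    ptl <- if (side == "bottom") cap_bot else cap_top
    for (i in seq_along(ids)) {
      b <- ptl[[i]]$bary; t <- ptl[[i]]$sector
      q <- b["u"] * cap$A + b["v"] * cap$Vt(t) + b["w"] * cap$Vt(t + 1)
      pr <- cap$proj(q)
      pos[ids[i], ] <- pr$pos; nrm[ids[i], ] <- pr$nrm
    }
    jrow <- if (side == "bottom") 1L else M + 1L
    for (j in 0:(cc - 1L)) {
      id <- tube_id[jrow, j + 1L]
      pr <- cap$proj(pos[id, ])
      pos[id, ] <- pr$pos; nrm[id, ] <- pr$nrm
    }
  }
  pos[, 3] <- pos[, 3] - zM / 2       # centre the particle on z = 0
  pos <- pos * a

  # --- regions -------------------------------------------------------------
  region <- rep(NA_character_, n)
  region[c(bot_cap_ids, tube_id[1L, ])] <- "cap_bottom"
  region[c(top_cap_ids, tube_id[M + 1L, ])] <- "cap_top"
  if (M >= 2L) region[as.vector(tube_id[2:M, ])] <- "midsection"
  if (arch$shape == "isometric") {
    region <- ifelse(pos[, 3] < 0, "cap_bottom", "cap_top")
  }

  em <- do.call(rbind, as.list(edges))
  capsomers <- data.frame(
    id = seq_len(n), kind = kind,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    region = region, ring_index = NA_integer_
  )
  lat <- new_capsomer_lattice(arch, capsomers, em, a)
  check_lattice_census(lat)
  lat
}

check_lattice_census <- function(lat) {
  arch <- lat$architecture
  k <- table(factor(lat$capsomers$kind, c("pentamer", "hexamer", "portal")))
  if (k[["pentamer"]] != arch$pentamer_sites ||
      k[["hexamer"]] != arch$hexamer_count ||
      k[["portal"]] != as.integer(arch$has_portal)) {
    stop("internal error: lattice census does not match architecture counts",
         call. = FALSE)
  }
  invisible(lat)
}

#' Apply a rigid motion to a capsomer lattice
#'
#' Rotates and translates all capsomer centres (and rotates normals and the
#' shell axis). Census, adjacency and all derived graph quantities are
#' invariant under this operation.
#'
#' @param lat A `capsomer_lattice`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed `capsomer_lattice`.
#' @export
transform_lattice <- function(lat, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(lat, "capsomer_lattice"))
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be a proper rotation matrix", call. = FALSE)
  }
  cs <- lat$capsomers
  xyz <- t(rotation %*% t(as.matrix(cs[, c("x", "y", "z")]))) +
    matrix(translation, nrow(cs), 3, byrow = TRUE)
  nn <- t(rotation %*% t(as.matrix(cs[, c("nx", "ny", "nz")])))
  cs[, c("x", "y", "z")] <- xyz
  cs[, c("nx", "ny", "nz")] <- nn
  lat$capsomers <- cs
  lat$axis <- as.vector(rotation %*% lat$axis)
  lat
}
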