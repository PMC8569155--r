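# Analyses on a built capsomer lattice: midsection ring partition, helical
# parameters of the tube, pentamer-to-pentamer lattice paths, and
# inter-capsomer dihedral angles.

#' Partition the midsection hexamers into axial rings
#'
#' Clusters the midsection hexamers of a prolate lattice by axial
#' coordinate. Every cluster must contain exactly `5*h1` hexamers (one
#' full turn of the tube); anything else signals a malformed lattice and is
#' a hard error. Isometric shells have no midsection and yield zero rings.
#'
#' @param lat A `capsomer_lattice` built by [build_prolate_lattice()].
#' @param tol Axial clustering tolerance as a fraction of the ring rise.
#' @return A list with `rings` (list of capsomer-id vectors, bottom to
#'   top), `ring_count`, `hexamers_per_ring`, and `lattice` (the input with
#'   `ring_index` filled in).
#' @examples
#' rp <- ring_partition(build_prolate_lattice(lattice_vectors(2, 0, 7, 0)))
#' rp$ring_count
#' @export
ring_partition <- function(lat, tol = 0.25) {
  stopifnot(inherits(lat, "capsomer_lattice"))
  cs <- lat$capsomers
  mid <- cs$region == "midsection" & cs$kind == "hexamer"
  per_ring <- 5L * lat$architecture$vectors$h1
  if (!any(mid)) {
    return(list(rings = list(), ring_count = 0L,
                hexamers_per_ring = per_ring, lattice = lat))
  }
  z <- cs$z[mid]; ids <- cs$id[mid]
  o <- order(z, ids)
  z <- z[o]; ids <- ids[o]
  rise <- sqrt(3) / 2 * lat$lattice_constant
  breaks <- c(0L, which(diff(z) > tol * rise), length(z))
  rings <- lapply(seq_len(length(breaks) - 1L), function(i) {
    sort(ids[(breaks[i] + 1L):breaks[i + 1L]])
  })
  sizes <- lengths(rings)
  if (any(sizes != per_ring)) {
    stop("ring of unexpected size (", paste(sizes, collapse = ","),
         "; expected ", per_ring, "): malformed lattice", call. = FALSE)
  }
  for (i in seq_along(rings)) {
    lat$capsomers$ring_index[match(rings[[i]], lat$capsomers$id)] <- i
  }
  list(rings = rings, ring_count = length(rings),
       hexamers_per_ring = per_ring, lattice = lat)
}

#' Helical parameters of the prolate midsection
#'
#' Measures the helix formed by the midsection hexamer rings: the rise is
#' the mean axial spacing between consecutive rings and the twist is the
#' mean azimuthal phase offset between consecutive rings (phases are
#' computed with the ring's own rotational symmetry, so the twist is
#' reported in `[0, 360/n)` degrees for an `n`-hexamer ring). For an
#' achiral rolled hexagonal lattice these evaluate to
#' `rise = lattice_constant * sqrt(3)/2` and `twist = 360/(2n)` exactly.
#'
#' @param lat A prolate `capsomer_lattice` with at least two rings.
#' @param tol Passed to [ring_partition()].
#' @return An object of class `helical_params` with fields `rise` (A),
#'   `twist` (degrees), `ring_count`, `hexamers_per_ring`, `tube_radius` (A).
#' @examples
#' helical_params(build_prolate_lattice(lattice_vectors(2, 0, 7, 0)))
#' @export
helical_params <- function(lat, tol = 0.25) {
  rp <- ring_partition(lat, tol = tol)
  if (rp$ring_count < 2L) {
    stop("helical parameters require at least 2 midsection rings", call. = FALSE)
  }
  cs <- lat$capsomers
  nper <- rp$hexamers_per_ring
  zbar <- numeric(rp$ring_count); phase <- numeric(rp$ring_count)
  radius <- numeric(rp$ring_count)
  for (i in seq_along(rp$rings)) {
    sel <- match(rp$rings[[i]], cs$id)
    zbar[i] <- mean(cs$z[sel])
    radius[i] <- mean(sqrt(cs$x[sel]^2 + cs$y[sel]^2))
    # phase of an n-fold symmetric point set: argument of sum(exp(i*n*phi))/n
    phi <- atan2(cs$y[sel], cs$x[sel])
    phase[i] <- Arg(sum(exp(1i * nper * phi))) / nper
  }
  sector <- 2 * pi / nper
  dphi <- (diff(phase)) %% sector
  twist <- mean(dphi) * 180 / pi
  structure(list(rise = mean(diff(zbar)), twist = twist,
                 ring_count = rp$ring_count, hexamers_per_ring = nper,
                 tube_radius = mean(radius)),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("helix: %d rings of %d hexamers, rise %.2f A, twist %.3f deg, tube radius %.1f A\n",
              x$ring_count, x$hexamers_per_ring, x$rise, x$twist, x$tube_radius))
  invisible(x)
}

#' Shortest pentamer-to-pentamer lattice path
#'
#' Unweighted shortest path in the capsomer adjacency graph between two
#' pentamers, reporting the number of hexamer capsomers strictly between
#' the endpoints. By default the endpoints are the axially lowest and
#' highest pentamers of the shell (a portal is not a pentamer, so on a
#' portal-bearing prolate head the lowest pentamer sits on the bottom
#' junction ring while the highest is the top apex). Among tied shortest
#' paths the one passing the fewest hexamers is reported; remaining ties
#' are broken by lexicographically smallest capsomer-id sequence.
#'
#' @param lat A `capsomer_lattice`.
#' @param from,to Optional capsomer ids overriding the default endpoints
#'   (must be pentamers).
#' @return A list with `hexamer_count`, `path_ids` (including endpoints),
#'   `from`, `to`.
#' @examples
#' lat <- build_prolate_lattice(lattice_vectors(2, 0, 7, 0), portal = TRUE)
#' shortest_pentamer_path(lat)$hexamer_count
#' @export
shortest_pentamer_path <- function(lat, from = NULL, to = NULL) {
  stopifnot(inherits(lat, "capsomer_lattice"))
  cs <- lat$capsomers
  pent <- cs[cs$kind == "pentamer", ]
  g <- lattice_graph(lat)
  if (igraph::components(g)$no != 1L) {
    stop("adjacency graph is disconnected: malformed lattice", call. = FALSE)
  }
  if (is.null(from)) {
    from <- pent$id[order(pent$z, pent$id)][1L]
  }
  if (is.null(to)) {
    to <- pent$id[order(-pent$z, pent$id)][1L]
  }
  if (cs$kind[match(from, cs$id)] != "pentamer" ||
      cs$kind[match(to, cs$id)] != "pentamer") {
    stop("path endpoints must be pentamers", call. = FALSE)
  }
  if (from == to) stop("endpoints coincide", call. = FALSE)
  asp <- igraph::all_shortest_paths(g, from = as.character(from),
                                    to = as.character(to))$vpaths
  paths <- lapply(asp, function(p) cs$id[as.integer(p)])
  hexn <- vapply(paths, function(p) {
    inner <- p[-c(1L, length(p))]
    sum(cs$kind[match(inner, cs$id)] == "hexamer")
  }, 0L)
  best <- which(hexn == min(hexn))
  if (length(best) > 1L) {
    keys <- vapply(paths[best], function(p) paste(sprintf("%06d", p), collapse = "/"), "")
    best <- best[order(keys)][1L]
  }
  list(hexamer_count = min(hexn), path_ids = paths[[best]], from = from, to = to)
}

#' Dihedral angle between two capsomer planes
#'
#' Interior angle between the planes perpendicular to two outward normals:
#' coplanar capsomers report 180 degrees, a sharper fold a smaller angle.
#'
#' @param n1,n2 Outward normal vectors (any non-zero length).
#' @return Angle in degrees, in `(0, 180]`.
#' @examples
#' dihedral_angle(c(0, 0, 1), c(0, 0, 1)) # 180
#' @export
dihedral_angle <- function(n1, n2) {
  l1 <- sqrt(sum(n1^2)); l2 <- sqrt(sum(n2^2))
  if (l1 < 1e-12 || l2 < 1e-12) stop("degenerate (zero-length) normal", call. = FALSE)
  cosang <- sum(n1 * n2) / (l1 * l2)
  180 - acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Dihedral angles around each pentamer
#'
#' For every pentamer, the interior dihedral angle between its capsomer
#' plane and the plane of each adjacent capsomer, computed from the stored
#' outward normals (coplanar = 180 degrees). By default only
#' pentamer-hexamer pairs are reported (the quantity compared between
#' isometric and prolate shells); `pairs = "all_adjacent"` includes
#' pentamer-pentamer and pentamer-portal contacts, which is the only
#' non-empty choice on a T = 1 shell.
#'
#' @param lat A `capsomer_lattice`.
#' @param pairs `"pentamer_hexamer"` (default) or `"all_adjacent"`.
#' @return An object of class `dihedral_report`: list with `pairs` (a
#'   data.frame `pentamer_id`, `neighbor_id`, `neighbor_kind`, `angle`),
#'   `mean`, `sd`, and `per_pentamer` (mean angle per pentamer).
#' @export
dihedral_angles <- function(lat, pairs = c("pentamer_hexamer", "all_adjacent")) {
  stopifnot(inherits(lat, "capsomer_lattice"))
  pairs <- match.arg(pairs)
  cs <- lat$capsomers
  nm <- as.matrix(cs[, c("nx", "ny", "nz")])
  if (any(abs(sqrt(rowSums(nm^2)) - 1) > 1e-9)) {
    stop("degenerate or non-unit normals in lattice", call. = FALSE)
  }
  kind <- cs$kind
  e <- lat$edges
  rows <- list()
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1]; b <- e[i, 2]
    ka <- kind[match(a, cs$id)]; kb <- kind[match(b, cs$id)]
    pa <- if (ka == "pentamer") a else if (kb == "pentamer") b else next
    nb <- if (pa == a) b else a
    kb2 <- kind[match(nb, cs$id)]
    if (pairs == "pentamer_hexamer" && kb2 != "hexamer") next
    ang <- dihedral_angle(nm[match(pa, cs$id), ], nm[match(nb, cs$id), ])
    rows[[length(rows) + 1L]] <- data.frame(pentamer_id = pa, neighbor_id = nb,
                                            neighbor_kind = kb2, angle = ang)
    if (kb2 == "pentamer") {   # a pentamer-pentamer fold belongs to both
      rows[[length(rows) + 1L]] <- data.frame(pentamer_id = nb, neighbor_id = pa,
                                              neighbor_kind = "pentamer", angle = ang)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pentamer_id = integer(), neighbor_id = integer(),
               neighbor_kind = character(), angle = numeric())
  per <- if (nrow(df)) tapply(df$angle, df$pentamer_id, mean) else numeric()
  structure(list(pairs = df,
                 mean = if (nrow(df)) mean(df$angle) else NA_real_,
                 sd = if (nrow(df) > 1) stats::sd(df$angle) else NA_real_,
                 per_pentamer = per),
            class = "dihedral_report")
}

#' @export
print.dihedral_report <- function(x, ...) {
  cat(sprintf("dihedral report: %d pentamer contacts, mean %.2f deg, sd %.2f deg\n",
              nrow(x$pairs), x$mean, x$sd))
  invisible(x)
}
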