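#' Triangulation number of a quasi-equivalent icosahedral lattice
#'
#' Computes the Caspar-Klug triangulation number `T = h^2 + hk + k^2` for a
#' lattice walk `(h, k)` between neighbouring five-fold vertices on the
#' hexagonal capsomer lattice. A `T` shell contains `60*T` subunits arranged
#' as 12 pentamers and `10*(T - 1)` hexamers.
#'
#' @param h,k Non-negative integers, not both zero.
#' @return A positive integer, the triangulation number.
#' @examples
#' t_number(2, 0) # 4, the end-cap architecture of a prolate phage head
#' t_number(1, 1) # 3
#' @export
t_number <- function(h, k) {
  check_hk(h, k)
  as.integer(h^2 + h * k + k^2)
}

check_hk <- function(h, k, what = "(h,k)") {
  if (length(h) != 1L || length(k) != 1L || !is.numeric(h) || !is.numeric(k) ||
      is.na(h) || is.na(k) || h != round(h) || k != round(k)) {
    stop(what, " must be a pair of integers", call. = FALSE)
  }
  if (h < 0 || k < 0) stop(what, " components must be non-negative", call. = FALSE)
  if (h == 0 && k == 0) stop(what, " must not be (0,0)", call. = FALSE)
  invisible(TRUE)
}

#' Lattice vectors of an isometric or prolate capsid
#'
#' Bundles the end-cap vector `(h1,k1)` and the midsection (elongation)
#' vector `(h2,k2)` of a five-fold prolate capsid. Isometric shells are the
#' degenerate case `(h2,k2) == (h1,k1)`.
#'
#' @param h1,k1 End-cap lattice vector components (non-negative integers).
#' @param h2,k2 Midsection lattice vector components; default to `(h1,k1)`,
#'   i.e. an isometric shell.
#' @return An object of class `lattice_vectors`.
#' @examples
#' lattice_vectors(2, 0, 7, 0) # the prolate phi12-type lattice
#' lattice_vectors(2, 0)       # isometric T = 4
#' @export
lattice_vectors <- function(h1, k1, h2 = h1, k2 = k1) {
  check_hk(h1, k1, "(h1,k1)")
  check_hk(h2, k2, "(h2,k2)")
  structure(list(h1 = as.integer(h1), k1 = as.integer(k1),
                 h2 = as.integer(h2), k2 = as.integer(k2)),
            class = "lattice_vectors")
}

#' @export
print.lattice_vectors <- function(x, ...) {
  cat(sprintf("lattice vectors: cap (%d,%d), midsection (%d,%d)%s\n",
              x$h1, x$k1, x$h2, x$k2,
              if (is_isometric_vectors(x)) " [isometric]" else ""))
  invisible(x)
}

is_isometric_vectors <- function(v) v$h2 == v$h1 && v$k2 == v$k1

#' Midsection triangulation number (Q number) of a prolate capsid
#'
#' For a genuinely prolate lattice the midsection number is
#' `T_mid = h1*h2 + h1*k2 + h2*k1 + k1*k2` (also called `Q`). For the exact
#' isometric degeneracy `(h2,k2) == (h1,k1)` the shell is a plain `T` shell
#' and `Q` is defined as `t_number(h1,k1)`, so that the total subunit count
#' `30*(T_end + Q)` reduces to the isometric `60*T`.
#'
#' @param v A [lattice_vectors()] object.
#' @return A positive integer.
#' @examples
#' q_number(lattice_vectors(2, 0, 7, 0)) # 14
#' q_number(lattice_vectors(2, 0))       # 4 (isometric degeneracy)
#' @export
q_number <- function(v) {
  stopifnot(inherits(v, "lattice_vectors"))
  if (is_isometric_vectors(v)) return(t_number(v$h1, v$k1))
  as.integer(v$h1 * v$h2 + v$h1 * v$k2 + v$h2 * v$k1 + v$k1 * v$k2)
}

#' Capsomer and subunit census of a capsid architecture
#'
#' Fills the complete accounting of a five-fold capsid lattice: end-cap and
#' midsection triangulation numbers, pentamer and hexamer capsomer counts,
#' and the number of capsid-protein (CP-equivalent) subunits. A closed shell
#' always has 12 five-fold sites; a portal, when present, occupies one of
#' them and contributes no CP copies, so the subunit count becomes
#' `30*(T_end + T_mid) - 5`.
#'
#' @param v A [lattice_vectors()] object.
#' @param has_portal Logical; does a portal replace one pentamer?
#' @return An object of class `capsid_architecture` with fields `vectors`,
#'   `t_end`, `t_mid`, `shape`, `has_portal`, `pentamer_sites`,
#'   `hexamer_count`, `cp_equivalent_subunits`.
#' @examples
#' architecture_counts(lattice_vectors(2, 0, 7, 0), has_portal = TRUE)
#' @export
architecture_counts <- function(v, has_portal = FALSE) {
  stopifnot(inherits(v, "lattice_vectors"), is.logical(has_portal))
  t_end <- t_number(v$h1, v$k1)
  t_mid <- q_number(v)
  iso <- is_isometric_vectors(v)
  if (!iso && t_mid < t_end) {
    stop("prolate lattice requires t_mid >= t_end; got T=", t_end,
         ", Q=", t_mid, call. = FALSE)
  }
  pent <- 12L - as.integer(has_portal)
  hexa <- as.integer((30L * (t_end + t_mid) - 60L) / 6L)
  structure(list(
    vectors = v,
    t_end = t_end,
    t_mid = t_mid,
    shape = if (iso) "isometric" else "prolate",
    has_portal = has_portal,
    pentamer_sites = pent,
    hexamer_count = hexa,
    cp_equivalent_subunits = 5L * pent + 6L * hexa
  ), class = "capsid_architecture")
}

#' @export
print.capsid_architecture <- function(x, ...) {
  cat(sprintf("capsid architecture: %s, T_end = %d, T_mid (Q) = %d\n",
              x$shape, x$t_end, x$t_mid))
  cat(sprintf("  %d pentamers%s, %d hexamers, %d CP-equivalent subunits\n",
              x$pentamer_sites, if (x$has_portal) " + 1 portal" else "",
              x$hexamer_count, x$cp_equivalent_subunits))
  invisible(x)
}

#' Enumerate architectures matching an observed census
#'
#' Inverse accounting: scans lattice vectors (canonical orientation
#' `h1 >= k1`, achiral midsection representative `k2 = 0`) for all
#' architectures whose census matches an observed total subunit or hexamer
#' count. For a cap vector `(h1,k1)` the tube seam constrains the
#' achievable midsection numbers to multiples of `h1 + k1`, so not every
#' `(T_end, Q)` pair on paper is realizable.
#'
#' @param subunits Observed CP-equivalent subunit count (optional).
#' @param hexamers Observed hexamer count (optional). Exactly one of
#'   `subunits`/`hexamers` must be given.
#' @param portal Logical; assume a portal replaces one pentamer.
#' @param max_component Brute-force search bound on lattice components.
#' @return A data.frame with one row per architecture, sorted by
#'   `(t_end, t_mid)`; zero rows when nothing matches.
#' @examples
#' enumerate_architectures(subunits = 535, portal = TRUE)
#' @export
enumerate_architectures <- function(subunits = NULL, hexamers = NULL,
                                    portal = FALSE, max_component = 20L) {
  if (is.null(subunits) == is.null(hexamers)) {
    stop("give exactly one of `subunits` or `hexamers`", call. = FALSE)
  }
  target <- if (is.null(subunits)) hexamers else subunits
  if (length(target) != 1L || !is.numeric(target) || target <= 0) {
    stop("constraint value must be a positive number", call. = FALSE)
  }
  rows <- list()
  seen <- character()
  for (h1 in 0:max_component) for (k1 in 0:h1) {
    if (h1 == 0 && k1 == 0) next
    t_end <- t_number(h1, k1)
    # isometric solution plus achiral prolate representatives (h2,0)
    for (h2 in 0:max_component) {
      if (h2 == 0) {
        v <- lattice_vectors(h1, k1) # isometric degeneracy
      } else {
        if (h2 * (h1 + k1) < t_end) next   # t_mid must be >= t_end
        v <- lattice_vectors(h1, k1, h2, 0L)
        if (is_isometric_vectors(v)) next  # already covered by h2 == 0 branch
      }
      arch <- architecture_counts(v, has_portal = portal)
      value <- if (is.null(subunits)) arch$hexamer_count else arch$cp_equivalent_subunits
      if (value != target) next
      key <- paste(arch$t_end, arch$t_mid, v$h1, v$k1, sep = "/")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        h1 = v$h1, k1 = v$k1, h2 = v$h2, k2 = v$k2,
        t_end = arch$t_end, t_mid = arch$t_mid, shape = arch$shape,
        pentamer_sites = arch$pentamer_sites, hexamer_count = arch$hexamer_count,
        cp_equivalent_subunits = arch$cp_equivalent_subunits
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(h1 = integer(), k1 = integer(), h2 = integer(), k2 = integer(),
               t_end = integer(), t_mid = integer(), shape = character(),
               pentamer_sites = integer(), hexamer_count = integer(),
               cp_equivalent_subunits = integer())
  out[order(out$t_end, out$t_mid, out$h1, out$k1), , drop = FALSE]
}
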