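# Independent oracles used across the test files.

# Census accounting from first principles: a closed five-fold shell has 12
# five-fold sites and 30*(T_end + Q) quasi-equivalent subunit positions;
# pentamers carry 5 subunits, hexamers 6, a portal none.
oracle_census <- function(t_end, q, portal = FALSE) {
  pent <- 12L - as.integer(portal)
  hexa <- (30L * (t_end + q) - 60L) / 6L
  list(pentamers = pent, hexamers = hexa,
       subunits = 5L * pent + 6L * hexa)
}

# brute-force enumeration oracle for the inverse census problem (achiral
# midsection representatives, canonical h1 >= k1), independent of the
# package's own search order
oracle_enumerate_hexamers <- function(target, bound = 20L) {
  hits <- list()
  for (h1 in 0:bound) for (k1 in 0:h1) {
    if (h1 + k1 == 0) next
    T <- h1^2 + h1 * k1 + k1^2
    for (m in 0:bound) {          # m = 0 denotes the isometric degeneracy
      Q <- if (m == 0) T else m * (h1 + k1)
      if (m > 0 && Q < T) next
      if (m == h1 && k1 == 0 && m != 0) next  # same as isometric case
      hexa <- (30 * (T + Q) - 60) / 6
      if (hexa == target) hits[[length(hits) + 1L]] <- c(h1, k1, T, Q)
    }
  }
  unique(do.call(rbind, hits))
}

# RMSD of the best rigid superposition found by sampling random rotations
# (translation solved exactly per rotation): an upper-bound oracle that any
# optimal method must beat
oracle_grid_rmsd <- function(X, Y, n_rot = 2000L, seed = 42L) {
  set.seed(seed)
  X0 <- sweep(X, 2, colMeans(X)); Y0 <- sweep(Y, 2, colMeans(Y))
  best <- Inf
  for (i in seq_len(n_rot)) {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    r <- sqrt(mean(rowSums((X0 - Y0 %*% t(Q))^2)))
    if (r < best) best <- r
  }
  best
}

# count hexamers whose lattice neighbours are exclusively hexamers
hexamer_only_count <- function(lat) {
  cs <- lat$capsomers
  hex_ids <- cs$id[cs$kind == "hexamer"]
  sum(vapply(hex_ids, function(i) {
    nb <- c(lat$edges[lat$edges[, 1] == i, 2], lat$edges[lat$edges[, 2] == i, 1])
    all(cs$kind[match(nb, cs$id)] == "hexamer")
  }, logical(1)))
}
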