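phi12 <- build_prolate_lattice(lattice_vectors(2, 0, 7, 0), portal = TRUE)

test_that("prolate construction reproduces the printed midsection organization", {
  cs <- phi12$capsomers
  expect_identical(sum(cs$kind == "hexamer"), 80L)
  expect_identical(sum(cs$kind == "pentamer"), 11L)
  expect_identical(sum(cs$kind == "portal"), 1L)
  expect_identical(sum(cs$kind == "hexamer" & cs$region == "midsection"), 60L)
  expect_identical(sum(cs$kind == "hexamer" & cs$region == "cap_bottom"), 10L)
  expect_identical(sum(cs$kind == "hexamer" & cs$region == "cap_top"), 10L)
  expect_identical(hexamer_only_count(phi12), 40L)
  expect_identical(cs$region[cs$kind == "portal"], "cap_bottom")
  expect_lt(cs$z[cs$kind == "portal"], min(cs$z[cs$kind == "pentamer"]))

  rp <- ring_partition(phi12)
  expect_identical(rp$ring_count, 6L)
  expect_true(all(lengths(rp$rings) == 10L))
})

test_that("helical parameters follow the rolled-lattice geometry", {
  hp <- helical_params(phi12)
  expect_equal(hp$twist, 18, tolerance = 1e-6)
  expect_equal(hp$rise, 110.85 * sqrt(3) / 2, tolerance = 1e-6)
  expect_equal(hp$rise, 96, tolerance = 0.1 / 96)
  expect_equal(hp$tube_radius, 10 * 110.85 / (2 * pi), tolerance = 1e-6)
  expect_identical(hp$ring_count, 6L)
  expect_identical(hp$hexamers_per_ring, 10L)
  # rise/lattice-constant ratio is sqrt(3)/2 for every achiral tube
  for (h1 in 1:3) for (h2 in c(5L, 7L)) {
    if (h2 * h1 < h1^2) next
    lat <- build_prolate_lattice(lattice_vectors(h1, 0, h2, 0), lattice_constant = 100)
    hp2 <- helical_params(lat)
    expect_equal(hp2$rise / 100, sqrt(3) / 2, tolerance = 1e-6)
    expect_equal(hp2$twist, 360 / (2 * hp2$hexamers_per_ring), tolerance = 1e-6)
  }
})

test_that("midsection rings scale with the lattice accounting law", {
  lat <- build_prolate_lattice(lattice_vectors(2, 0, 14, 0), portal = TRUE)
  rp <- ring_partition(lat)
  # rings * hexamers_per_ring must equal total hexamers minus the caps' 20
  expect_identical(rp$ring_count * rp$hexamers_per_ring,
                   lat$architecture$hexamer_count - 20L)
  expect_identical(rp$ring_count, 13L)
  sp <- shortest_pentamer_path(lat)
  expect_identical(sp$hexamer_count, 14L)
})

test_that("shortest pentamer paths reproduce the lattice walks", {
  sp <- shortest_pentamer_path(phi12)
  expect_identical(sp$hexamer_count, 7L)
  expect_identical(sp$path_ids[1], sp$from)
  inner <- sp$path_ids[-c(1, length(sp$path_ids))]
  kinds <- phi12$capsomers$kind[match(inner, phi12$capsomers$id)]
  expect_identical(sum(kinds == "hexamer"), 7L)

  # adjacent pentamers of the isometric T = 4 shell sit one hexamer apart
  iso <- build_prolate_lattice(lattice_vectors(2, 0, 2, 0))
  g <- lattice_graph(iso)
  pent <- iso$capsomers$id[iso$capsomers$kind == "pentamer"]
  d <- igraph::distances(g, v = as.character(pent[1]))[1, as.character(pent[-1])]
  nearest <- pent[-1][which.min(d)]
  sp2 <- shortest_pentamer_path(iso, from = pent[1], to = nearest)
  expect_identical(sp2$hexamer_count, 1L)
  expect_error(shortest_pentamer_path(iso, from = pent[1], to = pent[1]), "coincide")
})

test_that("isometric degeneracy: prolate (2,0,2,0) equals the (2,0) shell", {
  iso_p <- build_prolate_lattice(lattice_vectors(2, 0, 2, 0))
  iso_i <- build_icosahedral_lattice(2, 0)
  expect_identical(table(iso_p$capsomers$kind), table(iso_i$capsomers$kind))
  expect_true(igraph::isomorphic(lattice_graph(iso_p), lattice_graph(iso_i)))
  expect_identical(ring_partition(iso_p)$ring_count, 0L)
  expect_error(helical_params(iso_p), "at least 2")
})

test_that("geometry census equals the lattice accounting for small vectors", {
  for (h in 0:5) for (k in 0:5) {
    if (h + k == 0 || h < k) next
    lat <- build_icosahedral_lattice(h, k, lattice_constant = 50)
    a <- lat$architecture
    cs <- lat$capsomers
    expect_identical(sum(cs$kind == "pentamer"), a$pentamer_sites)
    expect_identical(sum(cs$kind == "hexamer"), a$hexamer_count)
    g <- lattice_graph(lat)
    deg <- igraph::degree(g)
    expect_true(all(deg[cs$kind != "hexamer"] == 5))
    expect_true(all(deg[cs$kind == "hexamer"] == 6))
    expect_equal(igraph::components(g)$no, 1)
    expect_false(igraph::any_multiple(g))
    expect_false(any(igraph::which_loop(g)))
  }
  for (h1 in 1:3) for (h2 in 2:5) for (k2 in 0:2) {
    v <- tryCatch(lattice_vectors(h1, 0, h2, k2), error = function(e) NULL)
    if (is.null(v)) next
    a <- tryCatch(architecture_counts(v), error = function(e) NULL)
    if (is.null(a)) next
    lat <- build_prolate_lattice(v, lattice_constant = 50)
    cs <- lat$capsomers
    expect_identical(sum(cs$kind == "pentamer"), a$pentamer_sites)
    expect_identical(sum(cs$kind == "hexamer"), a$hexamer_count)
    deg <- igraph::degree(lattice_graph(lat))
    expect_true(all(deg[cs$kind != "hexamer"] == 5))
    expect_true(all(deg[cs$kind == "hexamer"] == 6))
  }
})

test_that("the prolate end cap matches the isometric T = 4 shell (cap equivalence)", {
  iso <- build_icosahedral_lattice(2, 0)
  cap_ids <- phi12$capsomers$id[phi12$capsomers$region == "cap_top"]
  g_cap <- igraph::induced_subgraph(lattice_graph(phi12), as.character(cap_ids))
  iso_cap_ids <- iso$capsomers$id[iso$capsomers$z > max(iso$capsomers$z) * 0.3]
  g_iso <- igraph::induced_subgraph(lattice_graph(iso), as.character(iso_cap_ids))
  expect_identical(length(cap_ids), length(iso_cap_ids))
  expect_true(igraph::isomorphic(g_cap, g_iso))
})

test_that("dihedral angles follow the stated plane convention", {
  expect_equal(dihedral_angle(c(0, 0, 1), c(0, 0, 1)), 180)
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 1)), "degenerate")

  # T = 1: the 12 vertex-tangent capsomer planes bound a dodecahedron, so
  # adjacent pentamer planes meet at the dodecahedral dihedral angle
  lat1 <- build_icosahedral_lattice(1, 0)
  dr1 <- dihedral_angles(lat1, pairs = "all_adjacent")
  expect_identical(nrow(dr1$pairs), 60L)   # 30 contacts, both directions
  expect_equal(unname(dr1$mean), 180 - acos(1 / sqrt(5)) * 180 / pi, tolerance = 1e-9)
  expect_lt(dr1$sd, 1e-9)
  expect_identical(nrow(dihedral_angles(lat1)$pairs), 0L)  # no hexamers on T = 1

  # pentamer environments of the isometric shell and the prolate caps agree
  iso <- build_icosahedral_lattice(2, 0)
  dri <- dihedral_angles(iso)
  drp <- dihedral_angles(phi12)
  expect_true(all(dri$pairs$angle > 0 & dri$pairs$angle <= 180))
  expect_lt(abs(mean(dri$per_pentamer) - mean(drp$per_pentamer)), 5)
  expect_lt(max(abs(range(drp$per_pentamer) - mean(dri$per_pentamer))), 5)
})

test_that("rigid motions leave all derived lattice quantities unchanged", {
  R <- random_rotation(31)
  lat2 <- transform_lattice(phi12, R, c(25, -80, 12.5))
  expect_identical(lat2$edges, phi12$edges)
  expect_identical(table(lat2$capsomers$kind), table(phi12$capsomers$kind))
  expect_equal(sort(dihedral_angles(lat2)$pairs$angle),
               sort(dihedral_angles(phi12)$pairs$angle), tolerance = 1e-9)
  # ring partition and paths are graph/axis-frame quantities; re-align first
  back <- transform_lattice(lat2, t(R), as.vector(-t(R) %*% c(25, -80, 12.5)))
  expect_equal(back$capsomers$x, phi12$capsomers$x, tolerance = 1e-9)
  expect_identical(shortest_pentamer_path(back)$hexamer_count,
                   shortest_pentamer_path(phi12)$hexamer_count)
  expect_error(transform_lattice(phi12, diag(c(1, 1, -1))), "proper rotation")
})

test_that("doubly chiral caps are rejected as an unsupported seam", {
  expect_error(build_prolate_lattice(lattice_vectors(2, 1, 7, 0)), "unsupported")
})

test_that("lattice export round-trips and counts records", {
  f <- file.path(tempdir(), "phi12_lattice.csv")
  paths <- export_lattice(phi12, f, "csv")
  expect_length(paths, 2L)
  lat2 <- read_lattice_csv(f)
  expect_identical(nrow(lat2$capsomers), 92L)    # 80 hexamers + 11 pentamers + portal
  expect_identical(lat2$capsomers$kind, phi12$capsomers$kind)
  expect_equal(lat2$capsomers$x, phi12$capsomers$x, tolerance = 1e-9)
  expect_identical(unname(lat2$edges), unname(phi12$edges))
  expect_identical(lat2$architecture, phi12$architecture)

  fp <- file.path(tempdir(), "phi12_lattice.pdb")
  export_lattice(phi12, fp, "pdb")
  lines <- readLines(fp)
  expect_identical(sum(grepl("^HETATM", lines)), 92L)
  expect_identical(sum(grepl(" POR ", lines)), 1L)

  expect_error(export_lattice(phi12, f, ""), "unknown export format")
  expect_error(export_lattice(phi12, f, "xyz"), "unknown export format")
})
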