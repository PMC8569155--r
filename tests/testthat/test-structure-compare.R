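test_that("global alignment identity and correspondence behave as expected", {
  al <- align_sequences("MKTAYIAKQRGLDGLK", "MKTAYIAKQRGLDGLK")
  expect_identical(al$identity, 1)
  expect_identical(al$n_aligned, 16L)
  expect_identical(al$pairs$pos_a, al$pairs$pos_b)

  # shuffled sequences fall to background identity
  set.seed(8)
  aas <- names(capsidkit:::AVERAGE_RESIDUE_MASS)
  s <- paste(sample(aas, 200, TRUE), collapse = "")
  ident <- vapply(1:10, function(i) {
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    align_sequences(s, sh)$identity
  }, 0)
  expect_lt(mean(ident), 0.4)
  expect_error(align_sequences("", "AC"), "empty")
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  R <- random_rotation(19); tr <- c(12, -7, 30)
  ps <- gen_perturbed_structure(rotation = R, translation = tr, noise_sigma = 0,
                                seed = 4, n = 80)
  fit <- superpose(ps$b, ps$a)     # moving a onto its transformed copy
  expect_lt(fit$rmsd_all, 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, tr, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)

  ident <- superpose(ps$a, ps$a)
  expect_lt(ident$rmsd_all, 1e-12)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-12)

  degen <- chain_model("D", 1:4, rep("A", 4),
                       cbind(1:4, 2 * (1:4), 3 * (1:4)))
  expect_error(superpose(degen, degen), "degenerate")
})

test_that("superposition is least-squares optimal against a rotation-sampling oracle", {
  set.seed(33)
  for (rep in 1:3) {
    n <- sample(4:6, 1)
    X <- matrix(rnorm(3 * n, sd = 5), n, 3)
    Y <- matrix(rnorm(3 * n, sd = 5), n, 3)
    a <- chain_model("A", 1:n, rep("G", n), X)
    b <- chain_model("B", 1:n, rep("G", n), Y)
    fit <- superpose(a, b)
    expect_lte(fit$rmsd_all, oracle_grid_rmsd(X, Y, n_rot = 2000L, seed = rep) + 1e-9)
  }
})

test_that("RMSD is invariant to pre-rotation of either input and matches bio3d", {
  ps <- gen_perturbed_structure(noise_sigma = 1.5, seed = 6, n = 120)
  fit0 <- superpose(ps$b, ps$a)
  pre <- random_rotation(77)
  a_rot <- chain_model("A", ps$a$resno, ps$a$aa, t(pre %*% t(ps$a$xyz)))
  fit1 <- superpose(ps$b, a_rot)
  expect_equal(fit0$rmsd_all, fit1$rmsd_all, tolerance = 1e-9)

  # independent cross-check of the optimal RMSD with bio3d's fitter
  xyz_a <- matrix(t(ps$a$xyz), nrow = 1)
  xyz_b <- matrix(t(ps$b$xyz), nrow = 1)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(ps$b$xyz)), mobile = xyz_a,
                           fixed.inds = 1:360, mobile.inds = 1:360)
  rmsd_bio3d <- sqrt(mean(colSums(matrix((fitted - xyz_b)^2, nrow = 3))))
  expect_equal(fit0$rmsd_all, rmsd_bio3d, tolerance = 1e-6)
})

test_that("noise-limited RMSD matches the isotropic-noise expectation", {
  sigma <- 1
  ps <- gen_perturbed_structure(rotation = random_rotation(2), translation = c(3, 3, 3),
                                noise_sigma = sigma, seed = 10, n = 500)
  fit <- superpose(ps$b, ps$a)
  expect_lt(abs(fit$rmsd_all - sigma * sqrt(3)), 0.05 * sigma * sqrt(3))
})

test_that("core trimming recovers a planted rigid core", {
  set.seed(2)
  xyz <- matrix(rnorm(300) * 8, 100, 3)
  a <- chain_model("A", 1:100, rep("A", 100), xyz)
  moved <- xyz; moved[71:100, ] <- moved[71:100, ] + 30
  b <- chain_model("B", 1:100, rep("A", 100), moved)
  r <- core_rmsd(superpose(a, b), max_iter = 25)
  expect_identical(sort(r$core_pairs$pos_a), 1:70)
  expect_lt(r$rmsd_core, 1e-9)
  expect_gt(r$rmsd_all, 10)
  expect_lte(r$rmsd_core, r$rmsd_all)
  expect_true(all(r$core_pairs$pos_a %in% r$matched_pairs$pos_a))

  clean <- gen_perturbed_structure(rotation = random_rotation(3), seed = 8)
  rc <- core_rmsd(superpose(clean$b, clean$a))
  expect_identical(nrow(rc$core_pairs), nrow(rc$matched_pairs))
  expect_lt(rc$rmsd_core, 1e-9)
  expect_lt(rc$rmsd_all, 1e-9)
})

test_that("chain models read back from PDB text and superpose by residue number", {
  pdb_line <- function(serial, resno, chain, x, y, z) {
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, chain, resno, x, y, z)
  }
  set.seed(14)
  xyz <- matrix(rnorm(30) * 5, 10, 3)
  R <- random_rotation(5); tr <- c(2, 4, 6)
  xyz_b <- t(R %*% t(xyz)) + matrix(tr, 10, 3, byrow = TRUE)
  lines <- c(vapply(1:10, function(i) pdb_line(i, i + 100, "A",
                                               xyz[i, 1], xyz[i, 2], xyz[i, 3]), ""),
             vapply(1:10, function(i) pdb_line(i + 10, i + 100, "B",
                                               xyz_b[i, 1], xyz_b[i, 2], xyz_b[i, 3]), ""),
             "END")
  f <- file.path(tempdir(), "synthetic_pair.pdb")
  writeLines(lines, f)
  ca <- read_chain_model(f, "A"); cb <- read_chain_model(f, "B")
  expect_identical(ca$resno, 101:110)
  expect_identical(ca$aa, rep("A", 10))
  fit <- superpose(cb, ca)
  expect_lt(fit$rmsd_all, 1e-3)       # PDB coordinates carry 3 decimals
  expect_equal(fit$rotation, R, tolerance = 1e-3)
})
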