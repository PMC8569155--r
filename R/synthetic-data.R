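# Deterministic synthetic-data generators. Each generator takes a seed,
# emits machine-readable ground truth alongside the data, and produces
# byte-identical output for identical arguments. These emulate the
# statistical structure of the measured inputs (capsomer centres picked
# from a density map, deconvoluted intact masses, marker ladders, rigidly
# related atomic models) without any external downloads; they are
# synthetic stand-ins, not measured data.

#' Noisy capsomer point cloud on an ideal lattice
#'
#' Displaces the capsomer centres of an ideal shell by isotropic Gaussian
#' noise, keeping all labels: a stand-in for capsomer centres measured
#' from a reconstruction.
#'
#' @param v A [lattice_vectors()] object.
#' @param sigma Noise standard deviation per coordinate (Angstrom).
#' @param seed Integer seed.
#' @param lattice_constant,portal Passed to [build_prolate_lattice()].
#' @return List with `points` (data.frame `id`, `kind`, `x`, `y`, `z`),
#'   `truth` (the ideal `capsomer_lattice`), and `sigma`.
#' @export
gen_noisy_lattice <- function(v, sigma = 0, seed = 1L,
                              lattice_constant = 110.85, portal = FALSE) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  lat <- build_prolate_lattice(v, lattice_constant = lattice_constant, portal = portal)
  set.seed(seed)
  pts <- lat$capsomers[, c("id", "kind", "x", "y", "z")]
  n <- nrow(pts)
  pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  list(points = pts, truth = lat, sigma = sigma)
}

#' Random protein with a planted cleavage site
#'
#' Generates a random sequence (uniform over the 20 standard residues)
#' and the observed intact mass of its C-terminal fragment after cleavage
#' behind `cleavage_after`, optionally with Gaussian measurement error —
#' the synthetic counterpart of locating a scaffolding-domain boundary
#' from a deconvoluted intact mass.
#'
#' @param length Protein length (residues).
#' @param cleavage_after Cleavage position: the bond after this residue is
#'   cut (1 <= cleavage_after < length).
#' @param seed Integer seed.
#' @param mass_error_sd Gaussian error added to the observed mass (Da).
#' @return List with `protein` (a [protein_record()]), `observed_mass`,
#'   and `truth` (`cleavage_after`, `fragment_start`, `fragment_mass`).
#' @export
gen_protein_with_cleavage <- function(length, cleavage_after, seed = 1L,
                                      mass_error_sd = 0) {
  if (length < 2L) stop("length must be >= 2", call. = FALSE)
  if (cleavage_after < 1L || cleavage_after >= length) {
    stop("cleavage_after must satisfy 1 <= cleavage_after < length", call. = FALSE)
  }
  set.seed(seed)
  aa <- sample(names(AVERAGE_RESIDUE_MASS), length, replace = TRUE)
  seqc <- paste(aa, collapse = "")
  prot <- protein_record(sprintf("synthetic_L%d_seed%d", length, seed), seqc)
  frag <- substring(seqc, cleavage_after + 1L, length)
  obs <- average_mass(frag) + stats::rnorm(1, sd = mass_error_sd)
  list(protein = prot, observed_mass = obs,
       truth = list(cleavage_after = as.integer(cleavage_after),
                    fragment_start = as.integer(cleavage_after + 1L),
                    fragment_mass = average_mass(frag)))
}

#' Marker ladder on a known quadratic migration curve
#'
#' @param coeffs Quadratic coefficients `c(c0, c1, c2)` of
#'   `distance = c0 + c1*log10(MW) + c2*log10(MW)^2`.
#' @param marker_mws Marker molecular weights (kDa).
#' @param noise_sigma Gaussian noise on the distances.
#' @param seed Integer seed.
#' @return List with `markers` (data.frame `mw_kda`, `distance`) and
#'   `truth` (the coefficients and noise level).
#' @export
gen_gel_ladder <- function(coeffs, marker_mws, noise_sigma = 0, seed = 1L) {
  if (length(coeffs) != 3L) stop("coeffs must be length 3", call. = FALSE)
  set.seed(seed)
  l <- log10(marker_mws)
  d <- coeffs[1] + coeffs[2] * l + coeffs[3] * l^2 +
    stats::rnorm(length(l), sd = noise_sigma)
  list(markers = data.frame(mw_kda = marker_mws, distance = d),
       truth = list(coeffs = coeffs, noise_sigma = noise_sigma))
}

#' Random proper rotation matrix
#'
#' Uniform (Haar) random rotation via QR decomposition with sign fixing.
#'
#' @param seed Integer seed.
#' @return 3x3 proper rotation matrix.
#' @export
random_rotation <- function(seed = 1L) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Structure pair related by a known rigid transform plus noise
#'
#' Applies `rotation` and `translation` to a chain model and adds
#' isotropic Gaussian coordinate noise; ground truth is returned for
#' transform-recovery tests.
#'
#' @param chain A [chain_model()]; if missing, a random-walk backbone of
#'   `n` residues is generated.
#' @param rotation 3x3 proper rotation (improper matrices are rejected).
#' @param translation Length-3 vector (Angstrom).
#' @param noise_sigma Gaussian noise per coordinate (Angstrom).
#' @param seed Integer seed.
#' @param n Residue count for the generated backbone.
#' @return List with `a` (original), `b` (transformed + noise), `truth`
#'   (`rotation`, `translation`, `noise_sigma`).
#' @export
gen_perturbed_structure <- function(chain = NULL, rotation = diag(3),
                                    translation = c(0, 0, 0), noise_sigma = 0,
                                    seed = 1L, n = 100L) {
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be a proper rotation matrix", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(chain)) {
    steps <- matrix(stats::rnorm(3 * n), n, 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 3.8   # CA-CA virtual bond
    xyz <- apply(steps, 2, cumsum)
    aa <- sample(names(AVERAGE_RESIDUE_MASS), n, replace = TRUE)
    chain <- chain_model("A", seq_len(n), aa, xyz)
  }
  m <- nrow(chain$xyz)
  bxyz <- t(rotation %*% t(chain$xyz)) +
    matrix(translation, m, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * m, sd = noise_sigma), m, 3)
  b <- chain_model("B", chain$resno, chain$aa, bxyz)
  list(a = chain, b = b,
       truth = list(rotation = rotation, translation = translation,
                    noise_sigma = noise_sigma))
}
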