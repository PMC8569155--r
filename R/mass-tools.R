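# Intact-mass arithmetic: average (not monoisotopic) masses, matching
# deconvoluted ESI-TOF intact-mass measurements; cysteines reduced, no
# modifications. All mass constants are pinned here.

# Average residue masses (Da) of the 20 standard amino acids and water.
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Average molecular mass of a protein sequence
#'
#' Sum of standard average residue masses plus one water; cysteines are
#' taken as reduced and no modifications are applied, matching the way
#' deconvoluted ESI-TOF intact masses are reported.
#'
#' @param sequence Amino-acid string (1-letter codes, 20 standard residues).
#' @return Mass in Dalton.
#' @examples
#' average_mass("G") # free glycine, 75.07 Da
#' @export
average_mass <- function(sequence) {
  aa <- sequence_vector(sequence)
  sum(AVERAGE_RESIDUE_MASS[aa]) + WATER_MASS
}

sequence_vector <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(AVERAGE_RESIDUE_MASS))
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  aa
}

#' A protein record for intact-mass analysis
#'
#' @param id Identifier.
#' @param sequence Amino-acid string; residue numbering is 1-based.
#' @return Object of class `protein_record` with the full-length average
#'   mass precomputed.
#' @export
protein_record <- function(id, sequence) {
  aa <- sequence_vector(sequence)
  structure(list(id = id, sequence = paste(aa, collapse = ""),
                 length = length(aa), full_mass = average_mass(sequence)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein %s: %d residues, average mass %.1f Da\n",
              x$id, x$length, x$full_mass))
  invisible(x)
}

#' Read protein records from a FASTA file
#'
#' @param file FASTA path.
#' @return List of [protein_record()] objects.
#' @export
read_protein_fasta <- function(file) {
  ss <- Biostrings::readAAStringSet(file)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  out <- lapply(seq_along(ss), function(i) protein_record(ids[i], as.character(ss[[i]])))
  names(out) <- ids
  out
}

#' Map an observed intact mass to contiguous sequence fragments
#'
#' Finds every contiguous fragment of the protein whose computed average
#' mass lies within `tolerance` of the observed mass, for the given
#' truncation mode. The default, N-terminal truncation retaining the
#' C-terminus, is the signature of scaffolding (delta) domain removal in
#' HK97-type capsid proteins; the site label names the residues flanking
#' the cleaved bond.
#'
#' @param protein A [protein_record()].
#' @param observed Observed intact mass (Da).
#' @param tolerance Match tolerance (Da); the default 2.0 Da covers the
#'   deviations typical of deconvoluted intact masses.
#' @param mode `"n_truncation"` (retain C-terminus), `"c_truncation"`
#'   (retain N-terminus), or `"any_contiguous"`.
#' @return A data.frame of class `cleavage_matches`, sorted by
#'   `abs(delta)`: `start`, `end` (1-based inclusive), `calc_mass`,
#'   `delta` (calc - observed), `site_label`. Zero rows when nothing
#'   matches.
#' @examples
#' p <- protein_record("toy", "MKTAYIAKQRGLDGLK")
#' match_cleavage(p, observed = average_mass("GLDGLK"), tolerance = 0.1)
#' @export
match_cleavage <- function(protein, observed, tolerance = 2.0,
                           mode = c("n_truncation", "c_truncation", "any_contiguous")) {
  stopifnot(inherits(protein, "protein_record"))
  mode <- match.arg(mode)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be > 0", call. = FALSE)
  }
  aa <- strsplit(protein$sequence, "")[[1]]
  L <- length(aa)
  res <- AVERAGE_RESIDUE_MASS[aa]
  cum <- c(0, cumsum(res))            # cum[i+1] = mass of residues 1..i
  frag_mass <- function(s, e) cum[e + 1] - cum[s] + WATER_MASS
  cand <- switch(mode,
    n_truncation = cbind(start = 1:L, end = L),
    c_truncation = cbind(start = 1L, end = 1:L),
    any_contiguous = {
      idx <- which(upper.tri(matrix(0, L + 1, L + 1)), arr.ind = TRUE)
      cbind(start = idx[, 1], end = idx[, 2] - 1L)
    })
  mass <- cum[cand[, "end"] + 1] - cum[cand[, "start"]] + WATER_MASS
  hit <- abs(mass - observed) <= tolerance
  cand <- cand[hit, , drop = FALSE]; mass <- mass[hit]
  o <- order(abs(mass - observed), cand[, "start"])
  cand <- cand[o, , drop = FALSE]; mass <- mass[o]
  label <- vapply(seq_len(nrow(cand)), function(i) {
    s <- cand[i, "start"]; e <- cand[i, "end"]
    if (s == 1L && e == L) return("full length")
    parts <- character()
    if (s > 1L) parts <- c(parts, sprintf("between %s%d and %s%d", aa[s - 1], s - 1, aa[s], s))
    if (e < L) parts <- c(parts, sprintf("between %s%d and %s%d", aa[e], e, aa[e + 1], e + 1))
    paste(parts, collapse = "; ")
  }, "")
  out <- data.frame(start = as.integer(cand[, "start"]), end = as.integer(cand[, "end"]),
                    calc_mass = mass, delta = mass - observed,
                    site_label = if (nrow(cand)) label else character())
  attr(out, "protein_id") <- protein$id
  attr(out, "observed") <- observed
  class(out) <- c("cleavage_matches", class(out))
  out
}

#' Delta-domain annotation from an N-terminal truncation match
#'
#' Splits the protein into the cleaved-off N-terminal scaffolding (delta)
#' domain and the mature capsid-protein region implied by a single
#' N-truncation match.
#'
#' @param protein A [protein_record()].
#' @param match One row of a [match_cleavage()] result with
#'   `mode = "n_truncation"` (i.e. `end == length(protein)`).
#' @return List with `delta_domain = c(start, end)` (or `NULL` when the
#'   match is full length), `mature = c(start, end)`, and `site_label`.
#' @export
delta_domain_report <- function(protein, match) {
  stopifnot(inherits(protein, "protein_record"))
  s <- match$start[1]; e <- match$end[1]
  if (e != protein$length) {
    stop("delta-domain annotation requires an N-terminal truncation match ",
         "(fragment must retain the C-terminus)", call. = FALSE)
  }
  list(delta_domain = if (s > 1L) c(1L, s - 1L) else NULL,
       mature = c(s, e),
       site_label = if (s > 1L) match$site_label[1] else "no cleavage")
}
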