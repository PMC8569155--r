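# Stochastic simulator of the pentamer-species assembly decision: a portal
# (or portal-free) nucleus of capsid-protein hexamers recruits pentamers
# that are either the helper-phage capsid protein (CP) or its
# island-encoded homolog (Ccm). Ccm pentamers commit the shell to the
# small isometric T = 4 form; CP pentamers commit it to the prolate form.
# The decision rule is an explicit modelling choice: the underlying
# biology is a strict either/or outcome, not a claim that capsids grow by
# addition of preformed capsomers.

#' Parameters of the assembly-decision simulation
#'
#' @param rho_ccm Relative propensity of Ccm over CP at each pentamer
#'   site; each site independently draws Ccm with probability
#'   `rho_ccm / (1 + rho_ccm)`. `0` = no Ccm, `Inf` = Ccm always.
#' @param portal_nucleation If `TRUE` the nucleus contains a portal, which
#'   occupies one five-fold site (11 pentamer sites); portal-free
#'   nucleation (possible for the isometric form) leaves 12.
#' @param commitment Decision rule. `"first_site"`: the species of the
#'   first pentamer recruited to the nucleus commits the shape (matching
#'   the observed strict either/or outcome). `"unanimous_ring"`: the five
#'   first-ring pentamer sites must agree; mixed draws yield an aberrant
#'   (uncommitted) particle.
#' @param n_trials Number of independent assembly trials.
#' @param seed Integer seed; fixed seed gives identical outcome lists.
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(rho_ccm = 1, portal_nucleation = TRUE,
                            commitment = c("first_site", "unanimous_ring"),
                            n_trials = 1000L, seed = 1L) {
  commitment <- match.arg(commitment)
  if (!is.numeric(rho_ccm) || length(rho_ccm) != 1L || is.na(rho_ccm) || rho_ccm < 0) {
    stop("rho_ccm must be a single non-negative number (Inf allowed)", call. = FALSE)
  }
  if (!is.numeric(n_trials) || n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  structure(list(rho_ccm = rho_ccm, portal_nucleation = isTRUE(portal_nucleation),
                 commitment = commitment, n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "assembly_params")
}

# census of the two committed outcomes, from the lattice accounting module
assembly_censuses <- function(portal) {
  iso <- architecture_counts(lattice_vectors(2, 0), has_portal = portal)
  pro <- architecture_counts(lattice_vectors(2, 0, 7, 0), has_portal = TRUE)
  list(isometric = iso, prolate = pro)
}

#' Simulate assembly-decision trials
#'
#' Per trial, each pentamer site draws species Ccm with probability
#' `rho_ccm / (1 + rho_ccm)`, independently, in site order from a single
#' seeded generator. The commitment rule maps the draws to a shape; the
#' committed particle is then filled with the census of the realized
#' architecture ((2,0) isometric T = 4 with Ccm pentamers and CP hexamers,
#' or (2,0,7,0) prolate all-CP with portal). Aberrant particles (possible
#' only under `"unanimous_ring"`) carry their mixed first-ring draws and
#' `NA` copy numbers.
#'
#' @param p An [assembly_params()] object.
#' @return A data.frame of class `assembly_outcomes`, one row per trial:
#'   `shape`, `cp_copies`, `ccm_copies`, `rings_built`, plus the per-site
#'   species draws in attribute `"species"`.
#' @examples
#' out <- simulate_assembly(assembly_params(rho_ccm = 1, n_trials = 100, seed = 7))
#' table(out$shape)
#' @export
simulate_assembly <- function(p) {
  stopifnot(inherits(p, "assembly_params"))
  cens <- assembly_censuses(p$portal_nucleation)
  n_sites <- cens$isometric$pentamer_sites
  q <- if (is.infinite(p$rho_ccm)) 1 else p$rho_ccm / (1 + p$rho_ccm)
  set.seed(p$seed)
  # one generator per run; species draws consumed in site order within trial
  draws <- matrix(stats::runif(p$n_trials * n_sites) < q,
                  nrow = p$n_trials, ncol = n_sites, byrow = TRUE)
  shape <- character(p$n_trials)
  if (p$commitment == "first_site") {
    shape <- ifelse(draws[, 1L], "isometric", "prolate")
  } else {
    ring <- draws[, 1:5, drop = FALSE]
    shape <- ifelse(rowSums(ring) == 5L, "isometric",
                    ifelse(rowSums(ring) == 0L, "prolate", "aberrant"))
  }
  iso <- cens$isometric; pro <- cens$prolate
  cp <- ifelse(shape == "prolate", pro$cp_equivalent_subunits,
               ifelse(shape == "isometric", 6L * iso$hexamer_count, NA_integer_))
  ccm <- ifelse(shape == "prolate", 0L,
                ifelse(shape == "isometric", 5L * iso$pentamer_sites, NA_integer_))
  rings <- ifelse(shape == "prolate", 6L, ifelse(shape == "isometric", 0L, NA_integer_))
  species <- matrix(ifelse(draws, "ccm", "cp"), nrow = p$n_trials)
  species[shape == "isometric", ] <- "ccm"
  species[shape == "prolate", ] <- "cp"
  out <- data.frame(trial = seq_len(p$n_trials), shape = shape,
                    cp_copies = cp, ccm_copies = ccm, rings_built = rings)
  attr(out, "species") <- species
  attr(out, "params") <- p
  class(out) <- c("assembly_outcomes", class(out))
  out
}

#' Exact outcome probabilities of the assembly-decision model
#'
#' Closed-form counterpart of [simulate_assembly()]: with per-site Ccm
#' probability `q = rho/(1+rho)`, the `"first_site"` rule gives isometric
#' probability `q`; `"unanimous_ring"` gives `q^5` isometric, `(1-q)^5`
#' prolate, and the rest aberrant.
#'
#' @param p An [assembly_params()] object.
#' @return Named numeric vector `c(isometric=, prolate=, aberrant=)`.
#' @examples
#' analytic_isometric_fraction(assembly_params(rho_ccm = 1))["isometric"]
#' @export
analytic_isometric_fraction <- function(p) {
  stopifnot(inherits(p, "assembly_params"))
  q <- if (is.infinite(p$rho_ccm)) 1 else p$rho_ccm / (1 + p$rho_ccm)
  if (p$commitment == "first_site") {
    c(isometric = q, prolate = 1 - q, aberrant = 0)
  } else {
    c(isometric = q^5, prolate = (1 - q)^5, aberrant = 1 - q^5 - (1 - q)^5)
  }
}

#' Summarize assembly outcomes
#'
#' Shape fractions with Wilson score 95% confidence intervals and mean
#' subunit compositions per shape.
#'
#' @param outcomes Result of [simulate_assembly()].
#' @param conf Confidence level for the Wilson intervals.
#' @return A data.frame with one row per shape: `shape`, `n`, `fraction`,
#'   `ci_lo`, `ci_hi`, `mean_cp`, `mean_ccm`.
#' @export
outcome_summary <- function(outcomes, conf = 0.95) {
  if (!inherits(outcomes, "assembly_outcomes") || nrow(outcomes) == 0L) {
    stop("outcome_summary needs a non-empty assembly_outcomes object", call. = FALSE)
  }
  n <- nrow(outcomes)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  shapes <- c("isometric", "prolate", "aberrant")
  rows <- lapply(shapes, function(s) {
    k <- sum(outcomes$shape == s)
    ph <- k / n
    den <- 1 + z^2 / n
    ctr <- (ph + z^2 / (2 * n)) / den
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    data.frame(shape = s, n = k, fraction = ph,
               ci_lo = max(0, ctr - hw), ci_hi = min(1, ctr + hw),
               mean_cp = if (k) mean(outcomes$cp_copies[outcomes$shape == s]) else NA_real_,
               mean_ccm = if (k) mean(outcomes$ccm_copies[outcomes$shape == s]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[out$n > 0 | out$shape != "aberrant", , drop = FALSE]
}
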