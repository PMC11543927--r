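#' Construct a native-MS species distribution
#'
#' Per-stoichiometry intensities (species P, PL, PL2, ... PLn) observed at a
#' single titration point. Intensities are used as concentration proxies
#' under the standard equal-response-factor assumption.
#'
#' @param intensities Non-negative vector for stoichiometries 0..n_max (at
#'   least one positive; n_max >= 1).
#' @param Lt_uM Total ligand concentration.
#' @param Pt_uM Total protein concentration.
#' @return A `species_distribution` object.
#' @export
species_distribution <- function(intensities, Lt_uM, Pt_uM) {
  stopifnot(length(intensities) >= 2L, all(intensities >= 0),
            any(intensities > 0), Lt_uM >= 0, Pt_uM > 0)
  structure(list(intensities = as.numeric(intensities),
                 n_max = length(intensities) - 1L,
                 Lt_uM = Lt_uM, Pt_uM = Pt_uM),
            class = "species_distribution")
}

#' Occupancy statistics of one species distribution
#'
#' Normalizes intensities to fractions, computes the average occupancy
#' `nu = sum(i * f_i)`, the free ligand `Lfree = Lt - nu * Pt` (floored at 0
#' with a warning) and the Scatchard coordinates `(nu, nu/Lfree)`.
#'
#' @param dist A `species_distribution`.
#' @return An `occupancy_result` list with `fractions`, `nu`, `Lfree_uM`,
#'   `scatchard_x`, `scatchard_y` (NA and flagged when Lfree <= 0).
#' @export
occupancy <- function(dist) {
  stopifnot(inherits(dist, "species_distribution"))
  f <- dist$intensities / sum(dist$intensities)
  i <- seq_along(f) - 1L
  nu <- sum(i * f)
  Lfree <- dist$Lt_uM - nu * dist$Pt_uM
  flagged <- FALSE
  if (Lfree < 0) {
    warning("computed free ligand negative; floored at 0")
    Lfree <- 0
  }
  sy <- if (Lfree > 0) nu / Lfree else if (nu == 0) 0 else { flagged <- TRUE; NA_real_ }
  structure(list(fractions = f, nu = nu, Lfree_uM = Lfree,
                 scatchard_x = nu, scatchard_y = sy,
                 scatchard_undefined = flagged,
                 Lt_uM = dist$Lt_uM, Pt_uM = dist$Pt_uM),
            class = "occupancy_result")
}

#' @method print occupancy_result
#' @export
print.occupancy_result <- function(x, ...) {
  cat("Occupancy: nu =", fmt6(x$nu), " Lfree =", fmt6(x$Lfree_uM), "uM\n")
  cat("  fractions:", paste(fmt6(x$fractions), collapse = " "), "\n")
  if (x$scatchard_undefined) cat("  Scatchard point undefined (Lfree <= 0)\n")
  else cat("  Scatchard (x, y): (", fmt6(x$scatchard_x), ", ",
           fmt6(x$scatchard_y), ")\n", sep = "")
  invisible(x)
}

#' Expected species fractions for n non-interacting identical sites
#'
#' The per-site occupancy `p` solves the ligand-depleted isotherm
#' `p = Lfree/(Kd + Lfree)` with `Lfree = Lt - n p Pt`, i.e. the root in
#' \[0,1\] of `n Pt p^2 - (Kd + Lt + n Pt) p + Lt = 0`; species fractions are
#' binomial, `f_i = C(n,i) p^i (1-p)^(n-i)`.
#'
#' @param n_sites Number of identical sites (>= 1).
#' @param Kd_uM Per-site dissociation constant (> 0).
#' @param Pt_uM Total protein.
#' @param Lt_uM Total ligand.
#' @return List with `p` (per-site occupancy) and `fractions` (length
#'   `n_sites + 1`).
#' @export
identical_sites_fractions <- function(n_sites, Kd_uM, Pt_uM, Lt_uM) {
  stopifnot(n_sites >= 1, Kd_uM > 0, Pt_uM >= 0, Lt_uM >= 0)
  a <- n_sites * Pt_uM
  b <- Kd_uM + Lt_uM + a
  p <- if (a == 0) Lt_uM / (Kd_uM + Lt_uM)
       else (b - sqrt(b * b - 4 * a * Lt_uM)) / (2 * a)
  p <- min(max(p, 0), 1)
  list(p = p, fractions = dbinom(0:n_sites, n_sites, p))
}

# SSR of observed vs identical-sites expected fractions across a titration
.sites_ssr <- function(log10Kd, titration, n_sites) {
  Kd <- 10^log10Kd
  sum(vapply(titration, function(d) {
    fobs <- d$intensities / sum(d$intensities)
    fexp <- identical_sites_fractions(n_sites, Kd, d$Pt_uM, d$Lt_uM)$fractions
    m <- min(length(fobs), length(fexp))
    fo <- fobs[seq_len(m)]; fe <- fexp[seq_len(m)]
    # mass beyond the fitted site count compared against 0
    extra <- if (length(fobs) > m) sum(fobs[-seq_len(m)]^2) else 0
    sum((fo - fe)^2) + extra
  }, 0))
}

#' Fit the non-interacting identical-sites model to a titration
#'
#' Finds the single per-site Kd minimizing the summed squared difference
#' between observed species fractions and the binomial expectation across
#' all titration points. The minimized sum per degree of freedom is the
#' deviation statistic: values above a simulated null quantile (see
#' [null_deviation_quantile()]) flag site heterogeneity or cooperativity —
#' the same reasoning as spotting curvature in a Scatchard plot.
#'
#' @param titration List of `species_distribution` (>= 3 points).
#' @param n_sites Number of sites assumed (default 3; a 4th sparsely
#'   populated stoichiometry may be unspecific and is then compared to 0).
#' @return A `sites_fit` object with `Kd_uM`, `deviation`, `ssr`, `dof`.
#' @export
fit_identical_sites <- function(titration, n_sites = 3L) {
  stopifnot(length(titration) >= 3L)
  if (all(vapply(titration, function(d) sum(d$intensities[-1]), 0) == 0))
    stop("degenerate titration: all points apo; nothing to fit",
         call. = FALSE)
  opt <- optimize(.sites_ssr, c(-2, 6), titration = titration,
                  n_sites = n_sites, tol = 1e-8)
  nres <- sum(vapply(titration, function(d)
    max(length(d$intensities), n_sites + 1L), 0))
  dof <- max(nres - 1L, 1L)
  structure(list(Kd_uM = 10^opt$minimum, ssr = opt$objective,
                 deviation = opt$objective / dof, dof = dof,
                 n_sites = n_sites, n_points = length(titration)),
            class = "sites_fit")
}

#' @method print sites_fit
#' @export
print.sites_fit <- function(x, ...) {
  cat("Identical-sites fit:", x$n_sites, "sites,", x$n_points, "points\n")
  cat("  Kd =", fmt6(x$Kd_uM), "uM;  deviation statistic =",
      fmt6(x$deviation), "\n")
  invisible(x)
}

#' @method coef sites_fit
#' @export
coef.sites_fit <- function(object, ...) {
  c(Kd_uM = object$Kd_uM, deviation = object$deviation)
}

#' Simulated null quantile of the identical-sites deviation statistic
#'
#' Parametric calibration: simulates multinomial species counts from the
#' identical-sites model, refits, and returns the requested quantile of the
#' deviation statistic. Preferred over an asymptotic chi-square because
#' native-MS counts are small.
#'
#' @param n_sites,Kd_uM,Pt_uM Model parameters under the null.
#' @param Lt_grid Titration ligand concentrations.
#' @param counts_N Multinomial sample size per point.
#' @param n_sim Number of simulations (default 200).
#' @param prob Quantile (default 0.95).
#' @param seed RNG seed.
#' @return Numeric quantile; attribute `"values"` holds all simulated
#'   statistics.
#' @export
null_deviation_quantile <- function(n_sites, Kd_uM, Pt_uM, Lt_grid,
                                    counts_N = 5000, n_sim = 200,
                                    prob = 0.95, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  vals <- vapply(seq_len(n_sim), function(k) {
    tit <- lapply(Lt_grid, function(Lt) {
      pr <- identical_sites_fractions(n_sites, Kd_uM, Pt_uM, Lt)$fractions
      species_distribution(as.numeric(rmultinom(1, counts_N, pr)),
                           Lt_uM = Lt, Pt_uM = Pt_uM)
    })
    fit_identical_sites(tit, n_sites)$deviation
  }, 0)
  structure(quantile(vals, prob, names = FALSE), values = vals)
}

# save/restore RNG state so seeded helpers do not disturb the caller
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else function() invisible(NULL)
}

#' Construct a two-ligand one-site competition system
#'
#' @param Pt_uM Total protein; `At_uM`, `Bt_uM` total ligands; `KdA_uM`,
#'   `KdB_uM` dissociation constants for the single shared site.
#' @param At_uM,Bt_uM,KdA_uM,KdB_uM See above.
#' @return A `competition_system` list.
#' @export
competition_system <- function(Pt_uM, At_uM, Bt_uM, KdA_uM, KdB_uM) {
  stopifnot(Pt_uM >= 0, At_uM >= 0, Bt_uM >= 0, KdA_uM > 0, KdB_uM > 0)
  structure(list(Pt_uM = Pt_uM, At_uM = At_uM, Bt_uM = Bt_uM,
                 KdA_uM = KdA_uM, KdB_uM = KdB_uM),
            class = "competition_system")
}

#' Solve the two-ligand one-site competition equilibrium
#'
#' Damped fixed-point iteration on the free concentrations of P + A <-> PA
#' and P + B <-> PB under mass balance; converges to a mass-balance residual
#' below `tol`.
#'
#' @param sys A `competition_system`.
#' @param tol Relative-change tolerance (default 1e-12).
#' @param max_iter Iteration cap (default 10000).
#' @param damping Update damping in (0,1\] (default 0.5).
#' @return List with `fraction_PA`, `fraction_PB`, `fraction_free` (of total
#'   P), plus free concentrations.
#' @export
solve_competition <- function(sys, tol = 1e-12, max_iter = 10000L,
                              damping = 0.5) {
  stopifnot(inherits(sys, "competition_system"))
  Pt <- sys$Pt_uM; At <- sys$At_uM; Bt <- sys$Bt_uM
  KdA <- sys$KdA_uM; KdB <- sys$KdB_uM
  if (Pt == 0) return(list(fraction_PA = NA_real_, fraction_PB = NA_real_,
                           fraction_free = NA_real_, Afree_uM = At,
                           Bfree_uM = Bt, Pfree_uM = 0))
  Af <- At; Bf <- Bt
  for (it in seq_len(max_iter)) {
    Pf <- Pt / (1 + Af / KdA + Bf / KdB)
    Af_new <- At / (1 + Pf / KdA)
    Bf_new <- Bt / (1 + Pf / KdB)
    dA <- Af_new - Af; dB <- Bf_new - Bf
    Af <- Af + damping * dA
    Bf <- Bf + damping * dB
    rel <- max(abs(dA) / (Af + 1e-300), abs(dB) / (Bf + 1e-300))
    if (rel < tol) break
  }
  if (it == max_iter && rel >= tol)
    stop("competition solver did not converge", call. = FALSE)
  Pf <- Pt / (1 + Af / KdA + Bf / KdB)
  PA <- Pf * Af / KdA
  PB <- Pf * Bf / KdB
  list(fraction_PA = PA / Pt, fraction_PB = PB / Pt,
       fraction_free = Pf / Pt, Afree_uM = Af, Bfree_uM = Bf, Pfree_uM = Pf)
}

#' Competition titration curve
#'
#' Bound fractions across a titrant grid in the presence of a fixed
#' competitor — the design of sub-saturating native-MS displacement
#' experiments (e.g. titrating Ent1 0-50 uM against 20 uM Ent2).
#'
#' @param Pt_uM Total protein.
#' @param fixed List/vector `(label, conc_uM, Kd_uM)` for the fixed ligand.
#' @param titrant List with `label`, `grid_uM` (ascending non-negative) and
#'   `Kd_uM`.
#' @return A `competition_curve` data frame: titrant concentration, bound
#'   fractions of titrant, fixed ligand and free protein.
#' @export
competition_curve <- function(Pt_uM, fixed, titrant) {
  grid <- titrant$grid_uM
  stopifnot(all(grid >= 0), !is.unsorted(grid))
  rows <- lapply(grid, function(a) {
    s <- solve_competition(competition_system(
      Pt_uM, At_uM = a, Bt_uM = fixed$conc_uM,
      KdA_uM = titrant$Kd_uM, KdB_uM = fixed$Kd_uM))
    data.frame(titrant_uM = a,
               frac_bound_titrant = s$fraction_PA,
               frac_bound_fixed = s$fraction_PB,
               frac_free = s$fraction_free)
  })
  out <- do.call(rbind, rows)
  attr(out, "titrant") <- titrant$label
  attr(out, "fixed") <- fixed$label
  class(out) <- c("competition_curve", "data.frame")
  out
}

#' @method print competition_curve
#' @export
print.competition_curve <- function(x, ...) {
  cat("Competition: titrating", attr(x, "titrant"), "against fixed",
      attr(x, "fixed"), "\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @method plot competition_curve
#' @export
plot.competition_curve <- function(x, ...) {
  plot(x$titrant_uM, x$frac_bound_fixed, type = "b", ylim = c(0, 1),
       xlab = paste0(attr(x, "titrant"), " (uM)"),
       ylab = "bound fraction of P", ...)
  lines(x$titrant_uM, x$frac_bound_titrant, type = "b", lty = 2)
  legend("topright", legend = c(attr(x, "fixed"), attr(x, "titrant")),
         lty = c(1, 2), bty = "n")
  invisible(x)
}
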