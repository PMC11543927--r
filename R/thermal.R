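# Gas constant, kJ/(mol K)
RGAS <- 8.314e-3

#' Construct a melting curve
#'
#' One nanoDSF trace at a single ligand concentration: temperature grid (deg
#' C), fluorescence signal (350 nm intensity or 350/330 ratio), total ligand
#' and protein concentrations (uM).
#'
#' @param temperature_C Strictly increasing temperature grid, >= 20 points.
#' @param signal Numeric trace, same length.
#' @param ligand_uM Total ligand concentration Lt (>= 0).
#' @param protein_uM Total protein concentration Pt (> 0).
#' @return A `melting_curve` object.
#' @export
melting_curve <- function(temperature_C, signal, ligand_uM, protein_uM) {
  stopifnot(length(temperature_C) == length(signal))
  if (length(temperature_C) < 20L)
    stop("melting curve needs at least 20 points", call. = FALSE)
  if (any(diff(temperature_C) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (ligand_uM < 0 || protein_uM <= 0)
    stop("require ligand_uM >= 0 and protein_uM > 0", call. = FALSE)
  structure(list(temperature_C = temperature_C, signal = signal,
                 ligand_uM = ligand_uM, protein_uM = protein_uM),
            class = "melting_curve")
}

#' Two-state unfolding model parameters
#'
#' Holds the apo midpoint `Tm0_K` (K), the van't Hoff unfolding enthalpy
#' `dHu_kJmol` at Tm0 (kJ/mol) and the heat-capacity change `dCp_kJmolK`
#' (kJ/(mol K), default 0, user-settable but not fitted).
#'
#' @param Tm0_K Apo melting temperature in Kelvin (> 273).
#' @param dHu_kJmol Unfolding enthalpy (> 0).
#' @param dCp_kJmolK Heat-capacity change; default 0.
#' @return A `thermo_model` object.
#' @export
thermo_model <- function(Tm0_K, dHu_kJmol, dCp_kJmolK = 0) {
  if (Tm0_K <= 273) stop("Tm0_K must exceed 273 K", call. = FALSE)
  if (dHu_kJmol <= 0) stop("dHu_kJmol must be positive", call. = FALSE)
  structure(list(Tm0_K = Tm0_K, dHu_kJmol = dHu_kJmol,
                 dCp_kJmolK = dCp_kJmolK, R = RGAS),
            class = "thermo_model")
}

# Gibbs-Helmholtz unfolding free energy, kJ/mol (vectorised over T)
dG_unfold <- function(T_K, model) {
  with(model, dHu_kJmol * (1 - T_K / Tm0_K) +
         dCp_kJmolK * ((T_K - Tm0_K) - T_K * log(T_K / Tm0_K)))
}

#' Fraction unfolded of the two-state model
#'
#' `fu = Ku/(1+Ku)` with `Ku = exp(-dGu/(R T))` and the Gibbs-Helmholtz free
#' energy `dGu(T) = dHu (1 - T/Tm0) + dCp ((T - Tm0) - T log(T/Tm0))`. At
#' `T = Tm0` (with dCp = 0) the fraction is exactly 0.5.
#'
#' @param T_K Temperature(s) in Kelvin (> 0).
#' @param model A `thermo_model`.
#' @return Fraction unfolded in \[0,1\], same length as `T_K`.
#' @export
fraction_unfolded <- function(T_K, model) {
  stopifnot(all(T_K > 0))
  Ku <- exp(-dG_unfold(T_K, model) / (RGAS * T_K))
  Ku / (1 + Ku)
}

#' Free ligand concentration at the melting midpoint
#'
#' At the midpoint half the protein is folded, so ligand depletion follows
#' `Lfree = Lt - (Pt/2) Lfree/(Kd + Lfree)`; the unique root in \[0, Lt\] is
#' the positive root of the quadratic
#' `Lfree^2 + (Kd + Pt/2 - Lt) Lfree - Kd Lt = 0`.
#'
#' @param Kd_uM Dissociation constant (> 0).
#' @param Lt_uM Total ligand (>= 0).
#' @param Pt_uM Total protein (>= 0).
#' @return Free ligand concentration in uM.
#' @export
free_ligand_at_tm <- function(Kd_uM, Lt_uM, Pt_uM) {
  stopifnot(Kd_uM > 0, Lt_uM >= 0, Pt_uM >= 0)
  b <- Kd_uM + Pt_uM / 2 - Lt_uM
  (-b + sqrt(b * b + 4 * Kd_uM * Lt_uM)) / 2
}

#' Predict the ligand-shifted melting temperature
#'
#' Thermodynamic linkage: binding to the folded state raises the apparent
#' midpoint, which satisfies `Ku(Tm) = 1 + Lfree/Kd`. With dCp = 0 the root
#' is closed-form; otherwise it is bracketed on \[Tm0, Tm0 + 60 K\].
#'
#' @param model A `thermo_model`.
#' @param Kd_uM Dissociation constant (> 0).
#' @param Lt_uM Total ligand (vectorised).
#' @param Pt_uM Total protein.
#' @return Predicted Tm in Kelvin, one per `Lt_uM`.
#' @export
predict_tm <- function(model, Kd_uM, Lt_uM, Pt_uM) {
  stopifnot(Kd_uM > 0)
  vapply(Lt_uM, function(Lt) {
    if (Lt <= 0) return(model$Tm0_K)
    Lf <- free_ligand_at_tm(Kd_uM, Lt, Pt_uM)
    cc <- log1p(Lf / Kd_uM)   # ln(1 + Lfree/Kd) >= 0
    if (model$dCp_kJmolK == 0) {
      # dHu (1 - T/Tm0) + R T c = 0  =>  T = dHu / (dHu/Tm0 - R c)
      denom <- model$dHu_kJmol / model$Tm0_K - RGAS * cc
      if (denom <= 0)
        stop("Tm shift exceeds the physical bracket; check parameters",
             call. = FALSE)
      return(model$dHu_kJmol / denom)
    }
    g <- function(T_K) dG_unfold(T_K, model) + RGAS * T_K * cc
    hi <- model$Tm0_K + 60
    if (g(hi) > 0)
      stop("no Tm bracket within [Tm0, Tm0 + 60 K]", call. = FALSE)
    uniroot(g, c(model$Tm0_K, hi), tol = 1e-10)$root
  }, 0)
}

#' Detect the melting temperature of one trace
#'
#' The Tm is the temperature of the extremum (largest absolute value) of the
#' Savitzky-Golay-smoothed first derivative of the signal. A trace whose
#' derivative extremum does not rise above 3x the median absolute derivative
#' has no detectable transition.
#'
#' @param curve A `melting_curve`.
#' @param smoothing_window Savitzky-Golay window length (odd, default 9;
#'   polynomial order 3).
#' @return Tm in Kelvin, with attribute `sign` (+1 signal rises on melting,
#'   -1 falls).
#' @export
detect_tm <- function(curve, smoothing_window = 9L) {
  stopifnot(inherits(curve, "melting_curve"))
  x <- curve$temperature_C
  y <- curve$signal
  if (smoothing_window %% 2L == 0L) smoothing_window <- smoothing_window + 1L
  ys <- signal::sgolayfilt(y, p = 3, n = smoothing_window)
  dy <- diff(ys) / diff(x)
  xm <- (x[-1] + x[-length(x)]) / 2
  dys <- signal::sgolayfilt(dy, p = 3, n = smoothing_window)
  i <- which.max(abs(dys))
  if (max(abs(dys)) < 3 * median(abs(dys)))
    stop("NoTransition: derivative extremum indistinct from baseline",
         call. = FALSE)
  structure(xm[i] + 273.15, sign = sign(dys[i]))
}

# Sum of squared Tm residuals for parameters th = (log10Kd, dHu, Tm0)
.tmshift_ssr <- function(th, Lt, Tm_obs, Pt, dCp) {
  Kd <- 10^th[1]
  if (th[2] <= 0 || th[3] <= 273) return(1e10)
  model <- structure(list(Tm0_K = th[3], dHu_kJmol = th[2],
                          dCp_kJmolK = dCp, R = RGAS),
                     class = "thermo_model")
  pred <- tryCatch(predict_tm(model, Kd, Lt, Pt), error = function(e) NULL)
  if (is.null(pred)) return(1e10)
  sum((pred - Tm_obs)^2)
}

#' Fit an apparent KD from a Tm-shift titration
#'
#' Least-squares fit of `(log10 Kd, dHu, Tm0)` to observed melting
#' temperatures across a ligand titration, under the two-state
#' ligand-coupled stability model (`Ku(Tm) = 1 + Lfree/Kd`, one-to-one
#' binding, binding enthalpy approximated as 0 so the KD is apparent and
#' refers to the melting-temperature regime). The fit runs from multiple Kd
#' starting points (1, 10, 100, 1000 uM) and keeps the best; `log10 Kd` is
#' bounded to \[-2, 5\]. The 95% confidence interval comes from a profile
#' scan over `log10 Kd` with an F-based sum-of-squares threshold.
#'
#' @param tm_observations Data frame or matrix with columns `Lt_uM` and
#'   `Tm_K` (>= 4 points including Lt = 0), or a list of melting curves whose
#'   Tms are detected first.
#' @param Pt_uM Total protein concentration (uM).
#' @param dCp_kJmolK Heat-capacity change, fixed (default 0).
#' @param compute_ci Compute the profile CI (default TRUE).
#' @param model_init Optional `thermo_model` supplying starting `dHu`/`Tm0`.
#' @return A `tmshift_fit` object with elements `Kd_app_uM`, `ci95`
#'   (lower/upper, upper may be `Inf` when the profile never crosses the
#'   threshold), `model` (fitted `thermo_model`), `tm_table` (Lt, observed
#'   and predicted Tm), `residual_norm`, `convergence`.
#' @examples
#' m <- thermo_model(Tm0_K = 318.15, dHu_kJmol = 400)
#' lt <- 3750 / 2^(10:0)
#' tm <- predict_tm(m, Kd_uM = 138, Lt_uM = c(0, lt), Pt_uM = 8)
#' fit <- fit_kd_tmshift(data.frame(Lt_uM = c(0, lt), Tm_K = tm), Pt_uM = 8)
#' coef(fit)
#' @export
fit_kd_tmshift <- function(tm_observations, Pt_uM, dCp_kJmolK = 0,
                           compute_ci = TRUE, model_init = NULL) {
  if (is.list(tm_observations) && !is.data.frame(tm_observations) &&
      inherits(tm_observations[[1]], "melting_curve")) {
    curves <- tm_observations
    tm_observations <- data.frame(
      Lt_uM = vapply(curves, function(cu) cu$ligand_uM, 0),
      Tm_K = vapply(curves, function(cu) as.numeric(detect_tm(cu)), 0))
  }
  obs <- as.data.frame(tm_observations)
  stopifnot(all(c("Lt_uM", "Tm_K") %in% names(obs)))
  obs <- obs[order(obs$Lt_uM), ]
  if (nrow(obs) < 4L)
    stop("need at least 4 titration points", call. = FALSE)
  if (min(obs$Lt_uM) > 0)
    stop("titration must include an Lt = 0 (apo) point", call. = FALSE)
  if (any(diff(obs$Tm_K) < -0.5))
    warning("observed Tm not monotone non-decreasing in Lt; ",
            "fit may be unreliable")
  Lt <- obs$Lt_uM
  Tm <- obs$Tm_K

  tm0_init <- Tm[Lt == 0][1]
  dhu_init <- if (!is.null(model_init)) model_init$dHu_kJmol else 400
  if (!is.null(model_init)) tm0_init <- model_init$Tm0_K

  best <- NULL
  for (kd0 in c(1, 10, 100, 1000)) {
    fit <- optim(c(log10(kd0), dhu_init, tm0_init), .tmshift_ssr,
                 Lt = Lt, Tm_obs = Tm, Pt = Pt_uM, dCp = dCp_kJmolK,
                 method = "L-BFGS-B",
                 lower = c(-2, 50, tm0_init - 10),
                 upper = c(5, 3000, tm0_init + 10),
                 control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- best$par
  model <- thermo_model(th[3], th[2], dCp_kJmolK)
  Kd <- 10^th[1]
  ssr <- best$value
  n <- length(Lt)

  ci <- c(NA_real_, NA_real_)
  ci_unbounded <- FALSE
  if (compute_ci) {
    # F-based profile threshold for one parameter at 95%
    dof <- max(n - 3L, 1L)
    thr <- ssr * (1 + qf(0.95, 1, dof) / dof)
    prof <- function(lk) {
      inner <- optim(c(th[2], th[3]),
                     function(p) .tmshift_ssr(c(lk, p), Lt, Tm, Pt_uM,
                                              dCp_kJmolK),
                     method = "Nelder-Mead",
                     control = list(maxit = 400))
      inner$value
    }
    grid <- seq(-2, 5, by = 0.1)
    pv <- vapply(grid, prof, 0)
    below <- pv <= thr
    if (any(below)) {
      lo_i <- min(which(below)); hi_i <- max(which(below))
      lo <- if (lo_i == 1L) grid[1] else {
        # linear interpolation of the crossing
        x1 <- grid[lo_i - 1L]; x2 <- grid[lo_i]
        x1 + (x2 - x1) * (pv[lo_i - 1L] - thr) / (pv[lo_i - 1L] - pv[lo_i])
      }
      if (hi_i == length(grid)) {
        hi <- Inf; ci_unbounded <- TRUE
      } else {
        x1 <- grid[hi_i]; x2 <- grid[hi_i + 1L]
        hi <- x1 + (x2 - x1) * (thr - pv[hi_i]) / (pv[hi_i + 1L] - pv[hi_i])
      }
      ci <- c(10^lo, if (is.finite(hi)) 10^hi else Inf)
    }
  }

  structure(list(
    Kd_app_uM = Kd,
    ci95 = ci,
    ci95_upper_unbounded = ci_unbounded,
    model = model,
    tm_table = data.frame(Lt_uM = Lt, Tm_obs_K = Tm,
                          Tm_pred_K = predict_tm(model, Kd, Lt, Pt_uM)),
    Pt_uM = Pt_uM,
    residual_norm = sqrt(ssr),
    convergence = best$convergence
  ), class = "tmshift_fit")
}

#' @method print tmshift_fit
#' @export
print.tmshift_fit <- function(x, ...) {
  cat("Tm-shift binding fit (two-state, 1:1 ligand-coupled stability)\n")
  cat(sprintf("  Kd_app: %s uM  (CI95 %s - %s uM%s)\n",
              fmt6(x$Kd_app_uM), fmt6(x$ci95[1]),
              if (is.finite(x$ci95[2])) fmt6(x$ci95[2]) else "Inf",
              if (isTRUE(x$ci95_upper_unbounded)) ", upper open" else ""))
  cat(sprintf("  Tm0: %s K   dHu: %s kJ/mol   dCp: %s kJ/(mol K)\n",
              fmt6(x$model$Tm0_K), fmt6(x$model$dHu_kJmol),
              fmt6(x$model$dCp_kJmolK)))
  cat(sprintf("  %d titration points, residual norm %s K\n",
              nrow(x$tm_table), fmt6(x$residual_norm)))
  invisible(x)
}

#' @method summary tmshift_fit
#' @export
summary.tmshift_fit <- function(object, ...) {
  print(object)
  cat("\nPer-point melting temperatures:\n")
  tab <- object$tm_table
  tab$residual_K <- tab$Tm_obs_K - tab$Tm_pred_K
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @method coef tmshift_fit
#' @export
coef.tmshift_fit <- function(object, ...) {
  c(Kd_app_uM = object$Kd_app_uM, Tm0_K = object$model$Tm0_K,
    dHu_kJmol = object$model$dHu_kJmol)
}

#' @method predict tmshift_fit
#' @export
predict.tmshift_fit <- function(object, newdata = NULL, ...) {
  Lt <- if (is.null(newdata)) object$tm_table$Lt_uM else newdata$Lt_uM
  predict_tm(object$model, object$Kd_app_uM, Lt, object$Pt_uM)
}

#' @method residuals tmshift_fit
#' @export
residuals.tmshift_fit <- function(object, ...) {
  object$tm_table$Tm_obs_K - object$tm_table$Tm_pred_K
}

#' @method plot tmshift_fit
#' @export
plot.tmshift_fit <- function(x, ...) {
  tab <- x$tm_table
  lt <- tab$Lt_uM
  lt_plot <- ifelse(lt > 0, lt, min(lt[lt > 0]) / 4)
  grid <- exp(seq(log(min(lt_plot)), log(max(lt)), length.out = 100))
  plot(lt_plot, tab$Tm_obs_K - 273.15, log = "x",
       xlab = "ligand (uM, apo plotted off-scale left)",
       ylab = "Tm (deg C)",
       main = sprintf("Tm shift: Kd_app = %s uM", fmt6(x$Kd_app_uM)), ...)
  lines(grid, predict_tm(x$model, x$Kd_app_uM, grid, x$Pt_uM) - 273.15)
  invisible(x)
}
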