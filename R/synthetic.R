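# Seeded generators emulating every input the analysis stages consume.
# Forward models here are written independently of the fitting code so
# recovery tests exercise a genuine round trip.

#' Generate a toy proteome with planted motifs
#'
#' Random background sequences (uniform over the 20 residues) with motif
#' instances planted at chosen positions. Disorder tracks are piecewise:
#' baseline 0.1 (ordered), planted spans set to 0.9 when `disordered` is
#' TRUE and 0.1 otherwise. The returned manifest is the truth set, including
#' a brute-force self-scan for background collisions.
#'
#' @param n_proteins Number of sequences.
#' @param length_range Sequence length range (default 120-300).
#' @param plants Data frame with columns `protein` (index), `position`
#'   (1-based start), `instance` (literal motif instance, e.g. "DLIDL"),
#'   `disordered` (logical). May be empty.
#' @param motif `motif_spec` used for the manifest self-scan (default the
#'   `[DSNTV]` CBM variant).
#' @param seed RNG seed.
#' @return List with `sequences` (named character), `tracks` (named list of
#'   disorder probabilities), and `manifest` (plants plus the exhaustive
#'   self-scan hit table `all_hits`).
#' @export
gen_toy_proteome <- function(n_proteins, plants = NULL,
                             length_range = c(120L, 300L),
                             motif = cbm_motifs()$CBM, seed = 1L) {
  restore <- .Random.seed_exists(); on.exit(restore(), add = TRUE)
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  ids <- sprintf("prot%03d", seq_len(n_proteins))
  seqs <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), "")
  names(seqs) <- ids
  tracks <- lapply(lens, function(L) rep(0.1, L))
  names(tracks) <- ids
  if (!is.null(plants) && nrow(plants) > 0) {
    spans <- cbind(plants$position,
                   plants$position + nchar(plants$instance) - 1L)
    for (i in seq_len(nrow(plants))) {
      pi <- plants$protein[i]
      if (spans[i, 2] > lens[pi])
        stop("plant exceeds sequence bounds", call. = FALSE)
      same <- which(plants$protein == plants$protein[i])
      same <- same[same != i]
      if (any(spans[same, 1] <= spans[i, 2] & spans[same, 2] >= spans[i, 1]))
        stop("overlapping plants in protein ", pi, call. = FALSE)
      ch <- strsplit(seqs[pi], "")[[1]]
      ch[spans[i, 1]:spans[i, 2]] <- strsplit(plants$instance[i], "")[[1]]
      seqs[pi] <- paste(ch, collapse = "")
      if (isTRUE(plants$disordered[i]))
        tracks[[pi]][spans[i, 1]:spans[i, 2]] <- 0.9
    }
  }
  all_hits <- do.call(rbind, lapply(ids, function(id)
    scan_sequence(seqs[[id]], motif, protein_id = id)))
  list(sequences = seqs, tracks = tracks,
       manifest = list(seed = seed, plants = plants, all_hits = all_hits))
}

#' Generate a nanoDSF Tm-shift titration
#'
#' Simulates one melting trace per ligand concentration of a 1:1 dilution
#' series (default: 11 points from 3.75 mM, plus an apo curve). The forward
#' model couples two-state unfolding to one-to-one folded-state binding:
#' the apparent unfolding constant is `K_app(T) = Ku(T) / (1 + Lfree/Kd)`
#' with ligand depletion taken at the midpoint (folded protein = Pt/2), and
#' the signal is `baseline_n(T) + (baseline_u(T) - baseline_n(T)) * f_app`.
#'
#' @param model A `thermo_model` (apo stability).
#' @param Kd_uM True dissociation constant.
#' @param Pt_uM Total protein (default 8, the standard assay concentration).
#' @param top_Lt_uM Top ligand concentration of the dilution series
#'   (default 3750 uM).
#' @param n_points Number of non-zero ligand points (default 11).
#' @param dilution Serial dilution factor (default 2 = 1:1 dilutions).
#' @param include_apo Add an Lt = 0 curve (default TRUE).
#' @param temp_grid_C Temperature grid (default 20-95 by 0.5).
#' @param baselines List with native/unfolded intercepts and slopes
#'   (`bn0`, `bn1`, `bu0`, `bu1`).
#' @param noise_sd Gaussian noise SD in signal units (default 0).
#' @param seed RNG seed.
#' @return List with `curves` (list of `melting_curve`) and `manifest`
#'   (truth: Kd, model parameters, ligand series, seed).
#' @export
gen_melting_titration <- function(model, Kd_uM, Pt_uM = 8,
                                  top_Lt_uM = 3750, n_points = 11L,
                                  dilution = 2, include_apo = TRUE,
                                  temp_grid_C = seq(20, 95, by = 0.5),
                                  baselines = list(bn0 = 1.0, bn1 = -0.002,
                                                   bu0 = 2.0, bu1 = -0.001),
                                  noise_sd = 0, seed = 1L) {
  restore <- .Random.seed_exists(); on.exit(restore(), add = TRUE)
  set.seed(seed)
  lt <- top_Lt_uM / dilution^(seq_len(n_points) - 1L)
  lt <- sort(lt)
  if (include_apo) lt <- c(0, lt)
  TK <- temp_grid_C + 273.15
  curves <- lapply(lt, function(Lt) {
    # independent forward model: apparent two-state with midpoint depletion
    Lf <- if (Lt > 0) {
      b <- Kd_uM + Pt_uM / 2 - Lt
      (-b + sqrt(b^2 + 4 * Kd_uM * Lt)) / 2
    } else 0
    dG <- model$dHu_kJmol * (1 - TK / model$Tm0_K) +
      model$dCp_kJmolK * ((TK - model$Tm0_K) - TK * log(TK / model$Tm0_K))
    Kapp <- exp(-dG / (RGAS * TK)) / (1 + Lf / Kd_uM)
    fapp <- Kapp / (1 + Kapp)
    bn <- baselines$bn0 + baselines$bn1 * temp_grid_C
    bu <- baselines$bu0 + baselines$bu1 * temp_grid_C
    sig <- bn + (bu - bn) * fapp
    if (noise_sd > 0) sig <- sig + rnorm(length(sig), 0, noise_sd)
    melting_curve(temp_grid_C, sig, ligand_uM = Lt, protein_uM = Pt_uM)
  })
  list(curves = curves,
       manifest = list(seed = seed, Kd_uM = Kd_uM, Pt_uM = Pt_uM,
                       Tm0_K = model$Tm0_K, dHu_kJmol = model$dHu_kJmol,
                       dCp_kJmolK = model$dCp_kJmolK, Lt_uM = lt,
                       noise_sd = noise_sd))
}

#' Generate a native-MS species titration
#'
#' Equilibrium species probabilities sampled as multinomial counts.
#' `binding = list(kind = "identical", n = 3, Kd_uM = 50)` uses the
#' independent-identical-sites binomial model;
#' `binding = list(kind = "stepwise", Kd_uM = c(...))` uses macroscopic
#' sequential dissociation constants (partition-function weights
#' `w_i = prod_j Lfree/Kd_j`), solved self-consistently for free ligand.
#' Stepwise constants equal to `Kd * i/(n - i + 1)` reproduce the identical
#' non-interacting case exactly (the classic statistical-factor identity).
#'
#' @param binding Binding model description (see above).
#' @param Pt_uM Total protein (default 1.75, the native-MS assay value).
#' @param Lt_grid Ligand concentrations (uM).
#' @param counts_N Multinomial size per point (default 5000).
#' @param seed RNG seed.
#' @return List with `titration` (list of `species_distribution`) and
#'   `manifest` (truth parameters and exact fractions per point).
#' @export
gen_species_titration <- function(binding, Pt_uM = 1.75,
                                  Lt_grid = c(2, 5, 10, 20, 50, 100),
                                  counts_N = 5000, seed = 1L) {
  restore <- .Random.seed_exists(); on.exit(restore(), add = TRUE)
  set.seed(seed)
  probs <- lapply(Lt_grid, function(Lt)
    .species_probs(binding, Pt_uM, Lt))
  titration <- lapply(seq_along(Lt_grid), function(k) {
    counts <- as.numeric(rmultinom(1, counts_N, probs[[k]]))
    if (all(counts == 0)) counts[1] <- 1
    species_distribution(counts, Lt_uM = Lt_grid[k], Pt_uM = Pt_uM)
  })
  list(titration = titration,
       manifest = list(seed = seed, binding = binding, Pt_uM = Pt_uM,
                       Lt_grid = Lt_grid, counts_N = counts_N,
                       fractions = probs))
}

# exact species probabilities for either binding model (independent of the
# analyzers: stepwise partition function solved by damped fixed point)
.species_probs <- function(binding, Pt_uM, Lt_uM) {
  if (binding$kind == "identical") {
    n <- binding$n
    # ligand-depleted per-site isotherm, solved on Lfree by fixed point
    Lf <- Lt_uM
    for (it in 1:10000) {
      p <- Lf / (binding$Kd_uM + Lf)
      Lf_new <- max(Lt_uM - n * p * Pt_uM, 0)
      if (abs(Lf_new - Lf) < 1e-14 * (Lf + 1e-300)) break
      Lf <- Lf + 0.5 * (Lf_new - Lf)
    }
    p <- Lf / (binding$Kd_uM + Lf)
    dbinom(0:n, n, p)
  } else if (binding$kind == "stepwise") {
    kds <- binding$Kd_uM
    n <- length(kds)
    Lf <- Lt_uM
    for (it in 1:10000) {
      w <- cumprod(c(1, Lf / kds))
      f <- w / sum(w)
      nu <- sum((0:n) * f)
      Lf_new <- max(Lt_uM - nu * Pt_uM, 0)
      if (abs(Lf_new - Lf) < 1e-14 * (Lf + 1e-300)) break
      Lf <- Lf + 0.5 * (Lf_new - Lf)
    }
    w <- cumprod(c(1, Lf / kds))
    w / sum(w)
  } else stop("unknown binding kind: ", binding$kind, call. = FALSE)
}

#' Generate acceptor-photobleaching FRET ROIs
#'
#' Per-group ROI tables with known true efficiency: donor post-bleach
#' intensities are lognormal, `donor_pre = donor_post (1 - E/100)` with
#' per-ROI efficiency drawn `Normal(true_E, sd)`; acceptor pre is lognormal
#' and acceptor post follows the bleach fraction distribution.
#'
#' @param groups Data frame with columns `label`, `true_E_pct`, `n`, `sd`.
#' @param bleach_mean Mean acceptor bleach fraction (default 0.92).
#' @param bleach_sd SD of the bleach fraction (default 0.03).
#' @param seed RNG seed.
#' @return List with `rois` (data frame in the ROI CSV layout) and
#'   `manifest` (truth table and seed).
#' @export
gen_fret_rois <- function(groups, bleach_mean = 0.92, bleach_sd = 0.03,
                          seed = 1L) {
  restore <- .Random.seed_exists(); on.exit(restore(), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    n <- groups$n[g]
    dpost <- rlnorm(n, log(1000), 0.3)
    E <- rnorm(n, groups$true_E_pct[g], groups$sd[g])
    apre <- rlnorm(n, log(800), 0.3)
    bleach <- pmin(pmax(rnorm(n, bleach_mean, bleach_sd), 0), 1)
    data.frame(
      roi_id = sprintf("%s_%03d", groups$label[g], seq_len(n)),
      group = groups$label[g],
      donor_pre = dpost * (1 - E / 100),
      donor_post = dpost,
      acceptor_pre = apre,
      acceptor_post = apre * (1 - bleach),
      stringsAsFactors = FALSE)
  })
  list(rois = do.call(rbind, rows),
       manifest = list(seed = seed, groups = groups,
                       bleach_mean = bleach_mean, bleach_sd = bleach_sd))
}

#' Generate a synthetic C-alpha structure
#'
#' An ideal alpha-helical C-alpha trace (rise 1.5 A, radius 2.3 A, 100
#' degrees per residue) — a simple, reproducible stand-in coordinate set for
#' superposition tests and fixtures.
#'
#' @param n_res Number of residues.
#' @param start_resno First residue number (default 1).
#' @param entry_id,chain_id Labels.
#' @return A `structure_model`.
#' @export
gen_helix_structure <- function(n_res, start_resno = 1L,
                                entry_id = "synthetic_helix",
                                chain_id = "A") {
  i <- seq_len(n_res) - 1L
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  structure_model(start_resno + i, xyz, entry_id = entry_id,
                  chain_id = chain_id)
}

#' Write a structure model as a minimal PDB file
#'
#' Emits standard ATOM records (CA only, ALA residues) so synthetic models
#' can round-trip through [load_calpha()].
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @export
write_calpha_pdb <- function(model, path) {
  lines <- vapply(seq_along(model$resno), function(i)
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, model$chain_id, model$resno[i],
            model$xyz[i, 1], model$xyz[i, 2], model$xyz[i, 3]), "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
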