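test_that("occupancy statistics follow the definitions", {
  d <- species_distribution(c(1, 2, 1), Lt_uM = 10, Pt_uM = 2)
  o <- occupancy(d)
  expect_equal(o$fractions, c(0.25, 0.5, 0.25))
  expect_equal(o$nu, 1)
  expect_equal(o$Lfree_uM, 8)
  expect_equal(o$scatchard_y, 1 / 8)

  apo <- occupancy(species_distribution(c(5, 0, 0, 0, 0), 10, 2))
  expect_equal(apo$nu, 0)
  expect_equal(apo$scatchard_y, 0)

  full <- occupancy(species_distribution(c(0, 0, 0, 1), 10, 2))
  expect_equal(full$nu, 3)

  # Lfree <= 0: floored with warning, Scatchard flagged
  expect_warning(o2 <- occupancy(species_distribution(c(0, 0, 1), 1, 2)),
                 "floored")
  expect_true(o2$scatchard_undefined)
})

test_that("identical-sites fractions solve the depleted isotherm", {
  expect_equal(identical_sites_fractions(3, 10, 2, 0)$fractions,
               c(1, 0, 0, 0))
  sat <- identical_sites_fractions(3, 10, 2, 1e9)
  expect_gt(sat$fractions[4], 1 - 1e-6)
  # frozen fixed-point oracle for n=3, Kd=10, Pt=2, Lt=10
  r <- identical_sites_fractions(3, 10, 2, 10)
  expect_equal(r$p, 0.42661558184824167, tolerance = 1e-10)
  expect_equal(r$fractions, dbinom(0:3, 3, 0.42661558184824167),
               tolerance = 1e-9)
  expect_equal(sum(r$fractions), 1, tolerance = 1e-12)
})

test_that("Scatchard linearity is exact for the identical-sites model", {
  n <- 3; Kd <- 25; Pt <- 1.75
  for (Lt in c(0.5, 2, 7, 20, 60, 150, 400)) {
    r <- identical_sites_fractions(n, Kd, Pt, Lt)
    nu <- n * r$p
    Lfree <- Lt - nu * Pt
    expect_equal(nu / Lfree, (n - nu) / Kd, tolerance = 1e-9)
  }
})

test_that("identical-sites fit recovers Kd and deviation separates models", {
  g <- gen_species_titration(list(kind = "identical", n = 3, Kd_uM = 50),
                             counts_N = 5000, seed = 21L)
  fit <- fit_identical_sites(g$titration, n_sites = 3)
  expect_lt(abs(fit$Kd_uM / 50 - 1), 0.10)

  thr <- null_deviation_quantile(3, 50, 1.75, g$manifest$Lt_grid,
                                 counts_N = 5000, n_sim = 100, seed = 22L)
  expect_lt(fit$deviation, thr)

  coop <- gen_species_titration(
    list(kind = "stepwise", Kd_uM = c(200, 50, 12.5)),
    counts_N = 5000, seed = 23L)
  coop_fit <- fit_identical_sites(coop$titration, n_sites = 3)
  expect_gt(coop_fit$deviation, thr)

  # exact binomial point: zero deviation at the generating Kd
  pr <- identical_sites_fractions(3, 50, 1.75, 20)$fractions
  tit1 <- lapply(c(5, 20, 80), function(Lt) species_distribution(
    identical_sites_fractions(3, 50, 1.75, Lt)$fractions * 1e6, Lt, 1.75))
  exact <- fit_identical_sites(tit1, 3)
  expect_lt(exact$deviation, 1e-10)
  expect_lt(abs(exact$Kd_uM / 50 - 1), 1e-3)

  apo_only <- lapply(c(1, 2, 3), function(Lt)
    species_distribution(c(10, 0, 0, 0), Lt, 1.75))
  expect_error(fit_identical_sites(apo_only), "degenerate")
})

test_that("statistical-factor stepwise constants reproduce the binomial law", {
  # Kd_i = Kd * i / (n - i + 1) is the non-interacting identical case
  n <- 3; Kd <- 40
  kds <- Kd * (1:n) / (n - (1:n) + 1)
  for (Lt in c(3, 15, 60)) {
    coop <- gen_species_titration(list(kind = "stepwise", Kd_uM = kds),
                                  Pt_uM = 1.75, Lt_grid = Lt,
                                  counts_N = 10, seed = 1L)
    expect_equal(coop$manifest$fractions[[1]],
                 identical_sites_fractions(n, Kd, 1.75, Lt)$fractions,
                 tolerance = 1e-8)
  }
})

test_that("competition solver honours closed forms, symmetry and mass", {
  # Bt = 0 reduces to the 1:1 quadratic
  Pt <- 1.75; At <- 20; KdA <- 138
  s <- solve_competition(competition_system(Pt, At, 0, KdA, 177))
  quad <- ((Pt + At + KdA) - sqrt((Pt + At + KdA)^2 - 4 * Pt * At)) / (2 * Pt)
  expect_equal(s$fraction_PA, quad, tolerance = 1e-9)
  expect_equal(s$fraction_PB, 0)

  sym <- solve_competition(competition_system(1.75, 20, 20, 150, 150))
  expect_equal(sym$fraction_PA, sym$fraction_PB, tolerance = 1e-10)

  # frozen numerical oracle (independent least-squares solve)
  s2 <- solve_competition(competition_system(1.75, 20, 20, 138, 177))
  expect_equal(s2$fraction_PA, 0.11427172936678466, tolerance = 1e-7)
  expect_equal(s2$fraction_PB, 0.08928992917380163, tolerance = 1e-7)
  expect_gt(s2$fraction_PA, s2$fraction_PB)

  # mass conservation to 1e-9
  expect_equal(s2$Afree_uM + s2$fraction_PA * 1.75, 20, tolerance = 1e-9)
  expect_equal(s2$Bfree_uM + s2$fraction_PB * 1.75, 20, tolerance = 1e-9)
  expect_equal(s2$fraction_PA + s2$fraction_PB + s2$fraction_free, 1,
               tolerance = 1e-12)
})

test_that("competition curves are monotone and ordered by titrant strength", {
  grid <- c(0, 5, 10, 15, 20, 25, 30, 50)
  cc <- competition_curve(1.75, fixed = list(label = "B", conc_uM = 20,
                                             Kd_uM = 177),
                          titrant = list(label = "A", grid_uM = grid,
                                         Kd_uM = 138))
  expect_equal(nrow(cc), 8L)
  expect_true(all(diff(cc$frac_bound_fixed) <= 1e-12))

  weak <- competition_curve(1.75, fixed = list(label = "B", conc_uM = 20,
                                               Kd_uM = 177),
                            titrant = list(label = "A", grid_uM = grid,
                                           Kd_uM = 500))
  expect_true(all(cc$frac_bound_fixed[-1] < weak$frac_bound_fixed[-1]))

  # infinitely weak titrant leaves the fixed ligand untouched
  inert <- competition_curve(1.75, fixed = list(label = "B", conc_uM = 20,
                                                Kd_uM = 177),
                             titrant = list(label = "A", grid_uM = grid,
                                            Kd_uM = 1e12))
  expect_equal(diff(range(inert$frac_bound_fixed)), 0, tolerance = 1e-9)
})

test_that("displacement asymmetry favours the stronger ligand", {
  grid <- c(0, 5, 10, 15, 20, 25, 30, 50)
  a_into_b <- competition_curve(1.75,
    fixed = list(label = "B", conc_uM = 20, Kd_uM = 177),
    titrant = list(label = "A", grid_uM = grid, Kd_uM = 138))
  b_into_a <- competition_curve(1.75,
    fixed = list(label = "A", conc_uM = 20, Kd_uM = 138),
    titrant = list(label = "B", grid_uM = grid, Kd_uM = 177))
  drop_b <- a_into_b$frac_bound_fixed[1] - a_into_b$frac_bound_fixed
  drop_a <- b_into_a$frac_bound_fixed[1] - b_into_a$frac_bound_fixed
  # absolute drops favour the stronger titrant over the sub-saturating range
  mid <- grid > 0 & grid <= 30
  expect_true(all(drop_b[mid] > drop_a[mid]))
  # relative displacement (fraction of the baseline complex lost) favours
  # the stronger titrant at every non-zero grid point
  rel_b <- drop_b / a_into_b$frac_bound_fixed[1]
  rel_a <- drop_a / b_into_a$frac_bound_fixed[1]
  expect_true(all(rel_b[-1] > rel_a[-1]))
})

test_that("species CSV round-trips through the reader", {
  tmp <- withr::local_tempdir()
  g <- gen_species_titration(list(kind = "identical", n = 3, Kd_uM = 50),
                             seed = 2L)
  df <- do.call(rbind, lapply(g$titration, function(d)
    data.frame(Lt_uM = d$Lt_uM, Pt_uM = d$Pt_uM,
               n_bound = seq_along(d$intensities) - 1L,
               intensity = d$intensities)))
  f <- file.path(tmp, "species.csv")
  write.csv(df, f, row.names = FALSE)
  back <- read_species_csv(f)
  expect_equal(length(back), length(g$titration))
  expect_equal(back[[1]]$intensities, g$titration[[1]]$intensities)
})
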