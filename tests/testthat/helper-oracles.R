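# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force window checks for motif scanning,
# textbook Welch formulas for the trim-0 Yuen limit, fixed-point iteration
# for equilibrium roots, and numerical rotation optimization for Kabsch.

# exhaustive window-by-window motif check
brute_scan <- function(seq, classes) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(classes)
  if (length(chars) < L) return(integer())
  starts <- integer()
  for (s in seq_len(length(chars) - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!chars[s + k - 1L] %in% classes[[k]]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# textbook Welch two-sample t-test
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# fixed-point iteration for midpoint free ligand
lfree_fixed_point <- function(Kd, Lt, Pt) {
  Lf <- Lt
  for (i in 1:100000) {
    nxt <- Lt - (Pt / 2) * Lf / (Kd + Lf)
    if (abs(nxt - Lf) < 1e-14) break
    Lf <- nxt
  }
  Lf
}

# minimum RMSD over rigid transforms by numerical optimization of an
# axis-angle rotation plus translation (independent of the SVD route)
rmsd_numeric_oracle <- function(P, Q) {
  obj <- function(par) {
    ax <- par[1:3]; th <- sqrt(sum(ax^2))
    if (th < 1e-12) Rm <- diag(3) else {
      k <- ax / th
      K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                  byrow = TRUE)
      Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    moved <- Q %*% t(Rm)
    moved <- sweep(moved, 2, par[4:6], `+`)
    sqrt(mean(rowSums((moved - P)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, 0.2, -0.3, 0, 0, 0),
                     c(-1, 1, 0.5, 1, -1, 1))) {
    o <- optim(start, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# axis-angle rotation matrix (Rodrigues) for constructing rigid transforms
.kabsch_rot_for_test <- function(ax) {
  th <- sqrt(sum(ax^2)); k <- ax / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# random ROI data frame in the CSV layout
make_rois <- function(groups, n, e_mean, e_sd, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(groups), function(g) {
    dpost <- rlnorm(n[g], log(1000), 0.3)
    E <- rnorm(n[g], e_mean[g], e_sd[g])
    data.frame(roi_id = paste0(groups[g], "_", seq_len(n[g])),
               group = groups[g],
               donor_pre = dpost * (1 - E / 100), donor_post = dpost,
               acceptor_pre = 100, acceptor_post = 5)
  }))
}
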