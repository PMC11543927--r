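#' Acceptor-photobleaching FRET efficiency of one ROI
#'
#' Donor dequenching after acceptor destruction:
#' `E = 100 (donor_post - donor_pre) / donor_post` (percent). Negative
#' efficiencies are retained — dropping them would bias group means upward.
#'
#' @param donor_pre,donor_post Background-subtracted mean donor intensities
#'   before/after bleaching (`donor_post` must be > 0).
#' @return Efficiency in percent (vectorised).
#' @export
fret_efficiency <- function(donor_pre, donor_post) {
  if (any(donor_post <= 0))
    stop("donor_post must be positive for a defined efficiency",
         call. = FALSE)
  100 * (donor_post - donor_pre) / donor_post
}

#' Acceptor-bleaching quality control
#'
#' Keeps an ROI iff the acceptor bleach fraction
#' `1 - acceptor_post/acceptor_pre` reaches `min_bleach` (inclusive;
#' default 0.85, i.e. at least 85% of the acceptor destroyed).
#'
#' @param acceptor_pre,acceptor_post Acceptor intensities (vectorised).
#' @param min_bleach Minimum bleach fraction.
#' @return Logical keep flag; ROIs with `acceptor_pre <= 0` are dropped.
#' @export
bleach_qc <- function(acceptor_pre, acceptor_post, min_bleach = 0.85) {
  ok <- acceptor_pre > 0
  keep <- ok & (1 - acceptor_post / acceptor_pre >= min_bleach)
  keep[!ok] <- FALSE
  keep
}

#' Trimmed mean
#'
#' Mean after removing the `floor(trim * n)` smallest and largest values
#' (base R `mean(trim=)` semantics).
#'
#' @param x Numeric values.
#' @param trim Trim fraction gamma in \[0, 0.5).
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.2) {
  stopifnot(trim >= 0, trim < 0.5)
  if (length(x) - 2 * floor(trim * length(x)) < 2L)
    stop("too few values after trimming", call. = FALSE)
  mean(x, trim = trim)
}

# winsorized variance used by Yuen's statistic
.winsor_var <- function(x, trim) {
  n <- length(x)
  g <- floor(trim * n)
  xs <- sort(x)
  if (g > 0) {
    xs[seq_len(g)] <- xs[g + 1L]
    xs[(n - g + 1L):n] <- xs[n - g]
  }
  var(xs)
}

#' Yuen's trimmed-means two-sample test
#'
#' Robust two-sided comparison of trimmed means using winsorized variances:
#' with `h_i = n_i - 2 floor(trim n_i)` effective sizes,
#' `d_i = s2w_i (n_i - 1) / (h_i (h_i - 1))`,
#' `t = (xbar_t - ybar_t)/sqrt(d_1 + d_2)` with Welch-Satterthwaite degrees
#' of freedom. With `trim = 0` this is exactly Welch's t-test.
#'
#' @param x,y Numeric samples (>= 5 each).
#' @param trim Trim fraction gamma (default 0.2).
#' @return A `yuen_result` list: `trimmed_mean_1`, `trimmed_mean_2`,
#'   `t_statistic`, `df`, `p_value`, `trim`.
#' @export
yuen_test <- function(x, y, trim = 0.2) {
  stopifnot(length(x) >= 5L, length(y) >= 5L, trim >= 0, trim < 0.5)
  n1 <- length(x); n2 <- length(y)
  h1 <- n1 - 2L * floor(trim * n1)
  h2 <- n2 - 2L * floor(trim * n2)
  m1 <- mean(x, trim = trim); m2 <- mean(y, trim = trim)
  d1 <- .winsor_var(x, trim) * (n1 - 1) / (h1 * (h1 - 1))
  d2 <- .winsor_var(y, trim) * (n2 - 1) / (h2 * (h2 - 1))
  if (d1 + d2 <= 0) {
    if (m1 == m2)
      return(structure(list(trimmed_mean_1 = m1, trimmed_mean_2 = m2,
                            t_statistic = 0, df = h1 + h2 - 2,
                            p_value = 1, trim = trim),
                       class = "yuen_result"))
    stop("zero pooled winsorized variance with unequal trimmed means",
         call. = FALSE)
  }
  tstat <- (m1 - m2) / sqrt(d1 + d2)
  df <- (d1 + d2)^2 / (d1^2 / (h1 - 1) + d2^2 / (h2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(trimmed_mean_1 = m1, trimmed_mean_2 = m2,
                 t_statistic = tstat, df = df, p_value = p, trim = trim),
            class = "yuen_result")
}

#' @method print yuen_result
#' @export
print.yuen_result <- function(x, ...) {
  cat(sprintf(
    "Yuen trimmed-means test (trim = %.2f): t = %s, df = %s, p = %s\n",
    x$trim, fmt6(x$t_statistic), fmt6(x$df), fmt6(x$p_value)))
  cat("  trimmed means:", fmt6(x$trimmed_mean_1), "vs",
      fmt6(x$trimmed_mean_2), "\n")
  invisible(x)
}

#' Holm-Bonferroni adjustment
#'
#' Step-down Holm correction (order-preserving, monotone); wraps
#' [stats::p.adjust()].
#'
#' @param p Raw p-values in \[0,1\].
#' @return Adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "holm")
}

.stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Group-wise FRET comparison against a reference
#'
#' Applies bleach QC, computes per-ROI efficiencies, then per-group trimmed
#' means and Yuen tests of every group against the reference, Holm-adjusted.
#'
#' @param rois Data frame with columns `roi_id`, `group`, `donor_pre`,
#'   `donor_post`, `acceptor_pre`, `acceptor_post` (see [read_rois_csv()]).
#' @param reference_group Reference group label (e.g. `"WT"`).
#' @param trim Trim fraction (default 0.2).
#' @param min_bleach QC threshold (default 0.85).
#' @return A `fret_comparison` object: `table` (group, n_kept,
#'   trimmed_mean_pct, p_raw, p_adj, stars), `dropped` (ROI ids with drop
#'   reason), `efficiencies` (per kept ROI).
#' @export
compare_groups <- function(rois, reference_group, trim = 0.2,
                           min_bleach = 0.85) {
  if (!reference_group %in% rois$group)
    stop("reference group '", reference_group, "' not present",
         call. = FALSE)
  drop_reason <- rep(NA_character_, nrow(rois))
  keep <- bleach_qc(rois$acceptor_pre, rois$acceptor_post, min_bleach)
  drop_reason[!keep] <- "insufficient acceptor bleaching"
  bad_donor <- rois$donor_post <= 0
  drop_reason[bad_donor & is.na(drop_reason)] <- "non-positive donor_post"
  keep <- keep & !bad_donor
  kept <- rois[keep, , drop = FALSE]
  kept$E_pct <- fret_efficiency(kept$donor_pre, kept$donor_post)

  groups <- unique(c(reference_group,
                     setdiff(unique(kept$group), reference_group)))
  es <- split(kept$E_pct, factor(kept$group, levels = groups))
  n_kept <- vapply(es, length, 0L)
  if (any(n_kept < 5L))
    stop("each group needs >= 5 ROIs after QC; too few in: ",
         paste(groups[n_kept < 5L], collapse = ", "), call. = FALSE)
  tmeans <- vapply(es, trimmed_mean, 0, trim = trim)
  others <- setdiff(groups, reference_group)
  tests <- lapply(others, function(g)
    yuen_test(es[[g]], es[[reference_group]], trim = trim))
  p_raw <- vapply(tests, function(t) t$p_value, 0)
  p_adj <- holm_bonferroni(p_raw)
  tab <- data.frame(
    group = groups,
    n_kept = as.integer(n_kept),
    trimmed_mean_pct = tmeans,
    p_raw = c(NA, p_raw), p_adj = c(NA, p_adj),
    stars = c("", .stars(p_adj)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, reference = reference_group, trim = trim,
                 min_bleach = min_bleach,
                 dropped = data.frame(
                   roi_id = rois$roi_id[!is.na(drop_reason)],
                   reason = drop_reason[!is.na(drop_reason)]),
                 efficiencies = kept[, c("roi_id", "group", "E_pct")],
                 tests = setNames(tests, others)),
            class = "fret_comparison")
}

#' @method print fret_comparison
#' @export
print.fret_comparison <- function(x, ...) {
  cat("FRET comparison vs reference '", x$reference, "' (trim ",
      x$trim, ", min bleach ", x$min_bleach, ")\n", sep = "")
  tab <- x$table
  tab$trimmed_mean_pct <- fmt6(tab$trimmed_mean_pct)
  tab$p_adj <- ifelse(is.na(tab$p_adj), "-", fmt6(tab$p_adj))
  tab$p_raw <- NULL
  print(tab, row.names = FALSE)
  if (nrow(x$dropped) > 0)
    cat(nrow(x$dropped), "ROIs dropped by QC\n")
  invisible(x)
}

#' @method summary fret_comparison
#' @export
summary.fret_comparison <- function(object, ...) {
  print(object)
  if (nrow(object$dropped) > 0) {
    cat("\nDropped ROIs:\n")
    print(object$dropped, row.names = FALSE)
  }
  invisible(object)
}

#' @method plot fret_comparison
#' @export
plot.fret_comparison <- function(x, ...) {
  es <- split(x$efficiencies$E_pct,
              factor(x$efficiencies$group, levels = x$table$group))
  boxplot(es, ylab = "FRET efficiency (%)", ...)
  points(seq_along(es), x$table$trimmed_mean_pct, pch = 19)
  invisible(x)
}
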