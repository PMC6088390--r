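#' Per-cell concentration, abundance, eccentricity and orientation measures
#'
#' From the 18 ROI mean intensities \eqn{I_{\mu\nu}} and volumes
#' \eqn{V_{\mu\nu}} of one cell, computes for every channel:
#' \describe{
#'   \item{c}{volume-weighted mean intensity,
#'     \eqn{\sum I_{\mu\nu} V_{\mu\nu} / \sum V_{\mu\nu}} -- proportional to
#'     the cellular concentration of the stained species.}
#'   \item{a}{total intensity, \eqn{\sum I_{\mu\nu} V_{\mu\nu}} --
#'     proportional to abundance.}
#'   \item{r}{center of eccentricity,
#'     \eqn{\sum I_{\mu\nu} r_\mu / \sum I_{\mu\nu}} with shell
#'     eccentricities \eqn{r_\mu = (\mu - 1/2)/6}; larger values mean protein
#'     mass farther from the cell center.}
#'   \item{phi}{center of orientation,
#'     \eqn{\sum I_{\mu\nu} \phi_\nu / \sum I_{\mu\nu}} in degrees; larger
#'     values mean protein mass closer to the division plane.}
#' }
#' Channels with any missing ROI, or with zero total intensity (for r, phi),
#' are flagged \code{NA}.
#'
#' @param map a [bin_stack()] result (\code{sphericell_map}).
#' @param grid a [roi_grid()]; defaults to the map's own grid.
#' @return A data frame with one row per channel and columns
#'   \code{channel}, \code{c}, \code{a}, \code{r}, \code{phi}.
#' @export
cell_measures <- function(map, grid = map$grid) {
  stopifnot(inherits(map, "sphericell_map"))
  V <- map$volumes
  r_w <- matrix(grid$r_mu, grid$n_shells, grid$n_sectors)
  phi_w <- matrix(grid$phi_nu, grid$n_shells, grid$n_sectors, byrow = TRUE)
  res <- lapply(map$channel_names, function(ch) {
    I <- map$intensities[, , ch]
    if (anyNA(I))
      return(data.frame(channel = ch, c = NA_real_, a = NA_real_,
                        r = NA_real_, phi = NA_real_))
    a <- sum(I * V)
    cc <- a / sum(V)
    Ic <- sum(I)
    r <- if (Ic > 0) sum(I * r_w) / Ic else NA_real_
    phi <- if (Ic > 0) sum(I * phi_w) / Ic else NA_real_
    data.frame(channel = ch, c = cc, a = a, r = r, phi = phi)
  })
  do.call(rbind, res)
}

#' Percentile bootstrap confidence interval
#'
#' @param x numeric sample (length >= 2).
#' @param statistic function of a numeric vector returning a scalar.
#' @param n_boot number of bootstrap resamples (default 1000; a warning is
#'   issued below 100).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed; the interval is reproducible for a fixed seed.
#' @return Numeric \code{c(low, high)} percentile interval.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: interval will be unstable", call. = FALSE)
  stats_boot <- with_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                  nrow = n_boot)
    apply(idx, 1, function(i) statistic(x[i]))
  })
  q <- stats::quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

# two-sample percentile bootstrap of effect(a, b)
bootstrap_ci2 <- function(a, b, effect_fun, n_boot = 1000, level = 0.95,
                          seed = 1L) {
  stats_boot <- with_seed(seed, {
    ia <- matrix(sample.int(length(a), length(a) * n_boot, replace = TRUE), nrow = n_boot)
    ib <- matrix(sample.int(length(b), length(b) * n_boot, replace = TRUE), nrow = n_boot)
    vapply(seq_len(n_boot), function(k) effect_fun(a[ia[k, ]], b[ib[k, ]]),
           numeric(1))
  })
  q <- stats::quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Compare one per-cell measure between two groups of cells
#'
#' Concentration (\code{c}) and abundance (\code{a}) are log-normally
#' distributed across cells, so they are compared by Welch's t-test on log
#' values and the effect is the log2 fold change of geometric means,
#' \code{mean(log2 b) - mean(log2 a)}.  The bounded location scores
#' eccentricity (\code{r}) and orientation (\code{phi}) are tested on the raw
#' scale and the effect is the difference of group means (positive
#' eccentricity change = movement toward the periphery; positive orientation
#' change = movement toward the division plane).  Significance uses a
#' Bonferroni threshold \code{alpha / m}; a percentile bootstrap gives the
#' confidence interval of the effect.
#'
#' @param a,b numeric vectors: the measure for each cell of group A and B.
#' @param measure one of \code{"c"}, \code{"a"}, \code{"r"}, \code{"phi"}.
#' @param m number of comparisons for the Bonferroni correction (default 52).
#' @param alpha family-wise error level (default 0.05).
#' @param n_boot,level,seed bootstrap settings, see [bootstrap_ci()].
#' @return A one-row data frame with columns \code{measure}, \code{effect},
#'   \code{p_value}, \code{significant}, \code{ci_low}, \code{ci_high},
#'   \code{n_A}, \code{n_B}.
#' @export
compare_groups <- function(a, b, measure = c("c", "a", "r", "phi"), m = 52,
                           alpha = 0.05, n_boot = 1000, level = 0.95,
                           seed = 1L) {
  measure <- match.arg(measure)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 cells with finite measures per group", call. = FALSE)
  log_scale <- measure %in% c("c", "a")
  if (log_scale && (any(a <= 0) || any(b <= 0)))
    stop("log-scale measures must be positive", call. = FALSE)

  ta <- if (log_scale) log(a) else a
  tb <- if (log_scale) log(b) else b
  effect_fun <- if (log_scale) {
    function(x, y) (mean(log(y)) - mean(log(x))) / log(2)
  } else {
    function(x, y) mean(y) - mean(x)
  }
  effect <- effect_fun(a, b)
  p <- if (stats::sd(ta) == 0 && stats::sd(tb) == 0) {
    NA_real_  # zero variance in both groups: Welch statistic undefined
  } else {
    stats::t.test(tb, ta, var.equal = FALSE)$p.value
  }
  ci <- bootstrap_ci2(a, b, effect_fun, n_boot = n_boot, level = level,
                      seed = seed)
  data.frame(measure = measure, effect = effect, p_value = p,
             significant = !is.na(p) & p < bonferroni_threshold(alpha, m),
             ci_low = ci[["low"]], ci_high = ci[["high"]],
             n_A = length(a), n_B = length(b))
}

#' Per-ROI comparison maps between two groups of cells
#'
#' \code{mode = "log2diff"} returns the 6 x 3 map of per-ROI differences of
#' log2 group mean intensities.  \code{mode = "fold_test"} additionally runs
#' a Welch t-test on log intensities in every ROI, applies a Bonferroni
#' correction over the 18 ROIs and reports effects only where significant
#' (non-significant ROIs are \code{NA}).
#'
#' @param maps_a,maps_b lists of \code{sphericell_map} (>= 2 maps per group).
#' @param channel channel name to compare.
#' @param mode \code{"log2diff"} or \code{"fold_test"}.
#' @param alpha family-wise error level for \code{fold_test} (default 0.05,
#'   Bonferroni-corrected over 18 ROIs).
#' @return For \code{log2diff} a 6 x 3 matrix; for \code{fold_test} a list
#'   with \code{effect}, \code{p_value} and \code{significant} 6 x 3
#'   matrices.
#' @export
roi_comparisons <- function(maps_a, maps_b, channel,
                            mode = c("log2diff", "fold_test"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("need at least 2 maps per group", call. = FALSE)
  get_mat <- function(maps) t(vapply(maps, function(m)
    as.vector(m$intensities[, , channel]), numeric(18)))
  A <- get_mat(maps_a); B <- get_mat(maps_b)
  grid <- maps_a[[1]]$grid
  shape <- function(v) matrix(v, grid$n_shells, grid$n_sectors,
                              dimnames = list(shell = 1:6, sector = grid$sectors))
  if (any(colSums(!is.na(A)) == 0) || any(colSums(!is.na(B)) == 0))
    stop("an ROI is empty in every cell of a group", call. = FALSE)
  log2diff <- log2(colMeans(B, na.rm = TRUE)) - log2(colMeans(A, na.rm = TRUE))
  if (mode == "log2diff") return(shape(log2diff))

  p <- vapply(1:18, function(l) {
    la <- log(A[, l]); lb <- log(B[, l])
    la <- la[is.finite(la)]; lb <- lb[is.finite(lb)]
    if (length(la) < 2 || length(lb) < 2) return(NA_real_)
    if (stats::sd(la) == 0 && stats::sd(lb) == 0) return(NA_real_)
    stats::t.test(lb, la, var.equal = FALSE)$p.value
  }, numeric(1))
  sig <- !is.na(p) & p < bonferroni_threshold(alpha, 18)
  eff <- ifelse(sig, log2diff, NA_real_)
  list(effect = shape(eff), p_value = shape(p), significant = shape(sig))
}
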