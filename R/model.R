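#' Steady-state prediction of normalized ROI intensities
#'
#' Evaluates the steady-state recruitment/dimerization model for every cell:
#' the normalized intensity of species \eqn{i} in ROI \eqn{l} is
#' \deqn{\tilde I_{il} = d_i \tilde\alpha_{il} \tilde I_{i,t}
#'   \left(1 + \sum_j \tilde\alpha_{jl} \beta_{ij} \tilde I_{j,t}\right),}
#' with phase-specific scaling factors \eqn{d} and compartment affinities
#' \eqn{\tilde\alpha} (metaphase or segregation), phase-independent pairwise
#' affinities \eqn{\beta}, and the cell's normalized totals
#' \eqn{\tilde I_{i,t}} as input.  Pairs absent from the interaction set
#' contribute zero.
#'
#' @param params list with \code{d_meta}, \code{d_segr} (length-S),
#'   \code{alpha_meta}, \code{alpha_segr} (S x 18) and \code{beta}
#'   (S x S symmetric).
#' @param totals n_cells x S matrix of normalized cell totals.
#' @param phase factor of cell phases (metaphase/segregation).
#' @return n_cells x S x 18 array of predicted intensities.
#' @export
predict_roi_intensities <- function(params, totals, phase) {
  n <- nrow(totals); S <- ncol(totals)
  pred <- array(NA_real_, dim = c(n, S, 18),
                dimnames = list(NULL, colnames(totals), roi_labels()))
  B <- params$beta
  if (is.null(B)) B <- matrix(0, S, S)
  for (ph in c("metaphase", "segregation")) {
    cells <- which(phase == ph)
    if (length(cells) == 0L) next
    A <- if (ph == "metaphase") params$alpha_meta else params$alpha_segr
    dd <- if (ph == "metaphase") params$d_meta else params$d_segr
    Tm <- totals[cells, , drop = FALSE]
    for (l in 1:18) {
      Xl <- sweep(Tm, 2, A[, l], `*`)
      inner <- Xl %*% B
      base <- sweep(Tm, 2, dd * A[, l], `*`)
      pred[cells, , l] <- base * (1 + inner)
    }
  }
  pred
}

#' Heteroscedastic measurement error model
#'
#' Per-datapoint uncertainty used as least-squares weight: 5 percent of the
#' measured value plus 5 percent of the per-species maximum over all included
#' cells and ROIs.
#'
#' @param intensities n_cells x S x 18 array of measured (normalized)
#'   intensities.
#' @return Array of the same shape with the error of every data point.
#' @export
error_model <- function(intensities) {
  max_i <- apply(intensities, 2, max, na.rm = TRUE)
  if (any(max_i <= 0))
    stop("error model undefined: a species is zero in every cell", call. = FALSE)
  sweep(0.05 * intensities, 2, 0.05 * max_i, `+`)
}

#' Weighted residuals and residual sum of squares
#'
#' Residuals are \code{(data - model) / error} over all 18 x S ROI values of
#' every cell; the cell-average values enter the model as inputs (totals),
#' not as residuals.
#'
#' @param params parameter list as in [predict_roi_intensities()].
#' @param data a [roi_dataset()].
#' @return A list with \code{residuals} (numeric vector) and \code{rss}.
#' @export
model_objective <- function(params, data) {
  stopifnot(inherits(data, "roi_dataset"))
  pred <- predict_roi_intensities(params, data$totals, data$phase)
  eps <- error_model(data$intensities)
  r <- as.vector((data$intensities - pred) / eps)
  list(residuals = r, rss = sum(r^2))
}

# ---- parameter packing -----------------------------------------------------

# Representative species for the reference gauge: the parameterization is
# flat along one scale direction per connected component of the interaction
# graph (scaling alpha of all member species by c, their d by 1/c and the
# component's beta entries by 1/c leaves every prediction unchanged);
# isolated species carry the classic d * alpha product trade-off.  Fixing
# the first-phase scaling factor of one representative per component (the
# lowest species index) removes every flat direction.
gauge_representatives <- function(S, pairs) {
  comp <- seq_len(S)  # union-find over the interaction graph
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
    if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(S), find, integer(1))
  sort(unique(vapply(split(seq_len(S), roots), min, integer(1))))
}

# Free-parameter bookkeeping for the log10-scale optimizer.  `pairs` is a
# K x 2 matrix of species indices (i <= j); `fixed_d` names species whose
# scaling factor in the first present phase is held at 1 (reference gauge).
make_param_spec <- function(S, pairs, phases_present, fixed_d = integer(0),
                            bounds = default_bounds()) {
  first_phase <- phases_present[1]
  free_d_meta <- if (first_phase == "metaphase") setdiff(seq_len(S), fixed_d)
                 else seq_len(S)
  free_d_segr <- if (first_phase == "segregation") setdiff(seq_len(S), fixed_d)
                 else seq_len(S)
  blocks <- list(); lower <- c(); upper <- c()
  n_used <- 0L
  add <- function(name, n, b) {
    blocks[[name]] <<- if (n > 0) n_used + seq_len(n) else integer(0)
    n_used <<- n_used + n
    lower <<- c(lower, rep(log10(b[1]), n))
    upper <<- c(upper, rep(log10(b[2]), n))
  }
  add("d_meta", if ("metaphase" %in% phases_present) length(free_d_meta) else 0, bounds$d)
  add("d_segr", if ("segregation" %in% phases_present) length(free_d_segr) else 0, bounds$d)
  add("alpha_meta", if ("metaphase" %in% phases_present) S * 18 else 0, bounds$alpha)
  add("alpha_segr", if ("segregation" %in% phases_present) S * 18 else 0, bounds$alpha)
  add("beta", nrow(pairs), bounds$beta)
  list(S = S, pairs = pairs, free_d_meta = free_d_meta,
       free_d_segr = free_d_segr, fixed_d = fixed_d,
       phases_present = phases_present, blocks = blocks,
       lower = lower, upper = upper, n_par = length(lower))
}

# Transform a parameter list into the reference gauge without changing any
# prediction: for each interaction component (and isolated species), divide
# the scaling factors of its members by the representative's first-phase d,
# multiply their alpha rows by it, and divide the component's beta entries.
gauge_canonicalize <- function(params, S, pairs, fixed_d, phases_present) {
  comp <- seq_len(S)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
    if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(S), find, integer(1))
  first <- phases_present[1]
  for (r in fixed_d) {
    members <- which(roots == roots[r])
    cc <- if (first == "metaphase") params$d_meta[r] else params$d_segr[r]
    if (!is.finite(cc) || cc <= 0) next
    params$d_meta[members] <- params$d_meta[members] / cc
    params$d_segr[members] <- params$d_segr[members] / cc
    params$alpha_meta[members, ] <- params$alpha_meta[members, , drop = FALSE] * cc
    params$alpha_segr[members, ] <- params$alpha_segr[members, , drop = FALSE] * cc
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (roots[i] == roots[r])
        params$beta[i, j] <- params$beta[j, i] <- params$beta[i, j] / cc
    }
  }
  params
}

default_bounds <- function() {
  list(alpha = c(1e-3, 1e2), d = c(1e-3, 1e2), beta = c(1e-7, 1e2))
}

# log10 parameter vector -> natural-scale parameter list
unpack_params <- function(par, spec, species) {
  S <- spec$S
  take <- function(name, default) {
    idx <- spec$blocks[[name]]
    if (length(idx) == 0) default else 10^par[idx]
  }
  d_meta <- d_segr <- rep(1, S)
  if (length(spec$blocks$d_meta)) d_meta[spec$free_d_meta] <- take("d_meta", NULL)
  if (length(spec$blocks$d_segr)) d_segr[spec$free_d_segr] <- take("d_segr", NULL)
  am <- matrix(take("alpha_meta", rep(1, S * 18)), S, 18)
  as_ <- matrix(take("alpha_segr", rep(1, S * 18)), S, 18)
  beta <- matrix(0, S, S)
  bv <- take("beta", numeric(0))
  if (length(bv)) for (k in seq_len(nrow(spec$pairs))) {
    i <- spec$pairs[k, 1]; j <- spec$pairs[k, 2]
    beta[i, j] <- beta[j, i] <- bv[k]
  }
  dimnames(am) <- dimnames(as_) <- list(species, roi_labels())
  dimnames(beta) <- list(species, species)
  list(d_meta = stats::setNames(d_meta, species),
       d_segr = stats::setNames(d_segr, species),
       alpha_meta = am, alpha_segr = as_, beta = beta)
}

pack_params <- function(params, spec) {
  par <- numeric(spec$n_par)
  put <- function(name, vals) {
    idx <- spec$blocks[[name]]
    if (length(idx)) par[idx] <<- log10(vals)
  }
  put("d_meta", params$d_meta[spec$free_d_meta])
  put("d_segr", params$d_segr[spec$free_d_segr])
  put("alpha_meta", as.vector(params$alpha_meta))
  put("alpha_segr", as.vector(params$alpha_segr))
  if (nrow(spec$pairs))
    put("beta", params$beta[spec$pairs])
  par
}

# residuals, predictions and analytic Jacobian in log10 parameter space
model_engine <- function(data, spec) {
  Tm <- data$totals
  n <- nrow(Tm); S <- spec$S
  eps <- error_model(data$intensities)
  eps_v <- as.vector(eps)
  dat_v <- as.vector(data$intensities)
  cells_by_phase <- list(metaphase = which(data$phase == "metaphase"),
                         segregation = which(data$phase == "segregation"))
  N <- n * S * 18
  ln10 <- log(10)

  compute <- function(par, want_jac = FALSE) {
    p <- unpack_params(par, spec, data$species)
    pred <- array(0, dim = c(n, S, 18))
    base <- array(0, dim = c(n, S, 18))
    B <- p$beta
    for (ph in spec$phases_present) {
      cells <- cells_by_phase[[ph]]
      A <- if (ph == "metaphase") p$alpha_meta else p$alpha_segr
      dd <- if (ph == "metaphase") p$d_meta else p$d_segr
      Tc <- Tm[cells, , drop = FALSE]
      for (l in 1:18) {
        Xl <- sweep(Tc, 2, A[, l], `*`)
        inner <- Xl %*% B
        bs <- sweep(Tc, 2, dd * A[, l], `*`)
        base[cells, , l] <- bs
        pred[cells, , l] <- bs * (1 + inner)
      }
    }
    res <- (dat_v - as.vector(pred)) / eps_v
    if (!want_jac) return(list(residuals = res, pred = pred, params = p))

    J <- matrix(0, N, spec$n_par)
    for (ph in spec$phases_present) {
      cells <- cells_by_phase[[ph]]
      if (length(cells) == 0L) next
      A <- if (ph == "metaphase") p$alpha_meta else p$alpha_segr
      d_block <- if (ph == "metaphase") "d_meta" else "d_segr"
      a_block <- if (ph == "metaphase") "alpha_meta" else "alpha_segr"
      roi_off <- (0:17) * n * S
      # d columns
      d_cols <- spec$blocks[[d_block]]
      free_d <- if (ph == "metaphase") spec$free_d_meta else spec$free_d_segr
      for (fi in seq_along(free_d)) {
        i <- free_d[fi]
        rows <- rep(cells + (i - 1) * n, 18) + rep(roi_off, each = length(cells))
        J[rows, d_cols[fi]] <- ln10 * as.vector(pred[cells, i, ])
      }
      # alpha columns (layout: S x 18, species fastest)
      a_cols <- spec$blocks[[a_block]]
      row_base <- outer(cells, (seq_len(S) - 1) * n, `+`)  # |cells| x S
      for (l in 1:18) {
        base_l <- matrix(base[cells, , l], length(cells), S)
        pred_l <- matrix(pred[cells, , l], length(cells), S)
        rows <- as.vector(row_base + (l - 1) * n * S)
        for (ip in seq_len(S)) {
          vals <- ln10 * base_l *
            outer(Tm[cells, ip] * A[ip, l], B[, ip])
          vals[, ip] <- vals[, ip] + ln10 * pred_l[, ip]
          J[rows, a_cols[(l - 1) * S + ip]] <- as.vector(vals)
        }
      }
      # beta columns (shared across phases; accumulate)
      b_cols <- spec$blocks$beta
      if (length(b_cols)) for (k in seq_len(nrow(spec$pairs))) {
        i <- spec$pairs[k, 1]; j <- spec$pairs[k, 2]
        bij <- B[i, j]
        rows_i <- rep(cells + (i - 1) * n, 18) + rep(roi_off, each = length(cells))
        vals_i <- ln10 * bij * matrix(base[cells, i, ], length(cells), 18) *
          outer(Tm[cells, j], A[j, ])
        J[rows_i, b_cols[k]] <- J[rows_i, b_cols[k]] + as.vector(vals_i)
        if (i != j) {
          rows_j <- rep(cells + (j - 1) * n, 18) + rep(roi_off, each = length(cells))
          vals_j <- ln10 * bij * matrix(base[cells, j, ], length(cells), 18) *
            outer(Tm[cells, i], A[i, ])
          J[rows_j, b_cols[k]] <- J[rows_j, b_cols[k]] + as.vector(vals_j)
        }
      }
    }
    # residual = (data - pred)/eps, so d res / d par = -J_pred / eps
    list(residuals = res, jacobian = -J / eps_v, pred = pred, params = p)
  }
  list(compute = compute, eps = eps, N = N)
}

#' Fit the steady-state affinity model
#'
#' Multi-start bounded nonlinear least squares in log10 parameter space.
#' Start points are sampled log-uniformly within the parameter bounds
#' (compartment affinities and scaling factors in \[1e-3, 1e2\], pairwise
#' affinities in \[1e-7, 1e2\]); each start is refined by
#' Levenberg-Marquardt (\code{minpack.lm::nls.lm}) with an analytic Jacobian
#' and box constraints, and the best-RSS start is returned.  Residuals are
#' weighted by the heteroscedastic error model ([error_model()]).  The fit
#' is considered converged when the RSS spread between the best and
#' runner-up start is below the largest squared single-datapoint residual
#' of the best fit.
#'
#' The parameterization carries structural scale indeterminacies: within
#' every connected component of the interaction graph, multiplying the
#' compartment affinities of all member species by a constant while dividing
#' their scaling factors and the component's pairwise affinities by the same
#' constant leaves every prediction unchanged (for species without
#' interactions, only the product of scaling factor and compartment affinity
#' is determined).  \code{gauge = "reference"} fixes the first-phase scaling
#' factor of one representative species per component to 1, which removes
#' every flat direction and makes pairwise affinities comparable across
#' fits; \code{gauge = "free"} fits the fully free parameterization, in
#' which case only products \code{d * alpha} and component-rescaled
#' \code{beta} are interpretable.
#'
#' @param data a [roi_dataset()].
#' @param interactions list of species pairs (length-2 character or integer
#'   vectors; homodimers allowed) whose pairwise affinities are free.
#' @param n_starts number of random starts (default 50).
#' @param seed RNG seed for start sampling.
#' @param gauge \code{"free"} (all parameters free, as in the original
#'   fitting protocol) or \code{"reference"} (scale indeterminacies removed
#'   by per-component reference species).
#' @param bounds list with elements \code{alpha}, \code{d}, \code{beta},
#'   each \code{c(lower, upper)} on the natural scale.
#' @param start optional parameter list used as an additional (warm) start.
#' @param maxiter maximum Levenberg-Marquardt iterations for the polish
#'   stage.
#' @param explore_maxiter iteration cap for the exploration pass over all
#'   starts; the \code{polish_top} best exploration results are then refined
#'   to full convergence.
#' @param polish_top number of exploration results to polish (default 3).
#' @return An object of class \code{affinity_fit}; see
#'   \code{\link{summary.affinity_fit}}, \code{\link{coef.affinity_fit}},
#'   \code{\link{predict.affinity_fit}}.
#' @export
fit_affinity_model <- function(data, interactions = list(), n_starts = 50,
                               seed = 1L, gauge = c("free", "reference"),
                               bounds = default_bounds(), start = NULL,
                               maxiter = 300, explore_maxiter = 10,
                               polish_top = 3) {
  stopifnot(inherits(data, "roi_dataset"))
  gauge <- match.arg(gauge)
  S <- length(data$species)
  pairs <- normalize_pairs(interactions, data$species)
  phases_present <- levels(data$phase)[table(data$phase) > 0]
  fixed_d <- if (gauge == "reference") gauge_representatives(S, pairs)
             else integer(0)
  spec <- make_param_spec(S, pairs, phases_present, fixed_d, bounds)
  engine <- model_engine(data, spec)

  starts <- with_seed(seed, {
    matrix(stats::runif(n_starts * spec$n_par, min = rep(spec$lower, each = n_starts),
                        max = rep(spec$upper, each = n_starts)),
           nrow = n_starts, ncol = spec$n_par)
  })
  # deterministic start at the bound midpoints; empirically a reliable basin
  starts <- rbind((spec$lower + spec$upper) / 2, starts)
  if (!is.null(start)) {
    if (gauge == "reference")
      start <- gauge_canonicalize(start, S, pairs, fixed_d, phases_present)
    warm <- pmin(pmax(pack_params(start, spec), spec$lower), spec$upper)
    starts <- rbind(warm, starts)
  }

  fn <- function(par) engine$compute(par)$residuals
  jac <- function(par) engine$compute(par, want_jac = TRUE)$jacobian
  run_lm <- function(par0, iter_cap) {
    ctrl <- minpack.lm::nls.lm.control(maxiter = iter_cap, ftol = 1e-10,
                                       ptol = 1e-10, gtol = 0)
    try(suppressWarnings(
      minpack.lm::nls.lm(par = par0, lower = spec$lower, upper = spec$upper,
                         fn = fn, jac = jac, control = ctrl)), silent = TRUE)
  }

  # racing multi-start: every start gets a short Levenberg-Marquardt budget,
  # the best fifth continues with a larger budget, and the top few are
  # polished to full convergence
  results <- vector("list", nrow(starts))
  rss <- rep(Inf, nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- run_lm(starts[s, ], min(explore_maxiter, maxiter))
    if (inherits(fit, "try-error")) next
    results[[s]] <- fit
    rss[s] <- fit$deviance
  }
  if (all(!is.finite(rss)))
    stop("all optimization starts failed: ",
         paste(unique(vapply(results, function(r)
           if (is.null(r)) "error" else r$message %||% "", character(1))),
           collapse = "; "), call. = FALSE)
  refine <- function(keep, iter_cap) {
    for (s in keep) {
      if (!is.finite(rss[s])) next
      fit <- run_lm(results[[s]]$par, iter_cap)
      if (inherits(fit, "try-error")) next
      if (fit$deviance < rss[s]) {
        results[[s]] <<- fit
        rss[s] <<- fit$deviance
      }
    }
  }
  if (nrow(starts) > polish_top)
    refine(utils::head(order(rss), max(polish_top, ceiling(nrow(starts) / 5))),
           min(3 * explore_maxiter, maxiter))
  refine(utils::head(order(rss), polish_top), maxiter)

  best <- which.min(rss)
  best_fit <- results[[best]]
  final <- engine$compute(best_fit$par)
  max_sq_res <- max(final$residuals^2)
  sorted <- sort(rss[is.finite(rss)])
  spread <- if (length(sorted) > 1) sorted[2] - sorted[1] else 0

  structure(list(params = final$params, rss = sorted[1],
                 residuals = final$residuals, fitted = final$pred,
                 start_rss = rss, best_start_index = best,
                 n_starts = nrow(starts), spread = spread,
                 converged = spread <= max_sq_res,
                 max_sq_residual = max_sq_res,
                 pairs = pairs, species = data$species,
                 phases_present = phases_present,
                 gauge = gauge,
                 gauge_species = data$species[fixed_d],
                 bounds = bounds, seed = seed, data = data,
                 n_par = spec$n_par, n_obs = engine$N,
                 call = match.call()),
            class = "affinity_fit")
}

# normalize a list of pairs to a K x 2 index matrix with i <= j
normalize_pairs <- function(interactions, species) {
  if (length(interactions) == 0L)
    return(matrix(integer(0), 0, 2))
  pairs <- t(vapply(interactions, function(p) {
    idx <- if (is.character(p)) match(p, species) else as.integer(p)
    if (length(idx) != 2L || anyNA(idx) || any(idx < 1) || any(idx > length(species)))
      stop("invalid interaction pair: ", paste(p, collapse = ","), call. = FALSE)
    sort(idx)
  }, integer(2)))
  if (anyDuplicated(pairs)) stop("duplicate interaction pairs", call. = FALSE)
  pairs
}

#' Rescale compartment affinities by the fitted scaling factors
#'
#' Reports, per species row and phase, the product of the scaling factor
#' \code{d} and the compartment affinities \code{alpha} -- the combination
#' that is identifiable irrespective of the scale indeterminacy of the raw
#' factors.
#'
#' @param fit an [fit_affinity_model()] result.
#' @return A list with \code{alpha_meta_scaled}, \code{alpha_segr_scaled}
#'   (S x 18) and the raw \code{alpha_meta}, \code{alpha_segr}.
#' @export
rescale_roi_affinities <- function(fit) {
  stopifnot(inherits(fit, "affinity_fit"))
  p <- fit$params
  list(alpha_meta_scaled = p$alpha_meta * p$d_meta,
       alpha_segr_scaled = p$alpha_segr * p$d_segr,
       alpha_meta = p$alpha_meta, alpha_segr = p$alpha_segr)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.affinity_fit <- function(x, ...) {
  cat("Steady-state affinity model fit\n")
  cat("  species:      ", length(x$species), " (",
      paste(x$species, collapse = ", "), ")\n", sep = "")
  cat("  interactions: ", nrow(x$pairs), "\n", sep = "")
  cat("  parameters:   ", x$n_par, " free, ", x$n_obs, " weighted residuals\n", sep = "")
  cat("  rss: ", format(x$rss, digits = 6), "  (", x$n_starts, " starts, spread ",
      format(x$spread, digits = 3), ", converged: ", x$converged, ")\n", sep = "")
  invisible(x)
}

#' Summarize an affinity model fit
#'
#' @param object an \code{affinity_fit}.
#' @param ... unused.
#' @return A list of class \code{summary.affinity_fit} with the fitted
#'   pairwise affinities, ranges of the scaled compartment affinities and
#'   fit diagnostics.
#' @export
summary.affinity_fit <- function(object, ...) {
  p <- object$params
  beta_tab <- if (nrow(object$pairs)) {
    data.frame(species_i = object$species[object$pairs[, 1]],
               species_j = object$species[object$pairs[, 2]],
               beta = p$beta[object$pairs])
  } else data.frame(species_i = character(0), species_j = character(0),
                    beta = numeric(0))
  sc <- rescale_roi_affinities(object)
  # cell-average consistency: the volume-weighted average of the fitted ROI
  # intensities should track the normalized cell averages used as inputs
  w <- object$data$volumes / sum(object$data$volumes)
  pred_avg <- apply(object$fitted, c(1, 2), function(v) sum(v * w))
  avg_dev <- abs(pred_avg / object$data$totals - 1)
  out <- list(beta = beta_tab,
              avg_consistency_median = stats::median(avg_dev),
              alpha_scaled_range = range(c(sc$alpha_meta_scaled, sc$alpha_segr_scaled)),
              rss = object$rss, n_par = object$n_par, n_obs = object$n_obs,
              n_starts = object$n_starts, spread = object$spread,
              converged = object$converged, gauge = object$gauge, gauge_species = object$gauge_species)
  class(out) <- "summary.affinity_fit"
  out
}

#' @export
print.summary.affinity_fit <- function(x, ...) {
  cat("Affinity model: rss = ", format(x$rss, digits = 6), " on ", x$n_obs,
      " residuals, ", x$n_par, " parameters\n", sep = "")
  cat("  multi-start: ", x$n_starts, " starts, spread ",
      format(x$spread, digits = 3), ", converged: ", x$converged, "\n", sep = "")
  if (x$gauge == "reference") cat("  reference gauge species: ", paste(x$gauge_species, collapse = ", "), "
", sep = "")
  cat("  scaled compartment affinities (d * alpha) in [",
      paste(format(x$alpha_scaled_range, digits = 3), collapse = ", "), "]\n", sep = "")
  cat("  cell-average consistency (median rel. deviation): ",
      format(x$avg_consistency_median, digits = 3), "\n", sep = "")
  if (nrow(x$beta)) {
    cat("  pairwise affinities:\n")
    print(x$beta, row.names = FALSE, digits = 4)
  } else cat("  no pairwise affinities in the model\n")
  invisible(x)
}

#' @export
coef.affinity_fit <- function(object, ...) {
  p <- object$params
  out <- c(stats::setNames(p$d_meta, paste0("d_meta.", object$species)),
           stats::setNames(p$d_segr, paste0("d_segr.", object$species)),
           stats::setNames(as.vector(p$alpha_meta),
                           paste0("alpha_meta.", outer(object$species, roi_labels(), paste, sep = "."))),
           stats::setNames(as.vector(p$alpha_segr),
                           paste0("alpha_segr.", outer(object$species, roi_labels(), paste, sep = "."))))
  if (nrow(object$pairs)) {
    bn <- paste0("beta.", object$species[object$pairs[, 1]], ":",
                 object$species[object$pairs[, 2]])
    out <- c(out, stats::setNames(object$params$beta[object$pairs], bn))
  }
  out
}

#' Predict ROI intensities from a fitted affinity model
#'
#' @param object an \code{affinity_fit}.
#' @param newdata optional [roi_dataset()] (defaults to the training data);
#'   only its totals and phases are used.
#' @param ... unused.
#' @return n_cells x S x 18 array of predicted normalized intensities.
#' @export
predict.affinity_fit <- function(object, newdata = NULL, ...) {
  data <- newdata %||% object$data
  predict_roi_intensities(object$params, data$totals, data$phase)
}

#' @export
fitted.affinity_fit <- function(object, ...) object$fitted

#' @export
residuals.affinity_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  if (type == "weighted") return(object$residuals)
  as.vector(object$data$intensities - object$fitted)
}

#' @export
deviance.affinity_fit <- function(object, ...) object$rss

#' Plot observed versus fitted ROI intensities
#'
#' @param x an \code{affinity_fit}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.affinity_fit <- function(x, ...) {
  obs <- as.vector(x$data$intensities)
  fit <- as.vector(x$fitted)
  graphics::plot(fit, obs, xlab = "fitted intensity", ylab = "observed intensity",
                 pch = 16, cex = 0.4, col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(0, 1, col = "grey40")
  invisible(x)
}
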