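#' Likelihood-ratio forward selection of pairwise affinities
#'
#' Greedy best-first selection: starting from the known interaction set, at
#' every step the model is refitted once per remaining candidate pair with
#' that pair added (full multi-start protocol, plus a warm start at the
#' current best fit).  The candidate with the largest reduction of the
#' weighted residual sum of squares is accepted if the reduction exceeds the
#' 95 percent quantile of the chi-square distribution with one degree of
#' freedom (3.841 for \code{alpha = 0.05}; under the fixed Gaussian error
#' model the RSS is -2 log-likelihood up to a constant, so the RSS drop is
#' the likelihood-ratio statistic).  Selection stops when no candidate
#' passes.
#'
#' @param data a [roi_dataset()].
#' @param known list of known (literature) interaction pairs.
#' @param candidates list of candidate pairs; defaults to all unordered
#'   species pairs including homodimers, minus the known set.
#' @param n_starts multi-start count per candidate refit (default 50).
#' @param alpha per-step test level (default 0.05).
#' @param seed RNG seed; candidate refits use seeds derived from it.
#' @param max_steps cap on accepted pairs (default unlimited).
#' @param base_start optional parameter list used as warm start for the
#'   baseline (known-interactions) fit, e.g. in calibration experiments.
#' @param gauge,bounds,maxiter passed to [fit_affinity_model()].
#' @return A list of class \code{selection_trace} with \code{selected}
#'   (list of accepted pairs, in order), \code{trace} (data frame: step,
#'   pair, delta_chi2, accepted), \code{threshold}, \code{base_fit} and
#'   \code{final_fit}.
#' @export
forward_select <- function(data, known = list(), candidates = NULL,
                           n_starts = 50, alpha = 0.05, seed = 1L,
                           max_steps = Inf, base_start = NULL,
                           gauge = c("free", "reference"),
                           bounds = default_bounds(), maxiter = 100) {
  species <- data$species
  known_m <- normalize_pairs(known, species)
  if (is.null(candidates)) {
    all_pairs <- which(upper.tri(diag(length(species)), diag = TRUE), arr.ind = TRUE)
    candidates <- lapply(seq_len(nrow(all_pairs)), function(k)
      sort(unname(all_pairs[k, ])))
  }
  cand_m <- normalize_pairs(candidates, species)
  if (nrow(known_m)) {
    dup <- apply(cand_m, 1, function(p) any(known_m[, 1] == p[1] & known_m[, 2] == p[2]))
    cand_m <- cand_m[!dup, , drop = FALSE]
  }
  threshold <- stats::qchisq(1 - alpha, df = 1)

  to_list <- function(m) lapply(seq_len(nrow(m)), function(k) m[k, ])
  current <- known_m
  fit <- fit_affinity_model(data, to_list(current), n_starts = n_starts,
                            seed = seed, gauge = gauge, bounds = bounds,
                            start = base_start, maxiter = maxiter,
                            polish_top = 1)
  base_fit <- fit
  trace <- data.frame(step = integer(0), species_i = character(0),
                      species_j = character(0), delta_chi2 = numeric(0),
                      accepted = logical(0))
  selected <- list()
  step <- 0L
  while (nrow(cand_m) > 0 && step < max_steps) {
    step <- step + 1L
    deltas <- rep(NA_real_, nrow(cand_m))
    fits <- vector("list", nrow(cand_m))
    for (k in seq_len(nrow(cand_m))) {
      trial <- rbind(current, cand_m[k, ])
      warm <- fit$params
      i <- cand_m[k, 1]; j <- cand_m[k, 2]
      warm$beta[i, j] <- warm$beta[j, i] <- sqrt(prod(bounds$beta))
      f_k <- fit_affinity_model(data, to_list(trial), n_starts = n_starts,
                                seed = seed + 1000L * step + k,
                                gauge = gauge, bounds = bounds,
                                start = warm, maxiter = maxiter,
                                polish_top = 1)
      fits[[k]] <- f_k
      deltas[k] <- fit$rss - f_k$rss
    }
    best <- which.max(deltas)
    # guard against a poorly converged reference model: refit the current
    # model warm-started at the best candidate solution with its extra pair
    # removed, so the compared optima are locally consistent (nested models)
    warm_back <- fits[[best]]$params
    i <- cand_m[best, 1]; j <- cand_m[best, 2]
    warm_back$beta[i, j] <- warm_back$beta[j, i] <- 0
    back <- fit_affinity_model(data, to_list(current), n_starts = 0,
                               seed = seed + 1000L * step,
                               gauge = gauge, bounds = bounds,
                               start = warm_back, maxiter = maxiter,
                               polish_top = 1)
    if (back$rss < fit$rss) fit <- back
    deltas[best] <- fit$rss - fits[[best]]$rss
    accepted <- deltas[best] > threshold
    trace <- rbind(trace, data.frame(
      step = step,
      species_i = species[cand_m[best, 1]],
      species_j = species[cand_m[best, 2]],
      delta_chi2 = deltas[best], accepted = accepted))
    if (!accepted) break
    selected <- c(selected, list(cand_m[best, ]))
    current <- rbind(current, cand_m[best, ])
    fit <- fits[[best]]
    cand_m <- cand_m[-best, , drop = FALSE]
  }
  structure(list(selected = selected, trace = trace, threshold = threshold,
                 base_fit = base_fit, final_fit = fit),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Forward selection of pairwise affinities (threshold ",
      format(x$threshold, digits = 4), ")\n", sep = "")
  if (nrow(x$trace) == 0) cat("  no candidates tested\n") else
    print(x$trace, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Contribution (withdrawal) test of one fitted pairwise affinity
#'
#' Removes one pair from a fitted model, refits with the same multi-start
#' protocol (warm-started at the fitted parameters), and reports the
#' chi-square increase \code{rss_without - rss_with}.  The pair contributes
#' significantly if the increase exceeds the 95 percent chi-square(1)
#' quantile.
#'
#' @param data a [roi_dataset()].
#' @param fit an [fit_affinity_model()] result containing \code{pair}.
#' @param pair length-2 species pair (character or integer).
#' @param n_starts,seed,alpha,maxiter fitting/test settings.
#' @return A list with \code{delta_chi2}, \code{significant},
#'   \code{threshold}, \code{inconclusive} (non-convergent refit) and
#'   \code{refit}.
#' @export
contribution_test <- function(data, fit, pair, n_starts = fit$n_starts,
                              seed = fit$seed + 1L, alpha = 0.05,
                              maxiter = 100) {
  stopifnot(inherits(fit, "affinity_fit"))
  pm <- normalize_pairs(list(pair), data$species)
  hit <- which(fit$pairs[, 1] == pm[1] & fit$pairs[, 2] == pm[2])
  if (length(hit) != 1L)
    stop("pair is not part of the fitted interaction set", call. = FALSE)
  remaining <- fit$pairs[-hit, , drop = FALSE]
  warm <- fit$params
  warm$beta[pm[1], pm[2]] <- warm$beta[pm[2], pm[1]] <- 0
  refit <- fit_affinity_model(
    data, lapply(seq_len(nrow(remaining)), function(k) remaining[k, ]),
    n_starts = n_starts, seed = seed, gauge = fit$gauge,
    bounds = fit$bounds, start = warm, maxiter = maxiter, polish_top = 1)
  delta <- refit$rss - fit$rss
  threshold <- stats::qchisq(1 - alpha, df = 1)
  list(delta_chi2 = delta, significant = delta > threshold,
       threshold = threshold, inconclusive = !isTRUE(refit$converged),
       refit = refit)
}
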