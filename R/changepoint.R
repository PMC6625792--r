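# Constrained two-change-point model of categorical ensemble emissions,
# fit by multi-restart hard Expectation-Maximization.
#
# Per trial the 1.5 s of analyzable activity (150 bins of 10 ms) passes
# through three states: detection (one shared emission distribution
# alpha_D), identity (one distribution per taste quality, alpha_I), and
# palatability (one per taste, alpha_P). C_I is the number of detection
# bins (the identity state starts at bin C_I + 1) and C_P the last identity
# bin (the palatability state starts at bin C_P + 1).

CP_BIN <- 0.01
CP_N_BINS <- 150L

cp_windows <- function(condition) {
  switch(condition,
    control = list(keep = list(c(0, 1.5)), excised = NULL, splice_bin = NA),
    early = list(keep = list(c(0.5, 2.0)), excised = c(0.0, 0.5),
                 splice_bin = 0L),
    middle = list(keep = list(c(0, 0.7), c(1.2, 2.0)),
                  excised = c(0.7, 1.2), splice_bin = 70L),
    late = list(keep = list(c(0, 1.4), c(1.9, 2.0)),
                excised = c(1.4, 1.9), splice_bin = 140L),
    stop("unsupported condition for change-point analysis: ", condition)
  )
}

# Admissible change-point bin ranges (inclusive), per condition. C_I covers
# [0.2, 0.6] s of the analyzable series (early perturbation: from 0.1 s);
# C_P covers [C_I + 0.2 s, 1.3 s] (middle: from C_I + 0.1 s).
cp_constraints <- function(condition) {
  list(
    ci_min = if (condition == "early") 10L else 20L,
    ci_max = 60L,
    gap = if (condition == "middle") 10L else 20L,
    cp_max = 130L
  )
}

#' Convert a spike-train session to categorical ensemble series
#'
#' Aggregates spikes into 10 ms non-overlapping bins and marks each bin with
#' the index of the neuron that spiked (0 = no spike). When two or more
#' neurons spike in one bin, one is chosen uniformly at random (seeded).
#' Trials of one laser condition are selected; on laser trials the 0.5 s
#' laser window is excised and the flanking segments concatenated, so every
#' trial yields 150 bins (1.5 s) of analyzable activity: control uses
#' 0-1.5 s, early uses 0.5-2.0 s, middle splices 0-0.7 s with 1.2-2.0 s,
#' late splices 0-1.4 s with 1.9-2.0 s.
#'
#' @param x a [spike_train_set()].
#' @param condition `"control"`, `"early"`, `"middle"` or `"late"`.
#' @param seed integer seed for collision resolution.
#' @return object of class `categorical_series`: list with `symbols`
#'   (trials x 150 integer matrix), `taste` (per trial), `trial` (original
#'   trial indices), `n_neurons`, `condition`, `excised` (removed absolute
#'   window or `NULL`), `splice_bin` (series bin index after which the
#'   excision sits, `NA` if none).
#' @export
make_categorical <- function(x, condition = "control", seed = 1) {
  stopifnot(inherits(x, "spike_train_set"))
  win <- cp_windows(condition)
  need <- max(vapply(win$keep, max, numeric(1)))
  if (x$window[2] < need)
    stop("trials end at ", x$window[2], " s but condition '", condition,
         "' needs activity out to ", need, " s")
  keep <- which(as.character(x$labels$laser_condition) == condition)
  if (!length(keep)) stop("no trials with laser condition '", condition, "'")
  set.seed(seed)
  n_tr <- length(keep)
  S <- matrix(0L, n_tr, CP_N_BINS)
  for (j in seq_len(n_tr)) {
    i <- keep[j]
    col <- 0L
    for (w in win$keep) {
      starts <- seq(w[1], w[2] - CP_BIN / 2, by = CP_BIN)
      for (b in seq_along(starts)) {
        hit <- which(vapply(x$spikes[[i]], function(st)
          any(st >= starts[b] & st < starts[b] + CP_BIN), logical(1)))
        col <- col + 1L
        S[j, col] <- if (length(hit) == 0) 0L
                     else if (length(hit) == 1) hit
                     else hit[sample.int(length(hit), 1)]
      }
    }
  }
  structure(list(symbols = S, taste = as.character(x$labels$taste_id[keep]),
                 trial = keep, n_neurons = x$n_neurons,
                 condition = condition, excised = win$excised,
                 splice_bin = win$splice_bin),
            class = "categorical_series")
}

# Admissible (C_I, C_P) pairs, ordered by (C_I, C_P) ascending so that
# which.max() breaks likelihood ties toward the earliest pair.
cp_pairs <- function(cons, n_bins) {
  ci <- integer(0); cp <- integer(0)
  for (a in cons$ci_min:cons$ci_max) {
    b <- seq.int(a + cons$gap, cons$cp_max)
    b <- b[b < n_bins]
    if (length(b)) {
      ci <- c(ci, rep.int(a, length(b)))
      cp <- c(cp, b)
    }
  }
  if (!length(ci)) stop("no admissible (C_I, C_P) pair under the constraints")
  list(ci = ci, cp = cp)
}

# M-step (pooled over trials): emission counts per state, normalized.
# assign: list(ci=, cp=) integer vectors per trial.
cp_mstep <- function(S, taste, group, n_neurons, assign) {
  K <- n_neurons + 1L
  n_tr <- nrow(S)
  cnt_d <- numeric(K)
  cnt_i <- matrix(0, 2, K, dimnames = list(c("Suc", "Qui"), NULL))
  cnt_p <- matrix(0, 4, K, dimnames = list(TASTE_LEVELS, NULL))
  n_bins <- ncol(S)
  for (j in seq_len(n_tr)) {
    ci <- assign$ci[j]; cp <- assign$cp[j]
    cnt_d <- cnt_d + tabulate(S[j, seq_len(ci)] + 1L, K)
    cnt_i[group[j], ] <- cnt_i[group[j], ] +
      tabulate(S[j, (ci + 1L):cp] + 1L, K)
    cnt_p[taste[j], ] <- cnt_p[taste[j], ] +
      tabulate(S[j, (cp + 1L):n_bins] + 1L, K)
  }
  norm <- function(m) {
    if (is.matrix(m)) sweep(m, 1, pmax(rowSums(m), 1), "/")
    else m / max(sum(m), 1)
  }
  list(alpha_d = norm(cnt_d), alpha_i = norm(cnt_i), alpha_p = norm(cnt_p))
}

# log with zero probabilities mapped to a large finite penalty: keeps the
# cumulative-sum segment arithmetic below free of -Inf - -Inf = NaN while
# still excluding impossible segmentations from any argmax.
safe_log <- function(p) {
  l <- log(p)
  l[!is.finite(l)] <- -1e9
  l
}

# Hard E-step for one trial: log-likelihood of every admissible pair.
# `ld`, `li`, `lp` are safe_log()-ed emission distributions.
cp_pair_loglik <- function(s, ld, li, lp, pairs) {
  cd <- cumsum(ld[s + 1L])
  cifull <- cumsum(li[s + 1L])
  cpfull <- cumsum(lp[s + 1L])
  total_p <- cpfull[length(s)]
  cd[pairs$ci] + (cifull[pairs$cp] - cifull[pairs$ci]) +
    (total_p - cpfull[pairs$cp])
}

cp_total_loglik <- function(S, taste, group, alphas, assign) {
  ll <- 0
  n_bins <- ncol(S)
  for (j in seq_len(nrow(S))) {
    s <- S[j, ]
    ci <- assign$ci[j]; cp <- assign$cp[j]
    ll <- ll + sum(log(alphas$alpha_d[s[seq_len(ci)] + 1L])) +
      sum(log(alphas$alpha_i[group[j], s[(ci + 1L):cp] + 1L])) +
      sum(log(alphas$alpha_p[taste[j], s[(cp + 1L):n_bins] + 1L]))
  }
  ll
}

#' Fit the constrained two-change-point model by multi-restart hard EM
#'
#' Alternates a hard E-step -- per trial, exhaustive argmax over all
#' admissible (C_I, C_P) bin pairs of the joint likelihood under the current
#' emission distributions, ties broken toward the earliest (C_I, then C_P)
#' -- with an M-step that sets each categorical emission distribution to
#' the normalized emission counts pooled over every trial segment it
#' governs: one detection distribution, one identity distribution per taste
#' quality (sucrose vs quinine; or per taste with
#' `identity_groups = "taste"`), one palatability distribution per taste.
#' Each restart initializes the distributions from a symmetric Dirichlet(1)
#' and iterates until the total log-likelihood improves by less than `tol`
#' (or `max_iter`); the best restart by final log-likelihood is returned.
#' The log-likelihood is non-decreasing within a restart.
#'
#' @param series a [make_categorical()] result.
#' @param restarts number of random initializations.
#' @param tol absolute convergence threshold on the total log-likelihood.
#' @param max_iter iteration cap per restart.
#' @param seed integer RNG seed (fixes all restarts).
#' @param constraints optional override of the admissible bin ranges, a list
#'   with `ci_min`, `ci_max`, `gap`, `cp_max` (inclusive bin indices);
#'   defaults follow the series' condition.
#' @param identity_groups `"quality"` (2 identity distributions) or
#'   `"taste"` (4).
#' @return object of class `changepoint_fit`: list with `trials` (a
#'   `data.frame`: `trial`, `taste`, `c_i`, `c_p` in bins, `c_i_s`, `c_p_s`
#'   in series seconds, `c_p_abs` mapped back to absolute session time
#'   across any excised window, `post_prob` of the chosen pair under the
#'   final distributions), `alpha_d`, `alpha_i`, `alpha_p`, `loglik`,
#'   `best_restart`, `restart_logliks`, `converged`, `condition`.
#' @export
fit_changepoints <- function(series, restarts = 100, tol = 1e-8,
                             max_iter = 300, seed = 1, constraints = NULL,
                             identity_groups = c("quality", "taste")) {
  stopifnot(inherits(series, "categorical_series"))
  identity_groups <- match.arg(identity_groups)
  S <- series$symbols
  n_bins <- ncol(S)
  taste <- series$taste
  group <- if (identity_groups == "quality")
    ifelse(taste %in% c("DilSuc", "ConcSuc"), "Suc", "Qui") else taste
  cons <- if (is.null(constraints)) cp_constraints(series$condition)
          else constraints
  pairs <- cp_pairs(cons, n_bins)
  K <- series$n_neurons + 1L
  n_tr <- nrow(S)
  groups_u <- unique(group)
  set.seed(seed)
  best <- NULL
  restart_ll <- numeric(restarts)
  rdirichlet1 <- function() { g <- stats::rgamma(K, 1); g / sum(g) }
  for (r in seq_len(restarts)) {
    alphas <- list(
      alpha_d = rdirichlet1(),
      alpha_i = {
        m <- matrix(0, 2, K, dimnames = list(c("Suc", "Qui"), NULL))
        if (identity_groups == "taste")
          m <- matrix(0, 4, K, dimnames = list(TASTE_LEVELS, NULL))
        for (g in rownames(m)) m[g, ] <- rdirichlet1()
        m
      },
      alpha_p = {
        m <- matrix(0, 4, K, dimnames = list(TASTE_LEVELS, NULL))
        for (g in TASTE_LEVELS) m[g, ] <- rdirichlet1()
        m
      })
    assign <- list(ci = rep(cons$ci_min + cons$gap, n_tr),
                   cp = rep(cons$ci_min + 2L * cons$gap, n_tr))
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # hard E-step
      for (j in seq_len(n_tr)) {
        pl <- cp_pair_loglik(S[j, ], safe_log(alphas$alpha_d),
                             safe_log(alphas$alpha_i[group[j], ]),
                             safe_log(alphas$alpha_p[taste[j], ]), pairs)
        if (max(pl) < -1e8) next  # no feasible pair: keep the assignment
        k <- which.max(pl)
        assign$ci[j] <- pairs$ci[k]
        assign$cp[j] <- pairs$cp[k]
      }
      # M-step
      alphas <- cp_mstep(S, taste, group, series$n_neurons, assign)
      ll <- cp_total_loglik(S, taste, group, alphas, assign)
      if (is.finite(ll) && is.finite(ll_prev) && ll < ll_prev - 1e-9)
        stop("internal error: EM log-likelihood decreased")
      if (is.finite(ll) && ll - ll_prev < tol) {
        converged <- TRUE
        ll_prev <- ll
        break
      }
      ll_prev <- ll
    }
    restart_ll[r] <- ll_prev
    if (is.null(best) || ll_prev > best$loglik) {
      best <- list(alphas = alphas, assign = assign, loglik = ll_prev,
                   restart = r, converged = converged)
    }
  }
  # posterior probability of the chosen pair under the final alphas
  post <- numeric(n_tr)
  for (j in seq_len(n_tr)) {
    pl <- cp_pair_loglik(S[j, ], safe_log(best$alphas$alpha_d),
                         safe_log(best$alphas$alpha_i[group[j], ]),
                         safe_log(best$alphas$alpha_p[taste[j], ]), pairs)
    w <- exp(pl - max(pl))
    chosen <- which(pairs$ci == best$assign$ci[j] &
                      pairs$cp == best$assign$cp[j])
    post[j] <- w[chosen] / sum(w)
  }
  unsplice <- function(t_s) {
    if (is.null(series$excised)) return(t_s)
    if (series$condition == "early") return(t_s + series$excised[2])
    ifelse(t_s >= series$excised[1],
           t_s + (series$excised[2] - series$excised[1]), t_s)
  }
  trials <- data.frame(
    trial = series$trial, taste = taste,
    c_i = best$assign$ci, c_p = best$assign$cp,
    c_i_s = best$assign$ci * CP_BIN, c_p_s = best$assign$cp * CP_BIN,
    post_prob = post)
  trials$c_i_abs <- unsplice(trials$c_i_s)
  trials$c_p_abs <- unsplice(trials$c_p_s)
  structure(list(trials = trials, alpha_d = best$alphas$alpha_d,
                 alpha_i = best$alphas$alpha_i, alpha_p = best$alphas$alpha_p,
                 loglik = best$loglik, best_restart = best$restart,
                 restart_logliks = restart_ll, converged = best$converged,
                 condition = series$condition,
                 splice_bin = series$splice_bin),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat("<changepoint_fit> condition ", x$condition, ", ",
      nrow(x$trials), " trials, log-likelihood ",
      format(x$loglik, digits = 8), " (restart ", x$best_restart, ")\n",
      sep = "")
  invisible(x)
}

#' Partition trials by palatability transition vs laser onset
#'
#' Trials whose estimated palatability change-point (absolute session time)
#' precedes `laser_onset - 0.05` s are the `transition_first` group; trials
#' with the change-point in the 50 ms seam immediately before laser onset
#' are flagged (`seam`) and excluded from the partition, since change-points
#' in the two bins preceding a splice are uninterpretable; all remaining
#' trials form the `laser_first` group.
#'
#' @param fit a [fit_changepoints()] result.
#' @param laser_onset laser onset, seconds post delivery.
#' @return list with `transition_first`, `laser_first`, `seam`: integer
#'   vectors of original trial indices; plus `table`, the per-trial
#'   assignment as a `data.frame`.
#' @export
split_trials_by_transition <- function(fit, laser_onset) {
  stopifnot(inherits(fit, "changepoint_fit"))
  cp <- fit$trials$c_p_abs
  grp <- ifelse(cp < laser_onset - 0.05, "transition_first",
                ifelse(cp < laser_onset, "seam", "laser_first"))
  tab <- data.frame(trial = fit$trials$trial, c_p_abs = cp, group = grp)
  list(
    transition_first = fit$trials$trial[grp == "transition_first"],
    laser_first = fit$trials$trial[grp == "laser_first"],
    seam = fit$trials$trial[grp == "seam"],
    table = tab)
}
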