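#' Delta-rule weight update
#'
#' Moves the weight of the chosen (stimulus, response) pair toward the
#' delivered feedback by a fraction `alpha` of the prediction error:
#' `w + alpha * (us - w)`. With `w` and `us` in \[0, 1\] the update is a convex
#' combination, so weights can never leave \[0, 1\].
#'
#' @param w Current weight(s) in \[0, 1\].
#' @param us Feedback, 1 (reward) or 0 (nothing); recycled against `w`.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated weight(s).
#' @examples
#' update_weight(0.5, us = 1, alpha = 0.5)  # 0.75
#' @export
update_weight <- function(w, us, alpha) {
  stopifnot(all(alpha >= 0 & alpha <= 1))
  w + alpha * (us - w)
}

#' Softmax choice probabilities with an inverse-gain parameter
#'
#' The probability of a LEFT response given the two weights is
#' `exp(w_left/beta) / (exp(w_left/beta) + exp(w_right/beta))`. `beta` is the
#' inverse gain (exploration) parameter: small values sharpen choice toward
#' the larger weight (exploitation), large values flatten it toward 0.5
#' (exploration). Computed in the numerically stable logistic form of the
#' weight difference.
#'
#' @param w_left,w_right Weights of the two responses; vectors are accepted
#'   elementwise.
#' @param beta Inverse-gain parameter, strictly positive.
#' @return A list with numeric components `p_left` and `p_right` summing to 1.
#' @examples
#' choice_probabilities(0.75, 0.5, beta = 0.5)$p_left  # ~0.6225
#' @export
choice_probabilities <- function(w_left, w_right, beta) {
  if (any(beta <= 0)) stop("beta must be > 0 (beta <= 0 makes the softmax degenerate)")
  p_left <- stats::plogis((w_left - w_right) / beta)
  list(p_left = p_left, p_right = 1 - p_left)
}

#' Default (alpha, beta) search grid
#'
#' Learning rate alpha runs 0 to 1 in steps of `step`; the exploration
#' parameter beta runs `step` to 1 in the same steps. beta excludes 0 because
#' a zero-temperature softmax assigns probability 0 to observed choices
#' whenever the weights differ, making the log likelihood minus infinity.
#'
#' @param step Grid step, default 0.01.
#' @return A list with sorted numeric vectors `alpha_values`, `beta_values`.
#' @export
fit_grid_default <- function(step = 0.01) {
  stopifnot(step > 0, step <= 0.5)
  list(alpha_values = seq(0, 1, by = step),
       beta_values  = seq(step, 1, by = step))
}

# Internal: pull and check the (stimulus, response, us) arrays of a session.
# `session` is any data frame carrying those columns (a simulate_session()
# result or an imported long trial table restricted to one subject).
session_arrays <- function(session, contingency = NULL) {
  need <- c("stimulus", "response", "us")
  miss <- setdiff(need, names(session))
  if (length(miss))
    stop("malformed session: missing column(s) ", paste(miss, collapse = ", "))
  n <- nrow(session)
  if (n < 1L) stop("malformed session: no trials")
  stim <- as.character(session$stimulus)
  resp <- as.character(session$response)
  us <- as.numeric(session$us)
  if (!is.null(contingency)) {
    unknown <- which(!(stim %in% contingency$stimuli))
    if (length(unknown))
      stop(sprintf("malformed session: unknown stimulus '%s' at trial %d",
                   stim[unknown[1L]], unknown[1L]))
  }
  bad <- which(!(resp %in% c("LEFT", "RIGHT")))
  if (length(bad))
    stop(sprintf("malformed session: response '%s' at trial %d is not LEFT/RIGHT",
                 resp[bad[1L]], bad[1L]))
  bad_us <- which(!(us %in% c(0, 1)))
  if (length(bad_us))
    stop(sprintf("malformed session: us at trial %d is not 0/1", bad_us[1L]))
  list(stim = stim, resp = resp, us = us, n = n)
}

#' Sequential log likelihood of a choice sequence under the Q-learning model
#'
#' Replays a session trial by trial: on each trial the model probability of
#' the response the subject actually made is recorded from the softmax over
#' the current (stimulus, LEFT/RIGHT) weights, and then only the chosen
#' pair's weight is updated by the delta rule with the realized feedback.
#' The log likelihood is the sum of the per-trial log probabilities.
#'
#' @param session Data frame with one row per trial (columns `stimulus`,
#'   `response`, `us`), ordered by trial.
#' @param contingency Optional [make_contingency()] object; when supplied,
#'   session stimuli are checked against it.
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Inverse-gain parameter, > 0.
#' @param w_init Initial weight shared by all 12 (stimulus, response) pairs;
#'   default 0.5 (the midpoint of the feedback range, so the first choice to
#'   any stimulus is 50/50 and negative feedback is informative from trial 1).
#' @return A list: `lle` (log likelihood, nats, always <= 0), `p_choice`
#'   (per-trial probability of the observed response), `n_trials`.
#' @examples
#' cmap <- make_contingency(1)
#' ses <- simulate_session(agent_params(0.3, 0.2), cmap,
#'                         build_schedule(cmap, 2), seed = 3)
#' session_loglik(ses, cmap, alpha = 0, beta = 0.5)$lle  # 96 * log(0.5)
#' @export
session_loglik <- function(session, contingency = NULL, alpha, beta,
                           w_init = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, w_init >= 0, w_init <= 1)
  if (beta <= 0) stop("beta must be > 0")
  a <- session_arrays(session, contingency)
  stimuli <- if (!is.null(contingency)) contingency$stimuli else sort(unique(a$stim))
  w <- matrix(w_init, nrow = length(stimuli), ncol = 2L,
              dimnames = list(stimuli, c("LEFT", "RIGHT")))
  p_choice <- numeric(a$n)
  for (t in seq_len(a$n)) {
    s <- a$stim[t]; r <- a$resp[t]
    other <- if (r == "LEFT") "RIGHT" else "LEFT"
    p_choice[t] <- stats::plogis((w[s, r] - w[s, other]) / beta)
    w[s, r] <- w[s, r] + alpha * (a$us[t] - w[s, r])
  }
  list(lle = sum(log(p_choice)), p_choice = p_choice, n_trials = a$n)
}

#' McFadden pseudo-R-squared against the random responder
#'
#' Compares a fitted log likelihood with `r = n_trials * log(0.5)`, the log
#' likelihood of a purely random responder (p = 0.5 on every trial), as
#' `1 - lle / r`. It is 0 for a chance-level fit, 1 for perfect prediction,
#' and non-negative whenever the fit is at least as likely as chance — which
#' the grid search guarantees, because alpha = 0 with a symmetric weight
#' initialization reproduces the random responder exactly.
#'
#' @param lle Log likelihood (nats), <= 0.
#' @param n_trials Number of trials, >= 1.
#' @return The pseudo-R-squared value.
#' @examples
#' pseudo_r2(96 * log(0.5), 96)  # 0
#' pseudo_r2(-50, 96)            # ~0.2486
#' @export
pseudo_r2 <- function(lle, n_trials) {
  stopifnot(n_trials >= 1, all(lle <= 0))
  r <- n_trials * log(0.5)
  1 - lle / r
}

# Internal fast path: full log-likelihood surface over an (alpha, beta) grid.
# For a fixed session the weight trajectory depends on alpha only, so one
# vectorized replay per alpha yields the per-trial weight difference
# d_t = w(chosen) - w(unchosen); the surface is then
# lle(alpha, beta) = sum_t log plogis(d_t / beta), computed per beta column.
loglik_surface <- function(arrays, stimuli, alpha_values, beta_values, w_init) {
  na <- length(alpha_values); nt <- arrays$n
  idx_chosen <- match(paste(arrays$stim, arrays$resp), outer(stimuli, c("LEFT", "RIGHT"), paste))
  idx_other  <- match(paste(arrays$stim, ifelse(arrays$resp == "LEFT", "RIGHT", "LEFT")),
                      outer(stimuli, c("LEFT", "RIGHT"), paste))
  W <- matrix(w_init, nrow = na, ncol = 2L * length(stimuli))
  D <- matrix(0, nrow = na, ncol = nt)
  for (t in seq_len(nt)) {
    wc <- W[, idx_chosen[t]]
    D[, t] <- wc - W[, idx_other[t]]
    W[, idx_chosen[t]] <- wc + alpha_values * (arrays$us[t] - wc)
  }
  vapply(beta_values,
         function(b) rowSums(stats::plogis(D / b, log.p = TRUE)),
         numeric(na))  # na x nb matrix, rows alpha, cols beta
}

#' Grid-search maximum-likelihood fit of (alpha, beta)
#'
#' Evaluates [session_loglik()] at every point of the search grid and returns
#' the maximizing pair. Ties are broken deterministically in favor of the
#' smallest beta, then the smallest alpha. Because the grid contains
#' alpha = 0, the optimum is never worse than the random responder and the
#' reported pseudo-R-squared is never negative.
#'
#' @inheritParams session_loglik
#' @param grid A grid from [fit_grid_default()] (or the same structure with
#'   custom strictly increasing values; beta must exclude 0).
#' @return A one-row tibble of class `qdisc_fit`: `alpha_hat`, `beta_hat`,
#'   `lle`, `pseudo_r2`, `n_trials`.
#' @examples
#' cmap <- make_contingency(1)
#' ses <- simulate_session(agent_params(0.25, 0.15), cmap,
#'                         build_schedule(cmap, 2), seed = 3)
#' fit_grid(ses, cmap)
#' @export
fit_grid <- function(session, contingency = NULL, grid = fit_grid_default(),
                     w_init = 0.5) {
  stopifnot(is.list(grid), !is.null(grid$alpha_values), !is.null(grid$beta_values))
  av <- grid$alpha_values; bv <- grid$beta_values
  stopifnot(!is.unsorted(av, strictly = TRUE), !is.unsorted(bv, strictly = TRUE),
            all(av >= 0), all(av <= 1), all(bv > 0), all(bv <= 1))
  a <- session_arrays(session, contingency)
  stimuli <- if (!is.null(contingency)) contingency$stimuli else sort(unique(a$stim))
  L <- loglik_surface(a, stimuli, av, bv, w_init)
  best <- max(L)
  ties <- which(L == best, arr.ind = TRUE)
  # smallest beta (column) first, then smallest alpha (row)
  pick <- ties[order(ties[, 2L], ties[, 1L])[1L], , drop = FALSE]
  out <- tibble::tibble(
    alpha_hat = av[pick[1L, 1L]],
    beta_hat  = bv[pick[1L, 2L]],
    lle       = best,
    pseudo_r2 = pseudo_r2(best, a$n),
    n_trials  = a$n
  )
  class(out) <- c("qdisc_fit", class(out))
  out
}

#' Log-likelihood surface for diagnostics
#'
#' Returns the full grid of log likelihoods for one session, useful for
#' inspecting identifiability of the two parameters.
#'
#' @inheritParams fit_grid
#' @return A tibble with columns `alpha`, `beta`, `lle` (one row per grid
#'   point).
#' @export
loglik_grid <- function(session, contingency = NULL, grid = fit_grid_default(),
                        w_init = 0.5) {
  a <- session_arrays(session, contingency)
  stimuli <- if (!is.null(contingency)) contingency$stimuli else sort(unique(a$stim))
  L <- loglik_surface(a, stimuli, grid$alpha_values, grid$beta_values, w_init)
  tibble::tibble(
    alpha = rep(grid$alpha_values, times = length(grid$beta_values)),
    beta  = rep(grid$beta_values, each = length(grid$alpha_values)),
    lle   = as.vector(L)
  )
}

#' Fit every subject in a long trial table
#'
#' Splits a long-format trial table (one row per trial, multiple subjects) by
#' `subject_id`, fits each subject's choice sequence by [fit_grid()], and
#' stacks the results.
#'
#' @param trials Data frame with columns `subject_id`, `trial_index`,
#'   `stimulus`, `response`, `us` (the interchange format written by
#'   [write_trials()]).
#' @inheritParams fit_grid
#' @return A tibble with one row per subject: `subject_id`, `alpha_hat`,
#'   `beta_hat`, `lle`, `pseudo_r2`, `n_trials`.
#' @export
fit_subjects <- function(trials, contingency = NULL,
                         grid = fit_grid_default(), w_init = 0.5) {
  stopifnot("subject_id" %in% names(trials))
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    ses <- trials[trials$subject_id == id, , drop = FALSE]
    ses <- ses[order(ses$trial_index), , drop = FALSE]
    fit <- fit_grid(ses, contingency, grid, w_init)
    tibble::tibble(subject_id = id, fit)
  })
  do.call(rbind, rows)
}
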