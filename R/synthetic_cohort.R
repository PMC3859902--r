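#' Agent parameters
#'
#' A learning rate / exploration pair for a simulated Q-learning agent.
#' `alpha` in \[0, 1\] scales the prediction-error update; `beta` in (0, 1\]
#' is the inverse-gain (exploration) parameter of the softmax choice rule.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Exploration parameter in (0, 1\].
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta <= 1)
  if (beta <= 0) stop("beta must be > 0 (degenerate softmax)")
  structure(list(alpha = alpha, beta = beta), class = "agent_params")
}

#' Simulate one Q-learning agent's session
#'
#' Plays a schedule with the same model the fitter assumes: 12 weights, one
#' per (stimulus, LEFT/RIGHT) pair, all initialized at `w_init`. On each
#' trial the response is drawn from the softmax over the current weights of
#' the presented stimulus; feedback is deterministic (`us = 1` iff the
#' response matches the contingency's correct response, and `correct == us`);
#' then only the chosen pair's weight is updated by the delta rule.
#'
#' @param params An [agent_params()] pair.
#' @param contingency A [make_contingency()] object.
#' @param schedule A [build_schedule()] schedule.
#' @param seed Integer seed for the choice draws.
#' @param w_init Initial weight for every pair, default 0.5. The fitter must
#'   share this value for the alpha = 0 grid point to reproduce the random
#'   responder exactly.
#' @param subject_id Identifier stamped on every trial row.
#' @return A tibble of class `session_data`, 96 rows, columns `subject_id`,
#'   `trial_index`, `block`, `stimulus`, `response`, `us`, `correct`.
#' @examples
#' cmap <- make_contingency(1)
#' ses <- simulate_session(agent_params(0.2, 0.7), cmap,
#'                         build_schedule(cmap, 2), seed = 3)
#' mean(ses$correct)
#' @export
simulate_session <- function(params, contingency, schedule, seed,
                             w_init = 0.5, subject_id = "sim") {
  stopifnot(inherits(params, "agent_params"),
            inherits(contingency, "contingency_map"))
  if (params$beta <= 0) stop("beta must be > 0")
  stopifnot(w_init >= 0, w_init <= 1)
  n <- nrow(schedule)
  stim <- as.character(schedule$stimulus)
  correct_resp <- contingency$correct_response
  w <- matrix(w_init, nrow = 6L, ncol = 2L,
              dimnames = list(contingency$stimuli, c("LEFT", "RIGHT")))
  resp <- character(n); us <- integer(n)
  u <- withr::with_seed(seed, stats::runif(n))
  for (t in seq_len(n)) {
    s <- stim[t]
    p_left <- stats::plogis((w[s, "LEFT"] - w[s, "RIGHT"]) / params$beta)
    resp[t] <- if (u[t] < p_left) "LEFT" else "RIGHT"
    us[t] <- as.integer(resp[t] == correct_resp[[s]])
    w[s, resp[t]] <- w[s, resp[t]] + params$alpha * (us[t] - w[s, resp[t]])
  }
  out <- tibble::tibble(
    subject_id = subject_id,
    trial_index = schedule$trial_index,
    block = schedule$block,
    stimulus = stim,
    response = resp,
    us = us,
    correct = us
  )
  class(out) <- c("session_data", class(out))
  out
}

#' Simulate a purely random responder
#'
#' Each response is LEFT or RIGHT with probability 0.5 independent of
#' history — the chance baseline of the pseudo-R-squared validation.
#'
#' @inheritParams simulate_session
#' @return A `session_data` tibble like [simulate_session()].
#' @export
simulate_random_session <- function(schedule, contingency, seed,
                                    subject_id = "rand") {
  stopifnot(inherits(contingency, "contingency_map"))
  n <- nrow(schedule)
  stim <- as.character(schedule$stimulus)
  resp <- withr::with_seed(seed, {
    ifelse(stats::runif(n) < 0.5, "LEFT", "RIGHT")
  })
  us <- as.integer(resp == unname(contingency$correct_response[stim]))
  out <- tibble::tibble(
    subject_id = subject_id,
    trial_index = schedule$trial_index,
    block = schedule$block,
    stimulus = stim,
    response = resp,
    us = us,
    correct = us
  )
  class(out) <- c("session_data", class(out))
  out
}

# Truncated-normal draws by inverse-CDF sampling on the truncated interval.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Cohort-generating specification
#'
#' Defaults describe the study conditions the package emulates: 11 controls
#' and 17 patients whose generating (alpha, beta) are drawn from per-group
#' normal distributions with reference group means and SDs for patients and controls (alpha
#' truncated to \[0, 1\], beta to (0, 1\]); clinical covariates drawn
#' independently of alpha (so the covariate screen has a true null); and
#' three regional gray-matter values in which only vmPFC is directly coupled
#' to alpha while rIFG and NAcc are correlated bystanders.
#'
#' @param n_control,n_pd Group sizes.
#' @param alpha_mean,alpha_sd,beta_mean,beta_sd Named numeric pairs
#'   `c(control = , pd = )` giving the generating parameter distributions.
#' @param roi_effect Correlation-scale coupling of vmPFC to standardized
#'   alpha, in (-1, 1). Default 0.6: a strong single-region association,
#'   detectable at n = 17 in most cohorts but not all.
#' @param roi_cross_corr Correlation of each bystander region with vmPFC,
#'   in (-1, 1). Default 0.5: bystanders inherit an indirect alpha
#'   association of about `roi_effect * roi_cross_corr` = 0.3 that should
#'   vanish once vmPFC is partialled out.
#' @param master_seed Integer seed from which all per-subject seeds derive.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 11L, n_pd = 17L,
                        alpha_mean = c(control = 0.217, pd = 0.163),
                        alpha_sd   = c(control = 0.036, pd = 0.041),
                        beta_mean  = c(control = 0.70,  pd = 0.85),
                        beta_sd    = c(control = 0.26,  pd = 0.30),
                        roi_effect = 0.6, roi_cross_corr = 0.5,
                        master_seed = 1L) {
  stopifnot(n_control >= 1L, n_pd >= 1L,
            all(alpha_sd >= 0), all(beta_sd >= 0),
            abs(roi_cross_corr) < 1, abs(roi_effect) < 1)
  if (any(alpha_mean < 0 | alpha_mean > 1))
    stop("alpha_mean must lie in [0, 1]")
  structure(
    list(n_control = as.integer(n_control), n_pd = as.integer(n_pd),
         alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         beta_mean = beta_mean, beta_sd = beta_sd,
         roi_effect = roi_effect, roi_cross_corr = roi_cross_corr,
         master_seed = as.integer(master_seed)),
    class = "cohort_spec"
  )
}

# Clinical covariate generators: independent normals at reference PD
# summary statistics, clipped to plausible ranges. Controls get NA for
# disease-specific measures. These exist to give the null covariate screen
# something realistic to chew on; none is coupled to alpha.
clinical_defs <- list(
  disease_duration = list(mean = 5.6,  sd = 5.4,  lower = 0,   upper = 30),
  hoehn_yahr       = list(mean = 2.1,  sd = 0.52, lower = 1,   upper = 5),
  updrs_iii        = list(mean = 29.2, sd = 12.8, lower = 0,   upper = 108),
  dde              = list(mean = 616.1, sd = 453.1, lower = 0, upper = 3000),
  bdi              = list(mean = 10.6, sd = 6.9,  lower = 0,   upper = 63)
)

#' Sample a synthetic cohort with simulated sessions
#'
#' Draws per-subject generating parameters, clinical covariates and ROI
#' gray-matter values from a [cohort_spec()], gives every subject an
#' independent contingency (counterbalancing), schedule and simulated
#' session, and returns subject-level and trial-level tables.
#'
#' ROI construction: let `z` be the cohort-standardized generating alpha.
#' Then `vmPFC = roi_effect * z + sqrt(1 - roi_effect^2) * e0` on the
#' standard scale, and each bystander is
#' `roi_cross_corr * vmPFC + sqrt(1 - roi_cross_corr^2) * e`; all three are
#' rescaled to gray-matter-density-like units (mean 0.5, SD 0.05). Bystanders
#' therefore carry an alpha association only through vmPFC, giving the
#' partial-correlation analysis a recoverable ground truth.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with elements `subjects` (tibble: one row
#'   per subject with `subject_id`, `group`, `true_alpha`, `true_beta`,
#'   clinical columns, `vmPFC`, `rIFG`, `NAcc`) and `trials` (long tibble of
#'   all simulated sessions).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_control + spec$n_pd
  group <- c(rep("CONTROL", spec$n_control), rep("PD", spec$n_pd))
  gkey <- ifelse(group == "CONTROL", "control", "pd")

  draws <- withr::with_seed(spec$master_seed, {
    alpha <- vapply(gkey, function(g)
      rtruncnorm(1L, spec$alpha_mean[[g]], spec$alpha_sd[[g]], 0, 1), 0)
    beta <- vapply(gkey, function(g)
      rtruncnorm(1L, spec$beta_mean[[g]], spec$beta_sd[[g]], 1e-6, 1), 0)
    clin <- lapply(clinical_defs, function(d) {
      v <- rtruncnorm(n, d$mean, d$sd, d$lower, d$upper)
      ifelse(group == "PD", v, NA_real_)
    })
    z <- as.vector(scale(alpha))
    if (any(!is.finite(z))) z <- rep(0, n)  # degenerate sd = 0 cohorts
    lam <- spec$roi_effect; rho <- spec$roi_cross_corr
    vmpfc_z <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
    rifg_z <- rho * vmpfc_z + sqrt(1 - rho^2) * stats::rnorm(n)
    nacc_z <- rho * vmpfc_z + sqrt(1 - rho^2) * stats::rnorm(n)
    seeds <- sample.int(.Machine$integer.max, 3L * n)
    list(alpha = unname(alpha), beta = unname(beta), clin = clin,
         vmPFC = 0.5 + 0.05 * vmpfc_z, rIFG = 0.5 + 0.05 * rifg_z,
         NAcc = 0.5 + 0.05 * nacc_z, seeds = matrix(seeds, ncol = 3L))
  })

  ids <- sprintf("%s%02d", ifelse(group == "PD", "pd", "ctl"),
                 c(seq_len(spec$n_control), seq_len(spec$n_pd)))
  subjects <- tibble::tibble(
    subject_id = ids, group = group,
    true_alpha = draws$alpha, true_beta = draws$beta,
    tibble::as_tibble(draws$clin),
    vmPFC = draws$vmPFC, rIFG = draws$rIFG, NAcc = draws$NAcc
  )
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    cmap <- make_contingency(draws$seeds[i, 1L])
    sched <- build_schedule(cmap, draws$seeds[i, 2L])
    simulate_session(agent_params(draws$alpha[i], draws$beta[i]),
                     cmap, sched, seed = draws$seeds[i, 3L],
                     subject_id = ids[i])
  }))
  structure(list(subjects = subjects, trials = trials), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d CONTROL, %d PD), %d trial rows\n",
              nrow(x$subjects), sum(x$subjects$group == "CONTROL"),
              sum(x$subjects$group == "PD"), nrow(x$trials)))
  invisible(x)
}

#' Read/write long trial tables and cohort tables
#'
#' Tab-separated interchange formats: `write_trials()` writes one row per
#' trial (`subject_id`, `trial_index`, `block`, `stimulus`, `response`,
#' `us`, `correct`) — the format [fit_subjects()] consumes, and the format
#' real exported behavioral data should be coerced to. `write_cohort_table()`
#' writes one row per subject.
#'
#' @param trials,subjects Data frames as produced by [sample_cohort()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return tibbles.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' @rdname write_trials
#' @export
write_cohort_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_cohort_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
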