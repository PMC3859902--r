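# Independent oracles, deliberately written with different code structure
# than the package internals (plain lists, direct exponential ratios, no
# shared helpers), so they can arbitrate the sequential likelihood and the
# Welch statistic.

# Naive sequential likelihood: product of per-trial probabilities computed
# from scratch by refolding the whole weight history at every trial.
naive_session_loglik <- function(stim, resp, us, alpha, beta, w_init = 0.5) {
  weight_after <- function(upto) {
    # weights for every (stimulus, response) after replaying trials 1..upto
    w <- list()
    key <- function(s, r) paste0(s, ".", r)
    get_w <- function(s, r) if (is.null(w[[key(s, r)]])) w_init else w[[key(s, r)]]
    if (upto >= 1) {
      for (t in 1:upto) {
        wv <- get_w(stim[t], resp[t])
        w[[key(stim[t], resp[t])]] <- wv + alpha * (us[t] - wv)
      }
    }
    function(s, r) get_w(s, r)
  }
  total <- 0
  for (t in seq_along(stim)) {
    getw <- weight_after(t - 1L)
    other <- if (resp[t] == "LEFT") "RIGHT" else "LEFT"
    num <- exp(getw(stim[t], resp[t]) / beta)
    den <- num + exp(getw(stim[t], other) / beta)
    total <- total + log(num / den)
  }
  total
}

# Textbook Welch t statistic.
naive_welch_t <- function(a, b) {
  (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

# Enumerate every 2-stimulus session of a given length: all combinations of
# stimulus in {S1, S2}, response in {LEFT, RIGHT}, feedback in {0, 1}.
enumerate_sessions <- function(len) {
  opts <- expand.grid(rep(list(1:8), len))
  lapply(seq_len(nrow(opts)), function(i) {
    code <- as.integer(opts[i, ]) - 1L
    data.frame(
      trial_index = seq_len(len),
      stimulus = c("S1", "S2")[code %% 2L + 1L],
      response = c("LEFT", "RIGHT")[(code %/% 2L) %% 2L + 1L],
      us = (code %/% 4L) %% 2L
    )
  })
}
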