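# Shared small fixtures, rebuilt in code at load time.

fix_cmap <- make_contingency(seed = 11)
fix_sched <- build_schedule(fix_cmap, seed = 12)

# A session where every response is correct (follows the contingency).
all_correct_session <- function(cmap = fix_cmap, sched = fix_sched) {
  tibble::tibble(
    subject_id = "perfect",
    trial_index = sched$trial_index,
    block = sched$block,
    stimulus = sched$stimulus,
    response = unname(cmap$correct_response[sched$stimulus]),
    us = 1L,
    correct = 1L
  )
}

sim_one <- function(alpha, beta, seed, cmap = fix_cmap, sched = fix_sched) {
  simulate_session(agent_params(alpha, beta), cmap, sched, seed = seed)
}
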