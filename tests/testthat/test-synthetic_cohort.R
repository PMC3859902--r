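test_that("simulated sessions follow the schedule and deterministic feedback", {
  ses <- sim_one(0.3, 0.5, seed = 1)
  expect_equal(nrow(ses), 96L)
  expect_equal(ses$us, ses$correct)
  expect_true(all(ses$us %in% c(0L, 1L)))
  expect_length(validate_schedule(ses), 0L)  # inherits block structure
  # feedback consistent with the contingency
  expect_equal(ses$us,
               as.integer(ses$response == unname(fix_cmap$correct_response[ses$stimulus])))
  # determinism
  expect_identical(sim_one(0.3, 0.5, seed = 1), sim_one(0.3, 0.5, seed = 1))
  expect_error(simulate_session(agent_params(0.3, 0), fix_cmap, fix_sched, 1),
               "beta")
})

test_that("a no-learning agent responds at chance", {
  acc <- vapply(1:1000, function(i) mean(sim_one(0, 0.5, seed = i)$correct), 0)
  expect_gte(mean(acc), 0.485)
  expect_lte(mean(acc), 0.515)
})

test_that("an extreme exploiter repeats rewarded responses almost surely", {
  # after one reward, the chosen weight is 1 vs 0.5: softmax at beta = 0.01
  # gives > 0.99 repeat probability
  expect_gt(choice_probabilities(1, 0.5, 0.01)$p_left, 0.99)
  repeats <- total <- 0
  for (i in 1:30) {
    ses <- sim_one(1, 0.01, seed = 100 + i)
    for (s in unique(ses$stimulus)) {
      rows <- ses[ses$stimulus == s, ]
      rewarded <- which(rows$us == 1)
      if (length(rewarded) && rewarded[1] < nrow(rows)) {
        total <- total + 1
        repeats <- repeats +
          (rows$response[rewarded[1] + 1] == rows$response[rewarded[1]])
      }
    }
  }
  expect_gt(repeats / total, 0.95)
})

test_that("random responder sessions are fair coins, deterministically seeded", {
  ses <- simulate_random_session(fix_sched, fix_cmap, seed = 4)
  expect_equal(nrow(ses), 96L)
  expect_true(all(ses$us %in% c(0L, 1L)))
  expect_identical(ses, simulate_random_session(fix_sched, fix_cmap, seed = 4))
  acc <- vapply(1:1000, function(i)
    mean(simulate_random_session(fix_sched, fix_cmap, seed = i)$correct), 0)
  expect_gte(mean(acc), 0.485)
  expect_lte(mean(acc), 0.515)
})

test_that("a zero-learning-rate agent is distributionally a random responder", {
  acc_agent <- vapply(1:1500, function(i) mean(sim_one(0, 0.7, seed = i)$correct), 0)
  acc_rand <- vapply(1:1500, function(i)
    mean(simulate_random_session(fix_sched, fix_cmap, seed = 5000 + i)$correct), 0)
  ks <- suppressWarnings(ks.test(acc_agent, acc_rand))
  expect_gt(ks$p.value, 0.001)
  # response-repetition (runs) statistic agrees too
  rep_rate <- function(f, off) mean(vapply(1:300, function(i) {
    ses <- f(i + off); mean(ses$response[-1] == ses$response[-96])
  }, 0))
  r_agent <- rep_rate(function(i) sim_one(0, 0.7, seed = i), 0)
  r_rand <- rep_rate(function(i) simulate_random_session(fix_sched, fix_cmap, seed = i), 300)
  expect_lt(abs(r_agent - r_rand), 0.01)
})

test_that("session accuracy decreases with exploration at fixed learning rate", {
  mean_acc <- function(beta, n = 600) {
    mean(vapply(seq_len(n), function(i)
      mean(sim_one(0.25, beta, seed = 7000 + i)$correct), 0))
  }
  accs <- vapply(c(0.05, 0.3, 1.0), mean_acc, 0)
  # allow small sampling error on the non-increasing pattern
  expect_true(all(diff(accs) < 0.01))
  expect_gt(accs[1] - accs[3], 0.05)
})

test_that("cohort sampling honors the generating specification", {
  # degenerate SDs: identical parameters within group
  co0 <- sample_cohort(cohort_spec(n_control = 3, n_pd = 3,
                                   alpha_sd = c(control = 0, pd = 0),
                                   beta_sd = c(control = 0, pd = 0),
                                   master_seed = 2))
  expect_equal(length(unique(co0$subjects$true_alpha)), 2L)
  expect_equal(sort(unique(co0$subjects$true_alpha)), c(0.163, 0.217))

  # large cohort: sample means close to specified means (truncation negligible)
  co <- sample_cohort(cohort_spec(n_control = 1000, n_pd = 1000, master_seed = 3))
  pd <- co$subjects[co$subjects$group == "PD", ]
  ctl <- co$subjects[co$subjects$group == "CONTROL", ]
  expect_lt(abs(mean(pd$true_alpha) - 0.163), 0.01)
  expect_lt(abs(mean(ctl$true_alpha) - 0.217), 0.01)
  expect_true(all(co$subjects$true_alpha >= 0 & co$subjects$true_alpha <= 1))
  expect_true(all(co$subjects$true_beta > 0 & co$subjects$true_beta <= 1))
  # clinical covariates only for patients, null-coupled to alpha
  expect_true(all(is.na(ctl$updrs_iii)))
  expect_true(all(is.finite(pd$updrs_iii)))
  expect_lt(abs(cor(pd$true_alpha, pd$updrs_iii)), 0.08)
  # ROI coupling: vmPFC tracks alpha, bystanders only via vmPFC
  expect_gt(cor(pd$true_alpha, pd$vmPFC), 0.45)
  expect_lt(cor(pd$true_alpha, pd$rIFG), cor(pd$true_alpha, pd$vmPFC))
  expect_gt(cor(pd$vmPFC, pd$rIFG), 0.35)

  # null ROI coupling when the effect is switched off
  co_null <- sample_cohort(cohort_spec(n_control = 500, n_pd = 500,
                                       roi_effect = 0, master_seed = 4))
  expect_lt(abs(cor(co_null$subjects$true_alpha, co_null$subjects$vmPFC)), 0.08)

  expect_error(cohort_spec(alpha_mean = c(control = 1.2, pd = 0.2)), "alpha_mean")
})

test_that("every cohort session keeps feedback consistent and blocks intact", {
  co <- sample_cohort(cohort_spec(n_control = 3, n_pd = 3, master_seed = 9))
  expect_equal(co$trials$us, co$trials$correct)
  for (id in unique(co$trials$subject_id)) {
    ses <- co$trials[co$trials$subject_id == id, ]
    expect_length(validate_schedule(ses), 0L)
  }
})

test_that("trial and cohort tables round-trip through delimited text", {
  co <- sample_cohort(cohort_spec(n_control = 2, n_pd = 2, master_seed = 5))
  tpath <- withr::local_tempfile(fileext = ".tsv")
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_trials(co$trials, tpath)
  write_cohort_table(co$subjects, cpath)
  trials2 <- read_trials(tpath)
  subjects2 <- read_cohort_table(cpath)
  expect_equal(as.data.frame(trials2), as.data.frame(co$trials))
  expect_equal(subjects2$true_alpha, co$subjects$true_alpha)
  expect_equal(subjects2$vmPFC, co$subjects$vmPFC)
})
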