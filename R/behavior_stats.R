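# Vectorized permutation helpers. Both build a single n x n_perm index matrix
# under a local seed so results are reproducible and the global RNG is
# untouched.

perm_index_matrix <- function(n, n_perm, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
}

# Permutation p for a Pearson correlation: shuffle y, count |r*| >= |r|.
perm_cor_test <- function(x, y, n_perm = 10000L, seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, constant = TRUE))
  r_obs <- stats::cor(x, y)
  xs <- as.vector(scale(x)); ys <- as.vector(scale(y))
  idx <- perm_index_matrix(n, n_perm, seed)
  r_perm <- as.vector(crossprod(xs, matrix(ys[idx], nrow = n))) / (n - 1)
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  list(r = r_obs, p = p, n = n, constant = FALSE)
}

#' Block-wise accuracy of a session
#'
#' Proportion of correct trials per 12-trial block.
#'
#' @param session A `session_data` tibble (or any trial table with `block`
#'   and `correct` columns for one subject).
#' @return Named numeric vector of 8 proportions (`block1` .. `block8`),
#'   each a multiple of 1/12.
#' @export
block_accuracy <- function(session) {
  if (!all(c("block", "correct") %in% names(session)))
    stop("malformed session: need columns block, correct")
  blocks <- sort(unique(session$block))
  if (!identical(as.integer(blocks), 1:8))
    stop("malformed session: expected blocks 1..8")
  acc <- vapply(blocks, function(b) {
    idx <- session$block == b
    if (sum(idx) != 12L)
      stop(sprintf("malformed session: block %d has %d trials, expected 12",
                   b, sum(idx)))
    mean(session$correct[idx])
  }, 0)
  stats::setNames(acc, paste0("block", blocks))
}

#' Overall accuracy of a session
#'
#' @param session A `session_data` tibble.
#' @return Proportion of correct trials over the whole session.
#' @export
overall_accuracy <- function(session) {
  if (!"correct" %in% names(session))
    stop("malformed session: need column correct")
  mean(session$correct)
}

#' Block-accuracy matrix for a cohort
#'
#' @param trials Long trial table covering multiple subjects.
#' @return A tibble: `subject_id` plus `block1` .. `block8` accuracy columns.
#' @export
block_accuracy_table <- function(trials) {
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    acc <- block_accuracy(trials[trials$subject_id == id, , drop = FALSE])
    tibble::tibble(subject_id = id, !!!as.list(acc))
  })
  do.call(rbind, rows)
}

#' Two-sample contrast of a learning measure
#'
#' Compares a per-subject measure between two groups. The default is a
#' two-sided permutation test on the difference of group means (10,000
#' seeded label shuffles), the distribution-free choice suited to small
#' groups; Welch's t and the Mann-Whitney U test are provided for parity
#' with standard toolboxes.
#'
#' @param values_a,values_b Numeric measures for the two groups (>= 2 each).
#' @param method `"permutation"`, `"welch_t"` or `"mann_whitney"`.
#' @param n_perm Number of label shuffles for the permutation method.
#' @param seed Seed for the shuffles.
#' @param measure Label carried into the result.
#' @return A one-row tibble: `measure`, `method`, `statistic`, `p_value`,
#'   `mean_a`, `mean_b`.
#' @export
compare_groups <- function(values_a, values_b,
                           method = c("permutation", "welch_t", "mann_whitney"),
                           n_perm = 10000L, seed = 1L, measure = "measure") {
  method <- match.arg(method)
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  res <- switch(method,
    welch_t = {
      tt <- stats::t.test(values_a, values_b)
      list(stat = unname(tt$statistic), p = tt$p.value)
    },
    mann_whitney = {
      wt <- stats::wilcox.test(values_a, values_b, exact = FALSE)
      list(stat = unname(wt$statistic), p = wt$p.value)
    },
    permutation = {
      pooled <- c(values_a, values_b)
      na <- length(values_a); n <- length(pooled)
      d_obs <- mean(values_a) - mean(values_b)
      idx <- perm_index_matrix(n, n_perm, seed)
      pm <- matrix(pooled[idx], nrow = n)
      d_perm <- colMeans(pm[seq_len(na), , drop = FALSE]) -
        colMeans(pm[(na + 1L):n, , drop = FALSE])
      p <- (1 + sum(abs(d_perm) >= abs(d_obs) - 1e-12)) / (n_perm + 1)
      list(stat = d_obs, p = p)
    })
  tibble::tibble(measure = measure, method = method,
                 statistic = res$stat, p_value = res$p,
                 mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Screen clinical covariates against a learning measure
#'
#' Pearson correlation of each covariate with a target measure, with a
#' seeded permutation p-value. Used on patient cohorts to confirm that
#' clinical severity measures do not explain the learning-rate estimate.
#' Constant covariates are flagged (`constant = TRUE`, correlation `NA`).
#'
#' @param cohort_table Subject-level data frame.
#' @param covariates Character vector of covariate column names.
#' @param target Name of the target measure column.
#' @param n_perm,seed Permutation settings.
#' @return A tibble: `covariate`, `r`, `p`, `n`, `constant`.
#' @export
null_covariate_screen <- function(cohort_table, covariates, target,
                                  n_perm = 10000L, seed = 1L) {
  miss <- setdiff(c(covariates, target), names(cohort_table))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  y <- cohort_table[[target]]
  rows <- lapply(seq_along(covariates), function(i) {
    res <- perm_cor_test(cohort_table[[covariates[i]]], y,
                         n_perm = n_perm, seed = seed + i)
    tibble::tibble(covariate = covariates[i], r = res$r, p = res$p,
                   n = res$n, constant = res$constant)
  })
  do.call(rbind, rows)
}

#' Group contrasts for a fitted cohort
#'
#' Convenience wrapper: joins a per-subject fit table with group labels and
#' contrasts the recovered learning rate, recovered exploration parameter
#' and overall accuracy between groups. Block-wise accuracy contrasts get a
#' Bonferroni factor of 8 in the reported adjusted p.
#'
#' @param fits Fit table from [fit_subjects()].
#' @param subjects Subject table with `subject_id` and `group`.
#' @param trials Long trial table (for accuracy measures).
#' @inheritParams compare_groups
#' @return A tibble of [compare_groups()] rows (one per measure), plus
#'   block-wise rows with a `p_adjusted` column.
#' @export
group_report <- function(fits, subjects, trials,
                         method = "permutation", n_perm = 10000L, seed = 1L) {
  df <- merge(fits, subjects[, c("subject_id", "group")], by = "subject_id")
  ctl <- df$group == "CONTROL"
  acc_tab <- block_accuracy_table(trials)
  acc_tab$overall <- rowMeans(as.matrix(acc_tab[, paste0("block", 1:8)]))
  acc <- merge(acc_tab, subjects[, c("subject_id", "group")], by = "subject_id")
  acc_ctl <- acc$group == "CONTROL"
  main <- rbind(
    compare_groups(df$alpha_hat[ctl], df$alpha_hat[!ctl], method,
                   n_perm, seed, measure = "learning_rate"),
    compare_groups(df$beta_hat[ctl], df$beta_hat[!ctl], method,
                   n_perm, seed + 1L, measure = "exploration"),
    compare_groups(acc$overall[acc_ctl], acc$overall[!acc_ctl], method,
                   n_perm, seed + 2L, measure = "overall_accuracy")
  )
  main$p_adjusted <- main$p_value
  blocks <- do.call(rbind, lapply(1:8, function(b) {
    v <- acc[[paste0("block", b)]]
    compare_groups(v[acc_ctl], v[!acc_ctl], method, n_perm, seed + 2L + b,
                   measure = paste0("accuracy_block", b))
  }))
  blocks$p_adjusted <- pmin(1, blocks$p_value * 8)
  rbind(main, blocks)
}
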