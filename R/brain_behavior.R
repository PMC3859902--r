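# Coerce the ROI input (subjects x regions data frame or matrix) and align
# it with the per-subject measure. `measure` may be a bare numeric vector of
# matching length or a data frame with subject_id + one value column.
roi_matrix <- function(roi, measure) {
  if (is.data.frame(roi)) {
    ids <- if ("subject_id" %in% names(roi)) roi$subject_id else rownames(roi)
    m <- as.matrix(roi[, setdiff(names(roi), "subject_id"), drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(roi)
  }
  if (is.data.frame(measure)) {
    if (!"subject_id" %in% names(measure))
      stop("measure data frame needs a subject_id column")
    vcol <- setdiff(names(measure), "subject_id")[1L]
    pos <- match(rownames(m), measure$subject_id)
    if (anyNA(pos)) stop("misaligned subject ids between roi and measure")
    v <- measure[[vcol]][pos]
  } else {
    v <- as.numeric(measure)
    if (length(v) != nrow(m))
      stop("measure length does not match number of roi rows")
  }
  if (!all(is.finite(m))) stop("non-finite roi values")
  if (nrow(m) < 4L) stop("need at least 4 subjects")
  list(m = m, v = v)
}

#' Marginal region-by-region association with a learning measure
#'
#' Pearson correlation of each regional gray-matter value with a per-subject
#' measure (typically the recovered learning rate), with seeded permutation
#' p-values.
#'
#' @param roi Subjects-by-regions values: a matrix with region column names,
#'   or a data frame with a `subject_id` column plus one column per region.
#' @param measure Per-subject values, either a numeric vector aligned with
#'   the rows of `roi` or a data frame with `subject_id` and a value column
#'   (joined by id; misalignment is an error).
#' @param n_perm Number of shuffles of the measure (default 10,000).
#' @param seed Seed for the shuffles.
#' @return A tibble: `region`, `marginal_r`, `marginal_p`, `n`.
#' @export
marginal_association <- function(roi, measure, n_perm = 10000L, seed = 1L) {
  al <- roi_matrix(roi, measure)
  rows <- lapply(seq_len(ncol(al$m)), function(j) {
    res <- perm_cor_test(al$m[, j], al$v, n_perm = n_perm, seed = seed + j)
    tibble::tibble(region = colnames(al$m)[j],
                   marginal_r = res$r, marginal_p = res$p, n = res$n)
  })
  do.call(rbind, rows)
}

#' Partial association of one region, controlling for the others
#'
#' Residual-method partial correlation: both the target region's values and
#' the measure are regressed on the control regions (ordinary least squares
#' with intercept) and the residuals are correlated. Inference is by seeded
#' permutation of the measure residuals. For these dimensions the residual
#' method is algebraically equivalent to the inverse-correlation-matrix
#' formula.
#'
#' @inheritParams marginal_association
#' @param target_region Region whose unique association is tested; all other
#'   columns of `roi` act as controls.
#' @param kappa_max Condition-number threshold on the control design above
#'   which the controls are declared collinear (`collinear = TRUE`,
#'   partial correlation `NA`).
#' @return A one-row tibble: `region`, `partial_r`, `partial_p`, `n`,
#'   `collinear`.
#' @export
partial_association <- function(roi, measure, target_region,
                                n_perm = 10000L, seed = 1L,
                                kappa_max = 1e8) {
  al <- roi_matrix(roi, measure)
  if (!target_region %in% colnames(al$m))
    stop("unknown target region: ", target_region)
  controls <- setdiff(colnames(al$m), target_region)
  if (length(controls) < 1L) stop("need at least one control region")
  n <- nrow(al$m)
  if (n <= length(controls) + 2L)
    stop("need n > number of controls + 2 subjects")
  X <- cbind(1, al$m[, controls, drop = FALSE])
  kap <- tryCatch(kappa(crossprod(scale(al$m[, controls, drop = FALSE])),
                        exact = TRUE),
                  error = function(e) Inf)
  if (!is.finite(kap) || kap > kappa_max || qr(X)$rank < ncol(X)) {
    return(tibble::tibble(region = target_region, partial_r = NA_real_,
                          partial_p = NA_real_, n = n, collinear = TRUE))
  }
  res_t <- stats::lm.fit(X, al$m[, target_region])$residuals
  res_m <- stats::lm.fit(X, al$v)$residuals
  if (stats::sd(res_t) < 1e-12) {
    return(tibble::tibble(region = target_region, partial_r = NA_real_,
                          partial_p = NA_real_, n = n, collinear = TRUE))
  }
  r_obs <- stats::cor(res_t, res_m)
  xs <- as.vector(scale(res_t)); ys <- as.vector(scale(res_m))
  idx <- perm_index_matrix(n, n_perm, seed)
  r_perm <- as.vector(crossprod(xs, matrix(ys[idx], nrow = n))) / (n - 1)
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  tibble::tibble(region = target_region, partial_r = r_obs,
                 partial_p = p, n = n, collinear = FALSE)
}

#' Full marginal + partial association table
#'
#' For every region: its marginal correlation with the measure, and its
#' partial correlation controlling for all other regions. This reproduces
#' the logic of asking whether one region drives a set of correlated
#' structure-behavior associations: a genuine driver survives partialling,
#' correlated bystanders do not.
#'
#' @inheritParams marginal_association
#' @return A tibble: `region`, `marginal_r`, `marginal_p`, `partial_r`,
#'   `partial_p`, `n`, `collinear`.
#' @export
association_table <- function(roi, measure, n_perm = 10000L, seed = 1L) {
  marg <- marginal_association(roi, measure, n_perm = n_perm, seed = seed)
  part <- do.call(rbind, lapply(marg$region, function(rg)
    partial_association(roi, measure, rg, n_perm = n_perm, seed = seed)))
  out <- merge(marg, part[, c("region", "partial_r", "partial_p", "collinear")],
               by = "region", sort = FALSE)
  tibble::as_tibble(out[match(marg$region, out$region), ])
}
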