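# Column-orthonormal contrasts spanning the within-subject differences.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), `/`)
}

# Covariance of the orthonormally transformed level scores.
contrast_covariance <- function(x) {
  C <- orthonormal_contrasts(ncol(x))
  crossprod(C, stats::cov(x)) %*% C
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition of a complete subjects x levels matrix,
#' computed directly from sums of squares: the effect SS over the level
#' means, the error SS as the subject x level interaction, giving
#' `F = MS_effect / MS_error` on `(k - 1, (n - 1)(k - 1))` degrees of
#' freedom and partial eta-squared `SS_effect / (SS_effect + SS_error)`.
#' Sphericity diagnostics (Mauchly test, Greenhouse-Geisser and
#' Huynh-Feldt epsilons with the corrected p-values) are attached.
#'
#' @param x numeric matrix, subjects in rows (n >= 2), factor levels in
#'   columns (k >= 2), no missing cells
#' @return an object of class `rm_anova`
#' @export
rm_anova <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 within-subject levels")
  if (nrow(x) < 2) stop("need at least 2 subjects")
  if (anyNA(x)) stop("complete design required: no missing cells")
  n <- nrow(x)
  k <- ncol(x)
  g <- mean(x)
  ss_effect <- n * sum((colMeans(x) - g)^2)
  ss_subject <- k * sum((rowMeans(x) - g)^2)
  ss_error <- max(sum((x - g)^2) - ss_effect - ss_subject, 0)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  if (ss_effect <= .Machine$double.eps * n * k * max(1, g^2)) {
    F_stat <- 0
    peta <- 0
  } else {
    F_stat <- (ss_effect / df1) / (ss_error / df2)
    peta <- ss_effect / (ss_effect + ss_error)
  }
  mau <- mauchly_test(x)
  eps <- sphericity_epsilons(x)
  structure(list(F = F_stat, df_effect = df1, df_error = df2,
                 p_uncorrected = stats::pf(F_stat, df1, df2,
                                           lower.tail = FALSE),
                 p_gg = stats::pf(F_stat, eps["gg"] * df1, eps["gg"] * df2,
                                  lower.tail = FALSE),
                 p_hf = stats::pf(F_stat, eps["hf"] * df1, eps["hf"] * df2,
                                  lower.tail = FALSE),
                 epsilon_gg = unname(eps["gg"]),
                 epsilon_hf = unname(eps["hf"]),
                 mauchly_W = mau$W, mauchly_p = mau$p,
                 partial_eta_sq = peta,
                 ss = c(effect = ss_effect, subject = ss_subject,
                        error = ss_error),
                 means = colMeans(x), n = n, k = k),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA:", x$k, "levels x", x$n, "subjects\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g, partial eta^2 = %.4g\n",
              x$df_effect, x$df_error, x$F, x$p_uncorrected,
              x$partial_eta_sq))
  cat(sprintf("  Mauchly W = %.4g (p = %.4g); eps: GG = %.4g, HF = %.4g\n",
              x$mauchly_W, x$mauchly_p, x$epsilon_gg, x$epsilon_hf))
  cat(sprintf("  corrected p: GG F(%.3f, %.1f) = %.4g, HF F(%.3f, %.1f) = %.4g\n",
              x$epsilon_gg * x$df_effect, x$epsilon_gg * x$df_error, x$p_gg,
              x$epsilon_hf * x$df_effect, x$epsilon_hf * x$df_error, x$p_hf))
  invisible(x)
}

#' @export
summary.rm_anova <- function(object, ...) {
  data.frame(F = object$F, df_effect = object$df_effect,
             df_error = object$df_error, p = object$p_uncorrected,
             p_gg = object$p_gg, p_hf = object$p_hf,
             epsilon_gg = object$epsilon_gg, epsilon_hf = object$epsilon_hf,
             mauchly_W = object$mauchly_W, mauchly_p = object$mauchly_p,
             partial_eta_sq = object$partial_eta_sq)
}

#' Mauchly test of sphericity
#'
#' Tests the equal-variance-of-differences assumption of the
#' repeated-measures ANOVA from the covariance of orthonormal contrasts:
#' `W = det(A) / (tr(A)/(k-1))^(k-1)` with the standard chi-square
#' approximation for the p-value. With k = 2 sphericity holds
#' automatically (W = 1, p = 1); a singular contrast covariance gives
#' W = 0 with p = 0.
#'
#' @param x subjects x levels matrix
#' @return a list with `W`, `chi2`, `df`, `p`
#' @export
mauchly_test <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (k == 2) return(list(W = 1, chi2 = 0, df = 0L, p = 1))
  A <- contrast_covariance(x)
  q <- k - 1
  W <- det(A) / (sum(diag(A)) / q)^q
  df <- as.integer(k * (k - 1) / 2 - 1)
  if (!is.finite(W) || W <= 0)
    return(list(W = 0, chi2 = Inf, df = df, p = 0))
  nd <- n - 1                          # residual df
  rho <- 1 - (2 * q^2 + q + 2) / (6 * q * nd)
  chi2 <- -nd * rho * log(W)
  # Anderson's approximation: first-order chi-square plus a second-order
  # term (vanishing for k = 3, where (q - 2) = 0)
  w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * k + 2) /
    (288 * (nd * q * rho)^2)
  p1 <- stats::pchisq(chi2, df, lower.tail = FALSE)
  p2 <- stats::pchisq(chi2, df + 4, lower.tail = FALSE)
  list(W = W, chi2 = chi2, df = df, p = p1 + w2 * (p2 - p1))
}

#' Greenhouse-Geisser and Huynh-Feldt sphericity epsilons
#'
#' Degrees-of-freedom deflation factors for the repeated-measures F test
#' when sphericity fails: the Greenhouse-Geisser epsilon from the
#' eigenstructure of the orthonormal-contrast covariance,
#' `(tr A)^2 / ((k-1) tr(A^2))`, bounded in `[1/(k-1), 1]`, and the
#' Huynh-Feldt correction
#' `(n (k-1) eps_gg - 2) / ((k-1)(n - 1 - (k-1) eps_gg))` for n subjects,
#' capped at 1 and never below the Greenhouse-Geisser value.
#'
#' @param x subjects x levels matrix
#' @return named vector `c(gg = , hf = )`
#' @export
sphericity_epsilons <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (k == 2) return(c(gg = 1, hf = 1))
  A <- contrast_covariance(x)
  q <- k - 1
  gg <- sum(diag(A))^2 / (q * sum(A * A))
  hf <- (n * q * gg - 2) / (q * (n - 1 - q * gg))
  c(gg = gg, hf = max(gg, min(1, hf)))
}

#' Bonferroni-adjusted pairwise paired comparisons
#'
#' All `k (k - 1) / 2` paired t tests between factor levels, with each
#' raw p-value multiplied by the number of comparisons (capped at 1).
#'
#' @param x subjects x levels matrix (paired rows)
#' @return a data.frame with one row per level pair: `level_1`, `level_2`,
#'   `mean_diff`, `t`, `df`, `p_raw`, `p_bonferroni`
#' @export
bonferroni_pairwise <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  lv <- colnames(x)
  if (is.null(lv)) lv <- paste0("level", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    d <- x[, i1] - x[, i2]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = nrow(x) - 1),
                 p.value = 1)
    } else {
      tt <- stats::t.test(x[, i1], x[, i2], paired = TRUE)
    }
    data.frame(level_1 = lv[i1], level_2 = lv[i2], mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, m * tt$p.value))
  })
  do.call(rbind, rows)
}

#' Convert percent pupil-size deviations to a millimetre range
#'
#' Given percent deviations of directional group means from the grand
#' mean pupil size, returns the spanned range in millimetres of pupil
#' diameter under a declared arbitrary-unit-to-mm scale: the grand mean
#' corresponds to `pupil_diameter_mm` (5 mm for the artificial pupil), so
#' `range_mm = (max - min) / 100 * pupil_diameter_mm`.
#'
#' @param percent_dev numeric vector of percent deviations
#' @param pupil_diameter_mm assumed true pupil diameter, mm
#' @return range in mm
#' @export
pupil_deviation_range_mm <- function(percent_dev, pupil_diameter_mm = 5) {
  (max(percent_dev) - min(percent_dev)) / 100 * pupil_diameter_mm
}

#' Pupil size versus gaze direction analysis
#'
#' Tests whether measured pupil size depends on gaze direction using the
#' calibration grid's outer-medial and centre coordinates: a horizontal
#' triple (leftmost-middle, centre, rightmost-middle) and a vertical
#' triple (upmost-middle, centre, downmost-middle). Trials are split
#' evenly (seeded random halves) between the two one-way repeated-measures
#' ANOVAs so no trial enters both, avoiding a direction confound. Group
#' means, percent deviations from the grand mean and their mm-equivalent
#' range (via [pupil_deviation_range_mm()]) are reported per axis, with
#' Bonferroni-adjusted pairwise comparisons.
#'
#' @param fixations stacked [extract_fixations()] rows over trials with a
#'   `trial` column and `mean_pupil` values
#' @param grid the planned grid ([calibration_grid()])
#' @param split_seed seed for the even random trial split
#' @param pupil_diameter_mm assumed true pupil diameter for the mm scale
#' @return an object of class `pupil_direction`: per axis the level
#'   means, [rm_anova()], [bonferroni_pairwise()] table, percent
#'   deviations and `range_mm`
#' @export
pupil_direction_analysis <- function(fixations, grid = calibration_grid(),
                                     split_seed = 1,
                                     pupil_diameter_mm = 5) {
  if (!"trial" %in% names(fixations))
    stop("fixations must carry a 'trial' column")
  tg <- unclass(grid)
  x_mid <- stats::median(tg[, 1])
  y_mid <- stats::median(tg[, 2])
  row_idx <- which(tg[, 2] == y_mid)
  col_idx <- which(tg[, 1] == x_mid)
  h_idx <- c(left = row_idx[which.min(tg[row_idx, 1])],
             middle = row_idx[which(tg[row_idx, 1] == x_mid)],
             right = row_idx[which.max(tg[row_idx, 1])])
  v_idx <- c(up = col_idx[which.min(tg[col_idx, 2])],
             middle = col_idx[which(tg[col_idx, 2] == y_mid)],
             down = col_idx[which.max(tg[col_idx, 2])])
  if (length(h_idx) != 3 || length(v_idx) != 3)
    stop("grid lacks the medial/centre coordinates for a direction group")

  trials <- sort(unique(fixations$trial))
  set.seed(child_seed(split_seed, 13L))
  perm <- sample(trials)
  half <- floor(length(trials) / 2)
  split <- list(horizontal = sort(perm[seq_len(half)]),
                vertical = sort(perm[(half + 1):length(trials)]))

  build <- function(idx, trial_ids) {
    m <- sapply(idx, function(ti) {
      vapply(trial_ids, function(tr) {
        v <- fixations$mean_pupil[fixations$trial == tr &
                                    fixations$target_index == ti]
        if (length(v) == 0) NA_real_ else v[1]
      }, numeric(1))
    })
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 2)
      stop("missing direction group: too few complete trials")
    m
  }
  axis_result <- function(m) {
    pct <- 100 * (colMeans(m) / mean(m) - 1)
    list(data = m, means = colMeans(m), anova = rm_anova(m),
         pairwise = bonferroni_pairwise(m), percent_dev = pct,
         range_mm = pupil_deviation_range_mm(pct, pupil_diameter_mm))
  }
  structure(list(horizontal = axis_result(build(h_idx, split$horizontal)),
                 vertical = axis_result(build(v_idx, split$vertical)),
                 split = split, pupil_diameter_mm = pupil_diameter_mm),
            class = "pupil_direction")
}

#' @export
print.pupil_direction <- function(x, ...) {
  for (ax in c("horizontal", "vertical")) {
    r <- x[[ax]]
    cat(ax, "gaze direction (n =", nrow(r$data), "trials):\n")
    cat("  mean pupil [a.u.]: ",
        paste(sprintf("%s %.1f", names(r$means), r$means), collapse = ", "),
        "\n", sep = "")
    cat("  percent deviation: ",
        paste(sprintf("%s %+.3f%%", names(r$percent_dev), r$percent_dev),
              collapse = ", "), "\n", sep = "")
    cat(sprintf("  range: %.3f mm (at %g mm pupil)\n",
                r$range_mm, x$pupil_diameter_mm))
    cat(sprintf("  rm ANOVA: F(%.3f, %.1f) = %.4g, p(GG) = %.3g, partial eta^2 = %.3f\n",
                r$anova$epsilon_gg * r$anova$df_effect,
                r$anova$epsilon_gg * r$anova$df_error,
                r$anova$F, r$anova$p_gg, r$anova$partial_eta_sq))
  }
  invisible(x)
}
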