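## Repeated-measures ANOVA battery: balanced sums-of-squares decompositions
## computed from cell means, with Mauchly-gated Greenhouse-Geisser df
## correction and partial eta squared per effect.

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Greenhouse-Geisser epsilon from within-subject contrast scores
#'
#' `epsilon = tr(S)^2 / (d * tr(S^2))` for the covariance `S` of `d`
#' orthonormal contrast scores; lies in `(1/d, 1]`, equals 1 under
#' sphericity (hence exactly 1 for two-level factors, where `d = 1`).
#'
#' @param z Matrix of contrast scores, subjects in rows.
#' @return Epsilon.
#' @export
gg_epsilon <- function(z) {
  z <- as.matrix(z)
  d <- ncol(z)
  if (d < 2L) return(1)
  S <- stats::cov(z)
  sum(diag(S))^2 / (d * sum(S^2))
}

#' Mauchly's sphericity test from contrast scores
#'
#' Chi-square approximation to Mauchly's W on the covariance of orthonormal
#' within-subject contrasts. Returns `NA` when the test is unavailable
#' (fewer than 2 contrasts, or too few subjects for a nonsingular
#' covariance).
#'
#' @param z Matrix of contrast scores, subjects in rows.
#' @return p-value, or `NA_real_`.
#' @export
mauchly_p <- function(z) {
  z <- as.matrix(z)
  d <- ncol(z)
  n <- nrow(z)
  if (d < 2L || (n - 1L) <= d) return(NA_real_)
  S <- stats::cov(z)
  dt <- det(S)
  tr <- sum(diag(S))
  if (!is.finite(dt) || dt <= 0 || tr <= 0) return(NA_real_)
  W <- dt / (tr / d)^d
  chi <- -((n - 1) - (2 * d^2 + d + 2) / (6 * d)) * log(W)
  df <- d * (d + 1) / 2 - 1
  stats::pchisq(chi, df, lower.tail = FALSE)
}

anova_row <- function(effect, ss_effect, ss_error, df_num, df_den,
                      z = NULL, gg = "mauchly", alpha_mauchly = 0.05) {
  f <- if (ss_effect <= 1e-12) 0 else (ss_effect / df_num) / (ss_error / df_den)
  eps <- if (is.null(z)) 1 else gg_epsilon(z)
  mp <- if (is.null(z)) NA_real_ else mauchly_p(z)
  corrected <- switch(gg,
                      always = !is.null(z) && ncol(as.matrix(z)) >= 2L,
                      never = FALSE,
                      mauchly = !is.na(mp) && mp < alpha_mauchly)
  e <- if (corrected) eps else 1
  p <- stats::pf(f, df_num * e, df_den * e, lower.tail = FALSE)
  data.frame(effect = effect, df_num = df_num, df_den = df_den,
             ss_effect = ss_effect, ss_error = ss_error, f_value = f,
             epsilon_gg = eps, mauchly_p = mp, gg_applied = corrected,
             p_value = p,
             partial_eta_sq = if (ss_effect + ss_error <= 1e-12) 0
                              else ss_effect / (ss_effect + ss_error),
             stringsAsFactors = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA on a subjects-by-conditions matrix. For two
#' conditions the F statistic equals the square of the paired t statistic
#' and sphericity holds trivially (`epsilon_gg = 1`). This is the analysis
#' used to test the stimulus-order effect on per-observer DL estimates (the
#' Type B effect as a main effect of order).
#'
#' @param y Numeric matrix, subjects in rows, conditions in columns.
#' @param effect_name Label for the condition effect.
#' @param gg `"mauchly"` (correct when Mauchly's test is significant),
#'   `"always"`, or `"never"`.
#' @param alpha_mauchly Significance gate for the Mauchly test.
#' @return A one-row data frame (class `anova_result`).
#' @export
rm_anova_1way <- function(y, effect_name = "condition",
                          gg = c("mauchly", "always", "never"),
                          alpha_mauchly = 0.05) {
  gg <- match.arg(gg)
  y <- as.matrix(y)
  if (nrow(y) < 2L) stop("rm_anova_1way: need at least 2 subjects")
  if (ncol(y) < 2L) stop("rm_anova_1way: need at least 2 conditions")
  if (anyNA(y)) stop("rm_anova_1way: missing cells")
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ms_ <- rowMeans(y); mc <- colMeans(y)
  ss_subj <- k * sum((ms_ - grand)^2)
  ss_cond <- n * sum((mc - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  z <- y %*% orthonormal_contrasts(k)
  out <- anova_row(effect_name, ss_cond, ss_err, k - 1, (n - 1) * (k - 1),
                   z = z, gg = gg, alpha_mauchly = alpha_mauchly)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Two-way fully-within repeated-measures ANOVA
#'
#' Both factors vary within subjects; each effect is tested against its own
#' interaction with subjects. Used for the comparison-level-by-stimulus-order
#' analysis of response probabilities, where the slope difference between the
#' orders — the Type B effect — appears as the `A:B` interaction.
#'
#' @param y 3-dimensional array: subjects x levels of factor A x levels of
#'   factor B (e.g. observers x 9 comparisons x 2 orders).
#' @param factor_names Labels for factors A and B.
#' @inheritParams rm_anova_1way
#' @return Data frame (class `anova_result`) with one row per effect: A, B,
#'   and A:B.
#' @export
rm_anova_2way <- function(y, factor_names = c("c", "order"),
                          gg = c("mauchly", "always", "never"),
                          alpha_mauchly = 0.05) {
  gg <- match.arg(gg)
  stopifnot(is.array(y), length(dim(y)) == 3L)
  if (anyNA(y)) stop("rm_anova_2way: missing cells")
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 2L || a < 2L || b < 2L) stop("rm_anova_2way: need >= 2 levels everywhere")
  grand <- mean(y)
  mA <- apply(y, 2, mean); mB <- apply(y, 3, mean)
  mAB <- apply(y, c(2, 3), mean)
  mS <- apply(y, 1, mean)
  mAS <- apply(y, c(1, 2), mean); mBS <- apply(y, c(1, 3), mean)
  ss_A <- n * b * sum((mA - grand)^2)
  ss_B <- n * a * sum((mB - grand)^2)
  dev_AB <- mAB - outer(mA, rep(1, b)) - outer(rep(1, a), mB) + grand
  ss_AB <- n * sum(dev_AB^2)
  ss_S <- a * b * sum((mS - grand)^2)
  dev_AS <- mAS - outer(mS, rep(1, a)) - outer(rep(1, n), mA) + grand
  ss_AS <- b * sum(dev_AS^2)
  dev_BS <- mBS - outer(mS, rep(1, b)) - outer(rep(1, n), mB) + grand
  ss_BS <- a * sum(dev_BS^2)
  ss_tot <- sum((y - grand)^2)
  ss_ABS <- ss_tot - ss_A - ss_B - ss_AB - ss_S - ss_AS - ss_BS
  CA <- orthonormal_contrasts(a); CB <- orthonormal_contrasts(b)
  zA <- mAS %*% CA
  zB <- mBS %*% CB
  zAB <- t(vapply(seq_len(n),
                  function(s) as.numeric(t(CA) %*% y[s, , ] %*% CB),
                  numeric((a - 1) * (b - 1))))
  if ((a - 1) * (b - 1) == 1L) zAB <- matrix(zAB, ncol = 1L)
  out <- rbind(
    anova_row(factor_names[1], ss_A, ss_AS, a - 1, (n - 1) * (a - 1),
              z = zA, gg = gg, alpha_mauchly = alpha_mauchly),
    anova_row(factor_names[2], ss_B, ss_BS, b - 1, (n - 1) * (b - 1),
              z = zB, gg = gg, alpha_mauchly = alpha_mauchly),
    anova_row(paste(factor_names, collapse = ":"), ss_AB, ss_ABS,
              (a - 1) * (b - 1), (n - 1) * (a - 1) * (b - 1),
              z = zAB, gg = gg, alpha_mauchly = alpha_mauchly))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Three-way mixed (split-plot) ANOVA
#'
#' One two-level within-subjects factor (stimulus duration regime) crossed
#' with two two-level between-subjects factors (ISI and stimulus type);
#' subjects are nested in the between cells. Between effects are tested
#' against subjects-within-groups, within effects against the
#' duration-by-subjects-within-groups stratum. With a two-level within
#' factor sphericity holds trivially. Used on the per-observer
#' Weber-fraction Type B effects.
#'
#' @param data Data frame with columns `subject`, `duration` (within, two
#'   levels), `isi`, `stimulus_type` (between, two levels each) and the
#'   response `y`.
#' @return Data frame (class `anova_result`) with seven effect rows.
#' @export
mixed_anova_3way <- function(data) {
  needed <- c("subject", "duration", "isi", "stimulus_type", "y")
  stopifnot(is.data.frame(data), all(needed %in% names(data)))
  data$subject <- as.character(data$subject)
  dlev <- sort(unique(data$duration))
  ilev <- sort(unique(as.character(data$isi)))
  tlev <- sort(unique(as.character(data$stimulus_type)))
  if (length(dlev) != 2L || length(ilev) != 2L || length(tlev) != 2L) {
    stop("mixed_anova_3way: all three factors must have exactly 2 levels")
  }
  # subjects must appear once per duration level, in a single between cell
  tab <- table(data$subject)
  if (any(tab != 2L)) stop("mixed_anova_3way: each subject needs both duration levels")
  grp <- unique(data[, c("subject", "isi", "stimulus_type")])
  if (any(table(grp$subject) != 1L)) {
    stop("mixed_anova_3way: subjects must be nested in one isi x stimulus_type cell")
  }
  cell_n <- table(grp$isi, grp$stimulus_type)
  if (any(cell_n == 0)) stop("mixed_anova_3way: empty between-subject cell")
  if (length(unique(as.integer(cell_n))) != 1L) {
    stop("mixed_anova_3way: unbalanced between-subject cells")
  }
  n_cell <- as.integer(cell_n[1, 1])
  N <- nrow(grp)
  a <- 2L
  y <- data$y
  grand <- mean(y)
  d <- factor(data$duration, levels = dlev)
  i <- factor(as.character(data$isi), levels = ilev)
  tt <- factor(as.character(data$stimulus_type), levels = tlev)
  s <- factor(data$subject)
  m_d <- tapply(y, d, mean); m_i <- tapply(y, i, mean); m_t <- tapply(y, tt, mean)
  m_di <- tapply(y, list(d, i), mean); m_dt <- tapply(y, list(d, tt), mean)
  m_it <- tapply(y, list(i, tt), mean)
  m_dit <- tapply(y, list(d, i, tt), mean)
  m_s <- tapply(y, s, mean)
  # between stratum
  ss_i <- a * (2 * n_cell) * sum((m_i - grand)^2)
  ss_t <- a * (2 * n_cell) * sum((m_t - grand)^2)
  dev_it <- sweep(sweep(m_it, 1, m_i), 2, m_t) + grand
  ss_it <- a * n_cell * sum(dev_it^2)
  ss_between_subj <- a * sum((m_s - grand)^2)
  ss_subj_w <- ss_between_subj - ss_i - ss_t - ss_it
  df_subj_w <- N - 4L
  # within stratum
  ss_d <- N * sum((m_d - grand)^2)
  dev_di <- sweep(sweep(m_di, 1, m_d), 2, m_i) + grand
  ss_di <- (2 * n_cell) * sum(dev_di^2)
  dev_dt <- sweep(sweep(m_dt, 1, m_d), 2, m_t) + grand
  ss_dt <- (2 * n_cell) * sum(dev_dt^2)
  dev_dit <- m_dit
  for (jj in 1:2) for (kk in 1:2) for (ll in 1:2) {
    dev_dit[jj, kk, ll] <- m_dit[jj, kk, ll] - m_di[jj, kk] - m_dt[jj, ll] -
      m_it[kk, ll] + m_d[jj] + m_i[kk] + m_t[ll] - grand
  }
  ss_dit <- n_cell * sum(dev_dit^2)
  ss_tot <- sum((y - grand)^2)
  ss_err_w <- ss_tot - ss_i - ss_t - ss_it - ss_subj_w -
    ss_d - ss_di - ss_dt - ss_dit
  df_err_w <- (N - 4L) * (a - 1L)
  out <- rbind(
    anova_row("isi", ss_i, ss_subj_w, 1, df_subj_w),
    anova_row("stimulus_type", ss_t, ss_subj_w, 1, df_subj_w),
    anova_row("isi:stimulus_type", ss_it, ss_subj_w, 1, df_subj_w),
    anova_row("duration", ss_d, ss_err_w, 1, df_err_w),
    anova_row("duration:isi", ss_di, ss_err_w, 1, df_err_w),
    anova_row("duration:stimulus_type", ss_dt, ss_err_w, 1, df_err_w),
    anova_row("duration:isi:stimulus_type", ss_dit, ss_err_w, 1, df_err_w))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Power of the two-level repeated-measures F test
#'
#' Noncentral-F power for a within-subject factor, following the G*Power
#' "ANOVA: repeated measures, within factors" convention: the effect size is
#' `f = sqrt(eta_p_sq / (1 - eta_p_sq))`, the noncentrality is
#' `lambda = f^2 * n * levels / (1 - rm_correlation)` (default assumed
#' correlation among repeated measures 0.5), and power is
#' `P(F' > F_crit)` with `(levels - 1, (n - 1)(levels - 1))` df.
#'
#' @param eta_p_sq Partial eta squared of the effect (in (0, 1)).
#' @param n Number of subjects.
#' @param alpha Type I error rate.
#' @param rm_correlation Assumed correlation among repeated measures.
#' @param levels Number of levels of the within factor.
#' @return Power (probability).
#' @export
power_rm <- function(eta_p_sq, n, alpha = 0.05, rm_correlation = 0.5,
                     levels = 2) {
  stopifnot(is.numeric(eta_p_sq), length(eta_p_sq) == 1L,
            is.numeric(n), n >= 2, levels >= 2,
            alpha > 0, alpha < 1,
            rm_correlation > -1, rm_correlation < 1)
  if (!(eta_p_sq > 0 && eta_p_sq < 1)) {
    stop("power_rm: eta_p_sq must lie strictly in (0, 1)")
  }
  f2 <- eta_p_sq / (1 - eta_p_sq)
  lambda <- f2 * n * levels / (1 - rm_correlation)
  df1 <- levels - 1
  df2 <- (n - 1) * (levels - 1)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}
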