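#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning a tidy one-row
#' result; refuses constant input explicitly.
#'
#' @param values Numeric vector, 3 to 5000 observations, non-constant.
#' @return Data frame with `statistic` (W), `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  if (sd(values) == 0) stopf("Shapiro-Wilk is undefined for constant input")
  ht <- shapiro.test(values)
  data.frame(test = "shapiro_wilk", statistic = unname(ht$statistic),
             p = ht$p.value)
}

# Orthonormal basis of the contrast space of a k-level factor (rows sum
# to zero, rows orthonormal); epsilon is invariant to the basis choice.
orthonormal_contrasts <- function(k) {
  t(qr.Q(qr(stats::contr.helmert(k))))
}

gg_epsilon <- function(C, sigma) {
  S <- C %*% sigma %*% t(C)
  d <- nrow(C)
  tr <- sum(diag(S))
  eps <- tr^2 / (d * sum(S * S))
  min(eps, 1)
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject design with one or two crossed factors (e.g. side
#' of the brain and time), one observation per subject and cell. F ratios
#' come from the classical within-subject decomposition (each effect
#' tested against its own subject-interaction error term). Sphericity is
#' never assumed: for every effect with more than one numerator degree of
#' freedom, both numerator and denominator df are scaled by the
#' Greenhouse-Geisser epsilon estimated from the covariance of the
#' orthonormalized within-subject contrasts; a 2-level factor has
#' epsilon exactly 1.
#'
#' @param data Data frame in long format.
#' @param value,subject Column names of the response and the subject id.
#' @param within Character vector of one or two within-subject factor
#'   column names.
#' @return Data frame with one row per effect: `effect`, `df_num`,
#'   `df_den`, `statistic` (F), `epsilon`, `df_num_gg`, `df_den_gg`,
#'   `p_uncorrected`, `p` (Greenhouse-Geisser corrected).
#' @export
rm_anova_gg <- function(data, value = "value", subject = "subject",
                        within = c("side", "time")) {
  stopifnot(is.data.frame(data))
  if (!all(c(value, subject, within) %in% names(data)))
    stopf("data must contain columns: %s",
          paste(c(value, subject, within), collapse = ", "))
  if (length(within) < 1L || length(within) > 2L)
    stopf("within must name one or two factors")
  subj <- factor(data[[subject]])
  n <- nlevels(subj)
  if (n < 2L) stopf("repeated-measures ANOVA needs at least 2 subjects")
  facs <- lapply(within, function(w) factor(data[[w]]))
  lev <- vapply(facs, nlevels, 0L)
  if (any(lev < 2L)) stopf("each within factor needs at least 2 levels")
  y <- data[[value]]
  if (any(!is.finite(y))) stopf("response contains non-finite values")

  # n x (prod levels) subject-by-cell matrix, first factor varying slowest
  cell <- interaction(rev(facs), lex.order = FALSE)
  counts <- table(subj, cell)
  if (any(counts != 1L))
    stopf("design must be balanced and complete: one value per subject and cell")
  idx <- tapply(seq_along(y), list(subj, cell), identity)
  Y <- matrix(y[unlist(idx)], nrow = n)

  p_tot <- prod(lev)
  sigma <- cov(Y)
  grand <- mean(Y)

  if (length(within) == 1L) {
    a <- lev[1]
    m_a <- colMeans(Y)
    m_s <- rowMeans(Y)
    ss_a <- n * sum((m_a - grand)^2)
    ss_as <- sum((Y - outer(m_s, rep(1, a)) -
                    outer(rep(1, n), m_a) + grand)^2)
    C_a <- orthonormal_contrasts(a)
    eff <- list(list(name = within[1], ss = ss_a, df1 = a - 1,
                     ss_err = ss_as, df2 = (a - 1) * (n - 1),
                     C = C_a))
  } else {
    a <- lev[1]; b <- lev[2]
    # cells ordered with factor 1 slowest: reshape to n x b x a? Build means
    arr <- array(Y, c(n, b, a))  # cell index = (b fastest)
    m_s <- rowMeans(Y)
    m_a <- apply(arr, 3, mean)
    m_b <- apply(arr, 2, mean)
    m_ab <- apply(arr, c(3, 2), mean)        # a x b
    m_sa <- apply(arr, c(1, 3), mean)        # n x a
    m_sb <- apply(arr, c(1, 2), mean)        # n x b
    ss_a <- n * b * sum((m_a - grand)^2)
    ss_b <- n * a * sum((m_b - grand)^2)
    ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
    ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                        outer(rep(1, n), m_a) + grand)^2)
    ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                        outer(rep(1, n), m_b) + grand)^2)
    ss_tot <- sum((Y - grand)^2)
    ss_s <- a * b * sum((m_s - grand)^2)
    ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
    C_a <- orthonormal_contrasts(a)
    C_b <- orthonormal_contrasts(b)
    j_a <- matrix(rep(1 / sqrt(a), a), 1)
    j_b <- matrix(rep(1 / sqrt(b), b), 1)
    eff <- list(
      list(name = within[1], ss = ss_a, df1 = a - 1,
           ss_err = ss_as, df2 = (a - 1) * (n - 1),
           C = kronecker(C_a, j_b)),
      list(name = within[2], ss = ss_b, df1 = b - 1,
           ss_err = ss_bs, df2 = (b - 1) * (n - 1),
           C = kronecker(j_a, C_b)),
      list(name = paste(within, collapse = ":"), ss = ss_ab,
           df1 = (a - 1) * (b - 1), ss_err = ss_abs,
           df2 = (a - 1) * (b - 1) * (n - 1),
           C = kronecker(C_a, C_b)))
  }

  rows <- lapply(eff, function(e) {
    f <- (e$ss / e$df1) / (e$ss_err / e$df2)
    epsv <- if (e$df1 == 1) 1 else gg_epsilon(e$C, sigma)
    data.frame(effect = e$name, df_num = e$df1, df_den = e$df2,
               statistic = f, epsilon = epsv,
               df_num_gg = epsv * e$df1, df_den_gg = epsv * e$df2,
               p_uncorrected = pf(f, e$df1, e$df2, lower.tail = FALSE),
               p = pf(f, epsv * e$df1, epsv * e$df2, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Tukey post-hoc pairwise comparisons
#'
#' All pairwise level comparisons of one factor with studentized-range
#' adjusted p-values. For repeated-measures data (`error = "within"`,
#' the default) the data are collapsed to subject-by-level means and the
#' error term is the factor-by-subject interaction of the one-way RM
#' decomposition. `error = "between"` gives the classical one-way
#' (Tukey-Kramer) test against the pooled within-group variance.
#'
#' @param data Long-format data frame.
#' @param factor_name Column whose levels are compared.
#' @param value Response column name.
#' @param subject Subject column name (required for `error = "within"`).
#' @param error `"within"` or `"between"`.
#' @return Data frame with one row per pair: levels, `diff`, `se`, `q`,
#'   `df`, `p` (adjusted) and `stars`.
#' @export
tukey_posthoc <- function(data, factor_name, value = "value",
                          subject = "subject",
                          error = c("within", "between")) {
  error <- match.arg(error)
  stopifnot(is.data.frame(data))
  if (!all(c(factor_name, value) %in% names(data)))
    stopf("data must contain columns %s and %s", factor_name, value)
  f <- factor(data[[factor_name]])
  k <- nlevels(f)
  if (k < 2L) stopf("Tukey comparisons need at least 2 levels")
  y <- data[[value]]

  if (error == "within") {
    if (!subject %in% names(data))
      stopf("within-subject Tukey requires a subject column")
    s <- factor(data[[subject]])
    cellm <- tapply(y, list(s, f), mean)
    if (any(is.na(cellm))) stopf("design must be complete: every subject at every level")
    n <- nrow(cellm)
    m_l <- colMeans(cellm)
    m_s <- rowMeans(cellm)
    resid <- cellm - outer(m_s, rep(1, k)) - outer(rep(1, n), m_l) + mean(cellm)
    df_err <- (k - 1) * (n - 1)
    ms_err <- sum(resid^2) / df_err
    se_pair <- function(i, j) sqrt(ms_err / n)
  } else {
    ng <- tapply(y, f, length)
    vg <- tapply(y, f, stats::var)
    m_l <- tapply(y, f, mean)
    df_err <- sum(ng) - k
    ms_err <- sum((ng - 1) * vg) / df_err
    se_pair <- function(i, j) sqrt(ms_err / 2 * (1 / ng[i] + 1 / ng[j]))
  }

  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- m_l[j] - m_l[i]
    se <- se_pair(i, j)
    q <- abs(d) / se
    # for two means the studentized range reduces exactly to a t quantity;
    # the closed form also avoids ptukey's NaN at one denominator df
    p <- if (k == 2L) 2 * stats::pt(q / sqrt(2), df_err, lower.tail = FALSE)
         else ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    data.frame(level_1 = levels(f)[i], level_2 = levels(f)[j],
               diff = unname(d), se = unname(se), q = unname(q),
               df = df_err, p = unname(p))
  })
  out <- do.call(rbind, rows)
  out$stars <- ifelse(is.finite(out$p), significance_stars(pmin(out$p, 1)),
                      NA_character_)
  rownames(out) <- NULL
  out
}

#' Paired t-test
#'
#' Wrapper around [stats::t.test()] with an explicit error for
#' zero-variance differences.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @return Data frame with `statistic` (t), `df`, `p`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2L)
    stopf("paired t-test needs two vectors of equal length >= 2")
  d <- values_a - values_b
  if (sd(d) == 0)
    stopf("paired differences have zero variance; t statistic undefined")
  ht <- t.test(values_a, values_b, paired = TRUE)
  data.frame(test = "paired_t", statistic = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value)
}

#' Significance star labels
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001, `****` for
#' p < 0.0001, `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  vapply(p, function(pi) {
    if (pi < 0.0001) "****"
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, "")
}
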