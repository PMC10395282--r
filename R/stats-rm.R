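# Repeated-measures ANOVA with Greenhouse-Geisser correction, adjusted
# partial eta squared, and the jackknife F rescaling.

# orthonormal contrast matrix (k-1 x k) spanning the effect space
.ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- t(C) / sqrt(colSums(C^2))
  C
}

# Greenhouse-Geisser epsilon from the subjects x (effect variables) matrix
.gg_epsilon <- function(D) {
  S <- stats::cov(D)
  k <- ncol(D)
  eps <- sum(diag(S))^2 / (k * sum(S^2))
  min(1, max(1 / k, eps))
}

#' Repeated-measures ANOVA (1 or 2 within-subject factors)
#'
#' Standard within-subject sums-of-squares partitioning for a complete,
#' balanced design. Greenhouse-Geisser epsilon per effect is the covariance-
#' based estimator on the orthonormalized effect contrasts; both the
#' uncorrected and the GG-corrected p are reported, with the adjusted
#' partial eta squared effect size. For jackknifed inputs
#' (`jackknife = TRUE`) F is rescaled by (n-1)^2.
#'
#' @param values Numeric matrix subjects x cells.
#' @param factors data.frame, one row per cell (column order = `values`
#'   column order), one column per within factor (1 or 2 factors).
#' @param jackknife Set TRUE when `values` are leave-one-subject-out
#'   jackknife scores.
#' @return data.frame of class `AnovaResult`: one row per effect with `F`,
#'   `df_effect`, `df_error`, `epsilon_gg`, `p_uncorrected`, `p_gg`,
#'   `eta_p2`, `adj_eta_p2`, `jackknife`.
#' @export
rm_anova <- function(values, factors, jackknife = FALSE) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3) stop("need at least 3 subjects")
  if (anyNA(values)) stop("missing cells; the design must be complete")
  factors <- as.data.frame(factors)
  if (ncol(factors) < 1 || ncol(factors) > 2)
    stop("1 or 2 within-subject factors supported")
  if (nrow(factors) != ncol(values))
    stop("factors must describe the columns of values")
  fnames <- names(factors)
  levs <- lapply(factors, function(f) unique(as.character(f)))
  ks <- vapply(levs, length, 1L)
  if (prod(ks) != ncol(values))
    stop("design must be complete and balanced (", prod(ks), " cells expected)")

  res <- list()
  push <- function(effect, ssE, dfE, ssErr, dfErr, eps) {
    Fv <- if (ssE <= 1e-12 * max(ssErr, 1)) 0
          else (ssE / dfE) / (ssErr / dfErr)
    if (jackknife) Fv <- Fv / (n - 1)^2
    eta <- Fv * dfE / (Fv * dfE + dfErr)
    res[[length(res) + 1L]] <<- data.frame(
      effect = effect, F = Fv, df_effect = dfE, df_error = dfErr,
      epsilon_gg = eps,
      p_uncorrected = pf(Fv, dfE, dfErr, lower.tail = FALSE),
      p_gg = pf(Fv, eps * dfE, eps * dfErr, lower.tail = FALSE),
      eta_p2 = eta,
      adj_eta_p2 = adjusted_partial_eta_squared(Fv, dfE, dfErr),
      jackknife = jackknife)
  }

  if (length(ks) == 1L) {
    a <- ks[1]
    idx <- match(as.character(factors[[1]]), levs[[1]])
    Y <- values[, order(idx), drop = FALSE]
    m_a <- colMeans(Y); m_s <- rowMeans(Y); m <- mean(Y)
    ss_a <- n * sum((m_a - m)^2)
    resid <- sweep(sweep(Y, 2L, m_a), 1L, m_s) + m
    ss_err <- sum(resid^2)
    eps <- if (a > 2) .gg_epsilon(Y %*% t(.ortho_contrasts(a))) else 1
    push(fnames[1], ss_a, a - 1, ss_err, (a - 1) * (n - 1), eps)
  } else {
    a <- ks[1]; b <- ks[2]
    ia <- match(as.character(factors[[1]]), levs[[1]])
    ib <- match(as.character(factors[[2]]), levs[[2]])
    ord <- order(ia, ib)  # cells ordered A-major, B-minor
    Y <- values[, ord, drop = FALSE]
    arr <- array(Y, dim = c(n, b, a))  # [subject, B, A]
    m_sab <- aperm(arr, c(1, 3, 2))    # [subject, A, B]
    m_sa <- apply(m_sab, c(1, 2), mean)
    m_sb <- apply(m_sab, c(1, 3), mean)
    m_ab <- apply(m_sab, c(2, 3), mean)
    m_a <- rowMeans(m_ab); m_b <- colMeans(m_ab)
    m_s <- rowMeans(m_sa); m <- mean(Y)
    ss_a <- n * b * sum((m_a - m)^2)
    ss_b <- n * a * sum((m_b - m)^2)
    ss_ab <- n * sum((sweep(sweep(m_ab, 1L, m_a), 2L, m_b) + m)^2)
    ss_as <- b * sum((sweep(sweep(m_sa, 2L, m_a), 1L, m_s) + m)^2)
    ss_bs <- a * sum((sweep(sweep(m_sb, 2L, m_b), 1L, m_s) + m)^2)
    dev <- m_sab
    for (s in seq_len(n)) for (i in seq_len(a)) for (j in seq_len(b))
      dev[s, i, j] <- m_sab[s, i, j] - m_ab[i, j] - m_sa[s, i] -
        m_sb[s, j] + m_a[i] + m_b[j] + m_s[s] - m
    ss_abs <- sum(dev^2)
    Ca <- .ortho_contrasts(a); Cb <- .ortho_contrasts(b)
    eps_a <- if (a > 2) .gg_epsilon(m_sa %*% t(Ca)) else 1
    eps_b <- if (b > 2) .gg_epsilon(m_sb %*% t(Cb)) else 1
    Yab <- matrix(aperm(m_sab, c(1, 3, 2)), n)  # subject x (B within A)
    Cab <- kronecker(Ca, Cb)
    eps_ab <- if ((a - 1) * (b - 1) > 1) .gg_epsilon(Yab %*% t(Cab)) else 1
    push(fnames[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1), eps_a)
    push(fnames[2], ss_b, b - 1, ss_bs, (b - 1) * (n - 1), eps_b)
    push(paste(fnames, collapse = ":"), ss_ab, (a - 1) * (b - 1),
         ss_abs, (a - 1) * (b - 1) * (n - 1), eps_ab)
  }
  out <- do.call(rbind, res)
  class(out) <- c("AnovaResult", "data.frame")
  out
}

#' Adjusted partial eta squared
#'
#' Bias-adjusted effect size for repeated-measures F tests:
#' `df1 * (F - 1) / (df1 * F + df2)`, floored at 0 (the raw value is kept in
#' the `"raw"` attribute). Equals 0 at F = 1 and approaches 1 as F grows;
#' never exceeds the unadjusted partial eta squared.
#'
#' @param F F statistic (>= 0).
#' @param df_effect,df_error Degrees of freedom (> 0).
#' @return Adjusted partial eta squared in `[0, 1]`.
#' @export
adjusted_partial_eta_squared <- function(F, df_effect, df_error) {
  if (any(df_effect <= 0) || any(df_error <= 0))
    stop("degrees of freedom must be positive")
  raw <- df_effect * (F - 1) / (df_effect * F + df_error)
  out <- pmax(0, raw)
  attr(out, "raw") <- raw
  out
}

#' Jackknife F correction
#'
#' Rescales an F statistic computed on leave-one-subject-out jackknife
#' scores by (n - 1)^2 to restore nominal inference.
#'
#' @param F_jk F from the jackknife scores.
#' @param n_subjects Number of subjects (>= 3).
#' @return Corrected F.
#' @export
jackknife_f_correction <- function(F_jk, n_subjects) {
  if (n_subjects < 3) stop("jackknife correction needs at least 3 subjects")
  F_jk / (n_subjects - 1)^2
}

#' Simple effects: one-factor ANOVAs within levels of the other factor
#'
#' @param values Subjects x cells matrix.
#' @param factors Two-column cell design as in [rm_anova()].
#' @param by Name of the factor whose levels define the strata.
#' @param jackknife Passed through to [rm_anova()].
#' @return `AnovaResult` data.frame, one row per level of `by`.
#' @export
simple_effects <- function(values, factors, by, jackknife = FALSE) {
  factors <- as.data.frame(factors)
  if (!(by %in% names(factors))) stop("unknown factor: ", by)
  other <- setdiff(names(factors), by)
  if (length(other) != 1) stop("simple effects need a 2-factor design")
  out <- lapply(unique(as.character(factors[[by]])), function(lv) {
    sel <- which(factors[[by]] == lv)
    r <- rm_anova(values[, sel, drop = FALSE],
                  factors[sel, other, drop = FALSE], jackknife = jackknife)
    r$effect <- paste0(other, " | ", by, "=", lv)
    r
  })
  out <- do.call(rbind, out)
  class(out) <- c("AnovaResult", "data.frame")
  out
}
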