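#' Repeated-measures ANOVA for balanced fully-within designs
#'
#' Classical sums-of-squares decomposition for a complete, balanced design
#' with every factor manipulated within subjects and exactly one observation
#' per subject x cell. For each effect E the error term is the E x subject
#' interaction; partial eta squared is `SS_E / (SS_E + SS_error)`. For
#' effects with two or more numerator degrees of freedom, sphericity is
#' assessed with Mauchly's test and, when it rejects (or always, per
#' `correction`), both degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon before the p-value is computed.
#'
#' @param data Long data frame.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param factors Character vector of within-subject factor column names.
#' @param correction `"conditional"` (Greenhouse-Geisser when Mauchly
#'   rejects at `sphericity_alpha`), `"always"`, or `"never"`.
#' @param sphericity_alpha Mauchly rejection level for the conditional rule.
#' @return Data frame of class `imk_anova` with one row per effect:
#'   `effect`, `F`, `df_num`, `df_den` (fractional after correction), `p`,
#'   `partial_eta_sq`, `epsilon` (1 when uncorrected), `sphericity_p`.
#' @export
rm_anova <- function(data, dv, subject, factors,
                     correction = c("conditional", "always", "never"),
                     sphericity_alpha = 0.05) {
  correction <- match.arg(correction)
  data <- as.data.frame(data)
  for (v in c(dv, subject, factors))
    if (!v %in% names(data)) stop("column not found: ", v, call. = FALSE)
  data[[subject]] <- factor(data[[subject]])
  for (f in factors) data[[f]] <- factor(data[[f]])
  subj_lv <- levels(data[[subject]])
  fac_lv <- lapply(factors, function(f) levels(data[[f]]))
  names(fac_lv) <- factors
  n_subj <- length(subj_lv)
  if (n_subj < 2) stop("need at least 2 subjects", call. = FALSE)

  # completeness: exactly one observation per subject x cell
  cell_key <- interaction(data[c(subject, factors)], drop = FALSE)
  cnt <- table(cell_key)
  if (any(cnt == 0)) {
    bad <- names(cnt)[cnt == 0][1]
    stop("missing cell: ", bad, " — the design must be complete",
         call. = FALSE)
  }
  if (any(cnt > 1))
    stop("more than one observation per subject x cell; aggregate first",
         call. = FALSE)

  y <- data[[dv]]
  N <- length(y)
  vars <- c(subject, factors)
  k_lv <- c(n_subj, vapply(fac_lv, length, integer(1)))
  names(k_lv) <- vars

  # effect estimates by inclusion-exclusion over subsets, memoized by size
  est <- list()
  est[["(grand)"]] <- mean(y)
  subsets <- unlist(lapply(seq_along(vars), function(k)
    utils::combn(vars, k, simplify = FALSE)), recursive = FALSE)
  key_of <- function(s) paste(sort(s), collapse = ":")
  means_over <- function(s) {
    tapply(y, data[s], mean)
  }
  for (s in subsets) {
    m <- means_over(s)
    e <- m - est[["(grand)"]]
    if (length(s) > 1) {
      for (k in seq_len(length(s) - 1)) {
        for (u in utils::combn(s, k, simplify = FALSE)) {
          eu <- est[[key_of(u)]]
          # broadcast the sub-effect over the dimensions of s
          perm <- match(u, s)
          full <- array(0, dim = dim(m), dimnames = dimnames(m))
          idx <- do.call(expand.grid, dimnames(m))
          full[] <- as.vector(eu[as.matrix(idx[, perm, drop = FALSE])])
          e <- e - full
        }
      }
    }
    est[[key_of(s)]] <- e
  }
  ss_of <- function(s) (N / prod(k_lv[s])) * sum(est[[key_of(s)]]^2)
  df_of <- function(s) prod(k_lv[s] - 1L)

  # wide response matrix for sphericity (subjects x cells, cells in the
  # Kronecker order of `factors`)
  cells <- expand.grid(rev(fac_lv), stringsAsFactors = FALSE)
  cells <- cells[, rev(seq_along(factors)), drop = FALSE]
  names(cells) <- factors
  wide <- matrix(NA_real_, n_subj, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, N)
    for (f in factors) sel <- sel & data[[f]] == cells[[f]][i]
    wide[match(data[[subject]][sel], subj_lv), i] <- y[sel]
  }

  orth_contr <- function(k) {
    q <- qr.Q(qr(stats::contr.helmert(k)))
    q
  }
  effect_contrast <- function(eff) {
    C <- matrix(1, 1, 1)
    for (f in factors) {
      k <- length(fac_lv[[f]])
      M <- if (f %in% eff) orth_contr(k) else matrix(1 / k, k, 1)
      C <- C %x% M
    }
    C
  }

  fac_subsets <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(fac_subsets, function(eff) {
    ss_e <- ss_of(eff); df_e <- df_of(eff)
    err <- c(subject, eff)
    ss_r <- ss_of(err); df_r <- df_of(err)
    Fv <- (ss_e / df_e) / (ss_r / df_r)
    # degenerate designs: a null effect is F = 0 even when the error SS
    # also vanishes
    if (!is.finite(Fv)) Fv <- if (ss_e <= 1e-20) 0 else Inf
    eps <- 1; sph_p <- NA_real_
    if (df_e >= 2) {
      C <- effect_contrast(eff)
      S <- stats::cov(wide %*% C)
      d <- ncol(S)
      tr <- sum(diag(S)); tr2 <- sum(S * S)
      eps_gg <- max(tr^2 / (d * tr2), 1 / d)
      detS <- det(S)
      W <- if (detS <= 0) 0 else detS / ((tr / d)^d)
      if (W > 0 && n_subj - 1 > 0) {
        fcorr <- 1 - (2 * d^2 + d + 2) / (6 * d * (n_subj - 1))
        x2 <- -(n_subj - 1) * fcorr * log(W)
        sph_p <- stats::pchisq(x2, d * (d + 1) / 2 - 1, lower.tail = FALSE)
      } else sph_p <- 0
      apply_gg <- switch(correction,
                         conditional = !is.na(sph_p) && sph_p < sphericity_alpha,
                         always = TRUE, never = FALSE)
      if (apply_gg) eps <- eps_gg
    }
    data.frame(effect = paste(eff, collapse = ":"), F = Fv,
               df_num = df_e * eps, df_den = df_r * eps,
               p = stats::pf(Fv, df_e * eps, df_r * eps, lower.tail = FALSE),
               partial_eta_sq = ss_e / (ss_e + ss_r),
               epsilon = eps, sphericity_p = sph_p)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("imk_anova", "data.frame")
  out
}

#' Multiple-comparison correction bookkeeping
#'
#' Bonferroni division of the family alpha by the number of tests; the
#' display value is rounded half away from zero to 4 decimals, so an alpha
#' of 0.05 over the 8 trackers displays as 0.0063.
#'
#' @param family_alpha Family-wise alpha.
#' @param n_tests Number of tests in the family.
#' @return List with `family_alpha`, `n_tests`, `corrected_alpha` (exact)
#'   and `corrected_alpha_display` (4-decimal display convention).
#' @export
multiple_comparisons <- function(family_alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  ca <- family_alpha / n_tests
  list(family_alpha = family_alpha, n_tests = as.integer(n_tests),
       corrected_alpha = ca,
       corrected_alpha_display = sign(ca) * floor(abs(ca) * 1e4 + 0.5) / 1e4)
}

#' Post-hoc paired t-tests with Bonferroni control
#'
#' Two-tailed paired t for each comparison; a comparison is flagged
#' significant when its p-value falls below the Bonferroni-corrected alpha.
#'
#' @param pairs Named list of comparisons; each element is a list with
#'   numeric vectors `x` and `y` (paired, equal length).
#' @param mc Output of [multiple_comparisons()].
#' @return Data frame with `comparison`, `t`, `df`, `p`, `g_rm`,
#'   `significant`.
#' @export
posthoc_t <- function(pairs, mc = multiple_comparisons(0.05, length(pairs))) {
  rows <- lapply(names(pairs), function(nm) {
    x <- pairs[[nm]]$x; y <- pairs[[nm]]$y
    if (length(x) != length(y) || length(x) < 3)
      stop("paired samples of equal length >= 3 required for ", nm,
           call. = FALSE)
    d <- x - y
    n <- length(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      t <- mean(d) / (sdd / sqrt(n))
    }
    p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
    g <- suppressWarnings(hedges_g_rm(x, y))
    data.frame(comparison = nm, t = t, df = n - 1, p = p, g_rm = g$g_rm,
               significant = p < mc$corrected_alpha)
  })
  do.call(rbind, rows)
}

#' Hedges' g for repeated-measures comparisons
#'
#' Small-sample-corrected standardized effect size for paired designs:
#' `g_rm = [(m1 - m2) / sqrt(s1^2 + s2^2 - 2 r s1 s2)] * sqrt(2 (1 - r)) *
#' J(n - 1)` with the correction `J(v) = 1 - 3 / (4 v - 1)` and `r` the
#' correlation between the paired condition scores.
#'
#' @param x1,x2 Paired numeric vectors (n >= 3).
#' @return List with `g_rm` and `r_pair`; `g_rm` is `NA` with a warning
#'   when the denominator is zero (identical difference scores).
#' @export
hedges_g_rm <- function(x1, x2) {
  n <- length(x1)
  if (length(x2) != n || n < 3)
    stop("paired samples of equal length >= 3 required", call. = FALSE)
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  r <- if (s1 > 0 && s2 > 0) stats::cor(x1, x2) else 0
  denom_sq <- s1^2 + s2^2 - 2 * r * s1 * s2
  if (denom_sq <= 0) {
    warning("zero denominator: effect size undefined")
    return(list(g_rm = NA_real_, r_pair = r))
  }
  J <- 1 - 3 / (4 * (n - 1) - 1)
  g <- (mean(x1) - mean(x2)) / sqrt(denom_sq) * sqrt(2 * (1 - r)) * J
  list(g_rm = g, r_pair = r)
}
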