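# Two-group differential expression with empirical-Bayes variance moderation.
#
# Per gene, an ordinary two-sample fit gives the case-minus-control mean
# difference, the pooled residual variance s^2 and its degrees of freedom.
# The gene-wise variances are then shrunk toward a scaled inverse-chi-square
# prior (d0, s0^2) fitted by the method of moments on log s^2: the mean and
# variance of log s^2 are matched to their digamma/trigamma expressions, the
# trigamma equation solved by monotone Newton root-finding. The moderated
# statistic
#   t_mod = mean_diff / sqrt(s2_post * (1/n1 + 1/n2)),
#   s2_post = (d0 * s0^2 + df * s^2) / (d0 + df)
# is referred to a t distribution with d0 + df degrees of freedom (normal
# when d0 is infinite); p-values are Benjamini-Hochberg adjusted.

#' Auto-detect linear-scale intensities and log2-transform
#'
#' If the 99th-percentile value exceeds 50 the matrix is treated as raw
#' linear intensities and `log2(x + 1)` is applied (logged loudly);
#' otherwise the study is returned unchanged. Negative values together with
#' linear-scale detection are an error.
#'
#' @param study an [expression_study()].
#' @return An [expression_study()], possibly log2-transformed.
#' @export
maybe_log2 <- function(study) {
  q99 <- stats::quantile(study$values, 0.99, names = FALSE)
  if (q99 <= 50) return(study)
  if (any(study$values < 0)) {
    stop_an("matrix looks linear-scale (99th percentile ", signif(q99, 4),
            ") but contains negative values; transform manually")
  }
  an_log("values look linear-scale (99th percentile ", signif(q99, 4),
         "); applying log2(x + 1)")
  expression_study(log2(study$values + 1), study$groups)
}

#' Per-gene two-group fit
#'
#' @param study an [expression_study()].
#' @return data.frame `(gene, mean_diff, s2, df_resid)` where `mean_diff` is
#'   case minus control, `s2` the pooled within-group variance and
#'   `df_resid = n_case + n_control - 2`. A constant gene passes through with
#'   `s2 = 0` (moderation rescues it downstream).
#' @export
two_group_fit <- function(study) {
  case <- study$values[, study$groups == "case", drop = FALSE]
  ctrl <- study$values[, study$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  mean_diff <- rowMeans(case) - rowMeans(ctrl)
  ss1 <- rowSums((case - rowMeans(case))^2)
  ss2 <- rowSums((ctrl - rowMeans(ctrl))^2)
  df <- n1 + n2 - 2L
  data.frame(gene = study$genes, mean_diff = unname(mean_diff),
             s2 = unname((ss1 + ss2) / df), df_resid = df,
             n_case = n1, n_control = n2,
             stringsAsFactors = FALSE)
}

# solve trigamma(x) = y for x > 0; trigamma is strictly decreasing
#' @noRd
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (x <= 0) x <- 1e-8
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior (d0 degrees of freedom, scale
#' s0^2) to the observed gene-wise variances by moment matching on
#' `log(s2)`. If the empirical variance of log s2 does not exceed the
#' sampling variance `trigamma(df/2)` there is no excess dispersion and
#' `d0 = Inf` (complete shrinkage to a common variance).
#'
#' @param s2 numeric vector of gene-wise residual variances; zeros are
#'   excluded from fitting. At least 10 positive values required.
#' @param df_resid residual degrees of freedom (scalar, shared by all genes).
#' @return An `ebayes_prior` list with `d0` and `s0_sq`.
#' @export
estimate_prior <- function(s2, df_resid) {
  pos <- s2[is.finite(s2) & s2 > 0]
  if (length(pos) < 10L) {
    stop_an("need at least 10 genes with positive variance to fit the prior")
  }
  z <- log(pos)
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df_resid / 2)
  if (evar <= 0) {
    prior <- list(d0 = Inf, s0_sq = exp(emean))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = d0, s0_sq = s0_sq)
  }
  structure(prior, class = "ebayes_prior")
}

#' Moderated t-statistics and the DEG table
#'
#' @param fit data.frame from [two_group_fit()].
#' @param prior an `ebayes_prior` from [estimate_prior()]; `d0 = 0` turns
#'   moderation off and reproduces the ordinary pooled t-test exactly.
#' @param threshold adjusted-p cutoff defining `is_deg` (default 0.05).
#' @return data.frame `(gene, mean_diff, s2, t_mod, df_total, p, p_adj,
#'   is_deg)` sorted by p then gene id.
#' @export
moderated_t <- function(fit, prior, threshold = 0.05) {
  d0 <- prior$d0
  df <- fit$df_resid
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s0_sq, nrow(fit))
  } else if (d0 == 0) {
    fit$s2
  } else {
    (d0 * prior$s0_sq + df * fit$s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / fit$n_case + 1 / fit$n_control))
  t_mod <- fit$mean_diff / se
  t_mod[se == 0 & fit$mean_diff == 0] <- 0
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[is.infinite(t_mod)] <- 0
  p_adj <- bh_adjust(p)
  out <- data.frame(gene = fit$gene, mean_diff = fit$mean_diff, s2 = fit$s2,
                    t_mod = t_mod, df_total = df_total, p = p, p_adj = p_adj,
                    is_deg = p_adj < threshold, stringsAsFactors = FALSE)
  out[order(out$p, out$gene), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated front door to `stats::p.adjust(method = "BH")`: inputs must lie
#' in (0, 1] (a p-value of exactly 0 is only produced internally for
#' infinite test statistics and is accepted).
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values in input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_an("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Full differential-expression analysis of a study
#'
#' Convenience wrapper: [maybe_log2()] then [two_group_fit()],
#' [estimate_prior()] and [moderated_t()].
#'
#' @param study an [expression_study()].
#' @param threshold adjusted-p DEG cutoff (default 0.05).
#' @return DEG table as from [moderated_t()].
#' @export
run_diffexp <- function(study, threshold = 0.05) {
  study <- maybe_log2(study)
  fit <- two_group_fit(study)
  prior <- estimate_prior(fit$s2, fit$df_resid[1L])
  moderated_t(fit, prior, threshold = threshold)
}
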