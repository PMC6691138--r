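# Survey-weighted estimation under a stratified design with >=2 PSUs per
# stratum: Taylor-linearized means, threshold shares, and the 10%
# relative-change significance rule.

#' Specify a stratified PSU survey design
#'
#' @param weights Positive survey weights, one per participant.
#' @param strata Stratum labels.
#' @param psu Primary sampling unit labels (nested within strata).
#' @return Object of class `survey_design_spec` (a data frame).
#' @export
survey_design <- function(weights, strata, psu) {
  stopifnot(length(weights) == length(strata), length(strata) == length(psu))
  if (any(weights <= 0)) stopf("survey weights must be positive")
  d <- data.frame(weight = weights, stratum = as.character(strata),
                  psu = as.character(psu), stringsAsFactors = FALSE)
  npsu <- tapply(d$psu, d$stratum, function(x) length(unique(x)))
  if (any(npsu < 2))
    stopf("stratum '%s' has a single PSU; variance cannot be estimated (collapse strata)",
          names(npsu)[npsu < 2][1])
  class(d) <- c("survey_design_spec", "data.frame")
  d
}

#' Survey-weighted mean with Taylor-linearized confidence interval
#'
#' The mean is the ratio estimator `sum(w x) / sum(w)`.  Its variance is
#' estimated by Taylor linearization: the linearized residuals
#' `z_i = w_i (x_i - mean) / sum(w)` are totalled per PSU, and the variance is
#' the sum over strata of `n_h / (n_h - 1)` times the squared deviations of
#' PSU totals from their stratum mean.  The confidence interval uses a normal
#' reference (`mean +/- 1.96 SE` at the default level).
#'
#' Subpopulations are handled as estimation domains: observations outside
#' `domain` (or with `NA` values) contribute zero residual but their PSUs
#' remain in the variance computation, so the design structure is retained.
#'
#' @param x Numeric outcome, aligned with the design rows.
#' @param design A [survey_design()].
#' @param domain Optional logical vector selecting a subpopulation.
#' @param conf_mult Critical multiplier for the interval (1.96 default).
#' @return One-row data frame of class `survey_estimate`: `mean`, `se`,
#'   `ci_low`, `ci_high`, `n` (domain size).
#' @export
survey_mean_ci <- function(x, design, domain = NULL, conf_mult = 1.96) {
  stopifnot(inherits(design, "survey_design_spec"),
            length(x) == nrow(design))
  d <- if (is.null(domain)) rep(TRUE, length(x)) else domain
  stopifnot(length(d) == length(x))
  d <- d & !is.na(x)
  if (!any(d)) stopf("empty estimation domain")
  w <- design$weight * d
  xs <- ifelse(d, x, 0)
  W <- sum(w)
  est <- sum(w * xs) / W
  z <- w * (xs - est) / W  # zero outside the domain
  psu_tot <- tapply(z, list(design$stratum, design$psu), sum, default = 0)
  var_est <- 0
  for (h in rownames(psu_tot)) {
    th <- psu_tot[h, ]
    th <- th[!is.na(th)]
    # PSUs not occurring in stratum h are structural, not observed zeros
    present <- unique(design$psu[design$stratum == h])
    th <- th[names(th) %in% present]
    nh <- length(th)
    var_est <- var_est + nh / (nh - 1) * sum((th - mean(th))^2)
  }
  se <- sqrt(var_est)
  out <- data.frame(mean = est, se = se, ci_low = est - conf_mult * se,
                    ci_high = est + conf_mult * se, n = sum(d))
  class(out) <- c("survey_estimate", "data.frame")
  out
}

#' Survey-weighted share of persons at or above a threshold
#'
#' Weighted proportion with `value >= threshold`, with the same linearized
#' variance and domain semantics as [survey_mean_ci()].
#'
#' @inheritParams survey_mean_ci
#' @param values Numeric outcome per person.
#' @param threshold Threshold defining the share.
#' @return A `survey_estimate` for the proportion.
#' @export
share_above_threshold <- function(values, design, threshold, domain = NULL,
                                  conf_mult = 1.96) {
  survey_mean_ci(as.numeric(values >= threshold), design, domain = domain,
                 conf_mult = conf_mult)
}

#' Ten-percent relative-change significance rule
#'
#' Because large surveys make even trivial differences statistically
#' significant, a modeled-versus-observed difference is flagged only when it
#' is both materially large and statistically reliable: the relative change
#' must exceed `margin` (strictly: a change of exactly 10% is not flagged),
#' and a Wald test that the absolute difference exceeds `margin` times the
#' observed mean (combined SE, normal reference) must reject at `alpha`.
#'
#' @param observed,modeled `survey_estimate` rows for the same outcome.
#' @param margin Relative-change threshold (fraction, default 0.10).
#' @param alpha Significance level.
#' @return List: `relative_change`, `p_value`, `significant`, `evaluable`.
#' @export
relative_change_test <- function(observed, modeled, margin = 0.10,
                                 alpha = 0.05) {
  if (observed$mean == 0)
    return(list(relative_change = NA_real_, p_value = NA_real_,
                significant = FALSE, evaluable = FALSE))
  rel <- (modeled$mean - observed$mean) / observed$mean
  se <- sqrt(observed$se^2 + modeled$se^2)
  stat <- abs(modeled$mean - observed$mean) - margin * abs(observed$mean)
  p <- if (se > 0) min(1, 2 * stats::pnorm(stat / se, lower.tail = FALSE))
       else as.numeric(stat <= 0)  # degenerate SEs: 0 if beyond margin, 1 otherwise
  list(relative_change = rel, p_value = p,
       significant = abs(rel) > margin && p < alpha, evaluable = TRUE)
}
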