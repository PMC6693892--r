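#' One-sample t-test against a reference level
#'
#' Thin wrapper around the classical one-sample t statistic, used to test
#' decoding accuracies against the theoretical 50% chance level and RSA
#' betas against zero.
#'
#' @param values numeric vector (n >= 2).
#' @param popmean reference mean (e.g. 0.5 for chance).
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
one_sample_t <- function(values, popmean = 0.5,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0)
    stop("zero variance: t statistic undefined", call. = FALSE)
  ht <- stats::t.test(values, mu = popmean, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Paired t-test with Cohen's d
#'
#' Paired t on the within-subject differences, with the paired effect size
#' \eqn{d_z = \bar{d}/s_d} by default (\code{method = "pooled"} divides by
#' the pooled SD of the two conditions instead). Zero-variance differences
#' with a non-zero mean are flagged as an infinite effect size.
#'
#' @param values_a,values_b paired numeric vectors of equal length (n >= 2).
#' @param method effect-size denominator, \code{"dz"} or \code{"pooled"}.
#' @return list with \code{t}, \code{df}, \code{p}, \code{cohens_d}.
#' @export
paired_t_with_d <- function(values_a, values_b, method = c("dz", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1, p = 1, cohens_d = 0))
    warning("zero-variance differences: effect size infinite")
    return(list(t = Inf, df = length(d) - 1, p = 0,
                cohens_d = sign(mean(d)) * Inf))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  denom <- if (method == "dz") sdd
           else sqrt((stats::var(values_a) + stats::var(values_b)) / 2)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), cohens_d = mean(d) / denom)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA on a complete, balanced long table. Each
#' effect's F is reported with Greenhouse-Geisser (or Huynh-Feldt)
#' epsilon-corrected degrees of freedom; effects with a single numerator
#' degree of freedom satisfy sphericity automatically (epsilon = 1).
#' Fitting is delegated to the multivariate linear-model machinery of
#' \pkg{car}.
#'
#' @param data long-format data frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor columns.
#' @param subject name of the subject identifier column.
#' @param correction \code{"greenhouse-geisser"} or \code{"huynh-feldt"}.
#' @return data frame with one row per effect: \code{effect}, \code{F},
#'   \code{df1}, \code{df2} (epsilon-multiplied, possibly fractional),
#'   \code{epsilon}, \code{p} (corrected), \code{p_uncorrected}.
#' @export
rm_anova <- function(data, dv, within, subject = "subject",
                     correction = c("greenhouse-geisser", "huynh-feldt")) {
  correction <- match.arg(correction)
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])

  cells <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  tab <- table(data[[subject]], cells)
  if (any(tab != 1))
    stop("design must be complete and balanced: one observation per ",
         "subject and within-cell", call. = FALSE)

  ord <- order(data[[subject]], cells)
  d <- data[ord, ]
  wide <- matrix(d[[dv]], nrow = nlevels(data[[subject]]), byrow = TRUE)
  # columns of 'wide' follow the lex.order interaction; rebuild idata to match
  idata <- expand.grid(lapply(rev(within), function(w) levels(data[[w]])),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = TRUE)
  names(idata) <- rev(within)
  idata <- idata[, within, drop = FALSE]

  mlm <- stats::lm(wide ~ 1)
  aov_res <- car::Anova(mlm, idata = idata,
                        idesign = stats::as.formula(
                          paste("~", paste(within, collapse = "*"))),
                        type = "III")
  s <- suppressWarnings(summary(aov_res, multivariate = FALSE))
  uni <- s$univariate.tests
  effects <- setdiff(rownames(uni), "(Intercept)")
  eps_tab <- s$pval.adjustments
  eps_col <- if (correction == "greenhouse-geisser") "GG eps" else "HF eps"

  out <- do.call(rbind, lapply(effects, function(e) {
    f <- uni[e, "F value"]
    df1 <- uni[e, "num Df"]
    df2 <- uni[e, "den Df"]
    p_unc <- uni[e, "Pr(>F)"]
    eps <- 1
    if (!is.null(eps_tab) && e %in% rownames(eps_tab)) {
      eps <- min(1, eps_tab[e, eps_col])
      if (!is.finite(eps)) eps <- 1  # 1-df effects: sphericity automatic
    }
    p_corr <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    data.frame(effect = e, F = f, df1 = eps * df1, df2 = eps * df2,
               epsilon = eps, p = p_corr, p_uncorrected = p_unc,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Linear trend of group means across ordered ROIs
#'
#' Ordinary least squares of per-ROI group means on the ROI ordinal
#' position (1, 2, ...), testing for a monotone gradient along the visual
#' hierarchy.
#'
#' @param group_means numeric vector of means, in hierarchy order (>= 3).
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{r_squared}, \code{slope}.
#' @export
linear_trend <- function(group_means) {
  n <- length(group_means)
  stopifnot(n >= 3)
  idx <- seq_len(n)
  fit <- stats::lm(group_means ~ idx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((group_means - mean(group_means))^2)
  if (ss_tot == 0)
    return(list(F = 0, df1 = 1, df2 = n - 2, p = 1, r_squared = 0, slope = 0))
  r2 <- 1 - ss_res / ss_tot
  f <- (ss_tot - ss_res) / (ss_res / (n - 2))
  list(F = f, df1 = 1, df2 = n - 2,
       p = stats::pf(f, 1, n - 2, lower.tail = FALSE),
       r_squared = r2, slope = unname(stats::coef(fit)[2]))
}
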