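#' Two-tailed paired t test on matched FF/FFPE summary values
#'
#' The per-pair differences are `ffpe - ff`; `t = mean(d) / (sd(d)/sqrt(n))`
#' with `n - 1` degrees of freedom.  When every difference is exactly zero
#' the statistic is degenerate and the two-sided p value is reported as 1;
#' a constant non-zero difference (zero variance, non-zero mean) is an
#' error.
#'
#' @param ff_values,ffpe_values equal-length paired numeric vectors, n >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t_test <- function(ff_values, ffpe_values) {
  stopifnot(length(ff_values) == length(ffpe_values),
            length(ff_values) >= 2)
  d <- ffpe_values - ff_values
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1))
    stop_config("paired differences have zero variance but non-zero mean")
  }
  ht <- t.test(ffpe_values, ff_values, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way ANOVA with Dunnett comparisons against a control group
#'
#' Classical one-way ANOVA (F and p) followed by Dunnett-adjusted
#' comparisons of every other group against the control.  The adjustment
#' uses a seeded Monte-Carlo estimate of the null distribution of the
#' maximum absolute Dunnett statistic (group-mean contrasts studentized by
#' the pooled error variance), so results are deterministic given the seed;
#' with a single comparison it reduces to an unadjusted pooled two-sample t
#' test up to Monte-Carlo error.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param control_index index of the control group in `groups`.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param ndraws number of Monte-Carlo draws (default 1e5).
#' @return list with `F`, `p_anova`, `comparisons` (data.frame `group, diff,
#'   t, p_adj`), and `degenerate` flag (any zero-variance group of size 2,
#'   or all groups constant).
#' @export
anova_dunnett <- function(groups, control_index = 1L, seed = 1L,
                          ndraws = 1e5) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2))
    stop_config("every group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  degenerate <- any(vapply(groups, function(v) length(v) == 2 && var(v) == 0,
                           logical(1)))
  if (var(y) == 0) {  # all observations identical: F = 0 path
    others <- setdiff(seq_along(groups), control_index)
    return(list(F = 0, p_anova = 1,
                comparisons = data.frame(group = names(groups)[others],
                                         diff = 0, t = 0, p_adj = 1,
                                         stringsAsFactors = FALSE),
                degenerate = TRUE))
  }
  fit <- lm(y ~ g)
  an <- anova(fit)
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]
  Fstat <- an[["F value"]][1]
  p_anova <- an[["Pr(>F)"]][1]
  if (is.nan(Fstat) || mse == 0) {   # all groups identical constants
    Fstat <- 0; p_anova <- 1; mse <- 0
    degenerate <- TRUE
  }
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  ci <- control_index
  others <- setdiff(seq_along(groups), ci)
  se <- sqrt(pmax(mse, .Machine$double.eps) * (1 / ns[others] + 1 / ns[ci]))
  tstat <- (means[others] - means[ci]) / se
  p_adj <- with_substream(seed, "dunnett_mc", {
    k <- length(others)
    zc <- rnorm(ndraws, 0, sqrt(1 / ns[ci]))
    s2 <- rchisq(ndraws, df_err) / df_err
    maxT <- rep(0, ndraws)
    Tmat <- matrix(0, ndraws, k)
    for (j in seq_len(k)) {
      zj <- rnorm(ndraws, 0, sqrt(1 / ns[others[j]]))
      Tmat[, j] <- (zj - zc) / sqrt(s2 * (1 / ns[others[j]] + 1 / ns[ci]))
    }
    maxT <- apply(abs(Tmat), 1, max)
    vapply(abs(tstat), function(tt) mean(maxT >= tt), numeric(1))
  })
  if (mse == 0) p_adj <- ifelse(abs(means[others] - means[ci]) > 0, 0, 1)
  list(F = Fstat, p_anova = p_anova,
       comparisons = data.frame(group = names(groups)[others],
                                diff = unname(means[others] - means[ci]),
                                t = unname(tstat), p_adj = unname(p_adj),
                                stringsAsFactors = FALSE),
       degenerate = degenerate)
}
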