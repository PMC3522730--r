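#' Analytic power of the two-sided allelic test
#'
#' Normal-approximation power of the 1-df allelic (per-allele) test comparing
#' allele frequencies between `2 * n_cases` case alleles and
#' `2 * n_controls` control alleles. The control allele frequency is `maf`;
#' the case frequency follows from multiplying the control odds by the
#' per-allele odds ratio. The critical value uses the pooled-null standard
#' error and power is evaluated under the alternative standard error:
#' `power = Phi((|p1 - p0| - z_{alpha/2} * SE0) / SE1)`.
#'
#' @param or Per-allele odds ratio (> 1 for risk direction; protective ORs
#'   < 1 are handled via their reciprocal, by symmetry of the two-sided
#'   test).
#' @param maf Control minor allele frequency in (0, 0.5].
#' @param alpha Two-sided significance level.
#' @param n_cases,n_controls Subject counts (alleles are twice these).
#' @return Power in (0, 1); exactly `alpha` when `or = 1` (the test size).
#' @export
power_allelic <- function(or, maf, alpha = 0.05 / 320, n_cases = 494,
                          n_controls = 536) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (or <= 0) stop("odds ratio must be positive")
  if (or == 1) return(alpha)
  if (or < 1) or <- 1 / or
  p0 <- maf
  odds1 <- or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  m1 <- 2 * n_cases; m0 <- 2 * n_controls
  pbar <- (m1 * p1 + m0 * p0) / (m1 + m0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / m1 + 1 / m0))
  se1 <- sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((abs(p1 - p0) - z * se0) / se1)
}

#' Detectable odds ratio at a target power
#'
#' Inverts [power_allelic()] by bisection to the smallest risk-direction
#' per-allele odds ratio achieving the target power; for the protective
#' direction the reciprocal of the risk bound is returned (the largest
#' protective OR still detectable).
#'
#' @param maf Control minor allele frequency.
#' @param power Target power (default 0.80).
#' @param alpha Two-sided significance level (default the Bonferroni level
#'   0.05/320 of a 320-test family).
#' @param n_cases,n_controls Subject counts.
#' @param direction `"risk"` or `"protective"`.
#' @param or_max Upper search bound (default 50); power still below target
#'   there is an error.
#' @return The detectable odds ratio bound.
#' @export
detectable_or <- function(maf, power = 0.80, alpha = 0.05 / 320,
                          n_cases = 494, n_controls = 536,
                          direction = c("risk", "protective"),
                          or_max = 50) {
  direction <- match.arg(direction)
  if (power <= 0 || power >= 1) stop("target power must be in (0, 1)")
  f <- function(o) power_allelic(o, maf, alpha, n_cases, n_controls) - power
  if (f(or_max) < 0)
    stop("target power ", power, " unattainable below OR ", or_max,
         " at MAF ", maf)
  root <- stats::uniroot(f, c(1 + 1e-9, or_max), tol = 1e-9)$root
  if (direction == "risk") root else 1 / root
}
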