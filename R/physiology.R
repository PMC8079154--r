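# Small physiology computations: ordinary least-squares rate of change of
# dissolved oxygen, gross photosynthesis from the light and dark slopes
# (oG = oL + oD, with oD the positive consumption magnitude), and Welch's
# two-sample t-test, which is also the shared comparison utility of the
# read-level screen and the longevity analysis.

#' Oxygen-concentration rate by linear regression
#'
#' Ordinary least squares of concentration (mg O2 l^-1) on time, with the
#' slope expressed per minute (input times are seconds). The caller selects
#' the measurement window; no acclimation trimming is automated.
#'
#' @param time_s numeric vector of times in seconds, strictly increasing,
#'   length >= 3.
#' @param conc_mg_l numeric vector of oxygen concentrations (mg/l), same
#'   length.
#' @return a list: `slope` (mg O2 l^-1 min^-1), `intercept` (mg/l),
#'   `r_squared`.
#' @export
#' @examples
#' fitOxygenRate(c(0, 60, 120), c(10, 9, 8))$slope  # -1
fitOxygenRate <- function(time_s, conc_mg_l) {
    if (length(time_s) < 3L)
        stop("need >= 3 points for a rate fit")
    if (length(conc_mg_l) != length(time_s))
        stop("time and concentration lengths differ")
    if (any(diff(time_s) <= 0))
        stop("times must be strictly increasing")
    t_min <- time_s / 60
    fit <- stats::lm(conc_mg_l ~ t_min)
    tss <- sum((conc_mg_l - mean(conc_mg_l))^2)
    r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2)
}

#' Gross photosynthetic oxygen rate
#'
#' `oL` is the net oxygen rate under light, `oD` the consumption magnitude
#' in darkness (the negated dark slope, clamped at 0 with a warning when
#' the dark slope is positive — oxygen production in the dark is
#' biologically unexpected), and the gross rate is their sum:
#' `oG = oL + oD`.
#'
#' @param light_slope,dark_slope slopes from [fitOxygenRate()] in
#'   consistent units (mg O2 l^-1 min^-1).
#' @return a list with `oL`, `oD`, `oG`.
#' @export
#' @examples
#' grossPhotosynthesis(0.03, -0.02)$oG  # 0.05
grossPhotosynthesis <- function(light_slope, dark_slope) {
    oD <- -dark_slope
    if (dark_slope > 0) {
        warning("positive dark slope (oxygen produced in darkness); ",
                "consumption clamped to 0")
        oD <- 0
    }
    list(oL = light_slope, oD = oD, oG = light_slope + oD)
}

#' Welch's two-sample t-test
#'
#' Closed form: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p from the t
#' distribution. Degenerate inputs are handled explicitly: when both
#' groups have zero variance, equal means give `t = 0, p = 1` and unequal
#' means give an infinite `t` with `p = 0` and a warning.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2, finite.
#' @return a list: `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b`.
#' @export
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4, p = 0.288
welchTTest <- function(group_a, group_b) {
    if (length(group_a) < 2L || length(group_b) < 2L)
        stop("each group needs >= 2 observations")
    if (!all(is.finite(group_a)) || !all(is.finite(group_b)))
        stop("groups must be finite")
    n1 <- length(group_a); n2 <- length(group_b)
    m1 <- mean(group_a); m2 <- mean(group_b)
    v1 <- stats::var(group_a); v2 <- stats::var(group_b)
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
        if (m1 == m2) {
            t <- 0; df <- n1 + n2 - 2; p <- 1
        } else {
            warning("zero variance in both groups with unequal means")
            t <- sign(m1 - m2) * Inf; df <- n1 + n2 - 2; p <- 0
        }
    } else {
        t <- (m1 - m2) / sqrt(se2)
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        p <- 2 * stats::pt(-abs(t), df)
    }
    list(t = t, df = df, p = p, mean_a = m1, mean_b = m2,
         sd_a = sqrt(v1), sd_b = sqrt(v2), n_a = n1, n_b = n2)
}
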