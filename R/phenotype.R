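#' Electrolyte leakage rate from conductivity measurements
#'
#' Membrane damage from cold stress is assayed by shaking stem sections in
#' ultrapure water, measuring the initial electrical conductivity, boiling to
#' kill the tissue, and measuring the maximal conductivity. The electrolyte
#' leakage rate (ELR) is the initial conductivity as a percentage of the
#' maximal conductivity.
#'
#' @param initial initial conductivity (uS/cm), numeric vector.
#' @param maximum post-boil maximal conductivity (uS/cm), same length.
#' @return ELR in percent.
#' @examples
#' elr(20, 80)  # 25
#' @export
elr <- function(initial, maximum) {
  stopifnot(is.numeric(initial), is.numeric(maximum),
            length(initial) == length(maximum))
  if (any(maximum <= 0)) stop("maximum conductivity must be > 0")
  if (any(initial > maximum)) {
    warning("initial conductivity exceeds maximum for some records; ELR > 100%")
  }
  100 * initial / maximum
}

#' Accumulated low temperature over a treatment schedule
#'
#' Treatments are applied as successive constant-temperature stages
#' (here 24 h each, stepping 4, -4, -9, -14, -19, -24, -29 degC). The
#' accumulated low temperature Ac_LT of a sample is the product of stage
#' temperature and stage duration summed over the stages the sample has
#' completed, in degC h. `cumulative = FALSE` returns only the final stage's
#' product.
#'
#' @param temperature stage temperatures (degC), in treatment order.
#' @param duration stage durations (h), recycled if length 1.
#' @param cumulative sum over all completed stages (default) or use only the
#'   last stage.
#' @return Ac_LT in degC h.
#' @examples
#' compute_ac_lt(4, 24)                                 # 96
#' compute_ac_lt(c(4, -4, -9, -14, -19, -24, -29), 24)  # -2280
#' @export
compute_ac_lt <- function(temperature, duration = 24, cumulative = TRUE) {
  if (length(temperature) == 0) stop("empty treatment schedule")
  duration <- rep_len(duration, length(temperature))
  if (any(duration < 0)) stop("stage durations must be >= 0")
  if (cumulative) sum(temperature * duration) else
    temperature[length(temperature)] * duration[length(duration)]
}

#' Two-sided Welch t-test with significance labels
#'
#' Unequal-variance t-test between two groups of replicate measurements
#' (e.g. ELR assay replicates of two cultivars at one temperature), with the
#' conventional star labels: "ns" for p > 0.05, "*" for p <= 0.05, "**" for
#' p <= 0.01, "***" for p <= 0.001 (the most significant applicable bin).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic`, `p_value`, `label`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: no within-group variability
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    tt <- list(statistic = c(t = 0), p.value = p)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  p <- tt$p.value
  label <- if (p <= 0.001) "***" else if (p <= 0.01) "**" else
    if (p <= 0.05) "*" else "ns"
  list(statistic = unname(tt$statistic), p_value = p, label = label)
}

#' Relative expression ratio by the 2^-ddCt method
#'
#' ddCt = (Ct_target - Ct_reference) under treatment (freezing) minus
#' (Ct_target - Ct_reference) under control (chilling); the expression ratio
#' is 2^-ddCt. All arguments are vectorized.
#'
#' @param ct_target_treatment,ct_ref_treatment Ct of target and internal
#'   reference gene under the treatment condition.
#' @param ct_target_control,ct_ref_control Ct of target and reference gene
#'   under the control condition.
#' @return list with `ddct` and `ratio`.
#' @examples
#' ddct_ratio(20, 18, 24, 19)$ratio  # 8
#' @export
ddct_ratio <- function(ct_target_treatment, ct_ref_treatment,
                       ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_treatment, ct_ref_treatment,
               ct_target_control, ct_ref_control)
  if (!all(is.finite(cts))) stop("non-finite Ct value")
  ddct <- (ct_target_treatment - ct_ref_treatment) -
    (ct_target_control - ct_ref_control)
  list(ddct = ddct, ratio = 2^(-ddct))
}
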