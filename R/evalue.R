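# E-value: minimum confounder strength needed to explain away a risk ratio.

#' E-value for unmeasured confounding
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need with both exposure and
#' outcome to fully explain away an observed association. For a risk ratio
#' `RR >= 1` it equals `RR + sqrt(RR * (RR - 1))`; a risk ratio below 1 is
#' inverted first, making the measure symmetric around the null.
#'
#' @param rr observed risk ratio(s), all `> 0`.
#' @return data.frame with `rr_input`, `rr_effective` (after inversion,
#'   `>= 1`) and `evalue` (`>= rr_effective >= 1`; equals 1 iff `rr = 1`).
#' @examples
#' evalue_from_rr(c(2, 0.5, 1))
#' @export
evalue_from_rr <- function(rr) {
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0))
    stop(mr_error("config", "risk ratios must be finite and > 0"))
  eff <- ifelse(rr < 1, 1 / rr, rr)
  data.frame(rr_input = rr, rr_effective = eff,
             evalue = eff + sqrt(eff * (eff - 1)))
}
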