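#' Convert an enzyme loading to a volumetric rate
#'
#' One enzyme unit (U) converts 1 umol of substrate per minute, so in a
#' well-mixed volume 1 U ml^-1 = 1 umol min^-1 ml^-1 = 1 mM min^-1 =
#' 1/60 mM s^-1. All internal kinetics use mM and seconds; loadings are
#' entered in U ml^-1, the unit enzyme preparations are titrated in.
#'
#' @param vmax_U_per_ml Non-negative enzyme loading(s) in U ml^-1.
#' @return Maximal rate(s) in mM s^-1.
#' @examples
#' units_to_rate(6)    # 0.1 mM/s
#' units_to_rate(0.05) # 8.33e-4 mM/s
#' @export
units_to_rate <- function(vmax_U_per_ml) {
  if (!is.numeric(vmax_U_per_ml) || any(!is.finite(vmax_U_per_ml)) ||
      any(vmax_U_per_ml < 0)) {
    stop("enzyme loading must be non-negative and finite (U ml^-1)",
         call. = FALSE)
  }
  vmax_U_per_ml / 60
}

# seconds in an hour / a day; used at the reporting boundary only
.S_PER_H <- 3600
.S_PER_DAY <- 86400

#' Molecular weight of the C10H16 monoterpene products
#'
#' Limonene, pinene and sabinene are isomers, all 136.24 g mol^-1, so the
#' titre conversion is independent of the synthase chosen.
#' @export
MONOTERPENE_MW <- 136.24
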