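#' Unit conversions for thermal comfort work
#'
#' The field mixes SI units with two conventional units: the clo for
#' clothing insulation (1 clo = 0.155 m2K/W) and the Met for metabolic
#' heat production (1 Met = 58.2 W per m2 of body surface area).
#'
#' @param clo Clothing insulation in clo.
#' @param insulation Clothing insulation in m2K/W.
#' @param met Metabolic rate in Met.
#' @param rate Metabolic rate in W/m2.
#' @return The converted numeric vector.
#' @examples
#' clo_to_insulation(1)   # 0.155 m2K/W
#' wm2_to_met(58.2)       # 1 Met
#' @name units
NULL

# conversion constants used throughout
CLO_M2KW <- 0.155
MET_WM2 <- 58.2

#' @rdname units
#' @export
clo_to_insulation <- function(clo) clo * CLO_M2KW

#' @rdname units
#' @export
insulation_to_clo <- function(insulation) insulation / CLO_M2KW

#' @rdname units
#' @export
met_to_wm2 <- function(met) met * MET_WM2

#' @rdname units
#' @export
wm2_to_met <- function(rate) rate / MET_WM2
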