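#' Convert a pressure between mmHg and barye
#'
#' The package works internally in CGS units, where pressure is measured in
#' barye (dyn/cm^2), while clinical pressures are reported in mmHg.  The
#' conversion constant is 1 mmHg = 1333.22 barye.
#'
#' @param value numeric vector of pressures.
#' @param from,to unit tags, one of `"mmHg"` or `"barye"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_pressure(1, "mmHg", "barye")    # 1333.22
#' convert_pressure(80, "mmHg", "barye")   # 106657.6
#' @export
convert_pressure <- function(value, from = c("mmHg", "barye"),
                             to = c("mmHg", "barye")) {
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(is.numeric(value))
  if (from == to) {
    return(value)
  }
  if (from == "mmHg") value * .BARYE_PER_MMHG else value * .MMHG_PER_BARYE
}
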