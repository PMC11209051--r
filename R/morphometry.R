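# Volume and semen arithmetic.

#' Ellipsoid volume from calliper dimensions
#'
#' `V = 0.5236 * length * width * height`, used for scrotal sac and
#' transcutaneous (calliper) testicular volume.
#'
#' @param length,width,height dimensions in cm (vectorized, >= 0).
#' @return volume in cm^3.
#' @export
#' @examples
#' volume_clinical(3, 2, 2)
volume_clinical <- function(length, width, height) {
  check_dims(length, width, height)
  0.5236 * length * width * height
}

#' Ultrasonographic testicular volume
#'
#' `V = length * width * height * 0.71`, with the dimensions measured on
#' frozen B-mode images (sagittal, transverse and dorsal diameters).
#'
#' @inheritParams volume_clinical
#' @return volume in cm^3.
#' @export
#' @examples
#' volume_us(3, 2, 2)
volume_us <- function(length, width, height) {
  check_dims(length, width, height)
  0.71 * length * width * height
}

check_dims <- function(...) {
  v <- c(...)
  if (any(v < 0, na.rm = TRUE)) stop("dimensions must be >= 0")
  invisible(TRUE)
}

#' Sperm concentration from haemocytometer counts
#'
#' The average chamber count is multiplied by one million to give
#' spermatozoa per millilitre (the dilution and chamber geometry are folded
#' into the single factor; record the dilution as metadata when it differs
#' from 1:100).
#'
#' @param mean_chamber_count average spermatozoa counted per chamber (>= 0).
#' @return spermatozoa per mL.
#' @export
#' @examples
#' sperm_concentration(150)
sperm_concentration <- function(mean_chamber_count) {
  if (any(mean_chamber_count < 0, na.rm = TRUE)) {
    stop("chamber counts must be >= 0")
  }
  mean_chamber_count * 1e6
}

#' Total spermatozoa in the ejaculate
#'
#' @param concentration spermatozoa per mL.
#' @param volume_ml ejaculate volume in mL (>= 0).
#' @return total spermatozoa count.
#' @export
total_sperm_count <- function(concentration, volume_ml) {
  if (any(volume_ml < 0, na.rm = TRUE)) stop("volume must be >= 0")
  concentration * volume_ml
}

#' Fertility threshold on total sperm count
#'
#' A sample is fertile when the total sperm count strictly exceeds
#' 200 million; exactly 200 million is not fertile.
#'
#' @param total total spermatozoa count (vectorized).
#' @return logical.
#' @export
#' @examples
#' is_fertile(c(2e8, 2e8 + 1))
is_fertile <- function(total) {
  total > 2e8
}

#' Sperm viability from a stained smear
#'
#' `live / (live + dead) * 100`, from eosin-nigrosin counts targeting 300
#' spermatozoa. When fewer than 300 cells were counted the result carries a
#' `low_count` attribute (small early ejaculates).
#'
#' @param live,dead counts of live and dead spermatozoa (vectorized).
#' @return percentage, with logical attribute `low_count`.
#' @export
#' @examples
#' sperm_viability(270, 30)
sperm_viability <- function(live, dead) {
  if (any(live < 0 | dead < 0, na.rm = TRUE)) stop("counts must be >= 0")
  tot <- live + dead
  if (any(tot == 0, na.rm = TRUE)) {
    stop("viability undefined: no spermatozoa counted")
  }
  out <- live / tot * 100
  attr(out, "low_count") <- tot < 300
  out
}

#' Percent of the mature value
#'
#' Expresses a growth measurement as a percentage of its adult value, the
#' convention used to relate somatometrics to the puberty milestones.
#'
#' @param value measured value.
#' @param mature_value adult reference value (> 0).
#' @return percentage.
#' @export
percent_of_maturity <- function(value, mature_value) {
  if (any(mature_value <= 0, na.rm = TRUE)) {
    stop("mature_value must be positive")
  }
  value / mature_value * 100
}
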