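#' Convert tumor diameter to spherical volume
#'
#' Tumors are modelled as spheres, so a diameter `d` (cm) corresponds to a
#' volume of `pi/6 * d^3` cubic centimetres. A 0.618 mm sphere — the smallest
#' lesion resolvable on thin-slice CT — has volume 1.24e-4 cm^3, which is the
#' package's default detectability threshold.
#'
#' @param d Diameter in cm (vectorised, must be non-negative).
#' @return Volume in cm^3.
#' @seealso [volume_to_diameter()]
#' @examples
#' diameter_to_volume(0.0618) # ~1.24e-4 cm^3, the CT threshold
#' volume_to_diameter(diameter_to_volume(2)) # round trip
#' @export
diameter_to_volume <- function(d) {
  if (any(d < 0, na.rm = TRUE)) abort("diameter must be non-negative")
  pi / 6 * d^3
}

#' Convert spherical volume to tumor diameter
#'
#' Exact inverse of [diameter_to_volume()].
#'
#' @param v Volume in cm^3 (vectorised, must be non-negative).
#' @return Diameter in cm.
#' @export
volume_to_diameter <- function(v) {
  if (any(v < 0, na.rm = TRUE)) abort("volume must be non-negative")
  (6 * v / pi)^(1 / 3)
}
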