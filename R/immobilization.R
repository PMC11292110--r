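#' Amount of receptor immobilized per gram of gel
#'
#' Quantifies immobilization yield from gel-electrophoresis densitometry:
#' the target-band fraction of total lane intensity is measured in the
#' protein supernatant before and after contact with the activated gel,
#' and the depletion, scaled by the total protein offered, gives the mass
#' bound per gram of gel:
#'
#'   amount = (fraction_before - fraction_after) * total_protein / gel_mass
#'
#' Band fractions are taken as inputs; densitometry of the gel image
#' itself is out of scope. The total supernatant protein must be supplied
#' explicitly — it is a measured quantity, not a constant.
#'
#' @param band_fraction_before Target-band fraction of the supernatant
#'   before immobilization, in \[0, 1\].
#' @param band_fraction_after Target-band fraction after immobilization,
#'   in \[0, 1\]; must not exceed `band_fraction_before`.
#' @param total_protein Total protein in the supernatant contacted with
#'   the gel, mg (> 0).
#' @param gel_mass Gel mass, g (> 0).
#' @return Immobilized amount in mg per g of gel.
#' @examples
#' immobilized_amount(0.0386, 0.0142, total_protein = 100, gel_mass = 1)
#' @export
immobilized_amount <- function(band_fraction_before, band_fraction_after,
                               total_protein, gel_mass) {
  stopifnot(is.numeric(band_fraction_before), is.numeric(band_fraction_after),
            is.numeric(total_protein), is.numeric(gel_mass))
  if (band_fraction_before < 0 || band_fraction_before > 1 ||
      band_fraction_after < 0 || band_fraction_after > 1) {
    stop("band fractions must lie in [0, 1]", call. = FALSE)
  }
  if (band_fraction_after > band_fraction_before) {
    stop("negative immobilization: band fraction increased after immobilization",
         call. = FALSE)
  }
  if (total_protein <= 0) stop("`total_protein` must be > 0", call. = FALSE)
  if (gel_mass <= 0) stop("`gel_mass` must be > 0", call. = FALSE)
  (band_fraction_before - band_fraction_after) * total_protein / gel_mass
}
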