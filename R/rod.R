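#' Elastic-rod model of a transmembrane helix
#'
#' Semiflexible-rod description of a long transmembrane helix (TM1): a rod of
#' contour length `L` with persistence length `L_p` (bending stiffness
#' `K_S = L_p * kBT`). Energies are expressed in kBT.
#'
#' @param L_p persistence length, nm (default 100, typical for protein
#'   alpha-helices).
#' @param L contour length, nm (default 11).
#' @return object of class `rod_model`.
#' @export
rod_model <- function(L_p = 100, L = 11) {
  stop_if(L_p <= 0 || L <= 0, "L_p and L must be > 0")
  structure(list(L_p = L_p, L = L), class = "rod_model")
}

#' Circular-arc bending energy of the rod
#'
#' For a uniform circular curvature 1/r along the whole rod the elastic
#' energy integral reduces to `E(r) = L_p * L / (2 r^2)` in kBT units;
#' strictly decreasing in r.
#'
#' @param rod a [rod_model()].
#' @param r radius of curvature, nm (> 0).
#' @return energy in kBT.
#' @export
bending_energy <- function(rod, r) {
  stop_if(any(r <= 0), "radius must be > 0")
  rod$L_p * rod$L / (2 * r^2)
}

#' Radius of curvature at a given bending energy
#'
#' Exact inverse of [bending_energy()]: `r = sqrt(L_p * L / (2 E))`.
#'
#' @param rod a [rod_model()]; @param E energy in kBT (> 0).
#' @return radius, nm.
#' @export
radius_at_energy <- function(rod, E) {
  stop_if(any(E <= 0), "energy must be > 0")
  sqrt(rod$L_p * rod$L / (2 * E))
}

#' Lateral end deflection of the bent rod
#'
#' `arc` mode treats the rod as a circular arc: `d = r (1 - cos(L/r))`;
#' `small_angle` uses the leading-order form `d = L^2 / (2 r)`. The modes
#' agree to first order as `L/r -> 0`. The arc expression is only meaningful
#' for `L/r < pi/2`.
#'
#' @param rod a [rod_model()]; @param r radius, nm;
#' @param mode `"arc"` (default) or `"small_angle"`.
#' @return end displacement, nm.
#' @export
end_deflection <- function(rod, r, mode = c("arc", "small_angle")) {
  mode <- match.arg(mode)
  stop_if(any(r <= 0), "radius must be > 0")
  stop_if(any(rod$L / r >= pi / 2), "L/r >= pi/2: arc model invalid")
  if (mode == "arc") r * (1 - cos(rod$L / r)) else rod$L^2 / (2 * r)
}
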