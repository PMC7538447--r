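#' Honeycomb (hexagonal) initial configuration
#'
#' Places a centre cell plus complete hexagonal rings on a triangular
#' lattice, the equilibrium packing of equal spheres in 2D: every
#' nearest-neighbour pair sits exactly at `spacing`. Valid cell counts are
#' the centred hexagonal numbers 1, 7, 19, 37, 61, ... (`1 + 3k(k+1)` for
#' `k` rings).
#'
#' Cells are ordered by ring (centre first) and, within a ring, by polar
#' angle, giving deterministic ids.
#'
#' @param n_cells A centred hexagonal number.
#' @param spacing Nearest-neighbour distance, default 1 cell diameter (the
#'   rest length, so the configuration is a mechanical equilibrium).
#' @param radius Cell radius, default 0.5.
#' @param eta Drag coefficient.
#' @return A [cell_population()] centred on the origin.
#' @examples
#' pop <- honeycomb_population(19)
#' population_radius(pop) # 0.5 + 2: the outer corners sit 2 diameters out
#' @export
honeycomb_population <- function(n_cells, spacing = 1, radius = 0.5, eta = 1) {
  k <- (sqrt(12 * n_cells - 3) - 3) / 6 # rings solving 1 + 3k(k+1) = n
  if (abs(k - round(k)) > 1e-9) {
    abort(paste0(
      "n_cells must be a centred hexagonal number (1, 7, 19, 37, ...); got ",
      n_cells
    ))
  }
  k <- round(k)
  qr <- expand.grid(q = -k:k, r = -k:k)
  qr <- qr[abs(qr$q + qr$r) <= k & pmax(abs(qr$q), abs(qr$r)) <= k, ]
  x <- spacing * (qr$q + qr$r / 2)
  y <- spacing * (sqrt(3) / 2) * qr$r
  ring <- pmax(abs(qr$q), abs(qr$r), abs(qr$q + qr$r))
  ord <- order(ring, atan2(y, x))
  cell_population(
    data.frame(
      cell_id = seq_len(n_cells),
      x = x[ord], y = y[ord], radius = radius
    ),
    dim = 2, eta = eta
  )
}
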