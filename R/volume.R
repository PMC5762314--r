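#' Convert between tumor volume and cell count
#'
#' Long-horizon simulations are compared with xenograft tumor measurements by
#' assuming a fixed packing density of 1e8 cells per cubic centimeter.
#'
#' @param volume_cm3 Non-negative tumor volume(s) in cm^3.
#' @param cells_per_cm3 Packing density (default `1e8`).
#' @return `cells_from_volume()` returns cell counts rounded to the nearest
#'   integer; `volume_from_cells()` returns volumes in cm^3.
#' @examples
#' cells_from_volume(1)      # 100,000,000
#' volume_from_cells(2.5e7)  # 0.25
#' @export
cells_from_volume <- function(volume_cm3, cells_per_cm3 = 1e8) {
  if (any(volume_cm3 < 0) || anyNA(volume_cm3)) {
    stop("volume must be non-negative", call. = FALSE)
  }
  round(volume_cm3 * cells_per_cm3)
}

#' @rdname cells_from_volume
#' @param cells Non-negative cell count(s).
#' @export
volume_from_cells <- function(cells, cells_per_cm3 = 1e8) {
  if (any(cells < 0) || anyNA(cells)) {
    stop("cell count must be non-negative", call. = FALSE)
  }
  cells / cells_per_cm3
}
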