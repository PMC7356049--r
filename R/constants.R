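#' Avogadro's number
#'
#' CODATA value of the Avogadro constant, used in all copy-number to
#' concentration conversions.
#'
#' @format A length-one numeric, mol^-1.
#' @export
AVOGADRO <- 6.02214076e23

# 1 A^3 in dm^3 (1 A = 1e-9 dm)
.A3_TO_DM3 <- 1e-27

#' Volume of an orthorhombic cell in dm^3
#'
#' Converts box edge lengths in Angstrom to the cell volume in dm^3 (the
#' unit in which molar concentrations of simulation copies are formed:
#' c = n / (N_A * V)).
#'
#' @param box numeric length-3 vector of orthorhombic edge lengths (Angstrom).
#' @return volume in dm^3.
#' @examples
#' box_volume_dm3(c(338.6, 338.6, 338.6)) # ~3.88e-22 dm^3
#' @export
box_volume_dm3 <- function(box) {
  box <- as.numeric(box)
  stopifnot(length(box) == 3L, all(box > 0))
  prod(box) * .A3_TO_DM3
}

#' Molar concentration of n copies in a periodic cell
#'
#' @param n number of copies in the cell.
#' @param volume_dm3 cell volume in dm^3.
#' @return concentration in mol/dm^3 (M).
#' @export
copies_to_molar <- function(n, volume_dm3) {
  stopifnot(n >= 0, volume_dm3 > 0)
  n / (AVOGADRO * volume_dm3)
}

# polynomial rolling hash over a character scalar; used only for config
# provenance hashes (collision resistance is not a requirement here)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
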