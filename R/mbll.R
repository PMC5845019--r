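#' Molar extinction coefficients for oxy- and deoxyhemoglobin
#'
#' Literature values at the three measurement wavelengths 780, 805 and
#' 830 nm, in 1/(mM cm).  805 nm is close to the isosbestic point where
#' the two chromophores absorb almost equally.  Device-specific constants
#' are not standardised, so the table is a plain data.frame and can be
#' replaced by any table with the same columns (or read from a text file
#' with [read_extinction()]).
#'
#' @return data.frame with columns `wavelength_nm`, `hbo2`, `hbr`.
#' @export
default_extinction <- function() {
  data.frame(
    wavelength_nm = c(780, 805, 830),
    hbo2 = c(0.736, 0.870, 0.974),
    hbr  = c(1.105, 0.830, 0.693)
  )
}

#' Read / write an extinction-coefficient table
#'
#' @param path file path of a tab-separated table with columns
#'   `wavelength_nm`, `hbo2`, `hbr`.
#' @param ext a table as returned by [default_extinction()].
#' @export
read_extinction <- function(path) {
  ext <- utils::read.table(path, sep = "\t", header = TRUE)
  .validate_extinction(ext)
  ext
}

#' @rdname read_extinction
#' @export
write_extinction <- function(ext, path) {
  utils::write.table(ext, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_extinction <- function(ext) {
  need <- c("wavelength_nm", "hbo2", "hbr")
  if (!all(need %in% names(ext)))
    stop("extinction table must have columns ",
         paste(need, collapse = ", "))
  E <- as.matrix(ext[, c("hbo2", "hbr")])
  if (qr(E)$rank < 2)
    stop("extinction matrix is rank deficient; the chromophore system ",
         "cannot be solved")
  invisible(E)
}

#' Modified Beer-Lambert law conversion
#'
#' Converts optical-density changes measured at several wavelengths to
#' pathlength-scaled hemoglobin concentration changes.  For each time
#' sample the overdetermined linear system
#' `dOD(lambda) = eps(lambda, HbO2) * L*dHbO2 + eps(lambda, HbR) * L*dHbR`
#' is solved by ordinary least squares.  The unknown photon pathlength L
#' is not resolved here: outputs carry it as a common multiplicative
#' factor, which the downstream Z-scoring cancels.
#'
#' @param delta_od wavelengths x samples numeric matrix of optical-density
#'   changes, rows ordered as in `ext`.
#' @param ext extinction table, see [default_extinction()].
#' @return list with numeric vectors/matrices `hbo2`, `hbr`, `hbt`
#'   (samples, L-scaled concentration units); `hbt = hbo2 + hbr` exactly.
#' @export
od_to_hb <- function(delta_od, ext = default_extinction()) {
  if (!is.matrix(delta_od)) delta_od <- matrix(delta_od, nrow = 1)
  E <- .validate_extinction(ext)
  if (nrow(delta_od) != nrow(E))
    stop("delta_od must have one row per wavelength in the extinction table")
  # least squares for all samples at once: C = (E'E)^-1 E' dOD
  C <- solve(crossprod(E), crossprod(E, delta_od))
  list(hbo2 = C[1, ], hbr = C[2, ], hbt = C[1, ] + C[2, ])
}
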