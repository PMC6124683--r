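#' Hemoglobin extinction-coefficient table
#'
#' Construct or load the molar extinction coefficients of deoxyhemoglobin
#' (Hb) and oxyhemoglobin (HbO2) at the device wavelengths. Coefficients are
#' decadic (base-10 absorbance) in cm^-1 mM^-1, the convention paired with
#' the decadic attenuation computed by [delta_attenuation()].
#'
#' The shipped default covers 735, 805 and 850 nm: the Hb and HbO2
#' absorption peaks in the near-infrared window plus a wavelength near the
#' isosbestic point (805 nm) where the two chromophores absorb almost
#' equally, which decouples total-hemoglobin from oxygenation changes.
#'
#' @param wavelength_nm numeric vector of wavelengths (nm).
#' @param eps_hb,eps_hbo2 decadic molar extinction coefficients,
#'   cm^-1 mM^-1, positive, same length as `wavelength_nm`.
#' @return A data frame of class `extinction_table` with columns
#'   `wavelength_nm`, `eps_hb`, `eps_hbo2`.
#' @examples
#' eps <- default_extinction()
#' eps
#' @export
extinction_table <- function(wavelength_nm, eps_hb, eps_hbo2) {
  stopifnot(length(wavelength_nm) == length(eps_hb),
            length(wavelength_nm) == length(eps_hbo2))
  if (any(eps_hb <= 0) || any(eps_hbo2 <= 0))
    stop("extinction coefficients must be positive")
  if (anyDuplicated(wavelength_nm))
    stop("duplicated wavelengths in extinction table")
  out <- data.frame(wavelength_nm = as.numeric(wavelength_nm),
                    eps_hb = as.numeric(eps_hb),
                    eps_hbo2 = as.numeric(eps_hbo2))
  out <- out[order(out$wavelength_nm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("extinction_table", "data.frame")
  out
}

#' @rdname extinction_table
#' @param file path to a TSV with columns `wavelength_nm`, `eps_hb`,
#'   `eps_hbo2`; `#` lines are comments. Defaults to the packaged table.
#' @export
default_extinction <- function(file = system.file("extdata",
                                                  "hemoglobin_extinction.tsv",
                                                  package = "nirstilt")) {
  tab <- read.delim(file, comment.char = "#", header = TRUE)
  extinction_table(tab$wavelength_nm, tab$eps_hb, tab$eps_hbo2)
}

#' The three device wavelengths (nm)
#' @keywords internal
device_wavelengths <- function() c(735, 805, 850)

# Check an extinction table covers the device wavelengths and that 805 nm is
# the near-isosbestic wavelength (smallest |eps_hb - eps_hbo2| of the three).
validate_extinction <- function(eps, wavelengths = device_wavelengths()) {
  stopifnot(inherits(eps, "extinction_table"))
  if (!all(wavelengths %in% eps$wavelength_nm))
    stop("extinction table must cover wavelengths: ",
         paste(wavelengths, collapse = ", "))
  sub <- eps[match(wavelengths, eps$wavelength_nm), ]
  gap <- abs(sub$eps_hb - sub$eps_hbo2)
  iso <- which(wavelengths == 805)
  if (length(iso) == 1 && which.min(gap) != iso)
    warning("805 nm is not the closest-to-isosbestic wavelength in this table")
  invisible(sub)
}
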