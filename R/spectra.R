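# Spectral parameterization of tissue optical properties.
# Units: concentrations uM; epsilon cm^-1 uM^-1; mu_a, mu_s' cm^-1;
# wavelengths nm; water_fraction dimensionless (0-1).

#' Chromophore concentration set
#'
#' A set of tissue chromophore concentrations: oxyhaemoglobin, deoxy-
#' haemoglobin, the cytochrome-c-oxidase redox-state difference (oxidised
#' minus reduced, which may be negative in general), and the water volume
#' fraction treated as a fixed background absorber.
#'
#' @param hbo Oxyhaemoglobin concentration (uM, >= 0).
#' @param hb Deoxyhaemoglobin concentration (uM, >= 0).
#' @param cco_redox CCO redox-state difference concentration (uM).
#' @param water_fraction Water volume fraction in `[0, 1]`.
#' @return Object of class `chromophore_set`.
#' @export
#' @examples
#' chromophore_set(60, 25, 8.5)
chromophore_set <- function(hbo, hb, cco_redox = 0, water_fraction = 0.75) {
  stopifnot(is.numeric(hbo), is.numeric(hb), is.numeric(cco_redox),
            length(hbo) == 1, length(hb) == 1, length(cco_redox) == 1)
  if (hbo < 0 || hb < 0) stop("haemoglobin concentrations must be >= 0")
  if (water_fraction < 0 || water_fraction > 1) {
    stop("water_fraction must lie in [0, 1]")
  }
  structure(list(hbo = hbo, hb = hb, cco_redox = cco_redox,
                 water_fraction = water_fraction),
            class = "chromophore_set")
}

#' Power-law scattering parameters
#'
#' Reduced scattering is modelled as a power law in wavelength,
#' `mu_s'(lambda) = a * (lambda / lambda0)^(-b)`, the standard Mie-regime
#' approximation for soft tissue. `a` is the reduced scattering coefficient
#' at the reference wavelength and `b` the scattering power.
#'
#' @param a Scattering amplitude (cm^-1 at `lambda0`, > 0).
#' @param b Scattering power (dimensionless; > 0 gives the physical,
#'   decreasing-with-wavelength behaviour).
#' @param lambda0 Reference wavelength (nm, > 0); 500 nm by convention here.
#' @return Object of class `scatter_law`.
#' @export
#' @examples
#' scatter_law(24.2, 1.611)
scatter_law <- function(a, b, lambda0 = 500) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (a <= 0) stop("scattering amplitude a must be > 0")
  if (lambda0 <= 0) stop("reference wavelength lambda0 must be > 0")
  structure(list(a = a, b = b, lambda0 = lambda0), class = "scatter_law")
}

#' Per-wavelength absorption and reduced scattering
#'
#' Container pairing wavelengths with absorption and reduced scattering
#' coefficients.
#'
#' @param wavelengths Wavelengths (nm).
#' @param mu_a Absorption coefficients (cm^-1, >= 0).
#' @param mu_s_prime Reduced scattering coefficients (cm^-1, > 0).
#' @return A data frame of class `optical_properties` with columns
#'   `wavelength_nm`, `mu_a`, `mu_s_prime`.
#' @export
optical_properties <- function(wavelengths, mu_a, mu_s_prime) {
  stopifnot(length(wavelengths) == length(mu_a),
            length(wavelengths) == length(mu_s_prime))
  if (any(mu_a < 0)) stop("mu_a must be >= 0")
  if (any(mu_s_prime <= 0)) stop("mu_s_prime must be > 0")
  structure(data.frame(wavelength_nm = wavelengths, mu_a = mu_a,
                       mu_s_prime = mu_s_prime),
            class = c("optical_properties", "data.frame"))
}

#' Absorption spectrum from chromophore concentrations
#'
#' Beer-Lambert mixing: `mu_a(lambda) = sum_i eps_i(lambda) * C_i +
#' water_fraction * mu_a_water(lambda)`.
#'
#' @param chromophores A [chromophore_set()].
#' @param table An [nir_extinction_table()].
#' @param wavelengths Wavelengths (nm); each must be present in `table`.
#' @return Numeric vector of absorption coefficients (cm^-1).
#' @export
#' @examples
#' tab <- nir_extinction_table()
#' absorption_spectrum(chromophore_set(60, 25, 8.5), tab, c(690, 830))
absorption_spectrum <- function(chromophores, table, wavelengths) {
  stopifnot(inherits(chromophores, "chromophore_set"))
  i <- ext_rows(table, wavelengths)
  conc <- c(chromophores$hbo, chromophores$hb, chromophores$cco_redox)
  drop(table$epsilon[i, , drop = FALSE] %*% conc) +
    chromophores$water_fraction * table$mu_a_water[i]
}

#' Reduced scattering spectrum from power-law parameters
#'
#' @param law A [scatter_law()].
#' @param wavelengths Wavelengths (nm, > 0).
#' @return Numeric vector of reduced scattering coefficients (cm^-1).
#' @export
#' @examples
#' scattering_spectrum(scatter_law(24.2, 1.611), c(690, 830))
scattering_spectrum <- function(law, wavelengths) {
  stopifnot(inherits(law, "scatter_law"))
  if (any(wavelengths <= 0)) stop("wavelengths must be > 0")
  law$a * (wavelengths / law$lambda0)^(-law$b)
}

#' Beer-Lambert unmixing of chromophore concentrations
#'
#' Least-squares inversion of the Beer-Lambert law: solves
#' `epsilon %*% C = mu_a - water_fraction * mu_a_water` for the chromophore
#' concentrations. With two wavelengths only the two haemoglobin species are
#' solved (the CCO redox difference is not identifiable and is reported as
#' zero); with three or more wavelengths all three chromophores are solved.
#'
#' @param optics An [optical_properties()] object (its `mu_s_prime` column is
#'   ignored here).
#' @param table An [nir_extinction_table()].
#' @param water_fraction Fixed water volume fraction subtracted as a known
#'   background before inversion.
#' @param fit_cco Whether to solve for the CCO redox difference; defaults to
#'   `TRUE` when at least three wavelengths are available.
#' @return A [chromophore_set()] (concentrations may be negative: the
#'   least-squares solution is not constrained).
#' @export
#' @examples
#' tab <- nir_extinction_table()
#' truth <- chromophore_set(60, 25, 8.5)
#' wl <- fd_wavelengths("eight")
#' op <- optical_properties(wl, absorption_spectrum(truth, tab, wl),
#'                          scattering_spectrum(scatter_law(24.2, 1.611), wl))
#' unmix_concentrations(op, tab)
unmix_concentrations <- function(optics, table, water_fraction = 0.75,
                                 fit_cco = NULL) {
  stopifnot(inherits(optics, "optical_properties"))
  wl <- optics$wavelength_nm
  i <- ext_rows(table, wl)
  if (is.null(fit_cco)) fit_cco <- length(wl) >= 3
  n_chrom <- if (fit_cco) 3L else 2L
  if (length(wl) < n_chrom) {
    stop("need at least ", n_chrom, " wavelengths to solve ", n_chrom,
         " chromophores (got ", length(wl), ")")
  }
  E <- table$epsilon[i, seq_len(n_chrom), drop = FALSE]
  if (qr(E)$rank < n_chrom) {
    stop("extinction matrix is rank-deficient over the requested wavelengths")
  }
  y <- optics$mu_a - water_fraction * table$mu_a_water[i]
  sol <- qr.solve(E, y)
  structure(list(hbo = sol[[1]], hb = sol[[2]],
                 cco_redox = if (fit_cco) sol[[3]] else 0,
                 water_fraction = water_fraction),
            class = "chromophore_set")
}

#' @export
print.chromophore_set <- function(x, digits = 4, ...) {
  cat(sprintf(
    "chromophores (uM): HbO %.*g  Hb %.*g  CCOredox %.*g | water %.2f\n",
    digits, x$hbo, digits, x$hb, digits, x$cco_redox, x$water_fraction))
  invisible(x)
}
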