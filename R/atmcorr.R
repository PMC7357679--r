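# Radiometric calibration of imagery against in situ optical stations:
# upwelling diffuse attenuation from paired sub-surface radiometry,
# propagation to the surface by Beer's law, remote sensing reflectance,
# band averaging against sensor spectral response functions, and per-band
# linear regression to gain/offset calibrations.

#' Construct an in situ radiometric station
#'
#' Hyperspectral measurements on a common wavelength grid: downwelling
#' irradiance above the surface Es(0+), upwelling radiance at 0.65 m and
#' 0.21 m depth, and (carried, unused by the formulas) upwelling irradiance
#' at 0.21 m.  The depth difference between the two radiance sensors is
#' 0.65 - 0.21 = 0.44 m.
#'
#' @param wavelengths wavelength grid in nm.
#' @param Es0plus downwelling spectral irradiance above the surface.
#' @param Lu065,Lu021 upwelling spectral radiance at 0.65 m / 0.21 m depth.
#' @param Eu021 optional upwelling irradiance at 0.21 m.
#' @param location optional (row, col) pixel location of the station.
#' @return an object of class `radiometric_station`.
#' @export
radiometric_station <- function(wavelengths, Es0plus, Lu065, Lu021,
                                Eu021 = NULL, location = NULL) {
  n <- length(wavelengths)
  stopifnot(length(Es0plus) == n, length(Lu065) == n, length(Lu021) == n)
  if (any(Es0plus <= 0) || any(Lu065 <= 0) || any(Lu021 <= 0)) {
    stop("radiometric spectra must be positive", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, Es0plus = Es0plus,
                 Lu065 = Lu065, Lu021 = Lu021, Eu021 = Eu021,
                 location = location),
            class = "radiometric_station")
}

#' Read a station CSV file
#'
#' Expected columns: `wavelength`, `Es0plus`, `Lu065`, `Lu021` and
#' optionally `Eu021`.  The pixel location, if known, is given in columns
#' `row`/`col` (constant within the file).
#'
#' @param path CSV path.
#' @return a `radiometric_station`.
#' @export
read_station <- function(path) {
  d <- utils::read.csv(path)
  need <- c("wavelength", "Es0plus", "Lu065", "Lu021")
  if (!all(need %in% names(d))) {
    stop("station CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  loc <- if (all(c("row", "col") %in% names(d))) as.numeric(c(d$row[1], d$col[1]))
  radiometric_station(d$wavelength, d$Es0plus, d$Lu065, d$Lu021,
                      Eu021 = d$Eu021, location = loc)
}

#' Spectral upwelling diffuse attenuation coefficient
#'
#' `K = -(1/z) * ln(Lu065 / Lu021)`, elementwise in wavelength, from paired
#' radiance spectra at 0.65 m and 0.21 m depth (z = sensor depth
#' difference).  A negative K (upper radiance exceeding the lower one) is
#' physically odd but numerically defined; it is returned with a warning.
#'
#' @param Lu065,Lu021 positive radiance spectra.
#' @param z depth difference in meters (default 0.44).
#' @return K spectrum in 1/m.
#' @export
diffuse_attenuation <- function(Lu065, Lu021, z = 0.44) {
  if (z <= 0) stop("`z` must be positive", call. = FALSE)
  if (any(Lu065 <= 0) || any(Lu021 <= 0)) {
    stop("radiances must be positive", call. = FALSE)
  }
  k <- -log(Lu065 / Lu021) / z
  if (any(k < 0)) {
    warning("negative attenuation at some wavelengths (Lu065 > Lu021)")
  }
  k
}

#' Propagate sub-surface radiance to just beneath the surface
#'
#' Beer's law: `Lu(0-) = Lu021 * exp(K * depth)` elementwise, using the
#' attenuation estimated between the two sensor depths.
#'
#' @param Lu021 radiance spectrum at `depth` m.
#' @param K attenuation spectrum (1/m).
#' @param depth sensor depth in meters (default 0.21).
#' @return Lu(0-) spectrum.
#' @export
propagate_to_surface <- function(Lu021, K, depth = 0.21) {
  if (depth < 0) stop("`depth` must be non-negative", call. = FALSE)
  stopifnot(length(Lu021) == length(K))
  Lu021 * exp(K * depth)
}

#' Water-leaving radiance above the surface
#'
#' `Lw(0+) = t * Lu(0-)` with a scalar cross-interface transmittance factor
#' (default 0.543, the standard radiance transfer factor for a flat
#' air-water interface).
#'
#' @param Lu0minus radiance spectrum just beneath the surface.
#' @param transmittance_factor scalar interface factor.
#' @return Lw(0+) spectrum.
#' @export
water_leaving_radiance <- function(Lu0minus, transmittance_factor = 0.543) {
  if (transmittance_factor <= 0) {
    stop("`transmittance_factor` must be positive", call. = FALSE)
  }
  transmittance_factor * Lu0minus
}

#' Remote sensing reflectance
#'
#' `Rrs = Lw(0+) / Es(0+)` elementwise (1/sr).
#'
#' @param Lw0plus water-leaving radiance above the surface.
#' @param Es0plus downwelling irradiance above the surface (> 0).
#' @return Rrs spectrum.
#' @export
remote_sensing_reflectance <- function(Lw0plus, Es0plus) {
  if (any(Es0plus <= 0)) stop("`Es0plus` must be positive", call. = FALSE)
  stopifnot(length(Lw0plus) == length(Es0plus))
  Lw0plus / Es0plus
}

#' Remote sensing reflectance of a station (full chain)
#'
#' Convenience composition: attenuation between the two sensor depths,
#' propagation of the 0.21 m radiance to the surface, cross-interface
#' transfer, and normalization by Es(0+).
#'
#' @param station a `radiometric_station`.
#' @param transmittance_factor scalar interface factor (default 0.543).
#' @return Rrs spectrum on the station's wavelength grid.
#' @export
rrs_from_station <- function(station, transmittance_factor = 0.543) {
  k <- diffuse_attenuation(station$Lu065, station$Lu021)
  lu0 <- propagate_to_surface(station$Lu021, k)
  remote_sensing_reflectance(water_leaving_radiance(lu0, transmittance_factor),
                             station$Es0plus)
}

#' Construct sensor spectral response functions
#'
#' @param bands named list; each element a list/data.frame with
#'   `wavelength` (nm) and non-negative `weight` vectors summing > 0.
#' @return an object of class `spectral_response`.
#' @export
spectral_response <- function(bands) {
  stopifnot(length(bands) >= 1L)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    stopifnot(length(b$wavelength) == length(b$weight))
    if (any(b$weight < 0) || sum(b$weight) <= 0) {
      stop("band ", nm, ": weights must be non-negative and sum > 0",
           call. = FALSE)
    }
  }
  structure(list(bands = bands), class = "spectral_response")
}

#' Read spectral response functions from CSV
#'
#' Expected columns: `band`, `wavelength`, `weight`; one block per band.
#'
#' @param path CSV path.
#' @return a `spectral_response`.
#' @export
read_spectral_response <- function(path) {
  d <- utils::read.csv(path)
  need <- c("band", "wavelength", "weight")
  if (!all(need %in% names(d))) {
    stop("response CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  spectral_response(lapply(split(d, factor(d$band, unique(d$band))),
                           function(b) list(wavelength = b$wavelength,
                                            weight = b$weight)))
}

#' Band-average a spectrum against sensor response functions
#'
#' Weighted mean per band, trapezoidal on the response grid:
#' `integral(w * s) / integral(w)`.  Response wavelengths outside the
#' spectrum's range get zero weight (with a warning); a band with no
#' overlap is an error.
#'
#' @param wavelengths spectrum wavelength grid (nm).
#' @param values spectrum values on that grid.
#' @param response a `spectral_response`.
#' @return named numeric vector, one value per band.
#' @export
band_average <- function(wavelengths, values, response) {
  stopifnot(inherits(response, "spectral_response"),
            length(wavelengths) == length(values))
  out <- numeric(length(response$bands))
  names(out) <- names(response$bands)
  for (nm in names(response$bands)) {
    b <- response$bands[[nm]]
    w <- b$weight
    inside <- b$wavelength >= min(wavelengths) & b$wavelength <= max(wavelengths)
    if (!all(inside)) {
      warning("band ", nm, ": response extends beyond the spectrum; ",
              "outside weights treated as 0")
      w[!inside] <- 0
    }
    if (sum(w) <= 0 || sum(inside) < 2L) {
      stop("band ", nm, ": no spectral overlap with the measurement",
           call. = FALSE)
    }
    s <- stats::approx(wavelengths, values, xout = b$wavelength,
                       rule = 1)$y
    s[!inside] <- 0
    out[nm] <- pracma::trapz(b$wavelength, w * s) /
      pracma::trapz(b$wavelength, w)
  }
  out
}

#' Fit per-band linear calibration against in situ values
#'
#' Ordinary least squares per band: `insitu = gain * image + offset`,
#' as used to remove atmospheric signal by matching image spectra to
#' surface measurements at the station pixels.
#'
#' @param insitu_band_values S x B matrix of station band values (e.g.
#'   band-averaged Rrs).
#' @param image_band_values S x B matrix of image values at the station
#'   pixels.
#' @return an object of class `band_calibration`: per band gain, offset,
#'   r-squared and station count.
#' @export
fit_band_calibration <- function(insitu_band_values, image_band_values) {
  insitu_band_values <- as.matrix(insitu_band_values)
  image_band_values <- as.matrix(image_band_values)
  stopifnot(all(dim(insitu_band_values) == dim(image_band_values)))
  s <- nrow(insitu_band_values)
  if (s < 2L) stop("need at least 2 stations", call. = FALSE)
  bn <- colnames(image_band_values)
  if (is.null(bn)) bn <- paste0("band", seq_len(ncol(image_band_values)))
  tab <- data.frame(band = bn, gain = NA_real_, offset = NA_real_,
                    r_squared = NA_real_, n_stations = s)
  for (j in seq_len(ncol(image_band_values))) {
    x <- image_band_values[, j]
    if (stats::sd(x) == 0) {
      stop("image band ", bn[j], " is constant; calibration is degenerate",
           call. = FALSE)
    }
    fit <- stats::lm(insitu_band_values[, j] ~ x)
    tab$gain[j] <- unname(stats::coef(fit)[2])
    tab$offset[j] <- unname(stats::coef(fit)[1])
    # suppress the "essentially perfect fit" note on noiseless fixtures
    tab$r_squared[j] <- suppressWarnings(summary(fit)$r.squared)
  }
  structure(list(table = tab), class = "band_calibration")
}

#' @export
print.band_calibration <- function(x, ...) {
  cat("Per-band linear calibration (insitu = gain * image + offset)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Apply a band calibration to a scene
#'
#' Maps every pixel of band b through `gain_b * value + offset_b`.
#' Corrected values are clipped to \[0, 1\] (reflectance scale); nodata is
#' untouched.
#'
#' @param scene an `msscene`.
#' @param calibration a `band_calibration` with one row per scene band.
#' @return the corrected `msscene`.
#' @export
apply_calibration <- function(scene, calibration) {
  stopifnot(inherits(scene, "msscene"), inherits(calibration, "band_calibration"))
  b <- dim(scene$pixels)[3]
  if (nrow(calibration$table) != b) {
    stop("calibration has ", nrow(calibration$table),
         " band(s) but scene has ", b, call. = FALSE)
  }
  px <- scene$pixels
  for (j in seq_len(b)) {
    px[, , j] <- calibration$table$gain[j] * px[, , j] +
      calibration$table$offset[j]
  }
  px <- pmin(pmax(px, 0), 1)
  multispectral_scene(px, band_names = scene$band_names,
                      nodata_mask = scene$nodata_mask, geo = scene$geo)
}

#' Image band values at station pixels
#'
#' Nearest-pixel lookup of the scene's band values at each station's
#' (row, col) location.
#'
#' @param scene an `msscene`.
#' @param stations list of `radiometric_station` objects with locations.
#' @return S x B matrix.
#' @export
stations_image_values <- function(scene, stations) {
  d <- dim(scene$pixels)
  out <- matrix(NA_real_, length(stations), d[3])
  colnames(out) <- scene$band_names
  for (i in seq_along(stations)) {
    loc <- stations[[i]]$location
    if (is.null(loc)) stop("station ", i, " has no location", call. = FALSE)
    r <- min(max(round(loc[1]), 1L), d[1])
    c_ <- min(max(round(loc[2]), 1L), d[2])
    out[i, ] <- scene$pixels[r, c_, ]
  }
  out
}
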