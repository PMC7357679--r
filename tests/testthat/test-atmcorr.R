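test_that("diffuse attenuation matches its closed form", {
  lu <- c(1, 2, 3)
  expect_equal(diffuse_attenuation(lu, lu), rep(0, 3), tolerance = 1e-12)
  k <- diffuse_attenuation(exp(-0.44) * lu, lu, z = 0.44)
  expect_equal(k, rep(1, 3), tolerance = 1e-12)
  expect_warning(diffuse_attenuation(2 * lu, lu), "negative attenuation")
  expect_error(diffuse_attenuation(c(-1, 1), c(1, 1)), "positive")
  expect_error(diffuse_attenuation(lu, lu, z = 0), "positive")
})

test_that("surface propagation is the inverse of attenuation", {
  lu <- c(0.5, 0.8, 1.2)
  expect_identical(propagate_to_surface(lu, rep(0, 3)), lu)
  expect_equal(propagate_to_surface(1, 1, depth = 0.21), exp(0.21),
               tolerance = 1e-12)
  set.seed(2)
  lu065 <- runif(10, 0.1, 1)
  lu021 <- runif(10, 0.2, 2)
  k <- suppressWarnings(diffuse_attenuation(lu065, lu021, z = 0.44))
  # propagating the deep reading through K over z recovers the shallow one
  expect_equal(lu021 * exp(-k * 0.44), lu065, tolerance = 1e-10)
  back <- propagate_to_surface(lu021, k, depth = 0.44)
  expect_equal(back, lu021^2 / lu065, tolerance = 1e-10)
})

test_that("reflectance chain matches arithmetic", {
  es <- rep(10, 4)
  expect_equal(remote_sensing_reflectance(es, es), rep(1, 4),
               tolerance = 1e-12)
  lw <- water_leaving_radiance(rep(2, 4), 0.543)
  expect_equal(remote_sensing_reflectance(lw, es), rep(0.1086, 4),
               tolerance = 1e-12)
  expect_equal(remote_sensing_reflectance(3 * lw, es),
               3 * remote_sensing_reflectance(lw, es), tolerance = 1e-12)
  expect_error(remote_sensing_reflectance(lw, rep(0, 4)), "positive")
})

test_that("band averaging is a weighted trapezoidal mean", {
  wl <- seq(400, 700, by = 2.5)
  resp <- spectral_response(list(
    b1 = list(wavelength = seq(500, 600, by = 5), weight = rep(1, 21))))
  flat <- band_average(wl, rep(0.7, length(wl)), resp)
  expect_equal(unname(flat), 0.7, tolerance = 1e-12)
  lin <- band_average(wl, 0.001 * wl, resp)
  expect_equal(unname(lin), 0.001 * 550, tolerance = 1e-9)  # mean endpoints
  off <- spectral_response(list(
    b1 = list(wavelength = seq(800, 900, by = 5), weight = rep(1, 21))))
  expect_error(suppressWarnings(band_average(wl, rep(1, length(wl)), off)),
               "overlap")
  partial <- spectral_response(list(
    b1 = list(wavelength = seq(650, 750, by = 5), weight = rep(1, 21))))
  expect_warning(band_average(wl, rep(1, length(wl)), partial), "beyond")
})

test_that("per-band calibration recovers known gain and offset", {
  set.seed(6)
  s <- 22
  b <- 4
  img <- matrix(runif(s * b, 0.05, 0.4), s, b)
  gains <- c(0.8, 1.1, 0.9, 1.3)
  offs <- c(0.02, -0.01, 0.04, 0.00)
  insitu <- sweep(sweep(img, 2, gains, "*"), 2, offs, "+")
  cal <- fit_band_calibration(insitu, img)
  expect_equal(cal$table$gain, gains, tolerance = 1e-10)
  expect_equal(cal$table$offset, offs, tolerance = 1e-10)
  expect_true(all(cal$table$n_stations == 22L))

  idcal <- fit_band_calibration(img, img)
  expect_equal(idcal$table$gain, rep(1, b), tolerance = 1e-10)
  expect_equal(idcal$table$offset, rep(0, b), tolerance = 1e-10)

  # with noise the estimates stay within 3 standard errors
  noisy <- insitu + matrix(rnorm(s * b, sd = 0.01), s, b)
  ncal <- fit_band_calibration(noisy, img)
  for (j in seq_len(b)) {
    fit <- lm(noisy[, j] ~ img[, j])
    se <- summary(fit)$coefficients[2, 2]
    expect_lt(abs(ncal$table$gain[j] - gains[j]), 3 * se + 1e-12)
  }
  const <- img; const[, 2] <- 0.3
  expect_error(fit_band_calibration(insitu, const), "band2")
  expect_error(fit_band_calibration(insitu[1, , drop = FALSE],
                                    img[1, , drop = FALSE]), "2 stations")
})

test_that("calibration applies per band over a scene", {
  sc <- grid_scene(6, 6, 2, seed = 4)
  cal <- structure(list(table = data.frame(
    band = c("band1", "band2"), gain = c(0.5, 2), offset = c(0.1, 0),
    r_squared = 1, n_stations = 5)), class = "band_calibration")
  out <- apply_calibration(sc, cal)
  expect_equal(out$pixels[, , 1], 0.5 * sc$pixels[, , 1] + 0.1,
               tolerance = 1e-12)
  expect_equal(out$pixels[, , 2], pmin(2 * sc$pixels[, , 2], 1),
               tolerance = 1e-12)
})

test_that("the full station chain recovers generative optics", {
  set.seed(9)
  wl <- seq(395, 795, by = 2.5)
  k_true <- 0.3 + 0.2 * sin(wl / 80)
  lu021 <- 0.5 + 0.3 * cos(wl / 100)
  lu065 <- lu021 * exp(-k_true * 0.44)
  es <- rep(5, length(wl))
  st <- radiometric_station(wl, es, lu065, lu021, location = c(3, 4))
  rrs <- rrs_from_station(st)
  want <- 0.543 * lu021 * exp(k_true * 0.21) / es
  expect_equal(rrs, want, tolerance = 1e-10)
})

test_that("station and response CSV readers round-trip", {
  wl <- seq(400, 500, by = 10)
  d <- data.frame(wavelength = wl, Es0plus = 5, Lu065 = 0.4, Lu021 = 0.6,
                  Eu021 = 0.9, row = 7, col = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  st <- read_station(f)
  expect_s3_class(st, "radiometric_station")
  expect_identical(st$location, c(7, 9))
  expect_equal(st$Lu021, rep(0.6, length(wl)))
  expect_error(read_station({
    f2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), f2, row.names = FALSE)
    f2
  }), "columns")

  rd <- data.frame(band = rep(c("blue", "green"), each = 3),
                   wavelength = c(450, 460, 470, 530, 540, 550),
                   weight = 1)
  fr <- withr::local_tempfile(fileext = ".csv")
  write.csv(rd, fr, row.names = FALSE)
  resp <- read_spectral_response(fr)
  expect_identical(names(resp$bands), c("blue", "green"))
})
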