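test_that("quantal release places all molecules at the release point", {
  geom <- synapse_geometry()
  m <- release_molecules(geom, q = 2700)
  expect_equal(nrow(m), 2700)
  expect_true(all(m$x == 0 & m$y == 0))
  expect_true(all(m$z == geom$cleft_height))
  expect_true(all(m$region == "cleft"))

  one <- release_molecules(geom, q = 1)
  expect_equal(nrow(one), 1)
  expect_equal(as.character(one$region), "cleft")
})

test_that("random release sites are uniform over the active-zone disc", {
  geom <- synapse_geometry()
  r <- withr::with_seed(2, vapply(1:10000, function(i) {
    m <- release_molecules(geom, q = 1, mode = "random_active_zone")
    sqrt(m$x^2 + m$y^2)
  }, numeric(1)))
  expect_true(all(r <= geom$psd_radius))
  ks <- suppressWarnings(stats::ks.test(r, function(q) (q / 110)^2))
  expect_gt(ks$p.value, 0.01)
  # density ~ r implies mean radius 2/3 r_a
  expect_equal(mean(r), 2 / 3 * 110, tolerance = 0.01)
})

test_that("free planar diffusion follows MSD = 4 D t", {
  big <- synapse_geometry(cleft_radius = 1e6, psd_radius = 1e5,
                          cleft_height = 1e5, outer_radius = 1e7)
  m <- release_molecules(big, q = 10000)
  m$z <- rep(5e4, nrow(m))
  nsteps <- 20; dt <- 0.1
  m <- withr::with_seed(3, {
    for (i in seq_len(nsteps)) m <- step_brownian(m, big, dt = dt)
    m
  })
  expect_equal(mean(m$x^2 + m$y^2), 4 * 330 * nsteps * dt, tolerance = 0.02)
})

test_that("boundary rules: reflection, escape, absorption, conservation", {
  geom <- synapse_geometry()
  m <- release_molecules(geom, q = 500)
  expect_identical(step_brownian(m[0, ], geom, dt = 0.1), m[0, ])
  expect_error(step_brownian(m, geom, dt = 0), "dt")

  m <- withr::with_seed(4, {
    for (i in 1:400) {
      m <- step_brownian(m, geom, dt = 0.1)
      cl <- m$region == "cleft"
      stopifnot(all(m$z[cl] >= 0), all(m$z[cl] <= geom$cleft_height),
                all(m$x[cl]^2 + m$y[cl]^2 <= geom$cleft_radius^2))
    }
    m
  })
  expect_equal(sum(count_regions(m)$n), 500)      # conservation
  expect_gt(sum(m$region == "extracellular"), 0)  # some escaped the rim

  # absorbed molecules never move again and the absorbed count is monotone
  small <- synapse_geometry(cleft_radius = 200, psd_radius = 110,
                            outer_radius = 300)
  m2 <- release_molecules(small, q = 300)
  n_abs <- 0
  m2 <- withr::with_seed(5, {
    for (i in 1:500) {
      m2 <- step_brownian(m2, small, dt = 0.1)
      k <- sum(m2$region == "absorbed")
      stopifnot(k >= n_abs); n_abs <- k
    }
    m2
  })
  expect_gt(n_abs, 0)
  was_absorbed <- which(m2$region == "absorbed")
  m3 <- withr::with_seed(6, step_brownian(m2, small, dt = 0.1))
  expect_equal(m3$x[was_absorbed], m2$x[was_absorbed])
  expect_true(all(m3$region[was_absorbed] == "absorbed"))
})

test_that("a sealed rim keeps the cleft-averaged concentration constant", {
  geom <- synapse_geometry()
  m <- release_molecules(geom, q = 800)
  m <- withr::with_seed(7, {
    for (i in 1:300) m <- step_brownian(m, geom, dt = 0.1, sealed_rim = TRUE)
    m
  })
  expect_true(all(m$region == "cleft"))
  prof <- concentration_profile(m, geom)
  vol <- pi * geom$cleft_radius^2 * geom$cleft_height
  expect_equal(sum(prof$n_molecules), 800)
  expect_equal(sum(prof$concentration_mM * prof$volume_nm3) / vol,
               800 / vol / 6.022e-4, tolerance = 1e-9)
})

test_that("concentration profile: units, conservation, empty cleft", {
  geom <- synapse_geometry()
  # uniformly mixed ensemble: volume-average 2700/(pi 200^2 19) nm^-3 in mM
  m <- withr::with_seed(8, {
    r <- geom$cleft_radius * sqrt(runif(2700))
    th <- runif(2700, 0, 2 * pi)
    structure(tibble::tibble(x = r * cos(th), y = r * sin(th),
                             z = runif(2700, 0, 19),
                             region = factor(rep("cleft", 2700),
                                             levels = c("cleft", "extracellular",
                                                        "absorbed"))),
              class = c("molecule_ensemble", "tbl_df", "tbl", "data.frame"))
  })
  prof <- concentration_profile(m, geom, dr = 10)
  cbar <- 2700 / (pi * 200^2 * 19) / 6.022e-4   # ~1.88 mM, derived by hand
  expect_equal(sum(prof$concentration_mM * prof$volume_nm3) /
                 sum(prof$volume_nm3), cbar, tolerance = 1e-9)
  expect_equal(stats::weighted.mean(prof$concentration_mM, prof$volume_nm3),
               cbar, tolerance = 0.08)  # per-ring estimates scatter around it
  expect_equal(sum(prof$n_molecules), 2700)

  empty <- release_molecules(geom, q = 0)
  expect_true(all(concentration_profile(empty, geom)$concentration_mM == 0))
  expect_error(concentration_profile(m, geom, dr = 0), "dr")
})

test_that("local cylinder estimator matches its definition and the rings", {
  geom <- synapse_geometry()
  pos <- manual_layout(c(0, 150), c(0, 0))
  none <- release_molecules(geom, q = 0)
  expect_equal(local_concentration(none, pos, geom), c(0, 0))

  # k molecules inside the sampling cylinder -> k / (pi rho^2 delta)
  k <- 7
  m <- structure(tibble::tibble(x = rep(5, k), y = rep(0, k), z = rep(3, k),
                                region = factor(rep("cleft", k),
                                                levels = c("cleft",
                                                           "extracellular",
                                                           "absorbed"))),
                 class = c("molecule_ensemble", "tbl_df", "tbl", "data.frame"))
  got <- local_concentration(m, pos, geom, rho_local = 20)
  expect_equal(got[1], k / (pi * 20^2 * 19) / 6.022e-4)
  expect_equal(got[2], 0)

  # on a uniform ensemble the cylinder and ring estimators agree
  unif <- withr::with_seed(9, {
    r <- geom$cleft_radius * sqrt(runif(20000))
    th <- runif(20000, 0, 2 * pi)
    structure(tibble::tibble(x = r * cos(th), y = r * sin(th),
                             z = runif(20000, 0, 19),
                             region = factor(rep("cleft", 20000),
                                             levels = c("cleft", "extracellular",
                                                        "absorbed"))),
              class = c("molecule_ensemble", "tbl_df", "tbl", "data.frame"))
  })
  loc <- local_concentration(unif, manual_layout(c(50, 100), c(0, 0)), geom)
  prof <- concentration_profile(unif, geom)
  ring <- prof$concentration_mM[c(6, 11)]  # rings covering r = 50, 100 nm
  expect_equal(loc, ring, tolerance = 0.15)
})
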