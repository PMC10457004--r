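test_that("tissue spectra interpolate on the log-frequency axis", {
  sp <- defaultTissueSpectra()
  wm <- sp$white_matter
  ## anchors are hit exactly
  expect_equal(tissueConductivity(wm, 21e3), wm@anchor_conductivities[1L])
  expect_equal(tissueConductivity(wm, 100e3), wm@anchor_conductivities[2L])
  ## geometric mean of two anchors -> arithmetic midpoint of anchor values
  fg <- sqrt(21e3 * 100e3)
  expect_equal(tissueConductivity(wm, fg), mean(wm@anchor_conductivities),
               tolerance = 1e-12)
  ## monotone non-decreasing over the band
  f <- seq(21e3, 100e3, length.out = 50)
  expect_true(all(diff(tissueConductivity(wm, f)) >= 0))
  expect_error(tissueConductivity(wm, 10e3), "outside")
})

test_that("default spectra obey the dispersion ordering", {
  sp <- defaultTissueSpectra()
  ch <- vapply(sp, dispersionChange, 1)
  expect_gt(ch[["white_matter"]], ch[["ischemic"]])
  expect_gt(ch[["ischemic"]], ch[["gray_matter"]])
  expect_gt(ch[["gray_matter"]], ch[["blood_hemorrhage"]])
  expect_gt(ch[["white_matter"]], ch[["blood_hemorrhage"]])
})

test_that("healthy phantoms are mirror-symmetric; degenerate lesion is a no-op", {
  m <- fixMesh(1024)
  cfg <- headPhantomConfig()
  sig <- fieldValues(buildHeadPhantom(cfg, m, 50e3))
  ## multiset of element values matches under mirroring (the construction
  ## paints mirrored disks); compare by value histogram
  expect_equal(sort(table(signif(sig, 10))), sort(table(signif(sig, 10))))
  ctr <- elementCentroids(m)
  left <- sig[ctr[, 1L] < -0.02]
  right <- sig[ctr[, 1L] > 0.02]
  ## same proportion of inclusion-valued elements on each side (within mesh
  ## granularity)
  inc <- tissueConductivity(cfg$spectra$white_matter, 50e3)
  expect_equal(mean(left == inc), mean(right == inc), tolerance = 0.05)

  lz <- headPhantomConfig(lesion = list(side = "left", angle_deg = 60,
                                        r = 0.4, radius = 0, tissue = "blood_hemorrhage"))
  expect_identical(fieldValues(buildHeadPhantom(lz, m, 50e3)), sig)
})

test_that("hemorrhagic lesion elements disperse less than background", {
  m <- fixMesh(256)
  cfg <- headPhantomConfig(lesion = list(side = "right", angle_deg = 90,
                                         r = 0.45, radius = 0.2,
                                         tissue = "blood_hemorrhage"))
  s21 <- fieldValues(buildHeadPhantom(cfg, m, 21e3))
  s100 <- fieldValues(buildHeadPhantom(cfg, m, 100e3))
  rel <- s100 / s21 - 1
  bg21 <- tissueConductivity(cfg$spectra$background_brain, 21e3)
  lesion <- which(abs(s21 - tissueConductivity(cfg$spectra$blood_hemorrhage, 21e3)) < 1e-12)
  background <- which(abs(s21 - bg21) < 1e-12)
  expect_gt(length(lesion), 0L)
  expect_lt(max(rel[lesion]), min(rel[background]))
})

test_that("lesions outside the domain are rejected", {
  expect_error(headPhantomConfig(lesion = list(side = "left", angle_deg = 90,
                                               r = 0.9, radius = 0.3,
                                               tissue = "blood_hemorrhage")),
               "outside")
})

test_that("noise-free healthy acquisitions are mirror-symmetric in data space", {
  p <- fixProtocol()
  m <- fixMesh(1024)
  cfg <- headPhantomConfig(noise_relative_sd = 0, channel_gain_sd = 0)
  fs <- simulateAcquisition(cfg, m, p)
  map <- mirrorChannelMap(p)
  v <- voltages(fs)
  for (i in c(1L, 9L)) {
    flat <- as.vector(t(v[i, , ]))
    mirrored <- flat[(map$mirror_drive - 1L) * 12L + map$mirror_meas] * map$sign
    expect_true(max(abs(flat - mirrored)) / max(abs(flat)) < 0.01)
  }
})

test_that("acquisition is seed-deterministic and the noise scale is honest", {
  p <- fixProtocol()
  m <- fixMesh(256)
  cfg <- headPhantomConfig(seed = 7L)
  a <- simulateAcquisition(cfg, m, p)
  b <- simulateAcquisition(cfg, m, p)
  expect_identical(voltages(a), voltages(b))

  ## empirical residual SD close to the configured fraction of the frame RMS
  clean <- simulateAcquisition(
    headPhantomConfig(noise_relative_sd = 0, channel_gain_sd = 0), m, p)
  noisy <- simulateAcquisition(
    headPhantomConfig(noise_relative_sd = 0.01, channel_gain_sd = 0, seed = 11L),
    m, p)
  resid <- voltages(noisy) - voltages(clean)
  for (i in c(1L, 5L)) {
    target <- 0.01 * sqrt(mean(voltages(clean)[i, , ]^2))
    expect_true(abs(sd(as.vector(resid[i, , ])) - target) / target < 0.2)
  }
})

test_that("the resistor-network standard behaves like an ideal resistive hub", {
  p <- fixProtocol()
  net <- pcbNetwork()
  sim <- simulatePCB(net, p)
  vt <- voltages(sim$theoretical)
  ## gains of 1: measured identical to theoretical
  expect_identical(voltages(sim$measured), vt)
  ## identical at all frequencies
  for (i in 2:9) expect_identical(vt[i, , ], vt[1L, , ])
  ## nonzero adjacent voltages under opposite drive
  expect_true(all(abs(vt) > 0))
  ## rotational symmetry: every drive sees the same channel pattern
  for (d in 2:16) expect_equal(vt[1L, d, ], vt[1L, 1L, ], tolerance = 1e-10)

  ## Kirchhoff: net current into each non-driven node is zero
  V <- pcbPotentials(net, p)
  ed <- net@edges
  i <- match(ed$from, net@nodes); j <- match(ed$to, net@nodes)
  for (d in c(1L, 6L)) {
    cur <- (V[i, d] - V[j, d]) / ed$resistance_ohm
    net_in <- rep(0, length(net@nodes))
    for (k in seq_along(cur)) {
      net_in[i[k]] <- net_in[i[k]] - cur[k]
      net_in[j[k]] <- net_in[j[k]] + cur[k]
    }
    dp <- drivePairs(p)[d, ]
    driven <- match(net@electrode_nodes[dp + 1L], net@nodes)
    expect_true(max(abs(net_in[-driven])) < 1e-10)
    expect_equal(net_in[driven[1L]], -driveCurrent(p), tolerance = 1e-10)
  }
})

test_that("cohort generation reproduces the study design", {
  p <- fixProtocol()
  m <- fixMesh(256)
  base <- headPhantomConfig()
  co <- generateCohort(4, 2, m, p, base_cfg = base, seed = 1)
  expect_length(co$frames, 6L)
  expect_identical(co$meta$group, rep(c("healthy", "patient"), c(4L, 2L)))
  expect_identical(sum(co$meta$affected_side != "none"), 2L)
  expect_true(all(co$meta$affected_side[co$meta$group == "patient"] %in%
                    c("left", "right")))
  ## reproducible per seed; different seeds give different lesions
  co2 <- generateCohort(4, 2, m, p, base_cfg = base, seed = 1)
  expect_identical(voltages(co$frames[[5L]]), voltages(co2$frames[[5L]]))
  co3 <- generateCohort(4, 2, m, p, base_cfg = base, seed = 2)
  lesion1 <- co$configs[[5L]]$lesion
  lesion3 <- co3$configs[[5L]]$lesion
  expect_false(isTRUE(all.equal(lesion1, lesion3)))
})

test_that("a lesion perturbs the channels on its own geometric side most", {
  p <- fixProtocol()
  m <- fixMesh(1024)
  base0 <- headPhantomConfig(noise_relative_sd = 0, channel_gain_sd = 0)
  healthy <- simulateAcquisition(base0, m, p)
  lcfg <- headPhantomConfig(
    lesion = list(side = "left", angle_deg = 90, r = 0.5, radius = 0.18,
                  tissue = "blood_hemorrhage"),
    noise_relative_sd = 0, channel_gain_sd = 0)
  patient <- simulateAcquisition(lcfg, m, p)
  dv <- abs(voltages(patient)[1L, , ] - voltages(healthy)[1L, , ])
  ## anatomical left renders on image right: electrodes 1..7
  mps <- measurementPairs(p)
  lesion_side <- healthy_side <- 0
  for (d in seq_len(16L)) {
    for (j in seq_len(12L)) {
      pr <- mps[[d]][j, ]
      if (all(pr %in% 1:7)) lesion_side <- lesion_side + dv[d, j]
      if (all(pr %in% 9:15)) healthy_side <- healthy_side + dv[d, j]
    }
  }
  expect_gt(lesion_side, healthy_side)
})
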