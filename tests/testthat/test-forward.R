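test_that("forward solve conserves current and satisfies the discrete system", {
  p <- fixProtocol()
  m <- fixMesh(256)
  sig <- fixSigma0(m)
  K <- mfeitsym:::assembleStiffness(m, sig)
  E <- mfeitsym:::electrodeMatrix(m)
  U <- solveForward(m, sig, p)
  I0 <- driveCurrent(p)
  for (d in c(1L, 5L, 9L)) {
    dp <- drivePairs(p)[d, ]
    b <- I0 * as.numeric(E[dp[1L] + 1L, ] - E[dp[2L] + 1L, ])
    res <- as.numeric(K %*% U[, d]) - b
    ## injected and extracted currents match the drive within 1e-8 relative
    inj <- sum(b[b > 0]); ext <- -sum(b[b < 0])
    expect_true(abs(inj - I0) / I0 < 1e-8)
    expect_true(abs(ext - I0) / I0 < 1e-8)
    ## no spurious current at any node
    expect_true(max(abs(res)) / I0 < 1e-8)
  }
  ## grounding: zero mean over the electrode boundary nodes
  bn <- unique(unlist(electrodeNodes(m)))
  expect_true(max(abs(colMeans(U[bn, ]))) < 1e-12 * max(abs(U)))
})

test_that("homogeneous-disk potentials have the drive-pair symmetries", {
  p <- fixProtocol()
  m <- fixMesh(256)
  u <- solveForward(m, rep(1, nElements(m)), p, drive_index = 1L) # drive (0,8)
  Ee <- as.numeric(mfeitsym:::electrodeMatrix(m) %*% u)
  ## symmetric under reflection through the drive axis: e -> (16 - e) mod 16
  ## (the mesh is exactly mirror-symmetric about the vertical axis)
  perm2 <- ((16L - (0:15)) %% 16L) + 1L
  expect_true(max(abs(Ee - Ee[perm2])) / max(abs(Ee)) < 1e-10)
  ## antisymmetric under the source-sink swap e -> (8 - e) mod 16; that
  ## reflection is across the horizontal axis, where the triangulation is
  ## only statistically symmetric, so agreement is to discretization
  perm <- ((8L - (0:15)) %% 16L) + 1L
  expect_true(max(abs(Ee + Ee[perm])) / max(abs(Ee)) < 1e-3)
  ## for the horizontal drive (4, 12) the source-sink swap is the vertical
  ## mirror, which is exact
  u4 <- solveForward(m, rep(1, nElements(m)), p, drive_index = 5L)
  E4 <- as.numeric(mfeitsym:::electrodeMatrix(m) %*% u4)
  expect_true(max(abs(E4 + E4[perm2])) / max(abs(E4)) < 1e-10)
})

test_that("voltages scale as 1/sigma under global conductivity scaling", {
  p <- fixProtocol()
  m <- fixMesh(64)
  v1 <- forwardFrame(m, rep(1, nElements(m)), p)
  v2 <- forwardFrame(m, rep(2, nElements(m)), p)
  expect_equal(v2, v1 / 2, tolerance = 1e-12)
})

test_that("measurement extraction is protocol-faithful", {
  p <- fixProtocol()
  m <- fixMesh(64)
  ## uniform potential field measures zero on every channel
  U <- matrix(3.14, nrow(meshNodes(m)), 16L)
  expect_true(all(abs(measureFrame(U, p, m)) < 1e-12))
  expect_error(measureFrame(U[, 1:5], p, m), "per protocol drive")
})

test_that("transfer impedances are reciprocal", {
  p <- fixProtocol()
  m <- fixMesh(256)
  E <- mfeitsym:::electrodeMatrix(m)
  zpair <- function(sig, drive, meas) {
    K <- mfeitsym:::assembleStiffness(m, sig)
    bd <- as.numeric(E[drive[1L] + 1L, ] - E[drive[2L] + 1L, ])
    bm <- as.numeric(E[meas[1L] + 1L, ] - E[meas[2L] + 1L, ])
    u <- mfeitsym:::solveGrounded(K, cbind(bd), m)
    sum(bm * u)
  }
  ## homogeneous: drive (0,8)/measure (4,5) vs swapped
  z1 <- zpair(rep(1, nElements(m)), c(0L, 8L), c(4L, 5L))
  z2 <- zpair(rep(1, nElements(m)), c(4L, 5L), c(0L, 8L))
  expect_true(abs(z1 - z2) / abs(z1) < 1e-8)
  ## heterogeneous field keeps reciprocity
  sig <- 1 + 0.5 * sin(3 * elementCentroids(m)[, 1L]) *
    cos(2 * elementCentroids(m)[, 2L])
  z1 <- zpair(sig, c(2L, 10L), c(6L, 7L))
  z2 <- zpair(sig, c(6L, 7L), c(2L, 10L))
  expect_true(abs(z1 - z2) / abs(z1) < 1e-6)
})

test_that("boundary voltages converge under mesh refinement", {
  p <- fixProtocol()
  ref <- buildMesh(16384)
  vref <- forwardFrame(ref, rep(1, nElements(ref)), p)
  errs <- vapply(c(256, 1024, 4096), function(n) {
    m <- buildMesh(n)
    v <- forwardFrame(m, rep(1, nElements(m)), p)
    sqrt(sum((v - vref)^2) / sum(vref^2))
  }, 1)
  expect_true(all(diff(errs) < 0))       # monotone improvement
  expect_true(errs[3L] < 0.01)           # within 1% of the reference
})

test_that("the adjoint Jacobian matches central finite differences", {
  p <- fixProtocol()
  m <- fixMesh(64)
  sig <- fixSigma0(m)
  J <- computeJacobian(m, sig, p)
  h <- 1e-6
  for (e in c(3L, 17L, 33L, 64L)) {
    sp <- sig; sp[e] <- sig[e] * (1 + h)
    sm <- sig; sm[e] <- sig[e] * (1 - h)
    fd <- as.vector(t(forwardFrame(m, sp, p) - forwardFrame(m, sm, p))) /
      (2 * h * sig[e])
    expect_true(max(abs(fd - J[, e])) / max(abs(J[, e])) < 0.01)
  }
})

test_that("sensitivity is stronger near the electrodes than at the center", {
  p <- fixProtocol()
  m <- fixMesh(256)
  J <- computeJacobian(m, rep(1, nElements(m)), p)
  ctr <- elementCentroids(m)
  r <- sqrt(rowSums(ctr^2))
  near <- which(r > 0.9)
  central <- which(r < 0.2)
  ## column norms: total sensitivity of the frame to each element,
  ## normalized by element area
  s <- sqrt(colSums(J^2)) / elementAreas(m)
  expect_gt(min(s[near]), max(s[central]))
})

test_that("the Jacobian is equivariant under rotation and mirror symmetry", {
  p <- fixProtocol()
  m <- fixMesh(1024)
  J <- fixJacobian(1024)
  ctr <- elementCentroids(m)
  nearestElement <- function(target) {
    vapply(seq_len(nrow(target)), function(i) {
      which.min((ctr[, 1L] - target[i, 1L])^2 +
                (ctr[, 2L] - target[i, 2L])^2)
    }, 1L)
  }

  ## rotating by one drive (22.5 deg) rotates the sensitivity pattern;
  ## the mesh is not rotation-periodic, so agreement is to discretization
  th <- 22.5 * pi / 180
  rot <- cbind(cos(th) * ctr[, 1L] - sin(th) * ctr[, 2L],
               sin(th) * ctr[, 1L] + cos(th) * ctr[, 2L])
  perm <- nearestElement(rot)
  for (d in c(1L, 7L)) {
    for (j in c(1L, 6L)) {
      r1 <- J[(d - 1L) * 12L + j, perm]
      r2 <- J[d * 12L + j, ]
      expect_lt(sqrt(sum((r1 - r2)^2) / sum(r2^2)), 0.05)
    }
  }

  ## the mesh is exactly mirror-symmetric: reflected channels have exactly
  ## reflected (sign-adjusted) sensitivities
  mperm <- nearestElement(cbind(-ctr[, 1L], ctr[, 2L]))
  expect_lt(max((ctr[mperm, 1L] + ctr[, 1L])^2), 1e-24)
  map <- mirrorChannelMap(p)
  for (r in c(1L, 50L, 120L, 192L)) {
    mirrored <- map$sign[r] *
      J[(map$mirror_drive[r] - 1L) * 12L + map$mirror_meas[r], ]
    expect_lt(max(abs(J[r, mperm] - mirrored)) / max(abs(mirrored)), 1e-12)
  }
})
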