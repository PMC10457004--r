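## Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixCached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fixProtocol <- function() fixCached("protocol", defaultProtocol)

fixMesh <- function(n) {
  fixCached(paste0("mesh", n), function() buildMesh(n))
}

## homogeneous background conductivity at the background frequency
fixSigma0 <- function(mesh) {
  s0 <- tissueConductivity(defaultTissueSpectra()$background_brain, 21e3)
  rep(s0, nElements(mesh))
}

fixJacobian <- function(n = 1024) {
  fixCached(paste0("jac", n), function() {
    m <- fixMesh(n)
    computeJacobian(m, fixSigma0(m), fixProtocol())
  })
}

fixReconstructor <- function(n = 1024) {
  fixCached(paste0("rec", n), function() {
    fdReconstructor(fixJacobian(n), fixMesh(n))
  })
}

## a default synthetic cohort processed end to end (the expensive fixture,
## shared between the cohort-level tests)
fixCohortReport <- function() {
  fixCached("cohort_report", function() {
    p <- fixProtocol()
    m <- fixMesh(1024)
    cohort <- generateCohort(16, 8, m, p, seed = 1)
    res <- processCohort(cohort, m, p)
    list(cohort = cohort, res = res,
         report = groupComparisonReport(res$features, res$asymmetry),
         report_onesided = groupComparisonReport(res$features, res$asymmetry,
                                                alternative = "less"))
  })
}

## synthetic image on a circular mask from a full grid of values
makeTestImage <- function(values, foreground_hz = 50e3,
                          background_hz = 21e3) {
  g <- nrow(values)
  cs <- (seq_len(g) - 0.5) * 2 / g - 1
  x <- matrix(rep(cs, each = g), g, g)        # column coordinate
  y <- matrix(rep(rev(cs), times = g), g, g)  # row 1 = top
  mask <- x^2 + y^2 <= 1
  v <- values
  v[!mask] <- NA_real_
  inm <- v[mask]
  new("EITImage", values = v, mask = mask,
      amax = if (length(inm)) max(abs(inm)) else 0,
      foreground_hz = foreground_hz, background_hz = background_hz)
}

## paint a filled disk of a value onto a grid matrix (row 1 = top)
paintDisk <- function(values, cx, cy, radius, value) {
  g <- nrow(values)
  cs <- (seq_len(g) - 0.5) * 2 / g - 1
  x <- matrix(rep(cs, each = g), g, g)
  y <- matrix(rep(rev(cs), times = g), g, g)
  values[(x - cx)^2 + (y - cy)^2 <= radius^2] <- value
  values
}

## brute-force connected-component oracle (independent of labelComponents):
## repeatedly dilates a single seed within the foreground
floodFillOracle <- function(bin, connectivity = 8L) {
  nr <- nrow(bin); nc <- ncol(bin)
  comp <- matrix(0L, nr, nc)
  lab <- 0L
  while (any(bin & comp == 0L)) {
    lab <- lab + 1L
    seed <- which(bin & comp == 0L)[1L]
    cur <- matrix(FALSE, nr, nc)
    cur[seed] <- TRUE
    repeat {
      grown <- cur
      idx <- which(cur, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          if (connectivity == 4L && dr != 0 && dc != 0) next
          r <- idx[k, 1L] + dr; c <- idx[k, 2L] + dc
          if (r >= 1 && r <= nr && c >= 1 && c <= nc && bin[r, c])
            grown[r, c] <- TRUE
        }
      }
      if (identical(grown, cur)) break
      cur <- grown
    }
    comp[cur] <- lab
  }
  comp
}

## exhaustive permutation oracle for the rank-sum test (tie-free samples)
rankSumEnumOracle <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n1 + n2, n1)
  allw <- apply(sets, 2L, function(ix) sum(seq_len(n1 + n2)[ix]))
  mu <- n1 * (n1 + n2 + 1) / 2
  switch(alternative,
    greater = mean(allw >= wobs),
    less = mean(allw <= wobs),
    two.sided = min(1, 2 * min(mean(allw >= wobs), mean(allw <= wobs))))
}

## normalized L1 left-right asymmetry of an image
imageAsymmetry <- function(img) {
  v <- imageValues(img)
  v[is.na(v)] <- 0
  fl <- v[, rev(seq_len(ncol(v)))]
  sum(abs(v - fl)) / sum(abs(v))
}
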