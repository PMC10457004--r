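#' @importFrom Matrix sparseMatrix Cholesky solve t crossprod
NULL

## Assemble the P1 stiffness matrix K(sigma) for the conduction equation
## div(sigma grad u) = 0 on the unit disk (natural boundary conditions).
assembleStiffness <- function(mesh, sigma) {
  sv <- if (is(sigma, "ConductivityField")) fieldValues(sigma) else sigma
  m <- nElements(mesh)
  stopifnot(length(sv) == m)
  tr <- mesh@triangles
  w <- sv * mesh@areas
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) {
    for (b in 1:3) {
      k <- k + 1L
      ii[[k]] <- tr[, a]
      jj[[k]] <- tr[, b]
      xx[[k]] <- w * (mesh@gradx[, a] * mesh@gradx[, b] +
                      mesh@grady[, a] * mesh@grady[, b])
    }
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(nrow(mesh@nodes), nrow(mesh@nodes)))
}

## Electrode averaging matrix: 16 x n_nodes, row e = 1/|nodes_e| on the
## electrode's boundary nodes. Used both to extract electrode potentials and
## (scaled by the drive current) to build injection vectors, which makes the
## discrete model exactly reciprocal.
electrodeMatrix <- function(mesh) {
  ns <- lapply(mesh@electrodes, as.integer)
  i <- rep(seq_len(16L), vapply(ns, length, 1L))
  j <- unlist(ns)
  x <- 1 / rep(vapply(ns, length, 1L), vapply(ns, length, 1L))
  sparseMatrix(i = i, j = j, x = x, dims = c(16L, nrow(mesh@nodes)))
}

## Solve K u = B (multiple right-hand sides), grounding by fixing node 1 and
## shifting each solution to zero mean over the boundary electrode nodes.
## Each RHS must sum to zero (pure Neumann compatibility).
solveGrounded <- function(K, B, mesh) {
  B <- as.matrix(B)
  if (max(abs(colSums(B))) > 1e-10 * max(abs(B)))
    stop("right-hand side violates current conservation")
  n <- nrow(K)
  free <- 2:n
  ch <- tryCatch(Cholesky(forceSymmetricCsparse(K[free, free])),
                 error = function(e)
                   stop("singular forward system (disconnected mesh?): ",
                        conditionMessage(e)))
  U <- matrix(0, n, ncol(B))
  U[free, ] <- as.matrix(solve(ch, B[free, , drop = FALSE]))
  bn <- unique(unlist(mesh@electrodes))
  sweep(U, 2L, colMeans(U[bn, , drop = FALSE]))
}

forceSymmetricCsparse <- function(K) {
  ## numeric symmetrization guard; K is symmetric up to rounding
  methods::as((K + Matrix::t(K)) / 2, "symmetricMatrix")
}

#' Solve the forward conduction problem for one (or all) drive pairs
#'
#' Solves the quasi-static conduction equation on the meshed disk with the
#' protocol's RMS drive current injected at the positive electrode of the
#' opposite pair and extracted at the negative electrode (gap electrode
#' model: the current is split uniformly over the electrode's boundary
#' nodes). Potentials are grounded by the zero-mean convention over the
#' electrode boundary nodes.
#'
#' @param mesh an [EITMesh-class].
#' @param sigma a [ConductivityField-class] (or numeric vector of element
#'   conductivities, S/m).
#' @param protocol an [EITProtocol-class].
#' @param drive_index 1-based drive index, or NULL (default) to solve all
#'   drives at once.
#' @return a numeric vector of node potentials (V) for a single drive, or a
#'   matrix (n_nodes x n_drives) when \code{drive_index} is NULL.
#' @export
solveForward <- function(mesh, sigma, protocol, drive_index = NULL) {
  K <- assembleStiffness(mesh, sigma)
  E <- electrodeMatrix(mesh)
  dp <- drivePairs(protocol)
  if (!is.null(drive_index)) {
    stopifnot(drive_index >= 1L, drive_index <= nrow(dp))
    dp <- dp[drive_index, , drop = FALSE]
  }
  I0 <- driveCurrent(protocol)
  B <- I0 * Matrix::t(E[dp[, 1L] + 1L, , drop = FALSE] -
                      E[dp[, 2L] + 1L, , drop = FALSE])
  U <- solveGrounded(K, B, mesh)
  if (!is.null(drive_index)) drop(U) else U
}

#' Apply the measurement protocol to solved potentials
#'
#' Extracts one differential voltage per measurement channel: electrode
#' potential is the mean over the electrode's boundary node set, and channel
#' voltage is (first electrode of the pair) minus (second).
#'
#' @param potentials node potentials: matrix (n_nodes x n_drives) or a list
#'   of per-drive vectors, in protocol drive order.
#' @param protocol an [EITProtocol-class].
#' @param mesh the [EITMesh-class] the potentials were solved on.
#' @return numeric matrix (n_drives x 12) of channel voltages (V).
#' @export
measureFrame <- function(potentials, protocol, mesh) {
  if (is.list(potentials)) potentials <- do.call(cbind, potentials)
  if (is.null(dim(potentials))) potentials <- cbind(potentials)
  dp <- drivePairs(protocol)
  if (ncol(potentials) != nrow(dp))
    stop("need one potential field per protocol drive (got ",
         ncol(potentials), ", protocol has ", nrow(dp), ")")
  E <- as.matrix(electrodeMatrix(mesh) %*% potentials)  # 16 x n_drives
  mps <- measurementPairs(protocol)
  out <- matrix(0, nrow(dp), 12L)
  for (d in seq_len(nrow(dp))) {
    mp <- mps[[d]]
    out[d, ] <- E[mp[, 1L] + 1L, d] - E[mp[, 2L] + 1L, d]
  }
  out
}

#' Simulate one noise-free frame (all drives, one conductivity field)
#'
#' Convenience wrapper: forward-solve every drive and apply the measurement
#' protocol.
#'
#' @inheritParams solveForward
#' @return numeric matrix (n_drives x 12) of channel voltages (V).
#' @export
forwardFrame <- function(mesh, sigma, protocol) {
  measureFrame(solveForward(mesh, sigma, protocol), protocol, mesh)
}

#' Sensitivity (Jacobian) of the measured voltages to element conductivity
#'
#' Computes the linearization J[m, e] = d(channel m voltage)/d(element e
#' conductivity) at a reference conductivity field by the adjoint-field
#' method: J[m, e] = -area_e * grad(w_m) . grad(u_d), where u_d is the drive
#' field and w_m the adjoint field of the measurement pair (unit current
#' injected through the measurement electrodes). Rows are ordered
#' drive-major: row (d-1)*12 + j is channel j of drive d.
#'
#' @param mesh an [EITMesh-class].
#' @param sigma_ref reference [ConductivityField-class] (or numeric vector).
#' @param protocol an [EITProtocol-class].
#' @return numeric matrix (n_drives*12 x n_elements), V per (S/m).
#' @export
computeJacobian <- function(mesh, sigma_ref, protocol) {
  K <- assembleStiffness(mesh, sigma_ref)
  E <- electrodeMatrix(mesh)
  dp <- drivePairs(protocol)
  ndr <- nrow(dp)
  I0 <- driveCurrent(protocol)

  ## drive fields
  Bd <- I0 * Matrix::t(E[dp[, 1L] + 1L, , drop = FALSE] -
                       E[dp[, 2L] + 1L, , drop = FALSE])
  ## adjoint fields, one per adjacent electrode pair (i, i+1), i = 0..15
  i0 <- 0:15
  Ba <- Matrix::t(E[i0 + 1L, , drop = FALSE] -
                  E[(i0 + 1L) %% 16L + 1L, , drop = FALSE])
  U <- solveGrounded(K, cbind(as.matrix(Bd), as.matrix(Ba)), mesh)
  Ud <- U[, seq_len(ndr), drop = FALSE]
  Ua <- U[, ndr + seq_len(16L), drop = FALSE]

  ## per-element gradients of each field
  gradOf <- function(V) {
    tr <- mesh@triangles
    gx <- mesh@gradx[, 1L] * V[tr[, 1L], ] + mesh@gradx[, 2L] * V[tr[, 2L], ] +
          mesh@gradx[, 3L] * V[tr[, 3L], ]
    gy <- mesh@grady[, 1L] * V[tr[, 1L], ] + mesh@grady[, 2L] * V[tr[, 2L], ] +
          mesh@grady[, 3L] * V[tr[, 3L], ]
    list(x = gx, y = gy)
  }
  gd <- gradOf(Ud)
  ga <- gradOf(Ua)

  m <- nElements(mesh)
  J <- matrix(0, ndr * 12L, m)
  mps <- measurementPairs(protocol)
  for (d in seq_len(ndr)) {
    mp <- mps[[d]]
    ## adjacent pair (i, i+1) has adjoint index i+1
    ai <- mp[, 1L] + 1L
    for (j in seq_len(12L)) {
      a <- ai[j]
      J[(d - 1L) * 12L + j, ] <-
        -mesh@areas * (gd$x[, d] * ga$x[, a] + gd$y[, d] * ga$y[, a])
    }
  }
  J
}
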