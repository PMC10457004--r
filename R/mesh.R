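#' Build a deterministic triangular mesh of the unit-disk imaging domain
#'
#' Triangulates the unit disk with concentric rings of nodes aligned to the
#' 16-electrode layout: ring k (of R) has 16k nodes at radius k/R, so the
#' boundary ring always carries a multiple of 16 nodes and the 16 electrode
#' arcs are equally spaced with electrode 0 centered at the top (anterior),
#' indices increasing clockwise. The construction is fully deterministic:
#' identical inputs give identical meshes. Element count is 16 R^2 with R
#' chosen so that the count is within about 30% of \code{n_target_elements}.
#'
#' @param n_target_elements requested element count (>= 64).
#' @param n_electrodes number of electrodes; must be 16.
#' @return an [EITMesh-class].
#' @examples
#' m <- buildMesh(1024)
#' nElements(m)          # 1024
#' sum(elementAreas(m))  # close to pi
#' @export
buildMesh <- function(n_target_elements, n_electrodes = 16L) {
  stopifnot(n_target_elements >= 64, n_electrodes == 16L)
  R <- max(2L, as.integer(round(sqrt(n_target_elements / 16))))

  ## nodes: center + rings, clockwise from the top
  ringStart <- integer(R + 1L)  # 1-based index of first node of ring k
  nodes <- matrix(0, nrow = 1L + 16L * sum(seq_len(R)), ncol = 2L)
  idx <- 1L
  for (k in seq_len(R)) {
    ringStart[k + 1L] <- idx + 1L
    nk <- 16L * k
    j <- seq_len(nk) - 1L
    th <- (90 - j * 360 / nk) * pi / 180
    nodes[idx + seq_len(nk), ] <- cbind(cos(th), sin(th)) * (k / R)
    idx <- idx + nk
  }
  ringStart[1L] <- 1L  # "ring 0" is the center node

  ringNode <- function(k, j) {
    # node index of the j-th (0-based, modular) node of ring k; k=0 -> center
    if (k == 0L) return(1L)
    ringStart[k + 1L] + (j %% (16L * k))
  }

  ## triangulate the right half (angle parameter t in [0, 1/2], clockwise
  ## from the top) and mirror it across the vertical axis, so the mesh is
  ## exactly mirror-symmetric: ring k node j reflects to node (16k - j) mod
  ## 16k. Left-right symmetry of the triangulation keeps healthy phantoms
  ## and their images free of mesh-induced asymmetry.
  mirrorNode <- function(k, j) ringNode(k, (16L * k - j))
  tris <- vector("list", R)
  ## ring 1: fan around the center, right half then its mirror image
  fan <- t(vapply(0:7, function(j)
    c(1L, ringNode(1L, j + 1L), ringNode(1L, j)), integer(3L)))
  fanm <- t(vapply(0:7, function(j)
    c(1L, mirrorNode(1L, j + 1L), mirrorNode(1L, j)), integer(3L)))
  tris[[1L]] <- rbind(fan, fanm)
  ## rings 2..R: angle-ordered merge of the two half node circles
  for (k in seq_len(R)[-1L]) {
    n1 <- 16L * (k - 1L); n2 <- 16L * k
    half <- matrix(0L, nrow = (n1 + n2) %/% 2L, ncol = 3L)
    i <- 0L; j <- 0L; t <- 0L
    while (i < n1 %/% 2L || j < n2 %/% 2L) {
      t <- t + 1L
      advance_outer <- i >= n1 %/% 2L ||
        (j < n2 %/% 2L && (j + 1) / n2 <= (i + 1) / n1)
      if (advance_outer) {
        half[t, ] <- c(ringNode(k - 1L, i), ringNode(k, j + 1L), ringNode(k, j))
        j <- j + 1L
      } else {
        half[t, ] <- c(ringNode(k - 1L, i), ringNode(k - 1L, i + 1L), ringNode(k, j))
        i <- i + 1L
      }
    }
    halfm <- half
    for (col in 1:3) {
      v <- half[, col]
      ring <- findInterval(v, ringStart[-1L])  # ring of each node (k-1 or k)
      jj <- v - ringStart[ring + 1L]
      halfm[, col] <- vapply(seq_along(v), function(q)
        mirrorNode(ring[q], jj[q]), 1L)
    }
    tris[[k]] <- rbind(half, halfm)
  }
  triangles <- do.call(rbind, tris)

  ## orient counter-clockwise, compute areas and P1 gradients
  x1 <- nodes[triangles[, 1L], 1L]; y1 <- nodes[triangles[, 1L], 2L]
  x2 <- nodes[triangles[, 2L], 1L]; y2 <- nodes[triangles[, 2L], 2L]
  x3 <- nodes[triangles[, 3L], 1L]; y3 <- nodes[triangles[, 3L], 2L]
  s <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- s < 0
  if (any(flip)) {
    tmp <- triangles[flip, 2L]
    triangles[flip, 2L] <- triangles[flip, 3L]
    triangles[flip, 3L] <- tmp
  }
  geo <- triangleGeometry(nodes, triangles)
  if (any(geo$areas < 1e-12))
    stop("meshing produced a degenerate (zero-area) triangle")

  ## electrode arcs on the boundary ring: nodes within half an electrode
  ## width (11.25 deg total) of each electrode center
  nb <- 16L * R
  jb <- seq_len(nb) - 1L
  bidx <- ringStart[R + 1L] + jb
  bang <- (90 - jb * 360 / nb) %% 360
  electrodes <- vector("list", 16L)
  for (e in 0:15) {
    ce <- (90 - 22.5 * e) %% 360
    d <- abs((bang - ce + 180) %% 360 - 180)
    electrodes[[e + 1L]] <- bidx[d <= 5.625 + 1e-9]
  }

  new("EITMesh", nodes = nodes, triangles = triangles,
      electrodes = electrodes, areas = geo$areas,
      gradx = geo$gradx, grady = geo$grady)
}

## areas and P1 shape-function gradients for each triangle
triangleGeometry <- function(nodes, triangles) {
  x <- matrix(nodes[triangles, 1L], ncol = 3L)
  y <- matrix(nodes[triangles, 2L], ncol = 3L)
  ## grad phi_i = (b_i, c_i) / (2A) with b_i = y_j - y_k, c_i = x_k - x_j
  b <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L])
  cc <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L])
  areas <- 0.5 * ((x[, 2L] - x[, 1L]) * (y[, 3L] - y[, 1L]) -
                  (x[, 3L] - x[, 1L]) * (y[, 2L] - y[, 1L]))
  list(areas = areas, gradx = b / (2 * areas), grady = cc / (2 * areas))
}

#' Element centroids of a mesh
#'
#' @param mesh an [EITMesh-class].
#' @return numeric matrix (n_elements x 2).
#' @export
elementCentroids <- function(mesh) {
  tr <- meshTriangles(mesh)
  nd <- meshNodes(mesh)
  (nd[tr[, 1L], , drop = FALSE] + nd[tr[, 2L], , drop = FALSE] +
     nd[tr[, 3L], , drop = FALSE]) / 3
}
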