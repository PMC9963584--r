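# Independent brute-force periodic Voronoi oracle.
#
# Enumerates ALL triples of bisector planes (all sites and their periodic
# images within a distance cutoff), solves each 3x3 system by Cramer's rule
# and keeps intersection points that satisfy every half-space constraint.
# Completely independent of the package's incremental clipping engine.
oracle_cell <- function(config, site = config$solute_index, cutoff = NULL,
                        tol = 1e-8) {
  L <- config$box_length
  pos <- config$positions
  n <- nrow(pos)
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)) * L
  disp <- matrix(0, 0, 3)
  for (j in seq_len(n)) {
    u <- pos[j, ] - pos[site, ]
    v <- sweep(shifts, 2, u, `+`)
    v <- v[rowSums(v^2) > 1e-12, , drop = FALSE]
    disp <- rbind(disp, v)
  }
  if (is.null(cutoff)) cutoff <- 0.9 * L
  repeat {
    d <- sqrt(rowSums(disp^2))
    keep <- d <= cutoff
    nrm <- disp[keep, , drop = FALSE] / d[keep]
    h <- d[keep] / 2
    np <- nrow(nrm)
    stopifnot(np >= 4)
    verts <- matrix(0, 0, 3)
    for (i in 1:(np - 2)) {
      for (j in (i + 1):(np - 1)) {
        # Cramer's rule, partially hoisted
        a <- nrm[i, ]; b <- nrm[j, ]
        cx <- a[2] * b[3] - a[3] * b[2]
        cy <- a[3] * b[1] - a[1] * b[3]
        cz <- a[1] * b[2] - a[2] * b[1]
        for (k in (j + 1):np) {
          cc <- nrm[k, ]
          det <- cx * cc[1] + cy * cc[2] + cz * cc[3]
          if (abs(det) < 1e-10) next
          p <- solve(rbind(a, b, cc), c(h[i], h[j], h[k]))
          if (all(nrm %*% p - h <= tol)) verts <- rbind(verts, p)
        }
      }
    }
    stopifnot(nrow(verts) >= 4)
    # dedup
    uq <- matrix(0, 0, 3)
    for (q in seq_len(nrow(verts))) {
      if (nrow(uq) == 0 ||
          min(rowSums(sweep(uq, 2, verts[q, ])^2)) > (10 * tol)^2)
        uq <- rbind(uq, verts[q, ])
    }
    maxv <- sqrt(max(rowSums(uq^2)))
    if (2 * maxv <= cutoff) break  # no excluded plane could have cut
    cutoff <- cutoff * 1.5
  }
  # faces: planes supporting >= 3 vertices
  on_plane <- abs(sweep(uq %*% t(nrm), 2, h)) <= 10 * tol
  face_planes <- which(colSums(on_plane) >= 3)
  vol <- 0
  areas <- numeric(0)
  for (fp in face_planes) {
    fv <- uq[on_plane[, fp], , drop = FALSE]
    nrm_f <- nrm[fp, ]
    e1 <- if (abs(nrm_f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * nrm_f) * nrm_f
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm_f[2] * e1[3] - nrm_f[3] * e1[2],
            nrm_f[3] * e1[1] - nrm_f[1] * e1[3],
            nrm_f[1] * e1[2] - nrm_f[2] * e1[1])
    ctr <- colMeans(fv)
    rel <- sweep(fv, 2, ctr)
    ang <- atan2(rel %*% e2, rel %*% e1)
    fv <- fv[order(ang), , drop = FALSE]
    a <- 0
    for (q in 2:(nrow(fv) - 1)) {
      u1 <- fv[q, ] - fv[1, ]; u2 <- fv[q + 1, ] - fv[1, ]
      cr <- c(u1[2] * u2[3] - u1[3] * u2[2], u1[3] * u2[1] - u1[1] * u2[3],
              u1[1] * u2[2] - u1[2] * u2[1])
      a <- a + 0.5 * sqrt(sum(cr^2))
    }
    areas <- c(areas, a)
    vol <- vol + a * h[fp] / 3
  }
  # edge count: pairs of face planes sharing exactly 2 vertices
  ne <- 0
  for (i in seq_along(face_planes)) {
    for (j in seq_along(face_planes)) {
      if (j <= i) next
      shared <- sum(on_plane[, face_planes[i]] & on_plane[, face_planes[j]])
      if (shared == 2) ne <- ne + 1
    }
  }
  list(vertices = uq, nf = length(face_planes), nv = nrow(uq), ne = ne,
       volume = vol, surface = sum(areas),
       face_d = 2 * h[face_planes])
}
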