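# Independent oracles. These deliberately use different algorithms from the
# package (candidate enumeration instead of Voronoi-region walking, plain
# all-faces scans instead of the grid index, list-based UPGMA instead of
# hclust) so agreement is informative.

# closest point on one triangle by candidate enumeration: the orthogonal
# projection onto the plane (if its barycentric coordinates are inside) and
# the clamped projections onto the three edges
oracle_point_triangle <- function(p, tri) {
  a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
  seg <- function(s, e) {
    t <- sum((p - s) * (e - s)) / sum((e - s)^2)
    s + min(max(t, 0), 1) * (e - s)
  }
  cand <- list(seg(a, b), seg(a, c), seg(b, c))
  e1 <- b - a; e2 <- c - a
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  uv <- solve(G, c(sum(e1 * (p - a)), sum(e2 * (p - a))))
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
    cand <- c(cand, list(a + uv[1] * e1 + uv[2] * e2))
  d <- vapply(cand, function(q) sum((p - q)^2), 1.0)
  list(point = cand[[which.min(d)]], distance = sqrt(min(d)))
}

# exact nearest distance from one point to every face of a mesh, vectorised
# over faces (candidate enumeration as above)
oracle_mesh_distance <- function(p, mesh) {
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  seg_d2 <- function(S, E) {
    D <- E - S
    Pm <- matrix(p, nrow(S), 3, byrow = TRUE)
    t <- rowSums((Pm - S) * D) / rowSums(D * D)
    t <- pmin(pmax(t, 0), 1)
    Q <- S + D * t
    rowSums((Pm - Q)^2)
  }
  d2 <- pmin(seg_d2(A, B), seg_d2(A, C), seg_d2(B, C))
  e1 <- B - A; e2 <- C - A
  Pm <- matrix(p, nrow(A), 3, byrow = TRUE)
  d11 <- rowSums(e1 * e1); d22 <- rowSums(e2 * e2); d12 <- rowSums(e1 * e2)
  r1 <- rowSums(e1 * (Pm - A)); r2 <- rowSums(e2 * (Pm - A))
  det <- d11 * d22 - d12^2
  u <- (d22 * r1 - d12 * r2) / det
  v <- (d11 * r2 - d12 * r1) / det
  inside <- u >= 0 & v >= 0 & (u + v) <= 1 & det > 0
  if (any(inside)) {
    Q <- A[inside, , drop = FALSE] + e1[inside, , drop = FALSE] * u[inside] +
      e2[inside, , drop = FALSE] * v[inside]
    d2[inside] <- pmin(d2[inside],
                       rowSums((Pm[inside, , drop = FALSE] - Q)^2))
  }
  sqrt(min(d2))
}

# agglomerative average-linkage (UPGMA) clustering on the raw dissimilarity,
# smallest-index pair on ties; returns merge heights and the member sets
# participating in each merge
oracle_upgma <- function(m, metric = "euclidean") {
  D <- as.matrix(dist(m, method = metric))
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd - 1e-12) {
          bestd <- d; best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1L]] <-
      list(height = bestd,
           left = rownames(m)[clusters[[best[1]]]],
           right = rownames(m)[clusters[[best[2]]]])
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Holm step-down adjustment computed from its definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}
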