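# Independent brute-force oracles used to validate the library kernels.
# These deliberately use different algorithms / code paths than the package.

# closest point on a triangle by projection + edge clamping (pure R)
oracle_point_tri_dist <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / max(sum(d * d), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * d))^2))
  }
  n <- pracma_cross(b - a, c - a)
  n2 <- sum(n * n)
  if (n2 < .Machine$double.eps)
    return(min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, a, c)))
  # barycentric coordinates of the projection
  q <- p - n * sum((p - a) * n) / n2
  areas <- c(sum(pracma_cross(b - q, c - q) * n),
             sum(pracma_cross(c - q, a - q) * n),
             sum(pracma_cross(a - q, b - q) * n)) / n2
  if (all(areas >= 0)) return(sqrt(sum((p - q)^2)))
  min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, a, c))
}

pracma_cross <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])

# exhaustive min-over-faces point-to-mesh distance
oracle_point_mesh_dist <- function(points, mesh) {
  apply(points, 1, function(p) {
    min(apply(mesh$faces, 1, function(f)
      oracle_point_tri_dist(p, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                            mesh$vertices[f[3], ])))
  })
}

# exhaustive nearest-neighbor squared-distance Chamfer with weights
oracle_chamfer <- function(p_pred, p_ref, w_ref = rep(1, nrow(p_ref))) {
  w <- w_ref / mean(w_ref)
  d2 <- function(a, b) {
    # full distance matrix
    outer(rowSums(a^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  }
  m <- d2(p_pred, p_ref)
  mean(apply(m, 1, min)) + mean(w * apply(m, 2, min))
}

# edge-triangle (segment) intersection used in the independent tri-tri test
oracle_seg_tri_hit <- function(p0, p1, a, b, c, tol = 1e-10) {
  m <- cbind(p1 - p0, a - b, a - c)
  if (abs(det(m)) < tol) return(FALSE)
  s <- solve(m, a - p0)
  t <- s[1]; u <- s[2]; v <- s[3]
  t > tol && t < 1 - tol && u > tol && v > tol && u + v < 1 - tol
}

# proper intersection of two non-coplanar triangles: some edge of one
# crosses the interior of the other
oracle_tri_tri <- function(t1, t2) {
  edges <- list(c(1, 2), c(2, 3), c(3, 1))
  for (e in edges) {
    if (oracle_seg_tri_hit(t1[e[1], ], t1[e[2], ], t2[1, ], t2[2, ], t2[3, ])) return(TRUE)
    if (oracle_seg_tri_hit(t2[e[1], ], t2[e[2], ], t1[1, ], t1[2, ], t1[3, ])) return(TRUE)
  }
  FALSE
}

# all-pairs self-intersection oracle (excludes faces sharing a vertex)
oracle_self_intersections <- function(mesh) {
  nf <- nrow(mesh$faces)
  hit <- rep(FALSE, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    if (length(intersect(mesh$faces[i, ], mesh$faces[j, ]))) next
    t1 <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    t2 <- mesh$vertices[mesh$faces[j, ], , drop = FALSE]
    if (oracle_tri_tri(t1, t2)) hit[i] <- hit[j] <- TRUE
  }
  hit
}

# random closed-ish small test mesh: perturbed icosphere
random_bumpy_sphere <- function(seed, level = 1, radius = 1, sd = 0.05) {
  m <- icosphere(level, radius)
  set.seed(seed)
  m$vertices <- m$vertices + matrix(rnorm(length(m$vertices), 0, sd), ncol = 3)
  m
}

# small deterministic single-triangle mesh
one_triangle <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                matrix(1:3, 1, 3), validate = FALSE)
}
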