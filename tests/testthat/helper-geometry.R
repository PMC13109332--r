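## Shared geometric fixtures, all built in code.

rand_rotation <- function() {
  rodrigues_rotation(rnorm(3), runif(1, 0, 2 * pi))
}

rand_similarity <- function(scale_range = c(0.5, 3), t_sd = 100) {
  similarity_transform(rand_rotation(), rnorm(3, 0, t_sd),
                       runif(1, scale_range[1], scale_range[2]))
}

rand_cloud <- function(n, sd = 1) {
  colored_point_cloud(matrix(rnorm(3 * n, sd = sd), n, 3),
                      matrix(runif(3 * n), n, 3))
}

## unit cube (0,1)^3 as 12 outward-oriented triangles
cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),      # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),      # top (+z)
             c(1, 2, 6), c(1, 6, 5),      # front (-y)
             c(2, 3, 7), c(2, 7, 6),      # right (+x)
             c(3, 4, 8), c(3, 8, 7),      # back (+y)
             c(4, 1, 5), c(4, 5, 8))      # left (-x)
  triangle_mesh(v, f)
}

tet_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  triangle_mesh(v, f)
}

## icosphere: subdivided icosahedron projected onto the sphere
icosphere_mesh <- function(radius = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_env <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- mid_env[[key]]
      if (!is.null(idx)) return(idx)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_env[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(c_, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- newf
  }
  triangle_mesh(v * radius, f)
}

## O(N^2) brute-force oracle for statistical outlier removal
sor_brute_force <- function(cloud, m, k) {
  d <- as.matrix(dist(cloud$points))
  diag(d) <- Inf
  per <- t(apply(d, 1L, function(r) {
    nn <- sort(r)[seq_len(m)]
    mu <- mean(nn)
    c(mu, sqrt(mean((nn - mu)^2)))
  }))
  d_bar <- mean(per[, 1])
  sigma <- mean(per[, 2])
  list(mean_dist = per[, 1], sd_dist = per[, 2],
       removed_ids = cloud$ids[per[, 1] > d_bar + k * sigma])
}

## scalar-loop hexcone conversion, independent of grDevices
hsv_oracle <- function(colors) {
  t(apply(colors, 1L, function(p) {
    mx <- max(p); mn <- min(p); d <- mx - mn
    h <- if (d == 0) 0
    else if (mx == p[1]) 60 * (((p[2] - p[3]) / d) %% 6)
    else if (mx == p[2]) 60 * ((p[3] - p[1]) / d + 2)
    else 60 * ((p[1] - p[2]) / d + 4)
    c(h, if (mx == 0) 0 else d / mx, mx)
  }))
}

## tiny scene for fast pipeline tests
small_scene_config <- function(seed = 1L, transform = similarity_transform()) {
  scene_config(n_blades = 60L, points_per_blade = 120L,
               soil_point_density = 0.1, n_reflection_noise = 300L,
               n_background_noise = 150L, applied_transform = transform,
               rng_seed = seed)
}
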