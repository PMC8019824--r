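# Independent reference implementations used as oracles. These share no
# code with the package: plain-R breadth-first searches and closed forms.

# offsets of the 3x3x3 neighbourhood in the same layout the package uses
# for configuration vectors: index o = (dx+1) + 3*(dy+1) + 9*(dz+1) + 1
nb27_offsets <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[order(g$dz, g$dy, g$dx), c("dx", "dy", "dz")])
})

offset_adjacent_r <- function(a, b, j) {
  d <- abs(a - b)
  ch <- max(d); l1 <- sum(d)
  if (ch != 1) return(FALSE)
  if (j == 6) return(l1 == 1)
  if (j == 18) return(l1 <= 2)
  TRUE
}

# count connected components among the rows of `pts` under j-adjacency
count_components_pts <- function(pts, j) {
  n <- nrow(pts)
  if (n == 0) return(0L)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      for (t in seq_len(n)) {
        if (!seen[t] &&
            offset_adjacent_r(pts[c0, ], pts[t, ], j)) {
          seen[t] <- TRUE
          queue <- c(queue, t)
        }
      }
    }
  }
  comps
}

# literal simple-point definition on a 27-cell configuration (centre at
# offset (0,0,0), black): one 26-component of black in N26 and one
# 6-component of white in N18 (6-paths inside N18) touching a face cell
oracle_is_simple <- function(nb27) {
  off <- nb27_offsets
  centre <- which(rowSums(abs(off)) == 0)
  black <- which(nb27 & seq_len(27) != centre)
  if (count_components_pts(off[black, , drop = FALSE], 26) != 1) return(FALSE)
  in18 <- which(rowSums(abs(off)) <= 2 & seq_len(27) != centre)
  white18 <- setdiff(in18, which(nb27))
  if (length(white18) == 0) return(FALSE)
  pts <- off[white18, , drop = FALSE]
  n <- nrow(pts)
  seen <- rep(FALSE, n)
  good <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s; queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      for (t in seq_len(n)) {
        if (!seen[t] && offset_adjacent_r(pts[c0, ], pts[t, ], 6)) {
          seen[t] <- TRUE; comp <- c(comp, t); queue <- c(queue, t)
        }
      }
    }
    if (any(rowSums(abs(pts[comp, , drop = FALSE])) == 1)) good <- good + 1L
  }
  good == 1L
}

# flood-fill component count over a full 3D logical array (26- or
# 6-connectivity), plain R
oracle_n_components <- function(occ, j = 26) {
  idx <- which(occ, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(idx))) assign(key[r], r, envir = lookup)
  off <- nb27_offsets[rowSums(abs(nb27_offsets)) > 0, , drop = FALSE]
  if (j == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  seen <- rep(FALSE, nrow(idx))
  comps <- 0L
  for (s in seq_len(nrow(idx))) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      for (r in seq_len(nrow(off))) {
        k <- paste(idx[c0, 1] + off[r, 1], idx[c0, 2] + off[r, 2],
                   idx[c0, 3] + off[r, 3])
        t <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(t) && !seen[t]) {
          seen[t] <- TRUE; queue <- c(queue, t)
        }
      }
    }
  }
  comps
}

# random blob volume: union of a few solid spheres on a small grid
random_blob <- function(shape = c(12, 12, 12), n_spheres = 3) {
  occ <- array(FALSE, shape)
  g <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                             z = seq_len(shape[3])))
  for (i in seq_len(n_spheres)) {
    c0 <- runif(3, 3, shape - 2)
    r <- runif(1, 1.2, 3)
    d2 <- (g[, 1] - c0[1])^2 + (g[, 2] - c0[2])^2 + (g[, 3] - c0[3])^2
    occ[g[d2 <= r^2, , drop = FALSE]] <- TRUE
  }
  binary_volume(occ)
}

uniform_axes <- function(n) {
  y <- matrix(rnorm(3 * n), ncol = 3)
  y / sqrt(rowSums(y^2))
}

# spherical quadrature grid (Gauss-Legendre x trapezoid), independent of
# the package's internal quadrature code
sphere_grid <- function(m = 80) {
  i <- seq_len(m - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, m, m)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  u <- e$values; wu <- 2 * e$vectors[1, ]^2
  phi <- (seq_len(2 * m) - 0.5) * pi / m
  X <- do.call(rbind, lapply(seq_along(u), function(k) {
    s <- sqrt(1 - u[k]^2)
    cbind(s * cos(phi), s * sin(phi), u[k])
  }))
  list(X = X, w = rep(wu, each = 2 * m) * pi / m)
}

# straight solid tube along the first axis, radius in voxels
tube_volume <- function(nx = 40, r = 3, pad = 3) {
  side <- 2 * pad + 1
  occ <- array(FALSE, c(nx, side, side))
  c0 <- pad + 1
  for (y in seq_len(side)) for (z in seq_len(side))
    if ((y - c0)^2 + (z - c0)^2 <= r^2) occ[, y, z] <- TRUE
  binary_volume(occ)
}

detected_cluster_slices <- function(flags, n_min = 4) {
  r <- rle(flags == "significant")
  pos <- cumsum(c(1, r$lengths))
  out <- integer(0)
  for (k in seq_along(r$values))
    if (r$values[k] && r$lengths[k] >= n_min)
      out <- c(out, (pos[k]:(pos[k] + r$lengths[k] - 1)) - 1L)
  out
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}
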