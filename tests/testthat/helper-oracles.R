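# Independent oracles used across the suite. Each is a deliberately naive,
# loop-based implementation kept separate from the package's code paths.

# polyline length of a densely resampled centerline
oracle_polyline_length <- function(spec, n = 10000L) {
  p <- resample_centerline(spec, n)
  sum(sqrt(rowSums(diff(p)^2)))
}

# exhaustive-cut threshold criteria; h[i] counts intensity i-1
oracle_cuts <- function(h) {
  occ <- which(h > 0) - 1L
  seq(min(occ), max(occ) - 1L)
}

oracle_otsu <- function(h) {
  p <- h / sum(h)
  v <- seq_along(h) - 1L
  best <- -Inf; bt <- NA
  for (t in oracle_cuts(h)) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(t + 1)] * v[1:(t + 1)]) / w0
    mu1 <- sum(p[-(1:(t + 1))] * v[-(1:(t + 1))]) / w1
    crit <- w0 * w1 * (mu0 - mu1)^2
    if (crit > best + 1e-12) { best <- crit; bt <- t }
  }
  bt
}

oracle_li <- function(h) {
  v <- seq_along(h) - 1L
  best <- Inf; bt <- NA
  for (t in oracle_cuts(h)) {
    i0 <- 1:(t + 1); i1 <- setdiff(seq_along(h), i0)
    a0 <- sum(h[i0] * v[i0]); n0 <- sum(h[i0])
    a1 <- sum(h[i1] * v[i1]); n1 <- sum(h[i1])
    s <- 0
    if (n0 > 0 && a0 > 0) s <- s - a0 * log(a0 / n0)
    if (n1 > 0 && a1 > 0) s <- s - a1 * log(a1 / n1)
    if (s < best - 1e-12) { best <- s; bt <- t }
  }
  bt
}

oracle_yen <- function(h) {
  p <- h / sum(h)
  best <- -Inf; bt <- NA
  for (t in oracle_cuts(h)) {
    i0 <- 1:(t + 1)
    w0 <- sum(p[i0]); w1 <- 1 - w0
    g0 <- sum(p[i0]^2); g1 <- sum(p[-i0]^2)
    if (w0 <= 0 || w1 <= 0 || g0 <= 0 || g1 <= 0) next
    crit <- -log(g0 * g1) + 2 * log(w0 * w1)
    if (crit > best + 1e-12) { best <- crit; bt <- t }
  }
  bt
}

oracle_renyi <- function(h, alpha = 2) {
  p <- h / sum(h)
  ent <- function(q) {
    q <- q[q > 0]
    if (!length(q)) return(-Inf)
    if (abs(alpha - 1) < 1e-12) return(-sum(q * log(q)))
    log(sum(q^alpha)) / (1 - alpha)
  }
  best <- -Inf; bt <- NA
  for (t in oracle_cuts(h)) {
    i0 <- 1:(t + 1)
    w0 <- sum(p[i0]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    crit <- ent(p[i0] / w0) + ent(p[-i0] / w1)
    if (crit > best + 1e-12) { best <- crit; bt <- t }
  }
  bt
}

oracle_shanbhag <- function(h) {
  p <- h / sum(h)
  n <- length(p)
  P1 <- cumsum(p)
  P2 <- rev(cumsum(rev(p)))
  best <- Inf; bt <- NA
  for (t in oracle_cuts(h)) {
    it <- t + 1L
    if (P1[it] <= 0 || P2[it + 1] <= 0) next
    term <- 0.5 / P1[it]
    eb <- 0
    if (it >= 2) for (ih in 2:it)
      eb <- eb - p[ih] * log(max(1 - term * P1[ih - 1], 1e-300))
    eb <- eb * term
    term <- 0.5 / P2[it + 1]
    eo <- 0
    if (it + 1 <= n - 1) for (ih in (it + 1):(n - 1))
      eo <- eo - p[ih] * log(max(1 - term * P2[ih + 1], 1e-300))
    eo <- eo * term
    crit <- abs(eb - eo)
    if (crit < best - 1e-12) { best <- crit; bt <- t }
  }
  bt
}

# moment-preserving reference: recompute p0 from raw moments, cut at the
# cumulative crossing (independent loop-based arithmetic)
oracle_moments <- function(h) {
  p <- h / sum(h)
  v <- seq_along(h) - 1L
  m1 <- sum(p * v); m2 <- sum(p * v^2); m3 <- sum(p * v^3)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- max(c1^2 - 4 * c0, 0)
  z0 <- 0.5 * (-c1 - sqrt(disc)); z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- 0
  for (i in seq_along(p)) {
    cum <- cum + p[i]
    if (cum >= p0) { t <- i - 1L; break }
  }
  cuts <- oracle_cuts(h)
  min(max(t, min(cuts)), max(cuts))
}

# iterated 3-bin smoothing until bimodal; valley between the two peaks
oracle_minimum <- function(h) {
  hs <- as.numeric(h)
  n_peaks <- function(x) {
    n <- length(x)
    sum(x > c(-Inf, x[-n]) & x >= c(x[-1], -Inf))
  }
  it <- 0
  while (n_peaks(hs) > 2) {
    n <- length(hs)
    hs <- (c(hs[1], hs[-n]) + hs + c(hs[-1], hs[n])) / 3
    it <- it + 1
    if (it > 10000) stop("not bimodal")
  }
  n <- length(hs)
  peaks <- which(hs > c(-Inf, hs[-n]) & hs >= c(hs[-1], -Inf))
  rng <- peaks[1]:peaks[2]
  rng[which.min(hs[rng])] - 1L
}

# random histogram with two modes plus noise (always >= 2 occupied bins)
random_histogram <- function(nbins = 256L) {
  h <- numeric(nbins)
  k <- sample(2:4, 1)
  for (j in seq_len(k)) {
    mu <- runif(1, 10, nbins - 10)
    sd <- runif(1, 3, 25)
    x <- pmin(pmax(round(rnorm(sample(200:2000, 1), mu, sd)), 0), nbins - 1)
    h <- h + tabulate(x + 1L, nbins)
  }
  h
}

# flood-fill connected-component labeling (queue-based, R only)
oracle_label <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        yy <- ci[1] + offs[r, 1]; xx <- ci[2] + offs[r, 2]
        zz <- ci[3] + offs[r, 3]
        if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] ||
            zz < 1 || zz > d[3]) next
        if (!mask[yy, xx, zz] || lab[yy, xx, zz] != 0L) next
        lab[yy, xx, zz] <- nxt
        queue <- c(queue, (zz - 1L) * d[1] * d[2] + (xx - 1L) * d[1] + yy)
      }
    }
  }
  lab
}

# plain Dijkstra over a skeleton voxel array with physical weights
oracle_dijkstra_lengths <- function(skel, vs) {
  d <- dim(skel)
  coords <- which(skel, arr.ind = TRUE)
  n <- nrow(coords)
  adj <- vector("list", n)
  key <- coords[, 1] + d[1] * (coords[, 2] - 1L) + d[1] * d[2] * (coords[, 3] - 1L)
  lut <- integer(prod(d)); lut[key] <- seq_len(n)
  for (i in seq_len(n)) {
    for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
      if (dy == 0 && dx == 0 && dz == 0) next
      yy <- coords[i, 1] + dy; xx <- coords[i, 2] + dx; zz <- coords[i, 3] + dz
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3])
        next
      if (!skel[yy, xx, zz]) next
      j <- lut[yy + d[1] * (xx - 1L) + d[1] * d[2] * (zz - 1L)]
      w <- sqrt((dx * vs[["dx"]])^2 + (dy * vs[["dy"]])^2 +
                (dz * vs[["dz"]])^2)
      adj[[i]] <- rbind(adj[[i]], c(j, w))
    }
  }
  dist_from <- function(src) {
    dist <- rep(Inf, n); dist[src] <- 0
    done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which(!done & dist == min(dist[!done]))[1]
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      if (!is.null(adj[[u]])) for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
        if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
      }
    }
    dist
  }
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), 0L)
  ends <- which(deg <= 1L)
  best <- 0
  for (e in ends) {
    dd <- dist_from(e)[ends]
    dd <- dd[is.finite(dd)]
    if (length(dd)) best <- max(best, max(dd))
  }
  best
}

# a random 26-connected self-avoiding voxel path in a small grid
random_voxel_path <- function(d = c(14L, 14L, 8L), len = 20L) {
  skel <- array(FALSE, d)
  p <- c(sample(3:(d[1] - 2), 1), sample(3:(d[2] - 2), 1),
         sample(3:(d[3] - 2), 1))
  skel[p[1], p[2], p[3]] <- TRUE
  for (i in seq_len(len)) {
    for (try in 1:20) {
      step <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
      if (all(step == 0L)) next
      q <- p + step
      if (any(q < 2L) || any(q > dim(skel) - 1L)) next
      if (skel[q[1], q[2], q[3]]) next
      # avoid touching the existing path except at p (keeps it a simple path)
      nb <- 0L
      for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
        if (skel[q[1] + dy, q[2] + dx, q[3] + dz]) nb <- nb + 1L
      }
      if (nb > 1L) next
      skel[q[1], q[2], q[3]] <- TRUE
      p <- q
      break
    }
  }
  skel
}

# tiny in-memory grouped dataset (two groups, one measurement)
make_two_group_dataset <- function(x1, x2, measurement = "cilia_length_um",
                                   reps = 1L) {
  mk <- function(vals, g, r) {
    rec <- data.frame(id = seq_along(vals))
    rec[[measurement]] <- vals
    cilia_table(rec, metadata = run_metadata("v0.1.7"),
                group_label = g, replicate_id = paste0("rep", r))
  }
  t1 <- mk(x1, "g1", 1); t2 <- mk(x2, "g2", 1)
  grouped_dataset(list(t1, t2))
}
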