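# Histogram auto-thresholding. All methods take a vector of bin counts
# (bin i holds intensity i-1, i.e. values 0 .. length(h)-1) and return an
# integer cut value t; foreground is intensity > t. Ties in any criterion are
# broken toward the lowest cut achieving the optimum, so every method is
# deterministic.

#' Histogram auto-thresholding
#'
#' Computes an intensity cut from a histogram of bin counts using one of the
#' classical formulations: Otsu (maximum between-class variance), Li (minimum
#' cross-entropy), Yen, Rényi entropy (two-class Rényi entropy maximization;
#' `alpha = 2` by default, `alpha -> 1` recovers the Kapur maximum-entropy
#' method), Moments (Tsai moment preservation), Minimum (iterated 3-bin
#' smoothing until bimodal, cut at the valley), and Shanbhag (fuzzy-entropy).
#' Foreground is defined as intensity strictly greater than the returned cut.
#'
#' @param histogram numeric vector of bin counts; bin `i` counts intensity
#'   `i - 1`. Must contain at least two distinct occupied bins.
#' @param method one of `"Otsu"`, `"Li"`, `"Yen"`, `"RenyiEntropy"`,
#'   `"Moments"`, `"Minimum"`, `"Shanbhag"`.
#' @param alpha Rényi entropy order (only used by `"RenyiEntropy"`).
#' @return integer cut value (0-based intensity).
#' @export
auto_threshold <- function(histogram,
                           method = c("Otsu", "Li", "Yen", "RenyiEntropy",
                                      "Moments", "Minimum", "Shanbhag"),
                           alpha = 2) {
  method <- match.arg(method)
  h <- as.numeric(histogram)
  if (!length(h) || any(h < 0) || sum(h) <= 0) stop("invalid histogram")
  if (sum(h > 0) < 2L)
    stop("no contrast: histogram has fewer than two occupied bins")
  switch(method,
         Otsu = th_otsu(h),
         Li = th_li(h),
         Yen = th_yen(h),
         RenyiEntropy = th_renyi(h, alpha),
         Moments = th_moments(h),
         Minimum = th_minimum(h),
         Shanbhag = th_shanbhag(h))
}

# candidate cuts: class0 = bins <= t must be non-empty and class1 non-empty
candidate_cuts <- function(h) {
  occ <- which(h > 0) - 1L            # occupied intensities
  seq(min(occ), max(occ) - 1L)
}

th_otsu <- function(h) {
  v <- seq_along(h) - 1L
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * v)
  mu_t <- mu[length(mu)]
  cuts <- candidate_cuts(h)
  i <- cuts + 1L
  w1 <- 1 - w0[i]
  crit <- ifelse(w0[i] > 0 & w1 > 0,
                 (mu_t * w0[i] - mu[i])^2 / (w0[i] * w1), -Inf)
  cuts[which.max(crit)]
}

th_li <- function(h) {
  # minimum cross entropy (exhaustive over cuts): minimize
  #   -[A0(t) log mu0(t) + A1(t) log mu1(t)],  A = sum(i * h_i) over the class
  v <- seq_along(h) - 1L
  cA <- cumsum(h * v)
  cN <- cumsum(h)
  A_t <- cA[length(cA)]
  N_t <- cN[length(cN)]
  cuts <- candidate_cuts(h)
  crit <- vapply(cuts, function(t) {
    i <- t + 1L
    a0 <- cA[i]; n0 <- cN[i]
    a1 <- A_t - a0; n1 <- N_t - n0
    term0 <- if (n0 > 0 && a0 > 0) a0 * log(a0 / n0) else 0
    term1 <- if (n1 > 0 && a1 > 0) a1 * log(a1 / n1) else 0
    -(term0 + term1)
  }, 0)
  cuts[which.min(crit)]
}

th_yen <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  G <- cumsum(p^2)
  G_t <- G[length(G)]
  cuts <- candidate_cuts(h)
  crit <- vapply(cuts, function(t) {
    i <- t + 1L
    g0 <- G[i]; g1 <- G_t - g0
    w0 <- P1[i]; w1 <- 1 - w0
    if (g0 <= 0 || g1 <= 0 || w0 <= 0 || w1 <= 0) return(-Inf)
    -log(g0 * g1) + 2 * log(w0 * w1)
  }, 0)
  cuts[which.max(crit)]
}

renyi_class_entropy <- function(p, alpha) {
  p <- p[p > 0]
  if (!length(p)) return(-Inf)
  if (abs(alpha - 1) < 1e-12) -sum(p * log(p))
  else log(sum(p^alpha)) / (1 - alpha)
}

th_renyi <- function(h, alpha = 2) {
  p <- h / sum(h)
  cuts <- candidate_cuts(h)
  crit <- vapply(cuts, function(t) {
    i <- t + 1L
    w0 <- sum(p[1:i]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) return(-Inf)
    renyi_class_entropy(p[1:i] / w0, alpha) +
      renyi_class_entropy(p[-(1:i)] / w1, alpha)
  }, 0)
  cuts[which.max(crit)]
}

th_moments <- function(h) {
  # Tsai moment-preserving: match the first three moments with a two-level
  # image, then cut where the cumulative distribution reaches the dark
  # fraction p0.
  p <- h / sum(h)
  v <- seq_along(h) - 1L
  m1 <- sum(p * v); m2 <- sum(p * v^2); m3 <- sum(p * v^3)
  cd <- m2 - m1^2
  if (cd <= 0) stop("no contrast: zero histogram variance")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(p)
  t <- which(cum >= p0)[1] - 1L
  cuts <- candidate_cuts(h)
  min(max(t, min(cuts)), max(cuts))
}

th_minimum <- function(h, max_iter = 10000L) {
  # iterated running mean of 3 until exactly two local maxima remain; the cut
  # is the (lowest) minimum between them
  hs <- as.numeric(h)
  smooth3 <- function(x) {
    n <- length(x)
    (c(x[1], x[-n]) + x + c(x[-1], x[n])) / 3
  }
  n_peaks <- function(x) {
    n <- length(x)
    left <- c(-Inf, x[-n]); right <- c(x[-1], -Inf)
    sum(x > left & x >= right)
  }
  it <- 0L
  while (n_peaks(hs) > 2L) {
    hs <- smooth3(hs)
    it <- it + 1L
    if (it > max_iter)
      stop("histogram did not become bimodal after ", max_iter,
           " smoothing iterations")
  }
  if (n_peaks(hs) < 2L)
    stop("no contrast: smoothed histogram is unimodal")
  n <- length(hs)
  left <- c(-Inf, hs[-n]); right <- c(hs[-1], -Inf)
  peaks <- which(hs > left & hs >= right)
  valley_range <- peaks[1]:peaks[2]
  valley <- valley_range[which.min(hs[valley_range])]
  valley - 1L
}

th_shanbhag <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  P2 <- rev(cumsum(rev(p)))      # P2[i] = sum p[i..n]
  n <- length(p)
  cuts <- candidate_cuts(h)
  crit <- vapply(cuts, function(t) {
    it <- t + 1L
    if (P1[it] <= 0 || P2[it + 1L] <= 0) return(Inf)
    term <- 0.5 / P1[it]
    ib <- 2:it
    ent_back <- if (it >= 2)
      -sum(p[ib] * log(pmax(1 - term * P1[ib - 1L], .Machine$double.xmin)))
    else 0
    ent_back <- ent_back * term
    term <- 0.5 / P2[it + 1L]
    io <- (it + 1L):(n - 1L)
    io <- io[io >= it + 1L & io <= n - 1L]
    ent_obj <- if (length(io))
      -sum(p[io] * log(pmax(1 - term * P2[io + 1L], .Machine$double.xmin)))
    else 0
    ent_obj <- ent_obj * term
    abs(ent_back - ent_obj)
  }, 0)
  cuts[which.min(crit)]
}

#' Build an integer intensity histogram
#'
#' @param values numeric intensities (rounded to integers).
#' @param n_bins number of bins (e.g. 256 for 8-bit, 65536 for 16-bit).
#' @return numeric vector of counts; bin `i` counts intensity `i - 1`.
#' @export
intensity_histogram <- function(values, n_bins = 256L) {
  v <- pmin(pmax(round(as.numeric(values)), 0), n_bins - 1L)
  tabulate(v + 1L, nbins = n_bins)
}
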