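# Independent brute-force oracles used to pin the implementations.
# These are deliberately written as plain per-element loops, not shared
# with any package code path.

# DOPU by direct per-voxel looping over the kernel window and repeats.
naive_dopu <- function(stokes, transverse = 3L, depth = 3L,
                       noise = list(n1 = 0, n2 = 0), corrected = TRUE) {
  d <- dim(stokes$S0)
  if (length(d) == 3L) d <- c(d, 1L)
  as4 <- function(a) array(a, dim = d)
  S0 <- as4(stokes$S0); Q <- as4(stokes$Q); U <- as4(stokes$U); V <- as4(stokes$V)
  hx <- (transverse - 1) %/% 2; hz <- (depth - 1) %/% 2
  out <- array(NA_real_, dim = d[1:3])
  eps <- 1e-12 * max(S0)
  for (x in seq_len(d[1])) for (b in seq_len(d[2])) for (z in seq_len(d[3])) {
    xs <- max(1, x - hx):min(d[1], x + hx)
    zs <- max(1, z - hz):min(d[3], z + hz)
    sq <- su <- sv <- ss0 <- 0
    mq <- mu <- mv <- 0; cnt <- 0
    for (xi in xs) for (zi in zs) for (r in seq_len(d[4])) {
      s0 <- S0[xi, b, zi, r]
      if (corrected) {
        sq <- sq + Q[xi, b, zi, r] - (noise$n1 - noise$n2)
        su <- su + U[xi, b, zi, r]
        sv <- sv + V[xi, b, zi, r]
        ss0 <- ss0 + s0 - (noise$n1 + noise$n2)
      } else if (s0 > 0) {
        mq <- mq + Q[xi, b, zi, r] / s0
        mu <- mu + U[xi, b, zi, r] / s0
        mv <- mv + V[xi, b, zi, r] / s0
        cnt <- cnt + 1
      }
    }
    out[x, b, z] <- if (corrected) {
      min(1, max(0, sqrt(sq^2 + su^2 + sv^2) / max(ss0, eps)))
    } else if (cnt > 0) {
      min(1, sqrt((mq / cnt)^2 + (mu / cnt)^2 + (mv / cnt)^2))
    } else 0
  }
  out
}

# Shanbhag criterion by a literal double loop over thresholds and levels.
naive_shanbhag <- function(hist) {
  total <- sum(hist)
  p <- hist / total
  cum <- cumsum(p)
  first <- which(cum > .Machine$double.eps)[1]
  last <- max(which((1 - cum) > .Machine$double.eps))
  best <- NA; best_c <- Inf
  for (t in first:last) {
    hb <- 0
    for (g in 1:t) {
      below <- if (g == 1) 0 else cum[g - 1]
      hb <- hb - p[g] * log(1 - 0.5 * below / cum[t])
    }
    hb <- hb * 0.5 / cum[t]
    hf <- 0
    if (t < 256) for (g in (t + 1):256) {
      hf <- hf - p[g] * log(1 - 0.5 * (1 - cum[g]) / (1 - cum[t]))
    }
    hf <- hf * 0.5 / (1 - cum[t])
    cr <- abs(hb - hf)
    if (cr < best_c) { best_c <- cr; best <- t }
  }
  best - 1L
}

# Cohen's kappa from an explicitly built contingency table.
naive_kappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  k <- length(cats)
  tab <- matrix(0, k, k, dimnames = list(cats, cats))
  for (i in seq_along(a)) tab[as.character(a[i]), as.character(b[i])] <-
      tab[as.character(a[i]), as.character(b[i])] + 1
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-15) return(1)
  (po - pe) / (1 - pe)
}

# Pearson chi-square from explicitly computed expected counts.
naive_chisq <- function(tab) {
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_counts)^2 / exp_counts)
}

# Constant fully polarized Stokes volume: every sample has normalized
# direction (q, u, v) scaled by s0.
uniform_stokes <- function(dims, q, u, v, s0 = 1) {
  structure(list(S0 = array(s0, dims), Q = array(q * s0, dims),
                 U = array(u * s0, dims), V = array(v * s0, dims)),
            class = "stokes_volume")
}

# Stokes volume with fully random polarized speckle: uniform unit Stokes
# directions, Gamma-distributed intensities.
random_speckle_stokes <- function(dims, shape = 1) {
  n <- prod(dims)
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  s0 <- stats::rgamma(n, shape, rate = shape)
  structure(list(S0 = array(s0, dims),
                 Q = array(dir[, 1] * s0, dims),
                 U = array(dir[, 2] * s0, dims),
                 V = array(dir[, 3] * s0, dims)),
            class = "stokes_volume")
}

# Small high-SNR acquisition geometry for eye-level tests.
test_params <- function(nx = 48L, nb = 24L, nz = 64L, nrep = 4L,
                        noise = 1e-4) {
  optic_params(n_alines = nx, n_bscans = nb, n_depth = nz, n_repeats = nrep,
               noise_energy_ch1 = noise, noise_energy_ch2 = noise)
}
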