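#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used for
#' the cohort report percentages (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.5)    # 1
#' round_half_up(84.65, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Complex circular-Gaussian deviates
#'
#' Draws zero-mean circular complex Gaussian samples with a given mean
#' energy E|z|^2 (each real component has variance energy/2).
#'
#' @param n number of deviates.
#' @param energy mean energy per sample; may be a vector recycled over `n`.
#' @return complex vector of length `n`.
#' @keywords internal
rcomplex_gauss <- function(n, energy) {
  sd <- sqrt(energy / 2)
  complex(real = stats::rnorm(n, sd = sd), imaginary = stats::rnorm(n, sd = sd))
}

# Sliding box sum along one margin of a 3-d array (zero beyond the borders,
# i.e. the kernel is cropped at the edges rather than padded).
shift_sum <- function(arr, half, margin) {
  if (half == 0L) return(arr)
  d <- dim(arr)
  out <- arr
  idx <- function(s) {
    i <- vector("list", 3L)
    for (k in 1:3) i[[k]] <- seq_len(d[k])
    i[[margin]] <- seq_len(d[margin]) + s
    keep <- i[[margin]] >= 1L & i[[margin]] <= d[margin]
    list(src = lapply(1:3, function(k) if (k == margin) i[[margin]][keep] else i[[k]]),
         dst = lapply(1:3, function(k) if (k == margin) seq_len(d[margin])[keep] else i[[k]]))
  }
  for (s in c(-seq_len(half), seq_len(half))) {
    ii <- idx(s)
    out[ii$dst[[1]], ii$dst[[2]], ii$dst[[3]]] <-
      out[ii$dst[[1]], ii$dst[[2]], ii$dst[[3]]] +
      arr[ii$src[[1]], ii$src[[2]], ii$src[[3]]]
  }
  out
}

# Box sum over a (2*hx+1) x (2*hz+1) window in the A-line (dim 1) and depth
# (dim 3) directions of an (x, b, z) array; window cropped at borders.
box_sum_xz <- function(arr, hx, hz) {
  shift_sum(shift_sum(arr, hx, 1L), hz, 3L)
}

#' Label connected components of a logical mask
#'
#' Components of a 2-d (8-connectivity) or 3-d (6-connectivity) mask,
#' used for hard-exudate mass detection and per-B-scan focus regions.
#'
#' @param mask logical matrix or 3-d array.
#' @return integer array of the same shape; 0 outside the mask, components
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  stopifnot(is.logical(mask), length(d) %in% c(2L, 3L))
  lab <- array(0L, dim = d)
  on <- which(mask)
  if (length(on) == 0L) return(lab)
  pos <- arrayInd(on, d)
  id <- array(0L, dim = d)
  id[on] <- seq_along(on)
  offsets <- if (length(d) == 2L) {
    rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))   # 8-connectivity
  } else {
    rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))   # 6-connectivity
  }
  lin_index <- function(coords) {
    if (length(d) == 2L) {
      (coords[, 2L] - 1L) * d[1L] + coords[, 1L]
    } else {
      ((coords[, 3L] - 1L) * d[2L] + (coords[, 2L] - 1L)) * d[1L] + coords[, 1L]
    }
  }
  edges <- NULL
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(pos, 2L, offsets[r, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (k in seq_along(d)) ok <- ok & nb[, k] >= 1L & nb[, k] <= d[k]
    if (!any(ok)) next
    nb_id <- id[lin_index(nb[ok, , drop = FALSE])]
    here <- id[on][ok]
    keep <- nb_id > 0L
    if (any(keep)) edges <- rbind(edges, cbind(here[keep], nb_id[keep]))
  }
  if (is.null(edges)) {
    comp <- seq_along(on)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(on) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(on)]
  }
  lab[on] <- as.integer(comp)
  lab
}

# 20*log10 compression of nonnegative intensities to 8-bit over a dB window
# below the maximum. Zeros map to the window floor.
log_compress_8bit <- function(x, window_db = 40) {
  mx <- max(x, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) return(array(0L, dim = dim(x)))
  db <- 20 * log10(pmax(x / mx, 10^(-window_db / 20 - 1)))
  db <- pmax(db, -window_db)
  g <- round_half_up(255 * (db + window_db) / window_db)
  storage.mode(g) <- "integer"
  g
}
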