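# Shared fixtures and independent oracles.

gray <- function(mat, px = 10) grayscale_image(mat, pixel_size_um = px)

vmask <- function(mat) binary_mask(mat, "vessel")

# Brute-force exact Euclidean distance to the nearest foreground
# pixel: O(N * M) min over all foreground pixels. Independent oracle
# for the two-pass transform.
bf_edt <- function(fg) {
  h <- nrow(fg)
  w <- ncol(fg)
  vr <- (which(fg) - 1L) %% h
  vc <- (which(fg) - 1L) %/% h
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- sqrt(min((vr - (i - 1L))^2 + (vc - (j - 1L))^2))
    }
  }
  out
}

# Student t lower-tail CDF through the regularized incomplete beta
# function, evaluated by Lentz continued fraction. Independent of
# stats::pt; used to cross-check p-values to 1e-10.
beta_cf <- function(x, a, b) {
  tiny <- 1e-300
  qab <- a + b
  qap <- a + 1
  qam <- a - 1
  c <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < tiny) d <- tiny
  d <- 1 / d
  hh <- d
  for (m in 1:300) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d
    if (abs(d) < tiny) d <- tiny
    c <- 1 + aa / c
    if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    hh <- hh * d * c
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d
    if (abs(d) < tiny) d <- tiny
    c <- 1 + aa / c
    if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    del <- d * c
    hh <- hh * del
    if (abs(del - 1) < 1e-15) break
  }
  hh
}

ibeta <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  bt <- exp(lgamma(a + b) - lgamma(a) - lgamma(b) +
              a * log(x) + b * log1p(-x))
  if (x < (a + 1) / (a + b + 2)) {
    bt * beta_cf(x, a, b) / a
  } else {
    1 - bt * beta_cf(1 - x, b, a) / b
  }
}

ref_pt <- function(t, df) {
  x <- df / (df + t^2)
  p <- 0.5 * ibeta(x, df / 2, 0.5)
  if (t > 0) 1 - p else p
}

# Plant k isolated square blobs of the given size on a background;
# returns the image and the 0-based top-left corners.
plant_blobs <- function(h, w, k, size, bg = 40, fg = 255, seed = 1) {
  choropoint:::with_seed(seed, plant_blobs_impl(h, w, k, size, bg, fg))
}

plant_blobs_impl <- function(h, w, k, size, bg, fg) {
  img <- matrix(bg, h, w)
  corners <- data.frame(row = integer(0), col = integer(0))
  occ <- matrix(FALSE, h, w)
  tries <- 0L
  while (nrow(corners) < k) {
    tries <- tries + 1L
    if (tries > 100000L) stop("could not place blobs")
    r <- sample.int(h - size + 1L, 1L) - 1L
    c <- sample.int(w - size + 1L, 1L) - 1L
    r0 <- max(1L, r - 1L)
    c0 <- max(1L, c - 1L)
    r1 <- min(h, r + size + 2L)
    c1 <- min(w, c + size + 2L)
    if (any(occ[r0:r1, c0:c1])) next
    occ[(r + 1L):(r + size), (c + 1L):(c + size)] <- TRUE
    img[(r + 1L):(r + size), (c + 1L):(c + size)] <- fg
    corners <- rbind(corners, data.frame(row = r, col = c))
  }
  list(image = gray(img), corners = corners)
}

# Chebyshev distance from each point in a to its matched point in b.
chebyshev_match <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  vapply(seq_len(nrow(a)), function(i) {
    min(pmax(abs(b$row - a$row[i]), abs(b$col - a$col[i])))
  }, numeric(1))
}

# A small fully analyzed synthetic world shared by several tests.
small_world <- function(seed = 11, affinity = 0, n_lesions = 150,
                        height = 250, width = 250) {
  sp <- synthetic_spec(height = height, width = width,
                       n_lesions = n_lesions, affinity = affinity,
                       seed = seed)
  generate_synthetic_eye(sp, eye_id = sprintf("s%d", seed))
}
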