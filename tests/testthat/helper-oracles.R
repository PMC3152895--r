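# Independent brute-force oracles: explicit loops, no shared code with the
# package implementations they check.

# Symmetrized co-occurrence probabilities at d = 1, theta = 0.
oracle_com <- function(m, Ng) {
  p <- matrix(0, Ng, Ng)
  for (x in seq_len(nrow(m))) {
    for (y in seq_len(ncol(m) - 1L)) {
      i <- m[x, y]; j <- m[x, y + 1L]
      p[i, j] <- p[i, j] + 1
      p[j, i] <- p[j, i] + 1
    }
  }
  p / sum(p)
}

# The 11 Haralick features, every sum written as an explicit loop.
oracle_com_features <- function(p) {
  ng <- nrow(p)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mx <- 0; my <- 0
  for (i in 1:ng) { mx <- mx + i * px[i]; my <- my + i * py[i] }
  vx <- 0; vy <- 0
  for (i in 1:ng) { vx <- vx + (i - mx)^2 * px[i]; vy <- vy + (i - my)^2 * py[i] }
  psum <- numeric(2 * ng); pdif <- numeric(ng)          # indices k and n+1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1L] <- pdif[abs(i - j) + 1L] + p[i, j]
  }
  asm <- 0; ent <- 0; sos <- 0; idm <- 0; cor_num <- 0
  for (i in 1:ng) for (j in 1:ng) {
    asm <- asm + p[i, j]^2
    if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
    sos <- sos + (i - mx)^2 * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    cor_num <- cor_num + i * j * p[i, j]
  }
  correlation <- if (vx == 0 || vy == 0) 0 else
    (cor_num - mx * my) / (sqrt(vx) * sqrt(vy))
  contrast <- 0; savg <- 0; sent <- 0
  for (n in 0:(ng - 1L)) contrast <- contrast + n^2 * pdif[n + 1L]
  for (k in 2:(2 * ng)) savg <- savg + k * psum[k]
  svar <- 0
  for (k in 2:(2 * ng)) {
    svar <- svar + (k - savg)^2 * psum[k]
    if (psum[k] > 0) sent <- sent - psum[k] * log(psum[k])
  }
  dmean <- 0
  for (n in 0:(ng - 1L)) dmean <- dmean + n * pdif[n + 1L]
  dvar <- 0; dent <- 0
  for (n in 0:(ng - 1L)) {
    dvar <- dvar + (n - dmean)^2 * pdif[n + 1L]
    if (pdif[n + 1L] > 0) dent <- dent - pdif[n + 1L] * log(pdif[n + 1L])
  }
  c("Angular Second Moment" = asm, "Contrast" = contrast,
    "Correlation" = correlation, "Entropy" = ent, "Sum of Squares" = sos,
    "Inverse Difference Moment" = idm, "Sum Average" = savg,
    "Sum Variance" = svar, "Sum Entropy" = sent,
    "Difference Variance" = dvar, "Difference Entropy" = dent)
}

# Scan lines of one direction by explicit coordinate walks.
oracle_lines <- function(m, theta) {
  nr <- nrow(m); nc <- ncol(m)
  lines <- list()
  if (theta == 0) {
    for (r in 1:nr) lines[[length(lines) + 1L]] <- m[r, ]
  } else if (theta == 90) {
    for (c in 1:nc) lines[[length(lines) + 1L]] <- m[, c]
  } else if (theta == 45) {
    # up-right: start on first column and bottom row
    starts <- rbind(cbind(1:nr, 1L), cbind(nr, 2:nc))
    for (s in seq_len(nrow(starts))) {
      r <- starts[s, 1]; c <- starts[s, 2]; v <- c()
      while (r >= 1 && c <= nc) { v <- c(v, m[r, c]); r <- r - 1L; c <- c + 1L }
      lines[[length(lines) + 1L]] <- v
    }
  } else if (theta == 135) {
    # down-right: start on top row and first column
    starts <- rbind(cbind(1L, 1:nc), cbind(2:nr, 1L))
    for (s in seq_len(nrow(starts))) {
      r <- starts[s, 1]; c <- starts[s, 2]; v <- c()
      while (r <= nr && c <= nc) { v <- c(v, m[r, c]); r <- r + 1L; c <- c + 1L }
      lines[[length(lines) + 1L]] <- v
    }
  }
  lines
}

# Run-length counts by walking each line pixel by pixel.
oracle_rlm <- function(m, theta, Ng) {
  counts <- matrix(0, Ng, max(nrow(m), ncol(m)))
  for (v in oracle_lines(m, theta)) {
    run_val <- v[1]; run_len <- 1L
    for (k in seq_along(v)[-1]) {
      if (v[k] == run_val) run_len <- run_len + 1L
      else {
        counts[run_val, run_len] <- counts[run_val, run_len] + 1
        run_val <- v[k]; run_len <- 1L
      }
    }
    counts[run_val, run_len] <- counts[run_val, run_len] + 1
  }
  counts
}

oracle_rlm_features <- function(counts, n_pixels) {
  n_runs <- sum(counts)
  sre <- 0; lre <- 0
  for (i in seq_len(nrow(counts))) for (l in seq_len(ncol(counts))) {
    sre <- sre + counts[i, l] / l^2
    lre <- lre + counts[i, l] * l^2
  }
  gln <- 0
  for (i in seq_len(nrow(counts))) gln <- gln + sum(counts[i, ])^2
  rln <- 0
  for (l in seq_len(ncol(counts))) rln <- rln + sum(counts[, l])^2
  c("Short Run Emphasis" = sre / n_runs, "Long Run Emphasis" = lre / n_runs,
    "Greylevel Non-uniformity" = gln / n_runs,
    "Run Length Non-uniformity" = rln / n_runs,
    "Fraction" = n_runs / n_pixels)
}

random_roi <- function(nr, nc, Ng) {
  matrix(sample.int(Ng, nr * nc, replace = TRUE), nr, nc)
}
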