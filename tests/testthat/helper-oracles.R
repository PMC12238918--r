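# Independent brute-force oracles for the watershed stack. These are kept
# deliberately naive (relaxation, per-cell path following) so they share no
# code path with the implementation they check.

# raise-until-drained relaxation: edge cells keep their elevation, interior
# cells start at +Inf and are repeatedly lowered to
# max(dem, min over 8 neighbors of filled) until a fixpoint
oracle_fill <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  filled <- matrix(Inf, nr, nc)
  filled[1, ] <- z[1, ]; filled[nr, ] <- z[nr, ]
  filled[, 1] <- z[, 1]; filled[, nc] <- z[, nc]
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        nbmin <- Inf
        for (k in 1:8) {
          r2 <- r + greenlakes:::D8_DR[k]; c2 <- c + greenlakes:::D8_DC[k]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
            nbmin <- min(nbmin, filled[r2, c2])
          }
        }
        newv <- max(z[r, c], nbmin)
        if (newv < filled[r, c]) {
          filled[r, c] <- newv
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  filled
}

# follow D8 codes from (r, c); returns the visited linear indices, or NULL
# if the path exceeds nr*nc steps (a cycle)
oracle_path <- function(codes, r, c) {
  nr <- nrow(codes); nc <- ncol(codes)
  path <- integer(0)
  for (step in seq_len(nr * nc + 1L)) {
    path <- c(path, r + (c - 1L) * nr)
    k <- codes[r, c]
    if (is.na(k) || k == 0L) return(path)
    r2 <- r + greenlakes:::D8_DR[k]; c2 <- c + greenlakes:::D8_DC[k]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) return(path)
    r <- r2; c <- c2
  }
  NULL
}

# watershed of an outlet by following the D8 path from every cell
oracle_watershed <- function(codes, outlet_r, outlet_c) {
  nr <- nrow(codes); nc <- ncol(codes)
  target <- outlet_r + (outlet_c - 1L) * nr
  mask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(codes[r, c])) next
      p <- oracle_path(codes, r, c)
      if (!is.null(p) && target %in% p) mask[r, c] <- TRUE
    }
  }
  mask
}

# accumulation by counting, per cell, how many cells' paths pass through it
oracle_accumulation <- function(codes) {
  nr <- nrow(codes); nc <- ncol(codes)
  acc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(codes[r, c])) next
      for (i in oracle_path(codes, r, c)) acc[i] <- acc[i] + 1
    }
  }
  acc[is.na(codes)] <- NA
  acc
}

random_dem <- function(nr, nc, seed) {
  set.seed(seed)
  grid_raster(matrix(runif(nr * nc, 0, 100), nr, nc), cell_size = 10)
}
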