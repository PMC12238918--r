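# Catchment delineation from an elevation raster: depression filling
# (priority flood, epsilon-free), D8 flow directions, flow accumulation,
# pour-point snapping and upstream basin traversal.

# Fixed D8 neighbor order and direction codes (1-8); code 0 = sink/edge
# outlet. Row 1 is the southernmost row, so "N" increments the row index.
#   1 = E, 2 = SE, 3 = S, 4 = SW, 5 = W, 6 = NW, 7 = N, 8 = NE
# Ties in steepest descent are broken by the first neighbor in this order.
D8_DR <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# Minimal binary heap on lexicographic (primary, secondary) keys, used by
# the priority flood. Environment-based; n is known in advance.
.heap_new <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$k1 <- numeric(capacity); e$k2 <- numeric(capacity)
  e$val <- integer(capacity); e$n <- 0L
  e
}

.heap_lt <- function(e, i, j) {
  e$k1[i] < e$k1[j] || (e$k1[i] == e$k1[j] && e$k2[i] < e$k2[j])
}

.heap_push <- function(e, k1, k2, val) {
  if (e$n == length(e$k1)) {  # grow (lazy deletion can exceed capacity)
    e$k1 <- c(e$k1, numeric(length(e$k1)))
    e$k2 <- c(e$k2, numeric(length(e$k2)))
    e$val <- c(e$val, integer(length(e$val)))
  }
  i <- e$n + 1L; e$n <- i
  e$k1[i] <- k1; e$k2[i] <- k2; e$val[i] <- val
  while (i > 1L) {
    p <- i %/% 2L
    if (.heap_lt(e, i, p)) {
      .heap_swap(e, i, p); i <- p
    } else break
  }
}

.heap_swap <- function(e, i, j) {
  tmp <- e$k1[i]; e$k1[i] <- e$k1[j]; e$k1[j] <- tmp
  tmp <- e$k2[i]; e$k2[i] <- e$k2[j]; e$k2[j] <- tmp
  tmpi <- e$val[i]; e$val[i] <- e$val[j]; e$val[j] <- tmpi
}

.heap_pop <- function(e) {
  out <- c(e$k1[1L], e$k2[1L], e$val[1L])
  e$k1[1L] <- e$k1[e$n]; e$k2[1L] <- e$k2[e$n]; e$val[1L] <- e$val[e$n]
  e$n <- e$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= e$n && .heap_lt(e, l, m)) m <- l
    if (r <= e$n && .heap_lt(e, r, m)) m <- r
    if (m == i) break
    .heap_swap(e, i, m); i <- m
  }
  out
}

#' Fill depressions in a DEM (priority flood)
#'
#' Raises every closed depression to its spill level so that each valid
#' cell has a non-ascending D8 path to the grid edge. The fill is
#' epsilon-free: spill surfaces are left flat (elevations are never
#' perturbed beyond the minimum raise), and flats are made drainable by
#' recording the order in which cells are dequeued during the flood -- a
#' breadth-first distance-to-outlet ordering that [compute_d8()] uses to
#' route flow across flat surfaces. Cells that already drain are returned
#' unchanged, so the operation is idempotent.
#'
#' @param dem A `grid_raster` of elevations; nodata cells are treated as
#'   holes through which water can exit.
#' @return A `grid_raster` of filled elevations carrying the dequeue
#'   ordering in its `fill_order` element.
#' @export
fill_depressions <- function(dem) {
  stopifnot(is_grid_raster(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  bad <- is_nodata(dem)
  if (all(bad)) stop("DEM is entirely nodata", call. = FALSE)
  n <- nr * nc
  filled <- z; filled[bad] <- NA_real_
  visited <- bad  # nodata never processed
  ord <- matrix(NA_integer_, nr, nc)
  heap <- .heap_new(2L * n)
  seqno <- 0
  # seed: valid cells on the grid edge or adjacent to a nodata hole
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (bad[rr, cc]) next
      seed <- rr == 1L || rr == nr || cc == 1L || cc == nc
      if (!seed) {
        for (k in 1:8) {
          r2 <- rr + D8_DR[k]; c2 <- cc + D8_DC[k]
          if (bad[r2, c2]) { seed <- TRUE; break }
        }
      }
      if (seed) {
        seqno <- seqno + 1
        .heap_push(heap, z[rr, cc], seqno, rr + (cc - 1L) * nr)
      }
    }
  }
  counter <- 0L
  while (heap$n > 0L) {
    popped <- .heap_pop(heap)
    idx <- as.integer(popped[3L])
    rr <- ((idx - 1L) %% nr) + 1L; cc <- ((idx - 1L) %/% nr) + 1L
    if (visited[rr, cc]) next  # lazy deletion
    visited[rr, cc] <- TRUE
    counter <- counter + 1L
    ord[rr, cc] <- counter
    filled[rr, cc] <- popped[1L]
    for (k in 1:8) {
      r2 <- rr + D8_DR[k]; c2 <- cc + D8_DC[k]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      if (visited[r2, c2]) next
      seqno <- seqno + 1
      .heap_push(heap, max(z[r2, c2], popped[1L]), seqno, r2 + (c2 - 1L) * nr)
    }
  }
  out <- grid_raster(ifelse(is.na(filled), dem$nodata, filled),
                     dem$x_origin, dem$y_origin, dem$cell_size, dem$nodata)
  out$fill_order <- ord
  out
}

.shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_lo <- max(1L, 1L + dr); r_hi <- min(nr, nr + dr)
  c_lo <- max(1L, 1L + dc); c_hi <- min(nc, nc + dc)
  if (r_lo > r_hi || c_lo > c_hi) return(out)
  rs <- r_lo:r_hi; cs <- c_lo:c_hi
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Compute D8 flow directions from a filled DEM
#'
#' Each cell is assigned the direction of steepest descent (elevation drop
#' divided by center-to-center distance; diagonals count `cell_size * sqrt(2)`)
#' among its eight neighbors, with ties broken by the fixed neighbor order
#' E, SE, S, SW, W, NW, N, NE. Cells on a flat (no strictly lower neighbor)
#' drain to the equal-elevation neighbor that was dequeued earliest during
#' depression filling, which guarantees an acyclic path to the spill point.
#' Cells with no outlet (only possible on the grid edge or next to nodata
#' holes after filling) receive code 0.
#'
#' @param filled A depression-free `grid_raster`, ideally as returned by
#'   [fill_depressions()]. If it lacks the `fill_order` ordering it is
#'   refilled internally (a no-op on drained terrain).
#' @return A `d8_flow` object with a `codes` matrix (0-8).
#' @export
compute_d8 <- function(filled) {
  stopifnot(is_grid_raster(filled))
  if (is.null(filled$fill_order)) filled <- fill_depressions(filled)
  z <- filled$values
  z[is_nodata(filled)] <- NA_real_
  ord <- filled$fill_order
  nr <- nrow(z); nc <- ncol(z)
  codes <- matrix(0L, nr, nc)
  best_g <- matrix(-Inf, nr, nc)
  for (k in 1:8) {
    zk <- .shift_mat(z, -D8_DR[k], -D8_DC[k])  # neighbor k's elevation at cell
    g <- (z - zk) / (D8_DIST[k] * filled$cell_size)
    take <- !is.na(g) & g > 0 & g > best_g
    codes[take] <- k
    best_g[take] <- g[take]
  }
  # flats: equal elevation, earlier fill order wins
  flat <- codes == 0L & !is.na(z)
  if (any(flat)) {
    best_ord <- matrix(Inf, nr, nc)
    for (k in 1:8) {
      zk <- .shift_mat(z, -D8_DR[k], -D8_DC[k])
      ok <- .shift_mat(ord, -D8_DR[k], -D8_DC[k])
      take <- flat & !is.na(zk) & zk == z & !is.na(ok) & ok < ord &
        ok < best_ord
      codes[take] <- k
      best_ord[take] <- ok[take]
    }
  }
  codes[is.na(z)] <- NA_integer_
  structure(list(codes = codes, cell_size = filled$cell_size,
                 x_origin = filled$x_origin, y_origin = filled$y_origin),
            class = "d8_flow")
}

#' @export
print.d8_flow <- function(x, ...) {
  cat(sprintf("<d8_flow> %d x %d cells (codes 0-8, order E,SE,S,SW,W,NW,N,NE)\n",
              nrow(x$codes), ncol(x$codes)))
  invisible(x)
}

# downstream linear index per cell (0 = outlet, NA = nodata)
.downstream_index <- function(flow) {
  codes <- flow$codes
  nr <- nrow(codes); nc <- ncol(codes)
  idx <- seq_len(nr * nc)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  k <- as.vector(codes)
  down <- integer(nr * nc)
  down[is.na(k)] <- NA_integer_
  nz <- which(!is.na(k) & k > 0L)
  r2 <- rr[nz] + D8_DR[k[nz]]
  c2 <- cc[nz] + D8_DC[k[nz]]
  out_of_grid <- r2 < 1L | r2 > nr | c2 < 1L | c2 > nc
  down[nz[out_of_grid]] <- 0L
  inb <- nz[!out_of_grid]
  down[inb] <- r2[!out_of_grid] + (c2[!out_of_grid] - 1L) * nr
  down
}

#' Flow accumulation
#'
#' Counts, for every cell, the number of cells draining through it (itself
#' included), by processing the D8 graph in topological order.
#'
#' @param flow A `d8_flow` object.
#' @return A `grid_raster` of accumulation counts.
#' @export
flow_accumulation <- function(flow) {
  stopifnot(inherits(flow, "d8_flow"))
  codes <- flow$codes
  nr <- nrow(codes); nc <- ncol(codes)
  down <- .downstream_index(flow)
  valid <- which(!is.na(down))
  indeg <- integer(nr * nc)
  has_down <- valid[down[valid] > 0L]
  tab <- tabulate(down[has_down], nbins = nr * nc)
  indeg <- tab
  acc <- rep(NA_real_, nr * nc)
  acc[valid] <- 1
  queue <- valid[indeg[valid] == 0L]
  head <- 1L
  processed <- 0L
  queue <- c(queue, integer(length(valid)))  # preallocate
  tail <- sum(indeg[valid] == 0L)
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    processed <- processed + 1L
    d <- down[i]
    if (d > 0L) {
      acc[d] <- acc[d] + acc[i]
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) { tail <- tail + 1L; queue[tail] <- d }
    }
  }
  if (processed < length(valid)) {
    onloop <- setdiff(valid, queue[seq_len(tail)])
    rr <- ((onloop[1L] - 1L) %% nr) + 1L
    cc <- ((onloop[1L] - 1L) %/% nr) + 1L
    stop(sprintf("flow field contains a cycle through cell (row %d, col %d)",
                 rr, cc), call. = FALSE)
  }
  grid_raster(matrix(ifelse(is.na(acc), -9999, acc), nr, nc),
              flow$x_origin, flow$y_origin, flow$cell_size, nodata = -9999)
}

#' Snap a pour point to the highest-accumulation cell nearby
#'
#' Mirrors the standard outlet-snapping step: the supplied coordinate is
#' moved to the cell with maximal flow accumulation within `radius` meters.
#' Ties are broken by distance to the original point, then by scan order
#' (column-major linear index, i.e., south-to-north within west-to-east).
#'
#' @param point Numeric `c(x, y)` in meters.
#' @param accum Accumulation `grid_raster` from [flow_accumulation()].
#' @param radius Search radius in meters (>= 0; 0 keeps the containing cell).
#' @return Integer `c(row, col)` of the snapped cell.
#' @export
snap_outlet <- function(point, accum, radius = 250) {
  stopifnot(is_grid_raster(accum), radius >= 0, length(point) >= 2)
  nr <- nrow(accum$values); nc <- ncol(accum$values)
  cs <- accum$cell_size
  cx <- accum$x_origin + (seq_len(nc) - 0.5) * cs
  cy <- accum$y_origin + (seq_len(nr) - 0.5) * cs
  dx2 <- outer(rep(1, nr), (cx - point[1])^2)
  dy2 <- outer((cy - point[2])^2, rep(1, nc))
  d2 <- dx2 + dy2
  ok <- d2 <= radius^2 + 1e-9 & !is_nodata(accum)
  if (!any(ok)) {
    stop(sprintf("no valid cell within %g m of (%g, %g)", radius,
                 point[1], point[2]), call. = FALSE)
  }
  a <- accum$values
  a[!ok] <- -Inf
  amax <- max(a)
  cand <- which(a == amax)
  if (length(cand) > 1L) {
    dd <- d2[cand]
    cand <- cand[dd == min(dd)]
    cand <- min(cand)  # scan order
  }
  c(row = ((cand - 1L) %% nr) + 1L, col = ((cand - 1L) %/% nr) + 1L)
}

#' Delineate the watershed upstream of an outlet cell
#'
#' Collects every cell whose D8 path reaches the outlet (outlet included)
#' by breadth-first traversal of the reversed flow graph.
#'
#' @param flow A `d8_flow` object.
#' @param outlet Integer `c(row, col)` of the outlet cell.
#' @return A 0/1 `grid_raster` mask of the catchment.
#' @export
delineate <- function(flow, outlet) {
  stopifnot(inherits(flow, "d8_flow"))
  codes <- flow$codes
  nr <- nrow(codes); nc <- ncol(codes)
  r0 <- as.integer(outlet[1L]); c0 <- as.integer(outlet[2L])
  stopifnot(r0 >= 1L, r0 <= nr, c0 >= 1L, c0 <= nc)
  if (is.na(codes[r0, c0])) stop("outlet cell is nodata", call. = FALSE)
  down <- .downstream_index(flow)
  inmask <- logical(nr * nc)
  start <- r0 + (c0 - 1L) * nr
  inmask[start] <- TRUE
  queue <- integer(nr * nc)
  queue[1L] <- start
  head <- 1L; tail <- 1L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    rr <- ((i - 1L) %% nr) + 1L; cc <- ((i - 1L) %/% nr) + 1L
    for (k in 1:8) {
      r2 <- rr + D8_DR[k]; c2 <- cc + D8_DC[k]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      j <- r2 + (c2 - 1L) * nr
      if (!inmask[j] && !is.na(down[j]) && down[j] == i) {
        inmask[j] <- TRUE
        tail <- tail + 1L
        queue[tail] <- j
      }
    }
  }
  grid_raster(matrix(as.numeric(inmask), nr, nc),
              flow$x_origin, flow$y_origin, flow$cell_size, nodata = -9999)
}

#' Catchment, lake and drainage areas from masks
#'
#' Area is cell count times `cell_size^2`, converted to square kilometers;
#' the drainage area is the catchment minus the lake surface.
#'
#' @param catchment_mask,lake_mask 0/1 `grid_raster` masks sharing geometry.
#'   Every lake cell must lie inside the catchment.
#' @return Named list with `catchment_km2`, `lake_km2`, `drainage_km2`.
#' @export
areas <- function(catchment_mask, lake_mask) {
  stopifnot_same_geometry(catchment_mask, lake_mask)
  cm <- catchment_mask$values > 0 & !is_nodata(catchment_mask)
  lm <- lake_mask$values > 0 & !is_nodata(lake_mask)
  if (any(lm & !cm)) {
    stop("lake cells fall outside the catchment mask: inconsistent inputs",
         call. = FALSE)
  }
  f <- catchment_mask$cell_size^2 / 1e6
  list(catchment_km2 = sum(cm) * f,
       lake_km2 = sum(lm) * f,
       drainage_km2 = (sum(cm) - sum(lm)) * f)
}
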