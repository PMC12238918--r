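test_that("filling leaves drained terrain unchanged and raises a pit to its spill", {
  plane <- east_plane(6, 6)
  expect_equal(fill_depressions(plane)$values, plane$values)

  m <- matrix(10, 5, 5)
  m[3, 3] <- 2  # one-cell pit in a plateau
  f <- fill_depressions(grid_raster(m))
  expect_equal(f$values[3, 3], 10)  # min neighboring elevation, no epsilon
  expect_equal(f$values[-13], m[-13])  # every other cell untouched
})

test_that("filling matches the raise-until-drained relaxation oracle", {
  for (seed in 1:3) {
    dem <- random_dem(30, 30, seed)
    f <- fill_depressions(dem)
    expect_equal(f$values, oracle_fill(dem$values), tolerance = 1e-12)
  }
})

test_that("filling is idempotent", {
  dem <- random_dem(25, 25, 7)
  f1 <- fill_depressions(dem)
  f2 <- fill_depressions(f1)
  expect_equal(f2$values, f1$values)
})

test_that("all-nodata raster is rejected", {
  g <- grid_raster(matrix(NA_real_, 4, 4))
  expect_error(fill_depressions(g), "nodata")
})

test_that("D8 on a plane dipping east codes east everywhere it can", {
  flow <- compute_d8(fill_depressions(east_plane(6, 6)))
  expect_true(all(flow$codes[, -6] == 1L))  # 1 = E
  # the flat east edge routes along itself (fill order) to a single outlet
  expect_true(all(flow$codes[, 6] %in% c(0L, 3L)))
  expect_equal(sum(flow$codes[, 6] == 0L), 1L)
})

test_that("steepest-descent ties go to the first neighbor in E,SE,S,SW,W,NW,N,NE order", {
  # center cell with E and N neighbors equally low: E (code 1) must win
  m <- matrix(5, 3, 3)
  m[2, 3] <- 1  # east of center
  m[3, 2] <- 1  # north of center
  flow <- compute_d8(fill_depressions(grid_raster(m)))
  expect_equal(flow$codes[2, 2], 1L)
})

test_that("every D8 path terminates at the grid edge without cycling", {
  for (seed in 4:6) {
    dem <- random_dem(20, 20, seed)
    flow <- compute_d8(fill_depressions(dem))
    for (r in seq_len(20)) {
      for (c in seq_len(20)) {
        p <- oracle_path(flow$codes, r, c)
        expect_false(is.null(p))
        last <- p[length(p)]
        lr <- ((last - 1) %% 20) + 1
        lc <- ((last - 1) %/% 20) + 1
        # path ends where flow leaves the grid (code 0 or edge cell)
        expect_true(flow$codes[lr, lc] == 0L ||
                      lr %in% c(1L, 20L) || lc %in% c(1L, 20L))
      }
    }
  }
})

test_that("flow accumulation counts chains, heads and matches the BFS oracle", {
  # 1x5 line flowing east
  line <- grid_raster(matrix(5:1, 1, 5))
  acc <- flow_accumulation(compute_d8(fill_depressions(line)))
  expect_equal(as.vector(acc$values), c(1, 2, 3, 4, 5))

  # tilted plane: every west-edge (column head) cell has accumulation 1
  plane_acc <- flow_accumulation(compute_d8(fill_depressions(east_plane(6, 6))))
  expect_true(all(plane_acc$values[, 1] == 1))

  for (seed in 10:12) {
    dem <- random_dem(20, 20, seed)
    flow <- compute_d8(fill_depressions(dem))
    acc <- flow_accumulation(flow)
    expect_equal(acc$values, oracle_accumulation(flow$codes))
  }
})

test_that("accumulation is conserved: outlet cells account for every valid cell", {
  dem <- random_dem(22, 18, 21)
  flow <- compute_d8(fill_depressions(dem))
  acc <- flow_accumulation(flow)
  down <- greenlakes:::.downstream_index(flow)
  outlets <- which(!is.na(down) & down == 0L)
  expect_equal(sum(acc$values[outlets]), sum(!is.na(flow$codes)))
})

test_that("a cyclic flow field is reported with a cell on the cycle", {
  # two cells pointing at each other: (1,1) -E-> (1,2) -W-> (1,1)
  flow <- structure(list(codes = matrix(c(1L, 5L), 1, 2),
                         cell_size = 1, x_origin = 0, y_origin = 0),
                    class = "d8_flow")
  expect_error(flow_accumulation(flow), "cycle")
})

test_that("outlet snapping maximizes accumulation, with distance tie-breaks", {
  dem <- random_dem(20, 20, 31)
  flow <- compute_d8(fill_depressions(dem))
  acc <- flow_accumulation(flow)
  # radius 0: the containing cell itself
  xy <- cell_xy(acc, 7, 9)
  expect_equal(unname(snap_outlet(xy, acc, 0)), c(7L, 9L))
  # property: snapped accumulation >= unsnapped, over random points
  set.seed(99)
  for (i in 1:25) {
    r <- sample(20, 1); c <- sample(20, 1)
    xy <- cell_xy(acc, r, c)
    sn <- snap_outlet(xy, acc, radius = 30)  # 3 cells
    expect_gte(acc$values[sn[1], sn[2]], acc$values[r, c])
  }
  expect_error(snap_outlet(c(1e6, 1e6), acc, 10), "no valid cell")
})

test_that("snapping jumps one cell onto a river line", {
  # carve a deep channel along row 3 of a plane: all flow funnels there
  m <- matrix(rep(rev(seq_len(8)) * 2, each = 8), 8, 8)
  m[3, ] <- m[3, ] - 10
  acc <- flow_accumulation(compute_d8(fill_depressions(grid_raster(m))))
  xy <- cell_xy(acc, 4, 4)  # one cell off the channel
  sn <- snap_outlet(xy, acc, radius = 2)
  expect_equal(unname(sn[1]), 3L)
})

test_that("delineation equals the forward path-following oracle", {
  for (seed in 41:43) {
    dem <- random_dem(20, 20, seed)
    flow <- compute_d8(fill_depressions(dem))
    acc <- flow_accumulation(flow)
    cell <- which(acc$values == max(acc$values))[1]
    r <- ((cell - 1) %% 20) + 1; c <- ((cell - 1) %/% 20) + 1
    mask <- delineate(flow, c(r, c))
    expect_equal(mask$values > 0, oracle_watershed(flow$codes, r, c))
  }
})

test_that("a source cell's watershed is itself; basins nest downstream", {
  dem <- random_dem(20, 20, 44)
  flow <- compute_d8(fill_depressions(dem))
  acc <- flow_accumulation(flow)
  src <- which(acc$values == 1)[1]
  r <- ((src - 1) %% 20) + 1; c <- ((src - 1) %/% 20) + 1
  m <- delineate(flow, c(r, c))
  expect_equal(sum(m$values), 1)
  # nestedness: follow the stream one step down; the downstream basin
  # must contain the upstream one
  down <- greenlakes:::.downstream_index(flow)
  big <- which(acc$values == max(acc$values))[1]
  d <- down[big]
  if (!is.na(d) && d > 0L) {
    up_mask <- delineate(flow, c(((big - 1) %% 20) + 1, ((big - 1) %/% 20) + 1))
    dn_mask <- delineate(flow, c(((d - 1) %% 20) + 1, ((d - 1) %/% 20) + 1))
    expect_true(all(dn_mask$values >= up_mask$values))
  }
})

test_that("areas convert cell counts and subtract the lake surface", {
  nr <- 60; nc <- 60
  catch <- matrix(0, nr, nc); lake <- matrix(0, nr, nc)
  catch[cbind(sample(nr, 100, replace = TRUE), 1:100 %% nc + 1)] <- 1
  catch <- matrix(0, nr, nc)
  catch[1:10, 1:10] <- 1  # 100 cells
  g_catch <- grid_raster(catch, cell_size = 100)
  g_lake <- grid_raster(matrix(0, nr, nc), cell_size = 100)
  a <- areas(g_catch, g_lake)
  expect_equal(a$catchment_km2, 1.0)

  # 2500-cell catchment, 36-cell lake at 100 m
  catch2 <- matrix(0, nr, nc); catch2[1:50, 1:50] <- 1
  lake2 <- matrix(0, nr, nc); lake2[10:15, 10:15] <- 1
  a2 <- areas(grid_raster(catch2, cell_size = 100),
              grid_raster(lake2, cell_size = 100))
  expect_equal(a2$drainage_km2, 24.64)

  # mimic the Latnjajaure numbers: 946 catchment / 77 lake cells at 100 m
  catch3 <- matrix(0, nr, nc); catch3[seq_len(946)] <- 1
  lake3 <- matrix(0, nr, nc); lake3[seq_len(77)] <- 1
  a3 <- areas(grid_raster(catch3, cell_size = 100),
              grid_raster(lake3, cell_size = 100))
  expect_equal(a3$catchment_km2, 9.46)
  expect_equal(a3$lake_km2, 0.77)
  expect_equal(a3$drainage_km2, 8.69)

  # lake outside catchment is inconsistent input
  lake_out <- matrix(0, nr, nc); lake_out[nr, nc] <- 1
  expect_error(areas(grid_raster(catch3, cell_size = 100),
                     grid_raster(lake_out, cell_size = 100)),
               "outside")
})
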