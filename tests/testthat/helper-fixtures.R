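# Small in-code fixtures shared across tests.

const_scene <- function(value, nr = 4, nc = 4, year = 2000, doy = 200,
                        hour = 12) {
  ndvi_scene(grid_raster(matrix(value, nr, nc)), year, doy, hour)
}

mat_scene <- function(m, year = 2000, doy = 200, hour = 12) {
  ndvi_scene(grid_raster(m), year, doy, hour)
}

full_mask <- function(nr = 4, nc = 4) grid_raster(matrix(1, nr, nc))

# plane dipping due east (row 1 = south, col nc = east edge, lowest)
east_plane <- function(nr = 6, nc = 6, cell_size = 1) {
  grid_raster(matrix(rep(rev(seq_len(nc)), each = nr), nr, nc),
              cell_size = cell_size)
}

# noiseless plot samples on an exact line density = a + b * ndvi
line_samples <- function(ndvi, slope, intercept, plots_per_site = 1) {
  n <- length(ndvi)
  idx <- rep(seq_len(n), each = plots_per_site)
  nv <- ndvi[idx]
  dens_p <- intercept + slope * nv
  dm <- 100
  veg_plot_samples(site_id = sprintf("s%02d", idx),
                   plot_id = rep(seq_len(plots_per_site), n),
                   ndvimax = nv, dry_mass = dm,
                   conc_p = dens_p * 1000 * 0.25 / dm,
                   conc_n = dens_p * 2000 * 0.25 / dm)
}
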