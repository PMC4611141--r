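# Shared fixtures: everything is built in code at test time.

# small isotropic hat for cheap lattice runs
small_kernel <- function(sigma = 2.5, grid = c(40, 40), ...) {
  build_kernel(kernel_spec(sigma_x = sigma, K = 1.2, beta = 6), grid = grid, ...)
}

# a kernel whose gains are zero: cells are uncoupled
uncoupled_kernel <- function(grid = c(5, 5)) {
  build_kernel(kernel_spec(sigma_x = 1, K = 1.2, beta = 6,
                           alpha_e = 0, alpha_i = 0), grid = grid)
}

# synthetic spike record: a bare-bones object understood by the metrics
# (spikes data frame + config), bypassing the simulator
synthetic_record <- function(spikes, grid = c(20, 20), duration = 100) {
  structure(list(spikes = spikes,
                 config = sim_config(grid = grid, duration = duration)),
            class = "field_sim")
}

# block of cells all spiking once at time t
block_spikes <- function(x0, y0, nx, ny, t = 1, each = 1) {
  g <- expand.grid(x = x0 + seq_len(nx) - 1, y = y0 + seq_len(ny) - 1)
  data.frame(x = rep(g$x, each), y = rep(g$y, each),
             t = rep(t, nrow(g) * each))
}

# independent connected-components oracle built on igraph
igraph_components <- function(active, connectivity = 8) {
  idx <- which(active)
  if (length(idx) == 0) return(0L)
  nx <- nrow(active)
  coord <- cbind((idx - 1L) %% nx, (idx - 1L) %/% nx)
  id <- seq_along(idx)
  edges <- NULL
  for (i in id) {
    dx <- abs(coord[, 1] - coord[i, 1])
    dy <- abs(coord[, 2] - coord[i, 2])
    nb <- if (connectivity == 8) {
      which(dx <= 1 & dy <= 1 & (dx + dy) > 0)
    } else {
      which(dx + dy == 1)
    }
    nb <- nb[nb > i]
    if (length(nb)) edges <- rbind(edges, cbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(if (is.null(edges)) matrix(0L, 0, 2) else edges,
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(id) - igraph::vcount(g)))
  igraph::components(g)$no
}
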