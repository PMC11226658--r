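## shared test helpers

## closed n-gon sampled on an axis-aligned ellipse with semi-axes a, b
ellipse_polygon <- function(a, b, n = 64L, rot = 0, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L, 2L)
  sweep(p %*% R, 2L, center, `+`)
}

## regular n-gon of unit circumradius
regular_polygon <- function(n, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(r * cos(th), r * sin(th))
}

## pure Brownian trajectory in a periodic box (exact Gaussian increments)
brownian_trajectory <- function(n_frames, n_cells, D, dt, L, seed) {
  set.seed(seed)
  pos <- array(NA_real_, c(n_frames, n_cells, 2L))
  pos[1L, , ] <- matrix(runif(2L * n_cells, 0, L), n_cells, 2L)
  sig <- sqrt(2 * D * dt)
  for (f in 2L:n_frames) {
    pos[f, , ] <- pos[f - 1L, , ] + matrix(rnorm(2L * n_cells, sd = sig),
                                           n_cells, 2L)
  }
  pos[, , 1L] <- pos[, , 1L] %% L
  pos[, , 2L] <- pos[, , 2L] %% L
  trajectory(pos, dt = dt, box = list(type = "periodic", Lx = L, Ly = L))
}

## a small equilibrated vertex-model tissue, cached per session
equilibrated_tissue <- local({
  cache <- new.env(parent = emptyenv())
  function(n_cells = 64L, temperature = 0.009, seed = 11L,
           equil_steps = 2000L) {
    key <- paste(n_cells, temperature, seed, equil_steps)
    if (is.null(cache[[key]])) {
      st <- init_tissue(n_cells, seed = seed, disorder = 0.3,
                        params = vm_params(temperature = temperature))
      eq <- suppressWarnings(
        vm_run(st, equil_steps, snapshot_stride = equil_steps,
               seed = seed + 1L, validate_every = 0L))
      cache[[key]] <- eq$final_state
    }
    cache[[key]]
  }
})
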