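test_that("init_tissue builds valid tissues, ordered and disordered", {
  for (dis in c(0, 0.3)) {
    st <- init_tissue(36L, disorder = dis, seed = 2L)
    expect_silent(validate_vm_state(st))
    expect_length(st$cells, 36L)
    ## degree-3 vertex count on the torus: V = 2F
    expect_equal(nrow(st$vertices), 72L)
    ## areas tile the box
    geo <- vm_polygons(st)
    expect_equal(sum(vapply(geo, polygon_area, numeric(1))),
                 prod(st$box), tolerance = 1e-8)
  }
})

test_that("the energy of the regular hexagonal tiling matches theory", {
  st <- init_tissue(36L, disorder = 0, seed = 1L)
  ## each cell: A = A0 exactly, P = perimeter of a regular hexagon of unit
  ## area = sqrt(8 sqrt(3)) vs P0 = 3.72
  p_hex <- sqrt(8 * sqrt(3))
  expect_equal(vm_energy(st), 36 * (p_hex - 3.72)^2, tolerance = 1e-8)
})

test_that("forces are the exact negative energy gradient", {
  st <- init_tissue(24L, disorder = 0.25, seed = 3L)
  F <- vm_forces(st)
  ## momentum conservation on the torus
  expect_lt(max(abs(colSums(F))), 1e-10)
  h <- 1e-7
  set.seed(1)
  for (v in sample(nrow(st$vertices), 8L)) {
    for (d in 1:2) {
      stp <- st; stp$vertices[v, d] <- stp$vertices[v, d] + h
      stm <- st; stm$vertices[v, d] <- stm$vertices[v, d] - h
      fd <- -(vm_energy(stp) - vm_energy(stm)) / (2 * h)
      expect_equal(F[v, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("zero-temperature dynamics descends the energy monotonically", {
  st <- init_tissue(24L, disorder = 0.25, seed = 4L,
                    params = vm_params(temperature = 0))
  e <- vm_energy(st)
  for (i in 1:40) {
    st <- suppressWarnings(vm_step(st))
    e2 <- vm_energy(st)
    expect_lte(e2, e + 1e-12)
    e <- e2
  }
})

test_that("frozen vertices never move and runs are seed-deterministic", {
  st <- equilibrated_tissue(36L, seed = 6L, equil_steps = 500L)
  stf <- freeze_exterior(st, n = 6L)
  before <- stf$vertices
  r1 <- suppressWarnings(vm_run(stf, 100L, seed = 13L, snapshot_stride = 50L))
  after <- r1$final_state$vertices
  expect_identical(after[!stf$mobile, ], before[!stf$mobile, ])
  expect_false(isTRUE(all.equal(after[stf$mobile, ], before[stf$mobile, ])))
  r2 <- suppressWarnings(vm_run(stf, 100L, seed = 13L, snapshot_stride = 50L))
  expect_identical(r1$final_state$vertices, r2$final_state$vertices)
  expect_identical(r1$t1_count, r2$t1_count)
})

test_that("T1 events preserve every topological invariant", {
  st <- equilibrated_tissue(36L, temperature = 0.02, seed = 8L,
                            equil_steps = 500L)
  vt <- suppressWarnings(vm_run(st, 1500L, seed = 17L, snapshot_stride = 500L,
                                validate_every = 100L))
  expect_gt(vt$t1_count, 0L)  # hot tissue must rearrange
  fin <- vt$final_state
  expect_silent(validate_vm_state(fin))
  expect_length(fin$cells, 36L)  # cell count conserved
  expect_equal(nrow(fin$vertices), 72L)
})

test_that("a direct T1 flip swaps the adjacencies of the four cells", {
  st <- equilibrated_tissue(36L, temperature = 0.02, seed = 8L,
                            equil_steps = 500L)
  ## find a flippable edge: walk edges until vm_t1 accepts one
  edges <- do.call(rbind, lapply(seq_along(st$cells), function(ci) {
    cyc <- st$cells[[ci]]
    cbind(cyc, c(cyc[-1L], cyc[1L]))
  }))
  edges <- unique(t(apply(edges, 1L, sort)))
  flipped <- FALSE
  for (i in seq_len(nrow(edges))) {
    st2 <- vm_t1(st, edges[i, 1L], edges[i, 2L])
    if (isTRUE(attr(st2, "accepted"))) { flipped <- TRUE; break }
  }
  expect_true(flipped)
  expect_silent(validate_vm_state(st2))
  expect_length(st2$cells, length(st$cells))
  ## post-flip edge has the reset length
  has_edge <- function(s, a, b) {
    any(vapply(s$cells, function(cyc) {
      n <- length(cyc)
      any(cyc == a & c(cyc[-1L], cyc[1L]) == b) ||
        any(cyc == b & c(cyc[-1L], cyc[1L]) == a)
    }, logical(1L)))
  }
  a <- edges[i, 1L]; b <- edges[i, 2L]
  expect_true(has_edge(st2, a, b))
  d <- st2$vertices[a, ] - st2$vertices[b, ]
  d <- d - st2$box * round(d / st2$box)
  expect_equal(sqrt(sum(d^2)), 1.02 * st$params$l_t1, tolerance = 1e-9)
})

test_that("vm_params enforces its domain and derives P0 from p0", {
  p <- vm_params(p0 = 3.9, A0 = 2)
  expect_equal(p$P0, 3.9 * sqrt(2))
  expect_equal(p$l_t1, 0.04 * sqrt(2))
  expect_error(vm_params(temperature = -1))
  expect_error(vm_params(A0 = 0))
})

test_that("trajectory and polygon views of a run are consistent", {
  st <- equilibrated_tissue(36L, seed = 6L, equil_steps = 500L)
  vt <- suppressWarnings(vm_run(st, 200L, seed = 19L, snapshot_stride = 20L))
  traj <- vm_as_trajectory(vt)
  expect_s3_class(traj, "trajectory")
  expect_equal(dim(traj$positions), c(11L, 36L, 2L))
  expect_equal(traj$dt, st$params$dt * 20L)
  pe <- vm_as_polygon_ensemble(vt)
  expect_s3_class(pe, "polygon_ensemble")
  expect_length(pe$frames, 11L)
  ## centroid of each polygon (wrapped) equals the trajectory position
  p1 <- pe$frames[[1L]][["1"]]
  c1 <- polygon_centroid(p1) %% st$box
  expect_equal(unname(c1), unname(traj$positions[1L, 1L, ]), tolerance = 1e-9)
})
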