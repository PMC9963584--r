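# Closed-form lattice cells: the primary geometric oracles.

test_that("simple cubic lattice gives a cube cell", {
  a <- 3.1
  cell <- voronoi_cell(make_lattice("sc", 4, a))
  expect_true(cell$converged)
  m <- cell_metrics(cell)
  expect_equal(m$nf, 6)
  expect_equal(m$nv, 8)
  expect_equal(m$ne, 12)
  expect_equal(m$volume, a^3, tolerance = 1e-9)
  expect_equal(m$surface, 6 * a^2, tolerance = 1e-9)
  expect_equal(m$rw, a / 2, tolerance = 1e-9)
  expect_equal(m$alpha, 6 / pi, tolerance = 1e-9)
  expect_true(all(abs(cell$face_d - a) < 1e-9))
})

test_that("fcc lattice gives the rhombic dodecahedron", {
  a <- 4.0
  d <- a / sqrt(2)  # nearest-neighbor distance
  m <- cell_metrics(voronoi_cell(make_lattice("fcc", 3, a)))
  expect_equal(m$nf, 12)
  expect_equal(m$nv, 14)
  expect_equal(m$ne, 24)
  expect_equal(m$volume, sqrt(2) / 2 * d^3, tolerance = 1e-9)
  expect_equal(m$surface, 3 * sqrt(2) * d^2, tolerance = 1e-9)
  expect_equal(m$rw, d / 2, tolerance = 1e-9)
  expect_equal(m$alpha, 3 * sqrt(2) / pi, tolerance = 1e-9)
})

test_that("bcc lattice gives the truncated octahedron", {
  a <- 4.0
  m <- cell_metrics(voronoi_cell(make_lattice("bcc", 3, a)))
  expect_equal(m$nf, 14)
  expect_equal(m$nv, 24)
  expect_equal(m$ne, 36)
  expect_equal(m$volume, a^3 / 2, tolerance = 1e-9)
})

test_that("clipping engine matches the brute-force half-space oracle", {
  # disordered frame: every topological count, V and S must agree
  cfg <- make_poisson(30, 9, seed = 77)
  for (site in c(1L, 7L, 19L)) {
    cell <- voronoi_cell(cfg, site = site)
    orc <- oracle_cell(cfg, site = site)
    expect_equal(cell$nf, orc$nf)
    expect_equal(cell$nv, orc$nv)
    expect_equal(cell$ne, orc$ne)
    expect_equal(cell$volume, orc$volume, tolerance = 1e-8)
    expect_equal(cell$surface, orc$surface, tolerance = 1e-8)
    expect_setequal(round(cell$face_d, 6), round(orc$face_d, 6))
    # vertex sets coincide
    for (q in seq_len(nrow(orc$vertices))) {
      dmin <- min(vapply(cell$faces, function(f)
        min(rowSums(sweep(f, 2, orc$vertices[q, ])^2)), numeric(1)))
      expect_lt(sqrt(dmin), 1e-6)
    }
  }
  # fcc cell again, via the independent oracle this time
  f <- make_lattice("fcc", 3, 3.0)
  orc <- oracle_cell(f, cutoff = 1.5 * 3.0)
  expect_equal(orc$nf, 12)
  expect_equal(orc$nv, 14)
  expect_equal(orc$volume, 3.0^3 / 4, tolerance = 1e-8)
})

test_that("every vertex carries a Voronoi certificate", {
  # vertex = point equidistant from the center and >= 3 face neighbors,
  # with no site of the frame (or image) closer
  cfg <- make_poisson(100, 12, seed = 13)
  cell <- voronoi_cell(cfg, site = 4L)
  rel <- minimum_image(
    matrix(cfg$positions[4L, ], 100, 3, byrow = TRUE), cfg$positions, 12)
  verts <- unique(round(do.call(rbind, cell$faces), 7))
  for (q in seq_len(nrow(verts))) {
    v <- verts[q, ]
    r0 <- sqrt(sum(v^2))  # distance to the center
    dn <- sqrt(rowSums(sweep(rel, 2, v)^2))
    dn <- dn[-4L]  # drop the center itself
    expect_gte(min(dn), r0 - 1e-6)            # no generator closer
    expect_gte(sum(abs(dn - r0) < 1e-6), 3)   # >= 3 cogenerators
  }
})

test_that("Euler relation and bisector bounds hold on random frames", {
  for (seed in 1:3) {
    cfg <- make_poisson(150, 11, seed = seed)
    tab <- tessellate_all(cfg)
    expect_true(all(tab$converged))
    expect_true(all(tab$nf + tab$nv - tab$ne == 2))
    expect_true(all(tab$nf >= 4))
    expect_true(all(tab$alpha >= 1))
    # min d/2 <= Rw <= R/2 for bisector-faced cells
    expect_true(all(tab$rw <= tab$cage_radius / 2 + 1e-12))
  }
  cfg <- make_poisson(60, 9, seed = 5)
  cell <- voronoi_cell(cfg)
  expect_gte(cell_metrics(cell)$rw, min(cell$face_d) / 2 - 1e-12)
})

test_that("tessellation fills space exactly", {
  a <- 2.5
  tab <- tessellate_all(make_lattice("sc", 4, a))
  expect_equal(nrow(tab), 64)
  expect_equal(tab$volume, rep(a^3, 64), tolerance = 1e-9)
  expect_equal(sum(tab$volume), (4 * a)^3, tolerance = 1e-9)
  cfg <- make_poisson(100, 10, seed = 21)
  tab <- tessellate_all(cfg)
  expect_equal(sum(tab$volume), 1000, tolerance = 1e-8)
})

test_that("descriptors are scale-equivariant", {
  cfg <- make_poisson(80, 10, seed = 9)
  s <- 2.7
  scaled <- configuration(cfg$positions * s, 10 * s, species = cfg$species,
                          solute_index = cfg$solute_index)
  m1 <- cell_metrics(voronoi_cell(cfg))
  m2 <- cell_metrics(voronoi_cell(scaled))
  expect_equal(m2$nf, m1$nf)
  expect_equal(m2$volume, m1$volume * s^3, tolerance = 1e-9)
  expect_equal(m2$surface, m1$surface * s^2, tolerance = 1e-9)
  expect_equal(m2$cage_radius, m1$cage_radius * s, tolerance = 1e-9)
  expect_equal(m2$rw, m1$rw * s, tolerance = 1e-9)
  expect_equal(m2$alpha, m1$alpha, tolerance = 1e-9)
})

test_that("low-density frames trigger image-shell expansion and stay exact", {
  # 10 sites in a 40 A box: cells extend far beyond L/4
  cfg <- make_poisson(10, 40, seed = 31)
  tab <- tessellate_all(cfg)
  expect_true(all(tab$converged))
  expect_equal(sum(tab$volume), 40^3, tolerance = 1e-8)
  cell <- voronoi_cell(cfg)
  expect_gte(cell$image_shell, 1L)
})

test_that("trajectory analysis flags rows and rejects degenerate input", {
  spec <- fixture_spec("poisson", n = 50, box_length = 8, seed = 2)
  frames <- make_trajectory(spec, 5)
  tab <- analyze_trajectory(frames)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$converged))
  expect_identical(attr(tab, "skipped"), 0L)
  expect_true(all(tab$nf + tab$nv - tab$ne == 2))
  lat <- analyze_trajectory(list(make_lattice("sc", 3, 3.0)))
  expect_equal(lat$volume, 27, tolerance = 1e-9)
  expect_error(analyze_trajectory(list()), "no frames")
})

test_that("cell metrics refuse unconverged or impossible cells", {
  cfg <- make_poisson(10, 40, seed = 31)
  p0 <- vp_params(max_image_shells = 0L)
  cell <- suppressWarnings(voronoi_cell(cfg, params = p0))
  expect_false(cell$converged)
  expect_error(cell_metrics(cell), "converge")
  expect_error(
    voronoi_cell(configuration(matrix(1, 5, 3), 10, solute_index = 1)),
    "coincident")
})
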