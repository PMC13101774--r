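# Mesh model, synthetic templates, areas, clusters, and file round-trips.

test_that("icosphere has the closed-form vertex/face counts and radius", {
  m0 <- make_icosphere(0, 1)
  expect_equal(nrow(m0$vertices), 12L)
  expect_equal(nrow(m0$faces), 20L)
  m2 <- make_icosphere(2, 1)
  expect_equal(nrow(m2$vertices), 162L)
  expect_equal(nrow(m2$faces), 20L * 16L)
  m3 <- make_icosphere(3, 2)
  expect_equal(sqrt(rowSums(m3$vertices^2)), rep(2, nrow(m3$vertices)),
               tolerance = 1e-12)
  expect_silent(validate_mesh(m3))
})

test_that("mesh invariant violations are caught", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), "repeated vertex")
  expect_error(triangle_mesh(rbind(v, c(2, 0, 0)),
                             rbind(c(1, 2, 3), c(1, 2, 4))),
               "zero-area")
  # two triangles sharing no edge: disconnected
  v6 <- rbind(v, v + 10)
  expect_error(triangle_mesh(v6, rbind(c(1, 2, 3), c(4, 5, 6))),
               "not edge-connected")
})

test_that("vertex areas are barycentric and homogeneous of degree 2", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                       rbind(c(1, 2, 3)), check = FALSE)
  expect_equal(vertex_areas(tri), rep(sqrt(3) / 4 / 3, 3), tolerance = 1e-12)
  m <- fix_sphere(4)
  expect_equal(sum(vertex_areas(m)), 4 * pi, tolerance = 0.01)
  expect_equal(sum(vertex_areas(m)), mesh_surface_area(m), tolerance = 1e-9)
  m2 <- m; m2$vertices <- m$vertices * 3
  expect_equal(vertex_areas(m2), 9 * vertex_areas(m), tolerance = 1e-12)
})

test_that("mesh_clusters partitions subsets into edge-connected components", {
  m <- fix_sphere(3)
  all_cl <- mesh_clusters(m, seq_len(nrow(m$vertices)))
  expect_length(all_cl, 1L)
  expect_equal(all_cl[[1]]$area, mesh_surface_area(m), tolerance = 1e-9)

  # two vertices with no connecting edge
  two <- mesh_clusters(m, c(1L, 400L))
  expect_length(two, 2L)

  # random 30% subset: partition property + igraph component oracle
  set.seed(42)
  subset <- sort(sample(nrow(m$vertices), round(0.3 * nrow(m$vertices))))
  cl <- mesh_clusters(m, subset)
  got <- sort(unlist(lapply(cl, `[[`, "vertices")))
  expect_identical(got, subset)  # disjoint union equals input
  expect_equal(sum(vapply(cl, `[[`, numeric(1), "area")),
               sum(vertex_areas(m)[subset]), tolerance = 1e-9)
  areas <- vapply(cl, `[[`, numeric(1), "area")
  expect_true(all(diff(areas) <= 1e-12))  # sorted descending
  skip_if_not_installed("igraph")
  e <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  keep <- e[, 1] %in% subset & e[, 2] %in% subset
  g <- igraph::graph_from_edgelist(
    matrix(match(e[keep, ], subset), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, length(subset) - igraph::gorder(g))
  expect_equal(length(cl), igraph::components(g)$no)
})

test_that("VTK and OFF round-trips preserve geometry and connectivity", {
  m <- make_icosphere(1, 1)
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(m, vtk)
  expect_match(readLines(vtk)[5], "^POINTS 42 float$")
  m2 <- read_mesh(vtk)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-15, ignore_attr = TRUE)
  expect_identical(m2$faces, m$faces)

  off <- withr::local_tempfile(fileext = ".off")
  write_mesh(fix_tetrahedron(), off)
  expect_identical(readLines(off)[2], "4 4 0")
  t2 <- read_mesh(off)
  expect_identical(t2$faces, fix_tetrahedron()$faces)

  # VTK -> OFF -> VTK preserves the face list
  write_mesh(m2, off)
  m3 <- read_mesh(off)
  vtk2 <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(m3, vtk2)
  expect_identical(read_mesh(vtk2)$faces, m$faces)
})

test_that("malformed mesh files are rejected with format errors", {
  bad <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("not a vtk file", "x", "ASCII"), bad)
  expect_error(read_mesh(bad), "line 1")

  quad <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 4.2", "t", "ASCII", "DATASET POLYDATA",
               "POINTS 4 float", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "POLYGONS 1 5", "4 0 1 2 3"), quad)
  expect_error(read_mesh(quad), "unsupported topology")

  off_quad <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), off_quad)
  expect_error(read_mesh(off_quad), "unsupported topology")
})

test_that("FreeSurfer binary surface, curv, label and CSV maps round-trip", {
  m <- make_icosphere(1, 100)
  fs <- withr::local_tempfile(fileext = ".surf")
  write_mesh(m, fs, format = "freesurfer")
  m2 <- read_mesh(fs, format = "freesurfer")
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6, ignore_attr = TRUE)

  vals <- sin(seq_len(nrow(m$vertices)))
  curv <- withr::local_tempfile(fileext = ".curv")
  write_surface_map(surface_map(vals, m), curv, format = "curv")
  expect_equal(read_surface_map(curv, m)$values, vals, tolerance = 1e-7)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_surface_map(surface_map(vals, m), csv)
  expect_equal(read_surface_map(csv, m)$values, vals, tolerance = 1e-12)

  mask <- vals > 0
  lab <- withr::local_tempfile(fileext = ".label")
  write_label(mask, m, lab)
  expect_identical(read_label(lab, m), mask)
})

test_that("surface_map enforces length and non-empty mask", {
  m <- fix_tetrahedron()
  expect_error(surface_map(1:3, m), "vertex count")
  expect_error(surface_map(1:4, m, mask = rep(FALSE, 4)), "at least one")
})
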