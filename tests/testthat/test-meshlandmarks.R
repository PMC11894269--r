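test_that("STL round trips preserve triangle counts and geometry", {
  fix <- get_mesh_fixture()
  bin <- withr::local_tempfile(fileext = ".stl")
  write_stl(fix$mesh, bin, format = "binary")
  back <- read_mesh(bin)
  expect_equal(nrow(back$triangles), nrow(fix$mesh$triangles))
  expect_equal(nrow(back$vertices), nrow(fix$mesh$vertices))
  # coordinates survive to float32 precision (vertex order may differ;
  # sort on coarsened keys so sub-float32 offsets cannot reorder rows)
  sort_rows <- function(m) m[order(round(m[, 1], 3), round(m[, 2], 3)), ]
  expect_lt(max(abs(sort_rows(back$vertices) - sort_rows(fix$mesh$vertices))),
            1e-4)
})

test_that("binary and ASCII encodings parse to identical geometry", {
  # a small sub-mesh keeps the ASCII file quick to parse
  truth <- synthetic_truth(seed = 9)
  small <- generate_dentition_mesh(truth, step = 1)$mesh
  bin <- withr::local_tempfile(fileext = ".stl")
  asc <- withr::local_tempfile(fileext = ".stl")
  write_stl(small, bin, format = "binary")
  write_stl(small, asc, format = "ascii")
  mb <- read_mesh(bin)
  ma <- read_mesh(asc)
  expect_equal(nrow(mb$triangles), nrow(ma$triangles))
  expect_lt(max(abs(mb$vertices - ma$vertices)), 1e-6)
})

test_that("unparseable or empty STL files raise format errors", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines("this is not an stl file", path)
  expect_error(read_mesh(path), class = "monson_io_error")
  writeLines(c("solid empty", "endsolid empty"), path)
  expect_error(read_mesh(path), class = "monson_io_error")
  expect_error(read_mesh(file.path(tempdir(), "does-not-exist.stl")),
               class = "monson_io_error")
})

test_that("degenerate triangles are dropped on read with a message", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0)),
                  rbind(c(1, 2, 3), c(1, 2, 4)))  # second is collinear
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(tri, path, format = "ascii")
  expect_message(back <- read_mesh(path), "degenerate")
  expect_equal(nrow(back$triangles), 1)
})

test_that("height fields project onto the occlusal axis and are frame-invariant", {
  fix <- get_mesh_fixture()
  h <- height_field(fix$mesh, occlusal_frame())
  expect_equal(h, unname(fix$mesh$vertices[, 3]))
  # rotating mesh and frame together leaves heights unchanged
  rot <- random_rotation(4)
  moved <- tri_mesh(fix$mesh$vertices %*% t(rot), fix$mesh$triangles)
  frame <- occlusal_frame(axis = as.numeric(rot %*% c(0, 0, 1)))
  expect_equal(height_field(moved, frame), h, tolerance = 1e-9)
  expect_error(occlusal_frame(axis = c(0, 0, 0)),
               class = "monson_validation_error")
})

test_that("a single-bump mesh yields exactly one candidate at its apex", {
  xs <- seq(-5, 5, by = 0.25)
  g <- expand.grid(x = xs, y = xs)
  g$z <- pmax(0, 4 - 2 * (g$x^2 + g$y^2))
  nx <- length(xs)
  ij <- expand.grid(i = seq_len(nx - 1), j = seq_len(nx - 1))
  v00 <- (ij$j - 1) * nx + ij$i
  tris <- rbind(cbind(v00, v00 + 1, v00 + nx + 1),
                cbind(v00, v00 + nx + 1, v00 + nx))
  mesh <- tri_mesh(as.matrix(g), tris)
  cands <- extract_tip_candidates(mesh)
  expect_equal(nrow(cands), 1)
  expect_equal(as.numeric(cands[1, c("x", "y", "z")]), c(0, 0, 4))
  # raising min_prominence above the bump height suppresses it
  none <- extract_tip_candidates(mesh, min_prominence = 10)
  expect_equal(nrow(none), 0)
  # a flat mesh has no supra-threshold vertices at all
  flat <- tri_mesh(cbind(as.matrix(g[, c("x", "y")]), 0), tris)
  expect_warning(empty <- extract_tip_candidates(flat), "no vertices")
  expect_equal(nrow(empty), 0)
})

test_that("all 26 cusp tips are recovered on the synthetic dentition", {
  fix <- get_mesh_fixture()
  cands <- extract_tip_candidates(fix$mesh)
  expect_equal(nrow(cands), 26)
  ap <- as.matrix(fix$apices$points[, c("x", "y", "z")])
  d <- apply(as.matrix(cands[, c("x", "y", "z")]), 1, function(p) {
    min(sqrt(rowSums(sweep(ap, 2, p)^2)))
  })
  expect_lt(max(d), 0.3)
})

test_that("suppression parameters act monotonically on the candidate count", {
  fix <- get_mesh_fixture()
  base <- nrow(extract_tip_candidates(fix$mesh))
  for (prom in c(2, 5, 8)) {
    expect_lte(nrow(extract_tip_candidates(fix$mesh, min_prominence = prom)),
               base)
  }
  n_prev <- base
  for (sep in c(5, 8, 12)) {
    n_cur <- nrow(extract_tip_candidates(fix$mesh, min_separation = sep))
    expect_lte(n_cur, n_prev)
    n_prev <- n_cur
  }
})

test_that("label assignment is exact on the template and stable under jitter", {
  fix <- get_mesh_fixture()
  tmpl <- fix$apices
  pts <- as.matrix(tmpl$points[, c("x", "y", "z")])
  exact <- assign_labels(pts, tmpl)
  expect_equal(exact$points$label, tmpl$points$label)
  expect_equal(attr(exact, "total_cost"), 0, tolerance = 1e-12)

  set.seed(17)
  jit <- pts + matrix(rnorm(length(pts), sd = 0.2), ncol = 3)
  rownames(jit) <- NULL
  jittered <- assign_labels(jit, tmpl)
  # same assignment as noiseless: each label lands on its own jittered point
  expect_equal(as.matrix(jittered$points[, c("x", "y", "z")]), jit,
               ignore_attr = TRUE, tolerance = 1e-12)

  partial <- assign_labels(pts[-7, ], tmpl)
  expect_equal(nrow(partial$points), 25)
  expect_length(attr(partial, "missing"), 1)
  expect_false(partial$complete)
})

test_that("detect-then-fit recovers the truth radius end-to-end", {
  fix <- get_mesh_fixture()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(fix$mesh, path)
  mesh <- read_mesh(path)
  labelled <- detect_landmarks(mesh, template = fix$apices)
  expect_true(labelled$complete)
  fit <- fit_sphere(labelled)
  expect_lt(abs(fit$radius - 77.35), 1)
})
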