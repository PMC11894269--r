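test_that("exact spheres are recovered exactly, including under translation", {
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (method in c("algebraic", "geometric")) {
    fit <- fit_sphere(octa, method = method)
    expect_equal(unname(fit$center), c(0, 0, 0), tolerance = 1e-12)
    expect_equal(fit$radius, 1, tolerance = 1e-12)
    expect_lt(fit$rms_residual, 1e-12)

    shifted <- sweep(octa, 2, c(10, 20, 30), "+")
    fit2 <- fit_sphere(shifted, method = method)
    expect_equal(unname(fit2$center), c(10, 20, 30), tolerance = 1e-9)
    expect_equal(fit2$radius, 1, tolerance = 1e-9)
  }
  # random exact configurations, both fits, 1e-9 relative error
  for (seed in 1:10) {
    pts <- exact_sphere_points(12, center = c(5, -3, 40), radius = 80,
                               seed = seed)
    for (method in c("algebraic", "geometric")) {
      fit <- fit_sphere(pts, method = method)
      expect_equal(fit$radius, 80, tolerance = 1e-9)
      expect_equal(unname(fit$center), c(5, -3, 40), tolerance = 1e-9)
    }
  }
})

test_that("fits are equivariant under rigid motion and scaling", {
  g <- generate_landmarks(synthetic_truth(seed = 11))
  pts <- as.matrix(g$landmarks$points[, c("x", "y", "z")])
  for (seed in 1:5) {
    rot <- random_rotation(seed)
    shift <- c(7, -13, 2) * seed
    moved <- sweep(pts %*% t(rot), 2, shift, "+")
    for (method in c("algebraic", "geometric")) {
      f0 <- fit_sphere(pts, method = method)
      f1 <- fit_sphere(moved, method = method)
      expect_equal(f1$radius, f0$radius, tolerance = 1e-9)
      expect_equal(unname(f1$center),
                   unname(as.numeric(rot %*% f0$center + shift)),
                   tolerance = 1e-7)
      expect_equal(f1$rms_residual, f0$rms_residual, tolerance = 1e-9)
      # scale equivariance
      s <- 2.5
      f2 <- fit_sphere(pts * s, method = method)
      expect_equal(f2$radius, s * f0$radius, tolerance = 1e-9)
      expect_equal(unname(f2$center), unname(s * f0$center),
                   tolerance = 1e-7)
      expect_equal(f2$rms_residual, s * f0$rms_residual, tolerance = 1e-9)
    }
  }
})

test_that("noisy arch configurations are fitted close to truth and to the oracle", {
  g <- generate_landmarks(synthetic_truth(seed = 5))
  pts <- as.matrix(g$landmarks$points[, c("x", "y", "z")])
  fit <- fit_sphere(pts)
  expect_lt(abs(fit$radius - 77.35), 0.5)
  oracle <- oracle_geometric_fit(pts, restarts = 20, seed = 99)
  expect_lt(abs(fit$radius - oracle$radius), 0.05)
  obj_fit <- sum(sphere_residuals(pts, fit)^2)
  expect_lt(obj_fit, oracle$value + 1e-6)
})

test_that("a displaced landmark separates the two objectives, both near their oracles", {
  g <- generate_landmarks(synthetic_truth(seed = 8))
  pts <- as.matrix(g$landmarks$points[, c("x", "y", "z")])
  # push one landmark 3 mm radially outward
  ctr <- c(0, 0, 100)
  d <- pts[13, ] - ctr
  pts[13, ] <- ctr + d * (1 + 3 / sqrt(sum(d^2)))
  fa <- fit_sphere_algebraic(pts)
  fg <- fit_sphere_geometric(pts)
  expect_false(isTRUE(all.equal(fa$radius, fg$radius, tolerance = 1e-8)))
  expect_lt(abs(fg$radius - oracle_geometric_fit(pts, seed = 1)$radius), 1)
  # the closed-form fit is at least as good as the black-box search on
  # its own objective, and the search lands in the same valley
  obj_alg <- function(c3, r) sum((rowSums(sweep(pts, 2, c3)^2) - r^2)^2)
  oa <- oracle_algebraic_fit(pts, seed = 1)
  expect_lte(obj_alg(fa$center, fa$radius), oa$value * (1 + 1e-9))
  expect_lt(abs(fa$radius - oa$radius), 1)
})

test_that("geometric refinement never increases the rms residual", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:30, 1)
    pts <- exact_sphere_points(n, center = rnorm(3, sd = 10),
                               radius = runif(1, 20, 120), seed = seed) +
      matrix(rnorm(3 * n, sd = runif(1, 0, 2)), ncol = 3)
    if (coplanarity_measure(pts) < 1e-4) next
    fa <- fit_sphere_algebraic(pts)
    fg <- fit_sphere_geometric(pts)
    expect_lte(fg$rms_residual, fa$rms_residual + 1e-12)
  }
})

test_that("geometric fit matches a multi-restart black-box minimiser", {
  skip_if_not_installed("minpack.lm")
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(5:30, 1)
    pts <- exact_sphere_points(n, center = rnorm(3, sd = 5),
                               radius = runif(1, 5, 50), seed = seed + 1000) +
      matrix(rnorm(3 * n, sd = 0.3), ncol = 3)
    if (coplanarity_measure(pts) < 1e-3) next
    fg <- fit_sphere_geometric(pts)
    obj_fit <- sum(sphere_residuals(pts, fg)^2)
    # independent route: Levenberg-Marquardt from minpack.lm, multi-restart
    obj_best <- Inf
    ctr <- colMeans(pts)
    r0 <- mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
    set.seed(seed + 2000)
    for (i in 1:10) {
      init <- c(ctr + rnorm(3, sd = r0 / 2), r0 * runif(1, 0.5, 2))
      res <- tryCatch(minpack.lm::nls.lm(
        par = init,
        fn = function(th) sqrt(rowSums(sweep(pts, 2, th[1:3])^2)) - th[4],
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(res)) obj_best <- min(obj_best, sum(res$fvec^2))
    }
    expect_lt(abs(obj_fit - obj_best), 1e-6)
  }
})

test_that("residuals are signed orthogonal distances consistent with the fit", {
  pts <- exact_sphere_points(15, center = c(1, 2, 3), radius = 10, seed = 4)
  fit <- fit_sphere(pts)
  expect_equal(sphere_residuals(pts, fit), rep(0, 15), tolerance = 1e-9)
  outside <- fit$center + c(0, 0, fit$radius + 2)
  expect_equal(sphere_residuals(rbind(outside), fit), 2, tolerance = 1e-9)
  for (seed in 1:10) {
    set.seed(seed)
    noisy <- pts + matrix(rnorm(45, sd = 0.5), ncol = 3)
    f <- fit_sphere(noisy)
    r <- sphere_residuals(noisy, f)
    expect_equal(sqrt(mean(r^2)), f$rms_residual, tolerance = 1e-9)
    expect_equal(max(abs(r)), f$max_residual, tolerance = 1e-9)
    expect_gte(f$max_residual, f$rms_residual)
  }
})

test_that("coplanarity measure flags flat sets and is rigid-motion invariant", {
  set.seed(7)
  flat <- cbind(matrix(runif(40), ncol = 2) * 10, 0)
  expect_equal(coplanarity_measure(flat), 0)
  sph <- exact_sphere_points(20, radius = 1, seed = 2)
  expect_gt(coplanarity_measure(sph), 0.1)
  rot <- random_rotation(3)
  moved <- sweep(sph %*% t(rot), 2, c(4, 5, 6), "+")
  expect_equal(coplanarity_measure(moved), coplanarity_measure(sph),
               tolerance = 1e-9)
})

test_that("degenerate inputs raise classed errors", {
  expect_error(fit_sphere_algebraic(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               class = "monson_computation_error")
  set.seed(1)
  flat <- cbind(matrix(runif(20), ncol = 2) * 10, 0)
  expect_error(fit_sphere_algebraic(flat),
               class = "monson_computation_error")
  expect_error(coplanarity_measure(rbind(c(0, 0, 0), c(1, 1, 1))),
               class = "monson_computation_error")
})

test_that("sphere fits serialise to JSON with per-landmark residuals", {
  g <- generate_landmarks(synthetic_truth(seed = 6))
  fit <- fit_sphere(g$landmarks)
  doc <- jsonlite::fromJSON(sphere_fit_json(fit, points = g$landmarks))
  expect_equal(doc$radius_mm, fit$radius, tolerance = 1e-12)
  expect_named(doc$center_mm, c("x", "y", "z"))
  expect_length(doc$residuals_mm, 26)
  expect_equal(doc$residuals_mm$Pt1,
               sphere_residuals(g$landmarks, fit)[1], tolerance = 1e-12)
})
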