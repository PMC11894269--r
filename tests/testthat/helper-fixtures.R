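# Shared fixtures and independent oracles for the test suite.

# Points exactly on a sphere, directions drawn uniformly but kept away
# from a common plane so configurations are never near-degenerate.
exact_sphere_points <- function(n, center = c(0, 0, 0), radius = 1,
                                seed = 1) {
  set.seed(seed)
  repeat {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    if (coplanarity_measure(u) > 0.05) break
  }
  sweep(u * radius, 2, center, "+")
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Independent oracle for the geometric sphere objective: black-box
# minimisation of sum((||p - c|| - R)^2) from multiple random restarts.
oracle_geometric_fit <- function(pts, restarts = 20, seed = 1) {
  obj <- function(th) sum((sqrt(rowSums(sweep(pts, 2, th[1:3])^2)) - th[4])^2)
  ctr <- colMeans(pts)
  scale0 <- mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(restarts)) {
    init <- c(ctr + rnorm(3, sd = scale0), scale0 * runif(1, 0.3, 3))
    sol <- tryCatch(
      optim(init, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(sol) && (is.null(best) || sol$value < best$value)) best <- sol
  }
  list(center = best$par[1:3], radius = best$par[4], value = best$value)
}

# Same idea for the algebraic (Kasa) objective sum((||p-c||^2 - R^2)^2);
# the objective depends on R only through R^2, so the radius is |R|.
oracle_algebraic_fit <- function(pts, restarts = 20, seed = 1) {
  obj <- function(th) sum((rowSums(sweep(pts, 2, th[1:3])^2) - th[4]^2)^2)
  ctr <- colMeans(pts)
  scale0 <- mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(restarts)) {
    init <- c(ctr + rnorm(3, sd = scale0), scale0 * runif(1, 0.3, 3))
    sol <- tryCatch(
      optim(init, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(sol) && (is.null(best) || sol$value < best$value)) best <- sol
  }
  list(center = best$par[1:3], radius = abs(best$par[4]), value = best$value)
}

# Exact two-sided Mann-Whitney p by brute-force enumeration over all
# group labelings (no-ties case), using the doubled-smaller-tail rule.
mw_enumeration_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  splits <- combn(n, n_a)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# ICC mean squares written out longhand for a small n x k table.
icc_hand_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msb <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msj <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - grand)^2) - (n - 1) * msb - (k - 1) * msj
  mse <- sse / ((n - 1) * (k - 1))
  list(
    msb = msb, msj = msj, mse = mse,
    consistency = (msb - mse) / (msb + (k - 1) * mse),
    agreement = (msb - mse) / (msb + (k - 1) * mse + k * (msj - mse) / n)
  )
}

# The synthetic dentition mesh fixture is expensive; build once per run.
mesh_fixture_env <- new.env(parent = emptyenv())
get_mesh_fixture <- function() {
  if (is.null(mesh_fixture_env$fix)) {
    mesh_fixture_env$fix <- generate_dentition_mesh(
      synthetic_truth(seed = 42))
  }
  mesh_fixture_env$fix
}

table1_path <- function() {
  system.file("extdata", "table1_repeated_radii.csv", package = "monson")
}

# Radius samples with exactly the requested mean and SD.
exact_moment_sample <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- as.numeric(scale(rnorm(n)))
  mean + sd * z
}
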