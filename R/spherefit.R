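#' Algebraic (Kasa) least-squares sphere fit
#'
#' Fits the sphere minimising the algebraic residual
#' \eqn{\sum_i (\|p_i - c\|^2 - R^2)^2}. Substituting
#' \eqn{\beta = (2c_x, 2c_y, 2c_z, R^2 - \|c\|^2)} linearises the problem:
#' each point contributes the equation
#' \eqn{2 c \cdot p_i + (R^2 - \|c\|^2) = \|p_i\|^2}, solved by ordinary
#' linear least squares. Deterministic and closed-form; it is the seed for
#' the geometric refinement in [fit_sphere_geometric()].
#'
#' @param points An n x 3 coordinate matrix (mm), a data frame with
#'   columns `x`, `y`, `z`, or a [landmark_set()]. At least 4 points, not
#'   all coplanar.
#' @param coplanar_tol Thickness-ratio threshold for the degeneracy check
#'   (see [coplanarity_measure()]).
#' @return A `sphere_fit` object: list with `center` (named length-3
#'   vector, mm), `radius` (mm), `rms_residual` and `max_residual`
#'   (orthogonal distances, mm), `n_points`, `method = "algebraic"`,
#'   `converged = TRUE`, and `partial` (`TRUE` when fitted from fewer
#'   than the full 26 landmarks).
#' @references Kasa, I. (1976). A circle fitting procedure and its error
#'   analysis. IEEE Transactions on Instrumentation and Measurement, 25, 8-14.
#' @export
fit_sphere_algebraic <- function(points, coplanar_tol = 1e-6) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < 4) {
    ms_computation_error(sprintf(
      "insufficient points for sphere fit: %d given, at least 4 required", n))
  }
  if (coplanarity_measure(pts) < coplanar_tol) {
    ms_computation_error(
      "degenerate configuration: points are coplanar (or nearly so); a sphere is not determined")
  }
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  beta <- qr.solve(A, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (r2 <= 0) {
    ms_computation_error("degenerate configuration: non-positive fitted radius")
  }
  new_sphere_fit(center, sqrt(r2), pts, method = "algebraic", converged = TRUE)
}

#' Geometric (orthogonal-distance) least-squares sphere fit
#'
#' Refines a sphere to minimise the geometric objective
#' \eqn{\sum_i (\|p_i - c\| - R)^2} (the sum of squared orthogonal
#' distances to the surface) by Levenberg-damped Gauss-Newton on the four
#' parameters \eqn{(c_x, c_y, c_z, R)}. Seeded from the algebraic fit
#' unless `init` is supplied. Damped steps are only accepted when they
#' reduce the objective, so the returned root-mean-square residual never
#' exceeds that of the initialisation.
#'
#' @inheritParams fit_sphere_algebraic
#' @param init Optional starting `sphere_fit` (defaults to
#'   [fit_sphere_algebraic()] on the same points).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param step_tol,grad_tol Convergence thresholds on the parameter step
#'   norm (mm) and the gradient norm.
#' @return A `sphere_fit` with `method = "geometric"`; `converged` is
#'   `FALSE` when the iteration cap was reached before the step and
#'   gradient criteria, in which case the best iterate seen is returned
#'   (never an error).
#' @export
fit_sphere_geometric <- function(points, init = NULL, max_iter = 100,
                                 step_tol = 1e-10, grad_tol = 1e-10,
                                 coplanar_tol = 1e-6) {
  pts <- as_point_matrix(points)
  if (is.null(init)) {
    init <- fit_sphere_algebraic(pts, coplanar_tol = coplanar_tol)
  } else if (!inherits(init, "sphere_fit")) {
    ms_validation_error("init must be a sphere_fit or NULL")
  }
  theta <- c(init$center, init$radius)
  obj <- function(th) {
    d <- sqrt(rowSums(sweep(pts, 2, th[1:3])^2))
    r <- d - th[4]
    list(r = r, d = d, sse = sum(r^2))
  }
  cur <- obj(theta)
  lambda <- 1e-3
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d <- pmax(cur$d, .Machine$double.eps)
    # Jacobian of residual r_i = ||p_i - c|| - R
    J <- cbind(-sweep(pts, 2, theta[1:3]) / d, -1)
    g <- crossprod(J, cur$r)
    if (sqrt(sum(g^2)) < grad_tol) { converged <- TRUE; break }
    H <- crossprod(J)
    step <- NULL
    repeat {
      delta <- tryCatch(solve(H + lambda * diag(4), -g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- obj(theta + as.numeric(delta))
        if (cand$sse <= cur$sse) { step <- as.numeric(delta); break }
      }
      lambda <- lambda * 2
      if (lambda > 1e12) break
    }
    if (is.null(step)) break  # no downhill step found at any damping
    theta <- theta + step
    cur <- obj(theta)
    lambda <- max(lambda * 0.5, 1e-12)
    if (sqrt(sum(step^2)) < step_tol) { converged <- TRUE; break }
  }
  if (theta[4] <= 0) {
    ms_computation_error("geometric fit collapsed to non-positive radius")
  }
  fit <- new_sphere_fit(theta[1:3], theta[4], pts, method = "geometric",
                        converged = converged)
  # refinement contract: never worse than the initialisation
  if (fit$rms_residual > init$rms_residual) {
    fit <- new_sphere_fit(init$center, init$radius, pts,
                          method = "geometric", converged = converged)
  }
  fit
}

#' Fit Monson's sphere to a landmark set
#'
#' Convenience wrapper: the default `"geometric"` method runs the
#' algebraic fit and refines it by orthogonal-distance minimisation;
#' `"algebraic"` stops after the closed-form fit.
#'
#' @inheritParams fit_sphere_algebraic
#' @param method `"geometric"` (default) or `"algebraic"`.
#' @return A `sphere_fit`.
#' @examples
#' octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
#'               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
#' fit_sphere(octa)
#' @export
fit_sphere <- function(points, method = c("geometric", "algebraic"),
                       coplanar_tol = 1e-6) {
  method <- match.arg(method)
  if (method == "algebraic") {
    fit_sphere_algebraic(points, coplanar_tol = coplanar_tol)
  } else {
    fit_sphere_geometric(points, coplanar_tol = coplanar_tol)
  }
}

new_sphere_fit <- function(center, radius, pts, method, converged) {
  radius <- unname(radius)
  center <- as.numeric(center)
  names(center) <- c("x", "y", "z")
  res <- sqrt(rowSums(sweep(pts, 2, center)^2)) - radius
  structure(
    list(center = center, radius = radius,
         rms_residual = sqrt(mean(res^2)),
         max_residual = max(abs(res)),
         n_points = nrow(pts),
         method = method, converged = converged,
         partial = nrow(pts) < 26,
         point_labels = rownames(pts)),
    class = "sphere_fit"
  )
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("Monson sphere fit (%s%s): R = %.3f mm, center = (%.3f, %.3f, %.3f) mm\n",
              x$method, if (x$partial) ", partial" else "",
              x$radius, x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  %d points, rms residual %.4f mm, max %.4f mm\n",
              x$n_points, x$rms_residual, x$max_residual))
  invisible(x)
}

#' Signed orthogonal residuals of points to a fitted sphere
#'
#' @param points Coordinates as for [fit_sphere()].
#' @param sphere A `sphere_fit`.
#' @return Numeric vector, order-aligned with the input:
#'   \eqn{\|p_i - c\| - R} in mm (positive outside the sphere). The root
#'   mean square of these equals `sphere$rms_residual` when evaluated on
#'   the fitted points.
#' @export
sphere_residuals <- function(points, sphere) {
  if (!inherits(sphere, "sphere_fit")) {
    ms_validation_error("sphere must be a sphere_fit")
  }
  pts <- as_point_matrix(points)
  as.numeric(sqrt(rowSums(sweep(pts, 2, sphere$center)^2)) - sphere$radius)
}

#' Coplanarity thickness ratio of a point configuration
#'
#' The smallest singular value of the centred coordinate matrix divided by
#' the largest: 0 for exactly coplanar points, invariant under rigid
#' motion, and used as the degeneracy check for sphere fitting (values
#' below `1e-6` are treated as coplanar by default).
#'
#' @param points At least 4 points, as for [fit_sphere()].
#' @return A dimensionless ratio in `[0, 1]`.
#' @export
coplanarity_measure <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 4) {
    ms_computation_error("coplanarity measure requires at least 4 points")
  }
  sv <- svd(scale(pts, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[1] == 0) return(0)
  sv[3] / sv[1]
}

#' Serialise a sphere fit to JSON
#'
#' @param sphere A `sphere_fit`.
#' @param points Optional coordinates (typically the fitted
#'   [landmark_set()]); when given, a per-point residual table keyed by
#'   landmark label is included.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
sphere_fit_json <- function(sphere, points = NULL, path = NULL) {
  if (!inherits(sphere, "sphere_fit")) {
    ms_validation_error("sphere must be a sphere_fit")
  }
  doc <- list(
    schema_version = "1.0",
    center_mm = as.list(sphere$center),
    radius_mm = sphere$radius,
    rms_residual_mm = sphere$rms_residual,
    max_residual_mm = sphere$max_residual,
    n_points = sphere$n_points,
    method = sphere$method,
    converged = sphere$converged,
    partial = sphere$partial
  )
  if (!is.null(points)) {
    pts <- as_point_matrix(points)
    res <- sphere_residuals(pts, sphere)
    labels <- rownames(pts)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(pts)))
    doc$residuals_mm <- stats::setNames(as.list(res), labels)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
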