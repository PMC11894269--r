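# Internal helpers: classed errors and seeded RNG scoping.

ms_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "monson_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ms_validation_error <- function(msg) ms_error(msg, "monson_validation_error")
ms_io_error         <- function(msg) ms_error(msg, "monson_io_error")
ms_computation_error <- function(msg) ms_error(msg, "monson_computation_error")

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream. All package generators route their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Coerce a landmark set / data.frame / matrix to an n x 3 coordinate matrix,
# carrying point labels through as rownames when available.
as_point_matrix <- function(x) {
  if (inherits(x, "landmark_set")) {
    m <- as.matrix(x$points[, c("x", "y", "z")])
    rownames(m) <- x$points$label
    return(m)
  }
  if (is.data.frame(x)) {
    cols <- intersect(c("x", "y", "z"), names(x))
    if (length(cols) == 3) {
      m <- as.matrix(x[, cols])
      if ("label" %in% names(x)) rownames(m) <- x$label
      return(m)
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || ncol(x) != 3) {
    ms_validation_error("points must be an n x 3 matrix of x, y, z coordinates")
  }
  storage.mode(x) <- "double"
  x
}
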