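#' The 26-point cusp-tip landmark scheme
#'
#' Returns the fixed table of the 26 reference-point labels used to fit
#' Monson's sphere: per side of the arch, the canine cusp tip, the buccal
#' and lingual cusps of the two premolars, and the mesio-/disto- buccal and
#' lingual cusps of the two molars (13 points per side, `Pt1`..`Pt26`).
#'
#' @return A data frame with one row per label and columns `code`
#'   (`"Pt1"`..`"Pt26"`), `tooth` (`"canine"`, `"premolar"`, `"molar"`),
#'   `cusp` (cusp role) and `side` (`"right"`, `"left"`).
#' @examples
#' tab <- landmark_labels()
#' table(tab$side)
#' @export
landmark_labels <- function() {
  .landmark_label_table
}

# Fixed label scheme. Premolar pairs: Pt3/Pt4 and Pt7/Pt8 are the right
# first/second premolar (buccal, lingual); Pt5/Pt6, Pt9/Pt10 their left
# counterparts. Molars: Pt11-14 right first, Pt15-18 left first, Pt19-22
# right second, Pt23-26 left second, each ordered MB, DB, ML, DL.
.landmark_label_table <- local({
  lab <- function(code, tooth, cusp, side) {
    data.frame(code = code, tooth = tooth, cusp = cusp, side = side,
               stringsAsFactors = FALSE)
  }
  molar <- function(codes, side) {
    lab(codes, "molar",
        c("mesio-buccal", "disto-buccal", "mesio-lingual", "disto-lingual"),
        side)
  }
  rbind(
    lab("Pt1", "canine", "cusp tip", "right"),
    lab("Pt2", "canine", "cusp tip", "left"),
    lab(c("Pt3", "Pt4"), "premolar", c("buccal", "lingual"), "right"),
    lab(c("Pt5", "Pt6"), "premolar", c("buccal", "lingual"), "left"),
    lab(c("Pt7", "Pt8"), "premolar", c("buccal", "lingual"), "right"),
    lab(c("Pt9", "Pt10"), "premolar", c("buccal", "lingual"), "left"),
    molar(paste0("Pt", 11:14), "right"),
    molar(paste0("Pt", 15:18), "left"),
    molar(paste0("Pt", 19:22), "right"),
    molar(paste0("Pt", 23:26), "left")
  )
})

.all_landmark_codes <- paste0("Pt", 1:26)

#' Construct a landmark set
#'
#' A landmark set holds labelled 3-D cusp-tip coordinates (in millimetres)
#' for one dentition. Labels must come from the `Pt1`..`Pt26` scheme of
#' [landmark_labels()]; a set carrying all 26 exactly once is "complete".
#'
#' @param points A data frame with columns `label`, `x`, `y`, `z`
#'   (coordinates in mm), or an n x 3 matrix with labels as rownames.
#' @param subject_id Opaque subject/model identifier.
#' @return An object of class `landmark_set` with elements `subject_id`,
#'   `points` (data frame, rows ordered `Pt1`..`Pt26`), `units` (`"mm"`)
#'   and `complete` (logical).
#' @export
landmark_set <- function(points, subject_id = "unknown") {
  if (is.matrix(points)) {
    points <- data.frame(label = rownames(points), x = points[, 1],
                         y = points[, 2], z = points[, 3],
                         stringsAsFactors = FALSE)
  }
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(points))) {
    ms_validation_error("points must have columns label, x, y, z")
  }
  points <- points[, need]
  bad <- setdiff(points$label, .all_landmark_codes)
  if (length(bad)) {
    ms_validation_error(paste0("unknown landmark label(s): ",
                               paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(points$label)) {
    dup <- unique(points$label[duplicated(points$label)])
    ms_validation_error(paste0("duplicated landmark label(s): ",
                               paste(dup, collapse = ", ")))
  }
  coords <- as.matrix(points[, c("x", "y", "z")])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    ms_validation_error("all coordinates must be finite numbers")
  }
  points <- points[order(match(points$label, .all_landmark_codes)), ]
  rownames(points) <- NULL
  structure(
    list(subject_id = as.character(subject_id), points = points,
         units = "mm",
         complete = setequal(points$label, .all_landmark_codes)),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set '%s': %d/26 points (%s), units mm\n",
              x$subject_id, nrow(x$points),
              if (x$complete) "complete" else "partial"))
  invisible(x)
}

.landmark_csv_header <- c("label", "x_mm", "y_mm", "z_mm")

#' Read a landmark CSV file
#'
#' Reads the package's landmark CSV dialect: header `label,x_mm,y_mm,z_mm`,
#' one row per reference point with labels from `Pt1`..`Pt26`, coordinates
#' in millimetres, `#` comment lines ignored.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default), missing or duplicated labels are an
#'   error; if `FALSE`, missing labels are permitted (recorded in the
#'   returned set's `complete` flag) but duplicates always fail.
#' @param subject_id Identifier attached to the set; defaults to the file
#'   name without extension.
#' @return A [landmark_set()].
#' @seealso [write_landmarks()], [validate_for_fitting()]
#' @export
read_landmarks <- function(path, strict = TRUE, subject_id = NULL) {
  if (!file.exists(path)) ms_io_error(paste0("file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) ms_io_error(paste0("empty landmark file: ", path))
  header <- trimws(strsplit(lines[[1]], ",")[[1]])
  if (!identical(tolower(header), .landmark_csv_header)) {
    ms_io_error(paste0("expected header 'label,x_mm,y_mm,z_mm' in ", path))
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    fields <- trimws(strsplit(lines[[i]], ",")[[1]])
    if (length(fields) != 4) {
      ms_io_error(sprintf("line %d of %s: expected 4 fields, got %d",
                          lineno[i], path, length(fields)))
    }
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(xyz))) {
      ms_io_error(sprintf("line %d of %s: non-numeric coordinate", lineno[i], path))
    }
    data.frame(label = fields[1], x = xyz[1], y = xyz[2], z = xyz[3],
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, rows)
  if (is.null(pts)) ms_io_error(paste0("no data rows in ", path))
  if (strict) {
    dup <- unique(pts$label[duplicated(pts$label)])
    missing <- setdiff(.all_landmark_codes, pts$label)
    if (length(dup) || length(missing)) {
      parts <- c(
        if (length(dup)) paste0("duplicated: ", paste(dup, collapse = ", ")),
        if (length(missing)) paste0("missing: ", paste(missing, collapse = ", "))
      )
      ms_validation_error(paste0("invalid landmark set in ", path, " (",
                                 paste(parts, collapse = "; "), ")"))
    }
  }
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  landmark_set(pts, subject_id = subject_id)
}

#' Write a landmark set to CSV
#'
#' Emits the dialect read by [read_landmarks()]: header
#' `label,x_mm,y_mm,z_mm`, rows in `Pt1`..`Pt26` order, full double
#' precision so that a write/read round trip preserves coordinates.
#'
#' @param set A [landmark_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(set, path) {
  if (!inherits(set, "landmark_set")) {
    ms_validation_error("set must be a landmark_set")
  }
  lines <- c(
    paste(.landmark_csv_header, collapse = ","),
    sprintf("%s,%.17g,%.17g,%.17g", set$points$label,
            set$points$x, set$points$y, set$points$z)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ms_io_error(paste0("cannot write ", path))
  invisible(path)
}

#' Check whether a landmark set can be fitted
#'
#' A sphere is determined by at least four points that are not all
#' coplanar. The report lists missing and duplicated labels, the
#' coplanarity thickness ratio (smallest/largest singular value of the
#' centred coordinates, see [coplanarity_measure()]) and a fit-ready
#' verdict. Sets with 4..25 points are fit-ready but will be flagged
#' `"partial"` by the fit.
#'
#' @param set A [landmark_set()].
#' @param coplanar_tol Thickness-ratio threshold below which the set is
#'   treated as coplanar (default `1e-6`).
#' @return A list with elements `n_points`, `missing`, `duplicated`,
#'   `thickness_ratio`, `coplanar`, `fit_ready` and `reasons`.
#' @export
validate_for_fitting <- function(set, coplanar_tol = 1e-6) {
  if (!inherits(set, "landmark_set")) {
    ms_validation_error("set must be a landmark_set")
  }
  pts <- as_point_matrix(set)
  missing <- setdiff(.all_landmark_codes, set$points$label)
  reasons <- character()
  thickness <- NA_real_
  coplanar <- NA
  if (nrow(pts) < 4) {
    reasons <- c(reasons, "insufficient points")
  } else {
    thickness <- coplanarity_measure(pts)
    coplanar <- thickness < coplanar_tol
    if (coplanar) reasons <- c(reasons, "coplanar")
  }
  list(
    n_points = nrow(pts),
    missing = missing,
    duplicated = character(),  # landmark_set construction forbids duplicates
    thickness_ratio = thickness,
    coplanar = coplanar,
    fit_ready = length(reasons) == 0,
    reasons = reasons
  )
}
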