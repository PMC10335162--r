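#' Named 2-D facial landmark sets
#'
#' A `landmark_set` holds named points for one subject in image pixel
#' coordinates: x increases rightward and y increases *downward* (image
#' convention, origin at the top-left). Side suffixes `_L` / `_R` are
#' anatomical, i.e. the subject's own left/right, so on an upright frontal
#' photograph the `_R` landmarks appear on the viewer's left.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param points Either a numeric matrix/data.frame with two columns (x, y)
#'   and landmark names as row names, or a named list of length-2 numeric
#'   vectors.
#' @return An object of class `landmark_set` with fields `subject_id` and
#'   `points` (an n x 2 matrix with row names).
#' @examples
#' ls <- landmark_set("s1", list(glabella = c(100, 50), menton = c(100, 250)))
#' landmark_names(ls)
#' @export
landmark_set <- function(subject_id, points = list()) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    fm_schema_error("subject_id must be a single character string")
  if (is.list(points) && !is.data.frame(points)) {
    if (length(points) > 0 && is.null(names(points)))
      fm_schema_error("points list must be named")
    m <- do.call(rbind, lapply(points, function(p) as.numeric(p[1:2])))
    if (is.null(m)) m <- matrix(numeric(0), ncol = 2)
    rownames(m) <- names(points)
  } else {
    m <- as.matrix(points)
    if (ncol(m) != 2) fm_schema_error("points must have two columns (x, y)")
    storage.mode(m) <- "double"
  }
  colnames(m) <- c("x", "y")
  nm <- rownames(m)
  if (nrow(m) > 0) {
    if (is.null(nm) || any(nm == ""))
      fm_schema_error("every landmark must be named")
    if (anyDuplicated(nm))
      fm_schema_error(paste0("duplicate landmark name(s): ",
                             paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (any(!is.finite(m)))
      fm_schema_error("landmark coordinates must be finite")
  }
  structure(list(subject_id = subject_id, points = m), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> subject '%s': %d landmarks\n",
              x$subject_id, nrow(x$points)))
  invisible(x)
}

#' @rdname landmark_set
#' @param ls A `landmark_set`.
#' @export
landmark_names <- function(ls) rownames(ls$points)

#' Fetch one landmark's coordinates
#'
#' @param ls A `landmark_set`.
#' @param name Landmark name.
#' @return Numeric length-2 vector `c(x, y)`.
#' @export
landmark_point <- function(ls, name) {
  if (!name %in% rownames(ls$points))
    fm_schema_error(paste0("missing landmark: ", name,
                           " (subject ", ls$subject_id, ")"))
  as.numeric(ls$points[name, ])
}

#' Core landmark names required by the measurement battery
#'
#' The full battery (facial thirds, widths, brow geometry, canthal tilt,
#' scleral show) consumes this fixed subset; detectors may supply arbitrary
#' additional named points, which are carried through I/O untouched.
#'
#' @return Character vector of required landmark names, sorted.
#' @export
core_landmarks <- function() {
  base <- c("trichion", "glabella", "nasion", "pronasale", "subnasale",
            "menton")
  paired <- c("zygion", "gonion", "alare", "endocanthion", "exocanthion",
              "pupil", "brow_medial", "brow_apex", "brow_lateral",
              "iris_inferior", "lowerlid_margin")
  sort(c(base, paste0(rep(paired, each = 2), c("_L", "_R"))))
}

#' Report missing core landmarks
#'
#' @param ls A `landmark_set`.
#' @return Character vector (possibly empty) of missing core landmark names,
#'   lexicographically sorted.
#' @export
validate_core <- function(ls) {
  sort(setdiff(core_landmarks(), landmark_names(ls)))
}

#' Read a landmark set from CSV or JSON
#'
#' CSV files have a single header line `name,x,y`; JSON files are a flat
#' object mapping landmark name to `[x, y]`. Coordinates are taken verbatim
#' (no normalisation). Unknown landmark names are retained.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param subject_id Subject identifier to attach; defaults to the file's
#'   base name without extension.
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json"),
                           subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) fm_io_error(paste0("no such file: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "csv"
  }
  sid <- subject_id %||% tools::file_path_sans_ext(basename(path))
  if (format == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      fm_parse_error(paste0("malformed JSON in ", path, ": ",
                                            conditionMessage(e))))
    if (length(obj) == 0)
      return(landmark_set(sid, list()))
    if (is.null(names(obj)))
      fm_parse_error(paste0("landmark JSON must be a name -> [x, y] map: ", path))
    pts <- lapply(obj, function(v) {
      v <- suppressWarnings(as.numeric(v))
      if (length(v) != 2 || any(!is.finite(v)))
        fm_parse_error(paste0("bad coordinate pair in ", path))
      v
    })
    return(landmark_set(sid, pts))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) fm_parse_error(paste0("empty landmark file: ", path))
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) == 0) return(landmark_set(sid, list()))
  parts <- strsplit(body, ",", fixed = TRUE)
  pts <- vector("list", length(body))
  nms <- character(length(body))
  for (i in seq_along(body)) {
    f <- parts[[i]]
    if (length(f) != 3)
      fm_parse_error(sprintf("malformed row at line %d of %s: '%s'",
                             i + 1L, path, body[i]))
    xy <- suppressWarnings(as.numeric(f[2:3]))
    if (any(!is.finite(xy)))
      fm_parse_error(sprintf("non-numeric coordinate at line %d of %s",
                             i + 1L, path))
    nms[i] <- trimws(f[1])
    pts[[i]] <- xy
  }
  if (anyDuplicated(nms))
    fm_schema_error(paste0("duplicate landmark name(s) in ", path, ": ",
                           paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  names(pts) <- nms
  landmark_set(sid, pts)
}

#' Write a landmark set to CSV or JSON
#'
#' Output round-trips bit-exactly through [read_landmarks()]: coordinates
#' are serialised with full double precision (17 significant digits).
#'
#' @param ls A [landmark_set].
#' @param path Destination file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @export
write_landmarks <- function(ls, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "csv"
  }
  ok <- tryCatch({
    if (format == "json") {
      # hand-rolled writer: %.17g guarantees a bit-exact double round trip,
      # which jsonlite's 15-digit default does not
      esc <- gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\",
                                       rownames(ls$points)))
      entries <- sprintf("\"%s\":[%.17g,%.17g]", esc,
                         ls$points[, 1], ls$points[, 2])
      writeLines(paste0("{", paste(entries, collapse = ","), "}"), path)
    } else {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("name,x,y", con)
      if (nrow(ls$points) > 0)
        writeLines(sprintf("%s,%.17g,%.17g", rownames(ls$points),
                           ls$points[, 1], ls$points[, 2]), con)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) fm_io_error(paste0("cannot write landmarks to ", path))
  invisible(path)
}

#' Read a cohort table
#'
#' A cohort table is a CSV with columns `subject_id,group,landmarks_path`
#' and optional `eye_left_path`, `eye_right_path`, `wtw_px_left`,
#' `wtw_px_right` (the latter two allow a manual white-to-white fallback
#' when no eye crops exist). Relative paths are resolved against the
#' table's own directory.
#'
#' @param path CSV file path.
#' @param check_files Verify that every referenced landmark file exists.
#' @return A data.frame with one row per subject.
#' @export
read_cohort_table <- function(path, check_files = TRUE) {
  if (!file.exists(path)) fm_io_error(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "landmarks_path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fm_schema_error(paste0("cohort table missing column(s): ",
                           paste(miss, collapse = ", ")))
  if (anyDuplicated(df$subject_id))
    fm_schema_error("duplicate subject_id in cohort table")
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p),
                                p, file.path(root, p))
  for (col in intersect(c("landmarks_path", "eye_left_path", "eye_right_path"),
                        names(df)))
    df[[col]] <- resolve(df[[col]])
  if (check_files) {
    bad <- df$landmarks_path[!file.exists(df$landmarks_path)]
    if (length(bad))
      fm_io_error(paste0("unresolvable landmark file(s): ",
                         paste(bad, collapse = ", ")))
  }
  df
}
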