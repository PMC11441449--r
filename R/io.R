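#' Construct a subject record
#'
#' Bundles all exams of one participant with group membership and, for
#' patients, the residual seeing-island area traced from fundus
#' autofluorescence (the structural disease-severity marker, in mm^2).
#'
#' @param subject_id Subject identifier.
#' @param group `"healthy"` or `"choroideremia"`.
#' @param island_area_mm2 Residual island area in mm^2, or `NA` (always
#'   permitted for healthy subjects). Must be positive when present.
#' @param exams Named list of [new_exam()] objects keyed
#'   `"<condition>.<color>.<session>"` (see [exam_key()]).
#' @return An object of class `sm_subject`.
#' @export
new_subject_record <- function(subject_id, group = c("healthy", "choroideremia"),
                               island_area_mm2 = NA_real_, exams = list()) {
  group <- match.arg(group)
  if (!is.na(island_area_mm2) && island_area_mm2 <= 0) {
    stop("island_area_mm2 must be positive when present", call. = FALSE)
  }
  stopifnot(all(vapply(exams, inherits, logical(1), "sm_exam")))
  structure(list(subject_id = subject_id, group = group,
                 island_area_mm2 = island_area_mm2, exams = exams),
            class = "sm_subject")
}

#' @rdname new_subject_record
#' @param condition,color,session Exam key components.
#' @export
exam_key <- function(condition, color, session) {
  paste(condition, color, session, sep = ".")
}

#' @export
print.sm_subject <- function(x, ...) {
  cat(sprintf("<sm_subject> %s (%s), %d exams%s\n", x$subject_id, x$group,
              length(x$exams),
              if (is.na(x$island_area_mm2)) "" else
                sprintf(", island %.2f mm^2", x$island_area_mm2)))
  invisible(x)
}

exam_csv_columns <- c("subject_id", "group", "eye", "condition", "color",
                      "session", "locus_id", "x_deg", "y_deg", "threshold_db")

#' Write and read exam tables
#'
#' A plain-text exchange format for microperimetry exams (device export
#' formats are proprietary): a directory holding `exams.csv` with one row per
#' tested locus (columns `subject_id, group, eye, condition, color, session,
#' locus_id, x_deg, y_deg, threshold_db`, non-seen loci as `-1.0`), one JSON
#' sidecar per exam under `sidecars/` carrying the fixation trace, catch
#' trials and metadata, and `grid.json` describing the grid geometry. The
#' round trip `read_exam_table(write_exam_table(x))` is lossless on all
#' fields including the non-seen sentinel.
#'
#' @param records List of [new_subject_record()] objects.
#' @param path Directory to write to / read from (created if needed).
#' @return `read_exam_table` returns a list of `sm_subject` records;
#'   `write_exam_table` returns `path` invisibly.
#' @export
write_exam_table <- function(records, path) {
  stopifnot(all(vapply(records, inherits, logical(1), "sm_subject")))
  dir.create(file.path(path, "sidecars"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  grids <- list()
  for (rec in records) {
    for (key in names(rec$exams)) {
      ex <- rec$exams[[key]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subject_id, group = rec$group, eye = ex$eye,
        condition = ex$condition, color = ex$color, session = ex$session,
        locus_id = ex$grid$loci$id, x_deg = ex$grid$loci$x,
        y_deg = ex$grid$loci$y, threshold_db = ex$thresholds)
      grids[[ex$grid$kind]] <- ex$grid
      sidecar <- list(
        fixation_trace = unname(apply(ex$fixation_trace, 1, c, simplify = FALSE)),
        catch_trials = lapply(ex$catch_trials, function(p) list(pressed = p)),
        fixation_target_intensity = ex$fixation_target_intensity,
        duration_s = ex$duration_s,
        eye_normalized = ex$eye_normalized,
        island_area_mm2 = rec$island_area_mm2)
      jsonlite::write_json(
        sidecar, file.path(path, "sidecars",
                           paste0(rec$subject_id, ".", key, ".json")),
        auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(path, "exams.csv"), row.names = FALSE)
  gdesc <- lapply(grids, function(g)
    list(kind = g$kind, ring_radii = g$ring_radii,
         points_per_ring = g$points_per_ring))
  jsonlite::write_json(gdesc, file.path(path, "grid.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_exam_table
#' @export
read_exam_table <- function(path) {
  csv <- file.path(path, "exams.csv")
  if (!file.exists(csv)) stop("no exams.csv under ", path, call. = FALSE)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  missing_cols <- setdiff(exam_csv_columns, names(tab))
  if (length(missing_cols)) {
    stop("exams.csv is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(tab$threshold_db == SENTINEL_NONSEEN |
                   (tab$threshold_db >= DB_RANGE[1] &
                      tab$threshold_db <= DB_RANGE[2])))
  if (length(bad)) {
    stop("threshold outside {-1} U [0,36] at exams.csv row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  key <- with(tab, paste(subject_id, condition, color, session, locus_id))
  if (anyDuplicated(key)) {
    stop("duplicate (subject, condition, color, session, locus) at exams.csv row(s) ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)
  }
  gdesc <- jsonlite::read_json(file.path(path, "grid.json"))
  grids <- lapply(gdesc, function(g)
    if (g$kind == "mesopic_10_2") build_grid("mesopic_10_2")
    else build_grid(g$kind, ring_radii = unlist(g$ring_radii),
                    points_per_ring = g$points_per_ring))
  records <- list()
  for (sid in unique(tab$subject_id)) {
    st <- tab[tab$subject_id == sid, , drop = FALSE]
    exams <- list()
    island <- NA_real_
    ekeys <- unique(st[, c("condition", "color", "session")])
    for (i in seq_len(nrow(ekeys))) {
      sel <- st$condition == ekeys$condition[i] & st$color == ekeys$color[i] &
        st$session == ekeys$session[i]
      rows <- st[sel, , drop = FALSE]
      rows <- rows[order(rows$locus_id), , drop = FALSE]
      grid <- grids[[which(vapply(grids, function(g)
        nrow(g$loci) == nrow(rows) &&
          isTRUE(all.equal(g$loci$x, rows$x_deg)) &&
          isTRUE(all.equal(g$loci$y, rows$y_deg)), logical(1)))[1]]]
      if (is.null(grid)) stop("no grid in grid.json matches exam loci for ",
                              sid, call. = FALSE)
      key <- exam_key(ekeys$condition[i], ekeys$color[i], ekeys$session[i])
      sc <- jsonlite::read_json(
        file.path(path, "sidecars", paste0(sid, ".", key, ".json")))
      trace <- do.call(rbind, lapply(sc$fixation_trace, unlist))
      ex <- new_exam(subject_id = sid, eye = rows$eye[1],
                     condition = ekeys$condition[i], color = ekeys$color[i],
                     grid = grid, thresholds = rows$threshold_db,
                     fixation_trace = trace,
                     catch_trials = vapply(sc$catch_trials,
                                           function(ct) isTRUE(ct$pressed),
                                           logical(1)),
                     fixation_target_intensity =
                       sc$fixation_target_intensity %||% NA_real_,
                     duration_s = sc$duration_s %||% NA_real_,
                     session = ekeys$session[i])
      ex$eye_normalized <- isTRUE(sc$eye_normalized)
      exams[[key]] <- ex
      if (!is.null(sc$island_area_mm2)) island <- sc$island_area_mm2
    }
    records[[sid]] <- new_subject_record(sid, st$group[1],
                                         island_area_mm2 = island,
                                         exams = exams)
  }
  unname(records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
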