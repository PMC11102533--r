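#' Read and write perimetry records as JSON
#'
#' Schema (version 1): an object
#' `{schema_version, eye, md, central: [{x, y, db} x4],
#'   pd: {pattern, cells: [{x, y, category}]}}`.
#'
#' @param record a [field_record()].
#' @param path file path.
#' @return `read_field_json()` returns a [field_record()];
#'   `write_field_json()` returns `path` invisibly.
#' @export
write_field_json <- function(record, path) {
  stopifnot(inherits(record, "field_record"))
  obj <- list(
    schema_version = 1L,
    eye = record$eye,
    md = record$md,
    central = record$central,
    pd = list(pattern = pd_pattern(record$pd),
              cells = dplyr::mutate(tibble::as_tibble(record$pd),
                                    category = as.character(.data$category)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_field_json
#' @export
read_field_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("eye", "md", "central", "pd")) {
    if (is.null(obj[[f]])) stop("field JSON is missing \"", f, "\"", call. = FALSE)
  }
  field_record(obj$eye, obj$md, obj$central,
               pd_matrix(obj$pd$pattern, cells = obj$pd$cells))
}

#' Read perimetry records from long-format CSV
#'
#' Columns: `field_id, eye, md, point_type, x_deg, y_deg, value`, with
#' `point_type` `"central"` (value = sensitivity in dB) or `"pd"`
#' (value = significance category). One `pattern` column (constant per
#' field) names the test pattern.
#'
#' @param path CSV file.
#' @return a tibble with one row per field: `field_id`, `eye`, `md` and a
#'   `field` list-column of [field_record()]s, ready for [grade_fields()].
#' @export
read_fields_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "eye", "md", "pattern", "point_type",
            "x_deg", "y_deg", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("fields CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(split(df, df$field_id), function(d) {
    central <- d[d$point_type == "central", ]
    pdc <- d[d$point_type == "pd", ]
    rec <- field_record(
      eye = central$eye[1], md = as.numeric(central$md[1]),
      central = tibble::tibble(x = central$x_deg, y = central$y_deg,
                               db = as.numeric(central$value)),
      pd = pd_matrix(d$pattern[1],
                     cells = tibble::tibble(x = pdc$x_deg, y = pdc$y_deg,
                                            category = pdc$value))
    )
    tibble::tibble(field_id = d$field_id[1], eye = rec$eye, md = rec$md,
                   field = list(rec))
  })
}

#' @rdname read_fields_csv
#' @param fields a tibble with a `field` list-column (and optional
#'   `field_id`).
#' @export
write_fields_csv <- function(fields, path) {
  rows <- purrr::map_dfr(seq_len(nrow(fields)), function(i) {
    rec <- fields$field[[i]]
    id <- if ("field_id" %in% names(fields)) fields$field_id[i]
          else sprintf("field%04d", i)
    dplyr::bind_rows(
      tibble::tibble(field_id = id, eye = rec$eye, md = rec$md,
                     pattern = pd_pattern(rec$pd), point_type = "central",
                     x_deg = rec$central$x, y_deg = rec$central$y,
                     value = as.character(rec$central$db)),
      tibble::tibble(field_id = id, eye = rec$eye, md = rec$md,
                     pattern = pd_pattern(rec$pd), point_type = "pd",
                     x_deg = rec$pd$x, y_deg = rec$pd$y,
                     value = as.character(rec$pd$category))
    )
  })
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a grading report as JSON
#'
#' `{grade_md, grade_central, grade_pd5, grade_pd1, overall,
#'   counts: {p5, p1, total}, thresholds_used}`; grade names serialise
#' lowercase.
#'
#' @param graded a `graded_field` from [grade_field()].
#' @param path file path.
#' @export
write_grading_json <- function(graded, path) {
  stopifnot(inherits(graded, "graded_field"))
  thr <- graded$thresholds
  obj <- list(
    grade_md = as.character(graded$grade_md),
    grade_central = as.character(graded$grade_central),
    grade_pd5 = as.character(graded$grade_pd5),
    grade_pd1 = as.character(graded$grade_pd1),
    overall = as.character(graded$overall),
    counts = graded$counts,
    thresholds_used = list(
      md_none_floor = thr$md_none_floor, md_mild_floor = thr$md_mild_floor,
      md_moderate_floor = thr$md_moderate_floor,
      central_low = thr$central_low, central_zero = thr$central_zero,
      pd5_mild_max = paste(thr$pd5_mild_max, collapse = "/"),
      pd5_moderate_max = paste(thr$pd5_moderate_max, collapse = "/"),
      pd1_mild_sup = paste(thr$pd1_mild_sup, collapse = "/"),
      pd1_moderate_sup = paste(thr$pd1_moderate_sup, collapse = "/")
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
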