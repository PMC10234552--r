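# Readers and writers for the pipeline's plain-text interchange formats:
# CSV tables with schema validation and GeoJSON LineString roads.

#' Table schemas used by the pipeline
#'
#' Named list of column-name -> type ("integer", "numeric", "character")
#' schemas for the CSV interchange tables: `blocks`, `monitors`,
#' `observations`, `grid_field`, `point_field`, `baseline`.
#'
#' @export
table_schemas <- list(
  blocks = c(block_id = "integer", x = "numeric", y = "numeric",
             county_id = "integer", tract_id = "integer",
             block_group_id = "integer", distance_to_road = "numeric",
             pop_total = "integer", pop_white = "integer",
             pop_black = "integer", pop_asian = "integer",
             pop_hispanic = "integer", pop_other = "integer",
             frac_25plus = "numeric"),
  monitors = c(site_id = "integer", x = "numeric", y = "numeric",
               pollutant = "character", schedule = "character"),
  observations = c(site_id = "integer", day = "integer", value = "numeric"),
  grid_field = c(cell = "integer", day = "integer", value = "numeric"),
  point_field = c(point_id = "integer", day = "integer", value = "numeric"),
  baseline = c(county_id = "integer", baseline_rate = "numeric")
)

check_schema <- function(df, schema, what = "table") {
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- character()
  for (col in names(schema)) {
    ok <- switch(schema[[col]],
                 integer = is.numeric(df[[col]]) &&
                   all(df[[col]] == round(df[[col]]), na.rm = TRUE),
                 numeric = is.numeric(df[[col]]),
                 character = is.character(df[[col]]) || is.factor(df[[col]]))
    if (!isTRUE(ok)) bad <- c(bad, col)
  }
  if (length(bad))
    stop(what, " column(s) with wrong type: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Read a CSV table and validate it against a schema
#'
#' @param path CSV file path.
#' @param schema A schema name from [table_schemas] or a named type vector.
#' @return The validated data.frame.
#' @export
read_table_checked <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1)
    schema <- table_schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, schema, what = basename(path))
  if (all(c("site_id", "day") %in% names(df)) &&
      anyDuplicated(df[c("site_id", "day")]))
    stop(basename(path), ": duplicated (site_id, day) records", call. = FALSE)
  df
}

#' Write a table as CSV
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write road segments as GeoJSON LineStrings
#'
#' @param roads Roads data.frame (`road_id`, `x0`, `y0`, `x1`, `y1`,
#'   `emission_rate`, `road_class`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_roads_geojson <- function(roads, path) {
  features <- lapply(seq_len(nrow(roads)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(c(roads$x0[i], roads$y0[i]),
                           c(roads$x1[i], roads$y1[i]))
      ),
      properties = list(id = roads$road_id[i],
                        emission_rate = roads$emission_rate[i],
                        road_class = roads$road_class[i])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read road segments from GeoJSON LineStrings
#'
#' @param path GeoJSON file with two-point LineString features carrying
#'   `id`, `emission_rate` and `road_class` properties.
#' @return Roads data.frame.
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    co <- f$geometry$coordinates
    data.frame(road_id = as.integer(f$properties$id),
               x0 = as.numeric(co[[1]][[1]]), y0 = as.numeric(co[[1]][[2]]),
               x1 = as.numeric(co[[2]][[1]]), y1 = as.numeric(co[[2]][[2]]),
               emission_rate = as.numeric(f$properties$emission_rate),
               road_class = as.character(f$properties$road_class))
  })
  out <- do.call(rbind, rows)
  if (any(out$emission_rate < 0))
    stop("negative emission_rate in ", basename(path), call. = FALSE)
  out
}
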