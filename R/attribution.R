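#' Per-unit break-down attribution map
#'
#' Runs a break-down attribution for every spatial unit and reshapes the
#' results into a units x features table of local contributions — the
#' input of contribution choropleths. The default is a single fixed
#' conditioning order shared by all units (ranked by global permutation
#' importance when a response column is available, otherwise the given
#' feature order), which keeps columns comparable across units. Greedy
#' mode reproduces per-unit break-down plots but orders features
#' per unit; its columns are flagged as non-comparable.
#'
#' @param model Fitted model or prediction function.
#' @param table A `county_table` with the model's feature columns.
#' @param features Features to attribute.
#' @param ordering `"fixed"` (default) or `"greedy"`.
#' @param order Explicit fixed order (overrides the importance ranking).
#' @param response Response column used to rank features for the default
#'   fixed order (ignored when `order` is given or absent from `table`).
#' @param n_reference Optional size of a seeded subsample of `table`
#'   used as the break-down reference data (speed knob; default: all
#'   units).
#' @param seed Seed for the reference subsample / importance ranking.
#' @return An `attribution_table` data frame: `unit_id`, `intercept`,
#'   one delta column per feature, `prediction`. Attribute `ordering`
#'   records the mode; in fixed mode attribute `order` records the
#'   shared conditioning order.
#' @export
attribution_map <- function(model, table, features,
                            ordering = c("fixed", "greedy"), order = NULL,
                            response = "response", n_reference = NULL,
                            seed = NULL) {
  ordering <- match.arg(ordering)
  stopifnot(all(features %in% names(table)))
  # the reference frame keeps every column so any model can predict on it;
  # only the attributed `features` are ever substituted
  reference <- as.data.frame(table)
  if (!is.null(n_reference) && n_reference < nrow(reference)) {
    idx <- if (is.null(seed)) sample.int(nrow(reference), n_reference)
           else withr::with_seed(seed, sample.int(nrow(reference), n_reference))
    reference <- reference[idx, , drop = FALSE]
  }
  if (ordering == "fixed" && is.null(order)) {
    if (response %in% names(table)) {
      imp <- permutation_importance(model, as.data.frame(table), response,
                                    features = features, n_repeats = 3,
                                    seed = seed)
      order <- imp$feature
    } else order <- features
  }

  rows <- lapply(seq_len(nrow(table)), function(i) {
    obs <- as.data.frame(table)[i, , drop = FALSE]
    bd <- tryCatch(
      break_down(model, reference, obs,
                 order = if (ordering == "fixed") order,
                 features = features),
      error = function(e) stop("break_down failed for unit ",
                               table$unit_id[i], ": ", conditionMessage(e)))
    d <- stats::setNames(bd$contributions$delta, bd$contributions$feature)
    c(intercept = bd$intercept, d[features], prediction = bd$prediction)
  })
  M <- do.call(rbind, rows)
  out <- data.frame(unit_id = table$unit_id, M, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("unit_id", "intercept", features, "prediction")
  attr(out, "ordering") <- ordering
  if (ordering == "fixed") attr(out, "order") <- order
  class(out) <- c("attribution_table", "data.frame")
  out
}

# Square polygon (closed ring) around a unit centroid.
unit_square <- function(x, y, half) {
  list(c(x - half, y - half), c(x + half, y - half),
       c(x + half, y + half), c(x - half, y + half),
       c(x - half, y - half))
}

#' Export a contribution choropleth as GeoJSON
#'
#' Writes one GeoJSON polygon feature per unit (unit squares built from
#' the lattice geometry) carrying `unit_id` and the chosen attribution
#' column as properties, in the unit order of `attr` (deterministic
#' property ordering).
#'
#' @param attr An `attribution_table` (or any data frame with `unit_id`
#'   and the requested column).
#' @param geometry A `county_table` providing `unit_id`, `x`, `y` and a
#'   `cell_size` attribute.
#' @param feature Name of the attribution column to export.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_choropleth <- function(attr, geometry, feature, path) {
  stopifnot(feature %in% names(attr))
  m <- match(attr$unit_id, geometry$unit_id)
  if (anyNA(m))
    stop("missing geometry for unit(s): ",
         paste(attr$unit_id[is.na(m)], collapse = ", "))
  half <- (attr(geometry, "cell_size") %||% 1) / 2
  feats <- lapply(seq_len(nrow(attr)), function(i) {
    g <- m[i]
    ring <- unit_square(geometry$x[g], geometry$y[g], half)
    list(type = "Feature",
         properties = list(unit_id = attr$unit_id[i],
                           feature = feature,
                           value = attr[[feature]][i]),
         geometry = list(type = "Polygon",
                         coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a contribution choropleth
#'
#' @param path GeoJSON file written by [export_choropleth()].
#' @return A data frame `unit_id`, `value` in file order.
#' @export
read_choropleth <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stop("not a FeatureCollection")
  data.frame(
    unit_id = vapply(fc$features, function(f) f$properties$unit_id, ""),
    value = vapply(fc$features, function(f) as.numeric(f$properties$value), 0),
    stringsAsFactors = FALSE)
}
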