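#' Spatial weights objects
#'
#' A `spatial_weights` object holds, for each unit, its neighbour list
#' and a parallel vector of nonnegative weights. Contiguity and distance
#' band constructors produce symmetric binary weights;
#' [row_standardize()] rescales each row to sum to one (the convention
#' required by local Moran statistics and the spatial regressions), while
#' Gi* conventionally uses binary weights with the unit itself included.
#'
#' @param ids Character vector of unit ids (defines the unit order).
#' @param neighbors List of integer vectors (indices into `ids`).
#' @param weights List of numeric vectors parallel to `neighbors`.
#' @param include_self Does each unit's list contain itself?
#' @param standardization `"binary"` or `"row"`.
#' @return A `spatial_weights` object.
#' @export
spatial_weights <- function(ids, neighbors, weights = NULL,
                            include_self = FALSE,
                            standardization = "binary") {
  n <- length(ids)
  stopifnot(length(neighbors) == n, !anyDuplicated(ids))
  if (is.null(weights))
    weights <- lapply(neighbors, function(nb) rep(1, length(nb)))
  stopifnot(length(weights) == n)
  for (i in seq_len(n)) {
    if (length(neighbors[[i]]) != length(weights[[i]]))
      stop("neighbors and weights differ in length for unit ", ids[i])
    if (any(weights[[i]] < 0)) stop("negative weight for unit ", ids[i])
    if (!include_self && i %in% neighbors[[i]])
      stop("unit ", ids[i], " neighbors itself but include_self is FALSE")
  }
  structure(list(ids = as.character(ids),
                 neighbors = lapply(neighbors, as.integer),
                 weights = lapply(weights, as.numeric),
                 include_self = include_self,
                 standardization = standardization),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  k <- lengths(x$neighbors)
  cat("Spatial weights: ", length(x$ids), " units, ",
      sprintf("%.2f", mean(k)), " mean neighbours, ",
      sum(k == 0), " isolate(s); include_self=", x$include_self,
      ", standardization=", x$standardization, "\n", sep = "")
  invisible(x)
}

#' Lattice contiguity weights
#'
#' Rook (edge-sharing) or queen (edge- or corner-sharing) neighbours on
#' the county lattice; binary symmetric weights. Units without
#' neighbours are retained with empty lists and reported via a warning.
#'
#' @param table A `county_table` with `row`/`col` indices.
#' @param rule `"queen"` or `"rook"`.
#' @param include_self Add each unit to its own list with weight 1
#'   (the Gi* "star" convention).
#' @return A `spatial_weights` object with binary weights.
#' @export
contiguity_weights <- function(table, rule = c("queen", "rook"),
                               include_self = FALSE) {
  rule <- match.arg(rule)
  if (!all(c("row", "col") %in% names(table)))
    stop("table must carry lattice indices (row, col)")
  off <- if (rule == "rook")
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, , drop = FALSE]
  key <- paste(table$row, table$col)
  lookup <- stats::setNames(seq_len(nrow(table)), key)
  nbs <- lapply(seq_len(nrow(table)), function(i) {
    cand <- paste(table$row[i] + off[, 1], table$col[i] + off[, 2])
    nb <- unname(lookup[cand])
    nb <- sort(nb[!is.na(nb)])
    if (include_self) sort(c(nb, i)) else nb
  })
  report_isolates(table$unit_id, nbs, include_self)
  spatial_weights(table$unit_id, nbs, include_self = include_self)
}

#' Distance band weights
#'
#' `w_ij = 1` iff the centroid distance between units i and j is at most
#' `band` (self excluded unless `include_self`). A band of 1.5 cell
#' sizes on a regular lattice reproduces queen contiguity.
#'
#' @param table A `county_table` with `x`/`y` centroids.
#' @param band Distance threshold (> 0), in coordinate units.
#' @inheritParams contiguity_weights
#' @return A `spatial_weights` object with binary weights.
#' @export
distance_band_weights <- function(table, band, include_self = FALSE) {
  if (band <= 0) stop("band must be > 0")
  xy <- cbind(table$x, table$y)
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  nn <- apply(d + diag(Inf, n), 1, min)
  if (band < min(nn))
    warning("band smaller than the minimum nearest-neighbour distance; ",
            "all units are isolates")
  nbs <- lapply(seq_len(n), function(i) {
    nb <- which(d[i, ] <= band)
    if (!include_self) nb <- setdiff(nb, i)
    sort(nb)
  })
  report_isolates(table$unit_id, nbs, include_self)
  spatial_weights(table$unit_id, nbs, include_self = include_self)
}

report_isolates <- function(ids, nbs, include_self) {
  iso <- lengths(nbs) == if (include_self) 1L else 0L
  if (include_self) iso <- iso & mapply(function(nb, i) identical(nb, i),
                                        nbs, seq_along(nbs))
  if (any(iso))
    warning(sum(iso), " unit(s) with no neighbours: ",
            paste(utils::head(ids[iso], 5), collapse = ", "),
            if (sum(iso) > 5) ", ..." else "")
  invisible(NULL)
}

#' Row-standardize spatial weights
#'
#' Rescales every unit's weights to sum to one; neighbour sets and
#' relative weights are preserved. Units with no neighbours keep empty
#' rows.
#'
#' @param W A `spatial_weights` object.
#' @return A `spatial_weights` object with `standardization = "row"`.
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  W$weights <- lapply(W$weights, function(w) if (length(w)) w / sum(w) else w)
  W$standardization <- "row"
  W
}

#' Dense weight matrix
#'
#' @param W A `spatial_weights` object.
#' @return An n x n numeric matrix (row/col order = `W$ids`).
#' @export
weights_matrix <- function(W) {
  n <- length(W$ids)
  M <- matrix(0, n, n, dimnames = list(W$ids, W$ids))
  for (i in seq_len(n)) M[i, W$neighbors[[i]]] <- W$weights[[i]]
  M
}

#' GAL interchange files
#'
#' Plain-text GAL dialect: first line is the number of units; then for
#' each unit a line `id k` followed by a line with its k neighbour ids
#' (an empty line when k = 0). Weights are binary; writing a
#' row-standardized object stores the neighbour structure only.
#'
#' @param W A `spatial_weights` object.
#' @param path File path.
#' @return `read_gal` returns a binary `spatial_weights`;
#'   `write_gal` returns `path` invisibly.
#' @export
write_gal <- function(W, path) {
  stopifnot(inherits(W, "spatial_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(W$ids)), con)
  for (i in seq_along(W$ids)) {
    nb <- W$neighbors[[i]]
    writeLines(paste(W$ids[i], length(nb)), con)
    writeLines(paste(W$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_gal
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("malformed GAL header: ", lines[1])
  if (length(lines) < 1 + 2 * n) stop("GAL file truncated: expected ", n, " units")
  heads <- lines[seq(2, by = 2, length.out = n)]
  bodies <- lines[seq(3, by = 2, length.out = n)]
  parts <- strsplit(trimws(heads), "\\s+")
  ids <- vapply(parts, `[`, "", 1)
  ks <- as.integer(vapply(parts, `[`, "", 2))
  if (anyNA(ks)) stop("malformed neighbour count in GAL file")
  nbs <- vector("list", n)
  include_self <- FALSE
  for (i in seq_len(n)) {
    nb_ids <- if (ks[i] == 0) character() else strsplit(trimws(bodies[i]), "\\s+")[[1]]
    if (length(nb_ids) != ks[i])
      stop("unit ", ids[i], " declares ", ks[i], " neighbours but lists ",
           length(nb_ids))
    idx <- match(nb_ids, ids)
    if (anyNA(idx))
      stop("GAL file references unknown id(s): ",
           paste(nb_ids[is.na(idx)], collapse = ", "))
    if (i %in% idx) include_self <- TRUE
    nbs[[i]] <- sort(idx)
  }
  spatial_weights(ids, nbs, include_self = include_self)
}
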