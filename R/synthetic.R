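#' Regular lattice of synthetic counties
#'
#' Builds the geometry skeleton of a synthetic study area: an
#' `nrows` x `ncols` grid of square units with centroids on a regular
#' grid. Covariates and the response are added later by
#' [simulate_risk_factors()] and [simulate_response()].
#'
#' @param nrows,ncols Lattice dimensions; both must be at least 3 so that
#'   every interior unit has a full contiguity neighbourhood.
#' @param cell_size Side length of a unit cell (abstract length units).
#' @return A `county_table` data frame with columns `unit_id`, `row`,
#'   `col`, `x`, `y`. Units are ordered row-major; `cell_size` is kept as
#'   an attribute for weight construction and polygon export.
#' @examples
#' head(make_lattice(4, 5))
#' @export
make_lattice <- function(nrows, ncols, cell_size = 1) {
  if (!is.numeric(nrows) || !is.numeric(ncols) || nrows < 3 || ncols < 3)
    stop("nrows and ncols must both be >= 3")
  if (cell_size <= 0) stop("cell_size must be positive")
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  grid <- expand.grid(col = seq_len(ncols), row = seq_len(nrows))
  tab <- data.frame(
    unit_id = sprintf("u%04d", seq_len(nrows * ncols)),
    row = grid$row,
    col = grid$col,
    x = (grid$col - 0.5) * cell_size,
    y = (grid$row - 0.5) * cell_size,
    stringsAsFactors = FALSE
  )
  attr(tab, "cell_size") <- cell_size
  attr(tab, "dims") <- c(nrows = nrows, ncols = ncols)
  class(tab) <- c("county_table", "data.frame")
  tab
}

#' Continuous and categorical feature specifications
#'
#' Helpers describing one simulated risk factor. Continuous features are
#' smoothed Gaussian fields affinely rescaled to `(min, max)`;
#' categorical features are obtained by slicing an auxiliary smoothed
#' field at quantile breaks so that every level occupies a spatially
#' coherent share of the map.
#'
#' @param name Column name in the county table.
#' @param min,max Range the rescaled field must span.
#' @param levels Character vector of category labels (in slicing order).
#' @param probs Optional level proportions (default: equal shares).
#' @return A list with class `feature_spec`.
#' @export
cont_feature <- function(name, min, max) {
  stopifnot(is.character(name), max > min)
  structure(list(type = "continuous", name = name, min = min, max = max),
            class = "feature_spec")
}

#' @rdname cont_feature
#' @export
cat_feature <- function(name, levels, probs = NULL) {
  stopifnot(is.character(name), length(levels) >= 2)
  if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
  if (length(probs) != length(levels) || any(probs <= 0))
    stop("probs must be positive and match levels")
  probs <- probs / sum(probs)
  structure(list(type = "categorical", name = name,
                 levels = as.character(levels), probs = probs),
            class = "feature_spec")
}

#' Default risk-factor panel
#'
#' A panel patterned on the covariates used in county-level lung-cancer
#' mortality modelling: behavioural (smoking prevalence), socio-economic
#' (poverty, uninsured), demographic composition, air pollutants, terrain
#' elevation, and three categorical zone factors (radon zone, urban-rural
#' class, coal-mining presence). Ranges are plausible US county values.
#'
#' @return A list of `feature_spec` objects.
#' @export
default_feature_specs <- function() {
  list(
    cont_feature("smoking",      5,   45),    # % adult smoking prevalence
    cont_feature("poverty",      5,   50),    # % below poverty line
    cont_feature("uninsured",    5,   30),    # % without health insurance
    cont_feature("pct_white",   20,   95),    # % white population
    cont_feature("pct_hispanic", 0,   60),    # % Hispanic population
    cont_feature("pct_over65",   8,   25),    # % population over 65
    cont_feature("pm25",         4,   15),    # ug/m3 fine particulates
    cont_feature("no2",          1,   20),    # ppb
    cont_feature("so2",        0.5,    5),    # ppb
    cont_feature("ozone",       30,   60),    # ppb
    cont_feature("elevation",    0, 2500),    # metres above sea level
    cat_feature("radon_zone", c("1", "2", "3")),
    cat_feature("urban_rural", c("metro", "suburban", "town", "rural")),
    cat_feature("coal", c("no", "yes"), probs = c(0.8, 0.2))
  )
}

# Separable Gaussian smoothing of a lattice field. `s` is the kernel scale
# in cell units; rows of the 1-d kernel matrices are normalized so the
# smoother preserves the mean level of the field.
smooth_field <- function(z, s) {
  kern <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * s^2))
    k / rowSums(k)
  }
  kern(nrow(z)) %*% z %*% t(kern(ncol(z)))
}

rescale_range <- function(z, lo, hi) {
  r <- range(z)
  if (diff(r) == 0) return(rep((lo + hi) / 2, length(z)))
  (z - r[1]) / diff(r) * (hi - lo) + lo
}

#' Simulate spatially autocorrelated risk factors
#'
#' Each continuous factor is an independent white-noise field smoothed by
#' a Gaussian kernel of scale `spatial_range` (in cell units) and then
#' affinely rescaled to its declared range; categorical factors slice an
#' auxiliary smoothed field at quantile breaks. Larger `spatial_range`
#' yields stronger positive spatial autocorrelation (global Moran's I
#' close to 1 for ranges of several cells); as the range shrinks towards
#' zero the fields approach independent noise.
#'
#' @param table A `county_table` from [make_lattice()].
#' @param spatial_range Gaussian kernel scale, in cells; must be > 0.
#' @param feature_specs List of [cont_feature()]/[cat_feature()] specs.
#' @param seed Optional integer; the generator is a pure function of
#'   `(table, spatial_range, feature_specs, seed)`.
#' @return The table with one column per feature appended.
#' @export
simulate_risk_factors <- function(table, spatial_range = 4,
                                  feature_specs = default_feature_specs(),
                                  seed = NULL) {
  stopifnot(inherits(table, "county_table"))
  if (spatial_range <= 0) stop("spatial_range must be > 0")
  bad <- vapply(feature_specs, function(f) !inherits(f, "feature_spec"), TRUE)
  if (any(bad)) stop("feature_specs must be built with cont_feature()/cat_feature()")
  dims <- attr(table, "dims")
  nr <- dims[["nrows"]]; nc <- dims[["ncols"]]
  idx <- cbind(table$row, table$col)

  gen <- function() {
    for (f in feature_specs) {
      z <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), spatial_range)
      v <- z[idx]
      if (f$type == "continuous") {
        table[[f$name]] <- rescale_range(v, f$min, f$max)
      } else {
        br <- stats::quantile(v, probs = cumsum(f$probs)[-length(f$probs)])
        lab <- f$levels[findInterval(v, br, left.open = TRUE) + 1L]
        table[[f$name]] <- factor(lab, levels = f$levels)
      }
    }
    table
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(out, "feature_specs") <- feature_specs
  out
}

#' Effect specification for the synthetic response surface
#'
#' Describes how the simulated mortality rate is assembled: an intercept,
#' additive per-feature effects (`linear` or `threshold_linear`, the
#' latter being `coef * max(x - threshold, 0)`), threshold interactions
#' of the form `coef * x_b * 1(x_a > threshold)`, categorical level
#' offsets, and Gaussian noise.
#'
#' @param intercept Baseline rate (per 100,000).
#' @param additive Named list; each element `list(shape=, coef=, threshold=)`.
#' @param interactions List of `list(a=, b=, threshold_a=, coef=)`.
#' @param categorical Named list of named offset vectors (per level).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param clip_zero Truncate negative responses at 0 (off by default so
#'   additivity diagnostics stay exact).
#' @return A list with class `effect_spec`.
#' @export
effect_spec <- function(intercept = 0, additive = list(),
                        interactions = list(), categorical = list(),
                        noise_sd = 0, clip_zero = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(intercept = intercept, additive = additive,
                 interactions = interactions, categorical = categorical,
                 noise_sd = noise_sd, clip_zero = clip_zero),
            class = "effect_spec")
}

#' Default response surface
#'
#' Calibrated qualitatively to county-level lung-cancer mortality
#' findings: positive effects of smoking (dominant), poverty, PM2.5 and
#' percent white population; negative effects of elevation and percent
#' Hispanic population; poverty additionally matters only where smoking
#' prevalence exceeds 30 percent (a threshold interaction); small radon /
#' urban-rural / coal offsets; additive noise of 6 rate units.
#'
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function() {
  effect_spec(
    intercept = 50,
    additive = list(
      smoking      = list(shape = "linear", coef =  1.0),
      poverty      = list(shape = "linear", coef =  0.15),
      pm25         = list(shape = "linear", coef =  0.8),
      pct_white    = list(shape = "linear", coef =  0.08),
      elevation    = list(shape = "linear", coef = -0.01),
      pct_hispanic = list(shape = "linear", coef = -0.15)
    ),
    interactions = list(
      list(a = "smoking", b = "poverty", threshold_a = 30, coef = 0.35)
    ),
    categorical = list(
      radon_zone  = c("1" = 0, "2" = 1.5, "3" = 3),
      urban_rural = c(metro = 0, suburban = 1, town = 2, rural = 3),
      coal        = c(no = 0, yes = 3)
    ),
    noise_sd = 6
  )
}

additive_term <- function(x, eff) {
  switch(eff$shape,
    linear = eff$coef * x,
    threshold_linear = eff$coef * pmax(x - eff$threshold, 0),
    stop("unknown effect shape: ", eff$shape)
  )
}

#' Simulate the response from a known effect surface
#'
#' Adds a `response` column (rate per 100,000):
#' `intercept + sum(additive) + sum(interactions) + categorical offsets +
#' N(0, noise_sd)`. The noiseless surface and the per-feature effect
#' functions are stored as attributes (`noiseless`, `effect_fns`) so
#' explainer output can be checked against ground truth; setting
#' `noise_sd = 0` in `effects` reproduces the noiseless surface exactly.
#'
#' @param table County table carrying every feature named in `effects`.
#' @param effects An [effect_spec()].
#' @param seed Optional integer seed for the noise draw.
#' @return The table with `response` appended and truth attributes set.
#' @export
simulate_response <- function(table, effects = default_effect_spec(),
                              seed = NULL) {
  stopifnot(inherits(effects, "effect_spec"))
  need <- c(names(effects$additive), names(effects$categorical),
            unlist(lapply(effects$interactions, function(it) c(it$a, it$b))))
  miss <- setdiff(unique(need), names(table))
  if (length(miss))
    stop("features not present in table: ", paste(miss, collapse = ", "))

  mu <- rep(effects$intercept, nrow(table))
  effect_fns <- list()
  for (nm in names(effects$additive)) {
    eff <- effects$additive[[nm]]
    if (identical(eff$shape, "threshold_linear")) {
      rng <- range(table[[nm]])
      if (eff$threshold < rng[1] || eff$threshold > rng[2])
        stop("threshold for ", nm, " outside the feature range")
    }
    mu <- mu + additive_term(table[[nm]], eff)
    effect_fns[[nm]] <- local({
      e <- eff
      function(x) additive_term(x, e)
    })
  }
  for (it in effects$interactions) {
    rng <- range(table[[it$a]])
    if (it$threshold_a < rng[1] || it$threshold_a > rng[2])
      stop("interaction threshold on ", it$a, " outside the feature range")
    mu <- mu + it$coef * table[[it$b]] * (table[[it$a]] > it$threshold_a)
  }
  for (nm in names(effects$categorical)) {
    off <- effects$categorical[[nm]]
    lev <- as.character(table[[nm]])
    unknown <- setdiff(unique(lev), names(off))
    if (length(unknown))
      stop("no categorical offset for level(s) ", paste(unknown, collapse = ", "),
           " of ", nm)
    mu <- mu + unname(off[lev])
  }

  draw <- function() stats::rnorm(nrow(table), 0, effects$noise_sd)
  eps <- if (effects$noise_sd == 0) rep(0, nrow(table))
         else if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  y <- mu + eps
  if (effects$clip_zero) y <- pmax(y, 0)
  table$response <- y
  attr(table, "noiseless") <- mu
  attr(table, "effect_fns") <- effect_fns
  attr(table, "effects") <- effects
  table
}

#' One-call synthetic study area
#'
#' Convenience wrapper: [make_lattice()] + [simulate_risk_factors()] +
#' [simulate_response()], with per-stage seeds derived from `seed`.
#'
#' @inheritParams make_lattice
#' @inheritParams simulate_risk_factors
#' @inheritParams simulate_response
#' @param seed Root seed for covariates and noise.
#' @return A complete `county_table`.
#' @export
simulate_counties <- function(nrows = 40, ncols = 40, cell_size = 1,
                              spatial_range = 4,
                              feature_specs = default_feature_specs(),
                              effects = default_effect_spec(), seed = 1) {
  tab <- make_lattice(nrows, ncols, cell_size)
  tab <- simulate_risk_factors(tab, spatial_range, feature_specs,
                               seed = derive_seed(seed, 1))
  simulate_response(tab, effects, seed = derive_seed(seed, 2))
}

# Per-stage seed derivation: deterministic, keeps values inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% .Machine$integer.max)
}

#' Read/write a county table as CSV
#'
#' Plain CSV, one row per unit; a `#types:` comment line records which
#' columns are categorical so factors survive the round trip.
#'
#' @param table A `county_table`.
#' @param path File path.
#' @return `read_county_csv` returns a `county_table`;
#'   `write_county_csv` returns `path` invisibly.
#' @export
write_county_csv <- function(table, path) {
  fac <- names(table)[vapply(table, is.factor, TRUE)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#types: factor=", paste(fac, collapse = ";")), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_county_csv
#' @export
read_county_csv <- function(path) {
  first <- readLines(path, n = 1)
  fac <- character()
  if (startsWith(first, "#types:")) {
    spec <- sub("^#types: factor=", "", first)
    if (nzchar(spec)) fac <- strsplit(spec, ";")[[1]]
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (nm in intersect(fac, names(tab))) tab[[nm]] <- factor(tab[[nm]])
  if (all(c("row", "col") %in% names(tab))) {
    attr(tab, "dims") <- c(nrows = max(tab$row), ncols = max(tab$col))
    if (all(c("x", "y") %in% names(tab)) && nrow(tab) > 1) {
      attr(tab, "cell_size") <- min(diff(sort(unique(tab$x))), diff(sort(unique(tab$y))))
    }
  }
  class(tab) <- c("county_table", "data.frame")
  tab
}
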