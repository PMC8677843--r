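#' Default pipeline configuration
#'
#' The full run configuration with documented defaults: a 20x20 lattice
#' with the default risk-factor panel and response surface, queen
#' contiguity weights, Gi-bin stratified 70/15/15 split, a reduced
#' three-family learner panel (sized for interactive runs; enlarge
#' `train$families`/`train$budget` for full studies), and fixed-order
#' attribution maps.
#'
#' @param seed Root seed; every stage derives its own seed from it.
#' @return A nested list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(
      lattice = list(nrows = 20, ncols = 20, cell_size = 1),
      spatial_range = 4
    ),
    weights = list(rule = "queen"),
    eda = list(n_perm = 199, lmi_factor = "smoking", k_strata = 5),
    split = list(fractions = c(train = 0.70, valid = 0.15, test = 0.15)),
    train = list(families = c("glm", "rf", "xgboost"), budget = 2,
                 folds = 5, mode = "all_models"),
    explain = list(n_repeats = 5, grid_size = 31,
                   profile_features = c("smoking", "poverty", "elevation")),
    map = list(features = c("smoking", "poverty", "elevation", "pm25"),
               n_reference = 200)
  )
}

#' Read and validate a YAML run configuration
#'
#' Reads the YAML file, overlays it on [default_run_config()] and
#' validates the schema; violations are reported with their field path
#' (e.g. `split.fractions`).
#'
#' @param path YAML file with a subset of the configuration fields.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_list(default_run_config(), user)
  if (!is.null(user$split$fractions))
    cfg$split$fractions <- unlist(user$split$fractions)
  validate_config(cfg)
  cfg
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
      modify_list(base[[nm]], new[[nm]]) else new[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  fail <- function(path, msg) stop("config error at ", path, ": ", msg,
                                   call. = FALSE)
  lat <- cfg$simulate$lattice
  if (is.null(lat$nrows) || is.null(lat$ncols) ||
      lat$nrows < 3 || lat$ncols < 3)
    fail("simulate.lattice", "nrows and ncols must be >= 3")
  if (cfg$simulate$spatial_range <= 0)
    fail("simulate.spatial_range", "must be > 0")
  if (is.null(cfg$weights$rule) && is.null(cfg$weights$band))
    fail("weights", "either rule (queen/rook) or band must be given")
  if (!is.null(cfg$weights$rule) &&
      !cfg$weights$rule %in% c("queen", "rook"))
    fail("weights.rule", "must be queen or rook")
  fr <- cfg$split$fractions
  if (is.null(names(fr)) || any(fr <= 0) || abs(sum(fr) - 1) > 1e-9)
    fail("split.fractions", "must be named, positive and sum to 1")
  ok <- tryCatch({ canonical_family(cfg$train$families); TRUE },
                 error = function(e) FALSE)
  if (!ok) fail("train.families", "unknown learner family")
  if (!cfg$train$mode %in% c("all_models", "best_of_family"))
    fail("train.mode", "must be all_models or best_of_family")
  if (cfg$train$folds < 2) fail("train.folds", "must be >= 2")
  invisible(cfg)
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full pipeline
#'
#' Executes the end-to-end flow — simulate, weights, exploratory spatial
#' statistics, Gi-bin stratified split, stacked-ensemble training,
#' evaluation, global explainers, attribution map — writing every
#' intermediate artifact (CSV/GAL/JSON/GeoJSON) into `out_dir` together
#' with a manifest (configuration, per-stage seeds, artifact checksums).
#' Rerunning the same configuration reproduces identical checksums.
#'
#' @param config A configuration list ([default_run_config()] /
#'   [read_run_config()]) or the path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  art <- character(0)
  put <- function(name) { art[[name]] <<- file.path(out_dir, name); art[[name]] }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------------
  stage_log("simulate", "lattice ", config$simulate$lattice$nrows, "x",
            config$simulate$lattice$ncols)
  tab <- run_stage("simulate", simulate_counties(
    nrows = config$simulate$lattice$nrows,
    ncols = config$simulate$lattice$ncols,
    cell_size = config$simulate$lattice$cell_size %||% 1,
    spatial_range = config$simulate$spatial_range,
    seed = derive_seed(seed, 10)))

  # -- weights ----------------------------------------------------------------
  stage_log("weights", config$weights$rule %||%
              paste("distance band", config$weights$band))
  W <- run_stage("weights", {
    if (!is.null(config$weights$band))
      distance_band_weights(tab, config$weights$band)
    else contiguity_weights(tab, config$weights$rule)
  })
  write_gal(W, put("w.gal"))
  Wstar <- if (!is.null(config$weights$band))
    distance_band_weights(tab, config$weights$band, include_self = TRUE)
  else contiguity_weights(tab, config$weights$rule, include_self = TRUE)

  # -- eda --------------------------------------------------------------------
  stage_log("eda", "Gi*, bivariate local Moran, q-statistics")
  features <- setdiff(names(tab),
                      c("unit_id", "row", "col", "x", "y", "response"))
  eda <- run_stage("eda", {
    hs <- gi_star(tab$response, Wstar)
    lmi <- bivariate_local_moran(tab$response, tab[[config$eda$lmi_factor]],
                                 row_standardize(W),
                                 n_perm = config$eda$n_perm,
                                 seed = derive_seed(seed, 20))
    qt <- q_table(tab, "response", features,
                  k_strata = config$eda$k_strata)
    list(hs = hs, lmi = lmi, qt = qt)
  })
  utils::write.csv(data.frame(eda$hs, lmi_cluster = eda$lmi$cluster,
                              lmi_I = eda$lmi$I_i),
                   put("eda.csv"), row.names = FALSE)
  utils::write.csv(eda$qt, put("qtable.csv"), row.names = FALSE)

  # -- split ------------------------------------------------------------------
  stage_log("split", paste(names(config$split$fractions), collapse = "/"))
  part <- run_stage("split", stratified_split(
    eda$hs$gi_bin, config$split$fractions, seed = derive_seed(seed, 30)))
  tab$gi_bin <- eda$hs$gi_bin
  tab$partition <- as.character(part)
  write_county_csv(tab, put("counties.csv"))

  # -- train ------------------------------------------------------------------
  stage_log("train", paste(config$train$families, collapse = ", "),
            " (mode ", config$train$mode, ")")
  fml <- stats::reformulate(features, response = "response")
  train_tab <- tab[tab$partition == "train", , drop = FALSE]
  fit <- run_stage("train", stack_ensemble(
    fml, train_tab, families = config$train$families,
    folds = config$train$folds, budget = config$train$budget,
    mode = config$train$mode, seed = derive_seed(seed, 40)))
  cards <- lapply(fit$candidates, `[[`, "card")
  jsonlite::write_json(cards, put("model_cards.json"), auto_unbox = TRUE,
                       digits = NA)

  # -- evaluate ---------------------------------------------------------------
  stage_log("evaluate", "per-partition metrics")
  evals <- run_stage("evaluate", {
    rows <- list()
    for (p in levels(part)) {
      sub <- tab[tab$partition == p, , drop = FALSE]
      pred <- predict(fit, sub)
      r <- eval_report(sub$response, pred)
      rows[[length(rows) + 1]] <- data.frame(
        model = "stack_ensemble", type = "stack-ensemble", partition = p,
        mae = r$mae, rmse = r$rmse, r2 = r$r2, n = r$n)
      fams <- unique(fit$cv$family)
      for (f in fams) {
        idx <- which(fit$cv$family == f)
        best <- idx[which.min(fit$cv$cv_rmse[idx])]
        bl <- fit$candidates[[best]]
        x <- build_design(stats::delete.response(fit$terms), sub,
                          fit$xlevels)$x
        pb <- predict(bl$fit, x)
        rb <- eval_report(sub$response, pb)
        rows[[length(rows) + 1]] <- data.frame(
          model = f, type = "base-learner", partition = p,
          mae = rb$mae, rmse = rb$rmse, r2 = rb$r2, n = rb$n)
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(evals, put("evaluation.csv"), row.names = FALSE)

  # -- explain ----------------------------------------------------------------
  stage_log("explain", "permutation importance and profiles")
  test_tab <- tab[tab$partition == "test", , drop = FALSE]
  expl <- run_stage("explain", {
    imp <- permutation_importance(fit, test_tab, "response",
                                  features = features,
                                  n_repeats = config$explain$n_repeats,
                                  seed = derive_seed(seed, 50))
    profs <- list()
    for (f in config$explain$profile_features) {
      gs <- config$explain$grid_size
      profs[[length(profs) + 1]] <- pd_profile(fit, train_tab, f, gs)
      profs[[length(profs) + 1]] <- ld_profile(fit, train_tab, f, gs)
      profs[[length(profs) + 1]] <- al_profile(fit, train_tab, f,
                                               n_intervals = max(2, gs %/% 2))
    }
    list(imp = imp, profiles = do.call(rbind, profs))
  })
  utils::write.csv(expl$imp, put("importance.csv"), row.names = FALSE)
  utils::write.csv(expl$profiles, put("profiles.csv"), row.names = FALSE)

  # -- map --------------------------------------------------------------------
  stage_log("map", "break-down attribution surfaces")
  amap <- run_stage("map", attribution_map(
    fit, tab, config$map$features, ordering = "fixed",
    n_reference = config$map$n_reference,
    seed = derive_seed(seed, 60)))
  utils::write.csv(as.data.frame(amap), put("attributions.csv"),
                   row.names = FALSE)
  export_choropleth(amap, tab, config$map$features[1], put("map.geojson"))

  # -- manifest ---------------------------------------------------------------
  checks <- vapply(art, function(p) unname(tools::md5sum(p)), "")
  manifest <- list(
    config = config,
    stage_seeds = list(simulate = derive_seed(seed, 10),
                       eda = derive_seed(seed, 20),
                       split = derive_seed(seed, 30),
                       train = derive_seed(seed, 40),
                       explain = derive_seed(seed, 50),
                       map = derive_seed(seed, 60)),
    versions = list(r = as.character(getRversion()),
                    geostackx = as.character(
                      utils::packageVersion("geostackx"))),
    artifacts = as.list(checks))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("done", length(art), " artifacts in ", out_dir)
  invisible(manifest)
}
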