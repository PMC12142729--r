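# Configuration-driven driver: validates a YAML run configuration, executes
# the requested stages in dependency order with per-stage seed substreams,
# and writes a machine-readable JSON run report with checksums so identical
# configurations reproduce identical artifacts.

stage_order <- c("prep", "structure", "diversity", "ibdibe", "gea")
stage_deps <- list(prep = character(0), structure = "prep",
                   diversity = "prep", ibdibe = "prep", gea = "prep")

stage_seed <- function(global_seed, stage) {
  # named substream: independent of stage execution order
  (global_seed * 10 + match(stage, stage_order)) %% .Machine$integer.max
}

#' Load and validate a pipeline run configuration
#'
#' The configuration is a YAML file with input paths (`vcf`, `coords`,
#' optional `layers`), an `output_dir`, a global `seed`, and optional
#' per-stage parameter blocks (`prep`, `structure`, `diversity`, `ibdibe`,
#' `gea`). Validation is side-effect-free and reports every fault at once.
#'
#' @param path YAML configuration file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, dir = dirname(path))
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from YAML).
#' @param dir directory against which relative paths are resolved.
#' @export
validate_run_config <- function(cfg, dir = ".") {
  faults <- character(0)
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
                         else file.path(dir, p)
  for (key in c("vcf", "coords")) {
    if (is.null(cfg[[key]])) {
      faults <- c(faults, paste0("missing required input: ", key))
    } else {
      cfg[[key]] <- resolve(cfg[[key]])
      if (!file.exists(cfg[[key]]))
        faults <- c(faults, paste0(key, " path does not exist: ", cfg[[key]]))
    }
  }
  if (!is.null(cfg$layers)) {
    cfg$layers <- vapply(cfg$layers, resolve, character(1))
    for (l in cfg$layers)
      if (!file.exists(l))
        faults <- c(faults, paste0("layer path does not exist: ", l))
  }
  if (is.null(cfg$output_dir))
    faults <- c(faults, "missing output_dir")
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (!is.numeric(cfg$seed))
    faults <- c(faults, "seed must be an integer")
  if (length(faults))
    stop("invalid configuration:\n  - ", paste(faults, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

artifact <- function(path, stage, params) {
  list(path = path, stage = stage,
       checksum = unname(tools::md5sum(path)), params = params)
}

#' Run the landscape-genomics pipeline
#'
#' Executes the requested stages in dependency order. `prep` reads the VCF
#' and coordinates, LD-prunes and imputes; `structure` fits clusters (fixed
#' K or cross-validated) and writes the Q matrix and, when layers are
#' present or a grid resolution is set, kriged ancestry maps; `diversity`
#' writes moving-window diversity rasters; `ibdibe` runs MMRR and GDM on
#' genetic vs geographic/environmental distances; `gea` runs RDA and LFMM
#' outlier scans. Every artifact is recorded in a JSON report with
#' parameters, seeds and checksums. A failed stage is marked in the report
#' and its dependants are skipped.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param stages subset of c("prep","structure","diversity","ibdibe","gea").
#' @return The run report (also written to `report.json` in `output_dir`).
#' @export
run_pipeline <- function(config, stages = stage_order) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, stage_order, several.ok = TRUE)
  needed <- unique(c(stages, unlist(stage_deps[stages])))
  stages <- stage_order[stage_order %in% needed]
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("landgen")),
                 r_version = as.character(getRversion()),
                 seed = config$seed, stages = list(), artifacts = list())
  state <- new.env()
  failed <- character(0)
  for (s in stages) {
    if (any(stage_deps[[s]] %in% failed)) {
      report$stages[[s]] <- list(status = "skipped",
                                 reason = "dependency failed")
      next
    }
    seed_s <- stage_seed(config$seed, s)
    res <- tryCatch({
      arts <- switch(s,
        prep = run_stage_prep(config, state, out, seed_s),
        structure = run_stage_structure(config, state, out, seed_s),
        diversity = run_stage_diversity(config, state, out, seed_s),
        ibdibe = run_stage_ibdibe(config, state, out, seed_s),
        gea = run_stage_gea(config, state, out, seed_s))
      report$artifacts <- c(report$artifacts, arts)
      list(status = "ok", seed = seed_s, n_artifacts = length(arts))
    }, error = function(e) {
      failed <<- c(failed, s)
      list(status = "failed", seed = seed_s, error = conditionMessage(e))
    })
    report$stages[[s]] <- res
  }
  report_path <- file.path(out, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}

run_stage_prep <- function(config, state, out, seed) {
  p <- config$prep
  g <- read_vcf(config$vcf)
  coords <- read_coords(config$coords)
  if (!identical(g$sample_ids, coords$id))
    stop("VCF sample order does not match the coordinates table")
  g <- ld_prune(g,
                window_size = p$ld_window %||% 50,
                window_step = p$ld_step %||% 5,
                r2_threshold = p$r2 %||% 0.2)
  if (anyNA(g$values)) {
    g <- if ((p$impute %||% "median") == "structure")
      impute_structure(g, k = p$k %||% 2, seed = seed)
    else impute_median(g)
  }
  state$genotypes <- g
  state$coords <- coords
  if (!is.null(config$layers)) {
    state$layers <- lapply(config$layers, read_gridsurface)
    state$env <- extract_env(state$layers, coords)
  }
  f <- file.path(out, "dosage.csv")
  write_dosage_csv(g, f)
  list(artifact(f, "prep", p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage_structure <- function(config, state, out, seed) {
  p <- config$structure
  g <- state$genotypes; coords <- state$coords
  k <- p$k
  arts <- list()
  if (is.null(k)) {
    sk <- select_k(g, coords, k_range = p$k_range %||% 1:4,
                   mode = if (isTRUE(p$auto_k)) "auto" else "manual",
                   seed = seed)
    f <- file.path(out, "k_selection.csv")
    utils::write.csv(sk$table, f, row.names = FALSE)
    arts <- c(arts, list(artifact(f, "structure", p)))
    k <- if (isTRUE(p$auto_k)) sk$chosen_k else stop(
      "structure stage needs k (or auto_k: true) in the configuration")
  }
  model <- fit_clusters(g, coords, k = k, lambda = p$lambda %||% 1.0,
                        seed = seed)
  state$ancestry <- model
  fq <- file.path(out, "qmatrix.csv")
  write_qmatrix_csv(model, fq)
  arts <- c(arts, list(artifact(fq, "structure", p)))
  grid <- if (!is.null(state$layers)) state$layers[[1]]
          else make_grid(coords, resolution = p$grid_res %||% 0.1)
  if (nrow(coords) >= 5) {
    maps <- krige_ancestry(model, coords, grid)
    for (i in seq_along(maps$ancestry)) {
      f <- file.path(out, sprintf("ancestry_k%d.asc", i))
      write_gridsurface(maps$ancestry[[i]], f)
      arts <- c(arts, list(artifact(f, "structure", p)))
    }
    f <- file.path(out, "dominant_cluster.asc")
    write_gridsurface(maps$dominant, f)
    arts <- c(arts, list(artifact(f, "structure", p)))
  }
  arts
}

run_stage_diversity <- function(config, state, out, seed) {
  p <- config$diversity
  g <- state$genotypes; coords <- state$coords
  grid <- if (!is.null(state$layers)) state$layers[[1]]
          else make_grid(coords, resolution = p$grid_res %||% 0.1)
  cfg <- diversity_config(statistic = p$stat %||% "het",
                          wdim = p$wdim %||% 3,
                          min_n = p$min_n %||% 2,
                          rarefy = isTRUE(p$rarefy),
                          g = p$g %||% (2 * (p$min_n %||% 2)))
  wd <- window_diversity(g, coords, grid, cfg)
  surf <- wd$surface
  if (isTRUE(p$interpolate))
    surf <- interpolate_surface(surf, method = p$method %||% "krige",
                                mask_to = p$mask %||% "extent",
                                coords = coords)
  f1 <- file.path(out, paste0("diversity_", cfg$statistic, ".asc"))
  f2 <- file.path(out, "diversity_counts.asc")
  write_gridsurface(surf, f1)
  write_gridsurface(wd$counts, f2)
  list(artifact(f1, "diversity", p), artifact(f2, "diversity", p))
}

run_stage_ibdibe <- function(config, state, out, seed) {
  p <- config$ibdibe
  g <- state$genotypes; coords <- state$coords
  gen <- genetic_distance(g, metric = p$gen_metric %||% "euclidean")
  geo <- geo_distance(coords, "linear")
  xs <- list(geographic = geo)
  if (!is.null(state$env)) {
    ed <- env_distance(state$env)
    xs <- c(xs, ed$per_variable)
  }
  fit <- mmrr(gen, xs, n_perm = p$n_perm %||% 999, seed = seed)
  f <- file.path(out, "mmrr.json")
  jsonlite::write_json(list(beta = as.list(fit$beta),
                            beta_p = as.list(fit$beta_p),
                            r_squared = fit$r_squared,
                            f_statistic = fit$f_statistic, f_p = fit$f_p),
                       f, auto_unbox = TRUE, digits = NA)
  arts <- list(artifact(f, "ibdibe", p))
  gdm <- gdm_fit(rescale_dist(gen), env = state$env, coords = coords,
                 use_geo = TRUE, seed = seed)
  fg <- file.path(out, "gdm.json")
  jsonlite::write_json(list(intercept = gdm$intercept,
                            coefficients = gdm$coefficients,
                            deviance_explained = gdm$deviance_explained,
                            importance = as.list(gdm$importance)),
                       fg, auto_unbox = TRUE, digits = NA)
  c(arts, list(artifact(fg, "ibdibe", p)))
}

run_stage_gea <- function(config, state, out, seed) {
  p <- config$gea
  g <- state$genotypes; coords <- state$coords
  if (is.null(state$env))
    stop("gea stage requires environmental layers in the configuration")
  arts <- list()
  model <- rda_fit(g, state$env)
  res <- rda_outliers_p(model, n_axes = min(p$axes %||% 2,
                                            length(model$eigenvalues)),
                        fdr = p$fdr %||% 0.05)
  f <- file.path(out, "rda_outliers.tsv")
  write_gea_tsv(res, f)
  arts <- c(arts, list(artifact(f, "gea", p)))
  k <- p$k %||% select_latent_k(g, method = p$k_method %||% "tracy_widom",
                                seed = seed, coords = coords)$k
  lf <- lfmm_ridge(g, state$env, k = k)
  out_l <- lfmm_outliers(lf, variable = 1, fdr = p$fdr %||% 0.1)
  f2 <- file.path(out, "lfmm_outliers.tsv")
  write_gea_tsv(out_l, f2)
  c(arts, list(artifact(f2, "gea", p)))
}
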