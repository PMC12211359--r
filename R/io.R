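#' Reference strategy-level results (bundled example data)
#'
#' Strategy-level statin-eligible fractions, lifetime ASCVD event fractions,
#' discounted per-person costs (2019 US$) and QALYs for soft- and hard-model
#' risk-threshold strategies among Chinese adults aged 30-75 (plus the soft
#' model by age group), as reported by a published nationwide cost-utility
#' analysis. Bundled for worked examples: ICER arithmetic, frontier
#' classification and optimal-threshold selection operate on these rows
#' exactly as on freshly computed [evaluate_threshold_grid()] output.
#' Thresholds are percentages; `NA` threshold is the no-treatment
#' comparator; `events_pct` is unavailable for the age-stratified rows.
#'
#' @param model `"soft"` or `"hard"`.
#' @param ages `"30-75"` (default), `"30-59"` or `"60-75"` (soft model only).
#' @return Tibble with columns `model`, `ages`, `threshold`, `eligible_pct`,
#'   `events_pct`, `cost`, `qalys`.
#' @export
#' @examples
#' build_frontier(reference_strategy_table("soft"))
reference_strategy_table <- function(model = c("soft", "hard"),
                                     ages = "30-75") {
  model <- match.arg(model)
  path <- system.file("extdata", "threshold_strategy_reference.csv",
                      package = "statincua", mustWork = TRUE)
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out <- x[x$model == model & x$ages == ages, , drop = FALSE]
  if (nrow(out) == 0) {
    stop(sprintf("No reference rows for model '%s', ages '%s'.", model, ages),
         call. = FALSE)
  }
  out
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, applies defaults (discount 0.05,
#' WTP anchors 10274 and 30823 US$/QALY, 1000 PSA iterations) and validates:
#' the `parameters` block must cover the full manifest of
#' [default_parameter_table()], thresholds must lie within the declared
#' grids (soft 10-20%, hard 5-15% plus 7.5%), and the discount rate within
#' 0-8% unless `allow_discount_override` is set.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return Validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(model = "soft", discount = 0.05,
                   wtp = c(10274, 30823), psa_n = 1000, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  manifest <- default_parameter_table()
  if (is.null(cfg$parameters)) {
    stop("Config must contain a `parameters` block.", call. = FALSE)
  }
  missing_par <- setdiff(manifest$name, names(cfg$parameters))
  if (length(missing_par) > 0) {
    stop("Config `parameters` block is missing: ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cfg$parameters)) {
    p <- cfg$parameters[[nm]]
    if (!is.null(p$low) && !is.null(p$high) &&
        (p$low > p$base || p$base > p$high)) {
      stop(sprintf("Parameter '%s' violates low <= base <= high.", nm),
           call. = FALSE)
    }
  }
  if (!cfg$model %in% c("soft", "hard")) {
    stop("`model` must be 'soft' or 'hard'.", call. = FALSE)
  }
  if (!is.null(cfg$thresholds)) {
    th <- as.numeric(cfg$thresholds)
    grid_lo <- if (cfg$model == "soft") 0.10 else 0.05
    grid_hi <- if (cfg$model == "soft") 0.20 else 0.15
    ok <- (th >= grid_lo & th <= grid_hi) |
      (cfg$model == "hard" & abs(th - 0.075) < 1e-12)
    if (!all(ok)) {
      stop(sprintf(
        "Thresholds outside the %s-model grid [%.0f%%, %.0f%%]: %s",
        cfg$model, 100 * grid_lo, 100 * grid_hi,
        paste(100 * th[!ok], collapse = ", ")), call. = FALSE)
    }
  }
  if (!isTRUE(cfg$allow_discount_override) &&
      (cfg$discount < 0 || cfg$discount > 0.08)) {
    stop("Discount rate must lie in [0, 0.08] (sensitivity range); set ",
         "`allow_discount_override: true` to exceed it.", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Parameter bundle from a run configuration
#'
#' @param cfg A [load_run_config()] result.
#' @return A [model_params()] with the configuration's base values applied.
#' @export
config_params <- function(cfg) {
  bases <- vapply(cfg$parameters, function(p) as.numeric(p$base), numeric(1))
  params <- apply_parameters(bases, model_params())
  params$discount <- cfg$discount
  params
}

#' Write results with a reproducibility sidecar
#'
#' Writes a CSV with stable column order plus a JSON sidecar
#' (`<path>.meta.json`) recording the package version, seed, content hash
#' and timestamp.
#'
#' @param x Data frame of results (strategy outcomes, frontier, curve...).
#' @param path Output CSV path.
#' @param seed Seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, seed = NA_integer_) {
  x <- as.data.frame(x)
  if (nrow(x) == 0) warning("Writing header-only CSV.", call. = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  meta <- list(
    package = "statincua",
    version = as.character(utils::packageVersion("statincua")),
    seed = seed,
    hash = rlang::hash(x),
    columns = names(x),
    rows = nrow(x),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path CSV path.
#' @return Tibble; sidecar metadata (if present) attached as attribute
#'   `meta`.
#' @export
read_results <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    attr(x, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  x
}
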