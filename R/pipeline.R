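## End-to-end orchestration: simulate -> derive -> describe -> meta -> gsem,
## with a JSON manifest of produced artifacts. All randomness flows from the
## single seed in the run configuration; each stage draws from a named
## substream derived from it, so disabling a stage does not shift the
## streams of the others.

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, derive = 211L, describe = 307L,
               meta = 401L, gsem = 503L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full IPV analysis pipeline
#'
#' Executes the enabled stages in order on either a simulated or a supplied
#' woman-level table, writing per-stage outputs (delimited text / JSON) and
#' a manifest with file hashes, the seed and per-stage row counts.
#'
#' @param out_dir output directory.
#' @param stages character subset of
#'   \code{c("simulate", "derive", "describe", "meta", "gsem")}.
#' @param seed integer master seed.
#' @param config simulator configuration (used by the simulate stage); its
#'   seed field is overridden by the pipeline substream.
#' @param input_path CSV of raw woman-level records (used when the simulate
#'   stage is disabled).
#' @param mapping column mapping for the derive stage.
#' @param spec GSEM model structure.
#' @param quad_order Gauss-Hermite order for the gsem stage.
#' @return manifest list (also written to \code{manifest.json}), invisibly.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("simulate", "derive", "describe",
                                    "meta", "gsem"),
                         seed = 1L,
                         config = NULL,
                         input_path = NULL,
                         mapping = default_column_map(),
                         spec = default_gsem_spec(),
                         quad_order = 15) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = as.integer(seed), stages = stages,
                   package_version = as.character(
                     utils::packageVersion("ipvgsem")),
                   outputs = list(), rows = list())
  add_output <- function(stage, path, n_rows) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]] %||%
                                      character(), basename(path))
    manifest$rows[[stage]] <<- n_rows
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  raw <- NULL
  if ("simulate" %in% stages) {
    tryCatch({
      cfg <- config %||% sim_config()
      cfg$seed <- stage_seed(seed, "simulate")
      raw <- simulate_population(cfg)
      paths <- write_simulation(raw, out_dir)
      add_output("simulate", paths[["data"]], nrow(raw))
    }, error = function(e) fail("simulate", e))
  } else if (!is.null(input_path)) {
    raw <- read.csv(input_path, stringsAsFactors = FALSE)
  }

  derived <- NULL
  if ("derive" %in% stages) {
    tryCatch({
      if (is.null(raw)) stop("no input table: enable the simulate stage ",
                             "or give input_path")
      issues <- validate_inputs(raw, mapping)
      if (nrow(issues)) {
        utils::write.csv(issues, file.path(out_dir, "validation.csv"),
                         row.names = FALSE)
      }
      derived <- build_analysis_table(raw, mapping)
      path <- file.path(out_dir, "derived.csv")
      write.csv(as.data.frame(derived), path, row.names = FALSE)
      add_output("derive", path, nrow(derived))
    }, error = function(e) fail("derive", e))
  }

  if ("describe" %in% stages) {
    tryCatch({
      if (is.null(derived)) stop("derive stage output required")
      tabs <- lapply(names(attr(derived, "factors")), function(f) {
        tab <- frequency_table(derived[[f]], derived$weight)
        cbind(variable = f, tab)
      })
      path <- file.path(out_dir, "frequency_tables.csv")
      write.csv(do.call(rbind, tabs), path, row.names = FALSE)
      add_output("describe", path, nrow(derived))
      prev <- country_prevalence(derived)
      path2 <- file.path(out_dir, "country_prevalence.csv")
      write.csv(prev, path2, row.names = FALSE)
      add_output("describe", path2, nrow(prev))
    }, error = function(e) fail("describe", e))
  }

  if ("meta" %in% stages) {
    tryCatch({
      if (is.null(derived)) stop("derive stage output required")
      meta <- pool_country_prevalence(country_prevalence(derived))
      path <- file.path(out_dir, "meta_result.json")
      jsonlite::write_json(
        list(pooled_p = meta$pooled_p, ci_low = meta$ci_low,
             ci_high = meta$ci_high, tau2 = meta$tau2, Q = meta$Q,
             I2 = meta$I2, p_het = meta$p_het,
             per_study = meta$per_study),
        path, auto_unbox = TRUE, digits = NA)
      add_output("meta", path, nrow(meta$per_study))
    }, error = function(e) fail("meta", e))
  }

  if ("gsem" %in% stages) {
    tryCatch({
      if (is.null(derived)) stop("derive stage output required")
      fit <- ipv_gsem(derived, spec = spec, quad_order = quad_order)
      path <- file.path(out_dir, "gsem_fit.json")
      jsonlite::write_json(
        list(theta = as.list(fit$theta), loglik = fit$loglik,
             aic = fit$aic, bic = fit$bic, converged = fit$converged,
             n = fit$n, quad_order = fit$quad_order,
             se = as.list(setNames(sqrt(diag(fit$vcov)),
                                   rownames(fit$vcov)))),
        path, auto_unbox = TRUE, digits = NA)
      add_output("gsem", path, fit$n)
      tab <- aor_table(fit)
      path2 <- file.path(out_dir, "aor_table.csv")
      write.csv(tab, path2, row.names = FALSE)
      add_output("gsem", path2, nrow(tab))
    }, error = function(e) fail("gsem", e))
  }

  files <- unique(unlist(manifest$outputs))
  manifest$hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Validate a raw woman-level table against a column mapping
#'
#' Reports unmapped required columns, unknown category codes, per-column
#' missingness and weight anomalies (non-positive or extreme values).
#'
#' @param records data.frame of raw records, or a path to a CSV file.
#' @param mapping column mapping, see \code{\link{default_column_map}}.
#' @return data.frame of issues with columns \code{check}, \code{column},
#'   \code{rows}, \code{detail}; zero rows when the table is clean.
#' @export
validate_inputs <- function(records, mapping = default_column_map()) {
  if (is.character(records)) {
    if (!file.exists(records)) stop("unreadable file: ", records)
    records <- read.csv(records, stringsAsFactors = FALSE)
  }
  issues <- list()
  note <- function(check, column, rows, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      check = check, column = column, rows = rows, detail = detail)
  }

  required <- c(unlist(mapping$design), unlist(mapping$indicators),
                unlist(mapping$acts), unlist(mapping$media),
                unlist(mapping$decisions), unlist(mapping$attitude),
                unlist(mapping$covariates))
  for (col in setdiff(required, names(records))) {
    note("unmapped_column", col, NA_integer_, "required column not found")
  }
  present <- intersect(required, names(records))
  for (col in present) {
    n_miss <- sum(is.na(records[[col]]))
    if (n_miss > 0) note("missing_values", col, n_miss,
                         sprintf("%.2f%% missing",
                                 100 * n_miss / nrow(records)))
  }

  wcol <- mapping$design[["weight"]]
  if (wcol %in% names(records)) {
    w <- records[[wcol]]
    bad <- which(!is.na(w) & w <= 0)
    if (length(bad)) {
      note("nonpositive_weight", wcol, length(bad),
           paste("rows", paste(utils::head(bad, 5), collapse = ", ")))
    }
    ok <- w[!is.na(w) & w > 0]
    extreme <- which(!is.na(w) & w > 0 & w > 10 * stats::median(ok))
    if (length(extreme)) {
      note("extreme_weight", wcol, length(extreme),
           "weight above 10x the median")
    }
  }

  codes <- list()
  for (f in names(mapping$covariates)) {
    codes[[mapping$covariates[[f]]]] <- ipv_factors()[[f]]
  }
  for (col in unlist(mapping$media)) codes[[col]] <- media_codes
  for (col in unlist(mapping$decisions)) codes[[col]] <- decision_codes
  for (col in unlist(mapping$attitude)) codes[[col]] <- c("yes", "no")
  for (col in intersect(names(codes), names(records))) {
    x <- records[[col]]
    bad <- !is.na(x) & !x %in% codes[[col]]
    if (any(bad)) {
      note("unknown_category", col, sum(bad),
           paste("codes:", paste(unique(x[bad]), collapse = ", ")))
    }
  }

  if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(check = character(), column = character(),
               rows = integer(), detail = character())
  }
}
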