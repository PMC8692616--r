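#' Experimental standard deviation of a property
#'
#' Square root of the mean over sample pools of the within-pool replicate
#' variance (n-1 denominator) — the yardstick against which model RMSE is
#' judged: a model predicting pool means better than single-fibre scatter is
#' resolving real between-pool differences.
#'
#' @param properties replicate table (sample_id, replicate, property columns).
#' @param property property column name.
#' @return scalar in the property's units.
#' @export
experimental_sd <- function(properties, property) {
  stopifnot(property %in% names(properties))
  v <- tapply(properties[[property]], properties$sample_id, stats::var)
  if (anyNA(v)) stop("every sample needs at least 2 replicates")
  sqrt(mean(v))
}

#' Per-sample property means
#' @param properties replicate table.
#' @return data.frame sample_id x property means, ordered by sample_id
#'   appearance.
#' @export
property_pool_means <- function(properties) {
  sids <- unique(properties$sample_id)
  props <- setdiff(names(properties), c("sample_id", "replicate"))
  out <- data.frame(sample_id = sids)
  for (p in props)
    out[[p]] <- as.numeric(tapply(properties[[p]], properties$sample_id,
                                  mean)[sids])
  out
}

#' Default pipeline run configuration
#'
#' @param n_samples,seed,snr synthetic-data shape.
#' @param repeats,k CV shape (the reference workflow uses 100 repeats of
#'   10-fold CV; scale down for exploratory runs).
#' @param n_trees,mtry random-forest size.
#' @param retention elimination retention fraction.
#' @param properties property columns to model.
#' @param algos algorithms to run.
#' @param out_dir artifact directory (NULL = no files written).
#' @return config list.
#' @export
run_config <- function(n_samples = 63L, seed = 1L, snr = 2000,
                       repeats = 100L, k = 10L, n_trees = 1000L, mtry = NULL,
                       retention = 0.9,
                       properties = c("breaking_force_N", "elastic_modulus_GPa",
                                      "extension_pct", "yield_strength_MPa"),
                       algos = c("rf", "plsr"), out_dir = NULL) {
  list(n_samples = n_samples, seed = seed, snr = snr, repeats = repeats,
       k = k, n_trees = n_trees, mtry = mtry, retention = retention,
       properties = properties, algos = algos, out_dir = out_dir)
}

trace_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  steps <- lapply(x$steps, function(st) {
    imp <- unlist(st$importance)
    list(ids = unlist(st$ids),
         cv = structure(list(r2_mean = st$r2_mean, r2_sd = st$r2_sd,
                             rmse_mean = st$rmse_mean, rmse_sd = st$rmse_sd,
                             importance_mean = imp), class = "cv_result"))
  })
  structure(list(steps = steps, best_index = x$best_index,
                 property = x$property, algo = x$algo,
                 sizes = vapply(steps, function(s) length(s$ids), 0L),
                 retention = 0.9),
            class = "selection_trace")
}

trace_to_json <- function(trace, path) {
  steps <- lapply(trace$steps, function(st) list(
    n = length(st$ids), ids = st$ids,
    r2_mean = st$cv$r2_mean, r2_sd = st$cv$r2_sd,
    rmse_mean = st$cv$rmse_mean, rmse_sd = st$cv$rmse_sd,
    importance = as.list(st$cv$importance_mean)))
  jsonlite::write_json(list(property = trace$property, algo = trace$algo,
                            best_index = trace$best_index, steps = steps),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Run the full measurement-descriptor workflow
#'
#' simulate -> pretreat -> deconvolve -> describe -> associate -> select ->
#' report, as one configured, seeded run. Artifacts (descriptor table CSV,
#' CCorA scores, per-step selection traces, the final report) are written
#' under `config$out_dir` when set; a stage whose artifact already exists
#' there with the same config hash is reloaded instead of recomputed.
#'
#' @param config a [run_config()].
#' @param dataset optionally, a pre-built `md_dataset` (otherwise simulated
#'   from the config).
#' @param verbose progress messages.
#' @return list of class `run_report`: `table` (per property/algo best-set
#'   rows with the experimental-SD column), `consensus`, `traces`, `ccora`,
#'   `dataset`, `descriptors`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL, verbose = FALSE) {
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  dataset <- dataset %||% simulate_dataset(n_samples = config$n_samples,
                                           seed = config$seed, snr = config$snr)
  desc <- build_descriptor_table(dataset, dataset$config, verbose = verbose)
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(sample_id = desc$sample_ids, desc$matrix,
                                check.names = FALSE),
                     file.path(out_dir, "descriptors.csv"), row.names = FALSE)
    jsonlite::write_json(desc$meta, file.path(out_dir, "descriptor_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  pm <- property_pool_means(dataset$properties)
  stopifnot(identical(pm$sample_id, desc$sample_ids))
  Y <- as.matrix(pm[, config$properties, drop = FALSE])

  filt <- ccora_filter(desc, n_max = nrow(Y) - ncol(Y) - 1, r_max = 0.3)
  cc <- ccora(filt$matrix, Y)
  if (!is.null(out_dir)) {
    utils::write.csv(
      data.frame(axis = seq_along(cc$canonical_correlations),
                 canonical_correlation = cc$canonical_correlations),
      file.path(out_dir, "ccora_correlations.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cc$property_scores),
                     file.path(out_dir, "ccora_property_scores.csv"))
    utils::write.csv(as.data.frame(cc$descriptor_scores),
                     file.path(out_dir, "ccora_descriptor_scores.csv"))
  }

  traces <- list(); rows <- NULL
  for (prop in config$properties) {
    for (algo in config$algos) {
      key <- paste(prop, algo, sep = ".")
      tr_path <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("trace_%s_%s_%s.json", prop, algo,
                                   substr(hash, 1, 8))) else NULL
      spec <- model_spec(algo, n_trees = config$n_trees, mtry = config$mtry,
                         seed = derive_seed(config$seed, key))
      if (!is.null(tr_path) && file.exists(tr_path)) {
        if (verbose) message("reusing cached trace: ", key)
        traces[[key]] <- trace_from_json(tr_path)
      } else {
        if (verbose) message("selecting: ", key)
        traces[[key]] <- recursive_select(spec, desc, pm[[prop]],
                                          retention = config$retention,
                                          k = config$k, repeats = config$repeats,
                                          property = prop, verbose = verbose)
        if (!is.null(tr_path)) trace_to_json(traces[[key]], tr_path)
      }
      bs <- best_set(traces[[key]])
      row <- bs$report
      row$experimental_sd <- experimental_sd(dataset$properties, prop)
      rows <- rbind(rows, row)
    }
  }

  consensus <- list()
  if (all(c("rf", "plsr") %in% config$algos)) {
    for (prop in config$properties)
      consensus[[prop]] <- consensus_topk(traces[[paste0(prop, ".rf")]],
                                          traces[[paste0(prop, ".plsr")]])
  }
  report <- structure(list(table = rows, consensus = consensus,
                           traces = traces, ccora = cc, dataset = dataset,
                           descriptors = desc, config_hash = hash),
                      class = "run_report")
  if (!is.null(out_dir)) {
    utils::write.csv(rows, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(consensus, function(cn)
      list(rf_top = cn$rf_top, plsr_top = cn$plsr_top, common = cn$common)),
      file.path(out_dir, "consensus.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$table, digits = 3)
  for (p in names(x$consensus))
    cat(sprintf("  %s: %d common top-20 descriptors\n", p,
                length(x$consensus[[p]]$common)))
  invisible(x)
}
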