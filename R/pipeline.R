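## End-to-end pipeline: simulate (optional) -> filter -> maps -> landscape
## -> interference, with a JSON run manifest.

#' Pipeline configuration
#'
#' Either simulate a synthetic dataset (`simulate = TRUE`, using `sim`) or
#' read crossover calls and informative spans from the given paths.
#'
#' @param simulate generate inputs with the synthetic simulator.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param calls_path,spans_path,markers_path,chrom_sizes_path input paths
#'   used when `simulate = FALSE` (`markers_path` is a PLINK `.map` file).
#' @param filter a [filter_config()].
#' @param assign crossover mass assignment mode for [build_map()].
#' @param telomere_window_bp window for [telomere_proportion()].
#' @param concentration_gap_bp gap threshold for [concentration_curve()].
#' @param concentration_bootstrap_n bootstrap resamples for the
#'   concentration curve.
#' @param interference_models models to fit (subset of
#'   `c("gamma", "gamma_escape")`).
#' @param interference_bootstrap_n bootstrap resamples for interference CIs
#'   (0 = point estimates only).
#' @param out_dir output directory.
#' @param seed seed applied at the start of the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim = sim_config(),
                            calls_path = NULL, spans_path = NULL,
                            markers_path = NULL, chrom_sizes_path = NULL,
                            filter = filter_config(),
                            assign = "overlap",
                            telomere_window_bp = 5e6,
                            concentration_gap_bp = 1e6,
                            concentration_bootstrap_n = 200L,
                            interference_models = c("gamma", "gamma_escape"),
                            interference_bootstrap_n = 0L,
                            out_dir = tempfile("canrec_run_"),
                            seed = 1L) {
  structure(list(simulate = simulate, sim = sim,
                 calls_path = calls_path, spans_path = spans_path,
                 markers_path = markers_path,
                 chrom_sizes_path = chrom_sizes_path,
                 filter = filter, assign = assign,
                 telomere_window_bp = telomere_window_bp,
                 concentration_gap_bp = concentration_gap_bp,
                 concentration_bootstrap_n = concentration_bootstrap_n,
                 interference_models = interference_models,
                 interference_bootstrap_n = interference_bootstrap_n,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return for the reader, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$chrom_lengths)) {
    sim_args$chrom_lengths <- as.data.frame(sim_args$chrom_lengths)
  }
  for (nm in c("n_meioses_per_sex", "nu", "p_escape", "total_cM")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  y$sim <- do.call(sim_config, sim_args)
  filt_args <- y$filter %||% list()
  if (!is.null(filt_args$blacklist_regions)) {
    filt_args$blacklist_regions <- as.data.frame(filt_args$blacklist_regions)
  }
  y$filter <- do.call(filter_config, filt_args)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$sim <- lapply(unclass(y$sim), function(v) {
    if (is.data.frame(v)) as.list(v)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)  # keep names in YAML
    else v
  })
  y$filter <- unclass(y$filter)
  yaml::write_yaml(y, path)
  invisible(path)
}

pipeline_stage <- function(name, expr, manifest) {
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), crossover filtering, sex-specific and
#' sex-averaged map construction, landscape statistics (telomeric
#' proportions, concentration curves) and interference fits, writing all
#' outputs and a JSON run manifest to the output directory. A dataset in
#' which no calls survive filtering still completes, with empty maps and an
#' explicit zero-survivor report.
#'
#' @param config a [pipeline_config()] or the path to a YAML file.
#' @return (invisibly) a list with the output directory, the manifest, and
#'   the principal in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(package_version = as.character(packageVersion("canrec")),
                   seed = config$seed, stages = list())

  ## --- inputs ---
  if (isTRUE(config$simulate)) {
    ds <- pipeline_stage("simulate", simulate_dataset(config$sim))
    calls <- ds$calls; spans <- ds$spans; markers <- ds$markers
    chrom_lengths <- config$sim$chrom_lengths
    write_crossover_calls(calls, file.path(config$out_dir, "calls_raw.tsv"))
    write_informative_spans(spans, file.path(config$out_dir, "spans.tsv"))
    manifest$stages$simulate <- list(n_true_events = nrow(ds$truth$events),
                                     n_observed_calls = nrow(calls))
  } else {
    chrom_lengths <- if (!is.null(config$chrom_sizes_path)) {
      read_chrom_sizes(config$chrom_sizes_path)
    } else NULL
    calls <- pipeline_stage("read_calls",
                            read_crossover_calls(config$calls_path,
                                                 chrom_lengths))
    spans <- if (!is.null(config$spans_path)) {
      pipeline_stage("read_spans", read_informative_spans(config$spans_path))
    } else NULL
    markers <- if (!is.null(config$markers_path)) {
      m <- pipeline_stage("read_markers", read_plink_map(config$markers_path))
      data.frame(chrom = m$chrom, pos_bp = m$pos_bp)
    } else NULL
    manifest$stages$read <- list(n_calls = nrow(calls))
  }

  ## --- filtering ---
  filt <- pipeline_stage("filter", apply_crossover_filters(calls, config$filter))
  calls_f <- filt$calls
  rep_df <- do.call(rbind, lapply(names(filt$reports), function(nm) {
    r <- filt$reports[[nm]]
    data.frame(rule = nm, n_in = r$n_in, n_removed = r$n_removed,
               n_surviving = r$n_surviving)
  }))
  write_tsv(rep_df, file.path(config$out_dir, "filter_report.tsv"))
  write_crossover_calls(calls_f, file.path(config$out_dir, "calls_filtered.tsv"))
  manifest$stages$filter <- list(n_in = nrow(calls), n_surviving = nrow(calls_f),
                                 per_rule = setNames(rep_df$n_removed, rep_df$rule))

  ## --- genetic maps ---
  maps <- list()
  if (!is.null(markers) && !is.null(spans)) {
    iv <- marker_intervals(markers)
    for (sx in c("female", "male")) {
      mids <- unique(calls_f$meiosis_id[norm_sex(calls_f$parent_sex) == sx])
      sp <- spans[spans$meiosis_id %in% mids, , drop = FALSE]
      neff <- suppressWarnings(effective_meioses(sp, iv))
      maps[[sx]] <- pipeline_stage(paste0("map_", sx),
                                   build_map(calls_f, neff, sex = sx,
                                             assign = config$assign))
      write_genetic_map(maps[[sx]],
                        file.path(config$out_dir, sprintf("map_%s.tsv", sx)))
    }
    maps$sex_averaged <- sex_average(maps$female, maps$male)
    write_genetic_map(maps$sex_averaged,
                      file.path(config$out_dir, "map_sex_averaged.tsv"))
    manifest$stages$maps <- lapply(maps, function(m) {
      list(total_cM = sum(m$cM), n_intervals = nrow(m))
    })
  }

  ## --- landscape ---
  landscape <- list()
  for (sx in intersect(c("female", "male"), names(maps))) {
    m <- maps[[sx]]
    if (sum(m$cM) > 0) {
      landscape[[sx]] <- list(
        telomere = telomere_proportion(m, config$telomere_window_bp,
                                       chrom_lengths),
        concentration = concentration_curve(
          m, gap_bp = config$concentration_gap_bp,
          bootstrap_n = config$concentration_bootstrap_n))
    }
  }
  if (length(landscape) > 0L) {
    tel_df <- data.frame(
      sex = names(landscape),
      telomere_prop = vapply(landscape, `[[`, numeric(1L), "telomere"),
      seq_frac_80 = vapply(landscape, function(l) {
        sequence_fraction_at(l$concentration, 0.8)
      }, numeric(1L)))
    write_tsv(tel_df, file.path(config$out_dir, "landscape_summary.tsv"))
    manifest$stages$landscape <- split(tel_df[-1L], tel_df$sex)
  }

  ## --- interference ---
  fits <- list()
  if (length(maps) > 0L && nrow(calls_f) > 0L) {
    for (sx in c("female", "male")) {
      mids <- unique(calls_f$meiosis_id[norm_sex(calls_f$parent_sex) == sx])
      if (length(mids) == 0L) next
      roster <- unique(calls_f[norm_sex(calls_f$parent_sex) == sx,
                               c("meiosis_id", "parent_sex")])
      xs <- to_genetic_scale(calls_f, maps[[sx]], meioses = roster)
      for (mod in config$interference_models) {
        key <- paste(sx, mod, sep = "_")
        fits[[key]] <- pipeline_stage(
          paste0("interference_", key),
          fit_interference(xs, model = mod,
                           bootstrap_n = config$interference_bootstrap_n))
        write_interference_fit(fits[[key]],
                               file.path(config$out_dir,
                                         sprintf("interference_%s.json", key)))
      }
    }
    manifest$stages$interference <- lapply(fits, function(f) {
      list(model = f$model, nu = f$nu, p = f$p, bic = f$bic, n = f$n)
    })
  } else {
    manifest$stages$interference <- list(skipped = "no surviving crossovers")
  }

  manifest$completed <- TRUE
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 calls = calls_f, maps = maps, landscape = landscape,
                 fits = fits))
}
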