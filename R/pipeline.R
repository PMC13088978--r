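# End-to-end pipeline: (synthetic) data -> optional melt-curve analysis ->
# iterative screen + random baseline -> evaluation report, with a manifest
# so a rerun from the same configuration reproduces every artifact
# byte-for-byte.

#' Evaluate a model-guided screen against its baselines
#'
#' Assembles the campaign report for one motif: hit rate of the valid
#' library, per-iteration enrichment factors and the recovery curve,
#' baseline mean/sd recovery at the same schedule, the recovered-versus-
#' unrecovered delta-Tm summary, and chemotype-cluster recovery.
#'
#' @param trace a `screen_trace` from [iterative_screen()].
#' @param baselines list of baseline traces from [random_screen()] (or
#'   `NULL`).
#' @param library the [screen_library()] screened.
#' @param table the [screen_table()] oracle.
#' @param cluster_cutoff Tanimoto-distance cutoff for chemotype clustering.
#' @return a named list report.
#' @export
evaluate_screen <- function(trace, baselines, library, table,
                            cluster_cutoff = 0.4) {
  tab <- motif_slice(table, trace$motif, library$ids)
  s <- summary(trace)
  rc <- recovery_curve(trace)
  hr <- hit_rate(trace$actives_total, trace$n_valid)

  active_ids <- library$ids[which(tab$valid & tab$active)]
  recovered_ids <- intersect(trace$tested_ids, active_ids)
  dtm <- stats::setNames(tab$delta_tm, library$ids)[active_ids]
  split_summary <- delta_tm_split_summary(dtm, recovered_ids,
                                          test = "wilcoxon")
  clus <- if (length(active_ids) >= 2) {
    cluster_recovery(library$fingerprints[active_ids, , drop = FALSE],
                     recovered_ids, cutoff = cluster_cutoff)
  } else NULL

  baseline_summary <- NULL
  if (!is.null(baselines) && length(baselines)) {
    rec <- sapply(baselines, function(b) summary(b)$fraction_recovered)
    rec <- as.matrix(rec)
    baseline_summary <- data.frame(
      fraction_screened = summary(baselines[[1]])$fraction_screened,
      mean_recovered = rowMeans(rec),
      sd_recovered = apply(rec, 1, stats::sd))
  }

  list(
    motif = trace$motif,
    n_library = trace$n_library,
    n_valid = trace$n_valid,
    actives_total = trace$actives_total,
    hit_rate_percent = hr$percent,
    iterations = s,
    recovery = as.data.frame(rc),
    baseline = baseline_summary,
    delta_tm_summary = split_summary,
    cluster_recovery = if (is.null(clus)) NULL else list(
      clusters = clus$clusters,
      singletons = clus$singletons,
      clustered_recovery = clus$clustered_recovery,
      singleton_recovery = clus$singleton_recovery),
    recovered_actives = sort_ids(recovered_ids)
  )
}

default_pipeline_config <- function() {
  list(
    seed = 1,
    synth = list(),          # synth_config() overrides; NULL to read inputs
    inputs = NULL,           # list(compounds=, labels=) or list(curves=)
    melt = list(enabled = FALSE),
    screen = list(motifs = c(1, 2)),
    evaluate = list(cluster_cutoff = 0.4)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full screening pipeline
#'
#' Stages: (1) obtain a campaign - either generated synthetically
#' (`config$synth`) or read from compound + label CSVs or a raw melt-curve
#' CSV (`config$inputs`); (2) optionally re-derive the label table from raw
#' melt curves (`config$melt$enabled`); (3) run the model-guided iterative
#' screen and the six-seed random baseline for each requested motif;
#' (4) evaluate and write artifacts: `trace_motif<k>.jsonl`,
#' `baseline_motif<k>_<seed>.jsonl`, `report.json`, `manifest.json`.
#' Rerunning with the same configuration reproduces the trace and report
#' files byte-for-byte (the manifest carries the only timestamp).
#'
#' @param config a nested list (see Details), or the path to a YAML file
#'   with the same structure. All fields are optional; the default runs a
#'   synthetic campaign on both motifs.
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with the campaign/library, traces, baselines
#'   and report.
#' @details Configuration fields: `seed` (master seed); `synth` (overrides
#'   for [synth_config()], or `NULL` to disable generation); `inputs`
#'   (`compounds` + `labels` CSV paths, or `curves` CSV path); `melt`
#'   (`enabled`, plus [tm_control()] overrides); `screen` (`motifs` plus
#'   [screen_config()] overrides); `evaluate` (`cluster_cutoff`).
#' @export
run_pipeline <- function(config = list(), out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  input_files <- character(0)

  # stage 1: campaign
  if (!is.null(cfg$synth)) {
    synth_args <- cfg$synth
    if (is.null(synth_args$seed)) synth_args$seed <- cfg$seed
    campaign <- generate_library(do.call(synth_config, synth_args))
    library <- campaign$library
    table <- campaign$table
  } else {
    assert_that(!is.null(cfg$inputs),
                "config needs either a synth block or an inputs block",
                subclass = "iterscreen_stage_error")
    campaign <- NULL
    if (!is.null(cfg$inputs$curves)) {
      curves <- read_melt_table(cfg$inputs$curves)
      table <- analyze_melt_curves(curves)
      input_files <- c(input_files, curves = cfg$inputs$curves)
    } else {
      table <- read_delta_tm_table(cfg$inputs$labels)
      input_files <- c(input_files, labels = cfg$inputs$labels)
    }
    records <- read_compound_table(cfg$inputs$compounds)
    input_files <- c(input_files, compounds = cfg$inputs$compounds)
    library <- library_from_records(records)
  }

  # stage 2: optional melt-curve re-derivation for synthetic campaigns
  if (isTRUE(cfg$melt$enabled) && !is.null(campaign)) {
    assay_args <- cfg$melt[setdiff(names(cfg$melt), "enabled")]
    if (is.null(assay_args$seed)) assay_args$seed <- derive_seed(cfg$seed, 5)
    curves <- generate_melt_curves(campaign,
                                   do.call(melt_assay_config, assay_args))
    table <- analyze_melt_curves(curves)
  }

  # stage 3: screens
  screen_args <- cfg$screen[setdiff(names(cfg$screen), "motifs")]
  if (is.null(screen_args$seed_diversity))
    screen_args$seed_diversity <- derive_seed(cfg$seed, 1)
  if (is.null(screen_args$seed_model))
    screen_args$seed_model <- derive_seed(cfg$seed, 2)
  if (is.null(screen_args$seeds_baseline))
    screen_args$seeds_baseline <- vapply(1:6, function(k)
      derive_seed(cfg$seed, 10 + k), integer(1))
  scfg <- do.call(screen_config, screen_args)

  motifs <- cfg$screen$motifs
  traces <- list()
  baselines <- list()
  reports <- list()
  for (motif in motifs) {
    key <- as.character(motif)
    traces[[key]] <- iterative_screen(library, table, motif, scfg)
    baselines[[key]] <- random_screen(library, table, motif, scfg)
    reports[[key]] <- evaluate_screen(traces[[key]], baselines[[key]],
                                      library, table,
                                      cfg$evaluate$cluster_cutoff)
    write_trace(traces[[key]],
                file.path(out_dir, sprintf("trace_motif%s.jsonl", key)))
    for (b in baselines[[key]]) {
      write_trace(b, file.path(out_dir,
                               sprintf("baseline_motif%s_%d.jsonl",
                                       key, b$seed)))
    }
  }

  # stage 4: report + overlap across motifs
  report <- list(motifs = reports)
  if (length(motifs) == 2) {
    act <- lapply(motifs, function(m) {
      tab <- motif_slice(table, m, library$ids)
      library$ids[which(tab$valid & tab$active)]
    })
    names(act) <- paste0("motif", motifs)
    recv <- lapply(seq_along(motifs), function(i)
      intersect(traces[[i]]$tested_ids, act[[i]]))
    names(recv) <- names(act)
    report$overlap <- overlap_analysis(act, recv)
  }
  write_report(report, file.path(out_dir, "report.json"))

  manifest <- run_manifest(cfg, input_files, seed = cfg$seed)
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  invisible(list(library = library, table = table, campaign = campaign,
                 traces = traces, baselines = baselines, report = report,
                 manifest = manifest))
}

# Build a screen_library from a compound-record data.frame (abstract
# fingerprint column, or SMILES featurized via the chemistry backend).
library_from_records <- function(records, spec = NULL) {
  if ("fingerprint" %in% names(records)) {
    bits <- strsplit(records$fingerprint, "")
    nb <- unique(lengths(bits))
    assert_that(length(nb) == 1, "fingerprint bit-strings differ in length")
    X <- do.call(rbind, lapply(bits, as.integer))
    rownames(X) <- records$compound_id
    desc_cols <- grep("^desc_", names(records), value = TRUE)
    D <- NULL
    if (length(desc_cols)) {
      D <- as.matrix(records[, desc_cols, drop = FALSE])
      rownames(D) <- records$compound_id
    }
    return(screen_library(X, D))
  }
  spec <- spec %||% feature_spec()
  fv <- lapply(seq_len(nrow(records)), function(i) {
    featurize(list(compound_id = records$compound_id[i],
                   smiles = records$smiles[i]), spec)
  })
  X <- do.call(rbind, lapply(fv, `[[`, "bits"))
  D <- do.call(rbind, lapply(fv, `[[`, "descriptors"))
  rownames(X) <- records$compound_id
  rownames(D) <- records$compound_id
  screen_library(X, D)
}
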