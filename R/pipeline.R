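# Configuration-driven orchestration: ingestion -> contingency ->
# disproportionality -> onset-time -> subgroup analyses, with stable sort
# orders so re-running a configuration yields byte-identical artifacts,
# and a JSON manifest recording every decision that shaped the run.

#' Build a pipeline run configuration
#'
#' @param drug Target drug name (exactly one).
#' @param faers_dir Directory of FAERS-style ASCII tables (`DEMO.txt`,
#'   `DRUG.txt`, `REAC.txt`, optional `THER/OUTC/INDI.txt`, `DELETED.txt`).
#' @param aggregate_paths Named character vector of VigiAccess-style
#'   aggregate count files; names label the databases.
#' @param synonyms Drug synonyms for matching.
#' @param soc_map_path Optional PT-to-SOC map file.
#' @param label_pts_path Optional file of labeled PTs (one per line) for
#'   flagging unlabeled signals.
#' @param thresholds A [signal_thresholds()].
#' @param stratifications Stratified reruns to perform (subset of `sex`,
#'   `age65`, `reporter_type`).
#' @param tto List of onset options: `zero_policy`, `bins`, `outlier_cap`.
#' @param out_dir Output directory for artifacts.
#' @param seed Integer seed for any simulation subcommands.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(drug,
                            faers_dir = NULL,
                            aggregate_paths = character(),
                            synonyms = character(),
                            soc_map_path = NULL,
                            label_pts_path = NULL,
                            thresholds = signal_thresholds(),
                            stratifications = c("sex", "age65", "reporter_type"),
                            tto = list(zero_policy = "half_day",
                                       bins = c(30, 60, 90, 180, 360),
                                       outlier_cap = Inf),
                            out_dir = "pvsignal_out",
                            seed = 1L) {
  if (length(drug) != 1) {
    abort("exactly one target drug is required", class = "pvsignal_config_error")
  }
  structure(
    list(drug = drug, faers_dir = faers_dir,
         aggregate_paths = aggregate_paths, synonyms = synonyms,
         soc_map_path = soc_map_path, label_pts_path = label_pts_path,
         thresholds = thresholds, stratifications = stratifications,
         tto = tto, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields mirror [pipeline_config()] arguments one-for-one; `overrides`
#' (e.g. from command-line flags) replace file fields by name.
#'
#' @param path YAML file path.
#' @param overrides Named list of field overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- modifyList(raw, overrides)
  th <- do.call(signal_thresholds, raw$thresholds %||% list())
  args <- raw[setdiff(names(raw), "thresholds")]
  args$thresholds <- th
  if (!is.null(args$aggregate_paths)) {
    args$aggregate_paths <- unlist(args$aggregate_paths)
  }
  do.call(pipeline_config, args)
}

#' Flag signals absent from the drug label
#'
#' @param signals A `signal_result` tibble (or character vector of events).
#' @param label_pts Character vector of labeled PTs (same vocabulary).
#' @return The signals with a logical `labeled` column; the unlabeled count
#'   is attached as attribute `n_unlabeled`.
#' @export
flag_unlabeled <- function(signals, label_pts) {
  if (is.character(signals)) signals <- tibble(event = signals)
  signals <- as_tibble(signals)
  signals$labeled <- signals$event %in% label_pts
  attr(signals, "n_unlabeled") <- sum(!signals$labeled)
  signals
}

pipeline_stage <- function(name, artifacts, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)),
          class = "pvsignal_stage_error",
          stage = name, partial_manifest = artifacts)
  })
}

write_artifact <- function(df, dir, name, artifacts) {
  path <- file.path(dir, name)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  artifacts[[name]] <- list(path = path, rows = nrow(df))
  artifacts
}

#' Run the full signal-detection pipeline
#'
#' Executes ingestion and deduplication, demographic summary, PT- and
#' SOC-level contingency construction, four-method disproportionality with
#' joint verdicts, cross-database intersection, time-to-onset analysis and
#' stratified reruns, writing UTF-8 TSV artifacts plus a JSON manifest.
#' Any stage error aborts with the stage name and the manifest of artifacts
#' completed so far attached to the condition.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the artifact manifest and key in-memory
#'   results (`reports`, `signals`, `overlap`, `weibull`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  needed <- c(
    if (!is.null(config$faers_dir)) config$faers_dir,
    config$aggregate_paths, config$soc_map_path, config$label_pts_path
  )
  missing_paths <- needed[!file.exists(needed)]
  if (length(missing_paths) > 0) {
    abort(paste0("input path(s) not found: ",
                 paste(missing_paths, collapse = ", ")),
          class = "pvsignal_config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  results <- list()
  th <- config$thresholds

  signal_lists <- list()

  if (!is.null(config$faers_dir)) {
    reports <- pipeline_stage("ingest", artifacts, {
      f <- function(name) {
        p <- file.path(config$faers_dir, paste0(name, ".txt"))
        if (file.exists(p)) p else NULL
      }
      paths <- list(demo = f("DEMO"), drug = f("DRUG"), reac = f("REAC"),
                    ther = f("THER"), outc = f("OUTC"), indi = f("INDI"))
      records <- parse_faers_tables(paths)
      deleted <- if (!is.null(f("DELETED"))) read_deleted_cases(f("DELETED")) else character()
      deduplicate_cases(records, deleted)
    })
    inform(paste0("ingest: ", nrow(reports), " deduplicated reports"))
    results$reports <- reports

    target <- pipeline_stage("filter", artifacts, {
      filter_primary_suspect(reports, config$drug, config$synonyms)
    })
    inform(paste0("filter: ", nrow(target), " primary-suspect reports for '",
                  config$drug, "'"))
    results$target <- target

    artifacts <- pipeline_stage("demographics", artifacts, {
      write_artifact(summarize_demographics(target), config$out_dir,
                     "demographics.tsv", artifacts)
    })

    pt_res <- pipeline_stage("signals_reports", artifacts, {
      tables <- build_pt_tables(reports, config$drug, config$synonyms)
      res <- apply_thresholds(
        signal_stats(tables, prior = if (nrow(tables) >= 10) NULL else
          mgps_prior(1, 1, 1, 1, w = 1)),
        th
      )
      res[order(-res$a, -xtfrm(res$ebgm), res$event), , drop = FALSE]
    })
    artifacts <- write_artifact(pt_res, config$out_dir,
                                "pt_signals_reports.tsv", artifacts)
    sig <- pt_res[pt_res$joint, , drop = FALSE]
    signal_lists$reports <- sig
    artifacts <- write_artifact(
      sig[order(-sig$a, -xtfrm(sig$ebgm), sig$event), ],
      config$out_dir, "pt_signal_list_by_count.tsv", artifacts)
    artifacts <- write_artifact(
      sig[order(-xtfrm(sig$ror), sig$event), ],
      config$out_dir, "pt_signal_list_by_ror.tsv", artifacts)

    if (!is.null(config$soc_map_path)) {
      artifacts <- pipeline_stage("signals_soc", artifacts, {
        soc_map <- read_soc_map(config$soc_map_path)
        soc_tables <- build_soc_tables(reports, config$drug, soc_map,
                                       config$synonyms)
        soc_res <- apply_thresholds(signal_stats(soc_tables), th)
        soc_res <- soc_res[order(-soc_res$a, soc_res$event), , drop = FALSE]
        write_artifact(soc_res, config$out_dir, "soc_signals.tsv", artifacts)
      })
    }

    artifacts <- pipeline_stage("onset_time", artifacts, {
      sample <- compute_onset(target,
                              outlier_cap = config$tto$outlier_cap %||% Inf)
      results$onset <- sample
      summ <- onset_summary(sample, bins = config$tto$bins %||% c(30, 60, 90, 180, 360))
      a2 <- write_artifact(summ$summary, config$out_dir, "tto_summary.tsv",
                           artifacts)
      a2 <- write_artifact(summ$bins, config$out_dir, "tto_bins.tsv", a2)
      wf <- fit_weibull(sample,
                        zero_policy = config$tto$zero_policy %||% "half_day")
      results$weibull <- wf
      a2 <- write_artifact(
        dplyr::bind_cols(tidy(wf), glance(wf)[c("n", "failure_type")]),
        config$out_dir, "weibull.tsv", a2)
      write_artifact(km_estimate(sample), config$out_dir, "km_curve.tsv", a2)
    })

    for (strat in config$stratifications) {
      artifacts <- pipeline_stage(paste0("subgroup_", strat), artifacts, {
        strata <- stratify(target, strat)
        a2 <- artifacts
        for (nm in names(strata)) {
          # within-stratum rerun uses the stratum of the full database so
          # comparator margins stay stratum-consistent
          full_strata <- stratify(reports, strat)
          res <- tryCatch(
            rerun_stratified_signals(full_strata[[nm]], config$drug,
                                     thresholds = th,
                                     synonyms = config$synonyms),
            error = function(e) NULL
          )
          if (!is.null(res)) {
            a2 <- write_artifact(res, config$out_dir,
                                 paste0("stratified_", strat, "_", nm, ".tsv"),
                                 a2)
          }
        }
        a2
      })
    }
  }

  for (nm in names(config$aggregate_paths)) {
    artifacts <- pipeline_stage(paste0("signals_", nm), artifacts, {
      agg <- read_aggregate_counts(config$aggregate_paths[[nm]])
      tables <- build_pt_tables(agg, config$drug)
      res <- apply_thresholds(signal_stats(tables), th)
      res <- res[order(-res$a, -xtfrm(res$ebgm), res$event), , drop = FALSE]
      signal_lists[[nm]] <- res[res$joint, , drop = FALSE]
      write_artifact(res, config$out_dir, paste0("pt_signals_", nm, ".tsv"),
                     artifacts)
    })
  }

  if (length(signal_lists) >= 2) {
    overlap <- intersect_signals(signal_lists[[1]], signal_lists[[2]])
    results$overlap <- overlap
    overlap_tbl <- tibble(
      set = c("shared", paste0("only_", names(signal_lists)[1]),
              paste0("only_", names(signal_lists)[2])),
      n = c(overlap$n_shared, overlap$n_only_x, overlap$n_only_y),
      events = c(paste(overlap$shared, collapse = "|"),
                 paste(overlap$only_x, collapse = "|"),
                 paste(overlap$only_y, collapse = "|"))
    )
    artifacts <- write_artifact(overlap_tbl, config$out_dir, "overlap.tsv",
                                artifacts)
    shared_sig <- signal_lists[[1]][signal_lists[[1]]$event %in% overlap$shared, ]
  } else if (length(signal_lists) == 1) {
    shared_sig <- signal_lists[[1]]
  } else {
    shared_sig <- NULL
  }

  if (!is.null(shared_sig) && !is.null(config$label_pts_path)) {
    label_pts <- trimws(readLines(config$label_pts_path, warn = FALSE))
    label_pts <- label_pts[nzchar(label_pts)]
    flagged <- flag_unlabeled(shared_sig, label_pts)
    results$n_unlabeled <- attr(flagged, "n_unlabeled")
    artifacts <- write_artifact(flagged, config$out_dir,
                                "signals_labeled_flag.tsv", artifacts)
  }
  results$signals <- signal_lists

  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    drug = config$drug,
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    tto = config$tto,
    stratifications = config$stratifications,
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
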