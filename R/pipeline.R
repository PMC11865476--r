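# End-to-end orchestration: simulate -> segment -> filter -> train/embed ->
# analyze -> report, driven by one YAML config. One global seed expands
# deterministically into per-stage seeds; a provenance record carries the
# config hash so outputs are traceable to the exact configuration; stage
# status is journalled so interrupted runs are detectable; re-running an
# identical config reproduces all tabular outputs bit for bit.

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or an equivalent named list, applies defaults,
#' and validates everything that can be checked before any compute: required
#' fields, class-mixture normalization, condition-effect parameters, filter
#' profile (name or readable YAML file), task name, and analysis settings.
#'
#' @param config YAML path or named list.
#' @return validated config list of class `run_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$output_dir)) stopf("config requires output_dir")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$channels)) config$channels <- c("DAPI", "EdU")
  config$channels <- unlist(config$channels)
  if (!"DAPI" %in% config$channels) stopf("channels must include DAPI")
  if (is.null(config$dialect)) config$dialect <- "mESC"
  config$dialect <- match.arg(config$dialect, c("mESC", "U2OS"))

  sim <- config$simulate
  if (is.null(sim)) stopf("config requires a simulate section")
  if (is.null(sim$n_fields)) sim$n_fields <- 4L
  if (is.null(sim$nuclei_per_field)) sim$nuclei_per_field <- 12L
  if (is.null(sim$class_mixture))
    sim$class_mixture <- list(early = 0.2, early_mid = 0.2, mid = 0.2,
                              mid_late = 0.2, late = 0.2)
  mix <- unlist(sim$class_mixture)
  if (any(!names(mix) %in% S_CLASSES))
    stopf("unknown class in class_mixture: %s",
          paste(setdiff(names(mix), S_CLASSES), collapse = ", "))
  if (is.null(sim$conditions)) sim$conditions <- list(control = list())
  sim$conditions <- lapply(sim$conditions, function(e)
    condition_effect(
      early_like_shift = if (is.null(e$early_like_shift)) 0 else e$early_like_shift,
      focus_count_multiplier = if (is.null(e$focus_count_multiplier)) 1 else e$focus_count_multiplier,
      artifact_rate = if (is.null(e$artifact_rate)) 0 else e$artifact_rate))
  config$simulate <- sim

  fl <- config$filter
  if (is.null(fl)) fl <- list(profile = config$dialect)
  if (!is.null(fl$profile_file)) {
    if (!file.exists(fl$profile_file))
      stopf("filter profile file '%s' does not exist", fl$profile_file)
    ov <- yaml::read_yaml(fl$profile_file)
    config$filter_profile <- do.call(filter_profile, c(list(name = "custom"), ov))
  } else {
    if (is.null(fl$profile)) fl$profile <- config$dialect
    config$filter_profile <- filter_profile(fl$profile)
  }
  config$filter <- fl

  if (is.null(config$task)) config$task <- "byol"
  config$task <- match.arg(config$task,
                           c("byol", "stage_classifier", "overall_classifier"))
  if (is.null(config$train)) config$train <- list()

  an <- config$analysis
  if (is.null(an)) an <- list()
  if (is.null(an$reference)) an$reference <- names(sim$conditions)[1]
  if (!an$reference %in% names(sim$conditions))
    stopf("analysis reference '%s' is not a configured condition", an$reference)
  if (is.null(an$rule) && is.null(an$quantile))
    an$quantile <- list(axis = "PC1", q = 0.9)
  config$analysis <- an
  structure(config, class = c("run_config", "list"))
}

# canonical md5 of the validated config (profile objects flattened)
config_hash <- function(config) {
  canon <- unclass(config)
  canon$filter_profile <- unclass(canon$filter_profile)
  canon$simulate$conditions <- lapply(canon$simulate$conditions, unclass)
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(canon, f)
  unname(tools::md5sum(f))
}

write_status <- function(dir, status) {
  yaml::write_yaml(status, file.path(dir, "pipeline_status.yaml"))
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages, in order: `simulate` (write a synthetic dataset), `segment`
#' (label nuclei per field, extract crops, match to ground truth by
#' centroid), `filter` (quality-control metrics + profile filters), `embed`
#' (train the configured model and embed all passing nuclei), `analyze`
#' (common-PC projection and threshold-proportion tests against the
#' reference condition), `report` (CSV tables and JSON summary). Each stage's
#' seed derives from the global `seed`; `pipeline_status.yaml` journals stage
#' completion and a failure halts the run with the failing stage marked.
#' `provenance.json` records the config hash and per-stage seeds.
#'
#' @param config YAML path or list accepted by [pipeline_config()].
#' @return (invisibly) list with `output_dir`, `provenance`, `analysis`
#'   (threshold-proportion results), and `report_paths`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seeds <- list(simulate = child_seed(config$seed, 1L),
                split = child_seed(config$seed, 2L),
                train = child_seed(config$seed, 3L))
  provenance <- list(config_hash = hash, seed = config$seed,
                     stage_seeds = seeds, task = config$task,
                     package_version = tryCatch(
                       as.character(utils::packageVersion("replistage")),
                       error = function(e) "dev"))
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  status <- list(config_hash = hash,
                 stages = list(simulate = "pending", segment = "pending",
                               filter = "pending", embed = "pending",
                               analyze = "pending", report = "pending"))
  write_status(out, status)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      status$stages[[name]] <<- paste("failed:", conditionMessage(e))
      write_status(out, status)
      stopf("pipeline halted at stage '%s': %s", name, conditionMessage(e))
    })
    status$stages[[name]] <<- "complete"
    write_status(out, status)
    res
  }

  # -- simulate ---------------------------------------------------------
  ds <- stage("simulate", function() {
    generate_dataset(file.path(out, "dataset"),
                     n_fields = config$simulate$n_fields,
                     nuclei_per_field = config$simulate$nuclei_per_field,
                     conditions = config$simulate$conditions,
                     class_mixture = unlist(config$simulate$class_mixture),
                     rng_seed = seeds$simulate, channels = config$channels,
                     dialect = config$dialect, overwrite = TRUE)
    read_dataset(file.path(out, "dataset"))
  })

  # -- segment ----------------------------------------------------------
  seg <- stage("segment", function() {
    recs <- list(); rows <- list(); k <- 0L
    for (fid in names(ds$fields)) {
      f <- ds$fields[[fid]]
      labels <- segment_field(f$field)
      rr <- extract_records(f$field, labels, crop_size_px = 80L, field_id = fid)
      truth <- ds$manifest[ds$manifest$field_id == fid, ]
      for (r in rr) {
        k <- k + 1L
        d <- sqrt((truth$centroid_row - r$props$centroid["row"])^2 +
                  (truth$centroid_col - r$props$centroid["col"])^2)
        j <- which.min(d)
        matched <- if (length(j) && d[j] <= 20) truth$id[j] else NA_character_
        r$labels$truth_id <- matched
        recs[[k]] <- r
        rows[[k]] <- data.frame(
          record = k, field_id = fid, label = r$source$label,
          centroid_row = unname(r$props$centroid["row"]),
          centroid_col = unname(r$props$centroid["col"]),
          area = r$props$area, truth_id = matched, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out, "segmentation.csv"), row.names = FALSE)
    list(records = recs, table = tab)
  })

  # -- filter -----------------------------------------------------------
  flt <- stage("filter", function() {
    recs <- lapply(seg$records, compute_qc)
    tab <- filter_records(recs, config$filter_profile)
    tab <- cbind(seg$table[, c("field_id", "label", "truth_id")], tab)
    utils::write.csv(tab, file.path(out, "filter_results.csv"), row.names = FALSE)
    list(records = recs[tab$pass], table = tab)
  })
  if (!length(flt$records)) stopf("no nuclei passed the quality filters")

  # -- embed ------------------------------------------------------------
  emb <- stage("embed", function() {
    keep <- flt$table[flt$table$pass, ]
    imgs <- array(0, c(80, 80, length(config$channels), length(flt$records)),
                  dimnames = list(NULL, NULL, config$channels, NULL))
    for (i in seq_along(flt$records)) imgs[, , , i] <- flt$records[[i]]$crop
    mi <- match(keep$truth_id, ds$manifest$id)
    meta <- data.frame(truth_id = keep$truth_id,
                       s_class = ds$manifest$s_class[mi],
                       condition = ds$manifest$condition[mi],
                       stringsAsFactors = FALSE)
    tr <- config$train
    if (config$task == "byol") {
      cfg <- byol_config(
        input_side = if (is.null(tr$input_side)) 32L else as.integer(tr$input_side),
        steps = if (is.null(tr$steps)) 150L else as.integer(tr$steps),
        batch_size = if (is.null(tr$batch_size)) 32L else as.integer(tr$batch_size),
        projection_size = if (is.null(tr$projection_size)) 32L else as.integer(tr$projection_size),
        projection_hidden_size = if (is.null(tr$projection_hidden_size)) 128L
                                 else as.integer(tr$projection_hidden_size),
        seed = seeds$train)
      model <- train_byol(imgs, cfg)
    } else {
      lab <- if (config$task == "stage_classifier") meta$s_class else NULL
      if (config$task == "overall_classifier") {
        man <- data.frame(s_class = meta$s_class,
                          artifact_class = "none", stringsAsFactors = FALSE)
        cfg <- train_config(
          input_side = if (is.null(tr$input_side)) 32L else as.integer(tr$input_side),
          max_epochs = if (is.null(tr$max_epochs)) 20L else as.integer(tr$max_epochs),
          seed = seeds$train)
        model <- train_overall_classifier(imgs, man, cfg, split_seed = seeds$split)
      } else {
        if (any(is.na(lab)))
          stopf("stage_classifier task requires every passing nucleus to match ground truth")
        sp <- stratified_split(lab, seed = seeds$split)
        cfg <- train_config(
          input_side = if (is.null(tr$input_side)) 32L else as.integer(tr$input_side),
          max_epochs = if (is.null(tr$max_epochs)) 20L else as.integer(tr$max_epochs),
          seed = seeds$train)
        model <- train_classifier(imgs[, , , sp$train, drop = FALSE], lab[sp$train],
                                  imgs[, , , sp$val, drop = FALSE], lab[sp$val], cfg)
      }
    }
    E <- embed_images(model, imgs)
    tab <- data.frame(truth_id = keep$truth_id, field_id = keep$field_id,
                      label = keep$label, condition = meta$condition,
                      s_class = meta$s_class, stringsAsFactors = FALSE)
    utils::write.csv(cbind(tab, as.data.frame(E)),
                     file.path(out, "embeddings.csv"), row.names = FALSE)
    list(model = model, embeddings = E, meta = tab)
  })

  # -- analyze ----------------------------------------------------------
  ana <- stage("analyze", function() {
    meta <- emb$meta
    ref <- config$analysis$reference
    is_ref <- meta$condition == ref
    if (sum(is_ref) < 4) stopf("too few reference nuclei for analysis")
    basis <- fit_pca(emb$embeddings[is_ref, , drop = FALSE])
    pc <- project_embeddings(emb$embeddings, basis)
    utils::write.csv(cbind(meta, pc), file.path(out, "pc_coordinates.csv"),
                     row.names = FALSE)
    if (!is.null(config$analysis$rule)) {
      rule <- do.call(threshold_rule, config$analysis$rule)
      grp <- meta$condition
      keep_rows <- rep(TRUE, nrow(pc))
    } else {
      q <- config$analysis$quantile
      # hold out half the reference set to choose the threshold, so the
      # compared reference nuclei are not the ones the cut was fit on
      ref_idx <- which(is_ref)
      hold <- ref_idx[seq_len(floor(length(ref_idx) / 2))]
      rule <- quantile_threshold_rule(pc[hold, , drop = FALSE],
                                      axis = q$axis, q = q$q)
      keep_rows <- !seq_len(nrow(pc)) %in% hold
      grp <- meta$condition
    }
    res <- threshold_proportions(pc[keep_rows, , drop = FALSE],
                                 grp[keep_rows], rule,
                                 pairs = lapply(setdiff(unique(grp), ref),
                                                function(g) c(ref, g)))
    jsonlite::write_json(res, file.path(out, "analysis.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res
  })

  # -- report -----------------------------------------------------------
  paths <- stage("report", function() {
    meta <- emb$meta
    csv <- file.path(out, "class_report.csv")
    pdf <- file.path(out, "class_report.pdf")
    known <- !is.na(meta$s_class)
    if (length(unique(meta$condition[known])) >= 2 &&
        length(unique(meta$s_class[known])) >= 2) {
      class_distribution_report(meta$s_class[known], meta$condition[known],
                                csv_path = csv, plot_path = pdf)
    } else {
      utils::write.csv(as.data.frame(table(class = meta$s_class[known],
                                           condition = meta$condition[known])),
                       csv, row.names = FALSE)
      pdf <- NULL
    }
    list(class_report_csv = csv, class_report_pdf = pdf,
         analysis_json = file.path(out, "analysis.json"))
  })

  invisible(list(output_dir = out, provenance = provenance,
                 analysis = ana, report_paths = paths))
}

#' Pipeline command-line entry point
#'
#' Thin subcommand dispatcher used by the installed CLI script
#' (`system.file("cli", "replistage.R", package = "replistage")`).
#' Subcommands: `simulate`, `segment`, `filter`, `train`, `byol-train`,
#' `embed`, `analyze`, `report` each run the full pipeline up to and
#' including that stage's outputs; `run` executes everything. All take
#' `--config <yaml>`; `simulate` alone needs only the `simulate` section.
#'
#' @param args character vector of command-line arguments.
#' @return exit code, invisibly (0 on success).
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "segment", "filter", "train", "byol-train",
                   "embed", "analyze", "report", "run")
  if (!length(args) || !args[1] %in% subcommands) {
    cat("usage: replistage.R <", paste(subcommands, collapse = "|"),
        "> --config <yaml>\n")
    return(invisible(1L))
  }
  sub <- args[1]
  cfg_i <- which(args == "--config")
  if (!length(cfg_i) || cfg_i + 1 > length(args))
    stopf("missing --config <yaml>")
  config <- pipeline_config(args[cfg_i + 1])
  if (sub == "simulate") {
    generate_dataset(file.path(config$output_dir, "dataset"),
                     n_fields = config$simulate$n_fields,
                     nuclei_per_field = config$simulate$nuclei_per_field,
                     conditions = config$simulate$conditions,
                     class_mixture = unlist(config$simulate$class_mixture),
                     rng_seed = child_seed(config$seed, 1L),
                     channels = config$channels, dialect = config$dialect,
                     overwrite = TRUE)
  } else {
    if (sub == "train") config$task <- "stage_classifier"
    if (sub == "byol-train") config$task <- "byol"
    run_pipeline(config)
  }
  invisible(0L)
}
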