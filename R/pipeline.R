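# Pipeline orchestration: simulate -> extract -> score -> analyze, with a
# manifest recording config hash, seeds and row counts at every stage.

#' Load and validate a run configuration
#'
#' The run config is a YAML file (or an equivalent named list) with the
#' sections `seed` (master seed), `out_dir`, optional `dataset_dir` (an
#' existing cohort; defaults to `<out_dir>/cohort`, which `simulate`
#' creates), `extraction` (overrides for [extraction_config()]), `cohort`
#' (overrides for [cohort_spec()]), and `analysis`
#' (`include_brightness`, `auc_anchor`). Every random stage consumes a seed
#' derived from the master seed and its stage label via [stage_seed()].
#'
#' @param config Path to a YAML file, a named list, or `NULL` for defaults.
#' @param seed,out_dir Optional overrides of the config values.
#' @return Object of class `run_config`.
#' @export
run_config <- function(config = NULL, seed = NULL, out_dir = NULL) {
  cfg <- if (is.null(config)) list()
         else if (is.character(config)) yaml::read_yaml(config)
         else if (is.list(config)) config
         else stop("config must be a YAML path or a named list",
                   call. = FALSE)
  defaults <- list(seed = 1L, out_dir = "viewfeat_run", dataset_dir = NULL,
                   extraction = list(), cohort = list(),
                   analysis = list(include_brightness = FALSE,
                                   auc_anchor = TRUE))
  cfg <- modifyList(defaults, cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$dataset_dir))
    cfg$dataset_dir <- file.path(cfg$out_dir, "cohort")
  cfg$extraction <- as_extraction_config(cfg$extraction)
  structure(cfg, class = "run_config")
}

#' Run the window-view pipeline
#'
#' Stages: `simulate` renders a synthetic cohort to `dataset_dir`;
#' `extract` computes per-image and per-participant features; `score`
#' computes the negative-affect composite and the discounting indifference
#' points/AUC; `analyze` builds the analysis table, the Spearman matrix and
#' the two stepwise regression designs; `all` runs all four. A manifest
#' (`manifest.json`) accumulates the config hash, the master and stage
#' seeds, and row counts including exclusion bookkeeping.
#'
#' @param stage One of `"simulate"`, `"extract"`, `"score"`, `"analyze"`,
#'   `"all"`.
#' @param config Passed to [run_config()].
#' @param seed,out_dir Optional overrides.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "extract", "score",
                                   "analyze"),
                         config = NULL, seed = NULL, out_dir = NULL) {
  stage <- match.arg(stage)
  cfg <- run_config(config, seed, out_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") c("simulate", "extract", "score", "analyze")
            else stage
  for (s in stages) {
    message("[viewfeat] stage: ", s)
    switch(s,
           simulate = stage_simulate(cfg),
           extract = stage_extract(cfg),
           score = stage_score(cfg),
           analyze = stage_analyze(cfg))
  }
  invisible(read_manifest(cfg$out_dir))
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

update_manifest <- function(cfg, stage, info) {
  man <- read_manifest(cfg$out_dir)
  man$config_hash <- digest::digest(list(unclass(cfg$extraction),
                                         cfg$cohort, cfg$analysis,
                                         cfg$seed))
  man$master_seed <- cfg$seed
  man$stages[[stage]] <- c(list(seed = stage_seed(cfg$seed, stage)), info)
  jsonlite::write_json(man, manifest_path(cfg$out_dir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(man)
}

write_csv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  write.csv(x, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

read_csv_checked <- function(path, required = NULL) {
  if (!file.exists(path)) stop("missing artifact: ", path, call. = FALSE)
  d <- tryCatch(read.csv(path),
                error = function(e) stop("malformed CSV ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (!is.null(required)) {
    miss <- setdiff(required, names(d))
    if (length(miss))
      stop("CSV ", path, " lacks columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  d
}

stage_simulate <- function(cfg) {
  spec <- do.call(cohort_spec,
                  modifyList(cfg$cohort,
                             list(seed = stage_seed(cfg$seed, "simulate"))))
  res <- generate_cohort(spec, cfg$dataset_dir)
  update_manifest(cfg, "simulate",
                  list(n_participants = spec$n_participants,
                       n_images = sum(res$demographics$image_count)))
}

stage_extract <- function(cfg) {
  feats <- extract_cohort_features(cfg$dataset_dir, cfg$extraction)
  write_csv_atomic(feats$per_image,
                   file.path(cfg$out_dir, "features_per_image.csv"))
  write_csv_atomic(feats$per_participant,
                   file.path(cfg$out_dir, "features_per_participant.csv"))
  update_manifest(cfg, "extract",
                  list(n_images = nrow(feats$per_image),
                       n_participants = nrow(feats$per_participant),
                       n_sky_missing = sum(is.na(feats$per_image$sky_ratio))))
}

stage_score <- function(cfg) {
  demo <- read_csv_checked(file.path(cfg$dataset_dir, "demographics.csv"),
                           "participant_id")
  out <- data.frame(participant_id = demo$participant_id)
  stadi_path <- file.path(cfg$dataset_dir, "stadi_items.csv")
  st <- read_csv_checked(stadi_path, c("participant_id",
                                       paste0("item_", 1:20)))
  na_scores <- data.frame(
    participant_id = st$participant_id,
    negative_affect = apply(st[, paste0("item_", 1:20)], 1L,
                            function(r) score_stadi(as.integer(r))))
  ch <- read_csv_checked(file.path(cfg$dataset_dir, "choices.csv"),
                         c("participant_id", "delay_label", "trial_index",
                           "choice"))
  auc_tab <- score_choice_log(ch, anchor = isTRUE(cfg$analysis$auc_anchor))
  out <- merge(out, na_scores, by = "participant_id", all.x = TRUE)
  out <- merge(out, auc_tab, by = "participant_id", all.x = TRUE)
  out <- out[order(out$participant_id), ]
  write_csv_atomic(out, file.path(cfg$out_dir, "outcomes.csv"))
  update_manifest(cfg, "score",
                  list(n_participants = nrow(out),
                       n_missing_negative_affect =
                         sum(is.na(out$negative_affect)),
                       n_missing_auc = sum(is.na(out$auc))))
}

#' Assemble the participant-level analysis table
#'
#' Joins ratings, demographics, per-participant averaged features and
#' scored outcomes into the one-row-per-participant table the statistical
#' designs consume.
#'
#' @param cfg A [run_config()] whose `extract` and `score` artifacts exist.
#' @return Data frame, one row per participant.
#' @export
build_analysis_table <- function(cfg) {
  ratings <- read_csv_checked(file.path(cfg$dataset_dir, "ratings.csv"),
                              c("participant_id", "pct_nature",
                                "pct_manmade", "pct_sky"))
  demo <- read_csv_checked(file.path(cfg$dataset_dir, "demographics.csv"),
                           c("participant_id", "sex"))
  feats <- read_csv_checked(file.path(cfg$out_dir,
                                      "features_per_participant.csv"),
                            c("participant_id", feature_names()))
  outc <- read_csv_checked(file.path(cfg$out_dir, "outcomes.csv"),
                           c("participant_id", "negative_affect", "auc"))
  tab <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                list(ratings, demo, feats[, c("participant_id",
                                              feature_names())]))
  tab <- merge(tab, outc[, c("participant_id", "negative_affect", "auc")],
               by = "participant_id", all.x = TRUE)
  bad <- with(tab, pct_nature + pct_manmade + pct_sky != 100)
  if (any(bad))
    stop("composition does not sum to 100 for: ",
         paste(tab$participant_id[bad], collapse = ", "), call. = FALSE)
  tab
}

stage_analyze <- function(cfg) {
  tab <- build_analysis_table(cfg)
  write_csv_atomic(tab, file.path(cfg$out_dir, "analysis_table.csv"))
  include_b <- isTRUE(cfg$analysis$include_brightness)
  roles <- analysis_roles(include_b)
  corr_tab <- encode_analysis_table(exclude_participants(tab))
  sm <- spearman_matrix(corr_tab, c(roles$ratings, roles$llvf))
  write_csv_atomic(data.frame(variable = rownames(sm$rho), sm$rho),
                   file.path(cfg$out_dir, "correlations_rho.csv"))
  write_csv_atomic(data.frame(variable = rownames(sm$p), sm$p),
                   file.path(cfg$out_dir, "correlations_p.csv"))
  dA <- design_A_feature_models(tab, include_b)
  dB <- design_B_outcome_models(tab, include_b)
  traces <- list()
  for (crit in names(dA)) for (st in c("stage1", "stage2")) {
    m <- dA[[crit]][[st]]
    write_model_csv(m, file.path(cfg$out_dir,
                                 sprintf("model_%s_%s.csv", crit, st)))
    traces[[paste(crit, st, sep = "_")]] <- m$trace
  }
  for (oc in names(dB)) {
    write_model_csv(dB[[oc]],
                    file.path(cfg$out_dir, sprintf("model_%s.csv", oc)))
    traces[[oc]] <- dB[[oc]]$trace
  }
  jsonlite::write_json(traces, file.path(cfg$out_dir,
                                         "selection_traces.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  n_total <- nrow(tab)
  n_analyzed <- nrow(exclude_participants(tab))
  update_manifest(cfg, "analyze", list(
    n_total = n_total,
    n_after_diverse_exclusion = n_analyzed,
    n_negative_affect_model = dB$negative_affect$n,
    n_auc_model = dB$auc$n,
    include_brightness = include_b))
}

write_model_csv <- function(m, path) {
  tab <- m$table
  tab$adj_r2 <- m$adj_r2
  tab$aic <- m$aic
  tab$n <- m$n
  write_csv_atomic(tab, path)
}

#' Summarize a completed pipeline run
#'
#' Prints the exclusion bookkeeping, the strongest Spearman correlations
#' and every selected regression model of a completed `analyze` stage.
#'
#' @param out_dir The run's output directory.
#' @return Invisibly, a list with the manifest, correlation matrix and
#'   model tables.
#' @export
report_run <- function(out_dir) {
  man <- read_manifest(out_dir)
  if (is.null(man$stages$analyze))
    stop("incomplete run: missing analyze stage artifacts in ", out_dir,
         call. = FALSE)
  rho <- read_csv_checked(file.path(out_dir, "correlations_rho.csv"))
  models <- list.files(out_dir, pattern = "^model_.*\\.csv$",
                       full.names = TRUE)
  cat("viewfeat run:", out_dir, "\n")
  an <- man$stages$analyze
  cat(sprintf("participants: %d simulated, %d after diverse-sex exclusion\n",
              an$n_total, an$n_after_diverse_exclusion))
  cat(sprintf("model Ns: negative affect %d, discounting AUC %d\n",
              an$n_negative_affect_model, an$n_auc_model))
  if (isTRUE(an$include_brightness))
    cat("NOTE: objective brightness features were force-included;",
        "they are flagged unreliable for ecological photographs\n")
  tabs <- list()
  for (f in models) {
    cat("\n--", basename(f), "--\n")
    tabs[[basename(f)]] <- read_csv_checked(f)
    print(tabs[[basename(f)]], row.names = FALSE)
  }
  invisible(list(manifest = man, rho = rho, models = tabs))
}
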