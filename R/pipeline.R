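#' Build an experiment configuration
#'
#' Collects every tunable element of an end-to-end synthetic experiment:
#' stimulus factor levels, ROI presets, cohort and design sizes, decoding
#' and RSA settings. The configuration is a plain list and serialises to
#' YAML or JSON with round-trip identity (\code{\link{write_config}}).
#'
#' @param numbers,item_areas,field_areas stimulus factor levels.
#' @param rois character vector of preset names, or a named list of
#'   \code{roi_preset} objects.
#' @param n_subjects,n_runs cohort and design size.
#' @param k,cost voxel count and SVM regularization for decoding/RSA.
#' @param rsa_models RSA model variants to fit.
#' @param tasks task labels.
#' @return list of class \code{"experiment_config"}.
#' @export
experiment_config <- function(numbers = c(6, 10, 17),
                              item_areas = c(0.04, 0.07, 0.12),
                              field_areas = c(20, 44),
                              rois = c("early", "intermediate", "higher"),
                              n_subjects = 20L, n_runs = 6L,
                              k = 800L, cost = 1,
                              rsa_models = c("full", "orthogonal_only",
                                             "non_numerical_only"),
                              tasks = c("number", "size")) {
  cfg <- list(numbers = numbers, item_areas = item_areas,
              field_areas = field_areas, rois = rois,
              n_subjects = as.integer(n_subjects),
              n_runs = as.integer(n_runs), k = as.integer(k), cost = cost,
              rsa_models = rsa_models, tasks = tasks)
  structure(cfg, class = c("experiment_config", "list"))
}

#' Write / read an experiment configuration
#'
#' @param config an \code{experiment_config}.
#' @param path output file; the format follows the extension
#'   (\code{.yaml}/\code{.yml} or \code{.json}).
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$rois <- if (is.list(cfg$rois)) lapply(cfg$rois, unclass) else cfg$rois
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, cfg)
}

resolve_presets <- function(rois, n_voxels = NULL) {
  if (is.character(rois)) {
    presets <- lapply(rois, function(nm) {
      if (is.null(n_voxels)) roi_preset(nm) else roi_preset(nm, n_voxels = n_voxels)
    })
    names(presets) <- rois
  } else {
    stopifnot(all(vapply(rois, inherits, TRUE, "roi_preset")))
    presets <- rois
    if (is.null(names(presets)))
      names(presets) <- vapply(presets, `[[`, "", "name")
  }
  presets
}

#' Audit the quantity design
#'
#' One-stop design diagnostics: the condition grid, the condition-level
#' correlations between all pairs of quantity dimensions, the 5 x 5
#' predictor-RDM correlation matrix, and the predictor VIFs.
#'
#' @param config an \code{experiment_config} (stimulus levels are taken
#'   from it); or pass levels directly via \code{...} to
#'   \code{\link{condition_grid}}.
#' @param ... overrides forwarded to \code{condition_grid}.
#' @return list of class \code{"design_audit"} with components
#'   \code{grid}, \code{dimension_correlations},
#'   \code{predictor_correlations}, \code{vifs}.
#' @export
audit_design <- function(config = experiment_config(), ...) {
  grid <- condition_grid(numbers = config$numbers,
                         item_areas = config$item_areas,
                         field_areas = config$field_areas, ...)
  dims <- quantity_dimensions
  dc <- matrix(NA_real_, length(dims), length(dims),
               dimnames = list(dims, dims))
  for (i in seq_along(dims)) {
    for (j in seq_along(dims)) {
      dc[i, j] <- tryCatch(dimension_correlation(grid, dims[i], dims[j]),
                           error = function(e) NA_real_)
    }
  }
  preds <- tryCatch(predictor_rdms(grid), error = function(e) NULL)
  pc <- if (!is.null(preds))
    tryCatch(predictor_correlations(preds), error = function(e) NULL)
  vifs <- if (!is.null(preds))
    tryCatch(rdm_vif(preds), error = function(e) NULL)
  structure(list(grid = grid, dimension_correlations = dc,
                 predictor_correlations = pc, vifs = vifs),
            class = "design_audit")
}

#' @export
print.design_audit <- function(x, ...) {
  cat("=== Condition grid ===\n")
  print(x$grid)
  cat("\n=== Condition-level dimension correlations ===\n")
  print(round(x$dimension_correlations, 3))
  if (!is.null(x$predictor_correlations)) {
    cat("\n=== Predictor-RDM correlations (153-pair vectors) ===\n")
    print(round(x$predictor_correlations, 3))
  }
  if (!is.null(x$vifs)) {
    cat("\n=== Predictor VIFs ===\n")
    print(round(x$vifs, 4))
  } else {
    cat("\nPredictor correlations/VIFs undefined for this design\n")
  }
  invisible(x)
}

#' Run a full synthetic experiment
#'
#' End-to-end pipeline for one cohort: for each ROI preset, simulates
#' beta patterns, then per subject selects voxels, decodes numerosity in
#' both tasks (and the task label), and fits the RSA regression per task
#' and model variant; finally computes group statistics (paired task
#' contrasts per dimension, repeated-measures ANOVA of decoding accuracy
#' over ROI x task, linear trend of the number beta across ROIs). The
#' entire run is deterministic given \code{seed}: ROI- and subject-level
#' streams are derived with \code{\link{derive_seed}}.
#'
#' @param config an \code{experiment_config}.
#' @param seed master seed.
#' @param out_dir optional directory; when given, per-subject decoding and
#'   RSA tables, group tables and the config are persisted as CSV/JSON.
#' @return object of class \code{"experiment_report"} with elements
#'   \code{decoding} (roi x task means +/- SEM), \code{rsa_betas}
#'   (roi x task x dimension means +/- SEM), \code{subject_decoding},
#'   \code{subject_betas} (tidy per-subject tables), \code{stats} (group
#'   tests), \code{provenance}.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           out_dir = NULL) {
  stim <- condition_grid(config$numbers, config$item_areas,
                         config$field_areas)
  presets <- resolve_presets(config$rois)
  preds <- predictor_rdms(stim)

  subj_dec <- list()
  subj_beta <- list()
  for (ri in seq_along(presets)) {
    roi_name <- names(presets)[ri]
    roi_seed <- derive_seed(seed, ri)
    pop <- make_population(presets[[ri]], seed = roi_seed,
                           stimulus_set = stim)
    ds <- simulate_betas(pop, stim, tasks = config$tasks,
                         n_subjects = config$n_subjects,
                         n_runs = config$n_runs,
                         seed = derive_seed(roi_seed, 1L))
    for (tk in config$tasks) {
      dec <- pairwise_number_decoding(ds, tk, k = config$k,
                                      cost = config$cost)
      subj_dec[[length(subj_dec) + 1L]] <-
        data.frame(roi = roi_name, task = tk,
                   subject = dec$subjects,
                   accuracy = unname(dec$mean_accuracy))
      for (s in seq_len(config$n_subjects)) {
        vox <- select_voxels(ds, s, config$k)
        nr <- neural_rdm(ds, s, tk, voxels = vox)
        for (mod in config$rsa_models) {
          fit <- rsa_fit(nr, preds, model = mod)
          subj_beta[[length(subj_beta) + 1L]] <-
            data.frame(roi = roi_name, task = tk, subject = s, model = mod,
                       dimension = names(fit$betas),
                       beta = unname(fit$betas),
                       r_squared = fit$r_squared)
        }
      }
    }
  }
  subj_dec <- do.call(rbind, subj_dec)
  subj_beta <- do.call(rbind, subj_beta)

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  decoding <- stats::aggregate(accuracy ~ roi + task, subj_dec, mean)
  decoding$sem <- stats::aggregate(accuracy ~ roi + task, subj_dec,
                                   sem)$accuracy
  full_beta <- subj_beta[subj_beta$model == "full", ]
  rsa_betas <- stats::aggregate(beta ~ roi + task + dimension, full_beta,
                                mean)
  rsa_betas$sem <- stats::aggregate(beta ~ roi + task + dimension,
                                    full_beta, sem)$beta

  stats_out <- group_statistics(subj_dec, full_beta, names(presets),
                                config$tasks)

  provenance <- list(seed = seed,
                     config_hash = config_digest(config),
                     package_version =
                       as.character(utils::packageVersion("quantsep")),
                     n_subjects = config$n_subjects)
  report <- structure(list(decoding = decoding, rsa_betas = rsa_betas,
                           subject_decoding = subj_dec,
                           subject_betas = subj_beta,
                           stats = stats_out, provenance = provenance),
                      class = "experiment_report")
  if (!is.null(out_dir)) persist_report(report, config, out_dir)
  report
}

group_statistics <- function(subj_dec, full_beta, roi_names, tasks) {
  out <- list()
  # task contrast on each dimension's beta, per ROI
  rows <- list()
  for (roi in roi_names) {
    for (dm in unique(full_beta$dimension)) {
      sub <- full_beta[full_beta$roi == roi & full_beta$dimension == dm, ]
      a <- sub$beta[sub$task == tasks[1]][order(sub$subject[sub$task == tasks[1]])]
      b <- sub$beta[sub$task == tasks[2]][order(sub$subject[sub$task == tasks[2]])]
      tt <- paired_t_with_d(a, b)
      rows[[length(rows) + 1L]] <-
        data.frame(roi = roi, dimension = dm, t = tt$t, df = tt$df,
                   p = tt$p, cohens_d = tt$cohens_d)
    }
  }
  out$beta_task_contrasts <- do.call(rbind, rows)
  # decoding accuracy vs chance per roi/task
  rows <- list()
  for (roi in roi_names) {
    for (tk in tasks) {
      v <- subj_dec$accuracy[subj_dec$roi == roi & subj_dec$task == tk]
      ht <- one_sample_t(v, 0.5)
      rows[[length(rows) + 1L]] <-
        data.frame(roi = roi, task = tk, t = ht$t, df = ht$df, p = ht$p)
    }
  }
  out$decoding_vs_chance <- do.call(rbind, rows)
  # rm ANOVA of accuracy over roi x task (needs >= 2 rois)
  if (length(roi_names) >= 2) {
    out$decoding_anova <- rm_anova(subj_dec, dv = "accuracy",
                                   within = c("roi", "task"))
  }
  # linear trend of the number beta across rois per task (needs >= 3 rois)
  if (length(roi_names) >= 3) {
    rows <- list()
    for (tk in tasks) {
      means <- vapply(roi_names, function(roi)
        mean(full_beta$beta[full_beta$roi == roi & full_beta$task == tk &
                              full_beta$dimension == "number"]), 0)
      lt <- linear_trend(means)
      rows[[length(rows) + 1L]] <-
        data.frame(task = tk, F = lt$F, df1 = lt$df1, df2 = lt$df2,
                   p = lt$p, r_squared = lt$r_squared)
    }
    out$number_beta_trend <- do.call(rbind, rows)
  }
  out
}

# stable digest of a config: serialised canonical JSON, summed bytes
config_digest <- function(config) {
  cfg <- unclass(config)
  if (is.list(cfg$rois)) cfg$rois <- lapply(cfg$rois, unclass)
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(bytes * seq_along(bytes)) %% 4294967291)
}

persist_report <- function(report, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  utils::write.csv(fmt(report$decoding),
                   file.path(out_dir, "decoding_group.csv"), row.names = FALSE)
  utils::write.csv(fmt(report$rsa_betas),
                   file.path(out_dir, "rsa_betas_group.csv"), row.names = FALSE)
  utils::write.csv(report$subject_decoding,
                   file.path(out_dir, "decoding_subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(report$subject_betas,
                   file.path(out_dir, "rsa_betas_subjects.csv"),
                   row.names = FALSE)
  for (nm in names(report$stats))
    utils::write.csv(fmt(report$stats[[nm]]),
                     file.path(out_dir, paste0("stats_", nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(out_dir, "config.json"))
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Synthetic quantity-separation experiment",
      sprintf("(n = %d, seed %s, config %s)\n",
              x$provenance$n_subjects, x$provenance$seed,
              x$provenance$config_hash))
  cat("\nMean numerosity decoding accuracy (+/- SEM):\n")
  print(transform(x$decoding, accuracy = round(accuracy, 3),
                  sem = round(sem, 4)), row.names = FALSE)
  cat("\nGroup RSA betas (full model), number dimension:\n")
  nb <- x$rsa_betas[x$rsa_betas$dimension == "number", ]
  print(transform(nb, beta = round(beta, 3), sem = round(sem, 4)),
        row.names = FALSE)
  invisible(x)
}
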