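#' ROI presets for the encoding-model simulator
#'
#' Archetypal voxel-population presets standing in for regions along the
#' dorsal visual stream. Each preset fixes, for a pool of \code{n_voxels}
#' voxels: the mixture of voxels tuned to each quantity dimension, the
#' response weight of each tuned sub-population, the task-dependent
#' multiplicative attention gain \eqn{\gamma} applied to each dimension's
#' sub-population, and the run-noise standard deviation.
#'
#' \itemize{
#'   \item \code{"early"}: dominated by extensive magnitudes (field area,
#'     surface area, density) with a weak numerosity population; attention
#'     gains all 1 (no task modulation).
#'   \item \code{"intermediate"}: mixed, with a moderate numerosity
#'     population whose gain in the number task is 1.4.
#'   \item \code{"higher"}: numerosity-dominated; the numerosity
#'     population's gain is 1.6 in the number task and 1 in the size task,
#'     all other gains task-equal.
#' }
#'
#' Any component can be overridden through \code{...}; \code{name =
#' "custom"} starts from the "intermediate" template.
#'
#' The default run-noise level (\code{noise_sd = 6}, response units) is
#' calibrated so that the "higher" preset yields number-task pairwise
#' numerosity decoding in the 0.6--0.8 accuracy band with 800 selected
#' voxels, the regime the analysis is designed for.
#'
#' @param name preset name.
#' @param ... overrides for \code{n_voxels}, \code{mixture},
#'   \code{weights}, \code{attention_gain}, \code{noise_sd},
#'   \code{baseline}, \code{number_tuning_width}.
#' @return an object of class \code{"roi_preset"}.
#' @export
roi_preset <- function(name = c("early", "intermediate", "higher", "custom"),
                       ...) {
  name <- match.arg(name)
  base <- switch(name,
    early = list(
      mixture = c(number = 0.15, avg_item_area = 0, total_field_area = 0.30,
                  total_surface_area = 0.20, density = 0.20, none = 0.15),
      gain_number_task = 1.0),
    intermediate = , custom = list(
      mixture = c(number = 0.35, avg_item_area = 0, total_field_area = 0.15,
                  total_surface_area = 0.10, density = 0.15, none = 0.25),
      gain_number_task = 1.4),
    higher = list(
      mixture = c(number = 0.50, avg_item_area = 0, total_field_area = 0.08,
                  total_surface_area = 0.05, density = 0.12, none = 0.25),
      gain_number_task = 1.6))
  dims <- quantity_dimensions
  gain <- matrix(1, 2, length(dims),
                 dimnames = list(c("number", "size"), dims))
  gain["number", "number"] <- base$gain_number_task
  preset <- list(
    name = name,
    n_voxels = 1000L,
    mixture = base$mixture,
    weights = c(number = 1, avg_item_area = 1, total_field_area = 1,
                total_surface_area = 1, density = 1),
    attention_gain = gain,
    noise_sd = 6.0,
    baseline = 1.0,
    number_tuning_width = 0.35)
  over <- list(...)
  bad <- setdiff(names(over), names(preset))
  if (length(bad)) stop("unknown preset fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  preset[names(over)] <- over
  validate_preset(preset)
  structure(preset, class = "roi_preset")
}

validate_preset <- function(p) {
  if (abs(sum(p$mixture) - 1) > 1e-8)
    stop("mixture proportions must sum to 1", call. = FALSE)
  if (any(p$mixture < 0)) stop("mixture proportions must be >= 0", call. = FALSE)
  if (any(p$attention_gain <= 0)) stop("attention gains must be > 0", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$n_voxels < 1) stop("n_voxels must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.roi_preset <- function(x, ...) {
  cat(sprintf("ROI preset '%s': %d voxels, noise sd %.2f\n",
              x$name, x$n_voxels, x$noise_sd))
  cat("  mixture: ",
      paste(sprintf("%s %.2f", names(x$mixture), x$mixture), collapse = ", "),
      "\n")
  g <- x$attention_gain
  mod <- which(g["number", ] != g["size", ])
  if (length(mod))
    cat("  task-modulated gains:",
        paste(sprintf("%s (number task %.2f / size task %.2f)",
                      colnames(g)[mod], g["number", mod], g["size", mod]),
              collapse = ", "), "\n")
  else cat("  attention gains task-equal\n")
  invisible(x)
}

#' Sample a tuned voxel population
#'
#' Allocates the preset's voxel pool to dimension-tuned sub-populations by
#' largest-remainder apportionment (deterministic counts, not multinomial)
#' and samples each voxel's tuning. Numerosity voxels are log-Gaussian
#' tuned with preferred values uniform on the log numerosity range extended
#' by one tuning width on each side; voxels tuned to the extensive
#' magnitudes are log-linear with random slope sign; \code{"none"} voxels
#' respond at baseline only.
#'
#' @param preset an \code{roi_preset}.
#' @param seed integer seed.
#' @param stimulus_set stimulus set whose numerosity levels anchor the
#'   preferred-value range (default the standard grid).
#' @return data frame of class \code{"voxel_population"}: one row per voxel
#'   with columns \code{dimension}, \code{form}, \code{preferred_log_value},
#'   \code{width}, \code{slope}, \code{weight}, \code{baseline}.
#' @export
make_population <- function(preset, seed = 1L,
                            stimulus_set = condition_grid()) {
  stopifnot(inherits(preset, "roi_preset"))
  validate_preset(preset)
  counts <- largest_remainder(preset$mixture, preset$n_voxels)
  dims <- rep(names(counts), counts)
  n <- length(dims)
  lognum <- log(range(attr(stimulus_set, "factor_levels")$numbers))
  w <- preset$number_tuning_width
  pop <- with_seed(seed, {
    pref <- ifelse(dims == "number",
                   stats::runif(n, lognum[1] - w, lognum[2] + w), NA_real_)
    slope <- ifelse(dims %in% c("number", "none"), NA_real_,
                    sample(c(-1, 1), n, replace = TRUE))
    data.frame(
      dimension = dims,
      form = ifelse(dims == "number", "log_gaussian",
                    ifelse(dims == "none", "none", "log_linear")),
      preferred_log_value = pref,
      width = ifelse(dims == "number", w, NA_real_),
      slope = slope,
      weight = ifelse(dims == "none", 0, preset$weights[dims]),
      baseline = preset$baseline,
      stringsAsFactors = FALSE)
  })
  structure(pop, preset = preset, class = c("voxel_population", "data.frame"))
}

# deterministic apportionment of n units to proportions p
largest_remainder <- function(p, n) {
  exact <- p * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    take <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# noise-free mean response of each voxel to each condition under a task:
# baseline + gain * weight * f(dimension value); returns conditions x voxels
population_response <- function(population, stimulus_set, task) {
  preset <- attr(population, "preset")
  if (!task %in% rownames(preset$attention_gain))
    stop("unknown task '", task, "'", call. = FALSE)
  nc <- nrow(stimulus_set)
  nv <- nrow(population)
  resp <- matrix(population$baseline, nc, nv, byrow = TRUE)
  logvals <- lapply(stimulus_set[quantity_dimensions], log)
  # normalisation anchors for log-linear tuning: midpoint and half-range
  mids <- vapply(logvals, function(v) mean(range(v)), 0)
  halfr <- vapply(logvals, function(v) diff(range(v)) / 2, 0)
  for (d in quantity_dimensions) {
    idx <- which(population$dimension == d)
    if (!length(idx)) next
    g <- preset$attention_gain[task, d]
    v <- logvals[[d]]
    if (d == "number") {
      f <- exp(-outer(v, population$preferred_log_value[idx], "-")^2 /
                 (2 * population$width[idx][1]^2))
    } else {
      u <- if (halfr[d] > 0) (v - mids[d]) / halfr[d] else v * 0
      f <- outer(u, population$slope[idx])
    }
    resp[, idx] <- resp[, idx] +
      g * matrix(population$weight[idx], nc, length(idx), byrow = TRUE) * f
  }
  resp
}

#' Simulate beta-like voxel patterns for a cohort
#'
#' Generates one beta pattern per subject, task, run and condition:
#' the population's noise-free tuned response under the task's attention
#' gains plus i.i.d. Gaussian run noise. Per-subject noise streams are
#' derived from the master seed with \code{\link{derive_seed}}, so a cohort
#' can be extended without changing earlier subjects.
#'
#' @param population a \code{voxel_population} from
#'   \code{\link{make_population}}.
#' @param stimulus_set a \code{stimulus_set}.
#' @param tasks tasks to simulate (rows of the preset's gain matrix).
#' @param n_subjects,n_runs cohort and design size (defaults 20 and 6).
#' @param seed master integer seed.
#' @return object of class \code{"beta_dataset"}: list with \code{values}
#'   (5-d array subject x task x run x condition x voxel),
#'   \code{stimulus_set}, \code{preset}, \code{tasks},
#'   \code{subject_seeds}.
#' @export
simulate_betas <- function(population, stimulus_set = condition_grid(),
                           tasks = c("number", "size"), n_subjects = 20L,
                           n_runs = 6L, seed = 1L) {
  stopifnot(inherits(population, "voxel_population"),
            n_subjects >= 1, n_runs >= 1)
  preset <- attr(population, "preset")
  nc <- nrow(stimulus_set)
  nv <- nrow(population)
  mu <- lapply(tasks, function(tk)
    population_response(population, stimulus_set, tk))
  names(mu) <- tasks
  values <- array(NA_real_,
                  dim = c(n_subjects, length(tasks), n_runs, nc, nv),
                  dimnames = list(NULL, tasks, NULL, stimulus_set$label, NULL))
  subject_seeds <- vapply(seq_len(n_subjects), function(i)
    derive_seed(seed, i), 0L)
  for (i in seq_len(n_subjects)) {
    noise <- with_seed(subject_seeds[i],
      array(stats::rnorm(length(tasks) * n_runs * nc * nv, 0, preset$noise_sd),
            dim = c(length(tasks), n_runs, nc, nv)))
    for (t in seq_along(tasks)) {
      for (r in seq_len(n_runs)) {
        values[i, t, r, , ] <- mu[[tasks[t]]] + noise[t, r, , ]
      }
    }
  }
  structure(list(values = values, stimulus_set = stimulus_set,
                 preset = preset, tasks = tasks,
                 subject_seeds = subject_seeds),
            class = "beta_dataset")
}

#' @export
print.beta_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Beta dataset ('%s' preset): %d subjects x %d tasks x %d runs x %d conditions x %d voxels\n",
              x$preset$name, d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Persist / load a beta dataset as a directory of CSVs
#'
#' Writes a JSON sidecar (preset, tasks, seeds, condition labels) and one
#' CSV per subject and task with rows = run x condition and columns =
#' voxels.
#'
#' @param dataset a \code{beta_dataset}.
#' @param dir output directory (created if needed).
#' @export
write_beta_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "beta_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$values)
  meta <- list(preset = unclass(dataset$preset), tasks = dataset$tasks,
               subject_seeds = dataset$subject_seeds,
               n_subjects = d[1], n_runs = d[3],
               labels = dataset$stimulus_set$label)
  meta$preset$attention_gain <- as.data.frame(dataset$preset$attention_gain)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  write_stimulus_set(dataset$stimulus_set, file.path(dir, "stimulus_set.csv"))
  for (i in seq_len(d[1])) {
    for (t in seq_along(dataset$tasks)) {
      m <- matrix(dataset$values[i, t, , , ], d[3] * d[4], d[5])
      df <- data.frame(run = rep(seq_len(d[3]), d[4]),
                       condition = rep(dataset$stimulus_set$label,
                                       each = d[3]))
      df <- cbind(df, as.data.frame(m))
      utils::write.csv(df,
                       file.path(dir, sprintf("sub%02d_%s.csv", i,
                                              dataset$tasks[t])),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_beta_dataset
#' @export
read_beta_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  set <- read_stimulus_set(file.path(dir, "stimulus_set.csv"))
  tasks <- meta$tasks
  ns <- meta$n_subjects; nr <- meta$n_runs
  nc <- nrow(set)
  first <- utils::read.csv(file.path(dir, sprintf("sub01_%s.csv", tasks[1])))
  nv <- ncol(first) - 2L
  values <- array(NA_real_, dim = c(ns, length(tasks), nr, nc, nv),
                  dimnames = list(NULL, tasks, NULL, set$label, NULL))
  for (i in seq_len(ns)) {
    for (t in seq_along(tasks)) {
      df <- utils::read.csv(file.path(dir, sprintf("sub%02d_%s.csv", i,
                                                   tasks[t])))
      m <- as.matrix(df[, -(1:2)])
      values[i, t, , , ] <- array(m, dim = c(nr, nc, nv))
    }
  }
  preset <- meta$preset
  preset$attention_gain <- as.matrix(preset$attention_gain)
  rownames(preset$attention_gain) <- tasks
  preset$mixture <- unlist(preset$mixture)
  preset$weights <- unlist(preset$weights)
  class(preset) <- "roi_preset"
  structure(list(values = values, stimulus_set = set, preset = preset,
                 tasks = tasks, subject_seeds = meta$subject_seeds),
            class = "beta_dataset")
}
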