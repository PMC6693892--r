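#' Select the most responsive voxels
#'
#' Synthetic analogue of selecting, per subject, the voxels responding most
#' strongly to an orthogonal all-stimuli-versus-baseline localizer
#' contrast: ranks voxels by their grand-mean response across all tasks,
#' runs and conditions and returns the top \code{k}. The grand mean is
#' orthogonal to any condition difference, so selection does not bias later
#' decoding. Ties break deterministically towards the lowest voxel index.
#'
#' @param dataset a \code{beta_dataset}.
#' @param subject subject index.
#' @param k number of voxels to keep (default 800).
#' @return integer vector of voxel indices, in selection order.
#' @export
select_voxels <- function(dataset, subject = 1L, k = 800L) {
  stopifnot(inherits(dataset, "beta_dataset"))
  nv <- dim(dataset$values)[5]
  if (k > nv)
    stop("k = ", k, " exceeds the ", nv, "-voxel pool", call. = FALSE)
  v <- dataset$values[subject, , , , , drop = FALSE]
  means <- apply(v, 5, mean)
  order(-means)[seq_len(k)]
}

#' Voxel-wise mean centering
#'
#' Subtracts each voxel's mean across all rows (patterns) of the matrix,
#' the voxel-wise scaling applied before both decoding and neural-RDM
#' construction. Centering preserves all pairwise pattern distances and is
#' idempotent.
#'
#' @param patterns numeric matrix, rows = patterns, columns = voxels.
#' @return the centered matrix.
#' @export
mean_center <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2L)
    stop("need >= 2 patterns to mean-center", call. = FALSE)
  sweep(patterns, 2, colMeans(patterns))
}

# patterns for one subject/task as a (run x condition) x voxel matrix with
# run/condition row metadata
subject_patterns <- function(dataset, subject, task, voxels = NULL) {
  t_idx <- match(task, dataset$tasks)
  if (is.na(t_idx)) stop("unknown task '", task, "'", call. = FALSE)
  d <- dim(dataset$values)
  v <- dataset$values[subject, t_idx, , , , drop = FALSE]
  m <- matrix(v, d[3] * d[4], d[5])
  if (!is.null(voxels)) m <- m[, voxels, drop = FALSE]
  list(x = m,
       run = rep(seq_len(d[3]), d[4]),
       condition = rep(seq_len(d[4]), each = d[3]))
}

# linear SVM train/test for one fold; decision values exactly 0 are ties
# and count as errors
svm_fold_accuracy <- function(x_train, y_train, x_test, y_test, cost) {
  fit <- e1071::svm(x_train, factor(y_train), kernel = "linear",
                    cost = cost, scale = FALSE, type = "C-classification")
  pred <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  correct <- as.character(pred) == as.character(y_test)
  correct[abs(dv[, 1]) < .Machine$double.eps] <- FALSE
  mean(correct)
}

#' Leave-one-run-out pairwise numerosity decoding
#'
#' For every pair of numerosity levels, trains a linear support vector
#' machine (regularization C = \code{cost}) to discriminate the two
#' numerosities from voxel patterns, collapsing across item size and field
#' area, and tests it on the held-out run of a leave-one-run-out
#' cross-validation cycle. Patterns are voxel-wise mean-centered across
#' the full (run x condition) matrix before cross-validation (set
#' \code{fold_center = TRUE} for stricter fold-wise centering computed on
#' the training runs only).
#'
#' @param dataset a \code{beta_dataset}.
#' @param task task whose patterns are decoded.
#' @param subjects subject indices (default all).
#' @param k voxels retained by \code{\link{select_voxels}}.
#' @param cost SVM regularization parameter C.
#' @param fold_center compute the centering means within each training fold.
#' @return object of class \code{"decoding_result"}: list with
#'   \code{pair_accuracies} (subjects x pairs matrix),
#'   \code{mean_accuracy} (per subject, unweighted mean over pairs),
#'   \code{task}, \code{n_folds}, \code{chance} = 0.5.
#' @export
pairwise_number_decoding <- function(dataset, task, subjects = NULL,
                                     k = 800L, cost = 1, fold_center = FALSE) {
  stopifnot(inherits(dataset, "beta_dataset"))
  d <- dim(dataset$values)
  if (d[3] < 2L) stop("need >= 2 runs for cross-validation", call. = FALSE)
  if (is.null(subjects)) subjects <- seq_len(d[1])
  numbers <- dataset$stimulus_set$number
  levels <- sort(unique(numbers))
  if (length(levels) < 2L) stop("need >= 2 numerosity levels", call. = FALSE)
  pairs <- utils::combn(levels, 2)
  pair_names <- apply(pairs, 2, function(p) paste(p, collapse = "v"))

  acc <- matrix(NA_real_, length(subjects), ncol(pairs),
                dimnames = list(subjects, pair_names))
  for (si in seq_along(subjects)) {
    vox <- select_voxels(dataset, subjects[si], k)
    sp <- subject_patterns(dataset, subjects[si], task, vox)
    x <- if (fold_center) sp$x else mean_center(sp$x)
    y_num <- numbers[sp$condition]
    for (pi in seq_len(ncol(pairs))) {
      keep <- y_num %in% pairs[, pi]
      acc[si, pi] <- loro_accuracy(x[keep, , drop = FALSE],
                                   factor(y_num[keep]), sp$run[keep],
                                   cost, fold_center)
    }
  }
  structure(list(pair_accuracies = acc,
                 mean_accuracy = rowMeans(acc),
                 subjects = subjects, task = task,
                 n_folds = d[3], chance = 0.5,
                 kind = "numerosity"),
            class = "decoding_result")
}

loro_accuracy <- function(x, y, run, cost, fold_center) {
  runs <- sort(unique(run))
  fold_acc <- vapply(runs, function(r) {
    tr <- run != r
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (fold_center) {
      mu <- colMeans(xtr)
      xtr <- sweep(xtr, 2, mu)
      xte <- sweep(xte, 2, mu)
    }
    if (length(unique(y[tr])) < 2L)
      stop("unbalanced runs: a training fold lacks one class", call. = FALSE)
    svm_fold_accuracy(xtr, y[tr], xte, y[!tr], cost)
  }, 0)
  mean(fold_acc)
}

#' Leave-one-run-out task decoding
#'
#' Trains a linear SVM to discriminate which task the subject performed,
#' collapsing across all stimulus conditions, with the same leave-one-run-
#' out protocol as \code{\link{pairwise_number_decoding}}.
#'
#' @inheritParams pairwise_number_decoding
#' @return a \code{"decoding_result"} with a single "pair" (task vs task).
#' @export
task_decoding <- function(dataset, subjects = NULL, k = 800L, cost = 1,
                          fold_center = FALSE) {
  stopifnot(inherits(dataset, "beta_dataset"))
  d <- dim(dataset$values)
  if (length(dataset$tasks) < 2L) stop("need >= 2 tasks", call. = FALSE)
  if (is.null(subjects)) subjects <- seq_len(d[1])
  acc <- matrix(NA_real_, length(subjects), 1,
                dimnames = list(subjects,
                                paste(dataset$tasks, collapse = "v")))
  for (si in seq_along(subjects)) {
    vox <- select_voxels(dataset, subjects[si], k)
    mats <- lapply(dataset$tasks, function(tk)
      subject_patterns(dataset, subjects[si], tk, vox))
    x <- do.call(rbind, lapply(mats, `[[`, "x"))
    y <- factor(rep(dataset$tasks, vapply(mats, function(m) nrow(m$x), 0L)))
    run <- unlist(lapply(mats, `[[`, "run"))
    if (!fold_center) x <- mean_center(x)
    acc[si, 1] <- loro_accuracy(x, y, run, cost, fold_center)
  }
  structure(list(pair_accuracies = acc, mean_accuracy = acc[, 1],
                 subjects = subjects, task = "task-label",
                 n_folds = d[3], chance = 0.5, kind = "task"),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Leave-one-run-out %s decoding (%d folds, chance %.2f)\n",
              x$kind, x$n_folds, x$chance))
  cat(sprintf("  %d subject(s); group mean accuracy %.3f (SEM %.3f)\n",
              nrow(x$pair_accuracies), mean(x$mean_accuracy),
              stats::sd(x$mean_accuracy) /
                sqrt(max(1, length(x$mean_accuracy)))))
  if (ncol(x$pair_accuracies) > 1) {
    cat("  pair means:",
        paste(sprintf("%s %.3f", colnames(x$pair_accuracies),
                      colMeans(x$pair_accuracies)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy data frame of decoding accuracies
#'
#' @param x a \code{decoding_result}.
#' @param ... unused.
#' @return data frame with columns subject, task, pair, accuracy.
#' @export
as.data.frame.decoding_result <- function(x, ...) {
  data.frame(subject = rep(x$subjects, ncol(x$pair_accuracies)),
             task = x$task,
             pair = rep(colnames(x$pair_accuracies), each = nrow(x$pair_accuracies)),
             accuracy = as.vector(x$pair_accuracies),
             stringsAsFactors = FALSE)
}

#' Write a decoding result as tidy CSV plus a JSON summary
#'
#' @param result a \code{decoding_result}.
#' @param csv_path,json_path output paths (either may be NULL).
#' @export
write_decoding_result <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "decoding_result"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(result), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(task = result$task, n_folds = result$n_folds,
           mean_accuracy = unname(result$mean_accuracy),
           subjects = result$subjects),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(result)
}
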