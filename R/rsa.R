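#' Construct an RDM object
#'
#' @param m symmetric dissimilarity matrix with zero diagonal.
#' @param labels condition labels.
#' @param kind \code{"neural"} or \code{"predictor:<dimension>"}.
#' @return matrix of class \code{"rdm"}.
#' @keywords internal
new_rdm <- function(m, labels, kind) {
  stopifnot(nrow(m) == ncol(m), nrow(m) == length(labels))
  if (max(abs(m - t(m))) > 1e-10) stop("RDM must be symmetric", call. = FALSE)
  if (any(abs(diag(m)) > 1e-12)) stop("RDM diagonal must be zero", call. = FALSE)
  if (any(!is.finite(m))) stop("RDM entries must be finite", call. = FALSE)
  dimnames(m) <- list(labels, labels)
  structure(m, kind = kind, class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, digits = 3, ...) {
  cat(sprintf("%s RDM, %d x %d conditions\n", attr(x, "kind"), nrow(x), ncol(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Neural representational dissimilarity matrix
#'
#' Builds the correlation-distance RDM (1 - Pearson correlation across
#' voxels) between the condition activity patterns of one subject and task.
#' Patterns are run-averaged to one pattern per condition, restricted to
#' the \code{k} most responsive voxels (\code{\link{select_voxels}}), and
#' voxel-wise mean-centered across conditions before the correlation
#' distance is computed.
#'
#' @param dataset a \code{beta_dataset}.
#' @param subject subject index.
#' @param task task label.
#' @param k number of selected voxels.
#' @param voxels optional explicit voxel indices (overrides \code{k}).
#' @return an \code{"rdm"} with entries in \code{[0, 2]}.
#' @export
neural_rdm <- function(dataset, subject = 1L, task, k = 800L, voxels = NULL) {
  stopifnot(inherits(dataset, "beta_dataset"))
  if (is.null(voxels)) voxels <- select_voxels(dataset, subject, k)
  sp <- subject_patterns(dataset, subject, task, voxels)
  nc <- nrow(dataset$stimulus_set)
  # run-average to one pattern per condition
  pat <- rowsum(sp$x, sp$condition) / tabulate(sp$condition, nc)
  pat <- mean_center(pat)
  sds <- apply(pat, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance pattern for condition ",
         paste(dataset$stimulus_set$label[sds == 0], collapse = ", "),
         call. = FALSE)
  m <- 1 - stats::cor(t(pat))
  diag(m) <- 0
  new_rdm(m, dataset$stimulus_set$label, "neural")
}

#' Log-distance predictor RDM for one quantity dimension
#'
#' Model dissimilarity matrix whose (i, j) entry is the absolute difference
#' of the dimension's values on a logarithmic scale,
#' \code{|log v_i - log v_j|}. Regression weights downstream are invariant
#' to the base, absorbed by z-scoring; natural log is used.
#'
#' @param stimulus_set a \code{stimulus_set}.
#' @param dimension one of \code{quantity_dimensions}.
#' @return an \code{"rdm"}.
#' @export
predictor_rdm <- function(stimulus_set, dimension) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  dimension <- match.arg(dimension, quantity_dimensions)
  v <- stimulus_set[[dimension]]
  if (any(v <= 0))
    stop("dimension values must be strictly positive for log distances",
         call. = FALSE)
  lv <- log(v)
  new_rdm(abs(outer(lv, lv, "-")), stimulus_set$label,
          paste0("predictor:", dimension))
}

#' All five predictor RDMs of the quantity design
#'
#' @param stimulus_set a \code{stimulus_set}.
#' @param dimensions dimensions to include (default all five).
#' @return named list of \code{"rdm"}s.
#' @export
predictor_rdms <- function(stimulus_set, dimensions = quantity_dimensions) {
  stats::setNames(lapply(dimensions, predictor_rdm,
                         stimulus_set = stimulus_set), dimensions)
}

#' Scale an RDM to the unit interval
#'
#' Display convention: linearly maps entries to \code{[0, 1]} (the diagonal
#' stays 0). Regression and VIF computations use unscaled matrices.
#'
#' @param rdm an \code{"rdm"}.
#' @export
scale_01 <- function(rdm) {
  stopifnot(inherits(rdm, "rdm"))
  v <- upper_tri_vec(rdm)
  if (max(v) == min(v)) stop("constant RDM cannot be rescaled", call. = FALSE)
  m <- (unclass(rdm) - min(v)) / (max(v) - min(v))
  diag(m) <- 0
  new_rdm(m, rownames(rdm), attr(rdm, "kind"))
}

#' Correlations between predictor RDMs
#'
#' Product-moment correlations between the vectorised upper triangles
#' (153 condition pairs for the 18-condition design) of a set of RDMs —
#' the design's collinearity audit.
#'
#' @param rdms named list of \code{"rdm"}s sharing condition labels.
#' @return correlation matrix.
#' @export
predictor_correlations <- function(rdms) {
  v <- rdm_design_matrix(rdms)
  if (any(apply(v, 2, stats::sd) == 0))
    stop("constant predictor RDM: ",
         paste(colnames(v)[apply(v, 2, stats::sd) == 0], collapse = ", "),
         call. = FALSE)
  stats::cor(v)
}

rdm_design_matrix <- function(rdms) {
  stopifnot(is.list(rdms), length(rdms) >= 1)
  labs <- rownames(rdms[[1]])
  for (r in rdms)
    if (!identical(rownames(r), labs))
      stop("RDMs must share condition labels", call. = FALSE)
  sapply(rdms, upper_tri_vec)
}

#' Variance inflation factors of a predictor-RDM set
#'
#' For each predictor, regresses its z-scored upper-triangle vector on the
#' z-scored vectors of all remaining predictors (with intercept) and
#' returns \eqn{VIF = 1/(1 - R^2)}. Perfectly collinear predictors yield
#' \code{Inf} with a warning.
#'
#' @param rdms named list of at least two \code{"rdm"}s.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
rdm_vif <- function(rdms) {
  v <- rdm_design_matrix(rdms)
  if (ncol(v) < 2L) stop("need >= 2 predictors for VIFs", call. = FALSE)
  z <- apply(v, 2, zscore)
  out <- vapply(seq_len(ncol(z)), function(i) {
    fit <- stats::lm.fit(cbind(1, z[, -i, drop = FALSE]), z[, i])
    rss <- sum(fit$residuals^2)
    tss <- sum(z[, i]^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(v)
  if (any(!is.finite(out)))
    warning("perfectly collinear predictors: ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Multiple-regression representational similarity analysis
#'
#' Fits the central model of the package: ordinary least squares of the
#' z-scored neural dissimilarity vector (upper triangle of the neural RDM)
#' on the z-scored log-distance predictor vectors, with intercept. The
#' per-dimension beta weights quantify the variance in pattern
#' dissimilarity uniquely explained by each quantity dimension over and
#' above the others.
#'
#' Three model variants select predictor subsets by name:
#' \code{"full"} (all five dimensions), \code{"orthogonal_only"} (number,
#' average item area, total field area — the orthogonally manipulated
#' factors), \code{"non_numerical_only"} (all but number).
#'
#' @param neural a neural \code{"rdm"}.
#' @param predictors named list of predictor \code{"rdm"}s (typically
#'   \code{\link{predictor_rdms}}).
#' @param model predictor subset.
#' @param z_neural z-score the neural vector in addition to the predictors.
#'   The default (\code{FALSE}) standardises the predictors only: the
#'   neural dissimilarity vector is already on the common correlation-
#'   distance scale, and dividing it by its own standard deviation couples
#'   the dimensions' betas through a shared normaliser, so that a selective
#'   amplification of one dimension would artifactually deflate every other
#'   beta when comparing fits across tasks. With \code{z_neural = TRUE}
#'   betas are additionally invariant to affine rescaling of the neural
#'   RDM.
#' @return object of class \code{"rsa_fit"}: \code{betas},
#'   \code{r_squared}, \code{vifs}, \code{n_pairs}, \code{model},
#'   \code{fitted_values}, \code{residuals}, \code{neural_z}.
#' @examples
#' set <- condition_grid()
#' preds <- predictor_rdms(set)
#' # a neural RDM exactly equal to the number predictor recovers beta = 1
#' fit <- rsa_fit(preds$number, preds["number"], model = "full")
#' coef(fit)
#' @export
rsa_fit <- function(neural, predictors,
                    model = c("full", "orthogonal_only", "non_numerical_only"),
                    z_neural = FALSE) {
  model <- match.arg(model)
  keep <- switch(model,
    full = names(predictors),
    orthogonal_only = c("number", "avg_item_area", "total_field_area"),
    non_numerical_only = c("avg_item_area", "total_field_area",
                           "total_surface_area", "density"))
  missing_p <- setdiff(keep, names(predictors))
  if (length(missing_p))
    stop("model '", model, "' needs predictors: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  predictors <- predictors[keep]

  y <- upper_tri_vec(neural)
  v <- rdm_design_matrix(predictors)
  if (!identical(rownames(neural), rownames(predictors[[1]])))
    stop("neural and predictor RDMs must share condition labels", call. = FALSE)
  z <- apply(v, 2, zscore)
  yz <- if (z_neural) zscore(y) else y

  qrz <- qr(cbind(`(Intercept)` = 1, z))
  if (qrz$rank < ncol(z) + 1L) {
    stop("rank-deficient predictor set; collinear predictors among: ",
         paste(colnames(z), collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, z), yz)
  betas <- fit$coefficients[-1]
  res <- fit$residuals
  r2 <- 1 - sum(res^2) / sum((yz - mean(yz))^2)
  vifs <- if (ncol(z) >= 2) rdm_vif(predictors)
          else stats::setNames(1, colnames(z))
  structure(list(betas = betas, r_squared = r2, vifs = vifs,
                 n_pairs = length(y), model = model,
                 intercept = fit$coefficients[1],
                 fitted_values = fit$fitted.values, residuals = res,
                 neural_z = yz, design = z),
            class = "rsa_fit")
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat(sprintf("RSA multiple regression (%s model, %d condition pairs)\n",
              x$model, x$n_pairs))
  tab <- data.frame(beta = round(x$betas, 4), VIF = round(x$vifs, 4))
  print(tab)
  cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.rsa_fit <- function(object, ...) {
  n <- object$n_pairs
  p <- length(object$betas) + 1L
  sigma2 <- sum(object$residuals^2) / (n - p)
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, object$design))))
  se <- sqrt(sigma2 * diag(xtx_inv))[-1]
  tval <- object$betas / se
  out <- list(coefficients = cbind(beta = object$betas, se = se, t = tval,
                                   p = 2 * stats::pt(-abs(tval), n - p)),
              r_squared = object$r_squared, vifs = object$vifs,
              model = object$model, n_pairs = n)
  class(out) <- "summary.rsa_fit"
  out
}

#' @export
print.summary.rsa_fit <- function(x, ...) {
  cat(sprintf("RSA multiple regression (%s model, %d condition pairs)\n",
              x$model, x$n_pairs))
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared: %.4f\n", x$r_squared))
  cat("VIFs:", paste(sprintf("%s %.4f", names(x$vifs), x$vifs),
                     collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.rsa_fit <- function(object, ...) object$betas

#' @export
fitted.rsa_fit <- function(object, ...) object$fitted_values

#' @export
residuals.rsa_fit <- function(object, ...) object$residuals

#' Write an RDM as a CSV matrix with condition-label header
#'
#' @param rdm an \code{"rdm"}.
#' @param path file path.
#' @export
write_rdm <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm"))
  utils::write.csv(as.data.frame(unclass(rdm)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @param kind RDM kind recorded on reading.
#' @export
read_rdm <- function(path, kind = "neural") {
  df <- utils::read.csv(path, check.names = FALSE)
  new_rdm(as.matrix(df), colnames(df), kind)
}

#' Tidy per-dimension table of an RSA fit
#'
#' @param x an \code{rsa_fit}.
#' @param ... unused.
#' @export
as.data.frame.rsa_fit <- function(x, ...) {
  data.frame(model = x$model, dimension = names(x$betas),
             beta = unname(x$betas), vif = unname(x$vifs[names(x$betas)]),
             r_squared = x$r_squared, stringsAsFactors = FALSE)
}
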