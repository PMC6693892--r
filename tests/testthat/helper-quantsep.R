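# Shared fixtures and independent oracles for the test suite.

# Build a beta_dataset directly from a values array, bypassing the
# simulator, so decoding/RSA inputs can be controlled exactly.
# values: array [subject, task, run, condition, voxel]
toy_dataset <- function(values, stimulus_set, tasks = c("number", "size")) {
  stopifnot(length(dim(values)) == 5)
  dimnames(values) <- list(NULL, tasks[seq_len(dim(values)[2])], NULL,
                           stimulus_set$label, NULL)
  structure(list(values = values, stimulus_set = stimulus_set,
                 preset = roi_preset("custom", n_voxels = dim(values)[5]),
                 tasks = tasks[seq_len(dim(values)[2])],
                 subject_seeds = seq_len(dim(values)[1])),
            class = "beta_dataset")
}

# A small two-numerosity stimulus grid for decoding toys.
toy_grid <- function(numbers = c(6, 10)) {
  condition_grid(numbers = numbers, item_areas = 0.07, field_areas = 20)
}

# Independent soft-margin linear SVM oracle: minimises the primal
# 0.5*||w||^2 + C * sum(hinge) by Nelder-Mead from several starts.
# Returns the accuracy on the test set with decision-value ties counted
# as errors, mirroring the package convention.
brute_svm_accuracy <- function(x_train, y_train, x_test, y_test, C = 1) {
  y <- ifelse(y_train == sort(unique(y_train))[1], 1, -1)
  yt <- ifelse(y_test == sort(unique(y_train))[1], 1, -1)
  obj <- function(par) {
    w <- par[-length(par)]
    b <- par[length(par)]
    margins <- 1 - y * (drop(x_train %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(margins, 0))
  }
  p <- ncol(x_train) + 1
  best <- NULL
  set.seed(42)
  for (s in 1:8) {
    start <- if (s == 1) rep(0.01, p) else stats::rnorm(p, sd = 0.5)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  w <- best$par[-p]
  b <- best$par[p]
  dv <- drop(x_test %*% w) + b
  mean(sign(dv) == yt & dv != 0)
}

# Monte-Carlo estimate of a convex polygon's area by rejection sampling
# inside the bounding box; 'pts' are the polygon's defining points.
mc_hull_area <- function(pts, n = 400000, seed = 99) {
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  k <- nrow(poly)
  inside <- function(px, py) {
    s <- rep(TRUE, length(px))
    sgn <- NULL
    for (i in seq_len(k)) {
      j <- if (i == k) 1 else i + 1
      cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
            (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
      if (is.null(sgn)) sgn <- sign(sum(cr))
      s <- s & (cr * sgn >= 0)
    }
    s
  }
  set.seed(seed)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  px <- stats::runif(n, xr[1], xr[2])
  py <- stats::runif(n, yr[1], yr[2])
  mean(inside(px, py)) * diff(xr) * diff(yr)
}

# Closed-form one-sample t from first principles.
oracle_one_sample_t <- function(x, mu) {
  n <- length(x)
  t <- (mean(x) - mu) / (stats::sd(x) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}
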