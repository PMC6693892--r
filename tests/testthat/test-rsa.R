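test_that("neural RDM entries hit the closed-form correlation-distance bounds", {
  set <- condition_grid(c(6, 10, 17), 0.07, 20)  # 3 conditions
  nv <- 10
  set.seed(2)
  v <- rnorm(nv)
  vals <- array(0, c(1, 1, 2, 3, nv))
  vals[1, 1, , 1, ] <- rep(v, each = 2)
  vals[1, 1, , 2, ] <- rep(v, each = 2)        # identical to condition 1
  vals[1, 1, , 3, ] <- rep(-2 * v, each = 2)   # anti-correlated
  ds <- toy_dataset(vals, set, tasks = "number")
  rdm <- neural_rdm(ds, 1, "number", k = nv)
  expect_equal(rdm[1, 2], 0, tolerance = 1e-12)
  expect_equal(rdm[1, 3], 2, tolerance = 1e-12)
  expect_true(all(diag(rdm) == 0))
  expect_equal(unclass(rdm), t(unclass(rdm)))
})

test_that("independent patterns give null-level correlation distances", {
  set <- condition_grid()
  nc <- nrow(set)
  nv <- 10000
  set.seed(3)
  vals <- array(rnorm(nc * nv), c(1, 1, 1, nc, nv))
  ds <- toy_dataset(vals, set, tasks = "number")
  rdm <- neural_rdm(ds, 1, "number", k = nv)
  off <- upper.tri(rdm)
  # voxel-wise centering across nc conditions induces E[cor] = -1/(nc - 1),
  # so the null expectation of the correlation distance is 1 + 1/(nc - 1)
  expect_true(all(abs(rdm[off] - (1 + 1 / (nc - 1))) < 0.05))
  expect_true(all(rdm[off] >= 0 & rdm[off] <= 2))
})

test_that("zero-variance patterns are reported by condition", {
  set <- condition_grid(c(6, 10), 0.07, 20)
  vals <- array(rnorm(1 * 1 * 2 * 2 * 5), c(1, 1, 2, 2, 5))
  # second condition = first + constant: after voxel-wise centering both
  # condition patterns are flat, so their correlation is undefined
  vals[1, 1, , 2, ] <- vals[1, 1, , 1, ] + 7
  ds <- toy_dataset(vals, set, tasks = "number")
  expect_error(neural_rdm(ds, 1, "number", k = 5), "N2-S1-TFA1")
})

test_that("predictor RDMs are absolute log distances", {
  set <- condition_grid()
  num <- predictor_rdm(set, "number")
  i6 <- which(set$number == 6)[1]
  i17 <- which(set$number == 17)[1]
  i6b <- which(set$number == 6)[2]
  expect_equal(num[i6, i17], log(17 / 6), tolerance = 1e-12)
  expect_equal(num[i6, i17], 1.04145, tolerance = 1e-5)
  expect_equal(num[i6, i6b], 0)
  expect_equal(max(upper_tri <- scale_01(num)), 1)
  expect_equal(min(diag(scale_01(num))), 0)
})

test_that("predictor correlations match an exhaustive pair-enumeration oracle", {
  set <- condition_grid()
  preds <- predictor_rdms(set)
  pc <- predictor_correlations(preds)
  expect_equal(diag(pc), setNames(rep(1, 5), quantity_dimensions))

  # independent brute-force: loop over all 153 pairs, accumulate sums
  oracle_cor <- function(va, vb) {
    xa <- c(); xb <- c()
    n <- length(va)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        xa <- c(xa, abs(log(va[i]) - log(va[j])))
        xb <- c(xb, abs(log(vb[i]) - log(vb[j])))
      }
    }
    sxy <- sum((xa - mean(xa)) * (xb - mean(xb)))
    sxy / sqrt(sum((xa - mean(xa))^2) * sum((xb - mean(xb))^2))
  }
  expect_equal(length(upper_tri_153 <- combn(18, 2)[1, ]), 153)
  expect_equal(pc["number", "density"],
               oracle_cor(set$number, set$density), tolerance = 1e-12)
  expect_equal(pc["number", "total_surface_area"],
               oracle_cor(set$number, set$total_surface_area),
               tolerance = 1e-12)
})

test_that("VIFs satisfy their regression definition", {
  set <- condition_grid()
  preds <- predictor_rdms(set)
  vifs <- rdm_vif(preds)
  expect_true(all(vifs >= 1))
  # definitional oracle through lm(): regress one z-scored vector on the rest
  z <- scale(sapply(preds, function(r) t(unclass(r))[lower.tri(r)]))
  for (d in c("number", "density")) {
    r2 <- summary(lm(z[, d] ~ z[, setdiff(colnames(z), d)]))$r.squared
    expect_equal(unname(vifs[d]), 1 / (1 - r2), tolerance = 1e-9)
  }
  # orthogonal toy predictors (zero-correlation 6-pair vectors) have VIF 1
  labs <- letters[1:4]
  mk <- function(v, k) {
    m <- matrix(0, 4, 4)
    m <- t(`[<-`(t(m), lower.tri(m), v - min(v)))
    m <- m + t(m)
    quantsep:::new_rdm(m, labs, k)
  }
  r1 <- mk(c(1, -1, 0, 0, 1, -1), "predictor:a")
  r2m <- mk(c(1, 1, -1, -1, 0, 0), "predictor:b")
  v <- rdm_vif(list(a = r1, b = r2m))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)
  # duplicated predictor flagged as infinite
  expect_warning(vdup <- rdm_vif(list(a = r1, b = r1)), "collinear")
  expect_true(all(!is.finite(vdup)))
})

test_that("a neural RDM equal to one z-scored predictor is exactly recovered", {
  set <- condition_grid()
  preds <- predictor_rdms(set)
  zvec <- scale(upper_tri_vec(preds$number))[, 1]
  m <- matrix(0, 18, 18)
  m[lower.tri(m)] <- 0  # fill upper triangle in row-major pair order
  m <- t(`[<-`(t(m), lower.tri(m), zvec))
  m <- m + t(m)
  neural <- quantsep:::new_rdm(m, set$label, "neural")
  fit <- rsa_fit(neural, preds, model = "full")
  expect_equal(unname(fit$betas["number"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$betas[names(fit$betas) != "number"])), 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_pairs, 153)
})

test_that("generative mixtures of predictors are recovered on average", {
  set <- condition_grid()
  preds <- predictor_rdms(set)
  z <- scale(sapply(preds, upper_tri_vec))
  rec <- matrix(NA_real_, 100, 2)
  for (s in 1:100) {
    set.seed(700 + s)
    y <- 0.6 * z[, "number"] + 0.3 * z[, "total_field_area"] +
      rnorm(153, sd = 0.1)
    m <- matrix(0, 18, 18)
    m <- t(`[<-`(t(m), lower.tri(m), y))
    m <- m + t(m)
    fit <- rsa_fit(quantsep:::new_rdm(m, set$label, "neural"), preds)
    rec[s, ] <- fit$betas[c("number", "total_field_area")]
  }
  expect_lt(abs(mean(rec[, 1]) - 0.6), 0.05)
  expect_lt(abs(mean(rec[, 2]) - 0.3), 0.05)
})

test_that("betas are invariant to the predictor log base and neural rescaling", {
  set <- condition_grid()
  preds <- predictor_rdms(set)
  # a different log base scales every predictor RDM by a constant;
  # z-scoring absorbs it
  preds10 <- lapply(preds, function(r)
    quantsep:::new_rdm(unclass(r) / log(10), rownames(r), attr(r, "kind")))
  set.seed(11)
  y <- rnorm(153)
  m <- matrix(0, 18, 18)
  m <- t(`[<-`(t(m), lower.tri(m), y))
  m <- m + t(m)
  neural <- quantsep:::new_rdm(m, set$label, "neural")
  f1 <- rsa_fit(neural, preds)
  f2 <- rsa_fit(neural, preds10)
  expect_equal(f1$betas, f2$betas, tolerance = 1e-10)

  # affine rescaling of the neural RDM leaves z-scored fits unchanged
  neural2 <- quantsep:::new_rdm({mm <- 3 * m + 5; diag(mm) <- 0; mm},
                                set$label, "neural")
  fz1 <- rsa_fit(neural, preds, z_neural = TRUE)
  fz2 <- rsa_fit(neural2, preds, z_neural = TRUE)
  expect_equal(fz1$betas, fz2$betas, tolerance = 1e-10)
  expect_equal(fz1$r_squared, fz2$r_squared, tolerance = 1e-10)
})

test_that("orthogonal predictors reduce multiple regression to simple correlation", {
  labs <- letters[1:4]
  # build two exactly orthogonal (in the 6-pair vector sense) predictors
  v1 <- c(1, -1, 0, 0, 1, -1)
  v2 <- c(1, 1, -1, -1, 0, 0)
  stopifnot(abs(cor(v1, v2)) < 1e-12)
  mk <- function(v, k) {
    m <- matrix(0, 4, 4)
    m <- t(`[<-`(t(m), lower.tri(m), v - min(v)))
    m <- m + t(m)
    quantsep:::new_rdm(m, labs, k)
  }
  preds <- list(a = mk(v1, "predictor:a"), b = mk(v2, "predictor:b"))
  set.seed(21)
  y <- rnorm(6)
  neural <- mk(y, "neural")
  fit <- rsa_fit(neural, preds, z_neural = TRUE)
  expect_equal(unname(fit$betas["a"]), cor(y, v1), tolerance = 1e-10)
  expect_equal(unname(fit$betas["b"]), cor(y, v2), tolerance = 1e-10)
})

test_that("reduced models never beat the full model in R-squared", {
  set <- condition_grid()
  pop <- make_population(roi_preset("early", n_voxels = 120L), seed = 61)
  ds <- simulate_betas(pop, set, n_subjects = 1, n_runs = 3, seed = 62)
  preds <- predictor_rdms(set)
  nr <- neural_rdm(ds, 1, "number", k = 100)
  full <- rsa_fit(nr, preds, "full")
  orth <- rsa_fit(nr, preds, "orthogonal_only")
  nonnum <- rsa_fit(nr, preds, "non_numerical_only")
  expect_gte(full$r_squared, orth$r_squared)
  expect_gte(full$r_squared, nonnum$r_squared)
  expect_equal(sort(names(orth$betas)),
               sort(c("number", "avg_item_area", "total_field_area")))
  expect_false("number" %in% names(nonnum$betas))
})

test_that("rank deficiency is an explicit failure", {
  set <- condition_grid()
  preds <- predictor_rdms(set)
  preds$density <- preds$number  # duplicate
  set.seed(31)
  y <- rnorm(153)
  m <- matrix(0, 18, 18)
  m <- t(`[<-`(t(m), lower.tri(m), y))
  m <- m + t(m)
  expect_error(
    suppressWarnings(rsa_fit(quantsep:::new_rdm(m, set$label, "neural"), preds)),
    "rank-deficient")
})

test_that("RDMs round-trip through CSV", {
  set <- condition_grid()
  rdm <- predictor_rdm(set, "number")
  path <- tempfile(fileext = ".csv")
  write_rdm(rdm, path)
  back <- read_rdm(path, "predictor:number")
  expect_equal(unclass(back), unclass(rdm), tolerance = 1e-12,
               ignore_attr = TRUE)
})
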