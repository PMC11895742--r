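test_that("correlation screen handles perfect and degenerate pairs", {
  x <- seq_len(20)
  out <- correlation_screen(data.frame(a = x, b = -x, c = rep(1, 20)))
  ab <- out[out$var1 == "a" & out$var2 == "b", ]
  expect_equal(ab$pearson_r, -1)
  expect_equal(ab$spearman_r, -1)
  ac <- out[out$var1 == "a" & out$var2 == "c", ]
  expect_true(is.na(ac$pearson_r))  # zero-variance column: undefined
  out2 <- correlation_screen(data.frame(a = x), response = x)
  expect_equal(out2$pearson_r, 1)
  expect_error(correlation_screen(data.frame(a = 1:2, b = 2:1)), "3 complete rows")
})

test_that("independent columns rarely show large correlations", {
  set.seed(41)
  big <- replicate(300, {
    m <- matrix(rnorm(100), ncol = 2)
    abs(correlation_screen(data.frame(a = m[, 1], b = m[, 2]))$pearson_r) < 0.3
  })
  expect_gte(mean(big), 0.95)
})

test_that("VIF matches its definition and flags collinearity", {
  set.seed(42)
  # orthogonal design: VIF exactly 1
  x1 <- rep(c(-1, 1), 10); x2 <- rep(c(-1, 1), each = 10)
  expect_equal(unname(vif(data.frame(x1, x2))), c(1, 1))
  # duplicated column: infinite
  dup <- rnorm(20)
  expect_true(all(is.infinite(vif(data.frame(a = dup, b = dup)))))
  # near-duplicate: VIF > 10, agreeing with a hand OLS R^2
  a <- rnorm(50); b <- a + rnorm(50, 0, 0.05); z <- rnorm(50)
  v <- vif(data.frame(a, b, z))
  r2 <- summary(lm(b ~ a + z))$r.squared
  expect_equal(unname(v["b"]), 1 / (1 - r2), tolerance = 1e-8)
  expect_gt(v["b"], 10)
})

test_that("collinearity dropping honors forced drops and records an audit", {
  set.seed(43)
  a <- rnorm(40); b <- a + rnorm(40, 0, 0.01); z <- rnorm(40); w <- rnorm(40)
  m <- data.frame(a, b, z, w)
  red <- drop_collinear(m, vif_threshold = 10)
  aud <- attr(red, "audit")
  expect_equal(nrow(aud), 1)
  expect_true(aud$dropped %in% c("a", "b"))   # exactly one of the near-dupes
  expect_setequal(names(red), setdiff(names(m), aud$dropped))

  red2 <- drop_collinear(m, vif_threshold = 10, forced_drops = "w")
  aud2 <- attr(red2, "audit")
  expect_equal(aud2$reason, c("forced", "vif"))
  expect_false("w" %in% names(red2))

  # all VIF below threshold: identity
  m3 <- data.frame(a = rnorm(30), z = rnorm(30))
  expect_equal(names(drop_collinear(m3)), names(m3))
  expect_equal(nrow(attr(drop_collinear(m3), "audit")), 0)
})

test_that("Poisson GLM: closed forms and saturation", {
  g <- fit_poisson_glm(c(2L, 2L, 2L))
  expect_equal(unname(g$coefficients["(Intercept)", "estimate"]), log(2),
               tolerance = 1e-8)
  expect_error(fit_poisson_glm(c(-1, 2, 3)), "non-negative")
  # one parameter per row: residual deviance 0
  y <- c(3L, 7L, 1L, 9L)
  gs <- fit_poisson_glm(y, data.frame(f1 = c(1, 0, 0, 0), f2 = c(0, 1, 0, 0),
                                      f3 = c(0, 0, 1, 0)))
  expect_lt(gs$deviance, 1e-8)
  expect_lte(gs$deviance, gs$null_deviance)
})

test_that("Poisson GLM recovers a known slope, agreeing with independent Newton", {
  set.seed(44)
  x <- runif(200, -0.5, 0.5)
  y <- rpois(200, exp(1 + 2 * x))
  g <- fit_poisson_glm(y, data.frame(x = x))
  est <- g$coefficients[, "estimate"]
  expect_lt(abs(est["x"] - 2), 0.15 * 2)
  newton <- oracle_poisson_newton(y, cbind(x))
  expect_equal(unname(est), unname(newton), tolerance = 1e-6)
})

test_that("adding predictors never increases Poisson deviance", {
  set.seed(45)
  for (rep in 1:5) {
    n <- 30
    m <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- rpois(n, exp(1 + 0.3 * m$a))
    d1 <- fit_poisson_glm(y, m[, "a", drop = FALSE])$deviance
    d2 <- fit_poisson_glm(y, m[, c("a", "b")])$deviance
    d3 <- fit_poisson_glm(y, m)$deviance
    expect_lte(d2, d1 + 1e-8)
    expect_lte(d3, d2 + 1e-8)
  }
})

test_that("the paired GLMs exclude one focal proxy each", {
  set.seed(46)
  n <- 20
  m <- data.frame(d114_110Cd = rnorm(n), d18O_apatite = rnorm(n),
                  other = rnorm(n))
  y <- rpois(n, exp(1.5 + 0.5 * m$d114_110Cd))
  pair <- run_glm_pair(y, m)
  expect_false("d114_110Cd" %in% rownames(pair$model_a$coefficients))
  expect_true("d18O_apatite" %in% rownames(pair$model_a$coefficients))
  expect_false("d18O_apatite" %in% rownames(pair$model_b$coefficients))
  expect_error(run_glm_pair(y, m[, -1]), "focal proxy missing")
  # identical focal columns give identical fits
  m2 <- m; m2$d18O_apatite <- m2$d114_110Cd
  pair2 <- run_glm_pair(y, m2)
  expect_equal(unname(pair2$model_a$coefficients[, "estimate"]),
               unname(pair2$model_b$coefficients[, "estimate"]),
               tolerance = 1e-10)
})

test_that("the model containing the driving proxy usually wins on AIC", {
  set.seed(47)
  wins <- replicate(200, {
    n <- 25
    m <- data.frame(d114_110Cd = rnorm(n), d18O_apatite = rnorm(n))
    y <- rpois(n, exp(1.2 + 0.8 * m$d18O_apatite))
    pair <- run_glm_pair(y, m)
    # model_a keeps d18O_apatite (drops the Cd proxy)
    pair$model_a$aic < pair$model_b$aic
  })
  expect_gte(mean(wins), 0.9)
})

test_that("Jaccard distances match enumeration and metric axioms", {
  inc <- cbind(b1 = c(1, 1, 0), b2 = c(1, 0, 1), b3 = c(1, 1, 0))
  d <- as.matrix(jaccard_distances(inc))
  expect_equal(d["b1", "b2"], 2 / 3)  # |A∩B| = 1, |A∪B| = 3
  expect_equal(d["b1", "b3"], 0)      # identical assemblages
  disj <- cbind(b1 = c(1, 1, 0), b2 = c(0, 0, 1))
  expect_equal(as.matrix(jaccard_distances(disj))["b1", "b2"], 1)
  # empty beds: distance 1 to non-empty, 0 to each other, with warning
  withz <- cbind(b1 = c(1, 0), b2 = c(0, 0), b3 = c(0, 0))
  expect_warning(dz <- as.matrix(jaccard_distances(withz)), "empty")
  expect_equal(dz["b2", "b3"], 0)
  expect_equal(dz["b1", "b2"], 1)

  # metric axioms on every 3-taxon incidence pattern over 3 beds
  pats <- expand.grid(rep(list(0:1), 9))
  for (i in seq_len(nrow(pats))) {
    m <- matrix(as.numeric(pats[i, ]), nrow = 3)
    colnames(m) <- c("x", "y", "z")
    if (any(colSums(m) == 0)) next
    dm <- as.matrix(jaccard_distances(m))
    expect_true(all(diag(dm) == 0))
    expect_equal(dm, t(dm))
    expect_lte(dm["x", "z"], dm["x", "y"] + dm["y", "z"] + 1e-12)
  }
})

test_that("unconstrained dbRDA equals classical PCoA", {
  set.seed(48)
  pts <- matrix(rnorm(30), ncol = 3)
  d <- dist(pts)
  res <- partial_dbrda(d)
  pcoa <- cmdscale(d, k = 2, eig = TRUE)
  eig_ref <- pcoa$eig[pcoa$eig > 1e-8]
  expect_equal(unname(res$unconstrained_eig[seq_along(eig_ref)]),
               eig_ref, tolerance = 1e-8)
})

test_that("degenerate and perfectly-explained configurations behave", {
  # all points identical: all eigenvalues ~ 0
  d0 <- dist(matrix(1, nrow = 6, ncol = 2))
  res0 <- partial_dbrda(d0)
  expect_true(all(abs(res0$unconstrained_eig) < 1e-10) ||
                length(res0$unconstrained_eig) == 0)

  # 1-D arrangement fully explained by its coordinate
  z <- seq(0, 1, length.out = 8)
  d1 <- dist(z)
  res1 <- partial_dbrda(d1, constraints = data.frame(z = z))
  expect_equal(res1$proportion_constrained, 1, tolerance = 1e-8)

  # saturated constraint set is rejected
  expect_error(partial_dbrda(d1, constraints = as.data.frame(
    matrix(rnorm(8 * 7), nrow = 8))), "saturated")
})

test_that("partialling out a condition removes its constrained signal", {
  set.seed(49)
  z <- rnorm(12)
  pts <- cbind(z, rnorm(12))
  d <- dist(pts)
  full <- partial_dbrda(d, constraints = data.frame(z = z))
  parted <- partial_dbrda(d, constraints = data.frame(w = rnorm(12)),
                          condition = data.frame(z = z))
  expect_lt(parted$proportion_constrained, full$proportion_constrained)
  expect_equal(parted$conditioned, "z")
})

test_that("permutation p-values: maximal statistic, determinism, relabeling", {
  set.seed(54)
  z <- seq(0, 1, length.out = 10)
  # a dominant constrained gradient plus a sliver of residual scatter so the
  # pseudo-F is finite; the observed statistic is still maximal
  d <- dist(cbind(z, 0.02 * rnorm(10)))
  res <- partial_dbrda(d, constraints = data.frame(z = z))
  p1 <- permutation_test_dbrda(res, n_perm = 199, seed = 9)
  expect_equal(p1$overall$p, 1 / 200)
  p2 <- permutation_test_dbrda(res, n_perm = 199, seed = 9)
  expect_equal(p1$overall$p, p2$overall$p)
  expect_equal(p1$terms$p, p2$terms$p)

  # joint relabeling of sites leaves the p-value distribution unchanged
  set.seed(50)
  pts <- matrix(rnorm(20), ncol = 2)
  w <- rnorm(10)
  perm <- sample(10)
  r1 <- partial_dbrda(dist(pts), constraints = data.frame(w = w))
  r2 <- partial_dbrda(dist(pts[perm, ]), constraints = data.frame(w = w[perm]))
  expect_equal(sum(r1$constrained_eig), sum(r2$constrained_eig),
               tolerance = 1e-10)
  expect_equal(permutation_test_dbrda(r1, n_perm = 199, seed = 3)$overall$F,
               permutation_test_dbrda(r2, n_perm = 199, seed = 3)$overall$F,
               tolerance = 1e-10)
})

test_that("square-root correction removes negative eigenvalues for Jaccard", {
  set.seed(51)
  inc <- matrix(rbinom(60, 1, 0.4), nrow = 6)
  colnames(inc) <- paste0("b", 1:10)
  inc[1, colSums(inc) == 0] <- 1
  d <- jaccard_distances(inc)
  plain <- partial_dbrda(d)
  corrected <- partial_dbrda(d, sqrt_correction = TRUE)
  expect_lte(corrected$imaginary_inertia, plain$imaginary_inertia + 1e-10)
})

test_that("variance-vs-extinction-rate table handles edge cases", {
  rates <- data.frame(bed_id = as.character(1:6),
                      rate = c(0.1, 0.2, 0.15, 0.4, 0.3, 0.5))
  bv <- rbind(
    data.frame(proxy = "match", bed_id = as.character(1:6),
               var = c(0.1, 0.2, 0.15, 0.4, 0.3, 0.5)),
    data.frame(proxy = "const", bed_id = as.character(1:6), var = 1),
    data.frame(proxy = "sparse", bed_id = as.character(1:6),
               var = c(0.2, NA, NA, NA, 0.1, NA))
  )
  out <- variance_vs_extinction_rate(bv, rates)
  expect_equal(out$spearman_r[out$proxy == "match"], 1)
  expect_true(is.na(out$spearman_r[out$proxy == "const"]))   # undefined
  expect_true(is.na(out$spearman_r[out$proxy == "sparse"]))  # < 4 complete beds
  expect_equal(out$n[out$proxy == "sparse"], 2L)
})

test_that("independent proxy variance is significant about 5% of the time", {
  set.seed(52)
  hits <- replicate(300, {
    rates <- data.frame(bed_id = as.character(1:15), rate = runif(15))
    bv <- data.frame(proxy = "p", bed_id = as.character(1:15),
                     var = rexp(15))
    out <- variance_vs_extinction_rate(bv, rates)
    !is.na(out$p) && out$p <= 0.05
  })
  expect_lt(mean(hits), 0.1)
})

test_that("polynomial trend: exact quadratic, horizontal mean, SE-level recovery", {
  x <- seq(-3, 3, length.out = 20)
  f <- fit_polynomial_trend(x, x^2)
  expect_equal(unname(f$coefficients), c(0, 0, 1), tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  fh <- fit_polynomial_trend(x, rep(2.5, 20))
  expect_equal(unname(fh$coefficients["b0"]), 2.5, tolerance = 1e-10)

  set.seed(53)
  y <- 1 - 0.5 * x + 0.8 * x^2 + rnorm(20, 0, 0.4)
  fn <- fit_polynomial_trend(x, y)
  se <- summary(fn$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(fn$coefficients["b2"] - 0.8), 2 * se[3])
  expect_error(fit_polynomial_trend(rep(1, 10), rnorm(10)), "degenerate")
})
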