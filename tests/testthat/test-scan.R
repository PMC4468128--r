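test_that("block whitener has the closed form, eigenvalues and inverse", {
  expect_equal(block_whitener(4, 0), diag(4))
  for (k in c(2, 5)) for (delta in c(0.3, 1, 7)) {
    A <- block_whitener(k, delta)
    S <- diag(k) + delta  # I + delta * J
    expect_equal(A %*% S %*% A, diag(k), tolerance = 1e-12)
    ev <- sort(eigen(A, symmetric = TRUE)$values)
    expect_equal(ev, sort(c(rep(1, k - 1), (1 + k * delta)^(-0.5))),
                 tolerance = 1e-12)
  }
  expect_error(block_whitener(3, -1), "non-negative")
})

test_that("whitening is the identity at delta = 0 and decorrelates residuals", {
  set.seed(41)
  lay <- make_simple_lattice(4, randomize = FALSE)
  g <- rnorm(16)
  rec <- sim_lattice_phenotypes(g, lay, h2 = 0.7, delta = 0)
  wd <- whiten_lattice(rec, lay, 0)
  expect_equal(wd$y, rec$value, tolerance = 1e-12)
  # with delta > 0: whitened residual covariance is close to sigma2 * I
  delta <- 4
  n_sim <- 400
  res <- replicate(n_sim, {
    r2 <- sim_lattice_phenotypes(g, lay, h2 = 0.7, delta = delta)
    w <- whiten_lattice(r2, lay, delta)
    X <- cbind(w$base, w$expand(diag(16)))
    qr.resid(qr(X), w$y)
  })
  sigma2 <- var(g) * 3 / 7
  emp <- tcrossprod(res) / n_sim
  offdiag <- emp[upper.tri(emp)]
  expect_lt(mean(abs(offdiag)), 0.05 * sigma2 + 3 * sigma2 / sqrt(n_sim))
})

test_that("whitened OLS equals dense GLS on a small lattice", {
  set.seed(43)
  lay <- make_simple_lattice(3, randomize = FALSE)
  g <- rnorm(9)
  rec <- sim_lattice_phenotypes(g, lay, h2 = 0.6, delta = 1.5)
  wd <- whiten_lattice(rec, lay, 1.5)
  x <- rnorm(9)  # arbitrary line-level regressor
  Xw <- cbind(wd$base, wd$expand(matrix(x)))
  fit_w <- qr(Xw)
  beta_w <- qr.coef(fit_w, wd$y)
  rss_w <- sum(qr.resid(fit_w, wd$y)^2)
  rec_s <- rec[order(rec$rep, rec$block, rec$line), ]
  block <- (rec_s$rep - 1) * 3 + rec_s$block
  X <- cbind(model.matrix(~ factor(rec_s$rep)), x[rec_s$line])
  fit_g <- gls_fit(rec_s$value, X, block, 1.5)
  expect_equal(unname(beta_w), unname(fit_g$beta), tolerance = 1e-9)
  expect_equal(rss_w, fit_g$rss, tolerance = 1e-9)
})

test_that("LOD score follows (n/2) log10(RSS0/RSS1) and the likelihood ratio", {
  expect_equal(lod_score(5, 5, 80), 0)
  expect_equal(lod_score(10, 1, 100), 50)
  expect_error(lod_score(0, 1, 10), "positive")
  # equivalence with Gaussian profile log-likelihoods on a random regression
  set.seed(45)
  n <- 30
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  r0 <- sum(lm.fit(matrix(1, n, 1), y)$residuals^2)
  r1 <- sum(lm.fit(cbind(1, x), y)$residuals^2)
  ll <- function(rss) -n / 2 * (log(2 * pi * rss / n) + 1)
  expect_equal(lod_score(r0, r1, n), (ll(r1) - ll(r0)) / log(10),
               tolerance = 1e-9)
})

test_that("forward selection: p = 0 empty; p = 1 equals best single marker", {
  set.seed(47)
  ex <- tiny_experiment()
  y <- as.numeric(arithmetic_means(ex$records))
  M <- ex$markers
  expect_length(select_covariates(M, y, p = 0), 0)
  s1 <- select_covariates(M, y, p = 1)
  rss <- apply(M, 2, function(x) sum(lm.fit(cbind(1, x), y)$residuals^2))
  expect_equal(unname(s1), unname(which.min(rss)))
  # p > markers errors
  expect_error(select_covariates(M, y, p = ncol(M) + 1), "exceeds")
})

test_that("first selected covariate tags the strongest simulated QTL", {
  set.seed(49)
  arch <- data.frame(chr = "1", pos = 30, effect = 1.5, type = "qtl")
  map <- even_map(2, 60, 7)
  hits <- replicate(100, {
    geno <- sim_ril_genotypes(locus_grid(map, step = NULL,
                                         extra = arch[, c("chr", "pos")]),
                              100)
    g <- genotypic_values(geno, arch)
    y <- g + rnorm(100, 0, 0.8)
    mk <- marker_genotypes(geno)
    s <- select_covariates(mk, y, p = 1)
    attr(mk, "chr")[s] == "1" && abs(attr(mk, "pos")[s] - 30) <= 10
  })
  expect_gte(mean(hits), 0.95)
})

test_that("single-marker scan equals the direct regression LOD oracle", {
  set.seed(51)
  ex <- tiny_experiment(n_draws = 3)
  y <- as.numeric(arithmetic_means(ex$records))
  prof <- cim_scan("rcbd", ex$draws, ex$markers, y, p = 0)
  # at marker positions all draws equal the data: LOD must match lm exactly
  mk <- which(ex$draws$grid$type == "marker")
  n <- length(y)
  for (i in mk[c(1, 4, 9)]) {
    x <- ex$markers[, ex$draws$grid$marker[i]]
    r0 <- sum(lm.fit(matrix(1, n, 1), y)$residuals^2)
    r1 <- sum(lm.fit(cbind(1, x), y)$residuals^2)
    expect_equal(prof$lod[i], lod_score(r0, r1, n), tolerance = 1e-9)
  }
})

test_that("averaged LOD with identical draws equals the single-fit LOD", {
  set.seed(53)
  ex <- tiny_experiment(n_draws = 6, step = 1e9)  # marker-only grid
  y <- as.numeric(arithmetic_means(ex$records))
  prof <- cim_scan("rcbd", ex$draws, ex$markers, y, p = 2)
  dr1 <- ex$draws
  dr1$draws <- dr1$draws[1, , , drop = FALSE]
  dr1$n_draws <- 1L
  prof1 <- cim_scan("rcbd", dr1, ex$markers, y, p = 2)
  expect_equal(prof$lod, prof1$lod, tolerance = 1e-12)
})

test_that("CIMLD scan LOD equals explicit GLS testing on a small lattice", {
  set.seed(55)
  ex <- tiny_experiment(k = 3, n_draws = 2, step = 1e9,
                        arch = tiny_arch(c(0.8, -0.5)))
  wd <- whiten_lattice(ex$records, ex$layout, ex$vc$delta)
  prof <- cim_scan("cimld", ex$draws, ex$markers, wd, p = 0)
  rec_s <- ex$records[order(ex$records$rep, ex$records$block,
                            ex$records$line), ]
  block <- (rec_s$rep - 1) * 3 + rec_s$block
  n <- nrow(rec_s)
  X0 <- model.matrix(~ factor(rec_s$rep))
  for (i in c(2, 8, 11)) {
    x <- ex$markers[, ex$draws$grid$marker[i]][rec_s$line]
    f0 <- gls_fit(rec_s$value, X0, block, ex$vc$delta)
    f1 <- gls_fit(rec_s$value, cbind(X0, x), block, ex$vc$delta)
    expect_equal(prof$lod[i], lod_score(f0$rss, f1$rss, n), tolerance = 1e-9)
  }
})

test_that("pure-noise phenotypes rarely reach LOD 2.5 genome-wide", {
  set.seed(57)
  map <- even_map()
  maxlod <- replicate(100, {
    geno <- sim_ril_genotypes(map, 196)
    y <- rnorm(196)
    dr <- impute_draws(geno, map, step = 5, n_draws = 12)
    prof <- cim_scan("rcbd", dr, geno, y, p = 3)
    max(prof$lod)
  })
  expect_gte(mean(maxlod < 2.5), 0.9)
})

test_that("covariates inside the window are excluded from both models", {
  set.seed(59)
  ex <- tiny_experiment(n_draws = 2, step = 1e9)
  y <- as.numeric(arithmetic_means(ex$records))
  # force a covariate exactly at a scanned marker; LOD there must still be
  # computed against a null without that covariate (no zero by collinearity)
  sel <- c(3L, 10L)
  prof <- cim_scan("rcbd", ex$draws, ex$markers, y, covariates = sel,
                   window = 10)
  i <- 3  # the covariate marker itself
  n <- length(y)
  keep <- ex$markers[, 10]
  x <- ex$markers[, 3]
  r0 <- sum(lm.fit(cbind(1, keep), y)$residuals^2)
  r1 <- sum(lm.fit(cbind(1, keep, x), y)$residuals^2)
  expect_equal(prof$lod[i], lod_score(r0, r1, n), tolerance = 1e-9)
})
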