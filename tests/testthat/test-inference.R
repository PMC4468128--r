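test_that("permutation threshold edge cases and quantile monotonicity", {
  set.seed(61)
  ex <- tiny_experiment(k = 4, n_draws = 2, step = 1e9)
  y <- as.numeric(arithmetic_means(ex$records))
  th <- permutation_threshold("rcbd", ex$draws, ex$markers, y,
                              n_perm = 19, alpha = 0.05, p = 2)
  expect_equal(as.numeric(th), max(attr(th, "maxima")))
  mx <- attr(th, "maxima")
  k95 <- min(ceiling(0.95 * 20), 19)
  expect_equal(as.numeric(th), sort(mx)[k95])
  # monotonicity in alpha on the same permutation maxima
  k80 <- min(ceiling(0.80 * 20), 19)
  expect_gte(sort(mx)[k95], sort(mx)[k80])
  expect_error(permutation_threshold("rcbd", ex$draws, ex$markers, y,
                                     n_perm = 10, alpha = 0.05, p = 2),
               "too few permutations")
})

test_that("permutation units agree for mean responses, differ for plots", {
  set.seed(62)
  ex <- tiny_experiment(k = 5, n_draws = 3)
  y <- as.numeric(arithmetic_means(ex$records))
  set.seed(1)
  t1 <- permutation_threshold("rcbd", ex$draws, ex$markers, y,
                              n_perm = 25, alpha = 0.05, p = 2,
                              unit = "plot")
  wd <- whiten_lattice(ex$records, ex$layout, ex$vc$delta)
  t2 <- permutation_threshold("cimld", ex$draws, ex$markers, wd,
                              n_perm = 25, alpha = 0.05, p = 2,
                              unit = "line")
  expect_true(is.finite(t1) && is.finite(t2) && t1 > 0 && t2 > 0)
})

test_that("genome-wide type-I error of the permutation test is near alpha", {
  # pure-noise null: plot and line units coincide in law; RCBD for speed
  set.seed(63)
  map <- genetic_map(chr = rep("1", 5), pos = seq(0, 40, by = 10))
  n_sim <- 150
  alpha <- 0.05
  hits <- replicate(n_sim, {
    geno <- sim_ril_genotypes(map, 48)
    y <- rnorm(48)
    dr <- impute_draws(geno, map, step = 5, n_draws = 2)
    prof <- cim_scan("rcbd", dr, geno, y, p = 1, window = 10)
    th <- permutation_threshold("rcbd", dr, geno, y, n_perm = 60,
                                alpha = alpha, p = 1, window = 10)
    max(prof$lod) > th
  })
  se <- sqrt(alpha * (1 - alpha) / n_sim)
  expect_lt(abs(mean(hits) - alpha), 3 * se + 1 / 60)
})

test_that("QTL calling: flat profiles, support intervals, region masking", {
  flat <- structure(data.frame(chr = "1", pos = seq(0, 100, 2), lod = 1,
                               effect = 0),
                    class = c("scan_profile", "data.frame"))
  expect_equal(nrow(call_qtls(flat, 2.5)), 0)
  expect_error(call_qtls(flat[0, ], 2.5), "empty")
  expect_error(call_qtls(flat, 0), "positive")
  # triangular peak: max 5 at 40, crossing 3.5 (= 5 - 1.5) at 30 and 50;
  # called at threshold 3.5 so the supra-threshold region is [30, 50]
  pos <- seq(0, 100, 2)
  tri <- pmax(0, 5 - 0.15 * abs(pos - 40))
  prof <- structure(data.frame(chr = "1", pos = pos, lod = tri, effect = 1),
                    class = c("scan_profile", "data.frame"))
  calls <- call_qtls(prof, 3.5)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 40)
  expect_equal(calls$support_lo, 30)
  expect_equal(calls$support_hi, 50)
  # two peaks 8 cM apart above threshold: one call at the higher peak
  lod2 <- pmax(pmax(0, 4 - 0.5 * abs(pos - 40)),
               pmax(0, 3.5 - 0.5 * abs(pos - 48)))
  prof2 <- structure(data.frame(chr = "1", pos = pos, lod = lod2,
                                effect = 1),
                     class = c("scan_profile", "data.frame"))
  calls2 <- call_qtls(prof2, 2.5, min_sep = 10)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$pos, 40)
})

test_that("no two calls fall within min_sep on a chromosome", {
  set.seed(65)
  for (i in 1:20) {
    pos <- seq(0, 150, 2)
    lod <- abs(cumsum(rnorm(length(pos), 0, 0.6)))
    prof <- structure(data.frame(chr = "1", pos = pos, lod = lod,
                                 effect = 0),
                      class = c("scan_profile", "data.frame"))
    calls <- call_qtls(prof, 1.5, min_sep = 12)
    if (nrow(calls) > 1) {
      d <- diff(sort(calls$pos))
      expect_true(all(d > 12))
    }
  }
})

test_that("lowering the threshold never removes a call position", {
  set.seed(66)
  pos <- seq(0, 150, 2)
  lod <- abs(cumsum(rnorm(length(pos), 0, 0.5)))
  prof <- structure(data.frame(chr = "1", pos = pos, lod = lod, effect = 0),
                    class = c("scan_profile", "data.frame"))
  hi <- call_qtls(prof, 3, min_sep = 10)
  lo <- call_qtls(prof, 2, min_sep = 10)
  expect_true(all(hi$pos %in% lo$pos))
})

test_that("power/FDR bookkeeping matches a brute-force window oracle", {
  truth <- data.frame(chr = c("1", "1", "2"), pos = c(20, 60, 35))
  # calls exactly at the true positions: full power, zero FDR
  exact <- list(data.frame(chr = truth$chr, pos = truth$pos))
  ev <- evaluate_calls(exact, truth, window = 10)
  expect_equal(ev$overall_power, 100)
  expect_equal(ev$fdr, 0)
  # no calls at all
  ev0 <- evaluate_calls(list(data.frame(chr = character(0),
                                        pos = numeric(0))), truth)
  expect_equal(ev0$overall_power, 0)
  expect_equal(ev0$fdr, 0)
  # random configurations vs oracle
  set.seed(67)
  for (i in 1:25) {
    calls_list <- lapply(1:4, function(r) {
      m <- rpois(1, 3)
      data.frame(chr = sample(c("1", "2"), m, TRUE),
                 pos = runif(m, 0, 80))
    })
    ev <- evaluate_calls(calls_list, truth, window = 10)
    # oracle
    det <- matrix(FALSE, 4, nrow(truth)); fp <- 0; nc <- 0
    for (r in 1:4) {
      cl <- calls_list[[r]]
      nc <- nc + nrow(cl)
      for (j in seq_len(nrow(cl))) {
        near <- cl$chr[j] == truth$chr & abs(cl$pos[j] - truth$pos) <= 5
        if (!any(near)) fp <- fp + 1
        det[r, near] <- TRUE
      }
    }
    expect_equal(ev$n_fp, fp)
    expect_equal(ev$overall_power, 100 * mean(colMeans(det)))
    expect_equal(ev$fdr, if (nc > 0) fp / nc else 0)
  }
})

test_that("pointwise power tallies exceedances per replicate threshold", {
  pos <- seq(0, 20, 5)
  mk <- function(lod) structure(data.frame(chr = "1", pos = pos, lod = lod,
                                           effect = 0),
                                class = c("scan_profile", "data.frame"))
  profs <- list(mk(rep(1, 5)), mk(rep(3, 5)))
  pw <- pointwise_power(profs, c(2, 2))
  expect_equal(pw$power, rep(0.5, 5))
  pw0 <- pointwise_power(profs, c(5, 5))
  expect_equal(pw0$power, rep(0, 5))
  set.seed(68)
  profs2 <- list(mk(runif(5, 0, 4)), mk(runif(5, 0, 4)), mk(runif(5, 0, 4)))
  th <- c(1, 2, 3)
  pw2 <- pointwise_power(profs2, th)
  oracle <- rowMeans(sapply(1:3, function(i) profs2[[i]]$lod > th[i]))
  expect_equal(pw2$power, oracle)
  expect_error(pointwise_power(profs2[1:2], th), "threshold")
})

test_that("per-QTL heritability uses the imputed genotype at the peak", {
  set.seed(69)
  ex <- tiny_experiment(n_draws = 4, step = 1e9)
  y <- as.numeric(arithmetic_means(ex$records))
  prof <- cim_scan("rcbd", ex$draws, ex$markers, y, p = 0)
  calls <- call_qtls(prof, 1)
  if (nrow(calls)) {
    h <- qtl_heritability(calls, ex$draws, y)
    expect_true(all(h$h2 >= 0 & h$h2 <= 1))
  }
})
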