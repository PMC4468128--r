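#' Multi-environment CIMLD scan with QTL-by-environment effects
#'
#' Extends the plot-level whitened scan to `s >= 2` environments treated as
#' fixed covariates.  The model at a test position contains the intercept,
#' environment effects, replication-within-environment effects, the
#' background covariate markers, the QTL main effect and the
#' QTL-by-environment interaction; whitening is applied block by block with
#' an environment-specific `delta`.  Three nested LOD scores are reported
#' at every position (averaged over imputation draws):
#' `lod_join` (null drops both QTL terms), `lod_g` (null drops the main
#' effect only) and `lod_ge` (null drops the interaction only), together
#' with the average main effect `effect_a` and interaction contrast
#' `effect_ae` (coefficient on the centered environment contrast, so that
#' `effect_a` is the across-environment mean effect).
#'
#' @param draws Imputation draws from [impute_draws()].
#' @param markers Observed marker matrix (`"ril_geno"`).
#' @param records Plot records with columns `env`, `rep`, `block`, `line`,
#'   `value`.
#' @param layouts Named list of `"lattice_layout"`s, one per environment.
#' @param deltas Named numeric vector of plug-in variance ratios per
#'   environment (from per-environment [lattice_anova()]).
#' @param covariates Covariate column indices into `markers`, or `NULL` to
#'   select `p` by forward stepwise on the whitened stacked data.
#' @param p,window As in [cim_scan()].
#' @return A `"scan_profile"` with columns `chr`, `pos`, `lod` (= joint),
#'   `lod_g`, `lod_ge`, `lod_join`, `effect_a`, `effect_ae`.
#' @export
multi_env_scan <- function(draws, markers, records, layouts, deltas,
                           covariates = NULL, p = 10, window = 10) {
  envs <- names(layouts)
  if (length(envs) < 2)
    stop("multi_env_scan needs >= 2 environments; use cim_scan for one")
  stopifnot(all(envs %in% unique(as.character(records$env))),
            all(envs %in% names(deltas)))
  wds <- lapply(envs, function(e) {
    whiten_lattice(records[records$env == e, , drop = FALSE],
                   layouts[[e]], deltas[[e]])
  })
  names(wds) <- envs
  y <- unlist(lapply(wds, `[[`, "y"), use.names = FALSE)
  n <- length(y)
  env_of_row <- rep(seq_along(envs), vapply(wds, `[[`, 0L, "n"))
  # base: intercept + env + rep-within-env, whitened env by env
  base <- matrix(0, n, 1 + (length(envs) - 1))
  base[, 1] <- 1
  for (e in seq_along(envs)[-1]) base[env_of_row == e, e] <- 1
  repcols <- do.call(rbind, lapply(seq_along(envs), function(e) {
    b <- wds[[e]]$base  # whitened [1, rep dummies] of that env
    b[, -1, drop = FALSE]
  }))
  # whiten the intercept/env columns per environment
  for (e in seq_along(envs)) {
    rows <- env_of_row == e
    w1 <- wds[[e]]$base[, 1]           # whitened constant column
    base[rows, ] <- base[rows, , drop = FALSE] * w1
  }
  Xrep <- matrix(0, n, ncol(repcols) * length(envs))
  cc <- 0
  for (e in seq_along(envs)) {
    rows <- env_of_row == e
    nr <- ncol(repcols)
    Xrep[rows, cc + seq_len(nr)] <- repcols[rows, , drop = FALSE]
    cc <- cc + nr
  }
  base <- cbind(base, Xrep)
  expand <- function(M) {
    do.call(rbind, lapply(wds, function(w) w$expand(M)))
  }
  # centered environment contrasts for the interaction columns
  zc <- stats::model.matrix(~ factor(env_of_row))[, -1, drop = FALSE]
  zc <- scale(zc, center = TRUE, scale = FALSE)
  Msel <- expand(markers)
  if (is.null(covariates))
    covariates <- select_covariates(Msel, y, base, p)
  covar <- if (length(covariates)) Msel[, covariates, drop = FALSE] else NULL
  cchr <- attr(markers, "chr")[covariates]
  cpos <- attr(markers, "pos")[covariates]
  dm <- .draw_matrices(draws)
  grid <- dm$grid
  P <- nrow(grid); D <- length(dm$Glist)
  lod_g <- lod_ge <- lod_join <- eff_a <- eff_ae <- numeric(P)
  for (i in seq_len(P)) {
    keep <- if (length(covariates))
      which(!(cchr == grid$chr[i] & abs(cpos - grid$pos[i]) <= window))
    else integer(0)
    B <- if (length(keep)) cbind(base, covar[, keep, drop = FALSE]) else base
    rss_null <- sum(.lm.fit(B, y)$residuals^2)
    for (d in seq_len(D)) {
      xq <- expand(dm$Glist[[d]][, i, drop = FALSE])
      xqe <- xq[, rep(1, ncol(zc)), drop = FALSE] * zc
      fit_full <- .lm.fit(cbind(B, xq, xqe), y)
      rss_full <- sum(fit_full$residuals^2)
      rss_noq <- sum(.lm.fit(cbind(B, xqe), y)$residuals^2)
      rss_noqe <- sum(.lm.fit(cbind(B, xq), y)$residuals^2)
      lod_join[i] <- lod_join[i] + max(0, n / 2 * log10(rss_null / rss_full))
      lod_g[i] <- lod_g[i] + max(0, n / 2 * log10(rss_noq / rss_full))
      lod_ge[i] <- lod_ge[i] + max(0, n / 2 * log10(rss_noqe / rss_full))
      cf <- fit_full$coefficients
      nb <- ncol(B)
      eff_a[i] <- eff_a[i] + cf[nb + 1]
      eff_ae[i] <- eff_ae[i] + mean(cf[nb + 1 + seq_len(ncol(zc))])
    }
  }
  prof <- data.frame(chr = grid$chr, pos = grid$pos,
                     lod = lod_join / D, lod_g = lod_g / D,
                     lod_ge = lod_ge / D, lod_join = lod_join / D,
                     effect_a = eff_a / D, effect_ae = eff_ae / D)
  structure(prof, method = "cimld_me", covariates = covariates,
            class = c("scan_profile", "data.frame"))
}
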