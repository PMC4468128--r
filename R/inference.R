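#' Genome-wide LOD threshold by permutation
#'
#' Churchill-Doerge permutation threshold: the phenotype-genotype link is
#' broken `n_perm` times, the scan is re-run on each permuted dataset, and
#' the empirical `1 - alpha` quantile of the genome-wide maximum averaged
#' LOD is returned.  Two permutation units are available:
#' \describe{
#'   \item{`"plot"`}{the response vector of the fitted regression is
#'     shuffled (for `"cimld"` the whitened plot-level response, treating
#'     its entries as exchangeable under the no-QTL null) -- the classic
#'     Churchill-Doerge scheme and the default;}
#'   \item{`"line"`}{the assignment of genotype rows to line labels is
#'     shuffled while phenotypes and field layout stay fixed, preserving
#'     the within-line and block error structure of the plot-level model.}
#' }
#' For the line-mean responses the two schemes coincide.  For `"cimld"`
#' they do not: the plot-level model leaves any unmodelled line-level
#' (genetic) variance duplicated across a line's plots, `"line"`
#' permutations calibrate against that duplication and therefore give
#' markedly higher thresholds on polygenic traits.
#'
#' Following standard CIM permutation practice, the fitted analysis model
#' is treated as fixed under permutation: the covariate marker set and the
#' plug-in `delta` are those of the observed data (the phenotypes never
#' change, so `delta` has nothing to be re-estimated from); set
#' `reselect = TRUE` to redo the forward covariate selection inside every
#' permutation instead (only with `unit = "line"`).
#'
#' @inheritParams cim_scan
#' @param n_perm Number of permutations (`(n_perm + 1) * alpha >= 1`).
#' @param alpha Genome-wide significance level.
#' @param unit Permutation unit, see Details.
#' @param reselect Re-run covariate selection within each permutation.
#' @return LOD threshold (the `ceiling((1-alpha)(n_perm+1))`-th order
#'   statistic of the permutation maxima), with the maxima as attribute
#'   `maxima`.
#' @export
permutation_threshold <- function(method = c("cimld", "amld", "rcbd"),
                                  draws, markers, response, layout = NULL,
                                  delta = NULL, n_perm = 1000, alpha = 0.05,
                                  p = 10, window = 10, covariates = NULL,
                                  unit = c("plot", "line"),
                                  reselect = FALSE) {
  method <- match.arg(method)
  unit <- match.arg(unit)
  if (n_perm < 1 || (n_perm + 1) * alpha < 1)
    stop("too few permutations for this alpha: (n_perm + 1) * alpha >= 1 ",
         "is required")
  if (method == "cimld" && !inherits(response, "whitened_data"))
    response <- whiten_lattice(response, layout, delta)
  su <- .scan_setup(method, draws, markers, response, layout, delta)
  if (is.null(covariates))
    covariates <- select_covariates(su$Msel, su$y, su$base, p)
  maxima <- if (reselect) {
    .perm_maxima_reselect(method, draws, markers, response, layout, delta,
                          n_perm, p, window)
  } else if (method == "cimld" && unit == "line") {
    .perm_maxima_cimld(draws, markers, response, covariates, n_perm, window)
  } else {
    .perm_maxima_shuffle(draws, markers, su, covariates, n_perm, window)
  }
  k <- min(ceiling((1 - alpha) * (n_perm + 1)), n_perm)
  structure(sort(maxima)[k], maxima = maxima)
}

# slow general path: full re-analysis (covariate re-selection) per permutation
.perm_maxima_reselect <- function(method, draws, markers, response, layout,
                                  delta, n_perm, p, window) {
  n_lines <- nrow(markers)
  dm <- .draw_matrices(draws)
  mchr <- attr(markers, "chr"); mpos <- attr(markers, "pos")
  vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(n_lines)
    su <- .scan_setup(method, draws, markers, response, layout, delta, perm)
    sel <- select_covariates(su$Msel, su$y, su$base, p)
    covar <- if (length(sel)) su$Msel[, sel, drop = FALSE] else NULL
    Glist <- lapply(dm$Glist, function(M) M[perm, , drop = FALSE])
    .scan_core(Glist, dm$grid, su$y, su$base, covar,
               mchr[sel], mpos[sel], window, su$expand, max_only = TRUE)
  }, 0)
}

# stack all draw matrices side by side: lines x (positions * D), plus the
# per-position exclusion grouping induced by the covariate map positions
.perm_prep <- function(draws, markers, covariates, window) {
  dm <- .draw_matrices(draws)
  D <- length(dm$Glist)
  P <- nrow(dm$grid)
  Gstack <- do.call(cbind, dm$Glist)
  cchr <- attr(markers, "chr")[covariates]
  cpos <- attr(markers, "pos")[covariates]
  pc <- length(covariates)
  excl <- lapply(seq_len(P), function(i)
    if (pc) which(cchr == dm$grid$chr[i] &
                    abs(cpos - dm$grid$pos[i]) <= window) else integer(0))
  key <- vapply(excl, paste, "", collapse = ",")
  groups <- lapply(unique(key), function(kk) {
    idx <- which(key == kk)
    list(idx = idx, keep = setdiff(seq_len(pc), excl[[idx[1]]]),
         cols = as.vector(outer(idx, (seq_len(D) - 1L) * P, `+`)))
  })
  list(Gstack = Gstack, D = D, P = P, groups = groups)
}

# fast permutation maxima under response shuffling: the design (base,
# covariates, test columns) is fixed across permutations, so the
# residualized test designs are precomputed once and every permutation
# costs one matrix-vector product per group.  For line-mean responses this
# is also exactly the genotype-row/line-label shuffle.
.perm_maxima_shuffle <- function(draws, markers, su, covariates, n_perm,
                                 window) {
  pp <- .perm_prep(draws, markers, covariates, window)
  y <- su$y
  n <- length(y)
  base <- su$base
  Cov <- if (length(covariates))
    su$Msel[, covariates, drop = FALSE] else NULL
  tol <- 1e-8 * n
  pre <- lapply(pp$groups, function(g) {
    U <- .orth(if (length(g$keep))
      cbind(base, Cov[, g$keep, drop = FALSE]) else base)
    Xt <- su$expand(pp$Gstack[, g$cols, drop = FALSE])
    Xt <- Xt - U %*% crossprod(U, Xt)
    list(U = U, Xt = Xt, den = colSums(Xt^2), m = length(g$idx))
  })
  vapply(seq_len(n_perm), function(i) {
    yp <- y[sample.int(n)]
    gmax <- 0
    for (g in pre) {
      yt <- yp - g$U %*% crossprod(g$U, yp)
      rss0 <- sum(yt^2)
      num <- drop(crossprod(g$Xt, yt))
      red <- ifelse(g$den > tol, num^2 / g$den, 0)
      rss1 <- pmax(rss0 - red, rss0 * 1e-12)
      lod <- rowMeans(matrix(pmax(0, n / 2 * log10(rss0 / rss1)),
                             g$m, pp$D))
      gmax <- max(gmax, lod)
    }
    gmax
  }, 0)
}

# fast permutation maxima for the plot-level whitened model.  All test
# statistics reduce to line-level quadratic forms:
#   numerator  g' W'(I-P)y*          with W = Sigma^(-1/2) E
#   denominator g' (W'W) g - ||V'g||, W'W = r I - c A A', V = W'U,
# where E expands lines to plots, A is the line-by-block incidence and
# c = delta / (1 + k delta); so each permutation needs one GEMM of the
# fixed draw stack against a handful of permuted line-level vectors.
.perm_maxima_cimld <- function(draws, markers, wd, covariates, n_perm,
                               window) {
  pp <- .perm_prep(draws, markers, covariates, window)
  n <- wd$n; k <- wd$k; delta <- wd$delta
  n_lines <- max(wd$line)
  r <- n / n_lines
  cblk <- delta / (1 + k * delta)
  A <- matrix(0, n_lines, length(unique(wd$block)))
  A[cbind(wd$line, match(wd$block, unique(wd$block)))] <- 1
  cs <- colSums(pp$Gstack)
  M <- markers[, covariates, drop = FALSE]
  tol <- 1e-8 * n
  agg <- function(x) rowsum(whiten_blocks(as.matrix(x), wd$block, k, delta),
                            wd$line, reorder = TRUE)
  vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(n_lines)
    Cp <- if (length(covariates)) wd$expand(M[perm, , drop = FALSE])
    ginfo <- lapply(pp$groups, function(g) {
      U <- .orth(if (length(g$keep))
        cbind(wd$base, Cp[, g$keep, drop = FALSE]) else wd$base)
      yt <- wd$y - U %*% crossprod(U, wd$y)
      list(rss0 = sum(yt^2), mline = agg(yt), V = agg(U))
    })
    ip <- order(perm)  # inverse permutation: (G[perm, ])' x = G' (x[ip])
    blockmat <- cbind(A[ip, , drop = FALSE],
                      do.call(cbind, lapply(ginfo, function(z)
                        cbind(z$mline, z$V)[ip, , drop = FALSE])))
    R <- crossprod(pp$Gstack, blockmat)
    na <- ncol(A)
    a2 <- rowSums(R[, seq_len(na), drop = FALSE]^2)
    off <- na
    gmax <- 0
    for (gi in seq_along(pp$groups)) {
      g <- pp$groups[[gi]]; z <- ginfo[[gi]]
      qv <- ncol(z$V)
      num <- R[g$cols, off + 1L]
      V2 <- rowSums(R[g$cols, off + 1L + seq_len(qv), drop = FALSE]^2)
      off <- off + 1L + qv
      den <- r * cs[g$cols] - cblk * a2[g$cols] - V2
      red <- ifelse(den > tol, num^2 / den, 0)
      rss1 <- pmax(z$rss0 - red, z$rss0 * 1e-12)
      lod <- rowMeans(matrix(pmax(0, n / 2 * log10(z$rss0 / rss1)),
                             length(g$idx), pp$D))
      gmax <- max(gmax, lod)
    }
    gmax
  }, 0)
}

#' Call QTLs from a scan profile
#'
#' Greedy peak extraction: the global maximum above `threshold` becomes a
#' call, positions within `min_sep` cM of it on the same chromosome are
#' masked, and the procedure repeats until nothing exceeds the threshold
#' (so two peaks closer than `min_sep` yield one call).  Each call's
#' support interval is the contiguous region around the peak in which the
#' LOD stays within `drop` units of the peak value.
#'
#' @param profile A `"scan_profile"` from [cim_scan()].
#' @param threshold LOD threshold (> 0).
#' @param min_sep Minimum separation between calls on a chromosome (cM).
#' @param drop LOD drop defining the support interval.
#' @return `data.frame` with one row per call: `chr`, `pos`, `lod`,
#'   `effect`, `support_lo`, `support_hi` (possibly zero rows).
#' @export
call_qtls <- function(profile, threshold, min_sep = 10, drop = 1.5) {
  if (nrow(profile) == 0) stop("empty scan profile")
  if (threshold <= 0) stop("threshold must be positive")
  lod <- profile$lod
  avail <- rep(TRUE, length(lod))
  calls <- list()
  while (any(avail & lod > threshold)) {
    i <- which(avail & lod > threshold)
    i <- i[which.max(lod[i])]
    ch <- profile$chr[i]; ps <- profile$pos[i]
    onchr <- which(profile$chr == ch)
    j <- match(i, onchr)
    # support interval: walk out while LOD >= peak - drop
    lo <- hi <- j
    while (lo > 1 && lod[onchr[lo - 1]] >= lod[i] - drop) lo <- lo - 1
    while (hi < length(onchr) && lod[onchr[hi + 1]] >= lod[i] - drop)
      hi <- hi + 1
    calls[[length(calls) + 1L]] <- data.frame(
      chr = ch, pos = ps, lod = lod[i], effect = profile$effect[i],
      support_lo = profile$pos[onchr[lo]], support_hi = profile$pos[onchr[hi]])
    avail[profile$chr == ch & abs(profile$pos - ps) <= min_sep] <- FALSE
  }
  if (length(calls) == 0)
    return(data.frame(chr = character(0), pos = numeric(0), lod = numeric(0),
                      effect = numeric(0), support_lo = numeric(0),
                      support_hi = numeric(0)))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Per-QTL variance explained
#'
#' Heritability attributed to each called QTL: the variance of
#' `effect * x` across lines, with `x` the average imputed genotype at the
#' peak, divided by the variance of the line-level response.
#'
#' @param calls Output of [call_qtls()].
#' @param draws The `"imputation_draws"` used in the scan.
#' @param response Line-level response vector (e.g. arithmetic means).
#' @return `calls` with an added `h2` column.
#' @export
qtl_heritability <- function(calls, draws, response) {
  vp <- stats::var(as.numeric(response))
  calls$h2 <- vapply(seq_len(nrow(calls)), function(i) {
    j <- which(draws$grid$chr == calls$chr[i] &
                 abs(draws$grid$pos - calls$pos[i]) < 1e-9)[1]
    x <- colMeans(matrix(draws$draws[, , j], ncol = dim(draws$draws)[2]))
    stats::var(calls$effect[i] * x) / vp
  }, 0)
  calls
}

#' Power and FDR against a known truth
#'
#' A call is a false positive iff no true QTL lies within `window/2` cM of
#' it (same chromosome); a true QTL is detected in a replicate iff at least
#' one call lies within `window/2` cM of it.  Per-QTL power is the fraction
#' of replicates in which the QTL is detected; overall power is the mean
#' per-QTL power; FDR is pooled over replicates (total false positives /
#' total calls, 0 when there are no calls).
#'
#' @param calls_list List (one element per simulation replicate) of call
#'   tables as returned by [call_qtls()].
#' @param truth `data.frame` of true QTLs with columns `chr`, `pos` (rows
#'   of a `"trait_arch"` with `type == "qtl"`).
#' @param window Detection window in cM, centered at the QTL/call.
#' @return List of class `"qtl_eval"`: `per_qtl_power` (fraction per true
#'   QTL), `overall_power` (percent), `fdr` (fraction), `n_calls`, `n_fp`.
#' @export
evaluate_calls <- function(calls_list, truth, window = 10) {
  if (window <= 0) stop("window must be positive")
  half <- window / 2
  truth <- truth[if ("type" %in% names(truth)) truth$type == "qtl"
                 else rep(TRUE, nrow(truth)), , drop = FALSE]
  nq <- nrow(truth)
  detected <- matrix(FALSE, length(calls_list), nq)
  n_calls <- n_fp <- 0L
  for (rpl in seq_along(calls_list)) {
    calls <- calls_list[[rpl]]
    if (is.null(calls) || nrow(calls) == 0) next
    n_calls <- n_calls + nrow(calls)
    near <- outer(seq_len(nrow(calls)), seq_len(nq), function(i, q)
      calls$chr[i] == truth$chr[q] & abs(calls$pos[i] - truth$pos[q]) <= half)
    detected[rpl, ] <- apply(near, 2, any)
    n_fp <- n_fp + sum(!apply(near, 1, any))
  }
  per_qtl <- colMeans(detected)
  names(per_qtl) <- sprintf("%s@%g", truth$chr, truth$pos)
  structure(list(per_qtl_power = per_qtl,
                 overall_power = 100 * mean(per_qtl),
                 fdr = if (n_calls > 0) n_fp / n_calls else 0,
                 n_calls = n_calls, n_fp = n_fp),
            class = "qtl_eval")
}

#' @export
print.qtl_eval <- function(x, ...) {
  cat(sprintf("overall power %.1f%%   FDR %.4f  (%d FP / %d calls)\n",
              x$overall_power, x$fdr, x$n_fp, x$n_calls))
  invisible(x)
}

#' Pointwise power curve
#'
#' Per scan-grid position, the fraction of replicates whose LOD exceeds
#' that replicate's threshold.
#'
#' @param profiles List of `"scan_profile"`s on a common grid.
#' @param thresholds Numeric vector, one threshold per replicate.
#' @return `data.frame` with `chr`, `pos`, `power`.
#' @export
pointwise_power <- function(profiles, thresholds) {
  if (length(profiles) != length(thresholds))
    stop("one threshold per profile is required")
  g0 <- profiles[[1]][, c("chr", "pos")]
  hits <- numeric(nrow(g0))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (nrow(p) != nrow(g0) || any(p$chr != g0$chr) || any(p$pos != g0$pos))
      stop("profiles are not on a common scan grid")
    hits <- hits + (p$lod > thresholds[i])
  }
  data.frame(chr = g0$chr, pos = g0$pos, power = hits / length(profiles))
}
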