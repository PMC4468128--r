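#' Inverse square root of the within-block covariance
#'
#' For one incomplete block of size `k` the covariance of its plots (in
#' units of `sigma^2`) is `I + delta J`, with `J` the all-ones matrix.  Its
#' inverse square root has the closed form
#' `I + ((1 + k delta)^(-1/2) - 1) / k * J`; applied block by block it
#' realizes `Sigma^(-1/2)` for the whole experiment, since plots in
#' different blocks are independent.
#'
#' @param k Block size.
#' @param delta Block-to-error variance ratio (>= 0).
#' @return A `k x k` symmetric matrix.
#' @examples
#' A <- block_whitener(2, 1)
#' A %*% (diag(2) + 1) %*% A  # identity
#' @export
block_whitener <- function(k, delta) {
  if (delta < 0) stop("delta must be non-negative")
  if (k < 1) stop("k must be >= 1")
  a <- ((1 + k * delta)^(-0.5) - 1) / k
  diag(k) + a
}

# apply the block whitener to a vector or matrix whose rows are grouped
# into equal-size-k blocks indexed by `block`
whiten_blocks <- function(x, block, k, delta) {
  a <- ((1 + k * delta)^(-0.5) - 1) / k
  if (a == 0) return(x)
  xm <- as.matrix(x)
  bs <- rowsum(xm, block, reorder = FALSE)
  out <- xm + a * bs[match(block, unique(block)), , drop = FALSE]
  if (is.matrix(x)) out else drop(out)
}

#' Whiten a lattice experiment
#'
#' Pre-multiplies the plot-level response and the fixed design columns
#' (intercept and replication dummies) by the block-diagonal
#' `Sigma^(-1/2)` built from [block_whitener()], so that the residuals of
#' the whitened model are homoscedastic and uncorrelated and the QTL scan
#' can proceed by ordinary least squares.  With `delta = 0` everything is
#' returned untransformed.
#'
#' @param records Plot-level `"pheno_records"`.
#' @param layout The matching `"lattice_layout"`.
#' @param delta Block-to-error variance ratio, normally `lattice_anova()$delta`.
#' @return List of class `"whitened_data"`: `y` (whitened response), `base`
#'   (whitened intercept + replication columns), `expand(M)` (a function
#'   mapping a lines x m matrix of genotype columns to their whitened
#'   plot-level expansion), `line` (line index per plot), `n`, `delta`.
#' @export
whiten_lattice <- function(records, layout, delta) {
  if (is.null(delta) || is.na(delta))
    stop("delta must be supplied (e.g. from lattice_anova)")
  k <- attr(layout, "k")
  rec <- .align_records(records, layout)
  block <- .global_block(rec$rep, rec$block, k)
  line <- as.integer(factor(rec$line))
  repf <- factor(rec$rep)
  base <- stats::model.matrix(~ repf)
  expand <- function(M) {
    M <- as.matrix(M)
    whiten_blocks(M[line, , drop = FALSE], block, k, delta)
  }
  structure(list(y = whiten_blocks(rec$value, block, k, delta),
                 base = whiten_blocks(base, block, k, delta),
                 expand = expand, line = line, block = block,
                 n = nrow(rec), k = k, delta = delta),
            class = "whitened_data")
}

#' LOD score from residual sums of squares
#'
#' `LOD = (n/2) log10(RSS0 / RSS1)` comparing a null model (RSS0) with the
#' model including the tested QTL (RSS1).  Negative values arising from
#' numerical noise are clamped at zero.
#'
#' @param rss0,rss1 Residual sums of squares of the null and QTL models.
#' @param n Number of observations.
#' @return LOD score(s).
#' @export
lod_score <- function(rss0, rss1, n) {
  if (any(rss0 <= 0) || any(rss1 <= 0)) stop("RSS must be positive")
  pmax(0, n / 2 * log10(rss0 / rss1))
}

# orthonormal basis of the column span of X
.orth <- function(X) {
  qx <- qr(X)
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

#' Forward stepwise selection of covariate markers
#'
#' Selects `p` background markers by forward stepwise least squares: at
#' each step the marker giving the largest residual-sum-of-squares
#' reduction (given the base design and the markers already chosen) enters.
#' Ties break deterministically in favour of the earlier column (map
#' order); markers collinear with the current model cannot enter.
#'
#' @param M Observed marker matrix on the response's observational scale
#'   (lines x markers for mean responses; whitened plot expansion for the
#'   plot-level model).
#' @param y Response vector (same scale as `M` rows).
#' @param base Base design matrix (e.g. intercept, replication dummies).
#' @param p Number of covariates to select (>= 0).
#' @return Integer vector of selected column indices (length `p`), with the
#'   columns' names if `M` has them.
#' @export
select_covariates <- function(M, y, base = matrix(1, length(y), 1), p = 3) {
  if (p < 0) stop("p must be >= 0")
  if (p > ncol(M)) stop("p exceeds the number of candidate markers")
  sel <- integer(0)
  if (p == 0) return(sel)
  U <- .orth(base)
  yt <- y - U %*% crossprod(U, y)
  Mt <- M - U %*% crossprod(U, M)
  tol <- 1e-8 * nrow(M)
  for (step in seq_len(p)) {
    num <- drop(crossprod(Mt, yt))
    den <- colSums(Mt^2)
    gain <- ifelse(den > tol, num^2 / den, -Inf)
    if (length(sel)) gain[sel] <- -Inf
    if (!any(is.finite(gain)))
      stop("no remaining marker is linearly independent of the model")
    j <- which.max(gain)
    sel <- c(sel, j)
    v <- Mt[, j] / sqrt(den[j])
    yt <- yt - v * sum(v * yt)
    Mt <- Mt - tcrossprod(v, drop(crossprod(Mt, v)))
  }
  names(sel) <- colnames(M)[sel]
  sel
}

# Core scan: averaged LOD over imputation draws at every grid position.
#
# Glist    list (length D) of lines x P binary matrices on the scan grid
# grid     data.frame chr, pos for the P columns
# y        response vector (length n)
# base     n x b fixed design (already whitened where applicable)
# covar    n x p covariate columns (already expanded/whitened), may be NULL
# covar_chr, covar_pos  map coordinates of the covariates
# window   exclusion window in cM (covariates within <= window of the test
#          position on the same chromosome leave both models)
# expand   function mapping a lines x m matrix to its n x m design columns
# max_only if TRUE return only the genome-wide maximum averaged LOD
.scan_core <- function(Glist, grid, y, base, covar = NULL,
                       covar_chr = NULL, covar_pos = NULL,
                       window = 10, expand = identity, max_only = FALSE) {
  n <- length(y)
  D <- length(Glist)
  P <- nrow(grid)
  p <- if (is.null(covar)) 0L else ncol(covar)
  if (p > 0) {
    excl <- lapply(seq_len(P), function(i)
      which(covar_chr == grid$chr[i] &
              abs(covar_pos - grid$pos[i]) <= window))
    key <- vapply(excl, paste, "", collapse = ",")
  } else {
    excl <- rep(list(integer(0)), P)
    key <- rep("", P)
  }
  lod_sum <- eff_sum <- numeric(P)
  tol <- 1e-8 * n
  for (kset in unique(key)) {
    idx <- which(key == kset)
    keep <- setdiff(seq_len(p), excl[[idx[1]]])
    U <- .orth(if (length(keep)) cbind(base, covar[, keep, drop = FALSE])
               else base)
    yt <- drop(y - U %*% crossprod(U, y))
    rss0 <- sum(yt^2)
    for (d in seq_len(D)) {
      X <- expand(Glist[[d]][, idx, drop = FALSE])
      Xt <- X - U %*% crossprod(U, X)
      num <- drop(crossprod(Xt, yt))
      den <- colSums(Xt^2)
      ok <- den > tol
      beta <- ifelse(ok, num / den, 0)
      rss1 <- pmax(rss0 - ifelse(ok, num^2 / den, 0), rss0 * 1e-12)
      lod_sum[idx] <- lod_sum[idx] + pmax(0, n / 2 * log10(rss0 / rss1))
      eff_sum[idx] <- eff_sum[idx] + beta
    }
  }
  if (max_only) return(max(lod_sum) / D)
  data.frame(chr = grid$chr, pos = grid$pos,
             lod = lod_sum / D, effect = eff_sum / D)
}

# derive (Glist, grid) from an imputation-draws object, optionally with
# genotype rows permuted over line labels
.draw_matrices <- function(draws, perm = NULL) {
  G <- draws$draws  # D x lines x positions
  D <- dim(G)[1]
  Glist <- lapply(seq_len(D), function(d) {
    M <- G[d, , , drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, ncol = dim(G)[3])
    if (!is.null(perm)) M <- M[perm, , drop = FALSE]
    M
  })
  list(Glist = Glist, grid = draws$grid)
}

# build the method-specific pieces of a scan: response, base design,
# expansion and the covariate-selection marker matrix on the right scale
.scan_setup <- function(method, draws, markers, response, layout = NULL,
                        delta = NULL, perm = NULL) {
  M <- if (is.null(perm)) markers else markers[perm, , drop = FALSE]
  if (method %in% c("rcbd", "amld")) {
    y <- as.numeric(response)
    base <- matrix(1, length(y), 1)
    expand <- identity
    Msel <- M
  } else if (method == "cimld") {
    wd <- response
    if (!inherits(wd, "whitened_data"))
      wd <- whiten_lattice(response, layout, delta)
    y <- wd$y
    base <- wd$base
    expand <- wd$expand
    Msel <- expand(M)
  } else stop("unknown method: ", method)
  list(y = y, base = base, expand = expand, M = M, Msel = Msel)
}

#' Composite interval mapping scan
#'
#' Genome scan with background marker covariates under one of three
#' response strategies:
#' \describe{
#'   \item{`"rcbd"`}{arithmetic line means (ignores the incomplete blocks,
#'     i.e. treats the experiment as a randomized complete block design);}
#'   \item{`"amld"`}{lattice-adjusted line means from [adjusted_means()];}
#'   \item{`"cimld"`}{the full plot-level model: the response, the
#'     intercept/replication design, the covariate markers and the tested
#'     genotype column (expanded to plots) are whitened by the
#'     block-covariance inverse square root, then tested by OLS.}
#' }
#' At each grid position and each imputation draw, the QTL model adds the
#' imputed test-locus genotype to the base + covariate model (covariates
#' within `window` cM of the position are dropped from both models) and
#' `LOD = (n/2) log10(RSS0/RSS1)` is computed; LOD scores are averaged
#' over the draws and the effect estimate is the average coefficient.
#'
#' @param method `"rcbd"`, `"amld"` or `"cimld"`.
#' @param draws Imputation draws from [impute_draws()].
#' @param markers Observed marker matrix (`"ril_geno"`, lines x markers)
#'   used for covariate selection and covariate columns.
#' @param response Line means (rcbd/amld) or plot-level `"pheno_records"`
#'   / `"whitened_data"` (cimld).
#' @param layout,delta Required for `method = "cimld"` when `response` is a
#'   `"pheno_records"`: the lattice layout and the plug-in variance ratio
#'   (from [lattice_anova()]).
#' @param covariates Covariate marker columns (indices into `markers`), or
#'   `NULL` to select `p` of them by [select_covariates()].
#' @param p Number of covariate markers when selecting (default 10;
#'   enough to tag a two-digit number of background QTL regions).
#' @param window Covariate exclusion window in cM.
#' @return A `data.frame` of class `"scan_profile"` with columns `chr`,
#'   `pos`, `lod`, `effect` and attributes `method`, `covariates`.
#' @export
cim_scan <- function(method = c("cimld", "amld", "rcbd"), draws, markers,
                     response, layout = NULL, delta = NULL,
                     covariates = NULL, p = 10, window = 10) {
  method <- match.arg(method)
  su <- .scan_setup(method, draws, markers, response, layout, delta)
  if (is.null(covariates))
    covariates <- select_covariates(su$Msel, su$y, su$base, p)
  covar <- if (length(covariates))
    su$Msel[, covariates, drop = FALSE] else NULL
  dm <- .draw_matrices(draws)
  prof <- .scan_core(dm$Glist, dm$grid, su$y, su$base, covar,
                     attr(markers, "chr")[covariates],
                     attr(markers, "pos")[covariates],
                     window, su$expand)
  structure(prof, method = method, covariates = covariates,
            class = c("scan_profile", "data.frame"))
}
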