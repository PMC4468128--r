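#' Construct a simple lattice layout
#'
#' A simple lattice accommodates `t = k^2` lines in two replications of `k`
#' incomplete blocks of size `k`: the lines are arranged in a `k x k`
#' square; blocks of replication 1 are its rows and blocks of replication 2
#' its columns, so any two lines meet in at most one block.
#'
#' @param k Block size (>= 2); the design holds `k^2` lines.
#' @param randomize Randomize the line-to-cell assignment and block order
#'   (uses the current RNG stream).
#' @return A `data.frame` of class `"lattice_layout"` with columns `rep`,
#'   `block` (1..k within replication) and `line` (1..k^2), one row per
#'   plot, plus attributes `k`, `r`, `t`.
#' @examples
#' lay <- make_simple_lattice(3, randomize = FALSE)
#' table(lay$rep, lay$block)
#' @export
make_simple_lattice <- function(k, randomize = TRUE) {
  if (k < 2) stop("block size k must be >= 2")
  t <- k * k
  square <- matrix(if (randomize) sample.int(t) else seq_len(t), k, k)
  b1 <- if (randomize) sample.int(k) else seq_len(k)
  b2 <- if (randomize) sample.int(k) else seq_len(k)
  rows <- lapply(seq_len(k), function(j) {
    data.frame(rep = 1L, block = j, line = square[b1[j], ])
  })
  cols <- lapply(seq_len(k), function(j) {
    data.frame(rep = 2L, block = j, line = square[, b2[j]])
  })
  lay <- do.call(rbind, c(rows, cols))
  rownames(lay) <- NULL
  structure(lay, k = k, r = 2L, t = t,
            class = c("lattice_layout", "data.frame"))
}

# canonical plot order and global block index (1..r*k)
.layout_order <- function(lay) order(lay$rep, lay$block, lay$line)

.global_block <- function(rep, block, k) (as.integer(rep) - 1L) * k +
  as.integer(block)

#' Simulate plot-level phenotypes on a lattice layout
#'
#' Generates `y_ijk = alpha_i + gamma_j(i) + g_k + e_ijk` for every plot of
#' `layout`: fixed replication effects `alpha = (0, rep_effect, ...)`,
#' random block-within-replication effects `gamma ~ N(0, delta * sigma^2)`
#' and errors `e ~ N(0, sigma^2)`, where `sigma^2 = Var(g) * (1/h2 - 1)` is
#' calibrated from the realized variance of the genotypic values `g` so
#' that `h2` is the total (plot-level) heritability.
#'
#' @param g Genotypic value per line (length `k^2`, in line-index order).
#' @param layout A `"lattice_layout"`.
#' @param h2 Total heritability in (0, 1]; `h2 = 1` gives noiseless data.
#' @param delta Block-to-error variance ratio `sigma_b^2 / sigma^2` (>= 0).
#' @param rep_effect Fixed effect added to every plot of replication 2
#'   (and, recycled, of later replications); replication 1 is the reference.
#' @return A `data.frame` of class `"pheno_records"` with columns `rep`,
#'   `block`, `line`, `value` in canonical plot order, with attributes
#'   `sigma2`, `sigma_b2`, `delta`, `block_effects`.
#' @export
sim_lattice_phenotypes <- function(g, layout, h2 = 0.7, delta = 1,
                                   rep_effect = 2) {
  k <- attr(layout, "k"); r <- attr(layout, "r"); t <- attr(layout, "t")
  if (length(g) != t) stop("length(g) must equal the number of lines k^2")
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  if (delta < 0) stop("delta must be non-negative")
  sigma2 <- stats::var(g) * (1 / h2 - 1)
  lay <- layout[.layout_order(layout), ]
  gb <- .global_block(lay$rep, lay$block, k)
  alpha <- c(0, rep(rep_effect, r - 1L))
  gamma <- stats::rnorm(r * k, 0, sqrt(delta * sigma2))
  eps <- stats::rnorm(nrow(lay), 0, sqrt(sigma2))
  y <- alpha[lay$rep] + gamma[gb] + g[lay$line] + eps
  structure(data.frame(rep = lay$rep, block = lay$block, line = lay$line,
                       value = y),
            sigma2 = sigma2, sigma_b2 = delta * sigma2, delta = delta,
            block_effects = gamma,
            class = c("pheno_records", "data.frame"))
}

# align phenotype records with a layout; returns records in canonical order
.align_records <- function(records, layout) {
  need <- c("rep", "block", "line", "value")
  if (!all(need %in% names(records))) stop("records must have columns ",
                                           paste(need, collapse = ", "))
  rec <- records[order(records$rep, records$block, records$line), ]
  lay <- layout[.layout_order(layout), ]
  if (nrow(rec) != nrow(lay) ||
      !all(rec$rep == lay$rep & rec$block == lay$block &
           rec$line == lay$line))
    stop("phenotype records do not match the layout (missing plots are ",
         "not supported; complete the design or drop the line)")
  if (anyNA(rec$value)) stop("missing plot values are not supported")
  rec
}

# Method-of-moments variance components for y = X beta + sum_v Z_v u_v + e.
# Nested projections add one random term at a time; expected sums of
# squares give a triangular linear system in (sigma_v^2, sigma^2).
.moment_components <- function(y, X, Zlist) {
  n <- length(y)
  qrs <- vector("list", length(Zlist) + 1L)
  M <- X
  qrs[[1]] <- qr(M)
  for (v in seq_along(Zlist)) {
    M <- cbind(M, Zlist[[v]])
    qrs[[v + 1L]] <- qr(M)
  }
  nv <- length(Zlist)
  ranks <- vapply(qrs, `[[`, 0L, "rank")
  full <- qrs[[nv + 1L]]
  df_res <- n - ranks[nv + 1L]
  if (df_res <= 0) stop("degenerate design: no residual degrees of freedom")
  rss <- sum(qr.resid(full, y)^2)
  sigma2 <- rss / df_res
  # SS for adding term v (adjusted for everything before it and for X)
  ss <- df <- numeric(nv)
  coefmat <- matrix(0, nv, nv)
  for (v in seq_len(nv)) {
    f1 <- qr.fitted(qrs[[v + 1L]], y); f0 <- qr.fitted(qrs[[v]], y)
    ss[v] <- sum(f1^2) - sum(f0^2)
    df[v] <- ranks[v + 1L] - ranks[v]
    if (df[v] <= 0) stop("degenerate design: random term ", v,
                         " is confounded with earlier terms")
    for (w in seq_len(nv)) {
      Zw <- Zlist[[w]]
      coefmat[v, w] <- sum(qr.fitted(qrs[[v + 1L]], Zw)^2) -
        sum(qr.fitted(qrs[[v]], Zw)^2)
    }
  }
  # E[ss_v] = sum_w coef[v,w] sigma_w^2 + df_v sigma^2; solve bottom-up
  comp <- solve(coefmat, ss - df * sigma2)
  comp <- pmax(comp, 0)
  list(components = comp, sigma2 = sigma2, ss = ss, df = df,
       df_res = df_res, rss = rss)
}

#' Lattice ANOVA variance components
#'
#' Fits the fixed-line, fixed-replication, random-block model to a complete
#' simple-lattice experiment and estimates the error variance `sigma^2`
#' (intra-block residual mean square) and block-within-replication variance
#' `sigma_b^2` by the method of moments: the block sum of squares adjusted
#' for replications and lines is equated to its expectation; a negative
#' moment estimate is truncated at zero.  The ratio `delta =
#' sigma_b^2 / sigma^2` is the plug-in used for whitening and adjusted
#' means.
#'
#' @param records Plot-level `"pheno_records"`.
#' @param layout The matching `"lattice_layout"`.
#' @return List of class `"lattice_vc"` with `sigma2`, `sigma_b2`, `delta`
#'   and an `anova` table (source/df/SS/MS).
#' @export
lattice_anova <- function(records, layout) {
  k <- attr(layout, "k")
  rec <- .align_records(records, layout)
  y <- rec$value
  repf <- factor(rec$rep)
  linef <- factor(rec$line)
  blockf <- factor(.global_block(rec$rep, rec$block, k))
  X <- stats::model.matrix(~ repf + linef)
  Z <- stats::model.matrix(~ blockf - 1)
  mm <- .moment_components(y, X, list(Z))
  sigma2 <- mm$sigma2
  sigma_b2 <- mm$components[1]
  # sequential SS for the display table
  q0 <- qr(matrix(1, length(y), 1))
  qr_rep <- qr(stats::model.matrix(~ repf))
  ss_rep <- sum(qr.fitted(qr_rep, y)^2) - sum(qr.fitted(q0, y)^2)
  qr_line <- qr(X)
  ss_line <- sum(qr.fitted(qr_line, y)^2) - sum(qr.fitted(qr_rep, y)^2)
  tab <- data.frame(
    source = c("replication", "lines (adj. reps)",
               "blocks within reps (adj. lines)", "residual"),
    df = c(qr_rep$rank - 1L, qr_line$rank - qr_rep$rank, mm$df[1],
           mm$df_res),
    SS = c(ss_rep, ss_line, mm$ss[1], mm$rss))
  tab$MS <- tab$SS / tab$df
  structure(list(sigma2 = sigma2, sigma_b2 = sigma_b2,
                 delta = sigma_b2 / sigma2, anova = tab),
            class = "lattice_vc")
}

#' @export
print.lattice_vc <- function(x, ...) {
  cat("Lattice ANOVA variance components\n")
  print(x$anova, row.names = FALSE)
  cat(sprintf("\nsigma^2 = %.4g   sigma_b^2 = %.4g   delta = %.4g\n",
              x$sigma2, x$sigma_b2, x$delta))
  invisible(x)
}

#' Arithmetic line means
#'
#' Per-line averages of the plot observations, ignoring the incomplete
#' block structure (the response of the RCBD strategy).
#'
#' @param records Plot-level `"pheno_records"`.
#' @return Named numeric vector (one mean per line, in line order) with
#'   attribute `kind = "arithmetic"`.
#' @export
arithmetic_means <- function(records) {
  linef <- factor(records$line)
  m <- rowsum(records$value, linef) / as.vector(table(linef))
  structure(drop(m), names = levels(linef), kind = "arithmetic")
}

#' Lattice-adjusted line means
#'
#' Generalized-least-squares estimates of the line means under fixed lines
#' and replications and random blocks with covariance
#' `sigma^2 (delta Z Z' + I)`, computed by whitening the observations and
#' design with the block whitener and solving ordinary least squares.  Each
#' adjusted mean is the line's estimate at the average replication level,
#' i.e. the intra-/inter-block information-combining "adjusted mean" of
#' classical lattice analysis.  With `delta = 0` they reduce to arithmetic
#' means.
#'
#' @param records Plot-level `"pheno_records"`.
#' @param layout The matching `"lattice_layout"`.
#' @param vc A `"lattice_vc"` from [lattice_anova()] (or a list with a
#'   `delta` element).
#' @return Named numeric vector with attribute `kind = "adjusted"`.
#' @export
adjusted_means <- function(records, layout, vc) {
  k <- attr(layout, "k")
  delta <- vc$delta
  if (is.null(delta) || is.na(delta)) stop("vc must supply delta")
  rec <- .align_records(records, layout)
  blockf <- .global_block(rec$rep, rec$block, k)
  repf <- factor(rec$rep)
  linef <- factor(rec$line)
  X <- stats::model.matrix(~ repf + linef)
  Xw <- whiten_blocks(X, blockf, k, delta)
  yw <- whiten_blocks(rec$value, blockf, k, delta)
  fit <- qr(Xw)
  if (fit$rank < ncol(Xw)) stop("singular design in adjusted-means solve")
  beta <- qr.coef(fit, yw)
  r <- nlevels(repf); t <- nlevels(linef)
  mu <- beta[1]
  rep_eff <- c(0, beta[seq_len(r - 1L) + 1L])
  line_eff <- c(0, beta[(r + 1L):(r + t - 1L)])
  structure(mu + mean(rep_eff) + line_eff, names = levels(linef),
            kind = "adjusted")
}

#' Broad-sense heritability from multi-environment variance components
#'
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_ge^2 / s + sigma^2 / (s r))` on a
#' line-mean basis across `s` environments with `r` replications each.
#'
#' @param sigma_g2 Genotypic (line) variance.
#' @param sigma_ge2 Line-by-environment interaction variance.
#' @param sigma2 Error variance.
#' @param s Number of environments; `r` replications per environment.
#' @param r Replications per environment.
#' @return Heritability in `[0, 1]`.
#' @export
estimate_heritability <- function(sigma_g2, sigma_ge2, sigma2, s, r) {
  if (any(c(sigma_g2, sigma_ge2, sigma2) < 0)) stop("components must be >= 0")
  if (s < 1 || r < 1) stop("s and r must be >= 1")
  denom <- sigma_g2 + sigma_ge2 / s + sigma2 / (s * r)
  if (denom == 0) stop("all variance components are zero")
  sigma_g2 / denom
}

#' Multi-environment variance components for line trials
#'
#' Method-of-moments components for the random-effects model
#' `y = env + rep(env) + line + line:env + block(env, rep) + error`
#' (environments and replications fixed, the rest random), fitted to plot records carrying an `env` column; used to feed
#' [estimate_heritability()].
#'
#' @param records Plot records with columns `env`, `rep`, `block`, `line`,
#'   `value`; blocks of constant size `k` within each (env, rep).
#' @param k Block size.
#' @return List with `sigma_g2`, `sigma_ge2`, `sigma_b2`, `sigma2`, `s`, `r`.
#' @export
multi_env_components <- function(records, k) {
  envf <- factor(records$env)
  repf <- interaction(envf, factor(records$rep), drop = TRUE)
  linef <- factor(records$line)
  gef <- interaction(linef, envf, drop = TRUE)
  blockf <- interaction(repf, factor(records$block), drop = TRUE)
  X <- stats::model.matrix(~ envf + repf)
  Zg <- stats::model.matrix(~ linef - 1)
  Zge <- stats::model.matrix(~ gef - 1)
  Zb <- stats::model.matrix(~ blockf - 1)
  mm <- .moment_components(records$value, X, list(Zg, Zge, Zb))
  list(sigma_g2 = mm$components[1], sigma_ge2 = mm$components[2],
       sigma_b2 = mm$components[3], sigma2 = mm$sigma2,
       s = nlevels(envf), r = nlevels(repf) / nlevels(envf))
}
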