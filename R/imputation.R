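#' Conditional genotype probability between two flanking markers
#'
#' Probability that a RIL carries parental allele 1 at a locus, given the
#' observed genotypes of its two flanking markers and the map distances to
#' them, under the two-state Markov chain with RIL-scale recombination
#' fractions `R = ril_adjust(haldane_r(d))`.  A missing flank (`NA`) is
#' marginalized with prior 0.5; with both flanks missing the probability
#' is 0.5.
#'
#' @param left,right Flanking genotypes, each 0, 1 or `NA`.
#' @param d_left,d_right Distances (cM) to the left/right flank (>= 0).
#' @return `P(genotype = 1 | flanks)`.
#' @examples
#' conditional_probability(1, 1, 10, 10)
#' @export
conditional_probability <- function(left, right, d_left, d_right) {
  RL <- ril_adjust(haldane_r(d_left))
  RR <- ril_adjust(haldane_r(d_right))
  # P(locus = 1 | left), treating NA as prior 0.5
  p_from_left <- ifelse(is.na(left), 0.5, ifelse(left == 1, 1 - RL, RL))
  # likelihood P(right | locus = s)
  l1 <- ifelse(is.na(right), 0.5, ifelse(right == 1, 1 - RR, RR))
  l0 <- ifelse(is.na(right), 0.5, ifelse(right == 1, RR, 1 - RR))
  num <- p_from_left * l1
  num / (num + (1 - p_from_left) * l0)
}

#' Multiple imputation of pseudo-marker genotypes
#'
#' Draws `n_draws` complete genotype configurations on the scan grid
#' (markers plus pseudo-markers every `step` cM), conditional on all
#' observed marker genotypes of each line, by forward filtering and
#' backward sampling of the two-state RIL hidden Markov chain.  At observed
#' marker positions every draw reproduces the data; draws are independent
#' given the data.  Uses the current RNG stream.
#'
#' @param geno Observed marker genotypes (`"ril_geno"`, entries 0/1/`NA`),
#'   columns matching `map` markers by name.
#' @param map The `"genetic_map"`.
#' @param step Pseudo-marker spacing in cM.
#' @param n_draws Number of imputations D (>= 1).
#' @return List of class `"imputation_draws"`: `draws` (integer array
#'   D x lines x positions), `grid` (the `"locus_grid"` restricted to
#'   marker/pseudo loci), `n_draws`.
#' @export
impute_draws <- function(geno, map, step = 2, n_draws = 16) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (step <= 0) stop("step must be positive")
  grid <- locus_grid(map, step = step)
  n_lines <- nrow(geno)
  D <- as.integer(n_draws)
  out <- array(0L, c(D, n_lines, nrow(grid)),
               dimnames = list(NULL, rownames(geno), grid$id))
  for (ch in unique(grid$chr)) {
    cols <- which(grid$chr == ch)
    g <- grid[cols, ]
    L <- nrow(g)
    obs <- matrix(NA_real_, n_lines, L)
    mk <- which(!is.na(g$marker))
    if (length(mk) == 0)
      stop("chromosome ", ch, " has no observed markers")
    j <- match(g$marker[mk], colnames(geno))
    if (anyNA(j)) stop("markers of chromosome ", ch,
                       " missing from the genotype matrix")
    obs[, mk] <- geno[, j]
    R <- if (L > 1) ril_adjust(haldane_r(diff(g$pos))) else numeric(0)
    # forward filter: f[, l] = P(state = 1 | obs_1..l) per line
    f <- matrix(0, n_lines, L)
    cur <- rep(0.5, n_lines)
    for (l in seq_len(L)) {
      if (l > 1) cur <- cur * (1 - R[l - 1]) + (1 - cur) * R[l - 1]
      o <- obs[, l]
      cur <- ifelse(is.na(o), cur, o)
      f[, l] <- cur
    }
    # backward sampling, vectorized over lines and draws
    S <- matrix(0L, D * n_lines, L)
    fl <- rep(f[, L], each = D)
    S[, L] <- as.integer(stats::runif(D * n_lines) < fl)
    for (l in rev(seq_len(L - 1L))) {
      v <- S[, l + 1L]
      fj <- rep(f[, l], each = D)
      t1 <- ifelse(v == 1L, 1 - R[l], R[l])   # T(1 -> v)
      t0 <- ifelse(v == 1L, R[l], 1 - R[l])   # T(0 -> v)
      p1 <- fj * t1 / (fj * t1 + (1 - fj) * t0)
      S[, l] <- as.integer(stats::runif(D * n_lines) < p1)
    }
    for (l in seq_len(L))
      out[, , cols[l]] <- S[, l]
  }
  structure(list(draws = out, grid = grid, n_draws = D),
            class = "imputation_draws")
}
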