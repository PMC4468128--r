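#' Simulate RIL genotypes along a locus grid
#'
#' Genotypes are parental-origin dummies (0/1) at every locus of `grid`.
#' Each chromosome is an independent two-state Markov chain along the
#' ordered loci: the first locus is Bernoulli(0.5) and the switch
#' probability between adjacent loci at distance `d` cM is the RIL-scale
#' recombination fraction `ril_adjust(haldane_r(d))`.  Lines are independent.
#' Uses the current RNG stream; call [set.seed()] for reproducibility.
#'
#' @param grid A `"locus_grid"` (or `"genetic_map"`, simulated at markers
#'   only).
#' @param n_lines Number of RILs (>= 2).
#' @param line_ids Optional line names; default `L001`, `L002`, ...
#' @return Integer matrix `n_lines` x `n_loci` of 0/1 with `dimnames`
#'   (line ids, locus ids) and attributes `chr`, `pos`, `type` describing
#'   the columns; class `"ril_geno"`.
#' @export
sim_ril_genotypes <- function(grid, n_lines, line_ids = NULL) {
  if (inherits(grid, "genetic_map")) grid <- locus_grid(grid, step = NULL)
  stopifnot(inherits(grid, "locus_grid"))
  if (nrow(grid) == 0) stop("empty locus grid")
  if (n_lines < 2) stop("need at least 2 lines")
  if (is.null(line_ids))
    line_ids <- sprintf("L%03d", seq_len(n_lines))
  G <- matrix(0L, n_lines, nrow(grid),
              dimnames = list(line_ids, grid$id))
  col <- 1
  for (ch in unique(grid$chr)) {
    pos <- grid$pos[grid$chr == ch]
    n_loc <- length(pos)
    g <- as.integer(stats::runif(n_lines) < 0.5)
    G[, col] <- g
    if (n_loc > 1) {
      R <- ril_adjust(haldane_r(diff(pos)))
      for (j in seq_len(n_loc - 1)) {
        switch <- stats::runif(n_lines) < R[j]
        g <- ifelse(switch, 1L - g, g)
        G[, col + j] <- g
      }
    }
    col <- col + n_loc
  }
  structure(G, chr = grid$chr, pos = grid$pos, type = grid$type,
            class = c("ril_geno", "matrix", "array"))
}

#' Subset a genotype matrix to its genotyped markers
#'
#' @param geno A `"ril_geno"` matrix from [sim_ril_genotypes()].
#' @return A `"ril_geno"` matrix restricted to columns of type `"marker"`.
#' @export
marker_genotypes <- function(geno) {
  keep <- attr(geno, "type") == "marker"
  structure(geno[, keep, drop = FALSE],
            chr = attr(geno, "chr")[keep], pos = attr(geno, "pos")[keep],
            type = attr(geno, "type")[keep],
            class = c("ril_geno", "matrix", "array"))
}

#' Ten-QTL trait architecture with polygenic background
#'
#' The classical ten-QTL configuration used in composite-interval-mapping
#' power studies (Zeng 1994), on a five-chromosome 150 cM genome: three
#' QTLs on each of chromosomes 1-3, one on chromosome 4, none on
#' chromosome 5, with fixed positions and additive effects.  On top of the
#' QTLs, `n_polygenes` small-effect background loci are placed uniformly at
#' random over the genome with effects drawn from U(0, `polygene_max`).
#' Effects are on the 0/1 parental-origin dummy coding.
#'
#' @param n_polygenes Number of polygenic background loci.
#' @param polygene_max Upper bound of the uniform polygene effect.
#' @param n_chr,chr_len Genome dimensions over which polygenes are placed.
#' @return A `data.frame` of class `"trait_arch"` with columns `chr`, `pos`,
#'   `effect`, `type` (`qtl`/`polygene`).
#' @examples
#' set.seed(1)
#' arch <- default_architecture()
#' sum(arch$type == "qtl")
#' @export
default_architecture <- function(n_polygenes = 100, polygene_max = 0.1,
                                 n_chr = 5, chr_len = 150) {
  qtl <- data.frame(
    chr = as.character(rep(1:4, c(3, 3, 3, 1))),
    pos = c(16, 48, 108, 3, 43, 77, 33, 68, 129, 26),
    effect = c(0.42, 0.75, 0.58, 1.02, -1.23, -1.26, -0.46, 1.61, 0.88, 0.74),
    type = "qtl", stringsAsFactors = FALSE)
  arch <- qtl
  if (n_polygenes > 0) {
    poly <- data.frame(
      chr = as.character(sample.int(n_chr, n_polygenes, replace = TRUE)),
      pos = stats::runif(n_polygenes, 0, chr_len),
      effect = stats::runif(n_polygenes, 0, polygene_max),
      type = "polygene", stringsAsFactors = FALSE)
    arch <- rbind(arch, poly)
  }
  arch <- arch[order(match(arch$chr, as.character(seq_len(n_chr))), arch$pos), ]
  rownames(arch) <- NULL
  class(arch) <- c("trait_arch", "data.frame")
  arch
}

#' Per-line genotypic values
#'
#' The genotypic value of a line is the dot product of its 0/1 genotypes at
#' the trait loci with the architecture's effects,
#' `g_k = sum_q b_q x_kq` over QTLs and polygenes.
#'
#' @param geno Genotypes from [sim_ril_genotypes()], simulated on a grid
#'   that contains every trait locus of `arch`.
#' @param arch A `"trait_arch"`.
#' @param tol Position-matching tolerance in cM.
#' @return Named numeric vector of genotypic values, one per line.
#' @export
genotypic_values <- function(geno, arch, tol = 1e-6) {
  chr <- attr(geno, "chr"); pos <- attr(geno, "pos")
  idx <- vapply(seq_len(nrow(arch)), function(i) {
    j <- which(chr == arch$chr[i] & abs(pos - arch$pos[i]) <= tol)
    if (length(j) == 0) NA_integer_ else j[1]
  }, integer(1))
  if (anyNA(idx))
    stop("genotypes missing trait-locus columns at: ",
         paste(sprintf("%s@%g", arch$chr[is.na(idx)],
                       arch$pos[is.na(idx)]), collapse = ", "))
  drop(geno[, idx, drop = FALSE] %*% arch$effect)
}
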