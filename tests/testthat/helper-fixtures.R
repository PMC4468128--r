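# Small shared fixtures, built in code.

# a compact two-chromosome genome for fast end-to-end tests
tiny_map <- function() even_map(n_chr = 2, chr_len = 60, n_markers = 7)

tiny_arch <- function(effects = c(1, -0.8)) {
  data.frame(chr = c("1", "2"), pos = c(25, 40), effect = effects,
             type = "qtl", stringsAsFactors = FALSE)
}

# simulate a complete tiny lattice experiment; returns all intermediates
tiny_experiment <- function(k = 6, h2 = 0.6, delta = 2, step = 3,
                            n_draws = 4, arch = tiny_arch(),
                            map = tiny_map()) {
  geno <- sim_ril_genotypes(locus_grid(map, step = NULL,
                                       extra = arch[, c("chr", "pos")]),
                            k^2)
  g <- genotypic_values(geno, arch)
  markers <- marker_genotypes(geno)
  layout <- make_simple_lattice(k)
  records <- sim_lattice_phenotypes(g, layout, h2 = h2, delta = delta)
  vc <- lattice_anova(records, layout)
  draws <- impute_draws(markers, map, step = step, n_draws = n_draws)
  list(map = map, arch = arch, geno = geno, g = g, markers = markers,
       layout = layout, records = records, vc = vc, draws = draws)
}

# dense GLS line-mean / regression oracle with covariance sigma2 (I + delta ZZ')
gls_fit <- function(y, X, block, delta) {
  Z <- stats::model.matrix(~ factor(block) - 1)
  Sigma <- diag(length(y)) + delta * tcrossprod(Z)
  Si <- solve(Sigma)
  beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  rss <- drop(t(y - X %*% beta) %*% Si %*% (y - X %*% beta))
  list(beta = drop(beta), rss = rss)
}
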