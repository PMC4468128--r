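#' Configuration of a power/FDR simulation study
#'
#' Bundles every knob of the simulation experiment comparing the three
#' mapping strategies under different block-variance ratios.  Defaults are
#' the full study conditions: a 196-line RIL population on a five
#' chromosome x 150 cM genome with 16 evenly spaced markers per chromosome,
#' ten QTLs plus 100 polygenes, total heritability 0.7, a 14x14 simple
#' lattice with two replications and replication effect 2, block variance
#' ratios 0.5/1/5/10, 100 replicates and 1000 permutations.  Reduced
#' presets simply pass smaller `n_replicates` / `n_perm` /
#' `perm_replicates`.
#'
#' @param deltas Block-to-error variance ratios to simulate.
#' @param h2 Total heritability of the simulated trait.
#' @param k Lattice block size (`k^2` lines).
#' @param rep_effect Fixed effect of replication 2.
#' @param n_replicates Simulation replicates per delta.
#' @param n_perm Permutations for the permutation threshold rule.
#' @param perm_replicates Number of replicates (per delta) for which
#'   permutation thresholds are computed; `0` disables the permutation
#'   rule; defaults to `n_replicates`.
#' @param fixed_threshold Fixed LOD threshold rule.
#' @param alpha Genome-wide level of the permutation rule.
#' @param step Scan/pseudo-marker grid step (cM).
#' @param n_draws Imputation draws D.
#' @param p Number of covariate markers.
#' @param window Covariate exclusion window (cM).
#' @param min_sep Minimum separation of QTL calls (cM).
#' @param eval_window Detection window for power/FDR (cM, centered).
#' @param n_chr,chr_len,markers_per_chr Genome layout.
#' @param n_polygenes Number of polygenic background loci.
#' @param seed Master seed; all replicate seeds derive from it.
#' @return List of class `"study_config"`.
#' @export
study_config <- function(deltas = c(0.5, 1, 5, 10), h2 = 0.7, k = 14,
                         rep_effect = 2, n_replicates = 100, n_perm = 1000,
                         perm_replicates = n_replicates,
                         fixed_threshold = 2.5, alpha = 0.05, step = 2,
                         n_draws = 16, p = 10, window = 10, min_sep = 10,
                         eval_window = 10, n_chr = 5, chr_len = 150,
                         markers_per_chr = 16, n_polygenes = 100, seed = 1) {
  cfg <- list(deltas = deltas, h2 = h2, k = k, rep_effect = rep_effect,
              n_replicates = as.integer(n_replicates),
              n_perm = as.integer(n_perm),
              perm_replicates = as.integer(perm_replicates),
              fixed_threshold = fixed_threshold, alpha = alpha, step = step,
              n_draws = as.integer(n_draws), p = as.integer(p),
              window = window, min_sep = min_sep, eval_window = eval_window,
              n_chr = as.integer(n_chr), chr_len = chr_len,
              markers_per_chr = as.integer(markers_per_chr),
              n_polygenes = as.integer(n_polygenes), seed = as.integer(seed))
  stopifnot(all(cfg$deltas >= 0), cfg$n_replicates >= 1, cfg$k >= 2,
            cfg$h2 > 0, cfg$h2 <= 1, cfg$n_draws >= 1)
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from a YAML file
#'
#' The file may set any argument of [study_config()]; unset fields keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"study_config"`.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(study_config, vals)
}

.study_methods <- c("rcbd", "amld", "cimld")

#' One end-to-end simulation replicate
#'
#' Simulates a RIL population and lattice phenotypes at one block-variance
#' ratio, runs the three scans on shared imputation draws, applies the
#' fixed and (optionally) permutation threshold rules and calls QTLs.
#'
#' @param config A `"study_config"`.
#' @param delta Block-variance ratio for this replicate.
#' @param seed Replicate seed (all randomness derives from it).
#' @param arch Optional `"trait_arch"`; by default the ten fixed QTLs plus
#'   a fresh draw of the polygenic background (polygene positions and
#'   effects are replicate-level nuisance and are redrawn per replicate).
#' @param permutation Compute the permutation thresholds as well.
#' @return List with `profiles`, `thresholds` (`fixed`, `perm` per method),
#'   `calls` (per method x rule), `delta_hat` and the inputs' summaries.
#' @export
run_replicate <- function(config, delta, seed, arch = NULL,
                          permutation = TRUE) {
  set.seed(seed)
  if (is.null(arch)) {
    arch <- default_architecture(n_polygenes = config$n_polygenes,
                                 n_chr = config$n_chr,
                                 chr_len = config$chr_len)
    # reduced genomes (smoke runs) keep only the loci they can carry
    arch <- arch[arch$chr %in% as.character(seq_len(config$n_chr)) &
                   arch$pos <= config$chr_len, , drop = FALSE]
  }
  map <- even_map(config$n_chr, config$chr_len, config$markers_per_chr)
  grid_sim <- locus_grid(map, step = NULL,
                         extra = arch[, c("chr", "pos")])
  geno <- sim_ril_genotypes(grid_sim, config$k^2)
  g <- genotypic_values(geno, arch)
  markers <- marker_genotypes(geno)
  layout <- make_simple_lattice(config$k)
  records <- sim_lattice_phenotypes(g, layout, h2 = config$h2, delta = delta,
                                    rep_effect = config$rep_effect)
  vc <- lattice_anova(records, layout)
  draws <- impute_draws(markers, map, step = config$step,
                        n_draws = config$n_draws)
  m_arith <- arithmetic_means(records)
  m_adj <- adjusted_means(records, layout, vc)
  wd <- whiten_lattice(records, layout, vc$delta)
  responses <- list(rcbd = m_arith, amld = m_adj, cimld = wd)
  profiles <- thresholds <- stats::setNames(vector("list", 3),
                                            .study_methods)
  for (m in .study_methods) {
    profiles[[m]] <- cim_scan(m, draws, markers, responses[[m]],
                              p = config$p, window = config$window)
    thr <- c(fixed = config$fixed_threshold)
    if (permutation)
      thr["perm"] <- permutation_threshold(
        m, draws, markers, responses[[m]], n_perm = config$n_perm,
        alpha = config$alpha, p = config$p, window = config$window)
    thresholds[[m]] <- thr
  }
  calls <- lapply(.study_methods, function(m) {
    lapply(thresholds[[m]], function(thr)
      call_qtls(profiles[[m]], thr, min_sep = config$min_sep))
  })
  names(calls) <- .study_methods
  list(profiles = profiles, thresholds = thresholds, calls = calls,
       delta_hat = vc$delta, sigma2 = vc$sigma2, var_g = stats::var(g),
       seed = seed)
}

#' Run the full simulation study
#'
#' Aggregates [run_replicate()] over all block-variance ratios and
#' replicates: overall and per-QTL power and pooled FDR per
#' (method, threshold rule, delta), average LOD profiles and pointwise
#' power curves.  Fully deterministic given `config$seed` (replicate seeds
#' are drawn up front from the master seed).
#'
#' @param config A `"study_config"`.
#' @param verbose Print one progress line per replicate.
#' @return List of class `"study_result"`: `power` (data frame with
#'   `delta`, `method`, `rule`, `power`, `fdr`, `n_calls`, `n_fp`),
#'   `per_qtl` (per-QTL power), `profiles` (average LOD per
#'   method/delta), `pointwise` (pointwise power curves, permutation rule),
#'   `arch`, `config`.
#' @export
run_study <- function(config, verbose = FALSE) {
  set.seed(config$seed)
  n_cells <- length(config$deltas) * config$n_replicates
  seeds <- matrix(sample.int(.Machine$integer.max, n_cells),
                  config$n_replicates, length(config$deltas))
  truth <- default_architecture(n_polygenes = 0, n_chr = config$n_chr,
                                chr_len = config$chr_len)
  truth <- truth[truth$chr %in% as.character(seq_len(config$n_chr)) &
                   truth$pos <= config$chr_len, , drop = FALSE]
  power_rows <- list(); per_qtl_rows <- list()
  profiles <- list(); pointwise <- list()
  for (di in seq_along(config$deltas)) {
    delta <- config$deltas[di]
    reps <- vector("list", config$n_replicates)
    for (rpl in seq_len(config$n_replicates)) {
      perm <- rpl <= config$perm_replicates
      reps[[rpl]] <- run_replicate(config, delta, seeds[rpl, di],
                                   permutation = perm)
      if (verbose)
        message(sprintf("delta=%g replicate %d/%d seed=%d%s", delta, rpl,
                        config$n_replicates, seeds[rpl, di],
                        if (perm) " (with permutations)" else ""))
    }
    rules <- c("fixed", if (config$perm_replicates > 0) "perm")
    for (m in .study_methods) {
      avg <- reps[[1]]$profiles[[m]][, c("chr", "pos")]
      avg$lod <- rowMeans(vapply(reps, function(r) r$profiles[[m]]$lod,
                                 numeric(nrow(avg))))
      profiles[[sprintf("%s_delta%g", m, delta)]] <- avg
      if (config$perm_replicates > 0) {
        sub <- reps[seq_len(config$perm_replicates)]
        pointwise[[sprintf("%s_delta%g", m, delta)]] <- pointwise_power(
          lapply(sub, function(r) r$profiles[[m]]),
          vapply(sub, function(r) r$thresholds[[m]]["perm"], 0))
      }
      for (rule in rules) {
        use <- if (rule == "perm") seq_len(config$perm_replicates)
        else seq_len(config$n_replicates)
        cl <- lapply(reps[use], function(r) r$calls[[m]][[rule]])
        ev <- evaluate_calls(cl, truth, window = config$eval_window)
        power_rows[[length(power_rows) + 1L]] <- data.frame(
          delta = delta, method = m, rule = rule,
          power = ev$overall_power, fdr = ev$fdr,
          n_calls = ev$n_calls, n_fp = ev$n_fp,
          n_replicates = length(use))
        per_qtl_rows[[length(per_qtl_rows) + 1L]] <- data.frame(
          delta = delta, method = m, rule = rule,
          qtl = names(ev$per_qtl_power), power = 100 * ev$per_qtl_power)
      }
    }
  }
  structure(list(power = do.call(rbind, power_rows),
                 per_qtl = do.call(rbind, per_qtl_rows),
                 profiles = profiles, pointwise = pointwise,
                 arch = truth, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Simulation study:", x$config$n_replicates, "replicates per delta\n\n")
  print(x$power, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write study tables and figure data
#'
#' Emits `power_table.tsv` and `fdr_table.tsv` (deltas x method-within-rule)
#' plus `avg_lod_<method>_<delta>.tsv` and
#' `pointwise_power_<method>_<delta>.tsv` under `dir`.
#'
#' @param result A `"study_result"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wide <- function(field) {
    p <- result$power
    out <- unique(p[, "delta", drop = FALSE])
    for (rule in unique(p$rule)) for (m in .study_methods) {
      sel <- p$rule == rule & p$method == m
      out[[paste(rule, m, sep = "_")]] <- p[[field]][sel][
        match(out$delta, p$delta[sel])]
    }
    out
  }
  for (f in c("power", "fdr")) {
    path <- file.path(dir, paste0(f, "_table.tsv"))
    utils::write.table(wide(f), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  for (nm in names(result$profiles)) {
    path <- file.path(dir, paste0("avg_lod_", nm, ".tsv"))
    utils::write.table(result$profiles[[nm]], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  for (nm in names(result$pointwise)) {
    path <- file.path(dir, paste0("pointwise_power_", nm, ".tsv"))
    utils::write.table(result$pointwise[[nm]], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
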