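#' Write genotypes and map as a rotated CSV
#'
#' One row per marker with columns `marker`, `chr`, `pos`, then one
#' genotype code per line (`A` = 0, `B` = 1, `-` = missing); the header row
#' carries the line ids.  The format round-trips bit-exactly through
#' [read_geno_csv()].
#'
#' @param geno Marker genotypes (`"ril_geno"`, lines x markers).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_geno_csv <- function(geno, path) {
  codes <- matrix("-", ncol(geno), nrow(geno))
  codes[t(geno) == 0] <- "A"
  codes[t(geno) == 1] <- "B"
  out <- cbind(marker = colnames(geno),
               chr = as.character(attr(geno, "chr")),
               pos = format(attr(geno, "pos"), digits = 15, trim = TRUE),
               codes)
  colnames(out) <- c("marker", "chr", "pos", rownames(geno))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes and map from a rotated CSV
#'
#' @param path File written by [write_geno_csv()] (or hand-made in the same
#'   dialect).
#' @return List with `geno` (a `"ril_geno"` matrix, `NA` for missing) and
#'   `map` (a `"genetic_map"`).
#' @export
read_geno_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 4) stop("expected marker, chr, pos plus genotype columns")
  map <- genetic_map(chr = raw$chr, pos = as.numeric(raw$pos),
                     marker = raw$marker)
  codes <- as.matrix(raw[, -(1:3), drop = FALSE])
  G <- matrix(NA_integer_, ncol(codes), nrow(codes),
              dimnames = list(colnames(codes), raw$marker))
  G[t(codes) == "A"] <- 0L
  G[t(codes) == "B"] <- 1L
  if (any(!codes %in% c("A", "B", "-")))
    stop("genotype codes must be A, B or -")
  G <- G[, map$marker, drop = FALSE]
  geno <- structure(G, chr = map$chr, pos = map$pos,
                    type = rep("marker", nrow(map)),
                    class = c("ril_geno", "matrix", "array"))
  list(geno = geno, map = map)
}

#' Write plot-level phenotype records as TSV
#'
#' Columns `env` (omitted when absent), `rep`, `block`, `line`, `value`.
#'
#' @param records A `"pheno_records"` data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_pheno_tsv <- function(records, path) {
  cols <- intersect(c("env", "rep", "block", "line", "value"),
                    names(records))
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read plot-level phenotype records from TSV
#'
#' @param path File in the dialect of [write_pheno_tsv()].
#' @return A `"pheno_records"` data frame.
#' @export
read_pheno_tsv <- function(path) {
  rec <- utils::read.delim(path, check.names = FALSE)
  need <- c("rep", "block", "line", "value")
  if (!all(need %in% names(rec)))
    stop("phenotype file must have columns rep, block, line, value")
  class(rec) <- c("pheno_records", "data.frame")
  rec
}

#' Write / read a lattice layout as TSV
#'
#' Columns `rep`, `block`, `line`.
#' @param layout A `"lattice_layout"`.
#' @param path File path.
#' @return `write_layout_tsv`: invisibly `path`; `read_layout_tsv`: a
#'   `"lattice_layout"`.
#' @export
write_layout_tsv <- function(layout, path) {
  utils::write.table(as.data.frame(layout)[, c("rep", "block", "line")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_tsv
#' @export
read_layout_tsv <- function(path) {
  lay <- utils::read.delim(path)
  if (!all(c("rep", "block", "line") %in% names(lay)))
    stop("layout file must have columns rep, block, line")
  k <- max(table(interaction(lay$rep, lay$block)))
  sizes <- table(interaction(lay$rep, lay$block, drop = TRUE))
  if (any(sizes != k)) stop("blocks are not of constant size")
  structure(lay, k = as.integer(k),
            r = length(unique(lay$rep)),
            t = length(unique(lay$line)),
            class = c("lattice_layout", "data.frame"))
}

#' Write a scan profile as TSV
#'
#' Columns `chr`, `pos_cM`, `lod`, `effect` (single environment) or the
#' multi-environment component columns when present.
#'
#' @param profile A `"scan_profile"`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_scan_tsv <- function(profile, path) {
  out <- as.data.frame(profile)
  names(out)[names(out) == "pos"] <- "pos_cM"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a QTL call table as TSV
#'
#' Columns `chr`, `pos_cM`, `lod`, `effect_a`, `effect_ae`, `support_lo`,
#' `support_hi`, `h2` (absent fields written as NA).
#'
#' @param calls Output of [call_qtls()] (optionally after
#'   [qtl_heritability()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_qtl_tsv <- function(calls, path) {
  out <- data.frame(chr = calls$chr, pos_cM = calls$pos, lod = calls$lod,
                    effect_a = if ("effect_a" %in% names(calls))
                      calls$effect_a else calls$effect,
                    effect_ae = if ("effect_ae" %in% names(calls))
                      calls$effect_ae else NA,
                    support_lo = calls$support_lo,
                    support_hi = calls$support_hi,
                    h2 = if ("h2" %in% names(calls)) calls$h2 else NA)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a scan profile
#'
#' Minimal base-graphics LOD profile with chromosomes laid side by side.
#'
#' @param x A `"scan_profile"`.
#' @param threshold Optional horizontal threshold line.
#' @param ... Passed to [plot()].
#' @export
plot.scan_profile <- function(x, threshold = NULL, ...) {
  chrs <- unique(x$chr)
  offs <- c(0, cumsum(vapply(chrs, function(ch) max(x$pos[x$chr == ch]) + 10,
                             0)))
  xx <- x$pos + offs[match(x$chr, chrs)]
  plot(xx, x$lod, type = "n", xlab = "position", ylab = "LOD", ...)
  for (ch in chrs) {
    i <- x$chr == ch
    graphics::lines(xx[i], x$lod[i])
  }
  graphics::abline(v = offs[-1] - 5, col = "grey", lty = 3)
  if (!is.null(threshold)) graphics::abline(h = threshold, col = 2, lty = 2)
  invisible(x)
}
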