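#' Haldane map function
#'
#' Converts a map distance in centiMorgans to a recombination fraction under
#' the Haldane (no-interference) model, `(1 - exp(-2d/100)) / 2`.
#'
#' @param d Map distance in cM (vectorised, all `>= 0`).
#' @return Recombination fraction(s), non-negative and below 0.5.
#' @examples
#' haldane_r(10)
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

#' RIL map expansion
#'
#' Converts a single-meiosis recombination fraction to the fraction observed
#' between loci of a selfed recombinant inbred line, `R = 2r / (1 + 2r)`
#' (Haldane & Waddington 1931).
#'
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @return RIL-scale recombination fraction(s).
#' @examples
#' ril_adjust(haldane_r(10))
#' @export
ril_adjust <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("recombination fraction must be in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Construct a genetic map
#'
#' A genetic map is a data frame with columns `marker`, `chr` and `pos`
#' (cM), with markers ordered by position within chromosome.
#'
#' @param chr Chromosome label per marker.
#' @param pos Position in cM per marker.
#' @param marker Marker names; unique genome-wide. Default `C<chr>M<index>`.
#' @return A `data.frame` of class `"genetic_map"`.
#' @export
genetic_map <- function(chr, pos, marker = NULL) {
  chr <- as.character(chr)
  if (length(pos) != length(chr)) stop("chr and pos lengths differ")
  if (any(pos < 0)) stop("positions must be non-negative")
  ord <- order(match(chr, unique(chr)), pos)
  chr <- chr[ord]; pos <- pos[ord]
  if (is.null(marker)) {
    idx <- stats::ave(seq_along(chr), chr, FUN = seq_along)
    marker <- paste0("C", chr, "M", idx)
  } else marker <- as.character(marker)[ord]
  if (anyDuplicated(marker)) stop("marker names must be unique genome-wide")
  n_per <- table(chr)
  if (any(n_per < 2)) stop("every chromosome needs at least 2 markers")
  map <- data.frame(marker = marker, chr = chr, pos = pos,
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Evenly spaced genetic map
#'
#' Convenience constructor for a genome of `n_chr` chromosomes of equal
#' length carrying evenly spaced markers (first marker at 0 cM, last at
#' `chr_len`).  The default corresponds to the five-chromosome, 150 cM,
#' 16-markers-per-chromosome genome commonly used in CIM simulation studies.
#'
#' @param n_chr Number of chromosomes.
#' @param chr_len Chromosome length in cM.
#' @param n_markers Markers per chromosome (>= 2).
#' @return A `"genetic_map"`.
#' @examples
#' map <- even_map()
#' table(map$chr)
#' @export
even_map <- function(n_chr = 5, chr_len = 150, n_markers = 16) {
  if (n_markers < 2) stop("need at least 2 markers per chromosome")
  genetic_map(chr = rep(seq_len(n_chr), each = n_markers),
              pos = rep(seq(0, chr_len, length.out = n_markers), n_chr))
}

#' Locus grid for simulation and scanning
#'
#' Merges marker positions, pseudo-marker positions on a regular `step` cM
#' grid, and any extra positions (e.g. trait loci) into one sorted,
#' deduplicated set of loci per chromosome.  Loci closer than `tol` cM are
#' merged (markers take precedence over trait loci over pseudo-markers).
#'
#' @param map A `"genetic_map"`.
#' @param step Pseudo-marker spacing in cM; `NULL` or `Inf` for none.
#' @param extra Optional data frame with columns `chr`, `pos` of additional
#'   loci (tagged `"trait"`).
#' @param tol Merge tolerance in cM.
#' @return A `data.frame` of class `"locus_grid"` with columns `chr`, `pos`,
#'   `type` (`marker`/`pseudo`/`trait`) and `marker` (name or `NA`).
#' @export
locus_grid <- function(map, step = 2, extra = NULL, tol = 1e-9) {
  stopifnot(inherits(map, "genetic_map"))
  pieces <- list()
  for (ch in unique(map$chr)) {
    m <- map[map$chr == ch, ]
    loc <- data.frame(chr = ch, pos = m$pos, type = "marker",
                      marker = m$marker, stringsAsFactors = FALSE)
    if (!is.null(extra)) {
      e <- extra[as.character(extra$chr) == ch, , drop = FALSE]
      if (nrow(e))
        loc <- rbind(loc, data.frame(chr = ch, pos = e$pos, type = "trait",
                                     marker = NA_character_))
    }
    if (!is.null(step) && is.finite(step)) {
      ps <- seq(min(m$pos), max(m$pos), by = step)
      loc <- rbind(loc, data.frame(chr = ch, pos = ps, type = "pseudo",
                                   marker = NA_character_))
    }
    # priority on near-coincident loci: marker > trait > pseudo
    pr <- match(loc$type, c("marker", "trait", "pseudo"))
    loc <- loc[order(loc$pos, pr), ]
    keep <- rep(TRUE, nrow(loc))
    last <- 1
    for (i in seq_len(nrow(loc))[-1]) {
      if (loc$pos[i] - loc$pos[last] <= tol) keep[i] <- FALSE else last <- i
    }
    pieces[[ch]] <- loc[keep, ]
  }
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  grid$id <- ifelse(is.na(grid$marker),
                    sprintf("%s@%g", grid$chr, grid$pos), grid$marker)
  class(grid) <- c("locus_grid", "data.frame")
  grid
}
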