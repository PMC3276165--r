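#' Variant site table
#'
#' Builds and validates the site metadata shared by haplotype panels and
#' genotype matrices: SNP identifier, 1-based base-pair position and the
#' two alleles of a biallelic site.
#'
#' @param id character vector of SNP identifiers.
#' @param position integer vector of 1-based base-pair positions, strictly
#'   increasing within a panel.
#' @param a0,a1 single-character allele labels; `a0` codes allele 0 and
#'   `a1` allele 1.
#' @return A `data.frame` with columns `id`, `position`, `a0`, `a1`.
#' @export
variant_sites <- function(id, position, a0, a1) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position <= 0L))
    stop("site positions must be positive integers")
  if (is.unsorted(position, strictly = TRUE))
    stop("site positions must be strictly increasing")
  if (any(a0 == a1)) stop("alleles a0 and a1 must differ at every site")
  data.frame(id = as.character(id), position = position,
             a0 = as.character(a0), a1 = as.character(a1),
             stringsAsFactors = FALSE)
}

#' Phased haplotype panel
#'
#' A reference (or truth) panel: binary alleles over sites x haplotypes
#' plus the site table.  Entries are 0/1 codes against the site's
#' `a0`/`a1` alleles.
#'
#' @param sites a site table from [variant_sites()].
#' @param alleles integer matrix, `nrow(sites)` x number of haplotypes,
#'   entries in \{0, 1\}.
#' @param haplotype_ids optional character vector of haplotype names.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(sites, alleles, haplotype_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != nrow(sites))
    stop("allele matrix has ", nrow(alleles), " rows but ", nrow(sites), " sites")
  if (length(alleles) && !all(alleles %in% c(0L, 1L)))
    stop("haplotype alleles must be 0 or 1")
  if (is.null(haplotype_ids))
    haplotype_ids <- paste0("hap", seq_len(ncol(alleles)))
  if (length(haplotype_ids) != ncol(alleles))
    stop("haplotype_ids length does not match haplotype count")
  structure(list(sites = sites, alleles = alleles,
                 haplotype_ids = as.character(haplotype_ids)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$sites), " sites x ", ncol(x$alleles),
      " haplotypes [", min(x$sites$position), "-", max(x$sites$position),
      " bp]\n", sep = "")
  invisible(x)
}

#' Number of haplotypes in a panel
#' @param panel a [haplotype_panel()].
#' @return Integer haplotype count.
#' @export
n_haplotypes <- function(panel) ncol(panel$alleles)

#' Subset a haplotype panel
#'
#' @param panel a [haplotype_panel()].
#' @param sites integer or logical index over sites (default all).
#' @param haplotypes integer or logical index over haplotypes (default all).
#' @return The subsetted `haplotype_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, haplotypes = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(panel$sites))
  if (is.null(haplotypes)) haplotypes <- seq_len(ncol(panel$alleles))
  haplotype_panel(panel$sites[sites, , drop = FALSE],
                  panel$alleles[sites, haplotypes, drop = FALSE],
                  panel$haplotype_ids[haplotypes])
}

#' Unphased study genotype matrix
#'
#' Genotypes in \{0, 1, 2\} (count of allele 1) with `NA` for missing, at
#' the study's typed sites.
#'
#' @param sites a site table from [variant_sites()].
#' @param genotypes integer matrix sites x individuals with entries 0/1/2
#'   or `NA`.
#' @param individual_ids optional character vector of sample names.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, genotypes, individual_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(sites))
    stop("genotype matrix has ", nrow(genotypes), " rows but ", nrow(sites), " sites")
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA")
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(ncol(genotypes)))
  if (length(individual_ids) != ncol(genotypes))
    stop("individual_ids length does not match individual count")
  structure(list(sites = sites, genotypes = genotypes,
                 individual_ids = as.character(individual_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$sites), " sites x ", ncol(x$genotypes),
      " individuals (", sum(is.na(x$genotypes)), " missing)\n", sep = "")
  invisible(x)
}

#' Genetic map
#'
#' A base-pair to centimorgan lookup.  Cumulative map positions are
#' linearly interpolated in physical position; beyond the map ends the
#' cumulative cM is held constant.
#'
#' @param position strictly increasing base-pair positions.
#' @param cm non-decreasing cumulative genetic positions in centimorgans.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(position, cm) {
  position <- as.numeric(position)
  cm <- as.numeric(cm)
  if (length(position) != length(cm))
    stop("position and cm must have the same length")
  if (length(position) == 0L) stop("genetic map is empty")
  if (is.unsorted(position, strictly = TRUE))
    stop("map positions must be strictly increasing")
  if (is.unsorted(cm)) stop("cumulative cM must be non-decreasing")
  structure(list(position = position, cm = cm), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", length(x$position), " points, ",
      round(max(x$cm) - min(x$cm), 3), " cM over ",
      max(x$position) - min(x$position), " bp\n", sep = "")
  invisible(x)
}

#' Interpolate genetic positions
#'
#' @param map a [genetic_map()].
#' @param positions base-pair positions to interpolate.
#' @return Cumulative cM at `positions` (linear interpolation, constant
#'   extrapolation beyond the map ends).
#' @export
interpolate_cm <- function(map, positions) {
  if (length(map$position) == 1L)
    return(rep(map$cm, length(positions)))
  stats::approx(map$position, map$cm, xout = positions, rule = 2)$y
}

#' Uniform-rate fallback genetic map
#'
#' Constant-rate map used when no genetic map is supplied.
#'
#' @param start,end base-pair bounds of the region.
#' @param rate recombination rate in cM/Mb (default 1).
#' @return A [genetic_map()] spanning the region.
#' @export
uniform_genetic_map <- function(start, end, rate = 1) {
  genetic_map(c(start, end), c(0, (end - start) * rate / 1e6))
}

#' Minor allele frequency of genotype rows
#'
#' @param genotypes matrix of genotypes in 0/1/2 with `NA` allowed
#'   (sites x individuals).
#' @return Numeric vector of per-site minor allele frequencies in
#'   \[0, 0.5\].
#' @export
genotype_maf <- function(genotypes) {
  p <- rowMeans(genotypes, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Minor allele frequency of panel sites
#'
#' @param panel a [haplotype_panel()].
#' @return Numeric vector of per-site minor allele frequencies.
#' @export
panel_maf <- function(panel) {
  p <- rowMeans(panel$alleles)
  pmin(p, 1 - p)
}
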