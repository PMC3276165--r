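# Readers/writers for the classic imputation text dialects:
# .hap/.legend (reference haplotypes), .gen/.sample (study genotypes as
# probability triples), and 3-column genetic maps.  All readers report
# the offending line number on malformed input.

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

#' Read an IMPUTE-style hap/legend reference panel
#'
#' The legend file has a header line (`id position a0 a1`) and one row
#' per site; the hap file has one space-separated row of 0/1 alleles per
#' site, one column per haplotype.
#'
#' @param hap_path path to the `.hap` file.
#' @param legend_path path to the `.legend` file.
#' @return A [haplotype_panel()].
#' @export
read_hap_legend <- function(hap_path, legend_path) {
  leg <- read_lines_checked(legend_path)
  leg <- leg[nzchar(leg)]
  if (length(leg) < 1L) stop("legend file is empty: ", legend_path)
  body <- leg[-1L]
  hap <- read_lines_checked(hap_path)
  hap <- hap[nzchar(hap)]
  if (length(hap) != length(body))
    stop("hap file has ", length(hap), " rows but legend has ",
         length(body), " sites (", hap_path, ")")
  fields <- strsplit(body, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("legend line ", which(nf < 4L)[1] + 1L, " has fewer than 4 fields")
  leg_mat <- do.call(rbind, lapply(fields, `[`, 1:4))
  pos <- suppressWarnings(as.integer(leg_mat[, 2]))
  if (any(is.na(pos)))
    stop("legend line ", which(is.na(pos))[1] + 1L, ": position is not an integer")
  sites <- variant_sites(leg_mat[, 1], pos, leg_mat[, 3], leg_mat[, 4])
  toks <- strsplit(hap, "[ \t]+")
  ntok <- lengths(toks)
  if (length(unique(ntok)) > 1L)
    stop("hap line ", which(ntok != ntok[1])[1],
         ": haplotype count differs from previous lines")
  alle <- suppressWarnings(vapply(toks, as.integer, integer(ntok[1])))
  if (ntok[1] == 1L) alle <- matrix(alle, nrow = 1L)
  bad <- which(colSums(is.na(alle) | !(alle %in% c(0L, 1L))) > 0L)
  if (length(bad))
    stop("hap line ", bad[1], " contains a token other than 0/1")
  haplotype_panel(sites, t(alle))
}

#' Write an IMPUTE-style hap/legend reference panel
#'
#' @param panel a [haplotype_panel()].
#' @param hap_path,legend_path output paths.
#' @return Invisibly, the panel.
#' @export
write_hap_legend <- function(panel, hap_path, legend_path) {
  leg <- c("id position a0 a1",
           paste(panel$sites$id, panel$sites$position,
                 panel$sites$a0, panel$sites$a1))
  writeLines(leg, legend_path)
  writeLines(apply(panel$alleles, 1L, paste, collapse = " "), hap_path)
  invisible(panel)
}

#' Read a .gen genotype-probability file
#'
#' Each row is `id rsid position a0 a1` followed by a probability triple
#' per individual.  Hard genotypes are called at the triple's argmax when
#' the winning probability reaches `threshold`; otherwise the genotype is
#' missing.  A triple of (0,0,0), or one summing below 0.1, is missing.
#'
#' @param gen_path path to the `.gen` file.
#' @param threshold calling threshold for the argmax probability
#'   (default 0.9).
#' @return A [genotype_matrix()]; the raw probability triples are kept in
#'   the `probs` element (sites x 3*individuals).
#' @export
read_gen <- function(gen_path, threshold = 0.9) {
  lines <- read_lines_checked(gen_path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("gen file is empty: ", gen_path)
  toks <- strsplit(lines, "[ \t]+")
  nf <- lengths(toks)
  if (any(nf < 8L) || any((nf - 5L) %% 3L != 0L))
    stop("gen line ", which(nf < 8L | (nf - 5L) %% 3L != 0L)[1],
         ": probabilities are not triples of length 3 per individual")
  if (length(unique(nf)) > 1L)
    stop("gen line ", which(nf != nf[1])[1], ": field count differs from line 1")
  n_ind <- (nf[1] - 5L) %/% 3L
  meta <- do.call(rbind, lapply(toks, `[`, 1:5))
  probs <- suppressWarnings(t(vapply(toks, function(x)
    as.numeric(x[-(1:5)]), numeric(3L * n_ind))))
  if (n_ind * 3L == 1L) probs <- matrix(probs, ncol = 1L)
  bad <- which(rowSums(is.na(probs)) > 0L)
  if (length(bad)) stop("gen line ", bad[1], ": non-numeric probability")
  bad <- which(rowSums(probs < 0) > 0L)
  if (length(bad)) stop("gen line ", bad[1], ": negative probability")
  sites <- variant_sites(meta[, 2], as.integer(meta[, 3]), meta[, 4], meta[, 5])
  geno <- matrix(NA_integer_, nrow(sites), n_ind)
  for (i in seq_len(n_ind)) {
    tri <- probs[, (3L * i - 2L):(3L * i), drop = FALSE]
    s <- rowSums(tri)
    win <- max.col(tri, ties.method = "first") - 1L
    pmaxv <- tri[cbind(seq_len(nrow(tri)), win + 1L)]
    call <- s >= 0.1 & pmaxv >= threshold
    geno[call, i] <- win[call]
  }
  gm <- genotype_matrix(sites, geno)
  gm$probs <- probs
  gm
}

#' Write posterior genotype probabilities as a .gen file
#'
#' @param sites a site table from [variant_sites()].
#' @param probs numeric matrix sites x (3 * individuals): per-individual
#'   probability triples `P(G=0), P(G=1), P(G=2)`, each summing to 1
#'   within 1e-6.
#' @param gen_path output path.
#' @param chr chromosome label written in column 1.
#' @return Invisibly, `gen_path`.
#' @export
write_gen <- function(sites, probs, gen_path, chr = "chr") {
  probs <- as.matrix(probs)
  if (nrow(probs) != nrow(sites)) stop("probs rows do not match sites")
  if (ncol(probs) %% 3L != 0L) stop("probs columns must come in triples")
  n_ind <- ncol(probs) %/% 3L
  for (i in seq_len(n_ind)) {
    s <- rowSums(probs[, (3L * i - 2L):(3L * i), drop = FALSE])
    if (any(abs(s - 1) > 1e-6))
      stop("probability triples for individual ", i, " do not sum to 1")
  }
  body <- paste(chr, sites$id, sites$position, sites$a0, sites$a1,
                apply(probs, 1L, function(x) paste(formatC(x, digits = 6,
                                                           format = "f"),
                                                   collapse = " ")))
  writeLines(body, gen_path)
  invisible(gen_path)
}

#' Read/write .sample files
#'
#' The two-line-header sample format: `ID_1 ID_2 missing` then `0 0 0`,
#' followed by one row per individual.
#'
#' @param path file path.
#' @return `read_sample()`: character vector of individual IDs.
#' @export
read_sample <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("sample file has no header: ", path)
  toks <- strsplit(lines[-(1:2)], "[ \t]+")
  vapply(toks, `[`, character(1), 2L)
}

#' @rdname read_sample
#' @param ids character vector of individual IDs to write.
#' @export
write_sample <- function(ids, path) {
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(seq_along(ids), ids, 0)), path)
  invisible(path)
}

#' Read a 3-column genetic map file
#'
#' Columns (after a header line): physical position (bp), local
#' recombination rate (cM/Mb; kept for information only) and cumulative
#' genetic position (cM).  Duplicate positions are collapsed keeping the
#' first occurrence.
#'
#' @param path path to the map file.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("genetic map has no data rows: ", path)
  toks <- strsplit(lines[-1L], "[ \t]+")
  nf <- lengths(toks)
  if (any(nf < 3L)) stop("map line ", which(nf < 3L)[1] + 1L, " has fewer than 3 fields")
  pos <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 1L)))
  cm <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 3L)))
  bad <- which(is.na(pos) | is.na(cm))
  if (length(bad)) stop("map line ", bad[1] + 1L, ": non-numeric field")
  keep <- !duplicated(pos)
  pos <- pos[keep]; cm <- cm[keep]
  ord <- order(pos)
  pos <- pos[ord]; cm <- cm[ord]
  if (is.unsorted(cm))
    stop("map line ", which(diff(cm) < 0)[1] + 2L, ": cumulative cM decreases")
  genetic_map(pos, cm)
}

#' Write a 3-column genetic map file
#'
#' @param map a [genetic_map()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_genetic_map <- function(map, path) {
  n <- length(map$position)
  rate <- if (n > 1L) c(diff(map$cm) / (diff(map$position) / 1e6), 0) else 0
  writeLines(c("position rate.cM.Mb cM",
               paste(format(map$position, scientific = FALSE, trim = TRUE),
                     formatC(rate, digits = 6, format = "f"),
                     formatC(map$cm, digits = 6, format = "f"))), path)
  invisible(path)
}

#' Align study sites to a reference panel
#'
#' Matches study sites to reference sites by position and allele pair.
#' Sites whose alleles appear in swapped order have their genotypes
#' flipped (g becomes 2 - g).  Sites at matching positions with
#' irreconcilable allele labels are dropped with a warning, as are study
#' sites absent from the reference.
#'
#' @param study a [genotype_matrix()].
#' @param reference a [haplotype_panel()].
#' @return The aligned `genotype_matrix` (a subset of `study` on the
#'   reference's allele coding).
#' @export
align_study_reference <- function(study, reference) {
  m <- match(study$sites$position, reference$sites$position)
  keep <- !is.na(m)
  flip <- logical(nrow(study$sites))
  conflict <- logical(nrow(study$sites))
  idx <- which(keep)
  for (i in idx) {
    r <- reference$sites[m[i], ]
    s <- study$sites[i, ]
    if (s$a0 == r$a0 && s$a1 == r$a1) next
    if (s$a0 == r$a1 && s$a1 == r$a0) flip[i] <- TRUE
    else conflict[i] <- TRUE
  }
  if (any(conflict))
    warning(sum(conflict), " study site(s) dropped for allele conflicts ",
            "with the reference panel")
  if (any(!keep))
    warning(sum(!keep), " study site(s) not present in the reference panel")
  sel <- keep & !conflict
  geno <- study$genotypes[sel, , drop = FALSE]
  fl <- flip[sel]
  geno[fl, ] <- 2L - geno[fl, , drop = FALSE]
  out_sites <- reference$sites[m[sel], , drop = FALSE]
  rownames(out_sites) <- NULL
  genotype_matrix(out_sites, geno, study$individual_ids)
}
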