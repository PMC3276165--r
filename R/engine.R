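# Top-level MCMC engine.  Each sweep alternates (1) diploid phase
# sampling at the typed sites, with templates drawn from the
# Hamming-nearest reference + other-study haplotypes, and (2) analytic
# haploid imputation of untyped sites, each newly sampled haplotype
# copying from its own custom panel of the k_hap Hamming-nearest
# reference haplotypes.  Post-burn-in genotype probability triples are
# averaged with equal weight.  Since step 2 never feeds back into the
# phase chain, burn-in sweeps run step 1 only.

#' Random genotype-consistent phase initialization
#'
#' Heterozygous sites are phased by a fair coin; missing sites are drawn
#' from the site allele frequency.
#'
#' @param genotypes integer matrix (typed sites x individuals) in 0/1/2
#'   with `NA` for missing.
#' @param freqs per-site allele-1 frequencies used for missing sites; by
#'   default estimated from the genotypes (0.5 where all are missing).
#' @return Integer haplotype matrix (sites x 2*individuals); columns
#'   2i-1 and 2i belong to individual i.
#' @export
initialize_phase <- function(genotypes, freqs = NULL) {
  M <- nrow(genotypes); N <- ncol(genotypes)
  if (is.null(freqs)) {
    freqs <- rowMeans(genotypes, na.rm = TRUE) / 2
    freqs[is.nan(freqs)] <- 0.5
  }
  haps <- matrix(0L, M, 2L * N)
  for (i in seq_len(N)) {
    g <- genotypes[, i]
    h1 <- as.integer(g >= 1L)  # placeholder, fixed below
    h1[g == 0L] <- 0L; h1[g == 2L] <- 1L
    h2 <- h1
    het <- which(g == 1L)
    if (length(het)) {
      coin <- stats::runif(length(het)) < 0.5
      h1[het] <- as.integer(coin)
      h2[het] <- 1L - h1[het]
    }
    mis <- which(is.na(g))
    if (length(mis)) {
      h1[mis] <- as.integer(stats::runif(length(mis)) < freqs[mis])
      h2[mis] <- as.integer(stats::runif(length(mis)) < freqs[mis])
    }
    haps[, 2L * i - 1L] <- h1
    haps[, 2L * i] <- h2
  }
  haps
}

#' Split a region into analysis chunks
#'
#' Non-overlapping core windows (default 5 Mb) tiling the region, each
#' extended by a buffer (default 250 kb) on both sides to absorb HMM edge
#' effects; buffers are clipped at the region bounds.  Intervals are
#' half-open `[start, end)`.
#'
#' @param start,end region bounds in bp.
#' @param chunk_size core window size in bp.
#' @param buffer buffer width in bp added to each side.
#' @return List of chunks, each a list with `core = c(start, end)` and
#'   `buffer = c(start, end)`.
#' @export
make_chunks <- function(start, end, chunk_size = 5e6, buffer = 250e3) {
  if (end <= start) stop("region end must exceed start")
  if (chunk_size <= 0 || buffer < 0) stop("non-positive chunk size or negative buffer")
  starts <- seq(start, end - 1, by = chunk_size)
  lapply(starts, function(s) {
    e <- min(s + chunk_size, end)
    list(core = c(s, e),
         buffer = c(max(start, s - buffer), min(end, e + buffer)))
  })
}

#' Run the imputation MCMC on one chunk
#'
#' @param study an aligned [genotype_matrix()] (see
#'   [align_study_reference()]).
#' @param reference a [haplotype_panel()].
#' @param map a [genetic_map()].
#' @param params a [model_params()].
#' @param chunk optional chunk from [make_chunks()]; by default a single
#'   chunk spanning all reference sites.  Sites inside the buffer are
#'   analyzed; the result records the core so [stitch()] can trim.
#' @return An `imputation_result` (see [impute_genotypes()] for the
#'   fields), or `NULL` with a warning if the chunk contains no typed
#'   sites.
#' @export
run_mcmc <- function(study, reference, map, params = model_params(),
                     chunk = NULL) {
  if (is.null(chunk)) {
    span <- c(min(reference$sites$position), max(reference$sites$position) + 1)
    chunk <- list(core = span, buffer = span)
  }
  rin <- reference$sites$position >= chunk$buffer[1] &
    reference$sites$position < chunk$buffer[2]
  sin <- study$sites$position >= chunk$buffer[1] &
    study$sites$position < chunk$buffer[2]
  ref <- subset_panel(reference, sites = which(rin))
  spos <- study$sites$position[sin]
  typed_idx <- which(ref$sites$position %in% spos)
  if (!length(typed_idx)) {
    warning("chunk [", chunk$core[1], ",", chunk$core[2],
            ") has no typed sites overlapping the reference; skipped")
    return(NULL)
  }
  smatch <- match(ref$sites$position[typed_idx], study$sites$position)
  geno <- study$genotypes[smatch, , drop = FALSE]
  N <- ncol(geno)
  untyped_idx <- setdiff(seq_len(nrow(ref$sites)), typed_idx)
  ref_typed <- ref$alleles[typed_idx, , drop = FALSE]
  ref_untyped_t <- t(ref$alleles[untyped_idx, , drop = FALSE])
  typed_pos <- ref$sites$position[typed_idx]
  untyped_pos <- ref$sites$position[untyped_idx]
  R <- ncol(ref_typed)
  k_hap <- params$k_hap
  if (k_hap > R) {
    message("k_hap = ", k_hap, " exceeds the ", R,
            " reference haplotypes; clamped")
    k_hap <- R
  }
  schedule <- build_transitions(map, typed_pos, params$Ne, params$k)
  ref_freq <- rowMeans(ref_typed)
  cur <- initialize_phase(geno, freqs = ref_freq)

  Mu <- length(untyped_idx); Mt <- length(typed_idx)
  A0 <- matrix(0, Mu, N); A1 <- matrix(0, Mu, N); A2 <- matrix(0, Mu, N)
  T0 <- matrix(0, Mt, N); T1 <- matrix(0, Mt, N); T2 <- matrix(0, Mt, N)
  n_avg <- params$iterations - params$burnin

  for (it in seq_len(params$iterations)) {
    # Step 1: phase updates
    for (i in seq_len(N)) {
      cols <- c(2L * i - 1L, 2L * i)
      pool <- cbind(ref_typed, cur[, -cols, drop = FALSE])
      sel <- phasing_candidates(cur[, cols[1]], cur[, cols[2]], pool, params$k)
      templ <- pool[, sel$indices, drop = FALSE]
      pair <- if (ncol(templ) >= 2L)
        diploid_sample_phase(geno[, i], templ, schedule, params)
      else list(h1 = cur[, cols[1]], h2 = cur[, cols[2]])
      cur[, cols[1]] <- pair$h1
      cur[, cols[2]] <- pair$h2
    }
    # Step 2: per-haplotype imputation from the k_hap nearest references
    if (it > params$burnin) {
      for (i in seq_len(N)) {
        p1u <- matrix(0, max(Mu, 1L), 2L)
        p1t <- matrix(0, Mt, 2L)
        for (h in 1:2) {
          hap <- cur[, 2L * i - 2L + h]
          selh <- select_k_nearest(hap, ref_typed, k_hap)
          fb <- haploid_forward_backward(hap,
                                         ref_typed[, selh$indices, drop = FALSE],
                                         schedule, params,
                                         return_gamma = FALSE)
          if (Mu)
            p1u[, h] <- impute_untyped(fb, ref_untyped_t, untyped_pos,
                                       typed_pos, map, params$Ne,
                                       sel = selh$indices, transposed = TRUE)
          p1t[, h] <- typed_allele_probs(fb)
        }
        if (Mu) {
          pa <- p1u[, 1]; pb <- p1u[, 2]
          A0[, i] <- A0[, i] + (1 - pa) * (1 - pb)
          A2[, i] <- A2[, i] + pa * pb
          A1[, i] <- A1[, i] + pa * (1 - pb) + (1 - pa) * pb
        }
        qa <- p1t[, 1]; qb <- p1t[, 2]
        T0[, i] <- T0[, i] + (1 - qa) * (1 - qb)
        T2[, i] <- T2[, i] + qa * qb
        T1[, i] <- T1[, i] + qa * (1 - qb) + (1 - qa) * qb
      }
    }
  }

  p0 <- A0 / n_avg; p1 <- A1 / n_avg; p2 <- A2 / n_avg
  untyped_sites <- ref$sites[untyped_idx, , drop = FALSE]
  rownames(untyped_sites) <- NULL
  typed_sites <- ref$sites[typed_idx, , drop = FALSE]
  rownames(typed_sites) <- NULL
  structure(list(
    untyped_sites = untyped_sites,
    probs = list(p0 = p0, p1 = p1, p2 = p2),
    dosage = p1 + 2 * p2,
    typed_sites = typed_sites,
    phased = cur,
    typed_missing = is.na(geno),
    typed_missing_probs = list(p0 = T0 / n_avg, p1 = T1 / n_avg,
                               p2 = T2 / n_avg),
    individual_ids = study$individual_ids,
    chunk = chunk, params = params,
    k_hap_used = k_hap
  ), class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("<imputation_result> ", nrow(x$untyped_sites), " untyped sites x ",
      length(x$individual_ids), " individuals (", nrow(x$typed_sites),
      " typed sites) in [", x$chunk$core[1], ",", x$chunk$core[2], ")\n",
      sep = "")
  invisible(x)
}

#' Stitch per-chunk results into one
#'
#' Each site's output is taken from the chunk whose core interval
#' contains it; buffer-only copies are discarded.
#'
#' @param chunk_results list of `imputation_result`s (NULL entries from
#'   skipped chunks are dropped).
#' @param chunks matching list of chunks from [make_chunks()].
#' @return A single `imputation_result` covering the whole region.
#' @export
stitch <- function(chunk_results, chunks) {
  keep <- !vapply(chunk_results, is.null, logical(1))
  chunk_results <- chunk_results[keep]
  chunks <- chunks[keep]
  if (!length(chunk_results)) stop("no chunk produced results")
  trim <- function(res) {
    core <- res$chunk$core
    ui <- res$untyped_sites$position >= core[1] & res$untyped_sites$position < core[2]
    ti <- res$typed_sites$position >= core[1] & res$typed_sites$position < core[2]
    res$untyped_sites <- res$untyped_sites[ui, , drop = FALSE]
    res$probs <- lapply(res$probs, function(m) m[ui, , drop = FALSE])
    res$dosage <- res$dosage[ui, , drop = FALSE]
    res$typed_sites <- res$typed_sites[ti, , drop = FALSE]
    res$phased <- res$phased[ti, , drop = FALSE]
    res$typed_missing <- res$typed_missing[ti, , drop = FALSE]
    res$typed_missing_probs <- lapply(res$typed_missing_probs,
                                      function(m) m[ti, , drop = FALSE])
    res
  }
  parts <- lapply(chunk_results, trim)
  out <- parts[[1]]
  if (length(parts) > 1L) {
    for (p in parts[-1]) {
      out$untyped_sites <- rbind(out$untyped_sites, p$untyped_sites)
      out$probs <- Map(rbind, out$probs, p$probs)
      out$dosage <- rbind(out$dosage, p$dosage)
      out$typed_sites <- rbind(out$typed_sites, p$typed_sites)
      out$phased <- rbind(out$phased, p$phased)
      out$typed_missing <- rbind(out$typed_missing, p$typed_missing)
      out$typed_missing_probs <- Map(rbind, out$typed_missing_probs,
                                     p$typed_missing_probs)
    }
  }
  out$chunk <- list(core = c(chunks[[1]]$core[1],
                             chunks[[length(chunks)]]$core[2]),
                    buffer = c(chunks[[1]]$buffer[1],
                               chunks[[length(chunks)]]$buffer[2]))
  rownames(out$untyped_sites) <- NULL
  rownames(out$typed_sites) <- NULL
  out
}

#' Impute a study dataset from a reference panel
#'
#' The top-level entry point: aligns study sites to the reference,
#' splits the region into buffered chunks, runs the MCMC on each chunk
#' with a per-chunk seeded RNG stream, and stitches the core results.
#'
#' @param study a [genotype_matrix()] of unphased study genotypes at the
#'   typed sites.
#' @param reference a [haplotype_panel()].
#' @param map a [genetic_map()]; if `NULL` a uniform 1 cM/Mb map over the
#'   region is used (reported with a message).
#' @param params a [model_params()].
#' @param region `c(start, end)` bp (half-open); defaults to the span of
#'   the reference sites.
#' @param chunk_size,buffer chunking controls in bp (defaults 5 Mb and
#'   250 kb).
#' @param seed optional integer; chunk i runs under `set.seed(seed + i - 1)`
#'   so parallel or re-ordered chunk execution is reproducible.
#' @return An `imputation_result`: untyped site table with per-individual
#'   genotype probability triples (`probs$p0`, `probs$p1`, `probs$p2`,
#'   each sites x individuals, averaged over post-burn-in sweeps),
#'   allele `dosage` in \[0, 2\], final-sweep phased haplotypes at typed
#'   sites, and probability triples at typed sites whose input genotype
#'   was missing.
#' @export
impute_genotypes <- function(study, reference, map = NULL,
                             params = model_params(), region = NULL,
                             chunk_size = 5e6, buffer = 250e3,
                             seed = NULL) {
  study <- align_study_reference(study, reference)
  if (is.null(region))
    region <- c(min(reference$sites$position),
                max(reference$sites$position) + 1)
  if (is.null(map)) {
    message("no genetic map supplied; using a uniform 1 cM/Mb map")
    map <- uniform_genetic_map(region[1], region[2])
  }
  chunks <- make_chunks(region[1], region[2], chunk_size, buffer)
  results <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    if (!is.null(seed)) set.seed(seed + ci - 1L)
    results[[ci]] <- run_mcmc(study, reference, map, params, chunks[[ci]])
  }
  stitch(results, chunks)
}
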