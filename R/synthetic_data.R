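# Seedable generator of structured multi-population haplotype panels.
# Ancestral allele frequencies are Beta-distributed; each population
# perturbs them by Balding-Nichols drift with a per-population divergence
# scalar; haplotypes are imperfect mosaics of a small set of population
# founders, which produces the local haplotype sharing and LD decay the
# copying model exploits.  Two ascertainment schemes mimic SNP-array
# design (MAF-weighted thinning) and low-coverage sequencing discovery
# (allele-count-dependent discovery probabilities per population).

#' Simulation configuration
#'
#' @param n_populations number of populations.
#' @param haplotypes_per_population haplotypes sampled per population;
#'   scalar or vector of length `n_populations`.
#' @param region_length region size in bp.
#' @param snp_density expected SNPs per kb before ascertainment.
#' @param split_depth per-population Balding-Nichols divergence scalars
#'   (F in \[0,1); larger = more drift from the shared ancestor; 0 =
#'   exchangeable with the ancestral pool).  Default recycles
#'   (0.05, 0.15, 0.30) across populations.  The realized pairwise F_ST
#'   is monotone in, but smaller than, these nominal values.
#' @param recomb_rate recombination rate in cM/Mb for the emitted map.
#' @param n_founders founder haplotypes per population for the mosaic
#'   process.
#' @param switch_rate per-site probability that a mosaic haplotype
#'   switches founder template (default 0.001, i.e. founder segments of
#'   ~1000 sites, a few hundred kb at the default SNP density —
#'   human-scale haplotype sharing).
#' @param mismatch_rate per-site copying-error probability of the mosaic
#'   process.
#' @param beta_shape shape parameter of the symmetric Beta ancestral
#'   frequency distribution (shape < 1 skews toward rare variants).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_populations = 3,
                       haplotypes_per_population = 200,
                       region_length = 2e6,
                       snp_density = 5,
                       split_depth = NULL,
                       recomb_rate = 1,
                       n_founders = 20,
                       switch_rate = 0.001,
                       mismatch_rate = 0.002,
                       beta_shape = 0.5) {
  if (length(haplotypes_per_population) == 1L)
    haplotypes_per_population <- rep(haplotypes_per_population, n_populations)
  if (is.null(split_depth)) split_depth <- c(0.02, 0.06, 0.15)
  split_depth <- rep_len(split_depth, n_populations)
  stopifnot(n_populations >= 1, all(haplotypes_per_population > 0),
            region_length > 0, snp_density > 0,
            length(haplotypes_per_population) == n_populations,
            length(split_depth) == n_populations,
            all(split_depth >= 0), all(split_depth < 1),
            recomb_rate >= 0, n_founders >= 1,
            switch_rate >= 0, switch_rate <= 1,
            mismatch_rate >= 0, mismatch_rate < 0.5)
  structure(list(n_populations = as.integer(n_populations),
                 haplotypes_per_population = as.integer(haplotypes_per_population),
                 region_length = region_length, snp_density = snp_density,
                 split_depth = split_depth, recomb_rate = recomb_rate,
                 n_founders = as.integer(n_founders),
                 switch_rate = switch_rate, mismatch_rate = mismatch_rate,
                 beta_shape = beta_shape),
            class = "sim_config")
}

# Mosaic haplotypes over a founder matrix (sites x founders).
mosaic_haplotypes <- function(founders, n, switch_rate, mismatch_rate) {
  M <- nrow(founders); Fk <- ncol(founders)
  out <- matrix(0L, M, n)
  for (h in seq_len(n)) {
    sw <- stats::runif(M) < switch_rate
    sw[1] <- TRUE
    seg <- cumsum(sw)
    pick <- sample.int(Fk, max(seg), replace = TRUE)
    hap <- founders[cbind(seq_len(M), pick[seg])]
    if (mismatch_rate > 0) {
      flip <- stats::runif(M) < mismatch_rate
      hap[flip] <- 1L - hap[flip]
    }
    out[, h] <- hap
  }
  out
}

#' Simulate multi-population haplotype panels
#'
#' @param config a [sim_config()].
#' @return List with `panels` (one [haplotype_panel()] per population),
#'   `combined` (all haplotypes side by side, with `pop` labels in
#'   `population`), `map` (a constant-rate [genetic_map()]), and
#'   `ancestral_freq` (the truth frequencies).
#' @export
simulate_panels <- function(config) {
  n_snps <- max(2L, round(config$snp_density * config$region_length / 1000))
  positions <- sort(sample.int(config$region_length - 1L, n_snps))
  p0 <- stats::rbeta(n_snps, config$beta_shape, config$beta_shape)
  p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
  sites <- variant_sites(paste0("snp", seq_len(n_snps)), positions,
                         rep("A", n_snps), rep("G", n_snps))
  # Shared ancestral founder pool; populations drift away from it by
  # redrawing whole founder SEGMENTS (expected fraction = split_depth)
  # from Balding-Nichols-perturbed frequencies.  Segmental redraw mimics
  # coalescent sharing: the non-redrawn parts of diverged founders remain
  # identical by descent to the ancestral pool, so rare alleles keep
  # intact haplotype backgrounds across populations, while redrawn
  # segments carry population-specific variation.  split_depth = 0
  # populations are exchangeable, and realized F_ST grows monotonically
  # with depth.
  nf <- config$n_founders
  ancestral <- matrix(as.integer(stats::runif(n_snps * nf) < p0), n_snps, nf)
  panels <- vector("list", config$n_populations)
  founder_sets <- vector("list", config$n_populations)
  for (d in seq_len(config$n_populations)) {
    Fd <- config$split_depth[d]
    founders <- ancestral
    if (Fd > 0) {
      pd <- stats::rbeta(n_snps, p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd)
      # divergence segments are an order of magnitude shorter than the
      # within-population mosaic segments, so the redrawn genome fraction
      # concentrates near split_depth while shared stretches stay long
      seg_rate <- max(10 * config$switch_rate, 20 / n_snps)
      for (f in seq_len(nf)) {
        sw <- stats::runif(n_snps) < seg_rate
        sw[1] <- TRUE
        seg <- cumsum(sw)
        mask <- (stats::runif(max(seg)) < Fd)[seg]
        if (any(mask))
          founders[mask, f] <- as.integer(stats::runif(sum(mask)) < pd[mask])
      }
    }
    founder_sets[[d]] <- founders
    alle <- mosaic_haplotypes(founders, config$haplotypes_per_population[d],
                              config$switch_rate, config$mismatch_rate)
    panels[[d]] <- haplotype_panel(sites, alle,
                                   paste0("pop", d, "_hap",
                                          seq_len(ncol(alle))))
  }
  names(panels) <- paste0("pop", seq_len(config$n_populations))
  combined <- haplotype_panel(sites, do.call(cbind,
                                             lapply(panels, `[[`, "alleles")),
                              unlist(lapply(panels, `[[`, "haplotype_ids")))
  combined$population <- rep(names(panels),
                             config$haplotypes_per_population)
  map <- uniform_genetic_map(0, config$region_length, config$recomb_rate)
  names(founder_sets) <- names(panels)
  list(panels = panels, combined = combined, map = map,
       ancestral_freq = p0, founders = founder_sets)
}

#' SNP-array-like ascertainment
#'
#' Thins a panel's sites to an array-like typed set: sampling without
#' replacement with weight proportional to MAF (favoring common SNPs, as
#' array design does), subject to a MAF floor.
#'
#' @param panel a [haplotype_panel()].
#' @param target_density typed SNPs per kb (default 0.17,
#'   genotyping-array scale).
#' @param maf_floor minimum MAF for a site to be eligible (default 0.05).
#' @param weight_by_maf set `FALSE` for uniform thinning.
#' @return Sorted integer indices of the selected ("typed") sites.
#' @export
ascertain_array <- function(panel, target_density = 0.17, maf_floor = 0.05,
                            weight_by_maf = TRUE) {
  maf <- panel_maf(panel)
  eligible <- which(maf >= maf_floor & maf > 0)
  if (!length(eligible)) stop("no site passes the MAF floor")
  span <- diff(range(panel$sites$position))
  n_target <- min(length(eligible),
                  max(1L, round(target_density * span / 1000)))
  w <- if (weight_by_maf) maf[eligible] else rep(1, length(eligible))
  sort(eligible[sample.int(length(eligible), n_target, prob = w)])
}

#' Low-coverage discovery model
#'
#' Maps the variant-allele count in a population sample to a discovery
#' probability; must be non-decreasing in the count and 0 at count 0.
#'
#' @param counts integer allele counts at which the curve is specified;
#'   counts above the largest use the last probability.
#' @param probs matching discovery probabilities in \[0, 1\].
#' @return A function `count -> probability` (vectorized).
#' @export
discovery_model <- function(counts, probs) {
  stopifnot(length(counts) == length(probs), all(probs >= 0), all(probs <= 1))
  ord <- order(counts)
  counts <- counts[ord]; probs <- probs[ord]
  if (is.unsorted(probs)) stop("discovery probability must be non-decreasing in allele count")
  function(ac) {
    p <- rep(0, length(ac))
    pos <- ac > 0
    idx <- findInterval(ac[pos], counts)
    p[pos] <- ifelse(idx == 0, 0, probs[pmax(idx, 1)])
    p
  }
}

#' Low-coverage discovery ascertainment
#'
#' Applies a discovery-probability curve independently per SNP in each
#' population's reference sample; a SNP discovered in any population is
#' retained (and kept, fully genotyped, in all panels).
#'
#' @param panels list of [haplotype_panel()]s sharing sites (one per
#'   population).
#' @param model a [discovery_model()] function.
#' @return Sorted integer indices of the retained sites.
#' @export
ascertain_discovery <- function(panels, model) {
  n_snps <- nrow(panels[[1]]$sites)
  kept <- rep(FALSE, n_snps)
  for (p in panels) {
    ac <- rowSums(p$alleles)  # variant (allele-1) copies in this sample
    kept <- kept | (stats::runif(n_snps) < model(ac))
  }
  sort(which(kept))
}

#' Build a study sample from held-out haplotypes
#'
#' Pairs haplotypes uniformly at random without replacement into
#' individuals; genotypes are allele sums at the typed sites; the truth
#' haplotypes are retained for evaluation.
#'
#' @param panel a [haplotype_panel()] of the haplotypes available for the
#'   study (must be disjoint from the reference).
#' @param n_individuals number of individuals to form.
#' @param typed_sites integer indices of the typed sites.
#' @return List with `study` (a [genotype_matrix()] at the typed sites),
#'   `truth` (full genotype matrix at all sites), `truth_haplotypes`
#'   (sites x 2n), and `hap_pairs` (the pairing).
#' @export
make_study <- function(panel, n_individuals, typed_sites) {
  H <- ncol(panel$alleles)
  if (2L * n_individuals > H)
    stop("need ", 2L * n_individuals, " haplotypes but only ", H, " available")
  pick <- sample.int(H, 2L * n_individuals)
  pairs <- matrix(pick, nrow = 2L)
  haps <- panel$alleles[, as.vector(pairs), drop = FALSE]
  truth <- haps[, seq(1, ncol(haps), 2), drop = FALSE] +
    haps[, seq(2, ncol(haps), 2), drop = FALSE]
  study <- genotype_matrix(panel$sites[typed_sites, , drop = FALSE],
                           truth[typed_sites, , drop = FALSE])
  list(study = study,
       truth = truth,
       truth_haplotypes = haps,
       hap_pairs = pairs)
}

#' Simulate a complete imputation experiment
#'
#' Convenience wrapper: simulate panels, hold out study haplotypes from
#' the first population, ascertain an array-like typed set on the
#' reference, and build the study sample.  The reference panel contains
#' all of populations 2..P and the non-held-out part of population 1.
#'
#' @param config a [sim_config()].
#' @param n_study number of study individuals (their 2n haplotypes are
#'   taken from population 1 and excluded from the reference).
#' @param target_density,maf_floor see [ascertain_array()].
#' @return List with `reference` ([haplotype_panel()]), `reference_pops`
#'   (population label per reference haplotype), `study`, `truth`,
#'   `typed_sites`, `map`, and the per-population `panels`.
#' @export
simulate_imputation_study <- function(config = sim_config(), n_study = 20,
                                      target_density = 0.17,
                                      maf_floor = 0.05) {
  sim <- simulate_panels(config)
  H1 <- ncol(sim$panels[[1]]$alleles)
  if (2L * n_study >= H1)
    stop("population 1 is too small to hold out ", n_study, " individuals")
  study_cols <- (H1 - 2L * n_study + 1L):H1
  ref_cols1 <- setdiff(seq_len(H1), study_cols)
  ref_alle <- cbind(sim$panels[[1]]$alleles[, ref_cols1, drop = FALSE],
                    do.call(cbind, lapply(sim$panels[-1], `[[`, "alleles")))
  ref_ids <- c(sim$panels[[1]]$haplotype_ids[ref_cols1],
               unlist(lapply(sim$panels[-1], `[[`, "haplotype_ids")))
  reference <- haplotype_panel(sim$panels[[1]]$sites, ref_alle, ref_ids)
  reference_pops <- c(rep(names(sim$panels)[1], length(ref_cols1)),
                      rep(names(sim$panels)[-1],
                          config$haplotypes_per_population[-1]))
  typed_sites <- ascertain_array(reference, target_density, maf_floor)
  held <- subset_panel(sim$panels[[1]], haplotypes = study_cols)
  st <- make_study(held, n_study, typed_sites)
  list(reference = reference, reference_pops = reference_pops,
       study = st$study, truth = st$truth,
       truth_haplotypes = st$truth_haplotypes,
       typed_sites = typed_sites, map = sim$map, panels = sim$panels,
       sites = sim$panels[[1]]$sites)
}

#' Write a simulated experiment to IMPUTE-style files
#'
#' @param experiment output of [simulate_imputation_study()].
#' @param prefix output path prefix; writes `<prefix>.hap`,
#'   `<prefix>.legend`, `<prefix>.gen`, `<prefix>.sample`,
#'   `<prefix>.map`.
#' @return Invisibly, the vector of written paths.
#' @export
write_experiment <- function(experiment, prefix) {
  paths <- paste0(prefix, c(".hap", ".legend", ".gen", ".sample", ".map"))
  write_hap_legend(experiment$reference, paths[1], paths[2])
  st <- experiment$study
  probs <- matrix(0, nrow(st$sites), 3L * ncol(st$genotypes))
  for (i in seq_len(ncol(st$genotypes))) {
    g <- st$genotypes[, i]
    tri <- matrix(0, length(g), 3)
    tri[cbind(which(!is.na(g)), g[!is.na(g)] + 1L)] <- 1
    tri[is.na(g), ] <- 1 / 3
    probs[, (3L * i - 2L):(3L * i)] <- tri
  }
  write_gen(st$sites, probs, paths[3])
  write_sample(st$individual_ids, paths[4])
  write_genetic_map(experiment$map, paths[5])
  invisible(paths)
}
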