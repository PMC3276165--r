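# The Li & Stephens haplotype-copying HMM layer: model parameters,
# recombination schedule, haploid forward-backward with analytic
# imputation of untyped sites, and the diploid phase sampler.

#' Model parameters for imputation
#'
#' Tuning parameters of the copying model and the MCMC.
#'
#' @param Ne effective population size used to scale genetic distances
#'   into switch rates (default 20000).
#' @param k number of template haplotypes per phasing update (default 80).
#' @param k_hap number of Hamming-nearest reference haplotypes used as
#'   templates for each study haplotype's imputation update (default 500).
#' @param iterations total MCMC sweeps (default 30).
#' @param burnin sweeps discarded before averaging (default 10).
#' @param lambda optional fixed per-site copying-error probability; by
#'   default a Watterson-style rate is derived from the active template
#'   count (see [lambda_mismatch()]).
#' @return A `model_params` list.
#' @export
model_params <- function(Ne = 20000, k = 80, k_hap = 500,
                         iterations = 30, burnin = 10, lambda = NULL) {
  stopifnot(Ne > 0, k >= 2, k_hap >= 1, iterations > 0,
            burnin > 0, burnin < iterations)
  if (!is.null(lambda) && (lambda <= 0 || lambda >= 0.5))
    stop("lambda must lie in (0, 0.5)")
  structure(list(Ne = Ne, k = as.integer(k), k_hap = as.integer(k_hap),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), lambda = lambda),
            class = "model_params")
}

#' Copying-error (mismatch) probability
#'
#' Watterson-style mutation parameter folded into a per-site copying
#' error: `theta = 1 / sum_{i=1}^{K-1} 1/i` and
#' `lambda = theta / (2 * (theta + K))`, recomputed for the active
#' template count K.  A fixed `lambda` in the model parameters overrides
#' this.
#'
#' @param K active number of template haplotypes.
#' @param params optional [model_params()] carrying an override.
#' @return The mismatch probability in (0, 0.5).
#' @export
lambda_mismatch <- function(K, params = NULL) {
  if (!is.null(params) && !is.null(params$lambda)) return(params$lambda)
  Keff <- max(K, 2L)
  theta <- 1 / sum(1 / seq_len(Keff - 1L))
  theta / (2 * (theta + Keff))
}

#' Recombination schedule between typed sites
#'
#' Converts genetic distances between adjacent typed sites into the
#' scaled recombination parameters `rho_j = 4 * Ne * d_j` (d in
#' Morgans) and the per-interval template-switch probabilities
#' `p_j = 1 - exp(-rho_j / K)`.  Transitions land uniformly: the
#' probability of moving to any specific other template is `p_j / K` and
#' of staying `(1 - p_j) + p_j / K`.
#'
#' @param map a [genetic_map()] (cumulative cM is interpolated linearly
#'   in bp, held constant beyond the map ends).
#' @param typed_positions sorted base-pair positions of the typed sites.
#' @param Ne effective population size.
#' @param K number of template states.
#' @return A `transition_schedule`: list with `rho`, `p_switch` (each of
#'   length `length(typed_positions) - 1`), `cm` (per-site genetic
#'   positions) and `K`.
#' @export
build_transitions <- function(map, typed_positions, Ne, K) {
  if (is.unsorted(typed_positions))
    stop("typed positions must be sorted")
  cm <- interpolate_cm(map, typed_positions)
  d <- diff(cm) / 100  # Morgans
  rho <- 4 * Ne * d
  structure(list(rho = rho, p_switch = 1 - exp(-rho / K),
                 cm = cm, K = as.integer(K)),
            class = "transition_schedule")
}

# Rescale a schedule's switch probabilities to a different template count.
reswitch <- function(schedule, K) {
  structure(list(rho = schedule$rho, p_switch = 1 - exp(-schedule$rho / K),
                 cm = schedule$cm, K = as.integer(K)),
            class = "transition_schedule")
}

#' Haploid forward-backward
#'
#' Exact HMM smoothing of one haplotype against K templates under the
#' copying model.  Missing observations emit 1 for every state.  Cost is
#' O(M * K) via the single-switch-rate transition structure.
#'
#' @param observed integer vector over typed sites: 0, 1 or `NA`.
#' @param templates integer matrix (typed sites x K) of template alleles.
#' @param schedule a [build_transitions()] schedule for the typed sites;
#'   its switch probabilities are rescaled to the template count.
#' @param params a [model_params()]; only a fixed `lambda` is consulted.
#' @param return_gamma set `FALSE` to skip materializing the full M x K
#'   posterior when only imputation summaries are needed (the engine's
#'   hot path).
#' @return A `copying_posterior`: list with `gamma` (M x K state
#'   posteriors, rows summing to 1; `NULL` when not requested), `loglik`,
#'   the per-typed-site allele posteriors `p1_typed`, and the scaled
#'   messages (`alphaT`, `bsT`, state-major) needed to extend the
#'   smoothing to untyped sites.
#' @export
haploid_forward_backward <- function(observed, templates, schedule,
                                     params = model_params(),
                                     return_gamma = TRUE) {
  templates <- as.matrix(templates)
  storage.mode(templates) <- "integer"
  K <- ncol(templates)
  if (nrow(templates) != length(observed))
    stop("observed length does not match template sites")
  lam <- lambda_mismatch(K, params)
  sch <- if (schedule$K == K) schedule else reswitch(schedule, K)
  fb <- .haploid_fb_cpp(as.integer(observed), templates, sch$p_switch, lam,
                        return_gamma)
  structure(list(gamma = if (return_gamma) fb$gamma else NULL,
                 alphaT = fb$alphaT, bsT = fb$bsT,
                 p1_typed = fb$p1_typed,
                 loglik = fb$loglik, observed = as.integer(observed),
                 templates = templates, schedule = sch, lambda = lam),
            class = "copying_posterior")
}

#' Analytic imputation of untyped sites
#'
#' Computes P(allele 1) at untyped positions by inserting each untyped
#' site into the HMM as a missing-observation column, which is exact
#' under the copying model:
#' `P(allele 1) = sum_z gamma_z * ((1-lambda) * 1\{h_z = 1\} + lambda * 1\{h_z = 0\})`.
#'
#' @param fb a `copying_posterior` from [haploid_forward_backward()].
#' @param templates_untyped integer matrix (untyped sites x K) of the
#'   same templates' alleles at the untyped sites; alternatively a
#'   larger panel matrix combined with `sel`.
#' @param untyped_positions base-pair positions of the untyped sites.
#' @param typed_positions base-pair positions of the typed sites the HMM
#'   ran on.
#' @param map a [genetic_map()].
#' @param Ne effective population size.
#' @param sel optional 1-based haplotype indices mapping the K template
#'   states into the columns (or transposed rows) of `templates_untyped`
#'   (avoids materializing the subset); default `1:K`.
#' @param transposed set `TRUE` when `templates_untyped` is already laid
#'   out as haplotypes x untyped sites (the engine precomputes this once
#'   per chunk to keep the hot loop in memory order).
#' @return Numeric vector of P(allele 1) in \[0, 1\] per untyped site.
#' @export
impute_untyped <- function(fb, templates_untyped, untyped_positions,
                           typed_positions, map, Ne, sel = NULL,
                           transposed = FALSE) {
  templates_untyped <- as.matrix(templates_untyped)
  storage.mode(templates_untyped) <- "integer"
  if (!transposed) templates_untyped <- t(templates_untyped)
  K <- nrow(fb$alphaT)
  if (is.null(sel)) {
    if (nrow(templates_untyped) != K)
      stop("untyped template count differs from typed template count")
    sel <- seq_len(K)
  } else if (length(sel) != K)
    stop("sel length differs from typed template count")
  if (ncol(templates_untyped) != length(untyped_positions))
    stop("untyped template rows must match untyped positions")
  M <- length(typed_positions)
  lam <- fb$lambda
  if (M == 0L)  # no typed data: uniform state posterior
    return(lam + (1 - 2 * lam) *
             colMeans(templates_untyped[sel, , drop = FALSE]))
  cm_u <- interpolate_cm(map, untyped_positions)
  cm_t <- fb$schedule$cm
  left <- findInterval(untyped_positions, typed_positions)
  d_left <- ifelse(left >= 1L, cm_u - cm_t[pmax(left, 1L)], 0) / 100
  d_right <- ifelse(left <= M - 1L, cm_t[pmin(left + 1L, M)] - cm_u, 0) / 100
  d_left <- pmax(d_left, 0)
  d_right <- pmax(d_right, 0)
  p_left <- 1 - exp(-4 * Ne * d_left / K)
  p_right <- 1 - exp(-4 * Ne * d_right / K)
  .impute_untyped_cpp(fb$alphaT, fb$bsT, templates_untyped,
                      as.integer(sel), as.integer(left),
                      p_left, p_right, lam)
}

#' Allele posteriors at the typed sites themselves
#'
#' P(allele 1) at each typed site from the smoothed state posteriors;
#' used to fill in typed sites whose study genotype is missing.
#'
#' @param fb a `copying_posterior`.
#' @return Numeric vector of P(allele 1) per typed site.
#' @export
typed_allele_probs <- function(fb) {
  fb$p1_typed
}

#' Sample a diploid phase configuration
#'
#' Forward filtering over template pairs with diploid emissions (the sum
#' over the allele assignments consistent with the genotype), followed by
#' backward sampling of a state-pair path and per-site allele assignment.
#' The returned pair is genotype-consistent at every non-missing site;
#' missing genotypes emit 1 and the alleles are drawn from the sampled
#' templates' emissions.
#'
#' @param genotypes integer vector over typed sites: 0, 1, 2 or `NA`.
#' @param templates integer matrix (typed sites x k) of template alleles.
#' @param schedule a [build_transitions()] schedule (rescaled to the
#'   template count).
#' @param params a [model_params()].
#' @return List with integer haplotypes `h1` and `h2`.
#' @export
diploid_sample_phase <- function(genotypes, templates, schedule,
                                 params = model_params()) {
  templates <- as.matrix(templates)
  storage.mode(templates) <- "integer"
  K <- ncol(templates)
  if (K < 2L) stop("diploid phasing needs at least 2 templates")
  lam <- lambda_mismatch(K, params)
  sch <- if (schedule$K == K) schedule else reswitch(schedule, K)
  .diploid_sample_cpp(as.integer(genotypes), templates, sch$p_switch, lam)
}
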