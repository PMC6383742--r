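#' Configuration for the forward Wright-Fisher simulation
#'
#' The default values state the validation design used throughout the
#' package: a 1 Mb genome with per-bp per-generation mutation rate 1e-8 and
#' recombination rate 3e-7; an ancestral population P1 of 5,000 diploids
#' burnt in for 50,000 generations; a donor population P2 of 2,000 splitting
#' from P1 and diverging without contact for 50,000 generations; migration
#' from P2 into P1 during the final 200 generations before sampling at a
#' per-generation rate `m`; 100 diploids sampled per population.  An
#' ancestor-proxy population (same size as P1) splits from P1 at migration
#' start, standing in for the unadmixed relative of the recipient.
#'
#' Population-size rescaling by `rescale_factor` Q divides sizes and
#' generation counts by Q and multiplies mu, rec, m and s by Q, preserving
#' the products N*mu, N*rec, N*m and N*s.
#'
#' @param genome_length genome length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param rec per-bp per-generation recombination rate.
#' @param N1 recipient/ancestral population size (diploids).
#' @param N2 donor population size.
#' @param N_anc_proxy ancestor-proxy population size (defaults to `N1`).
#' @param burn_in burn-in generations for P1.
#' @param divergence generations between the P2 split and migration start.
#' @param migration_gens generations of migration before sampling.
#' @param anc_split generations before sampling at which the ancestor-proxy
#'   population splits from the recipient lineage.  The default (2,000)
#'   gives the proxy a wild-relative level of divergence from the recipient
#'   (Fst ~ 0.2 at the default sizes) — far less than the recipient-donor
#'   divergence, but enough that the proxy is not simply the recipient
#'   itself, mirroring the role a related wild population plays in the real
#'   scan design.
#' @param m per-generation migration rate from donor into recipient.
#' @param s selection coefficient on beneficial donor alleles in the
#'   recipient (0 = neutral).
#' @param benefit_fraction fraction of donor-private polymorphic sites
#'   designated beneficial when `s > 0`.
#' @param n_sample diploids sampled per population (capped at the rescaled
#'   population size).
#' @param rescale_factor rescaling factor Q >= 1.
#' @param init `"forward"` runs the full forward burn-in; `"sfs"` seeds the
#'   ancestral population with standing variation drawn from the neutral
#'   site-frequency spectrum and shortens the burn-in to `2 * N1` (rescaled)
#'   generations of linkage equilibration — a desk-scale replacement for
#'   the long burn-in whose remaining initialization error is erased by the
#'   deep divergence phase.
#' @return a `sim_config` list of rescaled simulator parameters.
#' @export
sim_config <- function(genome_length = 1e6, mu = 1e-8, rec = 3e-7,
                       N1 = 5000, N2 = 2000, N_anc_proxy = N1,
                       burn_in = 50000, divergence = 50000,
                       migration_gens = 200, anc_split = 2000, m = 0.001,
                       s = 0,
                       benefit_fraction = 0.001, n_sample = 100,
                       rescale_factor = 1, init = c("forward", "sfs")) {
  init <- match.arg(init)
  Q <- rescale_factor
  if (Q < 1) stop("rescale_factor must be >= 1")
  stopifnot(m >= 0, m * Q <= 1, s >= 0, mu >= 0, rec >= 0)
  cfg <- list(
    genome_length = genome_length,
    mu = mu * Q, rec = rec * Q,
    N1 = as.integer(round(N1 / Q)), N2 = as.integer(round(N2 / Q)),
    N0 = as.integer(round(N_anc_proxy / Q)),
    burn_gens = as.integer(round(burn_in / Q)),
    div_gens = as.integer(round(divergence / Q)),
    mig_gens = max(1L, as.integer(round(migration_gens / Q))),
    anc_gens = max(1L, as.integer(round(anc_split / Q))),
    m = m * Q, s = s * Q,
    benefit_fraction = benefit_fraction,
    n_sample = as.integer(n_sample),
    rescale_factor = Q, init = init)
  if (init == "sfs") cfg$burn_gens <- 2L * cfg$N1
  if (min(cfg$N1, cfg$N2, cfg$N0) < 50)
    stop("over-rescaled: a population size fell below 50")
  class(cfg) <- "sim_config"
  cfg
}

#' Forward simulation with donor-ancestry tract tracking
#'
#' Runs the discrete-generation Wright-Fisher model of [sim_config()]:
#' burn-in, split, divergence, then unidirectional donor-to-recipient
#' migration with optional positive selection on a designated fraction of
#' donor-private alleles.  Every haplotype's donor-origin tracts are
#' tracked exactly through the migration phase, so the sampled recipient
#' genome carries known truth.  Deterministic given `seed`.
#'
#' @param config a `sim_config`.
#' @param seed optional integer seed.
#' @return list with `haps` (a [HaplotypeSet]: populations `ANC`, `REC`,
#'   `DON` with roles ancestor_proxy/recipient/donor; REF is the ancestral
#'   allele), `popmap`, and `truth` (class `SimTruth`: `tracts` data.frame
#'   with per-recipient-haplotype donor tracts in bp, `true_donor_fraction`
#'   in percent of the sampled recipient genome, `benefit_bp` positions of
#'   beneficial alleles, `genome_length`).
#' @export
simulate_forward <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ns <- c(min(config$n_sample, config$N0),
          min(config$n_sample, config$N1),
          min(config$n_sample, config$N2))
  raw <- .forward_sim_cpp(config$genome_length,
                          config$mu * config$genome_length,
                          config$rec * config$genome_length,
                          config$N1, config$N2, config$N0,
                          config$burn_gens, config$div_gens,
                          config$mig_gens, config$m, config$s,
                          config$benefit_fraction,
                          ns[1L], ns[2L], ns[3L], 100L,
                          if (identical(config$init, "sfs")) 1L else 0L,
                          config$anc_gens)
  pos <- floor(raw$positions) + 1
  keep <- !duplicated(pos)
  if (any(!keep))
    message("dropping ", sum(!keep),
            " site(s) colliding at the same bp after rounding")
  sites <- data.frame(chrom = "1", pos = as.integer(pos[keep]),
                      id = paste0("s", seq_len(sum(keep))),
                      ref = "A", alt = "T")
  samples <- c(paste0("ANC_", seq_len(ns[1L])),
               paste0("REC_", seq_len(ns[2L])),
               paste0("DON_", seq_len(ns[3L])))
  popmap <- PopulationMap(samples,
                          rep(c("ANC", "REC", "DON"), times = ns),
                          c(ANC = "ancestor_proxy", REC = "recipient",
                            DON = "donor"))
  haps <- HaplotypeSet(raw$alleles[, keep, drop = FALSE], sites, samples,
                       sort = FALSE)
  tracts <- data.frame(hap = raw$tract_hap,
                       chrom = rep("1", length(raw$tract_hap)),
                       start = raw$tract_start, end = raw$tract_end)
  truth <- structure(list(tracts = tracts,
                          true_donor_fraction = raw$true_donor_fraction,
                          n_recipient_haps = 2L * ns[2L],
                          benefit_bp = floor(raw$benefit_positions) + 1,
                          genome_length = config$genome_length),
                     class = "SimTruth")
  list(haps = haps, popmap = popmap, truth = truth)
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf(
    "SimTruth: %.2f%% of the sampled recipient genome is donor-origin (%d tracts on %d haplotypes)\n",
    x$true_donor_fraction, nrow(x$tracts), length(unique(x$tracts$hap))))
  invisible(x)
}
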