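# Seeded generators emulating the three data types the pipeline consumes:
# spot-position tables from live imaging, probe-level tiling ChIP signals
# with planted binding landscapes, and replicate expression matrices with
# planted up/down sets. Ground truth is always returned alongside.

#' Configuration for the spot-position simulator
#'
#' The null model is area-uniform positioning over the nuclear
#' cross-section: spots are scored in the single focal plane where the GFP
#' signal is brightest, so radial positions on a disc of radius R follow
#' r = R * sqrt(u), u ~ Uniform(0, 1). Non-uniform occupancy is expressed as
#' target probabilities of the three equal-area zones; within the drawn
#' zone's annulus the position is again area-uniform, so
#' \code{zone_probs = c(1/3, 1/3, 1/3)} reproduces the global uniform null
#' exactly. Pore colocalization is a per-cell Bernoulli event.
#'
#' @param n_cells number of cells (default 200, a typical per-condition
#'   count for live imaging panels).
#' @param zone_probs length-3 probabilities of zones 1..3; must sum to 1.
#' @param g1_fraction fraction of cells labelled G1 (unbudded); the rest are
#'   S (budded with spherical nucleus).
#' @param coloc_prob per-cell probability of complete signal overlap with
#'   the pore cluster (default 0.09, the random expectation).
#' @param diameter_um nuclear diameter in micrometres (default 2.0; only
#'   the ratio to diameter matters downstream).
#' @param seed integer RNG seed.
#' @return list of class \code{"spot_sim_config"}.
#' @export
spot_sim_config <- function(n_cells = 200L, zone_probs = rep(1 / 3, 3),
                            g1_fraction = 0.5, coloc_prob = 0.09,
                            diameter_um = 2.0, seed = 1L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != floor(n_cells)) {
    stop("'n_cells' must be a positive integer")
  }
  if (length(zone_probs) != 3L || any(zone_probs < 0) || any(zone_probs > 1) ||
      abs(sum(zone_probs) - 1) > 1e-12) {
    stop("'zone_probs' must be three probabilities summing to 1")
  }
  stopifnot_prob(g1_fraction, "g1_fraction")
  stopifnot_prob(coloc_prob, "coloc_prob")
  if (diameter_um <= 0) stop("'diameter_um' must be positive")
  structure(
    list(n_cells = as.integer(n_cells), zone_probs = as.numeric(zone_probs),
         g1_fraction = g1_fraction, coloc_prob = coloc_prob,
         diameter_um = diameter_um, seed = as.integer(seed)),
    class = "spot_sim_config"
  )
}

#' Simulate spot-position measurements
#'
#' Draws one imaged cell per row: a zone per \code{zone_probs}, an
#' area-uniform radial position within that zone's annulus, a cell-cycle
#' stage, and a Bernoulli pore-colocalization flag. Identical config and
#' seed give bit-identical output.
#'
#' @param config a [spot_sim_config()].
#' @return data.frame with columns \code{cell_id}, \code{stage} (G1/S),
#'   \code{distance_um}, \code{diameter_um}, \code{coloc} (logical),
#'   \code{zone_true}.
#' @export
simulate_spots <- function(config) {
  stopifnot(inherits(config, "spot_sim_config"))
  b <- zone_boundaries()
  # annulus bounds as centre distance on the unit-diameter scale:
  # zone 1 (peripheral) rho in (0.5 - b1, 0.5], zone 3 rho in [0, 0.5 - b2]
  rho_lo <- c(0.5 - b$b1, 0.5 - b$b2, 0)
  rho_hi <- c(0.5, 0.5 - b$b1, 0.5 - b$b2)
  with_seed(config$seed, {
    n <- config$n_cells
    zone <- sample.int(3L, n, replace = TRUE, prob = config$zone_probs)
    u <- stats::runif(n)
    rho <- sqrt(rho_lo[zone]^2 + u * (rho_hi[zone]^2 - rho_lo[zone]^2))
    ratio <- 0.5 - rho
    stage <- ifelse(stats::runif(n) < config$g1_fraction, "G1", "S")
    coloc <- stats::runif(n) < config$coloc_prob
    data.frame(
      cell_id = sprintf("cell_%05d", seq_len(n)),
      stage = stage,
      distance_um = ratio * config$diameter_um,
      diameter_um = config$diameter_um,
      coloc = coloc,
      zone_true = zone,
      stringsAsFactors = FALSE
    )
  })
}

#' Configuration for the tiling ChIP signal simulator
#'
#' Plants a binding landscape for a factor A and, jointly, for a factor B
#' whose positives are drawn conditionally on A (so that a target
#' conditional coincidence |A∩B|/|A| can be dialled in directly, the form in
#' which co-occupancy is reported). Each locus carries
#' \code{probes_per_locus} probe log2 ratios: Normal(\code{effect_log2},
#' \code{noise_sd}) at bound loci, Normal(0, \code{noise_sd}) elsewhere.
#'
#' @param chrom_sizes data.frame with columns \code{chrom}, \code{length}
#'   (bp); each chromosome is tiled with non-overlapping loci.
#' @param locus_size locus width in bp, 300 or 100.
#' @param probes_per_locus probes per locus (default 11).
#' @param probe_length probe length in nt (metadata only; default 25).
#' @param bound_fraction_a marginal probability a locus is A-bound
#'   (default 0.24, the genome-wide scale of a dispersed remodeler).
#' @param cond_overlap_b_given_a P(B bound | A bound) (default 0.76).
#' @param marginal_b target marginal probability of B (default 0.30); the
#'   off-A rate is derived from it and clamped to [0, 1].
#' @param effect_log2 mean probe log2 ratio at bound loci (default 1.5;
#'   0 gives a pure null landscape). Each bound locus additionally draws a
#'   strength multiplier uniform on 0.75--1.25, shared between the two
#'   factors where they are co-bound, so binding strengths at shared sites
#'   co-vary as they do on real arrays.
#' @param noise_sd probe noise SD (default 0.5).
#' @param seed integer RNG seed.
#' @return list of class \code{"tiling_sim_config"}.
#' @export
tiling_sim_config <- function(chrom_sizes, locus_size = 300L,
                              probes_per_locus = 11L, probe_length = 25L,
                              bound_fraction_a = 0.24,
                              cond_overlap_b_given_a = 0.76,
                              marginal_b = 0.30, effect_log2 = 1.5,
                              noise_sd = 0.5, seed = 1L) {
  stopifnot(is.data.frame(chrom_sizes),
            all(c("chrom", "length") %in% names(chrom_sizes)))
  if (!locus_size %in% c(300L, 100L)) stop("'locus_size' must be 300 or 100")
  if (any(chrom_sizes$length < locus_size)) {
    stop("every chromosome must fit at least one locus")
  }
  if (probes_per_locus < 5L) stop("'probes_per_locus' must be >= 5")
  stopifnot_prob(bound_fraction_a, "bound_fraction_a")
  stopifnot_prob(cond_overlap_b_given_a, "cond_overlap_b_given_a")
  stopifnot_prob(marginal_b, "marginal_b")
  if (effect_log2 < 0) stop("'effect_log2' must be >= 0")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  structure(
    list(chrom_sizes = chrom_sizes, locus_size = as.integer(locus_size),
         probes_per_locus = as.integer(probes_per_locus),
         probe_length = as.integer(probe_length),
         bound_fraction_a = bound_fraction_a,
         cond_overlap_b_given_a = cond_overlap_b_given_a,
         marginal_b = marginal_b, effect_log2 = effect_log2,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "tiling_sim_config"
  )
}

#' Simulate probe-level tiling ChIP signals for two factors
#'
#' Tiles each chromosome into non-overlapping loci, plants A/B-bound locus
#' sets (B conditionally on A), and draws per-probe log2 ratios. The planted
#' positive sets are returned as ground truth.
#'
#' @param config a [tiling_sim_config()].
#' @return list with \code{probes_a}, \code{probes_b} (long data.frames:
#'   \code{chrom}, \code{locus_start}, \code{locus_end}, \code{locus_id},
#'   \code{probe_index}, \code{log2_ratio}), \code{loci} (the grid with
#'   \code{bound_a}, \code{bound_b}), and \code{truth} (list of A and B
#'   positive locus ids).
#' @export
simulate_tiling <- function(config) {
  stopifnot(inherits(config, "tiling_sim_config"))
  cs <- config$chrom_sizes
  grids <- lapply(seq_len(nrow(cs)), function(i) {
    n_loci <- cs$length[i] %/% config$locus_size
    start <- (seq_len(n_loci) - 1L) * config$locus_size
    data.frame(chrom = cs$chrom[i], locus_start = start,
               locus_end = start + config$locus_size,
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, grids)
  loci$locus_id <- paste0(loci$chrom, ":", loci$locus_start)
  n <- nrow(loci)
  fa <- config$bound_fraction_a
  p_b_off_a <- if (fa >= 1) 0 else {
    min(1, max(0, (config$marginal_b - fa * config$cond_overlap_b_given_a) / (1 - fa)))
  }
  with_seed(config$seed, {
    loci$bound_a <- stats::runif(n) < fa
    loci$bound_b <- ifelse(loci$bound_a,
                           stats::runif(n) < config$cond_overlap_b_given_a,
                           stats::runif(n) < p_b_off_a)
    # per-locus binding-strength multiplier, shared between the two factors
    # at co-bound loci: real co-occupied sites scale together, which is what
    # paired log2 scatterplots across loci measure
    strength <- stats::runif(n, 0.75, 1.25)
    k <- config$probes_per_locus
    draw <- function(bound) {
      mu <- ifelse(rep(bound, each = k),
                   config$effect_log2 * rep(strength, each = k), 0)
      data.frame(
        chrom = rep(loci$chrom, each = k),
        locus_start = rep(loci$locus_start, each = k),
        locus_end = rep(loci$locus_end, each = k),
        locus_id = rep(loci$locus_id, each = k),
        probe_index = rep.int(seq_len(k), n),
        log2_ratio = stats::rnorm(n * k, mean = mu, sd = config$noise_sd),
        stringsAsFactors = FALSE
      )
    }
    probes_a <- draw(loci$bound_a)
    probes_b <- draw(loci$bound_b)
    list(
      probes_a = probes_a,
      probes_b = probes_b,
      loci = loci,
      truth = list(a = loci$locus_id[loci$bound_a],
                   b = loci$locus_id[loci$bound_b])
    )
  })
}

#' Configuration for the replicate expression simulator
#'
#' Genes get a baseline log2 intensity; wild-type replicates scatter around
#' it with \code{noise_sd}, and each mutant's replicates are shifted by that
#' mutant's planted per-gene log2 effect. Planted up/down sets are supplied
#' per mutant as named numeric vectors (gene -> log2 effect) and must be
#' disjoint within a mutant; a gene class map (e.g. "RP") can be attached.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per strain (>= 3 expected, >= 2 required).
#' @param strains strain labels; the first is the reference (wild type).
#' @param planted_up,planted_down named lists, mutant strain -> named
#'   numeric vector of positive log2 effects (genes named \code{gene_%05d}
#'   by index). Effects in \code{planted_down} are magnitudes and applied
#'   negatively.
#' @param class_labels optional named character vector, gene -> class.
#' @param noise_sd replicate noise SD (default 0.15 log2 units, typical
#'   biological + technical scatter of replicate microarrays).
#' @param baseline_mean,baseline_sd mean/SD of per-gene baselines
#'   (default 8 and 1.5 log2 units).
#' @param seed integer RNG seed.
#' @return list of class \code{"expr_sim_config"}.
#' @export
expr_sim_config <- function(n_genes = 6000L, n_reps = 3L,
                            strains = c("WT", "mutantA", "mutantB"),
                            planted_up = list(), planted_down = list(),
                            class_labels = NULL, noise_sd = 0.15,
                            baseline_mean = 8, baseline_sd = 1.5, seed = 1L) {
  if (n_genes < 1) stop("'n_genes' must be positive")
  if (n_reps < 2L) stop("at least 2 replicates per strain are required (t-test undefined below)")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  for (m in union(names(planted_up), names(planted_down))) {
    if (!m %in% strains) stop(sprintf("planted effects name unknown strain '%s'", m))
    shared <- intersect(names(planted_up[[m]]), names(planted_down[[m]]))
    if (length(shared) > 0L) {
      stop(sprintf("gene(s) planted both up and down in '%s': %s",
                   m, paste(utils::head(shared, 3L), collapse = ", ")))
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
         strains = strains, planted_up = planted_up,
         planted_down = planted_down, class_labels = class_labels,
         noise_sd = noise_sd, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, seed = as.integer(seed)),
    class = "expr_sim_config"
  )
}

#' Simulate a replicate expression matrix with planted effects
#'
#' @param config an [expr_sim_config()].
#' @return list with \code{mat} (genes x samples log2 matrix),
#'   \code{sample_map} (sample, strain), \code{truth} (per-mutant lists of
#'   planted up/down genes with effects) and \code{class_labels}.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  samples <- as.vector(t(outer(config$strains, seq_len(config$n_reps),
                               function(s, r) paste0(s, "_rep", r))))
  strain_of <- rep(config$strains, each = config$n_reps)
  effect <- matrix(0, nrow = config$n_genes, ncol = length(config$strains),
                   dimnames = list(genes, config$strains))
  for (m in names(config$planted_up)) {
    e <- config$planted_up[[m]]
    effect[names(e), m] <- effect[names(e), m] + e
  }
  for (m in names(config$planted_down)) {
    e <- config$planted_down[[m]]
    effect[names(e), m] <- effect[names(e), m] - abs(e)
  }
  with_seed(config$seed, {
    baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                             config$baseline_sd)
    mu <- baseline + effect[, strain_of, drop = FALSE]
    mat <- mu + stats::rnorm(length(mu), 0, config$noise_sd)
    dimnames(mat) <- list(genes, samples)
    list(
      mat = mat,
      sample_map = data.frame(sample = samples, strain = strain_of,
                              stringsAsFactors = FALSE),
      truth = list(up = config$planted_up, down = config$planted_down),
      class_labels = config$class_labels
    )
  })
}

#' Plant per-mutant up/down gene sets with a target overlap
#'
#' Convenience builder for [expr_sim_config()]: draws up- and down-regulated
#' gene sets for two mutants such that a stated fraction of the second
#' mutant's genes is shared with the first (the direction in which set
#' overlap is reported), with log2 effect magnitudes drawn uniformly from
#' \code{effect_range}.
#'
#' @param n_genes gene universe size (genes named \code{gene_%05d}).
#' @param n_up,n_down set sizes for each of the two mutants (length-2
#'   integer vectors, first mutant then second).
#' @param overlap fraction of the second mutant's set shared with the first.
#' @param mutants the two mutant strain labels.
#' @param effect_range range of log2 effect magnitudes (default 0.4 to 2.4,
#'   spanning just-detectable to strongly misregulated).
#' @param seed integer RNG seed.
#' @return list with \code{planted_up} and \code{planted_down} suitable for
#'   [expr_sim_config()].
#' @export
plant_de_sets <- function(n_genes, n_up = c(400L, 375L), n_down = c(450L, 506L),
                          overlap = 0.17, mutants = c("mutantA", "mutantB"),
                          effect_range = c(0.4, 2.4), seed = 1L) {
  stopifnot(length(n_up) == 2L, length(n_down) == 2L, length(mutants) == 2L)
  stopifnot_prob(overlap, "overlap")
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  with_seed(seed, {
    draw_pair <- function(n1, n2) {
      s1 <- sample(genes, n1)
      n_shared <- round(overlap * n2)
      shared <- sample(s1, min(n_shared, n1))
      rest <- sample(setdiff(genes, s1), n2 - length(shared))
      list(first = s1, second = c(shared, rest))
    }
    up <- draw_pair(n_up[1L], n_up[2L])
    # keep up/down disjoint within each mutant
    pool_down <- function(exclude1, exclude2, n1, n2) {
      s1 <- sample(setdiff(genes, exclude1), n1)
      n_shared <- round(overlap * n2)
      shared <- sample(setdiff(s1, exclude2), min(n_shared, n1))
      rest <- sample(setdiff(genes, c(s1, exclude2)), n2 - length(shared))
      list(first = s1, second = c(shared, rest))
    }
    down <- pool_down(up$first, up$second, n_down[1L], n_down[2L])
    eff <- function(g) stats::setNames(
      stats::runif(length(g), effect_range[1L], effect_range[2L]), g)
    list(
      planted_up = stats::setNames(list(eff(up$first), eff(up$second)), mutants),
      planted_down = stats::setNames(list(eff(down$first), eff(down$second)), mutants)
    )
  })
}
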