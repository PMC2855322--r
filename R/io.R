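# Readers/writers for the standard formats touched (GFF3, BED, TSV, JSON,
# YAML) and the end-to-end demo pipeline.

#' Read gene records from a GFF3 file
#'
#' Parses a GFF3 file (via \pkg{rtracklayer}) and returns gene records with
#' coordinates converted from GFF's 1-based inclusive convention to the
#' package-internal 0-based half-open convention. Records without a strand
#' are rejected: context classification needs gene orientation.
#'
#' @param path GFF3 file path.
#' @param feature_type feature type(s) to keep (default \code{"gene"}).
#' @return data.frame: \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop(sprintf("malformed GFF3 '%s': %s", path,
                                conditionMessage(e)), call. = FALSE)
                 })
  df <- as.data.frame(gr)
  if (!is.null(feature_type) && "type" %in% names(df)) {
    df <- df[df$type %in% feature_type, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no gene records found")
  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop("strandless gene record(s) rejected: gene orientation is required")
  }
  id <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  if ("Name" %in% names(df)) {
    id <- ifelse(is.na(id), as.character(df$Name), id)
  }
  out <- data.frame(
    gene_id = id,
    chrom = as.character(df$seqnames),
    start = as.integer(df$start - 1L), # 1-based inclusive -> 0-based half-open
    end = as.integer(df$end),
    strand = strand,
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write gene records as GFF3
#'
#' Inverse of [read_gff3()] for the package's internal gene table
#' (0-based half-open back to GFF3's 1-based inclusive).
#'
#' @param genes data.frame as returned by [read_gff3()].
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tnucorg\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start + 1L, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(lines, con)
  invisible(path)
}

#' Write binding calls or clusters as BED
#'
#' Standard 6-column BED (0-based half-open) with a \code{#} comment header.
#' For binding tracks the name is the locus id and the score is the locus
#' log2 ratio times 100, rounded to integer (clamped to BED's 0..1000);
#' for cluster tables the name encodes the locus count and the score uses
#' \code{peak_log2}. Unsorted input is sorted with a warning.
#'
#' @param x a \code{"binding_track"} or a cluster data.frame from
#'   [find_clusters()].
#' @param path output path.
#' @param comments extra comment lines for the header.
#' @export
write_bed <- function(x, path, comments = character()) {
  stopifnot(is.data.frame(x))
  if (nrow(x) > 1L) {
    o <- order(x$chrom, x$start)
    if (!identical(o, seq_len(nrow(x)))) {
      warning("unsorted intervals; sorting before writing")
      x <- x[o, , drop = FALSE]
    }
  }
  con <- file(path, "wt")
  on.exit(close(con))
  for (cm in c("nucorg BED: chrom start end name score strand", comments)) {
    writeLines(paste0("# ", cm), con)
  }
  if (nrow(x) > 0L) {
    name <- if ("locus_id" %in% names(x)) x$locus_id
            else sprintf("cluster_%d_loci", x$n_loci)
    log2col <- if ("log2_ratio" %in% names(x)) x$log2_ratio else x$peak_log2
    score <- pmax(0L, pmin(1000L, round_half_up(log2col * 100)))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.",
                       x$chrom, x$start, x$end, name, score), con)
  }
  invisible(path)
}

#' Read a chromosome sizes table
#'
#' @param path TSV with two columns, chromosome name and length in bp
#'   (headerless or headed \code{chrom}, \code{length}).
#' @return data.frame with \code{chrom}, \code{length}.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1, 1])), "chrom")) {
    df <- df[-1, , drop = FALSE]
  }
  data.frame(chrom = as.character(df[[1]]), length = as.integer(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its standard value:
#' per-locus ChIP call alpha 0.025, expression alpha 0.05, fold 1.25,
#' cluster min run 2, peak min log2 0.8 with top 10, subtelomere zone
#' 10 kb, random pore-colocalization expectation 0.09, and the three
#' simulator configurations for the demo run.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param out_dir output directory for [run_pipeline()].
#' @param ... overrides for any top-level field.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("nucorg_"), ...) {
  seed <- as.integer(seed)
  chrom_sizes <- data.frame(
    chrom = c("chr3", "chr4", "chr5", "chr6R"),
    # tiled at 300 bp these give 1322 / 4857 / 1849 / 413 loci, the
    # detectable-locus totals of the four-chromosome array
    length = c(396700L, 1457200L, 554800L, 124000L),
    stringsAsFactors = FALSE
  )
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    alpha_locus = 0.025,
    alpha_expr = 0.05,
    fold = 1.25,
    min_run = 2L,
    min_log2 = 0.8,
    top_k = 10L,
    zone_bp = 10000L,
    coloc_p0 = 0.09,
    spots = list(n_cells = 200L, zone_probs = c(0.49, 0.30, 0.21),
                 g1_fraction = 0.5, coloc_prob = 0.224),
    spots_control = list(n_cells = 200L, zone_probs = rep(1 / 3, 3),
                         g1_fraction = 0.5, coloc_prob = 0.09),
    tiling = list(chrom_sizes = chrom_sizes, locus_size = 300L,
                  bound_fraction_a = 0.24, cond_overlap_b_given_a = 0.76,
                  marginal_b = 0.30, effect_log2 = 1.5, noise_sd = 0.5),
    expression = list(n_genes = 6000L, n_reps = 3L,
                      strains = c("WT", "mutantA", "mutantB"),
                      n_up = c(400L, 375L), n_down = c(450L, 506L),
                      overlap = 0.17, noise_sd = 0.15, rp_genes = 120L)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot_prob(cfg$alpha_locus, "alpha_locus")
  stopifnot_prob(cfg$alpha_expr, "alpha_expr")
  if (cfg$fold <= 1) stop("'fold' must exceed 1")
  if (cfg$min_run < 1) stop("'min_run' must be >= 1")
  if (cfg$zone_bp <= 0) stop("'zone_bp' must be positive")
  if (!(cfg$coloc_p0 > 0 && cfg$coloc_p0 < 1)) stop("'coloc_p0' must be in (0, 1)")
  if (cfg$seed != floor(cfg$seed)) stop("'seed' must be an integer")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override the defaults of [pipeline_config()]; thresholds
#' are validated before any stage runs.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's.
#' @return a \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- as.integer(seed)
  if (!is.null(y$tiling$chrom_sizes)) {
    y$tiling$chrom_sizes <- as.data.frame(y$tiling$chrom_sizes,
                                          stringsAsFactors = FALSE)
  }
  do.call(pipeline_config, y)
}

#' Run the full demo pipeline
#'
#' Simulates the three data types under the configuration's seeds and runs
#' every analysis stage: zone scoring by stage with chi-squared tests and
#' the pore-colocalization test; binding calls for two factors with
#' clusters, top peaks, coincidence, subtelomere and track-correlation
#' statistics; and differential expression for two mutants with
#' classification, overlaps and the ranked top table. All tables are
#' written under \code{config$out_dir} with the configuration hash in a
#' header comment; the same config always yields byte-identical outputs.
#'
#' @param config a \code{"pipeline_config"}.
#' @return (invisibly) a list bundle with all stage results and
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific configuration only, not the output location
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  hdr <- c(sprintf("config_hash=%s", hash), sprintf("seed=%d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  message(sprintf("nucorg pipeline: seed=%d alpha_locus=%g alpha_expr=%g fold=%g min_run=%d min_log2=%g zone_bp=%d coloc_p0=%g [config %s]",
                  config$seed, config$alpha_locus, config$alpha_expr,
                  config$fold, config$min_run, config$min_log2,
                  config$zone_bp, config$coloc_p0, hash))

  # --- zone assay ---------------------------------------------------------
  zone <- stage("zone_assay", {
    sp_test <- simulate_spots(do.call(spot_sim_config,
      c(config$spots, list(seed = config$seed + 101L))))
    sp_ctrl <- simulate_spots(do.call(spot_sim_config,
      c(config$spots_control, list(seed = config$seed + 102L))))
    sp_test$condition <- "targeted"
    sp_ctrl$condition <- "control"
    spots <- rbind(sp_test, sp_ctrl)
    counts <- tabulate_zones(spots, group_by = c("condition", "stage"))
    tests <- lapply(seq_len(nrow(counts)),
                    function(i) zone_test_random(counts[i, ]))
    tab <- cbind(counts,
                 z1_pct = vapply(tests, function(t) t$percentages[1], 0),
                 z2_pct = vapply(tests, function(t) t$percentages[2], 0),
                 z3_pct = vapply(tests, function(t) t$percentages[3], 0),
                 chi2 = vapply(tests, `[[`, 0, "chi2"),
                 p = vapply(tests, `[[`, 0, "p"))
    write_tsv_commented(tab, file.path(config$out_dir, "zone_table.tsv"), hdr)
    coloc <- coloc_test(sum(sp_test$coloc), nrow(sp_test), config$coloc_p0)
    jsonlite::write_json(
      list(zone_table = tab, colocalization = unclass(coloc)[c("n", "k", "fraction", "p0", "p")]),
      file.path(config$out_dir, "zone_results.json"),
      auto_unbox = TRUE, digits = NA)
    list(spots = spots, counts = counts, tests = tests, table = tab,
         coloc = coloc)
  })

  # --- tiling ChIP --------------------------------------------------------
  chip <- stage("tiling_chip", {
    sim <- simulate_tiling(do.call(tiling_sim_config,
      c(config$tiling, list(seed = config$seed + 201L))))
    track_a <- call_track(sim$probes_a, alpha = config$alpha_locus,
                          factor_label = "A")
    track_b <- call_track(sim$probes_b, alpha = config$alpha_locus,
                          factor_label = "B")
    clusters <- find_clusters(track_a, min_run = config$min_run)
    peaks <- top_peaks(track_a, k = config$top_k,
                       min_log2 = config$min_log2, min_run = config$min_run)
    coin <- coincidence_table(track_a, track_b)
    subtel <- subtelomere_presence(track_a, config$tiling$chrom_sizes,
                                   zone_bp = config$zone_bp)
    corr <- correlate_tracks(track_a, track_b, subset = "a_positive")
    write_bed(track_a[track_positive(track_a), , drop = FALSE],
              file.path(config$out_dir, "calls_a.bed"), hdr)
    write_bed(track_b[track_positive(track_b), , drop = FALSE],
              file.path(config$out_dir, "calls_b.bed"), hdr)
    write_bed(clusters, file.path(config$out_dir, "clusters_a.bed"), hdr)
    write_tsv_commented(coin, file.path(config$out_dir, "coincidence.tsv"), hdr)
    write_tsv_commented(subtel, file.path(config$out_dir, "subtelomere.tsv"), hdr)
    write_tsv_commented(corr$pairs,
                        file.path(config$out_dir, "paired_log2.tsv"),
                        c(hdr, sprintf("spearman_rho=%.6f", corr$spearman_rho)))
    list(sim = sim, track_a = track_a, track_b = track_b,
         clusters = clusters, peaks = peaks, coincidence = coin,
         subtelomere = subtel, correlation = corr)
  })

  # --- differential expression -------------------------------------------
  de <- stage("diff_expression", {
    ex <- config$expression
    planted <- plant_de_sets(ex$n_genes, n_up = ex$n_up, n_down = ex$n_down,
                             overlap = ex$overlap,
                             mutants = ex$strains[2:3],
                             seed = config$seed + 301L)
    genes <- sprintf("gene_%05d", seq_len(ex$n_genes))
    rp_members <- with_seed(config$seed + 302L, sample(genes, ex$rp_genes))
    rp <- stats::setNames(rep("RP", ex$rp_genes), rp_members)
    sim <- simulate_expression(expr_sim_config(
      n_genes = ex$n_genes, n_reps = ex$n_reps, strains = ex$strains,
      planted_up = planted$planted_up, planted_down = planted$planted_down,
      class_labels = rp, noise_sd = ex$noise_sd,
      seed = config$seed + 303L))
    res1 <- de_test(sim$mat, sim$sample_map, mutant = ex$strains[2],
                    wt = ex$strains[1], fold = config$fold,
                    alpha = config$alpha_expr)
    res2 <- de_test(sim$mat, sim$sample_map, mutant = ex$strains[3],
                    wt = ex$strains[1], fold = config$fold,
                    alpha = config$alpha_expr)
    sets1 <- classify_changes(res1)
    sets2 <- classify_changes(res2)
    ov_down <- overlap_summary(sets2$down, sets1$down)
    ov_up <- overlap_summary(sets2$up, sets1$up)
    tt <- top_table(res1, res2, k = 40L, class_labels = rp)
    write_tsv_commented(res1, file.path(config$out_dir,
                                        paste0("de_", ex$strains[2], ".tsv")), hdr)
    write_tsv_commented(res2, file.path(config$out_dir,
                                        paste0("de_", ex$strains[3], ".tsv")), hdr)
    write_tsv_commented(tt, file.path(config$out_dir, "top_table.tsv"), hdr)
    jsonlite::write_json(
      list(down = unclass(ov_down)[c("n_a", "n_b", "n_both", "pct_a_in_b")],
           up = unclass(ov_up)[c("n_a", "n_b", "n_both", "pct_a_in_b")]),
      file.path(config$out_dir, "overlaps.json"), auto_unbox = TRUE,
      digits = NA)
    list(sim = sim, res1 = res1, res2 = res2, sets1 = sets1, sets2 = sets2,
         overlap_down = ov_down, overlap_up = ov_up, top_table = tt)
  })

  invisible(list(zone = zone, chip = chip, de = de,
                 out_dir = config$out_dir, config_hash = hash))
}
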