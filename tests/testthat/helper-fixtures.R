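# Fixture builders shared across test files.

# A binding track built directly from a status vector on a regular grid.
make_track <- function(status, log2 = NULL, chrom = "chrU", size = 300L,
                       start0 = 0L) {
  n <- length(status)
  if (is.logical(status)) {
    status <- ifelse(status, "positive", "not_significant")
  }
  if (is.null(log2)) log2 <- ifelse(status == "positive", 1, 0)
  starts <- start0 + (seq_len(n) - 1L) * size
  df <- data.frame(
    chrom = rep(chrom, length.out = n),
    start = starts,
    end = starts + size,
    locus_id = paste0(rep(chrom, length.out = n), ":", starts),
    resolution = size,
    log2_ratio = log2,
    p_up = ifelse(status == "positive", 1e-3, 0.5),
    p_down = ifelse(status == "negative", 1e-3, 0.5),
    status = status,
    stringsAsFactors = FALSE
  )
  nucorg:::as_binding_track(df)
}

# A long-format probe table with `k` probes per locus at the given means.
make_probe_table <- function(locus_means, k = 11L, sd = 0, chrom = "chrU",
                             size = 300L, seed = 1L) {
  n <- length(locus_means)
  starts <- (seq_len(n) - 1L) * size
  set.seed(seed)
  data.frame(
    chrom = chrom,
    locus_start = rep(starts, each = k),
    locus_end = rep(starts + size, each = k),
    locus_id = rep(paste0(chrom, ":", starts), each = k),
    probe_index = rep.int(seq_len(k), n),
    log2_ratio = rnorm(n * k, mean = rep(locus_means, each = k), sd = sd),
    stringsAsFactors = FALSE
  )
}

# Independent brute-force oracle for the exact one-sided signed-rank test:
# enumerate every sign vector explicitly and recompute ranks from scratch.
oracle_signed_rank <- function(values) {
  x <- values[values != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  list(p_up = mean(w_all >= w_obs), p_down = mean(w_all <= w_obs))
}

# Gene table in the internal convention (0-based half-open), as read_gff3
# would return it.
make_genes <- function(chrom, start, end, strand, id = NULL) {
  data.frame(
    gene_id = if (is.null(id)) paste0("g", seq_along(start)) else id,
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, stringsAsFactors = FALSE
  )
}

# Minimal de_result for threshold-logic tests.
make_de_result <- function(gene, log2_ratio, p, alpha = 0.05, fold = 1.25) {
  df <- data.frame(gene = gene, log2_ratio = log2_ratio, t = 0, p = p,
                   stringsAsFactors = FALSE)
  df$significant <- df$p < alpha
  df$changed <- abs(df$log2_ratio) >= log2(fold)
  df$direction <- ifelse(df$significant & df$changed,
                         ifelse(df$log2_ratio > 0, "up", "down"), "none")
  class(df) <- c("de_result", "data.frame")
  attr(df, "fold") <- fold
  attr(df, "alpha") <- alpha
  df
}

# The four-chromosome array geometry: 1322/4857/1849/413 loci at 300 bp.
array_chrom_sizes <- function() {
  data.frame(chrom = c("chr3", "chr4", "chr5", "chr6R"),
             length = c(396700L, 1457200L, 554800L, 124000L),
             stringsAsFactors = FALSE)
}
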