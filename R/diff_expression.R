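# Replicate-level differential expression: per-gene Welch t-tests,
# fold/significance classification, set overlaps, top tables, class effects.

#' Per-gene differential expression between two strains
#'
#' For every gene, compares replicate log2 intensities of a mutant strain
#' against the wild type with a two-sample Student t-test (pooled variance;
#' at 3-replicate designs the pooled test holds its nominal size where the
#' Welch approximation is markedly conservative -- see the vignette). The
#' effect is the mean difference of log2 values (mutant minus wild type). A
#' gene is \code{significant} when p < \code{alpha} (raw p-values; no
#' multiple-testing correction, by design -- see the vignette), and
#' \code{changed} when |log2 ratio| >= log2(\code{fold}), boundary
#' inclusive. \code{direction} is \code{up}/\code{down} only when both
#' flags hold, else \code{none}.
#'
#' Degenerate zero-variance genes are handled explicitly: equal means give
#' p = 1, unequal means with no within-group variance give p = 0.
#'
#' @param mat numeric matrix, genes x samples, log2 scale; rownames are gene
#'   ids, colnames are sample ids.
#' @param sample_map data.frame with columns \code{sample}, \code{strain}.
#' @param mutant,wt strain labels to compare.
#' @param fold fold-change threshold (> 1; default 1.25).
#' @param alpha significance threshold on raw p (default 0.05).
#' @return data.frame of class \code{"de_result"}: \code{gene},
#'   \code{log2_ratio}, \code{t}, \code{p}, \code{significant},
#'   \code{changed}, \code{direction}.
#' @export
de_test <- function(mat, sample_map, mutant, wt = "WT", fold = 1.25,
                    alpha = 0.05) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)),
            is.data.frame(sample_map),
            all(c("sample", "strain") %in% names(sample_map)))
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (!all(colnames(mat) %in% sample_map$sample)) {
    stop("every sample must be mapped to a strain")
  }
  strain_of <- sample_map$strain[match(colnames(mat), sample_map$sample)]
  for (s in c(mutant, wt)) {
    if (sum(strain_of == s) < 2L) {
      stop(sprintf("strain '%s' needs at least 2 replicates", s))
    }
  }
  if (fold <= 1) stop("'fold' must exceed 1")
  stopifnot_prob(alpha, "alpha")
  xm <- mat[, strain_of == mutant, drop = FALSE]
  xw <- mat[, strain_of == wt, drop = FALSE]
  n <- nrow(mat)
  tt <- vapply(seq_len(n), function(i) {
    a <- xm[i, ]; b <- xw[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      d <- mean(a) - mean(b)
      return(c(t = if (d == 0) 0 else sign(d) * Inf,
               p = if (d == 0) 1 else 0))
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    c(t = unname(ht$statistic), p = ht$p.value)
  }, c(t = 0, p = 0))
  res <- data.frame(
    gene = rownames(mat),
    log2_ratio = rowMeans(xm) - rowMeans(xw),
    t = tt["t", ],
    p = tt["p", ],
    stringsAsFactors = FALSE
  )
  res$significant <- res$p < alpha
  res$changed <- abs(res$log2_ratio) >= log2(fold)
  res$direction <- ifelse(res$significant & res$changed,
                          ifelse(res$log2_ratio > 0, "up", "down"),
                          "none")
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  attr(res, "mutant") <- mutant
  attr(res, "wt") <- wt
  attr(res, "fold") <- fold
  attr(res, "alpha") <- alpha
  res
}

#' Up- and down-regulated gene sets
#'
#' Partitions differential-expression results into up- and down-regulated
#' sets: significant (p < \code{alpha}) and changed by at least
#' \code{fold} (on the log2 scale, boundary inclusive) in the respective
#' direction.
#'
#' @param results a \code{"de_result"} from [de_test()].
#' @param fold,alpha thresholds; defaults are taken from \code{results}.
#' @return list with character vectors \code{up} and \code{down}.
#' @export
classify_changes <- function(results, fold = attr(results, "fold"),
                             alpha = attr(results, "alpha")) {
  stopifnot(inherits(results, "de_result"))
  if (is.null(fold)) fold <- 1.25
  if (is.null(alpha)) alpha <- 0.05
  if (fold <= 1) stop("'fold' must exceed 1")
  sig <- results$p < alpha
  lf <- log2(fold)
  list(up = results$gene[sig & results$log2_ratio >= lf],
       down = results$gene[sig & results$log2_ratio <= -lf])
}

#' Overlap between two gene sets
#'
#' Exact set intersection with integer-rounded (half-up) percentages in both
#' directions, the summary printed next to a two-set Venn diagram.
#'
#' @param a,b character vectors of gene ids.
#' @return \code{"overlap_summary"} object: \code{n_a}, \code{n_b},
#'   \code{n_both}, \code{pct_a_in_b} (= round(100 |A∩B| / |A|)),
#'   \code{pct_b_in_a}, \code{shared} (the intersection).
#' @examples
#' # 87 of 506 genes shared: 17% overlap
#' overlap_summary(paste0("g", 1:506), paste0("g", 1:87))$pct_a_in_b
#' @export
overlap_summary <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  both <- intersect(a, b)
  structure(
    list(n_a = length(a), n_b = length(b), n_both = length(both),
         pct_a_in_b = pct_int(length(both), length(a)),
         pct_b_in_a = pct_int(length(both), length(b)),
         shared = both),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Set overlap: |A| = %d, |B| = %d, |A ∩ B| = %d (%s%% of A, %s%% of B)\n",
              x$n_a, x$n_b, x$n_both, x$pct_a_in_b, x$pct_b_in_a))
  invisible(x)
}

#' Ranked table of the most up-regulated genes
#'
#' Ranks genes by the first mutant's log2 ratio (descending), keeps the top
#' \code{k}, and reports the second mutant's log2 ratio alongside; following
#' the field's table convention, the second ratio is shown in parentheses
#' when its own change is not significant (p >= 0.05). Optional class labels
#' (e.g. "Ribosomal protein") are attached per gene.
#'
#' @param results1,results2 \code{"de_result"} tables over the same gene
#'   universe (e.g. two mutants each vs wild type).
#' @param k number of rows (default 40); truncated to the universe size.
#' @param class_labels optional named character vector, gene -> class.
#' @return data.frame: \code{gene}, \code{log2_ratio_1}, \code{log2_ratio_2},
#'   \code{ratio_2_label} (parenthesized when not significant),
#'   \code{significant_2}, \code{class}.
#' @export
top_table <- function(results1, results2, k = 40L, class_labels = NULL) {
  stopifnot(inherits(results1, "de_result"), inherits(results2, "de_result"))
  if (!setequal(results1$gene, results2$gene)) {
    stop("results must share the same gene universe")
  }
  results2 <- results2[match(results1$gene, results2$gene), , drop = FALSE]
  ord <- order(-results1$log2_ratio)
  ord <- utils::head(ord, max(0L, k))
  r2 <- results2$log2_ratio[ord]
  sig2 <- results2$significant[ord]
  out <- data.frame(
    gene = results1$gene[ord],
    log2_ratio_1 = results1$log2_ratio[ord],
    log2_ratio_2 = r2,
    ratio_2_label = ifelse(sig2, sprintf("%.2f", r2), sprintf("(%.2f)", r2)),
    significant_2 = sig2,
    stringsAsFactors = FALSE
  )
  out$class <- if (is.null(class_labels)) {
    rep(NA_character_, nrow(out))
  } else {
    unname(class_labels[out$gene])
  }
  rownames(out) <- NULL
  out
}

#' Per-class effect comparison across two mutants
#'
#' Restricts to genes significantly misregulated in both mutants (the
#' convention for the paired log2 scatter), flags membership in a gene class
#' (e.g. ribosomal protein genes), and reports the class's mean log2 ratio
#' in each mutant.
#'
#' @param results1,results2 \code{"de_result"} tables over the same genes.
#' @param class_labels named character vector, gene -> class.
#' @param class the class label to summarise (e.g. \code{"RP"}).
#' @return list with \code{rows} (gene, log2_1, log2_2, in_class over the
#'   both-significant genes) and \code{class_mean_1}, \code{class_mean_2},
#'   \code{n_class}.
#' @export
class_effect_summary <- function(results1, results2, class_labels, class) {
  stopifnot(inherits(results1, "de_result"), inherits(results2, "de_result"))
  if (!class %in% class_labels) {
    stop(sprintf("unknown class label '%s'", class))
  }
  results2 <- results2[match(results1$gene, results2$gene), , drop = FALSE]
  keep <- results1$significant & results2$significant
  rows <- data.frame(
    gene = results1$gene[keep],
    log2_1 = results1$log2_ratio[keep],
    log2_2 = results2$log2_ratio[keep],
    stringsAsFactors = FALSE
  )
  rows$in_class <- !is.na(class_labels[rows$gene]) &
    class_labels[rows$gene] == class
  sel <- rows$in_class
  list(rows = rows,
       class_mean_1 = if (any(sel)) mean(rows$log2_1[sel]) else NA_real_,
       class_mean_2 = if (any(sel)) mean(rows$log2_2[sel]) else NA_real_,
       n_class = sum(sel))
}
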