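# Locus-level binding calls from tiling-array probe sets, and the
# cluster / coincidence / subtelomere statistics built on them.

# Cache of exact null tail probabilities for the signed-rank statistic,
# keyed by the rank multiset. With tie-free probe values at a fixed probe
# count the multiset is always 1..n, so each track effectively computes the
# null once.
.signed_rank_cache <- new.env(parent = emptyenv())

# Exact null of W = sum of ranks carrying a + sign, over all 2^n equiprobable
# sign assignments. Returns sorted unique W values with upper- and lower-tail
# probabilities P(W >= w), P(W <= w).
signed_rank_null <- function(ranks) {
  key <- paste(ranks, collapse = ",")
  hit <- .signed_rank_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(ranks)
  if (n > 14L) stop("exact enumeration limited to 14 nonzero values")
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% ranks)
  ws <- sort(unique(w))
  m <- length(w)
  cnt <- tabulate(match(w, ws), nbins = length(ws))
  out <- list(
    w = ws,
    p_ge = rev(cumsum(rev(cnt))) / m,
    p_le = cumsum(cnt) / m
  )
  .signed_rank_cache[[key]] <- out
  out
}

# One-sided exact signed-rank p-values for values vs 0. Zeros are dropped
# (standard signed-rank convention); ties among |values| get midranks, and
# the null still enumerates sign patterns of the observed rank multiset.
signed_rank_p <- function(values, max_exact = 14L) {
  x <- values[values != 0]
  n <- length(x)
  if (n == 0L) return(list(p_up = 1, p_down = 1, n_used = 0L))
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= max_exact) {
    null <- signed_rank_null(r)
    i <- match(w, null$w)
    list(p_up = null$p_ge[i], p_down = null$p_le[i], n_used = n)
  } else {
    # Normal approximation with tie correction and continuity correction
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    list(
      p_up = stats::pnorm((w - 0.5 - mu) / sigma, lower.tail = FALSE),
      p_down = stats::pnorm((w + 0.5 - mu) / sigma),
      n_used = n
    )
  }
}

#' Call binding at one array locus from its probe log2 ratios
#'
#' Each locus on the tiling array carries a set of per-probe log2 IP/input
#' ratios (nominally eleven 25-nt probes per 300-bp locus). Binding is called
#' by an exact one-sided Wilcoxon signed-rank test of those ratios against
#' zero: the null distribution is obtained by full enumeration of all 2^n
#' sign assignments of the nonzero values (midranks for tied magnitudes), so
#' p-values are exact for the nominal probe count. A locus is
#' \code{positive} when the upper-tail p-value is below \code{alpha}
#' (default 0.025), \code{negative} when the lower-tail p-value is, and
#' \code{not_significant} otherwise. The locus signal is summarised as the
#' median probe log2 ratio.
#'
#' @param values numeric vector of per-probe log2 ratios (>= 5 values).
#' @param alpha per-locus significance threshold (default 0.025).
#' @return list with \code{log2_ratio}, \code{p_up}, \code{p_down},
#'   \code{status}.
#' @examples
#' call_locus(rep(1, 11))$p_up # 1/2048
#' @export
call_locus <- function(values, alpha = 0.025) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) < 5L) stop("at least 5 probe values are required")
  stopifnot_prob(alpha, "alpha")
  p <- signed_rank_p(values)
  status <- if (p$n_used == 0L) {
    "not_significant"
  } else if (p$p_up < alpha) {
    "positive"
  } else if (p$p_down < alpha) {
    "negative"
  } else {
    "not_significant"
  }
  list(log2_ratio = stats::median(values), p_up = p$p_up, p_down = p$p_down,
       status = status)
}

#' Call binding along a whole probe table
#'
#' Applies [call_locus()] to every locus of a long-format probe table and
#' returns a sorted binding track.
#'
#' @param probes data.frame with columns \code{chrom}, \code{locus_start},
#'   \code{locus_end}, \code{locus_id}, \code{log2_ratio} (one row per
#'   probe). Extra columns are ignored.
#' @param alpha per-locus threshold passed to [call_locus()].
#' @param factor_label,condition_label free-text labels attached to the
#'   track (e.g. \code{"Arp6"}, \code{"wild-type"}).
#' @return data.frame of class \code{"binding_track"}, one row per locus,
#'   sorted by chromosome and start, with columns \code{chrom}, \code{start},
#'   \code{end}, \code{locus_id}, \code{resolution}, \code{log2_ratio},
#'   \code{p_up}, \code{p_down}, \code{status}.
#' @export
call_track <- function(probes, alpha = 0.025, factor_label = NA_character_,
                       condition_label = NA_character_) {
  need <- c("chrom", "locus_start", "locus_end", "locus_id", "log2_ratio")
  stopifnot(is.data.frame(probes), all(need %in% names(probes)))
  if (nrow(probes) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      locus_id = character(), resolution = integer(),
                      log2_ratio = numeric(), p_up = numeric(),
                      p_down = numeric(), status = character(),
                      stringsAsFactors = FALSE)
    return(as_binding_track(out, factor_label, condition_label))
  }
  key <- interaction(probes$chrom, probes$locus_start, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(probes)), key)
  first <- vapply(idx, function(i) i[1L], 0L)
  ids <- as.character(probes$locus_id[first])
  if (anyDuplicated(ids)) stop("duplicate locus ids in probe table")
  calls <- lapply(idx, function(i) call_locus(probes$log2_ratio[i], alpha = alpha))
  out <- data.frame(
    chrom = as.character(probes$chrom[first]),
    start = as.integer(probes$locus_start[first]),
    end = as.integer(probes$locus_end[first]),
    locus_id = ids,
    resolution = as.integer(probes$locus_end[first] - probes$locus_start[first]),
    log2_ratio = vapply(calls, `[[`, 0, "log2_ratio"),
    p_up = vapply(calls, `[[`, 0, "p_up"),
    p_down = vapply(calls, `[[`, 0, "p_down"),
    status = vapply(calls, `[[`, "", "status"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  as_binding_track(out, factor_label, condition_label)
}

as_binding_track <- function(df, factor_label = NA_character_,
                             condition_label = NA_character_) {
  attr(df, "factor_label") <- factor_label
  attr(df, "condition_label") <- condition_label
  class(df) <- unique(c("binding_track", class(df)))
  df
}

track_positive <- function(track) track$status == "positive"

#' Maximal runs of contiguous positive loci
#'
#' A cluster is a maximal run of at least \code{min_run} consecutive
#' positive loci on the array grid ("consecutive" means adjacent intervals:
#' each locus starts where the previous one ends, on the same chromosome).
#' The cluster's peak is the maximum locus log2 ratio within the run.
#'
#' @param track a \code{"binding_track"} from [call_track()].
#' @param min_run minimum run length (default 2).
#' @return data.frame with one row per cluster: \code{chrom}, \code{start},
#'   \code{end}, \code{n_loci}, \code{peak_log2}.
#' @export
find_clusters <- function(track, min_run = 2L) {
  stopifnot(inherits(track, "binding_track"), min_run >= 1)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_loci = integer(), peak_log2 = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(track) == 0L) return(empty)
  pos <- track_positive(track)
  # break runs at chromosome changes and at grid gaps
  adjacent <- c(FALSE, track$chrom[-1] == track$chrom[-nrow(track)] &
                  track$start[-1] == track$end[-nrow(track)])
  run_id <- cumsum(!(pos & adjacent & c(FALSE, pos[-length(pos)])))
  keep <- which(pos)
  if (length(keep) == 0L) return(empty)
  grp <- split(keep, run_id[keep])
  rows <- lapply(grp, function(i) {
    if (length(i) < min_run) return(NULL)
    data.frame(chrom = track$chrom[i[1L]],
               start = track$start[i[1L]],
               end = track$end[i[length(i)]],
               n_loci = length(i),
               peak_log2 = max(track$log2_ratio[i]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Highest-scoring binding clusters
#'
#' Ranks clusters (runs of at least \code{min_run} contiguous positive loci)
#' by their peak locus log2 ratio, keeps those with peak above
#' \code{min_log2}, and returns the top \code{k}.
#'
#' @inheritParams find_clusters
#' @param k number of peaks to keep (default 10).
#' @param min_log2 minimum peak signal log ratio (default 0.8, exclusive).
#' @return data.frame as [find_clusters()], ranked by \code{peak_log2}
#'   descending.
#' @export
top_peaks <- function(track, k = 10L, min_log2 = 0.8, min_run = 2L) {
  cl <- find_clusters(track, min_run = min_run)
  cl <- cl[cl$peak_log2 > min_log2, , drop = FALSE]
  cl <- cl[order(-cl$peak_log2, cl$chrom, cl$start), , drop = FALSE]
  out <- utils::head(cl, k)
  rownames(out) <- NULL
  out
}

# Map a track to a coarser grid (e.g. 100-bp loci into their containing
# 300-bp bin): a bin is positive if any member locus is positive; its log2
# is the member maximum.
map_to_grid <- function(track, size) {
  bin <- floor(track$start / size)
  key <- paste(track$chrom, bin)
  idx <- split(seq_len(nrow(track)), key)
  rows <- lapply(idx, function(i) {
    data.frame(
      chrom = track$chrom[i[1L]],
      start = as.integer(bin[i[1L]] * size),
      end = as.integer((bin[i[1L]] + 1) * size),
      locus_id = paste0(track$chrom[i[1L]], ":", bin[i[1L]] * size),
      resolution = as.integer(size),
      log2_ratio = max(track$log2_ratio[i]),
      p_up = min(track$p_up[i]),
      p_down = min(track$p_down[i]),
      status = if (any(track$status[i] == "positive")) "positive"
               else if (all(track$status[i] == "negative")) "negative"
               else "not_significant",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  as_binding_track(out, attr(track, "factor_label"),
                   attr(track, "condition_label"))
}

#' Coincidence of two binding tracks
#'
#' For each chromosome and pooled over all, counts the detectable loci (all
#' loci on the shared grid), the loci positive for factor A, and the
#' A-positive loci that are also positive for factor B. Percentages are
#' integer-rounded (half-up): A-positive as a percentage of detectable loci,
#' and A-and-B as a percentage of A-positive. Tracks on different grid
#' resolutions are first mapped to the coarser grid by containment.
#'
#' @param a,b \code{"binding_track"} objects on the same (or nestable) grid.
#' @return data.frame of class \code{"coincidence_table"}: one row per
#'   chromosome plus a \code{Total} row, with columns \code{chrom},
#'   \code{detectable}, \code{a_positive}, \code{a_positive_pct},
#'   \code{a_and_b}, \code{a_and_b_pct}.
#' @export
coincidence_table <- function(a, b) {
  stopifnot(inherits(a, "binding_track"), inherits(b, "binding_track"))
  ra <- unique(a$resolution); rb <- unique(b$resolution)
  size <- max(a$resolution, b$resolution)
  if (length(ra) > 1L || length(rb) > 1L || !identical(ra, rb)) {
    a <- map_to_grid(a, size)
    b <- map_to_grid(b, size)
  }
  key_a <- paste(a$chrom, a$start)
  key_b <- paste(b$chrom, b$start)
  if (!setequal(key_a, key_b)) stop("tracks are not on a shared locus grid")
  b <- b[match(key_a, key_b), , drop = FALSE]
  pos_a <- track_positive(a)
  pos_b <- track_positive(b)
  per_chrom <- function(sel, label) {
    det <- sum(sel)
    na <- sum(pos_a[sel])
    nab <- sum(pos_a[sel] & pos_b[sel])
    data.frame(chrom = label, detectable = det,
               a_positive = na, a_positive_pct = pct_int(na, det),
               a_and_b = nab, a_and_b_pct = pct_int(nab, na),
               stringsAsFactors = FALSE)
  }
  chroms <- unique(a$chrom)
  rows <- lapply(chroms, function(ch) per_chrom(a$chrom == ch, ch))
  rows <- c(rows, list(per_chrom(rep(TRUE, nrow(a)), "Total")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coincidence_table", "data.frame")
  out
}

#' @export
print.coincidence_table <- function(x, ...) {
  cat("Factor coincidence by chromosome (counts, % in parentheses)\n")
  df <- data.frame(
    chrom = x$chrom,
    detectable = x$detectable,
    a_positive = sprintf("%d (%d%%)", x$a_positive, x$a_positive_pct),
    a_and_b = ifelse(x$a_positive > 0,
                     sprintf("%d (%d%%)", x$a_and_b, x$a_and_b_pct),
                     sprintf("%d (-)", x$a_and_b)),
    stringsAsFactors = FALSE
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Paired log2 signals of two tracks with rank correlation
#'
#' Restricts to a subset of loci (by default the A-positive loci), pairs the
#' two tracks' log2 ratios there, and reports the Spearman rank correlation.
#' Used to compare one factor's binding strength against another's at the
#' first factor's binding sites.
#'
#' @param a,b \code{"binding_track"} objects on the same grid.
#' @param subset which loci to keep: \code{"a_positive"} (default),
#'   \code{"b_positive"}, or \code{"all"}.
#' @return list with \code{pairs} (data.frame \code{chrom}, \code{start},
#'   \code{locus_id}, \code{log2_a}, \code{log2_b}) and \code{spearman_rho}.
#' @export
correlate_tracks <- function(a, b, subset = c("a_positive", "b_positive", "all")) {
  subset <- match.arg(subset)
  stopifnot(inherits(a, "binding_track"), inherits(b, "binding_track"))
  key_a <- paste(a$chrom, a$start)
  key_b <- paste(b$chrom, b$start)
  if (!setequal(key_a, key_b)) stop("tracks are not on a shared locus grid")
  b <- b[match(key_a, key_b), , drop = FALSE]
  keep <- switch(subset,
                 a_positive = track_positive(a),
                 b_positive = track_positive(b),
                 all = rep(TRUE, nrow(a)))
  if (!any(keep)) stop("selected subset is empty")
  pairs <- data.frame(chrom = a$chrom[keep], start = a$start[keep],
                      locus_id = a$locus_id[keep],
                      log2_a = a$log2_ratio[keep], log2_b = b$log2_ratio[keep],
                      stringsAsFactors = FALSE)
  rho <- stats::cor(pairs$log2_a, pairs$log2_b, method = "spearman")
  list(pairs = pairs, spearman_rho = rho)
}

#' Positive loci in terminal subtelomere zones
#'
#' Counts the positive loci whose interval intersects the terminal
#' \code{zone_bp} (default 10 kb) at each chromosome end -- the nonrepetitive
#' subtelomeric windows where persistent binding is tabulated.
#'
#' @param track a \code{"binding_track"}.
#' @param chrom_sizes data.frame with columns \code{chrom} and \code{length}
#'   (bp).
#' @param zone_bp width of the terminal zone at each end (default 10000).
#' @return data.frame with one row per chromosome end present in the track:
#'   \code{chrom}, \code{end_side} ("left"/"right"), \code{zone_start},
#'   \code{zone_end}, \code{positive_loci}.
#' @export
subtelomere_presence <- function(track, chrom_sizes, zone_bp = 10000L) {
  stopifnot(inherits(track, "binding_track"), is.data.frame(chrom_sizes),
            all(c("chrom", "length") %in% names(chrom_sizes)), zone_bp > 0)
  chroms <- unique(track$chrom)
  missing <- setdiff(chroms, chrom_sizes$chrom)
  if (length(missing) > 0L) {
    stop(sprintf("chromosome(s) absent from sizes table: %s",
                 paste(missing, collapse = ", ")))
  }
  pos <- track[track_positive(track), , drop = FALSE]
  rows <- lapply(chroms, function(ch) {
    len <- chrom_sizes$length[match(ch, chrom_sizes$chrom)]
    zones <- data.frame(
      end_side = c("left", "right"),
      zone_start = c(0L, max(0L, len - zone_bp)),
      zone_end = c(min(zone_bp, len), len)
    )
    p <- pos[pos$chrom == ch, , drop = FALSE]
    zones$positive_loci <- vapply(seq_len(2L), function(i) {
      sum(p$start < zones$zone_end[i] & p$end > zones$zone_start[i])
    }, 0L)
    cbind(chrom = ch, zones, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic context of each called locus
#'
#' Labels every locus of a track by its position relative to annotated
#' genes: \code{divergent_promoter} when the locus overlaps the intergenic
#' region between the 5' starts of two divergently transcribed (head-to-head)
#' genes; \code{single_promoter} when it overlaps the region up to
#' \code{flank_bp} (default 400 bp) upstream of a single gene start;
#' \code{ORF_internal} when it lies inside a gene body; otherwise
#' \code{intergenic_other}. Precedence follows that order.
#'
#' @param track a \code{"binding_track"}.
#' @param genes data.frame of gene records as returned by [read_gff3()]:
#'   columns \code{gene_id}, \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand} in \code{+}/\code{-}.
#' @param flank_bp upstream flank defining a promoter (default 400).
#' @return the track with an added \code{context} column.
#' @export
classify_context <- function(track, genes, flank_bp = 400L) {
  stopifnot(inherits(track, "binding_track"), is.data.frame(genes),
            all(c("chrom", "start", "end", "strand") %in% names(genes)))
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("strandless gene records are not allowed")
  }
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2
  # promoter region of a gene: flank_bp upstream of its 5' start
  prom_start <- ifelse(genes$strand == "+",
                       pmax(0L, genes$start - flank_bp), genes$end)
  prom_end <- ifelse(genes$strand == "+",
                     genes$start, genes$end + flank_bp)
  # divergent intergenic regions: minus-strand gene immediately left of a
  # plus-strand gene, region between their 5' starts
  div <- do.call(rbind, lapply(unique(genes$chrom), function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    left <- g[-nrow(g), ]; right <- g[-1L, ]
    sel <- left$strand == "-" & right$strand == "+" & left$end <= right$start
    if (!any(sel)) return(NULL)
    data.frame(chrom = ch, start = left$end[sel], end = right$start[sel],
               stringsAsFactors = FALSE)
  }))
  ctx <- vapply(seq_len(nrow(track)), function(i) {
    ch <- track$chrom[i]; s <- track$start[i]; e <- track$end[i]
    if (!is.null(div)) {
      d <- div[div$chrom == ch, , drop = FALSE]
      if (nrow(d) > 0L && any(overlaps(s, e, d$start, d$end))) {
        return("divergent_promoter")
      }
    }
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) > 0L) {
      if (any(overlaps(s, e, prom_start[genes$chrom == ch],
                       prom_end[genes$chrom == ch]))) {
        return("single_promoter")
      }
      if (any(s >= g$start & e <= g$end)) return("ORF_internal")
    }
    "intergenic_other"
  }, "")
  track$context <- ctx
  track
}
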