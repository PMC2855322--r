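# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Integer rounding with ties going up (half-up), as used for all printed
#' percentages. Base `round()` rounds half to even, which would turn
#' e.g. 0.5 into 0.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Integer percentage num/den * 100, half-up; NA for den == 0.
pct_int <- function(num, den) {
  ifelse(den == 0, NA_integer_, round_half_up(100 * num / den))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a deparsed R object, as 8 hex digits. Used only to
# stamp output tables so a result file can be matched to its configuration.
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h in doubles to stay
    # exact above 2^31
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # kept exact in doubles: h * 2^24 mod 2^32 == (h mod 2^8) * 2^24
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# Write a data.frame as TSV with optional '#' comment header lines.
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
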