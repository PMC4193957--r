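# Internal helpers shared across modules. Coordinate convention: 0-based
# positions, half-open [start, end) intervals; R vectors are 1-based so a
# genomic position p maps to index p + 1.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All user-facing randomised operations route
# through this so a fixed seed gives bit-identical results.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Slice v[from:to] (1-based inclusive indices) padding out-of-range entries
# with zero. Used so that anchor windows may extend past the per-chromosome
# count vectors without special-casing boundaries.
.slice0 <- function(v, from, to) {
  n <- length(v)
  res <- numeric(to - from + 1L)
  lo <- max(from, 1L)
  hi <- min(to, n)
  if (lo <= hi) res[(lo - from + 1L):(hi - from + 1L)] <- v[lo:hi]
  res
}

# Tabulate 0-based positions into a count vector of length len.
.pos_tabulate <- function(pos, len) {
  pos <- pos[pos >= 0L & pos < len]
  tabulate(pos + 1L, nbins = len)
}

# Per-base coverage of 0-based half-open intervals, clipped to [0, len).
.coverage_vector <- function(start, end, len) {
  start <- pmax(start, 0L)
  end <- pmin(end, len)
  keep <- start < end
  start <- start[keep]
  end <- end[keep]
  if (!length(start)) return(numeric(len))
  d <- numeric(len + 1L)
  ds <- tabulate(start + 1L, nbins = len + 1L)
  de <- tabulate(end + 1L, nbins = len + 1L)
  cumsum(ds - de)[seq_len(len)]
}

# Extract a (chrom, pos) site data.frame from any object carrying those
# columns (snp tables, mutation lists, plain data.frames).
.as_sites <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "pos") %in% names(x)))
    return(data.frame(chrom = as.character(x$chrom), pos = as.integer(x$pos),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret object of class '", class(x)[1L], "' as genomic sites")
}

# Chromosome lengths: explicit > derived. When derived, the right boundary
# is taken as the furthest coordinate any computation will touch, so no
# anchor is dropped for exceeding an unknown chromosome end.
.resolve_lengths <- function(chrom_lengths, tags = NULL, anchors = NULL, W = 0L) {
  if (!is.null(chrom_lengths)) {
    stopifnot(!is.null(names(chrom_lengths)))
    return(chrom_lengths)
  }
  mx <- list()
  bump <- function(chr, val) {
    for (i in seq_along(chr)) {
      c0 <- chr[i]
      mx[[c0]] <<- max(mx[[c0]] %||% 0, val[i])
    }
  }
  if (!is.null(tags)) {
    iv <- if (inherits(tags, "TagSet")) tags$intervals else tags
    if (nrow(iv)) {
      agg <- tapply(iv$end, iv$chrom, max)
      bump(names(agg), as.numeric(agg))
    }
  }
  if (!is.null(anchors) && nrow(anchors)) {
    agg <- tapply(anchors$pos + W + 1, anchors$chrom, max)
    bump(names(agg), as.numeric(agg))
  }
  unlist(mx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_cols <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# Running mean with shrinking windows at the edges (no NA padding).
.running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- k %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
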