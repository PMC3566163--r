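# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# GRanges from 0-based half-open intervals.
.gr <- function(chrom, start, end, strand = "*") {
  if (length(start) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1L, end = end),
                         strand = strand)
}

# 0-based half-open data.frame from GRanges.
.gr_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Coerce an interval input (data.frame chrom/start/end, 0-based half-open)
# and validate basic sanity.
.as_intervals <- function(x, what = "intervals") {
  if (inherits(x, "GRanges")) x <- .gr_df(x)
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    .stopf("%s must be a data.frame with columns chrom, start, end", what)
  if (any(x$end < x$start)) .stopf("%s contain end < start", what)
  x
}
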