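# Intergenic-background null: length-matched random regions, binned FDR /
# approx-true / FNR curves, threshold at the FDR/FNR intersection, and the
# true-positive fraction of a sub-threshold window.

#' Sample length-matched background regions
#'
#' Places one region per requested length uniformly at random within the
#' intergenic space, rejecting overlaps with already-placed regions. Lengths
#' are placed in descending order (large regions are hardest to fit).
#' Deterministic for a fixed seed.
#'
#' @param space Intergenic intervals (data.frame `chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [intergenic_space()].
#' @param lengths Numeric multiset of region lengths in bp — typically the
#'   union-exon lengths of the annotated genes, so that number and length
#'   distribution of the null match the gene model.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per region before giving up.
#' @return data.frame (`chrom`, `start`, `end`) of class
#'   `background_regions`, with attribute `seed`. Region lengths reproduce
#'   `lengths` as a multiset.
#' @export
sample_background_regions <- function(space, lengths, seed, max_tries = 1000) {
  space <- .as_intervals(space, "space")
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
    attr(out, "seed") <- seed
    class(out) <- c("background_regions", "data.frame")
    return(out)
  }
  if (any(lengths <= 0)) .stopf("region lengths must be > 0")
  ord <- order(lengths, decreasing = TRUE)
  with_seed(seed, {
    placed_chrom <- character(0); placed_s <- numeric(0); placed_e <- numeric(0)
    res_s <- numeric(length(lengths)); res_e <- numeric(length(lengths))
    res_c <- character(length(lengths))
    for (k in ord) {
      len <- lengths[k]
      slots <- pmax(0, space$end - space$start - len + 1)
      if (sum(slots) == 0)
        .stopf("no intergenic interval can hold a region of length %d", len)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        iv <- sample.int(nrow(space), 1, prob = slots)
        s <- space$start[iv] + floor(stats::runif(1) * slots[iv])
        e <- s + len
        same <- placed_chrom == space$chrom[iv]
        if (!any(same & placed_s < e & placed_e > s)) { ok <- TRUE; break }
      }
      if (!ok)
        .stopf("could not place region of length %d after %d tries", len,
               max_tries)
      placed_chrom <- c(placed_chrom, space$chrom[iv])
      placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
      res_c[k] <- space$chrom[iv]; res_s[k] <- s; res_e[k] <- e
    }
    out <- data.frame(chrom = res_c, start = res_s, end = res_e,
                      stringsAsFactors = FALSE)
    attr(out, "seed") <- seed
    class(out) <- c("background_regions", "data.frame")
    out
  })
}

#' Default FPKM bin edges
#'
#' Log10-spaced detection-threshold grid, 5 bins per decade from 1e-3 to 1e3
#' FPKM.
#'
#' @param from,to Grid limits (FPKM).
#' @param per_decade Bins per decade.
#' @return Increasing numeric vector of bin edges.
#' @export
default_bin_edges <- function(from = 1e-3, to = 1e3, per_decade = 5) {
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

#' Bin gene and background expression for threshold calibration
#'
#' Counts genes (`genes`) and intergenic background regions (`intergenic`)
#' per FPKM bin `[edge_b, edge_{b+1})`, the per-bin false discovery rate
#' `fdr = min(1, intergenic / genes)` (0 when no genes are detected in the
#' bin) and the estimated true count `approx_true = genes * (1 - fdr)`.
#' Values outside the grid are not binned.
#'
#' @param gene_fpkm `expression_vector` (or bare numeric FPKMs) for annotated
#'   genes.
#' @param intergenic_fpkm Same for background regions.
#' @param bin_edges Strictly increasing edges; default [default_bin_edges()].
#' @return data.frame of class `threshold_curve` with one row per bin:
#'   `edge` (lower), `upper`, `genes`, `intergenic`, `fdr`, `approx_true`.
#' @export
bin_expression <- function(gene_fpkm, intergenic_fpkm,
                           bin_edges = default_bin_edges()) {
  g <- if (is.data.frame(gene_fpkm)) gene_fpkm$fpkm else as.numeric(gene_fpkm)
  i <- if (is.data.frame(intergenic_fpkm)) intergenic_fpkm$fpkm else
    as.numeric(intergenic_fpkm)
  if (any(diff(bin_edges) <= 0)) .stopf("bin_edges must be strictly increasing")
  B <- length(bin_edges) - 1
  bin_of <- function(x) {
    b <- findInterval(x, bin_edges, left.open = FALSE)
    b[b < 1 | x >= bin_edges[B + 1]] <- NA
    b
  }
  G <- tabulate(bin_of(g), nbins = B)
  I <- tabulate(bin_of(i), nbins = B)
  fdr <- ifelse(G == 0, 0, pmin(1, I / G))
  curve <- data.frame(edge = bin_edges[-(B + 1)], upper = bin_edges[-1],
                      genes = G, intergenic = I, fdr = fdr,
                      approx_true = G * (1 - fdr))
  class(curve) <- c("threshold_curve", "data.frame")
  curve
}

#' Fill cumulative FDR and FNR on a threshold curve
#'
#' At each candidate threshold (bin lower edge) the cumulative false
#' discovery rate is the background count at or above the threshold over the
#' gene count at or above it (capped at 1), and the false negative rate is
#' the estimated-true mass below the threshold over the total estimated-true
#' mass.
#'
#' @param curve A `threshold_curve` from [bin_expression()].
#' @return The curve with columns `FDR`, `FNR`, `cum_genes`, `cum_intergenic`
#'   added.
#' @export
cumulative_fdr_fnr <- function(curve) {
  stopifnot(inherits(curve, "threshold_curve"))
  cg <- rev(cumsum(rev(curve$genes)))
  ci <- rev(cumsum(rev(curve$intergenic)))
  FDR <- ifelse(cg == 0, 0, pmin(1, ci / cg))
  tot <- sum(curve$approx_true)
  below <- cumsum(c(0, curve$approx_true[-nrow(curve)]))
  FNR <- if (tot == 0) rep(0, nrow(curve)) else below / tot
  curve$cum_genes <- cg
  curve$cum_intergenic <- ci
  curve$FDR <- FDR
  curve$FNR <- FNR
  curve
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("threshold_curve: %d bins over [%g, %g] FPKM%s\n",
              nrow(x), x$edge[1], x$upper[nrow(x)],
              if ("FDR" %in% names(x)) " (cumulative fields filled)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Detection threshold at the FDR/FNR intersection
#'
#' The smallest bin edge at which the cumulative FDR no longer exceeds the
#' FNR. The analysis convention is to set the working threshold slightly
#' above this crossing.
#'
#' @param curve A `threshold_curve` with cumulative fields
#'   (see [cumulative_fdr_fnr()]).
#' @return List `theta_star` (FPKM edge), `fdr_at`, `fnr_at`.
#' @export
find_threshold <- function(curve) {
  stopifnot(inherits(curve, "threshold_curve"))
  if (!all(c("FDR", "FNR") %in% names(curve)))
    curve <- cumulative_fdr_fnr(curve)
  hit <- which(curve$FDR <= curve$FNR)
  if (length(hit) == 0)
    .stopf("FDR exceeds FNR over the whole grid: no crossing")
  b <- hit[1]
  list(theta_star = curve$edge[b], fdr_at = curve$FDR[b], fnr_at = curve$FNR[b])
}

#' True-positive fraction in a sub-threshold window
#'
#' Among targets with FPKM inside `[low, high]`, the estimated fraction that
#' is genuinely expressed: one minus the ratio of background-region hits to
#' gene hits in the window, floored at zero. This is the statistic behind
#' calling the 0.01-0.1 FPKM band "potentially expressed".
#'
#' @param gene_fpkm `expression_vector` or numeric FPKMs for genes.
#' @param intergenic_fpkm Same for background regions.
#' @param window Numeric `c(low, high)`, closed interval.
#' @return Fraction in `[0, 1]`.
#' @export
window_true_positive_fraction <- function(gene_fpkm, intergenic_fpkm,
                                          window = c(0.01, 0.1)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  g <- if (is.data.frame(gene_fpkm)) gene_fpkm$fpkm else as.numeric(gene_fpkm)
  i <- if (is.data.frame(intergenic_fpkm)) intergenic_fpkm$fpkm else
    as.numeric(intergenic_fpkm)
  ng <- sum(g >= window[1] & g <= window[2])
  ni <- sum(i >= window[1] & i <= window[2])
  if (ng == 0) .stopf("no genes in window [%g, %g]", window[1], window[2])
  max(0, 1 - ni / ng)
}

#' Write a threshold curve as TSV
#'
#' @param curve A `threshold_curve`.
#' @param path Output path.
#' @export
write_threshold_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
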