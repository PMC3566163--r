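# Cross-tissue expression profiling: detection calls, expressed / exclusive
# counts, cumulative expression, ranking, reproducibility, pseudogene
# subfamily composition, neighbourhood dependence and panel subsetting.

#' Classify detection calls for every matrix cell
#'
#' `expressed` above `t_high` (strictly), `potential` within the closed band
#' `[t_low, t_high]`, `not_detected` below `t_low`. The defaults are the
#' calibrated 0.1 FPKM detection threshold and the 0.01 floor of the
#' "potentially expressed" band; a tie at `t_high` is a potential call.
#'
#' @param mat An `expression_matrix`.
#' @param t_low,t_high Band limits in FPKM (`t_low < t_high`).
#' @return data.frame (`target_id`, `tissue`, `fpkm`, `call`).
#' @export
classify_calls <- function(mat, t_low = 0.01, t_high = 0.1) {
  stopifnot(inherits(mat, "expression_matrix"), t_low < t_high)
  f <- mat$fpkm
  out <- data.frame(target_id = rep(rownames(f), ncol(f)),
                    tissue = rep(colnames(f), each = nrow(f)),
                    fpkm = as.vector(f), stringsAsFactors = FALSE)
  out$call <- ifelse(out$fpkm > t_high, "expressed",
                     ifelse(out$fpkm >= t_low, "potential", "not_detected"))
  out
}

#' Cross-tissue expression profile
#'
#' Per tissue: counts of expressed targets split by biotype, the exclusively
#' expressed targets (above `t_high` in exactly that tissue and not above it
#' anywhere else), and cumulative expression (sum of FPKM values above
#' `t_low`). Per target: FPKM summed over all tissues, ranked; targets whose
#' sum reaches `rank_cutoff` are flagged as the most highly ectopically
#' expressed set.
#'
#' @param mat An `expression_matrix`.
#' @param t_low,t_high Detection band limits (FPKM).
#' @param rank_cutoff Summed-FPKM cutoff for the top set (default 0.5).
#' @return Object of class `profile_report`: list with `counts` (data.frame
#'   tissue x biotype), `exclusive` (named list of target ids per tissue),
#'   `cumulative` (named numeric per tissue), `ranking` (data.frame
#'   `target_id`, `summed_fpkm`, `rank`, `top`), and the thresholds used.
#' @export
profile_expression <- function(mat, t_low = 0.01, t_high = 0.1,
                               rank_cutoff = 0.5) {
  stopifnot(inherits(mat, "expression_matrix"), nrow(mat$fpkm) > 0)
  f <- mat$fpkm
  bt <- mat$meta$biotype
  expressed <- f > t_high

  counts <- data.frame(tissue = colnames(f),
                       or_gene = colSums(expressed[bt == "or_gene", , drop = FALSE]),
                       or_pseudogene = colSums(expressed[bt == "or_pseudogene", , drop = FALSE]),
                       non_or = colSums(expressed[bt == "non_or", , drop = FALSE]),
                       row.names = NULL, stringsAsFactors = FALSE)
  counts$total <- counts$or_gene + counts$or_pseudogene + counts$non_or

  n_expr <- rowSums(expressed)
  exclusive <- lapply(colnames(f), function(ts)
    rownames(f)[expressed[, ts] & n_expr == 1])
  names(exclusive) <- colnames(f)

  cumulative <- apply(f, 2, function(col) sum(col[col > t_low]))

  summed <- rowSums(f)
  ord <- order(summed, decreasing = TRUE)
  ranking <- data.frame(target_id = rownames(f)[ord],
                        biotype = bt[ord],
                        summed_fpkm = summed[ord],
                        rank = seq_along(ord),
                        top = summed[ord] >= rank_cutoff,
                        row.names = NULL, stringsAsFactors = FALSE)

  structure(list(counts = counts, exclusive = exclusive,
                 cumulative = cumulative, ranking = ranking,
                 t_low = t_low, t_high = t_high, rank_cutoff = rank_cutoff),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("profile_report (expressed: FPKM > %g; potential band >= %g)\n",
              x$t_high, x$t_low))
  print(x$counts)
  n_top <- sum(x$ranking$top)
  cat(sprintf("%d target(s) with summed FPKM >= %g\n", n_top, x$rank_cutoff))
  invisible(x)
}

#' Replicate overlap of weak detections
#'
#' Takes the targets of one data set whose FPKM falls in a weak-expression
#' window and asks what fraction is also detected (at `detect_floor` or
#' above) in an independent data set of the same or another tissue. High
#' overlap between replicates of one tissue, against low overlap with an
#' unrelated tissue, argues that the weak window is dominated by true
#' signal rather than random background.
#'
#' @param vecA,vecB `expression_vector`s over a shared target universe.
#' @param window Closed FPKM window in `vecA` (default `c(0.01, 0.1)`).
#' @param detect_floor Detection level in `vecB` (default 0.01).
#' @return List (`n_window`, `n_detected_in_other`, `fraction`) of class
#'   `overlap_report`.
#' @export
replicate_overlap <- function(vecA, vecB, window = c(0.01, 0.1),
                              detect_floor = 0.01) {
  stopifnot(length(window) == 2, window[1] < window[2])
  fb <- stats::setNames(vecB$fpkm, vecB$target_id)
  inw <- vecA$target_id[vecA$fpkm >= window[1] & vecA$fpkm <= window[2]]
  if (length(inw) == 0)
    .stopf("no targets of vecA inside window [%g, %g]", window[1], window[2])
  miss <- setdiff(inw, names(fb))
  if (length(miss)) .stopf("targets absent from vecB: %s",
                           paste(utils::head(miss), collapse = ", "))
  det <- sum(fb[inw] >= detect_floor)
  structure(list(n_window = length(inw), n_detected_in_other = det,
                 fraction = det / length(inw)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: %d/%d window targets detected (%.1f%%)\n",
              x$n_detected_in_other, x$n_window, 100 * x$fraction))
  invisible(x)
}

#' Coefficient of determination between two expression vectors
#'
#' Squared Pearson correlation over targets passing `floor` in both vectors,
#' in log10 space by default (expression spans orders of magnitude).
#'
#' @param vecA,vecB `expression_vector`s over a shared target universe.
#' @param floor Minimum FPKM in both vectors for a target to enter.
#' @param log_space Correlate log10 FPKM (default) or raw values.
#' @return R^2 in `[0, 1]`.
#' @export
correlation_r2 <- function(vecA, vecB, floor = 0.01, log_space = TRUE) {
  fb <- stats::setNames(vecB$fpkm, vecB$target_id)
  shared <- intersect(vecA$target_id, names(fb))
  fa <- stats::setNames(vecA$fpkm, vecA$target_id)[shared]
  fb <- fb[shared]
  keep <- fa >= floor & fb >= floor
  if (sum(keep) < 3)
    .stopf("fewer than 3 targets pass the floor in both vectors")
  a <- fa[keep]; b <- fb[keep]
  if (log_space) { a <- log10(a); b <- log10(b) }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
  stats::cor(a, b)^2
}

#' Dependence of OR expression on the genomic neighbourhood
#'
#' Two fractions over OR loci (genes and pseudogenes): among ORs expressed in
#' at least one tissue, the share with at least one non-OR adjacent locus;
#' and among ORs whose adjacent loci are exclusively OR-type, the share that
#' is expressed in at least one tissue.
#'
#' @param model A `gene_model`.
#' @param calls Call data.frame from [classify_calls()] covering the model's
#'   OR loci.
#' @param max_distance Passed to [adjacent_loci()].
#' @return List with `frac_expressed_with_non_or_neighbor`,
#'   `frac_or_neighbor_only_expressed`, and the underlying counts.
#' @export
neighbor_dependence <- function(model, calls, max_distance = Inf) {
  stopifnot(inherits(model, "gene_model"))
  or_ids <- model$loci$locus_id[model$loci$biotype %in%
                                  c("or_gene", "or_pseudogene")]
  if (length(or_ids) == 0) .stopf("model has no OR loci")
  expr_ids <- unique(calls$target_id[calls$call == "expressed"])
  nb <- lapply(or_ids, function(id)
    adjacent_loci(model, id, max_distance = max_distance))
  has_non_or <- vapply(nb, function(p) {
    any(vapply(p, function(l) !is.null(l) && l$biotype == "non_or",
               logical(1)))
  }, logical(1))
  has_neighbor <- vapply(nb, function(p)
    any(!vapply(p, is.null, logical(1))), logical(1))
  or_only <- has_neighbor & !has_non_or
  expressed <- or_ids %in% expr_ids

  if (sum(expressed) == 0)
    .stopf("no OR locus is expressed: first fraction undefined")
  frac1 <- sum(expressed & has_non_or) / sum(expressed)
  frac2 <- NA_real_
  if (sum(or_only) == 0)
    .stopf("no OR locus has exclusively OR neighbours: second fraction undefined")
  frac2 <- sum(or_only & expressed) / sum(or_only)
  list(frac_expressed_with_non_or_neighbor = frac1,
       frac_or_neighbor_only_expressed = frac2,
       n_expressed = sum(expressed),
       n_expressed_with_non_or_neighbor = sum(expressed & has_non_or),
       n_or_neighbor_only = sum(or_only),
       n_or_neighbor_only_expressed = sum(or_only & expressed))
}

#' Subfamily composition of highly expressed OR targets
#'
#' Among targets whose summed FPKM exceeds `cutoff`, the fraction belonging
#' to each OR (family, subfamily) — e.g. the dominance of the 7E subfamily
#' among expressed OR pseudogenes. Symbols that do not parse as OR
#' nomenclature are skipped with a warning. Merged labels (`A/B`) are
#' attributed via their first member.
#'
#' @param summed_fpkm Named numeric vector (names are OR symbols) of
#'   per-target FPKM sums over tissues.
#' @param cutoff Summed-FPKM cutoff (default 0.5, strict).
#' @return Named numeric vector of fractions per subfamily key (e.g. `"7E"`),
#'   decreasing; empty when nothing passes the cutoff.
#' @export
subfamily_composition <- function(summed_fpkm, cutoff = 0.5) {
  keep <- summed_fpkm > cutoff
  syms <- sub("/.*$", "", names(summed_fpkm)[keep])
  if (length(syms) == 0) return(stats::setNames(numeric(0), character(0)))
  parsed <- vapply(syms, function(s) {
    p <- tryCatch(parse_or_symbol(s), error = function(e) NULL)
    if (is.null(p)) NA_character_ else paste0(p$family, p$subfamily)
  }, "")
  if (anyNA(parsed)) {
    .warnf("skipped %d unparsable symbol(s): %s", sum(is.na(parsed)),
           paste(utils::head(syms[is.na(parsed)]), collapse = ", "))
    parsed <- parsed[!is.na(parsed)]
  }
  if (length(parsed) == 0) return(stats::setNames(numeric(0), character(0)))
  tb <- sort(table(parsed), decreasing = TRUE)
  stats::setNames(as.numeric(tb) / length(parsed), names(tb))
}

#' Subset an expression matrix to a gene panel
#'
#' Row-subset preserving tissue order; genes absent from the matrix are
#' reported with a warning. Backs housekeeping / signalling / chemoreceptor
#' panel tables.
#'
#' @param mat An `expression_matrix`.
#' @param genes Character vector of target ids.
#' @return An `expression_matrix` over the present genes.
#' @export
subset_panel <- function(mat, genes) {
  stopifnot(inherits(mat, "expression_matrix"), length(genes) > 0)
  present <- genes[genes %in% rownames(mat$fpkm)]
  miss <- setdiff(genes, present)
  if (length(miss))
    .warnf("panel gene(s) absent from matrix: %s", paste(miss, collapse = ", "))
  expression_matrix(mat$fpkm[present, , drop = FALSE],
                    counts = if (!is.null(mat$counts))
                      mat$counts[present, , drop = FALSE] else NULL,
                    biotype = mat$meta$biotype[match(present,
                                                     mat$meta$target_id)])
}
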