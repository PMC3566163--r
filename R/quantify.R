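# Fragment-to-locus assignment and FPKM; multi-tissue matrices; merging of
# near-identical OR groups.

#' Assign fragments to loci
#'
#' A fragment counts toward a locus when at least one aligned base of any of
#' its blocks overlaps the locus's exon union. A fragment may count toward
#' several overlapping loci, but at most once per locus. Fragments on
#' chromosomes absent from the model are skipped with a warning.
#'
#' @param aligns An `alignment_set`.
#' @param model A `gene_model`.
#' @return Named integer vector of fragment counts over all loci in the model.
#' @export
assign_fragments <- function(aligns, model) {
  stopifnot(inherits(aligns, "alignment_set"), inherits(model, "gene_model"))
  ids <- model$loci$locus_id
  counts <- stats::setNames(integer(length(ids)), ids)
  b <- aligns$blocks
  if (nrow(b) == 0 || length(ids) == 0) return(counts)
  unknown <- setdiff(unique(b$chrom), model$genome$chrom)
  if (length(unknown)) {
    .warnf("fragments on chromosome(s) absent from model skipped: %s",
           paste(unknown, collapse = ", "))
    b <- b[!b$chrom %in% unknown, ]
    if (nrow(b) == 0) return(counts)
  }
  bg <- .gr(b$chrom, b$start, b$end)
  eg <- .gr(model$exons$chrom, model$exons$start, model$exons$end)
  ov <- GenomicRanges::findOverlaps(bg, eg, ignore.strand = TRUE)
  if (length(ov) == 0) return(counts)
  frag <- b$fragment_id[S4Vectors::queryHits(ov)]
  loc <- model$exons$locus_id[S4Vectors::subjectHits(ov)]
  pair <- unique(paste(frag, loc, sep = "\r"))
  loc_hit <- sub("^.*\r", "", pair)
  tb <- table(loc_hit)
  counts[names(tb)] <- as.integer(tb)
  counts
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `count * 1e9 / (length * total_mapped)`. Vectorised.
#'
#' @param count Fragment count(s), >= 0.
#' @param length Union-exon (or region) length in bp, > 0.
#' @param total_mapped Total mapped fragments in the library, > 0.
#' @return Non-negative numeric.
#' @export
compute_fpkm <- function(count, length, total_mapped) {
  if (any(length <= 0)) .stopf("length must be > 0")
  if (any(total_mapped <= 0)) .stopf("total_mapped must be > 0")
  if (any(count < 0)) .stopf("count must be >= 0")
  count * 1e9 / (length * total_mapped)
}

#' Quantify all loci of a gene model in one tissue
#'
#' @param aligns An `alignment_set`.
#' @param model A `gene_model`.
#' @return An `expression_vector`: data.frame (`target_id`, `count`, `length`,
#'   `fpkm`) with attributes `tissue` and `total_mapped`.
#' @export
quantify_loci <- function(aligns, model) {
  counts <- assign_fragments(aligns, model)
  lens <- union_exon_length(model)
  expression_vector(data.frame(target_id = names(counts),
                               count = as.numeric(counts),
                               length = as.numeric(lens[names(counts)]),
                               stringsAsFactors = FALSE),
                    tissue = aligns$tissue,
                    total_mapped = aligns$total_mapped)
}

#' Quantify arbitrary regions
#'
#' Each region is treated as a single-exon target with the same
#' `total_mapped` denominator as the gene quantification — the backbone of
#' the intergenic background null.
#'
#' @param aligns An `alignment_set`.
#' @param regions data.frame (`chrom`, `start`, `end`; 0-based half-open),
#'   e.g. a [sample_background_regions()] result.
#' @return An `expression_vector` with targets named `chrom:start-end`.
#' @export
quantify_regions <- function(aligns, regions) {
  stopifnot(inherits(aligns, "alignment_set"))
  regions <- .as_intervals(regions, "regions")
  if (any(regions$end - regions$start <= 0)) .stopf("zero-length region")
  tid <- sprintf("%s:%d-%d", regions$chrom, as.integer(regions$start),
                 as.integer(regions$end))
  counts <- numeric(nrow(regions))
  b <- aligns$blocks
  if (nrow(b) > 0 && nrow(regions) > 0) {
    bg <- .gr(b$chrom, b$start, b$end)
    rg <- .gr(regions$chrom, regions$start, regions$end)
    ov <- GenomicRanges::findOverlaps(bg, rg, ignore.strand = TRUE)
    if (length(ov)) {
      pair <- unique(paste(b$fragment_id[S4Vectors::queryHits(ov)],
                           S4Vectors::subjectHits(ov), sep = "\r"))
      reg_hit <- as.integer(sub("^.*\r", "", pair))
      tb <- table(reg_hit)
      counts[as.integer(names(tb))] <- as.numeric(tb)
    }
  }
  expression_vector(data.frame(target_id = tid, count = counts,
                               length = regions$end - regions$start,
                               stringsAsFactors = FALSE),
                    tissue = aligns$tissue,
                    total_mapped = aligns$total_mapped)
}

#' Construct an expression vector
#'
#' @param df data.frame with `target_id`, `count`, `length` (bp); `fpkm` is
#'   (re)computed from the total.
#' @param tissue Tissue label.
#' @param total_mapped FPKM denominator.
#' @return data.frame of class `expression_vector`.
#' @export
expression_vector <- function(df, tissue, total_mapped) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("target_id", "count", "length") %in% names(df)))
  df$fpkm <- compute_fpkm(df$count, df$length, total_mapped)
  attr(df, "tissue") <- tissue
  attr(df, "total_mapped") <- as.numeric(total_mapped)
  class(df) <- c("expression_vector", "data.frame")
  df
}

#' Assemble an expression matrix from per-tissue vectors
#'
#' @param vectors List of `expression_vector`s with a shared target universe;
#'   targets missing from a vector get 0 with a warning.
#' @param biotype Optional named character vector (or `gene_model`) supplying
#'   per-target biotypes; targets not covered default to `"non_or"`.
#' @return Object of class `expression_matrix`: list with `fpkm` and `counts`
#'   matrices (targets x tissues) and a `meta` data.frame (`target_id`,
#'   `biotype`).
#' @export
build_matrix <- function(vectors, biotype = NULL) {
  stopifnot(length(vectors) >= 1)
  tissues <- vapply(vectors, function(v) attr(v, "tissue"), "")
  if (anyDuplicated(tissues)) .stopf("duplicate tissue name")
  targets <- unique(unlist(lapply(vectors, function(v) v$target_id)))
  fpkm <- matrix(0, nrow = length(targets), ncol = length(tissues),
                 dimnames = list(targets, tissues))
  counts <- fpkm
  for (k in seq_along(vectors)) {
    v <- vectors[[k]]
    miss <- setdiff(targets, v$target_id)
    if (length(miss))
      .warnf("tissue %s missing %d target(s); filled with 0", tissues[k],
             length(miss))
    fpkm[v$target_id, k] <- v$fpkm
    counts[v$target_id, k] <- v$count
  }
  if (inherits(biotype, "gene_model"))
    biotype <- stats::setNames(biotype$loci$biotype, biotype$loci$locus_id)
  bt <- rep("non_or", length(targets))
  if (!is.null(biotype)) {
    hit <- targets %in% names(biotype)
    bt[hit] <- unname(biotype[targets[hit]])
  }
  expression_matrix(fpkm, counts = counts, biotype = bt)
}

#' Construct an expression matrix from plain matrices
#'
#' @param fpkm Numeric matrix, targets in rows (rownames), tissues in columns
#'   (colnames).
#' @param counts Optional matching fragment-count matrix.
#' @param biotype Character vector per target (recycled), default `"non_or"`.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(fpkm, counts = NULL, biotype = "non_or") {
  fpkm <- as.matrix(fpkm)
  if ((nrow(fpkm) > 0 && is.null(rownames(fpkm))) || is.null(colnames(fpkm)))
    .stopf("fpkm matrix needs row (target) and column (tissue) names")
  if (is.null(rownames(fpkm)))
    rownames(fpkm) <- character(0)
  if (anyDuplicated(colnames(fpkm))) .stopf("duplicate tissue name")
  if (any(fpkm < 0)) .stopf("negative FPKM")
  meta <- data.frame(target_id = rownames(fpkm),
                     biotype = rep_len(biotype, nrow(fpkm)),
                     stringsAsFactors = FALSE)
  structure(list(fpkm = fpkm, counts = counts, meta = meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d targets x %d tissues\n",
              nrow(x$fpkm), ncol(x$fpkm)))
  print(utils::head(x$fpkm))
  invisible(x)
}

#' Merge near-identical target groups
#'
#' Targets whose coding sequences are nearly identical (e.g. OR2A4/OR2A7)
#' cannot be distinguished by short reads; their rows are summed per tissue
#' and presented together under a joined label.
#'
#' @param mat An `expression_matrix`.
#' @param groups List of character vectors of member target ids (disjoint);
#'   each group's label defaults to the members joined with `/`, or the
#'   list's names where given.
#' @return An `expression_matrix` with member rows replaced by group rows.
#' @export
merge_groups <- function(mat, groups) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (length(groups) == 0) return(mat)
  members <- unlist(groups)
  if (anyDuplicated(members)) .stopf("overlapping groups")
  miss <- setdiff(members, rownames(mat$fpkm))
  if (length(miss)) .stopf("unknown group member(s): %s",
                           paste(miss, collapse = ", "))
  labels <- names(groups)
  auto <- vapply(groups, paste, "", collapse = "/")
  if (is.null(labels)) labels <- auto else labels[labels == ""] <- auto[labels == ""]
  fpkm <- mat$fpkm; counts <- mat$counts
  add_f <- t(vapply(groups, function(g)
    colSums(fpkm[g, , drop = FALSE]), numeric(ncol(fpkm))))
  rownames(add_f) <- labels
  keep <- !rownames(fpkm) %in% members
  bt <- mat$meta$biotype[match(rownames(fpkm), mat$meta$target_id)]
  bt_grp <- vapply(groups, function(g)
    bt[match(g[1], rownames(fpkm))], "")
  new_f <- rbind(fpkm[keep, , drop = FALSE], add_f)
  new_c <- NULL
  if (!is.null(counts)) {
    add_c <- t(vapply(groups, function(g)
      colSums(counts[g, , drop = FALSE]), numeric(ncol(counts))))
    rownames(add_c) <- labels
    new_c <- rbind(counts[keep, , drop = FALSE], add_c)
  }
  expression_matrix(new_f, counts = new_c,
                    biotype = c(bt[keep], unname(bt_grp)))
}

#' Write an expression matrix as TSV
#'
#' Targets in rows, tissues in columns, biotype as the second column.
#'
#' @param mat An `expression_matrix`.
#' @param path Output path.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  out <- data.frame(target_id = rownames(mat$fpkm),
                    biotype = mat$meta$biotype,
                    mat$fpkm, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
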