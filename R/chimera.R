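# Chimeric (read-through) transcript detection from splice junctions,
# reading-frame classification, internal ORF splicing, and evidence for
# unannotated exons.
#
# A junction is genomic: donor = exclusive end of the left block, acceptor =
# start of the right block, donor < acceptor. On a "-" strand transcript the
# transcription-sense 5' site is therefore the genomic acceptor.

# exon rows whose 3' edge can emit a junction ending at `pos`
# (last aligned base pos-1 lies in the exon)
.donor_in_exon <- function(exons, chrom, pos) {
  which(exons$chrom == chrom & exons$start < pos & pos <= exons$end)
}
# exon rows containing base `pos`
.acceptor_in_exon <- function(exons, chrom, pos) {
  which(exons$chrom == chrom & exons$start <= pos & pos < exons$end)
}

#' Detect chimeric upstream-gene to OR transcripts
#'
#' A call is made for every junction — or chain of junctions sharing
#' intermediate annotated exons — whose transcription-sense donor lies in an
#' exon of a non-OR locus and whose final acceptor lands inside the span of
#' an OR gene or pseudogene on the same chromosome, in the upstream gene's
#' transcription direction. Junctions of known strand antisense to the
#' upstream gene are ignored; support of a chain is the minimum junction
#' support along it.
#'
#' @param junctions Junction data.frame (see [extract_junctions()]).
#' @param model A `gene_model`.
#' @param min_support Minimum per-junction fragment support (default 2).
#' @param allow_or_upstream Also report OR-to-OR chimeras (default FALSE:
#'   a non-OR upstream gene is required).
#' @param max_chain Maximum junctions per chain (default 5).
#' @return data.frame of class `chimera_calls`: `upstream_id`, `or_id`,
#'   `chrom`, `strand` (transcription direction), `exit` (genomic position
#'   leaving the upstream gene), `entry` (genomic position entering the OR),
#'   `n_junctions`, `support`, and a `chain` list-column of junction
#'   data.frames.
#' @export
detect_chimeras <- function(junctions, model, min_support = 2,
                            allow_or_upstream = FALSE, max_chain = 5) {
  stopifnot(inherits(model, "gene_model"))
  jn <- junctions[junctions$support >= min_support, , drop = FALSE]
  out <- list()
  if (nrow(jn) == 0) return(.chimera_calls(out))
  exons <- model$exons
  exons$chrom <- as.character(exons$chrom)
  loci <- model$loci
  or_loci <- loci[loci$biotype %in% c("or_gene", "or_pseudogene"), ]
  up_bt <- if (allow_or_upstream) c("non_or", "or_gene", "or_pseudogene") else
    "non_or"

  strand_ok <- function(js, s) js %in% c(s, "*", ".", "unknown")

  # depth-first chain extension in transcription direction `dir`
  extend <- function(u_row, dir, entry, chain, used) {
    res <- list()
    ors <- if (dir == "+")
      or_loci[or_loci$chrom == u_row$chrom & or_loci$span_start <= entry &
                entry < or_loci$span_end & or_loci$locus_id != u_row$locus_id, ]
    else
      or_loci[or_loci$chrom == u_row$chrom & or_loci$span_start < entry &
                entry <= or_loci$span_end & or_loci$locus_id != u_row$locus_id, ]
    if (nrow(ors)) {
      for (k in seq_len(nrow(ors))) {
        ch <- do.call(rbind, chain)
        res[[length(res) + 1]] <- list(
          upstream_id = u_row$locus_id, or_id = ors$locus_id[k],
          chrom = u_row$chrom, strand = dir,
          exit = if (dir == "+") chain[[1]]$donor else chain[[1]]$acceptor,
          entry = entry, n_junctions = length(chain),
          support = min(ch$support), chain = ch)
      }
      return(res)
    }
    if (length(chain) >= max_chain) return(res)
    ex_hit <- if (dir == "+") .acceptor_in_exon(exons, u_row$chrom, entry)
      else .donor_in_exon(exons, u_row$chrom, entry)
    for (e in ex_hit) {
      if (dir == "+") {
        nxt <- which(jn$chrom == u_row$chrom & jn$donor > entry &
                       jn$donor <= exons$end[e] & jn$donor > exons$start[e] &
                       strand_ok(jn$strand, dir))
      } else {
        nxt <- which(jn$chrom == u_row$chrom & jn$acceptor < entry &
                       jn$acceptor >= exons$start[e] &
                       jn$acceptor < exons$end[e] &
                       strand_ok(jn$strand, dir))
      }
      for (j in setdiff(nxt, used)) {
        res <- c(res, extend(u_row, dir,
                             entry = if (dir == "+") jn$acceptor[j] else jn$donor[j],
                             chain = c(chain, list(jn[j, ])),
                             used = c(used, j)))
      }
    }
    res
  }

  for (j in seq_len(nrow(jn))) {
    # "+" upstream genes: junction leaves an exon at its donor
    d_hit <- .donor_in_exon(exons, jn$chrom[j], jn$donor[j])
    for (e in d_hit) {
      u <- loci[loci$locus_id == exons$locus_id[e], ]
      if (u$strand != "+" || !u$biotype %in% up_bt) next
      if (!strand_ok(jn$strand[j], "+")) next
      out <- c(out, extend(u, "+", entry = jn$acceptor[j],
                           chain = list(jn[j, ]), used = j))
    }
    # "-" upstream genes: junction leaves an exon at its (genomic) acceptor
    a_hit <- .acceptor_in_exon(exons, jn$chrom[j], jn$acceptor[j])
    for (e in a_hit) {
      u <- loci[loci$locus_id == exons$locus_id[e], ]
      if (u$strand != "-" || !u$biotype %in% up_bt) next
      if (!strand_ok(jn$strand[j], "-")) next
      out <- c(out, extend(u, "-", entry = jn$donor[j],
                           chain = list(jn[j, ]), used = j))
    }
  }
  .chimera_calls(out)
}

.chimera_calls <- function(lst) {
  if (length(lst) == 0) {
    out <- data.frame(upstream_id = character(), or_id = character(),
                      chrom = character(), strand = character(),
                      exit = numeric(), entry = numeric(),
                      n_junctions = integer(), support = integer(),
                      stringsAsFactors = FALSE)
    out$chain <- list()
  } else {
    out <- data.frame(
      upstream_id = vapply(lst, `[[`, "", "upstream_id"),
      or_id = vapply(lst, `[[`, "", "or_id"),
      chrom = vapply(lst, `[[`, "", "chrom"),
      strand = vapply(lst, `[[`, "", "strand"),
      exit = vapply(lst, `[[`, 0, "exit"),
      entry = vapply(lst, `[[`, 0, "entry"),
      n_junctions = vapply(lst, function(x) as.integer(x$n_junctions), 1L),
      support = vapply(lst, function(x) as.integer(x$support), 1L),
      stringsAsFactors = FALSE)
    out$chain <- lapply(lst, `[[`, "chain")
    key <- sprintf("%s|%s|%g|%g", out$upstream_id, out$or_id, out$exit,
                   out$entry)
    out <- out[!duplicated(key), ]
    rownames(out) <- NULL
  }
  class(out) <- c("chimera_calls", "data.frame")
  out
}

#' @export
print.chimera_calls <- function(x, ...) {
  cat(sprintf("chimera_calls: %d call(s)\n", nrow(x)))
  if (nrow(x))
    print.data.frame(x[, setdiff(names(x), "chain")])
  invisible(x)
}

# coding bases of `locus` transcribed before leaving/entering at `pos`:
# side "before" = bases strictly 5' of pos in transcription direction `dir`
.coding_bases_5prime <- function(model, locus_id, pos, dir) {
  i <- match(locus_id, model$loci$locus_id)
  q <- model$loci[i, ]
  if (is.na(q$orf_start)) return(NA_real_)
  ex <- model$exons[model$exons$locus_id == locus_id, ]
  s <- pmax(ex$start, q$orf_start)
  e <- pmin(ex$end, q$orf_end)
  if (dir == "+") sum(pmax(0, pmin(e, pos) - s))
  else sum(pmax(0, e - pmax(s, pos)))
}

# coding bases of `locus` inside the genomic window [lo, hi)
.coding_bases_window <- function(model, locus_id, lo, hi) {
  q <- model$loci[match(locus_id, model$loci$locus_id), ]
  ex <- model$exons[model$exons$locus_id == locus_id, ]
  s <- pmax(pmax(ex$start, q$orf_start), lo)
  e <- pmin(pmin(ex$end, q$orf_end), hi)
  sum(pmax(0, e - s))
}

# upstream coding bases retained by a (possibly chained) chimeric
# transcript: everything 5' of the first exit plus the coding content of
# retained intermediate exon segments between consecutive junctions
.chain_upstream_coding <- function(model, cl) {
  ch <- cl$chain[[1]]
  dir <- cl$strand
  if (dir == "+") {
    c_u <- .coding_bases_5prime(model, cl$upstream_id, ch$donor[1], "+")
    if (is.na(c_u)) return(NA_real_)
    if (nrow(ch) > 1)
      for (j in seq_len(nrow(ch) - 1))
        c_u <- c_u + .coding_bases_window(model, cl$upstream_id,
                                          ch$acceptor[j], ch$donor[j + 1])
  } else {
    c_u <- .coding_bases_5prime(model, cl$upstream_id, ch$acceptor[1], "-")
    if (is.na(c_u)) return(NA_real_)
    if (nrow(ch) > 1)
      for (j in seq_len(nrow(ch) - 1))
        c_u <- c_u + .coding_bases_window(model, cl$upstream_id,
                                          ch$acceptor[j + 1], ch$donor[j])
  }
  c_u
}

#' Classify the reading-frame consequence of chimeric calls
#'
#' If the transcript enters the OR locus upstream (in transcription
#' direction) of the OR start codon, the OR ORF is intact
#' (`or_orf_intact`) — the chimeric mRNA still contains the complete OR
#' coding sequence. Otherwise, with `c_u` coding bases of the upstream ORF
#' retained by the transcript (5' of the first exit site, plus the coding
#' content of intermediate exon segments for chained calls) and `c_a` coding
#' bases of the OR ORF lost 5' of the entry site, the fusion is in frame iff
#' `c_u` and `c_a` are congruent modulo 3 (`fused_in_frame`), else
#' `fused_frameshift`.
#'
#' @param calls `chimera_calls` from [detect_chimeras()].
#' @param model A `gene_model` whose loci carry ORFs.
#' @return Character vector of frame statuses per call (`NA` where the
#'   upstream locus lacks an ORF and the entry point is inside the OR ORF).
#' @export
classify_fusion_frame <- function(calls, model) {
  stopifnot(inherits(model, "gene_model"))
  vapply(seq_len(nrow(calls)), function(k) {
    cl <- calls[k, ]
    or <- model$loci[match(cl$or_id, model$loci$locus_id), ]
    if (is.na(or$orf_start))
      .stopf("OR locus %s has no ORF", cl$or_id)
    dir <- cl$strand
    if (dir == "+") {
      if (cl$entry < or$orf_start) return("or_orf_intact")
      if (cl$entry >= or$orf_end)
        .stopf("entry point beyond the stop codon of %s", cl$or_id)
      c_a <- .coding_bases_5prime(model, cl$or_id, cl$entry, "+")
    } else {
      if (cl$entry > or$orf_end) return("or_orf_intact")
      if (cl$entry <= or$orf_start)
        .stopf("entry point beyond the stop codon of %s", cl$or_id)
      c_a <- .coding_bases_5prime(model, cl$or_id, cl$entry, "-")
    }
    c_u <- .chain_upstream_coding(model, cl)
    if (is.na(c_u)) {
      .warnf("upstream locus %s has no ORF: frame undecidable", cl$upstream_id)
      return(NA_character_)
    }
    if ((c_u - c_a) %% 3 == 0) "fused_in_frame" else "fused_frameshift"
  }, "")
}

#' Detect splicing events internal to OR open reading frames
#'
#' Junctions with both ends strictly inside a locus ORF remove
#' `acceptor - donor` coding bases from the mature transcript: an in-frame
#' deletion when the removed length is divisible by 3, otherwise a
#' frameshift — either way the fraction of mRNAs coding a complete receptor
#' is reduced.
#'
#' @param junctions Junction data.frame.
#' @param model A `gene_model`.
#' @param locus_ids Loci to scan; default all loci with an ORF.
#' @param min_support Minimum junction support (default 2).
#' @return data.frame (`locus_id`, `chrom`, `donor`, `acceptor`, `support`,
#'   `removed_coding_bp`, `consequence`).
#' @export
detect_internal_splicing <- function(junctions, model, locus_ids = NULL,
                                     min_support = 2) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(locus_ids))
    locus_ids <- model$loci$locus_id[!is.na(model$loci$orf_start)]
  jn <- junctions[junctions$support >= min_support, , drop = FALSE]
  out <- list()
  for (id in locus_ids) {
    q <- model$loci[match(id, model$loci$locus_id), ]
    if (is.na(q$orf_start)) .stopf("locus %s has no ORF", id)
    hit <- jn$chrom == q$chrom & jn$donor > q$orf_start &
      jn$acceptor < q$orf_end
    if (!any(hit)) next
    h <- jn[hit, ]
    h$locus_id <- id
    h$removed_coding_bp <- h$acceptor - h$donor
    h$consequence <- ifelse(h$removed_coding_bp %% 3 == 0,
                            "in_frame_deletion", "frameshift")
    out[[length(out) + 1]] <-
      h[, c("locus_id", "chrom", "donor", "acceptor", "support",
            "removed_coding_bp", "consequence")]
  }
  if (length(out) == 0)
    return(data.frame(locus_id = character(), chrom = character(),
                      donor = numeric(), acceptor = numeric(),
                      support = integer(), removed_coding_bp = numeric(),
                      consequence = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Junction endpoints unexplained by the annotation
#'
#' Reports junction donor/acceptor endpoints that neither fall inside any
#' annotated exon nor match an annotated exon boundary within `tolerance` bp
#' — evidence for unannotated exons (for ORs, typically novel 5'UTR exons
#' upstream of the coding exon). Identical endpoints from different
#' junctions are pooled, supports summed.
#'
#' @param junctions Junction data.frame.
#' @param model A `gene_model`.
#' @param min_support Minimum pooled support to report (default 2).
#' @param tolerance Boundary-matching slack in bp (default 0: exact).
#' @return data.frame (`chrom`, `position`, `side`, `support`).
#' @export
unannotated_exon_evidence <- function(junctions, model, min_support = 2,
                                      tolerance = 0) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  explained <- function(chrom, pos, side) {
    same <- ex$chrom == chrom
    if (!any(same)) return(FALSE)
    e <- ex[same, ]
    if (any(abs(e$start - pos) <= tolerance) ||
        any(abs(e$end - pos) <= tolerance)) return(TRUE)
    base <- if (side == "donor") pos - 1 else pos
    any(e$start <= base & base < e$end)
  }
  ends <- rbind(
    data.frame(chrom = junctions$chrom, position = junctions$donor,
               side = "donor", support = junctions$support,
               stringsAsFactors = FALSE),
    data.frame(chrom = junctions$chrom, position = junctions$acceptor,
               side = "acceptor", support = junctions$support,
               stringsAsFactors = FALSE))
  if (nrow(ends) == 0) return(ends)
  keep <- !mapply(explained, ends$chrom, ends$position, ends$side)
  ends <- ends[keep, , drop = FALSE]
  if (nrow(ends) == 0) return(ends)
  key <- paste(ends$chrom, ends$position, ends$side, sep = "\r")
  sup <- tapply(ends$support, key, sum)
  first <- !duplicated(key)
  out <- ends[first, c("chrom", "position", "side")]
  out$support <- as.integer(sup[key[first]])
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$chrom, out$position), ]
  rownames(out) <- NULL
  out
}
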