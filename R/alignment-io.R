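# Per-tissue alignment sets: fragments with spliced block structure,
# splice-junction extraction, flank coverage.

#' Construct an alignment set
#'
#' A tissue's mapped fragments. A fragment is a read (single-end) or a read
#' pair (paired-end); each mate/segment keeps its own spliced block structure
#' but the fragment counts once. `total_mapped` — the FPKM denominator — is
#' the number of fragments with at least one reported alignment, and may
#' exceed the fragments actually carried (a simulator or subsetting reader can
#' declare the full sequencing depth while materialising only reads of
#' interest).
#'
#' @param tissue Tissue label.
#' @param blocks data.frame with columns `fragment_id`, `segment` (integer,
#'   1 for single-end / mate index for paired-end), `chrom`, `strand`
#'   (`"+"`, `"-"`, `"*"`), `start`, `end` (0-based half-open). Blocks of a
#'   segment must be sorted with >= 1 bp gaps.
#' @param total_mapped Count of fragments with >= 1 reported alignment;
#'   default the number of distinct fragment ids in `blocks`.
#' @return Object of class `alignment_set`.
#' @export
alignment_set <- function(tissue, blocks, total_mapped = NULL) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  need <- c("fragment_id", "segment", "chrom", "strand", "start", "end")
  if (!all(need %in% names(blocks)))
    .stopf("blocks needs columns %s", paste(need, collapse = ", "))
  if (any(blocks$end <= blocks$start)) .stopf("empty or inverted block")
  blocks <- blocks[order(blocks$fragment_id, blocks$segment, blocks$start), ]
  rownames(blocks) <- NULL
  key <- paste(blocks$fragment_id, blocks$segment)
  prev <- c(FALSE, key[-1] == key[-nrow(blocks)])
  if (any(prev & blocks$start <= c(0, blocks$end[-nrow(blocks)])))
    .stopf("blocks within a segment must be separated by gaps of >= 1 bp")
  n_frag <- length(unique(blocks$fragment_id))
  if (is.null(total_mapped)) total_mapped <- n_frag
  if (total_mapped < n_frag)
    .stopf("total_mapped (%d) below number of carried fragments (%d)",
           total_mapped, n_frag)
  structure(list(tissue = tissue, blocks = blocks,
                 total_mapped = as.numeric(total_mapped)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set '%s': %d fragments carried, total_mapped = %s\n",
              x$tissue, length(unique(x$blocks$fragment_id)),
              format(x$total_mapped, big.mark = ",")))
  invisible(x)
}

#' Read per-tissue alignments (BED12 or SAM text)
#'
#' BED12: one line per read/mate; lines sharing a name form one fragment
#' (paired-end mates counted once). SAM: primary alignments become segments;
#' secondary/supplementary records are ignored; `total_mapped` counts distinct
#' mapped read names once regardless of multi-mapping.
#'
#' @param file Path to a `.bed` (BED12) or `.sam` file.
#' @param tissue Tissue label.
#' @param format `"auto"` (by extension), `"bed"` or `"sam"`.
#' @param total_mapped Override the denominator (e.g. the aligner-reported
#'   mapped-fragment total when the file was subset to regions of interest).
#' @return An `alignment_set`.
#' @export
read_alignments <- function(file, tissue,
                            format = c("auto", "bed", "sam"),
                            total_mapped = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", file, ignore.case = TRUE)) "sam" else "bed"
  blocks <- if (format == "bed") .read_bed12_blocks(file) else
    .read_sam_blocks(file)
  if (is.null(total_mapped) && !is.null(attr(blocks, "total_mapped")))
    total_mapped <- attr(blocks, "total_mapped")
  if (nrow(blocks) == 0)
    return(alignment_set(tissue, data.frame(fragment_id = character(),
                                            segment = integer(),
                                            chrom = character(),
                                            strand = character(),
                                            start = numeric(), end = numeric()),
                         total_mapped = if (is.null(total_mapped)) 0 else total_mapped))
  alignment_set(tissue, blocks, total_mapped = total_mapped)
}

.read_bed12_blocks <- function(file) {
  gr <- rtracklayer::import(file, format = "bed")
  if (length(gr) == 0)
    return(data.frame(fragment_id = character(), segment = integer(),
                      chrom = character(), strand = character(),
                      start = numeric(), end = numeric()))
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) .stopf("BED records need name fields")
  seg <- stats::ave(seq_along(nm), nm, FUN = seq_along)
  bl <- S4Vectors::mcols(gr)$blocks
  if (is.null(bl)) {  # plain BED: single block per record
    d <- .gr_df(gr)
    return(data.frame(fragment_id = nm, segment = as.integer(seg),
                      chrom = d$chrom,
                      strand = as.character(GenomicRanges::strand(gr)),
                      start = d$start, end = d$end,
                      stringsAsFactors = FALSE))
  }
  nb <- S4Vectors::elementNROWS(bl)
  flat <- unlist(bl, use.names = FALSE)
  rec <- rep(seq_along(gr), nb)
  data.frame(fragment_id = nm[rec], segment = as.integer(seg[rec]),
             chrom = as.character(GenomicRanges::seqnames(gr))[rec],
             strand = as.character(GenomicRanges::strand(gr))[rec],
             start = GenomicRanges::start(gr)[rec] - 1L +
               IRanges::start(flat) - 1L,
             end = GenomicRanges::start(gr)[rec] - 1L + IRanges::end(flat),
             stringsAsFactors = FALSE)
}

.read_sam_blocks <- function(file) {
  ln <- readLines(file)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0)
    return(data.frame(fragment_id = character(), segment = integer(),
                      chrom = character(), strand = character(),
                      start = numeric(), end = numeric()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- vapply(f, length, integer(1))
  if (any(nf < 11)) .stopf("malformed SAM record at line %d", which(nf < 11)[1])
  qname <- vapply(f, `[`, "", 1)
  flag <- as.integer(vapply(f, `[`, "", 2))
  rname <- vapply(f, `[`, "", 3)
  pos <- as.integer(vapply(f, `[`, "", 4))
  cigar <- vapply(f, `[`, "", 6)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  primary <- mapped & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  attr_total <- length(unique(qname[mapped]))
  keep <- which(primary)
  if (!length(keep))
    return(data.frame(fragment_id = character(), segment = integer(),
                      chrom = character(), strand = character(),
                      start = numeric(), end = numeric()))
  if (any(!grepl("^([0-9]+[MIDNSHP=X])+$", cigar[keep])))
    .stopf("unparsable CIGAR at line %d",
           keep[!grepl("^([0-9]+[MIDNSHP=X])+$", cigar[keep])][1])
  rg <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar[keep], pos = pos[keep], drop.D.ranges = FALSE)
  nb <- S4Vectors::elementNROWS(rg)
  flat <- unlist(rg, use.names = FALSE)
  rec <- rep(seq_along(keep), nb)
  seg <- ifelse(bitwAnd(flag[keep], 128L) > 0L, 2L, 1L)
  out <- data.frame(fragment_id = qname[keep][rec], segment = seg[rec],
                    chrom = rname[keep][rec],
                    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+")[rec],
                    start = IRanges::start(flat) - 1L,
                    end = IRanges::end(flat),
                    stringsAsFactors = FALSE)
  attr(out, "total_mapped") <- attr_total
  out
}

#' Write an alignment set as BED12
#'
#' One BED12 line per segment; mates share the fragment id in the name field.
#' Round-trips block structure exactly through [read_alignments()].
#'
#' @param aligns An `alignment_set`.
#' @param path Output path.
#' @export
write_bed12 <- function(aligns, path) {
  stopifnot(inherits(aligns, "alignment_set"))
  b <- aligns$blocks
  if (nrow(b) == 0) { file.create(path); return(invisible(path)) }
  key <- paste(b$fragment_id, b$segment, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  cs <- tapply(b$start, grp, min)[as.character(seq_len(sum(first)))]
  ce <- tapply(b$end, grp, max)[as.character(seq_len(sum(first)))]
  o <- order(grp, b$start)
  b2 <- b[o, ]; g2 <- grp[o]
  sizes <- tapply(b2$end - b2$start, g2, function(z) paste(as.integer(z), collapse = ","))
  offs <- vapply(split(b2$start - cs[g2], g2),
                 function(z) paste(as.integer(z), collapse = ","), "")
  n <- tabulate(g2)
  st <- b$strand[first]
  st[!st %in% c("+", "-")] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                   b$chrom[first], as.integer(cs), as.integer(ce),
                   b$fragment_id[first], st,
                   as.integer(cs), as.integer(ce), n,
                   sizes[as.character(seq_along(n))],
                   offs[as.character(seq_along(n))])
  writeLines(lines, path)
  invisible(path)
}

#' Extract splice junctions from an alignment set
#'
#' One junction per distinct (chrom, donor, acceptor, strand) gap between
#' consecutive blocks of a spliced segment. `donor` is the end of the left
#' block and `acceptor` the start of the right block (0-based half-open:
#' the intron is `[donor, acceptor)`). Support counts distinct fragments.
#'
#' @param aligns An `alignment_set`.
#' @param min_support Drop junctions with support below this (default 1).
#' @return data.frame (`chrom`, `donor`, `acceptor`, `strand`, `support`),
#'   sorted by position.
#' @export
extract_junctions <- function(aligns, min_support = 1) {
  stopifnot(inherits(aligns, "alignment_set"), min_support >= 1)
  b <- aligns$blocks
  empty <- data.frame(chrom = character(), donor = numeric(),
                      acceptor = numeric(), strand = character(),
                      support = integer(), stringsAsFactors = FALSE)
  if (nrow(b) < 2) return(empty)
  key <- paste(b$fragment_id, b$segment, sep = "\r")
  n <- nrow(b)
  same <- key[-1] == key[-n]
  if (!any(same)) return(empty)
  i <- which(same)  # junction between row i and i+1 (blocks sorted)
  j <- data.frame(chrom = b$chrom[i], donor = b$end[i],
                  acceptor = b$start[i + 1], strand = b$strand[i],
                  fragment_id = b$fragment_id[i], stringsAsFactors = FALSE)
  jk <- paste(j$chrom, j$donor, j$acceptor, j$strand, sep = "\r")
  sup <- tapply(j$fragment_id, jk, function(z) length(unique(z)))
  first <- !duplicated(jk)
  out <- j[first, c("chrom", "donor", "acceptor", "strand")]
  out$support <- as.integer(sup[jk[first]])
  out <- out[out$support >= min_support, ]
  out <- out[order(out$chrom, out$donor, out$acceptor), ]
  rownames(out) <- NULL
  out
}

#' Fragment coverage in the flanks of a locus
#'
#' Counts fragments with at least one aligned base within `flank` bp upstream
#' (`[span_start - flank, span_start)`) and downstream
#' (`[span_end, span_end + flank)`) of a locus span, clipped to the
#' chromosome. Used to check that an OR's signal does not leak from adjacent
#' regions.
#'
#' @param aligns An `alignment_set`.
#' @param model A `gene_model`.
#' @param locus_id Single locus id.
#' @param flank Window width in bp (default 2000).
#' @return Named numeric vector `c(upstream=, downstream=)`.
#' @export
flank_coverage <- function(aligns, model, locus_id, flank = 2000) {
  stopifnot(inherits(aligns, "alignment_set"), flank > 0)
  i <- match(locus_id, model$loci$locus_id)
  if (is.na(i)) .stopf("locus %s not in model", locus_id)
  q <- model$loci[i, ]
  glen <- model$genome$length[match(q$chrom, model$genome$chrom)]
  win <- data.frame(side = c("upstream", "downstream"),
                    start = c(max(0, q$span_start - flank), min(q$span_end, glen)),
                    end = c(q$span_start, min(glen, q$span_end + flank)))
  b <- aligns$blocks[aligns$blocks$chrom == q$chrom, ]
  cnt <- vapply(seq_len(2), function(k) {
    if (win$end[k] <= win$start[k] || nrow(b) == 0) return(0L)
    hit <- b$start < win$end[k] & b$end > win$start[k]
    length(unique(b$fragment_id[hit]))
  }, integer(1))
  stats::setNames(as.numeric(cnt), win$side)
}

#' Write junctions as TSV
#'
#' @param junctions Junction data.frame from [extract_junctions()].
#' @param path Output path.
#' @param tissue Optional tissue label column.
#' @export
write_junctions <- function(junctions, path, tissue = NA_character_) {
  out <- junctions
  out$tissue <- tissue
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
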