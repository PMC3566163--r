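# Gene model: genome, loci with merged exon structures, biotypes and ORFs.
#
# All coordinates inside the package are 0-based half-open; GTF input/output
# converts from/to the 1-based inclusive GTF convention.

#' Construct a gene model
#'
#' Assembles a validated gene model from a genome table, a locus table and an
#' exon table. Exons are merged (unioned) per locus; loci carry a biotype
#' distinguishing olfactory-receptor (OR) genes, OR pseudogenes and all other
#' loci, and optionally a genomic open-reading-frame (ORF) interval.
#'
#' @param genome data.frame with columns `chrom`, `length` (bp).
#' @param loci data.frame with columns `locus_id`, `symbol`, `chrom`, `strand`
#'   (`"+"` or `"-"`), `biotype` (`"or_gene"`, `"or_pseudogene"`, `"non_or"`),
#'   and optionally `orf_start`, `orf_end` (0-based half-open, `NA` if absent).
#' @param exons data.frame with columns `locus_id`, `start`, `end`
#'   (0-based half-open genomic coordinates).
#' @return An object of class `gene_model`: a list with elements `genome`,
#'   `loci` (with derived columns `span_start`, `span_end`, `exon_length`,
#'   `n_exons`) and `exons` (merged, sorted).
#' @export
gene_model <- function(genome, loci, exons) {
  genome <- as.data.frame(genome, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(genome)))
    .stopf("genome needs columns chrom, length")
  if (anyDuplicated(genome$chrom)) .stopf("duplicated chromosome names")
  if (any(genome$length <= 0)) .stopf("chromosome lengths must be > 0")

  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("locus_id", "symbol", "chrom", "strand", "biotype")
  if (!all(need %in% names(loci)))
    .stopf("loci needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(loci$locus_id)) .stopf("duplicated locus ids")
  if (!all(loci$chrom %in% genome$chrom))
    .stopf("locus chromosome(s) not in genome: %s",
           paste(unique(setdiff(loci$chrom, genome$chrom)), collapse = ", "))
  if (!all(loci$strand %in% c("+", "-")))
    .stopf("locus strand must be '+' or '-'")
  ok_bt <- c("or_gene", "or_pseudogene", "non_or")
  if (!all(loci$biotype %in% ok_bt))
    .stopf("unknown biotype(s): %s",
           paste(unique(setdiff(loci$biotype, ok_bt)), collapse = ", "))
  if (is.null(loci$orf_start)) loci$orf_start <- rep(NA_real_, nrow(loci))
  if (is.null(loci$orf_end)) loci$orf_end <- rep(NA_real_, nrow(loci))

  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (!all(c("locus_id", "start", "end") %in% names(exons)))
    .stopf("exons needs columns locus_id, start, end")
  if (!all(loci$locus_id %in% exons$locus_id))
    .stopf("every locus needs at least one exon")
  if (!all(exons$locus_id %in% loci$locus_id))
    .stopf("exon rows reference unknown loci")

  # merge exons per locus
  chrom_of <- stats::setNames(loci$chrom, loci$locus_id)
  gr <- .gr(chrom_of[exons$locus_id], exons$start, exons$end)
  red <- GenomicRanges::reduce(
    GenomicRanges::split(gr, factor(exons$locus_id, levels = loci$locus_id)))
  flat <- unlist(red, use.names = TRUE)
  exons <- data.frame(locus_id = names(flat),
                      chrom = as.character(GenomicRanges::seqnames(flat)),
                      start = GenomicRanges::start(flat) - 1L,
                      end = GenomicRanges::end(flat),
                      stringsAsFactors = FALSE)
  rownames(exons) <- NULL
  exons <- exons[order(match(exons$locus_id, loci$locus_id), exons$start), ]

  lens <- tapply(exons$end - exons$start, exons$locus_id, sum)
  loci$exon_length <- as.numeric(lens[loci$locus_id])
  loci$n_exons <- as.integer(table(exons$locus_id)[loci$locus_id])
  loci$span_start <- as.numeric(tapply(exons$start, exons$locus_id, min)[loci$locus_id])
  loci$span_end <- as.numeric(tapply(exons$end, exons$locus_id, max)[loci$locus_id])

  glen <- stats::setNames(genome$length, genome$chrom)
  if (any(exons$start < 0) || any(exons$end > glen[exons$chrom])) {
    bad <- exons$locus_id[exons$start < 0 | exons$end > glen[exons$chrom]][1]
    .stopf("exon outside chromosome bounds for locus %s", bad)
  }

  has_orf <- !is.na(loci$orf_start)
  if (any(has_orf & loci$biotype == "or_pseudogene")) {
    .warnf("ORF dropped for pseudogene loci (%s)",
           paste(loci$locus_id[has_orf & loci$biotype == "or_pseudogene"],
                 collapse = ", "))
    loci$orf_start[loci$biotype == "or_pseudogene"] <- NA_real_
    loci$orf_end[loci$biotype == "or_pseudogene"] <- NA_real_
    has_orf <- !is.na(loci$orf_start)
  }
  if (any(has_orf)) {
    # ORF must lie within the exon union
    oi <- which(has_orf)
    orf_cov <- vapply(oi, function(i) {
      ex <- exons[exons$locus_id == loci$locus_id[i], ]
      sum(pmax(0, pmin(ex$end, loci$orf_end[i]) - pmax(ex$start, loci$orf_start[i])))
    }, numeric(1))
    claimed <- loci$orf_end[oi] - loci$orf_start[oi]
    # contained means every orf base is exonic on the locus span ends
    if (any(loci$orf_start[oi] < loci$span_start[oi] |
            loci$orf_end[oi] > loci$span_end[oi]))
      .stopf("ORF outside exon span for locus %s",
             loci$locus_id[oi][which(loci$orf_start[oi] < loci$span_start[oi] |
                                     loci$orf_end[oi] > loci$span_end[oi])][1])
    attr(loci, "orf_exonic_bp") <- stats::setNames(orf_cov, loci$locus_id[oi])
    if (any(orf_cov <= 0)) .stopf("ORF has no exonic bases for locus %s",
                                  loci$locus_id[oi][orf_cov <= 0][1])
    rm(claimed)
  }

  structure(list(genome = genome, loci = loci, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d loci on %d chromosome(s) (%s bp)\n",
              nrow(x$loci), nrow(x$genome),
              format(sum(x$genome$length), big.mark = ",")))
  print(table(x$loci$biotype))
  invisible(x)
}

#' Read a gene model from GTF
#'
#' Parses exon (and, when present, CDS) records from a GTF stream and builds a
#' [gene_model()]. GTF coordinates (1-based inclusive) are converted to the
#' package's 0-based half-open convention, exons are unioned per gene, and CDS
#' records are collapsed to a genomic ORF interval per gene.
#'
#' Biotypes come from an explicit lookup table (HORDE-style membership is
#' external knowledge); symbols absent from the table default to `"non_or"`.
#'
#' @param gtf Path to (or connection of) a GTF file with `exon` records
#'   carrying `gene_id` attributes.
#' @param biotypes Optional data.frame with columns `symbol`, `biotype`, or a
#'   path to a two-column TSV of the same shape. See [read_biotype_table()].
#' @param genome Optional genome data.frame (`chrom`, `length`). When `NULL`,
#'   chromosome lengths are inferred as the maximum annotated coordinate.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(gtf, biotypes = NULL, genome = NULL) {
  empty_input <- is.character(gtf) && length(gtf) == 1 &&
    file.exists(gtf) && length(readLines(gtf, n = 1)) == 0
  gr <- if (empty_input) GenomicRanges::GRanges() else
    rtracklayer::import(gtf, format = "gtf")
  if (length(gr) == 0) {
    if (is.null(genome)) genome <- data.frame(chrom = character(),
                                              length = numeric())
    return(gene_model(genome,
                      loci = data.frame(locus_id = character(),
                                        symbol = character(),
                                        chrom = character(),
                                        strand = character(),
                                        biotype = character()),
                      exons = data.frame(locus_id = character(),
                                         start = numeric(), end = numeric())))
  }
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) .stopf("GTF records lack gene_id attributes")
  type <- if (!is.null(md$type)) as.character(md$type) else "exon"
  ex <- gr[type == "exon"]
  if (length(ex) == 0) .stopf("GTF contains no exon records")

  exd <- .gr_df(ex)
  exd$locus_id <- S4Vectors::mcols(ex)$gene_id
  sym <- S4Vectors::mcols(ex)$gene_name
  if (is.null(sym)) sym <- exd$locus_id
  sym[is.na(sym)] <- exd$locus_id[is.na(sym)]

  first <- !duplicated(exd$locus_id)
  loci <- data.frame(locus_id = exd$locus_id[first],
                     symbol = sym[first],
                     chrom = exd$chrom[first],
                     strand = as.character(GenomicRanges::strand(ex))[first],
                     stringsAsFactors = FALSE)
  loci$strand[!loci$strand %in% c("+", "-")] <- "+"

  if (is.character(biotypes) && length(biotypes) == 1)
    biotypes <- read_biotype_table(biotypes)
  if (is.null(biotypes)) {
    loci$biotype <- "non_or"
  } else {
    bt <- stats::setNames(biotypes$biotype, biotypes$symbol)
    loci$biotype <- ifelse(loci$symbol %in% names(bt),
                           unname(bt[loci$symbol]), "non_or")
  }

  cds <- gr[type == "CDS"]
  loci$orf_start <- NA_real_
  loci$orf_end <- NA_real_
  if (length(cds) > 0) {
    cd <- .gr_df(cds)
    cd$locus_id <- S4Vectors::mcols(cds)$gene_id
    os <- tapply(cd$start, cd$locus_id, min)
    oe <- tapply(cd$end, cd$locus_id, max)
    hit <- loci$locus_id %in% names(os)
    loci$orf_start[hit] <- as.numeric(os[loci$locus_id[hit]])
    loci$orf_end[hit] <- as.numeric(oe[loci$locus_id[hit]])
  }

  if (is.null(genome)) {
    mx <- tapply(exd$end, exd$chrom, max)
    genome <- data.frame(chrom = names(mx), length = as.numeric(mx),
                         stringsAsFactors = FALSE)
  }
  gene_model(genome, loci,
             exons = exd[, c("locus_id", "start", "end")])
}

#' Read a biotype lookup table
#'
#' Two-column tab-separated file mapping gene symbols to one of `or_gene`,
#' `or_pseudogene` or `non_or`.
#'
#' @param path Path to the TSV (header optional; columns symbol, biotype).
#' @return data.frame with columns `symbol`, `biotype`.
#' @export
read_biotype_table <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(tb[1, 1]), "symbol")) tb <- tb[-1, , drop = FALSE]
  names(tb)[1:2] <- c("symbol", "biotype")
  tb[, c("symbol", "biotype")]
}

#' Union-exon length of loci
#'
#' Total merged exonic bases per locus: the "kilobase of exon" denominator of
#' FPKM.
#'
#' @param model A `gene_model`.
#' @param locus_id Character vector of locus ids; default all loci.
#' @return Named numeric vector of exonic bp.
#' @export
union_exon_length <- function(model, locus_id = NULL) {
  stopifnot(inherits(model, "gene_model"))
  ids <- if (is.null(locus_id)) model$loci$locus_id else locus_id
  miss <- setdiff(ids, model$loci$locus_id)
  if (length(miss)) .stopf("unknown locus id(s): %s", paste(miss, collapse = ", "))
  stats::setNames(model$loci$exon_length[match(ids, model$loci$locus_id)], ids)
}

#' Intergenic space of a genome
#'
#' The genome minus every annotated locus span (first exon start to last exon
#' end, introns included) extended by `flank` bp on both sides, across one or
#' more annotation sets. This is the space from which background regions are
#' drawn: suitable regions lie neither within genes/introns nor within the
#' flank of any gene.
#'
#' @param models A `gene_model` or list of `gene_model`s (multiple annotation
#'   sets are all masked).
#' @param genome Genome data.frame; default the first model's genome.
#' @param flank Mask extension in bp on each side of a locus span (default
#'   10000).
#' @return data.frame (`chrom`, `start`, `end`; 0-based half-open) of class
#'   `interval_set`, sorted and disjoint. May be empty.
#' @export
intergenic_space <- function(models, genome = NULL, flank = 10000) {
  if (inherits(models, "gene_model")) models <- list(models)
  stopifnot(flank >= 0, length(models) >= 1)
  if (is.null(genome)) genome <- models[[1]]$genome

  masks <- lapply(models, function(m) {
    if (nrow(m$loci) == 0) return(NULL)
    data.frame(chrom = m$loci$chrom,
               start = pmax(0, m$loci$span_start - flank),
               end = m$loci$span_end + flank)
  })
  masks <- do.call(rbind, masks)

  genome_gr <- .gr(genome$chrom, 0, genome$length)
  if (is.null(masks) || nrow(masks) == 0) {
    out <- .gr_df(genome_gr)
  } else {
    glen <- stats::setNames(genome$length, genome$chrom)
    masks$end <- pmin(masks$end, glen[masks$chrom])
    gap <- GenomicRanges::setdiff(genome_gr,
                                  GenomicRanges::reduce(.gr(masks$chrom, masks$start, masks$end)))
    out <- .gr_df(gap)
  }
  out <- out[order(match(out$chrom, genome$chrom), out$start), ]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Nearest non-overlapping neighbours of a locus
#'
#' Upstream (lower-coordinate) and downstream (higher-coordinate) nearest
#' annotated loci on the same chromosome that do not overlap the query span,
#' any strand. Loci overlapping the query are skipped as neighbours.
#'
#' @param model A `gene_model`.
#' @param locus_id Single locus id.
#' @param max_distance Optional maximum span-to-span gap in bp (default
#'   `Inf`); a conventional 5e5 supports the half-megabase neighbourhood used
#'   in earlier work.
#' @return List with elements `upstream` and `downstream`, each a one-row
#'   locus data.frame or `NULL` when absent.
#' @export
adjacent_loci <- function(model, locus_id, max_distance = Inf) {
  stopifnot(inherits(model, "gene_model"))
  i <- match(locus_id, model$loci$locus_id)
  if (is.na(i)) .stopf("locus %s not in model", locus_id)
  q <- model$loci[i, ]
  same <- model$loci[model$loci$chrom == q$chrom &
                       model$loci$locus_id != q$locus_id, ]
  # non-overlapping on each side
  left <- same[same$span_end <= q$span_start, ]
  right <- same[same$span_start >= q$span_end, ]
  up <- NULL
  if (nrow(left)) {
    cand <- left[which.max(left$span_end), ]
    if (q$span_start - cand$span_end <= max_distance) up <- cand
  }
  down <- NULL
  if (nrow(right)) {
    cand <- right[which.min(right$span_start), ]
    if (cand$span_start - q$span_end <= max_distance) down <- cand
  }
  list(upstream = up, downstream = down)
}

#' Parse an olfactory-receptor symbol
#'
#' HORDE-style OR nomenclature `OR<family><subfamily><member>[P]`, e.g.
#' `OR7E19P` is family 7, subfamily E, member 19, pseudogene.
#'
#' @param symbol Character vector of symbols.
#' @return data.frame with columns `symbol`, `family` (integer), `subfamily`,
#'   `member`, `is_pseudogene`.
#' @export
parse_or_symbol <- function(symbol) {
  m <- regmatches(symbol, regexec("^OR([0-9]+)([A-Z]+)([0-9]+)(P?)$", symbol))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad))
    .stopf("not an OR symbol: %s", paste(symbol[bad], collapse = ", "))
  data.frame(symbol = symbol,
             family = as.integer(vapply(m, `[`, "", 2)),
             subfamily = vapply(m, `[`, "", 3),
             member = vapply(m, `[`, "", 4),
             is_pseudogene = vapply(m, `[`, "", 5) == "P",
             stringsAsFactors = FALSE)
}

#' Write an interval set as BED3
#'
#' @param x data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @param header Optional comment line(s) written before the records.
#' @export
write_bed3 <- function(x, path, header = NULL) {
  x <- .as_intervals(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  if (nrow(x))
    writeLines(sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start),
                       as.integer(x$end)), con)
  invisible(path)
}
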