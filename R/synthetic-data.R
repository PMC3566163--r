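# Synthetic data: toy genomes and annotations with known per-gene FPKM
# truth, Poisson fragment simulation with uniform intergenic noise, planted
# chimeric / internal splice junctions, and fixture I/O.

#' Configuration for a toy annotation
#'
#' Defaults describe the standard desk-scale study: two 500-kb chromosomes
#' carrying 60 loci (30 non-OR multi-exon genes, 20 single-exon OR genes with
#' ~1-kb intron-free ORFs, 10 OR pseudogenes without ORFs), an OR cluster
#' block, and one multi-exon upstream gene placed 5' of an OR to host planted
#' read-through chimeras.
#'
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param n_non_or,n_or,n_or_pseudo Locus counts per biotype.
#' @param or_exon_length Single OR exon length (bp).
#' @param or_orf_length OR ORF length (bp, forced to a multiple of 3).
#' @param non_or_n_exons,non_or_exon_length,non_or_intron_length Ranges
#'   (`c(min, max)`) for non-OR gene structure.
#' @param gap Range of intergenic gaps between consecutive loci (bp).
#' @param or_cluster_size Number of ORs laid down as one contiguous cluster.
#' @param readthrough Place an upstream non-OR gene 2 kb 5' of an OR gene
#'   (the read-through pair) at the start of the first chromosome.
#' @return Named list of class `toy_config`.
#' @export
toy_config <- function(n_chrom = 2, chrom_length = 5e5,
                       n_non_or = 30, n_or = 20, n_or_pseudo = 10,
                       or_exon_length = 1080, or_orf_length = 939,
                       non_or_n_exons = c(4, 7),
                       non_or_exon_length = c(120, 300),
                       non_or_intron_length = c(400, 1500),
                       gap = c(10000, 14000),
                       or_cluster_size = 6, readthrough = TRUE) {
  or_orf_length <- 3 * floor(or_orf_length / 3)
  cfg <- list(n_chrom = n_chrom, chrom_length = chrom_length,
              n_non_or = n_non_or, n_or = n_or, n_or_pseudo = n_or_pseudo,
              or_exon_length = or_exon_length, or_orf_length = or_orf_length,
              non_or_n_exons = non_or_n_exons,
              non_or_exon_length = non_or_exon_length,
              non_or_intron_length = non_or_intron_length,
              gap = gap, or_cluster_size = or_cluster_size,
              readthrough = readthrough)
  stopifnot(or_orf_length + 20 <= or_exon_length)
  class(cfg) <- "toy_config"
  cfg
}

.runif_int <- function(n, range) {
  range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1))
}

# distinct HORDE-style OR symbols; pseudogenes lean toward family 7E to give
# the subfamily-composition machinery something to chew on
.or_symbols <- function(n_gene, n_pseudo) {
  syms <- character(0)
  fam_pool <- c(1, 2, 4, 5, 51, 52, 6, 10)
  sub_pool <- c("A", "B", "C", "D", "E")
  draw <- function(n, suffix, bias7e) {
    out <- character(0)
    while (length(out) < n) {
      fam <- if (bias7e && stats::runif(1) < 0.5) 7 else sample(fam_pool, 1)
      sub <- if (fam == 7) "E" else sample(sub_pool, 1)
      cand <- sprintf("OR%d%s%d%s", fam, sub, .runif_int(1, c(1, 999)), suffix)
      if (!cand %in% c(syms, out)) out <- c(out, cand)
    }
    out
  }
  g <- draw(n_gene, "", FALSE); syms <- g
  p <- draw(n_pseudo, "P", TRUE)
  list(gene = g, pseudo = p)
}

#' Build a toy genome and annotation
#'
#' Lays loci along the chromosomes with randomised intergenic gaps,
#' deterministic for a fixed seed. OR genes are single-exon with an
#' intron-free ORF; pseudogenes carry no ORF; non-OR genes are multi-exon
#' with a spliced ORF (coding length a multiple of 3). When
#' `config$readthrough` is set, the first chromosome starts with a non-OR
#' gene 2 kb upstream of an OR gene, the pair used to plant chimeric
#' transcripts.
#'
#' @param config A [toy_config()].
#' @param seed Integer seed.
#' @return List with `model` (a `gene_model`), `biotypes` (data.frame
#'   `symbol`, `biotype`) and `readthrough` (`c(upstream=, or=)` locus ids,
#'   or `NULL`).
#' @export
build_toy_annotation <- function(config = toy_config(), seed = 1) {
  cfg <- config
  with_seed(seed, {
    syms <- .or_symbols(cfg$n_or, cfg$n_or_pseudo)
    descr <- c(
      lapply(seq_len(cfg$n_non_or), function(i)
        list(id = sprintf("GENE%03d", i), biotype = "non_or")),
      lapply(syms$gene, function(s) list(id = s, biotype = "or_gene")),
      lapply(syms$pseudo, function(s) list(id = s, biotype = "or_pseudogene")))

    # placement order: readthrough pair first, then OR cluster, then the rest
    # shuffled
    rt <- NULL
    ord <- sample(seq_along(descr))
    if (cfg$readthrough && cfg$n_non_or >= 1 && cfg$n_or >= 1) {
      up_i <- which(vapply(descr, function(d) d$biotype == "non_or",
                           TRUE))[1]
      or_i <- which(vapply(descr, function(d) d$biotype == "or_gene",
                           TRUE))[1]
      ord <- c(up_i, or_i, setdiff(ord, c(up_i, or_i)))
      rt <- c(upstream = descr[[up_i]]$id, or = descr[[or_i]]$id)
    }
    # move a cluster of ORs together
    or_pos <- which(vapply(descr[ord], function(d)
      d$biotype %in% c("or_gene", "or_pseudogene"), TRUE))
    or_pos <- setdiff(or_pos, 1:2)
    k <- min(cfg$or_cluster_size, length(or_pos))
    if (k > 1) {
      cl <- or_pos[seq_len(k)]
      rest <- setdiff(seq_along(ord), cl)
      at <- ceiling(length(ord) / 2)
      ord <- c(ord[rest[seq_len(min(at, length(rest)))]], ord[cl],
               ord[rest[-seq_len(min(at, length(rest)))]])
    }

    loci <- list(); exons <- list()
    chrom_names <- sprintf("chr%d", seq_len(cfg$n_chrom))
    per_chrom <- ceiling(length(descr) / cfg$n_chrom)
    cur_chrom <- 1; cursor <- .runif_int(1, cfg$gap); placed_on <- 0

    for (pos in seq_along(ord)) {
      d <- descr[[ord[pos]]]
      in_rt <- !is.null(rt) && d$id %in% rt
      if (placed_on >= per_chrom && !in_rt) {
        cur_chrom <- cur_chrom + 1
        if (cur_chrom > cfg$n_chrom) .stopf("infeasible packing: too many loci")
        cursor <- .runif_int(1, cfg$gap); placed_on <- 0
      }
      chrom <- chrom_names[cur_chrom]
      if (d$biotype == "non_or") {
        nex <- .runif_int(1, cfg$non_or_n_exons)
        ws <- .runif_int(nex, cfg$non_or_exon_length)
        ins <- if (nex > 1) .runif_int(nex - 1, cfg$non_or_intron_length)
               else integer(0)
        starts <- cursor + cumsum(c(0, ws[-nex] + ins))
        ends <- starts + ws
        # spliced ORF: trim so that coding length is a multiple of 3
        orf_s <- starts[1] + 30
        orf_e <- ends[nex] - 30
        cod <- sum(pmax(0, pmin(ends, orf_e) - pmax(starts, orf_s)))
        orf_e <- orf_e - (cod %% 3)
        exons[[length(exons) + 1]] <-
          data.frame(locus_id = d$id, start = starts, end = ends)
        loci[[length(loci) + 1]] <-
          data.frame(locus_id = d$id, symbol = d$id, chrom = chrom,
                     strand = if (in_rt) "+" else sample(c("+", "-"), 1),
                     biotype = d$biotype, orf_start = orf_s, orf_end = orf_e)
        span_end <- ends[nex]
      } else {
        s <- cursor; e <- s + cfg$or_exon_length
        orf_s <- s + 60; orf_e <- orf_s + cfg$or_orf_length
        exons[[length(exons) + 1]] <-
          data.frame(locus_id = d$id, start = s, end = e)
        loci[[length(loci) + 1]] <-
          data.frame(locus_id = d$id, symbol = d$id, chrom = chrom,
                     strand = if (in_rt) "+" else sample(c("+", "-"), 1),
                     biotype = d$biotype,
                     orf_start = if (d$biotype == "or_gene") orf_s else NA_real_,
                     orf_end = if (d$biotype == "or_gene") orf_e else NA_real_)
        span_end <- e
      }
      # 2-kb gap after a readthrough upstream gene, regular gap otherwise
      nxt_rt <- !is.null(rt) && identical(d$id, unname(rt["upstream"]))
      cursor <- span_end + if (nxt_rt) 2000 else .runif_int(1, cfg$gap)
      placed_on <- placed_on + 1
      if (cursor > cfg$chrom_length)
        .stopf("infeasible packing: chromosome %s overflows at locus %s",
               chrom, d$id)
    }
    model <- gene_model(
      genome = data.frame(chrom = chrom_names, length = cfg$chrom_length),
      loci = do.call(rbind, loci), exons = do.call(rbind, exons))
    bt <- data.frame(symbol = model$loci$symbol, biotype = model$loci$biotype,
                     stringsAsFactors = FALSE)
    list(model = model, biotypes = bt, readthrough = rt)
  })
}

#' Construct a truth table for simulation
#'
#' @param expr data.frame (`target_id`, `tissue`, `true_fpkm`); loci/tissues
#'   absent default to 0.
#' @param chimeras Optional data.frame (`tissue`, `upstream_id`, `or_id`,
#'   `donor`, `acceptor`, `n_fragments`) of planted chimeric junctions.
#' @param internal Optional data.frame (`tissue`, `locus_id`, `donor`,
#'   `acceptor`, `n_fragments`) of planted internal ORF splices.
#' @param noise_rate Fraction of `total_fragments` placed uniformly at random
#'   on the genome (`[0, 1)`).
#' @param noise_junctions Count of random support-1 spliced fragments per
#'   tissue.
#' @return List of class `truth_table`.
#' @export
truth_table <- function(expr, chimeras = NULL, internal = NULL,
                        noise_rate = 0, noise_junctions = 0) {
  expr <- as.data.frame(expr, stringsAsFactors = FALSE)
  stopifnot(all(c("target_id", "tissue", "true_fpkm") %in% names(expr)),
            all(expr$true_fpkm >= 0),
            noise_rate >= 0, noise_rate < 1)
  structure(list(expr = expr, chimeras = chimeras, internal = internal,
                 noise_rate = noise_rate, noise_junctions = noise_junctions),
            class = "truth_table")
}

#' Random truth table for a toy annotation
#'
#' Per tissue, each locus is expressed with a biotype-specific probability at
#' a log-uniform FPKM. ORs and OR pseudogenes emulate weak ectopic
#' expression; non-OR genes span housekeeping-like levels. When the
#' annotation carries a read-through pair, two chimeric junction sets are
#' planted per tissue — one entering the OR 5'UTR (OR ORF intact) and one
#' entering inside the OR ORF (fusion) — plus one internal ORF splice.
#'
#' @param annotation Result of [build_toy_annotation()].
#' @param tissues Character vector of tissue names.
#' @param seed Integer seed.
#' @param prop_or,or_fpkm Expression probability and log-uniform FPKM range
#'   for OR genes/pseudogenes.
#' @param prop_non_or,non_or_fpkm Same for non-OR genes.
#' @param noise_rate,noise_junctions See [truth_table()].
#' @param chimera_fragments Planted fragments per chimeric junction.
#' @return A `truth_table`.
#' @export
make_truth <- function(annotation, tissues, seed = 1,
                       prop_or = 0.35, or_fpkm = c(0.02, 10),
                       prop_non_or = 0.9, non_or_fpkm = c(0.5, 200),
                       noise_rate = 2e-5, noise_junctions = 5,
                       chimera_fragments = 8) {
  model <- annotation$model
  with_seed(seed, {
    rows <- list()
    for (ts in tissues) {
      is_or <- model$loci$biotype %in% c("or_gene", "or_pseudogene")
      p <- ifelse(is_or, prop_or, prop_non_or)
      rng_lo <- ifelse(is_or, or_fpkm[1], non_or_fpkm[1])
      rng_hi <- ifelse(is_or, or_fpkm[2], non_or_fpkm[2])
      on <- stats::runif(nrow(model$loci)) < p
      f <- exp(log(rng_lo) + stats::runif(nrow(model$loci)) *
                 (log(rng_hi) - log(rng_lo)))
      rows[[ts]] <- data.frame(target_id = model$loci$locus_id[on],
                               tissue = ts, true_fpkm = f[on],
                               stringsAsFactors = FALSE)
    }
    chim <- NULL
    if (!is.null(annotation$readthrough)) {
      up <- model$loci[match(annotation$readthrough["upstream"],
                             model$loci$locus_id), ]
      or <- model$loci[match(annotation$readthrough["or"],
                             model$loci$locus_id), ]
      up_ex <- model$exons[model$exons$locus_id == up$locus_id, ]
      donor <- up_ex$end[nrow(up_ex) - 1]  # penultimate exon donor site
      chim <- do.call(rbind, lapply(tissues, function(ts) data.frame(
        tissue = ts, upstream_id = up$locus_id, or_id = or$locus_id,
        donor = donor,
        acceptor = c(or$orf_start - 40, or$orf_start + 100),
        n_fragments = chimera_fragments, stringsAsFactors = FALSE)))
      intern <- do.call(rbind, lapply(tissues, function(ts) data.frame(
        tissue = ts, locus_id = or$locus_id,
        donor = or$orf_start + 210, acceptor = or$orf_start + 300,
        n_fragments = chimera_fragments, stringsAsFactors = FALSE)))
    } else intern <- NULL
    truth_table(do.call(rbind, rows), chimeras = chim, internal = intern,
                noise_rate = noise_rate, noise_junctions = noise_junctions)
  })
}

# map exon-space fragment intervals [s, s+fl) to genomic blocks
.exon_space_blocks <- function(ex, s, fl, ids, tissue) {
  w <- ex$end - ex$start
  cum <- cumsum(c(0, w))
  fr <- IRanges::IRanges(start = s + 1L, width = fl)
  seg <- IRanges::IRanges(start = cum[-length(cum)] + 1L, end = cum[-1])
  ov <- IRanges::findOverlaps(fr, seg)
  q <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
  bs <- ex$start[sj] + pmax(0, s[q] - cum[sj])
  be <- ex$start[sj] + pmin(w[sj], s[q] + fl - cum[sj])
  data.frame(fragment_id = ids[q], segment = 1L,
             chrom = ex$chrom[sj], strand = "*",
             start = bs, end = be, stringsAsFactors = FALSE)
}

#' Simulate one tissue's alignment set
#'
#' Per locus the fragment count is Poisson with mean
#' `true_fpkm * exon_length/1000 * total_fragments/1e6`; fragment starts are
#' uniform over exon-space positions keeping the fragment inside the exon
#' union, spliced across introns for multi-exon loci. `noise_rate *
#' total_fragments` single-block fragments land uniformly on the genome.
#' Planted chimeric/internal junction fragments are realised as spliced
#' fragments across the specified donor-acceptor pairs; `noise_junctions`
#' support-1 spliced fragments land at random. `total_mapped` is set to
#' `total_fragments` (the library's sequencing depth — unsimulated
#' transcripts account for the remainder). Deterministic for a fixed seed.
#'
#' @param model A `gene_model`.
#' @param truth A `truth_table`.
#' @param tissue Tissue name (rows of `truth$expr` are matched on it).
#' @param total_fragments Mapped-fragment depth (FPKM denominator).
#' @param fragment_length Read length in bp (default 75).
#' @param seed Integer seed.
#' @return An `alignment_set`.
#' @export
simulate_tissue <- function(model, truth, tissue, total_fragments = 2e6,
                            fragment_length = 75, seed = 1) {
  stopifnot(inherits(model, "gene_model"), inherits(truth, "truth_table"),
            total_fragments > 0)
  fl <- fragment_length
  ex_all <- model$exons
  expr <- truth$expr[truth$expr$tissue == tissue, , drop = FALSE]
  fpkm <- stats::setNames(rep(0, nrow(model$loci)), model$loci$locus_id)
  fpkm[expr$target_id] <- expr$true_fpkm
  short <- model$loci$exon_length < fl & fpkm[model$loci$locus_id] > 0
  if (any(short))
    .stopf("fragment_length %d exceeds the exon union of locus %s", fl,
           model$loci$locus_id[short][1])

  with_seed(seed, {
    blocks <- list()
    for (i in seq_len(nrow(model$loci))) {
      f <- fpkm[[model$loci$locus_id[i]]]
      if (f <= 0) next
      len <- model$loci$exon_length[i]
      lam <- f * (len / 1000) * (total_fragments / 1e6)
      n <- stats::rpois(1, lam)
      if (n == 0) next
      s <- floor(stats::runif(n) * (len - fl + 1))
      ex <- ex_all[ex_all$locus_id == model$loci$locus_id[i], ]
      ids <- sprintf("%s|%s|%d", tissue, model$loci$locus_id[i], seq_len(n))
      blocks[[length(blocks) + 1]] <- .exon_space_blocks(ex, s, fl, ids, tissue)
    }
    # uniform intergenic/genomic noise
    n_noise <- round(truth$noise_rate * total_fragments)
    if (n_noise > 0) {
      ci <- sample.int(nrow(model$genome), n_noise, replace = TRUE,
                       prob = model$genome$length)
      s <- floor(stats::runif(n_noise) * (model$genome$length[ci] - fl))
      blocks[[length(blocks) + 1]] <-
        data.frame(fragment_id = sprintf("%s|noise|%d", tissue,
                                         seq_len(n_noise)),
                   segment = 1L, chrom = model$genome$chrom[ci], strand = "*",
                   start = s, end = s + fl, stringsAsFactors = FALSE)
    }
    # planted spliced fragments across a junction (donor, acceptor)
    spliced <- function(chrom, donor, acceptor, n, tag) {
      a <- 10 + ((seq_len(n) - 1) %% (fl - 20))
      data.frame(fragment_id = rep(sprintf("%s|%s|%d", tissue, tag,
                                           seq_len(n)), each = 2),
                 segment = 1L, chrom = chrom, strand = "*",
                 start = as.vector(rbind(donor - a, acceptor)),
                 end = as.vector(rbind(donor, acceptor + (fl - a))),
                 stringsAsFactors = FALSE)
    }
    plant <- function(tab, id_cols, tag) {
      tab <- tab[tab$tissue == tissue, , drop = FALSE]
      for (r in seq_len(nrow(tab))) {
        chrom <- model$loci$chrom[match(tab[[id_cols]][r],
                                        model$loci$locus_id)]
        blocks[[length(blocks) + 1]] <<-
          spliced(chrom, tab$donor[r], tab$acceptor[r], tab$n_fragments[r],
                  sprintf("%s%d", tag, r))
      }
    }
    if (!is.null(truth$chimeras)) plant(truth$chimeras, "or_id", "chim")
    if (!is.null(truth$internal)) plant(truth$internal, "locus_id", "spl")
    # support-1 junction noise
    if (truth$noise_junctions > 0) {
      for (r in seq_len(truth$noise_junctions)) {
        ci <- sample.int(nrow(model$genome), 1,
                         prob = model$genome$length)
        s <- floor(stats::runif(1) * (model$genome$length[ci] - fl - 2100))
        gap <- 200 + floor(stats::runif(1) * 1800)
        a <- 10 + floor(stats::runif(1) * (fl - 20))
        blocks[[length(blocks) + 1]] <-
          data.frame(fragment_id = sprintf("%s|jnoise|%d", tissue, r),
                     segment = 1L, chrom = model$genome$chrom[ci],
                     strand = "*",
                     start = c(s, s + a + gap),
                     end = c(s + a, s + a + gap + (fl - a)),
                     stringsAsFactors = FALSE)
      }
    }
    b <- do.call(rbind, blocks)
    if (is.null(b))
      b <- data.frame(fragment_id = character(), segment = integer(),
                      chrom = character(), strand = character(),
                      start = numeric(), end = numeric())
    alignment_set(tissue, b, total_mapped = total_fragments)
  })
}

.write_gtf <- function(model, path) {
  lines <- character(0)
  for (i in seq_len(nrow(model$loci))) {
    q <- model$loci[i, ]
    ex <- model$exons[model$exons$locus_id == q$locus_id, ]
    at <- sprintf('gene_id "%s"; transcript_id "%s.1"; gene_name "%s";',
                  q$locus_id, q$locus_id, q$symbol)
    lines <- c(lines, sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                              ex$chrom, as.integer(ex$start + 1),
                              as.integer(ex$end), q$strand, at))
    if (!is.na(q$orf_start)) {
      cs <- pmax(ex$start, q$orf_start); ce <- pmin(ex$end, q$orf_end)
      keep <- ce > cs
      lines <- c(lines, sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                ex$chrom[keep], as.integer(cs[keep] + 1),
                                as.integer(ce[keep]), q$strand, at))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulation fixture to disk
#'
#' GTF + biotype TSV + one BED12 per tissue + truth TSV + a YAML manifest
#' recording seeds and denominators, so the whole study round-trips through
#' [read_fixture()].
#'
#' @param annotation Result of [build_toy_annotation()].
#' @param truth A `truth_table`.
#' @param aligns Named list of `alignment_set`s (names = tissues).
#' @param dir Output directory.
#' @param overwrite Refuse to write into a non-empty directory unless TRUE.
#' @param seed Seed to record in the manifest.
#' @export
write_fixture <- function(annotation, truth, aligns, dir, overwrite = FALSE,
                          seed = NA) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    .stopf("directory %s is not empty (use overwrite = TRUE)", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- annotation$model
  .write_gtf(model, file.path(dir, "model.gtf"))
  utils::write.table(annotation$biotypes, file.path(dir, "biotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(truth$expr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  beds <- character(0)
  for (ts in names(aligns)) {
    f <- sprintf("%s.bed", ts)
    write_bed12(aligns[[ts]], file.path(dir, f))
    beds[ts] <- f
  }
  manifest <- list(
    seed = seed,
    genome = stats::setNames(as.list(model$genome$length),
                             model$genome$chrom),
    files = c(list(gtf = "model.gtf", biotypes = "biotypes.tsv",
                   truth = "truth.tsv"), as.list(beds)),
    total_mapped = lapply(aligns, function(a) a$total_mapped),
    noise_rate = truth$noise_rate)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a simulation fixture back
#'
#' @param dir Fixture directory written by [write_fixture()].
#' @return List with `model`, `biotypes`, `truth` (expr data.frame) and
#'   `aligns` (named list of `alignment_set`s).
#' @export
read_fixture <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  genome <- data.frame(chrom = names(manifest$genome),
                       length = as.numeric(unlist(manifest$genome)),
                       stringsAsFactors = FALSE)
  model <- read_gene_model(file.path(dir, manifest$files$gtf),
                           biotypes = file.path(dir, manifest$files$biotypes),
                           genome = genome)
  truth <- utils::read.table(file.path(dir, manifest$files$truth),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  tissues <- names(manifest$total_mapped)
  aligns <- lapply(tissues, function(ts)
    read_alignments(file.path(dir, manifest$files[[ts]]), tissue = ts,
                    total_mapped = manifest$total_mapped[[ts]]))
  names(aligns) <- tissues
  list(model = model,
       biotypes = utils::read.table(file.path(dir, manifest$files$biotypes),
                                    sep = "\t", stringsAsFactors = FALSE,
                                    col.names = c("symbol", "biotype")),
       truth = truth, aligns = aligns)
}
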