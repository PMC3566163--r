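test_that("GTF exons are unioned per locus with 1-based to 0-based conversion", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G"; transcript_id "G.1";',
    'chr1\tsrc\texon\t151\t300\t.\t+\t.\tgene_id "G"; transcript_id "G.1";'),
    gtf)
  m <- read_gene_model(gtf, genome = data.frame(chrom = "chr1", length = 1e4))
  expect_equal(nrow(m$loci), 1)
  expect_equal(m$exons$start, 100)
  expect_equal(m$exons$end, 300)
  expect_equal(unname(union_exon_length(m, "G")), 200)
  expect_equal(m$loci$biotype, "non_or")  # unknown symbols default
})

test_that("an empty GTF stream yields a model with no loci", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(character(0), gtf)
  m <- read_gene_model(gtf)
  expect_s3_class(m, "gene_model")
  expect_equal(nrow(m$loci), 0)
})

test_that("biotype table assigns OR biotypes and CDS records become ORFs", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1001\t2200\t.\t+\t.\tgene_id "OR7E24"; gene_name "OR7E24";',
    'chr1\tsrc\tCDS\t1101\t2039\t.\t+\t.\tgene_id "OR7E24"; gene_name "OR7E24";',
    'chr1\tsrc\texon\t5001\t5400\t.\t-\t.\tgene_id "OR7E19P"; gene_name "OR7E19P";'),
    gtf)
  bt <- data.frame(symbol = c("OR7E24", "OR7E19P"),
                   biotype = c("or_gene", "or_pseudogene"))
  m <- read_gene_model(gtf, biotypes = bt)
  expect_equal(m$loci$biotype[m$loci$symbol == "OR7E24"], "or_gene")
  expect_equal(m$loci$orf_start[m$loci$symbol == "OR7E24"], 1100)
  expect_equal(m$loci$orf_end[m$loci$symbol == "OR7E24"], 2039)
  # pseudogenes never carry an ORF
  expect_true(is.na(m$loci$orf_start[m$loci$symbol == "OR7E19P"]))
})

test_that("exons outside chromosome bounds are rejected", {
  expect_error(
    gene_model(genome = data.frame(chrom = "chr1", length = 1000),
               loci = data.frame(locus_id = "G", symbol = "G", chrom = "chr1",
                                 strand = "+", biotype = "non_or"),
               exons = data.frame(locus_id = "G", start = 500, end = 1500)),
    "chromosome bounds")
})

test_that("union_exon_length handles overlap, disjoint exons, and matches a
          base-by-base oracle", {
  mk <- function(starts, ends) {
    gene_model(genome = data.frame(chrom = "c", length = 1e4),
               loci = data.frame(locus_id = "G", symbol = "G", chrom = "c",
                                 strand = "+", biotype = "non_or"),
               exons = data.frame(locus_id = "G", start = starts, end = ends))
  }
  expect_equal(unname(union_exon_length(mk(0, 1000))), 1000)
  expect_equal(unname(union_exon_length(mk(c(0, 50), c(100, 150)))), 150)
  expect_equal(unname(union_exon_length(mk(c(0, 200), c(100, 300)))), 200)
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    s <- sort(sample(0:9000, n))
    e <- pmin(10000, s + sample(50:2000, n, replace = TRUE))
    m <- mk(s, e)
    v <- logical(10000)
    for (i in seq_len(n)) v[(s[i] + 1):e[i]] <- TRUE
    expect_equal(unname(union_exon_length(m)), sum(v))
  }
})

test_that("intergenic_space excludes spans plus flanks and complements the
          masked space exactly", {
  m <- gene_model(genome = data.frame(chrom = "c", length = 1e5),
                  loci = data.frame(locus_id = "G", symbol = "G", chrom = "c",
                                    strand = "+", biotype = "non_or"),
                  exons = data.frame(locus_id = "G", start = 40000,
                                     end = 50000))
  sp <- intergenic_space(m, flank = 10000)
  expect_equal(sp$start, c(0, 60000))
  expect_equal(sp$end, c(30000, 100000))
  # no loci -> whole genome
  empty <- gene_model(genome = data.frame(chrom = "c", length = 1e5),
                      loci = data.frame(locus_id = character(),
                                        symbol = character(),
                                        chrom = character(),
                                        strand = character(),
                                        biotype = character())[0, ],
                      exons = data.frame(locus_id = "x", start = 1,
                                         end = 2)[0, ])
  sp0 <- intergenic_space(empty)
  expect_equal(sp0$start, 0)
  expect_equal(sp0$end, 1e5)
  # gene spanning the whole chromosome -> empty set
  all_g <- gene_model(genome = data.frame(chrom = "c", length = 1e4),
                      loci = data.frame(locus_id = "G", symbol = "G",
                                        chrom = "c", strand = "+",
                                        biotype = "non_or"),
                      exons = data.frame(locus_id = "G", start = 0,
                                         end = 1e4))
  expect_equal(nrow(intergenic_space(all_g, flank = 0)), 0)
  # intergenic + masked partition the genome (set algebra, random models)
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(1:5, 1)
    s <- sort(sample(seq(0, 9e4, by = 100), n))
    mm <- gene_model(genome = data.frame(chrom = "c", length = 1e5),
                     loci = data.frame(locus_id = paste0("G", 1:n),
                                       symbol = paste0("G", 1:n), chrom = "c",
                                       strand = "+", biotype = "non_or"),
                     exons = data.frame(locus_id = paste0("G", 1:n),
                                        start = s, end = s + 500))
    fl <- sample(c(0, 1000, 5000), 1)
    sp <- intergenic_space(mm, flank = fl)
    inter_bp <- sum(sp$end - sp$start)
    mask <- GenomicRanges::reduce(GenomicRanges::GRanges(
      "c", IRanges::IRanges(pmax(0, s - fl) + 1, pmin(1e5, s + 500 + fl))))
    expect_equal(inter_bp + sum(GenomicRanges::width(mask)), 1e5)
  }
})

test_that("adjacent_loci returns nearest non-overlapping neighbours and is
          symmetric", {
  m <- toy_model_abc()
  nb <- adjacent_loci(m, "B")
  expect_equal(nb$upstream$locus_id, "A")
  expect_equal(nb$downstream$locus_id, "C")
  # symmetry
  expect_equal(adjacent_loci(m, "A")$downstream$locus_id, "B")
  expect_equal(adjacent_loci(m, "C")$upstream$locus_id, "B")
  expect_null(adjacent_loci(m, "A")$upstream)
  expect_error(adjacent_loci(m, "Z"), "not in model")
  # overlapping loci are skipped as neighbours
  m2 <- gene_model(
    genome = data.frame(chrom = "c", length = 1e5),
    loci = data.frame(locus_id = c("A", "OV1", "B", "OV2"),
                      symbol = c("A", "OV1", "B", "OV2"), chrom = "c",
                      strand = "+", biotype = "non_or"),
    exons = data.frame(locus_id = c("A", "OV1", "B", "OV2"),
                       start = c(1000, 4500, 5000, 5500),
                       end = c(2000, 5600, 6000, 6500)))
  nb2 <- adjacent_loci(m2, "B")
  expect_equal(nb2$upstream$locus_id, "A")  # OV1/OV2 overlap B
  expect_null(nb2$downstream)
  # max_distance cuts far neighbours
  expect_null(adjacent_loci(m2, "B", max_distance = 1000)$upstream)
})

test_that("OR symbols parse per HORDE nomenclature and round-trip", {
  p <- parse_or_symbol("OR7E19P")
  expect_equal(p$family, 7)
  expect_equal(p$subfamily, "E")
  expect_equal(p$member, "19")
  expect_true(p$is_pseudogene)
  p2 <- parse_or_symbol("OR51E2")
  expect_equal(p2$family, 51)
  expect_false(p2$is_pseudogene)
  expect_error(parse_or_symbol("TRIM58"), "not an OR symbol")
  # round-trip
  syms <- c("OR2A4", "OR7E24", "OR10J6P", "OR52K3P")
  p3 <- parse_or_symbol(syms)
  expect_equal(sprintf("OR%d%s%s%s", p3$family, p3$subfamily, p3$member,
                       ifelse(p3$is_pseudogene, "P", "")), syms)
})
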