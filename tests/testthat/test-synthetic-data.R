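test_that("toy annotations satisfy the gene-model invariants and are
          seed-deterministic", {
  ann <- build_toy_annotation(toy_config(), seed = 11)
  m <- ann$model
  expect_s3_class(m, "gene_model")
  expect_equal(sum(m$loci$biotype == "or_gene"), 20)
  expect_equal(sum(m$loci$biotype == "or_pseudogene"), 10)
  expect_equal(sum(m$loci$biotype == "non_or"), 30)
  # OR genes single-exon with contained ORFs; pseudogenes never have ORFs
  or <- m$loci[m$loci$biotype == "or_gene", ]
  expect_true(all(or$n_exons == 1))
  expect_true(all(or$orf_end - or$orf_start == 939))
  expect_true(all(is.na(m$loci$orf_start[m$loci$biotype == "or_pseudogene"])))
  # the read-through pair sits 2 kb apart on the first chromosome
  rt <- ann$readthrough
  up <- m$loci[match(rt["upstream"], m$loci$locus_id), ]
  orr <- m$loci[match(rt["or"], m$loci$locus_id), ]
  expect_equal(orr$span_start - up$span_end, 2000)
  # deterministic regeneration
  ann2 <- build_toy_annotation(toy_config(), seed = 11)
  expect_identical(ann$model, ann2$model)
  # no ORs at all is a legal edge case
  ann0 <- build_toy_annotation(toy_config(n_or = 0, n_or_pseudo = 0,
                                          readthrough = FALSE), seed = 1)
  expect_equal(sum(ann0$model$loci$biotype != "non_or"), 0)
})

test_that("simulated fragment counts follow the lambda formula and the
          simulation is seed-deterministic", {
  ann <- build_toy_annotation(toy_config(), seed = 11)
  tr <- make_truth(ann, tissues = "t1", seed = 2)
  a1 <- simulate_tissue(ann$model, tr, "t1", total_fragments = 2e5, seed = 5)
  a2 <- simulate_tissue(ann$model, tr, "t1", total_fragments = 2e5, seed = 5)
  expect_identical(a1$blocks, a2$blocks)
  expect_equal(a1$total_mapped, 2e5)
  a3 <- simulate_tissue(ann$model, tr, "t1", total_fragments = 2e5, seed = 6)
  expect_false(identical(a1$blocks, a3$blocks))
  # lambda: a single 1000-bp locus at 10 FPKM and 1e6 fragments -> mean 10
  m1 <- gene_model(genome = data.frame(chrom = "c", length = 1e5),
                   loci = data.frame(locus_id = "G", symbol = "G",
                                     chrom = "c", strand = "+",
                                     biotype = "non_or"),
                   exons = data.frame(locus_id = "G", start = 1000,
                                      end = 2000))
  tr1 <- truth_table(data.frame(target_id = "G", tissue = "t",
                                true_fpkm = 10))
  n <- vapply(1:80, function(s) {
    al <- simulate_tissue(m1, tr1, "t", total_fragments = 1e6, seed = s)
    length(unique(al$blocks$fragment_id))
  }, 1)
  expect_gt(mean(n), 10 - 3 * sqrt(10 / 80))
  expect_lt(mean(n), 10 + 3 * sqrt(10 / 80))
  # zero truth and zero noise -> no fragments at all
  tr0 <- truth_table(data.frame(target_id = "G", tissue = "t",
                                true_fpkm = 0))
  a0 <- simulate_tissue(m1, tr0, "t", total_fragments = 1e6, seed = 1)
  expect_equal(nrow(a0$blocks), 0)
  # fragments longer than the exon union name the offending locus
  expect_error(simulate_tissue(m1, tr1, "t", total_fragments = 1e6,
                               fragment_length = 1500, seed = 1), "G")
})

test_that("simulated fragments stay inside the exon union and splice
          across introns", {
  m <- gene_model(genome = data.frame(chrom = "c", length = 1e5),
                  loci = data.frame(locus_id = "G", symbol = "G", chrom = "c",
                                    strand = "+", biotype = "non_or"),
                  exons = data.frame(locus_id = "G",
                                     start = c(1000, 5000, 9000),
                                     end = c(1100, 5120, 9100)))
  tr <- truth_table(data.frame(target_id = "G", tissue = "t",
                               true_fpkm = 300))
  al <- simulate_tissue(m, tr, "t", total_fragments = 1e6, seed = 9)
  expect_gt(nrow(al$blocks), 50)
  exonic <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "c", IRanges::IRanges(m$exons$start + 1, m$exons$end)))
  bg <- GenomicRanges::GRanges("c", IRanges::IRanges(al$blocks$start + 1,
                                                     al$blocks$end))
  # every aligned base is exonic
  expect_equal(sum(GenomicRanges::width(GenomicRanges::setdiff(bg, exonic))),
               0)
  # per-fragment aligned bases always total the fragment length
  per_frag <- tapply(al$blocks$end - al$blocks$start, al$blocks$fragment_id,
                     sum)
  expect_true(all(per_frag == 75))
  # spliced fragments exist (multi-block)
  expect_gt(max(table(al$blocks$fragment_id)), 1)
})

test_that("noise-only simulation gives genes and length-matched intergenic
          regions statistically indistinguishable counts", {
  ann <- null_annotation(n_loci = 300, chrom_length = 6e6, seed = 21)
  tr <- truth_table(data.frame(target_id = character(), tissue = character(),
                               true_fpkm = numeric()),
                    noise_rate = 0.01)
  al <- simulate_tissue(ann$model, tr, "t", total_fragments = 2e6, seed = 22)
  gene_v <- quantify_loci(al, ann$model)
  space <- intergenic_space(ann$model, flank = 2000)
  regs <- sample_background_regions(space, union_exon_length(ann$model),
                                    seed = 23)
  reg_v <- quantify_regions(al, regs)
  # chi-square on pooled count classes
  brk <- c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf)
  og <- table(cut(gene_v$count, brk))
  oi <- table(cut(reg_v$count, brk))
  keep <- (og + oi) > 0
  p <- suppressWarnings(stats::chisq.test(rbind(og[keep], oi[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("fixtures round-trip through disk exactly", {
  ann <- build_toy_annotation(toy_config(), seed = 31)
  tr <- make_truth(ann, tissues = c("t1", "t2"), seed = 32)
  als <- list(t1 = simulate_tissue(ann$model, tr, "t1", 1e5, seed = 33),
              t2 = simulate_tissue(ann$model, tr, "t2", 1e5, seed = 34))
  dir <- file.path(tempdir(), "fixture_rt")
  unlink(dir, recursive = TRUE)
  write_fixture(ann, tr, als, dir, seed = 31)
  # refuses to clobber without the flag
  expect_error(write_fixture(ann, tr, als, dir), "not empty")
  fx <- read_fixture(dir)
  expect_equal(fx$model$loci$locus_id, ann$model$loci$locus_id)
  expect_equal(fx$model$exons, ann$model$exons)
  expect_equal(fx$model$loci$orf_start, ann$model$loci$orf_start)
  expect_equal(fx$model$loci$biotype, ann$model$loci$biotype)
  for (ts in names(als)) {
    a <- als[[ts]]$blocks[order(als[[ts]]$blocks$fragment_id,
                                als[[ts]]$blocks$segment,
                                als[[ts]]$blocks$start), ]
    b <- fx$aligns[[ts]]$blocks[order(fx$aligns[[ts]]$blocks$fragment_id,
                                      fx$aligns[[ts]]$blocks$segment,
                                      fx$aligns[[ts]]$blocks$start), ]
    expect_equal(b$start, a$start)
    expect_equal(b$end, a$end)
    expect_equal(fx$aligns[[ts]]$total_mapped, als[[ts]]$total_mapped)
  }
  # manifest lists every file in the directory
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_setequal(c(unlist(man$files), "manifest.yaml"), list.files(dir))
})
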