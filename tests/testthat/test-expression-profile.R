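toy_mat <- function() {
  f <- matrix(c(0.5, 0.0, 0.05,
                0.2, 0.3, 0.15,
                0.05, 0.02, 0.0,
                0.0, 0.0, 0.0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("T", 1:3)))
  expression_matrix(f, biotype = "or_gene")
}

test_that("detection calls partition every cell at the band boundaries", {
  mat <- toy_mat()
  calls <- classify_calls(mat)
  expect_equal(nrow(calls), 12)
  expect_equal(sort(unique(calls$call)),
               c("expressed", "not_detected", "potential"))
  pick <- function(t, g) calls$call[calls$tissue == t & calls$target_id == g]
  expect_equal(pick("T3", "g2"), "expressed")    # 0.15 > 0.1
  expect_equal(pick("T3", "g1"), "potential")    # 0.05 in [0.01, 0.1]
  expect_equal(pick("T2", "g3"), "potential")    # 0.02
  expect_equal(pick("T1", "g4"), "not_detected")
  # boundary: exactly 0.1 is potential, exactly 0.01 is potential
  m2 <- expression_matrix(matrix(c(0.1, 0.01, 0.005, 0.11), 4, 1,
                                 dimnames = list(letters[1:4], "T")))
  c2 <- classify_calls(m2)
  expect_equal(c2$call, c("potential", "potential", "not_detected",
                          "expressed"))
  # counts per class sum to matrix size
  expect_equal(sum(table(calls$call)), 12)
})

test_that("profile enumerates expressed counts, exclusives, cumulative sums
          and the summed-FPKM ranking on the toy matrix", {
  rep <- profile_expression(toy_mat())
  expect_equal(rep$counts$or_gene, c(2, 1, 1))
  expect_equal(rep$exclusive$T1, "g1")
  expect_equal(rep$exclusive$T2, character(0))
  expect_equal(rep$exclusive$T3, character(0))
  expect_equal(unname(rep$cumulative), c(0.75, 0.32, 0.20))
  top <- rep$ranking$target_id[rep$ranking$top]
  expect_setequal(top, c("g1", "g2"))
  expect_equal(rep$ranking$summed_fpkm[rep$ranking$target_id == "g1"], 0.55)
  expect_equal(rep$ranking$summed_fpkm[rep$ranking$target_id == "g2"], 0.65)
  # exclusive lists are disjoint across tissues
  expect_lte(length(unlist(rep$exclusive)),
             length(unique(unlist(rep$exclusive))))
})

test_that("profile is equivariant under tissue permutation", {
  mat <- toy_mat()
  perm <- c("T3", "T1", "T2")
  mp <- expression_matrix(mat$fpkm[, perm], biotype = "or_gene")
  r1 <- profile_expression(mat)
  r2 <- profile_expression(mp)
  expect_equal(r2$cumulative[perm][colnames(mat$fpkm)],
               r1$cumulative[colnames(mat$fpkm)])
  expect_equal(r2$exclusive[colnames(mat$fpkm)],
               r1$exclusive[colnames(mat$fpkm)])
  expect_equal(r2$ranking, r1$ranking)
})

test_that("replicate overlap counts window targets detected in the other
          set", {
  vA <- expression_vector(data.frame(target_id = c("a", "b", "c", "d"),
                                     count = c(2, 3, 5, 400),
                                     length = 1000), "A", 1e8)
  # a,b,c in window (0.02..0.05), d far above
  fB <- c(a = 0.02, b = 0.5, c = 0, d = 4)
  vB <- expression_vector(data.frame(target_id = names(fB),
                                     count = fB * 100, length = 1000), "B",
                          1e8)
  ov <- replicate_overlap(vA, vB)
  expect_equal(ov$n_window, 3)
  expect_equal(ov$fraction, 2 / 3)
  expect_equal(replicate_overlap(vA, vA)$fraction, 1)
  vB0 <- expression_vector(data.frame(target_id = names(fB), count = 0,
                                      length = 1000), "B0", 1e8)
  expect_equal(replicate_overlap(vA, vB0)$fraction, 0)
  expect_error(replicate_overlap(vB0, vA), "window")
})

test_that("R^2 matches a hand regression and is scale invariant", {
  vec <- function(ts, fpkm) {
    expression_vector(data.frame(target_id = paste0("g", seq_along(fpkm)),
                                 count = fpkm, length = 1000), ts, 1e6)
  }
  a <- c(0.1, 1, 10, 100)
  expect_equal(correlation_r2(vec("a", a), vec("b", a)), 1)
  expect_equal(correlation_r2(vec("a", a), vec("b", 2 * a)), 1)
  b <- c(0.2, 0.5, 30, 40)
  r2_hand <- stats::cor(log10(a), log10(b))^2
  expect_equal(correlation_r2(vec("a", a), vec("b", b)), r2_hand)
  expect_equal(correlation_r2(vec("a", a), vec("b", b), log_space = FALSE),
               stats::cor(a, b)^2)
  expect_error(correlation_r2(vec("a", c(0.001, 0.002, 1, 2)),
                              vec("b", c(0.001, 0.002, 1, 2))),
               "fewer than 3")
})

test_that("neighbour dependence fractions follow the enumerated toy layouts", {
  # 4 ORs: OR_a, OR_b flanked by non-OR genes; OR_c, OR_d an isolated
  # OR-only pair. OR_a, OR_b, OR_c expressed.
  m <- gene_model(
    genome = data.frame(chrom = c("c", "d"), length = 1e6),
    loci = data.frame(
      locus_id = c("G1", "ORa", "G2", "ORb", "G3", "ORc", "ORd"),
      symbol = c("G1", "ORa", "G2", "ORb", "G3", "ORc", "ORd"),
      chrom = c(rep("c", 5), "d", "d"),
      strand = "+",
      biotype = c("non_or", "or_gene", "non_or", "or_gene", "non_or",
                  "or_gene", "or_pseudogene")),
    exons = data.frame(
      locus_id = c("G1", "ORa", "G2", "ORb", "G3", "ORc", "ORd"),
      start = c(1000, 5000, 9000, 13000, 17000, 500000, 504000),
      end = c(2000, 6000, 10000, 14000, 18000, 501000, 505000)))
  f <- matrix(c(1, 1, 1, 0), 4, 1,
              dimnames = list(c("ORa", "ORb", "ORc", "ORd"), "T"))
  calls <- classify_calls(expression_matrix(f, biotype = "or_gene"))
  nd <- neighbor_dependence(m, calls)
  # expressed ORs: a, b, c; with a non-OR neighbour: a, b -> 2/3
  expect_equal(nd$frac_expressed_with_non_or_neighbor, 2 / 3)
  # OR-only neighbourhood: c, d; expressed among them: c -> 1/2
  expect_equal(nd$frac_or_neighbor_only_expressed, 1 / 2)
})

test_that("subfamily composition counts families above the cutoff", {
  x <- c(OR7E19P = 2.6, OR4N1P = 2.2, OR7E5P = 1.0)
  comp <- subfamily_composition(x)
  expect_equal(unname(comp["7E"]), 2 / 3)
  expect_equal(unname(subfamily_composition(c(OR7E19P = 2.6))["7E"]), 1)
  expect_equal(length(subfamily_composition(c(OR7E19P = 0.4))), 0)
  # merged labels attribute via the first member; junk symbols warn
  expect_warning(
    comp2 <- subfamily_composition(c("OR2A1/OR2A42" = 1, JUNK = 2)),
    "unparsable")
  expect_equal(unname(comp2["2A"]), 1)
})

test_that("panel subsetting preserves tissue order and reports missing
          genes", {
  mat <- toy_mat()
  sub <- subset_panel(mat, c("g2", "g1"))
  expect_equal(rownames(sub$fpkm), c("g2", "g1"))
  expect_equal(colnames(sub$fpkm), colnames(mat$fpkm))
  expect_warning(sub2 <- subset_panel(mat, c("g1", "GNAL")), "GNAL")
  expect_equal(rownames(sub2$fpkm), "g1")
  expect_warning(sub3 <- subset_panel(mat, "ADCY3"), "absent")
  expect_equal(nrow(sub3$fpkm), 0)
})
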