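# Shared study constructors and independent oracles.

# Annotation of n identical single-exon loci (length exon_len) used by the
# background-null studies: 10-kb loci give a 0.05-FPKM quantum per fragment
# at 2e6 mapped fragments, fine enough to resolve the 0.01-0.15 band.
null_annotation <- function(n_loci, chrom_length, seed,
                            exon_len = 10000, gap = c(24000, 30000)) {
  build_toy_annotation(
    toy_config(n_chrom = 2, chrom_length = chrom_length,
               n_non_or = 0, n_or = n_loci, n_or_pseudo = 0,
               or_exon_length = exon_len, or_orf_length = 939,
               gap = gap, or_cluster_size = 0, readthrough = FALSE),
    seed = seed)
}

# Brute-force base-by-base overlap oracle for fragment assignment: a fragment
# counts toward a locus iff any aligned base is exonic for that locus.
bf_assign_oracle <- function(aligns, model) {
  glen <- stats::setNames(model$genome$length, model$genome$chrom)
  b <- aligns$blocks
  counts <- stats::setNames(integer(nrow(model$loci)), model$loci$locus_id)
  for (i in seq_len(nrow(model$loci))) {
    id <- model$loci$locus_id[i]
    ex <- model$exons[model$exons$locus_id == id, ]
    v <- logical(glen[[ex$chrom[1]]])
    for (r in seq_len(nrow(ex))) v[(ex$start[r] + 1):ex$end[r]] <- TRUE
    cs <- c(0, cumsum(v))  # exonic bases in [s, e) = cs[e+1] - cs[s+1]
    on_chr <- b$chrom == ex$chrom[1]
    exonic_bases <- cs[b$end[on_chr] + 1] - cs[b$start[on_chr] + 1]
    hit <- tapply(exonic_bases > 0, b$fragment_id[on_chr], any)
    counts[id] <- sum(hit)
  }
  counts
}

# Codon-scanning oracle for fusion frames: builds actual nucleotide
# sequences (alphabet A/C/G, so no stop codons arise), fuses the first c_u
# upstream coding bases to the OR ORF from offset c_a, translates both, and
# declares the fusion in frame iff the OR protein's C-terminal peptide
# reappears at the end of the fused protein.
codon_fusion_oracle <- function(c_u, c_a, seed = 42) {
  set.seed(seed)
  up <- paste(sample(c("A", "C", "G"), 900, replace = TRUE), collapse = "")
  or <- paste(sample(c("A", "C", "G"), 939, replace = TRUE), collapse = "")
  fused <- paste0(substr(up, 1, c_u), substr(or, c_a + 1, nchar(or)))
  fused <- substr(fused, 1, 3 * (nchar(fused) %/% 3))
  aa_or <- as.character(Biostrings::translate(Biostrings::DNAString(or)))
  aa_f <- as.character(Biostrings::translate(Biostrings::DNAString(fused)))
  tail_or <- substr(aa_or, nchar(aa_or) - 9, nchar(aa_or))
  endsWith(aa_f, tail_or)
}

# Expected threshold_curve from Poisson closed form for a zero+expressed
# mixture of identical loci (used as the analytic oracle for the
# crossing study). q = FPKM per fragment; lambda_e = signal means of the
# expressed loci.
expected_curve_oracle <- function(mu0, lambda_e, n_zero, q, edges) {
  B <- length(edges) - 1
  G <- I <- numeric(B)
  kmax <- 200000
  k_of <- function(edge) match(TRUE, (1:kmax) * q >= edge)  # float-consistent
  for (b in seq_len(B)) {
    k1 <- k_of(edges[b]); k2 <- k_of(edges[b + 1]); if (is.na(k2)) k2 <- kmax
    pz <- stats::ppois(k1 - 1, mu0, lower.tail = FALSE) -
      stats::ppois(k2 - 1, mu0, lower.tail = FALSE)
    pe <- mean(stats::ppois(k1 - 1, lambda_e + mu0, lower.tail = FALSE) -
                 stats::ppois(k2 - 1, lambda_e + mu0, lower.tail = FALSE))
    G[b] <- n_zero * pz + length(lambda_e) * pe
    I[b] <- (n_zero + length(lambda_e)) * pz
  }
  fdr <- ifelse(G == 0, 0, pmin(1, I / G))
  at <- G * (1 - fdr)
  cg <- rev(cumsum(rev(G))); ci <- rev(cumsum(rev(I)))
  data.frame(edge = edges[-(B + 1)],
             FDR = ifelse(cg == 0, 0, pmin(1, ci / cg)),
             FNR = cumsum(c(0, at[-B])) / sum(at))
}

# tiny hand-built gene model used across unit tests
toy_model_abc <- function() {
  gene_model(
    genome = data.frame(chrom = "chr1", length = 100000),
    loci = data.frame(
      locus_id = c("A", "B", "C"), symbol = c("A", "B", "C"),
      chrom = "chr1", strand = "+",
      biotype = c("non_or", "or_gene", "non_or"),
      orf_start = c(NA, 5100, NA), orf_end = c(NA, 5700, NA)),
    exons = data.frame(
      locus_id = c("A", "B", "C"),
      start = c(1000, 5000, 9000), end = c(2000, 6000, 10000)))
}

# Models for chimera tests: upstream multi-exon gene U ("+", 3 exons,
# spliced ORF) followed by a single-exon OR with a 939-bp ORF, plus a minus-
# strand mirror pair on another chromosome.
chimera_model <- function() {
  gene_model(
    genome = data.frame(chrom = c("c", "d"), length = 1e5),
    loci = data.frame(
      locus_id = c("U", "OR1", "V", "OR2", "N"),
      symbol = c("U", "OR1A1", "V", "OR2B2", "N"),
      chrom = c("c", "c", "d", "d", "c"),
      strand = c("+", "+", "-", "-", "+"),
      biotype = c("non_or", "or_gene", "non_or", "or_gene", "non_or"),
      orf_start = c(1050, 10100, 51050, 40100, NA),
      orf_end = c(3550, 11039, 53550, 41039, NA)),
    exons = data.frame(
      locus_id = c("U", "U", "U", "OR1", "V", "V", "V", "OR2", "N"),
      start = c(1000, 2000, 3000, 10000, 51000, 52000, 53000, 40000, 20000),
      end = c(1500, 2500, 3600, 11200, 51500, 52500, 53600, 41200, 21000)))
}

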