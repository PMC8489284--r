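make_panel <- function(seqs, atg_col = NULL) {
  promoter_panel(setNames(seqs, sprintf("L%02d", seq_along(seqs))), atg_col)
}

test_that("variant calling finds exactly the polymorphic columns", {
  p <- make_panel(c("ACGTA", "ACGTA", "ACCTA"))
  snps <- call_variant_sites(p)
  expect_length(snps$positions, 1)
  expect_equal(snps$columns, 3L)
  expect_equal(unname(snps$alleles[, 1]), c("G", "G", "C"))
  # identical panel: no variants
  expect_length(call_variant_sites(make_panel(rep("ACGTA", 3)))$positions, 0)
  expect_error(promoter_panel(c(a = "ACGT", b = "ACG")), "same length")
})

test_that("ATG-relative coordinates skip zero", {
  # 5-column panel with ATG column = 5: columns map to -4..-1, +1
  p <- make_panel(c("ACGTA", "TCGTA", "ACGAA"), atg_col = 5)
  snps <- call_variant_sites(p)
  expect_equal(snps$positions, c(-4L, -1L))
})

test_that("gap/N columns follow the complete-deletion policy", {
  p <- make_panel(c("ANGTA", "ACGTA", "ACCTA"))
  snps <- call_variant_sites(p)           # column 2 unusable, 3 variant
  expect_equal(snps$columns, 3L)
  expect_equal(snps$L_effective, 4L)
  d <- nucleotide_diversity(p)
  expect_equal(d$L_effective, 4L)
  # pairwise deletion keeps per-pair information
  d2 <- nucleotide_diversity(p, policy = "pairwise")
  expect_true(is.finite(d2$pi))
})

test_that("pi matches the closed form for a single pair", {
  seqs <- c(strrep("A", 100), paste0(strrep("A", 99), "C"))
  expect_equal(nucleotide_diversity(make_panel(seqs))$pi, 0.01)
  expect_equal(nucleotide_diversity(make_panel(rep("ACGT", 4)))$pi, 0)
  expect_error(nucleotide_diversity(make_panel("ACGT")), "at least 2")
})

test_that("pi equals the brute-force pairwise oracle on random panels", {
  set.seed(40)
  for (i in 1:10) {
    n <- sample(3:6, 1); L <- sample(50:200, 1)
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    seqs <- vapply(seq_len(n), function(s) {
      x <- base
      k <- sample(0:5, 1)
      if (k > 0) {
        pos <- sample(L, k)
        x[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      }
      paste0(x, collapse = "")
    }, "")
    p <- make_panel(seqs)
    expect_equal(nucleotide_diversity(p)$pi, brute_pi(p$seqs))
  }
})

test_that("pi agrees with ape's pairwise distances", {
  p <- generate_promoter_panel(seed = 41)
  M <- do.call(rbind, strsplit(unname(tolower(p$seqs)), ""))
  rownames(M) <- names(p$seqs)
  d <- ape::dist.dna(ape::as.DNAbin(M), model = "raw",
                     pairwise.deletion = FALSE)
  expect_equal(nucleotide_diversity(p)$pi, mean(d), tolerance = 1e-12)
})

test_that("pi is invariant to reordering and to column duplication", {
  p <- generate_promoter_panel(seed = 42, n_seqs = 10)
  pi1 <- nucleotide_diversity(p)$pi
  perm <- make_panel(unname(p$seqs[sample(10)]))
  expect_equal(nucleotide_diversity(perm)$pi, pi1)
  doubled <- make_panel(paste0(unname(p$seqs), unname(p$seqs)))
  expect_equal(nucleotide_diversity(doubled)$pi, pi1)
})

test_that("haplotype labels are frequency-ordered with stable ties", {
  seqs <- c("AAA", "CCC", "CCC", "GGG", "GGG")
  hg <- group_haplotypes(call_variant_sites(make_panel(seqs)))
  # CCC (first of the two 2-frequency patterns) -> Hap1, GGG -> Hap2,
  # AAA (singleton) -> Hap3
  expect_equal(unname(hg$labels), c("Hap3", "Hap1", "Hap1", "Hap2", "Hap2"))
  # permuting the input changes labels only per the tie rule
  seqs2 <- seqs[c(4, 5, 1, 2, 3)]
  hg2 <- group_haplotypes(call_variant_sites(make_panel(seqs2)))
  expect_equal(unname(hg2$labels), c("Hap1", "Hap1", "Hap3", "Hap2", "Hap2"))
})

test_that("haplotype grouping is a partition with N-tolerant rescue", {
  # N at the single variant column, compatible with both patterns
  seqs <- c("ACGT", "ACGA", "ACGT", "ACGN")
  hg <- group_haplotypes(call_variant_sites(make_panel(seqs),
                                            policy = "pairwise"))
  expect_length(hg$labels, 4)
  expect_equal(unname(hg$labels[4]), "ambiguous")
  expect_lte(nrow(hg$patterns), 4)
  # N compatible with exactly one pattern is rescued to it
  seqs2 <- c("AAAA", "AACC", "AAAA", "AANC")
  hg2 <- group_haplotypes(call_variant_sites(make_panel(seqs2),
                                             policy = "pairwise"))
  expect_equal(unname(hg2$labels[4]), unname(hg2$labels[2]))
  # all identical -> a single haplotype
  one <- group_haplotypes(call_variant_sites(make_panel(rep("ACGT", 5))))
  expect_equal(nrow(one$patterns), 1)
  expect_true(all(one$labels == "Hap1"))
})

test_that("default fixture yields 4 haplotypes with the 6/2/1 structure", {
  panel <- generate_promoter_panel(seed = 1)
  snps <- call_variant_sites(panel)
  expect_length(snps$positions, 9)
  expect_true(all(c(-799L, -796L) %in% snps$positions))
  hg <- group_haplotypes(snps)
  expect_equal(nrow(hg$patterns), 4)
  expect_equal(hg$patterns$snps_vs_hap1, c(0L, 6L, 2L, 1L))
})

test_that("haplotype-trait association separates a shifted haplotype", {
  set.seed(43)
  labels <- setNames(rep(paste0("Hap", 1:4), each = 4),
                     sprintf("L%02d", 1:16))
  traits <- setNames(rnorm(16, 10, 0.5), names(labels))
  traits[labels == "Hap3"] <- traits[labels == "Hap3"] + 10 * 0.5
  res <- haplotype_association(labels, traits)
  expect_lt(res$anova$p, 0.05)
  g <- res$groups
  hap3_letters <- strsplit(g$letters[g$group == "Hap3"], "")[[1]]
  others <- unlist(strsplit(g$letters[g$group != "Hap3"], ""))
  expect_false(any(hap3_letters %in% others))
  # constant traits: everyone shares one letter
  const <- haplotype_association(labels, setNames(rep(5, 16), names(labels)))
  expect_true(all(const$groups$letters == "a"))
  # a haplotype with a single line is excluded with a warning
  labs2 <- labels; labs2[1] <- "Hap9"
  expect_warning(haplotype_association(labs2, traits), "Hap9")
})

test_that("promoter panel FASTA round-trips", {
  p <- generate_promoter_panel(seed = 44, n_seqs = 6)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_promoter_panel(p, path)
  back <- read_promoter_panel(path)
  expect_equal(back$seqs, p$seqs)
  expect_equal(nucleotide_diversity(back)$pi, nucleotide_diversity(p)$pi)
})
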