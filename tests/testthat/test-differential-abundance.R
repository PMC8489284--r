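simple_matches <- function(quant) {
  data.frame(peptide = quant$peptide, loci = quant$protein_id,
             specificity = "locus_unique", stringsAsFactors = FALSE)
}

test_that("channel normalisation undoes per-channel scaling", {
  q <- manual_quant(list(
    list(peptide = "AAAAAK", protein_id = "p1", ck = c(10, 20, 30),
         np = c(40, 50, 60)),
    list(peptide = "CCCCCK", protein_id = "p2", ck = c(5, 15, 25),
         np = c(35, 45, 55))))
  # equal-sum channels pass through unchanged
  qe <- q
  for (cc in c("CK1", "CK2", "CK3", "NP1", "NP2", "NP3"))
    qe[[cc]] <- qe[[cc]] * 100 / sum(qe[[cc]])
  expect_equal(normalize_channels(qe, "total_sum"), qe)
  # doubling one channel is fully removed (ratios recovered)
  q2 <- q
  q2$NP1 <- q2$NP1 * 2
  n1 <- normalize_channels(q, "total_sum")
  n2 <- normalize_channels(q2, "total_sum")
  expect_equal(n2$NP1 / n2$CK1, n1$NP1 / n1$CK1, tolerance = 1e-12)
  # identity and error modes
  expect_identical(normalize_channels(q, "none"), q)
  qz <- q; qz$CK1 <- c(0, 0)
  expect_error(normalize_channels(qz, "total_sum"), "all-zero")
})

test_that("protein quantification sums unique peptides and forms the ratio", {
  q <- manual_quant(list(
    list(peptide = "AAAAAK", protein_id = "p1", ck = c(1, 1, 1),
         np = c(2, 2, 2)),
    list(peptide = "CCCCCK", protein_id = "p1", ck = c(3, 3, 3),
         np = c(6, 6, 6)),
    list(peptide = "DDDDDK", protein_id = "p2", ck = c(1, 1, 1),
         np = c(1, 1, 1))))
  m <- simple_matches(q)
  m$specificity[3] <- "family_shared"   # p2 has no unique peptide
  quants <- quantify_proteins(q, m)
  expect_equal(quants$protein_id, "p1")
  expect_equal(quants$CK1, 4)           # additivity: 1 + 3
  expect_equal(quants$ratio, 2.0)
  expect_equal(quants$n_unique_peptides, 2L)
  expect_error(quantify_proteins(q, m[-1, ]), "specificity record")
})

test_that("fold-change thresholds are inclusive and conserve counts", {
  mk <- function(ratio) list(peptide = paste0("P", which(ratios == ratio)))
  ratios <- c(1.20, 1.00, 0.83, 1.19, 0.84, 3.0, 0.2)
  rows <- lapply(seq_along(ratios), function(i)
    list(peptide = paste0(strrep(LETTERS[i], 5), "K"),
         protein_id = paste0("p", i), ck = c(1, 1, 1),
         np = rep(ratios[i], 3)))
  q <- manual_quant(rows)
  quants <- quantify_proteins(q, simple_matches(q))
  calls <- call_pdrps(quants, pdrp_call_config())
  cls <- setNames(calls$reg_class, calls$protein_id)
  expect_equal(unname(cls[c("p1", "p2", "p3", "p4", "p5", "p6", "p7")]),
               c("up", "unchanged", "down", "unchanged", "unchanged",
                 "up", "down"))
  counts <- attr(calls, "counts")
  expect_equal(sum(counts), nrow(quants))
})

test_that("a protein missing a channel is not_quantified", {
  q <- manual_quant(list(
    list(peptide = "AAAAAK", protein_id = "p1", ck = c(1, 0, 1),
         np = c(2, 2, 2)),
    list(peptide = "CCCCCK", protein_id = "p2", ck = c(1, 1, 1),
         np = c(2, 2, 2))))
  quants <- quantify_proteins(q, simple_matches(q))
  calls <- call_pdrps(quants, pdrp_call_config())
  cls <- setNames(calls$reg_class, calls$protein_id)
  expect_equal(unname(cls["p1"]), "not_quantified")
  expect_equal(unname(cls["p2"]), "up")
})

test_that("classes are invariant under global channel rescaling", {
  spec <- simulation_spec(seed = 20, n_families = 10, cv = 0.1)
  db <- generate_subgenome_proteome(spec)
  q <- simulate_itraq_experiment(db, spec)
  matches <- map_peptides(q$peptide, index_proteome(db))
  c1 <- call_pdrps(quantify_proteins(q, matches))
  q2 <- q
  for (cc in grep("^(CK|NP)", names(q2), value = TRUE))
    q2[[cc]] <- q2[[cc]] * 17.3
  c2 <- call_pdrps(quantify_proteins(q2, matches))
  expect_equal(c1$ratio, c2$ratio, tolerance = 1e-12)
  expect_equal(c1$reg_class, c2$reg_class)
})

test_that("null simulation keeps the false-positive rate low", {
  # planted fold change 1 everywhere, cv = 0.05: fold-threshold caller
  # must flag under 5% of ~200 proteins
  spec <- simulation_spec(seed = 21, n_families = 70, cv = 0.05,
                          singleton_fraction = 0)
  db <- generate_subgenome_proteome(spec)
  q <- simulate_itraq_experiment(db, spec)
  quants <- quantify_proteins(q, map_peptides(q$peptide, index_proteome(db)))
  expect_gte(nrow(quants), 200)
  calls <- call_pdrps(quants, pdrp_call_config())
  flagged <- mean(calls$reg_class %in% c("up", "down"))
  expect_lt(flagged, 0.05)
})

test_that("p-filtered null calls stay near the nominal level", {
  spec <- simulation_spec(seed = 22, n_families = 70, cv = 0.05,
                          singleton_fraction = 0)
  db <- generate_subgenome_proteome(spec)
  q <- simulate_itraq_experiment(db, spec)
  quants <- quantify_proteins(q, map_peptides(q$peptide, index_proteome(db)))
  calls <- call_pdrps(quants, pdrp_call_config(p_filter_enabled = TRUE))
  flagged <- mean(calls$reg_class %in% c("up", "down"))
  expect_lte(flagged, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(quants)))
})

test_that("planted up-regulation is recovered", {
  spec0 <- simulation_spec(seed = 23, n_families = 70, cv = 0.1,
                           singleton_fraction = 0)
  db <- generate_subgenome_proteome(spec0)
  planted <- setNames(rep(2.0, nrow(db)), db$locus_id)
  spec <- simulation_spec(seed = 23, n_families = 70, cv = 0.1,
                          singleton_fraction = 0, planted_effects = planted)
  q <- simulate_itraq_experiment(db, spec)
  quants <- quantify_proteins(q, map_peptides(q$peptide, index_proteome(db)))
  calls <- call_pdrps(quants, pdrp_call_config())
  expect_gte(mean(calls$reg_class == "up"), 0.95)
})

test_that("concordance counts matching directions", {
  mk_calls <- function(ratios, classes) {
    data.frame(protein_id = paste0("p", seq_along(ratios)), ratio = ratios,
               reg_class = classes, stringsAsFactors = FALSE)
  }
  a <- mk_calls(c(2, 0.5, 1.5), c("up", "down", "up"))
  expect_equal(concordance(a, a)$fraction, 1)
  flipped <- mk_calls(1 / c(2, 0.5, 1.5), c("down", "up", "down"))
  expect_equal(concordance(a, flipped)$fraction, 0)
  # 9-of-11 fixture: two proteins disagree by construction (one flips
  # direction, one drops below the call threshold)
  a11 <- mk_calls(c(rep(1.8, 9), 1.6, 0.6), c(rep("up", 10), "down"))
  b11 <- mk_calls(c(rep(1.7, 9), 0.7, 0.9),
                  c(rep("up", 9), "down", "unchanged"))
  rep11 <- concordance(a11, b11)
  expect_equal(rep11$n_concordant, 9)
  expect_equal(rep11$n_shared, 11)
  expect_error(concordance(a, mk_calls(2, "up")[0, ]), "shared")
})

test_that("volcano coordinates follow the closed form", {
  quants <- data.frame(protein_id = c("a", "b", "c"),
                       ratio = c(1, 2, 0.5), p_value = c(1, 0.1, 0.01))
  v <- volcano_coordinates(quants)
  expect_equal(v$log2_ratio, c(0, 1, -1))
  expect_equal(v$neg_log10_p, c(0, 1, 2))
  # p = 0 clips to a finite coordinate
  q0 <- data.frame(protein_id = "z", ratio = 2, p_value = 0)
  expect_true(is.finite(volcano_coordinates(q0)$neg_log10_p))
})
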