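test_that("database loader enforces its invariants", {
  expect_error(subgenome_proteindb(data.frame(locus_id = "x")), "missing")
  df <- data.frame(locus_id = c("a", "a"), subgenome = "A",
                   chromosome = "1A", family_id = "f", sequence = "MA",
                   stringsAsFactors = FALSE)
  expect_error(subgenome_proteindb(df), "duplicate")
  df2 <- data.frame(locus_id = "a", subgenome = "A", chromosome = "1B",
                    family_id = "f", sequence = "MA")
  expect_error(subgenome_proteindb(df2), "inconsistent")
  # two loci in one subgenome: rejected strictly, split permissively
  df3 <- data.frame(locus_id = c("a", "b"), subgenome = "A",
                    chromosome = "1A", family_id = "f",
                    sequence = c("MA", "MC"), stringsAsFactors = FALSE)
  expect_error(subgenome_proteindb(df3), "locus per subgenome")
  perm <- subgenome_proteindb(df3, strict = FALSE)
  expect_equal(length(unique(perm$family_id)), 2)
})

test_that("proteome FASTA round-trips through the header contract", {
  db <- tiny_db()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(db, path)
  back <- read_proteome_fasta(path)
  expect_equal(as.data.frame(back), as.data.frame(db))
  # sidecar locus map route
  plain <- withr::local_tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(seq_len(nrow(db)), function(i)
    c(paste0(">", db$locus_id[i]), db$sequence[i]))), plain)
  back2 <- read_proteome_fasta(plain, locus_map = as.data.frame(db)[1:4])
  expect_equal(as.data.frame(back2), as.data.frame(db))
})

test_that("peptide matching classifies specificity correctly", {
  idx <- index_proteome(tiny_db())
  expect_equal(map_peptide("CCCCCK", idx)$specificity, "locus_unique")
  expect_equal(map_peptide("CCCCCK", idx)$loci, "F1.A")
  m <- map_peptide("MAAAK", idx)          # in all three F1 homoeologs
  expect_equal(m$specificity, "family_shared")
  expect_setequal(m$loci, c("F1.A", "F1.B", "F1.D"))
  expect_equal(map_peptide("WWWWWWWWW", idx)$specificity, "cross_family")
  expect_equal(map_peptide("QQQQQQ", idx)$specificity, "unmatched")
  expect_error(map_peptide("", idx), "non-empty")
  expect_error(map_peptide("abc1", idx), "non-empty")
})

test_that("empty database returns unmatched for every query", {
  empty <- generate_subgenome_proteome(simulation_spec(n_families = 0))
  idx <- index_proteome(empty)
  expect_equal(map_peptide("AAAAAA", idx)$specificity, "unmatched")
})

test_that("I/L collapse is off by default and available as an option", {
  db <- subgenome_proteindb(data.frame(
    locus_id = "g.A", subgenome = "A", chromosome = "1A",
    family_id = "g", sequence = "MKAILK", stringsAsFactors = FALSE))
  expect_equal(map_peptide("ALLK", index_proteome(db))$specificity,
               "unmatched")
  expect_equal(map_peptide("ALLK",
                           index_proteome(db, collapse_il = TRUE))$loci,
               "g.A")
})

test_that("map_peptide agrees with an independent substring scan", {
  db <- generate_subgenome_proteome(
    simulation_spec(seed = 11, n_families = 10, homoeolog_divergence = 0.08))
  idx <- index_proteome(db)
  set.seed(12)
  peptides <- unlist(lapply(sample(nrow(db), 25, replace = TRUE), function(r) {
    s <- db$sequence[r]
    start <- sample(nchar(s) - 10, 1)
    substr(s, start, start + sample(5:12, 1))
  }))
  peptides <- c(peptides, replicate(25, paste0(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 8, replace = TRUE),
    collapse = "")))
  for (p in peptides)
    expect_setequal(map_peptide(p, idx)$loci, naive_peptide_scan(p, db))
})

test_that("adding sequences only moves specificity toward more shared", {
  rank <- c(unmatched = 0, locus_unique = 1, family_shared = 2,
            cross_family = 3)
  db_small <- generate_subgenome_proteome(
    simulation_spec(seed = 13, n_families = 4, homoeolog_divergence = 0.1))
  db_big <- generate_subgenome_proteome(
    simulation_spec(seed = 13, n_families = 8, homoeolog_divergence = 0.1))
  # the first 4 families are identical draws under the shared seed
  expect_true(all(db_small$locus_id %in% db_big$locus_id))
  idx_s <- index_proteome(db_small); idx_b <- index_proteome(db_big)
  set.seed(14)
  for (r in sample(nrow(db_small), 20, replace = TRUE)) {
    s <- db_small$sequence[r]
    start <- sample(nchar(s) - 8, 1)
    p <- substr(s, start, start + 7)
    expect_gte(rank[[map_peptide(p, idx_b)$specificity]],
               rank[[map_peptide(p, idx_s)$specificity]])
  }
})

test_that("protein assignment follows the unique-peptide rule", {
  db <- tiny_db()
  idx <- index_proteome(db)
  mk <- function(peps) lapply(peps, map_peptide, index = idx)
  # unique evidence for one homoeolog of a triplet -> single_bias
  a <- assign_protein("p1", mk(c("DDDDDK", "MAAAK")), db)
  expect_equal(a$category, "B")
  expect_equal(a$bias_flag, "single_bias")
  # singleton family -> singleton flag
  s <- assign_protein("p2", mk(c("SSSSSK", "TTTTTK")), db)
  expect_equal(s$category, "D")
  expect_equal(s$bias_flag, "singleton")
  # unique peptides for two homoeologs -> multi, combined category
  m <- assign_protein("p3", mk(c("CCCCCK", "EEEEEK")), db)
  expect_equal(m$category, "A+D")
  expect_equal(m$bias_flag, "multi")
  # family-shared evidence only: family known, no specific assignment
  u <- assign_protein("p4", mk(c("MAAAK")), db)
  expect_equal(u$category, "unassigned")
  expect_equal(u$family_id, "F1")
  # cross-family evidence only -> unassigned, family unknown
  x <- assign_protein("p5", mk(c("WWWWWWWWW")), db)
  expect_equal(x$category, "unassigned")
  expect_true(is.na(x$family_id))
  # conflicting unique peptides across families -> error
  expect_error(assign_protein("p6", mk(c("CCCCCK", "FFFFFK")), db),
               "conflicting")
})

test_that("assignment summary reproduces the published percentage style", {
  s <- summarize_assignment(data.frame(
    category = c(rep("A", 738), rep("B", 62), rep("A+B", 215)),
    bias_flag = c(rep("single_bias", 738), rep("singleton", 62),
                  rep("multi", 215)), stringsAsFactors = FALSE))
  expect_equal(s$n_assigned, 1015)
  expect_equal(s$by_bias["single_bias", "pct"], 72.7)
  expect_equal(s$by_bias["singleton", "pct"], 6.1)
  expect_equal(sum(s$by_category$count), 1015)
  # empty input -> all-zero summary
  e <- summarize_assignment(list())
  expect_equal(e$n_assigned, 0)
  expect_true(all(e$by_bias$count == 0))
})

test_that("assignments recover the truly expressed homoeolog", {
  spec <- simulation_spec(seed = 15, n_families = 100, cv = 0.05,
                          homoeolog_divergence = 0.05)
  db <- generate_subgenome_proteome(spec)
  truth <- vapply(split(db$locus_id, db$family_id), `[`, "", 1L)
  q <- simulate_itraq_experiment(db, spec, expressed_loci = unname(truth))
  asg <- assign_proteins(q, index_proteome(db))
  ok <- vapply(names(asg), function(pid) {
    a <- asg[[pid]]
    fam <- sub("\\..*$", "", a$assigned_loci[1])
    length(a$assigned_loci) == 1 && identical(a$assigned_loci, unname(truth[fam]))
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})
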