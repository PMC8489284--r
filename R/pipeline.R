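#' Translate a complete ORF
#'
#' Conceptual translation of a coding sequence under the standard
#' genetic code (via [Biostrings::translate()]), after validating that
#' the sequence is a complete ORF: length divisible by 3, starts with
#' ATG, and contains exactly one stop codon, at the end. The protein
#' length is therefore `length/3 - 1` residues (a 1566-bp CDS gives a
#' 521-aa protein; a 705-bp CDS gives 234 aa).
#'
#' @param cds Nucleotide string over `A,C,G,T` (case-insensitive).
#' @return The deduced amino-acid string (without the stop).
#' @examples
#' translate_orf("ATGAAATAA")   # "MK"
#' translate_orf("ATGTAA")      # "M", the minimal ORF
#' @export
translate_orf <- function(cds) {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds))
    stop("coding sequence must be over A,C,G,T", call. = FALSE)
  if (nchar(cds) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3", call. = FALSE)
  if (substr(cds, 1L, 3L) != "ATG")
    stop("coding sequence must start with ATG", call. = FALSE)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  if (stops[1] == -1L || length(stops) != 1L || stops != nchar(aa))
    stop("ORF must contain exactly one stop codon, at the end",
         call. = FALSE)
  substr(aa, 1L, nchar(aa) - 1L)
}

#' Build a random valid ORF of a given length
#'
#' Utility for bookkeeping checks: an ATG start, random internal codons
#' drawn from the 61 sense codons excluding ATG-independent stops, and a
#' terminal TAA.
#'
#' @param n_nt Total ORF length in nucleotides (divisible by 3, >= 6).
#' @param seed Integer seed.
#' @return Nucleotide string of length `n_nt` accepted by
#'   [translate_orf()].
#' @export
random_orf <- function(n_nt, seed = 1L) {
  n_nt <- as.integer(n_nt)
  if (n_nt < 6L || n_nt %% 3L != 0L)
    stop("ORF length must be >= 6 and divisible by 3", call. = FALSE)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste0,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  with_seed(seed, paste0(
    c("ATG", sample(sense, n_nt / 3L - 2L, replace = TRUE), "TAA"),
    collapse = ""))
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates every synthetic input (subgenome proteome, reporter
#' quantification table, promoter panel, CAPS amplicon pair), runs all
#' analysis stages, and optionally writes the TSV/FASTA reports to a
#' directory. Deterministic given the seed.
#'
#' @param seed Integer seed driving every generator.
#' @param out_dir Optional directory for the report files; `NULL` (the
#'   default) writes nothing.
#' @param n_families Families in the simulated proteome (default 60, a
#'   small but structured database).
#' @param cv Reporter noise coefficient of variation (default 0.1).
#' @param up_fraction,down_fraction Fractions of loci planted with fold
#'   change 2.0 and 0.5 (defaults 0.1 each); the rest stay at 1.
#' @return A list bundle of class `"triadquant_demo"`: the generated
#'   inputs and the outputs of every stage.
#' @examples
#' \donttest{
#' demo <- run_demo(seed = 1, n_families = 20)
#' summary_report(demo)
#' }
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, n_families = 60L,
                     cv = 0.1, up_fraction = 0.1, down_fraction = 0.1) {
  spec0 <- simulation_spec(seed = seed, n_families = n_families, cv = cv)
  db <- generate_subgenome_proteome(spec0)
  planted <- numeric(0)
  if (nrow(db)) {
    k_up <- floor(up_fraction * nrow(db))
    k_dn <- floor(down_fraction * nrow(db))
    pick <- with_seed(seed + 2L, sample(db$locus_id, k_up + k_dn))
    planted <- stats::setNames(c(rep(2.0, k_up), rep(0.5, k_dn)), pick)
  }
  spec <- simulation_spec(seed = seed, n_families = n_families, cv = cv,
                          planted_effects = planted)
  quant_tab <- simulate_itraq_experiment(db, spec)
  quant_tab <- normalize_channels(quant_tab, "total_sum")
  idx <- index_proteome(db)
  matches <- map_peptides(quant_tab$peptide, idx)
  quants <- quantify_proteins(quant_tab, matches)
  calls <- call_pdrps(quants, pdrp_call_config())
  assignments <- assign_proteins(quant_tab, idx)
  asum <- summarize_assignment(assignments, db)
  chrom <- chromosome_distribution(assignments, db)
  mats <- locus_abundance_matrices(calls, assignments)
  balance <- test_balance_all(mats)

  panel <- generate_promoter_panel(seed = seed)
  snps <- call_variant_sites(panel)
  div <- nucleotide_diversity(panel)
  haps <- group_haplotypes(snps)
  traits <- with_seed(seed + 3L, {
    shift <- c(Hap1 = 0, Hap2 = -1, Hap3 = 2, Hap4 = 0)
    v <- stats::rnorm(length(haps$labels), 10, 0.5) +
      ifelse(haps$labels %in% names(shift), shift[haps$labels], 0)
    stats::setNames(v, names(haps$labels))
  })
  assoc <- haplotype_association(haps$labels, traits)
  fx <- generate_caps_fixture(caps_fixture_spec(seed = seed))
  caps <- design_caps(fx$cut, fx$uncut, list(fx$enzyme))

  bundle <- structure(list(
    seed = seed, db = db, quant_table = quant_tab, matches = matches,
    calls = calls, planted = planted, assignments = assignments,
    assignment_summary = asum, chromosome_distribution = chrom,
    balance = balance, panel = panel, snps = snps, diversity = div,
    haplotypes = haps, association = assoc, caps_fixture = fx,
    caps_candidates = caps), class = "triadquant_demo")
  if (!is.null(out_dir)) write_demo_reports(bundle, out_dir)
  bundle
}

write_demo_reports <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_proteome_fasta(bundle$db, file.path(out_dir, "proteome.fasta"))
  tsv(bundle$quant_table, "peptide_quant.tsv")
  tsv(bundle$matches, "peptide_matches.tsv")
  tsv(as.data.frame(bundle$calls), "protein_calls.tsv")
  tsv(volcano_coordinates(bundle$calls), "volcano.tsv")
  tsv(bundle$chromosome_distribution, "chromosome_distribution.tsv")
  tsv(bundle$balance, "homoeolog_balance.tsv")
  write_promoter_panel(bundle$panel, file.path(out_dir, "promoter_panel.fasta"))
  tsv(bundle$haplotypes$patterns, "haplotype_patterns.tsv")
  tsv(as.data.frame(bundle$caps_candidates), "caps_candidates.tsv")
  writeLines(utils::capture.output(summary_report(bundle)),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Human-readable pipeline summary
#'
#' Prints the count tables of a demo (or assembled) run: responsive-
#' protein classes, homoeolog expression categories and bias classes
#' with 1-decimal half-up percentages, the chromosome distribution of
#' assigned loci, and the promoter-panel haplotype/diversity/CAPS
#' results.
#'
#' @param bundle A `"triadquant_demo"` bundle from [run_demo()].
#' @return The bundle, invisibly.
#' @export
summary_report <- function(bundle) {
  stopifnot(inherits(bundle, "triadquant_demo"))
  cat("=== Responsive-protein calls ===\n")
  print(attr(bundle$calls, "counts"))
  cat("\n=== Homoeolog assignment ===\n")
  print(bundle$assignment_summary)
  cat("\n=== Homoeolog balance (multi-homoeolog proteins) ===\n")
  bt <- table(bundle$balance$balance)
  cat(sprintf("tested families: %d; unbalanced (p < 0.05): %d\n",
              nrow(bundle$balance),
              if ("unbalanced" %in% names(bt)) bt[["unbalanced"]] else 0L))
  cat("\n=== Promoter panel ===\n")
  print(bundle$snps)
  print(bundle$diversity)
  print(bundle$haplotypes)
  cat("\n=== Haplotype-trait association ===\n")
  print(bundle$association)
  cat("\n=== CAPS marker ===\n")
  print(bundle$caps_candidates)
  invisible(bundle)
}

#' @export
print.triadquant_demo <- function(x, ...) {
  cat(sprintf("<triadquant_demo> seed %d: %d loci, %d peptide rows, %d quantified proteins\n",
              x$seed, nrow(x$db), nrow(x$quant_table), nrow(x$calls)))
  cat("use summary_report() for the full tables\n")
  invisible(x)
}
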