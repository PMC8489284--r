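#' Simulation specification for the proteomics arm
#'
#' Collects every knob of the synthetic proteomics experiment: a
#' homoeolog-triplet protein database and a 3 control (CK) + 3
#' phosphate-deficiency (NP) replicate reporter-intensity design with
#' planted fold changes.
#'
#' @param seed Integer seed; a fixed seed makes every generated artefact
#'   byte-identical across runs.
#' @param n_families Number of homoeolog families to simulate.
#' @param homoeolog_divergence Expected amino-acid substitutions per site
#'   between homoeologs of one family, in `[0, 1)`.
#' @param singleton_fraction Fraction of families carrying a single locus
#'   (no homoeologs in the other two subgenomes), in `[0, 1]`.
#' @param protein_length_range Length-2 integer vector, residue range of
#'   simulated proteins.
#' @param n_replicates Biological replicates per condition (default 3,
#'   the study design).
#' @param planted_effects Named numeric vector: locus id -> true NP/CK
#'   fold change. Loci not named default to fold change 1.
#' @param cv Coefficient of variation of the multiplicative log-normal
#'   channel noise (>= 0; 0 gives noise-free intensities).
#' @return An object of class `"simulation_spec"`.
#' @examples
#' simulation_spec(seed = 1, n_families = 20, cv = 0.1)
#' @export
simulation_spec <- function(seed = 1L, n_families = 100L,
                            homoeolog_divergence = 0.05,
                            singleton_fraction = 0.06,
                            protein_length_range = c(200L, 600L),
                            n_replicates = 3L,
                            planted_effects = numeric(0), cv = 0.1) {
  if (!is.numeric(homoeolog_divergence) || homoeolog_divergence < 0 ||
      homoeolog_divergence >= 1)
    stop("homoeolog_divergence must be in [0, 1)", call. = FALSE)
  if (singleton_fraction < 0 || singleton_fraction > 1)
    stop("singleton_fraction must be in [0, 1]", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_families < 0) stop("n_families must be >= 0", call. = FALSE)
  protein_length_range <- as.integer(protein_length_range)
  if (length(protein_length_range) != 2L ||
      any(protein_length_range < 1L) ||
      protein_length_range[1] > protein_length_range[2])
    stop("protein_length_range must be a valid (min, max) pair",
         call. = FALSE)
  if (n_replicates < 2L)
    stop("need at least 2 replicates per condition", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_families = as.integer(n_families),
                 homoeolog_divergence = homoeolog_divergence,
                 singleton_fraction = singleton_fraction,
                 protein_length_range = protein_length_range,
                 n_replicates = as.integer(n_replicates),
                 planted_effects = planted_effects, cv = cv),
            class = "simulation_spec")
}

# evaluate expr with a private RNG stream; the caller's RNG state is
# untouched, and a fixed seed gives identical draws
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a subgenome-partitioned protein database
#'
#' Simulates homoeolog families of the allohexaploid wheat kind: each
#' family carries one locus per subgenome (A, B and D) unless sampled as
#' a singleton, homoeolog sequences within a family differ by
#' independent substitutions at the spec's divergence rate, and family
#' `i` is placed on homoeologous chromosome group `(i - 1) %% 7 + 1`
#' (chromosomes `1A`..`7D`).
#'
#' @param spec A [simulation_spec()].
#' @return A [subgenome_proteindb()] with locus ids of the form
#'   `FAM0001.A`.
#' @examples
#' db <- generate_subgenome_proteome(simulation_spec(seed = 1, n_families = 5))
#' db
#' @export
generate_subgenome_proteome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (i in seq_len(spec$n_families)) {
      fam <- sprintf("FAM%04d", i)
      grp <- (i - 1L) %% 7L + 1L
      len <- sample(spec$protein_length_range[1]:spec$protein_length_range[2], 1L)
      base <- paste0(c("M", sample(AA20, len - 1L, replace = TRUE)),
                     collapse = "")
      subs <- if (stats::runif(1) < spec$singleton_fraction)
        sample(c("A", "B", "D"), 1L) else c("A", "B", "D")
      for (sg in subs) {
        seqc <- strsplit(base, "")[[1]]
        n_mut <- stats::rbinom(1L, len, spec$homoeolog_divergence)
        if (n_mut > 0) {
          pos <- sample.int(len, n_mut)
          for (p in pos) {
            seqc[p] <- sample(setdiff(AA20, seqc[p]), 1L)
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = paste0(fam, ".", sg), subgenome = sg,
          chromosome = paste0(grp, sg), family_id = fam,
          sequence = paste0(seqc, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(locus_id = character(0), subgenome = character(0),
                 chromosome = character(0), family_id = character(0),
                 sequence = character(0), stringsAsFactors = FALSE)
    subgenome_proteindb(df)
  })
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein after every K or R not followed by P (trypsin's
#' rule), optionally concatenating up to `missed_cleavages` consecutive
#' fragments, and filters peptides to a length window. With
#' `missed_cleavages = 0` and no length filter the fragments concatenate
#' back to the input.
#'
#' @param protein Amino-acid string over the 20-letter alphabet.
#' @param min_len,max_len Peptide length window in residues (defaults
#'   6-50, the usual search-engine convention).
#' @param missed_cleavages Maximum missed cleavages per peptide.
#' @return Character vector of peptides, in N-to-C order of their start.
#' @examples
#' tryptic_digest("AAAKGGGRCCC", min_len = 1)
#' tryptic_digest("AKPGR", min_len = 1)   # K-P suppresses the cut
#' @export
tryptic_digest <- function(protein, min_len = 6L, max_len = 50L,
                           missed_cleavages = 0L) {
  if (nchar(protein) == 0L) return(character(0))
  protein <- toupper(protein)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", protein))
    stop("non-amino-acid character in protein sequence", call. = FALSE)
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, n)
  bounds <- unique(bounds[bounds <= n])
  frags <- substring(protein, utils::head(bounds, -1L) + 1L, bounds[-1L])
  out <- character(0)
  for (i in seq_along(frags)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > length(frags)) break
      pep <- paste0(frags[i:j], collapse = "")
      if (nchar(pep) >= min_len && nchar(pep) <= max_len)
        out <- c(out, pep)
    }
  }
  out
}

#' Simulate an isobaric-reporter quantification table
#'
#' Generates peptide-level reporter intensities for a 3+3 CK/NP design
#' from a subgenome protein database. Each expressed locus receives a
#' log-normal baseline abundance; its tryptic peptides get log-normal
#' response weights; a peptide row's intensity in each channel is the
#' sum over expressing loci that contain the peptide, times the locus'
#' planted NP/CK fold change in NP channels, times multiplicative
#' log-normal noise with the spec's coefficient of variation. At
#' `cv = 0` the protein-level ratio estimated from unique peptides
#' equals the planted fold change exactly.
#'
#' @param db A [subgenome_proteindb()].
#' @param spec A [simulation_spec()]; `spec$planted_effects` names must
#'   exist in `db`.
#' @param expressed_loci Character vector of locus ids that are
#'   expressed (default: all). Peptides of unexpressed loci carry no
#'   signal and are absent from the table, emulating homoeolog
#'   expression bias.
#' @param min_len,max_len,missed_cleavages Digestion settings passed to
#'   [tryptic_digest()].
#' @return A data frame of class `"peptide_quant"`: `peptide`,
#'   `protein_id` (the reported protein identity, family-level: a search
#'   database built without subgenome resolution collapses homoeologs
#'   into one reported protein), `source_proteins` (comma-separated
#'   contributing loci, the simulation truth), and intensity columns
#'   `CK1..CKn`, `NP1..NPn`.
#' @export
simulate_itraq_experiment <- function(db, spec, expressed_loci = NULL,
                                      min_len = 6L, max_len = 50L,
                                      missed_cleavages = 0L) {
  stopifnot(inherits(db, "subgenome_proteindb"),
            inherits(spec, "simulation_spec"))
  if (length(spec$planted_effects) &&
      !all(names(spec$planted_effects) %in% db$locus_id))
    stop("planted_effects names must be locus ids present in db",
         call. = FALSE)
  if (is.null(expressed_loci)) expressed_loci <- db$locus_id
  if (!all(expressed_loci %in% db$locus_id))
    stop("unknown locus in expressed_loci", call. = FALSE)
  nrep <- spec$n_replicates
  sigma <- sqrt(log(1 + spec$cv^2))
  with_seed(spec$seed + 1L, {
    expr <- db[db$locus_id %in% expressed_loci, , drop = FALSE]
    base_ab <- stats::rlnorm(nrow(expr), meanlog = log(1e6), sdlog = 0.5)
    names(base_ab) <- expr$locus_id
    fc <- rep(1, nrow(expr)); names(fc) <- expr$locus_id
    planted <- spec$planted_effects[names(spec$planted_effects) %in% expr$locus_id]
    fc[names(planted)] <- planted

    # peptide -> per-channel noise-free signal, summed over source loci
    pep_ck <- new.env(parent = emptyenv())
    pep_np <- new.env(parent = emptyenv())
    pep_src <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(expr))) {
      lid <- expr$locus_id[r]
      peps <- tryptic_digest(expr$sequence[r], min_len, max_len,
                             missed_cleavages)
      if (!length(peps)) next
      w <- stats::rlnorm(length(peps), meanlog = 0, sdlog = 0.3)
      for (k in seq_along(peps)) {
        p <- peps[k]
        s <- base_ab[[lid]] * w[k]
        pep_ck[[p]] <- (if (is.null(pep_ck[[p]])) 0 else pep_ck[[p]]) + s
        pep_np[[p]] <- (if (is.null(pep_np[[p]])) 0 else pep_np[[p]]) +
          s * fc[[lid]]
        pep_src[[p]] <- c(pep_src[[p]], lid)
      }
    }
    peps <- sort(ls(pep_ck))
    m <- matrix(0, nrow = length(peps), ncol = 2L * nrep)
    colnames(m) <- c(paste0("CK", seq_len(nrep)), paste0("NP", seq_len(nrep)))
    for (i in seq_along(peps)) {
      p <- peps[i]
      noise <- if (sigma > 0) exp(stats::rnorm(2L * nrep, 0, sigma)) else
        rep(1, 2L * nrep)
      m[i, ] <- c(rep(pep_ck[[p]], nrep), rep(pep_np[[p]], nrep)) * noise
    }
    fam_of <- stats::setNames(db$family_id, db$locus_id)
    out <- data.frame(
      peptide = peps,
      protein_id = vapply(peps, function(p)
        paste(sort(unique(fam_of[pep_src[[p]]])), collapse = ","), ""),
      source_proteins = vapply(peps, function(p)
        paste(sort(unique(pep_src[[p]])), collapse = ","), ""),
      m, stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("peptide_quant", "data.frame")
    out
  })
}

#' Default promoter haplotype patterns
#'
#' The packaged default emulates the structure of the studied promoter
#' panel: nine SNP positions upstream of ATG forming four haplotypes,
#' with Hap2, Hap3 and Hap4 differing from the reference Hap1 at six,
#' two and one positions respectively. Hap3 carries the C->G variants
#' at positions -799 and -796 that abolish the Fnu4HI site used by the
#' CAPS assay.
#'
#' @return A list with `positions` (ATG-relative, +1 = A of ATG, no 0)
#'   and `alleles`, a haplotype x position character matrix.
#' @export
default_haplotype_patterns <- function() {
  positions <- c(-1350L, -1200L, -1000L, -799L, -796L, -600L, -450L,
                 -281L, -150L)
  ref <- c("A", "T", "G", "C", "C", "A", "G", "C", "T")
  alt <- c("G", "C", "A", "G", "G", "T", "A", "T", "C")
  alleles <- rbind(Hap1 = ref, Hap2 = ref, Hap3 = ref, Hap4 = ref)
  colnames(alleles) <- as.character(positions)
  hap2_cols <- as.character(c(-1350L, -1200L, -1000L, -600L, -450L, -281L))
  alleles["Hap2", hap2_cols] <- alt[match(hap2_cols, colnames(alleles))]
  alleles["Hap3", c("-799", "-796")] <- c("G", "G")
  alleles["Hap4", "-150"] <- "C"
  list(positions = positions, alleles = alleles)
}

#' Generate an aligned promoter panel
#'
#' Simulates an equal-length aligned panel of promoter sequences drawn
#' from a set of haplotype patterns. Outside the SNP positions every
#' sequence is identical (the shared promoter backbone); at each SNP
#' position a sequence carries its haplotype's allele. The default
#' emulates the studied design: 62 cultivar sequences spanning -1513 to
#' +1 relative to ATG, nine SNPs, four haplotypes.
#'
#' @param n_seqs Number of sequences (default 62).
#' @param length Alignment length in bp (default 1514 = positions -1513
#'   to +1).
#' @param patterns Haplotype patterns as from
#'   [default_haplotype_patterns()].
#' @param frequencies Per-haplotype fractions summing to 1 (default
#'   30/14/10/8 out of 62, reference haplotype most frequent).
#' @param seed Integer seed.
#' @return A `"promoter_panel"` object: list with `seqs` (named
#'   character vector of aligned sequences), `atg_col` (column of the A
#'   of ATG) and `length`. The generating haplotype of each sequence is
#'   kept in the `truth` attribute.
#' @examples
#' panel <- generate_promoter_panel(seed = 1)
#' panel
#' @export
generate_promoter_panel <- function(n_seqs = 62L, length = 1514L,
                                    patterns = default_haplotype_patterns(),
                                    frequencies = c(30, 14, 10, 8) / 62,
                                    seed = 1L) {
  if (abs(sum(frequencies) - 1) > 1e-8)
    stop("frequencies must sum to 1", call. = FALSE)
  if (length(frequencies) != nrow(patterns$alleles))
    stop("one frequency per haplotype pattern required", call. = FALSE)
  if (any(duplicated(patterns$positions)))
    stop("conflicting alleles: duplicated SNP position in patterns",
         call. = FALSE)
  atg_col <- as.integer(length)   # +1 (A of ATG) is the last column
  cols <- promoter_pos_to_col(patterns$positions, atg_col)
  if (any(cols < 1L | cols > length))
    stop("SNP position outside the panel coordinate range", call. = FALSE)
  with_seed(seed, {
    backbone <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    backbone[atg_col] <- "A"      # first base of ATG
    counts <- round(frequencies * n_seqs)
    # largest-remainder fix so counts sum to n_seqs
    while (sum(counts) != n_seqs) {
      i <- if (sum(counts) < n_seqs) which.max(frequencies * n_seqs - counts)
           else which.min(frequencies * n_seqs - counts)
      counts[i] <- counts[i] + sign(n_seqs - sum(counts))
    }
    hap_of <- rep(rownames(patterns$alleles), counts)
    seqs <- character(n_seqs)
    for (s in seq_len(n_seqs)) {
      x <- backbone
      x[cols] <- patterns$alleles[hap_of[s], ]
      seqs[s] <- paste0(x, collapse = "")
    }
    names(seqs) <- sprintf("line%02d", seq_len(n_seqs))
    structure(list(seqs = seqs, atg_col = atg_col, length = length),
              class = "promoter_panel",
              truth = stats::setNames(hap_of, names(seqs)))
  })
}

# ATG-relative coordinates: +1 = A of ATG, strictly negative upstream,
# no position 0
promoter_pos_to_col <- function(pos, atg_col) {
  ifelse(pos > 0, atg_col + pos - 1L, atg_col + pos)
}

promoter_col_to_pos <- function(col, atg_col) {
  ifelse(col >= atg_col, col - atg_col + 1L, col - atg_col)
}

#' @export
print.promoter_panel <- function(x, ...) {
  cat(sprintf("<promoter_panel> %d aligned sequences, %d bp (%+d .. %+d)\n",
              length(x$seqs), x$length,
              promoter_col_to_pos(1L, x$atg_col),
              promoter_col_to_pos(x$length, x$atg_col)))
  invisible(x)
}

#' Specification of the CAPS amplicon fixture
#'
#' @param amplicon_length Amplicon length in bp (default 703, the size
#'   of the genotyping fragment).
#' @param enzyme The discriminating [enzyme()] (default Fnu4HI, GCNGC).
#' @param site_start 0-based start of the recognition site on the
#'   amplicon (default 455, so the cut at `site_start + cut_offset`
#'   yields 457 + 246 bp fragments).
#' @param snp_positions Promoter coordinates of the two diagnostic SNPs
#'   (default -799 and -796).
#' @param cut_allele,uncut_allele Nucleotide carried at each SNP by the
#'   cleavable and non-cleavable allele (defaults C/C vs G/G).
#' @param seed Integer seed for the amplicon backbone.
#' @return An object of class `"caps_fixture_spec"`.
#' @export
caps_fixture_spec <- function(amplicon_length = 703L,
                              enzyme = triadquant::enzyme("Fnu4HI", "GCNGC", 2L),
                              site_start = 455L,
                              snp_positions = c(-799L, -796L),
                              cut_allele = c("C", "C"),
                              uncut_allele = c("G", "G"),
                              seed = 1L) {
  if (nchar(enzyme$recognition) > amplicon_length)
    stop("recognition longer than amplicon: cannot place a site",
         call. = FALSE)
  if (site_start < 0L || site_start + nchar(enzyme$recognition) > amplicon_length)
    stop("site does not fit inside the amplicon", call. = FALSE)
  structure(list(amplicon_length = as.integer(amplicon_length),
                 enzyme = enzyme, site_start = as.integer(site_start),
                 snp_positions = snp_positions, cut_allele = cut_allele,
                 uncut_allele = uncut_allele, seed = as.integer(seed)),
            class = "caps_fixture_spec")
}

#' Generate the allele pair of a CAPS amplicon
#'
#' Builds two equal-length amplicon sequences differing only at the
#' diagnostic SNPs: the cut allele carries exactly one recognition site
#' of the spec's enzyme (spanning the SNPs), the uncut allele carries
#' none, and no second site exists anywhere in either allele. With the
#' defaults this reproduces the gel logic of the promoter CAPS assay: a
#' 703-bp amplicon that Fnu4HI cleaves into two fragments for the
#' C-allele haplotypes and leaves intact for the G-allele haplotype.
#'
#' @param spec A [caps_fixture_spec()].
#' @return List with elements `cut`, `uncut` (sequences), `enzyme`,
#'   `site_start` and `snp_cols` (0-based SNP offsets on the amplicon).
#' @examples
#' fx <- generate_caps_fixture()
#' digest(fx$cut, fx$enzyme)
#' digest(fx$uncut, fx$enzyme)
#' @export
generate_caps_fixture <- function(spec = caps_fixture_spec()) {
  stopifnot(inherits(spec, "caps_fixture_spec"))
  e <- spec$enzyme
  L <- spec$amplicon_length
  rl <- nchar(e$recognition)
  with_seed(spec$seed, {
    backbone <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # engineered site on the cut allele: GC.GC with the two SNP bases as
    # the internal C's; the uncut allele replaces them and loses the site
    site <- c("G", "C", "A", "G", "C")[seq_len(min(5L, rl))]
    if (e$recognition == "GCNGC") {
      snp_off <- spec$site_start + c(1L, 4L)
    } else {
      snp_off <- spec$site_start + c(1L, rl - 1L)
      site <- strsplit(gsub("N", "A", e$recognition), "")[[1]]
    }
    cut <- backbone
    cut[spec$site_start + seq_len(rl)] <- site
    cut[snp_off + 1L] <- spec$cut_allele
    uncut <- cut
    uncut[snp_off + 1L] <- spec$uncut_allele
    # scrub stray sites elsewhere: mutate the first base of any
    # off-target hit (same base in both alleles) until only the
    # engineered site remains
    for (iter in 1:100) {
      cs <- as.integer(find_sites(paste0(cut, collapse = ""), e))
      us <- as.integer(find_sites(paste0(uncut, collapse = ""), e))
      stray <- sort(unique(c(setdiff(cs, spec$site_start), us)))
      stray <- setdiff(stray, spec$site_start)
      if (!length(stray)) break
      protected <- c(spec$site_start + seq_len(rl), snp_off + 1L)
      cand <- setdiff(stray[1] + seq_len(rl), protected)
      p <- cand[1]
      repl <- if (cut[p] == "T") "A" else "T"
      cut[p] <- repl; uncut[p] <- repl
    }
    cutseq <- paste0(cut, collapse = "")
    uncutseq <- paste0(uncut, collapse = "")
    if (length(find_sites(cutseq, e)) != 1L ||
        length(find_sites(uncutseq, e)) != 0L)
      stop("could not place a unique discriminating site", call. = FALSE)
    list(cut = cutseq, uncut = uncutseq, enzyme = e,
         site_start = spec$site_start, snp_cols = snp_off,
         snp_positions = spec$snp_positions)
  })
}
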