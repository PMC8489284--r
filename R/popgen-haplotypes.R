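#' Read an aligned promoter panel from FASTA
#'
#' Sequences must be pre-aligned (equal length) over the alphabet
#' `A,C,G,T,N,-`. ATG-relative coordinates follow the convention +1 =
#' first base of ATG, strictly negative upstream, no position 0; by
#' default the last alignment column is taken as +1 (a panel spanning
#' `-L+1 .. +1`), or pass the ATG column explicitly.
#'
#' @param path FASTA file of aligned sequences.
#' @param atg_col 1-based alignment column of the A of ATG (default: the
#'   last column).
#' @return A `"promoter_panel"` object (see
#'   [generate_promoter_panel()]).
#' @export
read_promoter_panel <- function(path, atg_col = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dna))
  names(seqs) <- sub("\\s.*$", "", names(dna))
  promoter_panel(seqs, atg_col)
}

#' Construct a promoter panel from sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param atg_col 1-based column of the A of ATG (default last column).
#' @return A `"promoter_panel"` object.
#' @export
promoter_panel <- function(seqs, atg_col = NULL) {
  if (!length(seqs)) stop("empty panel", call. = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("aligned sequences must all have the same length", call. = FALSE)
  if (any(!grepl("^[ACGTN-]*$", seqs)))
    stop("alphabet must be A,C,G,T,N,-", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  if (is.null(atg_col)) atg_col <- L
  structure(list(seqs = seqs, atg_col = as.integer(atg_col), length = L),
            class = "promoter_panel")
}

panel_matrix <- function(panel) {
  do.call(rbind, strsplit(unname(panel$seqs), ""))
}

# columns free of gap/N in every sequence (complete-deletion policy);
# pairwise deletion handles missingness per sequence pair instead
used_columns <- function(M, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (policy == "complete") which(colSums(M == "N" | M == "-") == 0) else
    seq_len(ncol(M))
}

#' Call variant sites on a promoter panel
#'
#' Reports every alignment column with two or more distinct A/C/G/T
#' alleles, with ATG-relative positions. Under the default complete-
#' deletion policy, columns containing any gap or N in any sequence are
#' excluded before calling (the same columns excluded from diversity
#' estimation); under pairwise deletion gap/N characters are ignored
#' within each column.
#'
#' @param panel A `"promoter_panel"`.
#' @param policy `"complete"` (default) or `"pairwise"` gap/N handling.
#' @return A list of class `"snp_matrix"`: `positions` (ATG-relative),
#'   `columns` (alignment columns), `alleles` (sequence x position
#'   character matrix), `multiallelic` (logical per position),
#'   `L_effective` (columns used).
#' @examples
#' panel <- generate_promoter_panel(seed = 1)
#' call_variant_sites(panel)
#' @export
call_variant_sites <- function(panel, policy = c("complete", "pairwise")) {
  stopifnot(inherits(panel, "promoter_panel"))
  policy <- match.arg(policy)
  M <- panel_matrix(panel)
  use <- used_columns(M, policy)
  n_alleles <- vapply(use, function(j) {
    length(unique(M[, j][M[, j] %in% c("A", "C", "G", "T")]))
  }, 0L)
  var_cols <- use[n_alleles >= 2L]
  alleles <- M[, var_cols, drop = FALSE]
  dimnames(alleles) <- list(names(panel$seqs),
                            promoter_col_to_pos(var_cols, panel$atg_col))
  structure(list(
    positions = promoter_col_to_pos(var_cols, panel$atg_col),
    columns = var_cols,
    alleles = alleles,
    multiallelic = n_alleles[n_alleles >= 2L] > 2L,
    L_effective = length(use)),
    class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d variant site(s) over %d used columns\n",
              length(x$positions), x$L_effective))
  if (length(x$positions))
    cat("positions:", paste(x$positions, collapse = ", "), "\n")
  invisible(x)
}

#' Nucleotide diversity (pi)
#'
#' Nei-Li nucleotide diversity: the average proportion of differing
#' sites between two sequences of the panel,
#' `pi = sum over pairs d_ij / (C(n,2) * L_effective)`, where `d_ij`
#' counts differing used columns. Under complete deletion (default)
#' `L_effective` excludes every column containing a gap or N; under
#' pairwise deletion each pair is compared over its own gap/N-free
#' columns and the per-pair proportions are averaged.
#'
#' @param panel A `"promoter_panel"`.
#' @param policy `"complete"` (default) or `"pairwise"`.
#' @return List of class `"diversity_estimate"`: `pi`, `n`,
#'   `L_effective` (`NA` under pairwise deletion), `n_pairs`.
#' @examples
#' pi <- nucleotide_diversity(generate_promoter_panel(seed = 1))
#' pi$pi
#' @export
nucleotide_diversity <- function(panel, policy = c("complete", "pairwise")) {
  stopifnot(inherits(panel, "promoter_panel"))
  policy <- match.arg(policy)
  n <- length(panel$seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  M <- panel_matrix(panel)
  if (policy == "complete") {
    use <- used_columns(M, "complete")
    if (!length(use))
      stop("no usable columns: L_effective = 0", call. = FALSE)
    M <- M[, use, drop = FALSE]
    total <- 0
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      total <- total + sum(M[i, ] != M[j, ])
    pi <- total / (choose(n, 2) * length(use))
    Leff <- length(use)
  } else {
    props <- numeric(0)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      ok <- M[i, ] %in% c("A", "C", "G", "T") &
            M[j, ] %in% c("A", "C", "G", "T")
      if (!any(ok)) stop("a pair shares no usable column", call. = FALSE)
      props <- c(props, sum(M[i, ok] != M[j, ok]) / sum(ok))
    }
    pi <- mean(props)
    Leff <- NA_integer_
  }
  structure(list(pi = pi, n = n, L_effective = Leff,
                 n_pairs = choose(n, 2)),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("pi = %.4g  (n = %d sequences, %s columns, %d pairs)\n",
              x$pi, x$n,
              if (is.na(x$L_effective)) "pairwise-deleted" else x$L_effective,
              x$n_pairs))
  invisible(x)
}

#' Group sequences into haplotypes
#'
#' Sequences with identical allele vectors over the variant sites share
#' a haplotype. Labels `Hap1, Hap2, ...` are ordered by descending
#' frequency, ties broken by first occurrence in the input; the pattern
#' table reports each haplotype's alleles and its SNP-count difference
#' from the reference `Hap1` (the most frequent haplotype). A sequence
#' with N at a variant site is labelled `"ambiguous"` unless its
#' non-N alleles are compatible with exactly one observed pattern.
#'
#' @param m A `"snp_matrix"` from [call_variant_sites()].
#' @return List of class `"haplotype_grouping"`: `labels` (per
#'   sequence), `patterns` (data frame: `haplotype`, `n_lines`, one
#'   column per SNP position, `snps_vs_hap1`).
#' @examples
#' hg <- group_haplotypes(call_variant_sites(generate_promoter_panel(seed = 1)))
#' hg$patterns
#' @export
group_haplotypes <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  A <- m$alleles
  n <- nrow(A)
  if (!n) stop("need at least 1 sequence", call. = FALSE)
  if (!ncol(A)) {
    labels <- stats::setNames(rep("Hap1", n), rownames(A))
    pat <- data.frame(haplotype = "Hap1", n_lines = n, snps_vs_hap1 = 0L,
                      stringsAsFactors = FALSE)
    return(structure(list(labels = labels, patterns = pat),
                     class = "haplotype_grouping"))
  }
  key <- apply(A, 1L, paste0, collapse = "")
  clean <- !grepl("[N-]", key)
  pat_keys <- unique(key[clean])
  freq <- vapply(pat_keys, function(k) sum(key == k), 0L)
  first <- vapply(pat_keys, function(k) which(key == k)[1], 0L)
  ord <- order(-freq, first)
  pat_keys <- pat_keys[ord]
  labels <- rep("ambiguous", n)
  for (h in seq_along(pat_keys)) labels[key == pat_keys[h]] <-
    paste0("Hap", h)
  # N-tolerant rescue: assign iff compatible with exactly one pattern
  for (i in which(!clean)) {
    ai <- A[i, ]
    comp <- vapply(pat_keys, function(k) {
      pk <- strsplit(k, "")[[1]]
      all(ai == pk | ai %in% c("N", "-"))
    }, TRUE)
    if (sum(comp) == 1L) labels[i] <- paste0("Hap", which(comp))
  }
  names(labels) <- rownames(A)
  ref <- strsplit(pat_keys[1], "")[[1]]
  pat <- data.frame(haplotype = paste0("Hap", seq_along(pat_keys)),
                    n_lines = vapply(seq_along(pat_keys), function(h)
                      sum(labels == paste0("Hap", h)), 0L),
                    stringsAsFactors = FALSE)
  allele_cols <- do.call(rbind, strsplit(pat_keys, ""))
  colnames(allele_cols) <- colnames(A)
  pat <- cbind(pat, as.data.frame(allele_cols, stringsAsFactors = FALSE))
  pat$snps_vs_hap1 <- vapply(seq_along(pat_keys), function(h)
    sum(strsplit(pat_keys[h], "")[[1]] != ref), 0L)
  structure(list(labels = labels, patterns = pat),
            class = "haplotype_grouping")
}

#' @export
print.haplotype_grouping <- function(x, ...) {
  cat(sprintf("%d haplotype(s) over %d sequence(s)\n",
              nrow(x$patterns), length(x$labels)))
  print(x$patterns)
  invisible(x)
}

#' Haplotype-trait association
#'
#' One-way ANOVA of a quantitative trait across haplotype groups,
#' followed by Duncan's multiple range test: the design used to ask
#' whether promoter haplotypes associate with expression level or P
#' content across cultivar sets. Haplotypes with fewer than 2 lines are
#' excluded with a warning.
#'
#' @param labels Named haplotype labels (line id -> haplotype), as from
#'   [group_haplotypes()].
#' @param traits Named numeric vector (line id -> trait value).
#' @param alpha Significance level for the letter grouping.
#' @return List of class `"haplotype_association"`: `anova` (F, df, p),
#'   `groups` (per-haplotype mean, sd, n, Duncan letters).
#' @export
haplotype_association <- function(labels, traits, alpha = 0.05) {
  shared <- intersect(names(labels), names(traits))
  if (!length(shared)) stop("no shared line ids", call. = FALSE)
  lab <- labels[shared]; tr <- traits[shared]
  keep_h <- names(which(table(lab) >= 2L))
  keep_h <- setdiff(keep_h, "ambiguous")
  dropped <- setdiff(unique(lab), keep_h)
  if (length(dropped))
    warning("excluding haplotype(s) with <2 lines (or ambiguous): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  sel <- lab %in% keep_h
  groups <- split(unname(tr[sel]), lab[sel])
  if (length(groups) < 2L)
    stop("need >= 2 haplotypes with >= 2 lines each", call. = FALSE)
  fit <- one_way_anova(groups)
  letters_df <- duncan_mrt(groups, alpha)
  letters_df$sd <- vapply(letters_df$group, function(g)
    stats::sd(groups[[g]]), 0)
  structure(list(anova = fit[c("F", "df1", "df2", "p")],
                 groups = letters_df[c("group", "mean", "sd", "n",
                                       "letters")]),
            class = "haplotype_association")
}

#' @export
print.haplotype_association <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(x$groups)
  cat("Groups sharing a letter do not differ (Duncan's MRT)\n")
  invisible(x)
}

#' Write a promoter panel as aligned FASTA
#'
#' @param panel A `"promoter_panel"`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoter_panel <- function(panel, path) {
  dna <- Biostrings::DNAStringSet(panel$seqs)
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}
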