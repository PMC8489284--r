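#' Subgenome-partitioned protein database
#'
#' Validating constructor for the locus-resolved protein database: one
#' row per locus with its subgenome (A/B/D), chromosome label (e.g.
#' `"4B"`), homoeolog family id and amino-acid sequence.
#'
#' @param df Data frame with columns `locus_id`, `subgenome`,
#'   `chromosome`, `family_id`, `sequence`.
#' @param strict If `TRUE` (default) a family with more than one locus
#'   in the same subgenome is rejected; if `FALSE` such extra loci are
#'   split off into their own single-locus families (suffix `.par<k>`),
#'   the permissive reading of within-subgenome paralogs.
#' @return The data frame with class `"subgenome_proteindb"`.
#' @examples
#' subgenome_proteindb(data.frame(
#'   locus_id = "G1.A", subgenome = "A", chromosome = "1A",
#'   family_id = "G1", sequence = "MKAAA"))
#' @export
subgenome_proteindb <- function(df, strict = TRUE) {
  need <- c("locus_id", "subgenome", "chromosome", "family_id", "sequence")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  rownames(df) <- NULL
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id in database", call. = FALSE)
  if (nrow(df) && !all(df$subgenome %in% c("A", "B", "D")))
    stop("subgenome must be one of A, B, D", call. = FALSE)
  bad <- df$subgenome != substring(df$chromosome, nchar(df$chromosome))
  if (any(bad))
    stop("subgenome inconsistent with chromosome suffix for: ",
         paste(df$locus_id[bad], collapse = ", "), call. = FALSE)
  dup <- duplicated(df[c("family_id", "subgenome")])
  if (any(dup)) {
    if (strict)
      stop(">1 locus per subgenome in family(ies): ",
           paste(unique(df$family_id[dup]), collapse = ", "),
           " (use strict = FALSE to split paralogs)", call. = FALSE)
    k <- stats::ave(seq_len(nrow(df)),
                    paste(df$family_id, df$subgenome),
                    FUN = seq_along)
    df$family_id[k > 1L] <- paste0(df$family_id[k > 1L], ".par",
                                   k[k > 1L] - 1L)
  }
  class(df) <- c("subgenome_proteindb", "data.frame")
  df
}

#' @export
print.subgenome_proteindb <- function(x, ...) {
  cat(sprintf("<subgenome_proteindb> %d loci, %d families (A:%d B:%d D:%d)\n",
              nrow(x), length(unique(x$family_id)),
              sum(x$subgenome == "A"), sum(x$subgenome == "B"),
              sum(x$subgenome == "D")))
  invisible(x)
}

#' Read/write the protein database as FASTA
#'
#' Headers follow the contract `locusID|subgenome|chromosome|familyID`.
#' `read_proteome_fasta()` also accepts a plain FASTA plus a sidecar TSV
#' locus map (columns `locus_id`, `subgenome`, `chromosome`,
#' `family_id`) for databases whose headers carry only the locus id.
#'
#' @param db A [subgenome_proteindb()].
#' @param path FASTA file path.
#' @param locus_map Optional data frame or TSV path mapping locus ids to
#'   subgenome/chromosome/family.
#' @param strict Passed to [subgenome_proteindb()].
#' @return `read_proteome_fasta()` returns a [subgenome_proteindb()];
#'   `write_proteome_fasta()` returns `path` invisibly.
#' @export
write_proteome_fasta <- function(db, path) {
  stopifnot(inherits(db, "subgenome_proteindb"))
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- paste(db$locus_id, db$subgenome, db$chromosome,
                     db$family_id, sep = "|")
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path, locus_map = NULL, strict = TRUE) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  if (is.null(locus_map)) {
    parts <- strsplit(hdr, "|", fixed = TRUE)
    if (any(lengths(parts) != 4L))
      stop("FASTA header not of the form locusID|subgenome|chromosome|familyID",
           call. = FALSE)
    df <- data.frame(locus_id = vapply(parts, `[`, "", 1L),
                     subgenome = vapply(parts, `[`, "", 2L),
                     chromosome = vapply(parts, `[`, "", 3L),
                     family_id = vapply(parts, `[`, "", 4L),
                     sequence = as.character(aa), stringsAsFactors = FALSE)
  } else {
    if (is.character(locus_map))
      locus_map <- utils::read.table(locus_map, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
    ids <- sub("\\s.*$", "", hdr)
    m <- match(ids, locus_map$locus_id)
    if (anyNA(m))
      stop("loci missing from locus map: ",
           paste(utils::head(ids[is.na(m)]), collapse = ", "), call. = FALSE)
    df <- data.frame(locus_id = ids,
                     subgenome = locus_map$subgenome[m],
                     chromosome = locus_map$chromosome[m],
                     family_id = locus_map$family_id[m],
                     sequence = as.character(aa), stringsAsFactors = FALSE)
  }
  subgenome_proteindb(df, strict = strict)
}

#' Index a protein database for peptide lookup
#'
#' Builds an exact-substring lookup structure over all locus sequences.
#' Peptide-to-proteome matching at a 100% identity cut-off for a
#' full-length peptide is exact substring search, so the index simply
#' prepares the sequences (optionally collapsing I/L, which isobaric
#' mass spectrometry cannot distinguish) for vectorised fixed-string
#' scans; results are independent of insertion order.
#'
#' @param db A [subgenome_proteindb()].
#' @param collapse_il If `TRUE`, treat I and L as equivalent during
#'   matching. Default `FALSE`: the genomic database distinguishes them.
#' @return An object of class `"peptide_index"`.
#' @export
index_proteome <- function(db, collapse_il = FALSE) {
  stopifnot(inherits(db, "subgenome_proteindb"))
  seqs <- db$sequence
  if (collapse_il) seqs <- gsub("I", "L", seqs, fixed = TRUE)
  structure(list(db = db, seqs = seqs, collapse_il = collapse_il),
            class = "peptide_index")
}

#' Map one peptide against the indexed proteome
#'
#' Finds every locus whose protein contains the peptide as an exact,
#' full-length substring (the 100% identity criterion) and classifies
#' the match specificity: `locus_unique` (one locus), `family_shared`
#' (several loci, all one family), `cross_family` (loci from at least
#' two families) or `unmatched`.
#'
#' @param peptide Non-empty uppercase peptide string.
#' @param index A [index_proteome()] result.
#' @return A list of class `"peptide_match"`: `peptide`, `loci`
#'   (character vector of locus ids), `specificity`.
#' @examples
#' db <- generate_subgenome_proteome(simulation_spec(seed = 1, n_families = 3))
#' idx <- index_proteome(db)
#' map_peptide(substr(db$sequence[1], 10, 24), idx)
#' @export
map_peptide <- function(peptide, index) {
  stopifnot(inherits(index, "peptide_index"))
  if (!nzchar(peptide) || !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptide))
    stop("peptide must be a non-empty uppercase amino-acid string",
         call. = FALSE)
  q <- if (index$collapse_il) gsub("I", "L", peptide, fixed = TRUE) else peptide
  hit <- which(grepl(q, index$seqs, fixed = TRUE))
  loci <- index$db$locus_id[hit]
  fams <- unique(index$db$family_id[hit])
  specificity <- if (!length(loci)) "unmatched"
    else if (length(loci) == 1L) "locus_unique"
    else if (length(fams) == 1L) "family_shared"
    else "cross_family"
  structure(list(peptide = peptide, loci = loci, specificity = specificity),
            class = "peptide_match")
}

#' Map many peptides
#'
#' @param peptides Character vector of peptides.
#' @param index A [index_proteome()] result.
#' @return Data frame of class `"peptide_match_table"`: `peptide`,
#'   `loci` (comma-separated), `specificity`.
#' @export
map_peptides <- function(peptides, index) {
  ms <- lapply(peptides, map_peptide, index = index)
  out <- data.frame(
    peptide = peptides,
    loci = vapply(ms, function(m) paste(m$loci, collapse = ","), ""),
    specificity = vapply(ms, function(m) m$specificity, ""),
    stringsAsFactors = FALSE)
  class(out) <- c("peptide_match_table", "data.frame")
  out
}

#' Assign a protein to specific homoeologs
#'
#' Protein-level rule: the assigned loci are the union of loci hit by
#' the protein's `locus_unique` peptides, which must fall within one
#' family. A protein supported only by `family_shared` peptides (or
#' only cross-family ones) cannot be resolved to specific homoeologs
#' and is returned `unassigned` (its family, when unambiguous, is still
#' recorded). The expression category is the sorted set of assigned
#' subgenomes (`A`, `B+D`, `A+B+D`, ...) and the bias flag separates
#' `single_bias` (one locus expressed, family has homoeologs),
#' `singleton` (family has a single locus) and `multi` (several
#' homoeologs expressed).
#'
#' @param protein_id Identifier for the reported protein.
#' @param matches List of [map_peptide()] results (or a
#'   `peptide_match_table`) for this protein's peptides.
#' @param db The [subgenome_proteindb()].
#' @return A list of class `"homoeolog_assignment"`: `protein_id`,
#'   `family_id`, `assigned_loci`, `category`, `bias_flag`.
#' @export
assign_protein <- function(protein_id, matches, db) {
  stopifnot(inherits(db, "subgenome_proteindb"))
  if (inherits(matches, "peptide_match_table")) {
    matches <- lapply(seq_len(nrow(matches)), function(i) {
      loci <- strsplit(matches$loci[i], ",", fixed = TRUE)[[1]]
      list(peptide = matches$peptide[i], loci = loci[nzchar(loci)],
           specificity = matches$specificity[i])
    })
  }
  if (!length(matches)) stop("need at least one peptide match", call. = FALSE)
  spec_of <- vapply(matches, function(m) m$specificity, "")
  uniq <- matches[spec_of == "locus_unique"]
  fam_of_locus <- stats::setNames(db$family_id, db$locus_id)
  sg_of_locus <- stats::setNames(db$subgenome, db$locus_id)
  fam_size <- table(db$family_id)

  unassigned <- function(family_id = NA_character_) {
    structure(list(protein_id = protein_id, family_id = family_id,
                   assigned_loci = character(0), category = "unassigned",
                   bias_flag = "unassigned"),
              class = "homoeolog_assignment")
  }
  if (!length(uniq)) {
    shared <- matches[spec_of == "family_shared"]
    fams <- unique(unlist(lapply(shared, function(m)
      unique(fam_of_locus[m$loci]))))
    return(unassigned(if (length(fams) == 1L) fams else NA_character_))
  }
  loci <- sort(unique(unlist(lapply(uniq, `[[`, "loci"))))
  fams <- unique(fam_of_locus[loci])
  if (length(fams) > 1L)
    stop("conflicting locus_unique peptides across families for ",
         protein_id, ": ", paste(fams, collapse = ", "), call. = FALSE)
  sgs <- sort(unique(sg_of_locus[loci]))
  category <- paste(sgs, collapse = "+")
  nfam <- as.integer(fam_size[[fams]])
  bias_flag <- if (length(loci) >= 2L) "multi"
    else if (nfam == 1L) "singleton" else "single_bias"
  structure(list(protein_id = protein_id, family_id = unname(fams),
                 assigned_loci = loci, category = category,
                 bias_flag = bias_flag),
            class = "homoeolog_assignment")
}

#' Assign every protein of a quantification table
#'
#' Groups the peptide match table by reported protein identity (the
#' `protein_id` column, or `source_proteins` when absent) and runs
#' [assign_protein()] on each group. The reported identity is what the
#' upstream search produced; the subgenome resolution comes entirely
#' from re-mapping the peptides here. Proteins whose unique peptides
#' conflict across families are excluded with a warning.
#'
#' @param quant A `peptide_quant` table.
#' @param index A [index_proteome()] result.
#' @return List of `homoeolog_assignment` objects, named by protein id.
#' @export
assign_proteins <- function(quant, index) {
  mt <- map_peptides(quant$peptide, index)
  ids <- quant$protein_id %||% quant$source_proteins
  src <- strsplit(ids, ",", fixed = TRUE)
  row_of <- split(rep(seq_along(src), lengths(src)), unlist(src))
  out <- list()
  for (pid in names(row_of)) {
    rows <- row_of[[pid]]
    a <- tryCatch(assign_protein(pid, mt[rows, , drop = FALSE], index$db),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(a)) out[[pid]] <- a
  }
  out
}

#' Summarise homoeolog assignments
#'
#' Tabulates counts and percentages per expression category, bias flag,
#' subgenome and chromosome. Percentages are over the assigned total
#' and reported with 1-decimal half-up rounding, the convention used
#' for the published summary figures.
#'
#' @param assignments List of `homoeolog_assignment` objects, or a data
#'   frame with columns `category`, `bias_flag` (and optionally
#'   `chromosome` counts via assigned loci).
#' @param db Optional [subgenome_proteindb()] used to resolve the
#'   chromosomes of assigned loci.
#' @return A list of class `"assignment_summary"` with components
#'   `n_assigned`, `by_category`, `by_bias`, `by_subgenome`,
#'   `by_chromosome` (each a data frame with `count` and `pct`).
#' @examples
#' # the published bias proportions from their raw counts:
#' s <- summarize_assignment(data.frame(
#'   category = c(rep("A", 738), rep("B", 62), rep("A+B", 215)),
#'   bias_flag = c(rep("single_bias", 738), rep("singleton", 62),
#'                 rep("multi", 215))))
#' s$by_bias
#' @export
summarize_assignment <- function(assignments, db = NULL) {
  if (is.data.frame(assignments)) {
    cat_v <- assignments$category
    bias_v <- assignments$bias_flag
    loci <- character(0)
  } else {
    assigned <- Filter(function(a) a$category != "unassigned", assignments)
    cat_v <- vapply(assigned, `[[`, "", "category")
    bias_v <- vapply(assigned, `[[`, "", "bias_flag")
    loci <- unlist(lapply(assigned, `[[`, "assigned_loci"))
  }
  n <- length(cat_v)
  tab <- function(v, levels = NULL) {
    t <- if (is.null(levels)) table(v) else table(factor(v, levels = levels))
    data.frame(count = as.integer(t),
               pct = if (n) round_half_up(100 * as.integer(t) / n, 1) else
                 rep(0, length(t)),
               row.names = names(t))
  }
  cat_levels <- c("A", "B", "D", "A+B", "A+D", "B+D", "A+B+D")
  sg_v <- unlist(strsplit(cat_v, "+", fixed = TRUE))
  by_chr <- NULL
  if (!is.null(db) && length(loci)) {
    chr <- stats::setNames(db$chromosome, db$locus_id)[loci]
    by_chr <- chromosome_distribution_counts(chr)
  }
  structure(list(n_assigned = n,
                 by_category = tab(cat_v, cat_levels),
                 by_bias = tab(bias_v, c("single_bias", "singleton", "multi")),
                 by_subgenome = tab(sg_v, c("A", "B", "D")),
                 by_chromosome = by_chr),
            class = "assignment_summary")
}

#' @export
print.assignment_summary <- function(x, ...) {
  cat(sprintf("Homoeolog assignment summary (%d assigned proteins)\n\n",
              x$n_assigned))
  cat("By expression category:\n"); print(x$by_category)
  cat("\nBy bias class:\n"); print(x$by_bias)
  cat("\nBy subgenome (loci of multi-homoeolog proteins count once each):\n")
  print(x$by_subgenome)
  if (!is.null(x$by_chromosome)) {
    cat("\nBy chromosome (per assigned locus):\n"); print(x$by_chromosome)
  }
  invisible(x)
}
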