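#' Locus abundance matrices for multi-homoeolog proteins
#'
#' For each family whose protein is expressed from 2-3 homoeologs,
#' collects the per-replicate abundances of every contributing locus
#' (locus-unique peptide evidence only) into one matrix per family,
#' ready for the balance test. Families where some contributing locus
#' lacks quantification are reported untestable.
#'
#' @param quants A `protein_quant` data frame (one row per locus).
#' @param assignments List of `homoeolog_assignment` objects.
#' @param condition Which channels to use: `"NP"`, `"CK"` or `"both"`
#'   (default `"NP"`, the treatment in which bias is asked about).
#' @return Named list (by family id) of matrices, rows = loci, columns =
#'   replicates; untestable family ids are in the `untestable`
#'   attribute.
#' @export
locus_abundance_matrices <- function(quants, assignments,
                                     condition = c("NP", "CK", "both")) {
  condition <- match.arg(condition)
  ch <- channel_cols(quants)
  if (condition != "both")
    ch <- grep(paste0("^", condition), ch, value = TRUE)
  multi <- Filter(function(a) a$bias_flag == "multi", assignments)
  out <- list(); untestable <- character(0)
  for (a in multi) {
    rows <- match(a$assigned_loci, quants$protein_id)
    if (anyNA(rows)) { untestable <- c(untestable, a$family_id); next }
    m <- as.matrix(quants[rows, ch, drop = FALSE])
    rownames(m) <- a$assigned_loci
    if (any(!is.finite(m)) || any(m <= 0)) {
      untestable <- c(untestable, a$family_id); next
    }
    out[[a$family_id]] <- m
  }
  attr(out, "untestable") <- unique(untestable)
  out
}

#' Test expression balance across homoeologs
#'
#' One-way ANOVA across the contributing loci of one family, on log
#' abundances, with loci as groups and replicates as observations:
#' p < `alpha` declares the family's expression unbalanced. For two
#' loci this is equivalent to the pooled two-sample t-test (F = t^2).
#'
#' @param m Numeric matrix, rows = loci (>= 2), columns = replicate
#'   abundances (> 0, >= 2 per locus).
#' @param alpha Significance level (default 0.05, the published
#'   criterion).
#' @return List: `balance` (`"balanced"`/`"unbalanced"`), `p`, `F`,
#'   `df1`, `df2`.
#' @examples
#' m <- rbind(a = c(100, 110, 95), b = c(1000, 1050, 980))
#' test_balance(m)
#' @export
test_balance <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need >= 2 loci", call. = FALSE)
  if (ncol(m) < 2L) stop("need >= 2 replicates per locus", call. = FALSE)
  if (any(m <= 0)) stop("abundances must be positive", call. = FALSE)
  groups <- lapply(seq_len(nrow(m)), function(i) log(m[i, ]))
  names(groups) <- rownames(m) %||% paste0("locus", seq_len(nrow(m)))
  fit <- one_way_anova(groups)
  list(balance = if (fit$p < alpha) "unbalanced" else "balanced",
       p = fit$p, F = fit$F, df1 = fit$df1, df2 = fit$df2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Balance test over all multi-homoeolog families
#'
#' @param mats Output of [locus_abundance_matrices()].
#' @param alpha Significance level.
#' @return Data frame: `family_id`, `n_loci`, `p`, `balance`.
#' @export
test_balance_all <- function(mats, alpha = 0.05) {
  rows <- lapply(names(mats), function(f) {
    r <- test_balance(mats[[f]], alpha)
    data.frame(family_id = f, n_loci = nrow(mats[[f]]), p = r$p,
               balance = r$balance, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(0), n_loci = integer(0),
               p = numeric(0), balance = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

WHEAT_CHROMOSOMES <- paste0(rep(1:7, each = 3), c("A", "B", "D"))

chromosome_distribution_counts <- function(chr_labels) {
  known <- chr_labels %in% WHEAT_CHROMOSOMES
  if (any(!known))
    warning("skipping unknown chromosome label(s): ",
            paste(unique(chr_labels[!known]), collapse = ", "),
            call. = FALSE)
  t <- table(factor(chr_labels[known], levels = WHEAT_CHROMOSOMES))
  data.frame(chromosome = WHEAT_CHROMOSOMES, count = as.integer(t),
             stringsAsFactors = FALSE)
}

#' Chromosome distribution of assigned loci
#'
#' Counts assigned loci over the 21 wheat chromosomes (1A..7D); a
#' protein assigned to several homoeologs contributes one count per
#' locus. Unknown chromosome labels are reported and skipped.
#'
#' @param assignments List of `homoeolog_assignment` objects.
#' @param db The [subgenome_proteindb()] carrying chromosome tags.
#' @return Data frame `chromosome`, `count` over all 21 labels; total
#'   equals the number of assigned loci.
#' @export
chromosome_distribution <- function(assignments, db) {
  stopifnot(inherits(db, "subgenome_proteindb"))
  loci <- unlist(lapply(Filter(function(a) a$category != "unassigned",
                               assignments), `[[`, "assigned_loci"))
  if (!length(loci))
    return(data.frame(chromosome = WHEAT_CHROMOSOMES,
                      count = integer(21), stringsAsFactors = FALSE))
  chr <- stats::setNames(db$chromosome, db$locus_id)[loci]
  chromosome_distribution_counts(unname(chr))
}
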