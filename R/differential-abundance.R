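channel_cols <- function(table) {
  grep("^(CK|NP)[0-9]+$", names(table), value = TRUE)
}

#' Normalise reporter channels
#'
#' Per-channel rescaling so that every channel has equal total (or
#' median) intensity, removing loading differences between isobaric
#' channels while preserving within-channel structure.
#'
#' @param table A `peptide_quant` data frame (columns `CK*`, `NP*`).
#' @param method `"total_sum"` (default), `"median"` or `"none"`.
#' @return The table with rescaled channel columns; the common target
#'   is the mean of the per-channel statistics, so the overall intensity
#'   scale is preserved.
#' @export
normalize_channels <- function(table, method = c("total_sum", "median", "none")) {
  method <- match.arg(method)
  if (method == "none") return(table)
  ch <- channel_cols(table)
  if (!length(ch)) stop("no reporter channel columns found", call. = FALSE)
  stat <- vapply(table[ch], if (method == "total_sum") sum else stats::median,
                 0)
  if (any(stat == 0))
    stop("channel with all-zero intensities cannot be normalised: ",
         paste(ch[stat == 0], collapse = ", "), call. = FALSE)
  target <- mean(stat)
  for (k in seq_along(ch)) table[[ch[k]]] <- table[[ch[k]]] * target / stat[k]
  table
}

#' Protein-level quantification from unique peptides
#'
#' Rolls peptide reporter intensities up to proteins: a protein's
#' abundance in each channel is the sum of reporter areas over its
#' `locus_unique` peptides (shared peptides carry no locus-resolved
#' information and are discarded), mirroring quantification by unique
#' peptide reporter peak area. The per-protein NP/CK fold change is the
#' mean over NP replicates of `NP_i / mean(CK)`; a protein with no
#' unique peptide is `not_quantified`.
#'
#' @param table A `peptide_quant` data frame.
#' @param matches A `peptide_match_table` from [map_peptides()] covering
#'   every peptide in `table`.
#' @return Data frame of class `"protein_quant"`: `protein_id`, one
#'   column per channel, `n_unique_peptides`, `ratio`, `p_value`
#'   (two-sided pooled t-test on log abundances), `reg_class` (filled by
#'   [call_pdrps()], initialised `"unchanged"`/`"not_quantified"`).
#' @export
quantify_proteins <- function(table, matches) {
  stopifnot(inherits(matches, "data.frame"))
  m <- match(table$peptide, matches$peptide)
  if (anyNA(m))
    stop("every peptide row needs a specificity record", call. = FALSE)
  spec <- matches$specificity[m]
  loci <- matches$loci[m]
  ch <- channel_cols(table)
  ck <- grep("^CK", ch, value = TRUE)
  np <- grep("^NP", ch, value = TRUE)
  keep <- spec == "locus_unique"
  ids <- sort(unique(loci[keep]))
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (cc in ch) out[[cc]] <- NA_real_
  out$n_unique_peptides <- 0L
  rows_of <- split(which(keep), loci[keep])
  for (i in seq_along(ids)) {
    rows <- rows_of[[ids[i]]]
    for (cc in ch) out[[cc]][i] <- sum(table[[cc]][rows])
    out$n_unique_peptides[i] <- length(rows)
  }
  ckm <- rowMeans(out[, ck, drop = FALSE])
  out$ratio <- rowMeans(out[, np, drop = FALSE] / ckm)
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    a <- log(as.numeric(out[i, ck])); b <- log(as.numeric(out[i, np]))
    if (any(!is.finite(c(a, b)))) return(NA_real_)   # zero/missing channel
    student_t(a, b)$p
  }, 0)
  out$reg_class <- "unchanged"
  attr(out, "channels") <- list(ck = ck, np = np)
  class(out) <- c("protein_quant", "data.frame")
  out
}

#' Configuration for responsive-protein calling
#'
#' @param up_threshold Inclusive up-regulation fold-change bound
#'   (default 1.20).
#' @param down_threshold Inclusive down-regulation bound (default 0.83).
#' @param alpha Significance level for the optional p-value gate.
#' @param require_all_replicates Require positive intensity in every
#'   channel (default `TRUE`); proteins failing it are `not_quantified`.
#' @param p_filter_enabled If `TRUE`, calls additionally require
#'   `p_value < alpha`. Default `FALSE`: the published responsive set is
#'   defined by the fold thresholds alone.
#' @return List of class `"pdrp_call_config"`.
#' @export
pdrp_call_config <- function(up_threshold = 1.20, down_threshold = 0.83,
                             alpha = 0.05, require_all_replicates = TRUE,
                             p_filter_enabled = FALSE) {
  if (!(down_threshold < 1 && 1 < up_threshold))
    stop("need down_threshold < 1 < up_threshold", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(up_threshold = up_threshold,
                 down_threshold = down_threshold, alpha = alpha,
                 require_all_replicates = require_all_replicates,
                 p_filter_enabled = p_filter_enabled),
            class = "pdrp_call_config")
}

#' Call responsive proteins
#'
#' Classifies each quantified protein as `up` (fold change >=
#' `up_threshold`), `down` (<= `down_threshold`) or `unchanged`; both
#' thresholds are inclusive. A protein lacking a positive intensity in
#' any required channel is `not_quantified`. The two-sided pooled
#' Student's t-test on log abundances is always computed; it gates the
#' call only when `p_filter_enabled`.
#'
#' @param quants A `protein_quant` data frame.
#' @param cfg A [pdrp_call_config()].
#' @return `quants` with `reg_class` filled, plus a `counts` attribute
#'   (named integer vector over the four classes).
#' @examples
#' \dontrun{
#' calls <- call_pdrps(quants, pdrp_call_config())
#' attr(calls, "counts")
#' }
#' @export
call_pdrps <- function(quants, cfg = pdrp_call_config()) {
  stopifnot(inherits(cfg, "pdrp_call_config"))
  ch <- channel_cols(quants)
  ok <- rep(TRUE, nrow(quants))
  if (cfg$require_all_replicates)
    ok <- Reduce(`&`, lapply(quants[ch], function(x) !is.na(x) & x > 0))
  if (cfg$p_filter_enabled && length(ch) < 4L)
    stop("p-filter needs >= 2 replicates per condition", call. = FALSE)
  cls <- rep("unchanged", nrow(quants))
  up <- ok & quants$ratio >= cfg$up_threshold
  down <- ok & quants$ratio <= cfg$down_threshold
  if (cfg$p_filter_enabled) {
    up <- up & quants$p_value < cfg$alpha
    down <- down & quants$p_value < cfg$alpha
  }
  cls[up] <- "up"; cls[down] <- "down"; cls[!ok] <- "not_quantified"
  quants$reg_class <- cls
  counts <- vapply(c("up", "down", "unchanged", "not_quantified"),
                   function(k) sum(cls == k), 0L)
  attr(quants, "counts") <- counts
  quants
}

#' Concordance between two call sets
#'
#' Per-protein direction comparison between two independently quantified
#' call sets (e.g. isobaric-reporter discovery vs targeted PRM
#' validation): a shared protein is concordant when its log fold changes
#' agree in sign and its regulation classes match.
#'
#' @param callsA,callsB `protein_quant` data frames with `reg_class`.
#' @return List of class `"concordance_report"`: `n_shared`,
#'   `n_concordant`, `fraction`, and the per-protein comparison table.
#' @export
concordance <- function(callsA, callsB) {
  shared <- intersect(callsA$protein_id, callsB$protein_id)
  if (!length(shared))
    stop("no shared protein ids between the two call sets", call. = FALSE)
  a <- callsA[match(shared, callsA$protein_id), ]
  b <- callsB[match(shared, callsB$protein_id), ]
  conc <- sign(log(a$ratio)) == sign(log(b$ratio)) &
    a$reg_class == b$reg_class
  structure(list(n_shared = length(shared), n_concordant = sum(conc),
                 fraction = mean(conc),
                 table = data.frame(protein_id = shared,
                                    ratio_A = a$ratio, ratio_B = b$ratio,
                                    class_A = a$reg_class,
                                    class_B = b$reg_class,
                                    concordant = conc,
                                    stringsAsFactors = FALSE)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordant for %d of %d shared proteins (%.1f%%)\n",
              x$n_concordant, x$n_shared, 100 * x$fraction))
  invisible(x)
}

#' Volcano plot coordinates
#'
#' @param quants A `protein_quant` data frame with `ratio` and
#'   `p_value`.
#' @return Data frame `protein_id`, `log2_ratio`, `neg_log10_p`; a fold
#'   change of 1 maps to x = 0, and p = 0 is clipped to the smallest
#'   positive double before the log.
#' @export
volcano_coordinates <- function(quants) {
  p <- pmax(quants$p_value, .Machine$double.xmin)
  data.frame(protein_id = quants$protein_id,
             log2_ratio = log2(quants$ratio),
             neg_log10_p = -log10(p), stringsAsFactors = FALSE)
}
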