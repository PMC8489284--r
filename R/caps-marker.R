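#' Restriction enzyme definitions
#'
#' A small editable enzyme table drives the in-silico CAPS work. The
#' packaged default table (`inst/extdata/enzymes.tsv`) seeds Fnu4HI
#' (recognition `GCNGC`, top-strand cut 2 bases into the site), the
#' enzyme behind the promoter-haplotype CAPS marker.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence over the IUPAC nucleotide
#'   alphabet (`ACGTRYSWKMBDHVN`).
#' @param cut_offset Bases from the site start to the top-strand cut,
#'   in `[0, nchar(recognition)]`.
#' @return An object of class `"enzyme"`.
#' @examples
#' enzyme("Fnu4HI", "GCNGC", 2)
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", recognition))
    stop("invalid IUPAC code in recognition sequence: ", recognition,
         call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  structure(list(name = as.character(name), recognition = recognition,
                 cut_offset = cut_offset), class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s  %s  cut at +%d\n", x$name, x$recognition,
              x$cut_offset))
  invisible(x)
}

#' Load an enzyme table
#'
#' Reads a TSV with columns `name`, `recognition`, `cut_offset` into a
#' list of [enzyme()] objects. With no argument, the table shipped with
#' the package is used.
#'
#' @param path Path to a TSV file, or `NULL` for the packaged table.
#' @return Named list of `"enzyme"` objects.
#' @export
read_enzymes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "triadquant",
                        mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  enz <- Map(enzyme, tab$name, tab$recognition, tab$cut_offset)
  names(enz) <- tab$name
  enz
}

# IUPAC code -> set of matched bases (N matches ACGT only; an N in the
# *target* sequence is never matched)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_regex <- function(recognition) {
  paste0(vapply(strsplit(recognition, "")[[1]], function(code) {
    paste0("[", paste0(IUPAC_SETS[[code]], collapse = ""), "]")
  }, ""), collapse = "")
}

#' Find restriction sites
#'
#' Scans the top strand of a sequence for all (possibly overlapping)
#' matches of an enzyme's recognition sequence under IUPAC expansion.
#' `N` in the target never matches. `GCNGC` (Fnu4HI) is its own reverse
#' complement, so a single top-strand pass finds every site; for
#' non-palindromic recognitions reverse-strand matches are reported too,
#' flagged by the `strand` attribute.
#'
#' @param seq Nucleotide string over `A,C,G,T,N`.
#' @param e An [enzyme()].
#' @return Integer vector of 0-based site start positions (sorted,
#'   deduplicated across strands), with a `strand` character attribute
#'   (`"+"`/`"-"`) of the same length.
#' @examples
#' find_sites("AAGCAGCAA", enzyme("Fnu4HI", "GCNGC", 2))  # 2
#' @export
find_sites <- function(seq, e) {
  stopifnot(inherits(e, "enzyme"))
  seq <- toupper(seq)
  if (nchar(seq) > 0 && !grepl("^[ACGTN]+$", seq))
    stop("sequence must be over A,C,G,T,N", call. = FALSE)
  scan_one <- function(pattern) {
    if (nchar(seq) < nchar(pattern)) return(integer(0))
    hits <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), seq,
                     perl = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  }
  fwd <- scan_one(e$recognition)
  rc <- revcomp_iupac(e$recognition)
  if (identical(rc, e$recognition)) {
    res <- fwd
    strand <- rep("+", length(fwd))
  } else {
    rev <- setdiff(scan_one(rc), fwd)
    res <- c(fwd, rev)
    strand <- c(rep("+", length(fwd)), rep("-", length(rev)))
    o <- order(res)
    res <- res[o]; strand <- strand[o]
  }
  attr(res, "strand") <- strand
  res
}

IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")

revcomp_iupac <- function(x) {
  paste0(rev(unname(IUPAC_COMP[strsplit(x, "")[[1]]])), collapse = "")
}

#' Digest a sequence in silico
#'
#' Predicts the fragment lengths produced by complete digestion of a
#' linear sequence. Cut positions are `site_start + cut_offset` on the
#' top strand (overhangs are ignored: gel-band prediction depends only
#' on the backbone cut location). Overlapping sites each contribute a
#' cut; with no site the full-length sequence is returned as one
#' fragment.
#'
#' @inheritParams find_sites
#' @return Integer vector of ordered fragment lengths; always sums to
#'   `nchar(seq)`.
#' @examples
#' digest("AAGCAGCAA", enzyme("Fnu4HI", "GCNGC", 2))  # 4 5
#' @export
digest <- function(seq, e) {
  n <- nchar(seq)
  sites <- find_sites(seq, e)
  cuts <- sort(unique(as.integer(sites) + e$cut_offset))
  cuts <- cuts[cuts > 0L & cuts < n]
  diff(c(0L, cuts, n))
}

#' Design CAPS markers for an allele pair
#'
#' Screens a list of enzymes for recognition sites present in exactly
#' one of two equal-length amplicon alleles (position-wise set
#' difference), the in-silico core of cleaved-amplified-polymorphic-
#' sequence (CAPS) genotyping: an enzyme that cuts one allele but not
#' the other turns the SNP into a gel-readable presence/absence of
#' digestion.
#'
#' @param alleleA,alleleB Equal-length amplicon sequences.
#' @param enzymes List of [enzyme()] objects (default: packaged table).
#' @return A data frame of class `"caps_candidates"` with one row per
#'   discriminating site: `enzyme`, `site_pos` (0-based), `cut_allele`
#'   (`"A"` or `"B"`), `fragments_A`, `fragments_B` (comma-separated
#'   lengths), and `min_band_diff`, the smallest pairwise difference
#'   between the two alleles' band sets (gel resolvability); rows are
#'   sorted by decreasing `min_band_diff`. Identical amplicons yield
#'   zero rows.
#' @examples
#' fx <- generate_caps_fixture()
#' design_caps(fx$cut, fx$uncut)
#' @export
design_caps <- function(alleleA, alleleB, enzymes = read_enzymes()) {
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  if (nchar(alleleA) != nchar(alleleB))
    stop("alleles must be equal length", call. = FALSE)
  rows <- list()
  for (e in enzymes) {
    sA <- as.integer(find_sites(alleleA, e))
    sB <- as.integer(find_sites(alleleB, e))
    for (pos in sort(union(setdiff(sA, sB), setdiff(sB, sA)))) {
      fA <- digest(alleleA, e)
      fB <- digest(alleleB, e)
      band_diff <- min(abs(outer(fA, fB, "-")))
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = e$name, site_pos = pos,
        cut_allele = if (pos %in% sA) "A" else "B",
        fragments_A = paste(fA, collapse = ","),
        fragments_B = paste(fB, collapse = ","),
        min_band_diff = band_diff, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enzyme = character(0), site_pos = integer(0),
               cut_allele = character(0), fragments_A = character(0),
               fragments_B = character(0), min_band_diff = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(-out$min_band_diff, out$enzyme, out$site_pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("caps_candidates", "data.frame")
  out
}

#' @export
print.caps_candidates <- function(x, ...) {
  cat(sprintf("CAPS candidates: %d discriminating site(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}
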