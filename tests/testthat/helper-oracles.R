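# Independent brute-force oracles, deliberately coded differently from
# the package implementations they check.

# position-by-position IUPAC scan (0-based starts, top strand only)
naive_iupac_scan <- function(seq, recognition) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  r <- strsplit(recognition, "")[[1]]
  hits <- integer(0)
  if (length(s) < length(r)) return(hits)
  for (i in 0:(length(s) - length(r))) {
    ok <- TRUE
    for (k in seq_along(r)) {
      if (!(s[i + k] %in% sets[[r[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# average pairwise per-site difference over all unordered pairs,
# complete deletion of gap/N columns
brute_pi <- function(seqs) {
  M <- do.call(rbind, strsplit(unname(seqs), ""))
  keep <- apply(M, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  M <- M[, keep, drop = FALSE]
  n <- nrow(M)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, sum(M[i, ] != M[j, ]))
  mean(d) / ncol(M)
}

# substring scan via Biostrings, independent of the grepl-based index
naive_peptide_scan <- function(peptide, db) {
  hits <- Biostrings::vcountPattern(peptide,
                                    Biostrings::AAStringSet(db$sequence))
  db$locus_id[hits > 0]
}

# minimal hand-built database: two triplet families and one singleton,
# sequences engineered so peptide sharing is fully known
tiny_db <- function() {
  shared9 <- "WWWWWWWWW"   # 9-mer planted in both families
  subgenome_proteindb(data.frame(
    locus_id = c("F1.A", "F1.B", "F1.D", "F2.A", "F2.B", "F2.D", "S1.D"),
    subgenome = c("A", "B", "D", "A", "B", "D", "D"),
    chromosome = c("1A", "1B", "1D", "2A", "2B", "2D", "3D"),
    family_id = c("F1", "F1", "F1", "F2", "F2", "F2", "S1"),
    sequence = c(
      paste0("MAAAK", "CCCCCK", shared9, "K"),   # F1.A: unique CCCCCK
      paste0("MAAAK", "DDDDDK", shared9, "K"),   # F1.B: unique DDDDDK
      paste0("MAAAK", "EEEEEK", shared9, "K"),   # F1.D: unique EEEEEK
      paste0("MGGGK", "FFFFFK", shared9, "K"),   # F2.A
      paste0("MGGGK", "HHHHHK", shared9, "K"),   # F2.B
      paste0("MGGGK", "MMMMMK", shared9, "K"),   # F2.D
      "MSSSSSKTTTTTK"),                          # singleton
    stringsAsFactors = FALSE))
}

# reporter table with known channel values for quantification tests
manual_quant <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(peptide = r$peptide, protein_id = r$protein_id,
               source_proteins = r$protein_id,
               CK1 = r$ck[1], CK2 = r$ck[2], CK3 = r$ck[3],
               NP1 = r$np[1], NP2 = r$np[2], NP3 = r$np[3],
               stringsAsFactors = FALSE)
  }))
  class(df) <- c("peptide_quant", "data.frame")
  df
}
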