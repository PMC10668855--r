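# Standard genetic code, sense-codon bookkeeping and small alphabet helpers.

.NUC <- c("T", "C", "A", "G")

.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Sense codons of the standard genetic code
#'
#' @param code named character vector mapping codons to one-letter amino
#'   acids, with stop codons encoded as `"*"`.  Defaults to the standard
#'   code; supply an alternative table for other codes.
#' @return Character vector of the (61 for the standard code) sense codons,
#'   in fixed TCAG order.
#' @export
sense_codons <- function(code = .GENETIC_CODE) {
  names(code)[code != "*"]
}

#' Codon-level bookkeeping for a genetic code
#'
#' Precomputes, for the sense codons, the encoded amino acid, and for every
#' ordered pair of codons whether they differ at exactly one position,
#' whether that change is a transition, and whether it is synonymous.
#'
#' @inheritParams sense_codons
#' @return List with elements `codons`, `aa` (amino acid per codon),
#'   `single` (logical matrix: one-nucleotide difference), `transition`
#'   (logical matrix), `synonymous` (logical matrix), `diff_pos` (integer
#'   matrix, position 1-3 of the single difference, NA otherwise).
#' @export
codon_table <- function(code = .GENETIC_CODE) {
  codons <- sense_codons(code)
  n <- length(codons)
  aa <- unname(code[codons])
  spl <- do.call(rbind, strsplit(codons, ""))
  single <- matrix(FALSE, n, n)
  transition <- matrix(FALSE, n, n)
  diff_pos <- matrix(NA_integer_, n, n)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (p in 1:3) assign(paste0("d", p), outer(spl[, p], spl[, p], "!="))
  ndiff <- get("d1") + get("d2") + get("d3")
  single <- ndiff == 1
  for (p in 1:3) {
    dp <- get(paste0("d", p))
    diff_pos[single & dp] <- p
  }
  for (i in seq_len(n)) {
    js <- which(single[i, ])
    for (j in js) {
      p <- diff_pos[i, j]
      a <- spl[i, p]; b <- spl[j, p]
      transition[i, j] <- (purine[a] == purine[b])
    }
  }
  synonymous <- outer(aa, aa, "==") & single
  list(codons = codons, aa = aa, single = single,
       transition = transition, synonymous = synonymous,
       diff_pos = diff_pos)
}

# cached standard-code table (built once at load)
.codon_env <- new.env(parent = emptyenv())
std_codon_table <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- codon_table()
  .codon_env$tab
}

#' Identify 4-fold degenerate codon columns
#'
#' A codon column is 4-fold degenerate when every non-missing codon in the
#' column belongs to a codon family whose third position is free (all four
#' third-position nucleotides encode the same amino acid) and all taxa share
#' the same first two nucleotides.
#'
#' @param codons character vector of codons observed in one alignment
#'   column (missing entries `NA`).
#' @inheritParams sense_codons
#' @return `TRUE` if the column qualifies as 4-fold degenerate.
#' @export
is_fourfold_column <- function(codons, code = .GENETIC_CODE) {
  obs <- codons[!is.na(codons)]
  if (length(obs) == 0L) return(FALSE)
  pre <- substr(obs, 1, 2)
  if (length(unique(pre)) != 1L) return(FALSE)
  fam <- paste0(pre[1], c("T", "C", "A", "G"))
  aas <- code[fam]
  length(unique(aas)) == 1L && all(aas != "*")
}
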