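# Alignment container: a character matrix (taxa x sites) with an alphabet tag.
# DNA and AA alignments store one symbol per cell; codon alignments store one
# codon (3-letter string) per cell.  Missing data are NA internally; on disk
# '-', '?', 'N' (DNA) and 'X' (AA) all read back as missing.

MISSING_DNA <- c("-", "?", "N", "n")
MISSING_AA <- c("-", "?", "X", "x")

#' Construct an alignment
#'
#' @param mat character matrix, taxa in rows (rownames = taxon labels),
#'   sites in columns.  For `alphabet = "CODON"` each cell is a codon
#'   (three-letter string).  Missing cells are `NA`.
#' @param alphabet one of `"DNA"`, `"AA"`, `"CODON"`.
#' @return Object of class `aln`.
#' @export
new_alignment <- function(mat, alphabet = c("DNA", "AA", "CODON")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("taxon labels must be unique")
  if (alphabet == "CODON") {
    vals <- mat[!is.na(mat)]
    bad <- setdiff(unique(vals), sense_codons())
    if (length(bad))
      stop("non-sense or stop codons in codon alignment: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(mat = mat, alphabet = alphabet), class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("<aln> %s alignment: %d taxa x %d %s\n", x$alphabet,
              nrow(x$mat), ncol(x$mat),
              if (x$alphabet == "CODON") "codons" else "sites"))
  invisible(x)
}

#' @export
dim.aln <- function(x) dim(x$mat)

aln_taxa <- function(aln) rownames(aln$mat)

#' Convert a codon alignment to its nucleotide matrix
#' @param aln codon alignment (`aln`, alphabet `"CODON"`)
#' @return `aln` with alphabet `"DNA"` and 3x the columns.
#' @export
codon_to_nuc <- function(aln) {
  stopifnot(inherits(aln, "aln"), aln$alphabet == "CODON")
  m <- aln$mat
  out <- matrix(NA_character_, nrow(m), 3L * ncol(m),
                dimnames = list(rownames(m), NULL))
  for (p in 1:3)
    out[, seq(p, by = 3, length.out = ncol(m))] <-
      substr(m, p, p)
  new_alignment(out, "DNA")
}

#' Group nucleotide columns of a codon-structured DNA alignment into codons
#' @param aln DNA alignment whose length is divisible by 3 and whose
#'   non-missing triplets are sense codons; triplets containing any missing
#'   base become missing codons.
#' @return codon `aln`
#' @export
nuc_to_codon <- function(aln) {
  stopifnot(inherits(aln, "aln"), aln$alphabet == "DNA",
            ncol(aln$mat) %% 3 == 0)
  m <- toupper(aln$mat)
  m[m %in% MISSING_DNA] <- NA
  nc <- ncol(m) / 3
  out <- matrix(NA_character_, nrow(m), nc,
                dimnames = list(rownames(m), NULL))
  for (k in seq_len(nc)) {
    tri <- m[, (3 * k - 2):(3 * k), drop = FALSE]
    cod <- paste0(tri[, 1], tri[, 2], tri[, 3])
    cod[apply(is.na(tri), 1, any)] <- NA
    out[, k] <- cod
  }
  new_alignment(out, "CODON")
}

#' Read a FASTA alignment
#'
#' Thin wrapper over [ape::read.FASTA()]; all rows must be equal length.
#'
#' @param file path to a FASTA file
#' @param alphabet `"DNA"`, `"AA"` or `"CODON"` (codon files are stored as
#'   nucleotide FASTA and regrouped on read).
#' @return `aln`
#' @export
read_alignment <- function(file, alphabet = c("DNA", "AA", "CODON")) {
  alphabet <- match.arg(alphabet)
  type <- if (alphabet == "AA") "AA" else "DNA"
  x <- ape::read.FASTA(file, type = type)
  m <- toupper(as.character(as.matrix(x)))
  if (alphabet == "AA") {
    m[m %in% MISSING_AA] <- NA
    return(new_alignment(m, "AA"))
  }
  m[m %in% MISSING_DNA] <- NA
  a <- new_alignment(m, "DNA")
  if (alphabet == "CODON") nuc_to_codon(a) else a
}

#' Write an alignment to FASTA
#' @param aln alignment; codon alignments are written as nucleotides.
#' @param file output path
#' @param missing symbol used for missing cells (default `-`)
#' @export
write_alignment <- function(aln, file, missing = "-") {
  stopifnot(inherits(aln, "aln"))
  m <- if (aln$alphabet == "CODON") codon_to_nuc(aln)$mat else aln$mat
  m[is.na(m)] <- if (aln$alphabet == "CODON")
    strrep(missing, 1) else missing
  seqs <- apply(m, 1, paste0, collapse = "")
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(file)
}

# indicator (partial-likelihood) tip matrices: states x sites, 1 where the
# observed state is compatible, 1 everywhere for missing data
tip_partials <- function(aln, states) {
  m <- aln$mat
  lapply(seq_len(nrow(m)), function(i) {
    X <- matrix(0, length(states), ncol(m))
    idx <- match(m[i, ], states)
    known <- which(!is.na(idx))
    X[cbind(idx[known], known)] <- 1
    X[, is.na(idx)] <- 1
    X
  })
}
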