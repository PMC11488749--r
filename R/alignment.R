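#' Aligned barcode sequences for one nominal species at one locus
#'
#' A `locus_alignment` holds the product of an external aligner for a single
#' species x locus combination: equal-length sequences over the alphabet
#' `A, C, G, T, -, N` (plus IUPAC ambiguity codes, all treated as missing by
#' downstream comparisons).
#'
#' @param species Species name.
#' @param locus Locus name (e.g. `"coi"`, `"cytb"`).
#' @param ids Character vector of unique sequence identifiers.
#' @param sequences Character vector of aligned sequences, one string per id,
#'   all the same number of columns.
#' @return An object of class `locus_alignment`: a list with elements
#'   `species`, `locus`, `ids`, `sequences` and `length` (alignment columns).
#' @examples
#' aln <- locus_alignment("sp1", "coi", c("a", "b"), c("ACGT", "ACGA"))
#' aln$length
#' @export
locus_alignment <- function(species, locus, ids, sequences) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("ids and sequences must have the same length")
  if (length(ids) < 1L) stop("alignment must contain at least one sequence")
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("all sequences must have equal aligned length")
  structure(
    list(species = as.character(species)[1L], locus = as.character(locus)[1L],
         ids = ids, sequences = sequences, length = L),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus_alignment: %s / %s — %d sequences x %d columns\n",
              x$species, x$locus, length(x$ids), x$length))
  invisible(x)
}

# n x L character matrix view of an alignment (rows named by sequence id)
seq_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

# logical matrix: TRUE where the residue is an unambiguous base
base_matrix <- function(m) m == "A" | m == "C" | m == "G" | m == "T"

#' Read one species x locus alignment from a FASTA file
#'
#' Thin wrapper over [ape::read.FASTA()] that returns a [locus_alignment].
#' Species and locus are taken from arguments, not parsed from headers.
#'
#' @param path Path to an aligned FASTA file.
#' @inheritParams locus_alignment
#' @return A [locus_alignment].
#' @export
read_locus_alignment <- function(path, species, locus) {
  dna <- ape::read.FASTA(path)
  ch <- as.character(dna)
  seqs <- vapply(ch, function(s) paste(toupper(s), collapse = ""), character(1))
  locus_alignment(species, locus, names(dna), unname(seqs))
}

#' Write a locus alignment to FASTA
#'
#' @param aln A [locus_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_alignment <- function(aln, path) {
  m <- tolower(seq_matrix(aln))
  dna <- ape::as.DNAbin(m)
  ape::write.FASTA(dna, path)
  invisible(path)
}
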