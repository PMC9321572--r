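# Thin I/O helpers around the standard formats (FASTA via ape, newick via
# ape::read.tree/write.tree, CSV via base R).

#' Write an alignment to FASTA
#'
#' @param aln Character matrix alignment.
#' @param file Output path.
#' @export
write_alignment <- function(aln, file) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  ape::write.FASTA(ape::as.DNAbin(tolower(aln)), file)
  invisible(file)
}

#' Read a FASTA alignment into a character matrix
#'
#' All sequences must have equal length.
#'
#' @param file FASTA path.
#' @return Character matrix (upper case), rows named by sequence.
#' @export
read_alignment <- function(file) {
  dna <- ape::read.FASTA(file)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned (unequal lengths)")
  m <- toupper(as.character(as.matrix(dna)))
  rownames(m) <- names(dna)
  m
}
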