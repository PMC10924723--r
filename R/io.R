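# Readers and writers for the standard interchange formats. Parsing is
# delegated to ape; these wrappers only convert to and from the package's
# plain-matrix containers.

#' Write an alignment to FASTA
#' @param aln Character matrix of nucleotide states with tip rownames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  dna <- ape::as.DNAbin(aln)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read an alignment from FASTA
#' @param path FASTA file path.
#' @return Character matrix of upper-case states (plain matrix).
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  out <- toupper(as.character(as.matrix(dna)))

  out
}

#' Write an alignment to relaxed NEXUS
#' @inheritParams write_fasta
#' @export
write_nexus_alignment <- function(aln, path) {
  x <- split(unname(aln), row(aln))
  names(x) <- rownames(aln)
  ape::write.nexus.data(x, path, format = "dna", interleaved = FALSE)
  invisible(path)
}

#' Write a character matrix to NEXUS (DATATYPE=STANDARD, MISSING=?)
#' @param m Integer character matrix (states `0..k-1`, `NA` missing).
#' @param path Output file path.
#' @export
write_nexus_characters <- function(m, path) {
  ch <- matrix(as.character(m), nrow(m), ncol(m))
  ch[is.na(ch)] <- "?"
  x <- split(unname(ch), row(ch))
  names(x) <- rownames(m)
  ape::write.nexus.data(x, path, format = "standard", interleaved = FALSE)
  invisible(path)
}

#' Read a character matrix from NEXUS
#' @param path NEXUS file path.
#' @return Integer matrix with `NA` for `?` (plain matrix).
#' @export
read_nexus_characters <- function(path) {
  x <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(x, function(v) {
    v[v == "?" | v == "-"] <- NA
    suppressWarnings(as.integer(v))
  }))
  rownames(m) <- names(x)

  m
}

#' Write a character matrix to CSV
#'
#' One row per taxon, first column `taxon`, missing cells written as `?`.
#' @inheritParams write_nexus_characters
#' @export
write_characters_csv <- function(m, path) {
  ch <- matrix(as.character(m), nrow(m), ncol(m))
  ch[is.na(ch)] <- "?"
  df <- data.frame(taxon = rownames(m), ch, check.names = FALSE)
  colnames(df) <- c("taxon", paste0("char", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a character matrix from CSV written by [write_characters_csv()]
#' @param path CSV file path.
#' @return Integer matrix (plain matrix).
#' @export
read_characters_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "?"] <- NA
  m <- matrix(suppressWarnings(as.integer(m)), nrow(df),
              ncol(df) - 1L)
  rownames(m) <- df$taxon
  colnames(m) <- NULL

  m
}
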