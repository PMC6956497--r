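## RNA sequence input and normalization.
##
## Sequences are held as named character vectors of RNA strings (A/C/G/U).
## DNA input (T) is normalized to U; lowercase is accepted; IUPAC
## ambiguity codes are rejected with the offending record named.

.RNA_CODES <- c(A = 0L, C = 1L, G = 2L, U = 3L)

.encode_rna <- function(seq) {
  v <- .RNA_CODES[strsplit(seq, "", fixed = TRUE)[[1]]]
  if (anyNA(v)) stop("invalid RNA residue in sequence")
  unname(v)
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U and validates that only A/C/G/U remain.
#'
#' @param seq Character string (DNA or RNA).
#' @param id Optional record name used in error messages.
#' @return Normalized RNA string.
#' @export
normalize_rna <- function(seq, id = "<sequence>") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("T", "U", toupper(seq))
  if (!nzchar(s)) stop("empty sequence in record '", id, "'")
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop("record '", id, "' contains non-ACGU character(s): ",
         paste(bad, collapse = ", "), " (ambiguity codes are not supported)")
  }
  s
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-record FASTA, DNA or RNA alphabet; residues are uppercased and T
#' is converted to U. Duplicate record ids and ambiguity codes are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA strings; names are the FASTA ids
#'   (first whitespace-delimited token of each header).
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate sequence id in ", path, ": '", dup[1], "'")
  seqs <- as.character(set)
  out <- vapply(seq_along(seqs), function(t) normalize_rna(seqs[t], ids[t]),
                character(1))
  names(out) <- ids
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs Named character vector of RNA strings.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_rna_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of an RNA string
#'
#' @param seq RNA string (A/C/G/U).
#' @return The reverse complement as an RNA string.
#' @export
reverse_complement_rna <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}
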