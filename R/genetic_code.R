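# NCBI translation tables bundled for mitochondrial barcode work.
.SUPPORTED_CODES <- c(1L, 2L, 4L, 5L, 9L, 13L, 14L)

#' Genetic code by NCBI translation table number
#'
#' Wraps the NCBI genetic-code tables (via Biostrings) in a small container
#' used by the translation and dN/dS machinery. Table 5, the invertebrate
#' mitochondrial code, is the default throughout the package because it is
#' the code under which insect COI barcodes are translated.
#'
#' @param table_id Integer NCBI translation table number. Bundled tables:
#'   1 (standard), 2 (vertebrate mito), 4, 5 (invertebrate mito), 9, 13, 14.
#' @return An object of class `genetic_code`: a list with `table_id`, a
#'   64-entry named character vector `codons` mapping codon to one-letter
#'   amino acid (`*` for stop), and `stop_codons`.
#' @examples
#' gc5 <- genetic_code(5)
#' gc5$codons[["ATA"]]  # "M" under the invertebrate mitochondrial code
#' @export
genetic_code <- function(table_id = 5L) {
  table_id <- as.integer(table_id)
  if (!table_id %in% .SUPPORTED_CODES) {
    abort(paste0("Unsupported genetic code table ", table_id,
                 "; bundled tables: ", paste(.SUPPORTED_CODES, collapse = ", ")))
  }
  codons <- Biostrings::getGeneticCode(as.character(table_id))
  stopifnot(length(codons) == 64L)
  structure(
    list(table_id = table_id,
         codons = codons,
         stop_codons = names(codons)[codons == "*"]),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table", x$table_id, "|",
      length(x$stop_codons), "stop codons:",
      paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

# Translate one codon string; gaps and ambiguity resolve to '-' or 'X'.
translate_codon <- function(codon, code) {
  if (codon == "---") return("-")
  if (grepl("-", codon, fixed = TRUE)) return("X")
  if (!grepl("^[ACGT]{3}$", codon)) return("X")
  unname(code$codons[[codon]])
}
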