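#' Vertebrate mitochondrial genetic code
#'
#' Codon table for translating human mtDNA protein genes. Differs from the
#' standard code at four codons: TGA = Trp, ATA = Met, AGA and AGG = stop.
#' Incomplete stop codons completed by polyadenylation are irrelevant for
#' substitution effect calls and are not modelled.
#'
#' @return Named character vector of length 64 mapping codons (e.g. `"GCC"`)
#'   to three-letter amino-acid codes, with `"Ter"` for stop codons.
#' @export
#' @examples
#' mito_codon_table()[["TGA"]]  # "Trp", not a stop
mito_codon_table <- function() {
  .mito_code_env$table
}

.mito_code_env <- new.env(parent = emptyenv())

.build_mito_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # codon order: third base fastest would differ; rebuild explicitly
  codons <- character(64)
  k <- 1
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons[k] <- paste0(b1, b2, b3)
    k <- k + 1
  }
  std <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  code1 <- setNames(std, codons)
  # vertebrate mitochondrial reassignments
  code1[["TGA"]] <- "W"
  code1[["ATA"]] <- "M"
  code1[["AGA"]] <- "*"
  code1[["AGG"]] <- "*"
  aa3 <- c(
    F = "Phe", L = "Leu", S = "Ser", Y = "Tyr", C = "Cys", W = "Trp",
    P = "Pro", H = "His", Q = "Gln", R = "Arg", I = "Ile", M = "Met",
    T = "Thr", N = "Asn", K = "Lys", V = "Val", A = "Ala", D = "Asp",
    E = "Glu", G = "Gly", `*` = "Ter"
  )
  setNames(unname(aa3[code1]), codons)
}

.mito_code_env$table <- .build_mito_code()

.mito_stop_codons <- c("TAA", "TAG", "AGA", "AGG")

#' Translate a codon under the vertebrate mitochondrial code
#'
#' @param codon Character vector of 3-base codons (ACGT).
#' @return Three-letter amino-acid codes (`"Ter"` for stops).
#' @export
translate_mito_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- !codon %in% names(.mito_code_env$table)
  if (any(bad)) {
    stop("not a valid codon: ", paste(codon[bad], collapse = ", "))
  }
  unname(.mito_code_env$table[codon])
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a vector of bases
#' @param bases Character vector of single bases.
#' @return Reverse-complemented character vector.
#' @keywords internal
.revcomp <- function(bases) {
  rev(unname(.complement[bases]))
}
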