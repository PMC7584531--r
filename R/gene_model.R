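#' @noRd
.mt_genome_length <- 16569L

.mt_regions <- c("complexI", "complexIII", "complexIV", "ATPsynthase",
                 "rRNA", "tRNA", "noncoding")

# Coding overlaps present in the canonical human mtDNA annotation. ATP8/ATP6
# and ND4L/ND4 are the classic frameshifted overlaps; ATP6/CO3 share the single
# base 9207 where the ATP6 stop codon overlaps the CO3 start codon.
.known_coding_overlaps <- list(
  c("MT-ATP8", "MT-ATP6"),
  c("MT-ND4L", "MT-ND4"),
  c("MT-ATP6", "MT-CO3")
)

#' Load an mtDNA gene model
#'
#' Builds the gene model used for variant localisation and effect annotation:
#' the 37 mitochondrial genes plus the control region, a 16,569-base reference
#' sequence, and a total, exclusive assignment of every position to one of the
#' seven functional regions (complex I, III, IV, ATP synthase, rRNA, tRNA,
#' non-coding). Positions inside the known gene overlaps are tie-broken to the
#' feature that starts first, so the ATP8/ATP6 overlap is tallied under ATP
#' synthase and the ND4L/ND4 overlap under complex I.
#'
#' @param annotation_path TSV with columns `locus`, `start`, `end`, `strand`
#'   (`heavy`/`light`), `product_class` (one of the seven regions). 1-based
#'   inclusive coordinates; the control region is represented as two segments
#'   (16024-16569 and 1-576). Defaults to the packaged annotation.
#' @param fasta_path Single-record FASTA of the reference sequence. Defaults to
#'   the packaged synthetic rCRS stand-in (see [build_synthetic_reference()]).
#' @return An object of class `mt_gene_model`: list with `features` (tibble),
#'   `sequence` (character vector of single bases, length 16569), and internal
#'   position-to-locus/region lookup maps.
#' @export
load_gene_model <- function(annotation_path = mt_annotation_file(),
                            fasta_path = mt_reference_file()) {
  feats <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                           progress = FALSE, comment = "#")
  required <- c("locus", "start", "end", "strand", "product_class")
  missing_cols <- setdiff(required, names(feats))
  if (length(missing_cols) > 0) {
    stop("annotation file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(feats$strand)) || !all(feats$strand %in% c("heavy", "light"))) {
    stop("every feature needs strand 'heavy' or 'light'")
  }
  if (!all(feats$product_class %in% .mt_regions)) {
    stop("unknown product_class: ",
         paste(setdiff(feats$product_class, .mt_regions), collapse = ", "))
  }

  fa <- Biostrings::readDNAStringSet(fasta_path)
  if (length(fa) != 1) stop("reference FASTA must contain exactly one record")
  seq_chr <- strsplit(as.character(fa[[1]]), "")[[1]]
  genome_length <- length(seq_chr)

  if (any(feats$start < 1 | feats$end > genome_length | feats$start > feats$end)) {
    stop("feature coordinates outside 1..", genome_length, " or start > end")
  }

  .check_coding_overlaps(feats)

  # Position maps with first-start priority tie-breaking.
  locus_map <- rep(NA_character_, genome_length)
  region_map <- rep(NA_character_, genome_length)
  ord <- order(feats$start, feats$end)
  for (i in ord) {
    idx <- feats$start[i]:feats$end[i]
    unset <- is.na(locus_map[idx])
    locus_map[idx[unset]] <- feats$locus[i]
    region_map[idx[unset]] <- feats$product_class[i]
  }
  gaps <- is.na(locus_map)
  locus_map[gaps] <- "intergenic"
  region_map[gaps] <- "noncoding"

  model <- structure(
    list(
      features = tibble::as_tibble(feats),
      sequence = seq_chr,
      genome_length = genome_length,
      locus_map = locus_map,
      region_map = region_map
    ),
    class = "mt_gene_model"
  )
  if (genome_length == .mt_genome_length &&
      length(unique(region_map)) != length(.mt_regions)) {
    stop("full-genome model must cover all seven regions")
  }
  model
}

.check_coding_overlaps <- function(feats) {
  coding <- feats[feats$product_class %in%
                    c("complexI", "complexIII", "complexIV", "ATPsynthase"), ]
  if (nrow(coding) < 2) return(invisible(NULL))
  allowed <- vapply(.known_coding_overlaps,
                    function(p) paste(sort(p), collapse = "|"), character(1))
  for (i in seq_len(nrow(coding) - 1)) {
    for (j in (i + 1):nrow(coding)) {
      if (coding$start[j] <= coding$end[i] && coding$start[i] <= coding$end[j]) {
        pair <- paste(sort(c(coding$locus[i], coding$locus[j])), collapse = "|")
        if (!pair %in% allowed) {
          stop("unexpected coding-gene overlap: ", coding$locus[i], " / ",
               coding$locus[j])
        }
      }
    }
  }
  invisible(NULL)
}

#' @export
print.mt_gene_model <- function(x, ...) {
  cat("mt gene model:", nrow(x$features), "features,",
      x$genome_length, "bases,",
      length(unique(x$region_map)), "regions\n")
  invisible(x)
}

#' Locate a position on the gene model
#'
#' Resolves an rCRS coordinate to its locus and functional region. Positions in
#' intergenic spacers return locus `"intergenic"`, region `"noncoding"`;
#' positions inside gene overlaps resolve deterministically to the feature
#' starting first.
#'
#' @param position Integer vector of 1-based rCRS coordinates.
#' @param model An `mt_gene_model`.
#' @return Tibble with columns `position`, `locus`, `region`.
#' @export
#' @examples
#' model <- mt_gene_model()
#' locate(c(9055, 14167, 73), model)
locate <- function(position, model) {
  stopifnot(inherits(model, "mt_gene_model"))
  position <- as.integer(position)
  if (any(is.na(position) | position < 1 | position > model$genome_length)) {
    stop("position out of range 1..", model$genome_length)
  }
  tibble::tibble(
    position = position,
    locus = model$locus_map[position],
    region = model$region_map[position]
  )
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are purine-purine (A/G) or pyrimidine-pyrimidine (C/T)
#' exchanges; all other substitutions are transversions. Classification is
#' symmetric in the two alleles.
#'
#' @param ref_allele,alt_allele Character vectors of single bases (ACGT).
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
classify_substitution <- function(ref_allele, alt_allele) {
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  ok <- ref_allele %in% c("A", "C", "G", "T") & alt_allele %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("alleles must be single bases in {A,C,G,T}")
  if (any(ref_allele == alt_allele)) stop("ref and alt alleles must differ")
  purine <- c("A", "G")
  same_class <- (ref_allele %in% purine) == (alt_allele %in% purine)
  ifelse(same_class, "transition", "transversion")
}

#' m.-notation key for a variant
#'
#' @param position,ref,alt Variant coordinates and alleles.
#' @return Character vector like `"m.11778G>A"`.
#' @export
variant_key <- function(position, ref, alt) {
  sprintf("m.%d%s>%s", as.integer(position), ref, alt)
}

#' Parse m.-notation variant keys
#' @param key Character vector like `"m.11778G>A"`.
#' @return Tibble with `position`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  m <- regmatches(key, regexec("^m\\.([0-9]+)([ACGT])>([ACGT])$", key))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("malformed variant key: ", paste(key[bad], collapse = ", "))
  tibble::tibble(
    position = as.integer(vapply(m, `[`, character(1), 2)),
    ref = vapply(m, `[`, character(1), 3),
    alt = vapply(m, `[`, character(1), 4)
  )
}

#' Packaged annotation / reference paths and cached full model
#'
#' `mt_annotation_file()` and `mt_reference_file()` return the paths of the
#' packaged gene annotation and synthetic reference FASTA; `mt_gene_model()`
#' loads the packaged model once per session and caches it.
#'
#' @return File path, or an `mt_gene_model`.
#' @export
mt_annotation_file <- function() {
  system.file("extdata", "mt_gene_annotation.tsv", package = "mtassoc",
              mustWork = TRUE)
}

#' @rdname mt_annotation_file
#' @export
mt_reference_file <- function() {
  system.file("extdata", "rcrs_synthetic.fasta", package = "mtassoc",
              mustWork = TRUE)
}

.model_cache <- new.env(parent = emptyenv())

#' @rdname mt_annotation_file
#' @export
mt_gene_model <- function() {
  if (is.null(.model_cache$model)) {
    .model_cache$model <- load_gene_model()
  }
  .model_cache$model
}
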