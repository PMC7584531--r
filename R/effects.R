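#' Annotate the coding effect of an mtDNA substitution
#'
#' Translates the affected codon under the vertebrate mitochondrial genetic
#' code for variants in protein-coding genes (reverse-complementing for the
#' light-strand gene MT-ND6), and classifies the change as synonymous or
#' non-synonymous. Variants in rRNA/tRNA genes are `rna-change`; variants in
#' the control region or intergenic spacers are `non-coding-change`.
#' Synonymous calls are written `p.Xaa<pos>=`, non-synonymous `p.XaaNYyy`.
#'
#' Positions inside the known coding overlaps are annotated with respect to
#' every overlapping reading frame; the effect of the tie-broken primary locus
#' is reported in the main columns and the remaining frames in
#' `overlap_effects`. Variants falling in the 1-2 dangling bases of a gene
#' whose length is not a codon multiple (incomplete terminal codon, completed
#' by polyadenylation in vivo) have no codon to translate and are classified
#' `rna-change`.
#'
#' @param position rCRS coordinate(s).
#' @param ref,alt Reference and alternate alleles on the heavy strand.
#' @param model An `mt_gene_model`.
#' @return Tibble with one row per variant: `position`, `ref`, `alt`, `locus`,
#'   `region`, `category`, `protein_change`, `codon_index`, `overlap_effects`.
#' @export
#' @examples
#' model <- mt_gene_model()
#' annotate_effect(9055, "G", "A", model)   # p.Ala177Thr in MT-ATP6
annotate_effect <- function(position, ref, alt, model) {
  annotate_effects(position, ref, alt, model)
}

.coding_regions <- c("complexI", "complexIII", "complexIV", "ATPsynthase")

# Effect of a substitution with respect to one protein-coding feature.
# feat is a one-row list/data.frame. Returns NULL when the position sits in
# the incomplete terminal codon.
.frame_effect <- function(position, alt, feat, seq_chr) {
  if (feat$strand == "heavy") {
    off <- position - feat$start
    codon_index <- off %/% 3L + 1L
    codon_start <- feat$start + (codon_index - 1L) * 3L
    if (codon_start + 2L > feat$end) return(NULL)
    codon <- seq_chr[codon_start:(codon_start + 2L)]
    cp <- off %% 3L + 1L
    alt_codon <- codon
    alt_codon[cp] <- alt
  } else {
    off <- feat$end - position
    codon_index <- off %/% 3L + 1L
    cp <- off %% 3L + 1L
    hi <- feat$end - (codon_index - 1L) * 3L
    lo <- hi - 2L
    if (lo < feat$start) return(NULL)
    codon <- .revcomp(seq_chr[lo:hi])
    alt_codon <- codon
    alt_codon[cp] <- unname(.complement[alt])
  }
  ref_aa <- .mito_code_env$table[[paste(codon, collapse = "")]]
  alt_aa <- .mito_code_env$table[[paste(alt_codon, collapse = "")]]
  if (ref_aa == alt_aa) {
    list(category = "synonymous",
         protein_change = sprintf("p.%s%d=", ref_aa, codon_index),
         codon_index = codon_index)
  } else {
    list(category = "non-synonymous",
         protein_change = sprintf("p.%s%d%s", ref_aa, codon_index, alt_aa),
         codon_index = codon_index)
  }
}

.coding_feats_at <- function(position, model) {
  feats <- model$features
  hit <- feats$product_class %in% .coding_regions &
    feats$start <= position & feats$end >= position
  feats[hit, ]
}

.annotate_one <- function(position, ref, alt, model) {
  expected <- model$sequence[position]
  if (expected != ref) {
    stop(sprintf("reference mismatch at position %d: model has %s, variant has %s",
                 position, expected, ref))
  }
  locus <- model$locus_map[position]
  region <- model$region_map[position]

  coding <- .coding_feats_at(position, model)
  if (nrow(coding) > 0) {
    effs <- list()
    for (i in seq_len(nrow(coding))) {
      fe <- .frame_effect(position, alt, coding[i, ], model$sequence)
      if (!is.null(fe)) effs[[coding$locus[i]]] <- fe
    }
    if (length(effs) > 0) {
      primary_name <- if (locus %in% names(effs)) locus else names(effs)[1]
      pe <- effs[[primary_name]]
      others <- effs[setdiff(names(effs), primary_name)]
      overlap <- if (length(others) == 0) NA_character_ else {
        paste(vapply(names(others), function(nm) {
          paste0(nm, ":", others[[nm]]$protein_change)
        }, character(1)), collapse = ";")
      }
      return(list(position = position, ref = ref, alt = alt,
                  locus = locus, region = region,
                  category = pe$category, protein_change = pe$protein_change,
                  codon_index = pe$codon_index, overlap_effects = overlap))
    }
    return(list(position = position, ref = ref, alt = alt,
                locus = locus, region = region,
                category = "rna-change", protein_change = "",
                codon_index = NA_integer_, overlap_effects = NA_character_))
  }

  category <- if (region %in% c("rRNA", "tRNA")) "rna-change" else "non-coding-change"
  list(position = position, ref = ref, alt = alt,
       locus = locus, region = region,
       category = category, protein_change = "",
       codon_index = NA_integer_, overlap_effects = NA_character_)
}

#' @rdname annotate_effect
#' @export
annotate_effects <- function(position, ref, alt, model) {
  stopifnot(inherits(model, "mt_gene_model"))
  position <- as.integer(position)
  if (any(is.na(position) | position < 1 | position > model$genome_length)) {
    stop("position out of range 1..", model$genome_length)
  }
  n <- length(position)
  stopifnot(length(ref) == n, length(alt) == n)
  ref <- toupper(ref)
  alt <- toupper(alt)
  classify_substitution(ref, alt)  # validates alleles up front
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- .annotate_one(position[i], ref[i], alt[i], model)
  }
  tibble::tibble(
    position = vapply(rows, `[[`, integer(1), "position"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    locus = vapply(rows, `[[`, character(1), "locus"),
    region = vapply(rows, `[[`, character(1), "region"),
    category = vapply(rows, `[[`, character(1), "category"),
    protein_change = vapply(rows, `[[`, character(1), "protein_change"),
    codon_index = vapply(rows, function(r) {
      ci <- r$codon_index
      if (is.null(ci) || is.na(ci)) NA_integer_ else as.integer(ci)
    }, integer(1)),
    overlap_effects = vapply(rows, `[[`, character(1), "overlap_effects")
  )
}

# Fast category lookup for the simulator: effect category of (position, alt)
# with respect to the tie-broken primary locus, without reference checking.
.category_of <- function(position, alt, model) {
  region <- model$region_map[position]
  if (!region %in% .coding_regions) {
    return(if (region %in% c("rRNA", "tRNA")) "rna-change" else "non-coding-change")
  }
  locus <- model$locus_map[position]
  feats <- model$features
  feat <- feats[feats$locus == locus, ]
  fe <- .frame_effect(position, alt, feat, model$sequence)
  if (is.null(fe)) "rna-change" else fe$category
}

#' Translate a protein gene's full reading frame
#'
#' Translates every complete codon of a gene from the model sequence. Used to
#' check that packaged references carry open reading frames (no internal stop
#' codons).
#'
#' @param locus Gene symbol, e.g. `"MT-ND1"`.
#' @param model An `mt_gene_model`.
#' @return Character vector of three-letter amino acids, one per full codon.
#' @export
translate_gene <- function(locus, model) {
  feat <- model$features[model$features$locus == locus, ]
  if (nrow(feat) != 1) stop("locus not found (or not unique): ", locus)
  if (!feat$product_class %in% .coding_regions) stop(locus, " is not protein-coding")
  len <- feat$end - feat$start + 1L
  n_codon <- len %/% 3L
  sense <- if (feat$strand == "heavy") {
    model$sequence[feat$start:feat$end]
  } else {
    .revcomp(model$sequence[feat$start:feat$end])
  }
  vapply(seq_len(n_codon), function(i) {
    translate_mito_codon(paste(sense[(3 * i - 2):(3 * i)], collapse = ""))
  }, character(1))
}
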