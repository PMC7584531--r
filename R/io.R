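#' Read and write cohorts as long-format TSV
#'
#' Columns: `subject_id`, `group`, `position`, `ref`, `alt`, `heteroplasmy`
#' (percent). The subject table is derived from the distinct
#' (subject_id, group) pairs, so a subject must carry at least one variant to
#' survive a TSV round trip; the VCF representation keeps variant-free
#' subjects as all-reference samples.
#'
#' @param path File path.
#' @return An `mt_cohort` (reader) or `path` invisibly (writer).
#' @export
read_cohort_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  stopifnot(all(c("subject_id", "group", "position", "ref", "alt",
                  "heteroplasmy") %in% names(d)))
  subjects <- dplyr::distinct(d, .data$subject_id, .data$group)
  variants <- d[, c("subject_id", "position", "ref", "alt", "heteroplasmy")]
  mt_cohort(subjects, variants)
}

#' @rdname read_cohort_tsv
#' @param cohort An `mt_cohort`.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "mt_cohort"))
  d <- dplyr::left_join(
    cohort$variants[, c("subject_id", "position", "ref", "alt", "heteroplasmy")],
    cohort$subjects[, c("subject_id", "group")],
    by = "subject_id"
  )
  d <- d[order(d$subject_id, d$position, d$alt),
         c("subject_id", "group", "position", "ref", "alt", "heteroplasmy")]
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' Read and write cohorts as multi-sample VCF
#'
#' One sample per subject; genotypes are haploid (`1` carrier / `0`
#' non-carrier) with the mutant-allele fraction in an `AF` FORMAT field
#' (heteroplasmy percent / 100). Group labels are carried in
#' `##SAMPLE=<ID=...,Group=...>` header lines so the VCF and TSV readers
#' produce identical cohorts from equivalent content. Files are written
#' bgzip-compressed (`.vcf.gz`) through vcfR.
#'
#' @param path File path (`.vcf` or `.vcf.gz`).
#' @return An `mt_cohort` (reader) or the written path invisibly (writer).
#' @export
read_cohort_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  sample_lines <- grep("^##SAMPLE=", meta, value = TRUE)
  ids <- sub(".*ID=([^,>]+).*", "\\1", sample_lines)
  groups <- sub(".*Group=([^,>]+).*", "\\1", sample_lines)
  if (length(ids) == 0) stop("VCF lacks ##SAMPLE meta lines with Group tags")
  subjects <- tibble::tibble(subject_id = ids, group = groups)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  af <- suppressWarnings(vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE))
  fix <- vcfR::getFIX(vcf)
  pos <- as.integer(fix[, "POS"])
  rows <- list()
  for (s in colnames(gt)) {
    carrier <- !is.na(gt[, s]) & gt[, s] %in% c("1", "1/1", "1|1")
    if (!any(carrier)) next
    rows[[s]] <- tibble::tibble(
      subject_id = s,
      position = pos[carrier],
      ref = fix[carrier, "REF"],
      alt = fix[carrier, "ALT"],
      heteroplasmy = round(as.numeric(af[carrier, s]) * 100, 6)
    )
  }
  variants <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(subject_id = character(), position = integer(),
                   ref = character(), alt = character(),
                   heteroplasmy = numeric())
  }
  mt_cohort(subjects, variants)
}

#' @rdname read_cohort_vcf
#' @param cohort An `mt_cohort`.
#' @export
write_cohort_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "mt_cohort"))
  v <- cohort$variants
  uniq <- dplyr::distinct(v, .data$position, .data$ref, .data$alt)
  uniq <- uniq[order(uniq$position, uniq$alt), ]
  subjects <- cohort$subjects

  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", .mt_genome_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Mutant allele fraction\">",
    sprintf("##SAMPLE=<ID=%s,Group=%s>", subjects$subject_id, subjects$group)
  )
  fix <- cbind(
    CHROM = rep("chrM", nrow(uniq)),
    POS = as.character(uniq$position),
    ID = variant_key(uniq$position, uniq$ref, uniq$alt),
    REF = uniq$ref, ALT = uniq$alt,
    QUAL = rep(".", nrow(uniq)), FILTER = rep(".", nrow(uniq)),
    INFO = rep(".", nrow(uniq))
  )
  ukey <- paste(uniq$position, uniq$alt)
  gt <- matrix("0:.", nrow = nrow(uniq), ncol = nrow(subjects),
               dimnames = list(NULL, subjects$subject_id))
  vkey <- paste(v$position, v$alt)
  ridx <- match(vkey, ukey)
  cidx <- match(v$subject_id, subjects$subject_id)
  gt[cbind(ridx, cidx)] <- sprintf("1:%.4f", v$heteroplasmy / 100)
  gt <- cbind(FORMAT = rep("GT:AF", nrow(uniq)), gt)

  vcf <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  vcfR::write.vcf(vcf, path)
  invisible(path)
}

#' Read auxiliary input tables
#'
#' `read_frequency_table()` reads a population-frequency TSV (either columns
#' `variant` + `percent` in m.-notation, or `position` + `alt` + `percent`).
#' `read_score_table()` reads a pathogenicity-score TSV (`variant` and/or
#' `protein_change`, plus `score` in [0,1]). `read_association_list()` reads a
#' reported-association TSV (`variant`, `annotation`, optional extras).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_frequency_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  .as_frequency_table(d)
}

#' @rdname read_frequency_table
#' @export
read_score_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  stopifnot("score" %in% names(d))
  d
}

#' @rdname read_frequency_table
#' @export
read_association_list <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  stopifnot(all(c("variant", "annotation") %in% names(d)))
  d
}

#' Paths of the packaged synthetic auxiliary tables
#' @return File path.
#' @export
mt_frequency_file <- function() {
  system.file("extdata", "population_frequency_synthetic.tsv",
              package = "mtassoc", mustWork = TRUE)
}

#' @rdname mt_frequency_file
#' @export
mt_score_file <- function() {
  system.file("extdata", "pathogenicity_scores_synthetic.tsv",
              package = "mtassoc", mustWork = TRUE)
}

#' @rdname mt_frequency_file
#' @export
mt_association_file <- function() {
  system.file("extdata", "reported_associations.tsv",
              package = "mtassoc", mustWork = TRUE)
}

#' @rdname mt_frequency_file
#' @export
mt_haplotree_file <- function() {
  system.file("extdata", "haplotree_mini.tsv", package = "mtassoc",
              mustWork = TRUE)
}

#' @rdname mt_frequency_file
#' @export
mt_haplotree_ignore_file <- function() {
  system.file("extdata", "haplotree_ignore.txt", package = "mtassoc",
              mustWork = TRUE)
}
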