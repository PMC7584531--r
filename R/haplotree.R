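#' Load a haplogroup marker tree
#'
#' Reads a phylotree-style marker tree: TSV with columns `name`, `parent`
#' (empty for the root), `defining_variants` (comma-separated m.-notation) and
#' optionally `report` (the reporting-level haplogroup label, defaulting to the
#' node name). The packaged mini-tree is a coarse rCRS-rooted scoring tree
#' covering the 12 reporting haplogroups B, H, HV, I, J, K, N, T, U, V, W, X
#' plus the JT, U8 and U8b trunk nodes, with K descending from U8b. Full
#' Phylotree imports are supported through the same format.
#'
#' @param tree_path TSV path (default: packaged mini-tree).
#' @param ignore_path Optional file listing one position per line to exclude
#'   from scoring (mutational hotspots such as 16519). `NULL` disables.
#' @return Object of class `mt_haplotree`: tibble of nodes with cumulative
#'   root-to-node defining-variant sets, plus the ignore list.
#' @export
load_haplotree <- function(tree_path = mt_haplotree_file(),
                           ignore_path = mt_haplotree_ignore_file()) {
  d <- readr::read_tsv(tree_path, show_col_types = FALSE, progress = FALSE,
                       comment = "#", trim_ws = TRUE)
  stopifnot(all(c("name", "parent", "defining_variants") %in% names(d)))
  d$parent[is.na(d$parent) | d$parent == ""] <- NA_character_
  if (!"report" %in% names(d)) d$report <- d$name
  d$report[is.na(d$report)] <- d$name[is.na(d$report)]

  if (anyDuplicated(d$name)) {
    stop("duplicate haplogroup name: ", d$name[duplicated(d$name)][1])
  }
  roots <- which(is.na(d$parent))
  if (length(roots) != 1) stop("tree must have exactly one root")
  orphan <- !is.na(d$parent) & !d$parent %in% d$name
  if (any(orphan)) {
    stop("node with unknown parent: ", d$name[orphan][1])
  }

  own <- lapply(d$defining_variants, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    trimws(strsplit(s, ",")[[1]])
  })
  lapply(unlist(own), parse_variant_key)  # validates notation

  # cumulative sets and depth by walking to the root; cycle-safe
  n <- nrow(d)
  idx <- setNames(seq_len(n), d$name)
  cumulative <- vector("list", n)
  depth <- integer(n)
  for (i in seq_len(n)) {
    acc <- character(0)
    j <- i
    steps <- 0
    while (!is.na(d$parent[j])) {
      acc <- c(own[[j]], acc)
      j <- idx[[d$parent[j]]]
      steps <- steps + 1
      if (steps > n) stop("cycle in tree at node ", d$name[i])
    }
    acc <- c(own[[j]], acc)
    cumulative[[i]] <- unique(acc)
    depth[i] <- steps
  }

  ignore <- integer(0)
  if (!is.null(ignore_path)) {
    lines <- readLines(ignore_path)
    lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
    ignore <- as.integer(lines)
  }

  structure(
    list(
      nodes = tibble::tibble(
        name = d$name, parent = d$parent, report = d$report,
        depth = depth, defining = own, cumulative = cumulative
      ),
      ignore_positions = ignore
    ),
    class = "mt_haplotree"
  )
}

#' @export
print.mt_haplotree <- function(x, ...) {
  cat("haplogroup tree:", nrow(x$nodes), "nodes,",
      length(unique(x$nodes$report)), "reporting labels\n")
  invisible(x)
}

#' Assign a haplogroup by marker concordance
#'
#' Scores every tree node against a subject's variant set as
#' `matched - lambda * missing`, where `matched` counts the node's cumulative
#' root-to-node defining variants present in the profile and `missing` those
#' absent; the best-scoring node wins, with ties broken by greater depth and
#' then lexicographically smaller name. Positions on the tree's ignore list
#' contribute neither matches nor penalties. This concordance score is this
#' package's own definition (the external services used in published studies
#' do not document theirs); it is validated by exact label recovery on
#' marker-complete synthetic cohorts.
#'
#' @param variant_keys Character vector of m.-notation variant keys carried by
#'   one subject (order-irrelevant).
#' @param tree An `mt_haplotree`.
#' @param lambda Penalty per expected-but-absent defining variant. Default 0.5.
#' @return One-row tibble: `haplogroup`, `report`, `matched`, `expected`,
#'   `score`.
#' @export
assign_haplogroup <- function(variant_keys, tree, lambda = 0.5) {
  stopifnot(inherits(tree, "mt_haplotree"))
  if (nrow(tree$nodes) == 0) stop("empty haplogroup tree")
  if (length(tree$ignore_positions) > 0 && length(variant_keys) > 0) {
    pos <- parse_variant_key(variant_keys)$position
    variant_keys <- variant_keys[!pos %in% tree$ignore_positions]
  }
  nodes <- tree$nodes
  scored <- lapply(nodes$cumulative, function(def) {
    if (length(def) > 0 && length(tree$ignore_positions) > 0) {
      dpos <- parse_variant_key(def)$position
      def <- def[!dpos %in% tree$ignore_positions]
    }
    matched <- sum(def %in% variant_keys)
    c(matched = matched, expected = length(def))
  })
  matched <- vapply(scored, `[[`, numeric(1), "matched")
  expected <- vapply(scored, `[[`, numeric(1), "expected")
  score <- matched - lambda * (expected - matched)
  ord <- order(-score, -nodes$depth, nodes$name)
  best <- ord[1]
  tibble::tibble(
    haplogroup = nodes$name[best],
    report = nodes$report[best],
    matched = as.integer(matched[best]),
    expected = as.integer(expected[best]),
    score = score[best]
  )
}

#' Assign haplogroups to every subject of a cohort
#'
#' @param cohort An `mt_cohort`.
#' @param tree An `mt_haplotree` (default: packaged mini-tree).
#' @param lambda Mismatch penalty, see [assign_haplogroup()].
#' @return The cohort with `haplogroup` (node name) and `haplogroup_report`
#'   (reporting label) filled on the subject table.
#' @export
assign_haplogroups <- function(cohort, tree = load_haplotree(), lambda = 0.5) {
  stopifnot(inherits(cohort, "mt_cohort"))
  v <- cohort$variants
  keys_by_subject <- split(variant_key(v$position, v$ref, v$alt), v$subject_id)
  calls <- lapply(cohort$subjects$subject_id, function(s) {
    assign_haplogroup(keys_by_subject[[s]] %||% character(0), tree, lambda)
  })
  calls <- dplyr::bind_rows(calls)
  cohort$subjects$haplogroup <- calls$haplogroup
  cohort$subjects$haplogroup_report <- calls$report
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
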