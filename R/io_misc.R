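#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with validation: leaf labels must be unique and
#' branch lengths finite and non-negative.
#'
#' @param path Path to a Newick file (first tree is returned).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("Newick file not found: ", path))
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (is.null(tr)) abort(paste0("could not parse Newick in ", path))
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("duplicate leaf label: ",
                 tr$tip.label[duplicated(tr$tip.label)][1L]))
  }
  if (!is.null(tr$edge.length)) {
    if (any(!is.finite(tr$edge.length))) abort("non-finite branch length in tree")
    if (any(tr$edge.length < 0)) abort("negative branch length in tree")
  }
  tr
}

#' Read BED intervals for one sample
#'
#' BED coordinates are 0-based half-open and pass through unchanged.
#'
#' @param path BED file (3+ columns, no header).
#' @param sample_id Sample label attached to every interval; defaults to the
#'   file name without extension.
#' @return Tibble with columns `scaffold`, `start`, `end`, `sample_id`.
#' @export
read_intervals <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  if (!any(keep)) {
    return(tibble(scaffold = character(), start = numeric(), end = numeric(),
                  sample_id = character()))
  }
  fields <- strsplit(lines[keep], "\t| +")
  lineno <- which(keep)
  short <- lengths(fields) < 3L
  if (any(short)) {
    abort(paste0("malformed BED line ", lineno[short][1L], ": fewer than 3 fields"))
  }
  out <- tibble(
    scaffold = map_chr(fields, 1),
    start = as.numeric(map_chr(fields, 2)),
    end = as.numeric(map_chr(fields, 3)),
    sample_id = sample_id
  )
  bad <- out$start >= out$end
  if (any(bad)) {
    abort(paste0("BED start >= end at line ", lineno[bad][1L]))
  }
  out
}

#' Merge intervals to canonical non-overlapping form
#'
#' Within each (scaffold, sample) the intervals are merged so that the result
#' is sorted, non-overlapping and non-adjacent-duplicated; merging is
#' idempotent and preserves total covered length.
#'
#' @param intervals Tibble with `scaffold`, `start`, `end` and optionally
#'   `sample_id`.
#' @return Tibble of the same shape with merged intervals.
#' @export
canonicalize_intervals <- function(intervals) {
  if (!"sample_id" %in% names(intervals)) intervals$sample_id <- "sample"
  if (nrow(intervals) == 0L) return(intervals)
  intervals |>
    group_by(.data$scaffold, .data$sample_id) |>
    dplyr::reframe({
      ir <- IRanges::reduce(IRanges::IRanges(start = .data$start + 1, end = .data$end))
      tibble(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
    }) |>
    select("scaffold", "start", "end", "sample_id") |>
    arrange(.data$scaffold, .data$sample_id, .data$start)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Accepts the full 12-column outfmt-6 layout or a reduced 6-column layout
#' (`query_id`, `subject_id`, `percent_identity`, `alignment_length`,
#' `e_value`, `bit_score`).
#'
#' @param path Tab-separated hits file, no header.
#' @return Tibble with columns `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `e_value`, `bit_score`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) abort(paste0("hits file not found: ", path))
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tab) == 12L) {
    out <- tibble(query_id = as.character(tab[[1]]),
                  subject_id = as.character(tab[[2]]),
                  percent_identity = as.numeric(tab[[3]]),
                  alignment_length = as.numeric(tab[[4]]),
                  e_value = as.numeric(tab[[11]]),
                  bit_score = as.numeric(tab[[12]]))
  } else if (ncol(tab) == 6L) {
    out <- tibble(query_id = as.character(tab[[1]]),
                  subject_id = as.character(tab[[2]]),
                  percent_identity = as.numeric(tab[[3]]),
                  alignment_length = as.numeric(tab[[4]]),
                  e_value = as.numeric(tab[[5]]),
                  bit_score = as.numeric(tab[[6]]))
  } else {
    abort(paste0("hits file must have 6 or 12 columns, got ", ncol(tab)))
  }
  if (any(out$e_value < 0)) {
    abort(paste0("negative e-value at line ", which(out$e_value < 0)[1L]))
  }
  if (any(out$percent_identity < 0 | out$percent_identity > 100)) {
    abort("percent_identity outside [0, 100]")
  }
  out
}

#' Write a named list of result tables as TSV files
#'
#' @param results Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tables <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(results[[nm]]), p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
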