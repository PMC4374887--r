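#' Detect leucine-rich repeats
#'
#' Scans for the LRR core pattern `LxxLxLxx` where `L` is any of L/I/V/F and
#' `x` any residue. Every 8-residue window matching the pattern is marked;
#' overlapping and adjacent matched windows are merged into runs, and maximal
#' runs of at least `min_run` residues are reported as repeats.
#'
#' @param protein Amino-acid string or one-row sequence tibble.
#' @param min_run Minimum run length in residues (default 16, i.e. two
#'   stacked core units).
#' @return Tibble with columns `start`, `end` (0-based half-open) and
#'   `length`; one row per repeat.
#' @export
#' @examples
#' detect_lrr(paste0(strrep("G", 10), "LAALNLSSLAALNLSS", strrep("G", 10)))
detect_lrr <- function(protein, min_run = 16L) {
  seq <- protein_string(protein)
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  if (n < 8L) {
    return(tibble(start = integer(), end = integer(), length = integer()))
  }
  h <- chars %in% c("L", "I", "V", "F")
  covered <- logical(n)
  # core unit LxxLxLxx: hydrophobic at relative positions 1, 4, 6
  for (i in seq_len(n - 7L)) {
    if (h[i] && h[i + 3L] && h[i + 5L]) covered[i:(i + 7L)] <- TRUE
  }
  runs <- runs_at_least(covered, min_run)
  tibble(start = runs$start - 1L, end = runs$end,
         length = runs$end - runs$start + 1L)
}
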