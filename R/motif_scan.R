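#' Scan a protein for library motifs
#'
#' Slides each motif's log-odds position weight matrix along the protein and
#' reports non-overlapping placements scoring at or above the motif's
#' threshold. Placements for one motif are chosen greedily by score (ties:
#' leftmost), so the best-scoring placement is always reported first; the
#' scan is fully deterministic.
#'
#' @param protein Either a single amino-acid string or a one-row sequence
#'   tibble (as from [read_fasta()]).
#' @param lib Motif library tibble (default [default_motif_library()]).
#' @return Tibble with columns `motif`, `region`, `start`, `end` (0-based
#'   half-open on the protein), `score`.
#' @export
#' @examples
#' scan_motifs(paste0(strrep("A", 30), "YDVFLSFRGEDTRDNFTSHLY", strrep("A", 30)))
scan_motifs <- function(protein, lib = default_motif_library()) {
  seq <- protein_string(protein)
  if (nchar(seq) == 0L) abort("empty protein sequence")
  codes <- match(strsplit(toupper(seq), "")[[1L]], LETTERS)
  if (anyNA(codes)) abort("protein contains non-letter residues")
  n <- length(codes)
  out <- list()
  for (k in seq_len(nrow(lib))) {
    pwm <- consensus_pwm(lib$consensus[k])
    m <- nrow(pwm)
    if (m > n) next
    scores <- motif_scores_all(pwm, codes)
    hits <- which(scores >= lib$threshold[k])
    if (!length(hits)) next
    # greedy non-overlapping selection by score, ties leftmost
    ord <- hits[order(-scores[hits], hits)]
    taken <- logical(n)
    for (i in ord) {
      span <- i:(i + m - 1L)
      if (!any(taken[span])) {
        taken[span] <- TRUE
        out[[length(out) + 1L]] <- tibble(
          motif = lib$name[k], region = lib$region[k],
          start = i - 1L, end = i + m - 1L, score = scores[i]
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(motif = character(), region = character(),
                  start = integer(), end = integer(), score = numeric()))
  }
  bind_rows(out) |> arrange(.data$start, .data$motif)
}

# PWM score at every offset (1-based starts); O(n * m)
motif_scores_all <- function(pwm, codes) {
  n <- length(codes)
  m <- nrow(pwm)
  n_off <- n - m + 1L
  scores <- numeric(n_off)
  for (j in seq_len(m)) {
    scores <- scores + pwm[j, codes[j:(j + n_off - 1L)]]
  }
  scores
}

protein_string <- function(protein) {
  if (is.data.frame(protein)) {
    stopifnot("residues" %in% names(protein), nrow(protein) == 1L)
    protein$residues
  } else {
    stopifnot(is.character(protein), length(protein) == 1L)
    protein
  }
}
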