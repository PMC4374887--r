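#' Reciprocal-best-hit orthologs
#'
#' The best hit per query is chosen by bit score (ties: lower e-value, then
#' lexicographically smaller subject id). A pair (a, b) is an ortholog when
#' a's best hit in the other genome is b, b's best hit is a, and both hits
#' have e-value below `evalue_cut`. Each gene therefore appears in at most
#' one pair, and the result does not depend on which genome is called A.
#'
#' @param hits_ab Hit table (see [read_hits()]) with genome-A queries.
#' @param hits_ba Hit table with genome-B queries.
#' @param evalue_cut E-value cutoff (default 1e-20).
#' @return Tibble `gene_a`, `gene_b`, `evalue_ab`, `evalue_ba`, `bit_ab`,
#'   `bit_ba`.
#' @export
rbh_orthologs <- function(hits_ab, hits_ba, evalue_cut = 1e-20) {
  best_ab <- best_hits(hits_ab)
  best_ba <- best_hits(hits_ba)
  merged <- dplyr::inner_join(
    best_ab, best_ba,
    by = c("query_id" = "subject_id", "subject_id" = "query_id"),
    suffix = c("_ab", "_ba")
  )
  merged |>
    filter(.data$e_value_ab < evalue_cut, .data$e_value_ba < evalue_cut) |>
    dplyr::transmute(gene_a = .data$query_id, gene_b = .data$subject_id,
                     evalue_ab = .data$e_value_ab, evalue_ba = .data$e_value_ba,
                     bit_ab = .data$bit_score_ab, bit_ba = .data$bit_score_ba) |>
    arrange(.data$gene_a)
}

best_hits <- function(hits) {
  hits |>
    filter(.data$query_id != .data$subject_id) |>
    arrange(.data$query_id, dplyr::desc(.data$bit_score), .data$e_value,
            .data$subject_id) |>
    group_by(.data$query_id) |>
    slice(1L) |>
    ungroup()
}

#' Built-in all-vs-all protein similarity scores
#'
#' Global (Needleman-Wunsch) alignment of every cross-genome sequence pair
#' with BLOSUM62 and affine gaps, shaped like a BLAST tabular hit table so
#' [rbh_orthologs()] can run without an external search tool. E-values are
#' rank-based pseudo values (best hit per query gets 1e-25, each following
#' rank one decade weaker), flagged by the `provenance` attribute; a real
#' hit table takes precedence whenever available.
#'
#' @param set_a,set_b Sequence tibbles from [read_fasta()] (protein).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Hit table tibble (`query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `e_value`, `bit_score`) with
#'   `attr(, "provenance") == "builtin"`.
#' @export
builtin_scores <- function(set_a, set_b, gap_opening = 10, gap_extension = 0.5) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) abort("empty sequence set")
  rows <- list()
  for (i in seq_len(nrow(set_a))) {
    pat <- Biostrings::AAString(set_a$residues[i])
    for (j in seq_len(nrow(set_b))) {
      aln <- Biostrings::pairwiseAlignment(
        pat, Biostrings::AAString(set_b$residues[j]),
        substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
        gapExtension = gap_extension, type = "global"
      )
      rows[[length(rows) + 1L]] <- tibble(
        query_id = set_a$id[i], subject_id = set_b$id[j],
        percent_identity = Biostrings::pid(aln),
        alignment_length = Biostrings::nchar(aln),
        score = Biostrings::score(aln)
      )
    }
  }
  out <- bind_rows(rows) |>
    group_by(.data$query_id) |>
    arrange(dplyr::desc(.data$score), .data$subject_id, .by_group = TRUE) |>
    mutate(e_value = pmin(1, 1e-25 * 10^(dplyr::row_number() - 1)),
           bit_score = .data$score) |>
    ungroup() |>
    select("query_id", "subject_id", "percent_identity", "alignment_length",
           "e_value", "bit_score")
  attr(out, "provenance") <- "builtin"
  out
}

#' Gene ranks along scaffolds
#'
#' Position index of each gene on its scaffold (1-based, ordered by span
#' start, ties by gene id) — the coordinate system used by
#' [synteny_blocks()].
#'
#' @param ann A [genome_annotation()].
#' @return Tibble `gene_id`, `scaffold`, `rank`.
#' @export
gene_ranks <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  ann$genes |>
    arrange(.data$scaffold, .data$span_start, .data$gene_id) |>
    group_by(.data$scaffold) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup() |>
    select("gene_id", "scaffold", "rank")
}
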