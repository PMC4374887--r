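#' Permutation scan for gene conversion
#'
#' Detects improbably long identical fragments between sequence pairs in a
#' multiple alignment — the signature of gene conversion between paralogs.
#' The alignment is condensed to its polymorphic, gap-free columns; for each
#' sequence pair the fragment score is the longest run of agreement over
#' those columns (allowing up to `mismatch_allowance` disagreements inside
#' the run). The null distribution is built by permuting the condensed
#' columns `n_perm` times — under the null of no conversion, polymorphic
#' columns are exchangeable — and each pair's permutation P value is
#' Bonferroni-corrected across all pairs into a global P. Pairs with global
#' P at or below `p_cut` are reported. At least three sequences are required
#' so that shared ancestral states can be told apart from conversion.
#'
#' @param alignment Sequence tibble (`id`, `residues`), all rows equal length.
#' @param n_perm Number of column permutations (default 10,000).
#' @param mismatch_allowance Mismatches tolerated inside a fragment
#'   (default 0: strictly identical fragments).
#' @param seed Integer seed for the permutation RNG (mandatory for
#'   reproducibility).
#' @param p_cut Global-P reporting threshold (default 0.05).
#' @return Tibble with one row per significant pair: `seq_a`, `seq_b`,
#'   `score` (fragment length in polymorphic sites), `cond_start`,
#'   `cond_end` (condensed coordinates, 0-based half-open), `aln_start`,
#'   `aln_end` (original alignment coordinates, 0-based half-open, spanning
#'   first to last polymorphic site of the tract), `perm_p`, `global_p`.
#'   No polymorphic columns gives an empty result.
#' @export
geneconv_scan <- function(alignment, n_perm = 10000L, mismatch_allowance = 0L,
                          seed = 1L, p_cut = 0.05) {
  if (nrow(alignment) < 3L) {
    abort("gene-conversion scan requires at least 3 sequences")
  }
  lens <- nchar(alignment$residues)
  if (length(unique(lens)) != 1L) abort("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(alignment$residues), ""))
  rownames(mat) <- alignment$id
  no_gap <- colSums(mat == "-" | mat == "N" | mat == "X") == 0L
  poly <- no_gap & apply(mat, 2L, function(col) length(unique(col)) > 1L)
  empty <- tibble(seq_a = character(), seq_b = character(), score = integer(),
                  cond_start = integer(), cond_end = integer(),
                  aln_start = integer(), aln_end = integer(),
                  perm_p = numeric(), global_p = numeric())
  if (!any(poly)) return(empty)
  cond <- mat[, poly, drop = FALSE]
  cond_cols <- which(poly)
  n_sites <- ncol(cond)
  n_seq <- nrow(cond)
  pairs <- utils::combn(n_seq, 2L)
  n_pairs <- ncol(pairs)

  match_vecs <- map(seq_len(n_pairs), function(k) {
    cond[pairs[1L, k], ] == cond[pairs[2L, k], ]
  })
  obs <- map(match_vecs, ~ longest_fragment(.x, mismatch_allowance))
  obs_score <- map_int(obs, "length")

  set.seed(seed)
  exceed <- integer(n_pairs)
  for (it in seq_len(n_perm)) {
    idx <- sample.int(n_sites)
    for (k in seq_len(n_pairs)) {
      if (frag_at_least(match_vecs[[k]][idx], mismatch_allowance,
                        obs_score[k])) {
        exceed[k] <- exceed[k] + 1L
      }
    }
  }
  perm_p <- (exceed + 1) / (n_perm + 1)
  global_p <- pmin(1, perm_p * n_pairs)

  rows <- list()
  for (k in seq_len(n_pairs)) {
    if (global_p[k] > p_cut || obs_score[k] == 0L) next
    o <- obs[[k]]
    rows[[length(rows) + 1L]] <- tibble(
      seq_a = rownames(cond)[pairs[1L, k]],
      seq_b = rownames(cond)[pairs[2L, k]],
      score = o$length,
      cond_start = o$start - 1L, cond_end = o$end,
      aln_start = cond_cols[o$start] - 1L, aln_end = cond_cols[o$end],
      perm_p = perm_p[k], global_p = global_p[k]
    )
  }
  if (!length(rows)) return(empty)
  bind_rows(rows) |> arrange(.data$global_p, .data$seq_a, .data$seq_b)
}

# longest window over a logical agreement vector containing at most
# `allow` FALSE entries; returns 1-based inclusive bounds
longest_fragment <- function(m, allow = 0L) {
  n <- length(m)
  best_len <- 0L
  best_start <- 0L
  left <- 1L
  bad <- 0L
  for (right in seq_len(n)) {
    if (!m[right]) bad <- bad + 1L
    while (bad > allow) {
      if (!m[left]) bad <- bad - 1L
      left <- left + 1L
    }
    # trim window so it starts and ends on an agreement
    l <- left
    while (l <= right && !m[l]) l <- l + 1L
    if (m[right] && l <= right) {
      len <- right - l + 1L
      if (len > best_len) {
        best_len <- len
        best_start <- l
      }
    }
  }
  list(length = best_len, start = best_start,
       end = if (best_len > 0L) best_start + best_len - 1L else 0L)
}

# TRUE when some window with <= allow mismatches reaches length `target`
frag_at_least <- function(m, allow, target) {
  if (target == 0L) return(TRUE)
  if (allow == 0L) {
    r <- rle(m)
    return(any(r$values & r$lengths >= target))
  }
  longest_fragment(m, allow)$length >= target
}

#' Table-4-style summary of conversion events
#'
#' Aggregates conversion events by group (e.g. the phylogenetic group of the
#' cluster they came from): number of clusters with events, number of
#' events, number of distinct affected genes, and mean tract size in
#' original-alignment coordinates.
#'
#' @param events Tibble of conversion events (as from [geneconv_scan()]) with
#'   added columns `cluster_id` and `group`.
#' @return Tibble with one row per group plus a `Total` row.
#' @export
conversion_summary <- function(events) {
  if (nrow(events) == 0L) {
    return(tibble(group = character(), n_clusters = integer(),
                  n_events = integer(), affected_genes = integer(),
                  mean_tract_size = numeric()))
  }
  per_group <- events |>
    group_by(.data$group) |>
    summarise(n_clusters = dplyr::n_distinct(.data$cluster_id),
              n_events = n(),
              affected_genes = dplyr::n_distinct(c(.data$seq_a, .data$seq_b)),
              mean_tract_size = mean(.data$aln_end - .data$aln_start))
  total <- events |>
    summarise(group = "Total",
              n_clusters = dplyr::n_distinct(.data$cluster_id),
              n_events = n(),
              affected_genes = dplyr::n_distinct(c(.data$seq_a, .data$seq_b)),
              mean_tract_size = mean(.data$aln_end - .data$aln_start))
  bind_rows(per_group, total)
}
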