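#' Per-gene coverage fractions from mapped intervals
#'
#' Two coverage types per gene and sample: whole-gene coverage (covered
#' bases within the gene span divided by span length) and exon-only
#' coverage (covered bases within exons divided by total exon length).
#' Intervals are merged to canonical form first, so fractions lie in [0, 1];
#' depth is binarized (a base is covered or not).
#'
#' @param ann A [genome_annotation()].
#' @param intervals Interval tibble (`scaffold`, `start`, `end`,
#'   `sample_id`), e.g. from [read_intervals()]; several samples may be
#'   stacked.
#' @param gene_ids Genes to report (default all).
#' @return Tibble `gene_id`, `sample_id`, `gene_cov`, `exon_cov`, complete
#'   over genes x samples (uncovered genes get 0).
#' @export
coverage_fractions <- function(ann, intervals, gene_ids = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  genes <- ann$genes
  if (!is.null(gene_ids)) genes <- filter(genes, .data$gene_id %in% gene_ids)
  exon_len <- ann$exons |>
    group_by(.data$gene_id) |>
    summarise(exon_len = sum(.data$end - .data$start))
  if (any(exon_len$exon_len == 0)) abort("gene with zero-length exon set")
  iv <- canonicalize_intervals(intervals)
  samples <- unique(intervals$sample_id)
  if (!length(samples)) abort("no intervals supplied")
  rows <- list()
  for (s in samples) {
    ivs <- filter(iv, .data$sample_id == s)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      on_sc <- filter(ivs, .data$scaffold == g$scaffold)
      span_hit <- overlap_len(on_sc$start, on_sc$end, g$span_start, g$span_end)
      ex <- filter(ann$exons, .data$gene_id == g$gene_id)
      ex_hit <- 0
      for (e in seq_len(nrow(ex))) {
        ex_hit <- ex_hit + overlap_len(on_sc$start, on_sc$end,
                                       ex$start[e], ex$end[e])
      }
      el <- exon_len$exon_len[match(g$gene_id, exon_len$gene_id)]
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = g$gene_id, sample_id = s,
        gene_cov = span_hit / (g$span_end - g$span_start),
        exon_cov = ex_hit / el
      )
    }
  }
  bind_rows(rows)
}

overlap_len <- function(starts, ends, s, e) {
  if (!length(starts)) return(0)
  sum(pmax(0, pmin(ends, e) - pmax(starts, s)))
}

#' Threshold-based presence calls
#'
#' `Present` when coverage is strictly above `hi`, `Deleted` when strictly
#' below `lo`, `Partial` otherwise ("more than 85%" and "below 15%" are both
#' strict by default and configurable).
#'
#' @param cov Coverage tibble from [coverage_fractions()].
#' @param hi,lo Thresholds with `0 <= lo < hi <= 1` (defaults 0.85 / 0.15).
#' @param basis `"exon"` (default) or `"gene"`: which coverage fraction the
#'   call uses.
#' @return `cov` with added columns `call` (`Present`/`Partial`/`Deleted`)
#'   and `basis`.
#' @export
call_presence <- function(cov, hi = 0.85, lo = 0.15, basis = c("exon", "gene")) {
  basis <- match.arg(basis)
  if (!(lo >= 0 && lo < hi && hi <= 1)) abort("need 0 <= lo < hi <= 1")
  x <- if (basis == "exon") cov$exon_cov else cov$gene_cov
  cov |>
    mutate(call = dplyr::case_when(x > hi ~ "Present",
                                   x < lo ~ "Deleted",
                                   TRUE ~ "Partial"),
           basis = basis)
}

#' Wide presence matrix
#'
#' @param calls Output of [call_presence()].
#' @return Tibble, genes in rows, one column per sample holding the call.
#' @export
presence_matrix <- function(calls) {
  calls |>
    select("gene_id", "sample_id", "call") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "call")
}

#' Cross-sample coverage summary
#'
#' Counts genes by how widely they are covered across re-sequenced samples:
#' covered above `hi` in all samples, above `hi` in at least one, above the
#' extra `mid` tier in all samples, deleted (below `lo`) in at least one,
#' and deleted in all. Percentages are recomputed from the counts.
#'
#' @param cov Coverage tibble from [coverage_fractions()] covering every
#'   gene x sample combination.
#' @param basis `"exon"` or `"gene"`.
#' @param hi,lo,mid Coverage thresholds (defaults 0.85, 0.15, 0.5).
#' @return Tibble `category`, `n_genes`, `pct` (share of all genes).
#' @export
cross_sample_summary <- function(cov, basis = c("exon", "gene"), hi = 0.85,
                                 lo = 0.15, mid = 0.5) {
  basis <- match.arg(basis)
  x <- if (basis == "exon") cov$exon_cov else cov$gene_cov
  per_gene <- cov |>
    mutate(.cov = x) |>
    group_by(.data$gene_id) |>
    summarise(hi_all = all(.data$.cov > hi),
              hi_any = any(.data$.cov > hi),
              mid_all = all(.data$.cov > mid),
              del_any = any(.data$.cov < lo),
              del_all = all(.data$.cov < lo))
  n <- nrow(per_gene)
  counts <- c(
    above_hi_all_samples = sum(per_gene$hi_all),
    above_hi_any_sample = sum(per_gene$hi_any),
    above_mid_all_samples = sum(per_gene$mid_all),
    deleted_any_sample = sum(per_gene$del_any),
    deleted_all_samples = sum(per_gene$del_all)
  )
  tibble(category = names(counts), n_genes = unname(counts),
         pct = 100 * unname(counts) / n)
}

#' Parental support labels
#'
#' For genomes of hybrid origin: each gene is labelled by which parental
#' taxon's re-sequenced samples retain it. A parent supports a gene when the
#' gene is `Present` in at least half (rounded up) of that parent's samples;
#' genes supported by both parents are `both_parents`, by one
#' `<parent>_only`, by none `neither` — unless some sample shows a `Partial`
#' call, in which case an unsupported gene is `ambiguous`.
#'
#' @param calls Output of [call_presence()].
#' @param parent_map Tibble `sample_id`, `parent` mapping every sample to a
#'   parental taxon; each parent needs at least one sample.
#' @param min_frac Fraction of a parent's samples that must be Present
#'   (default 0.5, rounded up).
#' @return Tibble `gene_id`, `label`, plus one logical column per parent.
#' @export
parental_support <- function(calls, parent_map, min_frac = 0.5) {
  parents <- unique(parent_map$parent)
  if (length(parents) < 2L) abort("need at least two parental taxa")
  n_per <- count(parent_map, .data$parent)
  if (any(n_per$n == 0L)) abort("parent with zero samples")
  missing_s <- setdiff(unique(calls$sample_id), parent_map$sample_id)
  if (length(missing_s)) {
    abort(paste0("sample not in parent map: ", missing_s[1L]))
  }
  merged <- left_join(calls, parent_map, by = "sample_id")
  support <- merged |>
    group_by(.data$gene_id, .data$parent) |>
    summarise(supported = sum(.data$call == "Present") >=
                ceiling(min_frac * n()),
              any_partial = any(.data$call == "Partial"), .groups = "drop")
  wide <- support |>
    select("gene_id", "parent", "supported") |>
    tidyr::pivot_wider(names_from = "parent", values_from = "supported")
  partial <- support |>
    group_by(.data$gene_id) |>
    summarise(any_partial = any(.data$any_partial))
  lab <- map_chr(seq_len(nrow(wide)), function(i) {
    sup <- unlist(wide[i, parents])
    if (all(sup)) {
      "both_parents"
    } else if (sum(sup) == 1L) {
      paste0(parents[sup], "_only")
    } else if (partial$any_partial[match(wide$gene_id[i], partial$gene_id)]) {
      "ambiguous"
    } else {
      "neither"
    }
  })
  mutate(wide, label = lab) |>
    select("gene_id", "label", dplyr::all_of(parents))
}
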