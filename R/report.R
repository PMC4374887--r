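#' Run configuration with field-standard defaults
#'
#' Collects every numeric setting of the pipeline in one place. The
#' defaults are the standard operating points for this kind of analysis:
#' clade partition threshold 0.025 patristic units, 200-kb physical cluster
#' rule, reciprocal-best-hit e-value 1e-20, NBS-domain QC minimum 200 aa,
#' presence thresholds 85%/15% (plus a 50% reporting tier), synteny blocks
#' of at least 5 collinear pairs with fewer than 25 intervening genes,
#' and 10,000 gene-conversion permutations at global P 0.05. Every value
#' can be overridden; the config is echoed into outputs for provenance.
#'
#' @param ... Named overrides of any default.
#' @param seed Integer seed recorded with the run.
#' @return A `run_config` list.
#' @export
run_config <- function(..., seed = 1L) {
  cfg <- list(
    clade_threshold = 0.025,
    cluster_max_gap = 200000,
    rbh_evalue = 1e-20,
    qc_min_len = 200L,
    presence_hi = 0.85,
    presence_lo = 0.15,
    presence_mid = 0.5,
    synteny_min_pairs = 5L,
    synteny_max_gene_gap = 25L,
    geneconv_n_perm = 10000L,
    geneconv_p = 0.05,
    seed = as.integer(seed)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) abort(paste0("unknown config field: ", unknown[1L]))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Architecture-class report table
#'
#' Counts genes per class and genome and derives the LRR-containing
#' fraction (CNL + TNL + NL over the total). Percentages are recomputed
#' from the counts and rounded half-even to one decimal; the raw fraction
#' is kept in a machine column.
#'
#' @param classes Tibble with columns `genome_id`, `class` (one row per
#'   gene), or precomputed counts with columns `genome_id`, `class`, `n`.
#' @return Tibble per genome: `genome_id`, `CNL`, `TNL`, `NL`, `CN`, `TN`,
#'   `N`, `total`, `lrr_pct` (1 decimal), `lrr_frac_raw`.
#' @export
report_classification <- function(classes) {
  if (nrow(classes) == 0L) {
    return(tibble(genome_id = character(), CNL = integer(), TNL = integer(),
                  NL = integer(), CN = integer(), TN = integer(), N = integer(),
                  total = integer(), lrr_pct = numeric(),
                  lrr_frac_raw = numeric()))
  }
  counts <- if ("n" %in% names(classes)) {
    classes
  } else {
    count(classes, .data$genome_id, .data$class)
  }
  wide <- counts |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("CNL", "TNL", "NL", "CN", "TN", "N")) {
    if (!cl %in% names(wide)) wide[[cl]] <- 0L
  }
  wide |>
    mutate(total = .data$CNL + .data$TNL + .data$NL + .data$CN + .data$TN +
             .data$N,
           lrr_frac_raw = (.data$CNL + .data$TNL + .data$NL) / .data$total,
           lrr_pct = round(100 * .data$lrr_frac_raw, 1)) |>
    select("genome_id", "CNL", "TNL", "NL", "CN", "TN", "N", "total",
           "lrr_pct", "lrr_frac_raw")
}

#' Cluster report table
#'
#' Rounds the percent-clustered and mean-cluster-size columns of a
#' [cluster_summary()] to reporting precision while keeping raw values.
#'
#' @param summary Tibble from [cluster_summary()].
#' @return Tibble with `pct_clustered` rounded to 1 decimal,
#'   `mean_cluster_size` to 2, plus `_raw` machine columns.
#' @export
report_clusters <- function(summary) {
  summary |>
    mutate(pct_clustered_raw = .data$pct_clustered,
           mean_cluster_size_raw = .data$mean_cluster_size,
           pct_clustered = round(.data$pct_clustered, 1),
           mean_cluster_size = round(.data$mean_cluster_size, 2))
}

#' Assemble the full report from stage outputs
#'
#' A pure function of its inputs: every percentage is recomputed from
#' counts, so re-running on the same stage outputs reproduces the same
#' tables. Missing stages yield empty tables with headers.
#'
#' @param classes Gene class tibble (see [report_classification()]), or NULL.
#' @param cluster_summaries [cluster_summary()] output, or NULL.
#' @param composition [summarize_composition()] output, or NULL.
#' @param conversion [conversion_summary()] output, or NULL.
#' @param coverage [cross_sample_summary()] output, or NULL.
#' @param config A [run_config()] echoed into the result.
#' @return Named list of tibbles: `classification`, `clusters`,
#'   `clade_types`, `conversion`, `coverage`, `config`.
#' @export
run_report <- function(classes = NULL, cluster_summaries = NULL,
                       composition = NULL, conversion = NULL, coverage = NULL,
                       config = run_config()) {
  empty_classes <- tibble(genome_id = character(), class = character())
  list(
    classification = report_classification(classes %||% empty_classes),
    clusters = if (is.null(cluster_summaries)) {
      tibble(genome_id = character(), total_genes = integer(),
             genes_in_clusters = integer(), n_clusters = integer(),
             pct_clustered = numeric(), mean_cluster_size = numeric())
    } else {
      report_clusters(cluster_summaries)
    },
    clade_types = if (is.null(composition)) {
      tibble(type = character(), n_clades = integer())
    } else {
      composition$type_counts
    },
    conversion = conversion %||% conversion_summary(
      tibble(seq_a = character(), seq_b = character(), cluster_id = character(),
             group = character(), aln_start = integer(), aln_end = integer())
    ),
    coverage = coverage %||% tibble(category = character(),
                                    n_genes = integer(), pct = numeric()),
    config = tibble(field = names(unclass(config)),
                    value = map_chr(unclass(config), ~ format(.x)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
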