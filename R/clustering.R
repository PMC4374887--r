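#' Single-linkage physical clustering of genes along scaffolds
#'
#' Two genes link when they lie on the same scaffold and the gap between
#' their nearest span edges is at most `max_gap`; clusters are the connected
#' components with at least two members, so a chain of genes each within
#' `max_gap` of the next forms one cluster even when its ends are farther
#' apart. Genes are ordered within a cluster by span start (ties broken by
#' gene id).
#'
#' @param ann A [genome_annotation()].
#' @param gene_ids Genes to cluster (default: all genes in `ann`).
#' @param max_gap Maximum inter-gene edge gap in bp (default 200 kb).
#' @param distance `"edge"` (default: gap between nearest span edges) or
#'   `"start"` (start-to-start distance).
#' @return List with `clusters` (tibble `cluster_id`, `scaffold`, `gene_id`,
#'   `rank`, `genome_id`) and `singletons` (character vector of unclustered
#'   gene ids).
#' @export
cluster_genes <- function(ann, gene_ids = NULL, max_gap = 200000,
                          distance = c("edge", "start")) {
  stopifnot(inherits(ann, "genome_annotation"))
  distance <- match.arg(distance)
  if (!is.numeric(max_gap) || max_gap <= 0) abort("max_gap must be > 0")
  genes <- ann$genes
  if (!is.null(gene_ids)) {
    missing_g <- setdiff(gene_ids, genes$gene_id)
    if (length(missing_g)) abort(paste0("gene not in annotation: ", missing_g[1L]))
    genes <- filter(genes, .data$gene_id %in% gene_ids)
  }
  genes <- arrange(genes, .data$scaffold, .data$span_start, .data$gene_id)
  out <- list()
  singles <- character(0)
  cl_counter <- 0L
  for (sc in unique(genes$scaffold)) {
    g <- filter(genes, .data$scaffold == sc)
    n <- nrow(g)
    # chain along the scaffold; with a running max end this equals
    # single-linkage connected components on the line
    comp <- integer(n)
    comp[1L] <- 1L
    if (n > 1L) {
      run_end <- g$span_end[1L]
      run_start <- g$span_start[1L]
      for (i in 2:n) {
        gap <- if (distance == "edge") {
          g$span_start[i] - run_end
        } else {
          g$span_start[i] - run_start
        }
        if (gap <= max_gap) {
          comp[i] <- comp[i - 1L]
          run_end <- max(run_end, g$span_end[i])
        } else {
          comp[i] <- comp[i - 1L] + 1L
          run_end <- g$span_end[i]
        }
        run_start <- g$span_start[i]
      }
    }
    for (cc in unique(comp)) {
      members <- g[comp == cc, ]
      if (nrow(members) < 2L) {
        singles <- c(singles, members$gene_id)
      } else {
        cl_counter <- cl_counter + 1L
        out[[length(out) + 1L]] <- tibble(
          cluster_id = sprintf("%s_cl%03d", ann$genome_id, cl_counter),
          scaffold = sc, gene_id = members$gene_id,
          rank = seq_len(nrow(members)), genome_id = ann$genome_id
        )
      }
    }
  }
  clusters <- if (length(out)) bind_rows(out) else {
    tibble(cluster_id = character(), scaffold = character(),
           gene_id = character(), rank = integer(), genome_id = character())
  }
  list(clusters = clusters, singletons = sort(singles))
}

#' Tandem duplication pairs within clusters
#'
#' Pairs of genes that sit in the same physical cluster, belong to the same
#' clade (or exceed an identity floor), and are separated by at most
#' `max_intervening` genes in genome order. The default `max_intervening = 0`
#' (adjacent homologs) matches the usual tandem-array notion.
#'
#' @param clusters Cluster tibble from [cluster_genes()].
#' @param clade_map Tibble `gene_id`, `clade_id` (e.g. from
#'   [tidy.clade_partition()]); or `NULL` if `identity` is supplied.
#' @param identity Optional symmetric identity matrix (0-1) used instead of
#'   clades: pairs need identity >= `min_identity`.
#' @param min_identity Identity floor when `identity` is used.
#' @param max_intervening Maximum genes between the pair in genome order.
#' @return Tibble `gene_a`, `gene_b`, `cluster_id` (gene_a < gene_b).
#' @export
tandem_pairs <- function(clusters, clade_map = NULL, identity = NULL,
                         min_identity = 0.6, max_intervening = 0L) {
  same_kind <- function(a, b) {
    if (!is.null(clade_map)) {
      ca <- clade_map$clade_id[match(a, clade_map$gene_id)]
      cb <- clade_map$clade_id[match(b, clade_map$gene_id)]
      !is.na(ca) && !is.na(cb) && ca != "ORPHAN" && ca == cb
    } else if (!is.null(identity)) {
      identity[a, b] >= min_identity
    } else {
      abort("supply clade_map or identity")
    }
  }
  out <- list()
  for (cl in unique(clusters$cluster_id)) {
    members <- clusters |> filter(.data$cluster_id == cl) |> arrange(.data$rank)
    n <- nrow(members)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (j - i - 1L > max_intervening) next
        a <- members$gene_id[i]
        b <- members$gene_id[j]
        if (same_kind(a, b)) {
          out[[length(out) + 1L]] <- tibble(
            gene_a = min(a, b), gene_b = max(a, b), cluster_id = cl
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(gene_a = character(), gene_b = character(),
                  cluster_id = character()))
  }
  bind_rows(out)
}

#' Within- vs between-cluster identity distributions
#'
#' Splits all supplied gene pairs into within-cluster and between-cluster
#' sets, reports the two identity distributions, their means, and a
#' two-sample location test.
#'
#' @param clusters Cluster tibble from [cluster_genes()].
#' @param identity Symmetric pairwise identity matrix (values in 0-1) whose
#'   dimnames cover every clustered gene.
#' @param test `"t"` (Welch, default) or `"wilcox"`.
#' @return List with `pairs` (tibble `gene_a`, `gene_b`, `identity`,
#'   `relation`), `mean_within`, `mean_between`, `p_value`.
#' @export
identity_split <- function(clusters, identity, test = c("t", "wilcox")) {
  test <- match.arg(test)
  genes <- sort(unique(clusters$gene_id))
  missing_g <- setdiff(genes, rownames(identity))
  if (length(missing_g)) {
    abort(paste0("cluster member missing from identity matrix: ", missing_g[1L]))
  }
  if (any(identity < 0 | identity > 1, na.rm = TRUE)) {
    abort("identities must lie in [0, 1]")
  }
  all_genes <- intersect(rownames(identity), colnames(identity))
  cl_of <- setNames(clusters$cluster_id, clusters$gene_id)
  pairs <- tidyr::expand_grid(gene_a = all_genes, gene_b = all_genes) |>
    filter(.data$gene_a < .data$gene_b) |>
    mutate(identity = identity[cbind(.data$gene_a, .data$gene_b)],
           relation = dplyr::case_when(
             !is.na(cl_of[gene_a]) & !is.na(cl_of[gene_b]) &
               cl_of[gene_a] == cl_of[gene_b] ~ "within",
             TRUE ~ "between"
           ))
  w <- pairs$identity[pairs$relation == "within"]
  b <- pairs$identity[pairs$relation == "between"]
  p <- if (length(w) > 1L && length(b) > 1L && (stats::sd(c(w, b)) > 0)) {
    if (test == "t") t.test(w, b)$p.value else wilcox.test(w, b)$p.value
  } else {
    NA_real_
  }
  list(pairs = pairs, mean_within = mean(w), mean_between = mean(b),
       p_value = p)
}

#' Per-genome cluster summary table
#'
#' @param cluster_sets Named list (genome id -> result of [cluster_genes()]),
#'   or a single such result.
#' @param totals Optional named vector of total gene counts per genome; by
#'   default clustered + singleton counts.
#' @return Tibble with columns `genome_id`, `total_genes`, `genes_in_clusters`,
#'   `n_clusters`, `pct_clustered`, `mean_cluster_size`. Percentages are
#'   recomputed from the counts; an empty clustering yields 0% and `NA` mean.
#' @export
cluster_summary <- function(cluster_sets, totals = NULL) {
  if (!is.null(cluster_sets$clusters)) cluster_sets <- list(cluster_sets)
  rows <- imap(cluster_sets, function(cs, nm) {
    genome <- if (nrow(cs$clusters)) cs$clusters$genome_id[1L] else as.character(nm)
    n_in <- dplyr::n_distinct(cs$clusters$gene_id)
    n_cl <- dplyr::n_distinct(cs$clusters$cluster_id)
    total <- if (!is.null(totals) && genome %in% names(totals)) {
      totals[[genome]]
    } else {
      n_in + length(cs$singletons)
    }
    tibble(genome_id = genome, total_genes = total, genes_in_clusters = n_in,
           n_clusters = n_cl,
           pct_clustered = if (total > 0) 100 * n_in / total else NA_real_,
           mean_cluster_size = if (n_cl > 0) n_in / n_cl else NA_real_)
  })
  bind_rows(rows)
}
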