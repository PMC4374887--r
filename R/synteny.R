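#' Collinear synteny blocks from ortholog pairs
#'
#' For every scaffold pair, ortholog anchors are chained into maximal
#' collinear runs: ranks must be strictly monotone (increasing or
#' decreasing) on both scaffolds and consecutive anchors must be separated
#' by fewer than `max_gene_gap` genes on each genome. Chains are extracted
#' best-first (longest chain by dynamic programming, then its anchors are
#' removed and the search repeats), so each ortholog pair belongs to at most
#' one block; blocks with fewer than `min_pairs` anchors are discarded.
#'
#' @param orthologs Tibble `gene_a`, `gene_b` (e.g. from [rbh_orthologs()]).
#' @param ranks_a,ranks_b Rank tables from [gene_ranks()] for the two genomes.
#' @param min_pairs Minimum anchors per block (default 5).
#' @param max_gene_gap Maximum intervening genes between consecutive anchors
#'   (default 25, strict: the separation must be `< max_gene_gap`).
#' @return Tibble `block_id`, `scaffold_a`, `scaffold_b`, `orientation`
#'   (`"+"` or `"-"`), `pair_rank`, `gene_a`, `gene_b`, `rank_a`, `rank_b`.
#' @export
synteny_blocks <- function(orthologs, ranks_a, ranks_b, min_pairs = 5L,
                           max_gene_gap = 25L) {
  anchors <- orthologs |>
    left_join(rename(ranks_a, gene_a = "gene_id", scaffold_a = "scaffold",
                     rank_a = "rank"), by = "gene_a") |>
    left_join(rename(ranks_b, gene_b = "gene_id", scaffold_b = "scaffold",
                     rank_b = "rank"), by = "gene_b")
  if (anyNA(anchors$rank_a) || anyNA(anchors$rank_b)) {
    abort("ortholog gene missing from rank tables")
  }
  out <- list()
  block_n <- 0L
  groups <- anchors |> group_by(.data$scaffold_a, .data$scaffold_b)
  for (key in dplyr::group_split(groups)) {
    pool <- arrange(key, .data$rank_a, .data$rank_b)
    repeat {
      if (nrow(pool) < min_pairs) break
      best <- best_chain(pool$rank_a, pool$rank_b, max_gene_gap)
      if (length(best$idx) < min_pairs) break
      block_n <- block_n + 1L
      chain <- pool[best$idx, ]
      out[[length(out) + 1L]] <- chain |>
        mutate(block_id = sprintf("block_%03d", block_n),
               orientation = best$orientation,
               pair_rank = seq_len(nrow(chain))) |>
        select("block_id", "scaffold_a", "scaffold_b", "orientation",
               "pair_rank", "gene_a", "gene_b", "rank_a", "rank_b")
      pool <- pool[-best$idx, ]
    }
  }
  if (!length(out)) {
    return(tibble(block_id = character(), scaffold_a = character(),
                  scaffold_b = character(), orientation = character(),
                  pair_rank = integer(), gene_a = character(),
                  gene_b = character(), rank_a = integer(), rank_b = integer()))
  }
  bind_rows(out)
}

# longest collinear chain (increasing or decreasing in rank_b) under the gap
# cap on both genomes; anchors assumed sorted by rank_a
best_chain <- function(ra, rb, max_gene_gap) {
  n <- length(ra)
  chain_dir <- function(sign) {
    dp <- rep(1L, n)
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        ok <- ra[j] < ra[i] && (ra[i] - ra[j] - 1L) < max_gene_gap &&
          sign * (rb[i] - rb[j]) > 0 &&
          (abs(rb[i] - rb[j]) - 1L) < max_gene_gap
        if (ok && dp[j] + 1L > dp[i]) {
          dp[i] <- dp[j] + 1L
          prev[i] <- j
        }
      }
    }
    end <- which.max(dp)
    idx <- integer(0)
    while (end != 0L) {
      idx <- c(end, idx)
      end <- prev[end]
    }
    idx
  }
  inc <- chain_dir(1)
  dec <- chain_dir(-1)
  if (length(inc) >= length(dec)) {
    list(idx = inc, orientation = "+")
  } else {
    list(idx = dec, orientation = "-")
  }
}

#' Conserved cluster pairs across two genomes
#'
#' Clusters in genome A are matched to clusters in genome B through their
#' ortholog links: candidate cluster pairs sharing at least one ortholog are
#' matched greedily by descending link count (ties: smaller combined size,
#' then lexicographic ids), each cluster used at most once. A matched pair
#' is `complete` when every member of each cluster has an ortholog in the
#' other cluster and `partial` otherwise; clusters that end up with no
#' partner are listed unmatched.
#'
#' @param clusters_a,clusters_b Cluster tibbles from [cluster_genes()].
#' @param orthologs Ortholog tibble `gene_a`, `gene_b` with genome-A genes in
#'   `gene_a`.
#' @return List with `pairs` (tibble `cluster_a`, `cluster_b`, `status`,
#'   `n_links`, `size_a`, `size_b`) and `unmatched` (tibble `cluster_id`,
#'   `genome`).
#' @export
conserved_clusters <- function(clusters_a, clusters_b, orthologs) {
  cl_a <- setNames(clusters_a$cluster_id, clusters_a$gene_id)
  cl_b <- setNames(clusters_b$cluster_id, clusters_b$gene_id)
  links <- orthologs |>
    mutate(cluster_a = unname(cl_a[.data$gene_a]),
           cluster_b = unname(cl_b[.data$gene_b])) |>
    filter(!is.na(.data$cluster_a), !is.na(.data$cluster_b)) |>
    count(.data$cluster_a, .data$cluster_b, name = "n_links")
  size_a <- clusters_a |> count(.data$cluster_id, name = "size")
  size_b <- clusters_b |> count(.data$cluster_id, name = "size")
  links <- links |>
    mutate(size_a = size_a$size[match(.data$cluster_a, size_a$cluster_id)],
           size_b = size_b$size[match(.data$cluster_b, size_b$cluster_id)]) |>
    arrange(dplyr::desc(.data$n_links), .data$size_a + .data$size_b,
            .data$cluster_a, .data$cluster_b)
  used_a <- character(0)
  used_b <- character(0)
  rows <- list()
  for (i in seq_len(nrow(links))) {
    L <- links[i, ]
    if (L$cluster_a %in% used_a || L$cluster_b %in% used_b) next
    used_a <- c(used_a, L$cluster_a)
    used_b <- c(used_b, L$cluster_b)
    mem_a <- clusters_a$gene_id[clusters_a$cluster_id == L$cluster_a]
    mem_b <- clusters_b$gene_id[clusters_b$cluster_id == L$cluster_b]
    ortho_sub <- filter(orthologs, .data$gene_a %in% mem_a,
                        .data$gene_b %in% mem_b)
    complete <- all(mem_a %in% ortho_sub$gene_a) &&
      all(mem_b %in% ortho_sub$gene_b)
    rows[[length(rows) + 1L]] <- mutate(
      L, status = if (complete) "complete" else "partial"
    )
  }
  pairs <- if (length(rows)) {
    bind_rows(rows) |>
      select("cluster_a", "cluster_b", "status", "n_links", "size_a", "size_b")
  } else {
    tibble(cluster_a = character(), cluster_b = character(),
           status = character(), n_links = integer(), size_a = integer(),
           size_b = integer())
  }
  unmatched <- bind_rows(
    tibble(cluster_id = setdiff(unique(clusters_a$cluster_id), pairs$cluster_a),
           genome = "A"),
    tibble(cluster_id = setdiff(unique(clusters_b$cluster_id), pairs$cluster_b),
           genome = "B")
  )
  list(pairs = pairs, unmatched = unmatched)
}
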