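#' Patristic distance matrix of a tree
#'
#' Pairwise leaf-to-leaf distances, each the sum of branch lengths along the
#' connecting path (computed via [ape::cophenetic.phylo()]).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric numeric matrix with leaf labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) abort("tree has missing branch lengths")
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Partition a gene tree into clades by patristic distance
#'
#' Depth-first traversal from the root: a subtree is accepted as a clade as
#' soon as the chosen statistic (default: median) of its within-subtree
#' pairwise patristic distances is at or below `threshold`; accepted
#' subtrees are not descended into, so the parent of every reported clade
#' violates the threshold (maximality). Clades have at least two leaves;
#' leaves never inside an accepted subtree become orphans. Unrooted input is
#' midpoint-rooted first (or rooted on `outgroup` when given). The result is
#' a deterministic function of (tree, threshold, statistic).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param threshold Patristic-distance threshold (> 0); default 0.025.
#' @param statistic Summary of within-subtree pairwise distances compared to
#'   the threshold: `"median"` (default) or a percentile given as a number
#'   in (0, 100].
#' @param outgroup Optional leaf label to root on instead of midpoint.
#' @return A `clade_partition` object: list with `clades` (list of leaf-label
#'   character vectors in canonical order), `orphans`, `threshold`,
#'   `statistic`.
#' @export
partition_clades <- function(tree, threshold = 0.025, statistic = "median",
                             outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("threshold must be a positive number")
  }
  if (!ape::is.rooted(tree)) {
    tree <- if (!is.null(outgroup)) {
      ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    } else {
      phangorn::midpoint(tree)
    }
  }
  stat_fun <- if (identical(statistic, "median")) {
    function(x) median(x)
  } else if (is.numeric(statistic) && statistic > 0 && statistic <= 100) {
    function(x) unname(stats::quantile(x, statistic / 100, type = 7))
  } else {
    abort("statistic must be \"median\" or a percentile in (0, 100]")
  }

  d <- patristic_matrix(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under), use.names = FALSE)
  }
  clades <- list()
  orphans <- character(0)
  visit <- function(node) {
    leaves <- tips_under(node)
    if (length(leaves) == 1L) {
      orphans <<- c(orphans, leaves)
      return(invisible())
    }
    sub <- d[leaves, leaves]
    if (stat_fun(sub[upper.tri(sub)]) <= threshold) {
      clades[[length(clades) + 1L]] <<- sort(leaves)
      return(invisible())
    }
    for (ch in kids[[as.character(node)]]) visit(ch)
  }
  visit(root)
  if (length(clades)) {
    clades <- clades[order(map_chr(clades, 1L))]
  }
  structure(list(clades = clades, orphans = sort(orphans),
                 threshold = threshold, statistic = statistic),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("<clade_partition> ", length(x$clades), " clades, ",
      length(x$orphans), " orphans (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Turn a clade partition into a gene-to-clade table
#'
#' @param x A `clade_partition`.
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `clade_id`; orphans get clade_id
#'   `"ORPHAN"`. Clades are numbered in canonical order (`clade_001`, ...).
#' @method tidy clade_partition
#' @export
tidy.clade_partition <- function(x, ...) {
  rows <- imap(x$clades, function(members, i) {
    tibble(gene_id = members,
           clade_id = sprintf("clade_%03d", i))
  })
  out <- bind_rows(rows)
  if (length(x$orphans)) {
    out <- bind_rows(out, tibble(gene_id = x$orphans, clade_id = "ORPHAN"))
  }
  out
}

#' @method glance clade_partition
#' @export
glance.clade_partition <- function(x, ...) {
  sizes <- lengths(x$clades)
  tibble(n_clades = length(x$clades), n_orphans = length(x$orphans),
         largest_clade = if (length(sizes)) max(sizes) else 0L,
         mean_clade_size = if (length(sizes)) mean(sizes) else NA_real_,
         threshold = x$threshold)
}

#' Summarize clade composition by genome
#'
#' @param partition A `clade_partition`.
#' @param genome_map Tibble with columns `gene_id`, `genome_id` (or a named
#'   character vector gene -> genome).
#' @return List with `composition` (per-clade genome counts, one row per
#'   clade x genome), `type_counts` (clades per composition type, the
#'   composition type being the sorted genomes represented joined by `"+"`),
#'   and `frac_all_genomes_ge3` (fraction of clades with >= 3 members that
#'   contain every genome in `genome_map`).
#' @export
summarize_composition <- function(partition, genome_map) {
  stopifnot(inherits(partition, "clade_partition"))
  if (!is.data.frame(genome_map)) {
    genome_map <- tibble(gene_id = names(genome_map),
                         genome_id = unname(genome_map))
  }
  tab <- tidy(partition) |> filter(.data$clade_id != "ORPHAN")
  unmapped <- setdiff(tab$gene_id, genome_map$gene_id)
  if (length(unmapped)) {
    abort(paste0("leaf not in genome map: ", unmapped[1L]))
  }
  tab <- left_join(tab, genome_map, by = "gene_id")
  composition <- tab |>
    count(.data$clade_id, .data$genome_id, name = "n_genes")
  all_genomes <- sort(unique(genome_map$genome_id))
  per_clade <- composition |>
    group_by(.data$clade_id) |>
    summarise(type = paste(sort(unique(.data$genome_id)), collapse = "+"),
              size = sum(.data$n_genes),
              n_genomes = dplyr::n_distinct(.data$genome_id))
  type_counts <- per_clade |> count(.data$type, name = "n_clades") |>
    arrange(dplyr::desc(.data$n_clades))
  ge3 <- filter(per_clade, .data$size >= 3L)
  frac <- if (nrow(ge3)) {
    mean(ge3$n_genomes == length(all_genomes))
  } else {
    NA_real_
  }
  list(composition = composition, per_clade = per_clade,
       type_counts = type_counts, frac_all_genomes_ge3 = frac)
}

#' Assign leaves to top-level groups
#'
#' With `seeds` (a named list of leaf vectors) each group is the minimal
#' subtree covering its seed set; the subtrees must be disjoint, and leaves
#' outside every seed subtree are labelled `NA`. Without seeds the `k - 1`
#' internal edges with the largest branch lengths are cut (ties: edge order)
#' and the resulting leaf blocks become groups, so every leaf is labelled.
#'
#' @param tree An [ape::phylo] tree.
#' @param k Number of groups (>= 2); ignored when `seeds` is given.
#' @param seeds Optional named list of character vectors of leaf labels.
#' @return Tibble with columns `gene_id`, `group`.
#' @export
assign_groups <- function(tree, k = 3L, seeds = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (!is.null(seeds)) {
    if (is.null(names(seeds))) names(seeds) <- paste0("group_", seq_along(seeds))
    labs <- rep(NA_character_, ntip)
    covered <- list()
    for (g in names(seeds)) {
      idx <- match(seeds[[g]], tree$tip.label)
      if (anyNA(idx)) abort(paste0("seed leaf not in tree: ",
                                   seeds[[g]][is.na(idx)][1L]))
      tips <- if (length(idx) == 1L) {
        idx
      } else {
        mrca <- ape::getMRCA(tree, idx)
        unlist(phangorn::Descendants(tree, mrca, type = "tips"))
      }
      if (any(!is.na(labs[tips]))) {
        abort("seed-derived subtrees overlap")
      }
      labs[tips] <- g
    }
    return(tibble(gene_id = tree$tip.label, group = labs))
  }
  if (k < 2L) abort("k must be >= 2")
  edge <- tree$edge
  internal <- which(edge[, 2L] > ntip)
  if (length(internal) < k - 1L) {
    abort(paste0("tree has only ", length(internal),
                 " internal edges; cannot make ", k, " groups"))
  }
  cut <- internal[order(-tree$edge.length[internal], internal)][seq_len(k - 1L)]
  keep <- setdiff(seq_len(nrow(edge)), cut)
  # union-find over tree nodes using the kept edges
  parent <- seq_len(ntip + tree$Nnode)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in keep) {
    a <- find(edge[e, 1L]); b <- find(edge[e, 2L])
    if (a != b) parent[a] <- b
  }
  comp <- map_int(seq_len(ntip), find)
  # canonical group numbering: by smallest leaf label within each block
  blocks <- unname(split(tree$tip.label, comp))
  blocks <- blocks[order(map_chr(blocks, ~ sort(.x)[1L]))]
  lab_map <- unlist(map2(blocks, seq_along(blocks), function(tips, i) {
    setNames(rep(paste0("group_", i), length(tips)), tips)
  }))
  tibble(gene_id = tree$tip.label, group = unname(lab_map[tree$tip.label]))
}
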