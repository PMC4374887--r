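# fixture builders shared across test files; everything is generated in code

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal two-gene GFF3 (1-based inclusive coordinates)
fixture_gff3 <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    "scaf1\tsrc\tgene\t101\t1100\t.\t+\t.\tID=gA",
    "scaf1\tsrc\texon\t101\t300\t.\t+\t.\tID=gA.e1;Parent=gA",
    "scaf1\tsrc\texon\t401\t600\t.\t+\t.\tID=gA.e2;Parent=gA",
    "scaf1\tsrc\texon\t601\t700\t.\t+\t.\tID=gA.e3;Parent=gA",
    "scaf1\tsrc\texon\t801\t900\t.\t+\t.\tID=gA.e4;Parent=gA",
    "scaf1\tsrc\texon\t1001\t1100\t.\t+\t.\tID=gA.e5;Parent=gA",
    "scaf2\tsrc\tgene\t51\t250\t.\t-\t.\tID=gB",
    "scaf2\tsrc\texon\t51\t250\t.\t-\t.\tID=gB.e1;Parent=gB"
  ), ".gff3")
}

# annotation with genes laid out at given span starts (one exon per gene)
annotation_at <- function(starts, width = 1000, scaffold = "scaf1",
                          genome_id = "test") {
  ids <- sprintf("g%03d", seq_along(starts))
  genome_annotation(
    genes = tibble::tibble(gene_id = ids, scaffold = scaffold, strand = "+"),
    exons = tibble::tibble(gene_id = ids, start = starts,
                           end = starts + width),
    genome_id = genome_id
  )
}

# random caterpillar-ish tree with positive branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.01, 1), 4)
  tr
}

# independent patristic oracle: shortest path over the tree graph
patristic_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(n_nodes))
  )
  d <- igraph::distances(g, weights = tree$edge.length)
  out <- d[as.character(seq_len(ntip)), as.character(seq_len(ntip))]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# exhaustive top-down clade partition oracle: test every subtree
partition_oracle <- function(tree, threshold) {
  d <- patristic_oracle(tree)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  ok <- function(leaves) {
    sub <- d[leaves, leaves]
    stats::median(sub[upper.tri(sub)]) <= threshold
  }
  clades <- list()
  orphans <- character(0)
  recurse <- function(node) {
    leaves <- tips_under(node)
    if (length(leaves) == 1) {
      orphans <<- c(orphans, leaves)
    } else if (ok(leaves)) {
      clades[[length(clades) + 1]] <<- sort(leaves)
    } else {
      for (ch in kids[[as.character(node)]]) recurse(ch)
    }
  }
  recurse(ntip + 1L)
  list(clades = clades[order(vapply(clades, `[`, "", 1))],
       orphans = sort(orphans))
}

# brute-force union-find over all gene pairs (physical clustering oracle)
cluster_oracle <- function(ann, max_gap) {
  g <- ann$genes
  n <- nrow(g)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (g$scaffold[i] != g$scaffold[j]) next
      gap <- max(g$span_start[i], g$span_start[j]) -
        min(g$span_end[i], g$span_end[j])
      if (gap <= max_gap) parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  split(g$gene_id, comp)
}

# brute-force RBH oracle over full score tables
rbh_oracle <- function(hits_ab, hits_ba, cut = 1e-20) {
  best <- function(h, q) {
    sub <- h[h$query_id == q & h$subject_id != q, ]
    sub <- sub[order(-sub$bit_score, sub$e_value, sub$subject_id), ]
    sub[1, ]
  }
  pairs <- list()
  for (q in unique(hits_ab$query_id)) {
    ba <- best(hits_ab, q)
    bb <- best(hits_ba, ba$subject_id)
    if (identical(bb$subject_id, q) && ba$e_value < cut && bb$e_value < cut) {
      pairs[[length(pairs) + 1]] <- c(q, ba$subject_id)
    }
  }
  pairs
}

# exhaustive longest-collinear-chain oracle (all subsets, <= 12 anchors)
chain_oracle <- function(ra, rb, max_gene_gap) {
  n <- length(ra)
  best <- integer(0)
  idx_all <- seq_len(n)
  for (size in n:1) {
    if (size <= length(best)) break
    combos <- utils::combn(idx_all, size, simplify = FALSE)
    for (s in combos) {
      o <- s[order(ra[s])]
      if (any(duplicated(ra[o])) || any(duplicated(rb[o]))) next
      dra <- diff(ra[o])
      drb <- diff(rb[o])
      mono <- all(drb > 0) || all(drb < 0)
      gaps <- all(dra - 1 < max_gene_gap) && all(abs(drb) - 1 < max_gene_gap)
      if (mono && gaps && length(o) > length(best)) best <- o
    }
    if (length(best) == size) break
  }
  best
}

# NG86 oracle with independent pathway enumeration (recursive, memo-free)
ng86_oracle <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_frac <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    for (p in 1:3) for (nt in setdiff(bases, ch[p])) {
      m <- ch; m[p] <- nt
      if (code[[paste(m, collapse = "")]] == code[[codon]]) s <- s + 1 / 3
    }
    s
  }
  paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(list(s = 0, n = 0, stop = FALSE)))
    out <- list()
    for (p in pos) {
      ch <- strsplit(from, "")[[1]]
      ch[p] <- strsplit(to, "")[[1]][p]
      mid <- paste(ch, collapse = "")
      syn <- code[[from]] == code[[mid]]
      hit_stop <- code[[mid]] == "*"
      for (rest in paths(mid, to)) {
        out[[length(out) + 1]] <- list(s = rest$s + syn, n = rest$n + !syn,
                                       stop = rest$stop || hit_stop)
      }
    }
    out
  }
  starts <- seq(1, nchar(a), 3)
  ca <- substring(a, starts, starts + 2)
  cb <- substring(b, starts, starts + 2)
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    code[ca] != "*" & code[cb] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(vapply(ca, syn_frac, 1)) + sum(vapply(cb, syn_frac, 1))) / 2
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    pp <- paths(ca[i], cb[i])
    ok <- !vapply(pp, `[[`, TRUE, "stop")
    if (!any(ok)) ok <- rep(TRUE, length(pp))
    Sd <- Sd + mean(vapply(pp[ok], `[[`, 1, "s"))
    Nd <- Nd + mean(vapply(pp[ok], `[[`, 1, "n"))
  }
  list(S = S, N = 3 * length(ca) - S, Sd = Sd, Nd = Nd)
}

# all-substrings longest identical fragment oracle over a match vector
fragment_oracle <- function(m) {
  n <- length(m)
  best <- 0
  for (i in seq_len(n)) for (j in i:n) {
    if (all(m[i:j])) best <- max(best, j - i + 1)
  }
  best
}

# per-base boolean-array coverage oracle
coverage_oracle <- function(ann, intervals, gene_id, sample_id) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  iv <- intervals[intervals$sample_id == sample_id &
                    intervals$scaffold == g$scaffold, ]
  len <- max(c(g$span_end, iv$end, 0))
  covered <- logical(len)
  for (r in seq_len(nrow(iv))) {
    if (iv$end[r] > iv$start[r]) covered[(iv$start[r] + 1):iv$end[r]] <- TRUE
  }
  span_mask <- logical(len)
  span_mask[(g$span_start + 1):g$span_end] <- TRUE
  ex <- ann$exons[ann$exons$gene_id == gene_id, ]
  exon_mask <- logical(len)
  for (r in seq_len(nrow(ex))) {
    exon_mask[(ex$start[r] + 1):ex$end[r]] <- TRUE
  }
  list(gene_cov = sum(covered & span_mask) / sum(span_mask),
       exon_cov = sum(covered & exon_mask) / sum(exon_mask))
}

# random protein string
random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "D", "E", "G", "H", "K", "N", "Q", "R", "S", "T", "Y"),
               n, replace = TRUE), collapse = "")
}
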