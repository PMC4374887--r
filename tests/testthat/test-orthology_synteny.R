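hit_row <- function(q, s, bit, e = 1e-30) {
  tibble::tibble(query_id = q, subject_id = s, percent_identity = 90,
                 alignment_length = 100, e_value = e, bit_score = bit)
}

test_that("reciprocal best hits demand mutual best and the e-value cutoff", {
  ab <- dplyr::bind_rows(hit_row("a1", "b1", 500), hit_row("a1", "b2", 400),
                         hit_row("a2", "b2", 450))
  ba <- dplyr::bind_rows(hit_row("b1", "a1", 500), hit_row("b2", "a1", 460))
  orth <- rbh_orthologs(ab, ba)
  expect_equal(nrow(orth), 1L)  # a2->b2 but b2's best is a1: reciprocity fails
  expect_equal(orth$gene_a, "a1")
  expect_equal(orth$gene_b, "b1")

  weak <- rbh_orthologs(dplyr::mutate(ab, e_value = 1e-10),
                        dplyr::mutate(ba, e_value = 1e-10))
  expect_equal(nrow(weak), 0L)
})

test_that("RBH equals the all-pairs oracle on random score tables", {
  for (seed in 1:5) {
    set.seed(seed)
    na <- 20; nb <- 20
    tab <- expand.grid(query_id = sprintf("a%02d", 1:na),
                       subject_id = sprintf("b%02d", 1:nb),
                       stringsAsFactors = FALSE)
    tab$bit_score <- sample(1000, nrow(tab))
    tab$e_value <- 10^-sample(15:40, nrow(tab), replace = TRUE)
    tab$percent_identity <- 80
    tab$alignment_length <- 100
    ab <- tibble::as_tibble(tab)
    ba <- dplyr::rename(ab, query_id = subject_id, subject_id = query_id)
    got <- rbh_orthologs(ab, ba)
    want <- rbh_oracle(ab, ba)
    expect_setequal(purrr::map_chr(seq_len(nrow(got)),
                                   ~ paste(got$gene_a[.x], got$gene_b[.x])),
                    purrr::map_chr(want, paste, collapse = " "))
    # symmetric in genome order
    swapped <- rbh_orthologs(ba, ab)
    expect_setequal(paste(got$gene_a, got$gene_b),
                    paste(swapped$gene_b, swapped$gene_a))
  }
})

test_that("builtin scorer is symmetric, ranks identity highest, matches DP", {
  seqs <- tibble::tibble(
    id = c("s1", "s2", "s3"),
    alphabet = "protein",
    residues = c("MKTAYIAKQR", "MKTAYIAKQR", "MKTWYIGKQR")
  )
  hits <- builtin_scores(seqs[1, ], seqs)
  expect_equal(hits$percent_identity[hits$subject_id == "s2"], 100)
  expect_equal(which.max(hits$bit_score[match(c("s2", "s3"), hits$subject_id)]),
               1L)
  # symmetry of the global alignment score
  h12 <- builtin_scores(seqs[1, ], seqs[3, ])$bit_score
  h21 <- builtin_scores(seqs[3, ], seqs[1, ])$bit_score
  expect_equal(h12, h21)
  expect_error(builtin_scores(seqs[0, ], seqs), "empty")

  # gapless pair: score equals the direct BLOSUM62 sum (quadratic DP oracle
  # reduces to the diagonal when sequences are equal length and ungapped)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  a <- strsplit(seqs$residues[1], "")[[1]]
  b <- strsplit(seqs$residues[3], "")[[1]]
  expect_equal(h12, sum(BLOSUM62[cbind(a, b)]))
})

test_that("synteny chains respect min_pairs, gaps and monotone ranks", {
  ranks_a <- tibble::tibble(gene_id = sprintf("a%02d", 1:10), scaffold = "sA",
                            rank = 1:10)
  ranks_b <- tibble::tibble(gene_id = sprintf("b%02d", 1:10), scaffold = "sB",
                            rank = 1:10)
  orth6 <- tibble::tibble(gene_a = sprintf("a%02d", 1:6),
                          gene_b = sprintf("b%02d", 1:6))
  blocks <- synteny_blocks(orth6, ranks_a, ranks_b)
  expect_equal(dplyr::n_distinct(blocks$block_id), 1L)
  expect_equal(nrow(blocks), 6L)
  expect_equal(blocks$orientation[1], "+")

  # four collinear pairs only: below min_pairs, no block
  orth4 <- orth6[1:4, ]
  expect_equal(nrow(synteny_blocks(orth4, ranks_a, ranks_b)), 0L)

  # reversed order: one decreasing block
  orth_rev <- tibble::tibble(gene_a = sprintf("a%02d", 1:6),
                             gene_b = sprintf("b%02d", 6:1))
  rev_blocks <- synteny_blocks(orth_rev, ranks_a, ranks_b)
  expect_equal(rev_blocks$orientation[1], "-")
  expect_equal(nrow(rev_blocks), 6L)

  # a gap of >= max_gene_gap genes breaks the chain
  ranks_b_wide <- tibble::tibble(gene_id = sprintf("b%02d", 1:6),
                                 scaffold = "sB",
                                 rank = c(1, 2, 3, 40, 41, 42))
  broken <- synteny_blocks(orth6, ranks_a, ranks_b_wide, min_pairs = 3,
                           max_gene_gap = 25)
  expect_equal(dplyr::n_distinct(broken$block_id), 2L)
})

test_that("best chains equal exhaustive enumeration on small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 10
    ra <- sample(30, n)
    rb <- sample(30, n)
    ranks_a <- tibble::tibble(gene_id = sprintf("a%02d", 1:n), scaffold = "sA",
                              rank = ra)
    ranks_b <- tibble::tibble(gene_id = sprintf("b%02d", 1:n), scaffold = "sB",
                              rank = rb)
    orth <- tibble::tibble(gene_a = sprintf("a%02d", 1:n),
                           gene_b = sprintf("b%02d", 1:n))
    blocks <- synteny_blocks(orth, ranks_a, ranks_b, min_pairs = 2,
                             max_gene_gap = 8)
    first_len <- if (nrow(blocks)) {
      max(table(blocks$block_id))
    } else {
      0
    }
    want <- length(chain_oracle(ra, rb, 8))
    expect_equal(first_len, max(want, 0))
    # every emitted block satisfies its own invariants
    for (bid in unique(blocks$block_id)) {
      bl <- blocks[blocks$block_id == bid, ]
      expect_true(all(diff(bl$rank_a) > 0))
      expect_true(all(diff(bl$rank_b) > 0) || all(diff(bl$rank_b) < 0))
      expect_true(all(diff(bl$rank_a) - 1 < 8))
      expect_true(all(abs(diff(bl$rank_b)) - 1 < 8))
    }
  }
})

test_that("conserved clusters classify complete vs partial by ortholog cover", {
  mk_cl <- function(genome, cl, genes) {
    tibble::tibble(cluster_id = cl, scaffold = "s", gene_id = genes,
                   rank = seq_along(genes), genome_id = genome)
  }
  ca <- mk_cl("A", "A_cl1", c("a1", "a2", "a3"))
  cb <- mk_cl("B", "B_cl1", c("b1", "b2", "b3"))
  full <- tibble::tibble(gene_a = c("a1", "a2", "a3"),
                         gene_b = c("b1", "b2", "b3"))
  res <- conserved_clusters(ca, cb, full)
  expect_equal(res$pairs$status, "complete")

  res2 <- conserved_clusters(ca, cb, full[1:2, ])
  expect_equal(res2$pairs$status, "partial")

  # a cluster with no orthologs anywhere is unmatched
  ca2 <- dplyr::bind_rows(ca, mk_cl("A", "A_cl2", c("a8", "a9")))
  res3 <- conserved_clusters(ca2, cb, full)
  expect_true("A_cl2" %in% res3$unmatched$cluster_id)
})

test_that("duplicated-ancestor genomes give complete clusters and one block", {
  sim <- simulate_nbs(sim_config(seed = 19, n_orphans = 0L))
  cla <- cluster_genes(sim$genomes$genomeA)$clusters
  clb <- cluster_genes(sim$genomes$genomeB)$clusters
  cons <- conserved_clusters(cla, clb, sim$truth$orthologs)
  expect_true(all(cons$pairs$status == "complete"))
  expect_equal(nrow(cons$pairs), dplyr::n_distinct(cla$cluster_id))

  blocks <- synteny_blocks(sim$truth$orthologs,
                           gene_ranks(sim$genomes$genomeA),
                           gene_ranks(sim$genomes$genomeB))
  expect_equal(dplyr::n_distinct(blocks$block_id), 1L)
  expect_equal(nrow(blocks), nrow(sim$truth$orthologs))

  # orthologs recovered from built-in scores on a subset match the truth
  pa <- dplyr::filter(sim$proteins, startsWith(id, "genomeA"))[1:6, ]
  pb <- dplyr::filter(sim$proteins, startsWith(id, "genomeB"))[1:6, ]
  orth <- rbh_orthologs(builtin_scores(pa, pb), builtin_scores(pb, pa))
  truth_sub <- dplyr::filter(sim$truth$orthologs, gene_a %in% pa$id,
                             gene_b %in% pb$id)
  expect_setequal(paste(orth$gene_a, orth$gene_b),
                  paste(truth_sub$gene_a, truth_sub$gene_b))
})
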