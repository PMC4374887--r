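test_that("clustering respects the gap threshold and chains single linkage", {
  # spans of width 1 kb at 0, 150 kb, 400 kb: first two link, third does not
  ann <- annotation_at(c(0, 150000, 400000))
  res <- cluster_genes(ann, max_gap = 200000)
  expect_equal(sort(res$clusters$gene_id), c("g001", "g002"))
  expect_equal(res$singletons, "g003")

  # chain 150 kb apart pairwise: one 3-gene cluster though ends are > 200 kb
  chain <- annotation_at(c(0, 151000, 302000))
  res2 <- cluster_genes(chain, max_gap = 200000)
  expect_equal(dplyr::n_distinct(res2$clusters$cluster_id), 1L)
  expect_equal(nrow(res2$clusters), 3L)

  expect_error(cluster_genes(ann, max_gap = 0), "max_gap")
})

test_that("clusters equal the union-find oracle on random layouts", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    starts <- sort(sample(0:5e6, n))
    ann <- annotation_at(starts, width = 2000)
    # shuffle gene input order to check order invariance as well
    res <- cluster_genes(ann, max_gap = 120000,
                         gene_ids = sample(ann$genes$gene_id))
    got <- c(unname(split(res$clusters$gene_id, res$clusters$cluster_id)),
             as.list(res$singletons))
    want <- unname(cluster_oracle(ann, 120000))
    expect_setequal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("shrinking max_gap only refines the clustering", {
  set.seed(77)
  ann <- annotation_at(sort(sample(0:2e6, 80)), width = 1500)
  coarse <- cluster_genes(ann, max_gap = 150000)
  fine <- cluster_genes(ann, max_gap = 40000)
  coarse_of <- setNames(coarse$clusters$cluster_id, coarse$clusters$gene_id)
  fine_parts <- split(fine$clusters$gene_id, fine$clusters$cluster_id)
  for (members in fine_parts) {
    expect_equal(dplyr::n_distinct(coarse_of[members]), 1L)
  }
})

test_that("tandem pairs require same clade and bounded intervening genes", {
  ann <- annotation_at(c(0, 10000, 20000, 30000))
  cl <- cluster_genes(ann, max_gap = 200000)$clusters
  clade_map <- tibble::tibble(gene_id = sprintf("g%03d", 1:4),
                              clade_id = c("c1", "c1", "c2", "c1"))
  tp <- tandem_pairs(cl, clade_map)
  expect_equal(nrow(tp), 1L)  # only g001-g002 are adjacent and same clade
  expect_equal(tp$gene_a, "g001")

  # widening the intervening allowance picks up g002-g004 across g003
  tp2 <- tandem_pairs(cl, clade_map, max_intervening = 1L)
  expect_equal(nrow(tp2), 2L)

  # different clades adjacent: nothing
  other <- tibble::tibble(gene_id = sprintf("g%03d", 1:4),
                          clade_id = c("c1", "c2", "c3", "c4"))
  expect_equal(nrow(tandem_pairs(cl, other)), 0L)
})

test_that("tandem count on the simulated fixture matches planted arrays", {
  sim <- simulate_nbs(sim_config(seed = 12, n_orphans = 0L))
  cl <- cluster_genes(sim$genomes$genomeA)$clusters
  truth <- sim$truth$genes
  clade_map <- tibble::tibble(gene_id = paste0("genomeA|", truth$gene_id),
                              clade_id = truth$family)
  tp <- tandem_pairs(cl, clade_map)
  # planted arrays are contiguous family runs: adjacent same-family pairs
  expected <- sum(pmax(table(truth$family) - 1, 0))
  expect_equal(nrow(tp), expected)
})

test_that("identity split separates planted divergence levels", {
  ann <- annotation_at(c(0, 1000, 5e6, 5e6 + 1000))
  cl <- cluster_genes(ann, max_gap = 200000)
  ids <- sprintf("g%03d", 1:4)
  m <- matrix(0.4, 4, 4, dimnames = list(ids, ids))  # between-cluster level
  m[1, 2] <- m[2, 1] <- 0.9
  m[3, 4] <- m[4, 3] <- 0.85  # within-cluster level
  diag(m) <- 1
  split_res <- identity_split(cl$clusters, m)
  expect_equal(split_res$mean_within, mean(c(0.9, 0.85)))
  expect_equal(split_res$mean_between, 0.4)
  expect_gt(split_res$mean_within, split_res$mean_between)
  # distributions partition all supplied pairs
  expect_equal(nrow(split_res$pairs), choose(4, 2))

  # all-equal identities: means equal, test degenerate (NA p)
  flat <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  fr <- identity_split(cl$clusters, flat)
  expect_equal(fr$mean_within, fr$mean_between)
  expect_true(is.na(fr$p_value))

  expect_error(identity_split(cl$clusters, m[-1, -1]), "missing")
})

test_that("cluster summary reproduces printed percentage arithmetic", {
  fake <- function(genome, total, clustered, n_clusters) {
    # minimal cluster tibble with the right marginals
    clusters <- tibble::tibble(
      cluster_id = paste0(genome, "_cl", rep(seq_len(n_clusters),
                                             length.out = clustered)),
      scaffold = "s", gene_id = paste0(genome, "_g", seq_len(clustered)),
      rank = 1L, genome_id = genome
    )
    list(clusters = clusters,
         singletons = paste0(genome, "_s", seq_len(total - clustered)))
  }
  summ <- cluster_summary(list(
    fake("Cc", 618, 525, 108),
    fake("CsChina", 650, 500, 126),
    fake("CsUSA", 508, 207, 72)
  ))
  # printed values are truncation-style; agree within 0.1 of the raw percent
  expect_true(all(abs(summ$pct_clustered - c(84.9, 76.9, 40.7)) <= 0.1))
  expect_equal(round(summ$mean_cluster_size, 2)[1:2], c(4.86, 3.97))

  empty <- cluster_summary(list(list(
    clusters = tibble::tibble(cluster_id = character(), scaffold = character(),
                              gene_id = character(), rank = integer(),
                              genome_id = character()),
    singletons = c("a", "b"))), totals = c(none = 2))
  expect_equal(empty$pct_clustered, 0)
  expect_true(is.na(empty$mean_cluster_size))
})
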