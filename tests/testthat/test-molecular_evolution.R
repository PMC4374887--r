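test_that("backthreading expands gaps and round-trips translation", {
  aln <- tibble::tibble(id = c("x", "y"), residues = c("MKT", "MKT"))
  cds <- tibble::tibble(id = c("x", "y"),
                        residues = c("ATGAAAACT", "ATGAAGACC"))
  bt <- backthread(aln, cds)
  expect_equal(nchar(bt$residues), c(9L, 9L))
  expect_equal(bt$residues[1], "ATGAAAACT")

  gapped <- tibble::tibble(id = c("x", "y"), residues = c("MK-T", "MKQT"))
  cds2 <- tibble::tibble(id = c("x", "y"),
                         residues = c("ATGAAAACT", "ATGAAACAAACT"))
  bt2 <- backthread(gapped, cds2)
  expect_equal(bt2$residues[1], "ATGAAA---ACT")

  # terminal stop on the CDS is tolerated
  with_stop <- tibble::tibble(id = "x", residues = "MKT")
  expect_silent(backthread(with_stop,
                           tibble::tibble(id = "x", residues = "ATGAAAACTTAA")))

  bad <- tibble::tibble(id = "x", residues = "ATGAAAAAA")  # MKK, not MKT
  expect_error(backthread(tibble::tibble(id = "x", residues = "MKT"), bad),
               "at residue 3")

  # round-trip property on simulated families
  sim <- simulate_nbs(sim_config(seed = 3, n_families = 3))
  prot <- sim$proteins[1:4, ]
  cds_rec <- sim$cds[match(prot$id, sim$cds$id), ]
  bt3 <- backthread(prot, cds_rec)  # ungapped alignment
  for (i in 1:4) {
    expect_equal(translate_cds(bt3$residues[i]), prot$residues[i])
  }
})

test_that("NG86 hand-counts verify on single-codon and identical inputs", {
  same <- ng86_dnds("ATGAAAACT", "ATGAAAACT")
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)

  # TTT vs TTC: one synonymous difference; S(TTT) = S(TTC) = 1/3 so the
  # proportion pS = 3 saturates the Jukes-Cantor correction
  r <- ng86_dnds("TTT", "TTC")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S_sites, 1 / 3)
  expect_equal(r$dN, 0)
  expect_true(r$saturated)

  expect_error(ng86_dnds("---", "ATG"), "no comparable codons")
})

test_that("NG86 matches the pathway-enumeration oracle on random pairs", {
  set.seed(8)
  ok <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:5) {
    a <- paste(sample(ok, 30, replace = TRUE), collapse = "")
    # derive b by mutating a few bases so multi-hit codons occur
    bb <- strsplit(a, "")[[1]]
    idx <- sample(length(bb), 12)
    for (p in idx) bb[p] <- sample(c("A", "C", "G", "T"), 1)
    b <- paste(bb, collapse = "")
    got <- ng86_dnds(a, b)
    want <- ng86_oracle(a, b)
    expect_equal(got$S_sites, want$S, tolerance = 1e-10)
    expect_equal(got$N_sites, want$N, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    # symmetry and order invariance
    rev <- ng86_dnds(b, a)
    expect_equal(got$Sd, rev$Sd, tolerance = 1e-10)
    perm <- sample(nchar(a) / 3)
    starts <- (perm - 1) * 3 + 1
    ap <- paste(substring(a, starts, starts + 2), collapse = "")
    bp <- paste(substring(b, starts, starts + 2), collapse = "")
    shuffled <- ng86_dnds(ap, bp)
    expect_equal(got$dN, shuffled$dN, tolerance = 1e-10)
    expect_equal(got$dS, shuffled$dS, tolerance = 1e-10)
  }
})

test_that("synonymous-only evolution gives dN = 0 and dS near the truth", {
  for (seed in 1:3) {
    sp <- sim_synonymous_pair(300, 25, seed = seed)
    r <- ng86_dnds(sp$a, sp$b)
    expect_equal(r$dN, 0)
    truth <- sp$n_events / r$S_sites
    expect_lt(abs(r$dS - truth) / truth, 0.2)
  }
})

test_that("conversion scan requires 3 sequences and handles degenerate input", {
  two <- tibble::tibble(id = c("a", "b"), residues = c("ACGT", "ACGT"))
  expect_error(geneconv_scan(two), "at least 3")

  same <- tibble::tibble(id = c("a", "b", "c"),
                         residues = rep("ACGTACGT", 3))
  expect_equal(nrow(geneconv_scan(same, n_perm = 50)), 0L)
})

test_that("observed fragment scores equal the all-substrings oracle", {
  for (seed in 1:4) {
    aln <- sim_paralog_alignment(4, 600, divergence = 0.3, seed = seed)
    mat <- do.call(rbind, strsplit(aln$residues, ""))
    poly <- apply(mat, 2, function(col) length(unique(col)) > 1)
    cond <- mat[, poly, drop = FALSE]
    # compare the internal fragment scorer against brute force per pair
    pairs <- utils::combn(4, 2)
    for (k in seq_len(ncol(pairs))) {
      m <- cond[pairs[1, k], ] == cond[pairs[2, k], ]
      got <- nbskit:::longest_fragment(m, 0L)$length
      expect_equal(got, fragment_oracle(m))
    }
  }
})

test_that("a planted tract is detected and clean alignments stay quiet", {
  al <- sim_paralog_alignment(6, 2000, divergence = 0.05, seed = 101)
  planted <- plant_conversion(al, "par01", "par02", c(200, 1400))
  ev <- geneconv_scan(planted$alignment, n_perm = 1500, seed = 7)
  expect_true(nrow(ev) >= 1)
  expect_true(any(ev$seq_a == "par01" & ev$seq_b == "par02" &
                    ev$global_p <= 0.05))
  # the reported tract overlaps the planted one in alignment coordinates
  hit <- ev[ev$seq_a == "par01" & ev$seq_b == "par02", ][1, ]
  expect_lt(hit$aln_start, 1400)
  expect_gt(hit$aln_end, 200)

  quiet <- geneconv_scan(al, n_perm = 1500, seed = 7)
  expect_equal(nrow(quiet), 0L)
})

test_that("planting conversions validates tracts and zero length is a no-op", {
  al <- sim_paralog_alignment(3, 100, seed = 2)
  zero <- plant_conversion(al, "par01", "par02", c(10, 10))
  expect_equal(zero$alignment$residues, al$residues)

  first <- plant_conversion(al, "par01", "par02", c(10, 40))
  expect_error(plant_conversion(first$alignment, "par03", "par02", c(30, 60)),
               "overlapping")
  expect_error(plant_conversion(al, "par01", "par02", c(90, 150)),
               "outside")
})

test_that("selected-site positions split into regions that sum to the total", {
  domains <- tibble::tibble(gene_id = "g1", nbs_start = 100, nbs_end = 300,
                            length = 700)
  # 305 of 541 sites in the C-terminal region reproduces the 56.4% share
  sites <- tibble::tibble(
    gene_id = "g1",
    position = c(seq_len(100) - 1,                      # 100 N-terminal
                 100 + seq_len(136) - 1,                # 136 NBS
                 300 + seq_len(305) - 1)                # 305 C-terminal
  )
  summ <- site_region_summary(sites, domains)
  expect_equal(sum(summ$n_sites), 541L)
  expect_equal(summ$n_sites[summ$region == "C-terminal"], 305L)
  expect_equal(round(summ$pct[summ$region == "C-terminal"], 1), 56.4)

  all_nbs <- site_region_summary(
    tibble::tibble(gene_id = "g1", position = c(150, 200, 250)), domains)
  expect_equal(all_nbs$pct[all_nbs$region == "NBS"], 100)

  expect_error(site_region_summary(
    tibble::tibble(gene_id = "g1", position = 750), domains), "outside")
})
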