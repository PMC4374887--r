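test_that("planted motif consensi are found at their planted offsets", {
  lib <- default_motif_library()
  seq <- paste0(strrep("A", 30), "YDVFLSFRGEDTRDNFTSHLY", strrep("G", 40))
  hits <- scan_motifs(seq, lib)
  expect_equal(hits$motif, "TIR1")
  expect_equal(hits$start, 30L)
  expect_equal(hits$end, 51L)

  # random sequence without planted motifs yields nothing at the default
  # (stringent) thresholds
  expect_equal(nrow(scan_motifs(random_protein(400, seed = 5), lib)), 0L)
  expect_error(scan_motifs(""), "empty")
})

test_that("motif scan score equals the exhaustive all-offsets oracle", {
  lib <- default_motif_library()
  for (seed in 1:4) {
    set.seed(seed)
    k <- sample(nrow(lib), 1)
    # plant a concrete variant: bracket sets -> first member, wildcards -> A
    planted <- gsub("\\[([A-Z])[A-Z]*\\]", "\\1",
                    gsub("x", "A", lib$consensus[k]))
    seq <- paste0(random_protein(60, seed), planted, random_protein(60, seed + 100))
    hits <- scan_motifs(seq, lib[k, ])
    # independent oracle: score the PWM at every offset directly
    pwm <- nbskit:::consensus_pwm(lib$consensus[k])
    chars <- strsplit(seq, "")[[1]]
    oracle <- vapply(seq_len(nchar(seq) - nrow(pwm) + 1), function(i) {
      sum(vapply(seq_len(nrow(pwm)), function(j) {
        pwm[j, chars[i + j - 1]]
      }, 1))
    }, 1)
    expect_equal(max(hits$score), max(oracle))
    expect_equal(hits$start[which.max(hits$score)], which.max(oracle) - 1L)
  }
})

test_that("coiled-coil scoring flags ideal heptads but not helix breakers", {
  ideal <- score_coiled_coil(strrep("LEALEGK", 6))
  expect_gte(nrow(ideal$segments), 1L)
  expect_gt(max(ideal$probability), 0.9)

  polyp <- score_coiled_coil(strrep("P", 80))
  expect_lt(max(polyp$probability), 0.9)

  short <- score_coiled_coil("LEALEGK")  # below the smallest window
  expect_equal(nrow(short$segments), 0L)

  # locality: appending unrelated residues beyond one window leaves the
  # segment's probabilities unchanged
  base <- strrep("LEALEGK", 8)
  ext <- paste0(base, random_protein(60, seed = 9))
  p1 <- score_coiled_coil(base)$probability
  p2 <- score_coiled_coil(ext)$probability
  expect_equal(p1[1:20], p2[1:20])
})

test_that("coiled-coil window score equals direct propensity-table evaluation", {
  seq <- strrep("LEALEGK", 6)
  chars <- strsplit(seq, "")[[1]]
  tab <- cc_propensity_table()
  w <- 21
  # oracle: evaluate every window and frame directly from the shipped table
  best <- 0
  for (i in seq_len(nchar(seq) - w + 1)) {
    for (f in 0:6) {
      pos <- ((seq(i, i + w - 1) - 1 + f) %% 7) + 1
      gm <- exp(mean(log(tab[cbind(chars[i:(i + w - 1)], colnames(tab)[pos])])))
      g <- nbskit:::CC_GAUSS
      gcc <- exp(-0.5 * ((gm - g$cc_mean) / g$cc_sd)^2)
      gg <- exp(-0.5 * ((gm - g$g_mean) / g$g_sd)^2)
      best <- max(best, gcc / (gcc + g$g_weight * gg))
    }
  }
  got <- max(score_coiled_coil(seq, windows = 21)$probability)
  expect_equal(got, best, tolerance = 1e-12)
})

test_that("LRR detection counts planted repeat runs and matches brute force", {
  one <- detect_lrr(paste0(strrep("G", 10), "LAALNLSSLAALNLSS", strrep("G", 10)))
  expect_equal(nrow(one), 1L)

  unit <- "LAALNLSSLAALNLSS"
  three <- detect_lrr(paste0(strrep("G", 9), unit, strrep("D", 9), unit,
                             strrep("E", 9), unit, strrep("G", 9)))
  expect_equal(nrow(three), 3L)

  # boundaries equal an exhaustive window oracle
  set.seed(21)
  for (rep in 1:3) {
    seq <- paste0(random_protein(40, seed = rep), unit,
                  random_protein(30, seed = rep + 50))
    got <- detect_lrr(seq)
    chars <- strsplit(seq, "")[[1]]
    h <- chars %in% c("L", "I", "V", "F")
    covered <- logical(length(chars))
    for (i in seq_len(length(chars) - 7)) {
      if (h[i] && h[i + 3] && h[i + 5]) covered[i:(i + 7)] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    keep <- r$values & r$lengths >= 16
    expect_equal(got$start, (ends - r$lengths + 1)[keep] - 1L)
    expect_equal(got$end, ends[keep])
  }
})

test_that("architecture classification follows the domain-presence table", {
  lib <- default_motif_library()
  nbs_core <- paste0("GGVGKTT", strrep("A", 60), "KRFLLVLDDVW", strrep("D", 60),
                     "GSRIIITTRD", strrep("E", 60), "GLPLAL", strrep("G", 60),
                     "MHDV")
  cc <- strrep("LEALEGK", 6)
  tir <- paste0("YDVFLSFRGEDTRDNFTSHLY", "AIEASAISVIIFSEGYASSRWCLDELVKI")
  lrr <- strrep("LAALNLSS", 4)
  spacer <- strrep("G", 20)

  cases <- list(
    list(seq = paste0(cc, nbs_core, lrr), class = "CNL"),
    list(seq = paste0(tir, nbs_core, lrr), class = "TNL"),
    list(seq = paste0(spacer, nbs_core, lrr), class = "NL"),
    list(seq = paste0(cc, nbs_core, spacer), class = "CN"),
    list(seq = paste0(tir, nbs_core, spacer), class = "TN"),
    list(seq = paste0(spacer, nbs_core, spacer), class = "N"),
    # TIR takes precedence over CC when both N-terminal signals occur
    list(seq = paste0(tir, cc, nbs_core, lrr), class = "TNL")
  )
  for (cs in cases) {
    ann <- annotate_domains(cs$seq, lib)
    expect_equal(classify_architecture(ann), cs$class)
  }

  no_nbs <- annotate_domains(paste0(cc, spacer, lrr), lib)
  expect_error(classify_architecture(no_nbs), "no NBS span")
})

test_that("NBS QC filter applies length and motif rules monotonically", {
  make_ann <- function(span_len, motifs) {
    structure(list(protein_id = "p", nbs_span = c(0, span_len),
                   motif_hits = tibble::tibble(motif = motifs)),
              class = "domain_annotation")
  }
  expect_true(qc_nbs_domain(make_ann(250, c("P-loop", "MHDV"))))
  expect_false(qc_nbs_domain(make_ann(250, "P-loop")))
  expect_false(qc_nbs_domain(make_ann(150, c("P-loop", "MHDV"))))
  # monotone: adding a motif hit never flips pass -> fail
  expect_true(qc_nbs_domain(make_ann(250, c("P-loop", "MHDV", "GLPL"))))
})

test_that("class counts on a simulated genome equal the planted truth", {
  sim <- simulate_nbs(sim_config(seed = 42))
  pa <- dplyr::filter(sim$proteins, startsWith(id, "genomeA"))
  ann <- annotate_proteins(pa)
  truth <- dplyr::mutate(sim$truth$genes,
                         protein_id = paste0("genomeA|", gene_id))
  merged <- dplyr::left_join(ann, truth, by = "protein_id",
                             suffix = c("_called", "_true"))
  expect_equal(merged$class_called, merged$class_true)
  expect_true(all(ann$qc_pass))
  # every protein with an NBS span gets exactly one class; counts conserve
  expect_equal(sum(table(ann$class)), nrow(pa))
})
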