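#' Simulation configuration
#'
#' Bundles the knobs of the synthetic multi-genome NBS-family generator.
#' Defaults describe a desk-scale two-genome study in the
#' separation-of-scales regime: within-family branch lengths (0.002) far
#' below the clade-partition threshold (0.025), family and group stems far
#' above it, tandem arrays whose intra-cluster gaps (about 50 kb) sit well
#' inside the 200-kb cluster rule and inter-cluster gaps (at least 500 kb)
#' well outside it, and a noiseless deletion matrix for coverage calls.
#'
#' @param seed Mandatory integer seed; every downstream draw depends on it.
#' @param n_families Number of gene families (default 12).
#' @param family_size_range Inclusive range family sizes are drawn from.
#' @param n_orphans Long-branch singleton genes attached at the root.
#' @param class_probs Named probabilities over the six architecture classes
#'   used to assign one class per family; the default follows the observed
#'   class mixture in a citrus-like genome (CNL:TNL:NL roughly 117:82:68,
#'   the LRR-less remainder split evenly over CN/TN/N).
#' @param aa_subs_rate Per-site amino-acid substitution probability applied
#'   to spacer (non-domain) residues of each gene copy.
#' @param syn_subs_rate Per-codon synonymous substitution probability.
#' @param loss_rate Probability that a genome-B family member is lost
#'   (creates partially conserved clusters; default 0).
#' @param intra_gap,inter_gap Genomic gap between genes inside a cluster and
#'   between clusters, in bp.
#' @param tip_branch,family_stem,group_stem Branch lengths of the emitted
#'   tree: per-tip, per-family stem, per-group stem.
#' @param samples Coverage sample ids (default three pomelo, three mandarin).
#' @param parent_of Named vector sample -> parental taxon.
#' @param deletion_rate Per gene x sample probability of a planted deletion.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_families = 12L,
                       family_size_range = c(2L, 6L),
                       n_orphans = 2L,
                       class_probs = c(CNL = 117, TNL = 82, NL = 68,
                                       CN = 117, TN = 117, N = 117) / 618,
                       aa_subs_rate = 0.01,
                       syn_subs_rate = 0.01,
                       loss_rate = 0,
                       intra_gap = 50000,
                       inter_gap = 500000,
                       tip_branch = 0.002,
                       family_stem = 0.3,
                       group_stem = 1.5,
                       samples = c("pomelo1", "pomelo2", "pomelo3",
                                   "mandarin1", "mandarin2", "mandarin3"),
                       parent_of = NULL,
                       deletion_rate = 0.08) {
  if (missing(seed)) abort("sim_config requires a seed")
  if (any(c(aa_subs_rate, syn_subs_rate, loss_rate, deletion_rate) < 0)) {
    abort("rates must be >= 0")
  }
  if (is.null(parent_of)) {
    parent_of <- setNames(ifelse(grepl("^pomelo", samples), "pomelo", "mandarin"),
                          samples)
  }
  structure(list(seed = as.integer(seed), n_families = n_families,
                 family_size_range = family_size_range, n_orphans = n_orphans,
                 class_probs = class_probs / sum(class_probs),
                 aa_subs_rate = aa_subs_rate, syn_subs_rate = syn_subs_rate,
                 loss_rate = loss_rate, intra_gap = intra_gap,
                 inter_gap = inter_gap, tip_branch = tip_branch,
                 family_stem = family_stem, group_stem = group_stem,
                 samples = samples, parent_of = parent_of,
                 deletion_rate = deletion_rate),
            class = "sim_config")
}

# domain building blocks; these match the default motif library so the
# pipeline can re-detect what the generator plants
SIM_PARTS <- list(
  cc = strrep("LEALEGK", 6L),
  tir = paste0("YDVFLSFRGEDTRDNFTSHLY", "AIEASAISVIIFSEGYASSRWCLDELVKI",
               "GQIVIPVFYRVDPSDVRKQTG", "ENPEKVQKWRDALKEA"),
  lrr = strrep("LAALNLSS", 4L),
  nbs_motifs = c("GGVGKTT", "KRFLLVLDDVW", "GSRIIITTRD", "GLPLAL", "MHDV")
)

# residues used for random spacers; L/I/V/F excluded so spacers cannot form
# accidental LRR or coiled-coil signal
SPACER_AA <- c("A", "D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T", "W", "Y")

random_spacer <- function(n) paste(sample(SPACER_AA, n, replace = TRUE),
                                   collapse = "")

# ancestor protein for one family: N-terminal part by class, NBS core with
# planted motifs and >= 200 aa span, LRR tail when the class carries one.
# Returns the sequence plus a mask of mutable (spacer) positions.
sim_ancestor_protein <- function(class) {
  nter <- switch(substr(class, 1L, 1L),
                 "C" = SIM_PARTS$cc,
                 "T" = SIM_PARTS$tir,
                 random_spacer(30L))
  nter_fixed <- substr(class, 1L, 1L) %in% c("C", "T")
  core_parts <- list()
  core_mut <- list()
  motifs <- SIM_PARTS$nbs_motifs
  for (i in seq_along(motifs)) {
    core_parts[[length(core_parts) + 1L]] <- motifs[i]
    core_mut[[length(core_mut) + 1L]] <- rep(FALSE, nchar(motifs[i]))
    if (i < length(motifs)) {
      sp <- random_spacer(45L)
      core_parts[[length(core_parts) + 1L]] <- sp
      core_mut[[length(core_mut) + 1L]] <- rep(TRUE, nchar(sp))
    }
  }
  has_lrr <- endsWith(class, "L")
  cter <- if (has_lrr) SIM_PARTS$lrr else random_spacer(25L)
  seq <- paste0(nter, paste(unlist(core_parts), collapse = ""), cter)
  mutable <- c(rep(!nter_fixed, nchar(nter)), unlist(core_mut),
               rep(!has_lrr, nchar(cter)))
  list(seq = seq, mutable = mutable)
}

# codon table keyed by amino acid for deterministic back-translation
CODONS_BY_AA <- split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)

back_translate <- function(protein, codon_of = NULL) {
  aa <- strsplit(protein, "")[[1L]]
  codons <- map_chr(seq_along(aa), function(i) {
    if (!is.null(codon_of) && !is.na(codon_of[i]) &&
        GENETIC_CODE_TABLE[[codon_of[i]]] == aa[i]) {
      codon_of[i]
    } else {
      opts <- CODONS_BY_AA[[aa[i]]]
      opts[sample.int(length(opts), 1L)]
    }
  })
  codons
}

# single-base synonymous alternative codon, or the codon itself when none
# exists; restricting to one-base swaps keeps every synonymous event free of
# nonsynonymous pathway intermediates (relevant for serine's split codon box)
syn_swap <- function(codon) {
  opts <- setdiff(CODONS_BY_AA[[GENETIC_CODE_TABLE[[codon]]]], codon)
  ch <- strsplit(codon, "")[[1L]]
  opts <- opts[map_int(opts, function(o) {
    sum(strsplit(o, "")[[1L]] != ch)
  }) == 1L]
  if (!length(opts)) return(codon)
  opts[sample.int(length(opts), 1L)]
}

#' Simulate a multi-genome NBS gene family fixture with known truth
#'
#' Emits, per simulated genome, protein and CDS sequences, a gene
#' annotation with exon structure and tandem-cluster layout, a single
#' Newick gene tree whose subtrees are the planted families grouped into
#' three top-level groups, per-sample coverage intervals respecting a
#' planted deletion matrix, and truth tables for every pipeline stage.
#' Genome B is a speciation copy of genome A with optional member loss;
#' surviving members keep their genomic order, so planted clusters map to
#' conserved clusters and one whole-scaffold collinear block by
#' construction. Re-running with the same config reproduces the fixture
#' byte for byte.
#'
#' @param config A [sim_config()].
#' @return A `sim_result` list: `genomes` (named list of
#'   [genome_annotation()]), `proteins`, `cds` (sequence tibbles with
#'   genome-qualified ids), `tree` ([ape::phylo]), `coverage` (interval
#'   tibble for genome A, all samples), `truth` (list: `genes` — family,
#'   class, group, cluster and genome of every gene; `orthologs`;
#'   `deletions` — gene x sample logical matrix; `intron_truth`), and
#'   `config`.
#' @export
simulate_nbs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_fam <- config$n_families
  fam_sizes <- sample(seq(config$family_size_range[1L],
                          config$family_size_range[2L]), n_fam, replace = TRUE)
  classes <- sample(names(config$class_probs), n_fam, replace = TRUE,
                    prob = config$class_probs)
  # group by N-terminal type: TIR families in one group, the rest split
  # alternately into the two CC-flavoured groups
  group <- character(n_fam)
  group[startsWith(classes, "T")] <- "TIR"
  non_tir <- which(!startsWith(classes, "T"))
  group[non_tir] <- rep(c("CC1", "CC2"), length.out = length(non_tir))

  genes <- list()
  proteins <- list()
  cds <- list()
  for (f in seq_len(n_fam)) {
    anc <- sim_ancestor_protein(classes[f])
    anc_aa <- strsplit(anc$seq, "")[[1L]]
    anc_codons <- back_translate(anc$seq)
    for (m in seq_len(fam_sizes[f])) {
      gid <- sprintf("fam%02d_g%02d", f, m)
      aa <- anc_aa
      mut_pos <- which(anc$mutable & runif(length(aa)) < config$aa_subs_rate)
      for (p in mut_pos) aa[p] <- sample(setdiff(SPACER_AA, aa[p]), 1L)
      codons <- anc_codons
      changed <- which(aa != anc_aa)
      for (p in changed) {
        opts <- CODONS_BY_AA[[aa[p]]]
        codons[p] <- opts[sample.int(length(opts), 1L)]
      }
      syn_pos <- which(runif(length(codons)) < config$syn_subs_rate)
      for (p in syn_pos) codons[p] <- syn_swap(codons[p])
      proteins[[gid]] <- paste(aa, collapse = "")
      cds[[gid]] <- paste(codons, collapse = "")
      genes[[gid]] <- tibble(gene_id = gid, family = sprintf("fam%02d", f),
                             class = classes[f], group = group[f],
                             fam_index = m)
    }
  }
  for (o in seq_len(config$n_orphans)) {
    gid <- sprintf("orphan_g%02d", o)
    cls <- sample(names(config$class_probs), 1L, prob = config$class_probs)
    anc <- sim_ancestor_protein(cls)
    proteins[[gid]] <- anc$seq
    cds[[gid]] <- paste(back_translate(anc$seq), collapse = "")
    genes[[gid]] <- tibble(gene_id = gid, family = NA_character_, class = cls,
                           group = NA_character_, fam_index = 1L)
  }
  gene_truth <- bind_rows(genes)

  # --- genomic layout: one scaffold, each family a tandem array ---------
  n_exons_of <- c(CNL = 2L, TNL = 5L, NL = 2L, CN = 2L, TN = 5L, N = 1L)
  layout_genome <- function(genome_id, keep) {
    rows_g <- list()
    rows_e <- list()
    pos <- 10000
    prev_fam <- NULL
    ids <- gene_truth$gene_id[keep]
    for (gid in ids) {
      info <- gene_truth[gene_truth$gene_id == gid, ]
      fam <- if (is.na(info$family)) paste0("orphan_", gid) else info$family
      if (!is.null(prev_fam)) {
        pos <- pos + if (identical(fam, prev_fam)) config$intra_gap else config$inter_gap
      }
      prev_fam <- fam
      n_ex <- n_exons_of[[info$class]]
      cds_len <- nchar(cds[[gid]])
      exon_lens <- rep(cds_len %/% n_ex, n_ex)
      exon_lens[n_ex] <- exon_lens[n_ex] + cds_len %% n_ex
      start <- pos
      ex_start <- start
      for (e in seq_len(n_ex)) {
        rows_e[[length(rows_e) + 1L]] <- tibble(
          gene_id = paste0(genome_id, "|", gid),
          start = ex_start, end = ex_start + exon_lens[e]
        )
        ex_start <- ex_start + exon_lens[e] + if (e < n_ex) 2000 else 0
      }
      gene_end <- ex_start
      rows_g[[length(rows_g) + 1L]] <- tibble(
        gene_id = paste0(genome_id, "|", gid), scaffold = "scaf1",
        strand = "+"
      )
      pos <- gene_end
    }
    genome_annotation(bind_rows(rows_g), bind_rows(rows_e), genome_id)
  }

  keep_a <- rep(TRUE, nrow(gene_truth))
  keep_b <- runif(nrow(gene_truth)) >= config$loss_rate
  # never lose a whole family in B: keep at least one member
  for (f in unique(stats::na.omit(gene_truth$family))) {
    idx <- which(gene_truth$family %in% f)
    if (!any(keep_b[idx])) keep_b[idx[1L]] <- TRUE
  }
  ann_a <- layout_genome("genomeA", keep_a)
  ann_b <- layout_genome("genomeB", keep_b)

  seq_tbl <- function(genome_id, keep, pool, alphabet) {
    ids <- gene_truth$gene_id[keep]
    tibble(id = paste0(genome_id, "|", ids), alphabet = alphabet,
           residues = unname(unlist(pool[ids])))
  }
  prot_tbl <- bind_rows(seq_tbl("genomeA", keep_a, proteins, "protein"),
                        seq_tbl("genomeB", keep_b, proteins, "protein"))
  cds_tbl <- bind_rows(seq_tbl("genomeA", keep_a, cds, "dna"),
                       seq_tbl("genomeB", keep_b, cds, "dna"))

  orthologs <- tibble(
    gene_a = paste0("genomeA|", gene_truth$gene_id[keep_b]),
    gene_b = paste0("genomeB|", gene_truth$gene_id[keep_b])
  )

  # --- tree over genome-A genes: groups -> families -> tips --------------
  tipify <- function(gid) paste0("genomeA|", gid)
  fam_newick <- function(f) {
    members <- gene_truth$gene_id[gene_truth$family %in% f]
    paste0("(", paste0(tipify(members), ":", config$tip_branch,
                       collapse = ","), "):", config$family_stem)
  }
  group_newick <- function(g) {
    fams <- unique(gene_truth$family[gene_truth$group %in% g])
    inner <- if (length(fams) == 1L) {
      # avoid a unary node: splice the family under the group stem directly
      members <- gene_truth$gene_id[gene_truth$family %in% fams]
      paste0("(", paste0(tipify(members), ":", config$tip_branch,
                         collapse = ","), ")")
    } else {
      paste0("(", paste(map_chr(fams, fam_newick), collapse = ","), ")")
    }
    paste0(inner, ":", config$group_stem)
  }
  groups_present <- unique(stats::na.omit(gene_truth$group))
  parts <- map_chr(groups_present, group_newick)
  orphan_ids <- gene_truth$gene_id[is.na(gene_truth$family)]
  if (length(orphan_ids)) {
    parts <- c(parts, paste0(tipify(orphan_ids), ":", config$group_stem * 2))
  }
  tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))

  # --- planted deletions and coverage intervals on genome A --------------
  genes_a <- ann_a$genes
  del <- matrix(runif(nrow(genes_a) * length(config$samples)) <
                  config$deletion_rate,
                nrow = nrow(genes_a),
                dimnames = list(genes_a$gene_id, config$samples))
  cov_rows <- list()
  for (s in config$samples) {
    for (i in seq_len(nrow(genes_a))) {
      if (!del[i, s]) {
        cov_rows[[length(cov_rows) + 1L]] <- tibble(
          scaffold = genes_a$scaffold[i], start = genes_a$span_start[i],
          end = genes_a$span_end[i], sample_id = s
        )
      }
    }
  }
  coverage <- bind_rows(cov_rows)

  truth_genes <- gene_truth |>
    mutate(n_introns = unname(n_exons_of[.data$class]) - 1L)
  structure(list(
    genomes = list(genomeA = ann_a, genomeB = ann_b),
    proteins = prot_tbl, cds = cds_tbl, tree = tree, coverage = coverage,
    truth = list(genes = truth_genes, orthologs = orthologs, deletions = del),
    config = config
  ), class = "sim_result")
}

#' Write a simulated fixture to a directory
#'
#' Emits `<genome>_protein.fa`, `<genome>_cds.fa`, `<genome>.gff3`,
#' `tree.nwk`, `coverage_<sample>.bed` and truth TSVs under `dir`.
#'
#' @param sim A `sim_result` from [simulate_nbs()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(sim$genomes)) {
    write_fasta(filter(sim$proteins, startsWith(.data$id, paste0(g, "|"))),
                file.path(dir, paste0(g, "_protein.fa")))
    write_fasta(filter(sim$cds, startsWith(.data$id, paste0(g, "|"))),
                file.path(dir, paste0(g, "_cds.fa")))
    write_gff3(sim$genomes[[g]], file.path(dir, paste0(g, ".gff3")))
  }
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  for (s in unique(sim$coverage$sample_id)) {
    sub <- filter(sim$coverage, .data$sample_id == s)
    writeLines(paste(sub$scaffold, format(sub$start, scientific = FALSE,
                                          trim = TRUE),
                     format(sub$end, scientific = FALSE, trim = TRUE),
                     sep = "\t"),
               file.path(dir, paste0("coverage_", s, ".bed")))
  }
  write_tables(list(truth_genes = sim$truth$genes,
                    truth_orthologs = sim$truth$orthologs), dir)
  readr::write_tsv(as_tibble(sim$truth$deletions, rownames = "gene_id"),
                   file.path(dir, "truth_deletions.tsv"), progress = FALSE)
  invisible(dir)
}

#' Plant a gene-conversion tract into an alignment
#'
#' Copies the donor's residues over the acceptor's within `tract` (0-based
#' half-open alignment columns) and records the planted truth. Planting a
#' zero-length tract leaves the alignment unchanged. Overlapping planted
#' tracts on one acceptor are refused.
#'
#' @param alignment Sequence tibble (`id`, `residues`), equal row lengths.
#' @param donor,acceptor Sequence ids.
#' @param tract Numeric length-2: `c(start, end)`, 0-based half-open.
#' @return List with `alignment` (modified tibble carrying a
#'   `planted_tracts` attribute) and `truth` (one-row tibble).
#' @export
plant_conversion <- function(alignment, donor, acceptor, tract) {
  stopifnot(length(tract) == 2L)
  len <- nchar(alignment$residues[1L])
  if (tract[1L] < 0 || tract[2L] > len || tract[1L] > tract[2L]) {
    abort("tract outside alignment")
  }
  di <- match(donor, alignment$id)
  ai <- match(acceptor, alignment$id)
  if (is.na(di) || is.na(ai)) abort("donor or acceptor not in alignment")
  planted <- attr(alignment, "planted_tracts")
  if (!is.null(planted)) {
    same <- planted[planted$acceptor == acceptor, , drop = FALSE]
    if (nrow(same) && any(pmax(same$start, tract[1L]) <
                            pmin(same$end, tract[2L]))) {
      abort("overlapping planted tracts on one acceptor")
    }
  }
  truth <- tibble(donor = donor, acceptor = acceptor,
                  start = tract[1L], end = tract[2L])
  if (tract[2L] > tract[1L]) {
    donor_part <- substr(alignment$residues[di], tract[1L] + 1L, tract[2L])
    res <- alignment$residues[ai]
    alignment$residues[ai] <- paste0(
      substr(res, 1L, tract[1L]), donor_part,
      substr(res, tract[2L] + 1L, len)
    )
  }
  attr(alignment, "planted_tracts") <- bind_rows(planted, truth)
  list(alignment = alignment, truth = truth)
}

#' Simulate an alignment of diverged paralogs
#'
#' Independent per-site substitutions from a common random ancestor: each
#' tip mutates each site with probability `divergence / 2`, so expected
#' pairwise divergence is about `divergence`. Used to power-test the
#' gene-conversion scan.
#'
#' @param n_seqs Number of paralogs (>= 3 for [geneconv_scan()]).
#' @param n_sites Alignment length in nucleotides.
#' @param divergence Expected pairwise divergence (default 0.05).
#' @param seed Integer seed.
#' @return Sequence tibble (`id`, `alphabet`, `residues`).
#' @export
sim_paralog_alignment <- function(n_seqs, n_sites, divergence = 0.05, seed = 1L) {
  set.seed(seed)
  anc <- sample(BASES, n_sites, replace = TRUE)
  rows <- map(seq_len(n_seqs), function(i) {
    s <- anc
    mut <- which(runif(n_sites) < divergence / 2)
    for (p in mut) s[p] <- sample(setdiff(BASES, s[p]), 1L)
    tibble(id = sprintf("par%02d", i), alphabet = "dna",
           residues = paste(s, collapse = ""))
  })
  bind_rows(rows)
}

#' Simulate a synonymous-only CDS pair
#'
#' Starts from a random stop-free CDS and applies exactly `n_events`
#' synonymous codon swaps at distinct codons, so the pair differs only at
#' synonymous positions; dN is exactly 0 and the true synonymous divergence
#' is `n_events` substitutions over the sequence's synonymous sites.
#'
#' @param n_codons CDS length in codons.
#' @param n_events Number of synonymous substitutions to apply.
#' @param seed Integer seed.
#' @return List `a`, `b` (CDS strings) and `n_events` (events that actually
#'   changed a codon; codons with no synonymous alternative are skipped).
#' @export
sim_synonymous_pair <- function(n_codons, n_events, seed = 1L) {
  set.seed(seed)
  ok_codons <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  # restrict to codons with at least one synonymous alternative
  has_syn <- map_lgl(ok_codons, function(cd) {
    any(GENETIC_CODE_TABLE[setdiff(ok_codons, cd)] == GENETIC_CODE_TABLE[[cd]])
  })
  anc <- sample(ok_codons[has_syn], n_codons, replace = TRUE)
  target <- sample.int(n_codons, n_events)
  der <- anc
  applied <- 0L
  for (p in target) {
    swapped <- syn_swap(der[p])
    if (swapped != der[p]) {
      der[p] <- swapped
      applied <- applied + 1L
    }
  }
  list(a = paste(anc, collapse = ""), b = paste(der, collapse = ""),
       n_events = applied)
}
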