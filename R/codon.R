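#' Back-thread a protein alignment onto coding sequences
#'
#' Expands each aligned protein row to a codon alignment: every amino acid
#' becomes its source codon and every 1-residue gap a 3-nt gap, so the
#' translation of the output reproduces the protein alignment column for
#' column. Each CDS must translate to its (de-gapped) protein under the
#' standard code; a terminal stop codon on the CDS is tolerated.
#'
#' @param protein_alignment Sequence tibble (`id`, `residues`) of aligned
#'   proteins (gaps as `-`).
#' @param cds_records Sequence tibble of unaligned coding sequences with
#'   matching `id`s.
#' @return Sequence tibble of aligned CDS (`id`, `alphabet = "dna"`,
#'   `residues`), all rows the same length, a multiple of 3.
#' @export
backthread <- function(protein_alignment, cds_records) {
  out <- character(nrow(protein_alignment))
  for (i in seq_len(nrow(protein_alignment))) {
    id <- protein_alignment$id[i]
    j <- match(id, cds_records$id)
    if (is.na(j)) abort(paste0("no CDS for ", id))
    aa_aln <- toupper(protein_alignment$residues[i])
    cds <- toupper(cds_records$residues[j])
    aa <- gsub("-", "", aa_aln)
    tr <- translate_cds(cds)
    if (nchar(tr) != nchar(aa)) {
      abort(paste0("CDS/protein length mismatch for ", id, ": ",
                   nchar(tr), " aa translated vs ", nchar(aa), " aligned"))
    }
    tr_ch <- strsplit(tr, "")[[1L]]
    aa_ch <- strsplit(aa, "")[[1L]]
    mismatch <- which(tr_ch != aa_ch & tr_ch != "X" & aa_ch != "X")
    if (length(mismatch)) {
      abort(paste0("CDS does not translate to protein for ", id,
                   " at residue ", mismatch[1L]))
    }
    cod <- substring(cds, seq(1L, nchar(aa) * 3L, by = 3L),
                     seq(3L, nchar(aa) * 3L, by = 3L))
    aln_ch <- strsplit(aa_aln, "")[[1L]]
    expanded <- character(length(aln_ch))
    ci <- 0L
    for (p in seq_along(aln_ch)) {
      if (aln_ch[p] == "-") {
        expanded[p] <- "---"
      } else {
        ci <- ci + 1L
        expanded[p] <- cod[ci]
      }
    }
    out[i] <- paste(expanded, collapse = "")
  }
  tibble(id = protein_alignment$id, alphabet = "dna", residues = out)
}

#' Nei-Gojobori pairwise dN/dS
#'
#' The NG86 counting method with Jukes-Cantor correction. Synonymous site
#' counts per codon are the fractions of the three possible single-base
#' changes at each position that preserve the amino acid (changes creating a
#' stop count as nonsynonymous); expected sites are averaged over the two
#' sequences. Observed differences in multi-hit codons are averaged over all
#' equally weighted minimal substitution pathways, excluding pathways that
#' pass through a stop codon (unless every pathway does). Codon columns with
#' a gap or ambiguity in either sequence are excluded pairwise.
#'
#' @param codon_a,codon_b Aligned CDS strings of equal length (multiple of 3).
#' @return A `dnds_result` list: `n_codons`, `N_sites`, `S_sites`, `Nd`,
#'   `Sd`, `pN`, `pS`, `dN`, `dS`, `omega` (NA with `omega_undefined = TRUE`
#'   when dS = 0), `saturated` (TRUE when a JC correction is out of range).
#' @export
ng86_dnds <- function(codon_a, codon_b) {
  a <- toupper(if (is.data.frame(codon_a)) codon_a$residues[1] else codon_a)
  b <- toupper(if (is.data.frame(codon_b)) codon_b$residues[1] else codon_b)
  if (nchar(a) != nchar(b)) abort("aligned CDS must have equal length")
  if (nchar(a) %% 3L != 0L) abort("aligned CDS length must be a multiple of 3")
  n_cod <- nchar(a) %/% 3L
  starts <- seq(1L, nchar(a), by = 3L)
  cod_a <- substring(a, starts, starts + 2L)
  cod_b <- substring(b, starts, starts + 2L)
  usable <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b) &
    GENETIC_CODE_TABLE[cod_a] != "*" & GENETIC_CODE_TABLE[cod_b] != "*"
  cod_a <- cod_a[usable]
  cod_b <- cod_b[usable]
  if (!length(cod_a)) abort("no comparable codons after gap/ambiguity removal")

  S_sites <- (sum(map_dbl(cod_a, syn_sites)) + sum(map_dbl(cod_b, syn_sites))) / 2
  N_sites <- 3 * length(cod_a) - S_sites

  diffs <- map(seq_along(cod_a), ~ codon_path_diffs(cod_a[.x], cod_b[.x]))
  Sd <- sum(map_dbl(diffs, "syn"))
  Nd <- sum(map_dbl(diffs, "nonsyn"))

  pS <- if (S_sites > 0) Sd / S_sites else 0
  pN <- if (N_sites > 0) Nd / N_sites else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  saturated <- is.na(dS) || is.na(dN)
  omega_undefined <- saturated || isTRUE(dS == 0)
  omega <- if (!omega_undefined) dN / dS else NA_real_
  structure(list(n_codons = length(cod_a), N_sites = N_sites, S_sites = S_sites,
                 Nd = Nd, Sd = Sd, pN = pN, pS = pS, dN = dN, dS = dS,
                 omega = omega, omega_undefined = omega_undefined,
                 saturated = saturated),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat("<dnds_result> ", x$n_codons, " codons: dN = ", signif(x$dN, 4),
      ", dS = ", signif(x$dS, 4), ", omega = ",
      if (x$omega_undefined) "undefined" else signif(x$omega, 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy dnds_result
#' @export
tidy.dnds_result <- function(x, ...) {
  tibble(n_codons = x$n_codons, N_sites = x$N_sites, S_sites = x$S_sites,
         Nd = x$Nd, Sd = x$Sd, pN = x$pN, pS = x$pS, dN = x$dN, dS = x$dS,
         omega = x$omega, saturated = x$saturated)
}

BASES <- c("A", "C", "G", "T")

# fraction-weighted count of synonymous sites in one codon (NG86)
syn_sites <- function(codon) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  ch <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(BASES, ch[pos])) {
      mut <- ch
      mut[pos] <- nt
      mut_aa <- GENETIC_CODE_TABLE[[paste(mut, collapse = "")]]
      if (mut_aa == aa) s <- s + 1 / 3  # stop-codon changes count nonsynonymous
    }
  }
  s
}

# average synonymous/nonsynonymous differences over all minimal substitution
# pathways between two codons; pathways through stop codons dropped when any
# stop-free pathway exists
codon_path_diffs <- function(ca, cb) {
  ch_a <- strsplit(ca, "")[[1L]]
  ch_b <- strsplit(cb, "")[[1L]]
  pos <- which(ch_a != ch_b)
  k <- length(pos)
  if (k == 0L) return(list(syn = 0, nonsyn = 0))
  perms <- all_permutations(pos)
  path_counts <- list()
  for (p in seq_len(nrow(perms))) {
    cur <- ch_a
    s <- 0; ns <- 0; via_stop <- FALSE
    for (step in perms[p, ]) {
      nxt <- cur
      nxt[step] <- ch_b[step]
      aa1 <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]]
      aa2 <- GENETIC_CODE_TABLE[[paste(nxt, collapse = "")]]
      if (aa2 == "*") via_stop <- TRUE
      if (aa1 == aa2) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    path_counts[[p]] <- list(syn = s, nonsyn = ns, via_stop = via_stop)
  }
  ok <- !map_lgl(path_counts, "via_stop")
  if (!any(ok)) ok <- rep(TRUE, length(path_counts))
  kept <- path_counts[ok]
  list(syn = mean(map_dbl(kept, "syn")), nonsyn = mean(map_dbl(kept, "nonsyn")))
}

all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, nrow = 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}
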