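#' Annotate domains of one protein
#'
#' Runs the motif scan, coiled-coil scan and LRR scan, derives the NBS span
#' (first to last NBS-region motif hit) and the TIR/CC/LRR presence flags
#' used by [classify_architecture()].
#'
#' The TIR call requires hits to at least `tir_min_motifs` of the TIR1-4
#' motifs in the region preceding the NBS span (single-motif calls are
#' noisy). The CC call requires a coiled-coil segment starting before the
#' NBS span. The LRR call requires a repeat starting at or after the NBS
#' span end. External domain calls (e.g. from a profile-HMM run) can be
#' injected via `external_calls`, a tibble with columns `protein_id`,
#' `domain` (`TIR`, `CC`, `LRR`) that ORs into the scan-based flags.
#'
#' @param protein Amino-acid string or one-row sequence tibble with `id`.
#' @param lib Motif library (default [default_motif_library()]).
#' @param tir_min_motifs Minimum distinct TIR motifs for a TIR call.
#' @param cc_threshold Coiled-coil probability cutoff.
#' @param external_calls Optional imported domain-call tibble.
#' @param protein_id Id used when `protein` is a bare string.
#' @return A `domain_annotation` list: `protein_id`, `motif_hits`,
#'   `cc_segments`, `tir_present`, `cc_nterm`, `lrr_repeats`, `lrr_cterm`,
#'   `nbs_span` (length-2 numeric or `NULL`), `length`.
#' @export
annotate_domains <- function(protein, lib = default_motif_library(),
                             tir_min_motifs = 2L, cc_threshold = 0.9,
                             external_calls = NULL, protein_id = "protein") {
  if (is.data.frame(protein) && "id" %in% names(protein)) {
    protein_id <- protein$id[1L]
  }
  seq <- protein_string(protein)
  hits <- scan_motifs(seq, lib)
  cc <- score_coiled_coil(seq, threshold = cc_threshold)
  lrr <- detect_lrr(seq)

  nbs_hits <- filter(hits, .data$region == "NBS")
  nbs_span <- if (nrow(nbs_hits)) {
    c(min(nbs_hits$start), max(nbs_hits$end))
  } else {
    NULL
  }
  nter_end <- if (is.null(nbs_span)) nchar(seq) else nbs_span[1L]
  cter_start <- if (is.null(nbs_span)) 0 else nbs_span[2L]

  tir_names <- c("TIR1", "TIR2", "TIR3", "TIR4")
  tir_nter <- filter(hits, .data$motif %in% tir_names, .data$start < nter_end)
  tir_present <- length(unique(tir_nter$motif)) >= tir_min_motifs
  cc_nterm <- any(cc$segments$start < nter_end)
  lrr_cterm <- any(lrr$start >= cter_start)

  if (!is.null(external_calls)) {
    mine <- filter(external_calls, .data$protein_id == !!protein_id)
    tir_present <- tir_present || "TIR" %in% mine$domain
    cc_nterm <- cc_nterm || "CC" %in% mine$domain
    lrr_cterm <- lrr_cterm || "LRR" %in% mine$domain
  }

  structure(list(protein_id = protein_id, motif_hits = hits,
                 cc_segments = cc$segments, tir_present = tir_present,
                 cc_nterm = cc_nterm, lrr_repeats = lrr,
                 lrr_cterm = lrr_cterm, nbs_span = nbs_span,
                 length = nchar(seq)),
            class = "domain_annotation")
}

#' Classify a protein's domain architecture
#'
#' Maps domain presence to the six NBS-gene architecture classes: a TIR
#' domain gives the `T` prefix (taking precedence over CC when both are
#' present), otherwise an N-terminal coiled coil gives the `C` prefix; an
#' LRR region downstream of the NBS span appends the `L` suffix. The
#' resulting labels are CNL, TNL, NL, CN, TN and N.
#'
#' @param ann A `domain_annotation` from [annotate_domains()].
#' @return One of `"CNL"`, `"TNL"`, `"NL"`, `"CN"`, `"TN"`, `"N"`.
#' @export
classify_architecture <- function(ann) {
  stopifnot(inherits(ann, "domain_annotation"))
  if (is.null(ann$nbs_span)) {
    abort(paste0("protein ", ann$protein_id,
                 " has no NBS span; not an NBS gene"))
  }
  prefix <- if (ann$tir_present) "T" else if (ann$cc_nterm) "C" else ""
  suffix <- if (ann$lrr_cterm) "L" else ""
  paste0(prefix, "N", suffix)
}

#' QC filter on the NBS domain
#'
#' A protein passes when its NBS span is at least `min_len` residues long
#' and every motif in `require` was hit. This mirrors the usual inclusion
#' rule for NBS-domain phylogenies (both P-loop and MHDV present, span
#' longer than 200 aa).
#'
#' @param ann A `domain_annotation`.
#' @param min_len Minimum NBS span length in residues.
#' @param require Motif names that must all be present.
#' @return `TRUE`/`FALSE`.
#' @export
qc_nbs_domain <- function(ann, min_len = 200L, require = c("P-loop", "MHDV")) {
  stopifnot(inherits(ann, "domain_annotation"))
  if (is.null(ann$nbs_span)) return(FALSE)
  span_len <- ann$nbs_span[2L] - ann$nbs_span[1L]
  span_len >= min_len && all(require %in% ann$motif_hits$motif)
}

#' Annotate and classify a set of proteins
#'
#' Vectorized front end over [annotate_domains()], [classify_architecture()]
#' and [qc_nbs_domain()].
#'
#' @param proteins Sequence tibble from [read_fasta()].
#' @inheritParams annotate_domains
#' @inheritParams qc_nbs_domain
#' @return Tibble with one row per protein: `protein_id`, `class`,
#'   `tir_present`, `cc_nterm`, `lrr_cterm`, `nbs_start`, `nbs_end`,
#'   `qc_pass`, and an `annotation` list-column holding each
#'   `domain_annotation`. Proteins without an NBS span get class `NA`.
#' @export
annotate_proteins <- function(proteins, lib = default_motif_library(),
                              min_len = 200L, require = c("P-loop", "MHDV"),
                              external_calls = NULL) {
  rows <- map(seq_len(nrow(proteins)), function(i) {
    ann <- annotate_domains(proteins[i, ], lib = lib,
                            external_calls = external_calls)
    cls <- if (is.null(ann$nbs_span)) NA_character_ else classify_architecture(ann)
    tibble(protein_id = ann$protein_id, class = cls,
           tir_present = ann$tir_present, cc_nterm = ann$cc_nterm,
           lrr_cterm = ann$lrr_cterm,
           nbs_start = if (is.null(ann$nbs_span)) NA_real_ else ann$nbs_span[1L],
           nbs_end = if (is.null(ann$nbs_span)) NA_real_ else ann$nbs_span[2L],
           qc_pass = qc_nbs_domain(ann, min_len = min_len, require = require),
           annotation = list(ann))
  })
  bind_rows(rows)
}
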