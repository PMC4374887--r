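#' Read a FASTA file into a sequence tibble
#'
#' Wraps [Biostrings::readBStringSet()] and returns one row per record with
#' the record id preserved verbatim and residues upper-cased.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default), `"protein"` or `"dna"`. With `"auto"`
#'   the alphabet is inferred from residue composition: sequences made of
#'   ACGTN and gaps are called `dna`, anything else `protein`.
#' @return A tibble with columns `id`, `alphabet`, `residues`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "MAKT", ">g2", "MKLV"), tf)
#' read_fasta(tf)
read_fasta <- function(path, alphabet = c("auto", "protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no records in FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1L]))
  }
  res <- toupper(as.character(set))
  if (any(nchar(res) == 0L)) {
    abort(paste0("empty FASTA record: ", ids[nchar(res) == 0L][1L]))
  }
  alph <- if (alphabet == "auto") {
    ifelse(grepl("^[ACGTUN-]*$", res), "dna", "protein")
  } else {
    rep(alphabet, length(res))
  }
  tibble(id = ids, alphabet = alph, residues = unname(res))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` and `residues` (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds A DNA string whose length is a multiple of 3. A terminal stop
#'   codon is dropped; an internal stop translates to `*`.
#' @return The amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    abort(paste0("CDS length ", nchar(cds), " is not a multiple of 3"))
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
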