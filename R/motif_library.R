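#' Default NBS-gene motif library
#'
#' A library of conserved NBS-gene motifs used for domain delimitation and
#' QC. N-terminal entries are the TIR1-4 consensi plus the two CC1-type and
#' two CC2-type N-terminal motifs recovered from citrus NBS genes; the NBS
#' region carries the canonical plant P-loop, Kinase-2, RNBS-A/B/C/D, GLPL
#' and MHDV motifs. Consensi use `x` for "any residue" and `[..]` for a
#' residue set (e.g. `MHD[VL]`, matching the common MHDV/MHDL variants).
#'
#' Every motif is scored as a log-odds position weight matrix built from its
#' consensus (see [scan_motifs()]); `threshold` is the minimum score for a
#' hit, by default a fixed fraction of the motif's maximum attainable score
#' (0.9 for motifs shorter than 8 residues, 0.6 otherwise, so short anchors
#' like GLPL stay near-exact while long motifs tolerate divergence).
#'
#' @return A tibble with columns `name`, `region` (`N-terminal`, `NBS`,
#'   `C-terminal`), `consensus`, `threshold`.
#' @export
default_motif_library <- function() {
  defs <- tibble::tribble(
    ~name,       ~region,       ~consensus,
    "TIR1",      "N-terminal",  "YDVFLSFRGEDTRDNFTSHLY",
    "TIR2",      "N-terminal",  "AIEASAISVIIFSEGYASSRWCLDELVKI",
    "TIR3",      "N-terminal",  "GQIVIPVFYRVDPSDVRKQTG",
    "TIR4",      "N-terminal",  "ENPEKVQKWRDALKEA",
    "CC1-A",     "N-terminal",  "EEQQQMRRLNQVQGWLSRVEA",
    "CC1-B",     "N-terminal",  "GSQEIDKLCLGGYCSKNCKSSYKFGKKVA",
    "CC2-A",     "N-terminal",  "KKLTNMLEMIKAVLDDAEEKQ",
    "CC2-B",     "N-terminal",  "AVKLWLGKLKDAAYDVEDVLDEFQTEALR",
    "P-loop",    "NBS",         "GGxGKTT",
    "Kinase-2",  "NBS",         "KRFLLVLDDVW",
    "RNBS-A",    "NBS",         "FDLxAWVCVSQ",
    "RNBS-B",    "NBS",         "GSRIIITTRD",
    "RNBS-C",    "NBS",         "LSEDEAWELFxKxAF",
    "RNBS-D",    "NBS",         "CFLYCALFPED",
    "GLPL",      "NBS",         "GLPLAL",
    "MHDV",      "NBS",         "MHD[VL]"
  )
  defs$threshold <- map_dbl(defs$consensus, function(cns) {
    len <- length(parse_consensus(cns))
    frac <- if (len < 8) 0.9 else 0.6
    frac * max_motif_score(cns)
  })
  defs
}

#' Read / write a motif library as TSV
#'
#' The TSV carries columns `name`, `region`, `consensus`, `threshold`, so a
#' user-supplied library can replace [default_motif_library()] everywhere.
#'
#' @param path TSV path.
#' @return `read_motif_library()`: the library tibble.
#' @export
read_motif_library <- function(path) {
  lib <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("name", "region", "consensus", "threshold")
  miss <- setdiff(need, names(lib))
  if (length(miss)) abort(paste0("motif library missing column: ", miss[1L]))
  if (any(!is.finite(lib$threshold))) abort("motif threshold must be finite")
  lib
}

#' @rdname read_motif_library
#' @param lib Motif library tibble.
#' @export
write_motif_library <- function(lib, path) {
  readr::write_tsv(lib, path, progress = FALSE)
  invisible(path)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# consensus string -> list of allowed-residue sets, one per position
# ("x" -> empty set meaning wildcard)
parse_consensus <- function(consensus) {
  chars <- strsplit(consensus, "")[[1L]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, toupper(chars[j]))
        j <- j + 1L
      }
      if (j > length(chars)) abort(paste0("unclosed [ in consensus ", consensus))
      out[[length(out) + 1L]] <- set
      i <- j + 1L
    } else if (chars[i] %in% c("x", "X", ".")) {
      out[[length(out) + 1L]] <- character(0)
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- toupper(chars[i])
      i <- i + 1L
    }
  }
  out
}

# log-odds score matrix (positions x 26 letters) for a consensus;
# match probability 0.7 split over the allowed set, background 1/20
consensus_pwm <- function(consensus) {
  sets <- parse_consensus(consensus)
  bg <- 1 / 20
  m <- matrix(0, nrow = length(sets), ncol = 26,
              dimnames = list(NULL, LETTERS))
  for (p in seq_along(sets)) {
    set <- sets[[p]]
    if (length(set) == 0L) next  # wildcard scores 0 for everything
    match_s <- log2((0.7 / length(set)) / bg)
    mis_s <- log2((0.3 / (20 - length(set))) / bg)
    m[p, AA20] <- mis_s
    m[p, set] <- match_s
    m[p, setdiff(LETTERS, AA20)] <- 0  # X and other ambiguity codes neutral
  }
  m
}

# maximum attainable PWM score of a consensus
max_motif_score <- function(consensus) {
  m <- consensus_pwm(consensus)
  sum(apply(m, 1L, max))
}
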