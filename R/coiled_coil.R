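#' Coiled-coil propensity table
#'
#' Residue-by-heptad-position propensities used by [score_coiled_coil()].
#' Heptad positions are labelled a-g; a coiled coil buries hydrophobic
#' residues at a/d and exposes charged/polar residues at e/g. The table
#' encodes that preference: aliphatic residues (L/I/V/M) score high at a/d,
#' charged residues (E/K/Q/R) at e/g, helix breakers (G/P) are penalized at
#' core and interface positions. Values are relative propensities (1 =
#' indifferent).
#'
#' @return A 21 x 7 numeric matrix (rows: amino acids plus `X`, columns
#'   heptad positions `a`-`g`).
#' @export
cc_propensity_table <- function() {
  pos <- c("a", "b", "c", "d", "e", "f", "g")
  tab <- rbind(
    L = c(4.0, 0.7, 0.7, 4.0, 0.7, 0.7, 0.7),
    I = c(4.0, 0.7, 0.7, 4.0, 0.7, 0.7, 0.7),
    V = c(4.0, 0.7, 0.7, 4.0, 0.7, 0.7, 0.7),
    M = c(4.0, 0.7, 0.7, 4.0, 0.7, 0.7, 0.7),
    F = c(1.5, 0.5, 0.5, 1.5, 0.5, 0.5, 0.5),
    Y = c(1.5, 0.5, 0.5, 1.5, 0.5, 0.5, 0.5),
    W = c(0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4),
    A = c(1.8, 1.2, 1.2, 1.8, 1.2, 1.2, 1.2),
    E = c(0.4, 1.5, 1.5, 0.4, 2.5, 1.5, 2.5),
    K = c(0.4, 1.5, 1.5, 0.4, 2.5, 1.5, 2.5),
    Q = c(0.4, 1.5, 1.5, 0.4, 2.5, 1.5, 2.5),
    R = c(0.4, 1.5, 1.5, 0.4, 2.5, 1.5, 2.5),
    D = c(0.4, 1.2, 1.2, 0.4, 1.5, 1.2, 1.5),
    N = c(0.4, 1.2, 1.2, 0.4, 1.5, 1.2, 1.5),
    S = c(0.4, 1.2, 1.2, 0.4, 1.5, 1.2, 1.5),
    T = c(0.4, 1.2, 1.2, 0.4, 1.5, 1.2, 1.5),
    H = c(0.4, 1.2, 1.2, 0.4, 1.5, 1.2, 1.5),
    C = c(0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6),
    G = c(0.1, 1.0, 1.0, 0.1, 0.1, 1.0, 0.1),
    P = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    X = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0)
  )
  colnames(tab) <- pos
  tab
}

# two-Gaussian transform parameters: window geometric-mean propensity is
# compared against a coiled-coil population and a 30x-weighted globular
# population
CC_GAUSS <- list(cc_mean = 1.9, cc_sd = 0.35, g_mean = 0.95, g_sd = 0.25,
                 g_weight = 30)

#' Score coiled-coil propensity along a protein
#'
#' Sliding-window heptad scoring: for every window and each of the 7 heptad
#' register frames, the geometric mean of the per-residue, per-position
#' propensities ([cc_propensity_table()]) is transformed to a probability by
#' a two-Gaussian model (coiled-coil vs. 30x-weighted globular background).
#' Each residue receives the maximum probability over all windows and frames
#' covering it; maximal runs with probability >= `threshold` are reported as
#' segments.
#'
#' @param protein Amino-acid string or one-row sequence tibble.
#' @param windows Window lengths to scan (default 21 and 28 residues).
#' @param threshold Segment probability cutoff (default 0.9).
#' @return List with `probability` (numeric, one value per residue) and
#'   `segments` (tibble `start`, `end`, 0-based half-open, `max_prob`).
#'   Sequences shorter than the smallest window get all-zero probabilities
#'   and no segments.
#' @export
score_coiled_coil <- function(protein, windows = c(21L, 28L), threshold = 0.9) {
  seq <- protein_string(protein)
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  tab <- cc_propensity_table()
  chars[!chars %in% rownames(tab)] <- "X"
  logtab <- log(tab)
  prob <- numeric(n)
  for (w in windows) {
    if (n < w) next
    # cumulative log-propensity per frame for O(n) window sums
    for (f in 0:6) {
      pos_idx <- ((seq_len(n) - 1L + f) %% 7L) + 1L
      lp <- logtab[cbind(match(chars, rownames(tab)), pos_idx)]
      cs <- c(0, cumsum(lp))
      gm <- exp((cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w)
      p <- cc_two_gaussian(gm)
      # spread window probability to member residues, keep the max
      for (i in seq_along(p)) {
        span <- i:(i + w - 1L)
        prob[span] <- pmax(prob[span], p[i])
      }
    }
  }
  segments <- runs_at_least(prob >= threshold, 1L)
  seg_tbl <- tibble(start = segments$start - 1L, end = segments$end,
                    max_prob = map_dbl(seq_len(nrow(segments)), function(i) {
                      max(prob[segments$start[i]:segments$end[i]])
                    }))
  list(probability = prob, segments = seg_tbl)
}

cc_two_gaussian <- function(gm) {
  g <- CC_GAUSS
  gcc <- exp(-0.5 * ((gm - g$cc_mean) / g$cc_sd)^2)
  gg <- exp(-0.5 * ((gm - g$g_mean) / g$g_sd)^2)
  gcc / (gcc + g$g_weight * gg)
}

# maximal TRUE runs of length >= min_len; returns 1-based inclusive bounds
runs_at_least <- function(mask, min_len) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble(start = starts[keep], end = ends[keep])
}
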