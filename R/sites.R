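#' Assign selected sites to protein regions
#'
#' Positively-selected site positions (however obtained — e.g. from a codon
#' site-model run supplied as a TSV) are assigned to the N-terminal, NBS or
#' C-terminal region of their gene using the gene's NBS span, and counted
#' per region. Every site lands in exactly one region, so the counts sum to
#' the total.
#'
#' @param sites Tibble with columns `gene_id`, `position` (0-based residue
#'   index in the gene's protein).
#' @param domains Tibble with columns `gene_id`, `nbs_start`, `nbs_end`,
#'   `length` (protein length in residues).
#' @return Tibble with one row per region (`N-terminal`, `NBS`,
#'   `C-terminal`): `n_sites`, `pct` (share of all sites, in percent).
#' @export
site_region_summary <- function(sites, domains) {
  need <- setdiff(sites$gene_id, domains$gene_id)
  if (length(need)) abort(paste0("no domain boundaries for gene: ", need[1L]))
  merged <- left_join(sites, domains, by = "gene_id")
  bad <- merged$position < 0 | merged$position >= merged$length
  if (any(bad)) {
    abort(paste0("site position outside sequence for gene ",
                 merged$gene_id[bad][1L]))
  }
  merged <- merged |>
    mutate(region = dplyr::case_when(
      .data$position < .data$nbs_start ~ "N-terminal",
      .data$position < .data$nbs_end ~ "NBS",
      TRUE ~ "C-terminal"
    ))
  total <- nrow(merged)
  tibble(region = c("N-terminal", "NBS", "C-terminal")) |>
    left_join(count(merged, .data$region, name = "n_sites"), by = "region") |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           pct = 100 * .data$n_sites / total)
}
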