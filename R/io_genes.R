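#' Construct a genome annotation object
#'
#' The central gene-model container: a set of genes with exon structure on
#' named scaffolds. All coordinates are 0-based half-open; GFF3 input is
#' converted at the boundary by [read_gene_table()].
#'
#' @param genes Tibble with one row per gene: `gene_id`, `scaffold`, `strand`
#'   (`+`/`-`), and optionally `protein_id`, `cds_id`.
#' @param exons Tibble with one row per exon: `gene_id`, `start`, `end`
#'   (0-based half-open).
#' @param genome_id Genome label attached to every gene.
#' @param scaffold_lengths Named numeric vector of scaffold lengths in bp.
#'   If `NULL`, each scaffold length defaults to the largest exon end on it.
#' @return A `genome_annotation` object: a list with `genome_id`, `genes`
#'   (including derived `span_start`, `span_end`, `n_exons`, `n_introns`),
#'   `exons`, and `scaffold_lengths`.
#' @export
genome_annotation <- function(genes, exons, genome_id, scaffold_lengths = NULL) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  stopifnot(all(c("gene_id", "scaffold", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L]))
  }
  bad_strand <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(bad_strand)) abort(paste0("unknown strand: ", bad_strand[1L]))
  if (any(exons$start >= exons$end)) {
    i <- which(exons$start >= exons$end)[1L]
    abort(paste0("exon with start >= end for gene ", exons$gene_id[i]))
  }
  orphan <- setdiff(exons$gene_id, genes$gene_id)
  if (length(orphan)) abort(paste0("exon row for unknown gene: ", orphan[1L]))
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon)) abort(paste0("gene without exons: ", no_exon[1L]))

  exons <- arrange(exons, .data$gene_id, .data$start)
  ov <- exons |>
    group_by(.data$gene_id) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]))
  if (any(ov$bad)) {
    abort(paste0("overlapping exons in gene ", ov$gene_id[ov$bad][1L]))
  }
  span <- exons |>
    group_by(.data$gene_id) |>
    summarise(span_start = min(.data$start), span_end = max(.data$end),
              n_exons = n()) |>
    mutate(n_introns = .data$n_exons - 1L)
  genes <- left_join(genes, span, by = "gene_id")
  if (!"protein_id" %in% names(genes)) genes$protein_id <- genes$gene_id
  if (!"cds_id" %in% names(genes)) genes$cds_id <- genes$gene_id
  genes$genome_id <- genome_id

  if (is.null(scaffold_lengths)) {
    sl <- genes |>
      group_by(.data$scaffold) |>
      summarise(len = max(.data$span_end))
    scaffold_lengths <- setNames(sl$len, sl$scaffold)
  } else {
    missing_sc <- setdiff(genes$scaffold, names(scaffold_lengths))
    if (length(missing_sc)) {
      abort(paste0("scaffold missing from scaffold_lengths: ", missing_sc[1L]))
    }
    over <- genes$span_end > scaffold_lengths[genes$scaffold]
    if (any(over)) {
      abort(paste0("gene ", genes$gene_id[over][1L], " extends past scaffold end"))
    }
  }
  structure(list(genome_id = genome_id, genes = genes, exons = exons,
                 scaffold_lengths = scaffold_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, ": ", nrow(x$genes), " genes on ",
      length(x$scaffold_lengths), " scaffolds\n", sep = "")
  print(x$genes, n = 5)
  invisible(x)
}

#' Read gene models from GFF3 or a flat exon TSV
#'
#' GFF3 input may be two-level (`gene` rows with `exon` children) or
#' three-level (`gene` / `mRNA` / `exon`); coordinates are converted from
#' 1-based inclusive to the internal 0-based half-open convention. The TSV
#' dialect is one exon per row with columns `gene_id`, `scaffold`, `strand`,
#' `start`, `end` already 0-based half-open.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param genome_id Genome label; defaults to the file name without extension.
#' @param scaffold_lengths Optional named vector passed to [genome_annotation()].
#' @return A [genome_annotation()] object.
#' @export
read_gene_table <- function(path, dialect = c("gff3", "tsv"), genome_id = NULL,
                            scaffold_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("gene table not found: ", path))
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "scaffold", "strand", "start", "end")
    miss <- setdiff(need, names(tab))
    if (length(miss)) abort(paste0("gene TSV missing column: ", miss[1L]))
    genes <- distinct(tab, .data$gene_id, .data$scaffold, .data$strand)
    if (all(c("protein_id", "cds_id") %in% names(tab))) {
      genes <- distinct(tab, .data$gene_id, .data$scaffold, .data$strand,
                        .data$protein_id, .data$cds_id)
    }
    exons <- select(tab, "gene_id", "start", "end")
    return(genome_annotation(genes, exons, genome_id, scaffold_lengths))
  }

  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    abort(paste0("malformed GFF3 line ", lineno[nf != 9L][1L],
                 ": expected 9 tab-separated fields"))
  }
  m <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    found <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[found] <- sub(paste0("^(;)?", key, "="), "", sub("^;", "", hit))
    out
  }
  feat <- tibble(
    scaffold = m[, 1], type = m[, 3],
    start = as.numeric(m[, 4]) - 1, end = as.numeric(m[, 5]),
    strand = m[, 7],
    id = attr_get(m[, 9], "ID"), parent = attr_get(m[, 9], "Parent"),
    line = lineno
  )
  gene_rows <- filter(feat, .data$type == "gene")
  if (nrow(gene_rows) == 0L) abort(paste0("no gene features in ", path))
  bad <- setdiff(unique(gene_rows$strand), c("+", "-"))
  if (length(bad)) {
    abort(paste0("unknown strand '", bad[1L], "' at line ",
                 gene_rows$line[gene_rows$strand == bad[1L]][1L]))
  }
  # map mRNA id -> gene id so exons may point at either level
  mrna <- filter(feat, .data$type %in% c("mRNA", "transcript"))
  to_gene <- setNames(gene_rows$id, gene_rows$id)
  if (nrow(mrna)) to_gene <- c(to_gene, setNames(mrna$parent, mrna$id))
  exon_rows <- filter(feat, .data$type == "exon")
  if (nrow(exon_rows) == 0L) abort(paste0("no exon features in ", path))
  unknown <- !exon_rows$parent %in% names(to_gene)
  if (any(unknown)) {
    abort(paste0("exon with unknown Parent at line ", exon_rows$line[unknown][1L]))
  }
  exon_rows$gene_id <- unname(to_gene[exon_rows$parent])

  for (i in seq_len(nrow(exon_rows))) {
    g <- gene_rows[gene_rows$id == exon_rows$gene_id[i], ]
    if (exon_rows$start[i] < g$start || exon_rows$end[i] > g$end) {
      abort(paste0("exon outside gene span at line ", exon_rows$line[i]))
    }
  }
  genes <- tibble(gene_id = gene_rows$id, scaffold = gene_rows$scaffold,
                  strand = gene_rows$strand)
  exons <- select(exon_rows, "gene_id", "start", "end")
  genome_annotation(genes, exons, genome_id, scaffold_lengths)
}

#' Write a genome annotation to GFF3
#'
#' Inverse of [read_gene_table()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive GFF3 `gene` and `exon` rows.
#'
#' @param ann A [genome_annotation()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    writeLines(paste(g$scaffold, "nbskit", "gene", g$span_start + 1, g$span_end,
                     ".", g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(ex))) {
      writeLines(paste(g$scaffold, "nbskit", "exon", ex$start[j] + 1, ex$end[j],
                       ".", g$strand, ".",
                       paste0("ID=", g$gene_id, ".e", j, ";Parent=", g$gene_id),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
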