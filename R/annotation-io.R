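#' Read a gene-per-contig annotation table
#'
#' Reads a tab-delimited gene annotation table (one row per predicted gene,
#' annotated or not) and affiliates each gene with a taxon group through the
#' keyword lexicon. Rows with an empty lineage are unannotated genes; they
#' still count toward the contig's total gene number, which the classifier
#' needs for its annotation-density clause.
#'
#' Required columns: `contig_id`, `gene_id`, `lineage`, `bit_score`.
#' Optional: `gene_index` (order of the gene on its contig; derived from row
#' order within each contig when absent) and `e_value`.
#'
#' @param file Path to a TSV file, or a character vector of lines.
#' @param lexicon Keyword lexicon used to affiliate lineages; `NULL` skips
#'   affiliation (no `taxon_group` column is added).
#' @return A tibble of gene annotations with columns `contig_id`, `gene_id`,
#'   `gene_index`, `lineage`, `taxon_group`, `bit_score`, `e_value`.
#' @export
read_annotation_tsv <- function(file, lexicon = default_lexicon()) {
  tab <- readr::read_tsv(
    file,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("contig_id", "gene_id", "lineage", "bit_score")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("annotation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$lineage[is.na(tab$lineage)] <- ""
  bit <- suppressWarnings(as.numeric(tab$bit_score))
  blank_bit <- is.na(tab$bit_score) | !nzchar(trimws(tab$bit_score))
  bit[blank_bit] <- 0
  bad <- which(is.na(bit))
  if (length(bad) > 0) {
    stop("non-numeric bit_score at line ", bad[1] + 1L, ": '",
         tab$bit_score[bad[1]], "'", call. = FALSE)
  }
  tab$bit_score <- bit
  if ("e_value" %in% names(tab)) {
    tab$e_value <- suppressWarnings(as.numeric(tab$e_value))
  } else {
    tab$e_value <- NA_real_
  }
  if ("gene_index" %in% names(tab)) {
    tab$gene_index <- as.integer(tab$gene_index)
  } else {
    tab <- dplyr::mutate(
      dplyr::group_by(tab, .data$contig_id),
      gene_index = dplyr::row_number()
    )
    tab <- dplyr::ungroup(tab)
  }
  ann <- tibble::as_tibble(
    tab[c("contig_id", "gene_id", "gene_index", "lineage", "bit_score", "e_value")]
  )
  dup <- dplyr::filter(
    dplyr::add_count(ann, .data$contig_id, .data$gene_id), .data$n > 1
  )
  if (nrow(dup) > 0) {
    stop("duplicate gene_id within a contig: ",
         paste(unique(paste0(dup$contig_id, "/", dup$gene_id)), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(lexicon)) {
    ann$taxon_group <- affiliate(ann$lineage, lexicon)
    ann <- ann[c("contig_id", "gene_id", "gene_index", "lineage",
                 "taxon_group", "bit_score", "e_value")]
  }
  ann
}

#' Write a gene annotation table as TSV
#'
#' Inverse of [read_annotation_tsv()]; the `taxon_group` column (derived, not
#' primary data) is dropped so a round trip through disk re-derives it from
#' the lineage.
#'
#' @param annotations Gene annotation tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_annotation_tsv <- function(annotations, file) {
  keep <- intersect(
    c("contig_id", "gene_id", "gene_index", "lineage", "bit_score", "e_value"),
    names(annotations)
  )
  readr::write_tsv(annotations[keep], file, progress = FALSE)
  invisible(file)
}

#' Read BLAST tabular (outfmt 6) hits into a gene annotation table
#'
#' Alternate evidence path into the same data model as
#' [read_annotation_tsv()]: per-gene protein similarity hits in the standard
#' 12-column BLAST tabular format. For each query gene only the best hit is
#' retained (highest bit-score; ties broken by lowest e-value, then by file
#' order). Subject ids are mapped to lineage strings through `taxmap`;
#' subjects absent from the map yield `taxon_group = "unclassified"` with the
#' bit-score kept.
#'
#' Query ids are assumed to encode contig and gene as
#' `<contig_id><sep><gene_index>`, with the gene index as the final
#' `sep`-separated token (prodigal-style naming).
#'
#' @param file Path to a BLAST outfmt-6 file, or a character vector of lines.
#' @param taxmap Named character vector or two-column data frame
#'   (`subject_id`, `lineage`) mapping subject ids to lineage strings.
#' @param sep Separator between contig id and gene index in query ids.
#' @param lexicon Keyword lexicon for affiliation; `NULL` skips it.
#' @return A gene annotation tibble (see [read_annotation_tsv()]).
#' @export
read_blast_outfmt6 <- function(file, taxmap, sep = "_",
                               lexicon = default_lexicon()) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- if (length(file) == 1 && !grepl("\t", file)) {
    readLines(file, warn = FALSE)
  } else {
    file
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    empty <- tibble::tibble(
      contig_id = character(), gene_id = character(), gene_index = integer(),
      lineage = character(), bit_score = numeric(), e_value = numeric()
    )
    if (!is.null(lexicon)) empty$taxon_group <- character()
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield != 12L)
  if (length(bad) > 0) {
    stop("malformed BLAST tabular line ", bad[1], ": expected 12 columns, got ",
         nfield[bad[1]], call. = FALSE)
  }
  hits <- tibble::as_tibble(
    stats::setNames(as.data.frame(do.call(rbind, fields),
                                  stringsAsFactors = FALSE), cols)
  )
  hits$bitscore <- as.numeric(hits$bitscore)
  hits$evalue <- as.numeric(hits$evalue)
  hits$.ord <- seq_len(nrow(hits))

  best <- dplyr::arrange(hits, .data$qseqid, dplyr::desc(.data$bitscore),
                         .data$evalue, .data$.ord)
  best <- dplyr::distinct(best, .data$qseqid, .keep_all = TRUE)
  best <- dplyr::arrange(best, .data$.ord)

  if (is.data.frame(taxmap)) {
    taxmap <- stats::setNames(as.character(taxmap[[2]]), taxmap[[1]])
  }
  lineage <- unname(taxmap[best$sseqid])
  lineage[is.na(lineage)] <- ""

  idx_pat <- paste0(sep, "([0-9]+)$")
  gene_index <- suppressWarnings(
    as.integer(stringr::str_match(best$qseqid, idx_pat)[, 2])
  )
  contig_id <- stringr::str_remove(best$qseqid, idx_pat)
  contig_id[is.na(gene_index)] <- best$qseqid[is.na(gene_index)]

  ann <- tibble::tibble(
    contig_id = contig_id,
    gene_id = best$qseqid,
    gene_index = gene_index,
    lineage = lineage,
    bit_score = best$bitscore,
    e_value = best$evalue
  )
  ann <- dplyr::arrange(ann, .data$contig_id, .data$gene_index)
  if (!is.null(lexicon)) {
    ann$taxon_group <- affiliate(ann$lineage, lexicon)
    ann <- ann[c("contig_id", "gene_id", "gene_index", "lineage",
                 "taxon_group", "bit_score", "e_value")]
  }
  ann
}
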