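#' Read contig sequences from a FASTA file
#'
#' @param file Path to an (uncompressed or gzipped) nucleotide FASTA file.
#' @return A tibble with columns `contig_id` (first whitespace-delimited
#'   token of the header), `sequence` and `length` (bp).
#' @export
read_contig_fasta <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  ids <- sub("\\s.*$", "", names(seqs))
  tibble::tibble(
    contig_id = ids,
    sequence = unname(as.character(seqs)),
    length = Biostrings::width(seqs)
  )
}

#' Filter candidate contigs by length, gene content and archaeal evidence
#'
#' Order-preserving filter used at two stages of the screening workflow,
#' exposed as presets:
#'
#' * `"candidate"`: contigs strictly longer than 1,000 bp with at least 3
#'   ORFs, at least one of which affiliates with a reference archaeal virus
#'   (requires `n_orfs` and `has_archaeal_hit` columns).
#' * `"population"`: contigs strictly longer than 10,000 bp, the size floor
#'   for population-level dereplication and ecology.
#'
#' Explicit arguments override the preset.
#'
#' @param contigs Tibble of contig records; must contain `length`, plus
#'   `n_orfs` / `has_archaeal_hit` when those conditions are active.
#' @param preset `"candidate"`, `"population"`, or `"none"`.
#' @param min_length Strict lower bound on contig length (bp); `NULL`
#'   disables.
#' @param min_orfs Minimum ORF count (inclusive); `NULL` disables.
#' @param require_archaeal_hit Keep only contigs with `has_archaeal_hit`.
#' @return The filtered tibble, input order preserved.
#' @export
prefilter_contigs <- function(contigs,
                              preset = c("none", "candidate", "population"),
                              min_length = NULL, min_orfs = NULL,
                              require_archaeal_hit = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    candidate = list(min_length = 1000, min_orfs = 3, require_archaeal_hit = TRUE),
    population = list(min_length = 10000, min_orfs = NULL, require_archaeal_hit = FALSE),
    none = list(min_length = NULL, min_orfs = NULL, require_archaeal_hit = FALSE)
  )
  if (is.null(min_length)) min_length <- defaults$min_length
  if (is.null(min_orfs)) min_orfs <- defaults$min_orfs
  if (is.null(require_archaeal_hit)) {
    require_archaeal_hit <- defaults$require_archaeal_hit
  }
  if ((!is.null(min_length) && min_length < 0) ||
      (!is.null(min_orfs) && min_orfs < 0)) {
    stop("filter thresholds must be non-negative", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(contigs))
  if (!is.null(min_length)) {
    keep <- keep & contigs$length > min_length
  }
  if (!is.null(min_orfs)) {
    if (!"n_orfs" %in% names(contigs)) {
      stop("min_orfs filter needs an 'n_orfs' column", call. = FALSE)
    }
    keep <- keep & contigs$n_orfs >= min_orfs
  }
  if (isTRUE(require_archaeal_hit)) {
    if (!"has_archaeal_hit" %in% names(contigs)) {
      stop("archaeal-hit filter needs a 'has_archaeal_hit' column", call. = FALSE)
    }
    keep <- keep & contigs$has_archaeal_hit
  }
  contigs[keep, , drop = FALSE]
}

#' Pairwise average nucleotide identity between two contigs
#'
#' Computes ANI over the best local alignment of the two sequences
#' (Smith-Waterman, match +2 / mismatch -3 / gap open -5 / gap extend -2)
#' together with the fraction of the shorter sequence covered by the
#' alignment — the two quantities of the standard viral population
#' definition (>= 95% ANI across >= 80% of the shorter contig). `N` bases
#' never count as identities but aligned columns through them still count as
#' aligned.
#'
#' @param seq_a,seq_b Nucleotide sequences (character strings, A/C/G/T/N).
#' @return A one-row tibble: `ani` (percent identity over alignment columns,
#'   in \[0, 100\]) and `aligned_fraction_shorter` (aligned span on the
#'   shorter sequence / its length, in \[0, 1\]).
#' @export
#' @examples
#' contig_ani("ACGTACGTACGT", "ACGTACGTACGT")
contig_ani <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("cannot compute ANI on an empty sequence", call. = FALSE)
  }
  # canonical argument order makes the result exactly symmetric
  if (nchar(seq_a) > nchar(seq_b) ||
      (nchar(seq_a) == nchar(seq_b) && seq_a > seq_b)) {
    tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE
  )
  # N is ambiguous: neutral against everything rather than a mismatch
  mat["N", ] <- 0
  mat[, "N"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  columns <- length(p)
  idents <- sum(p == s & p %in% c("A", "C", "G", "T"))
  shorter_len <- nchar(seq_a)
  aligned_shorter <- sum(p != "-")
  tibble::tibble(
    ani = if (columns > 0) 100 * idents / columns else 0,
    aligned_fraction_shorter = aligned_shorter / shorter_len
  )
}

#' Greedy dereplication of contigs into viral populations
#'
#' Groups contigs into populations by the standard metric — >= `min_ani`
#' percent average nucleotide identity across >= `min_fraction` of the
#' shorter sequence — using greedy longest-first clustering: contigs are
#' sorted by length descending (ties broken by contig id), each contig joins
#' the first existing population whose *representative* it matches, and
#' otherwise founds a new population with itself as representative. The
#' representative is therefore always the longest member.
#'
#' @param contigs Tibble with `contig_id` and `sequence` columns (e.g. from
#'   [read_contig_fasta()]), typically pre-filtered with
#'   [prefilter_contigs()].
#' @param min_ani Minimum percent identity to join a population
#'   (default 95); boundary values merge.
#' @param min_fraction Minimum aligned fraction of the shorter sequence
#'   (default 0.8).
#' @return A tibble with one row per contig: `contig_id`, `length`,
#'   `population` (integer, in founding order), `representative_id`,
#'   `is_representative`, `ani_to_representative`,
#'   `aligned_fraction_shorter`. Populations partition the input.
#' @export
cluster_populations <- function(contigs, min_ani = 95, min_fraction = 0.8) {
  stopifnot(all(c("contig_id", "sequence") %in% names(contigs)))
  if (nrow(contigs) == 0) {
    return(tibble::tibble(
      contig_id = character(), length = integer(), population = integer(),
      representative_id = character(), is_representative = logical(),
      ani_to_representative = numeric(), aligned_fraction_shorter = numeric()
    ))
  }
  if (anyDuplicated(contigs$contig_id)) {
    stop("duplicate contig_id in input", call. = FALSE)
  }
  contigs <- dplyr::mutate(contigs, length = nchar(.data$sequence))
  ord <- order(-contigs$length, contigs$contig_id)
  contigs <- contigs[ord, ]

  pop <- integer(nrow(contigs))
  rep_idx <- integer(0)              # indices (into sorted contigs) of representatives
  ani_v <- numeric(nrow(contigs))
  frac_v <- numeric(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    assigned <- FALSE
    for (k in seq_along(rep_idx)) {
      res <- contig_ani(contigs$sequence[i], contigs$sequence[rep_idx[k]])
      if (res$ani >= min_ani && res$aligned_fraction_shorter >= min_fraction) {
        pop[i] <- k
        ani_v[i] <- res$ani
        frac_v[i] <- res$aligned_fraction_shorter
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      pop[i] <- length(rep_idx)
      ani_v[i] <- 100
      frac_v[i] <- 1
    }
  }
  tibble::tibble(
    contig_id = contigs$contig_id,
    length = contigs$length,
    population = pop,
    representative_id = contigs$contig_id[rep_idx[pop]],
    is_representative = seq_len(nrow(contigs)) %in% rep_idx,
    ani_to_representative = ani_v,
    aligned_fraction_shorter = frac_v
  )
}

#' Summarize populations from a clustering
#'
#' @param clusters Output of [cluster_populations()].
#' @return One row per population: `population`, `representative_id`,
#'   `n_members`, `member_ids` (comma-separated), `representative_length`.
#' @export
population_summary <- function(clusters) {
  dplyr::summarise(
    dplyr::group_by(clusters, .data$population, .data$representative_id),
    n_members = dplyr::n(),
    member_ids = paste(.data$contig_id, collapse = ","),
    representative_length = max(.data$length),
    .groups = "drop"
  )
}
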