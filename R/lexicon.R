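#' Taxon groups recognized by the classifier
#'
#' Coarse host-taxonomy classes for the best reference hit of a predicted
#' gene: archaeal virus, eukaryotic virus, phage (bacterial virus), cellular
#' organism, or unclassified (no hit / no keyword match). The order returned
#' here (minus `"unclassified"`) is the default lexicon matching priority:
#' specific archaeal-virus tokens are tried before the generic
#' `"virus"`/`"phage"` tokens so that, e.g., `"Halovirus"` is affiliated with
#' archaeal viruses rather than phage.
#'
#' @return Character vector of the five group names.
#' @export
taxon_groups <- function() {
  c("archaeal_virus", "eukaryotic_virus", "phage", "cellular", "unclassified")
}

#' Default keyword lexicon for taxonomic affiliation
#'
#' A starter lexicon mapping case-insensitive substrings of a gene's best-hit
#' lineage/organism string to a taxon group. Archaeal-virus keywords cover
#' the classical virus families of Archaea (fuselloviruses, rudiviruses,
#' lipothrixviruses, haloviruses, ...) and the host genera under which many
#' archaeal virus isolates are deposited. Groups are evaluated in priority
#' order `archaeal_virus`, `eukaryotic_virus`, `phage`, `cellular`; the first
#' group with any matching keyword wins, so specific tokens shadow the
#' generic `"virus"` and `"phage"` tokens of the phage group.
#'
#' Keyword searching on organism names is inherently approximate: a
#' best-practice analysis tailors the lexicon to its reference database
#' (see [read_lexicon()]).
#'
#' @return A tibble with columns `taxon_group` and `keyword`, ordered by
#'   matching priority.
#' @seealso [affiliate()], [read_lexicon()]
#' @export
#' @examples
#' affiliate("Sulfolobus spindle-shaped virus 1", default_lexicon())
default_lexicon <- function() {
  groups <- list(
    archaeal_virus = c(
      "spindle-shaped virus", "fusellovirus", "rudivirus", "lipothrixvirus",
      "bicaudavirus", "ampullavirus", "globulovirus", "salterprovirus",
      "turreted icosahedral virus", "pleolipovirus", "halovirus",
      "Sulfolobus", "Acidianus", "Aeropyrum", "Pyrococcus", "Thermoproteus",
      "Pyrobaculum", "Methanobacterium phage", "Methanothermobacter",
      "Methanococcus voltae", "Haloarcula", "Halorubrum", "Haloferax",
      "Halogeometricum", "Natrialba", "His1 virus", "His2 virus",
      "psiM2", "BJ1 virus"
    ),
    eukaryotic_virus = c(
      "mimivirus", "herpesvirus", "phycodnavirus", "Chlorella virus",
      "Ostreococcus virus", "Emiliania huxleyi virus", "Micromonas virus",
      "baculovirus", "poxvirus", "iridovirus", "adenovirus",
      "influenza", "coccolithovirus"
    ),
    phage = c(
      "phage", "Myoviridae", "Siphoviridae", "Podoviridae",
      "prophage", "virus"
    ),
    cellular = c(
      "bacterium", "bacteria", "archaeon", "archaea", "eukaryota",
      "Candidatus", "uncultured organism"
    )
  )
  tibble::tibble(
    taxon_group = rep(names(groups), lengths(groups)),
    keyword = unlist(groups, use.names = FALSE)
  )
}

validate_lexicon <- function(lexicon) {
  if (!is.data.frame(lexicon) ||
      !all(c("taxon_group", "keyword") %in% names(lexicon))) {
    stop("lexicon must be a data frame with columns 'taxon_group' and 'keyword'",
         call. = FALSE)
  }
  bad <- setdiff(unique(lexicon$taxon_group), setdiff(taxon_groups(), "unclassified"))
  if (length(bad) > 0) {
    stop("unknown taxon group(s) in lexicon: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(lexicon$keyword) | !nzchar(lexicon$keyword))) {
    stop("lexicon keywords must be non-empty", call. = FALSE)
  }
  invisible(lexicon)
}

#' Affiliate lineage strings with taxon groups by keyword search
#'
#' Scans each lineage (free-text taxonomy or organism name of a gene's best
#' reference hit) for the lexicon's keywords as case-insensitive substrings.
#' Groups are tried in the order they first appear in the lexicon; the first
#' group with any matching keyword wins. Keyword order *within* a group is
#' irrelevant. Empty, `NA`, or unmatched lineages map to `"unclassified"`.
#'
#' @param lineage Character vector of lineage/organism strings.
#' @param lexicon Keyword lexicon, as from [default_lexicon()] or
#'   [read_lexicon()].
#' @return Character vector of taxon groups, same length as `lineage`.
#' @export
#' @examples
#' affiliate(c("Prochlorococcus phage P-SSM2", ""), default_lexicon())
affiliate <- function(lineage, lexicon = default_lexicon()) {
  validate_lexicon(lexicon)
  out <- rep("unclassified", length(lineage))
  pending <- !is.na(lineage) & nzchar(lineage)
  for (grp in unique(lexicon$taxon_group)) {
    if (!any(pending)) break
    kws <- lexicon$keyword[lexicon$taxon_group == grp]
    hit <- rep(FALSE, sum(pending))
    sub <- lineage[pending]
    for (kw in kws) {
      hit <- hit | stringr::str_detect(
        sub, stringr::fixed(kw, ignore_case = TRUE)
      )
    }
    idx <- which(pending)[hit]
    out[idx] <- grp
    pending[idx] <- FALSE
  }
  out
}

#' Read a keyword lexicon from a plain-text file
#'
#' One keyword per line in the form `group: keyword`. Group priority is the
#' order in which groups first appear in the file. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param file Path to the lexicon file.
#' @return A lexicon tibble (columns `taxon_group`, `keyword`).
#' @export
read_lexicon <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regexpr(":", lines, fixed = TRUE)
  if (any(m < 0)) {
    stop("lexicon lines must have the form 'group: keyword'; offending line: ",
         lines[which(m < 0)[1]], call. = FALSE)
  }
  lex <- tibble::tibble(
    taxon_group = trimws(substr(lines, 1, m - 1)),
    keyword = trimws(substr(lines, m + 1, nchar(lines)))
  )
  validate_lexicon(lex)
  lex
}

#' Write a keyword lexicon to a plain-text file
#'
#' @param lexicon Lexicon tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_lexicon <- function(lexicon, file) {
  validate_lexicon(lexicon)
  writeLines(paste0(lexicon$taxon_group, ": ", lexicon$keyword), file)
  invisible(file)
}
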