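#' Classification thresholds
#'
#' Tunable thresholds of the majority-rules category classifier. Defaults
#' follow the published decision rules: a contig is archaeal-virus-like when
#' more than two thirds of its (non-eukaryotic) annotated genes affiliate
#' with reference archaeal viruses and at least one such annotation has
#' bit-score above 75; the printed "66.6%" and "33.3%" bounds are treated as
#' the exact rationals 2/3 and 1/3.
#'
#' @param majority_fraction Archaeal-virus gene fraction that must be
#'   *strictly* exceeded for categories 1 and 2 (default `2/3`).
#' @param minor_fraction Lower (inclusive) fraction bound of category 3
#'   (default `1/3`); the upper bound is `majority_fraction`, inclusive.
#' @param min_bit Bit-score floor: at least one archaeal-virus annotation
#'   must score strictly above this (default 75).
#' @param min_annotations_main Minimum number of annotated genes for the
#'   main category rules (default 3).
#' @param few_annotation_clause_max Maximum number of annotated genes for
#'   the category-1 few-annotation clause (default 2): contigs with 1-2
#'   annotations, all archaeal virus, are category 1.
#' @param require_min_bit_in_clause Should the few-annotation clause also
#'   enforce `min_bit`? Default `TRUE` (conservative).
#' @param count_cellular Should cellular-affiliated genes enter the
#'   denominator of the archaeal-virus fraction? Default `TRUE`. Eukaryotic
#'   virus hits never do.
#' @return A list of class `"category_thresholds"`.
#' @export
category_thresholds <- function(majority_fraction = 2 / 3,
                                minor_fraction = 1 / 3,
                                min_bit = 75,
                                min_annotations_main = 3L,
                                few_annotation_clause_max = 2L,
                                require_min_bit_in_clause = TRUE,
                                count_cellular = TRUE) {
  stopifnot(
    is.numeric(majority_fraction), is.numeric(minor_fraction),
    is.numeric(min_bit), min_bit > 0
  )
  if (!(minor_fraction > 0 && minor_fraction <= majority_fraction &&
        majority_fraction < 1)) {
    stop("need 0 < minor_fraction <= majority_fraction < 1", call. = FALSE)
  }
  structure(
    list(
      majority_fraction = majority_fraction,
      minor_fraction = minor_fraction,
      min_bit = min_bit,
      min_annotations_main = as.integer(min_annotations_main),
      few_annotation_clause_max = as.integer(few_annotation_clause_max),
      require_min_bit_in_clause = isTRUE(require_min_bit_in_clause),
      count_cellular = isTRUE(count_cellular)
    ),
    class = "category_thresholds"
  )
}

#' @export
print.category_thresholds <- function(x, ...) {
  cat("Category thresholds:\n")
  cat(sprintf("  archaeal fraction > %.4f (cat 1/2), in [%.4f, %.4f] (cat 3)\n",
              x$majority_fraction, x$minor_fraction, x$majority_fraction))
  cat(sprintf("  bit-score floor  > %g\n", x$min_bit))
  cat(sprintf("  main rules need >= %d annotations; clause covers 1-%d (min_bit %s)\n",
              x$min_annotations_main, x$few_annotation_clause_max,
              if (x$require_min_bit_in_clause) "enforced" else "waived"))
  cat(sprintf("  cellular genes in fraction denominator: %s\n",
              x$count_cellular))
  invisible(x)
}

#' Per-contig annotation profiles
#'
#' Collapses gene-level annotations into one row per contig: total and
#' annotated gene counts, counts and maximum bit-scores per taxon group, and
#' the archaeal-virus fraction of annotated genes. Eukaryotic-virus hits are
#' counted but excluded from both numerator and denominator of the fraction;
#' cellular hits enter the denominator when `count_cellular` (they can never
#' enter the numerator). A contig with an empty denominator has `NA`
#' fraction.
#'
#' @param annotations Gene annotation tibble with at least `contig_id`,
#'   `taxon_group` and `bit_score` (see [read_annotation_tsv()]).
#' @param n_genes_total Optional tibble (`contig_id`, `n_genes_total`)
#'   giving the total gene count per contig, for tables that only list
#'   annotated genes (e.g. BLAST hits). By default every row — including
#'   unannotated, empty-lineage rows — counts as one gene.
#' @param count_cellular See [category_thresholds()].
#' @return A tibble with one row per contig: `contig_id`, `n_genes_total`,
#'   `n_annotated`, `n_archaeal`, `n_phage`, `n_eukaryotic`, `n_cellular`,
#'   `arch_fraction`, and `max_bit_*` per group (`NA` when the group is
#'   absent).
#' @export
profile_contigs <- function(annotations, n_genes_total = NULL,
                            count_cellular = TRUE) {
  stopifnot(all(c("contig_id", "taxon_group", "bit_score") %in%
                  names(annotations)))
  max_or_na <- function(x) if (length(x) == 0) NA_real_ else max(x)
  grp_n <- function(g, grp) sum(g == grp)
  grp_max <- function(g, b, grp) max_or_na(b[g == grp])

  prof <- dplyr::summarise(
    dplyr::group_by(annotations, .data$contig_id),
    n_genes_total = dplyr::n(),
    n_annotated = sum(.data$taxon_group != "unclassified"),
    n_archaeal = grp_n(.data$taxon_group, "archaeal_virus"),
    n_phage = grp_n(.data$taxon_group, "phage"),
    n_eukaryotic = grp_n(.data$taxon_group, "eukaryotic_virus"),
    n_cellular = grp_n(.data$taxon_group, "cellular"),
    max_bit_archaeal = grp_max(.data$taxon_group, .data$bit_score, "archaeal_virus"),
    max_bit_phage = grp_max(.data$taxon_group, .data$bit_score, "phage"),
    max_bit_eukaryotic = grp_max(.data$taxon_group, .data$bit_score, "eukaryotic_virus"),
    max_bit_cellular = grp_max(.data$taxon_group, .data$bit_score, "cellular"),
    .groups = "drop"
  )
  if (!is.null(n_genes_total)) {
    stopifnot(all(c("contig_id", "n_genes_total") %in% names(n_genes_total)))
    prof$n_genes_total <- NULL
    prof <- dplyr::left_join(prof, n_genes_total[c("contig_id", "n_genes_total")],
                             by = "contig_id")
    if (any(is.na(prof$n_genes_total))) {
      stop("n_genes_total missing for contig(s): ",
           paste(utils::head(prof$contig_id[is.na(prof$n_genes_total)], 5),
                 collapse = ", "), call. = FALSE)
    }
    if (any(prof$n_genes_total < prof$n_annotated)) {
      stop("n_genes_total smaller than annotated gene count", call. = FALSE)
    }
  }
  denom <- prof$n_archaeal + prof$n_phage +
    if (count_cellular) prof$n_cellular else 0L
  prof$arch_fraction <- ifelse(denom > 0, prof$n_archaeal / denom, NA_real_)
  dplyr::relocate(prof, "arch_fraction", .after = "n_cellular")
}

#' Assign consensus categories to contig profiles
#'
#' Applies the three archaeal-virus category rules to per-contig profiles,
#' in precedence order 1, 2, 3:
#'
#' * **Category 1 (main):** at least `min_annotations_main` annotated genes,
#'   archaeal fraction strictly above `majority_fraction`, best archaeal
#'   bit-score strictly above `min_bit` and strictly above the best phage
#'   bit-score.
#' * **Category 1 (few-annotation clause):** 1 to
#'   `few_annotation_clause_max` annotated genes, *all* of them archaeal
#'   virus (bit floor enforced when `require_min_bit_in_clause`).
#' * **Category 2:** as category 1 (main) but the best phage bit-score
#'   equals or exceeds the best archaeal one.
#' * **Category 3:** fraction between `minor_fraction` and
#'   `majority_fraction` (both inclusive), bit floor passed, best archaeal
#'   bit strictly above best phage bit.
#'
#' Contigs matching no rule are `"none"`.
#'
#' @param profiles Output of [profile_contigs()].
#' @param thresholds A [category_thresholds()] object.
#' @return A tibble `contig_id`, `category` (factor `1`,`2`,`3`,`none`),
#'   `rule_trace` (semicolon-separated condition outcomes for the assigned
#'   rule, or for the furthest rule attempted).
#' @export
assign_categories <- function(profiles, thresholds = category_thresholds()) {
  t <- thresholds
  stopifnot(inherits(t, "category_thresholds"))
  denom <- profiles$n_archaeal + profiles$n_phage +
    if (t$count_cellular) profiles$n_cellular else 0L
  frac <- ifelse(denom > 0, profiles$n_archaeal / denom, NA_real_)
  bit_a <- ifelse(is.na(profiles$max_bit_archaeal), -Inf, profiles$max_bit_archaeal)
  bit_p <- ifelse(is.na(profiles$max_bit_phage), -Inf, profiles$max_bit_phage)
  n_ann <- profiles$n_annotated

  has_majority <- !is.na(frac) & frac > t$majority_fraction
  in_minor_band <- !is.na(frac) & frac >= t$minor_fraction &
    frac <= t$majority_fraction
  bit_floor <- bit_a > t$min_bit
  arch_beats_phage <- bit_a > bit_p
  enough <- n_ann >= t$min_annotations_main
  all_arch <- n_ann >= 1L & n_ann <= t$few_annotation_clause_max &
    profiles$n_archaeal == n_ann
  clause <- all_arch & (!t$require_min_bit_in_clause | bit_floor)

  cat1 <- (enough & has_majority & bit_floor & arch_beats_phage) | clause
  cat2 <- enough & has_majority & bit_floor & bit_p >= bit_a
  cat3 <- enough & in_minor_band & bit_floor & arch_beats_phage
  category <- dplyr::case_when(cat1 ~ "1", cat2 ~ "2", cat3 ~ "3",
                               .default = "none")

  fmt <- function(x) ifelse(x, "pass", "fail")
  rule_trace <- paste0(
    "n_annotated>=", t$min_annotations_main, ":", fmt(enough),
    ";fraction>", signif(t$majority_fraction, 4), ":", fmt(has_majority),
    ";fraction_in_band:", fmt(in_minor_band),
    ";max_bit_arch>", t$min_bit, ":", fmt(bit_floor),
    ";arch_bit>phage_bit:", fmt(arch_beats_phage),
    ";few_annotation_clause:", fmt(clause)
  )
  tibble::tibble(
    contig_id = profiles$contig_id,
    category = factor(category, levels = c("1", "2", "3", "none")),
    rule_trace = rule_trace
  )
}

#' Classify contigs from gene annotations
#'
#' End-to-end consensus classification: affiliates gene lineages with taxon
#' groups through the keyword lexicon, builds per-contig profiles, and
#' assigns each contig a category (1, 2, 3) or rejects it. Returns a fitted
#' classification object with [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @param annotations Gene annotation tibble (from [read_annotation_tsv()],
#'   [read_blast_outfmt6()] or [simulate_benchmark()]). When a `lineage`
#'   column is present and `lexicon` is non-`NULL`, taxon groups are
#'   (re-)derived from the lineages; otherwise an existing `taxon_group`
#'   column is used as-is.
#' @param lexicon Keyword lexicon; see [default_lexicon()].
#' @param thresholds A [category_thresholds()] object.
#' @inheritParams profile_contigs
#' @return An object of class `"contig_classification"` with elements
#'   `assignments` (tibble: contig_id, category, profile columns,
#'   rule_trace), `profiles`, and `thresholds`.
#' @export
#' @examples
#' sim <- simulate_benchmark(benchmark_config(n_archaeal = 5, n_phage = 20,
#'                                            seed = 42))
#' cl <- classify_contigs(sim$annotations)
#' glance(cl)
classify_contigs <- function(annotations, lexicon = default_lexicon(),
                             thresholds = category_thresholds(),
                             n_genes_total = NULL) {
  if (!is.null(lexicon) && "lineage" %in% names(annotations)) {
    annotations$taxon_group <- affiliate(annotations$lineage, lexicon)
  }
  if (!"taxon_group" %in% names(annotations)) {
    stop("annotations need a 'taxon_group' column or a 'lineage' column plus a lexicon",
         call. = FALSE)
  }
  profiles <- profile_contigs(annotations, n_genes_total = n_genes_total,
                              count_cellular = thresholds$count_cellular)
  assign <- assign_categories(profiles, thresholds)
  assignments <- dplyr::left_join(
    assign[c("contig_id", "category")], profiles, by = "contig_id"
  )
  assignments$rule_trace <- assign$rule_trace
  structure(
    list(assignments = assignments, profiles = profiles,
         thresholds = thresholds),
    class = "contig_classification"
  )
}

#' Partition contig ids by assigned category
#'
#' @param x A `"contig_classification"` object.
#' @return Named list of character vectors `cat1`, `cat2`, `cat3`,
#'   `rejected`; together they partition the classified contig ids.
#' @export
category_sets <- function(x) {
  stopifnot(inherits(x, "contig_classification"))
  a <- x$assignments
  list(
    cat1 = a$contig_id[a$category == "1"],
    cat2 = a$contig_id[a$category == "2"],
    cat3 = a$contig_id[a$category == "3"],
    rejected = a$contig_id[a$category == "none"]
  )
}

#' @export
print.contig_classification <- function(x, ...) {
  g <- glance(x)
  cat("Contig consensus classification\n")
  cat(sprintf("  %d contigs: %d category 1, %d category 2, %d category 3, %d rejected\n",
              g$n_contigs, g$n_cat1, g$n_cat2, g$n_cat3, g$n_rejected))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname classify_contigs
#' @param x A `"contig_classification"` object.
#' @param ... Unused.
#' @export
tidy.contig_classification <- function(x, ...) {
  x$assignments
}

#' @rdname classify_contigs
#' @export
glance.contig_classification <- function(x, ...) {
  a <- x$assignments
  tibble::tibble(
    n_contigs = nrow(a),
    n_cat1 = sum(a$category == "1"),
    n_cat2 = sum(a$category == "2"),
    n_cat3 = sum(a$category == "3"),
    n_rejected = sum(a$category == "none"),
    prop_positive = ifelse(nrow(a) > 0, mean(a$category != "none"), NA_real_)
  )
}

#' Plot a contig classification
#'
#' Scatter of each contig's archaeal-virus fraction against its best
#' archaeal bit-score, colored by assigned category, with the decision
#' boundaries drawn as reference lines.
#'
#' @param object A `"contig_classification"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contig_classification <- function(object, ...) {
  a <- object$assignments
  t <- object$thresholds
  ggplot2::ggplot(
    a[!is.na(a$arch_fraction), ],
    ggplot2::aes(x = .data$arch_fraction, y = .data$max_bit_archaeal,
                 colour = .data$category)
  ) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(t$minor_fraction, t$majority_fraction),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = t$min_bit, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "archaeal-virus fraction of annotated genes",
      y = "best archaeal-virus bit-score",
      colour = "category",
      title = "Consensus classification of contigs"
    )
}
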