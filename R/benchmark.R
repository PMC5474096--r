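#' Configuration for the synthetic labeled benchmark
#'
#' Describes a seeded generator of gene-per-contig annotation tables with
#' known truth labels, emulating a curated benchmark of viral contigs with
#' known hosts. Archaeal-virus-labeled contigs draw annotated genes
#' predominantly affiliated with reference archaeal viruses, with bit-scores
#' from a log-normal whose median sits above the quality floor, and are
#' constructed to satisfy the category criteria; phage-labeled contigs are
#' the mirror image, with phage-affiliated genes and weaker bit-scores.
#'
#' `confuser_count` phage-labeled contigs are built as known hard cases that
#' pass the category rules: sparse annotation profiles whose few annotated
#' genes affiliate with archaeal viruses (2 annotated of 52 genes, all
#' archaeal — the few-annotation clause; and 3 annotated of 5 genes with the
#' top-scoring hit archaeal — the quality rule of category 3). With
#' `p_cross = 0` (default) no other phage contig carries archaeal-virus
#' annotations, so the benchmark is separable apart from the confusers and
#' accuracy degrades by exactly `confuser_count / N`.
#'
#' @param n_archaeal,n_phage Number of archaeal-virus- and phage-labeled
#'   contigs.
#' @param confuser_count Number of phage-labeled confuser contigs built to
#'   pass category rules (counted within `n_phage`).
#' @param genes_per_contig_mean,genes_per_contig_min Poisson mean and lower
#'   clamp for genes per contig.
#' @param annotated_fraction Named vector, mean fraction of genes with a
#'   taxonomic annotation for `archaeal` and `phage` contigs (per-contig
#'   fractions drawn from a Beta with this mean).
#' @param bit_medians Named vector of log-normal bit-score medians per taxon
#'   group; archaeal-virus and phage medians straddle the quality floor.
#' @param bit_sdlog Log-scale SD of the bit-score distributions.
#' @param p_minor Probability that an annotated gene on a contig affiliates
#'   away from its contig's own class (spread over the other groups).
#' @param p_cross Probability that a minority annotation on a *phage* contig
#'   affiliates with archaeal viruses (default 0: separable background).
#' @param min_bit Quality floor the generator respects when enforcing that
#'   archaeal contigs pass (should match the classifier's `min_bit`).
#' @param seed Integer seed; the whole table is a deterministic function of
#'   the configuration.
#' @return A list of class `"benchmark_config"`.
#' @export
benchmark_config <- function(n_archaeal, n_phage, confuser_count = 0,
                             genes_per_contig_mean = 20,
                             genes_per_contig_min = 1,
                             annotated_fraction = c(archaeal = 0.25,
                                                    phage = 0.25),
                             bit_medians = c(archaeal_virus = 150,
                                             eukaryotic_virus = 90,
                                             phage = 55,
                                             cellular = 50),
                             bit_sdlog = 0.35,
                             p_minor = 0.15,
                             p_cross = 0,
                             min_bit = 75,
                             seed = 1) {
  stopifnot(n_archaeal >= 0, n_phage >= 0, confuser_count >= 0,
            confuser_count <= n_phage,
            genes_per_contig_mean > 0, genes_per_contig_min >= 1,
            all(annotated_fraction > 0), all(annotated_fraction <= 1),
            all(bit_medians > 0), bit_sdlog > 0,
            p_minor >= 0, p_minor < 1, p_cross >= 0, p_cross <= 1,
            min_bit > 0)
  structure(
    list(
      n_archaeal = as.integer(n_archaeal), n_phage = as.integer(n_phage),
      confuser_count = as.integer(confuser_count),
      genes_per_contig_mean = genes_per_contig_mean,
      genes_per_contig_min = as.integer(genes_per_contig_min),
      annotated_fraction = annotated_fraction,
      bit_medians = bit_medians, bit_sdlog = bit_sdlog,
      p_minor = p_minor, p_cross = p_cross,
      min_bit = min_bit, seed = as.integer(seed)
    ),
    class = "benchmark_config"
  )
}

# reference-organism name pools, one per taxon group; every name matches its
# group (and no earlier group) in default_lexicon()
lineage_pools <- function() {
  list(
    archaeal_virus = c(
      "Sulfolobus spindle-shaped virus 1",
      "Sulfolobus islandicus rod-shaped virus 2",
      "Acidianus filamentous virus 1",
      "Haloarcula hispanica icosahedral virus SH1",
      "Halorubrum pleomorphic virus 1",
      "Natrialba phage PhiCh1",
      "Methanobacterium phage psiM2",
      "Pyrococcus abyssi virus 1",
      "Thermoproteus tenax spherical virus 1"
    ),
    phage = c(
      "Prochlorococcus phage P-SSM2",
      "Escherichia phage T4",
      "Synechococcus phage S-PM2",
      "Pelagibacter phage HTVC010P",
      "Vibrio phage KVP40",
      "Mycobacterium phage L5",
      "uncultured Mediterranean phage uvMED"
    ),
    eukaryotic_virus = c(
      "Acanthamoeba polyphaga mimivirus",
      "Paramecium bursaria Chlorella virus 1",
      "Emiliania huxleyi virus 86",
      "Ostreococcus virus OsV5",
      "Micromonas virus SP1"
    ),
    cellular = c(
      "uncultured marine bacterium",
      "uncultured archaeon",
      "Candidatus Pelagibacter ubique",
      "Flavobacteria bacterium BBFL7",
      "marine actinobacterium PHSC20C1"
    )
  )
}

# draw from a log-normal truncated strictly above `bound` (vectorized)
rlnorm_above <- function(n, meanlog, sdlog, bound) {
  q <- stats::plnorm(bound, meanlog, sdlog)
  out <- stats::qlnorm(q + runif(n) * (1 - q), meanlog, sdlog)
  bad <- !is.finite(out) | out <= bound
  out[bad] <- bound[bad] * 1.1 + 1
  out
}

#' Simulate a labeled annotation-table benchmark
#'
#' Generates the gene-per-contig annotation table described by a
#' [benchmark_config()], along with its truth labels. The output is a
#' deterministic function of the configuration (same seed, same bytes).
#' Lineage strings are drawn from small pools of reference organism names
#' that the [default_lexicon()] affiliates with the intended taxon group, so
#' classifying the table exercises the full keyword path.
#'
#' @param config A [benchmark_config()].
#' @return A list with elements `annotations` (gene annotation tibble:
#'   `contig_id`, `gene_id`, `gene_index`, `lineage`, `taxon_group`,
#'   `bit_score`, `e_value`) and `truth` (tibble: `contig_id`, `truth`
#'   either `"archaeal_virus"` or `"phage"`, `is_confuser`).
#' @export
#' @examples
#' sim <- simulate_benchmark(benchmark_config(n_archaeal = 3, n_phage = 5,
#'                                            seed = 7))
#' sim$truth
simulate_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  cfg <- config
  set.seed(cfg$seed)
  pools <- lineage_pools()
  n_total <- cfg$n_archaeal + cfg$n_phage
  empty_ann <- tibble::tibble(
    contig_id = character(), gene_id = character(), gene_index = integer(),
    lineage = character(), taxon_group = character(),
    bit_score = numeric(), e_value = numeric()
  )
  empty_truth <- tibble::tibble(contig_id = character(), truth = character(),
                                is_confuser = logical())
  if (n_total == 0) {
    return(list(annotations = empty_ann, truth = empty_truth))
  }
  contig_id <- sprintf("ctg_%06d", seq_len(n_total))
  truth <- c(rep("archaeal_virus", cfg$n_archaeal), rep("phage", cfg$n_phage))
  is_confuser <- rep(FALSE, n_total)
  if (cfg$confuser_count > 0) {
    is_confuser[seq(n_total - cfg$confuser_count + 1L, n_total)] <- TRUE
  }

  # contig-level structure -------------------------------------------------
  n_genes <- pmax(cfg$genes_per_contig_min,
                  rpois(n_total, cfg$genes_per_contig_mean))
  frac_mean <- ifelse(truth == "archaeal_virus",
                      cfg$annotated_fraction[["archaeal"]],
                      cfg$annotated_fraction[["phage"]])
  conc <- 10
  frac <- stats::rbeta(n_total, frac_mean * conc, (1 - frac_mean) * conc)
  n_ann <- pmin(pmax(rbinom(n_total, n_genes, frac), 1L), n_genes)

  arch <- truth == "archaeal_virus"
  n_minor <- rbinom(n_total, n_ann, cfg$p_minor)
  n_minor[arch & n_ann <= 2] <- 0L   # few-annotation contigs stay pure

  # per-group annotated counts: a = own-class archaeal, p = phage,
  # e = eukaryotic, c = cellular
  a <- integer(n_total); p <- integer(n_total)
  e <- integer(n_total); cc <- integer(n_total)
  # archaeal contigs: minority split evenly over phage/eukaryotic/cellular
  mp <- rbinom(n_total, n_minor, 1 / 3)
  me <- rbinom(n_total, n_minor - mp, 1 / 2)
  mc <- n_minor - mp - me
  a[arch] <- (n_ann - n_minor)[arch]
  p[arch] <- mp[arch]; e[arch] <- me[arch]; cc[arch] <- mc[arch]
  # phage contigs: minority split between cellular/eukaryotic, with an
  # optional archaeal cross-annotation rate
  ma <- rbinom(n_total, n_minor, cfg$p_cross)
  rest <- n_minor - ma
  pe <- rbinom(n_total, rest, 1 / 2)
  pc <- rest - pe
  p[!arch] <- (n_ann - n_minor)[!arch]
  a[!arch] <- ma[!arch]; e[!arch] <- pe[!arch]; cc[!arch] <- pc[!arch]

  # enforce that archaeal-labeled contigs satisfy the fraction criterion:
  # arch count strictly above 2/3 of the (arch + phage + cellular) denominator
  d <- a + p + cc
  none_left <- arch & d == 0 & e > 0
  a[none_left] <- 1L; e[none_left] <- e[none_left] - 1L
  d <- a + p + cc
  need <- pmin(d, floor(2 * d / 3) + 1L)
  deficit <- pmax(0L, ifelse(arch, need - a, 0L))
  from_p <- pmin(deficit, p)
  p <- p - from_p
  from_c <- pmin(deficit - from_p, cc)
  cc <- cc - from_c
  a <- a + from_p + from_c

  # confusers override the drawn structure with the two hard-case patterns
  conf_idx <- which(is_confuser)
  if (length(conf_idx) > 0) {
    pat <- rep_len(c("clause", "quality"), length(conf_idx))
    clause <- conf_idx[pat == "clause"]
    qual <- conf_idx[pat == "quality"]
    n_genes[clause] <- 52L; n_ann[clause] <- 2L
    a[clause] <- 2L; p[clause] <- 0L; e[clause] <- 0L; cc[clause] <- 0L
    n_genes[qual] <- 5L; n_ann[qual] <- 3L
    a[qual] <- 2L; p[qual] <- 1L; e[qual] <- 0L; cc[qual] <- 0L
  }
  n_ann <- a + p + e + cc

  # gene-level table --------------------------------------------------------
  grp_counts <- rbind(archaeal_virus = a, phage = p,
                      eukaryotic_virus = e, cellular = cc,
                      unclassified = n_genes - n_ann)
  groups_flat <- rep(rep(rownames(grp_counts), ncol(grp_counts)),
                     as.vector(grp_counts))
  contig_flat <- rep(contig_id, colSums(grp_counts) * 0 + n_genes)
  # order genes within each contig: annotated groups then unannotated, in
  # the fixed group order above
  genes <- tibble::tibble(contig_id = contig_flat, taxon_group = groups_flat)
  genes <- dplyr::mutate(
    dplyr::group_by(genes, .data$contig_id),
    gene_index = dplyr::row_number()
  )
  genes <- dplyr::ungroup(genes)

  annotated <- genes$taxon_group != "unclassified"
  meanlogs <- log(cfg$bit_medians)[genes$taxon_group[annotated]]
  bit <- numeric(nrow(genes))
  bit[annotated] <- rlnorm(sum(annotated), meanlogs, cfg$bit_sdlog)

  lineage <- character(nrow(genes))
  for (g in names(pools)) {
    sel <- genes$taxon_group == g
    if (any(sel)) {
      lineage[sel] <- sample(pools[[g]], sum(sel), replace = TRUE)
    }
  }

  genes$bit_score <- round(bit, 1)
  genes$lineage <- lineage

  # enforce the quality criterion on archaeal-labeled (and confuser)
  # contigs: the top archaeal bit must exceed both the floor and every
  # phage bit on the contig
  must_pass <- contig_id[arch | is_confuser]
  gsub_idx <- which(genes$contig_id %in% must_pass)
  gi <- genes[gsub_idx, ]
  bound_tbl <- dplyr::summarise(
    dplyr::group_by(gi, .data$contig_id),
    bound = max(cfg$min_bit,
                .data$bit_score[.data$taxon_group == "phage"], na.rm = TRUE),
    top_arch = {
      ab <- .data$bit_score[.data$taxon_group == "archaeal_virus"]
      if (length(ab) > 0) max(ab) else -Inf
    },
    .groups = "drop"
  )
  fix <- bound_tbl[bound_tbl$top_arch <= bound_tbl$bound &
                     is.finite(bound_tbl$top_arch), ]
  if (nrow(fix) > 0) {
    new_bits <- round(rlnorm_above(
      nrow(fix), log(cfg$bit_medians[["archaeal_virus"]]), cfg$bit_sdlog,
      fix$bound
    ), 1)
    for (i in seq_len(nrow(fix))) {
      rows <- which(genes$contig_id == fix$contig_id[i] &
                      genes$taxon_group == "archaeal_virus")
      top <- rows[which.max(genes$bit_score[rows])]
      genes$bit_score[top] <- new_bits[i]
    }
  }

  genes$gene_id <- paste0(genes$contig_id, "_", genes$gene_index)
  genes$e_value <- ifelse(genes$taxon_group == "unclassified", NA_real_,
                          signif(2^(-genes$bit_score), 3))
  ann <- genes[c("contig_id", "gene_id", "gene_index", "lineage",
                 "taxon_group", "bit_score", "e_value")]
  list(
    annotations = ann,
    truth = tibble::tibble(contig_id = contig_id, truth = truth,
                           is_confuser = is_confuser)
  )
}

#' Score classifier output against truth labels
#'
#' A contig counts as predicted positive when its category is 1, 2 or 3.
#' Sensitivity is `TP / (TP + FN) * 100` over the archaeal-virus-labeled
#' contigs; accuracy is `(TP + TN) / N * 100`. Per-category tallies are
#' reported separately for true archaeal viruses and mislabeled phage, and
#' are not forced to reconcile with the collective counts.
#'
#' @param assignments A `"contig_classification"` object or a tibble with
#'   `contig_id` and `category`.
#' @param truth Truth tibble (`contig_id`, `truth`), as from
#'   [simulate_benchmark()].
#' @return An object of class `"benchmark_result"`: list with `summary`
#'   (one-row tibble: tp, fp, tn, fn, n, sensitivity, accuracy),
#'   `per_category` (counts per category and truth label) and `confusion`.
#' @export
evaluate_benchmark <- function(assignments, truth) {
  if (inherits(assignments, "contig_classification")) {
    assignments <- assignments$assignments
  }
  stopifnot(all(c("contig_id", "category") %in% names(assignments)))
  if (nrow(truth) == 0) stop("empty truth table", call. = FALSE)
  if (!setequal(assignments$contig_id, truth$contig_id)) {
    diff <- union(setdiff(assignments$contig_id, truth$contig_id),
                  setdiff(truth$contig_id, assignments$contig_id))
    stop("contig ids differ between assignments and truth: ",
         paste(head(diff, 10), collapse = ", "),
         if (length(diff) > 10) " ..." else "", call. = FALSE)
  }
  m <- dplyr::inner_join(assignments[c("contig_id", "category")], truth,
                         by = "contig_id")
  pos <- m$category %in% c("1", "2", "3")
  is_arch <- m$truth == "archaeal_virus"
  tp <- sum(pos & is_arch); fn <- sum(!pos & is_arch)
  fp <- sum(pos & !is_arch); tn <- sum(!pos & !is_arch)
  n <- nrow(m)
  summary <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    accuracy = 100 * (tp + tn) / n
  )
  per_category <- dplyr::count(m, .data$category, .data$truth,
                               name = "n_contigs", .drop = FALSE)
  confusion <- dplyr::count(
    dplyr::mutate(m, predicted = ifelse(pos, "archaeal_virus", "other")),
    .data$truth, .data$predicted, name = "n_contigs"
  )
  structure(
    list(summary = summary, per_category = per_category,
         confusion = confusion),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  s <- x$summary
  cat("Benchmark result\n")
  cat(sprintf("  n = %d contigs; sensitivity %.2f%%, accuracy %.3f%%\n",
              s$n, s$sensitivity, s$accuracy))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", s$tp, s$fp, s$tn, s$fn))
  invisible(x)
}

#' @rdname evaluate_benchmark
#' @param x A `"benchmark_result"` object.
#' @param ... Unused.
#' @export
tidy.benchmark_result <- function(x, ...) {
  x$per_category
}

#' @rdname evaluate_benchmark
#' @export
glance.benchmark_result <- function(x, ...) {
  x$summary
}

#' Plot per-category benchmark tallies
#'
#' @param object A `"benchmark_result"` object.
#' @param ... Unused.
#' @return A ggplot bar chart of contig counts per assigned category, split
#'   by truth label.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(
    object$per_category,
    ggplot2::aes(x = .data$category, y = .data$n_contigs, fill = .data$truth)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "assigned category", y = "contigs (log scale)",
                  fill = "truth")
}
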