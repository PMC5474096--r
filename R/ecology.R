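#' Coverage-normalized abundance of populations across samples
#'
#' Converts summed per-base read coverage into a normalized abundance:
#' `(depth_sum / contig_length) / sample_read_bases * scale`, i.e. mean
#' per-base coverage normalized by sequencing effort (total bases in the
#' trimmed read file), rescaled by `scale` to a convenient magnitude.
#' With `log = TRUE` the value reported is `log10(1 + linear)` so that zero
#' coverage maps to zero — the transform used for heatmap display; keep the
#' linear scale for Bray-Curtis.
#'
#' @param coverage Tibble with columns `sample_id`, `contig_id`,
#'   `depth_sum` (summed per-base depth, in bases); each (sample, contig)
#'   pair at most once. Missing pairs are treated as zero coverage.
#' @param contig_lengths Tibble (`contig_id`, `length`) in bp.
#' @param sample_read_bases Tibble (`sample_id`, `read_bases`): total bases
#'   in each sample's trimmed read file.
#' @param scale Rescaling constant (default `1e9`).
#' @param log Report `log10(1 + linear)` instead of the linear value.
#' @return A tibble `sample_id`, `contig_id`, `abundance` over the complete
#'   sample x contig grid, with attribute `transform` (`"linear"` or
#'   `"log10"`).
#' @export
normalize_abundance <- function(coverage, contig_lengths, sample_read_bases,
                                scale = 1e9, log = FALSE) {
  stopifnot(all(c("sample_id", "contig_id", "depth_sum") %in% names(coverage)))
  stopifnot(all(c("contig_id", "length") %in% names(contig_lengths)))
  stopifnot(all(c("sample_id", "read_bases") %in% names(sample_read_bases)))
  if (anyDuplicated(coverage[c("sample_id", "contig_id")])) {
    stop("duplicate (sample_id, contig_id) pair in coverage table", call. = FALSE)
  }
  if (any(coverage$depth_sum < 0)) {
    stop("negative depth_sum", call. = FALSE)
  }
  bad_len <- contig_lengths$contig_id[is.na(contig_lengths$length) |
                                        contig_lengths$length <= 0]
  if (length(bad_len) > 0) {
    stop("non-positive contig length for: ", paste(bad_len, collapse = ", "),
         call. = FALSE)
  }
  bad_rb <- sample_read_bases$sample_id[is.na(sample_read_bases$read_bases) |
                                          sample_read_bases$read_bases <= 0]
  if (length(bad_rb) > 0) {
    stop("non-positive read_bases for sample: ", paste(bad_rb, collapse = ", "),
         call. = FALSE)
  }
  missing_len <- setdiff(unique(coverage$contig_id), contig_lengths$contig_id)
  if (length(missing_len) > 0) {
    stop("no length for contig(s): ", paste(missing_len, collapse = ", "),
         call. = FALSE)
  }
  missing_rb <- setdiff(unique(coverage$sample_id), sample_read_bases$sample_id)
  if (length(missing_rb) > 0) {
    stop("no read_bases for sample(s): ", paste(missing_rb, collapse = ", "),
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    sample_id = unique(coverage$sample_id),
    contig_id = unique(coverage$contig_id)
  )
  ab <- dplyr::left_join(grid, coverage, by = c("sample_id", "contig_id"))
  ab$depth_sum[is.na(ab$depth_sum)] <- 0
  ab <- dplyr::left_join(ab, contig_lengths[c("contig_id", "length")],
                         by = "contig_id")
  ab <- dplyr::left_join(ab, sample_read_bases[c("sample_id", "read_bases")],
                         by = "sample_id")
  ab$abundance <- ab$depth_sum / ab$length / ab$read_bases * scale
  if (log) ab$abundance <- log10(1 + ab$abundance)
  out <- ab[c("sample_id", "contig_id", "abundance")]
  attr(out, "transform") <- if (log) "log10" else "linear"
  out
}

#' Pivot a long abundance table into a matrix
#'
#' @param abundance Long tibble (`sample_id`, `contig_id`, `abundance`).
#' @param rows Whether samples or contigs label the rows (vegan convention
#'   is samples as rows).
#' @return A numeric matrix with dimnames.
#' @export
abundance_matrix <- function(abundance, rows = c("sample", "contig")) {
  rows <- match.arg(rows)
  wide <- tidyr::pivot_wider(
    abundance,
    names_from = "contig_id", values_from = "abundance", values_fill = 0
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  if (rows == "contig") m <- t(m)
  m
}

#' Alpha diversity per sample
#'
#' Richness (number of populations with nonzero abundance), Shannon-Wiener
#' diversity `H' = -sum(p_i * log(p_i))` over proportions of the nonzero
#' linear abundances, and Pielou's evenness `J = H' / log(S)`. `J` is `NA`
#' when richness is 0 or 1 (evenness is undefined for a single population).
#'
#' @param abundance Long tibble (`sample_id`, `contig_id`, `abundance`) on
#'   the linear scale, e.g. from [normalize_abundance()] with `log = FALSE`.
#' @param base Logarithm base; the default `exp(1)` reports H' in nats.
#' @return A tibble `sample_id`, `richness`, `shannon`, `pielou`.
#' @export
#' @examples
#' ab <- tibble::tibble(sample_id = "s1", contig_id = c("a", "b"),
#'                      abundance = c(4, 1))
#' alpha_diversity(ab)
alpha_diversity <- function(abundance, base = exp(1)) {
  stopifnot(all(c("sample_id", "abundance") %in% names(abundance)))
  if (any(abundance$abundance < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  one <- function(x) {
    x <- x[x > 0]
    s <- length(x)
    if (s == 0) {
      return(tibble::tibble(richness = 0L, shannon = 0, pielou = NA_real_))
    }
    p <- x / sum(x)
    h <- -sum(p * log(p, base = base))
    tibble::tibble(
      richness = s,
      shannon = h,
      pielou = if (s > 1) h / log(s, base = base) else NA_real_
    )
  }
  dplyr::reframe(
    dplyr::group_by(abundance, .data$sample_id),
    one(.data$abundance)
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over the linear abundance
#' profiles of each pair of samples; two all-zero samples have distance 0 by
#' convention. Computed with [vegan::vegdist()].
#'
#' @param abundance Long abundance tibble (linear scale) or a numeric
#'   matrix with samples as rows.
#' @return A square symmetric matrix of Bray-Curtis dissimilarities in
#'   \[0, 1\] with zero diagonal and sample labels as dimnames.
#' @export
bray_curtis <- function(abundance) {
  m <- if (is.matrix(abundance)) abundance else abundance_matrix(abundance)
  if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
  # vegan warns on all-zero samples; their distances are set by the 0/0
  # convention below
  d <- suppressWarnings(as.matrix(vegan::vegdist(m, method = "bray")))
  d[is.nan(d)] <- 0   # 0/0: two empty samples are identical
  diag(d) <- 0
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation `r` between the upper-triangle entries of two
#' distance matrices over the same samples, with a one-tailed permutation
#' p-value: rows and columns of the second matrix are permuted jointly
#' `n_perm` times and `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param d1,d2 Square symmetric distance matrices with matching sample
#'   labels (dimnames); `d2` is reordered to `d1`'s label order. Unlabeled
#'   matrices are compared positionally.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation generator.
#' @return A one-row tibble: `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) {
    stop("distance matrices differ in size", call. = FALSE)
  }
  n <- nrow(d1)
  if (n < 3) stop("need at least 3 samples for a Mantel test", call. = FALSE)
  l1 <- rownames(d1); l2 <- rownames(d2)
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2)) {
      stop("sample labels differ: ",
           paste(union(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "),
           call. = FALSE)
    }
    d2 <- d2[l1, l1]
  }
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  r_obs <- stats::cor(v1, d2[ut])
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(v1, d2[p, p][ut])
  }, numeric(1))
  tibble::tibble(
    r = r_obs,
    p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
    n_perm = as.integer(n_perm)
  )
}

#' Heatmap of a (log-scaled) abundance matrix
#'
#' @param abundance Long abundance tibble (`sample_id`, `contig_id`,
#'   `abundance`).
#' @return A ggplot tile plot, populations on the x axis, samples on the y
#'   axis.
#' @export
plot_abundance_heatmap <- function(abundance) {
  ggplot2::ggplot(
    abundance,
    ggplot2::aes(x = .data$contig_id, y = .data$sample_id,
                 fill = .data$abundance)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "population", y = "sample",
                  fill = paste0("abundance\n(",
                                attr(abundance, "transform") %||% "linear",
                                ")")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
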