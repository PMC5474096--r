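# Independent truth table for the three category rules, written as a
# literal nested-if transcription of the published decision logic, one case
# at a time. Used to cross-check the vectorized classifier.

oracle_category <- function(n_annotated, n_arch, n_phage, n_cell, n_euk,
                            bit_arch, bit_phage,
                            majority = 2 / 3, minor = 1 / 3, min_bit = 75,
                            min_main = 3, clause_max = 2, clause_bit = TRUE,
                            count_cell = TRUE) {
  ba <- if (n_arch > 0) bit_arch else -Inf
  bp <- if (n_phage > 0) bit_phage else -Inf
  # category 1, few-annotation clause: 1-2 annotations, all archaeal
  if (n_annotated >= 1 && n_annotated <= clause_max && n_arch == n_annotated) {
    if (!clause_bit || ba > min_bit) return("1")
  }
  denom <- n_arch + n_phage + if (count_cell) n_cell else 0
  if (n_annotated >= min_main && denom > 0) {
    f <- n_arch / denom
    if (f > majority && ba > min_bit && ba > bp) return("1")
    if (f > majority && ba > min_bit && bp >= ba) return("2")
    if (f >= minor && f <= majority && ba > min_bit && ba > bp) return("3")
  }
  "none"
}

# build a gene-level annotation tibble for one contig from group counts;
# every gene in a group carries the same bit-score
make_contig_annotations <- function(contig_id, n_genes_total,
                                    n_arch = 0, n_phage = 0, n_euk = 0,
                                    n_cell = 0,
                                    bit_arch = 100, bit_phage = 80,
                                    bit_euk = 200, bit_cell = 50) {
  groups <- c(rep("archaeal_virus", n_arch), rep("phage", n_phage),
              rep("eukaryotic_virus", n_euk), rep("cellular", n_cell))
  bits <- c(rep(bit_arch, n_arch), rep(bit_phage, n_phage),
            rep(bit_euk, n_euk), rep(bit_cell, n_cell))
  n_ann <- length(groups)
  stopifnot(n_genes_total >= n_ann)
  groups <- c(groups, rep("unclassified", n_genes_total - n_ann))
  bits <- c(bits, rep(0, n_genes_total - n_ann))
  tibble::tibble(
    contig_id = contig_id,
    gene_id = paste0(contig_id, "_", seq_len(n_genes_total)),
    gene_index = seq_len(n_genes_total),
    lineage = ifelse(groups == "unclassified", "", groups),
    taxon_group = groups,
    bit_score = bits,
    e_value = NA_real_
  )
}
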