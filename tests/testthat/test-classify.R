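test_that("contig profiles follow the published counting rules", {
  # sparse contig: 2 annotated of 52 genes, both archaeal
  sparse <- make_contig_annotations("sparse", 52, n_arch = 2, bit_arch = 100)
  p <- profile_contigs(sparse)
  expect_equal(p$n_genes_total, 52)
  expect_equal(p$n_annotated, 2)
  expect_equal(p$arch_fraction, 1.0)

  # nothing annotated: fraction undefined
  bare <- make_contig_annotations("bare", 10)
  p <- profile_contigs(bare)
  expect_equal(p$n_annotated, 0)
  expect_true(is.na(p$arch_fraction))

  # eukaryotic hits are counted but excluded from the fraction
  mixed <- dplyr::bind_rows(
    make_contig_annotations("m", 4, n_arch = 2, n_phage = 1, n_euk = 1,
                            bit_arch = 120, bit_phage = 60, bit_euk = 200)
  )
  mixed$bit_score[mixed$taxon_group == "archaeal_virus"] <- c(90, 120)
  p <- profile_contigs(mixed)
  expect_equal(p$n_annotated, 4)
  expect_equal(p$arch_fraction, 2 / 3)
  expect_equal(p$max_bit_archaeal, 120)
  expect_equal(p$max_bit_phage, 60)
  expect_equal(p$max_bit_eukaryotic, 200)
})

test_that("supplied gene totals override row counts and are validated", {
  ann <- make_contig_annotations("c", 3, n_arch = 3, bit_arch = 100)
  totals <- tibble::tibble(contig_id = "c", n_genes_total = 52L)
  p <- profile_contigs(ann[ann$taxon_group != "unclassified", ], totals)
  expect_equal(p$n_genes_total, 52)
  expect_error(
    profile_contigs(ann, tibble::tibble(contig_id = "c", n_genes_total = 1L)),
    "smaller"
  )
  expect_error(
    profile_contigs(ann, tibble::tibble(contig_id = "other",
                                        n_genes_total = 5L)),
    "missing"
  )
})

test_that("category assignment reproduces the worked examples", {
  cases <- dplyr::bind_rows(
    # 2 annotated of 52, all archaeal, bits above the floor -> category 1
    make_contig_annotations("miscall_1", 52, n_arch = 2, bit_arch = 90),
    # 3 annotated of 5, 2 archaeal (top bit wins) -> fraction 2/3, category 3
    make_contig_annotations("miscall_3", 5, n_arch = 2, n_phage = 1,
                            bit_arch = 110, bit_phage = 80),
    # fraction 7/8 > 2/3 but a phage gene scores higher -> category 2
    make_contig_annotations("hgt", 12, n_arch = 7, n_phage = 1,
                            bit_arch = 90, bit_phage = 130),
    # bit floor fails -> none
    make_contig_annotations("weak", 9, n_arch = 2, n_phage = 4,
                            bit_arch = 70, bit_phage = 60)
  )
  cl <- classify_contigs(cases, lexicon = NULL)
  got <- setNames(as.character(cl$assignments$category),
                  cl$assignments$contig_id)
  expect_equal(got[["miscall_1"]], "1")
  expect_equal(got[["miscall_3"]], "3")
  expect_equal(got[["hgt"]], "2")
  expect_equal(got[["weak"]], "none")
  sets <- category_sets(cl)
  expect_equal(lengths(sets)[c("cat1", "cat2", "cat3", "rejected")],
               c(cat1 = 1L, cat2 = 1L, cat3 = 1L, rejected = 1L))
})

test_that("classification matches the independent rule oracle over a profile grid", {
  bits <- c(60, 75, 76, 100, 150)
  grid <- tidyr::expand_grid(
    n_ann = 0:6,
    n_arch = 0:6,
    bit_arch = bits,
    bit_phage = bits,
    cell_split = c(FALSE, TRUE)
  )
  grid <- grid[grid$n_arch <= grid$n_ann, ]
  rest <- grid$n_ann - grid$n_arch
  grid$n_cell <- ifelse(grid$cell_split, rest %/% 2, 0L)
  grid$n_phage <- rest - grid$n_cell
  expect_gt(nrow(grid), 1000)

  grid$contig_id <- sprintf("g%04d", seq_len(nrow(grid)))
  ann <- purrr::pmap_dfr(
    grid[c("contig_id", "n_ann", "n_arch", "n_phage", "n_cell",
           "bit_arch", "bit_phage")],
    function(contig_id, n_ann, n_arch, n_phage, n_cell, bit_arch, bit_phage) {
      make_contig_annotations(contig_id, n_genes_total = n_ann + 2,
                              n_arch = n_arch, n_phage = n_phage,
                              n_cell = n_cell,
                              bit_arch = bit_arch, bit_phage = bit_phage,
                              bit_cell = 50)
    }
  )
  cl <- classify_contigs(ann, lexicon = NULL)
  got <- setNames(as.character(cl$assignments$category),
                  cl$assignments$contig_id)[grid$contig_id]

  expected <- purrr::pmap_chr(
    grid[c("n_ann", "n_arch", "n_phage", "n_cell", "bit_arch", "bit_phage")],
    function(n_ann, n_arch, n_phage, n_cell, bit_arch, bit_phage) {
      oracle_category(n_annotated = n_ann, n_arch = n_arch,
                      n_phage = n_phage, n_cell = n_cell, n_euk = 0,
                      bit_arch = bit_arch, bit_phage = bit_phage)
    }
  )
  expect_equal(unname(got), expected)
})

test_that("fraction boundaries behave as specified: 2/3 is category 3, not 1", {
  # exactly 2/3 archaeal: never category 1/2, eligible for 3
  boundary <- make_contig_annotations("b", 6, n_arch = 4, n_phage = 2,
                                      bit_arch = 100, bit_phage = 80)
  cl <- classify_contigs(boundary, lexicon = NULL)
  expect_equal(as.character(cl$assignments$category), "3")
  # exactly 1/3 archaeal: eligible for category 3
  lower <- make_contig_annotations("l", 6, n_arch = 2, n_phage = 4,
                                   bit_arch = 100, bit_phage = 80)
  cl <- classify_contigs(lower, lexicon = NULL)
  expect_equal(as.character(cl$assignments$category), "3")
  # just above 1/3 stays in band; just below falls out
  below <- make_contig_annotations("bl", 7, n_arch = 2, n_phage = 5,
                                   bit_arch = 100, bit_phage = 80)
  cl <- classify_contigs(below, lexicon = NULL)
  expect_equal(as.character(cl$assignments$category), "none")
})

test_that("raising the archaeal bit-score never demotes a contig to none", {
  set.seed(4)
  for (i in 1:40) {
    n_ann <- sample(1:6, 1)
    n_arch <- sample(0:n_ann, 1)
    prof_ann <- make_contig_annotations(
      "m", n_ann + 3, n_arch = n_arch, n_phage = n_ann - n_arch,
      bit_arch = sample(c(60, 80, 120), 1), bit_phage = sample(c(60, 90), 1)
    )
    base_cat <- as.character(
      classify_contigs(prof_ann, lexicon = NULL)$assignments$category
    )
    boosted <- prof_ann
    boosted$bit_score[boosted$taxon_group == "archaeal_virus"] <-
      boosted$bit_score[boosted$taxon_group == "archaeal_virus"] + 100
    boost_cat <- as.character(
      classify_contigs(boosted, lexicon = NULL)$assignments$category
    )
    if (base_cat != "none") expect_false(boost_cat == "none")
  }
})

test_that("assignments always partition the classified contigs", {
  sim <- simulate_benchmark(benchmark_config(n_archaeal = 20, n_phage = 60,
                                             confuser_count = 3, seed = 9))
  cl <- classify_contigs(sim$annotations)
  sets <- category_sets(cl)
  expect_equal(sort(unlist(sets, use.names = FALSE)),
               sort(unique(sim$annotations$contig_id)))
  expect_equal(sum(lengths(sets)), dplyr::n_distinct(sim$annotations$contig_id))
})

test_that("thresholds are configurable and dominate: a huge bit floor rejects everything", {
  sim <- simulate_benchmark(benchmark_config(n_archaeal = 10, n_phage = 10,
                                             seed = 3))
  strict <- classify_contigs(sim$annotations,
                             thresholds = category_thresholds(min_bit = 1000))
  expect_true(all(strict$assignments$category == "none"))
  expect_error(category_thresholds(majority_fraction = 0.2,
                                   minor_fraction = 0.5),
               "minor_fraction")
})

test_that("the few-annotation clause bit floor can be waived", {
  weak_pure <- make_contig_annotations("w", 30, n_arch = 2, bit_arch = 50)
  strict <- classify_contigs(weak_pure, lexicon = NULL)
  expect_equal(as.character(strict$assignments$category), "none")
  waived <- classify_contigs(
    weak_pure, lexicon = NULL,
    thresholds = category_thresholds(require_min_bit_in_clause = FALSE)
  )
  expect_equal(as.character(waived$assignments$category), "1")
})

test_that("cellular genes can be excluded from the fraction denominator", {
  ann <- make_contig_annotations("c", 8, n_arch = 3, n_phage = 1, n_cell = 4,
                                 bit_arch = 100, bit_phage = 80)
  incl <- classify_contigs(ann, lexicon = NULL)   # 3/8 -> band -> cat 3
  expect_equal(as.character(incl$assignments$category), "3")
  excl <- classify_contigs(
    ann, lexicon = NULL,
    thresholds = category_thresholds(count_cellular = FALSE)
  )                                               # 3/4 -> majority -> cat 1
  expect_equal(as.character(excl$assignments$category), "1")
})

test_that("tidy, glance and autoplot work on classification objects", {
  sim <- simulate_benchmark(benchmark_config(n_archaeal = 5, n_phage = 10,
                                             seed = 2))
  cl <- classify_contigs(sim$annotations)
  td <- tidy(cl)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("contig_id", "category", "arch_fraction", "rule_trace")
                  %in% names(td)))
  g <- glance(cl)
  expect_equal(g$n_contigs, 15)
  expect_equal(g$n_cat1 + g$n_cat2 + g$n_cat3 + g$n_rejected, 15)
  expect_s3_class(autoplot(cl), "ggplot")
})
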