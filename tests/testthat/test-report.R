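test_that("per-chromosome summary reports counts and mean adjacent distance", {
  man <- tibble::tibble(chrom = c("1", "1", "1", "2"),
                        pos = c(1000, 11000, 21000, 500))
  s <- per_chromosome_summary(man)
  expect_equal(s$n_snps, c(3, 1))
  expect_equal(s$mean_distance_kbp, c(10.00, NA))

  # conservation on a synthetic panel
  genome <- genome_layout(c("1", "2"), c(2e6, 1e6))
  cand <- toy_candidates(500, genome, seed = 17)
  cand <- cand[!duplicated(cand[c("chrom", "pos")]), ]
  s2 <- per_chromosome_summary(cand)
  expect_equal(sum(s2$n_snps), nrow(cand))
})

test_that("group composition counts conserve the panel total", {
  man <- tibble::tibble(
    chrom = "1", pos = 1:12,
    group = rep(c("resequencing", "gwas", "snpdb"), c(5, 4, 3)),
    priority = rep(c("P2", "P1", "BACKGROUND"), c(5, 4, 3)))
  comp <- group_composition(man)
  expect_equal(sum(comp$n_snps), 12)
  expect_equal(comp$n_snps[comp$group == "gwas"], 4)

  empty <- group_composition(man[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("annotation summary percentages use half-up rounding", {
  ref <- chicken55k_summary_tables()
  man <- expand_counts(ref$consequences, "consequence")
  ann <- dplyr::filter(man, consequence != "unannotated") |>
    dplyr::select(chrom, pos, consequence)
  s <- annotation_summary(dplyr::select(man, chrom, pos), ann)
  # every published class percentage is reproduced from its count
  printed <- c("intron variant" = 48.43, "intergenic variant" = 30.86,
               "intron variant & noncoding transcript variant" = 7.63,
               "synonymous variant" = 3.07, "missense variant" = 1.13,
               "downstream gene variant (1 kb)" = 1.94,
               "upstream gene variant (1 kb)" = 1.67,
               "3 prime UTR variant" = 2.60, "5 prime UTR variant" = 0.44,
               "missense variant & splice region variant" = 0.02,
               "Splicing" = 0.36, "start/stop gained/lost/retained" = 0.02,
               "noncoding transcript exon variant" = 1.67)
  got <- setNames(s$pct, s$consequence)[names(printed)]
  expect_equal(unname(got), unname(printed))
  expect_equal(attr(s, "annotatable_pct"), 99.85)

  # all-unannotated toy panel
  toy <- tibble::tibble(chrom = "1", pos = 1:4)
  s2 <- annotation_summary(toy, tibble::tibble(chrom = character(),
                                               pos = numeric(),
                                               consequence = character()))
  expect_equal(attr(s2, "annotatable_n"), 0)
  expect_equal(attr(s2, "annotatable_pct"), 0)
})

test_that("panel overlap reports Venn regions matching a set-algebra oracle", {
  a <- tibble::tibble(chrom = "1", pos = c(100, 200))
  b <- tibble::tibble(chrom = "1", pos = c(200, 300))
  ov <- panel_overlap(a = a, b = b)
  expect_equal(ov$pairwise$n_overlap, 1)
  expect_equal(sum(ov$regions$n), 3)

  withr::with_seed(404, {
    keys <- paste0("1:", 1:300)
    sets <- lapply(1:3, function(i) sample(keys, 150))
    tabs <- lapply(sets, function(k) {
      tibble::tibble(chrom = "1", pos = as.numeric(sub("1:", "", k)))
    })
    ov3 <- panel_overlap(x = tabs[[1]], y = tabs[[2]], z = tabs[[3]])
    # brute-force region counts
    memb <- sapply(sets, function(s) keys %in% s)
    pat <- apply(memb, 1, function(r) paste(c("x", "y", "z")[r],
                                            collapse = "&"))
    expected <- table(pat[pat != ""])
    got <- setNames(ov3$regions$n, ov3$regions$region)
    expect_equal(got[names(expected)], setNames(as.integer(expected),
                                                names(expected)))
    expect_equal(sum(ov3$regions$n), sum(pat != ""))
  })

  # duplicate positions collapse with a warning
  dup <- tibble::tibble(chrom = "1", pos = c(100, 100, 200))
  expect_warning(ov4 <- panel_overlap(a = dup, b = b), "duplicate")
  expect_equal(ov4$pairwise$n_a, 2)
})
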