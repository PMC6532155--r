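test_that("minor allele frequency folds and delta_f is antisymmetric", {
  expect_equal(minor_allele_frequency(0.9), 0.1)
  expect_equal(minor_allele_frequency(0.5), 0.5)
  expect_equal(minor_allele_frequency(0.05), 0.05)
  expect_error(minor_allele_frequency(1.2), "\\[0, 1\\]")

  expect_equal(delta_f(0.40, 0.05), 0.35)
  withr::with_seed(5, {
    x <- runif(200, 0, 0.5)
    y <- runif(200, 0, 0.5)
    expect_equal(delta_f(x, y), -delta_f(y, x))
    expect_true(all(abs(delta_f(x, y)) <= 0.5))
  })
})

make_pool_table <- function(freq, chrom = NULL, is_indel = NULL) {
  n <- nrow(freq)
  loci <- tibble::tibble(
    snp_id = paste0("L", seq_len(n)),
    chrom = chrom %||% rep("1", n),
    pos = seq_len(n) * 100,
    ref = "A", alt = "G",
    is_indel = is_indel %||% rep(FALSE, n))
  pool_freq_table(loci, freq, setNames(rep(48L, ncol(freq)), colnames(freq)))
}

test_that("resequencing screen applies MAF, differential, W and indel rules", {
  roles <- breed_roles("Local", "Comm", control_for_local = "Comm",
                       control_for_commercial = "Local")
  cfg <- design_config()

  # differential of 0.40 stays below the local threshold of 0.609
  tab <- make_pool_table(cbind(Local = 0.45, Comm = 0.05))
  expect_equal(nrow(select_resequencing_candidates(tab, roles, cfg)), 0)

  # chromosome-W loci are removed regardless of differential
  cfg0 <- design_config(delta_f_threshold_local = 0,
                        delta_f_threshold_commercial = 0)
  tabw <- make_pool_table(cbind(Local = c(0.45, 0.45), Comm = c(0.05, 0.05)),
                          chrom = c("W", "1"))
  sel <- select_resequencing_candidates(tabw, roles, cfg0)
  expect_equal(sel$chrom, "1")

  # zero thresholds keep exactly the non-W, MAF-passing loci (filter replay)
  withr::with_seed(8, {
    f <- cbind(Local = runif(1000), Comm = runif(1000))
    chrom <- sample(c("1", "2", "W"), 1000, replace = TRUE)
    tabr <- make_pool_table(f, chrom = chrom)
    sel <- select_resequencing_candidates(tabr, roles, cfg0)
    maf_l <- pmin(f[, "Local"], 1 - f[, "Local"])
    maf_c <- pmin(f[, "Comm"], 1 - f[, "Comm"])
    expect_reseq <- (maf_l >= 0.05 & (maf_l - maf_c) >= 0) & chrom != "W"
    # the commercial role can also admit loci (Comm vs control Local)
    expect_comm <- (maf_c >= 0.05 & (maf_c - maf_l) >= 0) & chrom != "W"
    expect_setequal(sel$snp_id, tabr$loci$snp_id[expect_reseq | expect_comm])
    expect_true(all(sel$priority == "P2"))
  })

  # raising the threshold never gains survivors (monotonicity)
  withr::with_seed(9, {
    f <- cbind(Local = runif(400), Comm = runif(400))
    tabm <- make_pool_table(f)
    ns <- vapply(c(0, 0.1, 0.2, 0.3, 0.4), function(th) {
      nrow(select_resequencing_candidates(
        tabm, roles, design_config(delta_f_threshold_local = th,
                                   delta_f_threshold_commercial = th)))
    }, numeric(1))
    expect_true(all(diff(ns) <= 0))
  })

  # whitelisted indels pass with priority P1, other indels are dropped
  tabi <- make_pool_table(cbind(Local = c(0.45, 0.45), Comm = c(0.05, 0.05)),
                          is_indel = c(TRUE, TRUE))
  sel <- select_resequencing_candidates(tabi, roles, cfg0,
                                        indel_whitelist = "L1")
  expect_equal(sel$snp_id, "L1")
  expect_equal(sel$priority, "P1")
})

test_that("association screen takes the per-trait top fraction and unions", {
  withr::with_seed(21, {
    assoc <- tibble::tibble(
      chrom = "1", pos = seq_len(200), trait = "bw28",
      p = sample(seq(0.001, 1, length.out = 200)))
    sel <- select_gwas_candidates(assoc, 0.01)
    expect_equal(nrow(sel), 2)  # ceiling(0.01 * 200)
    expect_setequal(sel$pos, assoc$pos[order(assoc$p)][1:2])
    expect_true(all(sel$priority == "P1" & sel$group == "gwas"))
  })

  # two traits sharing their top marker: union of 2 + 2 has 3 members
  assoc2 <- tibble::tibble(
    chrom = "1",
    pos = c(1, 2, 3, 150, 1, 9, 8, 150),
    trait = rep(c("t1", "t2"), each = 4),
    p = c(0.001, 0.002, 0.5, 0.9, 0.001, 0.002, 0.5, 0.9))
  sel2 <- select_gwas_candidates(assoc2, 0.5)
  expect_equal(nrow(sel2), 3)
  expect_setequal(sel2$pos, c(1, 2, 9))
})

test_that("gene-based screen ranks by consequence and caps per gene", {
  cfg <- design_config()
  genes <- tibble::tibble(gene_id = "g1", chrom = "1",
                          start = 10000, end = 20000)

  # a marker 5 kb upstream of the gene is inside the flanked interval
  snps <- tibble::tibble(chrom = "1", pos = c(5500, 4999),
                         consequence = "intron variant")
  sel <- select_gene_candidates(snps, genes, cfg)
  expect_equal(sel$pos, 5500)

  # 7 introns + 1 missense, cap 5 -> missense plus 4 lowest-position introns
  snps2 <- tibble::tibble(chrom = "1",
                          pos = c(11000:11006, 15000),
                          consequence = c(rep("intron variant", 7),
                                          "missense variant"))
  sel2 <- select_gene_candidates(snps2, genes, cfg)
  expect_equal(nrow(sel2), 5)
  expect_setequal(sel2$pos, c(15000, 11000:11003))

  # cap not binding
  snps3 <- tibble::tibble(chrom = "1", pos = c(12000, 13000),
                          consequence = "synonymous variant")
  expect_equal(nrow(select_gene_candidates(snps3, genes, cfg)), 2)

  # per-gene emitted count never exceeds the cap (exhaustive recount)
  withr::with_seed(31, {
    genes4 <- tibble::tibble(gene_id = paste0("g", 1:5), chrom = "1",
                             start = seq(1e4, 9e4, by = 2e4),
                             end = seq(1e4, 9e4, by = 2e4) + 8000)
    snps4 <- tibble::tibble(
      chrom = "1", pos = sample.int(1e5, 300),
      consequence = sample(names(snpanel:::CONSEQUENCE_RANK), 300,
                           replace = TRUE))
    sel4 <- select_gene_candidates(snps4, genes4, cfg)
    for (k in seq_len(nrow(genes4))) {
      inside <- sel4$pos >= genes4$start[k] - 5000 &
        sel4$pos <= genes4$end[k] + 5000
      expect_lte(sum(inside), cfg$gene_cap)
    }
    # a locus in two flanked genes appears once
    expect_false(any(duplicated(sel4[c("chrom", "pos")])))
  })
})

test_that("feed-efficiency screen combines the Fst quantile and differential floors", {
  cfg <- design_config()
  tab <- tibble::tibble(chrom = "1", pos = seq_len(100) * 10,
                        fst = seq_len(100) / 100, mean_delta_f = 0.5)
  sel <- select_rfi_candidates(tab, cfg)
  expect_equal(sort(sel$score), c(0.96, 0.97, 0.98, 0.99, 1.00))

  # high Fst but weak differential is excluded
  tab2 <- dplyr::mutate(tab, mean_delta_f = ifelse(fst == 1, 0.30, 0.5))
  sel2 <- select_rfi_candidates(tab2, cfg)
  expect_false(1.00 %in% sel2$score)

  # empty survivor set is allowed
  tab3 <- dplyr::mutate(tab, mean_delta_f = 0.1)
  expect_equal(nrow(select_rfi_candidates(tab3, cfg)), 0)

  # degenerate Fst column warns and falls back to the differential filter
  tab4 <- tibble::tibble(chrom = "1", pos = 1:10 * 5,
                         fst = 0.2, mean_delta_f = rep(c(0.5, 0.1), 5))
  expect_warning(sel4 <- select_rfi_candidates(tab4, cfg), "degenerate")
  expect_equal(nrow(sel4), 5)
})

test_that("Weir-Cockerham Fst matches an independent ANOVA oracle", {
  expect_lte(wc_fst(16, 32, 16, 32), 0)
  expect_equal(wc_fst(16, 32, 16, 32, clamp = TRUE), 0)
  expect_equal(wc_fst(32, 32, 0, 32), 1)

  withr::with_seed(77, {
    for (i in seq_len(1000)) {
      n1 <- sample(4:80, 1)
      n2 <- sample(4:80, 1)
      a1 <- sample.int(n1 + 1, 1) - 1L
      a2 <- sample.int(n2 + 1, 1) - 1L
      if ((a1 == 0 && a2 == 0) || (a1 == n1 && a2 == n2)) next
      expect_equal(wc_fst(a1, n1, a2, n2), oracle_wc_fst(a1, n1, a2, n2),
                   tolerance = 1e-12)
    }
  })
})

test_that("candidate assembly deduplicates with P1 > P2 > BACKGROUND precedence", {
  p1 <- tibble::tibble(snp_id = "a", chrom = "1", pos = 100, ref = "A",
                       alt = "G", group = "gwas", priority = "P1",
                       validated = FALSE, is_indel = FALSE, score = 0.01)
  p2 <- dplyr::mutate(p1, group = "resequencing", priority = "P2",
                      score = 0.7)
  merged <- assemble_candidates(p1, p2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$priority, "P1")
  expect_equal(merged$group, "gwas")
  expect_equal(merged$other_groups, "resequencing")

  # disjoint groups are conserved
  genome <- genome_layout("1", 1e6)
  g1 <- toy_candidates(3, genome, seed = 1)
  g2 <- dplyr::mutate(toy_candidates(4, genome, seed = 2), pos = pos + 1)
  g3 <- dplyr::mutate(toy_candidates(5, genome, seed = 3), pos = pos + 2)
  stopifnot(nrow(dplyr::distinct(dplyr::bind_rows(g1, g2, g3),
                                 chrom, pos)) == 12)
  expect_equal(nrow(assemble_candidates(g1, g2, g3)), 12)

  # randomized overlap: output size equals distinct-(chrom, pos) count
  withr::with_seed(55, {
    big <- toy_candidates(200, genome, seed = 55)
    s1 <- big[sample.int(nrow(big), 120), ]
    s2 <- big[sample.int(nrow(big), 120), ]
    merged2 <- assemble_candidates(s1, s2)
    expect_equal(nrow(merged2),
                 nrow(dplyr::distinct(dplyr::bind_rows(s1, s2), chrom, pos)))
  })

  # conflicting alleles warn, higher priority wins
  clash <- dplyr::mutate(p2, ref = "C", alt = "T")
  expect_warning(m3 <- assemble_candidates(p1, clash), "conflicting")
  expect_equal(m3$ref, "A")
})
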