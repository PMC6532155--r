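test_that("the placement criterion reproduces hand-computed scores", {
  expect_equal(sd2(0, 2, c(1, 1)), 0.5)
  expect_equal(sd2(0, 22000, c(5500, 16500)), 75625000)
  expect_equal(sd2(5, 5, 5), 0)
  expect_error(sd2(0, 100, numeric(0)), "1 or 2")
  expect_error(sd2(0, 100, 200), "within the window")
})

test_that("pair and single selection minimise the criterion with low tie-breaks", {
  # symmetric three-candidate case: tie broken to the lower pair
  expect_equal(best_pair(0, 22000, c(5500, 11000, 16500)), c(5500, 11000))
  expect_equal(sd2(0, 22000, c(5500, 11000)), 66171875)

  expect_equal(best_pair(0, 22000, c(1, 2, 21999)),
               oracle_best_pair(0, 22000, c(1, 2, 21999)))
  expect_error(best_pair(0, 22000, c(1, 2)), ">= 3")

  expect_equal(best_single(0, 22000, c(4000, 12000)), 12000)
  expect_equal(best_single(0, 22000, 700), 700)
  # equidistant around the midpoint: low position wins
  expect_equal(best_single(0, 22000, c(10000, 12000)), 10000)

  withr::with_seed(101, {
    for (i in seq_len(50)) {
      s <- sample.int(1e6, 1)
      e <- s + 22000
      k <- sample(3:50, 1)
      cand <- s + sample.int(21999, k)
      expect_identical(best_pair(s, e, cand), oracle_best_pair(s, e, cand))
      expect_identical(best_single(s, e, cand), oracle_best_single(s, e, cand))
    }
  })
})

test_that("the first pass walks windows and applies the retention rules", {
  p1 <- snpanel:::priority1_pass

  # no candidates on 100 kb: five reserved-empty windows, the last partial
  r <- p1(numeric(0), 1e5, 22000)
  expect_equal(nrow(r$selections), 0)
  expect_equal(nrow(r$windows), 5)
  expect_equal(r$windows$start, c(1, 22001, 44001, 66001, 88001))
  expect_equal(r$windows$end[5], 1e5 + 1)

  # one or two candidates are retained as-is
  r2 <- p1(c(3000, 9000), 22000, 22000)
  expect_equal(sort(r2$selections$pos), c(3000, 9000))

  # three or more: the brute-force optimal pair is retained
  cand <- c(2000, 5000, 9000, 15000, 21000)
  r3 <- p1(cand, 22000, 22000)
  expect_equal(sort(r3$selections$pos),
               sort(oracle_best_pair(1, 22001, cand)))

  # the window after a retaining window starts at the rightmost retention
  r4 <- p1(c(10000, 30000), 1e5, 22000)
  expect_equal(r4$windows$start[2], 10000)
  expect_equal(r4$selections$pos, c(10000, 30000))

  # forced (whitelisted indel) candidates are always retained
  r5 <- p1(c(2000, 5000, 9000, 15000), 22000, 22000,
           forced = c(FALSE, FALSE, FALSE, TRUE))
  expect_true(15000 %in% r5$selections$pos)
  expect_equal(nrow(r5$selections), 2)
})

test_that("fill passes touch only empty windows and respect precedence", {
  p1 <- snpanel:::priority1_pass
  p2 <- snpanel:::priority2_pass
  bg <- snpanel:::background_pass

  base <- p1(c(10000, 11000), 1e5, 22000)  # window 1 filled, rest empty
  filled <- unique(base$selections$window_index)

  # empty window containing one P2 marker receives it
  f <- p2(base$windows, filled, 30000)
  expect_equal(f$pos, 30000)

  # a filled window is skipped even when P2 candidates sit inside it
  f2 <- p2(base$windows, filled, 10500)
  expect_equal(nrow(f2), 0)

  # randomized: filled count equals empty windows intersecting >= 1 P2
  withr::with_seed(202, {
    for (rep in 1:20) {
      cand1 <- sort(sample.int(2e5, sample(0:20, 1)))
      cand2 <- sort(sample.int(2e5, sample(1:30, 1)))
      r <- p1(cand1, 2e5, 22000)
      fl <- unique(r$selections$window_index)
      got <- p2(r$windows, fl, cand2)
      empty <- r$windows[!r$windows$index %in% fl, ]
      expected <- sum(vapply(seq_len(nrow(empty)), function(k) {
        any(cand2 >= empty$start[k] & cand2 < empty$end[k])
      }, logical(1)))
      expect_equal(nrow(got), expected)
    }
  })

  # background fill prefers validated markers over midpoint proximity
  r <- p1(numeric(0), 22000, 22000)
  g <- bg(r$windows, integer(0), c(2000, 11000), validated = c(TRUE, FALSE))
  expect_equal(g$pos, 2000)
  # without a database marker the window stays empty
  g2 <- bg(r$windows, integer(0), numeric(0), logical(0))
  expect_equal(nrow(g2), 0)
})

test_that("panel design is deterministic, bounded and provenance-complete", {
  cfg <- sim_config(seed = 99,
                    n_candidates = c(gwas = 60, candidate_gene = 60, rfi = 30,
                                     resequencing = 120, snpdb = 300))
  fx <- make_design_fixture(cfg)
  cand <- assemble_candidates(fx$candidates, snpdb = fx$snpdb)
  panel <- design_panel(fx$genome, cand)

  # determinism: byte-identical manifests across runs
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_panel_manifest(panel, f1)
  write_panel_manifest(design_panel(fx$genome, cand), f2)
  expect_identical(readLines(f1), readLines(f2))

  # occupancy: never more than two markers per window
  occ <- dplyr::count(panel$entries, chrom, window_index)
  expect_lte(max(occ$n), 2)

  # membership: every entry lies inside its recorded window
  joined <- dplyr::inner_join(
    panel$entries, panel$windows,
    by = c("chrom", "window_index" = "index"))
  expect_equal(nrow(joined), nrow(panel$entries))
  expect_true(all(joined$pos >= joined$start & joined$pos < joined$end))

  # sorted, unique positions
  expect_false(any(duplicated(panel$entries[c("chrom", "pos")])))
  by_chrom <- split(panel$entries$pos, panel$entries$chrom)
  expect_true(all(vapply(by_chrom, function(p) !is.unsorted(p), logical(1))))

  # fill passes only touched empty windows
  expect_true(all(panel$windows$n_p2 + panel$windows$n_bg <= 1))
  expect_true(all(panel$windows$n_p1 == 0 |
                    (panel$windows$n_p2 + panel$windows$n_bg) == 0))
})

test_that("a regular database grid yields one marker per window and full coverage", {
  genome <- genome_layout("1", 5e5)
  # one background marker every 5 kb: every 22 kb window contains several
  snpdb <- tibble::tibble(chrom = "1", pos = seq(2500, 5e5, by = 5000),
                          ref = "A", alt = "G", validated = FALSE)
  cand <- assemble_candidates(snpdb = snpdb)
  panel <- design_panel(genome, cand)
  expect_equal(nrow(panel$entries), nrow(panel$windows))
  expect_equal(sum(panel$windows$state == "EMPTY"), 0)
  # spacing: adjacent panel markers never further apart than two windows
  expect_lte(max(diff(panel$entries$pos)), 2 * 22000)

  # exactly one database marker per disjoint window -> panel size = windows
  snpdb1 <- tibble::tibble(chrom = "1", pos = seq(11000, 5e5, by = 22000),
                           ref = "A", alt = "G", validated = FALSE)
  panel1 <- design_panel(genome, assemble_candidates(snpdb = snpdb1))
  expect_equal(nrow(panel1$entries), nrow(panel1$windows))
})
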