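#' Simulation configuration
#'
#' Parameters for the seeded generators that emulate the data a panel
#' design consumes: pooled allele frequencies diverged between breeds
#' under the Balding-Nichols model, within-breed diploid genotypes with
#' first-order linkage, uniform missingness, and candidate/background
#' marker bundles for the designer.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration, so one seed yields byte-identical outputs.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_loci Number of simulated loci (allocated to chromosomes
#'   proportionally to length).
#' @param n_breeds Number of breeds/populations.
#' @param target_fst Balding-Nichols differentiation parameter in \[0, 1).
#' @param ancestral_range Range of the uniform ancestral allele-frequency
#'   distribution.
#' @param pool_size Diploid individuals per sequenced breed pool.
#' @param samples_per_pop Genotyped individuals per population.
#' @param ld_copy_rate Probability that a haplotype allele copies its
#'   left neighbour (first-order linkage), in \[0, 1).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param n_candidates Named integer vector of marker counts per source
#'   group for [make_design_fixture()] (names among `gwas`,
#'   `candidate_gene`, `rfi`, `resequencing`, `snpdb`).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(`1` = 2e6, `2` = 1e6),
                       n_loci = 2000,
                       n_breeds = 8,
                       target_fst = 0.10,
                       ancestral_range = c(0.05, 0.95),
                       pool_size = 48,
                       samples_per_pop = 20,
                       ld_copy_rate = 0.9,
                       missing_rate = 0.02,
                       n_candidates = c(gwas = 100, candidate_gene = 100,
                                        rfi = 50, resequencing = 200,
                                        snpdb = 400)) {
  check_that(!missing(seed) && is.finite(seed), "`seed` is mandatory")
  check_that(target_fst >= 0 && target_fst < 1,
             "`target_fst` must lie in [0, 1)")
  check_that(ld_copy_rate >= 0 && ld_copy_rate < 1,
             "`ld_copy_rate` must lie in [0, 1)")
  check_that(missing_rate >= 0 && missing_rate < 1,
             "`missing_rate` must lie in [0, 1)")
  check_that(all(chrom_lengths > 0), "chromosome lengths must be positive")
  structure(
    list(seed = as.integer(seed),
         chrom_lengths = chrom_lengths,
         n_loci = as.integer(n_loci),
         n_breeds = as.integer(n_breeds),
         target_fst = target_fst,
         ancestral_range = ancestral_range,
         pool_size = as.integer(pool_size),
         samples_per_pop = as.integer(samples_per_pop),
         ld_copy_rate = ld_copy_rate,
         missing_rate = missing_rate,
         n_candidates = n_candidates),
    class = "sim_config"
  )
}

sim_genome <- function(cfg) {
  genome_layout(names(cfg$chrom_lengths), unname(cfg$chrom_lengths))
}

# unique sorted positions per chromosome, counts proportional to length
draw_loci <- function(cfg, n, prefix = "snp") {
  w <- cfg$chrom_lengths / sum(cfg$chrom_lengths)
  alloc <- diff(round(cumsum(c(0, w * n))))
  out <- purrr::map2_dfr(names(cfg$chrom_lengths), alloc, function(cn, k) {
    len <- cfg$chrom_lengths[[cn]]
    k <- min(k, len)
    tibble(chrom = cn, pos = sort(sample.int(len, k)))
  })
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, nrow(out), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  out |>
    mutate(snp_id = paste0(prefix, "_", .data$chrom, "_", .data$pos),
           ref = ref, alt = unname(alt), is_indel = FALSE) |>
    select("snp_id", "chrom", "pos", "ref", "alt", "is_indel")
}

# Balding-Nichols draw of population frequencies around ancestral p
bn_draw <- function(p, fst) {
  if (fst == 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  rbeta(length(p), a, b)
}

#' Simulate pooled allele frequencies for several breeds
#'
#' Ancestral frequencies are drawn uniformly from
#' `cfg$ancestral_range`; each breed's true frequency is a
#' Balding-Nichols Beta draw with differentiation `cfg$target_fst`; the
#' reported pool estimate adds binomial sampling noise from
#' `2 * pool_size` allele draws.
#'
#' @param cfg A [sim_config()].
#' @return A [pool_freq_table()] with breeds `B1..Bn`.
#' @export
simulate_pool_frequencies <- function(cfg) {
  check_that(inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  withr::with_seed(cfg$seed, {
    loci <- draw_loci(cfg, cfg$n_loci)
    p <- runif(nrow(loci), cfg$ancestral_range[1], cfg$ancestral_range[2])
    freq <- vapply(seq_len(cfg$n_breeds), function(b) {
      true <- bn_draw(p, cfg$target_fst)
      rbinom(length(true), 2 * cfg$pool_size, true) / (2 * cfg$pool_size)
    }, numeric(nrow(loci)))
    colnames(freq) <- paste0("B", seq_len(cfg$n_breeds))
    pool_freq_table(loci, freq,
                    setNames(rep(cfg$pool_size, cfg$n_breeds),
                             colnames(freq)))
  })
}

#' Simulate population allele frequencies (no pool noise)
#'
#' Balding-Nichols frequencies for `n_pops` populations, used as input to
#' [simulate_genotypes()].
#'
#' @param cfg A [sim_config()].
#' @param n_pops Number of populations (defaults to `cfg$n_breeds`).
#' @return A list with `loci` (tibble) and `freq` (loci x populations
#'   matrix, columns `P1..Pn`).
#' @export
simulate_population_frequencies <- function(cfg, n_pops = cfg$n_breeds) {
  check_that(inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  withr::with_seed(cfg$seed, {
    loci <- draw_loci(cfg, cfg$n_loci)
    p <- runif(nrow(loci), cfg$ancestral_range[1], cfg$ancestral_range[2])
    freq <- vapply(seq_len(n_pops), function(b) bn_draw(p, cfg$target_fst),
                   numeric(nrow(loci)))
    colnames(freq) <- paste0("P", seq_len(n_pops))
    list(loci = loci, freq = freq)
  })
}

#' Simulate diploid genotypes with first-order linkage
#'
#' Per population, haplotypes are built chromosome by chromosome from
#' left to right: the first allele is Bernoulli in the population
#' frequency; each subsequent allele copies the previous allele of the
#' same haplotype with probability `ld_copy_rate` and is drawn fresh
#' otherwise. Two haplotypes are summed to a dosage and calls are masked
#' at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @param pop_freqs Output of [simulate_population_frequencies()] (or a
#'   list with `loci` and `freq` of the same shape).
#' @return A [geno_matrix()] with `samples_per_pop` samples per
#'   population, labelled by the frequency matrix column names.
#' @export
simulate_genotypes <- function(cfg, pop_freqs = simulate_population_frequencies(cfg)) {
  check_that(inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  loci <- pop_freqs$loci
  freq <- pop_freqs$freq
  withr::with_seed(cfg$seed + 1L, {
    blocks <- split(seq_len(nrow(loci)), chrom_factor(loci$chrom))
    n <- cfg$samples_per_pop
    pops <- colnames(freq)
    geno <- do.call(rbind, lapply(pops, function(pp) {
      f <- freq[, pp]
      hap <- function() {
        h <- matrix(0L, n, nrow(loci))
        for (idx in blocks) {
          ord <- idx[order(loci$pos[idx])]
          h[, ord[1]] <- rbinom(n, 1, f[ord[1]])
          for (j in seq_along(ord)[-1]) {
            copy <- runif(n) < cfg$ld_copy_rate
            fresh <- rbinom(n, 1, f[ord[j]])
            h[, ord[j]] <- ifelse(copy, h[, ord[j - 1]], fresh)
          }
        }
        h
      }
      hap() + hap()
    }))
    if (cfg$missing_rate > 0) {
      geno[runif(length(geno)) < cfg$missing_rate] <- NA_integer_
    }
    rownames(geno) <- paste0(rep(pops, each = n), "_", seq_len(n))
    colnames(geno) <- loci$snp_id
    geno_matrix(geno,
                samples = tibble(sample_id = rownames(geno),
                                 population = rep(pops, each = n)),
                loci = loci)
  })
}

#' Generate a complete design input bundle
#'
#' Emits an internally consistent set of design inputs: a genome layout,
#' candidate markers for the four selection groups (unique positions,
#' group sizes as configured) and a background database table with
#' assay-validated flags. When `dir` is given, the bundle is also written
#' as `genome.tsv`, `candidates.tsv` and `snpdb.tsv`.
#'
#' @param cfg A [sim_config()]; `cfg$n_candidates` sets the group sizes.
#' @param dir Optional output directory.
#' @return A list with `genome`, `candidates` (groups 1-4, a candidate
#'   tibble), `snpdb` (background tibble) and, if written, `paths`.
#' @export
make_design_fixture <- function(cfg, dir = NULL) {
  check_that(inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  nc <- cfg$n_candidates
  n_total <- sum(nc)
  check_that(n_total <= sum(cfg$chrom_lengths),
             "requested candidate density exceeds genome capacity")
  bundle <- withr::with_seed(cfg$seed + 2L, {
    loci <- draw_loci(cfg, n_total, prefix = "cand")
    loci <- loci[sample.int(nrow(loci)), ]
    grp <- rep(names(nc), times = nc)[seq_len(nrow(loci))]
    loci$group <- grp
    loci$priority <- group_priority(loci$group)
    loci$validated <- loci$group == "snpdb" & runif(nrow(loci)) < 0.5
    loci$score <- stats::runif(nrow(loci))
    cand <- loci |>
      filter(.data$group != "snpdb") |>
      arrange(.data$chrom, .data$pos) |>
      select("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
             "validated", "is_indel", "score")
    snpdb <- loci |>
      filter(.data$group == "snpdb") |>
      arrange(.data$chrom, .data$pos) |>
      select("snp_id", "chrom", "pos", "ref", "alt", "validated")
    list(genome = sim_genome(cfg), candidates = cand, snpdb = snpdb)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.tsv"),
               candidates = file.path(dir, "candidates.tsv"),
               snpdb = file.path(dir, "snpdb.tsv"))
    readr::write_tsv(bundle$genome, paths[["genome"]])
    write_candidate_table(bundle$candidates, paths[["candidates"]])
    readr::write_tsv(bundle$snpdb, paths[["snpdb"]])
    bundle$paths <- paths
  }
  bundle
}
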