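#' Marker call rate
#'
#' @param g Genotype column (dosages with `NA` for missing).
#' @return Fraction of non-missing calls.
#' @export
snp_call_rate <- function(g) {
  check_that(length(g) >= 1, "call rate needs at least one sample")
  mean(!is.na(g))
}

#' Minor allele frequency of a genotype column
#'
#' Alternate-allele frequency over called genotypes, folded to \[0, 0.5\].
#'
#' @param g Genotype column (dosages 0/1/2 with `NA` for missing).
#' @return The MAF.
#' @export
genotype_maf <- function(g) {
  g <- g[!is.na(g)]
  check_that(length(g) >= 1, "all genotypes missing")
  minor_allele_frequency(mean(g) / 2)
}

#' Exact Hardy-Weinberg test
#'
#' The standard exact conditional test for a biallelic marker: given the
#' total sample size and minor-allele count, the p-value sums the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count (no mid-p correction).
#' Monomorphic markers return 1 by convention.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major homozygote, heterozygote,
#'   minor homozygote in any order; the test is symmetric under allele
#'   relabelling).
#' @return p-value in (0, 1\].
#' @examples
#' hwe_exact_p(1, 0, 1)  # 1/3
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  check_that(all(c(n_aa, n_ab, n_bb) >= 0), "genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  check_that(n >= 1, "at least one genotype required")
  n_minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (n_minor == 0) return(1)
  # attainable heterozygote counts share the parity of the minor count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma(n - (n_minor + hets) / 2 + 1) +
    hets * log(2) +
    lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  check_that(!is.na(p_obs), "heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Genotype quality control
#'
#' Removes samples whose missing fraction exceeds
#' `qc$sample_missing_max`, then (on the retained cohort) markers failing
#' call rate, MAF, or the exact Hardy-Weinberg test in that order of
#' reason precedence. When population labels are present the HWE test is
#' run within each population and the smallest p-value is compared to the
#' threshold, so that population structure is not mistaken for typing
#' error.
#'
#' @param gm A [geno_matrix()].
#' @param qc A [qc_config()].
#' @return A list of class `qc_result`: `genotypes` (the filtered
#'   [geno_matrix()]), `samples` (per-sample missing rate and removal
#'   reason), `snps` (per-marker call rate, MAF, HWE p and removal
#'   reason).
#' @export
qc_filter <- function(gm, qc = qc_config()) {
  check_that(inherits(gm, "geno_matrix"), "`gm` must be a geno_matrix")
  miss <- unname(rowMeans(is.na(gm$geno)))
  samples <- gm$samples |>
    mutate(missing_rate = miss,
           removed = miss > qc$sample_missing_max,
           reason = ifelse(.data$removed, "sample_missing", NA_character_))
  keep_s <- !samples$removed
  geno <- gm$geno[keep_s, , drop = FALSE]
  pops <- gm$samples$population[keep_s]

  if (nrow(geno) == 0) {
    cr <- maf <- hwe <- rep(NA_real_, ncol(geno))
  } else {
    cr <- colMeans(!is.na(geno))
    maf <- apply(geno, 2, function(g) {
      if (all(is.na(g))) NA_real_ else genotype_maf(g)
    })
    hwe_groups <- if (all(is.na(pops))) list(seq_len(nrow(geno)))
                  else split(seq_len(nrow(geno)), pops)
    hwe <- apply(geno, 2, function(g) {
      ps <- vapply(hwe_groups, function(idx) {
        gg <- g[idx]
        gg <- gg[!is.na(gg)]
        if (length(gg) == 0) return(NA_real_)
        hwe_exact_p(sum(gg == 0), sum(gg == 1), sum(gg == 2))
      }, numeric(1))
      if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
    })
  }
  snps <- gm$loci |>
    mutate(call_rate = unname(cr), maf = unname(maf), hwe_p = unname(hwe),
           reason = dplyr::case_when(
             is.na(cr) | cr < qc$snp_call_rate_min ~ "call_rate",
             is.na(maf) | maf < qc$maf_min ~ "maf",
             !is.na(hwe) & hwe < qc$hwe_p_min ~ "hwe",
             .default = NA_character_),
           removed = !is.na(.data$reason))
  keep_m <- !snps$removed
  out <- geno_matrix(geno[, keep_m, drop = FALSE],
                     samples = gm$samples[keep_s, , drop = FALSE],
                     loci = gm$loci[keep_m, , drop = FALSE])
  structure(list(genotypes = out, samples = samples, snps = snps),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> kept %d/%d samples, %d/%d markers\n",
              sum(!x$samples$removed), nrow(x$samples),
              sum(!x$snps$removed), nrow(x$snps)))
  if (any(x$snps$removed)) {
    print(dplyr::count(filter(x$snps, .data$removed), .data$reason))
  }
  invisible(x)
}

#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) x$snps

#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) {
  tibble(n_samples_in = nrow(x$samples),
         n_samples_kept = sum(!x$samples$removed),
         n_snps_in = nrow(x$snps),
         n_snps_kept = sum(!x$snps$removed),
         n_removed_call_rate = sum(x$snps$reason %in% "call_rate"),
         n_removed_maf = sum(x$snps$reason %in% "maf"),
         n_removed_hwe = sum(x$snps$reason %in% "hwe"))
}

#' Per-population polymorphism summary
#'
#' For each population: the mean per-marker call rate (as a percentage),
#' the number of markers with MAF strictly above `maf_cutoff`, and the
#' mean MAF across all markers (not only the polymorphic ones).
#'
#' @param gm A [geno_matrix()] with population labels.
#' @param maf_cutoff Polymorphism cutoff (strict inequality).
#' @return A tibble with one row per population.
#' @export
polymorphism_summary <- function(gm, maf_cutoff = 0.05) {
  check_that(inherits(gm, "geno_matrix"), "`gm` must be a geno_matrix")
  pops <- unique(gm$samples$population)
  check_that(!all(is.na(pops)), "population labels required")
  purrr::map_dfr(pops, function(pp) {
    idx <- which(gm$samples$population %in% pp)
    check_that(length(idx) > 0, "population with zero samples: %s", pp)
    sub <- gm$geno[idx, , drop = FALSE]
    cr <- colMeans(!is.na(sub))
    maf <- apply(sub, 2, function(g) {
      if (all(is.na(g))) NA_real_ else genotype_maf(g)
    })
    tibble(population = pp,
           n_samples = length(idx),
           avg_call_rate_pct = round_half_up(100 * mean(cr), 2),
           n_polymorphic = sum(maf > maf_cutoff, na.rm = TRUE),
           mean_maf = round_half_up(mean(maf, na.rm = TRUE), 3))
  })
}
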