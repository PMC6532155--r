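#' Genome layout
#'
#' An ordered table of chromosome names and lengths. The order given here is
#' the canonical chromosome order used for window partitioning, manifest
#' sorting and reporting.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in base pairs (> 0).
#'
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("1", "2", "Z"), c(2e6, 1e6, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  check_that(length(chrom) == base::length(length),
             "`chrom` and `length` must have equal length")
  check_that(!anyDuplicated(chrom), "chromosome names must be unique")
  check_that(all(is.finite(length) & length > 0),
             "chromosome lengths must be positive")
  tibble(chrom = chrom, length = length)
}

#' Panel design configuration
#'
#' Collects every tunable of the design procedure. Defaults are the values
#' used for the chicken 55K array: 22 kb windows, allele-frequency
#' differential thresholds of 0.609 (local breeds) and 0.731 (commercial
#' lines), a 0.05 MAF floor, the top 1% of association p-values, 5 kb gene
#' flanks with at most 5 markers per gene, and a top-5% Fst screen with a
#' mean differential floor of 0.35 for the feed-efficiency group.
#'
#' @param window_length Window length in bp used to partition chromosomes.
#' @param delta_f_threshold_local,delta_f_threshold_commercial Minimum
#'   allele-frequency differential for resequencing candidates from local
#'   breeds and commercial lines respectively.
#' @param delta_f_mode `"signed"` computes the signed difference of folded
#'   MAFs (range \[-0.5, 0.5\]); `"absolute"` computes the absolute
#'   difference of unfolded alternate-allele frequencies (range \[0, 1\]),
#'   the only scale on which thresholds above 0.5 can select anything.
#' @param maf_min Minimum minor allele frequency for a resequencing
#'   candidate in its focal breed.
#' @param gwas_top_fraction Fraction of smallest association p-values kept
#'   per trait.
#' @param gene_flank Flank in bp added to either side of a gene interval.
#' @param gene_cap Maximum candidates emitted per gene.
#' @param rfi_fst_quantile Empirical Fst quantile below which
#'   feed-efficiency candidates are dropped.
#' @param rfi_delta_f_min Minimum mean allele-frequency differential for
#'   feed-efficiency candidates.
#' @param qc Quality-control thresholds, see [qc_config()].
#' @param random_seed Seed recorded with the design for reproducibility.
#'
#' @return A list of class `design_config`.
#' @export
design_config <- function(window_length = 22000,
                          delta_f_threshold_local = 0.609,
                          delta_f_threshold_commercial = 0.731,
                          delta_f_mode = c("signed", "absolute"),
                          maf_min = 0.05,
                          gwas_top_fraction = 0.01,
                          gene_flank = 5000,
                          gene_cap = 5L,
                          rfi_fst_quantile = 0.95,
                          rfi_delta_f_min = 0.35,
                          qc = qc_config(),
                          random_seed = 1L) {
  delta_f_mode <- match.arg(delta_f_mode)
  check_that(window_length > 0, "`window_length` must be > 0")
  check_prob(maf_min, "maf_min")
  check_prob(gwas_top_fraction, "gwas_top_fraction")
  check_that(gwas_top_fraction > 0, "`gwas_top_fraction` must be > 0")
  check_prob(rfi_fst_quantile, "rfi_fst_quantile")
  check_that(gene_flank >= 0, "`gene_flank` must be >= 0")
  check_that(gene_cap >= 1, "`gene_cap` must be >= 1")
  check_that(rfi_delta_f_min >= 0, "`rfi_delta_f_min` must be >= 0")
  structure(
    list(window_length = as.numeric(window_length),
         delta_f_threshold_local = delta_f_threshold_local,
         delta_f_threshold_commercial = delta_f_threshold_commercial,
         delta_f_mode = delta_f_mode,
         maf_min = maf_min,
         gwas_top_fraction = gwas_top_fraction,
         gene_flank = as.numeric(gene_flank),
         gene_cap = as.integer(gene_cap),
         rfi_fst_quantile = rfi_fst_quantile,
         rfi_delta_f_min = rfi_delta_f_min,
         qc = qc,
         random_seed = as.integer(random_seed)),
    class = "design_config"
  )
}

#' Genotype quality-control thresholds
#'
#' @param snp_call_rate_min Markers with a call rate below this are removed.
#' @param maf_min Markers with a minor allele frequency below this are
#'   removed.
#' @param hwe_p_min Markers with an exact Hardy-Weinberg p-value below this
#'   are removed (typing-error screen).
#' @param sample_missing_max Samples with a missing fraction above this are
#'   removed.
#'
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(snp_call_rate_min = 0.95,
                      maf_min = 0.05,
                      hwe_p_min = 0.001,
                      sample_missing_max = 0.10) {
  for (nm in c("snp_call_rate_min", "maf_min", "hwe_p_min",
               "sample_missing_max")) {
    check_prob(get(nm), nm)
  }
  structure(
    list(snp_call_rate_min = snp_call_rate_min,
         maf_min = maf_min,
         hwe_p_min = hwe_p_min,
         sample_missing_max = sample_missing_max),
    class = "qc_config"
  )
}

#' Breed roles for the resequencing screen
#'
#' Local breeds are screened against a commercial control line and
#' commercial lines against a reference local breed, mirroring the
#' reciprocal differential design used for the chicken array (local breeds
#' versus the Cobb paternal line; commercial lines versus Beijing-You).
#'
#' @param local_breeds,commercial_breeds Character vectors of breed names.
#' @param control_for_local Control breed used for local-breed differentials
#'   (a commercial line).
#' @param control_for_commercial Control breed used for commercial-line
#'   differentials (a local breed).
#'
#' @return A list of class `breed_roles`.
#' @export
breed_roles <- function(local_breeds, commercial_breeds,
                        control_for_local, control_for_commercial) {
  check_that(length(control_for_local) == 1 &&
               length(control_for_commercial) == 1,
             "controls must be single breed names")
  check_that(!control_for_local %in% local_breeds,
             "`control_for_local` cannot be one of `local_breeds`")
  check_that(!control_for_commercial %in% commercial_breeds,
             "`control_for_commercial` cannot be one of `commercial_breeds`")
  structure(
    list(local_breeds = as.character(local_breeds),
         commercial_breeds = as.character(commercial_breeds),
         control_for_local = as.character(control_for_local),
         control_for_commercial = as.character(control_for_commercial)),
    class = "breed_roles"
  )
}
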