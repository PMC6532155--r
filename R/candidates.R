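#' Minor allele frequency
#'
#' Folds an alternate-allele frequency onto \[0, 0.5\].
#'
#' @param f Numeric vector of allele frequencies in \[0, 1\].
#' @return `pmin(f, 1 - f)`.
#' @examples
#' minor_allele_frequency(c(0.9, 0.5, 0.05))
#' @export
minor_allele_frequency <- function(f) {
  check_prob(f[!is.na(f)], "f")
  pmin(f, 1 - f)
}

#' Allele-frequency differential between a breed and its control
#'
#' The signed difference of folded minor allele frequencies; antisymmetric
#' under swapping its arguments, with magnitude at most 0.5.
#'
#' @param maf_breed,maf_control Minor allele frequencies in \[0, 0.5\].
#' @return `maf_breed - maf_control`.
#' @export
delta_f <- function(maf_breed, maf_control) {
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 0.5))
  check_that(ok(maf_breed) && ok(maf_control),
             "MAF inputs must lie in [0, 0.5]")
  maf_breed - maf_control
}

#' Select resequencing candidates by frequency differential
#'
#' Implements the first candidate group: per focal breed, keep loci with a
#' minor allele frequency of at least `maf_min` whose differential against
#' the role-specific control breed meets the role's threshold (local or
#' commercial). Chromosome-W loci are removed. Indels are dropped unless
#' whitelisted, in which case they are emitted with priority `P1`; all
#' other survivors carry group `resequencing`, priority `P2`. A locus
#' passing in several breeds is emitted once with the largest differential
#' as its score.
#'
#' @param freqs A [pool_freq_table()].
#' @param roles A [breed_roles()]; all breeds must be columns of `freqs`.
#' @param config A [design_config()]; uses `maf_min`,
#'   `delta_f_threshold_local`, `delta_f_threshold_commercial` and
#'   `delta_f_mode`.
#' @param indel_whitelist Character vector of `snp_id`s of special-interest
#'   indels to force through with priority `P1`.
#'
#' @return A candidate tibble (see [read_candidate_table()]).
#' @export
select_resequencing_candidates <- function(freqs, roles, config,
                                           indel_whitelist = character()) {
  check_that(inherits(freqs, "pool_freq_table"),
             "`freqs` must be a pool_freq_table")
  check_that(nrow(freqs$loci) > 0, "empty frequency table")
  breeds <- colnames(freqs$freq)
  need <- c(roles$local_breeds, roles$commercial_breeds,
            roles$control_for_local, roles$control_for_commercial)
  miss <- setdiff(need, breeds)
  check_that(length(miss) == 0, "breed(s) missing from frequency table: %s",
             paste(miss, collapse = ", "))

  score_role <- function(focal, control, threshold) {
    f_b <- freqs$freq[, focal]
    f_c <- freqs$freq[, control]
    maf_b <- minor_allele_frequency(f_b)
    df <- if (config$delta_f_mode == "signed") {
      delta_f(maf_b, minor_allele_frequency(f_c))
    } else {
      abs(f_b - f_c)
    }
    pass <- !is.na(df) & !is.na(maf_b) & maf_b >= config$maf_min &
      df >= threshold
    ifelse(pass, df, NA_real_)
  }

  score_mat <- cbind(
    vapply(roles$local_breeds, score_role,
           numeric(nrow(freqs$loci)),
           control = roles$control_for_local,
           threshold = config$delta_f_threshold_local),
    vapply(roles$commercial_breeds, score_role,
           numeric(nrow(freqs$loci)),
           control = roles$control_for_commercial,
           threshold = config$delta_f_threshold_commercial)
  )
  best <- suppressWarnings(apply(score_mat, 1, max, na.rm = TRUE))
  keep <- is.finite(best)

  loci <- freqs$loci
  keep <- keep & loci$chrom != "W"
  whitelisted <- loci$is_indel & loci$snp_id %in% indel_whitelist
  keep <- (keep & !loci$is_indel) | whitelisted

  out <- loci[keep, , drop = FALSE]
  tibble(snp_id = out$snp_id, chrom = out$chrom, pos = out$pos,
         ref = out$ref, alt = out$alt,
         group = "resequencing",
         priority = ifelse(out$is_indel, "P1", "P2"),
         validated = FALSE,
         is_indel = out$is_indel,
         score = best[keep])
}

#' Select association candidates by top p-value fraction
#'
#' Per trait, the `ceiling(top_fraction * n)` markers with the smallest
#' p-values are taken; the union over traits is deduplicated by locus.
#' Survivors carry group `gwas`, priority `P1`, and their smallest p-value
#' as score.
#'
#' @param assoc Tibble with columns `chrom`, `pos`, `trait`, `p` and
#'   optionally `snp_id`, `ref`, `alt`.
#' @param top_fraction Fraction in (0, 1\] of smallest p-values kept per
#'   trait.
#' @return A candidate tibble.
#' @export
select_gwas_candidates <- function(assoc, top_fraction = 0.01) {
  check_that(nrow(assoc) > 0, "empty association table")
  check_that(top_fraction > 0 && top_fraction <= 1,
             "`top_fraction` must be in (0, 1]")
  check_that(all(assoc$p > 0 & assoc$p <= 1), "p-values must lie in (0, 1]")
  assoc <- as_tibble(assoc)
  if (!"snp_id" %in% names(assoc)) {
    assoc$snp_id <- paste0(assoc$chrom, ":", assoc$pos)
  }
  if (!"ref" %in% names(assoc)) assoc$ref <- NA_character_
  if (!"alt" %in% names(assoc)) assoc$alt <- NA_character_
  assoc |>
    group_by(.data$trait) |>
    arrange(.data$p, .data$chrom, .data$pos, .by_group = TRUE) |>
    filter(row_number() <= ceiling(top_fraction * dplyr::n())) |>
    ungroup() |>
    group_by(.data$chrom, .data$pos) |>
    summarise(snp_id = first(.data$snp_id), ref = first(.data$ref),
              alt = first(.data$alt), score = min(.data$p),
              .groups = "drop") |>
    mutate(group = "gwas", priority = "P1", validated = FALSE,
           is_indel = FALSE) |>
    select("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
           "validated", "is_indel", "score")
}

# consequence classes ranked for gene-based capping; smaller = kept first
CONSEQUENCE_RANK <- c(
  "missense variant" = 1, "missense variant & splice region variant" = 1,
  "Splicing" = 2, "splicing" = 2,
  "start/stop gained/lost/retained" = 3,
  "3 prime UTR variant" = 4, "5 prime UTR variant" = 4,
  "synonymous variant" = 5,
  "upstream gene variant (1 kb)" = 6, "downstream gene variant (1 kb)" = 6,
  "intron variant" = 7, "intron variant & noncoding transcript variant" = 7,
  "intergenic variant" = 8, "noncoding transcript exon variant" = 8,
  "unannotated" = 9
)

consequence_rank <- function(class) {
  r <- unname(CONSEQUENCE_RANK[class])
  ifelse(is.na(r), 9, r)
}

#' Select gene-based candidates with consequence-ranked capping
#'
#' Restricts loci to gene intervals extended by `gene_flank` on either
#' side, ranks them within each gene by predicted consequence severity
#' (missense/splice-region first, then splicing, start/stop changes, UTRs,
#' synonymous, 1 kb up/downstream, introns, everything else), and keeps at
#' most `gene_cap` per gene, breaking ties by ascending position. A locus
#' inside two flanked genes competes in both and is deduplicated on
#' emission. Survivors carry group `candidate_gene`, priority `P1`.
#'
#' @param snps Tibble with columns `chrom`, `pos`, `consequence` and
#'   optionally `snp_id`, `ref`, `alt`.
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param config A [design_config()]; uses `gene_flank` and `gene_cap`.
#' @return A candidate tibble.
#' @export
select_gene_candidates <- function(snps, genes, config = design_config()) {
  snps <- as_tibble(snps)
  genes <- as_tibble(genes)
  check_that(all(genes$start <= genes$end), "gene intervals need start <= end")
  if (!"snp_id" %in% names(snps)) {
    snps$snp_id <- paste0(snps$chrom, ":", snps$pos)
  }
  if (!"ref" %in% names(snps)) snps$ref <- NA_character_
  if (!"alt" %in% names(snps)) snps$alt <- NA_character_
  flanked <- genes |>
    mutate(lo = pmax(1, .data$start - config$gene_flank),
           hi = .data$end + config$gene_flank) |>
    select("gene_id", "chrom", "lo", "hi")
  inner_join(snps, flanked, by = join_by("chrom", between("pos", "lo", "hi"))) |>
    mutate(rank = consequence_rank(.data$consequence)) |>
    group_by(.data$gene_id) |>
    arrange(.data$rank, .data$pos, .by_group = TRUE) |>
    slice_head(n = config$gene_cap) |>
    ungroup() |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(group = "candidate_gene", priority = "P1", validated = FALSE,
           is_indel = FALSE, score = NA_real_) |>
    select("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
           "validated", "is_indel", "score")
}

#' Select feed-efficiency (RFI) candidates
#'
#' Keeps loci whose Fst reaches the `rfi_fst_quantile` empirical quantile
#' of the input Fst distribution (the top tail) and whose mean
#' allele-frequency differential between divergent lines is at least
#' `rfi_delta_f_min`. Survivors carry group `rfi`, priority `P1`, and
#' their Fst as score.
#'
#' @param stats Tibble with columns `chrom`, `pos`, `fst`, `mean_delta_f`
#'   and optionally `snp_id`, `ref`, `alt`.
#' @param config A [design_config()].
#' @return A candidate tibble.
#' @export
select_rfi_candidates <- function(stats, config = design_config()) {
  check_that(nrow(stats) > 0, "empty RFI statistics table")
  stats <- as_tibble(stats)
  check_that(all(is.finite(stats$fst)), "fst values must be finite")
  check_that(all(stats$mean_delta_f >= 0), "mean_delta_f must be >= 0")
  if (!"snp_id" %in% names(stats)) {
    stats$snp_id <- paste0(stats$chrom, ":", stats$pos)
  }
  if (!"ref" %in% names(stats)) stats$ref <- NA_character_
  if (!"alt" %in% names(stats)) stats$alt <- NA_character_
  q <- quantile(stats$fst, probs = config$rfi_fst_quantile, names = FALSE)
  if (length(unique(stats$fst)) == 1L) {
    warn("all Fst values identical; quantile filter degenerate, applying the frequency-differential filter only")
    keep <- stats$mean_delta_f >= config$rfi_delta_f_min
  } else {
    keep <- stats$fst >= q & stats$mean_delta_f >= config$rfi_delta_f_min
  }
  stats[keep, , drop = FALSE] |>
    mutate(group = "rfi", priority = "P1", validated = FALSE,
           is_indel = FALSE, score = .data$fst) |>
    select("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
           "validated", "is_indel", "score")
}

#' Assemble the unified candidate set
#'
#' Concatenates candidate tibbles from the group selectors plus background
#' database loci and deduplicates by (chrom, pos) with precedence
#' P1 > P2 > BACKGROUND; at equal priority the earlier input wins. The
#' winning record's group is retained and the other groups seen at that
#' locus are recorded in `other_groups`. Conflicting alleles at one
#' position raise a warning; the higher-precedence record wins.
#'
#' @param ... Candidate tibbles, in precedence order within equal priority.
#' @param snpdb Optional tibble of background loci (`chrom`, `pos`, `ref`,
#'   `alt`, `validated`, optionally `snp_id`); assigned group `snpdb`,
#'   priority `BACKGROUND`.
#' @return A candidate tibble with an extra `other_groups` column.
#' @export
assemble_candidates <- function(..., snpdb = NULL) {
  parts <- list(...)
  if (!is.null(snpdb)) {
    snpdb <- as_tibble(snpdb)
    if (!"snp_id" %in% names(snpdb)) {
      snpdb$snp_id <- paste0(snpdb$chrom, ":", snpdb$pos)
    }
    if (!"validated" %in% names(snpdb)) snpdb$validated <- FALSE
    snpdb <- snpdb |>
      mutate(group = "snpdb", priority = "BACKGROUND", is_indel = FALSE,
             score = NA_real_) |>
      select("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
             "validated", "is_indel", "score")
    parts <- c(parts, list(snpdb))
  }
  all <- bind_rows(parts)
  if (nrow(all) == 0) return(mutate(all, other_groups = character()))
  all <- all |>
    mutate(.prec = match(.data$priority, PRIORITY_LEVELS),
           .in_order = row_number()) |>
    arrange(.data$chrom, .data$pos, .data$.prec, .data$.in_order)
  dup_alleles <- all |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_allele = dplyr::n_distinct(paste(.data$ref, .data$alt)),
              .groups = "drop")
  if (any(dup_alleles$n_allele > 1)) {
    warn(sprintf("%d position(s) with conflicting alleles; keeping the higher-priority record",
                 sum(dup_alleles$n_allele > 1)))
  }
  all |>
    group_by(.data$chrom, .data$pos) |>
    summarise(snp_id = first(.data$snp_id), ref = first(.data$ref),
              alt = first(.data$alt),
              other_groups = paste(unique(.data$group[-1]), collapse = ","),
              group = first(.data$group),
              priority = first(.data$priority),
              validated = any(.data$validated),
              is_indel = first(.data$is_indel), score = first(.data$score),
              .groups = "drop") |>
    arrange(.data$chrom, .data$pos) |>
    select("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
           "validated", "is_indel", "score", "other_groups")
}
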