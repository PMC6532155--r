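#' Published summary counts of the chicken 55K array
#'
#' Loads the published summary tables of the chicken 55K genotyping array
#' shipped with the package as plain-text TSVs: per-chromosome marker
#' counts with mean adjacent distances, marker counts per candidate source
#' group, counts per predicted consequence class, and position overlaps
#' with the two pre-existing chicken arrays (600K and 60K). These serve as
#' reference inputs for the report arithmetic and worked examples.
#'
#' The candidate sub-counts of the feed-efficiency group (3740 markers
#' from the local-breed contrast and 580 from the commercial-line
#' contrast) are included under `rfi_candidates`.
#'
#' @return A list of tibbles: `chromosomes`, `groups`, `consequences`,
#'   `overlaps`, `rfi_candidates`.
#' @examples
#' ref <- chicken55k_summary_tables()
#' sum(ref$chromosomes$n_snps)
#' @export
chicken55k_summary_tables <- function() {
  rd <- function(name, ...) {
    readr::read_tsv(system.file("extdata", name, package = "snpanel",
                                mustWork = TRUE),
                    show_col_types = FALSE, ...)
  }
  list(
    chromosomes = rd("chicken55k_chromosomes.tsv",
                     col_types = readr::cols(chrom = readr::col_character())),
    groups = rd("chicken55k_groups.tsv"),
    consequences = rd("chicken55k_consequences.tsv"),
    overlaps = rd("chicken55k_overlaps.tsv"),
    rfi_candidates = tibble(contrast = c("local", "commercial"),
                            n_candidates = c(3740L, 580L))
  )
}

#' Expand summary counts into a synthetic manifest
#'
#' Builds a synthetic panel manifest whose per-chromosome (or per-group,
#' or per-consequence-class) counts equal a table of published counts, so
#' that the report operations can be exercised against printed summary
#' tables. Positions are placeholders (1, 2, ...) and carry no meaning
#' beyond uniqueness.
#'
#' @param counts Tibble with a label column and a count column `n`.
#' @param label Name of the label column; becomes the corresponding
#'   manifest column.
#' @return A manifest-like tibble with one row per marker.
#' @export
expand_counts <- function(counts, label) {
  counts <- as_tibble(counts)
  check_that(all(c(label, "n") %in% names(counts)),
             "`counts` needs columns '%s' and 'n'", label)
  out <- tibble(!!label := rep(counts[[label]], counts$n))
  n <- nrow(out)
  if (label != "chrom") out$chrom <- "1"
  out$pos <- seq_len(n)
  out$snp_id <- paste0(out$chrom, ":", out$pos)
  out
}
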