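panel_entries <- function(panel) {
  if (inherits(panel, "snp_panel")) panel$entries else as_tibble(panel)
}

panel_genome <- function(panel) {
  if (inherits(panel, "snp_panel")) panel$genome else NULL
}

#' Per-chromosome marker counts and mean adjacent distance
#'
#' The mean distance is the average of successive position differences on
#' each chromosome, reported in kb to two decimals (half-up); chromosomes
#' with fewer than two markers report `NA`.
#'
#' @param panel A `snp_panel` or manifest tibble with `chrom`, `pos`.
#' @return A tibble with columns `chrom`, `n_snps`, `mean_distance_kbp`.
#' @export
per_chromosome_summary <- function(panel) {
  entries <- panel_entries(panel)
  entries |>
    mutate(chrom = chrom_factor(.data$chrom, panel_genome(panel))) |>
    group_by(.data$chrom) |>
    summarise(
      n_snps = dplyr::n(),
      mean_distance_kbp = if (dplyr::n() >= 2) {
        round_half_up(mean(diff(sort(.data$pos))) / 1000, 2)
      } else NA_real_,
      .groups = "drop") |>
    mutate(chrom = as.character(.data$chrom))
}

#' Panel composition by source group and priority
#'
#' @param panel A `snp_panel` or manifest tibble with `group`, `priority`.
#' @return A tibble with one row per (group, priority) and counts; the
#'   counts sum to the panel size.
#' @export
group_composition <- function(panel) {
  entries <- panel_entries(panel)
  if (nrow(entries) == 0) {
    return(tibble(group = character(), priority = character(),
                  n_snps = integer()))
  }
  entries |>
    dplyr::count(.data$group, .data$priority, name = "n_snps") |>
    arrange(match(.data$group, CANDIDATE_GROUPS))
}

#' Consequence-annotation summary of a panel
#'
#' Joins the panel with a (chrom, pos) -> consequence-class table and
#' tabulates class counts with percentages of the panel total, rounded
#' half-up to two decimals. Loci absent from the annotation table count as
#' `"unannotated"`; the annotatable total (panel size minus unannotated)
#' and its percentage are attached as attributes `annotatable_n` /
#' `annotatable_pct` alongside `total`.
#'
#' @param panel A `snp_panel` or manifest tibble.
#' @param annotations Tibble with columns `chrom`, `pos`, `consequence`.
#' @return A tibble `consequence`, `n`, `pct` (descending by count), with
#'   summary attributes as described.
#' @export
annotation_summary <- function(panel, annotations) {
  entries <- panel_entries(panel)
  total <- nrow(entries)
  ann <- entries |>
    left_join(select(as_tibble(annotations), "chrom", "pos", "consequence"),
              by = c("chrom", "pos")) |>
    mutate(consequence = dplyr::coalesce(.data$consequence, "unannotated"))
  out <- ann |>
    dplyr::count(.data$consequence) |>
    mutate(pct = if (total > 0) round_half_up(100 * .data$n / total, 2) else 0) |>
    arrange(dplyr::desc(.data$n), .data$consequence)
  n_unann <- sum(ann$consequence == "unannotated")
  attr(out, "total") <- total
  attr(out, "annotatable_n") <- total - n_unann
  attr(out, "annotatable_pct") <-
    if (total > 0) round_half_up(100 * (total - n_unann) / total, 2) else 0
  out
}

#' Overlap of marker panels by exact position
#'
#' Compares two or three panels by exact (chrom, pos) identity and reports
#' every Venn region plus pairwise overlaps. Duplicate positions within a
#' panel are collapsed with a warning. The pairwise percentage is
#' `100 * |A intersect B| / |A|` (of the first-named panel of the pair),
#' rounded half-up to an integer.
#'
#' @param ... Two or three named panels (`snp_panel` objects or tibbles
#'   with `chrom`, `pos`).
#' @return A list of class `overlap_summary` with tibbles `regions`
#'   (Venn-region membership pattern and count) and `pairwise`
#'   (`panel_a`, `panel_b`, `n_a`, `n_overlap`, `pct_of_a`).
#' @export
panel_overlap <- function(...) {
  panels <- list(...)
  check_that(length(panels) %in% 2:3, "supply 2 or 3 panels")
  if (is.null(names(panels)) || any(names(panels) == "")) {
    names(panels) <- paste0("panel", seq_along(panels))
  }
  keysets <- lapply(panels, function(p) {
    e <- panel_entries(p)
    k <- paste0(e$chrom, ":", e$pos)
    if (anyDuplicated(k)) {
      warn("duplicate positions within a panel; deduplicating")
      k <- unique(k)
    }
    k
  })
  univ <- unique(unlist(keysets))
  memb <- vapply(keysets, function(k) univ %in% k, logical(length(univ)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(r) {
    paste(names(keysets)[r], collapse = "&")
  })
  regions <- tibble(region = pattern) |>
    dplyr::count(.data$region, name = "n") |>
    arrange(dplyr::desc(.data$n))
  pairs <- combn(names(keysets), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    n_ov <- length(intersect(keysets[[a]], keysets[[b]]))
    tibble(panel_a = a, panel_b = b,
           n_a = length(keysets[[a]]), n_overlap = n_ov,
           pct_of_a = round_half_up(100 * n_ov / length(keysets[[a]]), 0))
  })
  structure(list(regions = regions, pairwise = pairwise),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary>\nVenn regions:\n")
  print(x$regions)
  cat("pairwise:\n")
  print(x$pairwise)
  invisible(x)
}

#' @method tidy overlap_summary
#' @export
tidy.overlap_summary <- function(x, ...) x$regions
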