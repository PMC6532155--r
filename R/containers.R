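#' Pooled allele-frequency table
#'
#' Per-breed alternate-allele frequencies estimated from pooled sequencing.
#'
#' @param loci Tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`
#'   and optionally `is_indel` (logical, defaults to `FALSE`).
#' @param freq Numeric matrix, loci in rows and breeds in columns, of
#'   alternate-allele frequencies in \[0, 1\] (`NA` for missing).
#' @param pool_size Named integer vector: diploid individuals per breed pool.
#'
#' @return A list of class `pool_freq_table` with elements `loci`, `freq`
#'   and `pool_size`.
#' @export
pool_freq_table <- function(loci, freq, pool_size) {
  loci <- as_tibble(loci)
  if (!"is_indel" %in% names(loci)) loci$is_indel <- FALSE
  if (!"snp_id" %in% names(loci)) {
    loci$snp_id <- paste0(loci$chrom, ":", loci$pos)
  }
  freq <- as.matrix(freq)
  check_that(nrow(freq) == nrow(loci),
             "`freq` must have one row per locus (%d != %d)",
             nrow(freq), nrow(loci))
  check_that(!is.null(colnames(freq)), "`freq` must have breed column names")
  rng <- range(freq, na.rm = TRUE)
  check_that(rng[1] >= 0 && rng[2] <= 1, "frequencies must lie in [0, 1]")
  check_that(all(colnames(freq) %in% names(pool_size)),
             "`pool_size` must name every breed")
  structure(list(loci = loci, freq = freq,
                 pool_size = pool_size[colnames(freq)]),
            class = "pool_freq_table")
}

#' @export
print.pool_freq_table <- function(x, ...) {
  cat(sprintf("<pool_freq_table> %d loci x %d breeds\n",
              nrow(x$freq), ncol(x$freq)))
  cat("breeds:", paste(colnames(x$freq), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pool_freq_table Long-format view: one row per (locus, breed).
#' @param x A `pool_freq_table`.
#' @param ... Unused.
#' @export
as_tibble.pool_freq_table <- function(x, ...) {
  long <- as_tibble(x$freq)
  long$snp_id <- x$loci$snp_id
  long <- tidyr::pivot_longer(long, -"snp_id",
                              names_to = "breed", values_to = "freq")
  left_join(x$loci, long, by = "snp_id")
}

#' Genotype matrix
#'
#' Diploid genotypes coded as alternate-allele dosages 0/1/2 with `NA` for
#' missing calls. Samples are rows, loci columns.
#'
#' @param geno Integer matrix samples x loci with values in
#'   `c(0, 1, 2, NA)`; row names are sample ids, column names marker ids.
#' @param samples Tibble with columns `sample_id` and `population`
#'   (population may be `NA`). Defaults to the matrix row names.
#' @param loci Tibble describing the markers (`snp_id`, `chrom`, `pos`,
#'   optionally `ref`, `alt`). Defaults to the matrix column names.
#'
#' @return A list of class `geno_matrix` with elements `geno`, `samples`,
#'   `loci`.
#' @export
geno_matrix <- function(geno, samples = NULL, loci = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !(geno %in% 0:2)
  check_that(!any(bad), "genotypes must be 0, 1, 2 or NA")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("S", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- paste0("M", seq_len(ncol(geno)))
  if (is.null(samples)) {
    samples <- tibble(sample_id = rownames(geno), population = NA_character_)
  }
  samples <- as_tibble(samples)
  if (!"population" %in% names(samples)) samples$population <- NA_character_
  check_that(nrow(samples) == nrow(geno) &&
               all(samples$sample_id == rownames(geno)),
             "`samples` must match the matrix rows")
  if (is.null(loci)) {
    loci <- tibble(snp_id = colnames(geno),
                   chrom = NA_character_, pos = NA_real_)
  }
  loci <- as_tibble(loci)
  check_that(nrow(loci) == ncol(geno), "`loci` must match the matrix columns")
  structure(list(geno = geno, samples = samples, loci = loci),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d loci (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  pops <- unique(x$samples$population)
  if (!all(is.na(pops))) {
    cat("populations:", paste(stats::na.omit(pops), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn geno_matrix Long-format view: one row per (sample, locus).
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(sample_id = rep(rownames(x$geno), times = ncol(x$geno)),
         snp_id = rep(colnames(x$geno), each = nrow(x$geno)),
         dosage = as.integer(x$geno)) |>
    left_join(x$samples, by = "sample_id")
}

#' Assign population labels to samples
#'
#' @param gm A [geno_matrix()].
#' @param population Character vector, one label per sample, or a named
#'   vector keyed by sample id.
#' @return The modified `geno_matrix`.
#' @export
set_populations <- function(gm, population) {
  check_that(inherits(gm, "geno_matrix"), "`gm` must be a geno_matrix")
  if (!is.null(names(population))) {
    population <- unname(population[gm$samples$sample_id])
  }
  check_that(length(population) == nrow(gm$samples),
             "one population label per sample required")
  gm$samples$population <- as.character(population)
  gm
}
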