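CANDIDATE_GROUPS <- c("resequencing", "gwas", "candidate_gene", "rfi", "snpdb")
PRIORITY_LEVELS <- c("P1", "P2", "BACKGROUND")

# priority implied by source group; whitelisted indels in the resequencing
# group are promoted to P1 by the selector, not here
group_priority <- function(group, is_indel = FALSE) {
  dplyr::case_when(
    group == "snpdb" ~ "BACKGROUND",
    group == "resequencing" & !is_indel ~ "P2",
    .default = "P1"
  )
}

# validate a candidate tibble; `rows` are original file rows for messages
validate_candidates <- function(x, genome, rows = seq_len(nrow(x))) {
  need <- c("chrom", "pos", "ref", "alt", "group", "validated", "is_indel")
  miss <- setdiff(need, names(x))
  check_that(length(miss) == 0, "missing column(s): %s",
             paste(miss, collapse = ", "))
  bad_chrom <- !x$chrom %in% genome$chrom
  if (any(bad_chrom)) {
    abort(sprintf("row %d: chromosome '%s' not in genome layout",
                  rows[which(bad_chrom)[1]], x$chrom[which(bad_chrom)[1]]))
  }
  len <- setNames(genome$length, genome$chrom)
  bad_pos <- is.na(x$pos) | x$pos < 1 | x$pos > len[x$chrom]
  if (any(bad_pos)) {
    abort(sprintf(paste0("row %d: position %s outside [1, chromosome ",
                         "length] (positions are 1-based)"),
                  rows[which(bad_pos)[1]], x$pos[which(bad_pos)[1]]))
  }
  bad_allele <- !x$is_indel & (x$ref == x$alt)
  if (any(bad_allele)) {
    abort(sprintf("row %d: ref and alt alleles are identical",
                  rows[which(bad_allele)[1]]))
  }
  bad_group <- !x$group %in% CANDIDATE_GROUPS
  if (any(bad_group)) {
    abort(sprintf("row %d: unknown group '%s'",
                  rows[which(bad_group)[1]], x$group[which(bad_group)[1]]))
  }
  invisible(TRUE)
}

#' Read a candidate SNP table
#'
#' Reads a TSV of candidate markers with header columns `chrom`, `pos`,
#' `ref`, `alt`, `group`, `validated`, `is_indel` and optionally `snp_id`,
#' `score`, `priority`. Positions are 1-based. Rows violating the record
#' invariants are rejected with the offending line.
#'
#' @param path Path to a TSV file.
#' @param genome A [genome_layout()]; chromosomes must be known to it.
#'
#' @return A candidate tibble: `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `group`, `priority`, `validated`, `is_indel`, `score`.
#' @export
read_candidate_table <- function(path, genome) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         ref = readr::col_character(),
                         alt = readr::col_character(),
                         .default = readr::col_guess()))
  x <- as_tibble(x)
  validate_candidates(x, genome, rows = seq_len(nrow(x)) + 1L)
  if (!"snp_id" %in% names(x)) x$snp_id <- paste0(x$chrom, ":", x$pos)
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"priority" %in% names(x)) {
    x$priority <- group_priority(x$group, x$is_indel)
  }
  check_that(all(x$priority %in% PRIORITY_LEVELS), "invalid priority value")
  check_that(all((x$group == "snpdb") == (x$priority == "BACKGROUND")),
             "snpdb group and BACKGROUND priority must coincide")
  select(x, "snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
         "validated", "is_indel", "score")
}

#' Write a candidate SNP table
#'
#' Inverse of [read_candidate_table()]; the written file round-trips.
#'
#' @param candidates Candidate tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidate_table <- function(candidates, path) {
  cols <- c("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
            "validated", "is_indel", "score")
  readr::write_tsv(select(candidates, dplyr::all_of(cols)), path)
  invisible(path)
}

#' Write a panel manifest
#'
#' Emits a deterministic TSV with columns `snp_id`, `chrom`, `pos`, `ref`,
#' `alt`, `group`, `priority`, `pass`, `window_index`, sorted by
#' (chromosome order, position). Writing the same panel twice produces
#' byte-identical files.
#'
#' @param panel A [snp_panel] object (see [design_panel()]) or a tibble with
#'   the manifest columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel_manifest <- function(panel, path) {
  entries <- if (inherits(panel, "snp_panel")) panel$entries else as_tibble(panel)
  genome <- if (inherits(panel, "snp_panel")) panel$genome else NULL
  cols <- c("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
            "pass", "window_index")
  for (nm in setdiff(cols, names(entries))) entries[[nm]] <- NA
  entries <- entries |>
    mutate(.chrom_order = chrom_factor(.data$chrom, genome)) |>
    arrange(.data$.chrom_order, .data$pos) |>
    select(dplyr::all_of(cols))
  check_that(!anyDuplicated(entries[c("chrom", "pos")]),
             "panel contains duplicate (chrom, pos) entries")
  readr::write_tsv(entries, path)
  invisible(path)
}

#' Read diploid genotypes
#'
#' @param path Input file.
#' @param dialect `"vcf"` for a VCF with diploid GT fields (unphased or
#'   phased), or `"dosage_tsv"` for a TSV with columns `snp_id`, `chrom`,
#'   `pos` followed by one dosage column per sample (0/1/2, `NA` or `.` for
#'   missing).
#'
#' @details VCF calls are mapped to alternate-allele dosage; half-missing
#'   calls (`./0`) become missing. Records whose GT is not diploid raise an
#'   error; multi-allelic splitting is out of scope.
#'
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("vcf", "dosage_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  check_that(!is.null(gt), "VCF has no GT field")
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, ":", fix$POS), fix$ID)
  alleles <- strsplit(gsub("\\|", "/", as.vector(gt)), "/", fixed = TRUE)
  n_allele <- lengths(alleles)
  called <- !is.na(as.vector(gt))
  if (any(called & n_allele != 2)) {
    abort("unsupported record: GT ploidy is not 2")
  }
  dose <- vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".") || any(is.na(a))) return(NA_integer_)
    sum(as.integer(a) > 0L)
  }, integer(1))
  geno <- matrix(dose, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  geno <- t(geno)  # samples x loci
  colnames(geno) <- snp_id
  geno_matrix(geno,
              loci = tibble(snp_id = snp_id, chrom = fix$CHROM,
                            pos = as.numeric(fix$POS),
                            ref = fix$REF, alt = fix$ALT))
}

read_genotypes_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = c("NA", "."),
                       col_types = readr::cols(
                         snp_id = readr::col_character(),
                         chrom = readr::col_character(),
                         .default = readr::col_guess()))
  meta <- c("snp_id", "chrom", "pos")
  check_that(all(meta %in% names(x)),
             "dosage TSV needs columns snp_id, chrom, pos")
  samp <- setdiff(names(x), c(meta, "ref", "alt"))
  check_that(length(samp) >= 1, "dosage TSV has no sample columns")
  geno <- t(as.matrix(x[samp]))
  colnames(geno) <- x$snp_id
  rownames(geno) <- samp
  geno_matrix(geno, loci = x[intersect(c(meta, "ref", "alt"), names(x))])
}

#' Export a panel as BED
#'
#' BED is 0-based half-open: a marker at 1-based position `p` becomes the
#' interval `[p - 1, p)`. This is the only 0-based surface of the package.
#'
#' @param panel A [snp_panel] or manifest tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_bed <- function(panel, path) {
  entries <- if (inherits(panel, "snp_panel")) panel$entries else as_tibble(panel)
  genome <- if (inherits(panel, "snp_panel")) panel$genome else NULL
  bed <- entries |>
    mutate(.chrom_order = chrom_factor(.data$chrom, genome)) |>
    arrange(.data$.chrom_order, .data$pos) |>
    mutate(start = .data$pos - 1, end = .data$pos) |>
    select("chrom", "start", "end", "snp_id")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
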