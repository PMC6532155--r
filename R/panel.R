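#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %d markers on %d chromosome(s), %d windows\n",
              nrow(x$entries), nrow(x$genome), nrow(x$windows)))
  byp <- dplyr::count(x$entries, .data$pass)
  for (k in seq_len(nrow(byp))) {
    cat(sprintf("  %-10s %6d\n", byp$pass[k], byp$n[k]))
  }
  empty <- sum(x$windows$state == "EMPTY")
  cat(sprintf("  empty windows: %d of %d\n", empty, nrow(x$windows)))
  invisible(x)
}

#' Tidy a designed panel
#'
#' @param x A `snp_panel`.
#' @param ... Unused.
#' @return The manifest tibble, one row per selected marker.
#' @method tidy snp_panel
#' @export
tidy.snp_panel <- function(x, ...) x$entries

#' One-row summary of a designed panel
#'
#' @param x A `snp_panel`.
#' @param ... Unused.
#' @return A tibble with marker totals, per-pass counts, window occupancy
#'   and the largest same-chromosome gap between adjacent markers.
#' @method glance snp_panel
#' @export
glance.snp_panel <- function(x, ...) {
  gaps <- x$entries |>
    group_by(.data$chrom) |>
    summarise(g = if (dplyr::n() >= 2) max(diff(sort(.data$pos))) else NA_real_,
              .groups = "drop")
  tibble(
    n_snps = nrow(x$entries),
    n_priority1 = sum(x$entries$pass == "priority1"),
    n_priority2 = sum(x$entries$pass == "priority2"),
    n_background = sum(x$entries$pass == "background"),
    n_windows = nrow(x$windows),
    n_empty_windows = sum(x$windows$state == "EMPTY"),
    max_gap_bp = if (all(is.na(gaps$g))) NA_real_ else max(gaps$g, na.rm = TRUE)
  )
}

#' @export
as_tibble.snp_panel <- function(x, ...) x$entries

#' Plot marker counts per chromosome for a panel
#'
#' @param object A `snp_panel`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot snp_panel
#' @export
autoplot.snp_panel <- function(object, ...) {
  d <- object$entries |>
    mutate(chrom = chrom_factor(.data$chrom, object$genome)) |>
    dplyr::count(.data$chrom, .data$pass)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chrom, y = .data$n,
                                  fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chromosome", y = "markers selected", fill = "pass") +
    ggplot2::theme_minimal()
}
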