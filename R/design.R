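#' Positional variance criterion for marker placement in a window
#'
#' The placement score of one or two chosen positions inside a window is
#' the population variance of the point set consisting of the window start
#' `S`, the chosen position(s), and the window end `E`:
#' \deqn{SD^2 = \sum_{p \in \{S, N_i, N_j, E\}} (p - \bar x)^2 / 4}
#' (divisor 3 when a single position is chosen). Smaller values are
#' considered more evenly placed; note the criterion favours positions
#' near the window midpoint.
#'
#' @param window_start,window_end Window bounds in bp.
#' @param chosen Numeric vector of 1 or 2 chosen positions inside the
#'   window.
#' @return The score in bp^2.
#' @examples
#' sd2(0, 22000, c(5500, 16500))
#' @export
sd2 <- function(window_start, window_end, chosen) {
  check_that(length(chosen) >= 1, "`chosen` must contain 1 or 2 positions")
  check_that(all(chosen >= window_start & chosen <= window_end),
             "chosen positions must lie within the window")
  pts <- c(window_start, chosen, window_end)
  m <- mean(pts)
  sum((pts - m)^2) / length(pts)
}

#' Best marker pair in a window
#'
#' Exhaustively minimises [sd2()] over all candidate pairs; ties are broken
#' by the lexicographically smallest position pair.
#'
#' @param window_start,window_end Window bounds.
#' @param candidates Numeric vector of at least 3 candidate positions
#'   inside the window.
#' @return Sorted numeric vector of length 2.
#' @export
best_pair <- function(window_start, window_end, candidates) {
  check_that(length(candidates) >= 3,
             "need >= 3 candidates; use direct retention for 1 or 2")
  cand <- sort(candidates)
  pr <- combn(cand, 2)          # columns in lexicographic order
  s <- window_start + window_end
  m <- (s + pr[1, ] + pr[2, ]) / 4
  vals <- ((window_start - m)^2 + (pr[1, ] - m)^2 +
             (pr[2, ] - m)^2 + (window_end - m)^2) / 4
  pr[, which.min(vals)]
}

#' Best single marker in a window
#'
#' Minimises [sd2()] with one chosen point, which is equivalent to taking
#' the candidate nearest the window midpoint; ties are broken by the lower
#' position.
#'
#' @inheritParams best_pair
#' @param candidates Numeric vector of at least 1 candidate position.
#' @return A single position.
#' @export
best_single <- function(window_start, window_end, candidates) {
  check_that(length(candidates) >= 1, "no candidate in window")
  cand <- sort(candidates)
  m <- (window_start + cand + window_end) / 3
  vals <- ((window_start - m)^2 + (cand - m)^2 + (window_end - m)^2) / 3
  cand[which.min(vals)]
}

# Walk one chromosome left to right in windows of `window_length`,
# applying the retention rules to priority-1 candidates:
#   0 in window  -> window reserved empty, next window starts at its end
#   1-2          -> all retained
#   >= 3         -> the sd2-minimising pair retained
# After any retention the next window starts at the rightmost retained
# position; forced candidates (special-interest indels) are always
# retained and count toward occupancy. All candidates falling in a
# processed window are consumed whether retained or not.
priority1_pass <- function(positions, chrom_length, window_length,
                           forced = logical(length(positions))) {
  ord <- order(positions)
  positions <- positions[ord]
  forced <- forced[ord]
  sel_pos <- numeric(0)
  sel_win <- integer(0)
  win <- list()
  i <- 1L          # pointer into sorted candidates
  start <- 1
  idx <- 0L
  n <- length(positions)
  while (start <= chrom_length) {
    idx <- idx + 1L
    end <- min(start + window_length, chrom_length + 1)
    while (i <= n && positions[i] < start) i <- i + 1L
    j <- i
    while (j <= n && positions[j] < end) j <- j + 1L
    in_pos <- if (j > i) positions[i:(j - 1L)] else numeric(0)
    in_forced <- if (j > i) forced[i:(j - 1L)] else logical(0)
    chosen <- in_pos[in_forced]
    free <- in_pos[!in_forced]
    slots <- max(0L, 2L - length(chosen))
    if (length(free) > 0 && slots > 0) {
      if (length(free) <= slots) {
        chosen <- c(chosen, free)
      } else if (slots == 2L) {
        chosen <- c(chosen, best_pair(start, end, free))
      } else {
        chosen <- c(chosen, best_single(start, end, free))
      }
    }
    chosen <- sort(chosen)
    win[[idx]] <- c(index = idx, start = start, end = end,
                    n_p1 = length(chosen))
    if (length(chosen) > 0) {
      sel_pos <- c(sel_pos, chosen)
      sel_win <- c(sel_win, rep(idx, length(chosen)))
      start <- if (max(chosen) > start) max(chosen) else end
    } else {
      start <- end
    }
    i <- j
  }
  windows <- as_tibble(do.call(rbind, win))
  if (nrow(windows) == 0) {
    windows <- tibble(index = integer(), start = numeric(),
                      end = numeric(), n_p1 = numeric())
  }
  list(selections = tibble(pos = sel_pos, window_index = sel_win,
                           pass = rep("priority1", length(sel_pos))),
       windows = windows)
}

# Fill still-empty windows with the best single priority-2 candidate in
# each; windows that retained anything in the first pass are skipped.
priority2_pass <- function(windows, filled_windows, positions) {
  positions <- sort(positions)
  used <- logical(length(positions))
  sel_pos <- numeric(0)
  sel_win <- integer(0)
  for (k in seq_len(nrow(windows))) {
    if (windows$index[k] %in% filled_windows) next
    inside <- which(!used & positions >= windows$start[k] &
                      positions < windows$end[k])
    if (length(inside) == 0) next
    pick <- best_single(windows$start[k], windows$end[k], positions[inside])
    pick_i <- inside[which(positions[inside] == pick)[1]]
    used[pick_i] <- TRUE
    sel_pos <- c(sel_pos, pick)
    sel_win <- c(sel_win, windows$index[k])
  }
  tibble(pos = sel_pos, window_index = sel_win,
         pass = rep("priority2", length(sel_pos)))
}

# Fill windows still empty after both passes with one database marker
# each; assay-validated markers take precedence, then proximity to the
# window midpoint, then the lower position.
background_pass <- function(windows, filled_windows, positions, validated) {
  ord <- order(positions)
  positions <- positions[ord]
  validated <- validated[ord]
  used <- logical(length(positions))
  sel_pos <- numeric(0)
  sel_win <- integer(0)
  for (k in seq_len(nrow(windows))) {
    if (windows$index[k] %in% filled_windows) next
    inside <- which(!used & positions >= windows$start[k] &
                      positions < windows$end[k])
    if (length(inside) == 0) next
    mid <- (windows$start[k] + windows$end[k]) / 2
    o <- order(!validated[inside], abs(positions[inside] - mid),
               positions[inside])
    pick_i <- inside[o[1]]
    used[pick_i] <- TRUE
    sel_pos <- c(sel_pos, positions[pick_i])
    sel_win <- c(sel_win, windows$index[k])
  }
  tibble(pos = sel_pos, window_index = sel_win,
         pass = rep("background", length(sel_pos)))
}

#' Design a marker panel by windowed even placement
#'
#' Runs the three selection passes on every chromosome of `genome`:
#'
#' 1. **Priority 1** (trait-linked candidates and whitelisted indels):
#'    chromosomes are walked in windows of `config$window_length` bp;
#'    windows with one or two candidates retain them all, windows with
#'    three or more retain the pair minimising the positional variance
#'    criterion [sd2()]. After a retaining window, the next window starts
#'    at the rightmost retained position; after an empty window, at the
#'    window end. Forced indels are always retained.
#' 2. **Priority 2** (breed-differential resequencing candidates): each
#'    still-empty window receives its [best_single()] candidate.
#' 3. **Background** (database markers): each remaining empty window
#'    receives one marker, assay-validated markers first, then nearest the
#'    window midpoint.
#'
#' @param genome A [genome_layout()].
#' @param candidates A candidate tibble as produced by
#'   [assemble_candidates()] (unique positions; columns `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `group`, `priority`, `validated`, `is_indel`).
#' @param config A [design_config()].
#'
#' @return An object of class `snp_panel`: a list with `entries` (the
#'   manifest tibble, sorted by chromosome and position), `windows` (the
#'   window ledger with per-pass occupancy), `genome` and `config`.
#' @export
design_panel <- function(genome, candidates, config = design_config()) {
  candidates <- as_tibble(candidates)
  check_that(!anyDuplicated(candidates[c("chrom", "pos")]),
             "candidates must be unique by (chrom, pos); run assemble_candidates()")
  check_that(all(candidates$chrom %in% genome$chrom),
             "candidate chromosome absent from genome layout")
  entries <- list()
  ledgers <- list()
  for (ci in seq_len(nrow(genome))) {
    cn <- genome$chrom[ci]
    len <- genome$length[ci]
    cc <- filter(candidates, .data$chrom == cn)
    p1 <- filter(cc, .data$priority == "P1")
    p2 <- filter(cc, .data$priority == "P2")
    bg <- filter(cc, .data$priority == "BACKGROUND")
    r1 <- priority1_pass(p1$pos, len, config$window_length,
                         forced = p1$is_indel)
    filled <- unique(r1$selections$window_index)
    r2 <- priority2_pass(r1$windows, filled, p2$pos)
    filled2 <- c(filled, r2$window_index)
    r3 <- background_pass(r1$windows, filled2, bg$pos, bg$validated)
    sel <- bind_rows(r1$selections, r2, r3)
    if (nrow(sel) > 0) {
      sel <- left_join(sel, cc, by = "pos") |>
        mutate(chrom = cn)
      entries[[length(entries) + 1L]] <- sel
    }
    led <- r1$windows |>
      mutate(chrom = cn,
             n_p2 = as.numeric(.data$index %in% r2$window_index),
             n_bg = as.numeric(.data$index %in% r3$window_index),
             n_total = .data$n_p1 + .data$n_p2 + .data$n_bg,
             state = dplyr::case_when(
               .data$n_total == 0 ~ "EMPTY",
               .data$n_total == 1 ~ "FILLED_1",
               .default = "FILLED_2"),
             filled_by = dplyr::case_when(
               .data$n_p1 > 0 ~ "priority1",
               .data$n_p2 > 0 ~ "priority2",
               .data$n_bg > 0 ~ "background",
               .default = NA_character_)) |>
      select("chrom", "index", "start", "end", "n_p1", "n_p2", "n_bg",
             "n_total", "state", "filled_by")
    ledgers[[length(ledgers) + 1L]] <- led
  }
  entries <- bind_rows(entries)
  if (nrow(entries) == 0) {
    entries <- tibble(snp_id = character(), chrom = character(),
                      pos = numeric(), ref = character(), alt = character(),
                      group = character(), priority = character(),
                      pass = character(), window_index = integer())
  } else {
    entries <- entries |>
      mutate(.chrom_order = chrom_factor(.data$chrom, genome)) |>
      arrange(.data$.chrom_order, .data$pos) |>
      select("snp_id", "chrom", "pos", "ref", "alt", "group", "priority",
             "pass", "window_index")
  }
  structure(list(entries = entries,
                 windows = bind_rows(ledgers),
                 genome = genome,
                 config = config),
            class = "snp_panel")
}
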